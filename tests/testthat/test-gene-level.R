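# gene_level: ranking, net change, enrichment (vs brute-force oracle),
# hypergeometric overlap (vs enumeration oracle), composition rule.

diff_fixture <- function(genes, deltas) {
  data.table::data.table(chrom = "chr1", start = seq_along(deltas), strand = "+",
                         gene_id = genes, delta = deltas)
}

test_that("gene_average_delta ranks by mean delta with deterministic ties", {
  d <- diff_fixture(c("GB", "GB", "GA", "GC"), c(0.30, 0.10, 0.20, -0.10))
  r <- gene_average_delta(d)
  expect_equal(r$gene_id, c("GA", "GB", "GC"))  # 0.2 ties broken lexicographically
  expect_equal(r[gene_id == "GB", avg_delta], 0.20)
  expect_equal(r[gene_id == "GB", n_sites], 2L)
  expect_equal(r[gene_id == "GC", n_sites], 1L)
  expect_equal(r[gene_id == "GC", avg_delta], -0.10)
})

test_that("net_m6a_change counts strict sign crossings and is antisymmetric", {
  expect_equal(net_m6a_change(c(0.05, 0.03, -0.02)), 1L)
  expect_equal(net_m6a_change(c(0, 0, 0)), 0L)
  expect_equal(net_m6a_change(c(-0.3, -0.1)), -2L)
  expect_equal(net_m6a_change(c(0.05, 0.03, -0.02), min_abs = 0.04), 1L)
  set.seed(31)
  for (i in 1:20) {
    x <- round(rnorm(20, 0, 0.2), 3)
    expect_equal(net_m6a_change(-x), -net_m6a_change(x))
  }
})

# Independent oracle: literal walk down the ranking, one step at a time,
# tracking the extremes (ties in deviation resolve to the positive extremum).
es_brute <- function(scores, set, w = 1) {
  ord <- order(-scores, names(scores))
  scores <- scores[ord]
  hit <- names(scores) %in% set
  nh <- sum(hit); n <- length(scores)
  wh <- sum(abs(scores[hit])^w)
  rs <- 0; up <- -Inf; dn <- Inf
  for (i in seq_len(n)) {
    if (hit[i]) rs <- rs + (if (wh > 0) abs(scores[i])^w / wh else 1 / nh)
    else rs <- rs - 1 / (n - nh)
    if (rs > up) up <- rs
    if (rs < dn) dn <- rs
  }
  as.numeric(if (up > -dn - 1e-12) up else dn)
}

test_that("preranked_enrichment matches the brute-force running-sum oracle", {
  scores <- setNames(seq(1.0, 0.1, by = -0.1), paste0("g", 1:10))
  r <- preranked_enrichment(scores, c("g1", "g2", "g3"), weight_exponent = 1,
                            n_perm = 100, seed = 3)
  expect_equal(r$es, es_brute(scores, c("g1", "g2", "g3")))
  # extreme case: all members at the top with weight 0 -> ES = +1
  r0 <- preranked_enrichment(scores, c("g1", "g2", "g3"), weight_exponent = 0,
                             n_perm = 100, seed = 3)
  expect_equal(r0$es, 1)
  # random lists
  set.seed(13)
  for (i in 1:25) {
    n <- sample(5:20, 1)
    sc <- setNames(round(rnorm(n), 3), paste0("x", seq_len(n)))
    st <- sample(names(sc), sample(1:(n - 1), 1))
    w <- sample(c(0, 1, 2), 1)
    got <- preranked_enrichment(sc, st, weight_exponent = w, n_perm = 100, seed = i)
    expect_equal(got$es, es_brute(sc, st, w), tolerance = 1e-12)
  }
})

test_that("enrichment permutation p is seeded, bounded and guarded", {
  scores <- setNames(seq(2, 0.1, length.out = 15), paste0("g", 1:15))
  set <- c("g1", "g2", "g14")
  r1 <- preranked_enrichment(scores, set, n_perm = 500, seed = 99)
  r2 <- preranked_enrichment(scores, set, n_perm = 500, seed = 99)
  expect_identical(r1$p_perm, r2$p_perm)  # bit-for-bit reproducible
  expect_identical(r1$es, r2$es)
  expect_gte(r1$p_perm, 1 / 501)
  expect_lte(r1$p_perm, 1)
  expect_error(preranked_enrichment(scores, "absent", n_perm = 100, seed = 1),
               class = "m6aland_validation_error")
  expect_error(preranked_enrichment(scores, names(scores), n_perm = 100, seed = 1),
               class = "m6aland_validation_error")
  expect_error(preranked_enrichment(scores, set, n_perm = 10, seed = 1),
               class = "m6aland_validation_error")
})

test_that("enrichment_batch attaches BH q-values across sets", {
  scores <- setNames(seq(2, -2, length.out = 40), paste0("g", 1:40))
  sets <- list(top = paste0("g", 1:5), bottom = paste0("g", 36:40),
               random = paste0("g", c(3, 17, 29)))
  out <- enrichment_batch(scores, sets, n_perm = 200, seed = 5)
  expect_equal(nrow(out), 3L)
  expect_equal(out$q_value, p.adjust(out$p_perm, "BH"))
  expect_gt(out[gene_set_id == "top", es], 0)
  expect_lt(out[gene_set_id == "bottom", es], 0)
})

test_that("hypergeometric_overlap matches exhaustive enumeration", {
  # worked example: |U|=10, |A|=5, |B|=4, k=4 -> C(5,4)C(5,0)/C(10,4) = 5/210
  u <- paste0("u", 1:10)
  res <- hypergeometric_overlap(u[1:5], u[c(1:4)], u)
  expect_equal(res$k, 4L)
  expect_equal(res$p_value, 5 / 210, tolerance = 1e-12)
  expect_equal(res$expected, 5 * 4 / 10)
  # boundaries
  expect_equal(hypergeometric_overlap(u[1:3], u[4:6], u)$p_value, 1)  # k = 0
  expect_equal(hypergeometric_overlap(u[1:3], u, u)$p_value, 1)       # B = universe
  expect_error(hypergeometric_overlap("a", "b", character(0)),
               class = "m6aland_validation_error")
  # enumeration oracle on a few configurations (full sweep in acceptance)
  for (cfg in list(c(8, 3, 4), c(9, 5, 5), c(7, 2, 6))) {
    n_u <- cfg[1]; n_a <- cfg[2]; n_b <- cfg[3]
    uni <- paste0("z", seq_len(n_u))
    draws <- utils::combn(n_u, n_b)
    kv <- colSums(draws <= n_a)
    for (k in 0:min(n_a, n_b)) {
      if (n_b - k > n_u - n_a) next
      bset <- c(uni[seq_len(k)], uni[n_a + seq_len(n_b - k)])
      got <- hypergeometric_overlap(uni[seq_len(n_a)], bset, uni)
      expect_equal(got$p_value, mean(kv >= k), tolerance = 1e-12)
    }
  }
  # monotonicity: larger overlap at fixed margins never increases p
  ps <- vapply(0:4, function(k) {
    bset <- c(u[seq_len(k)], u[5 + seq_len(4 - k)])
    hypergeometric_overlap(u[1:5], bset, u)$p_value
  }, numeric(1))
  expect_true(all(diff(ps) <= 1e-15))
})

test_that("top_net_gain_de_composition applies filter, ranking and tie rules", {
  rec <- data.table::data.table(
    gene_id = c("g1", "g2", "g3", "g4", "g5", "g6"),
    n_sites = 2L, avg_delta = c(0.3, 0.1, 0.2, 0.05, 0.0, 0.4),
    net_change = c(3L, 2L, 2L, 1L, 0L, 5L))
  de <- data.table::data.table(
    gene_id = c("g1", "g2", "g3", "g4", "g5"),
    log2fc = c(-2, -1, 1.5, -0.5, 2), fdr = c(1e-4, 1e-3, 1e-3, 0.5, 1e-5),
    cell_line = "L")
  # g6 missing from the DE table; g4 fails fdr < 0.01
  res <- suppressWarnings(top_net_gain_de_composition(rec, de, top_n = 3))
  expect_equal(res$n_missing_de, 1L)
  expect_equal(res$top$gene_id, c("g1", "g3", "g2"))  # tie at net 2 broken by avg_delta
  expect_equal(res$n_down, 2L)
  expect_equal(res$n_up, 1L)
  expect_warning(top_net_gain_de_composition(rec, de, top_n = 10), "eligible")
  res2 <- suppressWarnings(top_net_gain_de_composition(rec, de, top_n = 10))
  expect_true(res2$short)
  expect_equal(res2$n_down + res2$n_up, 4L)  # g5 up, g1/g2 down, g3 up
})

test_that("GMT round trip", {
  sets <- list(alpha = c("g1", "g2"), beta = c("g3", "g4", "g5"))
  f <- tempfile(fileext = ".gmt")
  write_gmt(sets, f)
  expect_equal(read_gmt(f), sets)
  fbad <- tempfile(); writeLines("onlyone\tdesc", fbad)
  expect_error(read_gmt(fbad), class = "m6aland_data_error")
})
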