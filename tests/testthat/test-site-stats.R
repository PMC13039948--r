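# site_stats: aggregation, filtering, calling, differential counts, isoform
# classes, restoration.

test_that("aggregate_condition computes mean, aggregated coverage and level", {
  r <- rbind(
    site_records(start = 100L, valid_cov = 20L, n_mod = 8L, sample_id = "r1"),
    site_records(start = 100L, valid_cov = 20L, n_mod = 12L, sample_id = "r2"),
    site_records(start = 200L, valid_cov = 10L, n_mod = 5L, sample_id = "r1"),
    site_records(start = 200L, valid_cov = 0L, n_mod = 0L, sample_id = "r2"),
    site_records(start = 300L, valid_cov = 30L, n_mod = 9L, sample_id = "r1"),
    site_records(start = 300L, valid_cov = 10L, n_mod = 3L, sample_id = "r2"),
    site_records(start = 400L, valid_cov = 15L, n_mod = 3L, sample_id = "r1"))
  s <- aggregate_condition(r)
  g <- function(st) s[s$start == st]
  expect_equal(g(100L)$mean_level, 0.5)
  expect_equal(g(100L)$agg_cov, 40L)
  expect_equal(g(100L)$agg_level, 0.5)
  # zero-coverage replicate excluded from the mean, not counted as zero
  expect_equal(g(200L)$mean_level, 0.5)
  expect_equal(g(200L)$agg_cov, 10L)
  # unweighted mean of fractions vs pooled level
  expect_equal(g(300L)$mean_level, 0.3)
  expect_equal(g(300L)$agg_level, 12 / 40)
  # site absent from a replicate contributes nothing
  expect_equal(g(400L)$n_replicates, 1L)
  expect_error(aggregate_condition(rbind(r, site_records(start = 1L, valid_cov = 1L,
                                                         n_mod = 0L, condition = "other"))),
               class = "m6aland_validation_error")
})

make_summary <- function(start, cov, lvl, condition = "a") {
  data.table::data.table(chrom = "chr1", start = as.integer(start), strand = "+",
                         condition = condition, n_replicates = 2L,
                         mean_level = lvl, agg_cov = as.integer(cov),
                         agg_level = lvl)
}

test_that("filter_sites applies strict joint coverage/level thresholds", {
  a <- make_summary(c(1, 2, 3, 4), c(25, 25, 20, 25), c(0.05, 0.05, 0.5, 0.5))
  b <- make_summary(c(1, 2, 3, 5), c(25, 25, 40, 25), c(0.12, 0.05, 0.5, 0.5), "b")
  j <- filter_sites(a, b, min_agg_cov = 20L, min_level = 0.10)
  expect_equal(j$start, 1L)            # level passes in one condition only
  # site 2: level fails in both; site 3: cov 20 not > 20 (strict); site 4/5: one-sided
  expect_error(filter_sites(a, b, min_level = 1.5), class = "m6aland_validation_error")
})

test_that("call_m6a_sites uses strict thresholds on both axes", {
  s <- make_summary(c(1, 2, 3, 4), c(11, 100, 10, 50), c(0.51, 0.50, 0.90, 0.80))
  called <- call_m6a_sites(s)
  expect_equal(sort(called$start), c(1L, 4L))  # 0.50 excluded; cov 10 excluded
  # raw-record path: per-replicate levels
  r <- site_records(start = c(1, 2), valid_cov = c(20, 20), n_mod = c(11, 10))
  expect_equal(call_m6a_sites(r)$start, 1L)
})

test_that("differential_sites and threshold_counts match hand counts and nest", {
  a <- make_summary(1:3, 50, c(0.45, 0.35, 0.15))
  b <- make_summary(1:3, 50, c(0.20, 0.20, 0.20), "b")
  d <- differential_sites(filter_sites(a, b))
  expect_equal(d$delta, c(0.25, 0.15, -0.05))
  tc <- threshold_counts(d)
  expect_equal(tc$n_up_10, 2L)
  expect_equal(tc$n_up_20, 1L)
  expect_equal(tc$n_dn_10, 0L)
  # exact boundary excluded
  a2 <- make_summary(1, 50, 0.30); b2 <- make_summary(1, 50, 0.20, "b")
  tc2 <- threshold_counts(differential_sites(filter_sites(a2, b2)))
  expect_equal(tc2$n_up_10, 0L)
  # identity comparison: all zeros
  tc3 <- threshold_counts(differential_sites(filter_sites(a, data.table::copy(a))))
  expect_equal(tc3$n_up_10 + tc3$n_dn_10 + tc3$n_up_20 + tc3$n_dn_20, 0L)
})

test_that("threshold counts: nesting, antisymmetry and brute-force oracle", {
  set.seed(21)
  for (rep_i in 1:5) {
    n <- 50
    la <- runif(n); lb <- runif(n)
    a <- make_summary(1:n, 50, la)
    b <- make_summary(1:n, 50, lb, "b")
    d <- differential_sites(filter_sites(a, b))
    tc <- threshold_counts(d)
    expect_lte(tc$n_up_20, tc$n_up_10)
    expect_lte(tc$n_dn_20, tc$n_dn_10)
    # independent brute-force recount from the raw levels
    keep <- la > 0.1 | lb > 0.1
    deltas <- (la - lb)[keep]
    expect_equal(tc$n_up_10, sum(deltas > 0.10))
    expect_equal(tc$n_dn_20, sum(deltas < -0.20))
    # swapping condition labels negates deltas and swaps up/down counts
    tc_sw <- threshold_counts(differential_sites(filter_sites(b, a)))
    expect_equal(tc_sw$n_up_10, tc$n_dn_10)
    expect_equal(tc_sw$n_dn_10, tc$n_up_10)
    expect_equal(tc_sw$n_up_20, tc$n_dn_20)
  }
})

test_that("classify_isoforms bins modified-read fractions with a closed MEDIUM bin", {
  reads <- function(tid, n, nmod, called = 3L) {
    data.table::data.table(read_id = sprintf("%s_%d", tid, seq_len(n)), transcript_id = tid,
                           n_called_A = called, n_mod = nmod)
  }
  rr <- rbind(reads("HI", 20, rep(c(1L, 0L), c(16, 4))),     # 0.80 -> HIGH
              reads("MEDLO", 20, rep(c(2L, 0L), c(6, 14))),  # 0.30 -> MEDIUM (closed)
              reads("MEDHI", 20, rep(c(1L, 0L), c(14, 6))),  # 0.70 -> MEDIUM (closed)
              reads("LO", 15, rep(0L, 15)),                  # 0.00 -> LOW
              reads("TINY", 5, rep(1L, 5)),                  # below read minimum
              reads("EMPTY", 20, rep(0L, 20), called = 0L))  # uninformative reads
  res <- classify_isoforms(rr)
  cls <- setNames(res$profiles$class, res$profiles$transcript_id)
  expect_equal(cls[["HI"]], "HIGH")
  expect_equal(cls[["MEDLO"]], "MEDIUM")
  expect_equal(cls[["MEDHI"]], "MEDIUM")
  expect_equal(cls[["LO"]], "LOW")
  expect_false("TINY" %in% names(cls))
  expect_false("EMPTY" %in% names(cls))  # n_called_A = 0 reads excluded entirely
  expect_equal(res$n_unclassified, 1L)
  expect_equal(sum(res$proportions), 1)
})

test_that("restoration_analysis applies the strict >10% restoration rule", {
  hypo <- data.table::data.table(chrom = "chr1", start = 1:8, strand = "+",
                                 delta = rep(-0.2, 8))
  tr <- make_summary(1:8, 50, c(0.35, 0.28, rep(0.20, 5), 0.45), "treated")
  un <- make_summary(1:8, 50, rep(0.20, 8), "untreated")
  res <- restoration_analysis(hypo, tr, un)
  expect_equal(res$n_eligible, 8L)
  expect_equal(res$n_restored, 2L)   # +0.15 and +0.25; +0.08 is below threshold
  expect_equal(res$fraction, 0.25)
  expect_equal(sort(res$restored$start), c(1L, 8L))
  # sites failing the coverage filter drop out of the denominator
  un2 <- make_summary(1:8, c(rep(50, 4), rep(5, 4)), rep(0.20, 8), "untreated")
  expect_equal(restoration_analysis(hypo, tr, un2)$n_eligible, 4L)
  # empty eligible set is an error
  un3 <- make_summary(1:8, 5, rep(0.20, 8), "untreated")
  expect_error(restoration_analysis(hypo, tr, un3), class = "m6aland_data_error")
})
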