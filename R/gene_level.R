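# Gene-level statistics on differential sites: average-delta ranking, net
# m6A change, preranked enrichment with a gene-label permutation null,
# hypergeometric overlap tests, and the top-net-gain DE composition rule.

#' Per-gene average delta ranking
#'
#' One record per gene with at least one filtered differential site, ranked by
#' average delta descending; ties broken by gene id (lexicographic).
#'
#' @param diff_sites differential sites carrying a `gene_id` column
#'   ([differential_sites()] with annotation). Sites without a gene are
#'   excluded.
#' @param min_abs threshold passed to [net_m6a_change()] (default 0).
#' @return data.table `gene_id, n_sites, avg_delta, net_change`, ranked.
#' @export
gene_average_delta <- function(diff_sites, min_abs = 0) {
  d <- data.table::as.data.table(diff_sites)
  if (!"gene_id" %in% names(d))
    stop_validation("diff_sites must carry gene_id (annotate sites first)")
  d <- d[!is.na(gene_id)]
  out <- d[, list(n_sites = .N, avg_delta = mean(delta),
                  net_change = net_m6a_change(delta, min_abs = min_abs)),
           by = "gene_id"]
  data.table::setorder(out, -avg_delta, gene_id)
  out[]
}

#' Net m6A change of one gene
#'
#' Number of sites with delta strictly above `min_abs` minus the number
#' strictly below `-min_abs`. With the default `min_abs = 0`, any increase or
#' decrease counts; zeros count neither way.
#'
#' @param deltas numeric vector of per-site deltas.
#' @param min_abs magnitude a site must exceed to count (default 0).
#' @return integer net change.
#' @export
net_m6a_change <- function(deltas, min_abs = 0) {
  as.integer(sum(deltas > min_abs) - sum(deltas < -min_abs))
}

#' Preranked gene-set enrichment (weighted running-sum statistic)
#'
#' Genes are ordered by score descending (ties by gene id). Walking down the
#' ranking, set members increment the running sum by `|score|^weight_exponent`
#' normalized over set members, and non-members decrement it by `1/(N - Nh)`.
#' The enrichment score `es` is the maximum deviation from zero (signed;
#' a tie between the positive and negative extremum resolves positive). The
#' permutation null permutes gene labels (equivalently: redraws the set member
#' positions) with scores fixed;
#' `p_perm = (1 + #\{|es_perm| >= |es|\}) / (n_perm + 1)` and
#' `nes = es / mean(|es_perm| of the same sign as es)`.
#'
#' If every set member has score exactly zero under a positive weight
#' exponent, equal hit weights are used (degenerate-weight fallback).
#'
#' @param scores named numeric vector: ranking metric per gene (e.g. average
#'   delta).
#' @param gene_set character vector of gene ids.
#' @param weight_exponent hit-weight exponent (default 1).
#' @param n_perm number of label permutations (default 10000).
#' @param seed RNG seed for the permutation stream (required for
#'   reproducibility).
#' @return list of class `m6a_enrichment` with `es, nes, p_perm, n_perm,
#'   seed, n_hits, n_genes, leading_edge` (gene ids up to the extremum, in
#'   ranking order, for the `es` sign side).
#' @export
preranked_enrichment <- function(scores, gene_set, weight_exponent = 1,
                                 n_perm = 10000L, seed) {
  if (is.null(names(scores))) stop_validation("scores must be named by gene id")
  if (n_perm < 100) stop_validation("n_perm must be >= 100")
  ord <- order(-scores, names(scores))
  scores <- scores[ord]
  genes <- names(scores)
  n <- length(genes)
  hit <- genes %in% gene_set
  nh <- sum(hit)
  if (nh == 0) stop_validation("gene set has empty intersection with the ranked genes")
  if (nh == n) stop_validation("gene set covers the entire ranked universe (degenerate)")
  es_of <- function(hit_idx) {
    h <- logical(n); h[hit_idx] <- TRUE
    w <- abs(scores)^weight_exponent
    wh <- sum(w[h])
    inc <- if (wh > 0) w * h / wh else h / sum(h)
    dec <- (!h) / (n - sum(h))
    rs <- cumsum(inc - dec)
    up <- max(rs); dn <- min(rs)
    # ties in maximum deviation resolve to the positive extremum
    if (up > -dn - 1e-12) up else dn
  }
  es <- es_of(which(hit))
  set.seed(seed)
  es_perm <- vapply(seq_len(n_perm), function(i) es_of(sample.int(n, nh)), numeric(1))
  p_perm <- (1 + sum(abs(es_perm) >= abs(es))) / (n_perm + 1)
  same <- es_perm[sign(es_perm) == sign(es)]
  nes <- if (length(same)) es / mean(abs(same)) else NA_real_
  # leading edge: hits at or before the running-sum extremum (positive es)
  # or at/after it (negative es)
  w <- abs(scores)^weight_exponent
  wh <- sum(w[hit])
  inc <- if (wh > 0) w * hit / wh else hit / nh
  rs <- cumsum(inc - (!hit) / (n - nh))
  peak <- if (es >= 0) which.max(rs) else which.min(rs)
  le <- if (es >= 0) genes[seq_len(peak)][hit[seq_len(peak)]]
        else genes[peak:n][hit[peak:n]]
  structure(list(es = es, nes = nes, p_perm = p_perm, n_perm = as.integer(n_perm),
                 seed = as.integer(seed), n_hits = nh, n_genes = n,
                 leading_edge = le),
            class = "m6a_enrichment")
}

#' @export
print.m6a_enrichment <- function(x, ...) {
  cat(sprintf("<enrichment: ES %.3f, NES %.3f, p_perm %.4g (%d perms, seed %d), %d/%d genes in set>\n",
              x$es, x$nes, x$p_perm, x$n_perm, x$seed, x$n_hits, x$n_genes))
  invisible(x)
}

#' Enrichment over multiple gene sets with BH adjustment
#'
#' Runs [preranked_enrichment()] per set (sub-seeded deterministically from
#' `seed`) and adds Benjamini-Hochberg q-values across sets.
#'
#' @inheritParams preranked_enrichment
#' @param gene_sets named list of gene-id vectors (e.g. from [read_gmt()]).
#' @return data.table `gene_set_id, es, nes, p_perm, q_value, n_hits, seed`.
#' @export
enrichment_batch <- function(scores, gene_sets, weight_exponent = 1,
                             n_perm = 10000L, seed) {
  rows <- lapply(seq_along(gene_sets), function(i) {
    sub <- derive_seed(seed, "enrichment", i)
    r <- preranked_enrichment(scores, gene_sets[[i]], weight_exponent, n_perm, sub)
    data.table::data.table(gene_set_id = names(gene_sets)[i], es = r$es, nes = r$nes,
                           p_perm = r$p_perm, n_hits = r$n_hits, seed = sub)
  })
  out <- data.table::rbindlist(rows)
  out[, q_value := stats::p.adjust(p_perm, method = "BH")]
  data.table::setcolorder(out, c("gene_set_id", "es", "nes", "p_perm", "q_value",
                                 "n_hits", "seed"))
  out[]
}

#' Hypergeometric overlap test between two gene sets
#'
#' Upper-tail test of the observed intersection size against draws from a
#' finite universe: `p = P(X >= k)` with `X ~ Hypergeometric(|universe|,
#' |set_a|, |set_b|)`.
#'
#' @param set_a,set_b character vectors, subsets of `universe`.
#' @param universe character vector of all eligible genes (must be explicit;
#'   never defaulted).
#' @return list `k, expected, p_value, n_a, n_b, n_universe`.
#' @export
hypergeometric_overlap <- function(set_a, set_b, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop_validation("empty universe")
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (!all(set_a %in% universe) || !all(set_b %in% universe))
    stop_validation("set_a and set_b must be subsets of the universe")
  k <- length(intersect(set_a, set_b))
  n_a <- length(set_a); n_b <- length(set_b); n_u <- length(universe)
  p <- stats::phyper(k - 1, n_a, n_u - n_a, n_b, lower.tail = FALSE)
  list(k = k, expected = n_a * n_b / n_u, p_value = p,
       n_a = n_a, n_b = n_b, n_universe = n_u)
}

#' DE composition of the top net-m6A-gain genes
#'
#' Restricts ranked genes to those with `fdr < fdr_max` in the DE table, ranks
#' by net m6A change descending (ties by average delta descending, then gene
#' id), takes the top `top_n`, and counts down-/up-regulated genes among them.
#'
#' @param records gene rank records ([gene_average_delta()]).
#' @param de DE results ([read_de_table()]; one cell line).
#' @param top_n number of genes to take (default 100).
#' @param fdr_max strict FDR filter applied before ranking (default 0.01).
#' @return list `n_down, n_up, top` (the selected table), `n_missing_de`
#'   (ranked genes absent from the DE table), `short` (TRUE when fewer than
#'   `top_n` genes were eligible).
#' @export
top_net_gain_de_composition <- function(records, de, top_n = 100L, fdr_max = 0.01) {
  r <- data.table::as.data.table(records)
  d <- data.table::as.data.table(de)
  m <- merge(r, d[, c("gene_id", "log2fc", "fdr"), with = FALSE], by = "gene_id")
  n_missing <- nrow(r) - nrow(m)
  elig <- m[fdr < fdr_max]
  data.table::setorder(elig, -net_change, -avg_delta, gene_id)
  short <- nrow(elig) < top_n
  if (short) warning(sprintf("only %d eligible genes for top_n = %d", nrow(elig), top_n))
  top <- utils::head(elig, top_n)
  list(n_down = sum(top$log2fc < 0), n_up = sum(top$log2fc > 0),
       top = top[], n_missing_de = n_missing, short = short)
}

#' Read gene sets in GMT format
#' @param path GMT file (set id, description, then member genes, tab-separated).
#' @return named list of gene-id character vectors.
#' @export
read_gmt <- function(path) {
  lines <- read_lines_any(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) stop_data("GMT %s line %d: fewer than 3 fields", path, bad[1])
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1)
  sets
}

#' Write gene sets in GMT format
#' @param gene_sets named list of gene-id vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- vapply(names(gene_sets), function(nm)
    paste(c(nm, "m6Aland", gene_sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}
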