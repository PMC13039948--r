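# Site-level statistics: replicate aggregation, joint filtering, m6A site
# calling, differential sites with stratified threshold counts, isoform
# modification classes, and the treatment restoration analysis.
#
# Throughout, a site is keyed by (chrom, start, strand) and thresholds are
# strict inequalities (">" wording everywhere in the underlying analysis).

SITE_KEY <- c("chrom", "start", "strand")

#' Filter presets for the joint coverage filter
#'
#' `"methods"` requires aggregated coverage > 20 per condition; `"figure"`
#' requires > 10. Both require mean level > 10% in at least one condition.
#' The two presets exist because both thresholds are in circulation for this
#' analysis; the preset used is recorded in output metadata.
#' @param preset `"methods"` or `"figure"`.
#' @return list with `min_agg_cov` and `min_level`.
#' @export
filter_preset <- function(preset = c("methods", "figure")) {
  preset <- match.arg(preset)
  list(preset = preset, min_agg_cov = if (preset == "methods") 20L else 10L,
       min_level = 0.10)
}

#' Aggregate per-replicate site records into per-condition summaries
#'
#' `mean_level` is the unweighted mean of per-replicate levels over replicates
#' with `valid_cov > 0`; `agg_cov` and `agg_level` pool reads across
#' replicates. A site absent from a replicate contributes nothing (it is not
#' treated as zero).
#'
#' @param records site-record data.table (one condition; see [read_pileup()]).
#' @return data.table keyed by site with `condition, n_replicates, mean_level,
#'   agg_cov, agg_level`.
#' @export
aggregate_condition <- function(records) {
  r <- data.table::as.data.table(records)
  if (!nrow(r))
    return(data.table::data.table(chrom = character(0), start = integer(0),
                                  strand = character(0), condition = character(0),
                                  n_replicates = integer(0), mean_level = numeric(0),
                                  agg_cov = integer(0), agg_level = numeric(0)))
  if (length(unique(r$condition)) > 1)
    stop_validation("aggregate_condition expects records from a single condition")
  out <- r[, {
    lv <- n_mod[valid_cov > 0] / valid_cov[valid_cov > 0]
    list(n_replicates = length(unique(sample_id)),
         mean_level = if (length(lv)) mean(lv) else NA_real_,
         agg_cov = sum(valid_cov),
         agg_level = if (sum(valid_cov) > 0) sum(n_mod) / sum(valid_cov) else NA_real_)
  }, by = c(SITE_KEY, "condition")]
  data.table::setkeyv(out, SITE_KEY)
  out[]
}

#' Joint site filter across two conditions
#'
#' Keeps sites present in both conditions with aggregated coverage strictly
#' above `min_agg_cov` in *each* condition and mean level strictly above
#' `min_level` in *at least one* condition.
#'
#' @param summary_a,summary_b per-condition summaries from
#'   [aggregate_condition()].
#' @param min_agg_cov,min_level thresholds (strict); defaults are the
#'   `"methods"` preset (20 reads aggregated, 10% m6A).
#' @return data.table with the site key and suffixed per-condition columns
#'   (`level_a`, `level_b`, `agg_cov_a`, ... where `level_*` is the mean of
#'   replicate levels).
#' @export
filter_sites <- function(summary_a, summary_b, min_agg_cov = 20L, min_level = 0.10) {
  if (min_level < 0 || min_level > 1)
    stop_validation("min_level must lie in [0,1], got %s", min_level)
  a <- data.table::as.data.table(summary_a)
  b <- data.table::as.data.table(summary_b)
  j <- merge(a, b, by = SITE_KEY, suffixes = c("_a", "_b"))
  j <- j[agg_cov_a > min_agg_cov & agg_cov_b > min_agg_cov &
           (mean_level_a > min_level | mean_level_b > min_level)]
  data.table::setnames(j, c("mean_level_a", "mean_level_b"), c("level_a", "level_b"))
  j[]
}

#' Call m6A-modified sites
#'
#' A site is called when its level exceeds `level_threshold` and its coverage
#' exceeds `min_reads` (both strict). Accepts either a per-condition summary
#' (level = `mean_level`, coverage = `agg_cov`) or raw per-replicate records
#' (level = `n_mod/valid_cov`, coverage = `valid_cov`, one call set per
#' sample).
#'
#' @param x condition summary or site records.
#' @param level_threshold minimum stoichiometry, exclusive (default 0.5).
#' @param min_reads minimum coverage, exclusive (default 10).
#' @return data.table of called sites (subset of rows of `x`).
#' @export
call_m6a_sites <- function(x, level_threshold = 0.5, min_reads = 10L) {
  x <- data.table::as.data.table(x)
  if ("mean_level" %in% names(x)) {
    x[mean_level > level_threshold & agg_cov > min_reads]
  } else {
    x[valid_cov > 0][n_mod / valid_cov > level_threshold & valid_cov > min_reads]
  }
}

#' Differential sites between two conditions
#'
#' `delta = level_a - level_b` (difference of replicate-mean levels, in level
#' units; multiply by 100 for percentage points). If `annotation` is supplied
#' (from [annotate_sites()]), region and motif class are attached.
#'
#' @param joint output of [filter_sites()].
#' @param annotation optional site annotation table.
#' @return data.table of differential sites with `delta` (and annotation
#'   columns when available).
#' @export
differential_sites <- function(joint, annotation = NULL) {
  d <- data.table::as.data.table(joint)
  d[, delta := level_a - level_b]
  if (!is.null(annotation)) {
    ann <- data.table::as.data.table(annotation)
    keep <- intersect(c(SITE_KEY, "transcript_id", "gene_id", "tpos", "region",
                        "motif_class", "metagene_x"), names(ann))
    d <- merge(d, unique(ann[, keep, with = FALSE], by = SITE_KEY),
               by = SITE_KEY, all.x = TRUE, sort = FALSE)
    d[is.na(region), region := "UNASSIGNED"]
    d[is.na(motif_class), motif_class := "UNDEFINED"]
  }
  d[]
}

#' Threshold counts of differential sites, stratified
#'
#' Counts sites with `delta` strictly above +10%/+20% and strictly below
#' -10%/-20%, overall and per stratum. Counts are nested by construction
#' (`n_up_20 <= n_up_10`).
#'
#' @param diff differential sites from [differential_sites()].
#' @param by stratification columns (default region and motif class when
#'   present, otherwise none).
#' @return data.table with one row per stratum plus a `TOTAL` row, columns
#'   `n_sites, n_up_10, n_dn_10, n_up_20, n_dn_20`.
#' @export
threshold_counts <- function(diff, by = intersect(c("region", "motif_class"), names(diff))) {
  d <- data.table::as.data.table(diff)
  count1 <- function(x) list(n_sites = length(x),
                             n_up_10 = sum(x > 0.10), n_dn_10 = sum(x < -0.10),
                             n_up_20 = sum(x > 0.20), n_dn_20 = sum(x < -0.20))
  total <- d[, count1(delta)]
  if (length(by)) {
    strat <- d[, count1(delta), by = by]
    data.table::setorderv(strat, by)
    for (col in by) total[[col]] <- "TOTAL"
    out <- data.table::rbindlist(list(strat, total), use.names = TRUE)
  } else {
    out <- data.table::as.data.table(total)
  }
  out[]
}

#' Classify transcript isoforms by modified-read fraction
#'
#' The level of an isoform is the fraction of its informative reads (reads
#' querying at least one A) that carry at least one modified call. Classes:
#' `LOW` below `bins[1]`, `HIGH` above `bins[2]`, `MEDIUM` on the closed
#' interval between them. Transcripts with fewer than `min_reads` informative
#' reads are excluded and tallied.
#'
#' @param read_records data.table with `read_id, transcript_id, n_called_A,
#'   n_mod`.
#' @param bins class boundaries as fractions (default `c(0.30, 0.70)`).
#' @param min_reads minimum informative reads per isoform (default 10).
#' @return list with `profiles` (per-isoform table with `n_reads,
#'   n_modified_reads, level, class`), `proportions` (named fractions over
#'   classified isoforms) and `n_unclassified`.
#' @export
classify_isoforms <- function(read_records, bins = c(0.30, 0.70), min_reads = 10L) {
  r <- data.table::as.data.table(read_records)
  if (any(r$n_mod > r$n_called_A))
    stop_data("read-level records: n_mod exceeds n_called_A")
  r <- r[n_called_A > 0]
  prof <- r[, list(n_reads = .N, n_modified_reads = sum(n_mod >= 1)), by = "transcript_id"]
  n_unclassified <- sum(prof$n_reads < min_reads)
  prof <- prof[n_reads >= min_reads]
  prof[, level := n_modified_reads / n_reads]
  prof[, class := ifelse(level < bins[1], "LOW", ifelse(level > bins[2], "HIGH", "MEDIUM"))]
  props <- prop.table(table(factor(prof$class, levels = c("LOW", "MEDIUM", "HIGH"))))
  list(profiles = prof[], proportions = c(props), n_unclassified = n_unclassified)
}

#' Restoration of hypomethylated sites under treatment
#'
#' Given the hypomethylated site set from a tumor-vs-normal comparison
#' (`delta < -0.10`), a site is *restored* when the treated mean level exceeds
#' the untreated mean level by strictly more than `delta_min`. The eligible
#' denominator is the subset of hypo sites with both treated and untreated
#' coverage strictly above `min_agg_cov`.
#'
#' @param hypo_sites differential-site table restricted to hypomethylated
#'   sites (site key columns required).
#' @param treated_summary,untreated_summary condition summaries
#'   ([aggregate_condition()]) for the treated/untreated comparison.
#' @param delta_min restoration threshold, exclusive (default 0.10).
#' @param min_agg_cov coverage filter applied to both summaries (default 20,
#'   the `"methods"` preset).
#' @return list with `restored` (site table with `restore_delta`),
#'   `n_restored`, `n_eligible` and `fraction`.
#' @export
restoration_analysis <- function(hypo_sites, treated_summary, untreated_summary,
                                 delta_min = 0.10, min_agg_cov = 20L) {
  h <- data.table::as.data.table(hypo_sites)[, SITE_KEY, with = FALSE]
  tr <- data.table::as.data.table(treated_summary)
  un <- data.table::as.data.table(untreated_summary)
  j <- merge(merge(h, tr, by = SITE_KEY), un, by = SITE_KEY, suffixes = c("_tr", "_un"))
  elig <- j[agg_cov_tr > min_agg_cov & agg_cov_un > min_agg_cov]
  if (!nrow(elig))
    stop_data("restoration analysis: no hypomethylated site passes the coverage filter in both treated and untreated")
  elig[, restore_delta := mean_level_tr - mean_level_un]
  restored <- elig[restore_delta > delta_min]
  list(restored = restored[], n_restored = nrow(restored), n_eligible = nrow(elig),
       fraction = nrow(restored) / nrow(elig))
}
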