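# End-to-end orchestration: the landscape comparison (condition A vs B) and
# the treatment analysis (treated vs untreated + restoration + net change +
# DE composition + binding overlap), each emitting TSVs with metadata headers
# and a JSON run manifest. Every filter stage logs counts in/out so headline
# numbers are auditable.

#' Metagene density of called sites
#'
#' Histogram of metagene positions over `[0, 3)` (unit-width 5'UTR/CDS/3'UTR
#' segments).
#'
#' @param annotated_sites table with a `metagene_x` column.
#' @param n_bins number of bins over `[0, 3)` (default 30).
#' @return data.table `bin_lo, bin_hi, bin_mid, count, density`.
#' @export
metagene_density <- function(annotated_sites, n_bins = 30L) {
  x <- data.table::as.data.table(annotated_sites)$metagene_x
  x <- x[!is.na(x)]
  edges <- seq(0, 3, length.out = n_bins + 1)
  idx <- findInterval(x, edges, rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = n_bins)
  w <- 3 / n_bins
  data.table::data.table(bin_lo = edges[-(n_bins + 1)], bin_hi = edges[-1],
                         bin_mid = edges[-(n_bins + 1)] + w / 2,
                         count = counts,
                         density = if (sum(counts)) counts / sum(counts) / w else 0)
}

#' Replicate overlap of called m6A sites
#'
#' Calls sites per replicate (level and coverage strictly above the
#' thresholds) and reports per-replicate call counts plus all pairwise
#' intersection sizes within each condition.
#'
#' @param records site records (possibly several conditions).
#' @param level_threshold,min_reads calling thresholds (strict; defaults 0.5
#'   and 10).
#' @return data.table with rows per replicate (`n_called`) and per pair
#'   (`n_shared`).
#' @export
replicate_overlap <- function(records, level_threshold = 0.5, min_reads = 10L) {
  r <- data.table::as.data.table(records)
  called <- call_m6a_sites(r, level_threshold, min_reads)
  key_of <- function(d) paste(d$chrom, d$start, d$strand)
  rows <- list()
  for (cond in unique(called$condition)) {
    cc <- called[condition == cond]
    samples <- sort(unique(cc$sample_id))
    sets <- lapply(samples, function(s) key_of(cc[sample_id == s]))
    names(sets) <- samples
    for (s in samples)
      rows[[length(rows) + 1]] <- data.table::data.table(
        condition = cond, a = s, b = NA_character_, n = length(sets[[s]]), kind = "n_called")
    if (length(samples) > 1) {
      for (i in seq_len(length(samples) - 1)) for (j in (i + 1):length(samples))
        rows[[length(rows) + 1]] <- data.table::data.table(
          condition = cond, a = samples[i], b = samples[j],
          n = length(intersect(sets[[i]], sets[[j]])), kind = "n_shared")
    }
  }
  data.table::rbindlist(rows)
}

as_site_records <- function(x, condition) {
  if (is.character(x)) {
    nm <- names(x) %||% sprintf("%s_rep%d", condition, seq_along(x))
    x <- Map(function(p, s) read_pileup(p, sample_id = s, condition = condition), x, nm)
  }
  data.table::rbindlist(x, use.names = TRUE)
}

as_models <- function(models, fasta = NULL, fasta_is_genome = FALSE) {
  if (is.character(models)) read_transcript_models(models, fasta, fasta_is_genome)
  else models
}

write_manifest <- function(out_dir, entries) {
  entries$tool_version <- as.character(utils::packageVersion("m6Aland"))
  entries$created <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

checksum_files <- function(paths) {
  paths <- unlist(paths)
  paths <- paths[vapply(paths, function(p) is.character(p) && file.exists(p), TRUE)]
  if (!length(paths)) return(NULL)
  as.list(tools::md5sum(paths))
}

#' Run the landscape comparison (condition A vs condition B)
#'
#' Full site-level workflow: aggregate replicates per condition, joint
#' filter, annotate against representative transcripts, differential sites
#' with stratified threshold counts, per-replicate call overlap, metagene
#' density of called sites, gene ranking by average delta, and (optionally)
#' preranked enrichment and isoform classification.
#'
#' @param pileups_a,pileups_b per-replicate inputs for conditions A and B:
#'   either named character vectors of pileup paths or lists of site-record
#'   tables.
#' @param models transcript models (list) or a GTF path.
#' @param out_dir output directory (created).
#' @param condition_a,condition_b condition labels (delta = A - B).
#' @param fasta,fasta_is_genome sequence source when `models` is a GTF path.
#' @param gene_sets named list of gene-id vectors or a GMT path (optional).
#' @param read_records read-level table or path (optional; enables isoform
#'   classes).
#' @param filter_preset `"methods"` (aggregated coverage > 20) or `"figure"`
#'   (> 10).
#' @param utr3_extension 3'UTR extension in nt (default 100).
#' @param n_perm permutations for enrichment (default 1000 at pipeline level).
#' @param seed RNG seed (enrichment permutations).
#' @return list with all result tables (`differential`, `threshold_counts`,
#'   `gene_ranking`, `metagene`, `replicate_overlap`, `enrichment`,
#'   `isoforms`) plus `out_dir`.
#' @export
run_landscape_comparison <- function(pileups_a, pileups_b, models, out_dir,
                                     condition_a = "tumor", condition_b = "normal",
                                     fasta = NULL, fasta_is_genome = FALSE,
                                     gene_sets = NULL, read_records = NULL,
                                     filter_preset = "methods",
                                     utr3_extension = 100L, n_perm = 1000L, seed = 1L) {
  t0 <- proc.time()[["elapsed"]]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  preset <- filter_preset(filter_preset)
  rec_a <- as_site_records(pileups_a, condition_a)
  rec_b <- as_site_records(pileups_b, condition_b)
  mods <- as_models(models, fasta, fasta_is_genome)
  message(sprintf("[landscape] %d/%d records read for %s/%s",
                  nrow(rec_a), nrow(rec_b), condition_a, condition_b))
  sum_a <- aggregate_condition(rec_a)
  sum_b <- aggregate_condition(rec_b)
  joint <- filter_sites(sum_a, sum_b, preset$min_agg_cov, preset$min_level)
  message(sprintf("[landscape] %d sites in both conditions pass preset '%s' (cov > %d, level > %.2f)",
                  nrow(joint), preset$preset, preset$min_agg_cov, preset$min_level))
  ann <- annotate_sites(joint[, c("chrom", "start", "strand"), with = FALSE],
                        mods, utr3_extension)
  diff <- differential_sites(joint, ann)
  counts <- threshold_counts(diff)
  ranking <- gene_average_delta(diff)
  called_a <- call_m6a_sites(sum_a)
  mg <- metagene_density(annotate_sites(called_a[, c("chrom", "start", "strand"),
                                                 with = FALSE], mods, utr3_extension))
  ovl <- replicate_overlap(data.table::rbindlist(list(rec_a, rec_b)))
  meta <- list(filter_preset = preset$preset, min_agg_cov = preset$min_agg_cov,
               min_level = preset$min_level, condition_a = condition_a,
               condition_b = condition_b, utr3_extension = utr3_extension, seed = seed)
  write_tsv_meta(diff, file.path(out_dir, "sites_differential.tsv"), meta)
  write_tsv_meta(counts, file.path(out_dir, "threshold_counts.tsv"), meta)
  write_tsv_meta(ranking, file.path(out_dir, "gene_ranking.tsv"), meta)
  write_tsv_meta(mg, file.path(out_dir, "metagene_density.tsv"), meta)
  write_tsv_meta(ovl, file.path(out_dir, "replicate_overlap.tsv"), meta)
  enr <- NULL
  if (!is.null(gene_sets)) {
    if (is.character(gene_sets)) gene_sets <- read_gmt(gene_sets)
    scores <- stats::setNames(ranking$avg_delta, ranking$gene_id)
    enr <- enrichment_batch(scores, gene_sets, n_perm = n_perm, seed = seed)
    write_tsv_meta(enr, file.path(out_dir, "enrichment.tsv"),
                   c(meta, list(n_perm = n_perm)))
  }
  iso <- NULL
  if (!is.null(read_records)) {
    if (is.character(read_records)) read_records <- data.table::fread(read_records)
    iso <- classify_isoforms(read_records)
    iso_tab <- data.table::data.table(class = names(iso$proportions),
                                      proportion = as.numeric(iso$proportions))
    write_tsv_meta(iso_tab, file.path(out_dir, "isoform_classes.tsv"),
                   c(meta, list(n_unclassified = iso$n_unclassified)))
  }
  write_manifest(out_dir, list(
    stage = "landscape", filter = meta,
    n_records = c(a = nrow(rec_a), b = nrow(rec_b)),
    n_sites_joint = nrow(joint), n_genes_ranked = nrow(ranking),
    input_checksums = checksum_files(list(pileups_a, pileups_b, models)),
    config_hash = hash_object(meta),
    elapsed_s = round(proc.time()[["elapsed"]] - t0, 2)))
  list(differential = diff, threshold_counts = counts, gene_ranking = ranking,
       metagene = mg, replicate_overlap = ovl, enrichment = enr, isoforms = iso,
       summaries = list(a = sum_a, b = sum_b), out_dir = out_dir)
}

#' Run the treatment analysis (treated vs untreated)
#'
#' Treated-vs-untreated differential sites, restoration of a supplied
#' hypomethylated site set, per-gene net m6A change, DE composition of the
#' top net-gain genes, and (optionally) reader-binding overlap of gene sets.
#'
#' @param pileups_treated,pileups_untreated per-replicate inputs (paths or
#'   record tables).
#' @param models transcript models or a GTF path.
#' @param hypo_sites hypomethylated site set: a differential-site table (or
#'   path to a `sites_differential.tsv`) from the landscape run; rows with
#'   `delta < -0.10` are used.
#' @param out_dir output directory.
#' @param de DE table for the treated line (optional; enables composition).
#' @param binding binding intervals (table or BED path; optional).
#' @param overlap_gene_sets named list of gene sets for the binding overlap
#'   (e.g. common down/up genes; optional).
#' @param fasta,fasta_is_genome sequence source when `models` is a GTF path.
#' @param filter_preset,utr3_extension as in [run_landscape_comparison()].
#' @param top_n,fdr_max composition-rule parameters (defaults 100 and 0.01).
#' @param seed RNG seed recorded in outputs.
#' @return list with `differential`, `threshold_counts`, `restoration`,
#'   `net_change`, `composition`, `binding_overlap`, `out_dir`.
#' @export
run_treatment_analysis <- function(pileups_treated, pileups_untreated, models,
                                   hypo_sites, out_dir, de = NULL, binding = NULL,
                                   overlap_gene_sets = NULL,
                                   fasta = NULL, fasta_is_genome = FALSE,
                                   filter_preset = "methods", utr3_extension = 100L,
                                   top_n = 100L, fdr_max = 0.01, seed = 1L) {
  t0 <- proc.time()[["elapsed"]]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  preset <- filter_preset(filter_preset)
  if (is.null(hypo_sites)) stop_validation("hypo_sites is required: supply the landscape differential table (or its path)")
  if (is.character(hypo_sites)) hypo_sites <- read_tsv_meta(hypo_sites)$data
  hypo <- data.table::as.data.table(hypo_sites)
  if ("delta" %in% names(hypo)) hypo <- hypo[delta < -0.10]
  if (!nrow(hypo)) stop_data("hypo_sites contains no hypomethylated sites (delta < -0.10)")
  rec_t <- as_site_records(pileups_treated, "treated")
  rec_u <- as_site_records(pileups_untreated, "untreated")
  mods <- as_models(models, fasta, fasta_is_genome)
  sum_t <- aggregate_condition(rec_t)
  sum_u <- aggregate_condition(rec_u)
  joint <- filter_sites(sum_t, sum_u, preset$min_agg_cov, preset$min_level)
  message(sprintf("[treatment] %d sites pass preset '%s'", nrow(joint), preset$preset))
  ann <- annotate_sites(joint[, c("chrom", "start", "strand"), with = FALSE],
                        mods, utr3_extension)
  diff <- differential_sites(joint, ann)
  counts <- threshold_counts(diff)
  resto <- restoration_analysis(hypo, sum_t, sum_u, delta_min = 0.10,
                                min_agg_cov = preset$min_agg_cov)
  net <- gene_average_delta(diff)
  data.table::setorder(net, -net_change, -avg_delta, gene_id)
  meta <- list(filter_preset = preset$preset, min_agg_cov = preset$min_agg_cov,
               min_level = preset$min_level, utr3_extension = utr3_extension,
               seed = seed)
  write_tsv_meta(diff, file.path(out_dir, "treated_differential.tsv"), meta)
  write_tsv_meta(counts, file.path(out_dir, "treatment_threshold_counts.tsv"), meta)
  write_tsv_meta(resto$restored, file.path(out_dir, "restoration.tsv"),
                 c(meta, list(n_restored = resto$n_restored,
                              n_eligible = resto$n_eligible,
                              fraction = resto$fraction)))
  write_tsv_meta(net, file.path(out_dir, "net_change.tsv"), meta)
  comp <- NULL
  if (!is.null(de)) {
    if (is.character(de)) de <- read_de_table(de, cell_line = "treated_line")
    comp <- top_net_gain_de_composition(net, de, top_n = top_n, fdr_max = fdr_max)
    write_tsv_meta(comp$top, file.path(out_dir, "composition.tsv"),
                   c(meta, list(top_n = top_n, fdr_max = fdr_max,
                                n_down = comp$n_down, n_up = comp$n_up)))
  }
  bov <- NULL
  if (!is.null(binding) && !is.null(overlap_gene_sets)) {
    if (is.character(binding)) binding <- read_binding_bed(binding, "binding")
    called <- call_m6a_sites(sum_t)  # treated-or-untreated union of calls
    called <- unique(data.table::rbindlist(list(called, call_m6a_sites(sum_u)))[,
                       c("chrom", "start", "strand"), with = FALSE])
    called_ann <- annotate_sites(called, mods, utr3_extension)
    bov <- reader_binding_overlap(overlap_gene_sets, called_ann, binding)
    write_tsv_meta(bov$table, file.path(out_dir, "binding_overlap.tsv"), meta)
  }
  write_manifest(out_dir, list(
    stage = "treatment", filter = meta,
    n_sites_joint = nrow(joint), n_hypo_in = nrow(hypo),
    restoration = list(n_restored = resto$n_restored, n_eligible = resto$n_eligible,
                       fraction = resto$fraction),
    input_checksums = checksum_files(list(pileups_treated, pileups_untreated, models)),
    config_hash = hash_object(meta),
    elapsed_s = round(proc.time()[["elapsed"]] - t0, 2)))
  list(differential = diff, threshold_counts = counts, restoration = resto,
       net_change = net, composition = comp, binding_overlap = bov,
       summaries = list(treated = sum_t, untreated = sum_u), out_dir = out_dir)
}
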