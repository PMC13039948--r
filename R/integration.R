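# Integration across assays: differential-expression thresholding and
# multi-line intersection, and overlap of called m6A sites with m6A-reader
# (e.g. YTHDF2) binding intervals.

#' Significant up/down gene sets from one DE table
#'
#' Up: `fdr < fdr_max` and `log2fc > log2(fc_min)`; down: `fdr < fdr_max` and
#' `log2fc < -log2(fc_min)`. All inequalities strict; the fold-change
#' threshold is given on the linear scale.
#'
#' @param de DE results for one cell line ([read_de_table()]).
#' @param fdr_max FDR cutoff (default 0.05).
#' @param fc_min linear fold-change cutoff, must exceed 1 (default 1.5).
#' @return list `up`, `down` (gene-id character vectors) plus the thresholds.
#' @export
de_sets <- function(de, fdr_max = 0.05, fc_min = 1.5) {
  if (fc_min <= 1) stop_validation("fc_min must be > 1 (linear scale), got %s", fc_min)
  d <- data.table::as.data.table(de)
  lfc <- log2(fc_min)
  list(up = d[fdr < fdr_max & log2fc > lfc, gene_id],
       down = d[fdr < fdr_max & log2fc < -lfc, gene_id],
       fdr_max = fdr_max, fc_min = fc_min)
}

#' Intersect per-line DE sets across cell lines
#'
#' @param line_sets named list (one element per cell line) of [de_sets()]
#'   results.
#' @return list with `up_common`, `down_common`, `per_line` (the input), and a
#'   `counts` data.table (per line and common).
#' @export
intersect_lines <- function(line_sets) {
  if (length(line_sets) < 2) stop_validation("need >= 2 cell lines to intersect")
  up_common <- sort(Reduce(intersect, lapply(line_sets, `[[`, "up")))
  down_common <- sort(Reduce(intersect, lapply(line_sets, `[[`, "down")))
  counts <- data.table::data.table(
    line = c(names(line_sets), "common"),
    n_up = c(vapply(line_sets, function(s) length(s$up), integer(1)), length(up_common)),
    n_down = c(vapply(line_sets, function(s) length(s$down), integer(1)), length(down_common)))
  list(up_common = up_common, down_common = down_common,
       per_line = line_sets, counts = counts)
}

#' Overlap of gene sets with m6A sites inside reader-binding intervals
#'
#' A gene qualifies when at least one of its called m6A sites lies within at
#' least one binding interval (half-open; strand is ignored when the interval
#' strand is `"."`). Binding intervals from different `source_label`s are
#' analyzed separately, never merged. When exactly two gene sets are given, a
#' hypergeometric comparison of their qualifying genes over the union universe
#' is attached per source.
#'
#' @param gene_sets named list of gene-id vectors (e.g. common down/up genes).
#' @param called_sites called m6A sites carrying `chrom, start, strand` and
#'   `gene_id` (e.g. [call_m6a_sites()] output annotated via
#'   [annotate_sites()]).
#' @param binding binding intervals ([read_binding_bed()]).
#' @return list with `table` (data.table: `source_label, set, n_genes,
#'   n_qualifying, pct`), `qualifying` (nested list of gene ids per source and
#'   set) and `tests` (hypergeometric comparisons per source, when two sets).
#' @export
reader_binding_overlap <- function(gene_sets, called_sites, binding) {
  s <- data.table::as.data.table(called_sites)
  b <- data.table::as.data.table(binding)
  if (!"gene_id" %in% names(s))
    stop_validation("called_sites must carry gene_id (annotate sites first)")
  s <- s[!is.na(gene_id)]
  if (nrow(s) && nrow(b) && !length(intersect(unique(s$chrom), unique(b$chrom))))
    stop_data(paste("no chromosome names shared between sites (%s...) and intervals (%s...);",
                    "harmonize the genome build / chromosome naming (e.g. 'chr1' vs '1')"),
              s$chrom[1], b$chrom[1])
  rows <- list(); qual <- list(); tests <- list()
  for (src in unique(b$source_label)) {
    iv <- b[source_label == src]
    data.table::setkey(iv, chrom, start, end)
    q <- data.table::data.table(chrom = s$chrom, start = s$start, end = s$start + 1L,
                                strand = s$strand, gene_id = s$gene_id)
    ov <- data.table::foverlaps(q, iv, type = "within", nomatch = NULL)
    ov <- ov[strand == "." | strand == i.strand]
    bound_genes <- unique(ov$gene_id)
    qual[[src]] <- lapply(gene_sets, function(g) intersect(g, bound_genes))
    rows[[src]] <- data.table::data.table(
      source_label = src, set = names(gene_sets),
      n_genes = vapply(gene_sets, length, integer(1)),
      n_qualifying = vapply(qual[[src]], length, integer(1)))
    if (length(gene_sets) == 2) {
      # is binding concentrated in set 1 relative to draws from the union?
      uni <- union(gene_sets[[1]], gene_sets[[2]])
      tests[[src]] <- hypergeometric_overlap(unique(unlist(qual[[src]])),
                                             gene_sets[[1]], uni)
    }
  }
  tab <- data.table::rbindlist(rows)
  tab[, pct := 100 * n_qualifying / pmax(n_genes, 1L)]
  list(table = tab[], qualifying = qual, tests = tests)
}
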