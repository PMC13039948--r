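# Readers/writers for the external tables the pipeline consumes:
# modkit-style bedMethyl pileups (two dialects), DE tables, BED binding
# intervals. All genomic coordinates are 0-based half-open internally;
# conversion happens only at the I/O edge. All readers accept gzip.

#' Read a per-site modification pileup (bedMethyl dialect)
#'
#' Supports two tab-separated dialects:
#' * the 18-column modkit pileup: column 1 chrom, 2 start (0-based), 3 end,
#'   4 modification code, 6 strand, 10 valid coverage, 11 percent modified,
#'   12 modified-read count (columns beyond 12 are ignored);
#' * an 11-column fallback where column 10 is valid coverage and column 11 the
#'   percent modified, from which `n_mod = round(percent * valid_cov / 100)`
#'   (lossy reconstruction, documented as such).
#'
#' Rows whose modification code differs from `mod_code_filter` are skipped
#' silently; malformed rows raise a data error naming the line number.
#'
#' @param path pileup file (optionally gzipped).
#' @param sample_id replicate identifier attached to every record.
#' @param condition condition label attached to every record.
#' @param mod_code_filter modification code to keep (default `"a"`, m6A).
#' @return data.table of site records with columns `chrom, start, end, strand,
#'   mod_code, valid_cov, n_mod, level, sample_id, condition`; `level` is
#'   `n_mod/valid_cov`, `NA` where `valid_cov == 0`.
#' @export
read_pileup <- function(path, sample_id, condition, mod_code_filter = "a") {
  lines <- read_lines_any(path)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  if (length(lines) == 0) return(empty_site_records(sample_id, condition))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  bad <- which(ncols < 11L)
  if (length(bad)) stop_data("pileup %s line %d: expected >= 11 tab-separated columns, got %d",
                             path, bad[1], ncols[bad[1]])
  get <- function(i) vapply(fields, `[[`, "", i)
  chrom <- get(1); start_c <- get(2); end_c <- get(3)
  code <- get(4); strand <- get(6)
  cov_c <- get(10); pct_c <- get(11)
  bad <- which(!grepl("^[0-9]+$", start_c) | !grepl("^[0-9]+$", end_c))
  if (length(bad)) stop_data("pileup %s line %d: non-integer coordinates", path, bad[1])
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad)) stop_data("pileup %s line %d: unknown strand symbol '%s'",
                             path, bad[1], strand[bad[1]])
  bad <- which(!grepl("^[0-9]+$", cov_c))
  if (length(bad)) stop_data("pileup %s line %d: non-integer valid coverage", path, bad[1])
  valid_cov <- as.integer(cov_c)
  if (all(ncols >= 12L)) {
    nmod_c <- get(12)
    bad <- which(!grepl("^[0-9]+$", nmod_c))
    if (length(bad)) stop_data("pileup %s line %d: non-integer modified-read count", path, bad[1])
    n_mod <- as.integer(nmod_c)
  } else {
    pct <- suppressWarnings(as.numeric(pct_c))
    bad <- which(is.na(pct))
    if (length(bad)) stop_data("pileup %s line %d: non-numeric percent modified", path, bad[1])
    n_mod <- as.integer(round(pct * valid_cov / 100))
  }
  bad <- which(n_mod > valid_cov)
  if (length(bad)) stop_data("pileup %s line %d: n_mod (%d) exceeds valid coverage (%d)",
                             path, bad[1], n_mod[bad[1]], valid_cov[bad[1]])
  dt <- data.table::data.table(
    chrom = chrom, start = as.integer(start_c), end = as.integer(end_c),
    strand = strand, mod_code = code, valid_cov = valid_cov, n_mod = n_mod)
  dt <- dt[dt$mod_code == mod_code_filter]
  dt[, `:=`(level = ifelse(valid_cov > 0, n_mod / valid_cov, NA_real_),
            sample_id = sample_id, condition = condition)]
  dt[]
}

empty_site_records <- function(sample_id = character(0), condition = character(0)) {
  data.table::data.table(chrom = character(0), start = integer(0), end = integer(0),
                         strand = character(0), mod_code = character(0),
                         valid_cov = integer(0), n_mod = integer(0), level = numeric(0),
                         sample_id = character(0), condition = character(0))
}

#' Write site records in the 18-column bedMethyl pileup dialect
#'
#' Round-trips bit-exactly through [read_pileup()] for counts and coordinates.
#'
#' @param records site-record data.table (as from [read_pileup()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pileup <- function(records, path) {
  r <- data.table::as.data.table(records)
  n_canon <- r$valid_cov - r$n_mod
  pct <- ifelse(r$valid_cov > 0, 100 * r$n_mod / r$valid_cov, 0)
  out <- data.table::data.table(
    r$chrom, r$start, r$end, r$mod_code, r$valid_cov, r$strand,
    r$start, r$end, "255,0,0", r$valid_cov, sprintf("%.2f", pct), r$n_mod,
    n_canon, 0L, 0L, 0L, 0L, 0L)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a differential-expression result table
#'
#' Requires (case-insensitively) columns for gene id, log2 fold change and FDR;
#' the header-to-field mapping is configurable via `col_map`, each entry a
#' character vector of accepted header names in priority order.
#'
#' @param path TSV/CSV file (separator sniffed by `fread`; optionally gzipped).
#' @param cell_line label attached to every record.
#' @param col_map list with elements `gene`, `log2fc`, `fdr`.
#' @return data.table with columns `gene_id, log2fc, fdr, cell_line`.
#' @export
read_de_table <- function(path, cell_line,
                          col_map = list(gene = c("gene", "gene_id", "symbol"),
                                         log2fc = c("log2fc", "logfc", "log2foldchange"),
                                         fdr = c("fdr", "padj", "adj.p.val", "qvalue"))) {
  lines <- read_lines_any(path)
  dt <- data.table::fread(text = lines, header = TRUE)
  lower <- tolower(names(dt))
  pick <- function(cands, what) {
    hit <- which(lower %in% tolower(cands))
    if (!length(hit)) stop_validation("DE table %s: missing required column for '%s' (accepted: %s)",
                                      path, what, paste(cands, collapse = ", "))
    names(dt)[hit[1]]
  }
  out <- data.table::data.table(
    gene_id = as.character(dt[[pick(col_map$gene, "gene")]]),
    log2fc = as.numeric(dt[[pick(col_map$log2fc, "log2fc")]]),
    fdr = as.numeric(dt[[pick(col_map$fdr, "fdr")]]),
    cell_line = cell_line)
  if (anyDuplicated(out$gene_id))
    stop_data("DE table %s: duplicate gene_id '%s'", path,
              out$gene_id[anyDuplicated(out$gene_id)])
  if (nrow(out) && (min(out$fdr) < 0 || max(out$fdr) > 1))
    stop_validation("DE table %s: fdr outside [0,1]", path)
  out
}

#' Read reader-binding intervals from BED3+ (0-based half-open)
#'
#' @param path BED file (optionally gzipped).
#' @param source_label provenance label (e.g. which published binding-site
#'   set); intervals from different sources are analyzed separately downstream.
#' @return data.table with `chrom, start, end, strand, source_label`; strand is
#'   `"."` when the file has fewer than 6 columns.
#' @export
read_binding_bed <- function(path, source_label) {
  lines <- read_lines_any(path)
  lines <- lines[nzchar(lines) & !grepl("^(#|track|browser)", lines)]
  if (!length(lines))
    return(data.table::data.table(chrom = character(0), start = integer(0),
                                  end = integer(0), strand = character(0),
                                  source_label = character(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < 3L)) stop_data("BED %s line %d: fewer than 3 columns", path, which(ncols < 3L)[1])
  chrom <- vapply(fields, `[[`, "", 1)
  start <- as.integer(vapply(fields, `[[`, "", 2))
  end <- as.integer(vapply(fields, `[[`, "", 3))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) stop_data("BED %s line %d: non-integer coordinates", path, bad[1])
  bad <- which(start >= end)
  if (length(bad)) stop_data("BED %s line %d: start (%d) >= end (%d)",
                             path, bad[1], start[bad[1]], end[bad[1]])
  strand <- ifelse(ncols >= 6L, vapply(fields, function(f) f[min(6, length(f))], ""), ".")
  strand[!strand %in% c("+", "-", ".")] <- "."
  data.table::data.table(chrom = chrom, start = start, end = end,
                         strand = strand, source_label = source_label)
}

#' Write binding intervals as BED6
#' @param intervals data.table as from [read_binding_bed()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_binding_bed <- function(intervals, path) {
  x <- data.table::as.data.table(intervals)
  out <- data.table::data.table(x$chrom, x$start, x$end,
                                x$source_label %||% ".", 0L, x$strand)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}
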