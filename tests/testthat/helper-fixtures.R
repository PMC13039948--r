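# Fixture builders shared across the suite. Everything is generated in code;
# no binary fixtures.

# A pileup line in the 18-column modkit dialect.
pileup_line <- function(chrom = "chr1", start = 999L, code = "a", strand = "+",
                        valid_cov = 50L, n_mod = 20L) {
  pct <- if (valid_cov > 0) sprintf("%.2f", 100 * n_mod / valid_cov) else "0.00"
  paste(chrom, start, start + 1L, code, valid_cov, strand, start, start + 1L,
        "255,0,0", valid_cov, pct, n_mod, valid_cov - n_mod, 0, 0, 0, 0, 0,
        sep = "\t")
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# Minimal site-record table (one replicate).
site_records <- function(chrom = "chr1", start, strand = "+", valid_cov, n_mod,
                         sample_id = "s1", condition = "c") {
  data.table::data.table(
    chrom = chrom, start = as.integer(start), end = as.integer(start) + 1L,
    strand = strand, mod_code = "a", valid_cov = as.integer(valid_cov),
    n_mod = as.integer(n_mod),
    level = ifelse(valid_cov > 0, n_mod / valid_cov, NA_real_),
    sample_id = sample_id, condition = condition)
}

# Toy coding transcript: 5'UTR 50, CDS 300, 3'UTR 150 (length 500) with a
# deterministic sequence carrying known motifs.
toy_model <- function(strand = "+", exons = NULL, seq = NULL, chrom = "chrT",
                      id = "TX1", gene = "GENE1", cds = c(50L, 350L)) {
  if (is.null(exons)) exons <- matrix(c(1000L, 1500L), ncol = 2)
  len <- sum(exons[, 2] - exons[, 1])
  if (is.null(seq)) seq <- paste(rep(c("C", "G", "T", "C", "G"), length.out = len), collapse = "")
  transcript_model(id, gene, chrom, strand, exons,
                   cds_start_t = cds[1], cds_end_t = cds[2], sequence = seq)
}

# Plant a 5-mer into a sequence string at 0-based centre position tpos.
plant_motif <- function(seq, tpos, motif) {
  stopifnot(nchar(motif) == 5)
  paste0(substr(seq, 1, tpos - 2), motif, substr(seq, tpos + 4, nchar(seq)))
}

# Small deterministic synthetic config for fast tests.
small_config <- function(...) {
  synthetic_config(n_genes = 80L, hypo_gene_set_size = 20L, n_up_core = 10L,
                   n_private_per_line = 5L, read_depth = 40L, ...)
}
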