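# transcript_annotation: coordinate mapping, regions, motifs, metagene,
# representative transcripts, GTF/FASTA round trip.

test_that("genome_to_transcript handles both strands, introns and absence", {
  tp <- transcript_model("T", "G", "c", "+", matrix(c(100L, 200L, 110L, 210L), ncol = 2),
                         cds_start_t = 2L, cds_end_t = 14L)
  expect_equal(genome_to_transcript(205L, "+", tp), 15L)  # 10 + (205-200)
  expect_true(is.na(genome_to_transcript(150L, "+", tp)))  # intronic
  expect_true(is.na(genome_to_transcript(205L, "-", tp)))  # strand mismatch
  tm <- transcript_model("T", "G", "c", "-", matrix(c(100L, 110L), ncol = 2))
  expect_equal(genome_to_transcript(109L, "-", tm), 0L)  # 3'->5' reversal
  expect_equal(genome_to_transcript(100L, "-", tm), 9L)
})

test_that("coordinate round trip holds for every exonic base, both strands", {
  exons <- matrix(c(100L, 250L, 400L, 140L, 300L, 460L), ncol = 2)
  for (st in c("+", "-")) {
    t <- transcript_model("T", "G", "c", st, exons)
    for (tpos in seq_len(t$length) - 1L) {
      g <- transcript_to_genome(tpos, t)
      expect_equal(genome_to_transcript(g, st, t), tpos)
    }
    # extension window round trips too
    for (tpos in t$length + c(0L, 50L, 99L)) {
      g <- transcript_to_genome(tpos, t, extension = 100L)
      expect_equal(genome_to_transcript(g, st, t, extension = 100L), tpos)
    }
  }
})

test_that("assign_region partitions [0, length + extension)", {
  t <- toy_model()  # length 500, CDS [50, 350)
  expect_equal(assign_region(10L, t), "FIVE_UTR")
  expect_equal(assign_region(49L, t), "FIVE_UTR")
  expect_equal(assign_region(50L, t), "CDS")
  expect_equal(assign_region(349L, t), "CDS")
  expect_equal(assign_region(350L, t), "THREE_UTR")  # stop-codon-adjacent side
  expect_equal(assign_region(499L, t), "THREE_UTR")
  expect_equal(assign_region(560L, t, utr3_extension = 100L), "THREE_UTR_EXT")
  expect_error(assign_region(600L, t, utr3_extension = 100L), "out of range",
               class = "m6aland_validation_error")
  regions <- vapply(0:599, assign_region, character(1), t = t, utr3_extension = 100L)
  expect_equal(as.integer(table(regions)[c("FIVE_UTR", "CDS", "THREE_UTR", "THREE_UTR_EXT")]),
               c(50L, 300L, 150L, 100L))
  nc <- transcript_model("N", "G", "c", "+", matrix(c(0L, 200L), ncol = 2))
  expect_equal(assign_region(100L, nc), "NONCODING")
})

test_that("classify_motif implements the DRACH consensus with U/T equivalence", {
  len <- 60L
  base <- paste(rep("C", len), collapse = "")
  t_at <- function(motif, tpos = 30L) {
    toy_model(exons = matrix(c(0L, len), ncol = 2), seq = plant_motif(base, tpos, motif),
              cds = c(5L, 50L))
  }
  expect_equal(classify_motif(t_at("GGACT"), 30L), "DRACH")
  expect_equal(classify_motif(t_at("GGACU"), 30L), "DRACH")  # RNA alphabet
  expect_equal(classify_motif(t_at("AAACA"), 30L), "DRACH")
  expect_equal(classify_motif(t_at("TGACC"), 30L), "DRACH")
  expect_equal(classify_motif(t_at("GTACC"), 30L), "NON_DRACH")  # R position is U
  expect_equal(classify_motif(t_at("GGAGT"), 30L), "NON_DRACH")  # C position fails
  expect_equal(classify_motif(t_at("CGACT"), 30L), "NON_DRACH")  # D position fails
  expect_equal(classify_motif(t_at("GGGCT"), 30L), "UNDEFINED")  # central base not A
  expect_equal(classify_motif(t_at("GGACT", 30L), 1L), "UNDEFINED")  # truncated window
  expect_equal(classify_motif(t_at("GGACT", 30L), len - 2L), "UNDEFINED")
})

test_that("motif classes are invariant under reverse-complement placement", {
  # transcript A on + of genome G; transcript B on - of revcomp(G): spliced
  # transcript sequences are identical, so classes must agree site by site
  set.seed(5)
  seqc <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seqc)))
  dir <- tempfile(); dir.create(dir)
  fa <- file.path(dir, "g.fa")
  writeLines(c(">gplus", seqc, ">gminus", rc), fa)
  gtf <- file.path(dir, "a.gtf")
  writeLines(c(
    paste("gplus", "t", "exon", 1, 300, ".", "+", ".",
          'gene_id "GA"; transcript_id "TA";', sep = "\t"),
    paste("gminus", "t", "exon", 1, 300, ".", "-", ".",
          'gene_id "GB"; transcript_id "TB";', sep = "\t")), gtf)
  mods <- read_transcript_models(gtf, fa, fasta_is_genome = TRUE)
  expect_equal(mods$TA$sequence, mods$TB$sequence)
  cls_a <- vapply(0:299, function(p) classify_motif(mods$TA, p), character(1))
  cls_b <- vapply(0:299, function(p) classify_motif(mods$TB, p), character(1))
  expect_equal(cls_a, cls_b)
  expect_true(any(cls_a == "DRACH") || any(cls_a == "NON_DRACH"))
})

test_that("metagene_position scales the three regions to unit widths", {
  t <- transcript_model("T", "G", "c", "+", matrix(c(0L, 500L), ncol = 2),
                        cds_start_t = 100L, cds_end_t = 300L)
  expect_equal(metagene_position(200L, t), 1.5)  # CDS midpoint
  expect_equal(metagene_position(300L, t), 2.0)  # first base of 3'UTR
  expect_equal(metagene_position(25L, t), 0.25)  # 25/100 in the 5'UTR
  expect_equal(metagene_position(0L, t), 0)
  # missing 5'UTR -> undefined
  t2 <- transcript_model("T", "G", "c", "+", matrix(c(0L, 500L), ncol = 2),
                         cds_start_t = 0L, cds_end_t = 300L)
  expect_true(is.na(metagene_position(200L, t2)))
  nc <- transcript_model("N", "G", "c", "+", matrix(c(0L, 500L), ncol = 2))
  expect_true(is.na(metagene_position(200L, nc)))
})

test_that("representative transcript choice is deterministic", {
  mk <- function(id, cds_len, len) {
    transcript_model(id, "G", "c", "+", matrix(c(0L, len), ncol = 2),
                     cds_start_t = 0L, cds_end_t = cds_len)
  }
  expect_equal(choose_representative_transcript(list(mk("A", 300L, 900L), mk("B", 600L, 900L)))$transcript_id, "B")
  expect_equal(choose_representative_transcript(list(mk("A", 300L, 900L), mk("B", 300L, 1200L)))$transcript_id, "B")
  expect_equal(choose_representative_transcript(list(mk("T2", 300L, 900L), mk("T1", 300L, 900L)))$transcript_id, "T1")
  expect_error(choose_representative_transcript(list()), class = "m6aland_validation_error")
})

test_that("GTF/FASTA writers round trip through the readers", {
  seq1 <- paste(sample(rep(c("C", "G", "T"), 100))[1:150], collapse = "")
  m1 <- transcript_model("TX1", "G1", "chrZ", "+",
                         matrix(c(1000L, 1100L, 1150L, 1200L), ncol = 2, byrow = TRUE),
                         cds_start_t = 20L, cds_end_t = 110L, sequence = seq1)
  m2 <- transcript_model("TX2", "G2", "chrZ", "-",
                         matrix(c(5000L, 5150L), ncol = 2),
                         cds_start_t = 10L, cds_end_t = 100L, sequence = seq1)
  dir <- tempfile(); dir.create(dir)
  gtf <- file.path(dir, "m.gtf"); fa <- file.path(dir, "m.fa")
  write_gtf(list(m1, m2), gtf)
  write_transcript_fasta(list(m1, m2), fa)
  back <- read_transcript_models(gtf, fa)
  for (m in list(m1, m2)) {
    b <- back[[m$transcript_id]]
    expect_equal(b$exons, m$exons)
    expect_equal(b$strand, m$strand)
    expect_equal(b$cds_start_t, m$cds_start_t)
    expect_equal(b$cds_end_t, m$cds_end_t)
    expect_equal(b$sequence, m$sequence)
    expect_equal(b$gene_id, m$gene_id)
  }
})

test_that("annotate_sites keeps unassigned sites and breaks gene ties deterministically", {
  m1 <- toy_model(id = "TA", gene = "GB")
  m2 <- toy_model(id = "TB", gene = "GA")  # same span, smaller gene id
  sites <- data.table::data.table(chrom = "chrT", start = c(1100L, 9999L), strand = "+")
  ann <- annotate_sites(sites, list(m1, m2))
  expect_equal(ann$gene_id[1], "GA")
  expect_equal(ann$region[2], "UNASSIGNED")
  expect_true(is.na(ann$tpos[2]))
})
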