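# Transcript models and site annotation: genome<->transcript coordinate
# mapping, region assignment (5'UTR / CDS / 3'UTR / extended 3'UTR), DRACH
# motif classification, and metagene positions on the standard three-segment
# scale. All coordinates 0-based half-open; transcript positions (tpos) run
# 5'->3' in transcript orientation.

REGIONS <- c("FIVE_UTR", "CDS", "THREE_UTR", "THREE_UTR_EXT", "NONCODING", "UNASSIGNED")
MOTIF_CLASSES <- c("DRACH", "NON_DRACH", "UNDEFINED")

#' Construct a transcript model
#'
#' @param transcript_id,gene_id identifiers.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column matrix of genomic exon intervals (0-based
#'   half-open), any row order; stored sorted by genomic start.
#' @param cds_start_t,cds_end_t transcript coordinates (half-open) of the
#'   coding region; both `NA` for noncoding transcripts.
#' @param sequence optional transcript sequence (5'->3', DNA or RNA alphabet);
#'   length must equal the summed exon length.
#' @return an object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons,
                             cds_start_t = NA_integer_, cds_end_t = NA_integer_,
                             sequence = NULL) {
  exons <- matrix(as.integer(exons), ncol = 2)
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  if (any(exons[, 2] <= exons[, 1]))
    stop_validation("transcript %s: empty or inverted exon", transcript_id)
  if (nrow(exons) > 1 && any(exons[-1, 1] < exons[-nrow(exons), 2]))
    stop_validation("transcript %s: overlapping exons", transcript_id)
  if (!strand %in% c("+", "-")) stop_validation("transcript %s: bad strand", transcript_id)
  len <- sum(exons[, 2] - exons[, 1])
  if (!is.na(cds_start_t)) {
    if (is.na(cds_end_t) || cds_start_t < 0 || cds_start_t >= cds_end_t || cds_end_t > len)
      stop_validation("transcript %s: CDS [%s,%s) out of bounds for length %d",
                      transcript_id, cds_start_t, cds_end_t, len)
  }
  if (!is.null(sequence)) {
    sequence <- toupper(chartr("u", "t", as.character(sequence)))
    sequence <- chartr("U", "T", sequence)
    if (nchar(sequence) != len)
      stop_validation("transcript %s: sequence length %d != transcript length %d",
                      transcript_id, nchar(sequence), len)
  }
  structure(list(transcript_id = transcript_id, gene_id = gene_id, chrom = chrom,
                 strand = strand, exons = exons, length = len,
                 cds_start_t = as.integer(cds_start_t), cds_end_t = as.integer(cds_end_t),
                 sequence = sequence),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cds <- if (is.na(x$cds_start_t)) "noncoding" else sprintf("CDS [%d,%d)", x$cds_start_t, x$cds_end_t)
  cat(sprintf("<transcript_model %s (%s) %s:%s %d exon(s), length %d, %s%s>\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand, nrow(x$exons), x$length, cds,
              if (is.null(x$sequence)) "" else ", with sequence"))
  invisible(x)
}

is_coding <- function(t) !is.na(t$cds_start_t)

#' Map a genomic position to a transcript coordinate
#'
#' Returns the 0-based offset of `pos` in transcript orientation, or `NA` for
#' intronic/out-of-range positions or a strand mismatch. With `extension > 0`,
#' positions up to `extension` nt downstream of the annotated transcript end
#' (in transcript orientation) map to `tpos >= length` (the extended 3'UTR
#' window).
#'
#' @param pos genomic position (0-based, single base).
#' @param strand strand of the queried site.
#' @param t a [transcript_model()].
#' @param extension downstream extension in nt (default 0).
#' @return integer tpos or `NA`.
#' @export
genome_to_transcript <- function(pos, strand, t, extension = 0L) {
  if (strand != t$strand) return(NA_integer_)
  ex <- t$exons
  widths <- ex[, 2] - ex[, 1]
  if (t$strand == "+") {
    offs <- cumsum(c(0L, widths))[seq_len(nrow(ex))]
    i <- which(pos >= ex[, 1] & pos < ex[, 2])
    if (length(i)) return(as.integer(offs[i] + (pos - ex[i, 1])))
    dend <- ex[nrow(ex), 2]
    if (extension > 0 && pos >= dend && pos < dend + extension)
      return(as.integer(t$length + (pos - dend)))
  } else {
    ord <- rev(seq_len(nrow(ex)))  # transcript order: genomically last exon first
    offs <- cumsum(c(0L, widths[ord]))[seq_len(nrow(ex))]
    i <- which(pos >= ex[, 1] & pos < ex[, 2])
    if (length(i)) {
      k <- match(i, ord)
      return(as.integer(offs[k] + (ex[i, 2] - 1L - pos)))
    }
    dstart <- ex[1, 1]
    if (extension > 0 && pos < dstart && pos >= dstart - extension)
      return(as.integer(t$length + (dstart - 1L - pos)))
  }
  NA_integer_
}

#' Map a transcript coordinate back to a genomic position
#'
#' Inverse of [genome_to_transcript()] for `0 <= tpos < length + extension`.
#'
#' @inheritParams genome_to_transcript
#' @param tpos transcript coordinate.
#' @return genomic position (0-based).
#' @export
transcript_to_genome <- function(tpos, t, extension = 0L) {
  if (tpos < 0 || tpos >= t$length + extension)
    stop_validation("tpos %d out of range for transcript %s (length %d, extension %d)",
                    tpos, t$transcript_id, t$length, extension)
  ex <- t$exons
  widths <- ex[, 2] - ex[, 1]
  if (t$strand == "+") {
    if (tpos >= t$length) return(as.integer(ex[nrow(ex), 2] + (tpos - t$length)))
    offs <- cumsum(c(0L, widths))
    i <- findInterval(tpos, offs)
    as.integer(ex[i, 1] + (tpos - offs[i]))
  } else {
    if (tpos >= t$length) return(as.integer(ex[1, 1] - 1L - (tpos - t$length)))
    ord <- rev(seq_len(nrow(ex)))
    offs <- cumsum(c(0L, widths[ord]))
    k <- findInterval(tpos, offs)
    i <- ord[k]
    as.integer(ex[i, 2] - 1L - (tpos - offs[k]))
  }
}

#' Assign the transcript region of a site
#'
#' Partitions `[0, length + utr3_extension)` into `FIVE_UTR`, `CDS`,
#' `THREE_UTR` and `THREE_UTR_EXT` for coding transcripts; every tpos of a
#' noncoding transcript maps to `NONCODING`.
#'
#' @param tpos transcript coordinate.
#' @param t a [transcript_model()].
#' @param utr3_extension extension beyond the annotated transcript end in nt.
#' @return region string.
#' @export
assign_region <- function(tpos, t, utr3_extension = 100L) {
  if (tpos < 0 || tpos >= t$length + utr3_extension)
    stop_validation("tpos %d out of range [0, %d) for transcript %s",
                    tpos, t$length + utr3_extension, t$transcript_id)
  if (!is_coding(t)) return("NONCODING")
  if (tpos < t$cds_start_t) "FIVE_UTR"
  else if (tpos < t$cds_end_t) "CDS"
  else if (tpos < t$length) "THREE_UTR"
  else "THREE_UTR_EXT"
}

#' Classify the 5-mer motif context of a transcript position
#'
#' `DRACH` iff the window `[tpos-2, tpos+2]` matches `[AGU][AG]AC[ACU]`
#' (T and U are equivalent); `NON_DRACH` when the central base is A but the
#' pattern fails; `UNDEFINED` when the window is truncated, the sequence is
#' absent, or the central base is not A.
#'
#' @param t a [transcript_model()] with `sequence`.
#' @param tpos transcript coordinate of the central base.
#' @return one of `"DRACH"`, `"NON_DRACH"`, `"UNDEFINED"`.
#' @export
classify_motif <- function(t, tpos) {
  s <- t$sequence
  if (is.null(s) || tpos < 2 || tpos > t$length - 3) return("UNDEFINED")
  w <- substr(s, tpos - 1L, tpos + 3L)  # 1-based window around 0-based tpos
  if (substr(w, 3, 3) != "A") return("UNDEFINED")
  if (grepl("^[AGT][AG]AC[ACT]$", w)) "DRACH" else "NON_DRACH"
}

#' Metagene position on the three-segment transcript scale
#'
#' Each of 5'UTR, CDS and 3'UTR is scaled to unit width; a site at fraction
#' `f` of its region maps to `offset + f` with offsets 0/1/2. `NA` for
#' transcripts missing any region, for noncoding transcripts, and for sites in
#' the extended 3'UTR.
#'
#' @param tpos transcript coordinate.
#' @param t a [transcript_model()].
#' @return numeric in `[0, 3)` or `NA`.
#' @export
metagene_position <- function(tpos, t) {
  if (!is_coding(t)) return(NA_real_)
  u5 <- t$cds_start_t; cl <- t$cds_end_t - t$cds_start_t; u3 <- t$length - t$cds_end_t
  if (u5 < 1 || cl < 1 || u3 < 1) return(NA_real_)
  if (tpos < 0 || tpos >= t$length) return(NA_real_)
  if (tpos < u5) tpos / u5
  else if (tpos < t$cds_end_t) 1 + (tpos - t$cds_start_t) / cl
  else 2 + (tpos - t$cds_end_t) / u3
}

#' Choose the representative transcript of a gene
#'
#' Deterministic: longest CDS, ties broken by longest transcript, remaining
#' ties by lexicographically smallest transcript id.
#'
#' @param transcripts list of [transcript_model()] objects (all one gene).
#' @return the chosen `transcript_model`.
#' @export
choose_representative_transcript <- function(transcripts) {
  if (!length(transcripts)) stop_validation("no transcripts supplied")
  cds_len <- vapply(transcripts, function(t)
    if (is_coding(t)) t$cds_end_t - t$cds_start_t else 0L, integer(1))
  tlen <- vapply(transcripts, function(t) t$length, integer(1))
  ids <- vapply(transcripts, function(t) t$transcript_id, character(1))
  ord <- order(-cds_len, -tlen, ids)
  transcripts[[ord[1]]]
}

#' Representative transcript per gene
#'
#' @param models list of [transcript_model()] objects.
#' @return named list (by gene_id) of representative models.
#' @export
representative_models <- function(models) {
  genes <- vapply(models, function(t) t$gene_id, character(1))
  lapply(split(models, genes), choose_representative_transcript)
}

#' Read transcript models from a GTF (exon + CDS features)
#'
#' @param gtf_path GTF file with `gene_id`/`transcript_id` attributes.
#' @param fasta_path optional FASTA; either per-transcript sequences (names =
#'   transcript ids) or a genome, in which case transcript sequences are
#'   spliced (and reverse-complemented on `-`) internally.
#' @param fasta_is_genome set `TRUE` when `fasta_path` is a genome FASTA.
#' @return list of [transcript_model()] objects.
#' @export
read_transcript_models <- function(gtf_path, fasta_path = NULL, fasta_is_genome = FALSE) {
  gr <- rtracklayer::import(gtf_path)
  df <- as.data.frame(gr)
  df <- df[df$type %in% c("exon", "CDS"), , drop = FALSE]
  if (!nrow(df)) stop_data("GTF %s: no exon/CDS features", gtf_path)
  seqs <- NULL
  if (!is.null(fasta_path)) seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (!is.null(seqs)) names(seqs) <- sub("\\s.*$", "", names(seqs))
  models <- list()
  for (tid in unique(df$transcript_id)) {
    sub <- df[df$transcript_id == tid, , drop = FALSE]
    ex <- sub[sub$type == "exon", , drop = FALSE]
    if (!nrow(ex)) next
    exons <- cbind(ex$start - 1L, ex$end)  # GTF 1-based inclusive -> 0-based half-open
    strand <- as.character(ex$strand[1])
    chrom <- as.character(ex$seqnames[1])
    gene <- ex$gene_id[1]
    m <- transcript_model(tid, gene, chrom, strand, exons)
    cds <- sub[sub$type == "CDS", , drop = FALSE]
    if (nrow(cds)) {
      tpos <- unlist(lapply(seq_len(nrow(cds)), function(i)
        c(genome_to_transcript(cds$start[i] - 1L, strand, m),
          genome_to_transcript(cds$end[i] - 1L, strand, m))))
      tpos <- tpos[!is.na(tpos)]
      if (!length(tpos)) stop_data("GTF %s: CDS of %s outside its exons", gtf_path, tid)
      m$cds_start_t <- as.integer(min(tpos))
      m$cds_end_t <- as.integer(max(tpos) + 1L)
    }
    if (!is.null(seqs)) {
      if (fasta_is_genome) {
        if (!chrom %in% names(seqs))
          stop_data("FASTA %s: missing sequence for %s", fasta_path, chrom)
        pieces <- Biostrings::DNAStringSet(seqs[[chrom]],
                                           start = m$exons[, 1] + 1L, end = m$exons[, 2])
        sq <- Biostrings::DNAStringSet(paste(as.character(pieces), collapse = ""))
        if (strand == "-") sq <- Biostrings::reverseComplement(sq)
        m$sequence <- as.character(sq[[1]])
      } else if (tid %in% names(seqs)) {
        m$sequence <- as.character(seqs[[tid]])
      }
      if (!is.null(m$sequence) && nchar(m$sequence) != m$length)
        stop_data("sequence/annotation length mismatch for %s", tid)
    }
    models[[tid]] <- m
  }
  models
}

#' Annotate genomic sites against representative transcripts
#'
#' Maps each site (by `chrom`, `start`, `strand`) onto the representative
#' transcript of each gene, assigning transcript position, region, motif class
#' and metagene position. Sites falling in no representative transcript (nor
#' its extended 3'UTR window) are retained with `region = "UNASSIGNED"`.
#' When representative transcripts of several genes overlap a site, the gene
#' with the lexicographically smallest id wins (deterministic).
#'
#' @param sites data.table with at least `chrom`, `start`, `strand`.
#' @param models list of [transcript_model()] objects (all isoforms; the
#'   representative per gene is chosen internally) or the output of
#'   [representative_models()].
#' @param utr3_extension nt of extension beyond the transcript end treated as
#'   `THREE_UTR_EXT` (default 100).
#' @return copy of `sites` with columns `transcript_id, gene_id, tpos, region,
#'   motif_class, metagene_x` appended.
#' @export
annotate_sites <- function(sites, models, utr3_extension = 100L) {
  sites <- data.table::as.data.table(sites)
  reps <- if (!is.null(names(models)) &&
              all(vapply(models, function(m) inherits(m, "transcript_model"), TRUE)) &&
              identical(names(models), vapply(models, function(m) m$gene_id, character(1))))
    models else representative_models(models)
  reps <- unname(reps)
  idx <- exon_index(reps, utr3_extension)
  key <- unique(sites[, c("chrom", "start", "strand"), with = FALSE])
  q <- data.table::data.table(chrom = key$chrom, strand = key$strand,
                              gstart = key$start, gend = key$start + 1L,
                              site_i = seq_len(nrow(key)))
  data.table::setkey(idx, chrom, strand, gstart, gend)
  hits <- data.table::foverlaps(q, idx, type = "within", nomatch = NULL)
  ann <- data.table::data.table(chrom = key$chrom, start = key$start, strand = key$strand,
                                transcript_id = NA_character_, gene_id = NA_character_,
                                tpos = NA_integer_, region = "UNASSIGNED",
                                motif_class = "UNDEFINED", metagene_x = NA_real_)
  if (nrow(hits)) {
    hits[, tpos := ifelse(strand == "+",
                          toff + (i.gstart - gstart),
                          toff + (gend - 1L - i.gstart))]
    # one winner per site: smallest gene_id, then smallest transcript_id
    data.table::setorder(hits, site_i, gene_id, transcript_id)
    hits <- hits[!duplicated(hits$site_i)]
    mdl <- model_table(reps)
    hits <- merge(hits, mdl, by = "transcript_id", sort = FALSE)
    hits[, region := data.table::fcase(
      is.na(cds_start_t), "NONCODING",
      tpos < cds_start_t, "FIVE_UTR",
      tpos < cds_end_t, "CDS",
      tpos < tlen, "THREE_UTR",
      default = "THREE_UTR_EXT")]
    win <- ifelse(hits$tpos >= 2 & hits$tpos <= hits$tlen - 3 & !is.na(hits$seq),
                  substr(hits$seq, hits$tpos - 1L, hits$tpos + 3L), NA_character_)
    hits[, motif_class := ifelse(is.na(win), "UNDEFINED",
                          ifelse(substr(win, 3, 3) != "A", "UNDEFINED",
                          ifelse(grepl("^[AGT][AG]AC[ACT]$", win), "DRACH", "NON_DRACH")))]
    u5 <- hits$cds_start_t; cl <- hits$cds_end_t - hits$cds_start_t
    u3 <- hits$tlen - hits$cds_end_t
    mg <- ifelse(is.na(u5) | u5 < 1 | cl < 1 | u3 < 1 | hits$tpos >= hits$tlen, NA_real_,
          ifelse(hits$tpos < u5, hits$tpos / u5,
          ifelse(hits$tpos < hits$cds_end_t, 1 + (hits$tpos - u5) / cl,
                 2 + (hits$tpos - hits$cds_end_t) / u3)))
    hits[, metagene_x := mg]
    for (col in c("transcript_id", "gene_id", "tpos", "region", "motif_class", "metagene_x"))
      data.table::set(ann, hits$site_i, col, hits[[col]])
  }
  merged <- merge(sites, ann, by = c("chrom", "start", "strand"), sort = FALSE)
  merged[]
}

# flat interval index over exons plus the downstream extension window
exon_index <- function(reps, utr3_extension) {
  parts <- lapply(reps, function(m) {
    ex <- m$exons
    w <- ex[, 2] - ex[, 1]
    if (m$strand == "+") {
      toff <- cumsum(c(0L, w))[seq_len(nrow(ex))]
      gs <- ex[, 1]; ge <- ex[, 2]
      if (utr3_extension > 0) {
        gs <- c(gs, ex[nrow(ex), 2]); ge <- c(ge, ex[nrow(ex), 2] + utr3_extension)
        toff <- c(toff, m$length)
      }
    } else {
      ord <- rev(seq_len(nrow(ex)))
      toff_t <- cumsum(c(0L, w[ord]))[seq_len(nrow(ex))]
      toff <- toff_t[match(seq_len(nrow(ex)), ord)]
      gs <- ex[, 1]; ge <- ex[, 2]
      if (utr3_extension > 0) {
        gs <- c(gs, ex[1, 1] - utr3_extension); ge <- c(ge, ex[1, 1])
        toff <- c(toff, m$length)
      }
    }
    data.table::data.table(chrom = m$chrom, strand = m$strand,
                           gstart = as.integer(gs), gend = as.integer(ge),
                           toff = as.integer(toff),
                           transcript_id = m$transcript_id, gene_id = m$gene_id)
  })
  data.table::rbindlist(parts)
}

model_table <- function(reps) {
  data.table::data.table(
    transcript_id = vapply(reps, function(m) m$transcript_id, character(1)),
    tlen = vapply(reps, function(m) m$length, integer(1)),
    cds_start_t = vapply(reps, function(m) m$cds_start_t %||% NA_integer_, integer(1)),
    cds_end_t = vapply(reps, function(m) m$cds_end_t %||% NA_integer_, integer(1)),
    seq = vapply(reps, function(m) m$sequence %||% NA_character_, character(1)))
}

#' Write transcript models as GTF (exon + CDS features)
#'
#' @param models list of [transcript_model()] objects.
#' @param path output GTF path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path) {
  rows <- character(0)
  for (m in models) {
    attr_str <- sprintf('gene_id "%s"; transcript_id "%s";', m$gene_id, m$transcript_id)
    for (i in seq_len(nrow(m$exons)))
      rows <- c(rows, paste(m$chrom, "m6Aland", "exon", m$exons[i, 1] + 1L, m$exons[i, 2],
                            ".", m$strand, ".", attr_str, sep = "\t"))
    if (is_coding(m)) {
      # map the CDS transcript interval back to genomic blocks exon by exon
      for (tp in split_blocks(m$cds_start_t, m$cds_end_t, m)) {
        rows <- c(rows, paste(m$chrom, "m6Aland", "CDS", tp[1] + 1L, tp[2],
                              ".", m$strand, "0", attr_str, sep = "\t"))
      }
    }
  }
  writeLines(rows, path)
  invisible(path)
}

# genomic blocks covered by the transcript interval [t0, t1)
split_blocks <- function(t0, t1, m) {
  gpos <- vapply(t0:(t1 - 1L), transcript_to_genome, integer(1), t = m)
  gpos <- sort(gpos)
  brk <- which(diff(gpos) != 1L)
  starts <- gpos[c(1L, brk + 1L)]
  ends <- gpos[c(brk, length(gpos))] + 1L
  Map(c, starts, ends)
}

#' Write transcript sequences as FASTA
#' @param models list of [transcript_model()] objects carrying sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_transcript_fasta <- function(models, path) {
  keep <- Filter(function(m) !is.null(m$sequence), models)
  ss <- Biostrings::DNAStringSet(vapply(keep, function(m) m$sequence, character(1)))
  names(ss) <- vapply(keep, function(m) m$transcript_id, character(1))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
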