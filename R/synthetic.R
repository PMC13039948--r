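# Synthetic-data generator: emulates the processed per-site layer of a
# direct RNA-seq m6A experiment (tumor vs normal brain culture, plus a
# demethylase-inhibitor treated vs untreated pair) at desk scale. Every
# output is a pure function of (config, seed); sub-seeds are derived
# deterministically per stage.
#
# The stated world: stoichiometry is a mixture of a near-zero mass and a Beta
# methylated component at DRACH motifs, enriched near the stop codon; tumor
# gains m6A at DRACH CDS/3'UTR sites of a hypermethylated gene fraction and
# loses it at a planted "cell-cycle-like" gene set; treatment restores a
# fraction of the lost sites (full restoration by default). Coverage is
# negative-binomial per site x replicate; modified counts are binomial at the
# true stoichiometry (no extra site-level overdispersion).

#' Synthetic corpus configuration
#'
#' All generator parameters with desk-scale defaults. Fractions are in
#' `[0, 1]`; deltas are clamped so stoichiometries stay in `[0, 1]`.
#'
#' @param n_genes number of genes (one representative transcript each).
#' @param replicates biological replicates per condition.
#' @param utr5_range,cds_range,utr3_range min/max region lengths (nt).
#' @param max_exons exons per transcript are drawn uniformly from
#'   `1:max_exons`.
#' @param mean_drach_sites_per_gene Poisson mean of DRACH site count per gene
#'   (at least 1 site is always planted).
#' @param mean_non_drach_sites_per_gene Poisson mean of non-DRACH A sites.
#' @param frac_near_stop fraction of DRACH sites placed within
#'   `near_stop_window` nt downstream of the CDS end (the stop-codon
#'   enrichment of the metagene profile).
#' @param near_stop_window width of the stop-proximal window (nt, 3'UTR side).
#' @param region_weights placement weights for the remaining DRACH sites over
#'   `FIVE_UTR`/`CDS`/`THREE_UTR`.
#' @param zero_mass probability a background DRACH site draws from the
#'   near-zero stoichiometry component.
#' @param beta_meth,beta_low shape parameters `c(a, b)` of the methylated and
#'   near-zero Beta components.
#' @param hyper_gene_fraction,hyper_delta fraction of genes hypermethylated in
#'   tumor and the stoichiometry gain at their DRACH CDS/3'UTR sites.
#' @param hypo_gene_set_size,hypo_delta size of the planted hypomethylated
#'   gene set and the tumor stoichiometry loss at their DRACH sites.
#' @param restoration_fraction fraction of hypo-gene DRACH sites whose m6A is
#'   restored under treatment.
#' @param restoration_delta stoichiometry gain at restored sites in the
#'   treated condition; `NULL` (default) means full restoration
#'   (`hypo_delta`).
#' @param coverage_mean,coverage_dispersion negative-binomial coverage model
#'   (`mu` and `size`) per site, replicate and condition.
#' @param read_depth reads per transcript for the read-level table.
#' @param read_condition condition whose stoichiometries drive the read-level
#'   table.
#' @param de_lines synthetic cell-line labels for the DE tables.
#' @param p_down_given_gain,p_up_given_gain proportion of net-m6A-gain genes
#'   planted as significantly down-/up-regulated.
#' @param n_up_core number of planted commonly upregulated genes.
#' @param n_private_per_line per-line private significant genes per direction.
#' @param binding_down_fraction,binding_up_fraction fraction of
#'   common-down/common-up genes receiving reader-binding intervals over
#'   their DRACH sites.
#' @param binding_halfwidth half-width of each binding interval (nt).
#' @param binding_source label of the synthetic binding-site set.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 1000L,
                             replicates = 2L,
                             utr5_range = c(100L, 300L),
                             cds_range = c(300L, 1500L),
                             utr3_range = c(200L, 800L),
                             max_exons = 3L,
                             mean_drach_sites_per_gene = 6,
                             mean_non_drach_sites_per_gene = 2,
                             frac_near_stop = 0.7,
                             near_stop_window = 50L,
                             region_weights = c(FIVE_UTR = 0.1, CDS = 0.4, THREE_UTR = 0.5),
                             zero_mass = 0.2,
                             beta_meth = c(2, 2),
                             beta_low = c(1, 30),
                             hyper_gene_fraction = 0.2,
                             hyper_delta = 0.25,
                             hypo_gene_set_size = 100L,
                             hypo_delta = 0.25,
                             restoration_fraction = 0.25,
                             restoration_delta = NULL,
                             coverage_mean = 30,
                             coverage_dispersion = 10,
                             read_depth = 100L,
                             read_condition = "tumor",
                             de_lines = c("lineA", "lineB", "lineC"),
                             p_down_given_gain = 0.8,
                             p_up_given_gain = 0.05,
                             n_up_core = 50L,
                             n_private_per_line = 30L,
                             binding_down_fraction = 0.5,
                             binding_up_fraction = 0.05,
                             binding_halfwidth = 25L,
                             binding_source = "synthetic_reader") {
  cfg <- as.list(environment())
  cfg$restoration_delta <- restoration_delta %||% hypo_delta
  fr <- c(frac_near_stop, zero_mass, hyper_gene_fraction, restoration_fraction,
          p_down_given_gain, p_up_given_gain, binding_down_fraction, binding_up_fraction)
  if (any(fr < 0 | fr > 1)) stop_validation("all fractions must lie in [0,1]")
  if (min(utr5_range, cds_range, utr3_range) < 5)
    stop_validation("region lengths must be >= 5 nt")
  if (hypo_gene_set_size + round(hyper_gene_fraction * n_genes) > n_genes)
    stop_validation("hyper and hypo gene sets exceed the gene universe")
  structure(cfg, class = "synthetic_config")
}

CONDITIONS <- c("normal", "tumor", "treated", "untreated")

gene_ids <- function(n) sprintf("G%04d", seq_len(n))

#' Generate synthetic transcript annotation (models, GTF, FASTA)
#'
#' One representative transcript per gene on a synthetic chromosome, with
#' planted DRACH 5-mers at designated site positions and planted non-DRACH A
#' contexts elsewhere; the background sequence contains no other adenosines,
#' so every A in the transcriptome is a designed site context. Writes
#' round-trippable GTF and transcript FASTA when `dir` is given.
#'
#' @param config a [synthetic_config()].
#' @param seed master seed (integer).
#' @param dir optional output directory for `annotation.gtf` /
#'   `transcripts.fa`.
#' @return list with `models` (transcript models), `sites` (truth table:
#'   `gene_id, transcript_id, chrom, strand, gpos, tpos, region, motif_class,
#'   near_stop`) and `files`.
#' @export
generate_annotation <- function(config, seed, dir = NULL) {
  set.seed(derive_seed(seed, "annotation"))
  n <- config$n_genes
  ids <- gene_ids(n)
  models <- vector("list", n)
  site_rows <- vector("list", n)
  cursor <- 1000L  # genomic placement cursor on the synthetic chromosome
  chrom <- "chrS1"
  for (i in seq_len(n)) {
    u5 <- sample(config$utr5_range[1]:config$utr5_range[2], 1)
    cds <- sample(config$cds_range[1]:config$cds_range[2], 1)
    u3 <- sample(config$utr3_range[1]:config$utr3_range[2], 1)
    len <- u5 + cds + u3
    cds_start <- u5; cds_end <- u5 + cds
    # site positions on a 5-nt grid so planted 5-mers never overlap
    grid <- seq(2L, len - 5L, by = 5L)
    n_dr <- max(1L, stats::rpois(1, config$mean_drach_sites_per_gene))
    n_nd <- stats::rpois(1, config$mean_non_drach_sites_per_gene)
    near <- stats::rbinom(n_dr, 1, config$frac_near_stop) == 1
    win_hi <- cds_end + min(config$near_stop_window, u3)
    pool_near <- grid[grid >= cds_end & grid < win_hi]
    pool_reg <- list(FIVE_UTR = grid[grid < cds_start],
                     CDS = grid[grid >= cds_start & grid < cds_end],
                     THREE_UTR = grid[grid >= win_hi & grid < len - 5L])
    pos_dr <- integer(0)
    n_near <- min(sum(near), length(pool_near))
    if (n_near > 0) pos_dr <- sample_int(pool_near, n_near)
    n_rest <- n_dr - n_near
    if (n_rest > 0) {
      regs <- sample(names(config$region_weights), n_rest, replace = TRUE,
                     prob = config$region_weights)
      for (rg in names(config$region_weights)) {
        k <- sum(regs == rg)
        pool <- setdiff(pool_reg[[rg]], pos_dr)
        if (k > 0 && length(pool)) pos_dr <- c(pos_dr, sample_int(pool, min(k, length(pool))))
      }
    }
    pool_nd <- setdiff(grid, pos_dr)
    pos_nd <- if (n_nd > 0 && length(pool_nd)) sample_int(pool_nd, min(n_nd, length(pool_nd))) else integer(0)
    # background without adenosines; plant motif 5-mers centred on each site
    seq_chars <- sample(c("C", "G", "T"), len, replace = TRUE)
    for (p in pos_dr) {
      motif <- c(sample(c("G", "T"), 1), sample(c("A", "G"), 1), "A", "C",
                 sample(c("C", "T"), 1))
      seq_chars[(p - 1):(p + 3)] <- motif
    }
    for (p in pos_nd) seq_chars[(p - 1):(p + 3)] <- c("C", "G", "A", "C", "C")
    strand <- sample(c("+", "-"), 1)
    # 1..max_exons exons: cut the transcript at random points, insert introns
    n_ex <- sample.int(config$max_exons, 1)
    cuts <- if (n_ex > 1) sort(sample(seq(50L, len - 50L, by = 10L), n_ex - 1)) else integer(0)
    bounds <- cbind(c(0L, cuts), c(cuts, len))  # transcript-space exon chunks
    introns <- if (n_ex > 1) sample(80:400, n_ex - 1, replace = TRUE) else integer(0)
    gstart <- cursor
    exons <- matrix(0L, nrow = n_ex, ncol = 2)
    gp <- gstart
    for (e in seq_len(n_ex)) {
      w <- bounds[e, 2] - bounds[e, 1]
      exons[e, ] <- c(gp, gp + w)
      gp <- gp + w + if (e < n_ex) introns[e] else 0L
    }
    if (strand == "-") {
      # mirror so that transcript 5'->3' runs genomically right-to-left
      total <- gp - gstart
      exons <- cbind(2L * gstart + total - exons[, 2], 2L * gstart + total - exons[, 1])
      exons <- exons[order(exons[, 1]), , drop = FALSE]
    }
    cursor <- gp + 1000L
    m <- transcript_model(sprintf("T%04d", i), ids[i], chrom, strand, exons,
                          cds_start_t = cds_start, cds_end_t = cds_end,
                          sequence = paste(seq_chars, collapse = ""))
    models[[i]] <- m
    tpos_all <- c(pos_dr, pos_nd)
    if (length(tpos_all)) {
      gpos <- vapply(tpos_all, transcript_to_genome, integer(1), t = m)
      site_rows[[i]] <- data.table::data.table(
        gene_id = ids[i], transcript_id = m$transcript_id, chrom = chrom,
        strand = strand, gpos = gpos, tpos = tpos_all,
        region = vapply(tpos_all, assign_region, character(1), t = m,
                        utr3_extension = 0L),
        motif_class = c(rep("DRACH", length(pos_dr)), rep("NON_DRACH", length(pos_nd))),
        near_stop = c(pos_dr >= cds_end & pos_dr < win_hi, rep(FALSE, length(pos_nd))))
    }
  }
  names(models) <- vapply(models, function(m) m$transcript_id, character(1))
  sites <- data.table::rbindlist(site_rows)
  data.table::setorder(sites, gene_id, tpos)
  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- list(gtf = file.path(dir, "annotation.gtf"),
                  fasta = file.path(dir, "transcripts.fa"))
    write_gtf(models, files$gtf)
    write_transcript_fasta(models, files$fasta)
  }
  list(models = models, sites = sites, files = files)
}

# sample() without the size-1 surprise
sample_int <- function(pool, k) {
  if (length(pool) == 1) return(pool[seq_len(min(k, 1))])
  sample(pool, k)
}

#' Generate per-site modification pileups for all conditions
#'
#' Computes the true per-condition stoichiometry field from the annotation
#' truth (baseline mixture + planted tumor hyper/hypo effects + treatment
#' restoration), then draws coverage (negative binomial) and modified counts
#' (binomial) independently per replicate and emits 18-column pileups.
#'
#' @param annotation result of [generate_annotation()].
#' @param config a [synthetic_config()].
#' @param seed master seed.
#' @param dir optional output directory for
#'   `pileup_<condition>_rep<k>.bed` files and `truth_sites.tsv`.
#' @return list with `truth` (site table with per-condition stoichiometries
#'   and planted labels), `gene_labels`, `records` (nested list
#'   `records[[condition]][[replicate]]` of site-record tables) and `files`.
#' @export
generate_site_counts <- function(annotation, config, seed, dir = NULL) {
  set.seed(derive_seed(seed, "site_counts"))
  truth <- data.table::copy(annotation$sites)
  ids <- gene_ids(config$n_genes)
  n_hyper <- round(config$hyper_gene_fraction * config$n_genes)
  hyper_genes <- sample(ids, n_hyper)
  hypo_genes <- sample(setdiff(ids, hyper_genes), config$hypo_gene_set_size)
  truth[, hyper_gene := gene_id %in% hyper_genes]
  truth[, hypo_gene := gene_id %in% hypo_genes]
  n_s <- nrow(truth)
  base <- numeric(n_s)
  is_dr <- truth$motif_class == "DRACH"
  hypo_dr <- is_dr & truth$hypo_gene
  hyper_site <- is_dr & truth$hyper_gene & truth$region %in% c("CDS", "THREE_UTR")
  bg_dr <- is_dr & !truth$hypo_gene
  lowc <- stats::rbinom(n_s, 1, config$zero_mass) == 1
  base[bg_dr & !lowc] <- stats::rbeta(sum(bg_dr & !lowc), config$beta_meth[1], config$beta_meth[2])
  base[bg_dr & lowc] <- stats::rbeta(sum(bg_dr & lowc), config$beta_low[1], config$beta_low[2])
  # planted effects are exact: baselines at effect sites are rescaled so that
  # adding/subtracting the delta never clamps (hyper methylated component into
  # [0, 1 - hyper_delta]; hypo baselines into [hypo_delta, 1])
  resc <- hyper_site & !lowc
  base[resc] <- base[resc] * (1 - config$hyper_delta)
  base[hypo_dr] <- config$hypo_delta +
    (1 - config$hypo_delta) * stats::rbeta(sum(hypo_dr), config$beta_meth[1], config$beta_meth[2])
  base[!is_dr] <- stats::rbeta(sum(!is_dr), config$beta_low[1], config$beta_low[2])
  truth[, stoich_normal := base]
  tumor <- base
  tumor[hyper_site] <- clamp01(tumor[hyper_site] + config$hyper_delta)
  tumor[hypo_dr] <- clamp01(tumor[hypo_dr] - config$hypo_delta)
  truth[, hyper_site := hyper_site]
  truth[, hypo_site := hypo_dr]
  truth[, stoich_tumor := tumor]
  truth[, stoich_untreated := tumor]
  restored <- hypo_dr & stats::rbinom(n_s, 1, config$restoration_fraction) == 1
  treated <- tumor
  treated[restored] <- clamp01(treated[restored] + config$restoration_delta)
  truth[, restored := restored]
  truth[, stoich_treated := treated]
  records <- list()
  files <- list()
  if (!is.null(dir)) dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (cond in CONDITIONS) {
    records[[cond]] <- list()
    s_true <- truth[[paste0("stoich_", cond)]]
    for (rep_i in seq_len(config$replicates)) {
      set.seed(derive_seed(seed, paste0("counts_", cond), rep_i))
      cov <- stats::rnbinom(n_s, size = config$coverage_dispersion, mu = config$coverage_mean)
      nm <- stats::rbinom(n_s, cov, s_true)
      sid <- sprintf("%s_rep%d", cond, rep_i)
      rec <- data.table::data.table(
        chrom = truth$chrom, start = truth$gpos, end = truth$gpos + 1L,
        strand = truth$strand, mod_code = "a", valid_cov = cov, n_mod = nm,
        level = ifelse(cov > 0, nm / cov, NA_real_),
        sample_id = sid, condition = cond)
      records[[cond]][[rep_i]] <- rec
      if (!is.null(dir)) {
        f <- file.path(dir, sprintf("pileup_%s_rep%d.bed", cond, rep_i))
        write_pileup(rec, f)
        files[[sid]] <- f
      }
    }
  }
  if (!is.null(dir)) {
    tf <- file.path(dir, "truth_sites.tsv")
    write_tsv_meta(truth, tf, meta = list(seed = seed, config_hash = hash_object(unclass(config))))
    files$truth <- tf
  }
  list(truth = truth, records = records,
       gene_labels = data.table::data.table(
         gene_id = ids, hyper = ids %in% hyper_genes, hypo = ids %in% hypo_genes),
       files = files)
}

#' Generate a read-level modification table
#'
#' For each transcript, `read_depth` reads; each read queries every site of
#' the transcript and is modified at a site independently with probability
#' equal to that site's stoichiometry in `condition`. A transcript with
#' per-site stoichiometries `s_i` therefore has expected modified-read
#' fraction `1 - prod(1 - s_i)`.
#'
#' @param truth site truth table carrying `transcript_id` and a
#'   `stoich_<condition>` column ([generate_site_counts()]), or any table
#'   with `transcript_id` and `stoich` columns.
#' @param config a [synthetic_config()] (uses `read_depth`,
#'   `read_condition`).
#' @param seed master seed.
#' @param dir optional output directory for `read_level.tsv`.
#' @return data.table `read_id, transcript_id, n_called_A, n_mod`.
#' @export
generate_read_level <- function(truth, config, seed, dir = NULL) {
  set.seed(derive_seed(seed, "read_level"))
  tr <- data.table::as.data.table(truth)
  scol <- if ("stoich" %in% names(tr)) "stoich" else paste0("stoich_", config$read_condition)
  if (!scol %in% names(tr)) stop_validation("truth lacks a stoichiometry column ('%s')", scol)
  out <- tr[, {
    s <- .SD[[scol]]
    k <- length(s)
    nr <- config$read_depth
    mods <- matrix(stats::runif(k * nr) < s, nrow = k)
    list(read_id = sprintf("%s_r%04d", .BY[[1]], seq_len(nr)),
         n_called_A = k, n_mod = as.integer(colSums(mods)))
  }, by = "transcript_id"]
  data.table::setcolorder(out, c("read_id", "transcript_id", "n_called_A", "n_mod"))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    data.table::fwrite(out, file.path(dir, "read_level.tsv"), sep = "\t")
  }
  out[]
}

#' Generate DE tables for synthetic cell lines and reader-binding intervals
#'
#' Net-m6A-gain genes (hypo genes with at least one restored site) are
#' partitioned deterministically (sorted order) into a commonly downregulated
#' core (`p_down_given_gain`), a small upregulated slice (`p_up_given_gain`),
#' and non-significant remainder; a commonly upregulated core is taken from
#' unaffected genes. Each line adds seeded private significant genes. Binding
#' intervals are placed over the DRACH sites of a deterministic fraction of
#' the common cores. Changing `seed` changes fold-change noise and private
#' sets but never the planted cores.
#'
#' @param counts result of [generate_site_counts()].
#' @param config a [synthetic_config()].
#' @param seed master seed.
#' @param dir optional output directory (`de_<line>.tsv`, `binding.bed`,
#'   `truth_genes.tsv`).
#' @return list with `de` (named list of DE tables), `binding` (interval
#'   table), `truth` (per-gene planted labels: `down_core, up_core, gain,
#'   bound`), `files`.
#' @export
generate_de_and_binding <- function(counts, config, seed, dir = NULL) {
  set.seed(derive_seed(seed, "de_binding"))
  truth <- counts$truth
  ids <- counts$gene_labels$gene_id
  gain <- sort(unique(truth[restored == TRUE, gene_id]))
  n_down <- round(config$p_down_given_gain * length(gain))
  n_upg <- round(config$p_up_given_gain * length(gain))
  down_core <- gain[seq_len(n_down)]
  up_from_gain <- gain[seq_len(min(length(gain), n_down + n_upg))][-seq_len(n_down)]
  unaffected <- sort(setdiff(ids, c(unique(truth[hyper_gene == TRUE, gene_id]),
                                    unique(truth[hypo_gene == TRUE, gene_id]))))
  up_core <- c(up_from_gain, utils::head(unaffected, config$n_up_core))
  de <- list()
  for (li in seq_along(config$de_lines)) {
    line <- config$de_lines[li]
    set.seed(derive_seed(seed, "de_line", li))
    lfc <- stats::rnorm(length(ids), 0, 0.3)
    fdr <- stats::runif(length(ids), 0.05, 1)
    i_dn <- match(down_core, ids)
    lfc[i_dn] <- -stats::runif(length(i_dn), 1, 3)
    fdr[i_dn] <- 10^-stats::runif(length(i_dn), 3, 8)
    i_up <- match(up_core, ids)
    lfc[i_up] <- stats::runif(length(i_up), 1, 3)
    fdr[i_up] <- 10^-stats::runif(length(i_up), 3, 8)
    pool <- setdiff(ids, c(down_core, up_core))
    priv_dn <- sample(pool, config$n_private_per_line)
    priv_up <- sample(setdiff(pool, priv_dn), config$n_private_per_line)
    lfc[match(priv_dn, ids)] <- -stats::runif(length(priv_dn), 1, 3)
    fdr[match(priv_dn, ids)] <- 10^-stats::runif(length(priv_dn), 3, 8)
    lfc[match(priv_up, ids)] <- stats::runif(length(priv_up), 1, 3)
    fdr[match(priv_up, ids)] <- 10^-stats::runif(length(priv_up), 3, 8)
    de[[line]] <- data.table::data.table(gene_id = ids, log2fc = lfc, fdr = fdr,
                                         cell_line = line)
  }
  n_bd <- round(config$binding_down_fraction * length(down_core))
  n_bu <- round(config$binding_up_fraction * length(up_core))
  bound_genes <- c(down_core[seq_len(n_bd)], up_core[seq_len(n_bu)])
  bsites <- truth[gene_id %in% bound_genes & motif_class == "DRACH"]
  binding <- data.table::data.table(
    chrom = bsites$chrom,
    start = pmax(0L, bsites$gpos - config$binding_halfwidth),
    end = bsites$gpos + config$binding_halfwidth + 1L,
    strand = ".", source_label = config$binding_source)
  gene_truth <- data.table::data.table(
    gene_id = ids,
    down_core = ids %in% down_core, up_core = ids %in% up_core,
    gain = ids %in% gain, bound = ids %in% bound_genes)
  files <- list()
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (line in names(de)) {
      f <- file.path(dir, sprintf("de_%s.tsv", line))
      data.table::fwrite(de[[line]][, c("gene_id", "log2fc", "fdr"), with = FALSE],
                         f, sep = "\t")
      files[[paste0("de_", line)]] <- f
    }
    files$binding <- file.path(dir, "binding.bed")
    write_binding_bed(binding, files$binding)
    files$truth_genes <- file.path(dir, "truth_genes.tsv")
    write_tsv_meta(gene_truth, files$truth_genes, meta = list(seed = seed))
  }
  list(de = de, binding = binding, truth = gene_truth, files = files)
}

#' Generate the full synthetic corpus
#'
#' Runs annotation, site counts, read-level and DE/binding generation with
#' deterministic sub-seeds and (optionally) writes every external file the
#' pipeline consumes.
#'
#' @param config a [synthetic_config()].
#' @param seed master seed.
#' @param dir optional output directory.
#' @return list `annotation, counts, reads, de_binding, files`.
#' @export
generate_corpus <- function(config, seed, dir = NULL) {
  ann <- generate_annotation(config, seed, dir = dir)
  cnt <- generate_site_counts(ann, config, seed, dir = dir)
  rds <- generate_read_level(cnt$truth, config, seed, dir = dir)
  deb <- generate_de_and_binding(cnt, config, seed, dir = dir)
  list(annotation = ann, counts = cnt, reads = rds, de_binding = deb,
       files = c(ann$files, cnt$files, deb$files))
}
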