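#' Configuration for the synthetic study generator
#'
#' Defaults describe the study conditions the pipeline is validated under:
#' three timepoints (D0/D2/D6) with two replicates each, a bimodal
#' log2-FPKM expression mixture (active mode N(5, 1.5^2); silent mode
#' N(-4, 1) plus a point mass at exactly 0), ~28% active genes at D0,
#' replicate noise of 0.25 on the log2 scale, planted promoter/gene-body
#' mark occupancy with gain/loss dynamics, planted co-factor complexes at
#' promoters (75% of active promoters triple-bound), and enhancers defined
#' by overlapping H3K4me1/H3K27ac peak pairs, 46% of them
#' TFAP2C/LSD1-bound.
#'
#' @param seed integer parent seed; a fixed seed gives byte-identical output
#' @param n_chroms,chrom_length genome shape
#' @param n_genes genes to place (>= 10 kb spacing, log-normal lengths with
#'   median 20 kb)
#' @param frac_active_d0 fraction of genes transcriptionally active at D0
#' @param active_mean,active_sd,silent_mean,silent_sd log2-FPKM mixture modes
#' @param silent_zero_mass fraction of silent genes reported as exactly
#'   FPKM 0 (undetected) rather than the low mode
#' @param replicate_noise_sd per-replicate log2 noise
#' @param activity_flip_prob per-phase probability a gene switches
#'   active/silent (these switches are the large-effect planted DEGs)
#' @param active_deg_prob per-phase probability a stably active gene is
#'   planted as an up (and, independently, down) DEG
#' @param deg_shift log2 shift for planted active-gene DEGs; must exceed
#'   log2(fold threshold) + 3 * replicate_noise_sd so calls are recoverable
#' @param mark_flip_prob per-phase probability a mark's presence flips
#' @param frac_silent_jmjd2b,frac_cobound_k9,persist_frac occupancy cascade
#'   at D0: fraction of silent genes JMJD2B-bound, fraction of those also
#'   H3K9me3-marked, and the fraction of co-enriched silent genes forced to
#'   persist (marks and silence) through D6
#' @param triple_bound_active fraction of active promoters bound by all of
#'   JMJD2B, TFAP2C and LSD1
#' @param peak_width_mean,peak_width_sd planted peak width distribution (bp)
#' @param n_enhancers,enhancer_cobinding intergenic enhancer loci and the
#'   fraction of them TFAP2C+LSD1 co-bound
#' @param n_decoys background (non-planted) peaks per factor/timepoint,
#'   placed in intergenic space with weak q-values
#' @param frac_noncoding fraction of genes annotated noncoding
#' @return list of class `sim_config`
#' @export
simulate_config <- function(seed = 1L, n_chroms = 2L, chrom_length = 3e7,
                            n_genes = 1500L, frac_active_d0 = 0.28,
                            active_mean = 5, active_sd = 1.5,
                            silent_mean = -4, silent_sd = 1,
                            silent_zero_mass = 0.85,
                            replicate_noise_sd = 0.25,
                            activity_flip_prob = 0.05,
                            active_deg_prob = 0.1, deg_shift = 1.5,
                            mark_flip_prob = 0.15,
                            frac_silent_jmjd2b = 0.36,
                            frac_cobound_k9 = 0.61,
                            persist_frac = 0.4,
                            triple_bound_active = 0.75,
                            peak_width_mean = 400, peak_width_sd = 100,
                            n_enhancers = 200L, enhancer_cobinding = 0.46,
                            n_decoys = 500L, frac_noncoding = 0.3) {
  cfg <- as.list(environment())
  fracs <- c(frac_active_d0, silent_zero_mass, activity_flip_prob,
             active_deg_prob, mark_flip_prob, frac_silent_jmjd2b,
             frac_cobound_k9, persist_frac, triple_bound_active,
             enhancer_cobinding, frac_noncoding)
  if (any(fracs < 0 | fracs > 1)) stop_fmt("fractions must lie in [0, 1]")
  if (deg_shift <= log2(1.5) + 3 * replicate_noise_sd)
    stop_fmt("deg_shift too small for recoverable DEG calls")
  structure(cfg, class = "sim_config")
}

#' Simulate the toy genome and gene annotation
#'
#' Genes are placed left to right on alternating strands with 10-14 kb
#' spacing and log-normal lengths (median 20 kb, min 2 kb), keeping every
#' promoter window inside the chromosome. Errors if the genome cannot hold
#' the requested gene count.
#'
#' @param config a [simulate_config()]
#' @param seed optional seed (set by [simulate_study()] normally)
#' @return list with `sizes` (named lengths) and `genes` (`GRanges` with
#'   `gene_id`, `biotype`)
#' @export
simulate_genome <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sizes <- setNames(rep(as.integer(config$chrom_length), config$n_chroms),
                    paste0("chr", seq_len(config$n_chroms)))
  lens <- pmax(2000, round(rlnorm(config$n_genes, log(20000), 0.5)))
  gaps <- round(runif(config$n_genes, 10000, 14000))
  chrom <- character(config$n_genes)
  start <- integer(config$n_genes)
  ci <- 1L; pos <- 10000L
  for (i in seq_len(config$n_genes)) {
    s <- pos + gaps[i]
    if (s + lens[i] + 4000 > sizes[ci]) {
      ci <- ci + 1L
      if (ci > length(sizes))
        stop_fmt("genome too small for %d genes at the required spacing",
                 config$n_genes)
      pos <- 10000L
      s <- pos + gaps[i]
      if (s + lens[i] + 4000 > sizes[ci])
        stop_fmt("genome too small for %d genes at the required spacing",
                 config$n_genes)
    }
    chrom[i] <- names(sizes)[ci]
    start[i] <- s
    pos <- s + lens[i]
  }
  genes <- GenomicRanges::GRanges(chrom,
                                  IRanges::IRanges(start + 1L, start + lens),
                                  strand = rep_len(c("+", "-"), config$n_genes),
                                  seqinfo = GenomeInfoDb::Seqinfo(
                                    seqnames = names(sizes),
                                    seqlengths = as.integer(sizes)))
  mcols(genes)$gene_id <- sprintf("gene%04d", seq_len(config$n_genes))
  mcols(genes)$biotype <- ifelse(runif(config$n_genes) < config$frac_noncoding,
                                 "noncoding", "coding")
  list(sizes = sizes, genes = genes)
}

# Planted per-gene labels: activity trajectories, complex categories,
# mark-status matrices, DEG directions. All downstream classifications are
# derivable from (and checked against) this table.
simulate_truth <- function(genes, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(genes)
  ids <- mcols(genes)$gene_id
  act <- matrix(FALSE, n, 3, dimnames = list(ids, TIMEPOINTS))
  act[, 1] <- runif(n) < config$frac_active_d0
  act[, 2] <- xor(act[, 1], runif(n) < config$activity_flip_prob)
  act[, 3] <- xor(act[, 2], runif(n) < config$activity_flip_prob)

  # complex category at D0, conditional on D0 activity; the JMJD2B promoter
  # bit is read off the category so the two truths cannot disagree.
  # Order follows COMPLEX_CATEGORIES: JTL, TL, JT, JL, J_only, T_only,
  # L_only, unbound. Active promoters are predominantly triple-bound, with
  # small JMJD2B-only and TFAP2C-LSD1 compartments; silent promoters carry
  # JMJD2B without the co-factors far more often.
  p_active <- c(config$triple_bound_active, 0.02, 0.02, 0.02, 0.04, 0.02, 0.02)
  p_active <- c(p_active, 1 - sum(p_active))
  p_silent <- c(0.02, 0.025, 0.02, 0.02, 0.295, 0.01, 0.01)
  p_silent <- c(p_silent, 1 - sum(p_silent))
  complex <- character(n)
  is_act <- act[, 1]
  complex[is_act] <- sample(COMPLEX_CATEGORIES, sum(is_act), TRUE, p_active)
  complex[!is_act] <- sample(COMPLEX_CATEGORIES, sum(!is_act), TRUE, p_silent)

  J <- K9 <- K36 <- matrix(FALSE, n, 3, dimnames = list(ids, TIMEPOINTS))
  J[, 1] <- grepl("JMJD2B", complex)
  K9[, 1] <- ifelse(!is_act & J[, 1], runif(n) < config$frac_cobound_k9,
                    ifelse(!is_act, runif(n) < 0.15, runif(n) < 0.05))
  K36[, 1] <- ifelse(is_act, runif(n) < 0.85, runif(n) < 0.05)
  for (m in list(quote(J), quote(K9), quote(K36))) {
    mm <- eval(m)
    mm[, 2] <- xor(mm[, 1], runif(n) < config$mark_flip_prob)
    mm[, 3] <- xor(mm[, 2], runif(n) < config$mark_flip_prob)
    assign(as.character(m), mm)
  }

  # co-enriched silent genes forced persistent (marks and silence) at the
  # configured rate -- the stable repressed compartment
  cand <- !is_act & J[, 1] & K9[, 1]
  persist <- cand & runif(n) < config$persist_frac
  act[persist, ] <- FALSE
  J[persist, ] <- TRUE
  K9[persist, ] <- TRUE
  K36[persist, ] <- FALSE

  # DEG directions per phase: activity switches are forced DEGs; stably
  # active genes get planted fold shifts
  deg <- matrix("unchanged", n, 2,
                dimnames = list(ids, c("D0_D2", "D2_D6")))
  for (ph in 1:2) {
    up <- !act[, ph] & act[, ph + 1]
    dn <- act[, ph] & !act[, ph + 1]
    both <- act[, ph] & act[, ph + 1]
    r <- runif(n)
    up <- up | (both & r < config$active_deg_prob)
    dn <- dn | (both & r >= config$active_deg_prob &
                  r < 2 * config$active_deg_prob)
    deg[up, ph] <- "up"
    deg[dn, ph] <- "down"
  }

  # couple H3K9me3 dynamics to DEGs: a small fraction of DEG events
  # (default 3%, the paper-shaped proportion) is made negatively correlated
  # (up with K9 loss, down with K9 gain); the rest of the DEG genes keep a
  # persistent K9 state over that phase. Phase 1 can set both columns;
  # phase 2 only the later column, so an infeasible negative draw falls
  # back to persistence. The persistent co-enriched subset is never touched.
  neg_frac <- 0.03
  for (ph in 1:2) {
    is_deg <- deg[, ph] != "unchanged" & !persist
    neg <- is_deg & runif(n) < neg_frac
    upg <- deg[, ph] == "up"
    if (ph == 1L) {
      K9[neg & upg, 1] <- TRUE;  K9[neg & upg, 2] <- FALSE
      K9[neg & !upg, 1] <- FALSE; K9[neg & !upg, 2] <- TRUE
      keep <- is_deg & !neg
      K9[keep, 2] <- K9[keep, 1]
    } else {
      feas <- neg & ((upg & K9[, 2]) | (!upg & !K9[, 2]))
      K9[feas & upg, 3] <- FALSE
      K9[feas & !upg, 3] <- TRUE
      keep <- is_deg & !feas
      K9[keep, 3] <- K9[keep, 2]
    }
  }

  status <- structure(list(
    status = list(JMJD2B = J, H3K9me3 = K9, H3K36me3 = K36),
    gene_id = ids, mark_regions = DEFAULT_MARK_REGIONS,
    timepoints = TIMEPOINTS), class = "mark_status")

  list(activity = act, complex = factor(complex, COMPLEX_CATEGORIES),
       status = status, deg = deg, persist = persist,
       zero_type = runif(n) < config$silent_zero_mass)
}

#' Simulate the expression table from planted truth
#'
#' Active genes draw log2-FPKM around a per-gene active baseline; silent
#' genes are exactly 0 (undetected type) or draw around a low baseline.
#' Planted DEGs among stably active genes shift the baseline by
#' `deg_shift` per phase, which exceeds log2(1.5) + 3 x replicate noise so
#' directions are recoverable.
#'
#' @param truth result of the internal truth-planting step (see
#'   [simulate_study()])
#' @param config a [simulate_config()]
#' @param seed optional seed
#' @return an [fpkm_table()] with 3 timepoints x 2 replicates
#' @export
simulate_expression <- function(truth, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(truth$activity)
  base_active <- rnorm(n, config$active_mean, config$active_sd)
  base_silent <- rnorm(n, config$silent_mean, config$silent_sd)
  shift <- matrix(0, n, 3)
  for (ph in 1:2) {
    stable <- truth$activity[, ph] & truth$activity[, ph + 1]
    d <- ifelse(truth$deg[, ph] == "up", config$deg_shift,
                ifelse(truth$deg[, ph] == "down", -config$deg_shift, 0))
    shift[, ph + 1] <- shift[, ph] + ifelse(stable, d, 0)
  }
  samples <- data.frame(
    label = paste0(rep(TIMEPOINTS, each = 2), "_r", 1:2),
    timepoint = rep(TIMEPOINTS, each = 2),
    replicate = rep(1:2, 3), stringsAsFactors = FALSE)
  vals <- matrix(0, n, 6, dimnames = list(rownames(truth$activity),
                                          samples$label))
  for (j in seq_len(6)) {
    tp <- match(samples$timepoint[j], TIMEPOINTS)
    mu <- ifelse(truth$activity[, tp], base_active + shift[, tp], base_silent)
    fp <- 2^(mu + rnorm(n, 0, config$replicate_noise_sd))
    fp[!truth$activity[, tp] & truth$zero_type] <- 0
    vals[, j] <- fp
  }
  fpkm_table(vals, samples)
}

# One planted peak inside each window; width ~ N(mean, sd) clamped to
# [50, window width] (truncation logged), placed uniformly.
place_in_windows <- function(windows, config, q_lo, q_hi, prefix) {
  n <- length(windows)
  if (n == 0L)
    return(peak_set(character(0), integer(0), integer(0)))
  w <- pmax(50, round(rnorm(n, config$peak_width_mean, config$peak_width_sd)))
  ww <- GenomicRanges::width(windows)
  trunc <- w > ww
  if (any(trunc)) {
    msg_log("truncating %d peak(s) to their window", sum(trunc))
    w[trunc] <- ww[trunc]
  }
  off <- floor(runif(n) * (ww - w + 1))
  gr <- GenomicRanges::GRanges(GenomicRanges::seqnames(windows),
                               IRanges::IRanges(GenomicRanges::start(windows) + off,
                                                width = w))
  mcols(gr)$name <- paste0(prefix, "_", seq_len(n))
  mcols(gr)$score <- runif(n, 5, 15)
  mcols(gr)$qvalue <- runif(n, q_lo, q_hi)
  gr
}

# Sample n intervals of the given widths uniformly inside an allowed
# (intergenic) region set; segments chosen with probability proportional
# to their usable length.
sample_in_segments <- function(allowed, n, widths) {
  segw <- GenomicRanges::width(allowed)
  out_chrom <- character(n); out_start <- integer(n)
  for (i in seq_len(n)) {
    ok <- segw >= widths[i]
    if (!any(ok)) stop_fmt("no intergenic segment can hold a %d bp interval",
                           widths[i])
    usable <- ifelse(ok, segw - widths[i] + 1, 0)
    s <- sample.int(length(allowed), 1, prob = usable)
    out_chrom[i] <- as.character(GenomicRanges::seqnames(allowed))[s]
    out_start[i] <- GenomicRanges::start(allowed)[s] +
      floor(runif(1) * usable[s])
  }
  GenomicRanges::GRanges(out_chrom, IRanges::IRanges(out_start,
                                                     width = widths))
}

# Peak-shaped step track: low uniform background noise in 1 kb bins plus
# the planted peaks at amplitudes U(3, 8).
make_track <- function(peaks, sizes, noise_max = 0.3, noise_bin = 1000L) {
  noise <- lapply(names(sizes), function(ch) {
    len <- as.integer(sizes[[ch]])
    nb <- ceiling(len / noise_bin)
    widths <- rep(noise_bin, nb)
    widths[nb] <- len - noise_bin * (nb - 1L)
    S4Vectors::Rle(round(runif(nb, 0, noise_max), 3), widths)
  })
  names(noise) <- names(sizes)
  amp <- runif(length(peaks), 3, 8)
  cov <- GenomicRanges::coverage(peaks, weight = amp,
                                 width = as.list(setNames(as.integer(sizes),
                                                          names(sizes))))
  total <- IRanges::RleList(lapply(names(sizes), function(ch)
    noise[[ch]] + cov[[ch]]))
  names(total) <- names(sizes)
  methods::as(total, "GRanges")
}

#' Simulate peak sets, enhancers and signal tracks from planted truth
#'
#' For every planted "present" (gene, mark, timepoint) cell one peak is
#' placed inside the corresponding window (promoter for JMJD2B/H3K9me3/
#' TFAP2C/LSD1, gene body at >= 600 bp from the TSS for H3K36me3) with a
#' strong q-value (U(1e-8, 1e-4)); decoy background peaks carry weak
#' q-values (U(1e-4, 0.1)) and live in intergenic space clear of all
#' windows. Enhancer loci are overlapping H3K4me1/H3K27ac peak pairs
#' outside promoters, a configured fraction of which is TFAP2C+LSD1
#' co-bound. Tracks are peak-shaped step functions plus uniform noise.
#' Every peak carries its planted region class in `mcols()$planted_class`.
#'
#' @param truth planted truth (see [simulate_study()])
#' @param genes,sizes genome from [simulate_genome()]
#' @param config a [simulate_config()]
#' @param seed optional seed
#' @return list with `peaks` (nested `peaks[[factor]][[timepoint]]`),
#'   `tracks` (per-mark D0 `GRanges` signal), `enhancers` (truth loci)
#' @export
simulate_peaks_and_tracks <- function(truth, genes, sizes, config,
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  prom <- promoter_windows(genes, sizes)
  minus <- as.character(GenomicRanges::strand(genes)) == "-"
  body_s <- ifelse(minus, GenomicRanges::start(genes),
                   GenomicRanges::start(genes) + 600L)
  body_e <- ifelse(minus, GenomicRanges::end(genes) - 600L,
                   GenomicRanges::end(genes))
  body_win <- GenomicRanges::GRanges(GenomicRanges::seqnames(genes),
                                     IRanges::IRanges(body_s, body_e))

  genome_gr <- GenomicRanges::GRanges(names(sizes),
                                      IRanges::IRanges(1, as.integer(sizes)))
  gene_zones <- GenomicRanges::reduce(GenomicRanges::GRanges(
    GenomicRanges::seqnames(genes), IRanges::ranges(genes)) + 4000)
  gaps <- GenomicRanges::setdiff(genome_gr, gene_zones, ignore.strand = TRUE)

  # enhancer zones: 1600 bp (K4me1 600 left of centre, K27ac 1000 right),
  # one per intergenic gap, sampled among gaps that can hold one
  elig <- which(GenomicRanges::width(gaps) >= 1600)
  if (length(elig) < config$n_enhancers)
    stop_fmt("only %d intergenic gaps can hold the %d requested enhancers",
             length(elig), config$n_enhancers)
  pick <- sample(elig, config$n_enhancers)
  off <- floor(runif(config$n_enhancers) *
                 (GenomicRanges::width(gaps)[pick] - 1600 + 1))
  centre <- GenomicRanges::start(gaps)[pick] + off + 600L
  ch_e <- as.character(GenomicRanges::seqnames(gaps))[pick]
  k4 <- GenomicRanges::GRanges(ch_e, IRanges::IRanges(centre - 600L, centre + 599L))
  k27 <- GenomicRanges::GRanges(ch_e, IRanges::IRanges(centre - 200L, centre + 999L))
  enh_core <- GenomicRanges::GRanges(ch_e, IRanges::IRanges(centre - 200L, centre + 599L))
  mcols(enh_core)$enhancer_id <- sprintf("enh%04d", seq_len(config$n_enhancers))
  cobound <- runif(config$n_enhancers) < config$enhancer_cobinding
  mcols(enh_core)$cobound <- cobound

  allowed <- GenomicRanges::setdiff(gaps, enh_core + 1500, ignore.strand = TRUE)

  finish <- function(gr, cls, factor, tp) {
    mcols(gr)$planted_class <- rep_len(cls, length(gr))
    metadata(gr)$factor <- factor
    metadata(gr)$timepoint <- tp
    GenomeInfoDb_safe_seqlevels(gr, sizes)
  }
  decoys <- function(factor, tp) {
    n <- config$n_decoys
    w <- pmax(50, round(rnorm(n, config$peak_width_mean, config$peak_width_sd)))
    gr <- sample_in_segments(allowed, n, w)
    mcols(gr)$name <- sprintf("%s_%s_decoy_%d", factor, tp, seq_len(n))
    mcols(gr)$score <- runif(n, 1, 5)
    mcols(gr)$qvalue <- runif(n, 1e-4, 0.1)
    gr
  }
  planted <- function(mark, tp, windows, idx, cls) {
    gr <- place_in_windows(windows[idx], config, 1e-8, 1e-4,
                           paste(mark, tp, sep = "_"))
    mcols(gr)$gene_id <- if (cls == "enhancer") NA_character_ else
      mcols(genes)$gene_id[idx]
    gr
  }

  peaks <- list()
  st <- truth$status$status
  for (mark in c("JMJD2B", "H3K9me3", "H3K36me3")) {
    win <- if (DEFAULT_MARK_REGIONS[[mark]] == "promoter") prom else body_win
    cls <- if (DEFAULT_MARK_REGIONS[[mark]] == "promoter") "promoter" else "gene_body"
    peaks[[mark]] <- list()
    for (tp in TIMEPOINTS) {
      idx <- which(st[[mark]][, tp])
      p <- planted(mark, tp, win, idx, cls)
      mcols(p)$planted_class <- rep_len(cls, length(p))
      d <- decoys(mark, tp)
      mcols(d)$gene_id <- rep(NA_character_, length(d))
      mcols(d)$planted_class <- rep_len("other", length(d))
      peaks[[mark]][[tp]] <- finish(c(p, d), c(rep(cls, length(p)),
                                               rep("other", length(d))),
                                    mark, tp)
    }
  }

  # TFAP2C / LSD1 at D0: promoter peaks per the planted complex category,
  # plus enhancer peaks at co-bound enhancer loci, plus decoys
  enh_win <- enh_core
  for (fac in c("TFAP2C", "LSD1")) {
    idx <- which(grepl(fac, truth$complex))
    p_prom <- planted(fac, "D0", prom, idx, "promoter")
    p_enh <- place_in_windows(enh_win[cobound], config, 1e-8, 1e-4,
                              paste0(fac, "_D0_enh"))
    mcols(p_enh)$gene_id <- rep(NA_character_, length(p_enh))
    d <- decoys(fac, "D0")
    mcols(d)$gene_id <- rep(NA_character_, length(d))
    pk <- c(p_prom, p_enh, d)
    peaks[[fac]] <- list(D0 = finish(pk, c(rep("promoter", length(p_prom)),
                                           rep("enhancer", length(p_enh)),
                                           rep("other", length(d))),
                                     fac, "D0"))
  }

  for (fac in c("H3K4me1", "H3K27ac")) {
    src <- if (fac == "H3K4me1") k4 else k27
    mcols(src)$name <- sprintf("%s_%d", fac, seq_along(src))
    mcols(src)$score <- runif(length(src), 5, 15)
    mcols(src)$qvalue <- runif(length(src), 1e-8, 1e-4)
    mcols(src)$gene_id <- rep(NA_character_, length(src))
    peaks[[fac]] <- list(D0 = finish(src, "enhancer", fac, "D0"))
  }

  tracks <- list(
    JMJD2B_D0 = make_track(peaks$JMJD2B$D0[mcols(peaks$JMJD2B$D0)$planted_class != "other"], sizes),
    H3K9me3_D0 = make_track(peaks$H3K9me3$D0[mcols(peaks$H3K9me3$D0)$planted_class != "other"], sizes),
    H3K36me3_D0 = make_track(peaks$H3K36me3$D0[mcols(peaks$H3K36me3$D0)$planted_class != "other"], sizes))

  list(peaks = peaks, tracks = tracks, enhancers = enh_core)
}

#' Simulate a complete synthetic study with planted ground truth
#'
#' Orchestrates genome, truth, expression, peak and track simulation under
#' one parent seed. Byte-identical outputs under a fixed seed.
#'
#' @param config a [simulate_config()]
#' @return list of class `sim_study`: `config`, `sizes`, `genes`, `fpkm`,
#'   `peaks`, `tracks`, `enhancers`, `truth`
#' @export
simulate_study <- function(config = simulate_config()) {
  set.seed(config$seed)
  g <- simulate_genome(config)
  truth <- simulate_truth(g$genes, config)
  fpkm <- simulate_expression(truth, config)
  pt <- simulate_peaks_and_tracks(truth, g$genes, g$sizes, config)
  structure(list(config = config, sizes = g$sizes, genes = g$genes,
                 fpkm = fpkm, peaks = pt$peaks, tracks = pt$tracks,
                 enhancers = pt$enhancers, truth = truth),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf("Synthetic study: %d genes on %d chromosome(s), seed %d\n",
              length(x$genes), length(x$sizes), x$config$seed))
  cat(sprintf("  active at D0: %d; enhancer loci: %d\n",
              sum(x$truth$activity[, 1]), length(x$enhancers)))
  invisible(x)
}

#' Write a synthetic study as a self-contained directory
#'
#' Emits chrom.sizes, genes.bed12 (12 standard columns plus a biotype
#' column), fpkm.tsv, one narrowPeak file per factor/timepoint, bedGraph
#' tracks, truth.tsv and the generating config as YAML.
#'
#' @param study a [simulate_study()] result
#' @param dir output directory (created if needed)
#' @return invisibly, `dir`
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  write_chrom_sizes(study$sizes, fp("chrom.sizes"))
  write_gene_models(study$genes, fp("genes.bed12"))
  write_fpkm_table(study$fpkm, fp("fpkm.tsv"))
  for (fac in names(study$peaks))
    for (tp in names(study$peaks[[fac]]))
      write_peaks(study$peaks[[fac]][[tp]],
                  fp(sprintf("%s_%s.narrowPeak", tolower(fac), tp)),
                  format = "narrowPeak")
  for (tr in names(study$tracks))
    write_bedgraph(study$tracks[[tr]], fp(paste0(tolower(tr), ".bedGraph")))
  tt <- truth_table(study)
  write.table(tt, fp("truth.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- study$config
  class(cfg) <- NULL
  yaml::write_yaml(cfg, fp("config.yaml"))
  invisible(dir)
}

#' Flatten the planted truth into one row per gene
#' @param study a `sim_study`
#' @return data.frame
#' @export
truth_table <- function(study) {
  tr <- study$truth
  st <- tr$status$status
  data.frame(
    gene_id = mcols(study$genes)$gene_id,
    active_D0 = tr$activity[, 1], active_D2 = tr$activity[, 2],
    active_D6 = tr$activity[, 3],
    deg_D0_D2 = tr$deg[, 1], deg_D2_D6 = tr$deg[, 2],
    JMJD2B_D0 = st$JMJD2B[, 1], JMJD2B_D2 = st$JMJD2B[, 2],
    JMJD2B_D6 = st$JMJD2B[, 3],
    H3K9me3_D0 = st$H3K9me3[, 1], H3K9me3_D2 = st$H3K9me3[, 2],
    H3K9me3_D6 = st$H3K9me3[, 3],
    H3K36me3_D0 = st$H3K36me3[, 1], H3K36me3_D2 = st$H3K36me3[, 2],
    H3K36me3_D6 = st$H3K36me3[, 3],
    complex = as.character(tr$complex),
    state_D0 = unname(classify_state(tr$status, "D0")),
    persistent = tr$persist,
    row.names = NULL, stringsAsFactors = FALSE)
}
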