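#' Analysis configuration
#'
#' Houses every numeric constant the pipeline uses; all of them appear in
#' the provenance block of the emitted report. Defaults are the study
#' constants: zFPKM activity threshold -3, 1.5-fold DEG rule, promoter
#' -3 kb/+500 bp, top 65,000 peaks per set, 10,000 within-chromosome
#' shuffles.
#'
#' @param study_dir directory written by [write_study()] (or laid out the
#'   same way)
#' @param timepoints timepoint labels
#' @param zfpkm_threshold,fold_threshold,pseudocount expression constants
#' @param promoter_upstream,promoter_downstream promoter window (bp)
#' @param top_n peak-selection cutoff per factor/timepoint
#' @param n_shuffles,shuffle_seed randomized-control parameters
#' @param min_nonzero minimum non-zero genes per sample for the zFPKM fit
#' @param metagene_genes number of genes profiled in the metagene stage
#'   (subsampled for tractability; 0 disables the stage)
#' @param body_bins,flank_bins,flank_bp metagene binning
#' @return list of class `analysis_config`
#' @export
analysis_config <- function(study_dir,
                            timepoints = TIMEPOINTS,
                            zfpkm_threshold = -3,
                            fold_threshold = 1.5,
                            pseudocount = 0.1,
                            promoter_upstream = 3000L,
                            promoter_downstream = 500L,
                            top_n = 65000L,
                            n_shuffles = 10000L,
                            shuffle_seed = 1L,
                            min_nonzero = 100L,
                            metagene_genes = 300L,
                            body_bins = 100L, flank_bins = 30L,
                            flank_bp = 3000L) {
  structure(as.list(environment()), class = "analysis_config")
}

read_study_peaks <- function(dir, factor, timepoint, sizes) {
  path <- file.path(dir, sprintf("%s_%s.narrowPeak", tolower(factor), timepoint))
  if (!file.exists(path)) stop_fmt("missing peak file: %s", path)
  read_peaks(path, "narrowPeak", factor = factor, timepoint = timepoint,
             sizes = sizes)
}

#' Run the full integration pipeline on a study directory
#'
#' Stages run in order: expression (zFPKM activity calls, fold-change DEGs)
#' -> regions (promoters, gene bodies, putative enhancers, top-N peak
#' selection) -> integration (mark status, occupancy states, gain/loss
#' dynamics, DEG crosstabs, complex assignment) -> shuffle null -> metagene.
#' Any stage error aborts naming the stage.
#'
#' @param config an [analysis_config()]
#' @return list of class `summary_report`; see [write_report()]
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  dir <- config$study_dir
  stage <- function(name, expr) {
    msg_log("stage: %s", name)
    tryCatch(expr, error = function(e)
      stop_fmt("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  tp <- config$timepoints
  phases <- lapply(seq_len(length(tp) - 1L), function(i) tp[c(i, i + 1L)])

  inputs <- stage("load", {
    sizes <- read_chrom_sizes(file.path(dir, "chrom.sizes"))
    genes <- read_gene_models(file.path(dir, "genes.bed12"), "bed12", sizes)
    header <- strsplit(readLines(file.path(dir, "fpkm.tsv"), n = 1), "\t")[[1]][-1]
    meta <- data.frame(label = header,
                       timepoint = sub("_r\\d+$", "", header),
                       replicate = as.integer(sub("^.*_r", "", header)),
                       stringsAsFactors = FALSE)
    fpkm <- read_fpkm_table(file.path(dir, "fpkm.tsv"), meta)
    list(sizes = sizes, genes = genes, fpkm = fpkm)
  })
  sizes <- inputs$sizes; genes <- inputs$genes

  expr <- stage("expression", {
    zfit <- zfpkm_transform(inputs$fpkm, active_threshold = config$zfpkm_threshold,
                            min_nonzero = config$min_nonzero)
    active <- call_active(zfit, tp)
    degs <- lapply(phases, function(p)
      call_degs(inputs$fpkm, p, config$fold_threshold, config$pseudocount))
    names(degs) <- vapply(phases, paste, "", collapse = "_")
    list(zfit = zfit, active = active, degs = degs)
  })

  reg <- stage("regions", {
    promoters <- promoter_windows(genes, sizes, config$promoter_upstream,
                                  config$promoter_downstream)
    bodies <- gene_bodies(genes)
    facs <- c("JMJD2B", "H3K9me3", "H3K36me3")
    peaks <- lapply(setNames(facs, facs), function(f)
      lapply(setNames(tp, tp), function(t)
        top_n_peaks(read_study_peaks(dir, f, t, sizes), config$top_n)))
    for (f in c("TFAP2C", "LSD1", "H3K4me1", "H3K27ac"))
      peaks[[f]] <- list(D0 = top_n_peaks(read_study_peaks(dir, f, "D0", sizes),
                                          config$top_n))
    enhancers <- derive_enhancers(peaks$H3K4me1$D0, peaks$H3K27ac$D0, promoters)
    list(promoters = promoters, bodies = bodies, peaks = peaks,
         enhancers = enhancers)
  })

  # align expression-derived calls to annotation order
  gidx <- match(mcols(genes)$gene_id, rownames(expr$active))
  if (anyNA(gidx))
    stop_fmt("stage 'integration' failed: %d annotated gene(s) missing from the expression table",
             sum(is.na(gidx)))
  expr$active <- expr$active[gidx, , drop = FALSE]

  integ <- stage("integration", {
    status <- build_mark_status(genes, reg$promoters, reg$bodies, reg$peaks,
                                timepoints = tp)
    states <- vapply(tp, function(t) classify_state(status, t),
                     character(length(genes)))
    dyn <- lapply(setNames(names(DEFAULT_MARK_REGIONS),
                           names(DEFAULT_MARK_REGIONS)),
                  function(mk) classify_dynamics(status, mk))
    crosstabs <- list(); neg_union <- character(0); rev_union <- character(0)
    n_deg_total <- 0L
    for (i in seq_along(phases)) {
      ph_col <- paste0("phase_", paste(phases[[i]], collapse = "_"))
      ct <- deg_dynamics_crosstab(expr$degs[[i]], dyn$H3K9me3, ph_col,
                                  dynamics2 = dyn$JMJD2B)
      crosstabs[[names(expr$degs)[i]]] <- ct
      neg_union <- union(neg_union, ct$negative_genes)
      rev_union <- union(rev_union, ct$reverse_genes)
      n_deg_total <- n_deg_total + ct$n_deg
    }
    deg_gene_union <- unique(unlist(lapply(expr$degs, function(d)
      d$gene_id[d$direction != "unchanged"])))

    active_d0 <- expr$active[, tp[1]]
    prom_active <- reg$promoters[active_d0]
    complex_active <- assign_complex(prom_active, reg$peaks$JMJD2B$D0,
                                     reg$peaks$TFAP2C$D0, reg$peaks$LSD1$D0)

    # occupancy cascade among silent genes at D0
    J0 <- status$status$JMJD2B[, tp[1]]
    K90 <- status$status$H3K9me3[, tp[1]]
    silent0 <- !active_d0
    cob <- silent0 & J0 & K90
    persist <- cob &
      rowSums(status$status$JMJD2B) == ncol(status$status$JMJD2B) &
      rowSums(status$status$H3K9me3) == ncol(status$status$H3K9me3) &
      rowSums(expr$active) == 0
    cascade <- list(
      n_silent = sum(silent0), n_silent_j = sum(silent0 & J0),
      n_cobound = sum(cob), n_persistent = sum(persist),
      pct_silent_j = summarize_fractions(sum(silent0 & J0), sum(silent0)),
      pct_cobound = summarize_fractions(sum(cob), max(sum(silent0 & J0), 1)),
      pct_persistent = summarize_fractions(sum(persist), max(sum(cob), 1)))

    # up-DEGs with persistent-or-gained promoter JMJD2B per phase
    up_jmjd2b <- lapply(seq_along(phases), function(i) {
      ph_col <- paste0("phase_", paste(phases[[i]], collapse = "_"))
      d <- expr$degs[[i]]
      up <- d$gene_id[d$direction == "up"]
      lab <- dyn$JMJD2B[[ph_col]][match(up, dyn$JMJD2B$gene_id)]
      summarize_fractions(sum(lab %in% c("persistent_present", "gain")),
                          max(length(up), 1))
    })
    names(up_jmjd2b) <- names(expr$degs)

    # genome-wide distribution of triple-bound and TFAP2C-LSD1 loci
    # (JMJD2B peak list as the reference universe for the triple overlap)
    j0 <- reg$peaks$JMJD2B$D0
    t_hit <- overlap_any(j0, reg$peaks$TFAP2C$D0)$hit
    l_hit <- overlap_any(j0, reg$peaks$LSD1$D0)$hit
    jtl_loci <- j0[t_hit & l_hit]
    t0 <- reg$peaks$TFAP2C$D0
    tl_loci <- t0[overlap_any(t0, reg$peaks$LSD1$D0)$hit &
                    !overlap_any(t0, j0)$hit]
    dist_jtl <- annotate_region_class(jtl_loci, reg$promoters, reg$enhancers,
                                      reg$bodies)
    dist_tl <- annotate_region_class(tl_loci, reg$promoters, reg$enhancers,
                                     reg$bodies)
    venn <- list(jmjd2b = length(j0),
                 jmjd2b_tfap2c = sum(t_hit), jmjd2b_lsd1 = sum(l_hit),
                 triple = length(jtl_loci))
    list(status = status, states = states, dynamics = dyn,
         crosstabs = crosstabs,
         negative_genes = neg_union, reverse_genes = rev_union,
         n_deg_events = n_deg_total, n_deg_genes = length(deg_gene_union),
         complex_active = complex_active, cascade = cascade,
         up_jmjd2b = up_jmjd2b, dist_jtl = dist_jtl$tally,
         dist_tl = dist_tl$tally, venn = venn)
  })

  nulls <- stage("shuffle_null", {
    out <- list()
    for (fac in c("TFAP2C", "LSD1"))
      out[[fac]] <- null_max_overlap(reg$peaks[[fac]]$D0, reg$peaks$JMJD2B$D0,
                                     sizes, n_shuffles = config$n_shuffles,
                                     seed = config$shuffle_seed)
    out
  })

  meta <- if (config$metagene_genes == 0L) NULL else stage("metagene", {
    tracks <- list(
      JMJD2B = read_bedgraph(file.path(dir, "jmjd2b_d0.bedGraph"), sizes),
      H3K9me3 = read_bedgraph(file.path(dir, "h3k9me3_d0.bedGraph"), sizes))
    set.seed(config$shuffle_seed)
    idx <- sort(sample(length(genes), min(config$metagene_genes, length(genes))))
    sub_genes <- genes[idx]
    m <- scaled_region_matrix(tracks$JMJD2B, sub_genes, sizes,
                              upstream_flank = config$flank_bp,
                              downstream_flank = config$flank_bp,
                              body_bins = config$body_bins,
                              flank_bins = config$flank_bins)
    act_ids <- rownames(m)[rownames(m) %in%
                             rownames(expr$active)[expr$active[, tp[1]]]]
    sil_ids <- setdiff(rownames(m), act_ids)
    prof <- list(active = if (length(act_ids)) mean_profile(m, act_ids),
                 silent = if (length(sil_ids)) mean_profile(m, sil_ids))
    corr <- promoter_signal_correlation(tracks$JMJD2B, tracks$H3K9me3,
                                        reg$promoters, sizes, "spearman")
    list(profiles = prof, correlation = corr)
  })

  provenance <- list(
    package_version = as.character(utils::packageVersion("markstates")),
    config = unclass(config))

  structure(list(
    config = config,
    n_genes = length(genes),
    active_counts = colSums(expr$active),
    silent_counts = colSums(!expr$active),
    deg_counts = lapply(expr$degs, function(d) table(d$direction)),
    expression = expr, regions = reg, integration = integ,
    shuffle = nulls, metagene = meta,
    provenance = provenance), class = "summary_report")
}

#' @export
print.summary_report <- function(x, ...) {
  tp <- x$config$timepoints
  cat("Summary report\n")
  cat(sprintf("  genes: %d; active per timepoint: %s\n", x$n_genes,
              paste(sprintf("%s=%d", tp, x$active_counts[tp]), collapse = ", ")))
  cs <- x$integration$cascade
  cat(sprintf("  silent genes at %s bound by JMJD2B: %d/%d (%d%%)\n",
              tp[1], cs$n_silent_j, cs$n_silent, cs$pct_silent_j$percent))
  cat(sprintf("  of those also H3K9me3-marked: %d (%d%%); persistent: %d (%d%%)\n",
              cs$n_cobound, cs$pct_cobound$percent,
              cs$n_persistent, cs$pct_persistent$percent))
  neg <- length(x$integration$negative_genes)
  cat(sprintf("  DEGs negatively associated with H3K9me3: %d/%d gene-phase events\n",
              neg, x$integration$n_deg_events))
  ta <- x$integration$complex_active$tally
  tot <- sum(ta)
  cat(sprintf("  active promoters triple-bound: %d/%d (%d%%)\n",
              ta[["JMJD2B-TFAP2C-LSD1"]], tot,
              summarize_fractions(ta[["JMJD2B-TFAP2C-LSD1"]], tot)$percent))
  for (f in names(x$shuffle)) {
    s <- x$shuffle[[f]]
    cat(sprintf("  %s vs JMJD2B: observed %.1f%%, shuffle-null max %.1f%%\n",
                f, s$observed_percent, s$null_max_percent))
  }
  invisible(x)
}

#' Write a summary report to disk
#'
#' Emits a machine-readable JSON of every tally (with the provenance block)
#' plus tab-separated tables: per-gene states and dynamics, DEG-dynamics
#' crosstabs, complex tallies, region-class distributions.
#'
#' @param report a [run_pipeline()] result
#' @param dir output directory
#' @return invisibly, `dir`
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  ig <- report$integration
  json <- list(
    provenance = report$provenance,
    active_counts = as.list(report$active_counts),
    deg_counts = lapply(report$deg_counts, as.list),
    cascade = lapply(ig$cascade, function(v)
      if (is.list(v)) v[c("percent", "label")] else v),
    negative_correlation = list(
      n_gene_phase_events = length(ig$negative_genes),
      n_deg_events = ig$n_deg_events,
      n_deg_genes = ig$n_deg_genes,
      n_reverse_jmjd2b = length(ig$reverse_genes)),
    complex_at_active_promoters = as.list(ig$complex_active$tally),
    distribution_triple_loci = as.list(ig$dist_jtl),
    distribution_tfap2c_lsd1_loci = as.list(ig$dist_tl),
    venn = ig$venn,
    shuffle_null = lapply(report$shuffle, function(s)
      s[c("observed_count", "observed_percent", "null_max_count",
          "null_max_percent", "null_mean_percent", "n_shuffles", "seed")]),
    promoter_correlation = if (!is.null(report$metagene))
      report$metagene$correlation)
  jsonlite::write_json(json, fp("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  st <- data.frame(gene_id = ig$status$gene_id, ig$states,
                   check.names = FALSE)
  write.table(st, fp("states.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  for (mk in names(ig$dynamics))
    write.table(ig$dynamics[[mk]], fp(sprintf("dynamics_%s.tsv", tolower(mk))),
                sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(ig$crosstabs))
    write.table(as.data.frame(ig$crosstabs[[nm]]$counts),
                fp(sprintf("crosstab_%s.tsv", nm)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(ig$complex_active$tally),
              fp("complex_active_promoters.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
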