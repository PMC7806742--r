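#' zFPKM transform of an FPKM table
#'
#' Per sample, the transform of Hart et al.: over genes with FPKM > 0, let
#' x = log2(FPKM); fit a Gaussian-kernel density to x (Silverman bandwidth,
#' 512-point grid spanning `[min(x) - 3, max(x) + 3]` for determinism); take
#' the density mode mu, the mean U of the x above the mode, and the
#' half-normal spread sigma = (U - mu) * sqrt(pi/2); report
#' z = (x - mu) / sigma. Genes with FPKM = 0 are excluded from the fit and
#' flagged silent (z = NA).
#'
#' @param table an [fpkm_table()]
#' @param active_threshold z-score above which a gene counts as
#'   transcriptionally active (default -3, strict inequality)
#' @param min_nonzero minimum non-zero genes per sample for a reliable
#'   density fit (default 100)
#' @return object of class `zfpkm_fit`: list with `z` (genes x samples
#'   matrix, NA for zero-FPKM cells), `fit` (per-sample data.frame with
#'   `mu`, `U`, `sigma`), `samples`, `active_threshold`
#' @export
zfpkm_transform <- function(table, active_threshold = -3, min_nonzero = 100L) {
  stopifnot(inherits(table, "fpkm_table"))
  if (!is.finite(active_threshold)) stop_fmt("active_threshold must be finite")
  v <- table$values
  z <- matrix(NA_real_, nrow(v), ncol(v), dimnames = dimnames(v))
  fit <- data.frame(label = table$samples$label, mu = NA_real_,
                    U = NA_real_, sigma = NA_real_)
  for (j in seq_len(ncol(v))) {
    nz <- v[, j] > 0
    if (sum(nz) < min_nonzero)
      stop_fmt("sample '%s': only %d non-zero genes (< %d); density fit unreliable",
               colnames(v)[j], sum(nz), min_nonzero)
    x <- log2(v[nz, j])
    d <- density(x, bw = "nrd0", n = 512, from = min(x) - 3, to = max(x) + 3)
    mu <- d$x[which.max(d$y)]
    upper <- x[x > mu]
    if (length(upper) == 0L)
      stop_fmt("sample '%s': no mass above the density mode", colnames(v)[j])
    U <- mean(upper)
    sigma <- (U - mu) * sqrt(pi / 2)
    if (!is.finite(sigma) || sigma <= 0)
      stop_fmt("sample '%s': degenerate spread (sigma <= 0)", colnames(v)[j])
    z[nz, j] <- (x - mu) / sigma
    fit$mu[j] <- mu; fit$U[j] <- U; fit$sigma[j] <- sigma
  }
  structure(list(z = z, fit = fit, samples = table$samples,
                 active_threshold = active_threshold),
            class = "zfpkm_fit")
}

#' @export
print.zfpkm_fit <- function(x, ...) {
  cat(sprintf("zFPKM fit: %d genes x %d samples (active: z > %g)\n",
              nrow(x$z), ncol(x$z), x$active_threshold))
  print(x$fit, row.names = FALSE)
  invisible(x)
}

#' Call active/silent genes per timepoint
#'
#' A gene is active at a timepoint iff its zFPKM exceeds the threshold
#' (strictly) in at least one replicate of that timepoint (`rule = "any"`);
#' `rule = "all"` requires every replicate. Zero-FPKM replicates never count
#' as active. The active/silent partition is exhaustive.
#'
#' @param fit a `zfpkm_fit`
#' @param timepoints timepoints to call (default: all in the fit)
#' @param rule `"any"` (default) or `"all"` replicate rule
#' @return logical matrix, genes x timepoints; `TRUE` = active
#' @export
call_active <- function(fit, timepoints = NULL, rule = c("any", "all")) {
  stopifnot(inherits(fit, "zfpkm_fit"))
  rule <- match.arg(rule)
  timepoints <- timepoints %||% unique(fit$samples$timepoint)
  missing_tp <- setdiff(timepoints, fit$samples$timepoint)
  if (length(missing_tp))
    stop_fmt("timepoint(s) missing from fit: %s", paste(missing_tp, collapse = ", "))
  out <- matrix(NA, nrow(fit$z), length(timepoints),
                dimnames = list(rownames(fit$z), timepoints))
  for (tp in timepoints) {
    cols <- which(fit$samples$timepoint == tp)
    hit <- fit$z[, cols, drop = FALSE] > fit$active_threshold
    hit[is.na(hit)] <- FALSE
    out[, tp] <- if (rule == "any") rowSums(hit) > 0 else rowSums(hit) == length(cols)
  }
  out
}

#' Classify differentially expressed genes by fold change
#'
#' Per gene, fold = (mean FPKM at the later timepoint + pseudocount) /
#' (mean FPKM at the earlier timepoint + pseudocount); direction is `up`
#' when fold > `fold_threshold`, `down` when fold < 1/`fold_threshold`,
#' else `unchanged`.
#'
#' @param table an [fpkm_table()]
#' @param pair ordered character pair of timepoints, earlier first
#' @param fold_threshold ratio, > 1 (default 1.5)
#' @param pseudocount FPKM units added to both means (default 0.1)
#' @return data.frame with `gene_id`, `comparison`, `fold`, `direction`
#' @export
call_degs <- function(table, pair, fold_threshold = 1.5, pseudocount = 0.1) {
  stopifnot(inherits(table, "fpkm_table"), length(pair) == 2L)
  if (fold_threshold <= 1) stop_fmt("fold_threshold must be > 1")
  if (pseudocount < 0) stop_fmt("pseudocount must be >= 0")
  for (tp in pair)
    if (!tp %in% table$samples$timepoint)
      stop_fmt("timepoint '%s' missing from expression table", tp)
  m_early <- rowMeans(table$values[, table$samples$timepoint == pair[1], drop = FALSE])
  m_late <- rowMeans(table$values[, table$samples$timepoint == pair[2], drop = FALSE])
  fold <- (m_late + pseudocount) / (m_early + pseudocount)
  direction <- rep("unchanged", length(fold))
  direction[fold > fold_threshold] <- "up"
  direction[fold < 1 / fold_threshold] <- "down"
  data.frame(gene_id = rownames(table$values),
             comparison = paste(pair, collapse = "->"),
             fold = fold, direction = direction,
             row.names = NULL, stringsAsFactors = FALSE)
}
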