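#' Shuffle peaks within their own chromosomes
#'
#' Each peak is re-placed uniformly at random on its own chromosome with
#' identical length, so the per-chromosome multiplicity and the length
#' multiset are preserved exactly. Shuffled peaks may overlap one another.
#' Deterministic under a fixed seed.
#'
#' @param peaks `GRanges`
#' @param sizes named chromosome lengths
#' @param seed integer seed (`NULL` to use the current RNG state)
#' @return `GRanges` with the same metadata columns
#' @export
shuffle_peaks <- function(peaks, sizes, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chrom <- as.character(GenomicRanges::seqnames(peaks))
  absent <- setdiff(chrom, names(sizes))
  if (length(absent))
    stop_fmt("peak chromosome(s) absent from chrom sizes: %s",
             paste(absent, collapse = ", "))
  w <- GenomicRanges::width(peaks)
  len <- as.numeric(sizes[chrom])
  if (any(w > len)) stop_fmt("peak longer than its chromosome")
  start0 <- floor(runif(length(peaks)) * (len - w + 1))
  out <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1L, width = w))
  mcols(out) <- mcols(peaks)
  metadata(out) <- metadata(peaks)
  out
}

#' Percentage of one peak set overlapped by another
#'
#' 100 x (number of denominator-set intervals overlapping >= 1 interval of
#' the other set) / |denominator set|.
#'
#' @param factor,target `GRanges`
#' @param denominator `"factor"` or `"target"`: which set the percentage is
#'   a fraction of
#' @return numeric percentage
#' @export
overlap_percent <- function(factor, target, denominator = c("factor", "target")) {
  denominator <- match.arg(denominator)
  den <- if (denominator == "factor") factor else target
  oth <- if (denominator == "factor") target else factor
  if (length(den) == 0L) stop_fmt("empty denominator set")
  100 * overlap_any(den, oth)$count / length(den)
}

#' Within-chromosome shuffle null for peak-set overlap
#'
#' Shuffles the factor set `n_shuffles` times (shuffle i seeded with
#' `seed + i` so results are reproducible independent of execution order),
#' counts the target regions intersected by each shuffled set, and reports
#' the maximum alongside the observed (unshuffled) count — the randomized
#' control of the overlap bar charts.
#'
#' @param factor,target `GRanges`
#' @param sizes named chromosome lengths
#' @param n_shuffles number of shuffles (default 10000)
#' @param seed parent integer seed
#' @param keep_counts retain the per-shuffle counts (automatically dropped
#'   above 1000 shuffles to bound memory; the summary is always reported)
#' @return object of class `shuffle_null`: observed/null counts and
#'   percentages of the target set, null mean and 95th percentile
#' @export
null_max_overlap <- function(factor, target, sizes, n_shuffles = 10000L,
                             seed = 1L, keep_counts = n_shuffles <= 1000L) {
  if (n_shuffles < 1L) stop_fmt("n_shuffles must be >= 1")
  observed <- overlap_any(target, factor)$count
  n_target <- length(target)
  # split once; per shuffle only starts are redrawn
  chrom <- as.character(GenomicRanges::seqnames(factor))
  w <- GenomicRanges::width(factor)
  len <- as.numeric(sizes[chrom])
  if (anyNA(len)) stop_fmt("factor chromosome absent from chrom sizes")
  if (any(w > len)) stop_fmt("peak longer than its chromosome")
  tgt_by_chrom <- split(seq_len(n_target),
                        as.character(GenomicRanges::seqnames(target)))
  tgt_ir <- lapply(tgt_by_chrom, function(i) IRanges::ranges(target)[i])
  fac_by_chrom <- split(seq_along(factor), chrom)
  counts <- numeric(n_shuffles)
  for (i in seq_len(n_shuffles)) {
    set.seed(seed + i)
    start0 <- floor(runif(length(factor)) * (len - w + 1))
    hit_total <- 0L
    for (ch in names(tgt_ir)) {
      idx <- fac_by_chrom[[ch]]
      if (is.null(idx) || length(idx) == 0L) next
      shuf <- IRanges::IRanges(start0[idx] + 1L, width = w[idx])
      hit_total <- hit_total +
        sum(IRanges::countOverlaps(tgt_ir[[ch]], shuf) > 0L)
    }
    counts[i] <- hit_total
  }
  pct <- function(k) if (n_target > 0L) 100 * k / n_target else 0
  structure(list(
    observed_count = observed,
    observed_percent = pct(observed),
    null_max_count = max(counts),
    null_max_percent = pct(max(counts)),
    null_mean_percent = pct(mean(counts)),
    null_p95_percent = pct(unname(stats::quantile(counts, 0.95))),
    n_shuffles = n_shuffles, seed = seed, n_target = n_target,
    per_shuffle_counts = if (keep_counts) counts else NULL
  ), class = "shuffle_null")
}

#' @export
print.shuffle_null <- function(x, ...) {
  cat(sprintf(paste0("Shuffle null (%d shuffles, seed %d): observed %d/%d ",
                     "(%.1f%%); null max %.1f%%, mean %.1f%%\n"),
              x$n_shuffles, x$seed, x$observed_count, x$n_target,
              x$observed_percent, x$null_max_percent, x$null_mean_percent))
  invisible(x)
}
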