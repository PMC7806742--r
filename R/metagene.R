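#' Per-chromosome coverage of a signal track
#' @param track `GRanges` with `score` (sorted, non-overlapping steps)
#' @param sizes named chromosome lengths
#' @return `RleList`, one run-length vector per chromosome, implicit 0
#'   outside steps
#' @export
track_coverage <- function(track, sizes) {
  GenomicRanges::coverage(track, weight = mcols(track)$score,
                          width = as.list(setNames(as.integer(sizes), names(sizes))))
}

# Split a span of `len` bases into `nbins` spans; remainder bases go to the
# leftmost bins. Returns integer widths summing to len.
bin_widths <- function(len, nbins) {
  base <- len %/% nbins
  rem <- len %% nbins
  base + (seq_len(nbins) <= rem)
}

# Mean per bin of a numeric vector, given bin widths (cumsum trick).
bin_means <- function(vals, widths) {
  cs <- cumsum(c(0, vals))
  ends <- cumsum(widths)
  starts <- ends - widths
  (cs[ends + 1L] - cs[starts + 1L]) / widths
}

#' Scaled-region signal matrix (metagene)
#'
#' For each gene: a fixed-width upstream flank, the gene body scaled into
#' `body_bins` equal-base bins (remainder bases to the leftmost bins), and a
#' fixed-width downstream flank; each bin value is the mean per-base signal.
#' Rows are oriented 5' to 3' (TSS to TES) regardless of strand; flank bases
#' beyond the chromosome ends contribute value 0. Genes with bodies shorter
#' than `body_bins` are skipped with a logged warning.
#'
#' @param track `GRanges` signal track with `score`
#' @param genes `GRanges` gene models with `gene_id`
#' @param sizes named chromosome lengths
#' @param upstream_flank,downstream_flank flank sizes in bp (defaults 3000)
#' @param body_bins,flank_bins bin counts (defaults 100 and 30)
#' @return numeric matrix, one row per retained gene (rownames = gene_id),
#'   `2 * flank_bins + body_bins` columns
#' @export
scaled_region_matrix <- function(track, genes, sizes,
                                 upstream_flank = 3000L, downstream_flank = 3000L,
                                 body_bins = 100L, flank_bins = 30L) {
  stopifnot(body_bins >= 1L, flank_bins >= 1L,
            upstream_flank >= 1L, downstream_flank >= 1L)
  cov <- track_coverage(track, sizes)
  keep <- GenomicRanges::width(genes) >= body_bins
  if (any(!keep))
    msg_log("skipping %d gene(s) with body shorter than %d bins",
            sum(!keep), body_bins)
  genes <- genes[keep]
  ncol_out <- 2L * flank_bins + body_bins
  out <- matrix(NA_real_, length(genes), ncol_out,
                dimnames = list(mcols(genes)$gene_id, NULL))
  up_w <- bin_widths(upstream_flank, flank_bins)
  dn_w <- bin_widths(downstream_flank, flank_bins)
  for (i in seq_along(genes)) {
    ch <- as.character(GenomicRanges::seqnames(genes))[i]
    minus <- as.character(GenomicRanges::strand(genes))[i] == "-"
    gs <- GenomicRanges::start(genes)[i]
    ge <- GenomicRanges::end(genes)[i]
    left <- gs - (if (minus) downstream_flank else upstream_flank)
    right <- ge + (if (minus) upstream_flank else downstream_flank)
    len <- as.integer(sizes[[ch]])
    vals <- numeric(right - left + 1L)
    lo <- max(left, 1L); hi <- min(right, len)
    if (lo <= hi)
      vals[(lo - left + 1L):(hi - left + 1L)] <-
        as.numeric(S4Vectors::window(cov[[ch]], lo, hi))
    if (minus) vals <- rev(vals)
    widths <- c(up_w, bin_widths(ge - gs + 1L, body_bins), dn_w)
    out[i, ] <- bin_means(vals, widths)
  }
  out
}

#' Column-wise mean profile over a gene subset
#'
#' @param matrix a [scaled_region_matrix()] result
#' @param subset gene ids (must all be rows of the matrix)
#' @return numeric vector of per-bin means
#' @export
mean_profile <- function(matrix, subset = rownames(matrix)) {
  if (length(subset) == 0L) stop_fmt("empty gene subset")
  missing_g <- setdiff(subset, rownames(matrix))
  if (length(missing_g))
    stop_fmt("%d gene(s) not in matrix (first: %s)", length(missing_g), missing_g[1])
  colMeans(matrix[subset, , drop = FALSE])
}

#' Correlation of two signal tracks over promoters
#'
#' Mean per-promoter signal is computed for each track; the rank (Spearman,
#' default) or linear (Pearson) correlation between the two per-promoter
#' vectors is returned with its two-sided p-value.
#'
#' @param track_a,track_b `GRanges` signal tracks with `score`
#' @param promoters `GRanges` promoter windows (>= 3 required)
#' @param sizes named chromosome lengths
#' @param method `"spearman"` (default) or `"pearson"`
#' @return list with `estimate`, `p.value`, `method`, `n`
#' @export
promoter_signal_correlation <- function(track_a, track_b, promoters, sizes,
                                        method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (length(promoters) < 3L) stop_fmt("need >= 3 promoters")
  ma <- region_means(track_a, promoters, sizes)
  mb <- region_means(track_b, promoters, sizes)
  if (stats::sd(ma) == 0 || stats::sd(mb) == 0)
    stop_fmt("zero variance in promoter signal; correlation undefined")
  ct <- suppressWarnings(cor.test(ma, mb, method = method, exact = FALSE))
  list(estimate = unname(ct$estimate), p.value = ct$p.value,
       method = method, n = length(promoters))
}

# Mean per-base signal over each region.
region_means <- function(track, regions, sizes) {
  cov <- track_coverage(track, sizes)
  out <- numeric(length(regions))
  ch_all <- as.character(GenomicRanges::seqnames(regions))
  for (ch in unique(ch_all)) {
    idx <- which(ch_all == ch)
    v <- IRanges::Views(cov[[ch]],
                        start = GenomicRanges::start(regions)[idx],
                        end = GenomicRanges::end(regions)[idx])
    out[idx] <- IRanges::viewMeans(v)
  }
  out
}
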