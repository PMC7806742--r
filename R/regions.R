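#' Strand-aware promoter windows
#'
#' The promoter is the window from `upstream` bp 5' of the TSS to
#' `downstream` bp 3' of the TSS (default -3 kb / +500 bp), clipped to the
#' chromosome bounds. A window entirely outside its chromosome is an error.
#'
#' @param genes `GRanges` gene models with `gene_id`
#' @param sizes named chromosome lengths (required for clipping)
#' @param upstream,downstream window extents in bp
#' @return `GRanges` of promoter windows carrying `gene_id`
#' @export
promoter_windows <- function(genes, sizes, upstream = 3000L, downstream = 500L) {
  if (upstream + downstream < 1L) stop_fmt("empty promoter window")
  absent <- setdiff(as.character(GenomicRanges::seqnames(genes)), names(sizes))
  if (length(absent))
    stop_fmt("gene chromosome(s) absent from chrom sizes: %s",
             paste(absent, collapse = ", "))
  pr <- GenomicRanges::promoters(GenomicRanges::GRanges(
    GenomicRanges::seqnames(genes), IRanges::ranges(genes),
    strand = GenomicRanges::strand(genes)),
    upstream = upstream, downstream = downstream)
  len <- as.integer(sizes)[match(as.character(GenomicRanges::seqnames(pr)), names(sizes))]
  gone <- GenomicRanges::end(pr) < 1L | GenomicRanges::start(pr) > len
  if (any(gone))
    stop_fmt("promoter window entirely outside chromosome for gene '%s'",
             mcols(genes)$gene_id[which(gone)[1]])
  GenomicRanges::start(pr) <- pmax(GenomicRanges::start(pr), 1L)
  GenomicRanges::end(pr) <- pmin(GenomicRanges::end(pr), len)
  mcols(pr)$gene_id <- mcols(genes)$gene_id
  pr
}

#' Gene-body windows
#'
#' The full annotated genomic span, strand-independent.
#'
#' @param genes `GRanges` gene models
#' @return unstranded `GRanges` carrying `gene_id`
#' @export
gene_bodies <- function(genes) {
  gb <- GenomicRanges::GRanges(GenomicRanges::seqnames(genes),
                               IRanges::ranges(genes))
  mcols(gb)$gene_id <- mcols(genes)$gene_id
  gb
}

#' Do two intervals overlap by at least 1 bp?
#'
#' Overlap requires the same chromosome and at least one shared base;
#' half-open-adjacent intervals do not overlap.
#'
#' @param a,b single-interval `GRanges`
#' @return logical
#' @export
intersects <- function(a, b) {
  stopifnot(length(a) == 1L, length(b) == 1L)
  # different chromosomes simply never overlap; no need for shared seqlevels
  length(suppressWarnings(
    GenomicRanges::findOverlaps(a, b, ignore.strand = TRUE))) > 0L
}

#' Which query intervals overlap any target?
#'
#' @param query,targets `GRanges`
#' @return list with `hit` (per-query logical) and `count` (number of query
#'   intervals overlapped by >= 1 target)
#' @export
overlap_any <- function(query, targets) {
  hit <- GenomicRanges::countOverlaps(query, targets, ignore.strand = TRUE) > 0L
  list(hit = unname(hit), count = sum(hit))
}

#' Interval set algebra
#'
#' Base-level union, difference and intersection of peak sets. Results are
#' sorted and non-overlapping; strand is ignored throughout.
#'
#' @param a,b `GRanges`
#' @return `GRanges`
#' @export
merge_peaks <- function(a) {
  GenomicRanges::reduce(GenomicRanges::GRanges(GenomicRanges::seqnames(a),
                                               IRanges::ranges(a)))
}

#' @rdname merge_peaks
#' @export
subtract_peaks <- function(a, b) {
  a <- merge_peaks(a)
  if (length(b) == 0L) return(a)
  GenomicRanges::setdiff(a, merge_peaks(b), ignore.strand = TRUE)
}

#' @rdname merge_peaks
#' @export
intersect_peaks <- function(a, b) {
  GenomicRanges::intersect(merge_peaks(a), merge_peaks(b), ignore.strand = TRUE)
}

#' Select the top N peaks by significance
#'
#' The `n` peaks with the smallest linear-scale q-value, with the
#' deterministic tie-break (q ascending, score descending, chromosome,
#' start). A set of at most `n` peaks is returned whole.
#'
#' @param peaks `GRanges` peak set with a `qvalue` column
#' @param n number of peaks to keep (default 65000)
#' @return `GRanges`
#' @export
top_n_peaks <- function(peaks, n = 65000L) {
  q <- mcols(peaks)$qvalue
  if (is.null(q) || anyNA(q)) stop_fmt("top_n_peaks requires q-values on every peak")
  if (length(peaks) <= n) return(peaks)
  sc <- mcols(peaks)$score
  if (is.null(sc)) sc <- rep(0, length(peaks))
  sc[is.na(sc)] <- 0
  o <- order(q, -sc, as.character(GenomicRanges::seqnames(peaks)),
             GenomicRanges::start(peaks))
  peaks[sort(o[seq_len(n)])]
}

#' Derive putative enhancers
#'
#' Putative enhancers are the base-level intersection of H3K4me1 and
#' H3K27ac peaks lying outside promoters.
#'
#' @param h3k4me1,h3k27ac `GRanges` peak sets
#' @param promoters `GRanges` promoter windows
#' @return sorted, non-overlapping `GRanges`
#' @export
derive_enhancers <- function(h3k4me1, h3k27ac, promoters) {
  subtract_peaks(intersect_peaks(h3k4me1, h3k27ac), promoters)
}

#' Assign each peak a regulatory region class
#'
#' Each peak takes the highest-precedence class it overlaps (by >= 1 bp):
#' promoter > enhancer > gene body > other. The tallies partition the set.
#'
#' @param peaks `GRanges`
#' @param promoters,enhancers,bodies `GRanges` region sets
#' @return list with `class` (per-peak factor) and `tally` (named counts)
#' @export
annotate_region_class <- function(peaks, promoters, enhancers, bodies) {
  lv <- c("promoter", "enhancer", "gene_body", "other")
  cls <- rep("other", length(peaks))
  cls[overlap_any(peaks, bodies)$hit] <- "gene_body"
  cls[overlap_any(peaks, enhancers)$hit] <- "enhancer"
  cls[overlap_any(peaks, promoters)$hit] <- "promoter"
  cls <- factor(cls, levels = lv)
  list(class = cls, tally = table(cls))
}
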