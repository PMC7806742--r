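# Per-base bitmap oracle for interval set algebra on toy genomes.
# Everything here is deliberately naive: one logical per base.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

bm_cover <- function(gr, sizes) {
  out <- lapply(sizes, function(len) logical(len))
  ch <- as.character(seqnames(gr))
  for (i in seq_along(gr)) {
    v <- out[[ch[i]]]
    v[start(gr)[i]:end(gr)[i]] <- TRUE
    out[[ch[i]]] <- v
  }
  out
}

bm_to_granges <- function(bm) {
  lv <- names(bm)
  pieces <- lapply(lv, function(ch) {
    r <- rle(bm[[ch]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    GRanges(factor(rep(ch, sum(keep)), levels = lv),
            IRanges(starts[keep], ends[keep]))
  })
  do.call(c, pieces)
}

oracle_merge <- function(a, sizes) bm_to_granges(bm_cover(a, sizes))

oracle_subtract <- function(a, b, sizes) {
  ba <- bm_cover(a, sizes); bb <- bm_cover(b, sizes)
  bm_to_granges(Map(function(x, y) x & !y, ba, bb))
}

oracle_intersect <- function(a, b, sizes) {
  ba <- bm_cover(a, sizes); bb <- bm_cover(b, sizes)
  bm_to_granges(Map(`&`, ba, bb))
}

oracle_overlap_any <- function(query, targets, sizes) {
  bt <- bm_cover(targets, sizes)
  ch <- as.character(seqnames(query))
  vapply(seq_along(query), function(i)
    any(bt[[ch[i]]][start(query)[i]:end(query)[i]]), logical(1))
}

# random interval set on a toy genome (seqlevels fixed to genome order)
random_gr <- function(n, sizes, max_len = 500L) {
  ch <- sample(names(sizes), n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  s <- vapply(seq_len(n), function(i)
    sample.int(sizes[[ch[i]]] - len[i] + 1L, 1L), integer(1))
  GRanges(factor(ch, levels = names(sizes)), IRanges(s, width = len))
}

# canonical (chrom, start, end) frame for comparing interval sets
gr_df <- function(gr) {
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr), end = end(gr))
  df[order(df$chrom, df$start, df$end), , drop = FALSE]
}

# small synthetic study shared by several test files (cached per session)
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_study(simulate_config(
        seed = 42, n_genes = 400, chrom_length = 9e6,
        n_enhancers = 50, n_decoys = 100))
    cache
  }
})

# direct re-statement of the gain/loss definitions, independent of
# classify_dynamics internals
oracle_phase <- function(before, after) {
  if (!before && after) "gain"
  else if (before && !after) "loss"
  else if (before) "persistent_present"
  else "persistent_absent"
}
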