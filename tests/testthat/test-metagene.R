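toy_genes <- function(df) {
  g <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                              strand = df$strand)
  S4Vectors::mcols(g)$gene_id <- df$id
  g
}

step_track <- function(chrom, start, end, value) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  S4Vectors::mcols(gr)$score <- value
  gr
}

# naive per-base oracle for one gene row
oracle_row <- function(track, gene, sizes, up, down, body_bins, flank_bins) {
  ch <- as.character(GenomicRanges::seqnames(gene))
  len <- sizes[[ch]]
  base <- numeric(len)
  for (i in seq_along(track)) {
    if (as.character(GenomicRanges::seqnames(track))[i] != ch) next
    base[GenomicRanges::start(track)[i]:GenomicRanges::end(track)[i]] <-
      S4Vectors::mcols(track)$score[i]
  }
  minus <- as.character(GenomicRanges::strand(gene)) == "-"
  gs <- GenomicRanges::start(gene); ge <- GenomicRanges::end(gene)
  left <- gs - (if (minus) down else up)
  right <- ge + (if (minus) up else down)
  vals <- vapply(left:right, function(p)
    if (p >= 1 && p <= len) base[p] else 0, numeric(1))
  if (minus) vals <- rev(vals)
  widths <- c(markstates:::bin_widths(up, flank_bins),
              markstates:::bin_widths(ge - gs + 1, body_bins),
              markstates:::bin_widths(down, flank_bins))
  ends <- cumsum(widths); starts <- ends - widths + 1
  vapply(seq_along(widths), function(b)
    mean(vals[starts[b]:ends[b]]), numeric(1))
}

test_that("a constant track yields a constant matrix (mass conservation)", {
  sizes <- c(chr1 = 50000L)
  tr <- step_track("chr1", 1, 50000, 4.25)
  genes <- toy_genes(data.frame(chrom = "chr1", start = 20001, end = 30000,
                                strand = c("+"), id = "g1"))
  m <- scaled_region_matrix(tr, genes, sizes, 3000, 3000, 100, 30)
  expect_equal(dim(m), c(1, 160))
  expect_equal(unname(m[1, ]), rep(4.25, 160))
  expect_equal(mean(m), 4.25)
})

test_that("minus-strand rows equal the reversed plus-strand computation", {
  sizes <- c(chr1 = 40000L)
  set.seed(41)
  steps <- seq(1, 39000, by = 700)
  tr <- step_track("chr1", steps, steps + 399, runif(length(steps), 0, 5))
  plus <- toy_genes(data.frame(chrom = "chr1", start = 15001, end = 24800,
                               strand = "+", id = "gp"))
  minus <- toy_genes(data.frame(chrom = "chr1", start = 15001, end = 24800,
                                strand = "-", id = "gm"))
  mp <- scaled_region_matrix(tr, plus, sizes, 3000, 3000, 40, 10)
  mm <- scaled_region_matrix(tr, minus, sizes, 3000, 3000, 40, 10)
  # symmetric flanks + symmetric bin layout: minus row is the plus row reversed
  expect_equal(unname(mm[1, ]), rev(unname(mp[1, ])))
})

test_that("bin means match the per-base averaging oracle on random tracks", {
  set.seed(42)
  sizes <- c(chrA = 30000L, chrB = 20000L)
  for (rep_i in 1:5) {
    tr <- random_gr(40, sizes, max_len = 300)
    tr <- merge_peaks(tr)  # non-overlapping steps
    S4Vectors::mcols(tr)$score <- runif(length(tr), 0, 10)
    genes <- toy_genes(data.frame(
      chrom = c("chrA", "chrB"), start = c(5001, 4001), end = c(12000, 9000),
      strand = sample(c("+", "-"), 2, replace = TRUE), id = c("a", "b")))
    m <- scaled_region_matrix(tr, genes, sizes, 2000, 1500, 25, 8)
    for (k in 1:2)
      expect_equal(unname(m[k, ]),
                   oracle_row(tr, genes[k], sizes, 2000, 1500, 25, 8))
  }
})

test_that("short gene bodies are skipped with a message", {
  sizes <- c(chr1 = 10000L)
  tr <- step_track("chr1", 1, 10000, 1)
  genes <- toy_genes(data.frame(chrom = "chr1", start = c(3001, 6001),
                                end = c(3040, 9000), strand = "+",
                                id = c("tiny", "ok")))
  expect_message(m <- scaled_region_matrix(tr, genes, sizes, 1000, 1000, 50, 5),
                 "skipping 1")
  expect_identical(rownames(m), "ok")
})

test_that("profiles average the requested gene subset", {
  m <- matrix(1:12, 3, 4, dimnames = list(c("a", "b", "c"), NULL))
  expect_equal(mean_profile(m, "a"), unname(m["a", ]) + 0,
               ignore_attr = TRUE)
  expect_equal(mean_profile(m, c("a", "b")),
               unname((m["a", ] + m["b", ]) / 2), ignore_attr = TRUE)
  expect_error(mean_profile(m, character(0)), "empty")
  expect_error(mean_profile(m, "zz"), "not in matrix")
})

test_that("promoter signal correlation behaves at the extremes", {
  sizes <- c(chr1 = 100000L)
  set.seed(43)
  steps <- seq(1, 99000, by = 1000)
  a <- step_track("chr1", steps, steps + 799, runif(length(steps), 1, 10))
  b <- a
  neg <- a; S4Vectors::mcols(neg)$score <- 20 - S4Vectors::mcols(a)$score
  proms <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(seq(1001, 91001, by = 10000),
                                                   width = 3500))
  expect_equal(promoter_signal_correlation(a, b, proms, sizes)$estimate, 1)
  expect_equal(promoter_signal_correlation(a, neg, proms, sizes)$estimate, -1)
  flat <- step_track("chr1", 1, 100000, 2)
  expect_error(promoter_signal_correlation(a, flat, proms, sizes),
               "variance")
  expect_error(promoter_signal_correlation(a, b, proms[1:2], sizes), ">= 3")
})

test_that("independent tracks are near-uncorrelated over many promoters", {
  sizes <- c(chr1 = 600000L)
  set.seed(44)
  steps <- seq(1, 599000, by = 1000)
  a <- step_track("chr1", steps, steps + 999, runif(length(steps)))
  b <- step_track("chr1", steps, steps + 999, runif(length(steps)))
  proms <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(seq(1, 596500, by = 1193),
                                                   width = 1000))
  r <- promoter_signal_correlation(a, b, proms[1:500], sizes)$estimate
  expect_lt(abs(r), 0.15)
})
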