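toy_gene <- function(chrom = "chr1", start0 = 5000, end = 9000, strand = "+",
                     id = "g1") {
  g <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, end),
                              strand = strand)
  S4Vectors::mcols(g)$gene_id <- id
  g
}

test_that("promoter windows are strand-aware and clipped", {
  sizes <- c(chr1 = 1e6)
  # + strand, TSS at 0-based 10,000 -> [7,000, 10,500)
  p <- promoter_windows(toy_gene(start0 = 10000, end = 20000, strand = "+"), sizes)
  expect_equal(GenomicRanges::start(p), 7001)
  expect_equal(GenomicRanges::end(p), 10500)
  # - strand, TSS at 0-based 10,000 (span end) -> [9,500, 13,000)
  m <- promoter_windows(toy_gene(start0 = 2000, end = 10000, strand = "-"), sizes)
  expect_equal(GenomicRanges::start(m), 9501)
  expect_equal(GenomicRanges::end(m), 13000)
  # clipping at the chromosome start
  cl <- promoter_windows(toy_gene(start0 = 1000, end = 5000, strand = "+"), sizes)
  expect_equal(GenomicRanges::start(cl), 1)
  expect_equal(GenomicRanges::end(cl), 1500)
  # entirely outside
  far <- toy_gene(start0 = 999000, end = 999900, strand = "-")
  expect_error(promoter_windows(far, c(chr1 = 999000)), "beyond|outside")
})

test_that("gene bodies are the full span regardless of strand", {
  b1 <- gene_bodies(toy_gene(strand = "+"))
  b2 <- gene_bodies(toy_gene(strand = "-"))
  expect_equal(GenomicRanges::start(b1), 5001)
  expect_equal(GenomicRanges::end(b1), 9000)
  expect_equal(IRanges::ranges(b1), IRanges::ranges(b2))
})

test_that("overlap requires >= 1 shared base; half-open adjacency does not", {
  g <- function(s0, e) GenomicRanges::GRanges("chr1", IRanges::IRanges(s0 + 1, e))
  expect_true(intersects(g(0, 100), g(99, 200)))   # 1 bp
  expect_false(intersects(g(0, 100), g(100, 200))) # adjacent
  expect_true(intersects(g(0, 100), g(0, 100)))    # identical
  expect_false(intersects(g(0, 100),
                          GenomicRanges::GRanges("chr2", IRanges::IRanges(1, 100))))
})

test_that("merge, subtract and intersection match worked examples", {
  g <- function(s0, e) GenomicRanges::GRanges("chr1", IRanges::IRanges(s0 + 1, e))
  m <- merge_peaks(c(g(0, 10), g(5, 20)))
  expect_equal(GenomicRanges::start(m), 1); expect_equal(GenomicRanges::end(m), 20)
  s <- subtract_peaks(g(0, 20), g(5, 10))
  expect_equal(GenomicRanges::start(s), c(1, 11))
  expect_equal(GenomicRanges::end(s), c(5, 20))
  expect_length(intersect_peaks(g(0, 5), g(10, 20)), 0)
})

test_that("top-N selection sorts by linear q with the stated tie-break", {
  p <- peak_set(rep("chr1", 3), c(0, 200, 400), c(100, 300, 500),
                score = c(8, 5, 1), qvalue = c(0.01, 0.01, 0.5))
  expect_length(top_n_peaks(p, 65000), 3)        # small set returned whole
  top1 <- top_n_peaks(p, 1)
  expect_equal(S4Vectors::mcols(top1)$score, 8)  # tie on q broken by score
  set.seed(21)
  q <- runif(100)
  p2 <- peak_set(rep("chr1", 100), seq(0, 9900, 100), seq(50, 9950, 100),
                 qvalue = q)
  top <- top_n_peaks(p2, 30)
  expect_setequal(S4Vectors::mcols(top)$qvalue, sort(q)[1:30])  # sort-slice oracle
  expect_error(top_n_peaks(peak_set("chr1", 0, 10), 5), "q-value")
})

test_that("putative enhancers are K4me1/K27ac intersections outside promoters", {
  g <- function(s0, e) GenomicRanges::GRanges("chr1", IRanges::IRanges(s0 + 1, e))
  enh <- derive_enhancers(g(0, 1000), g(500, 1500), g(900, 1200))
  expect_equal(GenomicRanges::start(enh), 501)
  expect_equal(GenomicRanges::end(enh), 900)
  expect_length(derive_enhancers(g(0, 400), g(500, 900), g(0, 10)), 0)
})

test_that("region classes follow promoter > enhancer > gene_body > other", {
  g <- function(s0, e) GenomicRanges::GRanges("chr1", IRanges::IRanges(s0 + 1, e))
  peaks <- c(g(0, 100), g(250, 300), g(500, 600), g(5000, 5100))
  ann <- annotate_region_class(peaks,
                               promoters = g(50, 150),
                               enhancers = c(g(60, 120), g(240, 320)),
                               bodies = g(0, 1000))
  expect_equal(as.character(ann$class),
               c("promoter", "enhancer", "gene_body", "other"))
  expect_equal(sum(ann$tally), length(peaks))
})

test_that("set algebra agrees base-for-base with the bitmap oracle", {
  set.seed(22)
  sizes <- c(chrA = 50000L, chrB = 30000L)
  for (rep_i in 1:60) {
    a <- random_gr(sample(1:80, 1), sizes)
    b <- random_gr(sample(1:80, 1), sizes)
    expect_equal(gr_df(merge_peaks(a)), gr_df(oracle_merge(a, sizes)),
                 ignore_attr = TRUE)
    expect_equal(gr_df(subtract_peaks(a, b)),
                 gr_df(oracle_subtract(a, b, sizes)), ignore_attr = TRUE)
    expect_equal(gr_df(intersect_peaks(a, b)),
                 gr_df(oracle_intersect(a, b, sizes)), ignore_attr = TRUE)
    expect_equal(overlap_any(a, b)$hit, oracle_overlap_any(a, b, sizes))
  }
})

test_that("merge is idempotent and intersection is symmetric at base level", {
  set.seed(23)
  sizes <- c(chrA = 40000L)
  a <- random_gr(50, sizes); b <- random_gr(50, sizes)
  expect_identical(merge_peaks(merge_peaks(a)), merge_peaks(a))
  expect_identical(GenomicRanges::ranges(intersect_peaks(a, b)),
                   GenomicRanges::ranges(intersect_peaks(b, a)))
  expect_identical(GenomicRanges::ranges(subtract_peaks(a, GenomicRanges::GRanges())),
                   GenomicRanges::ranges(merge_peaks(a)))
})
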