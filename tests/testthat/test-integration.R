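g1 <- function(s0, e, ch = "chr1") {
  GenomicRanges::GRanges(ch, IRanges::IRanges(s0 + 1, e))
}

make_status <- function(J, K9, K36, ids = NULL) {
  n <- nrow(J)
  ids <- ids %||% paste0("g", seq_len(n))
  dn <- list(ids, markstates::TIMEPOINTS)
  dimnames(J) <- dimnames(K9) <- dimnames(K36) <- dn
  structure(list(status = list(JMJD2B = J, H3K9me3 = K9, H3K36me3 = K36),
                 gene_id = ids,
                 mark_regions = markstates::DEFAULT_MARK_REGIONS,
                 timepoints = markstates::TIMEPOINTS),
            class = "mark_status")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("mark presence reads promoters for JMJD2B/H3K9me3, bodies for H3K36me3", {
  genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10001, 20000),
                                  strand = "+")
  S4Vectors::mcols(genes)$gene_id <- "g1"
  sizes <- c(chr1 = 1e6)
  prom <- promoter_windows(genes, sizes)
  bodies <- gene_bodies(genes)
  empty <- GenomicRanges::GRanges()
  peaks <- list(
    JMJD2B = list(D0 = g1(7100, 7200), D2 = empty, D6 = empty),
    H3K9me3 = list(D0 = empty, D2 = empty, D6 = empty),
    H3K36me3 = list(D0 = g1(15000, 15400), D2 = empty, D6 = empty))
  st <- build_mark_status(genes, prom, bodies, peaks)
  expect_true(st$status$JMJD2B["g1", "D0"])     # peak inside promoter window
  expect_false(st$status$JMJD2B["g1", "D2"])
  expect_true(st$status$H3K36me3["g1", "D0"])   # peak inside gene body
  expect_false(any(st$status$H3K9me3))          # empty sets -> all absent
  expect_error(build_mark_status(genes, prom, bodies, peaks["JMJD2B"]),
               "H3K9me3")
})

test_that("the eight occupancy states are distinct and exhaustive", {
  combos <- expand.grid(J = c(TRUE, FALSE), K9 = c(TRUE, FALSE),
                        K36 = c(TRUE, FALSE))
  st <- make_status(J = matrix(combos$J, 8, 3),
                    K9 = matrix(combos$K9, 8, 3),
                    K36 = matrix(combos$K36, 8, 3))
  codes <- classify_state(st, "D0")
  expect_length(unique(codes), 8)
  expect_equal(unname(codes[combos$J & combos$K9 & !combos$K36]), "J+K9+K36-")
  expect_equal(unname(codes[!combos$J & !combos$K9 & !combos$K36]), "J-K9-K36-")
})

test_that("all eight trajectories map to the gain/loss phase definitions", {
  combos <- as.matrix(expand.grid(c(TRUE, FALSE), c(TRUE, FALSE),
                                  c(TRUE, FALSE)))
  st <- make_status(J = combos, K9 = combos, K36 = combos)
  dyn <- classify_dynamics(st, "JMJD2B")
  for (i in seq_len(nrow(combos))) {
    expect_equal(dyn$trajectory[i],
                 paste(ifelse(combos[i, ], "P", "A"), collapse = ""))
    expect_equal(dyn$phase_D0_D2[i], oracle_phase(combos[i, 1], combos[i, 2]))
    expect_equal(dyn$phase_D2_D6[i], oracle_phase(combos[i, 2], combos[i, 3]))
  }
  # gain <=> absence to presence; loss <=> presence to absence
  expect_equal(dyn$phase_D0_D2[!combos[, 1] & combos[, 2]],
               rep("gain", sum(!combos[, 1] & combos[, 2])))
  expect_equal(dyn$phase_D0_D2[combos[, 1] & !combos[, 2]],
               rep("loss", sum(combos[, 1] & !combos[, 2])))
})

test_that("DEG-dynamics crosstab identifies negative correlation and reversals", {
  st <- make_status(
    J = matrix(c(FALSE, TRUE, TRUE, TRUE,
                 TRUE, FALSE, TRUE, TRUE,
                 TRUE, FALSE, TRUE, TRUE), 4, 3),
    K9 = matrix(c(TRUE, FALSE, TRUE, TRUE,
                  FALSE, TRUE, TRUE, FALSE,
                  FALSE, TRUE, TRUE, FALSE), 4, 3),
    K36 = matrix(FALSE, 4, 3))
  degs <- data.frame(gene_id = paste0("g", 1:4),
                     comparison = "D0->D2",
                     fold = c(3, 0.3, 2, 0.5),
                     direction = c("up", "down", "up", "down"))
  dynK9 <- classify_dynamics(st, "H3K9me3")
  dynJ <- classify_dynamics(st, "JMJD2B")
  ct <- deg_dynamics_crosstab(degs, dynK9, "phase_D0_D2", dynamics2 = dynJ)
  # g1: up + K9 loss -> negative; g2: down + K9 gain -> negative
  # g3: up + K9 persistent -> not; g4: down + K9 loss -> not
  expect_setequal(ct$negative_genes, c("g1", "g2"))
  expect_equal(ct$n_deg, 4)
  expect_equal(sum(ct$counts), 4)
  # reversal: J must move opposite to K9 (g1 J gain vs K9 loss; g2 J loss vs K9 gain)
  expect_setequal(ct$reverse_genes, c("g1", "g2"))
  bad <- data.frame(gene_id = "missing", comparison = "x", fold = 2,
                    direction = "up")
  expect_error(deg_dynamics_crosstab(bad, dynK9, "phase_D0_D2"), "missing")
})

test_that("complex categories partition loci by the binding triple", {
  loci <- c(g1(0, 100), g1(200, 300), g1(400, 500), g1(600, 700))
  j <- c(g1(0, 50), g1(440, 460))
  t_ <- c(g1(50, 150), g1(250, 260))
  l <- c(g1(20, 80), g1(220, 280))
  cx <- assign_complex(loci, j, t_, l)
  expect_equal(as.character(cx$category),
               c("JMJD2B-TFAP2C-LSD1", "TFAP2C-LSD1", "JMJD2B_only", "unbound"))
  expect_equal(sum(cx$tally), length(loci))
})

test_that("percentage reporting rounds half away from zero with exact ratios", {
  expect_equal(summarize_fractions(334, 10655)$percent, 3L)
  expect_equal(summarize_fractions(10446, 14000)$percent, 75L)
  expect_equal(summarize_fractions(0, 50)$percent, 0L)
  expect_equal(summarize_fractions(1, 200)$percent, 1L)  # 0.5 -> 1, not banker's 0
  expect_equal(summarize_fractions(334, 10655)$label, "334/10655")
  expect_error(summarize_fractions(1, 0), "denominator")
  expect_error(summarize_fractions(5, 4), "exceeds")
})

test_that("state tallies partition the gene universe and subsets nest", {
  study <- small_study()
  st <- study$truth$status
  codes <- classify_state(st, "D0")
  expect_equal(sum(table(codes)), length(study$genes))
  act <- study$truth$activity[, "D0"]
  silent_j <- !act & st$status$JMJD2B[, "D0"]
  with_k9 <- silent_j & st$status$H3K9me3[, "D0"]
  without_k9 <- silent_j & !st$status$H3K9me3[, "D0"]
  expect_equal(sum(silent_j), sum(with_k9) + sum(without_k9))
  persistent <- with_k9 & rowSums(st$status$JMJD2B) == 3 &
    rowSums(st$status$H3K9me3) == 3 & rowSums(study$truth$activity) == 0
  expect_true(all(which(persistent) %in% which(with_k9)))
})
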