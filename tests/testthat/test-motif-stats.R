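# motif statistics

frsFromMotifs <- function(motif15, extraC = 0L, plus1 = "G") {
  n <- length(motif15)
  new("FilteredReadSet",
      m15code = racescreen:::encodeKmers(motif15, 15L), plus1 = plus1,
      extraC = rep_len(as.integer(extraC), n),
      umiCode = seq_len(n) - 1, umiLen = 5L)
}

test_that("countMotifs pools by span and conserves totals", {
  m <- c("AACCGGTTACGTACG", "AACCGGTTTTTTTTT", "AACCGGTAAAAAAAA")
  frs <- frsFromMotifs(m)
  c28 <- countMotifs(frs, c(2L, 8L))
  expect_equal(unname(c28[["AACCGGT"]]), 3)
  expect_equal(sum(c28), 3)
  cfull <- countMotifs(frs, c(2L, 16L))
  expect_equal(sum(cfull), 3)
  expect_setequal(names(cfull)[cfull > 0], m)
  # context-restricted counting equals filter-then-count
  frs2 <- frsFromMotifs(c("GGAAAAAAAAAAAAA", "GGCCCCCCCCCCCCC",
                          "ATAAAAAAAAAAAAA"))
  c48 <- countMotifs(frs2, c(4L, 8L), ctxSpan = c(2L, 3L), ctxMotif = "GG")
  expect_equal(sum(c48), 2)
  expect_error(countMotifs(frs, c(1L, 8L)), "invalid span")
})

test_that("normalization is a frequency ratio with a low-background guard", {
  tb <- normalizeMotifs(c(AA = 200, AC = 300, AG = 300, AT = 200),
                        c(AA = 100, AC = 300, AG = 300, AT = 300),
                        span = c(2L, 3L), totalReads = 1000, totalBg = 1000)
  df <- as.data.frame(tb)
  expect_equal(df$rel_abundance[df$motif == "AA"], 2.0)
  expect_equal(df$log2_rel[df$motif == "AA"], 1.0)
  # identical frequencies give rel 1
  same <- normalizeMotifs(c(AA = 50, AC = 50), c(AA = 500, AC = 500),
                          span = c(2L, 3L))
  expect_true(all(as.data.frame(same)$rel_abundance == 1))
  # below min_bg: flagged, no rank
  low <- normalizeMotifs(c(AA = 50, AC = 50), c(AA = 3, AC = 500),
                         span = c(2L, 3L), minBg = 10L)
  dl <- as.data.frame(low)
  expect_true(dl$low_background[dl$motif == "AA"])
  expect_true(is.na(dl$rank[dl$motif == "AA"]))
  expect_error(normalizeMotifs(c(AA = 0), c(AA = 0), span = c(2L, 3L)),
               "zero totals")
})

test_that("scaling all background counts leaves relative abundance unchanged", {
  set.seed(1)
  cnt <- setNames(rpois(16, 100) + 10, racescreen:::kmerStrings(2L))
  bg <- setNames(rpois(16, 80) + 10, racescreen:::kmerStrings(2L))
  a <- normalizeMotifs(cnt, bg, span = c(2L, 3L))
  b <- normalizeMotifs(cnt, bg * 7, span = c(2L, 3L))
  expect_equal(relAbundance(a), relAbundance(b))
})

test_that("homopolymer flags apply to the +1-prefixed motif", {
  rel <- setNames(rep(1, 3), c("GGGATCA", "ATCGATC", "AAAATCG"))
  tb <- toyTable(rel)
  fl <- flagHomopolymers(tb, minRun = 4L)
  df <- as.data.frame(fl)
  # +1 G prefix turns GGGATCA into GGGG...; AAAA is a run on its own
  expect_identical(df$homopolymer[match(c("GGGATCA", "ATCGATC", "AAAATCG"),
                                        df$motif)],
                   c(TRUE, FALSE, TRUE))
  # G-only rule ignores the AAAA run
  flG <- flagHomopolymers(tb, minRun = 4L, bases = "G")
  dfG <- as.data.frame(flG)
  expect_identical(dfG$homopolymer[match(c("GGGATCA", "AAAATCG"), dfG$motif)],
                   c(TRUE, FALSE))
  expect_true(setequal(df$rank[!df$homopolymer], seq_len(sum(!df$homopolymer))))
})

test_that("composition algebra: null, signal and background-only bias", {
  u <- matrix(250, 4L, 15L, dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_true(all(abs(compositionMatrix(u, u) - 0.25) < 1e-12))
  f <- u; f[, 3] <- c(400, 200, 200, 200)
  cm <- compositionMatrix(f, u)
  expect_equal(unname(cm[3, ]), c(0.4, 0.2, 0.2, 0.2))
  # bias present only in the background normalizes away entirely
  b <- u; b[, 5] <- c(700, 100, 100, 100)
  cm2 <- compositionMatrix(b, b)
  expect_true(all(abs(cm2 - 0.25) < 1e-12))
  expect_true(all(abs(rowSums(cm) - 1) < 1e-9))
  bz <- u; bz[1, 1] <- 0
  expect_error(compositionMatrix(u, bz), "zero background")
})

test_that("dinucleotide groups use type-7 quartiles and 1.5 IQR whiskers", {
  motifs <- paste0("AA", c("AAAAC", "AAACA", "AACAA"))
  tb <- toyTable(setNames(2^(1:3), motifs))
  g <- groupByDinucleotide(tb)
  aa <- g[g$dinuc == "AA", ]
  expect_equal(aa$n_motifs, 3L)
  expect_equal(c(aa$q1, aa$median, aa$q3), c(1.5, 2, 2.5))
  expect_equal(aa$whisker_lo, 1.5 - 1.5)
  expect_equal(aa$whisker_hi, 2.5 + 1.5)
  # a fully flagged group reports n = 0
  tb2 <- flagHomopolymers(toyTable(setNames(1, "CCCCCCC")), minRun = 4L)
  g2 <- groupByDinucleotide(tb2)
  expect_equal(g2$n_motifs[g2$dinuc == "CC"], 0L)
})

test_that("extra-G fractions are plain arithmetic with Wilson intervals", {
  m15 <- rep(paste0("GG", strrep("A", 13L)), 100L)   # class GGG
  e <- c(rep(1L, 77L), rep(2L, 2L), rep(0L, 21L))
  rep_ <- extraGFractions(frsFromMotifs(m15, e))
  gg <- rep_[rep_$class == "GGG", ]
  expect_equal(gg$frac_ge1, 0.79)
  expect_equal(gg$frac_eq2, 0.02)
  expect_equal(gg$frac_eq1 + gg$frac_eq2, gg$frac_ge1)
  expect_equal(c(gg$ge1_lo, gg$ge1_hi),
               racescreen:::.wilsonCI(79L, 100L))
  empty <- rep_[rep_$class == "GAA", ]
  expect_equal(empty$n, 0L)
  expect_true(is.na(empty$frac_ge1))
  allz <- extraGFractions(frsFromMotifs(m15, 0L))
  expect_equal(allz$frac_ge1[allz$class == "GGG"], 0)
})

test_that("ranking is dense, descending, with lexicographic ties", {
  tb <- toyTable(c(AAAAT = 3.0, ATAAT = 2.0, CCCGT = 1.0), span = c(4L, 8L))
  expect_equal(unname(motifRank(tb)), c(1, 2, 3))
  tied <- toyTable(c(TTTTT = 1.0, AAAAA = 1.0, GGGGG = 2.0), span = c(4L, 8L))
  r <- motifRank(tied)
  expect_equal(unname(r[c("GGGGG", "AAAAA", "TTTTT")]), c(1, 2, 3))
  # context ranking subsets a +2..+8 table by its +2/3 start
  tb28 <- toyTable(c(GGAAAAA = 4, GGCCCCC = 1, ATAAAAA = 9))
  rk <- rankMotifs(tb28, context = "GG")
  expect_equal(nrow(as.data.frame(rk)), 2L)
  expect_equal(unname(motifRank(rk)[["GGAAAAA"]]), 1)
  expect_error(rankMotifs(tb28, context = "TT"), "empty")
})

test_that("activity range is a quantile ratio", {
  tb <- toyTable(setNames(1:10, racescreen:::kmerStrings(7L)[1:10]))
  expect_equal(activityRange(tb, 0, 1), 10)
  expect_error(activityRange(tb, 0.9, 0.1), "out of order")
  expect_error(activityRange(toyTable(c(AAAAAAA = 1)), 0, 1), "at least 10")
})

test_that("replicate correlation over shared unflagged motifs", {
  rel <- setNames(2^seq(-2, 2, length.out = 12),
                  racescreen:::kmerStrings(7L)[1:12])
  a <- toyTable(rel)
  expect_equal(replicateCorrelation(a, a)$pearson_log2, 1.0)
  b <- toyTable(setNames(rev(unname(rel)), names(rel)))
  expect_equal(replicateCorrelation(a, b)$spearman, -1.0)
  expect_error(replicateCorrelation(toyTable(c(AAAAAAA = 1, AAAAAAC = 2)),
                                    toyTable(c(AAAAAAA = 1, AAAAAAC = 2))),
               "insufficient")
})

test_that("oversampling arithmetic", {
  expect_equal(oversampling(16384, c(2L, 8L)), 1.0)
  expect_equal(oversampling(35e6, c(2L, 8L)), 35e6 / 16384)
  expect_gt(oversampling(84e6, c(2L, 8L)), 5000)
  expect_error(oversampling(0, c(2L, 8L)), "positive")
})
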