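# promoter design: loading, scoring, edit-budget search, primer assembly

T7 <- "TAATACGACTCACTATA"

writeToyTable <- function(df) {
  f <- tempfile(fileext = ".tsv")
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  f
}

test_that("motif table loader validates and ranks", {
  f <- writeToyTable(data.frame(motif = c("AAATA", "ATAAT", "GCGCG"),
                                rel_abundance = c(3, 2, 1)))
  tb <- loadMotifTable(f, span = c(4L, 8L))
  expect_equal(unname(motifRank(tb)), c(1, 2, 3))
  f2 <- writeToyTable(data.frame(motif = c("AAATA", "AAATA"),
                                 rel_abundance = c(1, 2)))
  expect_error(loadMotifTable(f2, span = c(4L, 8L)), "duplicate")
  f3 <- writeToyTable(data.frame(motif = "AAATA", something = 1))
  expect_error(loadMotifTable(f3, span = c(4L, 8L)), "rel_abundance")
  f4 <- writeToyTable(data.frame(motif = "AAAT", rel_abundance = 1))
  expect_error(loadMotifTable(f4, span = c(4L, 8L)), "width")
})

test_that("scoring extracts the span motif downstream of the core promoter", {
  tb <- toyTable(c(AAATA = 3, ATAAT = 2, GCGCG = 1), span = c(4L, 8L))
  seq <- paste0("TT", T7, "GGG", "AAATA", "CTGACTGA")
  res <- scorePromoter(seq, tb)
  expect_equal(res@motif, "AAATA")
  expect_equal(res@rank, 1)
  expect_false(res@contextWarning)
  # non-GGG start carries a context warning flag
  res2 <- scorePromoter(paste0(T7, "GAT", "ATAAT", "CTGACTGA"), tb)
  expect_true(res2@contextWarning)
  expect_error(scorePromoter(paste0(T7, "GGG", "CCCCC", "CTGACTGA"), tb),
               "CCCCC")
  expect_error(scorePromoter(paste0("AAAA", "GGGAAATACTGACTGA"), tb),
               "core promoter")
  expect_error(scorePromoter(paste0(T7, "GGGAA"), tb), "too short")
})

test_that("zero edit budget returns the query itself", {
  tb <- toyTable(c(AAATA = 3, ATAAT = 2, GCGCG = 1), span = c(4L, 8L))
  seq <- paste0(T7, "GGG", "ATAAT", "CT")
  out <- optimizeInsert(seq, tb, maxInsertions = 0L, maxSubstitutions = 0L)
  expect_equal(nrow(out), 1L)
  expect_equal(out$sequence, seq)
  expect_equal(out$motif, "ATAAT")
  expect_equal(out$n_insertions + out$n_substitutions, 0)
})

test_that("single-edit search equals brute-force enumeration", {
  set.seed(4)
  rel <- setNames(runif(1024), racescreen:::kmerStrings(5L))
  tb <- toyTable(rel, span = c(4L, 8L))
  down0 <- "GGGTACGTCAG"
  seq <- paste0(T7, down0)
  out <- optimizeInsert(seq, tb, window = c(3L, 8L), maxInsertions = 1L,
                        maxSubstitutions = 1L)
  # brute force: all 0/1-insertion x 0/1-substitution combos in the window
  insOne <- function(s) {
    res <- character(0)
    for (p in 3:(min(8L, nchar(s)) + 1L)) for (b in c("A", "C", "G", "T"))
      res <- c(res, paste0(substr(s, 1, p - 1), b, substring(s, p)))
    unique(res)
  }
  subOne <- function(s) {
    res <- character(0)
    for (p in 3:min(8L, nchar(s))) for (b in c("A", "C", "G", "T"))
      res <- c(res, paste0(substr(s, 1, p - 1), b, substring(s, p + 1)))
    unique(res)
  }
  i1 <- insOne(down0); s1 <- subOne(down0)
  cand <- unique(c(down0, i1, s1,
                   unlist(lapply(i1, subOne)), unlist(lapply(s1, insOne))))
  bruteMotifs <- unique(substr(cand, 4, 8))
  expect_setequal(out$motif, bruteMotifs)
  expect_equal(out$rank[1], min(motifRank(tb)[bruteMotifs]))
  # candidates come out sorted by rank
  expect_true(all(diff(out$rank) >= 0))
})

test_that("insertion enumeration collapses duplicate outcomes", {
  tb <- toyTable(setNames(rep(1, 1024), racescreen:::kmerStrings(5L)),
                 span = c(4L, 8L))
  down0 <- "GGGAACC"
  out <- optimizeInsert(paste0(T7, down0), tb, window = c(3L, 8L),
                        maxInsertions = 2L, maxSubstitutions = 0L)
  # independent count of distinct sequences reachable by <= 2 insertions
  insertAll <- function(s) {
    res <- character(0)
    top <- min(8L, nchar(s)) + 1L
    for (p in 3:top) for (b in c("A", "C", "G", "T"))
      res <- c(res, paste0(substr(s, 1, p - 1), b, substring(s, p)))
    unique(res)
  }
  lvl1 <- insertAll(down0)
  lvl2 <- unique(unlist(lapply(lvl1, insertAll)))
  want <- unique(c(down0, lvl1, lvl2))
  want <- want[nchar(want) >= 8L]   # shorter outcomes carry no +4..+8 motif
  expect_equal(nrow(out), length(want))
  expect_setequal(substr(out$sequence, nchar(T7) + 1L, 100L), want)
})

test_that("a GA insertion at +3/+4 changes the scored +4..+8 motif", {
  set.seed(9)
  rel <- setNames(runif(1024), racescreen:::kmerStrings(5L))
  tb <- toyTable(rel, span = c(4L, 8L))
  seq <- paste0(T7, "GGG", "TCGAG", "TT")
  base <- scorePromoter(seq, tb)
  expect_equal(base@motif, "TCGAG")
  edited <- paste0(T7, "GGG", "GA", "TCGAG", "TT")  # GA inserted at +3/+4
  got <- scorePromoter(edited, tb)
  expect_equal(got@motif, "GATCG")
  # the two-insertion search must reach this candidate
  out <- optimizeInsert(seq, tb, window = c(3L, 8L), maxInsertions = 2L)
  expect_true("GATCG" %in% out$motif)
})

test_that("enlarging budgets never worsens the best attainable rank", {
  set.seed(5)
  rel <- setNames(runif(1024), racescreen:::kmerStrings(5L))
  tb <- toyTable(rel, span = c(4L, 8L))
  seq <- paste0(T7, "GGGTACGT", "CT")
  best <- sapply(0:2, function(k)
    optimizeInsert(seq, tb, maxInsertions = k, maxSubstitutions = 0L)$rank[1])
  expect_true(all(diff(best) <= 0))
  best2 <- optimizeInsert(seq, tb, maxInsertions = 2L,
                          maxSubstitutions = 1L)$rank[1]
  expect_lte(best2, best[3])
})

test_that("primer assembly annotates regions and warns on low AT", {
  p <- assemblePrimer("ATTA", T7, itr = "GGGAAATA", tail = "TTTT")
  expect_equal(p$sequence, paste0("ATTA", T7, "GGGAAATA", "TTTT"))
  expect_equal(p$at_fraction, 1.0)
  ann <- p$annotation
  expect_equal(ann$start[ann$region == "upstream_element"], -21L)
  expect_equal(ann$end[ann$region == "upstream_element"], -18L)
  expect_equal(ann$start[ann$region == "core"], -17L)
  expect_equal(ann$start[ann$region == "itr"], 1L)
  expect_warning(assemblePrimer("GCGC", T7, itr = "GGG"), "AT fraction")
  expect_error(assemblePrimer("ATXA", T7, itr = "GGG"), "A, C, G, T")
  # empty upstream element: core + ITR only
  p2 <- assemblePrimer("", T7, itr = "GGG")
  expect_false("upstream_element" %in% p2$annotation$region)
  # assembling then scoring round-trips the insert's table rank
  tb <- toyTable(c(AAATA = 3, ATAAT = 2, GCGCG = 1), span = c(4L, 8L))
  res <- scorePromoter(p$sequence, tb)
  expect_equal(res@motif, "AAATA")
  expect_equal(res@rank, 1)
})
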