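# filtering cascade

test_that("structural filter equals brute force on all position-16..21 variants", {
  bases <- c("A", "C", "G", "T")
  g <- expand.grid(rep(list(bases), 6L), stringsAsFactors = FALSE)
  mid <- do.call(paste0, g)                       # positions 16..21
  prefix <- "ACGTACGTACGTACG"
  reads <- paste0(prefix, mid, strrep("A", 35L - 21L))
  got <- structuralFilter(reads)
  want <- lapply(reads, bruteStructural)
  expect_identical(got$accept, vapply(want, `[[`, TRUE, "accept"))
  acc <- got$accept
  expect_identical(got$extra_c[acc],
                   vapply(want[acc], function(x) as.integer(x$extra), 0L))
  # only the AA/CA/CC whitelist at 17-18 can be accepted
  expect_true(all(substr(reads, 17L, 18L)[acc] %in% c("AA", "CA", "CC")))
  expect_true(all(substr(reads, 16L, 16L)[acc] == "C"))
})

test_that("poly(A) tolerance accepts 9 of 10 A but not 8 of 10", {
  r_ok <- paste0(strrep("G", 15L), "CCA", "AAAAAAAATA", strrep("A", 7L))
  r_bad <- paste0(strrep("G", 15L), "CCA", "AAAAATAATA", strrep("A", 7L))
  sf <- structuralFilter(c(r_ok, r_bad))
  expect_identical(sf$accept, c(TRUE, FALSE))
  expect_identical(sf$extra_c, c(1L, 1L))
  expect_error(structuralFilter("ACGT"), "too short")
})

test_that("toSense reverse-complements and rejects N", {
  expect_identical(toSense(paste0("ACGTACGTACGTACG", strrep("A", 20L))),
                   "CGTACGTACGTACGT")
  x <- paste0("ACGTACGTACGTACG", strrep("A", 20L))
  expect_identical(revComp(revComp(toSense(x))), toSense(x))
  withN <- paste0("ACGTACGNACGTACG", strrep("A", 20L))
  expect_true(is.na(toSense(withN)))
})

test_that("constant filter equals a brute-force Hamming scan", {
  cfg <- screenConfig()
  constants <- cfg@constantSeqs
  set.seed(1)
  rnd <- replicate(300, paste(sample(c("A", "C", "G", "T"), 15L, TRUE),
                              collapse = ""))
  # enrich with planted hits at distance 0, 1 and 2
  w <- substr(constants[[1]], 3L, 12L)
  d1 <- w; substr(d1, 4L, 4L) <- setdiff(c("A", "C", "G", "T"),
                                         substr(w, 4L, 4L))[1]
  d2 <- d1; substr(d2, 8L, 8L) <- setdiff(c("A", "C", "G", "T"),
                                          substr(d1, 8L, 8L))[1]
  probes <- c(rnd, paste0(c(w, d1, d2), "AAAAA"))
  keep <- constantSeqFilter(probes, constants, maxMismatch = 1L)
  brute <- !vapply(substr(probes, 1L, 10L), bruteConstantHit, TRUE,
                   constants = constants, maxMismatch = 1L)
  expect_identical(unname(keep), unname(brute))
  n <- length(probes)
  expect_false(keep[n - 2L])   # exact window
  expect_false(keep[n - 1L])   # one mismatch
  expect_true(keep[n])         # two mismatches survive
})

test_that("dedup keeps first occurrences of 15mer-UMI keys", {
  r1 <- c("AAACCCGGGTTTAAA", "AAACCCGGGTTTAAA", "AAACCCGGGTTTAAA")
  r2 <- c("CCCCC", "CCCCC", "GGGGG")
  expect_identical(dedupPairs(r1, r2), c(TRUE, FALSE, TRUE))
  set.seed(2)
  rnd1 <- replicate(50, paste(sample(c("A", "C", "G", "T"), 20L, TRUE),
                              collapse = ""))
  rnd2 <- replicate(50, paste(sample(c("A", "C", "G", "T"), 10L, TRUE),
                              collapse = ""))
  expect_true(all(dedupPairs(rnd1, rnd2)))
})

test_that("contaminant k-mer filter discards substrings and spares random reads", {
  set.seed(3)
  contam <- paste(sample(c("A", "C", "G", "T"), 5000L, TRUE), collapse = "")
  idx <- buildContaminantIndex(contam, k = 21L)
  hit <- substr(contam, 101L, 135L)
  hit_rc <- revComp(substr(contam, 2001L, 2035L))
  rnd <- replicate(200, paste(sample(c("A", "C", "G", "T"), 35L, TRUE),
                              collapse = ""))
  keep <- contaminantFilter(c(hit, hit_rc, rnd), idx, k = 21L)
  expect_identical(keep[1:2], c(FALSE, FALSE))
  expect_true(all(keep[-(1:2)]))   # collision probability < 5000/4^21
  expect_true(all(contaminantFilter(rnd, NULL)))
  expect_error(buildContaminantIndex("ACGT", k = 21L), "length >= k")
  expect_error(buildContaminantIndex(contam, k = 5L), ">= 11")
})

test_that("processRun matches ground truth exactly on clean reads", {
  cfg <- screenConfig()
  lib <- simulateTemplateLibrary(cfg, 1e6, seed = 4)
  model <- buildActivityModel("t7_like", seed = 4, pRtC = 0.3)
  tr <- transcribe(lib, model, 3000, seed = 5)
  rd <- makeReads(tr, cfg, model, errorRate = 0, dupRate = 0, seed = 6)
  out <- processRun(rd@read1, rd@read2, cfg)
  # expected: all reads pass structure (extras capped at 2), minus reads
  # whose +2..+11 10mer hits a constant window
  sense15 <- paste0(racescreen:::kmerStrings(7L)[rd@origin$m7],
                    racescreen:::kmerStrings(8L)[rd@origin$t8])
  constHit <- !constantSeqFilter(sense15, cfg@constantSeqs)
  expect_equal(out$stats@accepted, sum(!constHit))
  got <- as.data.frame(out$reads)
  expect_identical(got$motif15, sense15[!constHit])
  expect_identical(got$extra_c, rd@origin$extra_c[!constHit])
  expect_identical(got$umi,
                   racescreen:::kmerStrings(5L)[rd@origin$umi[!constHit]])
})

test_that("filter stats telescope and processing is idempotent", {
  cfg <- screenConfig()
  lib <- simulateTemplateLibrary(cfg, 1e5, seed = 7)
  tr <- transcribe(lib, buildActivityModel("t7_like", seed = 7), 2000, seed = 8)
  rd <- makeReads(tr, cfg, buildActivityModel("t7_like", seed = 7),
                  errorRate = 0.005, dupRate = 0.3, seed = 9)
  out <- processRun(rd@read1, rd@read2, cfg)
  s <- out$stats
  expect_equal(s@input, s@contaminantRemoved + s@dedupRemoved +
                 s@structureFailed + s@polyAFailed + s@constantRemoved +
                 s@accepted)
  expect_equal(s@input, length(rd@read1))
  # feeding the survivors back through changes nothing
  surv <- as.data.frame(out$reads)
  r1b <- paste0(revComp(surv$motif15),
                "C", c("AA", "CA", "CC")[surv$extra_c + 1L],
                strrep("A", 17L))
  r2b <- paste0(surv$umi, strrep("T", 30L))
  out2 <- processRun(r1b, r2b, cfg)
  expect_equal(out2$stats@accepted, nrow(surv))
  expect_identical(as.data.frame(out2$reads), surv)
})

test_that("chunking does not change results", {
  cfg <- screenConfig()
  lib <- simulateTemplateLibrary(cfg, 1e5, seed = 10)
  tr <- transcribe(lib, quietModel(), 5000, seed = 11)
  rd <- makeReads(tr, cfg, quietModel(), errorRate = 0.01, dupRate = 0.2,
                  seed = 12)
  a <- processRun(rd@read1, rd@read2, cfg, chunkSize = 333)
  b <- processRun(rd@read1, rd@read2, cfg, chunkSize = 1e6)
  expect_identical(a$reads@m15code, b$reads@m15code)
  expect_identical(as.data.frame(a$stats), as.data.frame(b$stats))
})

test_that("degenerate inputs are handled", {
  cfg <- screenConfig()
  out <- processRun(character(0), character(0), cfg)
  expect_equal(out$stats@input, 0)
  expect_length(out$reads, 0L)
  expect_error(processRun("ACGT", character(0), cfg), "mismatched")
  # paired FASTQ round trip
  f1 <- tempfile(fileext = ".fastq.gz"); f2 <- tempfile(fileext = ".fastq.gz")
  lib <- simulateTemplateLibrary(cfg, 1e5, seed = 13)
  tr <- transcribe(lib, quietModel(), 200, seed = 14)
  rd <- makeReads(tr, cfg, quietModel(), errorRate = 0, dupRate = 0, seed = 15)
  writeFastq(rd@read1, f1); writeFastq(rd@read2, f2)
  out2 <- processRun(f1, f2, cfg)
  out3 <- processRun(rd@read1, rd@read2, cfg)
  expect_identical(out2$reads@m15code, out3$reads@m15code)
})

test_that("dedup order relative to the structural filter is configurable", {
  # one structure-failing read shares its key with a later clean read:
  # dedup-first removes the clean copy, dedup-after keeps it
  bad <- paste0(strrep("A", 15L), "GAA", strrep("A", 17L))
  good <- paste0(strrep("A", 15L), "CAA", strrep("A", 17L))
  r2 <- rep("CCCCCTTTTTTTTTT", 2L)
  cfg1 <- screenConfig()
  out1 <- processRun(c(bad, good), r2, cfg1)
  expect_equal(out1$stats@accepted, 0)
  cfg2 <- screenConfig(dedupAfterStructure = TRUE)
  out2 <- processRun(c(bad, good), r2, cfg2)
  expect_equal(out2$stats@accepted, 1)
})

test_that("background processing uses the first 15 sense bases", {
  cfg <- screenConfig()
  lib <- simulateTemplateLibrary(cfg, 1e5, seed = 16)
  bgReads <- simulateBackground(lib, cfg, 500, errorRate = 0, seed = 17)
  bg <- processBackground(bgReads, cfg)
  expect_identical(motifs15(bg), substr(bgReads, 1L, 15L))
  cfgA <- screenConfig(bgAntisense = TRUE)
  bgA <- processBackground(revComp(bgReads), cfgA)
  expect_identical(sort(motifs15(bgA)), sort(substr(bgReads, 1L, 15L)))
})

test_that("fast simulation path equals the string path bit for bit", {
  cfg <- screenConfig()
  lib <- simulateTemplateLibrary(cfg, 1e6, seed = 18)
  model <- buildActivityModel("t7_like", seed = 18)
  tr <- transcribe(lib, model, 2e4, seed = 19)
  set.seed(20)
  fast <- racescreen:::.simChunkFast(tr, cfg, model, 0.002, 0.15)
  set.seed(20)
  rd <- makeReads(tr, cfg, model, errorRate = 0.002, dupRate = 0.15)
  slow <- racescreen:::.chunkFields(rd@read1, rd@read2, cfg, NULL)
  for (nm in names(slow))
    expect_identical(unname(fast[[nm]]), unname(slow[[nm]]), info = nm)
  set.seed(21)
  bgF <- racescreen:::.simBgCodesFast(lib, cfg, 2e4, 0.002)
  set.seed(21)
  bgS <- processBackground(simulateBackground(lib, cfg, 2e4, 0.002), cfg)
  expect_identical(unname(bgF), unname(bgS@m15code))
})
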