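# shared fixture builders (everything is generated in code)

tinyConfig <- function(...) screenConfig(...)

# a TranscriptSet with explicit motifs/tails/extra-G, for layout tests
manualTranscripts <- function(motif7, tail8, nExtraG = 0L) {
  m7 <- as.integer(racescreen:::encodeKmers(motif7, 7L)) + 1L
  t8 <- as.integer(racescreen:::encodeKmers(tail8, 8L)) + 1L
  n <- max(length(m7), length(t8))
  new("TranscriptSet", m7 = rep_len(m7, n), t8 = rep_len(t8, n),
      nExtraG = rep_len(as.integer(nExtraG), n), truth = data.frame())
}

# model with no 5' events at all (clean read layout)
quietModel <- function(...) {
  buildActivityModel("uniform", pExtraG1 = 0, pExtraG2 = 0, pRtC = 0, ...)
}

# a small MotifTable straight from rel abundances
toyTable <- function(rel, span = c(2L, 8L), plus1 = "G") {
  tb <- data.frame(motif = names(rel), count = NA_real_, bg_count = NA_real_,
                   rel_abundance = unname(rel), log2_rel = log2(unname(rel)),
                   low_background = FALSE, homopolymer = FALSE,
                   rank = NA_real_, stringsAsFactors = FALSE)
  tb <- racescreen:::.assignRanks(tb)
  new("MotifTable", span = as.integer(span), table = tb,
      totalReads = NA_real_, totalBg = NA_real_, plus1 = plus1)
}

# independent brute-force evaluator of the structural 5' end rule
bruteStructural <- function(read, window = 10L, minFrac = 0.9) {
  ch <- strsplit(read, "")[[1L]]
  d <- paste0(ch[17], ch[18])
  extra <- match(d, c("AA", "CA", "CC")) - 1L
  if (ch[16] != "C" || is.na(extra)) return(list(accept = FALSE, extra = extra))
  p <- 17L + extra
  win <- ch[p:(p + window - 1L)]
  list(accept = sum(win == "A") >= minFrac * window, extra = extra)
}

# brute-force Hamming scan of a 10mer against all constant windows
bruteConstantHit <- function(m10, constants, maxMismatch = 1L) {
  seqs <- c(constants, racescreen::revComp(constants))
  q <- strsplit(m10, "")[[1L]]
  for (s in seqs) {
    if (nchar(s) < 10L) next
    for (o in 1:(nchar(s) - 9L)) {
      w <- strsplit(substr(s, o, o + 9L), "")[[1L]]
      if (sum(w != q) <= maxMismatch) return(TRUE)
    }
  }
  FALSE
}
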