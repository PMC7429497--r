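# Streaming fast path for deep simulated runs. Draws exactly the same
# random variates in the same order as makeReads()/simulateBackground(), so
# a run is bit-identical whichever path executes it (asserted in the test
# suite); the reads themselves are assembled and filtered inside the C
# kernel without materializing R strings.

# usable when nothing downstream needs the read strings themselves
.fastPathOK <- function(config, contamIdx, writingFastq) {
  is.null(contamIdx) && config@darkCycleLossProb == 0 && !writingFastq &&
    !config@bgAntisense
}

.simChunkFast <- function(transcripts, config, model, errorRate, dupRate) {
  n <- length(transcripts@m7)
  rtc <- stats::rbinom(n, 1L, model@pRtC)
  extraVis <- pmin(transcripts@nExtraG + rtc, 2L)
  umiIdx <- sample.int(4L^config@umiLen, n, replace = TRUE)
  dup <- if (dupRate > 0) which(stats::runif(n) < dupRate) else integer(0)
  src <- c(seq_len(n), dup)
  nTot <- length(src)
  ev1 <- .drawReadEvents(nTot, config@read1Len, errorRate)
  ev2 <- .drawReadEvents(nTot, config@read2Len, errorRate)
  o1 <- order(ev1$ridx); o2 <- order(ev2$ridx)
  tabs <- .readTables(config)
  f <- .cppSimFields(tabs$rc8, transcripts@t8[src],
                     tabs$rc7, transcripts@m7[src],
                     tabs$sfx, extraVis[src] + 1L,
                     tabs$umi, umiIdx[src],
                     ev1$ridx[o1], ev1$pos[o1], ev1$shift[o1],
                     ev2$ridx[o2], ev2$pos[o2], ev2$shift[o2],
                     config@umiLen, config@polyAWindow, config@polyAMinFrac,
                     config@read1Len)
  f$contamKeep <- rep(TRUE, nTot)
  f
}

.simBgCodesFast <- function(lib, config, nReads, errorRate) {
  m7 <- sample.int(16384L, nReads, replace = TRUE, prob = lib@motifCounts)
  t8 <- sample.int(65536L, nReads, replace = TRUE, prob = lib@tailCounts)
  code <- (m7 - 1) * 65536 + (t8 - 1)
  ev <- .drawReadEvents(nReads, config@read1Len, errorRate)
  sel <- ev$pos <= 15L
  if (any(sel)) {
    r <- ev$ridx[sel]; w <- 4^(15L - ev$pos[sel])
    old <- (code[r] %/% w) %% 4
    delta <- ((old + ev$shift[sel]) %% 4 - old) * w
    # several events may hit distinct positions of one read: aggregate
    agg <- rowsum(delta, r)
    idx <- as.integer(rownames(agg))
    code[idx] <- code[idx] + agg[, 1L]
  }
  code
}
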