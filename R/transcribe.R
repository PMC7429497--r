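# In vitro transcription of the template pool under an activity model.

#' Transcribe a template library
#'
#' Samples `nTranscripts` RNA molecules with probability proportional to
#' `molecule_count x transcription_weight` of each +1..+8 motif (the +9..+16
#' tail does not affect initiation and is drawn from its library
#' distribution). Each transcript additionally receives 0, 1 or 2 slipped 5'
#' Gs according to its +1..+3 class probabilities.
#'
#' @param lib A [TemplateLibrary].
#' @param model An [ActivityModel].
#' @param nTranscripts Number of transcripts to emit.
#' @param seed Integer seed, or `NULL` to draw from the current RNG stream.
#' @return A [TranscriptSet]; `groundTruth()` returns the per-motif truth
#'   table (motif7, weight, transcripts, extra_g0/1/2).
#' @examples
#' lib <- simulateTemplateLibrary(screenConfig(), nMolecules = 1e5, seed = 1)
#' tr <- transcribe(lib, buildActivityModel("uniform"), 1000, seed = 2)
#' length(tr)
#' @export
transcribe <- function(lib, model, nTranscripts, seed = NULL) {
  if (nTranscripts <= 0) stop("nTranscripts must be positive")
  if (sum(lib@motifCounts) == 0) stop("empty template library")
  if (!is.null(seed)) set.seed(as.integer(seed))

  w7 <- .weights7(model)
  p <- lib@motifCounts * w7
  if (all(p == 0)) stop("no transcribable molecules (all weights x counts are 0)")
  counts7 <- as.vector(stats::rmultinom(1L, size = nTranscripts, prob = p))
  m7 <- rep.int(seq_len(16384L), counts7)
  t8 <- sample.int(65536L, nTranscripts, replace = TRUE, prob = lib@tailCounts)

  cls <- (m7 - 1L) %/% 1024L + 1L            # +2/3 dinucleotide index
  u <- stats::runif(nTranscripts)
  g2 <- model@pExtraG2[cls]; g1 <- model@pExtraG1[cls]
  nExtraG <- as.integer(u < g2) + as.integer(u < g1 + g2)

  truth <- data.frame(
    motif7 = kmerStrings(7L),
    weight = w7,
    transcripts = counts7,
    extra_g0 = tabulate(m7[nExtraG == 0L], 16384L),
    extra_g1 = tabulate(m7[nExtraG == 1L], 16384L),
    extra_g2 = tabulate(m7[nExtraG == 2L], 16384L),
    stringsAsFactors = FALSE)

  new("TranscriptSet", m7 = m7, t8 = t8, nExtraG = nExtraG, truth = truth)
}
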