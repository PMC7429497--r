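# Generics, accessors and show methods.

#' @rdname accessors
#' @param x An object.
#' @param ... Further arguments.
#' @export
setGeneric("motifCounts", function(x, ...) standardGeneric("motifCounts"))

#' @rdname accessors
#' @export
setGeneric("tailCounts", function(x, ...) standardGeneric("tailCounts"))

#' @rdname accessors
#' @export
setGeneric("modelWeights", function(x, ...) standardGeneric("modelWeights"))

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x, ...) standardGeneric("groundTruth"))

#' @rdname accessors
#' @export
setGeneric("motifs15", function(x, ...) standardGeneric("motifs15"))

#' @rdname accessors
#' @export
setGeneric("extraC", function(x, ...) standardGeneric("extraC"))

#' @rdname accessors
#' @export
setGeneric("umis", function(x, ...) standardGeneric("umis"))

#' @rdname accessors
#' @export
setGeneric("filterStats", function(x, ...) standardGeneric("filterStats"))

#' @rdname accessors
#' @export
setGeneric("motifSpan", function(x, ...) standardGeneric("motifSpan"))

#' @rdname accessors
#' @export
setGeneric("relAbundance", function(x, ...) standardGeneric("relAbundance"))

#' @rdname accessors
#' @export
setGeneric("motifRank", function(x, ...) standardGeneric("motifRank"))

#' Accessors for screen objects
#'
#' Small accessor family: `motifCounts`/`tailCounts` return template-library
#' segment counts; `modelWeights` the per +1..+8 motif transcription weights;
#' `groundTruth` the per-motif truth table; `motifs15`, `extraC`, `umis`
#' the per-read fields of a [FilteredReadSet]; `relAbundance` and
#' `motifRank` named columns of a [MotifTable].
#'
#' @name accessors
#' @param x An object.
#' @param ... Unused.
NULL

#' @rdname accessors
#' @export
setMethod("motifCounts", "TemplateLibrary", function(x, ...) {
  stats::setNames(x@motifCounts, kmerStrings(7L))
})

#' @rdname accessors
#' @export
setMethod("tailCounts", "TemplateLibrary", function(x, ...) {
  stats::setNames(x@tailCounts, kmerStrings(8L))
})

#' @rdname accessors
#' @param config A [ScreenConfig] supplying the +1 base for motif naming.
#' @export
setMethod("modelWeights", "ActivityModel", function(x, config = screenConfig(), ...) {
  w7 <- .weights7(x)
  stats::setNames(w7, paste0(config@plus1Base, kmerStrings(7L)))
})

#' @rdname accessors
#' @export
setMethod("groundTruth", "TranscriptSet", function(x, ...) x@truth)

#' @rdname accessors
#' @export
setMethod("groundTruth", "ScreenResult", function(x, ...) x@truth)

#' @rdname accessors
#' @export
setMethod("motifs15", "MotifReadSet", function(x, ...) decodeKmers(x@m15code, 15L))

#' @rdname accessors
#' @export
setMethod("extraC", "FilteredReadSet", function(x, ...) x@extraC)

#' @rdname accessors
#' @export
setMethod("umis", "FilteredReadSet", function(x, ...) decodeKmers(x@umiCode, x@umiLen))

#' @rdname accessors
#' @export
setMethod("filterStats", "ScreenResult", function(x, ...) x@stats)

#' @rdname accessors
#' @export
setMethod("motifSpan", "MotifTable", function(x, ...) x@span)

#' @rdname accessors
#' @export
setMethod("relAbundance", "MotifTable", function(x, ...) {
  stats::setNames(x@table$rel_abundance, x@table$motif)
})

#' @rdname accessors
#' @export
setMethod("motifRank", "MotifTable", function(x, ...) {
  stats::setNames(x@table$rank, x@table$motif)
})

#' @export
#' @rdname accessors
setMethod("length", "MotifReadSet", function(x) length(x@m15code))

#' Coerce a FilteredReadSet to a data.frame
#'
#' Materializes the per-read table (motif15, extra_c, umi).
#'
#' @param x A [FilteredReadSet].
#' @param ... Unused.
#' @export
setMethod("as.data.frame", "FilteredReadSet", function(x, ...) {
  data.frame(motif15 = motifs15(x), extra_c = x@extraC, umi = umis(x),
             stringsAsFactors = FALSE)
})

#' @rdname accessors
#' @export
setMethod("as.data.frame", "MotifTable", function(x, ...) x@table)

#' @rdname accessors
#' @export
setMethod("as.data.frame", "FilterStats", function(x, ...) {
  data.frame(stage = c("input", "contaminant_removed", "dedup_removed",
                       "structure_failed", "polyA_failed",
                       "constant_match_removed", "accepted"),
             reads = c(x@input, x@contaminantRemoved, x@dedupRemoved,
                       x@structureFailed, x@polyAFailed, x@constantRemoved,
                       x@accepted))
})

setMethod("show", "ScreenConfig", function(object) {
  cat("ScreenConfig [", object@polymeraseMode, "]\n", sep = "")
  cat("  randomized span: +", object@randomizedSpan[1], "..+",
      object@randomizedSpan[2], ", +1 base ", object@plus1Base, "\n", sep = "")
  cat("  reads: 2 x ", object@read1Len, " nt, UMI ", object@umiLen, " nt\n",
      sep = "")
  cat("  core promoter (-17..-1): ", object@upstreamCore, "\n", sep = "")
})

setMethod("show", "ActivityModel", function(object) {
  cat("ActivityModel [", object@mode, "], fold range ", object@foldRange,
      "\n", sep = "")
  cat("  itr factor (+4..+8): ",
      signif(min(object@itrFactor), 4), " .. ",
      signif(max(object@itrFactor), 4), "\n", sep = "")
  cat("  p(extra G | GGG start): ", object@pExtraG1[["GG"]], " / ",
      object@pExtraG2[["GG"]], "; p(RT C): ", object@pRtC, "\n", sep = "")
})

setMethod("show", "TemplateLibrary", function(object) {
  cat("TemplateLibrary: ", format(object@nMolecules, big.mark = ","),
      " molecules\n", sep = "")
})

setMethod("show", "TranscriptSet", function(object) {
  cat("TranscriptSet: ", length(object@m7), " transcripts, ",
      sum(object@truth$transcripts > 0), " motifs seen\n", sep = "")
})

setMethod("show", "FilteredReadSet", function(object) {
  cat("FilteredReadSet: ", length(object@m15code), " accepted reads\n",
      sep = "")
})

setMethod("show", "FilterStats", function(object) {
  print(as.data.frame(object))
})

setMethod("show", "MotifTable", function(object) {
  cat("MotifTable +", object@span[1], "..+", object@span[2], ": ",
      nrow(object@table), " motifs (", sum(!is.na(object@table$rank)),
      " ranked)\n", sep = "")
  cat("  totals: ", object@totalReads, " reads / ", object@totalBg,
      " background\n", sep = "")
})

setMethod("show", "DesignResult", function(object) {
  cat("DesignResult: motif ", object@motif, ", rel abundance ",
      signif(object@relAbundance, 4), ", rank ", object@rank, "\n", sep = "")
  if (nrow(object@edits))
    cat("  edits: ", paste(object@edits$type, object@edits$position,
                           object@edits$base, collapse = "; "), "\n", sep = "")
  if (object@contextWarning)
    cat("  note: +1..+3 context is not GGG\n")
})

setMethod("show", "ScreenResult", function(object) {
  cat("ScreenResult\n")
  print(as.data.frame(object@stats))
  s <- object@summary
  if (length(s))
    cat("  summary: ", paste(names(s), signif(unlist(s), 4), sep = "=",
                             collapse = ", "), "\n", sep = "")
})

# subset transcripts (used by the chunked orchestrator)
#' @export
setMethod("[", "TranscriptSet", function(x, i, j, ..., drop = TRUE) {
  new("TranscriptSet", m7 = x@m7[i], t8 = x@t8[i], nExtraG = x@nExtraG[i],
      truth = data.frame())
})

#' @export
setMethod("length", "TranscriptSet", function(x) length(x@m7))
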