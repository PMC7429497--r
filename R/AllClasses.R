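# Core S4 classes for the promoter-activity screen.

#' @import methods
NULL

# canonical phage polymerase core promoters, -17..-1 (the +1 G is not part
# of the core)
T7_CORE  <- "TAATACGACTCACTATA"
SP6_CORE <- "ATTTAGGTGACACTATA"

# default constant sequences used for background-read fill and the
# constant-sequence cross-contamination filter: a synthetic template backbone
# downstream of +16 plus standard flow-cell adapter constants
DEFAULT_CONSTANTS <- c(
  template_downstream = "CTGGAGTTCAGACGTGTGCTCTTCCGATCTTGGAATTCTCGGGTGCCAAGGAACTCCAGT",
  p5_adapter = "AATGATACGGCGACCACCGAGATCTACAC",
  p7_adapter = "CAAGCAGAAGACGGCATACGAGAT"
)

#' ScreenConfig: run configuration for a 5' RACE promoter screen
#'
#' Holds the read geometry, constant sequences and filter parameters of one
#' screen. Positions use TSS coordinates: +1 is the first transcribed base
#' (there is no position 0); read positions are 1-based.
#'
#' @slot polymeraseMode `"T7"` or `"SP6"`.
#' @slot randomizedSpan Integer length-2, the randomized promoter interval in
#'   TSS coordinates (default `c(2L, 16L)`).
#' @slot plus1Base Fixed +1 nucleotide (default `"G"`).
#' @slot read1Len,read2Len,umiLen Read geometry in nt.
#' @slot upstreamCore The -17..-1 core promoter sequence.
#' @slot constantSeqs Named character vector of constant sequences (template
#'   backbone, adapters) screened by the constant-sequence filter.
#' @slot polyAWindow,polyAMinFrac Poly(A)-tail check: window length after the
#'   extra-C block and minimum fraction of A within it.
#' @slot constantMaxMismatch Maximum Hamming distance for the +2..+11 10mer
#'   constant-sequence filter.
#' @slot minBg Minimum background count for a motif to enter normalization.
#' @slot homopolymerMinRun,homopolymerBases Homopolymer-flag rule applied to
#'   the +1-prefixed motif.
#' @slot contaminants Contaminant sequences (e.g. PhiX genome); empty
#'   disables the contaminant filter.
#' @slot contamK,contamMinHits K-mer size and hit threshold of the
#'   contaminant filter.
#' @slot dedupAfterStructure If `TRUE`, deduplicate after the structural
#'   filter instead of before.
#' @slot darkCycleLossProb,darkCycleMinRun Optional loss of reads whose
#'   Read1 carries a G homopolymer of at least `darkCycleMinRun`
#'   (two-channel chemistry artifact); probability 0 disables.
#' @slot bgAntisense If `TRUE` background reads are emitted antisense.
#' @export
setClass("ScreenConfig",
  slots = c(
    polymeraseMode = "character",
    randomizedSpan = "integer",
    plus1Base = "character",
    read1Len = "integer",
    read2Len = "integer",
    umiLen = "integer",
    upstreamCore = "character",
    constantSeqs = "character",
    polyAWindow = "integer",
    polyAMinFrac = "numeric",
    constantMaxMismatch = "integer",
    minBg = "integer",
    homopolymerMinRun = "integer",
    homopolymerBases = "character",
    contaminants = "character",
    contamK = "integer",
    contamMinHits = "integer",
    dedupAfterStructure = "logical",
    darkCycleLossProb = "numeric",
    darkCycleMinRun = "integer",
    bgAntisense = "logical"
  )
)

setValidity("ScreenConfig", function(object) {
  msg <- character(0)
  sp <- object@randomizedSpan
  if (length(sp) != 2L || sp[2] - sp[1] + 1L != 15L)
    msg <- c(msg, "randomizedSpan must cover 15 positions")
  if (!object@polymeraseMode %in% c("T7", "SP6"))
    msg <- c(msg, "polymeraseMode must be 'T7' or 'SP6'")
  if (object@umiLen < 1L) msg <- c(msg, "umiLen must be >= 1")
  if (object@read1Len < 15L + 1L + 2L + object@polyAWindow)
    msg <- c(msg, "read1Len too short for [15mer][C][<=2 extra C][polyA window]")
  if (object@read2Len < object@umiLen)
    msg <- c(msg, "read2Len must cover the UMI")
  seqs <- c(object@upstreamCore, object@constantSeqs)
  if (any(stringi::stri_detect_regex(seqs, "[^ACGT]")))
    msg <- c(msg, "sequences must be over {A,C,G,T}")
  if (!object@plus1Base %in% DNA_BASES)
    msg <- c(msg, "plus1Base must be one of A,C,G,T")
  if (object@polyAMinFrac < 0 || object@polyAMinFrac > 1)
    msg <- c(msg, "polyAMinFrac must be in [0,1]")
  if (object@darkCycleLossProb < 0 || object@darkCycleLossProb > 1)
    msg <- c(msg, "darkCycleLossProb must be in [0,1]")
  if (length(msg)) msg else TRUE
})

#' ActivityModel: ground-truth transcription weights and 5' event rates
#'
#' The latent promoter activity of the simulated screen. Transcription weight
#' of a +1..+8 motif factorizes as `classFactor[+2/3 dinucleotide] *
#' itrFactor[+4..+8 motif]` (the +1 base is fixed). 5' events are polymerase
#' slippage (extra G) with per +1..+3 class probabilities and class-free
#' non-templated C addition by reverse transcriptase.
#'
#' @slot mode One of `"uniform"`, `"t7_like"`, `"sp6_like"`, `"custom"`.
#' @slot classFactor Named numeric(16), +2/3 dinucleotide effect.
#' @slot itrFactor Named numeric(1024), +4..+8 motif effect.
#' @slot weights7 Optional numeric(16384) of non-factorizing weights per
#'   +2..+8 motif (mode `"custom"`); length 0 means use the factorized form.
#' @slot pExtraG1,pExtraG2 Named numeric(16): probability of one / two
#'   slipped G per +2/3 dinucleotide class (the +1 base is fixed).
#' @slot pRtC Probability of one non-templated C added by RT.
#' @slot foldRange Constructed max/min ratio of `itrFactor` (t7_like) or
#'   `classFactor` (sp6_like).
#' @slot seed Integer seed the model was drawn from.
#' @export
setClass("ActivityModel",
  slots = c(
    mode = "character",
    classFactor = "numeric",
    itrFactor = "numeric",
    weights7 = "numeric",
    pExtraG1 = "numeric",
    pExtraG2 = "numeric",
    pRtC = "numeric",
    foldRange = "numeric",
    seed = "integer"
  )
)

setValidity("ActivityModel", function(object) {
  msg <- character(0)
  if (length(object@classFactor) != 16L || any(object@classFactor <= 0))
    msg <- c(msg, "classFactor must be 16 positive values")
  if (length(object@itrFactor) != 1024L || any(object@itrFactor <= 0))
    msg <- c(msg, "itrFactor must be 1024 positive values")
  if (length(object@weights7) && (length(object@weights7) != 16384L ||
                                  any(object@weights7 <= 0)))
    msg <- c(msg, "weights7 must be empty or 16384 positive values")
  p1 <- object@pExtraG1; p2 <- object@pExtraG2
  if (length(p1) != 16L || length(p2) != 16L)
    msg <- c(msg, "pExtraG1/pExtraG2 must have 16 classes")
  if (any(p1 < 0) || any(p2 < 0) || any(p1 + p2 > 1))
    msg <- c(msg, "per class, pExtraG1 + pExtraG2 must lie in [0,1]")
  if (object@pRtC < 0 || object@pRtC > 1)
    msg <- c(msg, "pRtC must be in [0,1]")
  if (length(msg)) msg else TRUE
})

#' TemplateLibrary: a synthesized randomized promoter template pool
#'
#' Molecule counts of the randomized +2..+16 region. Because positions are
#' synthesized independently, the +2..+8 7mer and the +9..+16 8mer tail of a
#' molecule are independent; the pool is stored as multinomial counts over
#' each segment (both summing to `nMolecules`).
#'
#' @slot motifCounts Numeric(16384), molecule counts per +2..+8 7mer (code
#'   order).
#' @slot tailCounts Numeric(65536), molecule counts per +9..+16 8mer.
#' @slot baseBias 4 x 15 matrix of per-position synthesis base frequencies
#'   (rows A,C,G,T; columns +2..+16).
#' @slot nMolecules Library size.
#' @export
setClass("TemplateLibrary",
  slots = c(
    motifCounts = "numeric",
    tailCounts = "numeric",
    baseBias = "matrix",
    nMolecules = "numeric"
  )
)

setValidity("TemplateLibrary", function(object) {
  msg <- character(0)
  if (length(object@motifCounts) != 16384L) msg <- c(msg, "motifCounts must have 4^7 entries")
  if (length(object@tailCounts) != 65536L) msg <- c(msg, "tailCounts must have 4^8 entries")
  if (abs(sum(object@motifCounts) - object@nMolecules) > 1e-6 * max(1, object@nMolecules))
    msg <- c(msg, "motifCounts must sum to nMolecules")
  if (abs(sum(object@tailCounts) - object@nMolecules) > 1e-6 * max(1, object@nMolecules))
    msg <- c(msg, "tailCounts must sum to nMolecules")
  if (!all(dim(object@baseBias) == c(4L, 15L)))
    msg <- c(msg, "baseBias must be 4 x 15")
  if (any(abs(colSums(object@baseBias) - 1) > 1e-6))
    msg <- c(msg, "baseBias columns must sum to 1")
  if (length(msg)) msg else TRUE
})

#' TranscriptSet: simulated transcripts with ground truth
#'
#' One row per transcript: the +2..+8 motif and +9..+16 tail (as 1-based
#' indices into code order), and the number of slipped 5' Gs. The `truth`
#' table aggregates per +2..+8 motif: true weight, transcript count, and
#' tallies of extra-G events.
#'
#' @slot m7,t8 Integer indices (1-based k-mer codes + 1).
#' @slot nExtraG Integer 0/1/2 slipped Gs per transcript.
#' @slot truth Per-motif ground-truth data.frame.
#' @export
setClass("TranscriptSet",
  slots = c(m7 = "integer", t8 = "integer", nExtraG = "integer",
            truth = "data.frame")
)

setValidity("TranscriptSet", function(object) {
  n <- length(object@m7)
  if (length(object@t8) != n || length(object@nExtraG) != n)
    return("m7, t8 and nExtraG must have equal length")
  if (nrow(object@truth) && sum(object@truth$transcripts) != n)
    return("ground-truth transcript counts must sum to the number of transcripts")
  TRUE
})

#' SimReads: simulated paired reads with per-read origin
#'
#' @slot read1,read2 Character vectors of equal length.
#' @slot origin Per-read ground truth (transcript index, motif/tail indices,
#'   visible extra-C count, UMI index, duplicate flag).
#' @export
setClass("SimReads",
  slots = c(read1 = "character", read2 = "character", origin = "data.frame"))

setValidity("SimReads", function(object) {
  if (length(object@read1) != length(object@read2))
    return("read1 and read2 must be paired")
  if (nrow(object@origin) != length(object@read1))
    return("origin must have one row per read pair")
  TRUE
})

#' MotifReadSet: reads reduced to their sense +2..+16 sequence
#'
#' Compact integer-coded container for large runs; `motifs15()` materializes
#' the sequences.
#'
#' @slot m15code Numeric codes (0-based) of the sense 15mers.
#' @slot plus1 The fixed +1 base.
#' @export
setClass("MotifReadSet", slots = c(m15code = "numeric", plus1 = "character"))

#' FilteredReadSet: accepted 5' RACE reads
#'
#' One element per accepted read: the RNA-sense +2..+16 15mer (coded), the
#' number of extra 5' Cs observed in Read1 (0-2), and the UMI (coded).
#'
#' @slot extraC Integer 0/1/2 per read.
#' @slot umiCode Numeric UMI codes.
#' @slot umiLen UMI length in nt.
#' @export
setClass("FilteredReadSet", contains = "MotifReadSet",
  slots = c(extraC = "integer", umiCode = "numeric", umiLen = "integer"))

setValidity("FilteredReadSet", function(object) {
  n <- length(object@m15code)
  if (length(object@extraC) != n || length(object@umiCode) != n)
    return("extraC and umiCode must match m15code length")
  if (length(object@extraC) && !all(object@extraC %in% 0:2))
    return("extraC must be 0, 1 or 2")
  TRUE
})

#' FilterStats: telescoping per-stage read counts
#'
#' @slot input Total input read pairs.
#' @slot contaminantRemoved,dedupRemoved,structureFailed,polyAFailed,constantRemoved
#'   Reads removed at each stage, in pipeline order.
#' @slot accepted Reads surviving all stages.
#' @export
setClass("FilterStats",
  slots = c(input = "numeric", contaminantRemoved = "numeric",
            dedupRemoved = "numeric", structureFailed = "numeric",
            polyAFailed = "numeric", constantRemoved = "numeric",
            accepted = "numeric"))

setValidity("FilterStats", function(object) {
  tot <- object@contaminantRemoved + object@dedupRemoved +
    object@structureFailed + object@polyAFailed + object@constantRemoved +
    object@accepted
  if (!isTRUE(all.equal(tot, object@input)))
    return("stage counts must telescope to the input count")
  TRUE
})

#' MotifTable: background-normalized motif abundances
#'
#' Rows are motifs over a position span in TSS coordinates. Relative
#' abundance of motif m is `(count(m)/total) / (bg_count(m)/bg_total)`;
#' motifs with `bg_count < minBg` are flagged `low_background` and excluded
#' from ranking, as are homopolymer-flagged motifs. Ranks are dense, by
#' descending relative abundance, ties broken lexicographically.
#'
#' @slot span Integer length-2 position interval (e.g. `c(2L, 8L)`).
#' @slot table data.frame with columns motif, count, bg_count,
#'   rel_abundance, log2_rel, low_background, homopolymer, rank.
#' @slot totalReads,totalBg Normalization totals.
#' @slot plus1 The fixed +1 base (used by the homopolymer rule and class
#'   grouping).
#' @export
setClass("MotifTable",
  slots = c(span = "integer", table = "data.frame",
            totalReads = "numeric", totalBg = "numeric", plus1 = "character"))

setValidity("MotifTable", function(object) {
  tb <- object@table
  need <- c("motif", "count", "bg_count", "rel_abundance", "log2_rel",
            "low_background", "homopolymer", "rank")
  if (!all(need %in% names(tb)))
    return(paste("table must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(tb$motif)) return("duplicate motifs")
  r <- tb$rank[!is.na(tb$rank)]
  if (length(r) && !setequal(r, seq_along(r)))
    return("ranks must be a permutation of 1..n over ranked rows")
  TRUE
})

#' DesignResult: a scored promoter + initially transcribed region
#'
#' @slot sequence Full designed sequence.
#' @slot motif The scored motif at the table's span.
#' @slot relAbundance,rank Score of that motif in the supplied table.
#' @slot edits data.frame of applied edits (type, position, base).
#' @slot contextWarning `TRUE` when +1..+3 of the design is not GGG.
#' @export
setClass("DesignResult",
  slots = c(sequence = "character", motif = "character",
            relAbundance = "numeric", rank = "numeric", edits = "data.frame",
            contextWarning = "logical"))

#' ScreenResult: outputs of a full simulated screen run
#'
#' @slot filtered Accepted reads ([FilteredReadSet]).
#' @slot stats [FilterStats].
#' @slot table28,table48 [MotifTable]s over +2..+8 and +4..+8.
#' @slot composition Normalized per-position composition matrix.
#' @slot groups Dinucleotide group summaries.
#' @slot extraG Per +1..+3 class extra-G report.
#' @slot summary Named list of scalar summaries.
#' @slot truth Ground-truth table of the generating model.
#' @slot manifest Run manifest (seeds, hashes, file checksums).
#' @export
setClass("ScreenResult",
  slots = c(filtered = "FilteredReadSet", stats = "FilterStats",
            table28 = "MotifTable", table48 = "MotifTable",
            composition = "matrix", groups = "data.frame",
            extraG = "data.frame", summary = "list", truth = "data.frame",
            manifest = "list"))
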