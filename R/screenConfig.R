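# ScreenConfig constructor and YAML round-trip.

#' Create a screen configuration
#'
#' Builds a [ScreenConfig] with the default geometry of the screen: a +2..+16
#' randomized promoter with fixed +1 G, 2 x 35 nt paired reads and a 5 nt UMI
#' in Read2. All filter parameters are exposed as arguments.
#'
#' @param polymeraseMode `"T7"` or `"SP6"`; selects the default core
#'   promoter consensus.
#' @param randomizedSpan Randomized interval in TSS coordinates (must cover
#'   15 positions).
#' @param plus1Base Fixed +1 nucleotide.
#' @param read1Len,read2Len,umiLen Read geometry (nt).
#' @param upstreamCore -17..-1 core promoter; defaults to the canonical T7 or
#'   SP6 consensus according to `polymeraseMode`.
#' @param constantSeqs Named character vector of constant sequences used by
#'   the constant-sequence filter and as background-read fill.
#' @param polyAWindow,polyAMinFrac Poly(A) check: window length after the
#'   extra-C block and required fraction of A (defaults 10 and 0.9).
#' @param constantMaxMismatch Hamming tolerance of the constant filter
#'   (default 1).
#' @param minBg Minimum background count for normalization (default 10).
#' @param homopolymerMinRun,homopolymerBases Homopolymer flag rule
#'   (default: run of 4+, any base).
#' @param contaminants Contaminant sequences; empty disables the filter.
#' @param contamK,contamMinHits Contaminant k-mer filter parameters.
#' @param dedupAfterStructure Deduplicate after instead of before the
#'   structural filter.
#' @param darkCycleLossProb,darkCycleMinRun Optional dark-cycle loss of
#'   G-homopolymer reads in the simulator.
#' @param bgAntisense Emit background reads antisense.
#' @return A validated [ScreenConfig].
#' @examples
#' cfg <- screenConfig()
#' cfg
#' @export
screenConfig <- function(polymeraseMode = c("T7", "SP6"),
                         randomizedSpan = c(2L, 16L),
                         plus1Base = "G",
                         read1Len = 35L, read2Len = 35L, umiLen = 5L,
                         upstreamCore = NULL,
                         constantSeqs = DEFAULT_CONSTANTS,
                         polyAWindow = 10L, polyAMinFrac = 0.9,
                         constantMaxMismatch = 1L,
                         minBg = 10L,
                         homopolymerMinRun = 4L,
                         homopolymerBases = c("A", "C", "G", "T"),
                         contaminants = character(0),
                         contamK = 21L, contamMinHits = 1L,
                         dedupAfterStructure = FALSE,
                         darkCycleLossProb = 0,
                         darkCycleMinRun = 4L,
                         bgAntisense = FALSE) {
  polymeraseMode <- match.arg(polymeraseMode)
  if (is.null(upstreamCore))
    upstreamCore <- if (polymeraseMode == "T7") T7_CORE else SP6_CORE
  new("ScreenConfig",
      polymeraseMode = polymeraseMode,
      randomizedSpan = as.integer(randomizedSpan),
      plus1Base = plus1Base,
      read1Len = as.integer(read1Len), read2Len = as.integer(read2Len),
      umiLen = as.integer(umiLen),
      upstreamCore = upstreamCore,
      constantSeqs = constantSeqs,
      polyAWindow = as.integer(polyAWindow), polyAMinFrac = polyAMinFrac,
      constantMaxMismatch = as.integer(constantMaxMismatch),
      minBg = as.integer(minBg),
      homopolymerMinRun = as.integer(homopolymerMinRun),
      homopolymerBases = homopolymerBases,
      contaminants = contaminants,
      contamK = as.integer(contamK), contamMinHits = as.integer(contamMinHits),
      dedupAfterStructure = dedupAfterStructure,
      darkCycleLossProb = darkCycleLossProb,
      darkCycleMinRun = as.integer(darkCycleMinRun),
      bgAntisense = bgAntisense)
}

.CONFIG_KEYS <- c("polymerase_mode", "randomized_span", "plus1_base",
                  "read1_len", "read2_len", "umi_len", "upstream_core",
                  "constant_seqs", "polyA_window", "polyA_min_frac",
                  "constant_max_mismatch", "min_bg", "homopolymer_min_run",
                  "homopolymer_bases", "contaminants", "contam_k",
                  "contam_min_hits", "dedup_after_structure",
                  "dark_cycle_loss_prob", "dark_cycle_min_run",
                  "bg_antisense")

#' Read / write a screen configuration as YAML
#'
#' The YAML layout uses one snake_case key per configuration field; every
#' key must be present when reading (a missing key is an error naming it).
#'
#' @param path File path.
#' @return `readScreenConfig` returns a [ScreenConfig];
#'   `writeScreenConfig` returns `path` invisibly.
#' @export
readScreenConfig <- function(path) {
  y <- yaml::read_yaml(path)
  missing <- setdiff(.CONFIG_KEYS, names(y))
  if (length(missing))
    stop("config is missing key(s): ", paste(missing, collapse = ", "))
  screenConfig(polymeraseMode = y$polymerase_mode,
               randomizedSpan = as.integer(y$randomized_span),
               plus1Base = y$plus1_base,
               read1Len = y$read1_len, read2Len = y$read2_len,
               umiLen = y$umi_len,
               upstreamCore = y$upstream_core,
               constantSeqs = unlist(y$constant_seqs),
               polyAWindow = y$polyA_window, polyAMinFrac = y$polyA_min_frac,
               constantMaxMismatch = y$constant_max_mismatch,
               minBg = y$min_bg,
               homopolymerMinRun = y$homopolymer_min_run,
               homopolymerBases = unlist(y$homopolymer_bases),
               contaminants = as.character(unlist(y$contaminants)),
               contamK = y$contam_k, contamMinHits = y$contam_min_hits,
               dedupAfterStructure = y$dedup_after_structure,
               darkCycleLossProb = y$dark_cycle_loss_prob,
               darkCycleMinRun = y$dark_cycle_min_run,
               bgAntisense = y$bg_antisense)
}

#' @rdname readScreenConfig
#' @param config A [ScreenConfig].
#' @export
writeScreenConfig <- function(config, path) {
  y <- list(polymerase_mode = config@polymeraseMode,
            randomized_span = as.integer(config@randomizedSpan),
            plus1_base = config@plus1Base,
            read1_len = config@read1Len, read2_len = config@read2Len,
            umi_len = config@umiLen,
            upstream_core = config@upstreamCore,
            constant_seqs = as.list(config@constantSeqs),
            polyA_window = config@polyAWindow,
            polyA_min_frac = config@polyAMinFrac,
            constant_max_mismatch = config@constantMaxMismatch,
            min_bg = config@minBg,
            homopolymer_min_run = config@homopolymerMinRun,
            homopolymer_bases = config@homopolymerBases,
            contaminants = as.list(config@contaminants),
            contam_k = config@contamK,
            contam_min_hits = config@contamMinHits,
            dedup_after_structure = config@dedupAfterStructure,
            dark_cycle_loss_prob = config@darkCycleLossProb,
            dark_cycle_min_run = config@darkCycleMinRun,
            bg_antisense = config@bgAntisense)
  yaml::write_yaml(y, path)
  invisible(path)
}
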