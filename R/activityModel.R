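# Ground-truth activity models.

# expand per-class probability spec: scalar applied to the GGG class,
# (partially) named vector merged over defaults, or full length-16 vector
.classProbVector <- function(x, default) {
  dinucs <- kmerStrings(2L)
  out <- stats::setNames(rep(default, 16L), dinucs)
  if (is.null(x)) return(out)
  if (is.null(names(x))) {
    if (length(x) == 1L) out[] <- x
    else if (length(x) == 16L) out[] <- x
    else stop("class probabilities must be scalar, named, or length 16")
  } else {
    nm <- names(x)
    # accept either the +2/3 dinucleotide or the full +1..+3 class name
    nm <- ifelse(nchar(nm) == 3L, substr(nm, 2L, 3L), nm)
    if (!all(nm %in% dinucs)) stop("unknown +2/3 class name(s)")
    out[nm] <- x
  }
  out
}

# effective +2..+8 weights (length 16384, code order)
.weights7 <- function(model) {
  if (length(model@weights7)) return(model@weights7)
  code7 <- 0:16383
  model@classFactor[code7 %/% 1024 + 1L] * model@itrFactor[code7 %% 1024 + 1L]
}

#' Build a ground-truth promoter activity model
#'
#' Constructs the latent transcription weights and 5' event probabilities of
#' a simulated screen. Weights over the +1..+8 initially transcribed region
#' factorize into a +2/3 dinucleotide class effect and a +4..+8 motif effect
#' (the +1 base is fixed):
#'
#' * `"t7_like"`: the +4..+8 factor is drawn log-uniform and rescaled so its
#'   max/min ratio equals `foldRange` exactly, with an additive AT-content
#'   tilt so AT-rich motifs tend to score high; the class factor rises with
#'   the number of Gs in the +2/3 dinucleotide (GGG starts strongest).
#' * `"sp6_like"`: activity depends on the +2/3 dinucleotide only (16
#'   log-spaced levels spanning `foldRange`, A-rich dinucleotides highest);
#'   the +4..+8 factor is constant.
#' * `"uniform"`: all weights exactly 1.
#' * `"custom"`: supply `classFactor`/`itrFactor`, or a full `weights`
#'   vector over +2..+8 7mers.
#'
#' Slippage ("extra G") probabilities default to 0.79 (one G) and 0.02
#' (two Gs) for transcripts starting on a G triplet and 0 otherwise;
#' non-templated C addition by reverse transcriptase applies to all classes.
#'
#' @param mode Model flavor (see above).
#' @param foldRange Max/min ratio of the modelled activity effect; must be
#'   >= 1.
#' @param seed Integer seed; the model is fully reproducible from it.
#' @param pExtraG1,pExtraG2 Per +1..+3 class slippage probabilities: scalar,
#'   (partially) named vector (names as +2/3 dinucleotide or full +1..+3
#'   class), or length-16 vector. Defaults as above.
#' @param pRtC Probability of a non-templated RT C (default 0.05).
#' @param atTilt Strength of the AT-content tilt of the t7_like +4..+8
#'   factor (default 1; 0 disables).
#' @param classFactor,itrFactor,weights Custom-mode parameters.
#' @return An [ActivityModel].
#' @examples
#' m <- buildActivityModel("t7_like", foldRange = 5, seed = 7)
#' max(m@itrFactor) / min(m@itrFactor)  # exactly 5
#' @export
buildActivityModel <- function(mode = c("t7_like", "sp6_like", "uniform", "custom"),
                               foldRange = 5, seed = 1L,
                               pExtraG1 = NULL, pExtraG2 = NULL,
                               pRtC = 0.05, atTilt = 1,
                               classFactor = NULL, itrFactor = NULL,
                               weights = NULL) {
  mode <- match.arg(mode)
  if (foldRange < 1) stop("foldRange must be >= 1")
  seed <- as.integer(seed)
  set.seed(seed)

  dinucs <- kmerStrings(2L)
  fivemers <- kmerStrings(5L)
  cf <- stats::setNames(rep(1, 16L), dinucs)
  itr <- stats::setNames(rep(1, 1024L), fivemers)
  w7 <- numeric(0)

  if (mode == "t7_like") {
    u <- stats::runif(1024L)
    at <- (stringi::stri_count_fixed(fivemers, "A") +
             stringi::stri_count_fixed(fivemers, "T")) / 5
    score <- u + atTilt * at
    if (foldRange > 1) {
      # rank transform keeps the factor exactly log-uniform (equally spaced
      # in log space, max/min = foldRange) while the AT tilt biases which
      # motifs land high
      v <- (rank(score) - 1) / 1023
      itr[] <- foldRange^v
    }
    nG <- stringi::stri_count_fixed(dinucs, "G")
    cf[] <- 1.5^nG
  } else if (mode == "sp6_like") {
    nA <- stringi::stri_count_fixed(dinucs, "A")
    pref <- order(-nA, dinucs)            # AA first, then A-containing
    expo <- stats::setNames(numeric(16L), dinucs[pref])
    expo[] <- (16L - seq_len(16L)) / 15L  # 1 for the top class, 0 for last
    cf[dinucs[pref]] <- foldRange^expo
  } else if (mode == "custom") {
    if (!is.null(weights)) {
      if (length(weights) != 16384L) stop("weights must cover all 4^7 +2..+8 motifs")
      if (!is.null(names(weights))) weights <- weights[kmerStrings(7L)]
      w7 <- as.numeric(weights)
    } else {
      if (!is.null(classFactor)) cf[] <- classFactor[dinucs]
      if (!is.null(itrFactor)) itr[] <- itrFactor[fivemers]
    }
  }

  g1 <- .classProbVector(pExtraG1, 0); g2 <- .classProbVector(pExtraG2, 0)
  if (is.null(pExtraG1)) g1[["GG"]] <- 0.79
  if (is.null(pExtraG2)) g2[["GG"]] <- 0.02

  new("ActivityModel", mode = mode, classFactor = cf, itrFactor = itr,
      weights7 = w7, pExtraG1 = g1, pExtraG2 = g2, pRtC = pRtC,
      foldRange = foldRange, seed = seed)
}
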