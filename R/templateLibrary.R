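# Synthesis of the randomized promoter template pool.

# multinomial counts for possibly huge n, chunked below the integer limit
.bigMultinom <- function(n, prob) {
  counts <- numeric(length(prob))
  remaining <- n
  chunk <- 2^30
  while (remaining > 0) {
    s <- min(remaining, chunk)
    counts <- counts + as.numeric(stats::rmultinom(1L, size = s, prob = prob))
    remaining <- remaining - s
  }
  counts
}

# per-k-mer probability in code order from per-position base frequencies
# (columns of bias); first position most significant
.kmerProbs <- function(bias) {
  p <- 1
  for (i in seq_len(ncol(bias))) p <- rep(p, each = 4L) * bias[, i]
  p
}

#' Simulate a randomized template library
#'
#' Draws `nMolecules` template molecules whose +2..+16 segment is synthesized
#' i.i.d. per position from `baseBias` (allowing compositional bias of the
#' oligo synthesis). Because positions are independent, the pool is stored as
#' multinomial counts over the +2..+8 7mer and the +9..+16 8mer tail.
#'
#' @param config A [ScreenConfig].
#' @param nMolecules Library size (default `1e10`, roughly 10 ng of a short
#'   dsDNA template).
#' @param baseBias Either a length-4 frequency vector (A,C,G,T) applied to
#'   all positions, or a 4 x 15 matrix with one column per position +2..+16.
#'   Columns must sum to 1 (tolerance 1e-6). Default uniform.
#' @param seed Integer seed, or `NULL` to draw from the current RNG stream.
#' @return A [TemplateLibrary].
#' @examples
#' lib <- simulateTemplateLibrary(screenConfig(), nMolecules = 1e6, seed = 1)
#' sum(motifCounts(lib)) == 1e6
#' @export
simulateTemplateLibrary <- function(config, nMolecules = 1e10,
                                    baseBias = rep(0.25, 4), seed = NULL) {
  if (nMolecules <= 0) stop("nMolecules must be positive")
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(dim(baseBias))) {
    if (length(baseBias) != 4L) stop("baseBias vector must have 4 entries")
    baseBias <- matrix(baseBias, nrow = 4L, ncol = 15L)
  }
  if (!all(dim(baseBias) == c(4L, 15L))) stop("baseBias must be 4 x 15")
  if (any(abs(colSums(baseBias) - 1) > 1e-6))
    stop("baseBias columns must sum to 1")
  rownames(baseBias) <- DNA_BASES

  p7 <- .kmerProbs(baseBias[, 1:7, drop = FALSE])
  p8 <- .kmerProbs(baseBias[, 8:15, drop = FALSE])
  new("TemplateLibrary",
      motifCounts = .bigMultinom(nMolecules, p7),
      tailCounts = .bigMultinom(nMolecules, p8),
      baseBias = baseBias, nMolecules = nMolecules)
}

#' Per-position base frequencies of a template library
#'
#' Empirical base frequencies at positions +2..+16 of the synthesized pool.
#'
#' @param lib A [TemplateLibrary].
#' @return 4 x 15 matrix (rows A,C,G,T; columns +2..+16).
#' @export
libraryComposition <- function(lib) {
  out <- matrix(0, 4L, 15L, dimnames = list(DNA_BASES, paste0("+", 2:16)))
  for (i in 1:7) {
    d <- .kmerDigit(0:16383, 7L, i)
    out[, i] <- vapply(0:3, function(b) sum(lib@motifCounts[d == b]), 0)
  }
  for (i in 1:8) {
    d <- .kmerDigit(0:65535, 8L, i)
    out[, i + 7L] <- vapply(0:3, function(b) sum(lib@tailCounts[d == b]), 0)
  }
  sweep(out, 2L, colSums(out), "/")
}
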