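# Integer k-mer coding. Bases map A=0, C=1, G=2, T=3; a k-mer's code is its
# base-4 number with the first (5'-most) base most significant, so code order
# equals lexicographic order. Codes are stored as doubles (exact up to 2^53,
# i.e. k <= 26), 0-based; lookup tables are 1-based (code + 1).

DNA_BASES <- c("A", "C", "G", "T")

.kmer_cache <- new.env(parent = emptyenv())

#' All k-mers in code order
#'
#' Returns the 4^k DNA k-mers ordered by their integer code (equivalently,
#' lexicographically with A < C < G < T).
#'
#' @param k K-mer length (1-12).
#' @return Character vector of length `4^k`.
#' @keywords internal
kmerStrings <- function(k) {
  stopifnot(k >= 1, k <= 12)
  key <- as.character(k)
  if (!is.null(.kmer_cache[[key]])) return(.kmer_cache[[key]])
  g <- expand.grid(rep(list(DNA_BASES), k), stringsAsFactors = FALSE)
  # Var1 varies fastest; the last character must vary fastest in code order
  s <- do.call(paste0, g[, seq(k, 1L), drop = FALSE])
  if (4^k <= 65536) .kmer_cache[[key]] <- s
  s
}

# byte -> digit lookup (A/C/G/T upper case only; anything else NA)
.BYTE_DIGIT <- local({
  m <- rep(NA_integer_, 256L)
  m[utf8ToInt("A") + 1L] <- 0L
  m[utf8ToInt("C") + 1L] <- 1L
  m[utf8ToInt("G") + 1L] <- 2L
  m[utf8ToInt("T") + 1L] <- 3L
  m
})

#' Encode fixed-width k-mers to integer codes
#'
#' @param x Character vector, all elements of width `k`.
#' @param k K-mer width.
#' @return Numeric vector of 0-based codes; `NA` where `x` contains a
#'   character outside `ACGT`.
#' @keywords internal
encodeKmers <- function(x, k) {
  if (length(x) == 0L) return(numeric(0))
  if (any(stringi::stri_length(x) != k))
    stop("all sequences must have width ", k)
  d <- .BYTE_DIGIT[as.integer(charToRaw(stringi::stri_flatten(x))) + 1L]
  dim(d) <- c(k, length(x))
  colSums(d * 4^((k - 1L):0L))
}

# k x n digit matrix (0..3, NA for non-ACGT) of the first k characters of x
.digitMatrix <- function(x, k) {
  d <- .BYTE_DIGIT[as.integer(charToRaw(
    stringi::stri_flatten(stringi::stri_sub(x, 1L, k)))) + 1L]
  dim(d) <- c(k, length(x))
  d
}

#' Decode integer codes back to k-mer strings
#' @keywords internal
decodeKmers <- function(code, k) {
  if (k <= 8) return(kmerStrings(k)[code + 1])
  hi <- k - 8L
  stringi::stri_join(kmerStrings(hi)[code %/% 4^8 + 1],
                     kmerStrings(8L)[code %% 4^8 + 1])
}

# extract digit i (1-based from the 5' end) of k-mer codes
.kmerDigit <- function(code, k, i) (code %/% 4^(k - i)) %% 4

#' Sub-k-mer code
#'
#' Code of the sub-sequence spanning (1-based) positions `from..to` of a
#' k-mer given by code.
#' @keywords internal
subCode <- function(code, k, from, to) {
  (code %/% 4^(k - to)) %% 4^(to - from + 1L)
}

#' Reverse complement in code space
#' @keywords internal
revCompCode <- function(code, k) {
  res <- 0
  for (i in seq_len(k)) {
    res <- res + (3 - .kmerDigit(code, k, i)) * 4^(i - 1L)
  }
  res
}

#' Reverse complement of DNA strings
#'
#' Vectorized reverse complement over the `ACGTN` alphabet.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @examples
#' revComp("ACGTACGTACGTACG")
#' @export
revComp <- function(x) {
  chartr("ACGTN", "TGCAN", stringi::stri_reverse(x))
}

# Wilson score interval for a binomial proportion
.wilsonCI <- function(x, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, ctr - hw), min(1, ctr + hw))
}

# All sequences within Hamming distance <= d of s (d = 0 or 1 supported)
.hammingBall <- function(s, d = 1L) {
  out <- s
  if (d >= 1L) {
    k <- nchar(s)
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    for (i in seq_len(k)) {
      for (b in setdiff(DNA_BASES, ch[i])) {
        v <- ch; v[i] <- b
        out <- c(out, paste(v, collapse = ""))
      }
    }
  }
  unique(out)
}

# validate a DNA string over ACGT
.checkDNA <- function(x, what = "sequence") {
  bad <- stringi::stri_detect_regex(x, "[^ACGT]")
  if (any(bad)) stop(what, " must contain only A, C, G, T")
  invisible(x)
}
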