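# Read filtering: contaminant removal, 15mer-UMI dedup, structural 5' end
# filter, orientation conversion, constant-sequence filter. Stage order
# follows the analysis protocol: contaminant -> dedup -> structure ->
# reverse complement -> constant filter (dedup can be moved after the
# structural filter via the configuration).

#' Build a contaminant k-mer index
#'
#' Exact k-mer index over the supplied contaminant sequences, both strands.
#'
#' @param seqs Contaminant sequences (e.g. a PhiX genome).
#' @param k K-mer size (>= 11; default 21).
#' @return Character vector of unique k-mers.
#' @export
buildContaminantIndex <- function(seqs, k = 21L) {
  if (k < 11L) stop("k must be >= 11")
  seqs <- c(seqs, revComp(seqs))
  seqs <- seqs[nchar(seqs) >= k]
  if (!length(seqs)) stop("no contaminant sequence of length >= k")
  kmers <- unlist(lapply(seqs, function(s) {
    n <- nchar(s) - k + 1L
    stringi::stri_sub(s, seq_len(n), seq_len(n) + k - 1L)
  }))
  unique(kmers)
}

#' Flag contaminant reads by k-mer hits
#'
#' A read is a contaminant when at least `minHits` of its k-mers occur in
#' the index. With a `NULL` index the filter is disabled and all reads are
#' kept.
#'
#' @param reads Character vector of read sequences.
#' @param index K-mer index from [buildContaminantIndex()], or `NULL`.
#' @param k K-mer size the index was built with.
#' @param minHits Minimum k-mer hits to flag a read (default 1).
#' @return Logical vector: `TRUE` to keep the read.
#' @export
contaminantFilter <- function(reads, index, k = 21L, minHits = 1L) {
  if (is.null(index)) return(rep(TRUE, length(reads)))
  if (!length(index)) stop("empty contaminant index with filtering enabled")
  if (!length(reads)) return(logical(0))
  hits <- integer(length(reads))
  nk <- min(nchar(reads)) - k + 1L
  if (nk < 1L) return(rep(TRUE, length(reads)))
  for (o in seq_len(nk)) {
    hits <- hits + (stringi::stri_sub(reads, o, o + k - 1L) %in% index)
  }
  hits < minHits
}

#' Deduplicate read pairs by 15mer-UMI key
#'
#' Removes later occurrences of identical `(read1[1..15], UMI)` combinations;
#' order is otherwise preserved.
#'
#' @param read1 Read1 sequences.
#' @param read2 Read2 sequences (UMI in the first `umiLen` bases).
#' @param umiLen UMI length.
#' @return Logical vector: `TRUE` for the first occurrence of each key.
#' @export
dedupPairs <- function(read1, read2, umiLen = 5L) {
  key <- stringi::stri_join(stringi::stri_sub(read1, 1L, 15L),
                            stringi::stri_sub(read2, 1L, umiLen))
  !duplicated(key)
}

#' Structural 5' end filter
#'
#' Accepts a Read1 iff position 16 is `C`, positions 17-18 are one of
#' `AA`, `CA`, `CC` (0, 1 or 2 extra 5' Cs), and the poly(A) tail check
#' passes: at least `polyAMinFrac` of the `polyAWindow` bases starting at the
#' first tail A (position 17, 18 or 19 respectively) are `A`. Positions are
#' 1-based.
#'
#' @param read1 Character vector of Read1 sequences.
#' @param polyAWindow Tail window length (default 10).
#' @param polyAMinFrac Minimum A fraction in the window (default 0.9).
#' @return data.frame with columns `accept`, `extra_c` (NA unless the
#'   17-18 whitelist matched), `struct_ok`, `polya_ok`.
#' @examples
#' structuralFilter(paste0(strrep("T", 15), "CAA", strrep("A", 17)))
#' @export
structuralFilter <- function(read1, polyAWindow = 10L, polyAMinFrac = 0.9) {
  if (!length(read1))
    return(data.frame(accept = logical(0), extra_c = integer(0),
                      struct_ok = logical(0), polya_ok = logical(0)))
  if (min(stringi::stri_length(read1)) < 18L + polyAWindow)
    stop("read too short: structural filter needs length >= ",
         18L + polyAWindow)
  b16 <- stringi::stri_sub(read1, 16L, 16L)
  d <- stringi::stri_sub(read1, 17L, 18L)
  extra <- match(d, c("AA", "CA", "CC")) - 1L
  structOK <- b16 == "C" & !is.na(extra)
  polyaOK <- logical(length(read1))
  for (e in 0:2) {
    i <- which(structOK & extra == e)
    if (!length(i)) next
    p <- 17L + e
    win <- stringi::stri_sub(read1[i], p, p + polyAWindow - 1L)
    polyaOK[i] <- stringi::stri_count_fixed(win, "A") >=
      polyAMinFrac * polyAWindow
  }
  data.frame(accept = structOK & polyaOK, extra_c = extra,
             struct_ok = structOK, polya_ok = polyaOK)
}

#' Convert Read1 to the RNA-sense 15mer
#'
#' Reverse complement of `read1[1..15]`, giving the +2..+16 sequence in RNA
#' sense. Reads whose 15mer contains a base outside `ACGT` yield `NA` (the
#' reject signal).
#'
#' @param read1 Character vector of Read1 sequences.
#' @return Character vector of sense 15mers, `NA` where rejected.
#' @export
toSense <- function(read1) {
  m <- revComp(stringi::stri_sub(read1, 1L, 15L))
  m[stringi::stri_detect_regex(m, "[^ACGT]")] <- NA_character_
  m
}

# all length-10 windows of the constants (both strands) expanded to the
# Hamming ball of radius maxMismatch, returned as numeric codes
.constantWindowCodes <- function(constants, maxMismatch = 1L) {
  seqs <- c(constants, revComp(constants))
  seqs <- seqs[nchar(seqs) >= 10L]
  if (!length(seqs)) return(numeric(0))
  win <- unique(unlist(lapply(seqs, function(s) {
    n <- nchar(s) - 9L
    stringi::stri_sub(s, seq_len(n), seq_len(n) + 9L)
  })))
  ball <- win
  mm <- maxMismatch
  while (mm > 0L) {
    ball <- unique(unlist(lapply(ball, .hammingBall)))
    mm <- mm - 1L
  }
  encodeKmers(ball, 10L)
}

#' Constant-sequence cross-contamination filter
#'
#' Discards a read when the 10mer at RNA positions +2..+11 matches any
#' length-10 window of any constant sequence (either strand) within
#' `maxMismatch` substitutions.
#'
#' @param motif15 Sense +2..+16 sequences (only the first 10 nt are used).
#' @param constants Character vector of constant sequences.
#' @param maxMismatch Allowed Hamming distance (default 1).
#' @return Logical vector: `TRUE` to keep.
#' @export
constantSeqFilter <- function(motif15, constants, maxMismatch = 1L) {
  if (!length(constants)) stop("constants must be non-empty")
  codes <- .constantWindowCodes(constants, maxMismatch)
  m10 <- encodeKmers(substr(motif15, 1L, 10L), 10L)
  !(m10 %in% codes)
}

# ---- chunked internals -----------------------------------------------------

# per-chunk read fields used by the staged pipeline (one C pass; semantics
# equal to structuralFilter + toSense + encodeKmers, asserted in tests)
.chunkFields <- function(r1, r2, config, contamIdx = NULL) {
  n <- length(r1)
  if (n == 0L) {
    return(list(contamKeep = logical(0), keyCode = numeric(0),
                m15code = numeric(0), hasN = logical(0),
                structOK = logical(0), polyaOK = logical(0),
                extraC = integer(0), umiCode = numeric(0)))
  }
  f <- .cppReadFields(r1, r2, config@umiLen, config@polyAWindow,
                      config@polyAMinFrac)
  f$contamKeep <- contaminantFilter(r1, contamIdx, config@contamK,
                                    config@contamMinHits)
  f
}

# stage bookkeeping over concatenated chunk fields
.assembleRun <- function(f, config) {
  n <- length(f$keyCode)
  surv <- !logical(n)

  contamRm <- !f$contamKeep
  surv <- surv & !contamRm

  key <- f$keyCode * 4^config@umiLen + f$umiCode
  na <- which(is.na(key))
  if (length(na)) key[na] <- -na   # N-containing keys never collapse

  structFail <- f$hasN | !f$structOK
  polyaFail <- !structFail & !f$polyaOK

  dedupRm <- logical(n)
  if (!config@dedupAfterStructure) {
    dedupRm[surv] <- duplicated(key[surv])
    surv <- surv & !dedupRm
    stFail <- surv & structFail
    paFail <- surv & polyaFail
    surv <- surv & !structFail & !polyaFail
  } else {
    stFail <- surv & structFail
    paFail <- surv & polyaFail
    surv <- surv & !structFail & !polyaFail
    dedupRm[surv] <- duplicated(key[surv])
    surv <- surv & !dedupRm
  }

  key <- NULL; structFail <- NULL; polyaFail <- NULL

  codes <- .constantWindowCodes(config@constantSeqs, config@constantMaxMismatch)
  constRm <- logical(n)
  idx <- which(surv)
  if (length(idx)) {
    m10 <- subCode(f$m15code[idx], 15L, 1L, 10L)
    constRm[idx] <- m10 %in% codes
    surv <- surv & !constRm
  }

  acc <- which(surv)
  reads <- new("FilteredReadSet",
               m15code = f$m15code[acc], plus1 = config@plus1Base,
               extraC = as.integer(f$extraC[acc]),
               umiCode = f$umiCode[acc], umiLen = config@umiLen)
  stats <- new("FilterStats", input = n,
               contaminantRemoved = sum(contamRm),
               dedupRemoved = sum(dedupRm),
               structureFailed = sum(stFail),
               polyAFailed = sum(paFail),
               constantRemoved = sum(constRm),
               accepted = length(acc))
  list(reads = reads, stats = stats)
}

# concatenate per-chunk field lists, releasing each chunk's vector as it is
# consumed so peak memory stays near one copy of the run
.catFields <- function(chunks) {
  nms <- names(chunks[[1L]])
  out <- vector("list", length(nms))
  names(out) <- nms
  for (nm in nms) {
    out[[nm]] <- do.call(c, lapply(chunks, `[[`, nm))
    for (i in seq_along(chunks)) chunks[[i]][[nm]] <- NULL
  }
  out
}

#' Process a paired 5' RACE run
#'
#' Applies the full filtering cascade to paired reads: contaminant k-mer
#' filter, duplicate 15mer-UMI removal, structural 5' end filter (including
#' poly(A) check), reverse complementation to RNA sense (reads with `N` in
#' the 15mer are rejected with the structural stage), and the
#' constant-sequence filter on the +2..+11 10mer. Processing is chunked and
#' deterministic.
#'
#' @param r1,r2 Character vectors of reads, or paths to (gzipped) FASTQ
#'   files.
#' @param config A [ScreenConfig].
#' @param chunkSize Reads per processing chunk.
#' @return List with elements `reads` (a [FilteredReadSet]) and `stats`
#'   (a [FilterStats]).
#' @export
processRun <- function(r1, r2, config = screenConfig(), chunkSize = 2e6) {
  if (length(r1) == 1L && file.exists(r1) &&
      grepl("\\.(fastq|fq)(\\.gz)?$", r1)) {
    r1 <- unname(readFastq(r1)); r2 <- unname(readFastq(r2))
  }
  if (length(r1) != length(r2))
    stop("mismatched record counts: ", length(r1), " vs ", length(r2))
  contamIdx <- if (length(config@contaminants))
    buildContaminantIndex(config@contaminants, config@contamK) else NULL
  n <- length(r1)
  starts <- seq(1L, max(n, 1L), by = chunkSize)
  chunks <- lapply(starts, function(s) {
    if (n == 0L) return(.chunkFields(character(0), character(0), config))
    i <- s:min(s + chunkSize - 1L, n)
    .chunkFields(r1[i], r2[i], config, contamIdx)
  })
  .assembleRun(.catFields(chunks), config)
}

#' Process a background (template) library
#'
#' Uses the first 15 nt of each read as the sense +2..+16 sequence (reverse
#' complemented first when the configuration marks background reads as
#' antisense). Reads containing `N` there are dropped.
#'
#' @param bg Character vector of reads or a FASTQ path.
#' @param config A [ScreenConfig].
#' @return A [MotifReadSet].
#' @export
processBackground <- function(bg, config = screenConfig()) {
  if (length(bg) == 1L && file.exists(bg) &&
      grepl("\\.(fastq|fq)(\\.gz)?$", bg)) {
    bg <- unname(readFastq(bg))
  }
  if (!length(bg))
    return(new("MotifReadSet", m15code = numeric(0), plus1 = config@plus1Base))
  if (config@bgAntisense) bg <- revComp(bg)
  code <- .cppEncode15(bg)
  new("MotifReadSet", m15code = code[!is.na(code)],
      plus1 = config@plus1Base)
}
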