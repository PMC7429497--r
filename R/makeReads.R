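# Library preparation: paired 5' RACE reads, background reads, FASTQ I/O.

# substitution errors: a binomial total of error events placed uniformly
# over the (read, position) grid, at most one event per base; each event
# rotates the base to one of the three alternatives
.drawReadEvents <- function(n, width, rate) {
  if (n == 0L || rate <= 0)
    return(list(ridx = integer(0), pos = integer(0), shift = integer(0)))
  nev <- stats::rbinom(1L, n * width, rate)
  if (nev == 0L)
    return(list(ridx = integer(0), pos = integer(0), shift = integer(0)))
  ridx <- sample.int(n, nev, replace = TRUE)
  pos <- sample.int(width, nev, replace = TRUE)
  shift <- sample.int(3L, nev, replace = TRUE)
  keep <- !duplicated(ridx * width + pos)
  list(ridx = ridx[keep], pos = pos[keep], shift = shift[keep])
}

.applyEventPlan <- function(x, plan) {
  ridx <- plan$ridx; pos <- plan$pos
  if (!length(ridx)) return(x)
  old <- stringi::stri_sub(x[ridx], pos, pos)
  nb <- DNA_BASES[(match(old, DNA_BASES) - 1L + plan$shift) %% 4L + 1L]
  # one round of non-duplicated reads at a time so several hits on distinct
  # positions of one read are all honored
  while (length(ridx)) {
    first <- !duplicated(ridx)
    stringi::stri_sub(x[ridx[first]], pos[first], pos[first]) <- nb[first]
    ridx <- ridx[!first]; pos <- pos[!first]; nb <- nb[!first]
  }
  x
}

.applyErrors <- function(x, rate, width) {
  .applyEventPlan(x, .drawReadEvents(length(x), width, rate))
}

# lookup tables for fast read construction (memoized; the reverse
# complement of all 4^8 tails is the expensive piece)
.read_table_cache <- new.env(parent = emptyenv())
.readTables <- function(config) {
  key <- paste(config@plus1Base, config@read1Len, config@read2Len,
               config@umiLen, config@constantSeqs[["template_downstream"]],
               sep = "|")
  hit <- .read_table_cache[["tabs"]]
  if (!is.null(hit) && identical(hit$key, key)) return(hit)
  rc7 <- revComp(kmerStrings(7L))
  rc8 <- revComp(kmerStrings(8L))
  plus1c <- chartr("ACGT", "TGCA", config@plus1Base)
  fillA <- config@read1Len - 16L
  sfx <- vapply(0:2, function(e)
    paste0(strrep("C", e), strrep("A", fillA - e)), "")
  sfx <- paste0(plus1c, sfx)
  umi <- kmerStrings(config@umiLen)
  fill2src <- strrep(config@constantSeqs[["template_downstream"]], 4L)
  fill2 <- substr(fill2src, 1L, config@read2Len - config@umiLen)
  tabs <- list(key = key, rc7 = rc7, rc8 = rc8, sfx = sfx, umi = umi,
               fill2 = fill2)
  .read_table_cache[["tabs"]] <- tabs
  tabs
}

#' Generate paired 5' RACE reads from transcripts
#'
#' Emulates the library chemistry downstream of transcription. Read1 is the
#' antisense copy of the transcript 5' end:
#' `[revcomp(+16..+2)][C for the +1 G][0-2 extra C][poly(A) fill]`, where the
#' extra Cs record slipped 5' Gs and, with probability `pRtC`, one
#' non-templated C added by reverse transcriptase (visible extras are capped
#' at 2; the structural filter whitelist cannot represent more). Read2
#' carries the UMI in its first bases followed by constant fill. PCR
#' duplicates re-emit a molecule's pair with identical 15mer and UMI;
#' substitution errors are then applied independently per sequenced copy.
#' Optionally, reads whose Read1 holds a G homopolymer are dropped with the
#' configured dark-cycle loss probability.
#'
#' @param transcripts A [TranscriptSet] (or a subset of one).
#' @param config A [ScreenConfig].
#' @param model The generating [ActivityModel] (for `pRtC`).
#' @param errorRate Per-base substitution probability (default 0.001).
#' @param dupRate Probability that a molecule is re-emitted once as a PCR
#'   duplicate (default 0.1).
#' @param seed Integer seed, or `NULL` to draw from the current RNG stream.
#' @return A [SimReads]: paired reads plus a per-read `origin` table
#'   (transcript index, motif/tail indices, visible extra Cs, UMI index,
#'   duplicate flag) linking every read pair to its ground-truth transcript.
#' @export
makeReads <- function(transcripts, config, model, errorRate = 0.001,
                      dupRate = 0.1, seed = NULL) {
  if (errorRate < 0 || errorRate >= 1) stop("errorRate must be in [0,1)")
  if (dupRate < 0 || dupRate >= 1) stop("dupRate must be in [0,1)")
  if (!is.null(seed)) set.seed(as.integer(seed))
  tabs <- .readTables(config)
  n <- length(transcripts@m7)

  rtc <- stats::rbinom(n, 1L, model@pRtC)
  extraVis <- pmin(transcripts@nExtraG + rtc, 2L)
  umiIdx <- sample.int(4L^config@umiLen, n, replace = TRUE)

  dup <- if (dupRate > 0) which(stats::runif(n) < dupRate) else integer(0)
  src <- c(seq_len(n), dup)
  origin <- data.frame(transcript = src, m7 = transcripts@m7[src],
                       t8 = transcripts@t8[src], extra_c = extraVis[src],
                       umi = umiIdx[src],
                       duplicate = c(logical(n), !logical(length(dup))),
                       row.names = NULL)

  r1 <- .cppJoin3(tabs$rc8, origin$t8, tabs$rc7, origin$m7,
                  tabs$sfx, origin$extra_c + 1L)
  r2 <- .cppJoin1c(tabs$umi, origin$umi, tabs$fill2)

  if (config@darkCycleLossProb > 0) {
    runG <- stringi::stri_detect_regex(
      r1, paste0("G{", config@darkCycleMinRun, ",}"))
    drop <- runG & stats::runif(length(r1)) < config@darkCycleLossProb
    r1 <- r1[!drop]; r2 <- r2[!drop]
    origin <- origin[!drop, , drop = FALSE]
  }

  r1 <- .applyErrors(r1, errorRate, config@read1Len)
  r2 <- .applyErrors(r2, errorRate, config@read2Len)
  rownames(origin) <- NULL
  new("SimReads", read1 = r1, read2 = r2, origin = origin)
}

#' Generate background (template) reads
#'
#' Single-end direct sequencing of the untranscribed template pool: the sense
#' +2..+16 15mer followed by constant fill (or its reverse complement when
#' the configuration sets `bgAntisense`). Only the first 15 nt are used by
#' the analysis.
#'
#' @param lib A [TemplateLibrary].
#' @param config A [ScreenConfig].
#' @param nReads Number of background reads.
#' @param errorRate Per-base substitution probability.
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @return Character vector of reads.
#' @export
simulateBackground <- function(lib, config, nReads, errorRate = 0.001,
                               seed = NULL) {
  if (nReads <= 0) stop("nReads must be positive")
  if (!is.null(seed)) set.seed(as.integer(seed))
  m7 <- sample.int(16384L, nReads, replace = TRUE, prob = lib@motifCounts)
  t8 <- sample.int(65536L, nReads, replace = TRUE, prob = lib@tailCounts)
  fillsrc <- strrep(config@constantSeqs[["template_downstream"]], 4L)
  fill <- substr(fillsrc, 1L, config@read1Len - 15L)
  x <- .cppJoin3(kmerStrings(7L), m7, kmerStrings(8L), t8,
                 fill, rep.int(1L, nReads))
  if (config@bgAntisense) x <- revComp(x)
  .applyErrors(x, errorRate, config@read1Len)
}

#' Write sequences as gzipped FASTQ
#'
#' Plain 4-line FASTQ with constant quality `"I"`; appends when `append` is
#' `TRUE` so large runs can be written in chunks.
#'
#' @param seqs Character vector of reads.
#' @param path Output path (`.gz` implies gzip).
#' @param ids Read identifiers (default `read_1..n` offset by `idOffset`).
#' @param idOffset Offset added to default identifiers.
#' @param append Append to an existing file.
#' @return `path`, invisibly.
#' @export
writeFastq <- function(seqs, path, ids = NULL, idOffset = 0L, append = FALSE) {
  if (is.null(ids)) ids <- paste0("read_", idOffset + seq_along(seqs))
  con <- if (grepl("\\.gz$", path)) gzfile(path, if (append) "ab" else "wb")
         else file(path, if (append) "ab" else "wb")
  on.exit(close(con))
  rec <- stringi::stri_join("@", ids, "\n", seqs, "\n+\n",
                            strrep("I", stringi::stri_length(seqs)))
  writeLines(rec, con)
  invisible(path)
}

#' Read a FASTQ file
#'
#' Minimal validating reader for the package's 4-line FASTQ files. A
#' structurally invalid record raises an error naming its index.
#'
#' @param path FASTQ path (gzip transparent).
#' @return Character vector of read sequences (identifiers as names).
#' @export
readFastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L)
    stop("truncated FASTQ: ", path, " has ", length(lines),
         " lines (not a multiple of 4)")
  n <- length(lines) %/% 4L
  if (n == 0L) return(character(0))
  hd <- lines[seq(1L, by = 4L, length.out = n)]
  sq <- lines[seq(2L, by = 4L, length.out = n)]
  pl <- lines[seq(3L, by = 4L, length.out = n)]
  qu <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(hd, "@") | !startsWith(pl, "+") |
                 stringi::stri_length(sq) != stringi::stri_length(qu))
  if (length(bad))
    stop("malformed FASTQ record ", bad[1L], " in ", path)
  stats::setNames(sq, sub("^@", "", hd))
}
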