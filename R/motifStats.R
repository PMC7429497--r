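# Motif statistics: counting, background normalization, homopolymer flags,
# composition, group summaries, extra-G fractions, ranks, fold-range,
# replicate correlation, oversampling.

#' @importFrom data.table data.table
NULL

.checkSpan <- function(span) {
  span <- as.integer(span)
  if (length(span) != 2L || span[1] < 2L || span[2] > 16L || span[1] > span[2])
    stop("invalid span: must lie within +2..+16")
  span
}

#' Count motifs over a position span
#'
#' Pools reads with identical sequence over `span` (TSS coordinates within
#' +2..+16) and counts them. Optionally restricts to reads matching
#' `ctxMotif` over `ctxSpan` first (e.g. +2..+3 == "GG").
#'
#' @param x A [MotifReadSet] or [FilteredReadSet].
#' @param span Length-2 integer interval, e.g. `c(2, 8)`.
#' @param ctxSpan,ctxMotif Optional context restriction.
#' @return Named numeric vector of counts. For spans up to 9 nt the full
#'   motif space is returned (zeros included); wider spans return observed
#'   motifs only.
#' @export
countMotifs <- function(x, span = c(2L, 8L), ctxSpan = NULL, ctxMotif = NULL) {
  span <- .checkSpan(span)
  code <- x@m15code
  if (!is.null(ctxMotif)) {
    ctxSpan <- .checkSpan(ctxSpan)
    want <- encodeKmers(ctxMotif, ctxSpan[2] - ctxSpan[1] + 1L)
    code <- code[subCode(code, 15L, ctxSpan[1] - 1L, ctxSpan[2] - 1L) == want]
  }
  w <- span[2] - span[1] + 1L
  sub <- subCode(code, 15L, span[1] - 1L, span[2] - 1L)
  if (w <= 9L) {
    stats::setNames(as.numeric(tabulate(sub + 1L, 4^w)), kmerStrings(w))
  } else {
    dt <- data.table(code = sub)[, .N, by = "code"]
    dt <- dt[order(dt$code), ]
    stats::setNames(as.numeric(dt$N), decodeKmers(dt$code, w))
  }
}

# dense descending ranks with lexicographic tie-break over eligible rows
.assignRanks <- function(tb) {
  tb$rank <- NA_real_
  ok <- which(!tb$low_background & !tb$homopolymer & !is.na(tb$rel_abundance))
  if (length(ok)) {
    o <- ok[order(-tb$rel_abundance[ok], tb$motif[ok])]
    tb$rank[o] <- seq_along(o)
  }
  tb
}

#' Background-normalize motif counts
#'
#' Relative abundance of a motif is its read frequency divided by its
#' background (template) frequency:
#' `(count/total) / (bg_count/bg_total)`. Motifs observed fewer than `minBg`
#' times in the background are flagged `low_background`, get no relative
#' abundance, and are excluded from ranking.
#'
#' @param counts,bgCounts Named count vectors over one motif span (as
#'   returned by [countMotifs()]).
#' @param minBg Minimum background count (default 10).
#' @param span The span counted over (TSS coordinates).
#' @param plus1 The fixed +1 base.
#' @param totalReads,totalBg Normalization totals; default to the sums of
#'   the supplied counts (pass the run's filtered-read total when counting
#'   restricted subsets).
#' @return A [MotifTable] with dense ranks over unflagged motifs.
#' @examples
#' tb <- normalizeMotifs(c(AA = 200, AC = 300, AG = 300, AT = 200),
#'                       c(AA = 100, AC = 300, AG = 300, AT = 300),
#'                       span = c(2, 3))
#' @export
normalizeMotifs <- function(counts, bgCounts, minBg = 10L, span = c(2L, 8L),
                            plus1 = "G", totalReads = sum(counts),
                            totalBg = sum(bgCounts)) {
  if (totalReads <= 0 || totalBg <= 0) stop("zero totals")
  span <- .checkSpan(span)
  motifs <- union(names(counts), names(bgCounts))
  motifs <- motifs[order(motifs)]
  c1 <- stats::setNames(numeric(length(motifs)), motifs)
  c1[names(counts)] <- counts
  b1 <- stats::setNames(numeric(length(motifs)), motifs)
  b1[names(bgCounts)] <- bgCounts
  lowbg <- b1 < minBg
  rel <- ifelse(lowbg, NA_real_, (c1 / totalReads) / (b1 / totalBg))
  tb <- data.frame(motif = motifs, count = unname(c1), bg_count = unname(b1),
                   rel_abundance = unname(rel),
                   log2_rel = unname(log2(rel)),
                   low_background = unname(lowbg),
                   homopolymer = FALSE, rank = NA_real_,
                   stringsAsFactors = FALSE)
  tb <- .assignRanks(tb)
  new("MotifTable", span = span, table = tb, totalReads = totalReads,
      totalBg = totalBg, plus1 = plus1)
}

#' Flag homopolymeric motifs
#'
#' Flags motifs whose +1-prefixed sequence (for tables starting at +2;
#' otherwise the motif itself) contains a run of at least `minRun` identical
#' bases drawn from `bases`. Flagged motifs are excluded from ranking and
#' from group summaries. The default rule (run of 4+, any base) is one
#' admissible reading of homopolymer removal; both knobs are configurable.
#'
#' @param table A [MotifTable].
#' @param minRun Minimum run length (>= 2; default 4).
#' @param bases Bases whose runs count (default all four).
#' @return The table with updated `homopolymer` flags and recomputed ranks.
#' @export
flagHomopolymers <- function(table, minRun = 4L,
                             bases = c("A", "C", "G", "T")) {
  if (minRun < 2L) stop("minRun must be >= 2")
  tb <- table@table
  seqs <- if (table@span[1] == 2L) paste0(table@plus1, tb$motif) else tb$motif
  pat <- paste0("(", paste0(bases, "{", minRun, ",}", collapse = "|"), ")")
  tb$homopolymer <- stringi::stri_detect_regex(seqs, pat)
  tb <- .assignRanks(tb)
  methods::initialize(table, table = tb)
}

#' Background-normalized nucleotide composition
#'
#' Per position +2..+16, the read base frequencies are divided by the
#' background base frequencies and renormalized to sum to 1, so an unbiased
#' screen yields 0.25 everywhere.
#'
#' @param fg,bg [MotifReadSet]s (reads and background), or 4 x 15 count
#'   matrices (rows A,C,G,T).
#' @return 15 x 4 matrix of normalized frequencies (rows +2..+16).
#' @export
compositionMatrix <- function(fg, bg) {
  cf <- if (is.matrix(fg)) fg else positionCounts(fg)
  cb <- if (is.matrix(bg)) bg else positionCounts(bg)
  ff <- sweep(cf, 2L, colSums(cf), "/")
  fb <- sweep(cb, 2L, colSums(cb), "/")
  if (any(fb == 0)) stop("zero background frequency at some position/base")
  r <- ff / fb
  r <- sweep(r, 2L, colSums(r), "/")
  t(r)
}

#' Per-position base counts of a read set
#'
#' @param x A [MotifReadSet].
#' @return 4 x 15 count matrix (rows A,C,G,T; columns +2..+16).
#' @export
positionCounts <- function(x) {
  out <- matrix(0, 4L, 15L, dimnames = list(DNA_BASES, paste0("+", 2:16)))
  for (i in 1:15) {
    out[, i] <- tabulate(.kmerDigit(x@m15code, 15L, i) + 1L, 4L)
  }
  out
}

#' Group motif activities by +2/3 dinucleotide
#'
#' Splits the (unflagged, normalized) motifs of a +2..+8 table into the 16
#' +2/3 dinucleotide groups and summarizes `log2_rel` per group: quartiles
#' (linear interpolation, quantile type 7), median, IQR, and whisker bounds
#' at 1.5 x IQR beyond the quartiles.
#'
#' @param table A [MotifTable] whose span starts at +2 and covers +2..+8.
#' @return data.frame with one row per dinucleotide group.
#' @export
groupByDinucleotide <- function(table) {
  if (table@span[1] != 2L || table@span[2] < 8L)
    stop("table span must include +2..+8")
  tb <- table@table
  ok <- !tb$low_background & !tb$homopolymer & !is.na(tb$rel_abundance)
  grp <- substr(tb$motif, 1L, 2L)
  out <- lapply(kmerStrings(2L), function(g) {
    v <- tb$log2_rel[ok & grp == g]
    if (!length(v)) {
      return(data.frame(dinuc = g, n_motifs = 0L, q1 = NA_real_,
                        median = NA_real_, q3 = NA_real_, iqr = NA_real_,
                        whisker_lo = NA_real_, whisker_hi = NA_real_))
    }
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    data.frame(dinuc = g, n_motifs = length(v), q1 = q[1], median = q[2],
               q3 = q[3], iqr = iqr, whisker_lo = q[1] - 1.5 * iqr,
               whisker_hi = q[3] + 1.5 * iqr)
  })
  do.call(rbind, out)
}

#' Extra-G fractions per +1..+3 class
#'
#' Fraction of accepted reads with at least one, exactly one, and exactly two
#' extra 5' Cs (slipped Gs and/or the RT C), per +1..+3 start class, with
#' Wilson 95% intervals for `frac_ge1` and `frac_eq2`.
#'
#' @param reads A [FilteredReadSet].
#' @return data.frame with one row per class (n = 0 rows carry NA
#'   fractions).
#' @export
extraGFractions <- function(reads) {
  cls <- subCode(reads@m15code, 15L, 1L, 2L)
  out <- lapply(0:15, function(ci) {
    i <- which(cls == ci)
    n <- length(i)
    lab <- paste0(reads@plus1, kmerStrings(2L)[ci + 1L])
    if (n == 0L) {
      return(data.frame(class = lab, n = 0L, frac_ge1 = NA_real_,
                        frac_eq1 = NA_real_, frac_eq2 = NA_real_,
                        ge1_lo = NA_real_, ge1_hi = NA_real_,
                        eq2_lo = NA_real_, eq2_hi = NA_real_))
    }
    e <- reads@extraC[i]
    k1 <- sum(e >= 1L); k2 <- sum(e == 2L)
    ci1 <- .wilsonCI(k1, n); ci2 <- .wilsonCI(k2, n)
    data.frame(class = lab, n = n, frac_ge1 = k1 / n,
               frac_eq1 = sum(e == 1L) / n, frac_eq2 = k2 / n,
               ge1_lo = ci1[1], ge1_hi = ci1[2],
               eq2_lo = ci2[1], eq2_hi = ci2[2])
  })
  do.call(rbind, out)
}

#' Rank motifs within a start-class context
#'
#' Restricts a motif table to rows whose leading positions match `context`
#' (a +2/3 dinucleotide, or `NULL` for all rows) and assigns dense 1-based
#' ranks by descending relative abundance; ties break lexicographically.
#' Homopolymer- and low-background-flagged rows are excluded from ranking.
#'
#' @param table A [MotifTable].
#' @param context Optional +2/3 dinucleotide (tables starting at +2 only).
#' @return A [MotifTable] restricted to the context, ranks recomputed.
#' @export
rankMotifs <- function(table, context = NULL) {
  tb <- table@table
  if (!is.null(context)) {
    if (table@span[1] != 2L)
      stop("context ranking needs a table starting at +2")
    tb <- tb[startsWith(tb$motif, context), , drop = FALSE]
    if (!nrow(tb)) stop("empty table for context ", context)
  }
  if (!nrow(tb)) stop("empty table")
  tb <- .assignRanks(tb)
  rownames(tb) <- NULL
  methods::initialize(table, table = tb)
}

#' Activity fold-range of a motif table
#'
#' Ratio of the upper to the lower quantile of the relative abundances of
#' unflagged motifs (linear-interpolation quantiles). Quantiles (0, 1)
#' give max/min.
#'
#' @param table A [MotifTable].
#' @param lowQ,highQ Quantiles (defaults 0.01 and 0.99).
#' @return The fold range (scalar).
#' @export
activityRange <- function(table, lowQ = 0.01, highQ = 0.99) {
  if (lowQ >= highQ) stop("quantiles out of order")
  tb <- table@table
  v <- tb$rel_abundance[!tb$low_background & !tb$homopolymer &
                          !is.na(tb$rel_abundance)]
  if (length(v) < 10L) stop("need at least 10 unflagged motifs")
  q <- stats::quantile(v, c(lowQ, highQ), type = 7, names = FALSE)
  q[2] / q[1]
}

#' Correlation between replicate motif tables
#'
#' Pearson correlation of `log2_rel` and Spearman correlation of relative
#' abundance over the motifs unflagged in both replicates.
#'
#' @param tableA,tableB [MotifTable]s over the same span.
#' @return List with `pearson_log2`, `spearman`, `n_common`.
#' @export
replicateCorrelation <- function(tableA, tableB) {
  a <- tableA@table; b <- tableB@table
  oka <- !a$low_background & !a$homopolymer & !is.na(a$rel_abundance)
  okb <- !b$low_background & !b$homopolymer & !is.na(b$rel_abundance)
  common <- intersect(a$motif[oka], b$motif[okb])
  if (length(common) < 3L) stop("insufficient motif overlap between replicates")
  va <- a$log2_rel[match(common, a$motif)]
  vb <- b$log2_rel[match(common, b$motif)]
  list(pearson_log2 = stats::cor(va, vb),
       spearman = stats::cor(va, vb, method = "spearman"),
       n_common = length(common))
}

#' Motif oversampling factor
#'
#' Average reads available per possible motif of the span:
#' `total_reads / 4^span_width`.
#'
#' @param totalReads Total filtered reads.
#' @param span Position span (TSS coordinates).
#' @return Reads per motif.
#' @examples
#' oversampling(84e6, c(2, 8))  # ~5127
#' @export
oversampling <- function(totalReads, span = c(2L, 8L)) {
  if (totalReads <= 0) stop("totalReads must be positive")
  span <- .checkSpan(span)
  totalReads / 4^(span[2] - span[1] + 1L)
}
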