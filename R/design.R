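# Promoter design: scoring and constrained optimization of initially
# transcribed regions against a motif-activity table.

#' Load a motif table from TSV
#'
#' Reads a table with at least `motif` and `rel_abundance` columns
#' (`count`, `bg_count`, flag columns optional; `#` comment lines allowed)
#' and recomputes deterministic ranks.
#'
#' @param path TSV path.
#' @param span Position span the motifs cover (TSS coordinates).
#' @param plus1 The fixed +1 base.
#' @return A [MotifTable].
#' @export
loadMotifTable <- function(path, span = c(4L, 8L), plus1 = "G") {
  span <- .checkSpan(span)
  tb <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("motif", "rel_abundance") %in% names(tb)))
    stop("motif table needs columns 'motif' and 'rel_abundance'")
  if (anyDuplicated(tb$motif))
    stop("duplicate motif(s): ",
         paste(unique(tb$motif[duplicated(tb$motif)]), collapse = ", "))
  w <- span[2] - span[1] + 1L
  if (any(nchar(tb$motif) != w))
    stop("motifs must have width ", w, " for span +", span[1], "..+", span[2])
  .checkDNA(tb$motif, "motif")
  out <- data.frame(motif = tb$motif,
                    count = if ("count" %in% names(tb)) tb$count else NA_real_,
                    bg_count = if ("bg_count" %in% names(tb)) tb$bg_count else NA_real_,
                    rel_abundance = as.numeric(tb$rel_abundance),
                    log2_rel = log2(as.numeric(tb$rel_abundance)),
                    low_background = if ("low_background" %in% names(tb))
                      as.logical(tb$low_background) else FALSE,
                    homopolymer = if ("homopolymer" %in% names(tb))
                      as.logical(tb$homopolymer) else FALSE,
                    rank = NA_real_, stringsAsFactors = FALSE)
  out <- .assignRanks(out)
  new("MotifTable", span = span, table = out,
      totalReads = if ("count" %in% names(tb)) sum(tb$count) else NA_real_,
      totalBg = if ("bg_count" %in% names(tb)) sum(tb$bg_count) else NA_real_,
      plus1 = plus1)
}

# locate the core promoter and return the downstream (+1..) sequence
.downstreamOfCore <- function(sequence, core) {
  .checkDNA(sequence)
  hit <- stringi::stri_locate_first_fixed(sequence, core)
  if (is.na(hit[1, 1])) stop("core promoter not found in sequence")
  substring(sequence, hit[1, 2] + 1L)
}

#' Score a promoter + initially transcribed region
#'
#' Locates the configured core promoter (-17..-1) in `sequence`, extracts the
#' motif at the table's span downstream of +1, and returns its relative
#' abundance and rank. Designs whose +1..+3 start is not a G triplet are
#' flagged with a context warning (ranks in GGG-context tables are then not
#' directly comparable).
#'
#' @param sequence Promoter plus downstream sequence.
#' @param table A [MotifTable].
#' @param config A [ScreenConfig] (supplies the core promoter).
#' @return A [DesignResult].
#' @export
scorePromoter <- function(sequence, table, config = screenConfig()) {
  down <- .downstreamOfCore(sequence, config@upstreamCore)
  span <- table@span
  if (nchar(down) < max(8L, span[2]))
    stop("sequence too short downstream of +1: need at least ",
         max(8L, span[2]), " nt")
  motif <- substr(down, span[1], span[2])
  row <- match(motif, table@table$motif)
  if (is.na(row)) stop("motif ", motif, " not present in the table")
  ctx <- substr(down, 1L, 3L)
  new("DesignResult", sequence = sequence, motif = motif,
      relAbundance = table@table$rel_abundance[row],
      rank = table@table$rank[row],
      edits = data.frame(type = character(0), position = integer(0),
                         base = character(0)),
      contextWarning = !identical(ctx, "GGG"))
}

# all single-base insertions of seq within window positions [a, b+1]
# (insertion before position p) and substitutions within [a, b]
.singleEdits <- function(down, a, b) {
  out <- list()
  bmax <- min(b, nchar(down))
  for (p in a:(bmax + 1L)) {
    for (base in DNA_BASES) {
      ins <- paste0(substr(down, 1L, p - 1L), base, substring(down, p))
      out[[length(out) + 1L]] <- list(seq = ins, type = "insertion",
                                      pos = p, base = base)
    }
  }
  for (p in a:bmax) {
    old <- substr(down, p, p)
    for (base in setdiff(DNA_BASES, old)) {
      sub <- down
      substr(sub, p, p) <- base
      out[[length(out) + 1L]] <- list(seq = sub, type = "substitution",
                                      pos = p, base = base)
    }
  }
  out
}

#' Optimize an initially transcribed region under an edit budget
#'
#' Exhaustively enumerates all combinations of up to `maxInsertions`
#' single-base insertions and `maxSubstitutions` substitutions inside the
#' editable window (TSS coordinates on the evolving sequence), scores every
#' distinct outcome against the motif table, and returns candidates sorted by
#' rank, then fewest edits, then sequence. Duplicate sequences reachable by
#' different edit paths are collapsed to their minimal edit count.
#' Enumeration is complete for budgets up to 3 + 3.
#'
#' @param sequence Promoter plus downstream sequence (must contain the core
#'   promoter).
#' @param table A [MotifTable].
#' @param window Editable window in TSS coordinates (default `c(3, 8)`).
#' @param maxInsertions,maxSubstitutions Edit budgets.
#' @param maxTotalLength Optional cap on total sequence length.
#' @param config A [ScreenConfig].
#' @return data.frame of candidates: sequence, motif, rel_abundance, rank,
#'   n_insertions, n_substitutions.
#' @export
optimizeInsert <- function(sequence, table, window = c(3L, 8L),
                           maxInsertions = 1L, maxSubstitutions = 0L,
                           maxTotalLength = Inf, config = screenConfig()) {
  if (maxInsertions < 0L || maxSubstitutions < 0L) stop("budgets must be >= 0")
  if (window[1] < 2L) stop("editable window must lie downstream of +1")
  core <- config@upstreamCore
  down0 <- .downstreamOfCore(sequence, core)
  prefix <- substr(sequence, 1L,
                   stringi::stri_locate_first_fixed(sequence, core)[1, 2])

  # breadth-first enumeration over (insertions, substitutions) budgets,
  # collapsing duplicate sequences to minimal edit counts
  seen <- new.env(parent = emptyenv())
  assign(down0, c(0L, 0L), envir = seen)
  frontier <- list(list(seq = down0, ins = 0L, sub = 0L))
  while (length(frontier)) {
    nxt <- list()
    for (st in frontier) {
      for (ed in .singleEdits(st$seq, window[1], window[2])) {
        ni <- st$ins + (ed$type == "insertion")
        ns <- st$sub + (ed$type == "substitution")
        if (ni > maxInsertions || ns > maxSubstitutions) next
        if (nchar(prefix) + nchar(ed$seq) > maxTotalLength) next
        prev <- if (exists(ed$seq, envir = seen, inherits = FALSE))
          get(ed$seq, envir = seen) else NULL
        if (!is.null(prev) && sum(prev) <= ni + ns) next
        assign(ed$seq, c(ni, ns), envir = seen)
        nxt[[length(nxt) + 1L]] <- list(seq = ed$seq, ins = ni, sub = ns)
      }
    }
    frontier <- nxt
  }

  cand <- ls(seen)
  span <- table@span
  rows <- lapply(cand, function(s) {
    budget <- get(s, envir = seen)
    if (nchar(s) < span[2]) return(NULL)
    motif <- substr(s, span[1], span[2])
    row <- match(motif, table@table$motif)
    if (is.na(row) || is.na(table@table$rank[row])) return(NULL)
    data.frame(sequence = paste0(prefix, s), motif = motif,
               rel_abundance = table@table$rel_abundance[row],
               rank = table@table$rank[row],
               n_insertions = budget[1], n_substitutions = budget[2],
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows) || !nrow(rows)) stop("empty candidate set")
  o <- order(rows$rank, rows$n_insertions + rows$n_substitutions,
             rows$sequence)
  rows <- rows[o, , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

#' Assemble an annotated promoter primer
#'
#' Concatenates an (optionally empty) AT-rich upstream element, the -17..-1
#' core promoter, the initially transcribed region (+1..) and a tail, with
#' TSS-coordinate annotations. Warns when the upstream element's AT fraction
#' is below 0.75 (the element's purpose is to aid duplex melting and
#' polymerase recruitment at low template concentrations).
#'
#' @param upstreamElement Sequence placed immediately upstream of the core
#'   (e.g. `"ATTA"` at -21..-18); may be empty.
#' @param core The -17..-1 core promoter.
#' @param itr Initially transcribed sequence starting at +1.
#' @param tail Optional downstream tail.
#' @return List with `sequence`, `annotation` (region/start/end in TSS
#'   coordinates), and `at_fraction` of the upstream element.
#' @export
assemblePrimer <- function(upstreamElement = "", core = T7_CORE, itr,
                           tail = "") {
  for (s in c(upstreamElement, core, itr, tail))
    if (nzchar(s)) .checkDNA(s)
  atFrac <- if (nzchar(upstreamElement)) {
    mean(strsplit(upstreamElement, "")[[1L]] %in% c("A", "T"))
  } else NA_real_
  if (!is.na(atFrac) && atFrac < 0.75)
    warning("upstream element AT fraction ", signif(atFrac, 3),
            " is below 0.75")
  seqs <- c(upstream_element = upstreamElement, core = core, itr = itr,
            tail = tail)
  seqs <- seqs[nzchar(seqs)]
  ulen <- nchar(upstreamElement)
  ann <- list()
  if (ulen) ann$upstream_element <- c(-17L - ulen, -18L)
  ann$core <- c(-17L, -1L)
  ann$itr <- c(1L, nchar(itr))
  if (nzchar(tail)) ann$tail <- c(nchar(itr) + 1L, nchar(itr) + nchar(tail))
  annotation <- data.frame(region = names(ann),
                           start = vapply(ann, `[`, 0L, 1L),
                           end = vapply(ann, `[`, 0L, 2L),
                           row.names = NULL, stringsAsFactors = FALSE)
  list(sequence = paste(seqs, collapse = ""), annotation = annotation,
       at_fraction = atFrac)
}
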