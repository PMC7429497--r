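# End-to-end orchestration: simulate -> process -> analyze, with optional
# file outputs and a reproducibility manifest.

#' Run a full simulated screen
#'
#' Simulates a template library, transcribes it under the activity model,
#' generates paired 5' RACE reads and background reads, filters them, and
#' computes the motif statistics. Reads are generated and filtered in chunks
#' so arbitrarily deep runs hold only integer-coded per-read fields in
#' memory. All randomness flows from the single `seed`.
#'
#' @param config A [ScreenConfig].
#' @param model An [ActivityModel].
#' @param nReads Transcript read pairs to generate (pre-duplication).
#' @param nBackground Background reads (default: same depth).
#' @param seed Integer seed.
#' @param libSize Template library size (default 1e10 molecules).
#' @param baseBias Per-position synthesis bias (see
#'   [simulateTemplateLibrary()]).
#' @param errorRate,dupRate Sequencing error and PCR duplication rates.
#' @param chunkSize Reads per generation/processing chunk.
#' @param outDir If non-`NULL`, write all tables, FASTQ files and the run
#'   manifest there.
#' @param writeFastq Write `r1.fastq.gz`, `r2.fastq.gz`,
#'   `background.fastq.gz` under `outDir` (off by default; the tables do not
#'   need them).
#' @param verbose Print stage progress.
#' @return A [ScreenResult].
#' @examples
#' res <- runScreen(nReads = 2e4, nBackground = 2e4, seed = 1,
#'                  libSize = 1e6)
#' filterStats(res)
#' @export
runScreen <- function(config = screenConfig(),
                      model = buildActivityModel(
                        if (config@polymeraseMode == "T7") "t7_like"
                        else "sp6_like", seed = seed),
                      nReads = 1e6, nBackground = nReads, seed = 1L,
                      libSize = 1e10, baseBias = rep(0.25, 4),
                      errorRate = 0.001, dupRate = 0.1, chunkSize = 2e6,
                      outDir = NULL, writeFastq = FALSE, verbose = FALSE) {
  seed <- as.integer(seed)
  force(model)
  set.seed(seed)
  say <- function(...) if (verbose) message(...)

  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  fq <- function(name) file.path(outDir, name)

  say("simulating template library (", format(libSize, big.mark = ","),
      " molecules)")
  lib <- simulateTemplateLibrary(config, libSize, baseBias)
  say("transcribing ", nReads, " molecules")
  transcripts <- transcribe(lib, model, nReads)

  contamIdx <- if (length(config@contaminants))
    buildContaminantIndex(config@contaminants, config@contamK) else NULL

  say("generating and filtering reads")
  starts <- seq(1L, nReads, by = chunkSize)
  doFastq <- !is.null(outDir) && writeFastq
  fast <- .fastPathOK(config, contamIdx, doFastq)
  chunks <- vector("list", length(starts))
  nEmitted <- 0L
  for (ci in seq_along(starts)) {
    i <- starts[ci]:min(starts[ci] + chunkSize - 1L, nReads)
    if (fast) {
      chunks[[ci]] <- .simChunkFast(transcripts[i], config, model,
                                    errorRate, dupRate)
    } else {
      rd <- makeReads(transcripts[i], config, model, errorRate, dupRate)
      if (doFastq) {
        writeFastq(rd@read1, fq("r1.fastq.gz"), idOffset = nEmitted,
                   append = ci > 1L)
        writeFastq(rd@read2, fq("r2.fastq.gz"), idOffset = nEmitted,
                   append = ci > 1L)
        nEmitted <- nEmitted + length(rd@read1)
      }
      chunks[[ci]] <- .chunkFields(rd@read1, rd@read2, config, contamIdx)
    }
  }
  fields <- .catFields(chunks)
  chunks <- NULL
  run <- .assembleRun(fields, config)
  fields <- NULL
  filtered <- run$reads
  stats <- run$stats
  run <- NULL
  truth <- transcripts@truth
  transcripts <- NULL
  gc(FALSE)

  say("generating background (", nBackground, " reads)")
  bgStarts <- seq(1L, nBackground, by = chunkSize)
  bgCodes <- vector("list", length(bgStarts))
  nEmitted <- 0L
  for (ci in seq_along(bgStarts)) {
    nb <- min(bgStarts[ci] + chunkSize - 1L, nBackground) - bgStarts[ci] + 1L
    if (fast) {
      bgCodes[[ci]] <- .simBgCodesFast(lib, config, nb, errorRate)
    } else {
      bgReads <- simulateBackground(lib, config, nb, errorRate)
      if (doFastq) {
        writeFastq(bgReads, fq("background.fastq.gz"), idOffset = nEmitted,
                   append = ci > 1L)
        nEmitted <- nEmitted + length(bgReads)
      }
      bgCodes[[ci]] <- processBackground(bgReads, config)@m15code
    }
  }
  bg <- new("MotifReadSet", m15code = do.call(c, bgCodes),
            plus1 = config@plus1Base)

  say("computing motif statistics")
  res <- .analyzeScreen(filtered, bg, stats, config)
  res@truth <- truth

  res@manifest <- list(
    seed = seed, n_reads = nReads, n_background = nBackground,
    lib_size = libSize, error_rate = errorRate, dup_rate = dupRate,
    model_mode = model@mode, fold_range = model@foldRange,
    package_version = as.character(utils::packageVersion("racescreen")),
    config_hash = .configHash(config))

  if (!is.null(outDir)) {
    writeScreenOutputs(res, outDir, config)
    if (doFastq) {
      files <- c("r1.fastq.gz", "r2.fastq.gz", "background.fastq.gz")
      res@manifest$fastq_md5 <- as.list(tools::md5sum(file.path(outDir, files)))
    }
    jsonlite::write_json(res@manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}

.configHash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeScreenConfig(config, tmp)
  unname(tools::md5sum(tmp))
}

# shared analysis block: motif tables, composition, groups, extra-G, summary
.analyzeScreen <- function(filtered, bg, stats, config) {
  c28 <- countMotifs(filtered, c(2L, 8L))
  b28 <- countMotifs(bg, c(2L, 8L))
  t28 <- normalizeMotifs(c28, b28, minBg = config@minBg, span = c(2L, 8L),
                         plus1 = config@plus1Base)
  t28 <- flagHomopolymers(t28, config@homopolymerMinRun,
                          config@homopolymerBases)
  c48 <- countMotifs(filtered, c(4L, 8L))
  b48 <- countMotifs(bg, c(4L, 8L))
  t48 <- normalizeMotifs(c48, b48, minBg = config@minBg, span = c(4L, 8L),
                         plus1 = config@plus1Base)
  t48 <- flagHomopolymers(t48, config@homopolymerMinRun,
                          config@homopolymerBases)
  # composition is undefined when a base never occurs in the background at
  # some position (e.g. degenerate designs fixing +2/+3)
  comp <- if (length(filtered) && length(bg@m15code)) {
    tryCatch(compositionMatrix(filtered, bg),
             error = function(e) matrix(numeric(0), 0L, 0L))
  } else matrix(numeric(0), 0L, 0L)
  groups <- groupByDinucleotide(t28)
  exg <- extraGFractions(filtered)
  summary <- list(
    accepted_reads = stats@accepted,
    background_reads = length(bg@m15code),
    oversampling_28 = oversampling(max(stats@accepted, 1), c(2L, 8L)),
    activity_range_28 = tryCatch(activityRange(t28), error = function(e) NA_real_),
    activity_range_48 = tryCatch(activityRange(t48), error = function(e) NA_real_))
  new("ScreenResult", filtered = filtered, stats = stats, table28 = t28,
      table48 = t48, composition = comp, groups = groups, extraG = exg,
      summary = summary, truth = data.frame(), manifest = list())
}

#' Analyze processed reads against a background library
#'
#' The analysis half of [runScreen()] for externally processed inputs.
#'
#' @param filtered A [FilteredReadSet] from [processRun()].
#' @param bg A [MotifReadSet] from [processBackground()].
#' @param stats The run's [FilterStats].
#' @param config A [ScreenConfig].
#' @return A [ScreenResult] (ground truth and manifest empty).
#' @export
analyzeScreen <- function(filtered, bg, stats, config = screenConfig()) {
  .analyzeScreen(filtered, bg, stats, config)
}

#' Write the tabular outputs of a screen run
#'
#' Writes motif tables, composition, group summaries, extra-G report, filter
#' stats and scalar summaries under `dir`, as TSV with a header comment
#' naming the span, plus JSON for the scalar pieces, and echoes the
#' configuration as YAML.
#'
#' @param res A [ScreenResult].
#' @param dir Output directory.
#' @param config The run's [ScreenConfig].
#' @return `dir`, invisibly.
#' @export
writeScreenOutputs <- function(res, dir, config = screenConfig()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wtsv <- function(df, name, comment) {
    path <- file.path(dir, name)
    con <- file(path, "w")
    writeLines(paste0("# ", comment), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  wtsv(res@table28@table, "motif_table_+2_+8.tsv",
       "motifs over +2..+8 (RNA sense); rel_abundance = bg-normalized frequency ratio")
  wtsv(res@table48@table, "motif_table_+4_+8.tsv",
       "motifs over +4..+8 (RNA sense), all +2/3 contexts pooled")
  ctx <- rankMotifs(res@table28, "GG")
  wtsv(ctx@table, "motif_table_+4_+8_GGGctx.tsv",
       "+2..+8 motifs restricted to GGG starts; ranks are the +4..+8 ranks within the GGG context")
  if (length(res@composition))
    wtsv(data.frame(position = rownames(res@composition), res@composition),
         "composition.tsv", "background-normalized base composition per position")
  wtsv(res@groups, "groups_dinuc.tsv",
       "log2 rel abundance summaries per +2/3 dinucleotide (type-7 quartiles)")
  wtsv(res@extraG, "extra_g.tsv",
       "extra-5'-C fractions per +1..+3 class with Wilson 95% CIs")
  wtsv(as.data.frame(res@stats), "filter_stats.tsv", "per-stage read counts")
  st <- as.data.frame(res@stats)
  jsonlite::write_json(as.list(stats::setNames(st$reads, st$stage)),
                       file.path(dir, "filter_stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (length(res@filtered) <= 2e6) {
    wtsv(as.data.frame(res@filtered), "filtered_reads.tsv",
         "accepted reads: RNA-sense +2..+16 15mer, extra 5' C count, UMI")
  }
  if (nrow(res@truth))
    wtsv(res@truth, "ground_truth.tsv", "generating model ground truth per +2..+8 motif")
  jsonlite::write_json(res@summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeScreenConfig(config, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Build a packaged demonstration dataset
#'
#' `"tiny"` (1e3 reads, for unit tests) or `"demo"` (1e6 reads) fixtures
#' with fixed seeds and ground truth included.
#'
#' @param scale `"tiny"` or `"demo"`.
#' @param dir Optional output directory (passed to [runScreen()]).
#' @return A [ScreenResult].
#' @export
makeFixture <- function(scale = c("tiny", "demo"), dir = NULL) {
  scale <- match.arg(scale)
  n <- switch(scale, tiny = 1e3, demo = 1e6)
  libSize <- switch(scale, tiny = 1e5, demo = 1e8)
  seed <- switch(scale, tiny = 101L, demo = 202L)
  runScreen(nReads = n, nBackground = n, seed = seed, libSize = libSize,
            outDir = dir, writeFastq = !is.null(dir))
}
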