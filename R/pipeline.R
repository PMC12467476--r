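## End-to-end batch analysis: module derivation feeds the per-sequence
## analyzers; banding runs on the original sequences; results land as TSV
## tables plus a JSON run manifest.

.safeRun <- function(expr, id, what, errors) {
  tryCatch(expr, error = function(e) {
    message(sprintf("[skip] %s failed for '%s': %s", what, id,
                    conditionMessage(e)))
    errors$log <- c(errors$log, sprintf("%s:%s:%s", what, id,
                                        conditionMessage(e)))
    NULL
  })
}

.writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

## run blockiness / homopeptide / repetitiveness over a sequence set with
## deterministic per-(sequence, analyzer) sub-seeds
.analyzeSet <- function(seqs, seed, sampleSize, alpha, errors,
                        lowPower = NULL) {
  ids <- names(seqs)
  run1 <- function(fn, tag) {
    out <- lapply(ids, function(id) {
      set.seed(.sequenceSeed(seed, paste0(id, "#", tag)))
      .safeRun(fn(setNames(seqs[id], id)), id, tag, errors)
    })
    Filter(Negate(is.null), out)
  }
  blk <- run1(function(s) assessBlockiness(s, sampleSize, alpha), "blocky")
  hpp <- run1(function(s) assessHomopeptides(s, sampleSize, alpha),
              "homopeptide")
  rep_ <- run1(function(s) assessRepetitiveness(s, sampleSize, alpha),
               "repetitiveness")
  tabs <- list(blockiness = if (length(blk)) blockinessTable(blk),
               homopeptides = if (length(hpp)) homopeptideTable(hpp),
               repetitiveness = if (length(rep_)) repetitivenessTable(rep_))
  if (!is.null(lowPower))
    tabs <- lapply(tabs, function(df) {
      if (!is.null(df)) df$low_power <- lowPower[df$seq_id]
      df
    })
  tabs
}

#' Run the full pattern-analysis pipeline on a sequence batch
#'
#' With `cmodules = TRUE`, pooled multi-parameter scans are reduced to
#' compositional modules and boundary sets; the module sub-sequences are
#' then re-fed, together with the original sequences, to the blockiness,
#' homopeptide and repetitiveness analyzers. Banding runs on the original
#' sequences only. Per-sequence analyzer failures are logged and skipped so
#' a batch never aborts. All randomness derives deterministically from
#' `seed` and the sequence ids, so results are independent of input order
#' and byte-reproducible across runs.
#'
#' Output files in `outputDir`: `cmodules.fasta`, `cmodules.tsv`,
#' `boundary_sets.tsv`, `blockiness.tsv`, `banding.tsv`,
#' `homopeptides.tsv`, `repetitiveness.tsv`, module-level
#' `*_cmodules.tsv` variants, and
#' `manifest.json` (seed, grids, settings, versions, skip log). Modules
#' shorter than 10 residues are still analyzed but flagged `low_power` in
#' the module-level tables.
#'
#' @param input path to a protein FASTA file, or a sequence set.
#' @param outputDir output directory (created if needed).
#' @param cmodules logical: derive and re-analyze compositional modules
#'   (disable when the input already is a module set).
#' @param sampleSize scrambles / random endpoint sets per null (>= 100).
#' @param alpha significance level.
#' @param seed global seed; per-sequence sub-seeds derive from it.
#' @param moduleGrid,bandGrid scanner parameter grids.
#' @param background background mode or table (see
#'   [backgroundFrequencies()]); `"dataset"` uses the whole input batch.
#' @return invisibly, a list with the tables and the manifest.
#' @export
runPatternAnalysis <- function(input, outputDir, cmodules = TRUE,
                               sampleSize = 1000, alpha = 0.05, seed = 1,
                               moduleGrid = defaultModuleGrid(),
                               bandGrid = defaultBandGrid(),
                               background = "dataset") {
  if (sampleSize < 100) stop("sampleSize must be >= 100")
  isPath <- is.character(input) && length(input) == 1L &&
    is.null(names(input)) &&
    (file.exists(input) || grepl("[/\\\\]|\\.(fa|fasta|faa)$", input))
  if (isPath && !file.exists(input))
    stop("input file does not exist: ", input)
  seqs <- if (isPath) readProteinFasta(input) else .asSequenceSet(input)
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  bg <- backgroundFrequencies(seqs, background)
  errors <- new.env(); errors$log <- character()
  files <- character()
  out <- list()

  if (cmodules) {
    pooled <- scanBiasGrid(seqs, moduleGrid, background = bg)
    modules <- deriveModules(pooled)
    boundaries <- deriveBoundarySets(pooled)
    out$cmodules <- as.data.frame(modules)
    out$boundary_sets <- as.data.frame(boundaries)
    .writeTsv(out$cmodules, file.path(outputDir, "cmodules.tsv"))
    .writeTsv(out$boundary_sets, file.path(outputDir, "boundary_sets.tsv"))
    writeRegionFasta(seqs, modules, file.path(outputDir, "cmodules.fasta"))
    files <- c(files, "cmodules.tsv", "boundary_sets.tsv",
               "cmodules.fasta")
  }

  tabs <- .analyzeSet(seqs, seed, sampleSize, alpha, errors)
  for (nm in names(tabs)) {
    if (is.null(tabs[[nm]])) next
    out[[nm]] <- tabs[[nm]]
    .writeTsv(tabs[[nm]], file.path(outputDir, paste0(nm, ".tsv")))
    files <- c(files, paste0(nm, ".tsv"))
  }

  bandRows <- list()
  for (id in names(seqs)) {
    set.seed(.sequenceSeed(seed, paste0(id, "#banding")))
    ass <- .safeRun(assessBanding(setNames(seqs[id], id), bandGrid,
                                  background = bg, nSamples = sampleSize,
                                  alpha = alpha)[[1L]],
                    id, "banding", errors)
    if (length(ass)) bandRows <- c(bandRows, ass)
  }
  out$banding <- bandReportTable(bandRows)
  .writeTsv(out$banding, file.path(outputDir, "banding.tsv"))
  files <- c(files, "banding.tsv")

  if (cmodules && length(modules)) {
    modSeqs <- setNames(
      substring(seqs[modules@seqId], modules@start, modules@end),
      sprintf("%s/%d-%d", modules@seqId, modules@start, modules@end))
    lowPower <- setNames(modules@w < 10L, names(modSeqs))
    mtabs <- .analyzeSet(modSeqs, seed, sampleSize, alpha, errors,
                         lowPower = lowPower)
    for (nm in names(mtabs)) {
      if (is.null(mtabs[[nm]])) next
      fn <- paste0(nm, "_cmodules.tsv")
      out[[paste0(nm, "_cmodules")]] <- mtabs[[nm]]
      .writeTsv(mtabs[[nm]], file.path(outputDir, fn))
      files <- c(files, fn)
    }
  }

  ## one-line category summaries per analyzer
  .rate <- function(df, col = "call") {
    if (is.null(df) || !nrow(df)) return("no results")
    paste(sprintf("%s=%d", names(table(df[[col]])), table(df[[col]])),
          collapse = " ")
  }
  message("blockiness calls: ", .rate(out$blockiness))
  message("homopeptide calls: ", .rate(out$homopeptides))
  message("repetitiveness calls: ", .rate(out$repetitiveness))
  message("band-set calls: ", .rate(out$banding))

  manifest <- list(
    seed = seed, sample_size = sampleSize, alpha = alpha,
    cmodules = cmodules, background = if (is.numeric(background))
      "user" else background,
    module_grid = moduleGrid, band_grid = bandGrid,
    n_sequences = length(seqs), files = files,
    skipped = errors$log,
    package_version = as.character(packageVersion("cbpatterns")),
    r_version = R.version.string)
  jsonlite::write_json(manifest, file.path(outputDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  out$manifest <- manifest
  invisible(out)
}
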