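## Config-driven end-to-end runs and the delimited/JSON interchange formats.

#' Pipeline run configuration
#'
#' @slot design a [CohortDesign-class] for simulated input, or NULL.
#' @slot inputDir directory with `spectra.tsv` + `metadata.tsv` for ingested
#'   input (character(0) when simulating).
#' @slot processing a [ProcessingConfig-class].
#' @slot contrasts list of `c(positive, reference)` group-label pairs.
#' @slot k cross-validation folds.
#' @slot nPerm permutations per contrast.
#' @slot alpha significance level (CV-ANOVA and loading cutoffs).
#' @slot pcaA PCA dimensions for Hotelling outlier gating.
#' @slot outlierAlpha level of the Hotelling limit.
#' @slot seed master seed; per-contrast seeds are derived from it.
#' @slot outDir output directory.
#' @exportClass PipelineConfig
setClass("PipelineConfig",
  slots = c(design = "ANY", inputDir = "character",
            processing = "ProcessingConfig", contrasts = "list",
            k = "integer", nPerm = "integer", alpha = "numeric",
            pcaA = "integer", outlierAlpha = "numeric", seed = "integer",
            outDir = "character")
)

setValidity("PipelineConfig", function(object) {
  msg <- NULL
  if (is.null(object@design) && !length(object@inputDir))
    msg <- c(msg, "either a design (simulate) or an inputDir (ingest) is required")
  if (object@k < 2L) msg <- c(msg, "k must be >= 2")
  if (object@nPerm < 1L) msg <- c(msg, "nPerm must be >= 1")
  for (ct in object@contrasts)
    if (length(ct) != 2L) msg <- c(msg, "each contrast must be a label pair")
  if (is.null(msg)) TRUE else msg
})

#' Construct a PipelineConfig
#'
#' @param design optional [CohortDesign-class] (simulated input).
#' @param inputDir optional directory of an ingested cohort (see
#'   [writeCohort()] for the layout).
#' @param processing a [ProcessingConfig-class].
#' @param contrasts list of `c(positive, reference)` pairs; defaults to
#'   every non-control group versus the first group of the design.
#' @param k,nPerm,alpha,pcaA,outlierAlpha,seed,outDir see slots.
#' @return A [PipelineConfig-class].
#' @export
pipelineConfig <- function(design = NULL, inputDir = character(0),
                           processing = processingConfig(),
                           contrasts = NULL, k = 7, nPerm = 200,
                           alpha = 0.05, pcaA = 2, outlierAlpha = 0.05,
                           seed = 1, outDir = tempfile("nmr_run_")) {
  if (is.null(contrasts)) {
    contrasts <- list()
    if (!is.null(design) && length(design@groups) >= 2L) {
      ref <- names(design@groups)[1L]
      for (g in names(design@groups)[-1L])
        contrasts[[length(contrasts) + 1L]] <- c(g, ref)
    }
  }
  new("PipelineConfig", design = design, inputDir = inputDir,
      processing = processing, contrasts = contrasts,
      k = as.integer(k), nPerm = as.integer(nPerm), alpha = alpha,
      pcaA = as.integer(pcaA), outlierAlpha = outlierAlpha,
      seed = as.integer(seed), outDir = outDir)
}

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig:",
      if (!is.null(object@design)) "simulated input" else
        paste("ingest from", object@inputDir), "\n")
  cat(sprintf("  %d contrast(s), k = %d, nPerm = %d, alpha = %g, seed = %d\n",
              length(object@contrasts), object@k, object@nPerm,
              object@alpha, object@seed))
})

## ---------------------------------------------------------------------------
## Design / config serialisation
## ---------------------------------------------------------------------------

.designToList <- function(design) {
  list(groups = as.list(design@groups),
       effects = lapply(design@effects, as.list),
       shift_jitter_sd = design@shiftJitterSd,
       residual_jitter_sd = design@residualJitterSd,
       drift_regions = design@driftRegions,
       noise_sd = design@noiseSd,
       baseline_amplitude = design@baselineAmplitude,
       lipoprotein_scale = design@lipoproteinScale,
       intensity_cv = design@intensityCv,
       seed = design@seed,
       ppm_max = max(design@ppmAxis), ppm_min = min(design@ppmAxis),
       ppm_step = abs(design@ppmAxis[2L] - design@ppmAxis[1L]),
       frequency_mhz = design@frequencyMHz)
}

.listToDesign <- function(x) {
  cohortDesign(groups = unlist(x$groups),
               effects = lapply(x$effects, unlist),
               shiftJitterSd = x$shift_jitter_sd %||% 0.003,
               residualJitterSd = x$residual_jitter_sd %||% 5e-4,
               driftRegions = if (!is.null(x$drift_regions)) {
                 if (is.matrix(x$drift_regions))
                   lapply(seq_len(nrow(x$drift_regions)),
                          function(i) x$drift_regions[i, ])
                 else lapply(x$drift_regions, unlist)
               } else list(c(1.43, 1.50), c(6.98, 7.10), c(7.70, 7.84)),
               noiseSd = x$noise_sd %||% 0.01,
               baselineAmplitude = x$baseline_amplitude %||% 0.05,
               lipoproteinScale = x$lipoprotein_scale %||% 1,
               intensityCv = x$intensity_cv %||% 0,
               seed = x$seed %||% 1L,
               ppmAxis = seq(x$ppm_max %||% 9.5, x$ppm_min %||% 0.2,
                             by = -(x$ppm_step %||% 0.001)),
               frequencyMHz = x$frequency_mhz %||% 599.35)
}

#' Read a pipeline configuration from YAML
#'
#' Recognised top-level keys: `design` (the simulation recipe), `input_dir`,
#' `contrasts` (list of two-element lists), `k`, `n_perm`, `alpha`, `pca_a`,
#' `outlier_alpha`, `seed`, `out_dir`, and `processing` overrides
#' (`lb_hz`, `bin_width`, `bin_range`, `water_region`, `align_regions`,
#' `reference_ppm`).
#'
#' @param path YAML file path.
#' @return A [PipelineConfig-class].
#' @export
readPipelineConfig <- function(path) {
  x <- yaml::read_yaml(path)
  pc <- x$processing %||% list()
  processing <- processingConfig(
    lbHz = pc$lb_hz %||% 1,
    zeroFillTo = pc$zero_fill_to %||% 65536L,
    binWidth = pc$bin_width %||% 0.004,
    binRange = unlist(pc$bin_range) %||% c(0.5, 9.0),
    waterRegion = unlist(pc$water_region) %||% c(4.23, 5.18),
    alignRegions = if (!is.null(pc$align_regions))
      lapply(pc$align_regions, unlist)
    else list(c(1.43, 1.50), c(6.98, 7.10), c(7.70, 7.84)),
    referencePpm = pc$reference_ppm %||% 5.236)
  pipelineConfig(
    design = if (!is.null(x$design)) .listToDesign(x$design) else NULL,
    inputDir = x$input_dir %||% character(0),
    processing = processing,
    contrasts = if (!is.null(x$contrasts))
      lapply(x$contrasts, unlist) else NULL,
    k = x$k %||% 7, nPerm = x$n_perm %||% 200, alpha = x$alpha %||% 0.05,
    pcaA = x$pca_a %||% 2, outlierAlpha = x$outlier_alpha %||% 0.05,
    seed = x$seed %||% 1,
    outDir = x$out_dir %||% tempfile("nmr_run_"))
}

## ---------------------------------------------------------------------------
## Cohort and matrix interchange
## ---------------------------------------------------------------------------

#' Write a cohort to a directory
#'
#' Layout: `spectra.tsv` (first column `ppm`, one column per sample),
#' `metadata.tsv` (`sample_id`, `group`, `time_point`) and, for simulated
#' cohorts, `truth.json` with the generating design.
#'
#' @param cohort a [LabeledCohort-class] (shared ppm axis).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mat <- vapply(cohort@spectra, function(s) s@intensity,
                numeric(length(cohort@spectra[[1L]]@ppm)))
  df <- data.frame(ppm = cohort@spectra[[1L]]@ppm, mat, check.names = FALSE)
  names(df) <- c("ppm", cohort@sampleIds)
  write.table(df, file.path(dir, "spectra.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(
    data.frame(sample_id = cohort@sampleIds, group = cohort@groupLabels,
               time_point = cohort@timePoints),
    file.path(dir, "metadata.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  if (is(cohort@design, "CohortDesign"))
    jsonlite::write_json(.designToList(cohort@design),
                         file.path(dir, "truth.json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(dir)
}

#' Read a cohort from a directory
#'
#' @param dir directory written by [writeCohort()] (or hand-assembled with
#'   the same layout).
#' @return A [LabeledCohort-class].
#' @export
readCohort <- function(dir) {
  df <- read.delim(file.path(dir, "spectra.tsv"), check.names = FALSE)
  meta <- read.delim(file.path(dir, "metadata.tsv"), check.names = FALSE,
                     colClasses = "character")
  ppm <- df$ppm
  ids <- setdiff(names(df), "ppm")
  .stopIfNot(setequal(ids, meta$sample_id),
             "metadata sample ids do not match the spectra columns")
  spectra <- lapply(meta$sample_id, function(id) nmrSpectrum(ppm, df[[id]]))
  truthPath <- file.path(dir, "truth.json")
  design <- if (file.exists(truthPath))
    .listToDesign(jsonlite::read_json(truthPath, simplifyVector = TRUE))
  else NULL
  new("LabeledCohort", spectra = spectra, sampleIds = meta$sample_id,
      groupLabels = meta$group,
      timePoints = meta$time_point %||% rep("", nrow(meta)),
      design = design)
}

#' Write a binned feature table
#'
#' `<prefix>.tsv` holds one row per bin (`ppm_upper`, `ppm_lower`,
#' `ppm_center`, then one column per sample); `<prefix>.provenance.json`
#' records the processing configuration, exclusions, alignment shifts and
#' the normalisation flag.
#'
#' @param x a [BinnedSpectra-class].
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
writeBinnedSpectra <- function(x, prefix) {
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  rd <- rowData(x)
  df <- data.frame(ppm_upper = rd$ppmUpper, ppm_lower = rd$ppmLower,
                   ppm_center = rd$ppmCenter,
                   as.data.frame(assay(x, "binned")), check.names = FALSE)
  write.table(df, paste0(prefix, ".tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  md <- metadata(x)
  cfg <- md$config
  prov <- list(
    config = list(lb_hz = cfg@lbHz, zero_fill_to = cfg@zeroFillTo,
                  bin_width = cfg@binWidth, bin_range = cfg@binRange,
                  water_region = cfg@waterRegion,
                  align_regions = cfg@alignRegions,
                  reference_ppm = cfg@referencePpm),
    excluded_regions = apply(md$excludedRegions, 1L, identity,
                             simplify = FALSE),
    aligned_regions = md$alignedRegions,
    alignment_shifts = md$alignmentShifts,
    normalized = isTRUE(md$normalized),
    samples = as.list(colData(x)$sample_id),
    groups = as.list(colData(x)$group))
  jsonlite::write_json(prov, paste0(prefix, ".provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Read a binned feature table
#'
#' Reconstructs a [BinnedSpectra-class] from the pair written by
#' [writeBinnedSpectra()].
#'
#' @param prefix path prefix used at write time.
#' @return A [BinnedSpectra-class].
#' @export
readBinnedSpectra <- function(prefix) {
  df <- read.delim(paste0(prefix, ".tsv"), check.names = FALSE)
  prov <- jsonlite::read_json(paste0(prefix, ".provenance.json"),
                              simplifyVector = TRUE)
  ids <- setdiff(names(df), c("ppm_upper", "ppm_lower", "ppm_center"))
  vals <- as.matrix(df[, ids, drop = FALSE])
  cfg <- processingConfig(
    lbHz = prov$config$lb_hz, zeroFillTo = prov$config$zero_fill_to,
    binWidth = prov$config$bin_width, binRange = prov$config$bin_range,
    waterRegion = prov$config$water_region,
    alignRegions = if (is.matrix(prov$config$align_regions))
      lapply(seq_len(nrow(prov$config$align_regions)),
             function(i) prov$config$align_regions[i, ])
    else prov$config$align_regions,
    referencePpm = prov$config$reference_ppm)
  se <- SummarizedExperiment(
    assays = list(binned = vals),
    rowData = DataFrame(ppmUpper = df$ppm_upper, ppmLower = df$ppm_lower,
                        ppmCenter = df$ppm_center),
    colData = DataFrame(sample_id = ids,
                        group = prov$groups %||% rep(NA_character_,
                                                     length(ids)),
                        time_point = rep("", length(ids)),
                        row.names = ids))
  ex <- prov$excluded_regions
  exm <- if (is.matrix(ex)) ex
  else if (length(ex)) matrix(unlist(lapply(ex, as.numeric)),
                              ncol = 2L, byrow = TRUE)
  else matrix(numeric(0), ncol = 2L)
  metadata(se) <- list(config = cfg, excludedRegions = exm,
                       alignedRegions = prov$aligned_regions %||% list(),
                       alignmentShifts = prov$alignment_shifts %||% list(),
                       normalized = isTRUE(prov$normalized), design = NULL)
  new("BinnedSpectra", se)
}

#' Serialise an O-PLS-DA model to JSON
#'
#' @param model an [OPLSDAModel-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeOplsModel <- function(model, path) {
  jsonlite::write_json(
    list(w = model@w, t_pred = model@tPred, p_pred = model@pPred,
         w_orth = model@wOrth, t_orth = model@tOrth, p_orth = model@pOrth,
         b = model@b, y_encoding = as.list(model@yEncoding),
         center = model@center, scale = model@scale,
         keep = model@keep, bin_ppm = model@binPpm),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an O-PLS-DA model from JSON
#'
#' @param path file written by [writeOplsModel()].
#' @return An [OPLSDAModel-class].
#' @export
readOplsModel <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  enc <- unlist(x$y_encoding)
  new("OPLSDAModel", w = x$w, tPred = x$t_pred, pPred = x$p_pred,
      wOrth = x$w_orth, tOrth = x$t_orth, pOrth = x$p_orth, b = x$b,
      yEncoding = enc, center = x$center, scale = x$scale,
      keep = as.integer(x$keep), binPpm = as.numeric(x$bin_ppm))
}

## ---------------------------------------------------------------------------
## End-to-end run
## ---------------------------------------------------------------------------

.logLine <- function(con, ...) {
  msg <- paste0(...)
  message(msg)
  if (!is.null(con)) writeLines(paste(format(Sys.time(), "%H:%M:%S"), msg),
                                con)
}

#' Run the full pipeline
#'
#' Simulates (or ingests) a cohort, processes it to the normalised binned
#' matrix, gates outliers once on the pooled cohort by Hotelling's
#' T-squared in PCA score space, then for every configured contrast fits
#' and validates PLS-DA/O-PLS-DA models, derives back-scaled correlation
#' loadings and the significant-bin table, and writes all artifacts to the
#' output directory. Deterministic for a fixed config seed.
#'
#' Artifacts: `cohort/` (simulated input), `binned.tsv` +
#' `binned.provenance.json`, `validation_grid.tsv`, per-contrast
#' `loading_profile_*.tsv`, `significant_bins_*.tsv` and `model_*.json`,
#' `provenance.json`, `run.log`.
#'
#' @param config a [PipelineConfig-class].
#' @return Invisibly, a list with `binned`, `outliers`, `reports`,
#'   `profiles`, `grid` and `outDir`.
#' @export
runPipeline <- function(config) {
  validObject(config)
  dir.create(config@outDir, recursive = TRUE, showWarnings = FALSE)
  logCon <- file(file.path(config@outDir, "run.log"), open = "wt")
  on.exit(close(logCon))
  .logLine(logCon, "pipeline start (seed ", config@seed, ")")

  if (!is.null(config@design)) {
    cohort <- simulateCohort(config@design)
    writeCohort(cohort, file.path(config@outDir, "cohort"))
    .logLine(logCon, "simulated ", length(cohort@spectra), " spectra")
  } else {
    cohort <- readCohort(config@inputDir)
    .logLine(logCon, "ingested ", length(cohort@spectra), " spectra from ",
             config@inputDir)
  }

  binned <- processCohort(cohort, config@processing)
  .logLine(logCon, "binned matrix: ", nrow(binned), " bins x ",
           ncol(binned), " samples")

  ## pooled outlier gate, once, before any contrast fitting
  scaled <- scaleMatrix(binned, "unit_variance")
  pca <- fitPCA(scaled, A = min(config@pcaA, ncol(binned) - 1L))
  out <- detectOutliers(pca, config@outlierAlpha)
  .logLine(logCon, sum(out), " outlier(s) excluded by Hotelling T2 (",
           ncol(binned) - sum(out), " samples retained)")
  kept <- binned[, !out]

  writeBinnedSpectra(kept, file.path(config@outDir, "binned"))

  groups <- groupsOf(kept)
  reports <- list()
  profiles <- list()
  for (i in seq_along(config@contrasts)) {
    ct <- config@contrasts[[i]]
    tag <- paste0(ct[1L], "_vs_", ct[2L])
    if (!all(ct %in% groups)) {
      .logLine(logCon, "contrast ", tag, " skipped: unknown label")
      next
    }
    sel <- groups %in% ct
    if (min(table(groups[sel])) < 3L) {
      .logLine(logCon, "contrast ", tag,
               " skipped: fewer than 3 samples on one side")
      next
    }
    sub <- kept[, sel]
    rep <- validateContrast(sub, groupsOf(sub), positive = ct[1L],
                            k = config@k, nPerm = config@nPerm,
                            alpha = config@alpha,
                            seed = config@seed + 1000L * i)
    scSub <- scaleMatrix(sub, "unit_variance")
    model <- fitOplsDa(scSub, groupsOf(sub), positive = ct[1L])
    prof <- backscaledLoadings(model, sub, alpha = config@alpha)
    reports[[tag]] <- rep
    profiles[[tag]] <- prof
    write.table(as.data.frame(prof),
                file.path(config@outDir,
                          paste0("loading_profile_", tag, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(significantBins(prof),
                file.path(config@outDir,
                          paste0("significant_bins_", tag, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeOplsModel(model, file.path(config@outDir,
                                    paste0("model_", tag, ".json")))
    .logLine(logCon, "contrast ", tag, ": Q2(OPLS) = ",
             round(rep@q2Opls, 3), ", AUC = ", round(rep@auc, 3),
             ", verdict = ", ifelse(rep@verdict, "valid", "invalid"))
  }

  grid <- if (length(reports)) reportValidationGrid(reports) else NULL
  if (!is.null(grid))
    write.table(grid, file.path(config@outDir, "validation_grid.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)

  jsonlite::write_json(
    list(package_version = as.character(utils::packageVersion("serumNMR")),
         seed = config@seed, k = config@k, n_perm = config@nPerm,
         alpha = config@alpha, pca_a = config@pcaA,
         outliers_excluded = sum(out),
         samples_retained = ncol(kept),
         contrasts = lapply(config@contrasts, as.list),
         design = if (!is.null(config@design))
           .designToList(config@design) else NULL),
    file.path(config@outDir, "provenance.json"), auto_unbox = TRUE,
    digits = NA)
  .logLine(logCon, "pipeline done")
  invisible(list(binned = kept, outliers = out, reports = reports,
                 profiles = profiles, grid = grid, outDir = config@outDir))
}
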