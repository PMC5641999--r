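#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

## ---------------------------------------------------------------------------
## Raw signal containers
## ---------------------------------------------------------------------------

#' Free-induction decay
#'
#' Complex time-domain NMR signal together with the acquisition metadata
#' needed to map its Fourier transform onto a chemical-shift axis.
#'
#' @slot points complex vector, the acquired (or simulated) FID.
#' @slot dwellTime sampling interval in seconds; the spectral width in Hz is
#'   `1/dwellTime`.
#' @slot frequencyMHz spectrometer proton frequency in MHz (ppm-Hz conversion).
#' @slot carrierPpm chemical shift (ppm) of the carrier (zero-offset)
#'   frequency.
#' @exportClass NMRFid
setClass("NMRFid",
  slots = c(
    points = "complex",
    dwellTime = "numeric",
    frequencyMHz = "numeric",
    carrierPpm = "numeric"
  )
)

setValidity("NMRFid", function(object) {
  msg <- NULL
  if (length(object@points) < 2L)
    msg <- c(msg, "an FID needs at least 2 points")
  if (length(object@dwellTime) != 1L || !is.finite(object@dwellTime) ||
      object@dwellTime <= 0)
    msg <- c(msg, "dwellTime must be a single positive number")
  if (length(object@frequencyMHz) != 1L || object@frequencyMHz <= 0)
    msg <- c(msg, "frequencyMHz must be a single positive number")
  if (length(object@carrierPpm) != 1L || !is.finite(object@carrierPpm))
    msg <- c(msg, "carrierPpm must be a single finite number")
  if (is.null(msg)) TRUE else msg
})

#' Construct an NMRFid
#'
#' @param points complex (or numeric, promoted to complex) FID points.
#' @param dwellTime sampling interval in seconds.
#' @param frequencyMHz spectrometer frequency in MHz.
#' @param carrierPpm ppm value at the carrier frequency.
#' @return An [NMRFid-class] object.
#' @export
nmrFid <- function(points, dwellTime, frequencyMHz = 599.35, carrierPpm = 4.85) {
  new("NMRFid", points = as.complex(points), dwellTime = as.numeric(dwellTime),
      frequencyMHz = as.numeric(frequencyMHz), carrierPpm = as.numeric(carrierPpm))
}

setMethod("show", "NMRFid", function(object) {
  cat("NMRFid:", length(object@points), "points,",
      "sw", format(1 / object@dwellTime, digits = 6), "Hz,",
      object@frequencyMHz, "MHz\n")
})

#' One-dimensional NMR spectrum
#'
#' Real intensities on a strictly descending ppm axis. When produced by
#' [fourierTransform()] the complex spectrum is retained internally so that
#' phase correction remains possible downstream; spectra simulated directly
#' in the frequency domain carry an empty complex slot.
#'
#' @slot ppm strictly monotone-descending chemical-shift axis (ppm).
#' @slot intensity real intensities, same length as `ppm`.
#' @slot complexIntensity complex intensities (length 0 if unavailable).
#' @slot processing list of provenance entries accumulated by the processing
#'   steps (applied phase, reference shift, baseline parameters, ...).
#' @exportClass NMRSpectrum
setClass("NMRSpectrum",
  slots = c(
    ppm = "numeric",
    intensity = "numeric",
    complexIntensity = "complex",
    processing = "list"
  )
)

setValidity("NMRSpectrum", function(object) {
  msg <- NULL
  if (length(object@ppm) != length(object@intensity))
    msg <- c(msg, "ppm and intensity must have equal length")
  if (length(object@ppm) >= 2L && any(diff(object@ppm) >= 0))
    msg <- c(msg, "ppm axis must be strictly monotone descending")
  if (length(object@complexIntensity) != 0L &&
      length(object@complexIntensity) != length(object@ppm))
    msg <- c(msg, "complexIntensity must be empty or match the axis length")
  if (is.null(msg)) TRUE else msg
})

#' Construct an NMRSpectrum
#'
#' @param ppm descending ppm axis.
#' @param intensity real intensities.
#' @param complexIntensity optional complex intensities.
#' @param processing optional provenance list.
#' @return An [NMRSpectrum-class] object.
#' @export
nmrSpectrum <- function(ppm, intensity, complexIntensity = complex(0),
                        processing = list()) {
  new("NMRSpectrum", ppm = as.numeric(ppm), intensity = as.numeric(intensity),
      complexIntensity = as.complex(complexIntensity), processing = processing)
}

setMethod("show", "NMRSpectrum", function(object) {
  cat("NMRSpectrum:", length(object@ppm), "points,",
      format(min(object@ppm), digits = 4), "to",
      format(max(object@ppm), digits = 4), "ppm\n")
})

## ---------------------------------------------------------------------------
## Simulation types
## ---------------------------------------------------------------------------

#' Metabolite resonance template
#'
#' A named set of Lorentzian components (center, relative intensity,
#' halfwidth). Broad lipoprotein envelopes are templates whose halfwidth is
#' large (>= 20 Hz); all other metabolites use sharp lines.
#'
#' @slot name metabolite name.
#' @slot components data.frame with columns `center` (ppm),
#'   `relIntensity` (>= 0) and `halfwidthHz` (> 0, full width at half
#'   maximum in Hz).
#' @exportClass MetaboliteTemplate
setClass("MetaboliteTemplate",
  slots = c(name = "character", components = "data.frame")
)

setValidity("MetaboliteTemplate", function(object) {
  msg <- NULL
  cmp <- object@components
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "name must be a single non-empty string")
  need <- c("center", "relIntensity", "halfwidthHz")
  if (!all(need %in% names(cmp)))
    msg <- c(msg, "components needs columns center, relIntensity, halfwidthHz")
  else {
    if (nrow(cmp) < 1L) msg <- c(msg, "at least one component is required")
    if (any(cmp$center < 0 | cmp$center > 10))
      msg <- c(msg, "component centers must lie in [0, 10] ppm")
    if (any(cmp$halfwidthHz <= 0)) msg <- c(msg, "halfwidths must be > 0")
    if (any(cmp$relIntensity < 0)) msg <- c(msg, "relative intensities must be >= 0")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a MetaboliteTemplate
#'
#' @param name metabolite name.
#' @param centers component centers in ppm.
#' @param intensities relative intensities (recycled to length of `centers`).
#' @param halfwidthsHz full widths at half maximum in Hz (recycled).
#' @return A [MetaboliteTemplate-class] object.
#' @export
metaboliteTemplate <- function(name, centers, intensities, halfwidthsHz = 1.5) {
  new("MetaboliteTemplate", name = name,
      components = data.frame(
        center = as.numeric(centers),
        relIntensity = rep_len(as.numeric(intensities), length(centers)),
        halfwidthHz = rep_len(as.numeric(halfwidthsHz), length(centers))
      ))
}

setMethod("show", "MetaboliteTemplate", function(object) {
  cat("MetaboliteTemplate", object@name, "-", nrow(object@components),
      "component(s) at", paste(format(object@components$center, digits = 4),
                               collapse = ", "), "ppm\n")
})

#' Synthetic cohort design
#'
#' Fully specifies a synthetic serum cohort: group sizes, group-dependent
#' fold-changes on named metabolites, and the nuisance model (chemical-shift
#' jitter, between-subject concentration variability, smooth baseline,
#' additive noise). A design plus a template library is a complete,
#' reproducible recipe: the same design always yields the same cohort.
#'
#' @slot groups named integer vector: group label -> number of samples.
#' @slot effects list: metabolite name -> named numeric vector of
#'   fold-changes per group (groups omitted default to fold 1).
#' @slot shiftJitterSd per-metabolite, per-sample chemical-shift jitter SD
#'   (ppm) for metabolites with a resonance inside a drift region.
#' @slot residualJitterSd jitter SD (ppm) for all other metabolites
#'   (sub-bin positional noise).
#' @slot driftRegions list of ppm intervals whose metabolites drift with the
#'   full jitter SD (pH- and ion-sensitive resonances).
#' @slot noiseSd additive Gaussian noise SD (intensity units, per point).
#' @slot baselineAmplitude amplitude of the smooth random baseline.
#' @slot lipoproteinScale multiplier applied to broad (halfwidth >= 20 Hz)
#'   envelope templates.
#' @slot intensityCv between-subject log-normal concentration variability
#'   (SD of log fold) applied per metabolite per sample.
#' @slot seed integer RNG seed.
#' @slot ppmAxis descending ppm axis on which spectra are simulated.
#' @slot frequencyMHz spectrometer frequency used to convert Hz halfwidths.
#' @exportClass CohortDesign
setClass("CohortDesign",
  slots = c(
    groups = "integer",
    effects = "list",
    shiftJitterSd = "numeric",
    residualJitterSd = "numeric",
    driftRegions = "list",
    noiseSd = "numeric",
    baselineAmplitude = "numeric",
    lipoproteinScale = "numeric",
    intensityCv = "numeric",
    seed = "integer",
    ppmAxis = "numeric",
    frequencyMHz = "numeric"
  )
)

setValidity("CohortDesign", function(object) {
  msg <- NULL
  if (length(object@groups) < 1L || is.null(names(object@groups)) ||
      any(!nzchar(names(object@groups))))
    msg <- c(msg, "groups must be a named integer vector")
  if (any(object@groups < 1L)) msg <- c(msg, "each group needs n >= 1")
  for (nm in names(object@effects)) {
    fx <- object@effects[[nm]]
    if (is.null(names(fx)) || !all(names(fx) %in% names(object@groups)))
      msg <- c(msg, sprintf("effects[['%s']] must name existing groups", nm))
    if (any(fx <= 0)) msg <- c(msg, "fold-changes must be > 0")
  }
  if (object@residualJitterSd < 0)
    msg <- c(msg, "residualJitterSd must be >= 0")
  if (object@shiftJitterSd < 0 || object@noiseSd < 0 ||
      object@baselineAmplitude < 0 || object@intensityCv < 0)
    msg <- c(msg, "standard deviations and amplitudes must be >= 0")
  if (object@lipoproteinScale < 0) msg <- c(msg, "lipoproteinScale must be >= 0")
  if (length(object@ppmAxis) < 2L || any(diff(object@ppmAxis) >= 0))
    msg <- c(msg, "ppmAxis must be strictly descending")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "CohortDesign", function(object) {
  cat("CohortDesign:",
      paste(sprintf("%s(n=%d)", names(object@groups), object@groups),
            collapse = ", "), "\n")
  if (length(object@effects))
    cat("  effects on:", paste(names(object@effects), collapse = ", "), "\n")
  cat(sprintf("  jitter sd %.4g ppm, noise sd %.4g, baseline %.4g, conc. CV %.4g, seed %d\n",
              object@shiftJitterSd, object@noiseSd, object@baselineAmplitude,
              object@intensityCv, object@seed))
})

#' Labelled cohort of spectra
#'
#' @slot spectra list of [NMRSpectrum-class] (or [NMRFid-class]) objects.
#' @slot sampleIds sample identifiers.
#' @slot groupLabels group label per sample.
#' @slot timePoints optional time-point label per sample ("" if unused).
#' @slot design the generating [CohortDesign-class] (or NULL for ingested
#'   data); simulated cohorts carry their ground truth here.
#' @exportClass LabeledCohort
setClass("LabeledCohort",
  slots = c(
    spectra = "list",
    sampleIds = "character",
    groupLabels = "character",
    timePoints = "character",
    design = "ANY"
  )
)

setValidity("LabeledCohort", function(object) {
  msg <- NULL
  n <- length(object@spectra)
  if (length(object@sampleIds) != n || length(object@groupLabels) != n ||
      length(object@timePoints) != n)
    msg <- c(msg, "spectra, sampleIds, groupLabels, timePoints must have equal length")
  if (anyDuplicated(object@sampleIds)) msg <- c(msg, "sampleIds must be unique")
  if (n >= 2L && is(object@spectra[[1L]], "NMRSpectrum")) {
    ax <- object@spectra[[1L]]@ppm
    same <- vapply(object@spectra, function(s)
      is(s, "NMRSpectrum") && length(s@ppm) == length(ax) &&
        isTRUE(all.equal(s@ppm, ax, tolerance = 1e-12)), logical(1))
    if (!all(same)) msg <- c(msg, "all spectra must share one ppm axis")
  }
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "LabeledCohort", function(object) {
  tab <- table(object@groupLabels)
  cat("LabeledCohort:", length(object@spectra), "spectra;",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## Binned feature table
## ---------------------------------------------------------------------------

#' Binned spectral feature table
#'
#' A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' whose rows are constant-width ppm bins (rowData: `ppmUpper`, `ppmLower`,
#' `ppmCenter`) and whose columns are samples (colData: `sample_id`, `group`,
#' `time_point`). Processing provenance lives in `metadata()`:
#' `config` (the [ProcessingConfig-class]), `excludedRegions`,
#' `alignedRegions`, `alignmentShifts` and the `normalized` flag.
#'
#' @exportClass BinnedSpectra
setClass("BinnedSpectra", contains = "SummarizedExperiment")

setValidity("BinnedSpectra", function(object) {
  msg <- NULL
  rd <- rowData(object)
  if (!all(c("ppmUpper", "ppmLower", "ppmCenter") %in% names(rd)))
    return("rowData needs ppmUpper, ppmLower, ppmCenter")
  w <- rd$ppmUpper - rd$ppmLower
  if (nrow(object) && diff(range(w)) > 1e-9)
    msg <- c(msg, "bin width must be constant")
  md <- metadata(object)
  ex <- md$excludedRegions
  if (!is.null(ex) && nrow(ex)) {
    eps <- 1e-9
    for (i in seq_len(nrow(ex))) {
      hit <- rd$ppmUpper > ex[i, 1L] + eps & rd$ppmLower < ex[i, 2L] - eps
      if (any(hit)) {
        msg <- c(msg, "a surviving bin intersects an excluded region")
        break
      }
    }
  }
  if (isTRUE(md$normalized) && ncol(object)) {
    s <- colSums(assay(object, "binned"))
    if (any(abs(s - 1) > 1e-9))
      msg <- c(msg, "normalized flag set but sample sums differ from 1")
  }
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "BinnedSpectra", function(object) {
  callNextMethod()
  md <- metadata(object)
  ex <- md$excludedRegions
  cat("bin width:", format(binWidthOf(object), digits = 4), "ppm;",
      if (!is.null(ex) && nrow(ex))
        paste0(nrow(ex), " excluded region(s); ") else "",
      "normalized: ", isTRUE(md$normalized), "\n", sep = "")
})

## ---------------------------------------------------------------------------
## Chemometric model types
## ---------------------------------------------------------------------------

#' Column-scaled data matrix
#'
#' @slot values n x p scaled matrix (zero-variance columns removed).
#' @slot center per-column means of the kept columns.
#' @slot scale per-column standard deviations used (1s for mean-centering).
#' @slot mode `"unit_variance"` or `"mean_center"`.
#' @slot binPpm ppm centers of the kept columns (NA-filled when the source
#'   matrix carries no bin annotation).
#' @slot keep indices of kept columns in the source matrix.
#' @exportClass ScaledMatrix
setClass("ScaledMatrix",
  slots = c(values = "matrix", center = "numeric", scale = "numeric",
            mode = "character", binPpm = "numeric", keep = "integer")
)

setValidity("ScaledMatrix", function(object) {
  p <- ncol(object@values)
  if (length(object@center) != p || length(object@scale) != p ||
      length(object@binPpm) != p || length(object@keep) != p)
    return("center/scale/binPpm/keep must match the column count")
  if (!object@mode %in% c("unit_variance", "mean_center"))
    return("mode must be 'unit_variance' or 'mean_center'")
  TRUE
})

setMethod("show", "ScaledMatrix", function(object) {
  cat("ScaledMatrix:", nrow(object@values), "x", ncol(object@values),
      sprintf("(%s)\n", object@mode))
})

#' Principal component model
#'
#' @slot scores n x A score matrix.
#' @slot loadings p x A orthonormal loading matrix.
#' @slot eigenvalues score variances, non-increasing.
#' @exportClass PCAModel
setClass("PCAModel",
  slots = c(scores = "matrix", loadings = "matrix", eigenvalues = "numeric")
)

setMethod("show", "PCAModel", function(object) {
  cat("PCAModel:", ncol(object@scores), "component(s);",
      "score variances", paste(format(object@eigenvalues, digits = 4),
                               collapse = ", "), "\n")
})

#' PLS-DA model (NIPALS PLS1)
#'
#' @slot weights p x A weight matrix (unit-norm columns).
#' @slot scores n x A score matrix.
#' @slot loadings p x A X-loading matrix.
#' @slot q per-component y-loadings.
#' @slot coefficients regression vector on the scaled X.
#' @slot yEncoding named numeric, class label -> +1/-1.
#' @slot center,scale,keep,binPpm scaling parameters of the training matrix.
#' @exportClass PLSDAModel
setClass("PLSDAModel",
  slots = c(weights = "matrix", scores = "matrix", loadings = "matrix",
            q = "numeric", coefficients = "numeric", yEncoding = "numeric",
            center = "numeric", scale = "numeric", keep = "integer",
            binPpm = "numeric")
)

setMethod("show", "PLSDAModel", function(object) {
  cat("PLSDAModel:", ncol(object@scores), "component(s),",
      length(object@coefficients), "variables;",
      "classes", paste(names(object@yEncoding), collapse = " vs "), "\n")
})

#' O-PLS-DA model (one predictive + one orthogonal component)
#'
#' Single-response orthogonal projection to latent structures: variation in
#' X uncorrelated with the class vector is filtered into one orthogonal
#' component before a single predictive component is fitted.
#'
#' @slot w unit-norm predictive weight vector.
#' @slot tPred predictive scores.
#' @slot pPred predictive loadings.
#' @slot wOrth unit-norm orthogonal weight vector (zero if no orthogonal
#'   variation was present).
#' @slot tOrth orthogonal scores (uncorrelated with y by construction).
#' @slot pOrth orthogonal loadings.
#' @slot b scalar regression coefficient of y on `tPred`.
#' @slot yEncoding named numeric, class label -> +1/-1.
#' @slot center,scale,keep,binPpm scaling parameters of the training matrix.
#' @exportClass OPLSDAModel
setClass("OPLSDAModel",
  slots = c(w = "numeric", tPred = "numeric", pPred = "numeric",
            wOrth = "numeric", tOrth = "numeric", pOrth = "numeric",
            b = "numeric", yEncoding = "numeric",
            center = "numeric", scale = "numeric", keep = "integer",
            binPpm = "numeric")
)

setValidity("OPLSDAModel", function(object) {
  msg <- NULL
  if (abs(sqrt(sum(object@w^2)) - 1) > 1e-8)
    msg <- c(msg, "predictive weights must have unit norm")
  if (sum(object@wOrth^2) > 0 &&
      abs(sum(object@w * object@wOrth)) > 1e-8)
    msg <- c(msg, "w and wOrth must be orthogonal")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "OPLSDAModel", function(object) {
  cat("OPLSDAModel: 1 predictive + 1 orthogonal component,",
      length(object@w), "variables;",
      "classes", paste(names(object@yEncoding), collapse = " vs "), "\n")
})

#' Back-scaled correlation loading profile
#'
#' Per-bin back-scaled loadings (loading times column SD, so the profile
#' resembles a spectrum) with the Pearson correlation of each bin against
#' the predictive score and the critical correlation used as the
#' significance cutoff.
#'
#' @slot ppm bin centers.
#' @slot backscaled back-scaled loading per bin.
#' @slot r Pearson correlation of each (unscaled) bin with the predictive
#'   score.
#' @slot rCrit critical correlation at the chosen alpha.
#' @slot significant logical mask, `abs(r) >= rCrit`.
#' @slot direction "up"/"down" per bin (positive class relative to the
#'   reference class).
#' @slot n number of samples behind the correlations.
#' @slot alpha significance level of the cutoff.
#' @exportClass LoadingProfile
setClass("LoadingProfile",
  slots = c(ppm = "numeric", backscaled = "numeric", r = "numeric",
            rCrit = "numeric", significant = "logical",
            direction = "character", n = "integer", alpha = "numeric")
)

setValidity("LoadingProfile", function(object) {
  msg <- NULL
  if (any(abs(object@r) > 1 + 1e-9)) msg <- c(msg, "|r| must be <= 1")
  if (any(object@significant & abs(object@r) < object@rCrit - 1e-12))
    msg <- c(msg, "significant bins must satisfy |r| >= rCrit")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "LoadingProfile", function(object) {
  cat("LoadingProfile:", length(object@ppm), "bins;",
      sum(object@significant), "significant at |r| >=",
      format(object@rCrit, digits = 3),
      sprintf("(n = %d, alpha = %g)\n", object@n, object@alpha))
})

#' Model validation report
#'
#' Cross-validated Q2 for the PLS-DA and O-PLS-DA models of one group
#' contrast, the permutation-test distribution, CV-ANOVA, the cross-validated
#' ROC AUC, and the combined verdict (valid only when the permutation test
#' and CV-ANOVA both pass).
#'
#' @slot contrast "positive vs reference" label.
#' @slot n number of samples.
#' @slot q2Pls sevenfold-CV Q2 of the PLS-DA model.
#' @slot q2Opls sevenfold-CV Q2 of the O-PLS-DA model.
#' @slot r2 training R2 of the O-PLS-DA model.
#' @slot permQ2 permutation-null Q2 values (PLS-DA).
#' @slot permPass TRUE when `q2Pls > max(permQ2)`.
#' @slot cvAnovaF,cvAnovaP CV-ANOVA statistic and p-value (O-PLS-DA
#'   residuals).
#' @slot cvAnovaPass TRUE when `cvAnovaP < alpha`.
#' @slot auc area under the ROC curve of the cross-validated scores.
#' @slot verdict `permPass && cvAnovaPass`.
#' @slot alpha significance level for CV-ANOVA.
#' @slot seed RNG seed that fixed folds and permutations.
#' @exportClass ValidationReport
setClass("ValidationReport",
  slots = c(contrast = "character", n = "integer",
            q2Pls = "numeric", q2Opls = "numeric", r2 = "numeric",
            permQ2 = "numeric", permPass = "logical",
            cvAnovaF = "numeric", cvAnovaP = "numeric",
            cvAnovaPass = "logical", auc = "numeric", verdict = "logical",
            alpha = "numeric", seed = "integer")
)

setValidity("ValidationReport", function(object) {
  msg <- NULL
  if (object@auc < 0 || object@auc > 1) msg <- c(msg, "auc must lie in [0, 1]")
  if (object@verdict != (object@permPass && object@cvAnovaPass))
    msg <- c(msg, "verdict must equal permPass && cvAnovaPass")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "ValidationReport", function(object) {
  cat(sprintf("ValidationReport [%s], n = %d\n", object@contrast, object@n))
  cat(sprintf("  Q2(PLS-DA) = %.3f   Q2(O-PLS-DA) = %.3f   R2 = %.3f\n",
              object@q2Pls, object@q2Opls, object@r2))
  cat(sprintf("  permutation (%d): %s   CV-ANOVA p = %.3g: %s   AUC = %.3f\n",
              length(object@permQ2),
              if (object@permPass) "pass" else "fail",
              object@cvAnovaP,
              if (object@cvAnovaPass) "pass" else "fail",
              object@auc))
  cat("  verdict:", if (object@verdict) "VALID" else "invalid", "\n")
})

#' STOCSY correlation trace
#'
#' @slot driverPpm ppm of the driver bin.
#' @slot ppm surviving bin centers.
#' @slot covariance covariance of each bin with the driver across samples.
#' @slot correlation Pearson correlation of each bin with the driver.
#' @exportClass StocsyTrace
setClass("StocsyTrace",
  slots = c(driverPpm = "numeric", ppm = "numeric",
            covariance = "numeric", correlation = "numeric")
)

setValidity("StocsyTrace", function(object) {
  if (any(abs(object@correlation) > 1 + 1e-9, na.rm = TRUE))
    return("|correlation| must be <= 1")
  TRUE
})

setMethod("show", "StocsyTrace", function(object) {
  cat("StocsyTrace: driver", format(object@driverPpm, digits = 5), "ppm,",
      length(object@ppm), "bins;",
      sum(abs(object@correlation) > 0.8, na.rm = TRUE),
      "bins with |r| > 0.8\n")
})
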