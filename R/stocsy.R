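## Statistical total correlation spectroscopy.

#' STOCSY trace from a driver bin
#'
#' Correlates the bin containing the driver chemical shift against every
#' surviving bin across samples. Peaks belonging to the same molecule show
#' near-unit correlation with the driver; statistically connected molecules
#' (shared pathways, common regulation) show intermediate correlation.
#'
#' @param x a [BinnedSpectra-class] with at least 4 samples.
#' @param driverPpm chemical shift of the driver; must fall inside a
#'   surviving bin.
#' @return A [StocsyTrace-class].
#' @export
stocsyTrace <- function(x, driverPpm) {
  .stopIfNot(ncol(x) >= 4, "STOCSY needs at least 4 samples")
  rd <- rowData(x)
  j <- which(rd$ppmLower < driverPpm & rd$ppmUpper >= driverPpm)
  if (!length(j))
    stop("driver at ", driverPpm,
         " ppm falls in no surviving bin (excluded region or out of range)")
  j <- j[1L]
  m <- .sampleMatrix(x)
  d <- m[, j]
  cv <- unname(drop(cov(d, m)))
  cr <- unname(drop(cor(d, m)))
  new("StocsyTrace", driverPpm = rd$ppmCenter[j], ppm = rd$ppmCenter,
      covariance = cv, correlation = cr)
}

#' @describeIn stocsyTrace data.frame view (ppm, covariance, correlation).
#' @param ... unused.
#' @export
setMethod("as.data.frame", "StocsyTrace", function(x, ...) {
  data.frame(ppm = x@ppm, covariance = x@covariance,
             correlation = x@correlation)
})

#' Correlation between two spectral regions
#'
#' Pearson correlation between the summed intensities of two ppm regions
#' across samples (for example the phenylalanine and tyrosine aromatic
#' multiplets), with a two-tailed p-value from the exact t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))`, or from a permutation null when
#' requested.
#'
#' @param x a [BinnedSpectra-class].
#' @param regionA,regionB `c(low, high)` ppm intervals mapping to surviving
#'   bins.
#' @param method `"parametric"` (t transform) or `"permutation"`.
#' @param nPerm permutations for the permutation method.
#' @param seed seed for the permutation method.
#' @return list with `r`, `p`, `n`.
#' @export
peakCorrelation <- function(x, regionA, regionB,
                            method = c("parametric", "permutation"),
                            nPerm = 999, seed = 1) {
  method <- match.arg(method)
  rd <- rowData(x)
  m <- .sampleMatrix(x)
  pick <- function(r) {
    idx <- which(rd$ppmCenter >= r[1L] & rd$ppmCenter <= r[2L])
    .stopIfNot(length(idx) >= 1, "region ", r[1L], "-", r[2L],
               " maps to no surviving bin")
    if (length(idx) == 1L) m[, idx] else rowSums(m[, idx, drop = FALSE])
  }
  a <- pick(regionA)
  b <- pick(regionB)
  .stopIfNot(sd(a) > 0 && sd(b) > 0, "a region has zero variance across samples")
  n <- length(a)
  r <- cor(a, b)
  if (method == "parametric") {
    if (abs(r) >= 1) {
      p <- 0
    } else {
      tv <- r * sqrt((n - 2) / (1 - r^2))
      p <- 2 * pt(abs(tv), df = n - 2, lower.tail = FALSE)
    }
  } else {
    p <- .withSeed(seed, {
      rp <- vapply(seq_len(nPerm), function(i)
        cor(a, b[sample.int(n)]), numeric(1))
      (1 + sum(abs(rp) >= abs(r))) / (nPerm + 1)
    })
  }
  list(r = r, p = p, n = n)
}
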