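# Internal helpers shared across modules.

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Fast column standard deviations (denominator n - 1).
.colSds <- function(x) {
  n <- nrow(x)
  if (n < 2L) return(rep(NA_real_, ncol(x)))
  m <- colMeans(x)
  v <- (colSums(x * x) - n * m * m) / (n - 1)
  sqrt(pmax(v, 0))
}

# Samples x bins matrix from a BinnedSpectra (assay is bins x samples).
.sampleMatrix <- function(x) {
  stopifnot(is(x, "BinnedSpectra"))
  m <- t(assay(x, "binned"))
  colnames(m) <- format(rowData(x)$ppmCenter, trim = TRUE)
  rownames(m) <- colnames(x)
  m
}

# Encode two-class labels as +1 (positive class) / -1 (reference class).
# If `positive` is NULL the second sorted unique label is taken as positive,
# except that a label named like a control ("control", "ctrl", "healthy")
# is always the reference.
.encodeY <- function(labels, positive = NULL) {
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (length(lev) != 2L)
    stop("exactly two classes are required, got: ", paste(lev, collapse = ", "))
  if (is.null(positive)) {
    ctrl <- lev[tolower(lev) %in% c("control", "ctrl", "controls", "healthy")]
    positive <- if (length(ctrl) == 1L) setdiff(lev, ctrl) else lev[2L]
  }
  if (!positive %in% lev) stop("positive class '", positive, "' not present")
  enc <- c(-1, 1)
  names(enc) <- c(setdiff(lev, positive), positive)
  list(y = unname(enc[labels]), encoding = enc)
}

# Cumulative trapezoidal integral of y over ascending x, evaluated at
# arbitrary points `at` (exact for the piecewise-linear interpolant).
.cumTrapzAt <- function(x, y, at) {
  n <- length(x)
  cum <- c(0, cumsum(0.5 * (y[-1] + y[-n]) * diff(x)))
  j <- findInterval(at, x, rightmost.closed = TRUE)
  j <- pmin(pmax(j, 1L), n - 1L)
  frac <- at - x[j]
  slope <- (y[j + 1L] - y[j]) / (x[j + 1L] - x[j])
  cum[j] + frac * (y[j] + 0.5 * slope * frac)
}

.isBroadTemplate <- function(template) {
  any(template@components$halfwidthHz >= 20)
}

.stopIfNot <- function(ok, ...) if (!ok) stop(..., call. = FALSE)
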