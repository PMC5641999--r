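## PCA / Hotelling gating, PLS-DA, O-PLS-DA, back-scaled correlation loadings.

#' Center and scale a feature matrix
#'
#' Mean-centers (and for `"unit_variance"` scales to unit SD) each column,
#' dropping zero-variance columns with a warning. The scaling parameters are
#' stored so they can be re-applied to out-of-sample data.
#'
#' @param x a [BinnedSpectra-class] or a samples-x-variables matrix.
#' @param mode `"unit_variance"` (default) or `"mean_center"`.
#' @return A [ScaledMatrix-class].
#' @export
scaleMatrix <- function(x, mode = c("unit_variance", "mean_center")) {
  mode <- match.arg(mode)
  ppm <- rep(NA_real_, 0)
  if (is(x, "BinnedSpectra")) {
    ppm <- binCenters(x)
    x <- .sampleMatrix(x)
  }
  .stopIfNot(nrow(x) >= 3, "at least 3 samples are required")
  if (!length(ppm)) ppm <- rep(NA_real_, ncol(x))
  ctr <- colMeans(x)
  sds <- .colSds(x)
  keep <- seq_len(ncol(x))
  if (mode == "unit_variance") {
    zero <- sds == 0
    if (any(zero)) {
      warning(sum(zero), " zero-variance column(s) dropped before scaling")
      keep <- keep[!zero]
    }
    vals <- sweep(sweep(x[, keep, drop = FALSE], 2L, ctr[keep]),
                  2L, sds[keep], "/")
    sc <- sds[keep]
  } else {
    vals <- sweep(x, 2L, ctr)
    sc <- rep(1, length(keep))
  }
  new("ScaledMatrix", values = vals, center = ctr[keep], scale = sc,
      mode = mode, binPpm = ppm[keep], keep = as.integer(keep))
}

# Apply stored scaling parameters to new unscaled data (full columns).
.applyScaling <- function(scaled, x) {
  x <- x[, scaled@keep, drop = FALSE]
  sweep(sweep(x, 2L, scaled@center), 2L, scaled@scale, "/")
}

# Fast internal unit-variance scaler used inside cross-validation loops.
.uvScale <- function(x) {
  ctr <- colMeans(x)
  sds <- .colSds(x)
  keep <- which(sds > 0)
  list(values = sweep(sweep(x[, keep, drop = FALSE], 2L, ctr[keep]),
                      2L, sds[keep], "/"),
       center = ctr, scale = sds, keep = keep)
}

#' Principal component analysis
#'
#' Top-A principal components by singular value decomposition of the scaled
#' matrix. Eigenvalues are the score variances (singular values squared over
#' n - 1). Loading signs follow the convention that each loading's largest
#' absolute element is positive.
#'
#' @param scaled a [ScaledMatrix-class].
#' @param A number of components, at most `min(n - 1, p)`.
#' @return A [PCAModel-class].
#' @export
fitPCA <- function(scaled, A = 2) {
  X <- scaled@values
  n <- nrow(X)
  .stopIfNot(A >= 1 && A <= min(n - 1L, ncol(X)),
             "A must lie in [1, min(n - 1, p)]")
  sv <- svd(X, nu = A, nv = A)
  flip <- vapply(seq_len(A), function(a) {
    v <- sv$v[, a]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  loadings <- sweep(sv$v[, seq_len(A), drop = FALSE], 2L, flip, "*")
  scores <- sweep(sv$u[, seq_len(A), drop = FALSE], 2L,
                  flip * sv$d[seq_len(A)], "*")
  rownames(scores) <- rownames(X)
  new("PCAModel", scores = scores, loadings = loadings,
      eigenvalues = sv$d[seq_len(A)]^2 / (n - 1))
}

#' Hotelling's T-squared control limit
#'
#' The F-based `100 * (1 - alpha)` percent confidence limit for the
#' T-squared of A PCA score dimensions estimated from n samples:
#' `A (n - 1) (n + 1) / (n (n - A)) * qf(1 - alpha, A, n - A)`.
#'
#' @param n number of samples.
#' @param A number of score dimensions.
#' @param alpha significance level (0.05 for the conventional 95% ellipse).
#' @return The T-squared threshold.
#' @export
hotellingT2Limit <- function(n, A = 2, alpha = 0.05) {
  .stopIfNot(n > A && A >= 1, "need n > A >= 1")
  A * (n - 1) * (n + 1) / (n * (n - A)) * qf(1 - alpha, A, n - A)
}

#' Hotelling's T-squared of each sample
#'
#' @param pca a [PCAModel-class].
#' @return Per-sample T-squared values, `sum_a t_a^2 / lambda_a`.
#' @export
hotellingT2 <- function(pca) {
  rowSums(sweep(pca@scores^2, 2L, pca@eigenvalues, "/"))
}

#' Flag multivariate outliers in PCA score space
#'
#' A sample is flagged when its T-squared over the model's score dimensions
#' exceeds the Hotelling limit at the given level.
#'
#' @param pca a [PCAModel-class].
#' @param alpha significance level.
#' @return Logical exclusion mask (TRUE = outlier).
#' @export
detectOutliers <- function(pca, alpha = 0.05) {
  n <- nrow(pca@scores)
  hotellingT2(pca) > hotellingT2Limit(n, ncol(pca@scores), alpha)
}

#' Fit a PLS-DA model (NIPALS PLS1)
#'
#' Sequential NIPALS extraction for a single two-class response: for each
#' component the weight is `X'y` normalised, scores `t = Xw`, loadings
#' `p = X't / t't`, with X and y deflated after every component. The first
#' weight vector is therefore proportional to the covariance of each
#' variable with the class vector.
#'
#' @param scaled a [ScaledMatrix-class].
#' @param y class labels (two classes) or a numeric +1/-1 vector.
#' @param ncomp number of components.
#' @param positive label of the positive class (defaults to the non-control
#'   of the two labels).
#' @return A [PLSDAModel-class].
#' @export
fitPlsDa <- function(scaled, y, ncomp = 2, positive = NULL) {
  if (is.numeric(y)) {
    enc <- c("-1" = -1, "1" = 1)
    yv <- y
  } else {
    e <- .encodeY(y, positive)
    enc <- e$encoding
    yv <- e$y
  }
  X <- scaled@values
  yc <- yv - mean(yv)
  p <- ncol(X)
  W <- P <- matrix(0, p, ncomp)
  Tm <- matrix(0, nrow(X), ncomp)
  q <- numeric(ncomp)
  Xd <- X
  yd <- yc
  actual <- 0L
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t <- drop(Xd %*% w)
    tt <- sum(t^2)
    if (tt < 1e-12) break
    pl <- drop(crossprod(Xd, t)) / tt
    qa <- sum(yd * t) / tt
    Xd <- Xd - tcrossprod(t, pl)
    yd <- yd - t * qa
    W[, a] <- w
    P[, a] <- pl
    Tm[, a] <- t
    q[a] <- qa
    actual <- a
  }
  .stopIfNot(actual >= 1L, "y is orthogonal to every column of X")
  W <- W[, seq_len(actual), drop = FALSE]
  P <- P[, seq_len(actual), drop = FALSE]
  Tm <- Tm[, seq_len(actual), drop = FALSE]
  q <- q[seq_len(actual)]
  B <- drop(W %*% solve(crossprod(P, W), q))
  new("PLSDAModel", weights = W, scores = Tm, loadings = P, q = q,
      coefficients = B, yEncoding = enc, center = scaled@center,
      scale = scaled@scale, keep = scaled@keep, binPpm = scaled@binPpm)
}

#' Fit an O-PLS-DA model (one predictive + one orthogonal component)
#'
#' Single-y orthogonal signal correction: the initial predictive weight is
#' `X'y` normalised; the orthogonal weight is the part of the predictive
#' loading orthogonal to it; the orthogonal component `t_orth p_orth'` is
#' removed from X; and the predictive component is refitted on the filtered
#' matrix. By construction the orthogonal scores are exactly uncorrelated
#' with the class vector.
#'
#' @param scaled a [ScaledMatrix-class] (unit-variance scaling is the
#'   convention for spectral data).
#' @param y class labels (two classes) or a numeric +1/-1 vector.
#' @param positive label of the positive class.
#' @return An [OPLSDAModel-class].
#' @export
fitOplsDa <- function(scaled, y, positive = NULL) {
  if (is.numeric(y)) {
    enc <- c("-1" = -1, "1" = 1)
    yv <- y
  } else {
    e <- .encodeY(y, positive)
    enc <- e$encoding
    yv <- e$y
  }
  X <- scaled@values
  .stopIfNot(ncol(X) >= 2, "at least two variables are required")
  yc <- yv - mean(yv)
  w <- drop(crossprod(X, yc))
  nw <- sqrt(sum(w^2))
  .stopIfNot(nw > 1e-12, "y is orthogonal to every column of X")
  w <- w / nw
  t1 <- drop(X %*% w)
  p1 <- drop(crossprod(X, t1)) / sum(t1^2)
  wo <- p1 - sum(w * p1) * w
  nwo <- sqrt(sum(wo^2))
  if (nwo > 1e-10) {
    wo <- wo / nwo
    to <- drop(X %*% wo)
    po <- drop(crossprod(X, to)) / sum(to^2)
    Xf <- X - tcrossprod(to, po)
  } else {
    ## no y-orthogonal structure: keep zero orthogonal component
    wo <- numeric(ncol(X))
    to <- numeric(nrow(X))
    po <- numeric(ncol(X))
    Xf <- X
  }
  w2 <- drop(crossprod(Xf, yc))
  w2 <- w2 / sqrt(sum(w2^2))
  tp <- drop(Xf %*% w2)
  pp <- drop(crossprod(Xf, tp)) / sum(tp^2)
  b <- sum(yc * tp) / sum(tp^2)
  new("OPLSDAModel", w = w2, tPred = tp, pPred = pp, wOrth = wo, tOrth = to,
      pOrth = po, b = b, yEncoding = enc, center = scaled@center,
      scale = scaled@scale, keep = scaled@keep, binPpm = scaled@binPpm)
}

# Orthogonal-signal removal for (already scaled) rows; exactly idempotent
# because wOrth' pOrth = 1 by construction.
.removeOrthogonal <- function(model, Xs) {
  if (!sum(model@wOrth^2)) return(Xs)
  Xs - tcrossprod(drop(Xs %*% model@wOrth), model@pOrth)
}

#' Predict class scores for new samples
#'
#' Applies the training scaling, removes the orthogonal component, projects
#' onto the predictive weight and returns the predicted response
#' `yhat = b * t_pred` together with hard class assignments by sign.
#'
#' @param object an [OPLSDAModel-class].
#' @param newdata a [BinnedSpectra-class] or an unscaled samples-x-variables
#'   matrix with the training matrix's (pre-drop) columns.
#' @param ... unused.
#' @return A list with `tPred`, `yhat` and `class` (labels from the training
#'   encoding).
#' @export
setMethod("predict", "OPLSDAModel", function(object, newdata, ...) {
  if (is(newdata, "BinnedSpectra")) newdata <- .sampleMatrix(newdata)
  if (max(object@keep) > ncol(newdata))
    stop("newdata has fewer columns than the training matrix")
  Xs <- sweep(sweep(newdata[, object@keep, drop = FALSE], 2L, object@center),
              2L, object@scale, "/")
  Xf <- .removeOrthogonal(object, Xs)
  tp <- drop(Xf %*% object@w)
  yhat <- object@b * tp
  lab <- names(object@yEncoding)[match(sign(yhat) >= 0,
                                       object@yEncoding > 0)]
  list(tPred = tp, yhat = yhat, class = lab)
})

#' Critical Pearson correlation at a given sample size
#'
#' The two-tailed critical value of the Pearson correlation coefficient at
#' level `alpha`: \eqn{r_{crit} = t / \sqrt{t^2 + n - 2}} with `t` the
#' `1 - alpha / 2` Student-t quantile at `n - 2` degrees of freedom. Used as
#' the significance cutoff for correlation-coded loadings; at alpha = 0.05
#' it spans 0.32 (n = 38) to 0.48 (n = 17) over typical contrast sizes.
#'
#' @param n number of samples (>= 4).
#' @param alpha two-tailed significance level.
#' @return The critical correlation.
#' @export
correlationCutoff <- function(n, alpha = 0.05) {
  .stopIfNot(n >= 4, "n must be >= 4")
  tq <- qt(1 - alpha / 2, df = n - 2)
  tq / sqrt(tq^2 + n - 2)
}

#' Back-scaled correlation loadings
#'
#' Multiplies the predictive loading of each bin by the bin's training SD
#' (so the profile has the shape of a spectrum) and computes the Pearson
#' correlation of each unscaled bin with the predictive score, flagging bins
#' whose `|r|` reaches the critical correlation for the model's sample size.
#'
#' @param model an [OPLSDAModel-class].
#' @param x the unscaled data behind the model: a [BinnedSpectra-class] or
#'   samples-x-variables matrix.
#' @param alpha significance level of the cutoff.
#' @return A [LoadingProfile-class].
#' @export
backscaledLoadings <- function(model, x, alpha = 0.05) {
  if (is(x, "BinnedSpectra")) x <- .sampleMatrix(x)
  X <- x[, model@keep, drop = FALSE]
  n <- nrow(X)
  r <- drop(cor(model@tPred, X))
  r[is.na(r)] <- 0
  rc <- correlationCutoff(n, alpha)
  bs <- model@pPred * model@scale
  new("LoadingProfile", ppm = model@binPpm, backscaled = bs, r = r,
      rCrit = rc, significant = abs(r) >= rc,
      direction = ifelse(bs >= 0, "up", "down"), n = as.integer(n),
      alpha = alpha)
}

#' As-data.frame view of a loading profile
#'
#' @param x a [LoadingProfile-class].
#' @param ... unused.
#' @return data.frame with ppm, backscaled, r, significant, direction.
#' @export
setMethod("as.data.frame", "LoadingProfile", function(x, ...) {
  data.frame(ppm = x@ppm, backscaled = x@backscaled, r = x@r,
             significant = x@significant, direction = x@direction)
})

#' Table of significantly changed bins
#'
#' Filters a loading profile to the bins passing the correlation cutoff and
#' reports their direction (up = higher in the positive class than in the
#' reference class). An optional assignment map labels bins with metabolite
#' names by ppm window.
#'
#' @param profile a [LoadingProfile-class].
#' @param assignments optional named list of `c(low, high)` ppm windows.
#' @return data.frame with columns `ppm`, `metabolite` (if assignments are
#'   given), `direction`, `r`, `backscaled`.
#' @export
significantBins <- function(profile, assignments = NULL) {
  sel <- which(profile@significant)
  out <- data.frame(ppm = profile@ppm[sel],
                    direction = profile@direction[sel],
                    r = profile@r[sel],
                    backscaled = profile@backscaled[sel])
  if (!is.null(assignments)) {
    lab <- rep(NA_character_, nrow(out))
    for (nm in names(assignments)) {
      w <- assignments[[nm]]
      hit <- is.na(lab) & out$ppm >= w[1L] & out$ppm <= w[2L]
      lab[hit] <- nm
    }
    out <- cbind(out[1L], metabolite = lab, out[-1L])
  }
  out[order(-abs(out$r)), , drop = FALSE]
}
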