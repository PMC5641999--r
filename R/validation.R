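## Model validity machinery: sevenfold-CV Q2, permutation test, CV-ANOVA,
## ROC/AUC and the combined verdict.

# Stratified fold assignment using the current RNG stream. Every training
# fold is checked to contain both classes.
.stratFolds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    i <- which(y == cl)
    fold[i[sample.int(length(i))]] <- rep_len(seq_len(k), length(i))
  }
  for (j in unique(fold)) {
    if (length(unique(y[fold != j])) < 2L)
      stop("a training fold would contain a single class; reduce k or add samples")
  }
  fold
}

# One cross-validation pass. X is the raw (unscaled) matrix; unit-variance
# scaling is refit inside every training fold and applied to the held-out
# samples, so no information leaks from the test fold.
.cvPredict <- function(X, yv, k, method, ncomp) {
  fold <- .stratFolds(yv, k)
  yhat <- numeric(length(yv))
  for (j in sort(unique(fold))) {
    tr <- fold != j
    sc <- .uvScale(X[tr, , drop = FALSE])
    ytr <- yv[tr]
    off <- mean(ytr)
    Xte <- sweep(sweep(X[!tr, sc$keep, drop = FALSE], 2L,
                       sc$center[sc$keep]), 2L, sc$scale[sc$keep], "/")
    if (method == "oplsda") {
      sm <- new("ScaledMatrix", values = sc$values,
                center = sc$center[sc$keep], scale = sc$scale[sc$keep],
                mode = "unit_variance",
                binPpm = rep(NA_real_, length(sc$keep)),
                keep = as.integer(sc$keep))
      m <- fitOplsDa(sm, ytr)
      Xf <- .removeOrthogonal(m, Xte)
      yhat[!tr] <- off + m@b * drop(Xf %*% m@w)
    } else {
      sm <- new("ScaledMatrix", values = sc$values,
                center = sc$center[sc$keep], scale = sc$scale[sc$keep],
                mode = "unit_variance",
                binPpm = rep(NA_real_, length(sc$keep)),
                keep = as.integer(sc$keep))
      m <- fitPlsDa(sm, ytr, ncomp = ncomp)
      yhat[!tr] <- off + drop(Xte %*% m@coefficients)
    }
  }
  list(yhat = yhat, fold = fold)
}

#' Cross-validated Q2
#'
#' Sevenfold (by default) stratified cross-validation of a PLS-DA or
#' O-PLS-DA model: one-seventh of the samples is repeatedly left out,
#' predicted back into a model fitted (including its unit-variance scaling)
#' on the remainder, and `Q2 = 1 - PRESS / SS_y` is computed from the
#' pooled out-of-fold predictions with the overall mean of y as reference.
#'
#' @param x a [BinnedSpectra-class] or unscaled samples-x-variables matrix.
#' @param y two-class labels or numeric +1/-1.
#' @param k number of folds.
#' @param seed RNG seed fixing the fold assignment.
#' @param method `"oplsda"` (one predictive + one orthogonal component) or
#'   `"plsda"`.
#' @param ncomp PLS-DA component count (ignored for O-PLS-DA).
#' @param positive label of the positive class.
#' @return list with `q2`, `r2` (training fit of the same model class),
#'   `press`, `ssy`, per-sample cross-validated `residuals` and `predicted`
#'   scores, and the `fold` assignment.
#' @export
crossValidatedQ2 <- function(x, y, k = 7, seed = 1,
                             method = c("oplsda", "plsda"), ncomp = 2,
                             positive = NULL) {
  method <- match.arg(method)
  if (is(x, "BinnedSpectra")) x <- .sampleMatrix(x)
  if (is.numeric(y)) yv <- y
  else yv <- .encodeY(y, positive)$y
  cv <- .withSeed(seed, .cvPredict(x, yv, k, method, ncomp))
  press <- sum((yv - cv$yhat)^2)
  ssy <- sum((yv - mean(yv))^2)
  ## training R2 of the same model class, fitted once on the full data
  sc <- .uvScale(x)
  sm <- new("ScaledMatrix", values = sc$values, center = sc$center[sc$keep],
            scale = sc$scale[sc$keep], mode = "unit_variance",
            binPpm = rep(NA_real_, length(sc$keep)),
            keep = as.integer(sc$keep))
  fitted <- if (method == "oplsda") {
    m <- fitOplsDa(sm, yv)
    mean(yv) + m@b * m@tPred
  } else {
    m <- fitPlsDa(sm, yv, ncomp = ncomp)
    mean(yv) + drop(sm@values %*% m@coefficients)
  }
  r2 <- 1 - sum((yv - fitted)^2) / ssy
  list(q2 = 1 - press / ssy, r2 = r2, press = press, ssy = ssy,
       residuals = yv - cv$yhat, predicted = cv$yhat, fold = cv$fold,
       model = m)
}

#' Permutation test of a cross-validated model
#'
#' Recomputes the full cross-validated Q2 under `nPerm` random relabelings
#' (permutations drawn uniformly over orderings; an identity draw counts).
#' The model passes when the Q2 of the true labels exceeds the maximum
#' permuted Q2 - the criterion used to declare a model predictive rather
#' than overfitted.
#'
#' @inheritParams crossValidatedQ2
#' @param nPerm number of permutations (200 by convention).
#' @return list with `q2` (true labels), `permQ2` (length `nPerm`), `pass`.
#' @export
permutationTest <- function(x, y, nPerm = 200, k = 7, seed = 1,
                            method = c("plsda", "oplsda"), ncomp = 2,
                            positive = NULL) {
  method <- match.arg(method)
  if (is(x, "BinnedSpectra")) x <- .sampleMatrix(x)
  if (is.numeric(y)) yv <- y
  else yv <- .encodeY(y, positive)$y
  .stopIfNot(nPerm >= 1, "nPerm must be >= 1")
  .withSeed(seed, {
    real <- .cvPredict(x, yv, k, method, ncomp)
    ssy <- sum((yv - mean(yv))^2)
    q2 <- 1 - sum((yv - real$yhat)^2) / ssy
    permQ2 <- vapply(seq_len(nPerm), function(b) {
      yp <- yv[sample.int(length(yv))]
      cv <- .cvPredict(x, yp, k, method, ncomp)
      1 - sum((yp - cv$yhat)^2) / sum((yp - mean(yp))^2)
    }, numeric(1))
    list(q2 = q2, permQ2 = permQ2, pass = q2 > max(permQ2))
  })
}

#' CV-ANOVA significance test
#'
#' F-test comparing the cross-validated prediction error against the total
#' response variation: `F = ((SS_y - PRESS) / df1) / (PRESS / df2)` with
#' `df1` the number of fitted model components and `df2 = n - df1 - 1`.
#' When the cross-validated model predicts worse than the mean
#' (`PRESS >= SS_y`) the statistic is non-positive and `p = 1`.
#'
#' @param cvResiduals per-sample cross-validated residuals from
#'   [crossValidatedQ2()].
#' @param y the response the residuals refer to (labels or +1/-1).
#' @param modelDf fitted component count (2 for one predictive plus one
#'   orthogonal component).
#' @return list with `F` and `p`.
#' @export
cvAnova <- function(cvResiduals, y, modelDf = 2) {
  if (!is.numeric(y)) y <- .encodeY(y)$y
  n <- length(y)
  .stopIfNot(length(cvResiduals) == n, "residuals and y differ in length")
  press <- sum(cvResiduals^2)
  ssy <- sum((y - mean(y))^2)
  df1 <- modelDf
  df2 <- n - modelDf - 1
  Fv <- ((ssy - press) / df1) / (press / df2)
  p <- if (Fv <= 0) 1 else pf(Fv, df1, df2, lower.tail = FALSE)
  list(F = Fv, p = p)
}

#' Area under the ROC curve
#'
#' Mann-Whitney identity on predicted scores: the probability that a random
#' positive sample scores above a random negative one, ties counted half
#' (average ranks).
#'
#' @param yTrue two-class labels or +1/-1.
#' @param scores predicted scores (higher = more positive class).
#' @return AUC in `[0, 1]`.
#' @export
rocAuc <- function(yTrue, scores) {
  if (!is.numeric(yTrue)) yTrue <- .encodeY(yTrue)$y
  pos <- yTrue > 0
  n1 <- sum(pos)
  n0 <- sum(!pos)
  .stopIfNot(n1 > 0 && n0 > 0, "both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Validate one group contrast
#'
#' Runs the full validity battery for a two-group comparison: sevenfold-CV
#' Q2 of the PLS-DA model with its permutation test, sevenfold-CV Q2 of the
#' O-PLS-DA model with CV-ANOVA on its cross-validated residuals, and the
#' ROC AUC of the cross-validated O-PLS-DA scores. The model is declared
#' valid only when the permutation test and CV-ANOVA pass simultaneously.
#'
#' @param x a [BinnedSpectra-class] or unscaled matrix.
#' @param y two-class labels.
#' @param positive label of the positive class (the contrast is reported as
#'   "positive vs reference").
#' @param k folds.
#' @param nPerm permutations.
#' @param alpha CV-ANOVA significance level.
#' @param seed RNG seed fixing folds and permutations.
#' @param plsNcomp PLS-DA component count.
#' @return A [ValidationReport-class].
#' @export
validateContrast <- function(x, y, positive = NULL, k = 7, nPerm = 200,
                             alpha = 0.05, seed = 1, plsNcomp = 2) {
  if (is(x, "BinnedSpectra")) x <- .sampleMatrix(x)
  e <- .encodeY(y, positive)
  yv <- e$y
  contrast <- paste(names(e$encoding)[e$encoding > 0], "vs",
                    names(e$encoding)[e$encoding < 0])
  perm <- permutationTest(x, yv, nPerm = nPerm, k = k, seed = seed,
                          method = "plsda", ncomp = plsNcomp)
  cvO <- crossValidatedQ2(x, yv, k = k, seed = seed + 1L, method = "oplsda")
  an <- cvAnova(cvO$residuals, yv, modelDf = 2)
  auc <- rocAuc(yv, cvO$predicted)
  new("ValidationReport",
      contrast = contrast, n = length(yv),
      q2Pls = perm$q2, q2Opls = cvO$q2, r2 = cvO$r2,
      permQ2 = perm$permQ2, permPass = perm$pass,
      cvAnovaF = an$F, cvAnovaP = an$p, cvAnovaPass = an$p < alpha,
      auc = auc, verdict = perm$pass && an$p < alpha,
      alpha = alpha, seed = as.integer(seed))
}

#' Combined model verdict
#'
#' @param report a [ValidationReport-class].
#' @return TRUE only when the permutation test and CV-ANOVA both passed.
#' @export
modelVerdict <- function(report) {
  report@permPass && report@cvAnovaPass
}

#' Validation grid across contrasts
#'
#' One row per contrast with the columns of a classical model-validation
#' table: Q2 of the PLS-DA and O-PLS-DA models, the permutation and
#' CV-ANOVA outcomes, the ROC AUC and the combined verdict.
#'
#' @param reports list of [ValidationReport-class] objects.
#' @return data.frame, one row per report.
#' @export
reportValidationGrid <- function(reports) {
  .stopIfNot(length(reports) >= 1, "at least one report is required")
  do.call(rbind, lapply(reports, function(r) {
    data.frame(contrast = r@contrast, n = r@n,
               q2_plsda = r@q2Pls, q2_oplsda = r@q2Opls,
               permutation_pass = r@permPass,
               cv_anova_p = r@cvAnovaP, cv_anova_pass = r@cvAnovaPass,
               auc = r@auc,
               verdict = ifelse(r@verdict, "valid", "invalid"))
  }))
}
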