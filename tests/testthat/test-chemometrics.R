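test_that("scaling centers, scales and reapplies exactly", {
  set.seed(21)
  X <- matrix(rnorm(40 * 12, mean = 3, sd = 2), 40, 12)
  sc <- scaleMatrix(X, "unit_variance")
  expect_equal(unname(colMeans(sc@values)), rep(0, 12), tolerance = 1e-9)
  expect_equal(unname(apply(sc@values, 2, sd)), rep(1, 12), tolerance = 1e-9)
  mc <- scaleMatrix(X, "mean_center")
  expect_equal(unname(colMeans(mc@values)), rep(0, 12), tolerance = 1e-9)
  expect_equal(apply(mc@values, 2, sd), apply(X, 2, sd), tolerance = 1e-12)
  ## stored parameters reproduce the training values bit-identically
  expect_identical(serumNMR:::.applyScaling(sc, X), sc@values)
  ## zero-variance columns are dropped with a warning
  X[, 3] <- 5
  expect_warning(sc2 <- scaleMatrix(X, "unit_variance"), "zero-variance")
  expect_equal(ncol(sc2@values), 11)
  expect_false(3L %in% sc2@keep)
})

test_that("PCA matches the eigendecomposition oracle and reconstructs", {
  set.seed(22)
  X <- matrix(rnorm(30 * 8), 30, 8)
  sc <- scaleMatrix(X, "mean_center")
  A <- 5
  pca <- fitPCA(sc, A)
  orc <- eigen(cov(sc@values), symmetric = TRUE)
  expect_equal(pca@eigenvalues, orc$values[1:A], tolerance = 1e-8)
  for (a in 1:A)
    expect_equal(abs(pca@loadings[, a]), abs(orc$vectors[, a]),
                 tolerance = 1e-8)
  ## eigenvalues non-increasing; loadings orthonormal; scores uncorrelated
  expect_true(all(diff(pca@eigenvalues) <= 1e-12))
  expect_equal(crossprod(pca@loadings), diag(A), tolerance = 1e-8)
  offDiag <- cov(pca@scores)[upper.tri(diag(A))]
  expect_lt(max(abs(offDiag)), 1e-8)
  ## full-rank reconstruction recovers the matrix
  full <- fitPCA(sc, 8)
  expect_equal(full@scores %*% t(full@loadings), sc@values, tolerance = 1e-8)
  expect_error(fitPCA(sc, 40), "A must lie")
})

test_that("Hotelling limit matches the F-based closed form and its asymptote", {
  ## frozen oracle: 2*99*101/(100*98) * F_(0.95)(2, 98) = 6.3039
  expect_equal(hotellingT2Limit(100, 2, 0.05), 6.30386549534466,
               tolerance = 1e-9)
  ## decreasing in alpha
  a <- seq(0.01, 0.2, by = 0.01)
  lims <- vapply(a, function(al) hotellingT2Limit(50, 2, al), numeric(1))
  expect_true(all(diff(lims) < 0))
  ## large-n limit approaches the chi-square quantile (5.991) within 2%
  expect_equal(hotellingT2Limit(10000, 2, 0.05), 5.991464547107979,
               tolerance = 0.02)
  expect_error(hotellingT2Limit(2, 2), "need n > A")
})

test_that("outlier gating flags about alpha under the null and respects T2", {
  set.seed(23)
  X <- matrix(rnorm(2000 * 10), 2000, 10)
  pca <- fitPCA(scaleMatrix(X, "mean_center"), 2)
  frac <- mean(detectOutliers(pca, 0.05))
  ## binomial 95% band around 0.05 at n = 2000
  expect_gt(frac, 0.05 - 1.96 * sqrt(0.05 * 0.95 / 2000))
  expect_lt(frac, 0.05 + 1.96 * sqrt(0.05 * 0.95 / 2000))
  ## a sample exactly at the score-space origin is never flagged
  X2 <- rbind(X[1:50, ], colMeans(X[1:50, ]))
  pca2 <- fitPCA(scaleMatrix(X2, "mean_center"), 2)
  expect_false(detectOutliers(pca2)[51])
  ## sign flips of score columns do not change the flag set
  pca3 <- pca
  pca3@scores <- -pca3@scores
  expect_identical(detectOutliers(pca3), detectOutliers(pca))
})

test_that("NIPALS PLS1 has the closed-form first weight and reaches least squares", {
  set.seed(24)
  X <- matrix(rnorm(20 * 8), 20, 8)
  y <- rep(c(-1, 1), each = 10)
  sc <- scaleMatrix(X, "unit_variance")
  m <- fitPlsDa(sc, y, ncomp = 1)
  w0 <- drop(crossprod(sc@values, y - mean(y)))
  expect_equal(m@weights[, 1], w0 / sqrt(sum(w0^2)), tolerance = 1e-10)
  ## successive scores orthogonal
  m3 <- fitPlsDa(sc, y, ncomp = 3)
  g <- crossprod(m3@scores)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
  ## at full rank the fitted values equal the least-squares fit
  mf <- fitPlsDa(sc, y, ncomp = 8)
  fitPls <- drop(sc@values %*% mf@coefficients)
  fitLs <- oracleLsFit(sc@values, y - mean(y))
  expect_equal(fitPls, fitLs, tolerance = 1e-6)
  ## a single-class response is rejected
  expect_error(fitPlsDa(sc, rep("a", 20)), "two classes")
})

test_that("O-PLS-DA filter is orthogonal to y and collapses when nothing to remove", {
  set.seed(25)
  n <- 30
  y <- rep(c(-1, 1), each = n / 2)
  ## X carries y in one direction plus tiny isotropic noise
  cdir <- rnorm(40)
  X <- outer(y, cdir) + matrix(rnorm(n * 40, sd = 1e-8), n, 40)
  sc <- scaleMatrix(X, "mean_center")
  m <- fitOplsDa(sc, y)
  expect_lt(var(m@tOrth), 1e-10 * var(m@tPred))
  pls1 <- fitPlsDa(sc, y, ncomp = 1)
  expect_equal(m@tPred, pls1@scores[, 1], tolerance = 1e-6)
  ## general data: exact orthogonality guarantees
  X2 <- matrix(rnorm(n * 40), n, 40)
  m2 <- fitOplsDa(scaleMatrix(X2, "unit_variance"), y)
  expect_lt(abs(cor(m2@tOrth, y)), 1e-10)
  expect_lt(abs(sum(m2@w * m2@wOrth)), 1e-10)
  expect_equal(sqrt(sum(m2@w^2)), 1, tolerance = 1e-10)
  ## flipping the class encoding flips score signs only
  m2b <- fitOplsDa(scaleMatrix(X2, "unit_variance"), -y)
  expect_equal(m2b@tPred, -m2@tPred, tolerance = 1e-8)
  expect_equal(abs(m2b@b), abs(m2@b), tolerance = 1e-8)
})

test_that("O-PLS prediction is consistent, centered and filter-invariant", {
  set.seed(26)
  n <- 24
  X <- matrix(rnorm(n * 15, mean = 2), n, 15)
  y <- rep(c("control", "case"), each = n / 2)
  sc <- scaleMatrix(X, "unit_variance")
  m <- fitOplsDa(sc, y)
  pr <- predict(m, X)
  ## training set reproduces training scores
  expect_equal(pr$tPred, m@tPred, tolerance = 1e-10)
  ## the training mean row predicts exactly zero
  pr0 <- predict(m, matrix(colMeans(X), 1))
  expect_equal(pr0$yhat, 0, tolerance = 1e-10)
  ## adding the orthogonal loading direction leaves the prediction unchanged
  delta <- 3 * (m@pOrth * m@scale)
  shifted <- X[3, ] + delta
  expect_equal(predict(m, matrix(shifted, 1))$yhat,
               predict(m, matrix(X[3, ], 1))$yhat, tolerance = 1e-10)
  ## removal operator is exactly idempotent
  Xs <- serumNMR:::.applyScaling(sc, X)
  once <- serumNMR:::.removeOrthogonal(m, Xs)
  twice <- serumNMR:::.removeOrthogonal(m, once)
  expect_equal(twice, once, tolerance = 1e-12)
  expect_error(predict(m, X[, 1:3]), "fewer columns")
})

test_that("correlation cutoff reproduces the published 0.32-0.48 span", {
  ## frozen independent values: t-quantile transform at n-2 df
  expect_equal(correlationCutoff(38), 0.3202171692180443, tolerance = 1e-9)
  expect_equal(correlationCutoff(17), 0.4821460169003326, tolerance = 1e-9)
  expect_equal(round(correlationCutoff(38), 2), 0.32)
  expect_equal(round(correlationCutoff(17), 2), 0.48)
  ## strictly decreasing in n
  rc <- vapply(4:100, correlationCutoff, numeric(1))
  expect_true(all(diff(rc) < 0))
  expect_error(correlationCutoff(3), "n must be >= 4")
})

test_that("back-scaled loadings carry correct signs, bounds and null behaviour", {
  set.seed(27)
  n <- 200
  p <- 30
  y <- rep(c(-1, 1), each = n / 2)
  X <- matrix(rnorm(n * p), n, p)
  X[, 1:5] <- X[, 1:5] + outer(y, rep(0.8, 5))
  ## columns 21:30 are independent of everything by construction
  sc <- scaleMatrix(X, "unit_variance")
  m <- fitOplsDa(sc, y)
  prof <- backscaledLoadings(m, X)
  expect_true(all(abs(prof@r) <= 1))
  ## back-scaled sign equals the sign of cov(tPred, column)
  cv <- drop(cov(m@tPred, X))
  expect_equal(sign(prof@backscaled[abs(cv) > 1e-8]),
               sign(cv[abs(cv) > 1e-8]))
  ## independent columns: near-zero mean correlation, few significant
  nullIdx <- 21:30
  se <- 1 / sqrt(n - 3)
  expect_lt(abs(mean(prof@r[nullIdx])), 3 * se / sqrt(length(nullIdx)) + 2 * se)
  expect_lte(sum(prof@significant[nullIdx]), 3)
  ## the injected columns dominate
  expect_true(all(prof@significant[1:5]))
  expect_equal(unique(prof@direction[1:5]), "up")
})

test_that("significant-bin tables subset the mask and respect assignments", {
  prof <- new("LoadingProfile", ppm = c(2.5, 2.6, 8.4), backscaled = c(1, -2, 0.5),
              r = c(0.8, -0.7, 0.1), rCrit = 0.5,
              significant = c(TRUE, TRUE, FALSE),
              direction = c("up", "down", "up"), n = 20L, alpha = 0.05)
  tab <- significantBins(prof, assignments = list(citrate = c(2.4, 2.7)))
  expect_equal(nrow(tab), 2)
  expect_true(all(abs(tab$r) >= 0.5))
  expect_equal(tab$metabolite, c("citrate", "citrate"))
  expect_equal(tab$direction[tab$ppm == 2.5], "up")
  ## empty mask gives an empty table
  prof@significant <- rep(FALSE, 3)
  expect_equal(nrow(significantBins(prof)), 0)
})

test_that("a simulated fold-change appears as significant 'up' bins end-to-end", {
  design <- cohortDesign(c(control = 8, case = 8),
                         effects = list(formate = c(case = 1.8)),
                         intensityCv = 0.1, noiseSd = 0.005, seed = 31)
  co <- simulateCohort(design)
  b <- processCohort(co)
  m <- fitOplsDa(scaleMatrix(b), groupsOf(b), positive = "case")
  prof <- backscaledLoadings(m, b)
  tab <- significantBins(prof, assignments = list(formate = c(8.42, 8.46)))
  hit <- tab[!is.na(tab$metabolite) & tab$metabolite == "formate", ]
  expect_gte(nrow(hit), 1)
  expect_true(all(hit$direction == "up"))
})
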