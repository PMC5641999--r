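test_that("Q2 approaches 1 when y is encoded in X and never exceeds R2", {
  set.seed(41)
  n <- 42
  y <- rep(c("control", "case"), each = n / 2)
  yv <- rep(c(-1, 1), each = n / 2)
  ## y perfectly encoded: every column is a multiple of the class vector
  X <- outer(yv, runif(20, 0.5, 2))
  cv <- crossValidatedQ2(X, y, k = 7, seed = 1)
  expect_gt(cv$q2, 0.99)
  expect_lte(cv$q2, cv$r2 + 1e-12)
  expect_lte(cv$r2, 1)
  ## per-sample residuals and predictions are consistent
  expect_equal(cv$residuals, yv - cv$predicted, tolerance = 1e-12)
  ## deterministic for a fixed seed
  cv2 <- crossValidatedQ2(X, y, k = 7, seed = 1)
  expect_identical(cv$q2, cv2$q2)
  expect_identical(cv$fold, cv2$fold)
})

test_that("null-label Q2 is non-positive for the vast majority of datasets", {
  set.seed(42)
  y <- rep(c("a", "b"), each = 30)
  q2s <- replicate(200, {
    X <- matrix(rnorm(60 * 200), 60, 200)
    crossValidatedQ2(X, y, seed = sample.int(1e6, 1))$q2
  })
  expect_gte(mean(q2s <= 0), 0.8)
  expect_lt(median(q2s), -0.1)
})

test_that("stratified folding guards against single-class training folds", {
  X <- matrix(rnorm(10 * 5), 10, 5)
  y <- c(rep("a", 9), "b")
  expect_error(crossValidatedQ2(X, y, k = 7, seed = 1), "single class")
})

test_that("permutation test calibrates to 1/(nPerm+1) under exchangeability", {
  set.seed(43)
  reps <- 60
  passes <- sum(replicate(reps, {
    X <- matrix(rnorm(30 * 50), 30, 50)
    y <- rep(c("a", "b"), each = 15)
    permutationTest(X, y, nPerm = 19, seed = sample.int(1e6, 1))$pass
  }))
  ## observed pass count consistent with Binomial(reps, 1/20)
  expect_gt(binom.test(passes, reps, p = 1 / 20)$p.value, 0.001)
})

test_that("permutation test passes with high confidence on a strong contrast", {
  set.seed(44)
  n <- 60
  y <- rep(c("control", "case"), each = n / 2)
  yv <- rep(c(-1, 1), each = n / 2)
  X <- matrix(rnorm(n * 80), n, 80)
  X[, 1:10] <- X[, 1:10] + outer(yv, rep(1.2, 10))
  pt <- permutationTest(X, y, nPerm = 50, seed = 7)
  expect_true(pt$pass)
  expect_gt(pt$q2, max(pt$permQ2))
  expect_length(pt$permQ2, 50)
})

test_that("CV-ANOVA follows its F form, edge cases and invariances", {
  y <- rep(c(-1, 1), each = 20)
  ## near-perfect prediction: p -> 0
  res <- rnorm(40, sd = 1e-6)
  out <- cvAnova(res, y)
  expect_lt(out$p, 1e-12)
  ## PRESS >= SS_y reports p = 1
  res2 <- 2 * y
  expect_equal(cvAnova(res2, y)$p, 1)
  ## F invariant to rescaling y (and residuals) by a constant
  res3 <- rnorm(40, sd = 0.8)
  a <- cvAnova(res3, y)
  b <- cvAnova(5 * res3, 5 * y)
  expect_equal(a$F, b$F, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)
  ## the F value matches the stated formula
  press <- sum(res3^2)
  ssy <- sum((y - mean(y))^2)
  expect_equal(a$F, ((ssy - press) / 2) / (press / (40 - 3)), tolerance = 1e-12)
})

test_that("ROC AUC follows the Mann-Whitney identity with half ties", {
  ## perfectly separated scores
  expect_equal(rocAuc(c(-1, -1, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  ## all-tied scores
  expect_equal(rocAuc(c(-1, -1, 1, 1), rep(0.5, 4)), 0.5)
  ## enumerated example: 3 of 4 pairs concordant
  expect_equal(rocAuc(c(1, 1, -1, -1), c(0.9, 0.4, 0.6, 0.1)), 0.75)
  ## equivariant under strictly monotone transforms
  set.seed(45)
  y <- rep(c(-1, 1), each = 25)
  s <- rnorm(50) + y
  expect_equal(rocAuc(y, s), rocAuc(y, exp(s)), tolerance = 1e-12)
  ## agrees with the pROC oracle
  oracle <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = s,
                                           quiet = TRUE, direction = "<")))
  expect_equal(rocAuc(y, s), oracle, tolerance = 1e-12)
  expect_error(rocAuc(rep(1, 4), 1:4), "both classes")
})

test_that("the verdict is the strict conjunction of both tests", {
  mk <- function(perm, anova) {
    new("ValidationReport", contrast = "case vs control", n = 20L,
        q2Pls = 0.5, q2Opls = 0.5, r2 = 0.8, permQ2 = rep(-0.2, 10),
        permPass = perm, cvAnovaF = 3, cvAnovaP = ifelse(anova, 0.01, 0.2),
        cvAnovaPass = anova, auc = 0.9, verdict = perm && anova,
        alpha = 0.05, seed = 1L)
  }
  expect_false(modelVerdict(mk(TRUE, FALSE)))
  expect_false(modelVerdict(mk(FALSE, TRUE)))
  expect_false(modelVerdict(mk(FALSE, FALSE)))
  expect_true(modelVerdict(mk(TRUE, TRUE)))
  ## grid mirrors the conjunction rule
  grid <- reportValidationGrid(list(mk(TRUE, FALSE), mk(TRUE, TRUE)))
  expect_equal(grid$verdict, c("invalid", "valid"))
  expect_equal(nrow(grid), 2)
})

test_that("validateContrast is deterministic and internally consistent", {
  set.seed(46)
  n <- 36
  y <- rep(c("control", "case"), each = n / 2)
  yv <- rep(c(-1, 1), each = n / 2)
  X <- matrix(rnorm(n * 40), n, 40)
  X[, 1:6] <- X[, 1:6] + outer(yv, rep(1, 6))
  r1 <- validateContrast(X, y, nPerm = 25, seed = 3)
  r2 <- validateContrast(X, y, nPerm = 25, seed = 3)
  expect_identical(r1@q2Pls, r2@q2Pls)
  expect_identical(r1@permQ2, r2@permQ2)
  expect_identical(r1@auc, r2@auc)
  expect_equal(r1@verdict, r1@permPass && r1@cvAnovaPass)
  expect_lte(r1@q2Opls, r1@r2)
  expect_true(r1@auc >= 0 && r1@auc <= 1)
  expect_match(r1@contrast, "case vs control")
})
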