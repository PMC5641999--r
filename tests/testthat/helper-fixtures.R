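# Shared fixtures and independent oracles, built in code at test time.

# A deterministic, nuisance-free design: no jitter, no noise, no baseline.
noiselessDesign <- function(groups = c(control = 2, case = 2),
                            effects = list(), intensityCv = 0, seed = 1,
                            ppmAxis = seq(9.5, 0.2, by = -0.001)) {
  cohortDesign(groups = groups, effects = effects,
               shiftJitterSd = 0, residualJitterSd = 0, noiseSd = 0,
               baselineAmplitude = 0, intensityCv = intensityCv,
               seed = seed, ppmAxis = ppmAxis)
}

# Single-Lorentzian spectrum on a given axis.
lorentzSpectrum <- function(center, hwPpm, ppm = seq(6, 4, by = -5e-4),
                            height = 1) {
  h <- hwPpm / 2
  nmrSpectrum(ppm, height * h * h / ((ppm - center)^2 + h * h))
}

# Independent PCA oracle: eigendecomposition of the covariance matrix.
oraclePca <- function(X, A) {
  e <- eigen(cov(X), symmetric = TRUE)
  list(eigenvalues = e$values[seq_len(A)] * (nrow(X) - 1) / (nrow(X) - 1),
       loadings = e$vectors[, seq_len(A), drop = FALSE])
}

# Independent least-squares oracle for fitted values (minimum-norm pinv).
oracleLsFit <- function(X, y) {
  drop(X %*% MASS::ginv(X) %*% y)
}

# Unit-variance scale a plain matrix into a ScaledMatrix via the package API.
uvScaled <- function(X) scaleMatrix(X, "unit_variance")

# Binned, excluded, aligned, normalised matrix for a cohort without the
# baseline-estimation step (exact for synthetic baseline-free spectra).
binnedNoBaseline <- function(cohort, config = processingConfig()) {
  processCohort(cohort, config, baseline = FALSE)
}
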