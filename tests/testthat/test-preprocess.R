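make_tiny <- function(n_above = c(7L, 6L), n = 10L) {
  p <- length(n_above)
  labels <- paste0("m", seq_len(p))
  values <- matrix(2, n, p, dimnames = list(NULL, labels))
  censored <- matrix(FALSE, n, p)
  for (j in seq_len(p)) {
    k <- n - n_above[j]
    if (k > 0) {
      censored[seq_len(k), j] <- TRUE
      values[seq_len(k), j] <- 1  # placeholder = LOD
    }
  }
  biomarker_dataset(values, censored, matrix(FALSE, n, p),
                    lod = stats::setNames(rep(1, p), labels),
                    lipid_adjusted = stats::setNames(rep(FALSE, p), labels),
                    covariates = data.frame(lipid = rep(4, n)))
}

test_that("the 60% detection rule is strict and order-preserving", {
  ds <- make_tiny(c(7L, 6L))
  expect_equal(lod_inclusion_filter(ds), "m1")  # 0.7 > 0.6; 0.6 dropped

  # a full synthetic panel where every biomarker passes comes back complete,
  # in input order
  spec <- default_synthetic_spec(n_samples = 281, lod_quantile = 0.2,
                                 seed = 2)
  sim <- simulate_dataset(spec)
  kept <- lod_inclusion_filter(sim$dataset)
  expect_identical(kept, colnames(sim$dataset$values))
  expect_length(kept, 19L)

  # all-missing biomarker errors with its label
  ds2 <- make_tiny(c(7L, 7L))
  ds2$missing[, 2] <- TRUE
  ds2$censored[, 2] <- FALSE
  expect_error(lod_inclusion_filter(ds2), "m2")
})

test_that("lipid adjustment and log transform are applied once, consistently", {
  n <- 8L
  labels <- c("fat", "plain")
  values <- matrix(2, n, 2, dimnames = list(NULL, labels))
  ds <- biomarker_dataset(values, lod = c(fat = 0.5, plain = 0.5),
                          lipid_adjusted = c(fat = TRUE, plain = FALSE),
                          covariates = data.frame(lipid = rep(4, n)))
  out <- prepare_concentrations(ds)
  expect_equal(unname(out$values[1, "fat"]), log(0.5), tolerance = 1e-12)  # 2/4
  expect_equal(unname(out$values[1, "plain"]), log(2), tolerance = 1e-12)
  # LOD becomes sample-specific for lipid-adjusted labels
  expect_equal(unname(out$log_lod[1, "fat"]), log(0.5 / 4), tolerance = 1e-12)
  expect_equal(unname(out$log_lod[1, "plain"]), log(0.5), tolerance = 1e-12)
  expect_error(prepare_concentrations(out), "already")

  ds$values[2, "plain"] <- -1
  expect_error(prepare_concentrations(ds), "nonpositive")
})

test_that("truncated-normal mean matches numerical integration", {
  # oracle: direct numerical integration of the truncated density
  oracle <- function(mu, sigma, upper) {
    stats::integrate(function(x) x * stats::dnorm(x, mu, sigma), -Inf,
                     upper)$value / stats::pnorm(upper, mu, sigma)
  }
  for (case in list(c(0, 1, 0), c(1.5, 0.7, 1.0), c(-2, 2, 1))) {
    expect_equal(truncated_normal_mean(case[1], case[2], case[3]),
                 oracle(case[1], case[2], case[3]), tolerance = 1e-8)
  }
  expect_equal(truncated_normal_mean(0, 1, 0), -sqrt(2 / pi),
               tolerance = 1e-10)
  # truncation inactive in the far-below limit
  expect_equal(truncated_normal_mean(-10, 1, 0), -10, tolerance = 1e-6)
})

test_that("below-LOD imputation is conditional, bounded and beats LOD/sqrt(2)", {
  spec <- block_synthetic_spec(400, sizes = c(4, 3), n_isolated = 1,
                               lod_quantile = 0.3, seed = 13)
  sim <- simulate_dataset(spec)
  ds <- prepare_concentrations(sim$dataset)
  out <- impute_below_lod(ds)
  # all imputed values strictly below their (log) LOD
  expect_true(all(out$values[out$censored] < out$log_lod[out$censored]))
  # column means closer to the uncensored truth than LOD/sqrt(2) substitution
  sub <- ds$values
  sub[ds$censored] <- ds$log_lod[ds$censored] - log(sqrt(2))
  truth <- colMeans(sim$truth$true_log_values)
  err_imp <- abs(colMeans(out$values) - truth)
  err_sub <- abs(colMeans(sub) - truth)
  expect_lt(mean(err_imp), mean(err_sub))

  # no censored cells -> identity
  spec0 <- block_synthetic_spec(100, sizes = c(3, 2), lod_quantile = 0,
                                seed = 1)
  ds0 <- prepare_concentrations(simulate_dataset(spec0)$dataset)
  expect_equal(impute_below_lod(ds0)$values, ds0$values)
})

test_that("singular conditional fits fall back to univariate censored ML", {
  n <- 300L
  set.seed(4)
  x <- rnorm(n)
  z <- rnorm(n)
  values <- cbind(a = exp(x), c1 = exp(z), c2 = exp(z))
  lod <- c(a = exp(unname(stats::quantile(x, 0.25))), c1 = 1e-6, c2 = 1e-6)
  censored <- sweep(values, 2, lod, `<`)
  ds <- biomarker_dataset(values, censored, lod = lod,
                          covariates = data.frame(lipid = rep(1, n)))
  ds$values[censored] <- rep(lod, each = n)[censored]
  ds <- prepare_concentrations(ds)
  # c1 and c2 are identical -> collinear predictors for a
  expect_warning(out <- impute_below_lod(ds), "singular|truncated")
  expect_true(all(out$values[out$censored] < out$log_lod[out$censored]))
})

test_that("two-stage missing imputation is exact for perfect predictors", {
  spec <- block_synthetic_spec(200, sizes = c(3, 2), n_isolated = 0,
                               lod_quantile = 0, seed = 5)
  ds <- prepare_concentrations(simulate_dataset(spec)$dataset)
  ds <- impute_below_lod(ds)
  # duplicate a biomarker, blank one cell of the copy
  v <- cbind(ds$values, dup = ds$values[, "bm01"])
  ds2 <- biomarker_dataset(exp(v), lod = stats::setNames(rep(1e-9, ncol(v)),
                                                         colnames(v)),
                           covariates = ds$covariates)
  ds2 <- impute_below_lod(prepare_concentrations(ds2))
  ds2$values[5, "dup"] <- NA
  ds2$missing[5, "dup"] <- TRUE
  out <- impute_missing(ds2)
  expect_equal(unname(out$values[5, "dup"]), unname(ds2$values[5, "bm01"]),
               tolerance = 1e-6)
  expect_false(anyNA(out$values))

  # no missing -> identity
  out0 <- impute_missing(ds)
  expect_equal(out0$values, ds$values)
})

test_that("regression imputation beats column means under MCAR", {
  spec <- block_synthetic_spec(500, sizes = c(5, 4), n_isolated = 0,
                               lod_quantile = 0, missing_rate = 0.10,
                               seed = 17)
  sim <- simulate_dataset(spec)
  ds <- impute_below_lod(prepare_concentrations(sim$dataset))
  out <- impute_missing(ds)
  truth <- sim$truth$true_log_values
  m <- ds$missing
  rmse <- function(x) sqrt(mean((x[m] - truth[m])^2))
  colmean <- ds$values
  for (j in seq_len(ncol(colmean)))
    colmean[m[, j], j] <- mean(ds$values[!m[, j], j])
  expect_lt(rmse(out$values), rmse(colmean))
})

test_that("covariates are imputed before biomarkers, by type", {
  spec <- block_synthetic_spec(300, sizes = c(3, 2), lod_quantile = 0,
                               missing_rate = 0.05, seed = 23)
  sim <- simulate_dataset(spec)
  ds <- impute_below_lod(prepare_concentrations(sim$dataset))
  ds$covariates$age[1:10] <- NA
  ds$covariates$smoking[11:18] <- NA
  out <- impute_missing(ds)
  expect_false(anyNA(out$covariates))
  expect_true(all(out$covariates$smoking %in% c(0, 1)))
  expect_false(anyNA(out$values))
})

test_that("residualization recovers betas and zeroes exact fits", {
  n <- 2000L
  set.seed(31)
  covs <- data.frame(age = rnorm(n, 30, 4), bmi = rnorm(n, 24, 4),
                     smoking = rbinom(n, 1, 0.15))
  noise <- rnorm(n)
  y <- 0.05 * covs$age + 0.02 * covs$bmi + 0.3 * covs$smoking + noise
  mat <- cbind(y = y, exact = 2 * covs$age)
  am <- residualize(mat, c("age", "bmi", "smoking"), covariates = covs)
  # exact linear function of a covariate -> all-zero residuals
  expect_lt(max(abs(am$values[, "exact"])), 1e-8)
  # column means are zero after residualization with intercept
  expect_lt(max(abs(colMeans(am$values))), 1e-8)
  # the implied fit recovers the planted betas within 3 SE
  fit <- lm(y ~ age + bmi + smoking, data = covs)
  est <- coef(summary(fit))
  for (cv in c("age", "bmi", "smoking")) {
    truth <- c(age = 0.05, bmi = 0.02, smoking = 0.3)[cv]
    expect_lt(abs(est[cv, "Estimate"] - truth), 3 * est[cv, "Std. Error"])
  }
  # collinear adjustment set errors
  covs$age2 <- covs$age * 2
  expect_error(residualize(mat, c("age", "age2"), covariates = covs),
               "collinear")
})

test_that("correlations are invariant to covariate-plane shifts", {
  n <- 400L
  set.seed(37)
  covs <- data.frame(age = rnorm(n, 30, 4), bmi = rnorm(n, 24, 4))
  mat <- matrix(rnorm(n * 4), n, 4,
                dimnames = list(NULL, paste0("m", 1:4)))
  r1 <- correlation_matrix(residualize(mat, c("age", "bmi"),
                                       covariates = covs))
  shifted <- mat
  shifted[, 2] <- shifted[, 2] + 0.7 * covs$age - 1.3 * covs$bmi
  r2 <- correlation_matrix(residualize(shifted, c("age", "bmi"),
                                       covariates = covs))
  expect_lt(max(abs(r1 - r2)), 1e-8)
})

test_that("correlation matrices behave at the edge cases", {
  n <- 5000L
  set.seed(41)
  mat <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("m", 1:4)))
  r <- correlation_matrix(mat)
  expect_equal(diag(r), stats::setNames(rep(1, 4), paste0("m", 1:4)))
  expect_lt(max(abs(r[upper.tri(r)])), 0.05)  # independent columns

  dup <- cbind(mat, m5 = mat[, 1], m6 = -mat[, 1])
  r2 <- correlation_matrix(dup)
  expect_equal(r2["m1", "m5"], 1)
  expect_equal(r2["m1", "m6"], -1)

  const <- cbind(mat, flat = rep(1, n))
  expect_error(correlation_matrix(const), "flat")
})
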