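#' Biomarker dataset container
#'
#' Holds a sample-by-biomarker concentration matrix together with the
#' censoring (below limit of detection) and missingness masks, per-biomarker
#' LOD and lipid-adjustment metadata, and the maternal covariate table.
#' Values of censored cells store the LOD as a placeholder until
#' [impute_below_lod()] replaces them; missing cells are `NA`.
#'
#' @param values numeric sample x biomarker matrix (concentrations; after
#'   [prepare_concentrations()], natural-log concentrations).
#' @param censored logical matrix, `TRUE` where the measurement fell below
#'   the LOD.
#' @param missing logical matrix, `TRUE` where the measurement is absent.
#' @param lod named positive numeric vector of detection limits (original
#'   concentration scale).
#' @param lipid_adjusted named logical vector: expressed per gram blood
#'   lipid during preparation?
#' @param covariates data.frame of per-sample covariates (maternal `age` in
#'   years, pre-pregnancy `bmi` in kg/m^2, `smoking` 0/1, `parity`,
#'   `multiples` 0/1, blood `lipid` in g/L).
#' @return an object of class `biomarker_dataset`.
#' @export
biomarker_dataset <- function(values, censored = NULL, missing = NULL,
                              lod = NULL, lipid_adjusted = NULL,
                              covariates = NULL) {
  values <- as.matrix(values)
  labels <- colnames(values)
  if (is.null(labels)) stop("values must have column names (biomarker labels)")
  n <- nrow(values); p <- ncol(values)
  if (is.null(censored)) censored <- matrix(FALSE, n, p)
  if (is.null(missing)) missing <- is.na(values)
  censored <- as.matrix(censored); missing <- as.matrix(missing)
  stopifnot(identical(dim(censored), dim(values)),
            identical(dim(missing), dim(values)))
  if (any(censored & missing))
    stop("censored_mask and missing_mask must be disjoint")
  if (is.null(lod)) lod <- stats::setNames(rep(.Machine$double.eps, p), labels)
  lod <- lod[labels]
  if (any(!is.finite(lod)) || any(lod <= 0))
    stop("all LOD values must be positive and finite")
  if (is.null(lipid_adjusted))
    lipid_adjusted <- stats::setNames(rep(FALSE, p), labels)
  lipid_adjusted <- lipid_adjusted[labels]
  if (is.null(covariates)) covariates <- data.frame(row.names = seq_len(n))
  stopifnot(nrow(covariates) == n)
  structure(list(values = values, censored = censored, missing = missing,
                 lod = lod, lipid_adjusted = lipid_adjusted,
                 covariates = covariates, log_scale = FALSE, log_lod = NULL,
                 provenance = character()),
            class = "biomarker_dataset")
}

#' @export
print.biomarker_dataset <- function(x, ...) {
  cat(sprintf(paste0("biomarker_dataset: %d samples x %d biomarkers ",
                     "(%.1f%% censored, %.1f%% missing)%s\n"),
              nrow(x$values), ncol(x$values), 100 * mean(x$censored),
              100 * mean(x$missing),
              if (x$log_scale) ", log scale" else ""))
  if (length(x$provenance))
    cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

record_stage <- function(dataset, stage) {
  dataset$provenance <- c(dataset$provenance, stage)
  dataset
}

require_stage <- function(dataset, stage, op) {
  if (!stage %in% dataset$provenance)
    stop(op, " requires ", stage, " to have been applied first ",
         "(pipeline order: lod_inclusion_filter -> prepare_concentrations ",
         "-> impute_below_lod -> impute_missing -> residualize)")
  invisible(dataset)
}

#' Keep a subset of biomarkers
#' @param dataset a `biomarker_dataset`.
#' @param labels biomarker labels to retain (order preserved as given).
#' @return the subsetted `biomarker_dataset`.
#' @export
keep_biomarkers <- function(dataset, labels) {
  stopifnot(all(labels %in% colnames(dataset$values)))
  dataset$values <- dataset$values[, labels, drop = FALSE]
  dataset$censored <- dataset$censored[, labels, drop = FALSE]
  dataset$missing <- dataset$missing[, labels, drop = FALSE]
  dataset$lod <- dataset$lod[labels]
  dataset$lipid_adjusted <- dataset$lipid_adjusted[labels]
  if (!is.null(dataset$log_lod))
    dataset$log_lod <- dataset$log_lod[, labels, drop = FALSE]
  dataset
}

#' Limit-of-detection inclusion filter
#'
#' Retains the biomarkers whose fraction of non-missing measurements
#' strictly above the LOD exceeds `threshold` (strict inequality: a
#' biomarker exactly at the threshold is dropped). This is the usual
#' quantification-rate rule applied before network estimation.
#'
#' @param dataset a `biomarker_dataset` on the concentration scale.
#' @param threshold required detection fraction in (0, 1); default 0.6.
#' @return character vector of retained labels, in input order.
#' @export
lod_inclusion_filter <- function(dataset, threshold = 0.6) {
  stopifnot(inherits(dataset, "biomarker_dataset"),
            threshold > 0, threshold < 1)
  labels <- colnames(dataset$values)
  n_obs <- colSums(!dataset$missing)
  if (any(n_obs == 0L))
    stop("biomarker(s) with all values missing: ",
         paste(labels[n_obs == 0L], collapse = ", "))
  frac_above <- colSums(!dataset$censored & !dataset$missing) / n_obs
  labels[frac_above > threshold]
}

#' Apply the LOD filter and record it in provenance
#'
#' Convenience wrapper: [lod_inclusion_filter()] then [keep_biomarkers()].
#'
#' @inheritParams lod_inclusion_filter
#' @return the filtered `biomarker_dataset`.
#' @export
apply_lod_filter <- function(dataset, threshold = 0.6) {
  kept <- lod_inclusion_filter(dataset, threshold)
  if (length(kept) == 0L) stop("no biomarker passes the LOD inclusion rule")
  record_stage(keep_biomarkers(dataset, kept), "lod_inclusion_filter")
}

#' Lipid-adjust and log-transform concentrations
#'
#' Divides lipid-adjusted biomarkers by each sample's blood lipid (grams per
#' litre, so concentrations become per gram blood lipid) and natural-log
#' transforms all values. Detection limits are transformed consistently:
#' for lipid-adjusted biomarkers the censoring threshold becomes
#' sample-specific, `log(lod / lipid_i)`, stored in the `log_lod` matrix.
#' Masks are unchanged. Applying the transformation twice is an error.
#'
#' @param dataset a `biomarker_dataset` on the concentration scale.
#' @return the transformed `biomarker_dataset` (`log_scale = TRUE`).
#' @export
prepare_concentrations <- function(dataset) {
  stopifnot(inherits(dataset, "biomarker_dataset"))
  if (dataset$log_scale)
    stop("prepare_concentrations has already been applied to this dataset")
  values <- dataset$values
  labels <- colnames(values)
  n <- nrow(values)
  log_lod <- matrix(rep(log(dataset$lod), each = n), n, length(labels),
                    dimnames = list(NULL, labels))
  if (any(dataset$lipid_adjusted)) {
    lipid <- dataset$covariates$lipid
    if (is.null(lipid) || any(!is.finite(lipid)) || any(lipid <= 0))
      stop("lipid adjustment requires a positive, complete 'lipid' covariate")
    adj <- labels[dataset$lipid_adjusted]
    values[, adj] <- values[, adj] / lipid
    log_lod[, adj] <- log(outer(1 / lipid, dataset$lod[adj]))
  }
  bad <- which(!dataset$censored & !dataset$missing & values <= 0,
               arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("nonpositive concentration among uncensored values, e.g. row ",
         bad[1L, 1L], ", biomarker ", labels[bad[1L, 2L]])
  values <- log(values)
  values[dataset$missing] <- NA_real_
  dataset$values <- values
  dataset$log_lod <- log_lod
  dataset$log_scale <- TRUE
  record_stage(dataset, "prepare_concentrations")
}

# univariate ML fit of a left-censored normal: uncensored observations x,
# per-observation censoring thresholds a for the censored ones
censored_normal_ml <- function(x, a) {
  mu0 <- mean(x); s0 <- stats::sd(x)
  if (!is.finite(s0) || s0 <= 0) s0 <- 1
  nll <- function(par) {
    mu <- par[1L]; sigma <- exp(par[2L])
    -(sum(stats::dnorm(x, mu, sigma, log = TRUE)) +
        sum(stats::pnorm(a, mu, sigma, log.p = TRUE)))
  }
  fit <- stats::optim(c(mu0, log(s0)), nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  list(mu = fit$par[1L], sigma = exp(fit$par[2L]))
}

#' Impute below-LOD values by conditional truncated-normal expectation
#'
#' For each biomarker with censored cells, a conditional normal model
#' (response: log value; predictors: all other biomarkers' log values) is
#' fitted by maximum likelihood accounting for the left censoring of the
#' response — a censored Gaussian (Tobit) regression, so that rows below
#' the LOD contribute their censoring probability rather than being
#' dropped (ordinary least squares on the uncensored rows alone would be
#' biased by the selection). Each censored cell is then replaced by the
#' expectation of the fitted conditional normal truncated above at the
#' cell's log LOD, `E[X | X < log lod, mean = fitted, sd = sigma_hat]` — a
#' deterministic single conditional imputation. Missing predictor cells
#' are temporarily filled with column means for the fit and prediction
#' only. If the conditional fit is singular or fails to converge, the
#' biomarker falls back to a univariate censored-normal ML fit of its
#' marginal, with a warning.
#'
#' @param dataset a log-scale `biomarker_dataset`.
#' @return the dataset with all censored placeholders replaced by imputed
#'   values strictly below their (log) LOD; masks unchanged.
#' @export
impute_below_lod <- function(dataset) {
  stopifnot(inherits(dataset, "biomarker_dataset"))
  if (!dataset$log_scale)
    stop("impute_below_lod expects log-scale values; run ",
         "prepare_concentrations first")
  values <- dataset$values
  labels <- colnames(values)
  if (!any(dataset$censored)) return(record_stage(dataset, "impute_below_lod"))

  # predictor matrix: current values with missing cells mean-filled
  filled <- values
  for (j in seq_along(labels)) {
    m <- dataset$missing[, j]
    if (any(m)) filled[m, j] <- mean(values[!m, j])
  }

  for (j in seq_along(labels)) {
    cens_j <- dataset$censored[, j]
    if (!any(cens_j)) next
    use <- !dataset$missing[, j]
    # left-censored response: censored rows carry their (log) LOD
    y <- values[, j]
    y[cens_j] <- dataset$log_lod[cens_j, j]
    event <- as.integer(!cens_j)           # 0 = left-censored
    X <- filled[, -j, drop = FALSE]
    a <- dataset$log_lod[cens_j, j]
    pred <- tryCatch({
      dat <- as.data.frame(X[use, , drop = FALSE])
      names(dat) <- paste0("p", seq_len(ncol(X)))
      dat$.y <- y[use]
      dat$.e <- event[use]
      fit <- survival::survreg(
        survival::Surv(.y, .e, type = "left") ~ ., data = dat,
        dist = "gaussian")
      beta <- stats::coef(fit)
      if (anyNA(beta)) stop("singular censored-regression fit")
      Xc <- cbind(1, X[cens_j, , drop = FALSE])
      list(mu = drop(Xc %*% beta[c("(Intercept)",
                                   paste0("p", seq_len(ncol(X))))]),
           sigma = fit$scale)
    }, error = function(e) NULL, warning = function(w) NULL)
    if (is.null(pred)) {
      warning("conditional fit singular or non-convergent for ", labels[j],
              "; falling back to univariate truncated-normal ML")
      ml <- censored_normal_ml(values[!cens_j & use, j], a)
      pred <- list(mu = rep(ml$mu, sum(cens_j)), sigma = ml$sigma)
    }
    imp <- truncnorm_upper_mean(pred$mu, pred$sigma, a)
    eps <- 1e-10 * pmax(1, abs(a))
    values[cens_j, j] <- pmin(imp, a - eps)
  }
  dataset$values <- values
  record_stage(dataset, "impute_below_lod")
}

drop_constant_cols <- function(X_df, obs) {
  keep <- vapply(X_df, function(col) length(unique(col[obs])) > 1L,
                 logical(1))
  X_df[keep]
}

impute_one_binary <- function(y, X_df, obs) {
  X_df <- drop_constant_cols(X_df, obs)
  dat <- cbind(.y = y, X_df)
  fit <- suppressWarnings(stats::glm(.y ~ ., data = dat[obs, , drop = FALSE],
                                     family = stats::binomial()))
  if (!fit$converged) {
    warning("logistic imputation model did not converge; using mode")
    tab <- table(y[obs])
    return(rep(as.numeric(names(tab)[which.max(tab)]), sum(!obs)))
  }
  pr <- stats::predict(fit, newdata = X_df[!obs, , drop = FALSE],
                       type = "response")
  as.numeric(pr >= 0.5)
}

impute_one_continuous <- function(y, X_df, obs, stochastic, resid_scale) {
  X_df <- drop_constant_cols(X_df, obs)
  dat <- cbind(.y = y, X_df)
  fit <- stats::lm(.y ~ ., data = dat[obs, , drop = FALSE])
  pred <- stats::predict(fit, newdata = X_df[!obs, , drop = FALSE])
  if (stochastic) {
    s <- stats::sigma(fit)
    pred <- pred + stats::rnorm(length(pred), 0, s * resid_scale)
  }
  unname(pred)
}

#' Two-stage single imputation of missing covariates and biomarkers
#'
#' Stage one imputes covariates with missing values from the complete
#' covariates and the (mean-filled) observed biomarkers: linear-regression
#' conditional means for continuous covariates, logistic regression with a
#' 0.5 classification threshold for binary ones. Stage two imputes missing
#' biomarker values by linear regression on all covariates plus the other
#' biomarkers. Deterministic by default; `stochastic = TRUE` adds a
#' residual-scale noise draw governed by `seed`.
#'
#' @param dataset a log-scale `biomarker_dataset` after [impute_below_lod()].
#' @param seed integer seed (used only when `stochastic`).
#' @param stochastic add residual noise to imputed continuous values?
#' @return the dataset with no missing cells; the missing mask still records
#'   which cells were imputed.
#' @export
impute_missing <- function(dataset, seed = 1L, stochastic = FALSE) {
  stopifnot(inherits(dataset, "biomarker_dataset"))
  require_stage(dataset, "impute_below_lod", "impute_missing")
  values <- dataset$values
  labels <- colnames(values)
  covs <- dataset$covariates
  if (stochastic) set.seed(derive_seed(seed, 11L))

  cov_missing_frac <- vapply(covs, function(x) mean(is.na(x)), numeric(1))
  bio_missing_frac <- colMeans(dataset$missing)
  if (any(cov_missing_frac >= 1) )
    stop("covariate(s) entirely missing: ",
         paste(names(covs)[cov_missing_frac >= 1], collapse = ", "))
  if (any(bio_missing_frac >= 1))
    stop("biomarker(s) entirely missing: ",
         paste(labels[bio_missing_frac >= 1], collapse = ", "))
  if (any(cov_missing_frac >= 0.5) || any(bio_missing_frac >= 0.5))
    stop("imputation requires < 50% missing values per column")

  bio_filled <- values
  for (j in seq_along(labels)) {
    m <- is.na(bio_filled[, j])
    if (any(m)) bio_filled[m, j] <- mean(bio_filled[!m, j])
  }

  # stage 1: covariates (complete covariates + observed biomarkers as predictors)
  complete_covs <- names(covs)[cov_missing_frac == 0]
  for (v in names(covs)[cov_missing_frac > 0]) {
    obs <- !is.na(covs[[v]])
    X_df <- cbind(covs[complete_covs], as.data.frame(bio_filled))
    covs[[v]][!obs] <-
      if (is_binary(covs[[v]]))
        impute_one_binary(covs[[v]], X_df, obs)
      else
        impute_one_continuous(covs[[v]], X_df, obs, stochastic, 1)
  }

  # stage 2: biomarkers (all covariates + other biomarkers as predictors)
  for (j in seq_along(labels)) {
    m <- dataset$missing[, j]
    if (!any(m)) next
    X_df <- cbind(covs, as.data.frame(bio_filled[, -j, drop = FALSE]))
    values[m, j] <- impute_one_continuous(values[, j], X_df, !m,
                                          stochastic, 1)
  }

  dataset$values <- values
  dataset$covariates <- covs
  record_stage(dataset, "impute_missing")
}

#' Residualize log concentrations on covariates
#'
#' Per biomarker, an ordinary-least-squares fit with intercept on the named
#' covariates; the returned values are the residuals. This removes linear
#' confounding (e.g. maternal age, BMI, smoking) before network estimation.
#'
#' @param x a complete log-scale `biomarker_dataset`, or a numeric matrix
#'   (in which case `covariates` must be supplied).
#' @param adjust_for names of covariate columns to adjust for.
#' @param covariates data.frame of covariates when `x` is a matrix.
#' @return an object of class `analytical_matrix`: `values` (residual
#'   matrix, columns mean-zero), `adjusted_for`, `labels`.
#' @export
residualize <- function(x, adjust_for, covariates = NULL) {
  if (inherits(x, "biomarker_dataset")) {
    covariates <- x$covariates
    values <- x$values
    if (anyNA(values))
      stop("residualize requires complete data; run impute_missing first")
  } else {
    values <- as.matrix(x)
    if (is.null(covariates)) stop("covariates must be supplied")
  }
  stopifnot(length(adjust_for) >= 1L, all(adjust_for %in% names(covariates)),
            nrow(covariates) == nrow(values))
  X <- stats::model.matrix(~ ., data = covariates[adjust_for])
  if (kappa(X, exact = TRUE) > 1e10)
    stop("collinear covariates in adjustment set: ",
         paste(adjust_for, collapse = ", "))
  qrX <- qr(X)
  res <- values - X %*% qr.coef(qrX, values)
  structure(list(values = res, adjusted_for = adjust_for,
                 labels = colnames(values)),
            class = "analytical_matrix")
}

#' Coerce to the analysis-ready matrix class
#' @param values numeric matrix with column names.
#' @param adjusted_for covariates already adjusted for (bookkeeping only).
#' @return an `analytical_matrix`.
#' @export
analytical_matrix <- function(values, adjusted_for = character()) {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    colnames(values) <- paste0("V", seq_len(ncol(values)))
  structure(list(values = values, adjusted_for = adjusted_for,
                 labels = colnames(values)),
            class = "analytical_matrix")
}

am_values <- function(x) {
  if (inherits(x, "analytical_matrix")) x$values else as.matrix(x)
}

#' Pearson correlation matrix of an analytical matrix
#'
#' @param x an `analytical_matrix` or numeric matrix (>= 3 rows).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(x) {
  v <- am_values(x)
  stopifnot(nrow(v) >= 3L)
  sds <- apply(v, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant column(s): ",
         paste(colnames(v)[sds == 0], collapse = ", "))
  stats::cor(v)
}

#' Write an analytical (residualized) matrix as TSV
#'
#' Tab-separated with a leading `sample` id column; the adjustment set is
#' recorded in a `#adjusted_for:` header line.
#'
#' @param am an `analytical_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_analytical_tsv <- function(am, path) {
  stopifnot(inherits(am, "analytical_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#adjusted_for:\t",
                    paste(am$adjusted_for, collapse = "\t")), con)
  df <- data.frame(sample = seq_len(nrow(am$values)), am$values,
                   check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
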