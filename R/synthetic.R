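#' Biomarker panels of the three FLEHS newborn campaigns
#'
#' Label sets mirroring the cord-blood biomarker panels of the three Flemish
#' Environment and Health Study campaigns, used to size demo datasets and to
#' drive panel-intersection analyses. The third-campaign panel published 19
#' biomarkers but lists one PCB congener twice; to keep 19 distinct labels
#' the panel here adds the synthetic stand-in congener PCB156.
#'
#' @return a named list with character vectors `flehs1` (7 labels), `flehs2`
#'   (12) and `flehs3` (19).
#' @export
flehs_panels <- function() {
  flehs1 <- c("cadmium", "lead", "ppDDE", "HCB", "PCB138", "PCB153", "PCB180")
  flehs2 <- c("cadmium", "lead", "ppDDE", "PCB138", "PCB153", "PCB180",
              "arsenic", "copper", "manganese", "thallium", "PFOS", "PFOA")
  flehs3 <- c(flehs2,
              "HCB", "PCB118", "PCB146", "PCB170", "PCB156", "PFHXS", "PFNA")
  list(flehs1 = flehs1, flehs2 = flehs2, flehs3 = flehs3)
}

#' Build a partition from community blocks
#'
#' @param blocks list of character vectors, one per community.
#' @param isolated labels belonging to no community ("unassigned").
#' @return named integer vector mapping each label to its community id;
#'   `NA` marks unassigned labels.
#' @export
partition_from_blocks <- function(blocks, isolated = character()) {
  labels <- c(unlist(blocks, use.names = FALSE), isolated)
  if (anyDuplicated(labels))
    stop("labels must appear exactly once across blocks and isolated")
  part <- rep(NA_integer_, length(labels))
  names(part) <- labels
  for (i in seq_along(blocks)) part[blocks[[i]]] <- i
  part
}

normalize_partition <- function(partition) {
  stopifnot(!is.null(names(partition)), !anyDuplicated(names(partition)))
  if (is.character(partition)) {
    partition[partition == "unassigned"] <- NA_character_
    partition <- stats::setNames(as.integer(factor(partition)), names(partition))
  }
  partition
}

#' Construct a block-structured precision matrix with target partial correlations
#'
#' Builds the ground-truth precision (inverse covariance) matrix of a
#' synthetic biomarker panel: within each community every pair gets the
#' target partial correlation, listed bridge edges get their own value, and
#' all other pairs are exactly conditionally independent. Construction sets
#' the off-diagonals of a unit-diagonal matrix, boosts the diagonal until
#' the smallest eigenvalue reaches `min_eigenvalue`, and rescales so the
#' implied covariance has unit diagonal (which leaves partial correlations
#' unchanged). When boosting is needed (dense blocks with strong targets can
#' be infeasible as stated), the attained within-block partial correlation
#' is `within_block_pcorr` shrunk by the boost; the attained values are
#' recovered by [partial_correlations_from_precision()].
#'
#' @param partition named map label -> community id (`NA` or "unassigned"
#'   for isolated labels), e.g. from [partition_from_blocks()].
#' @param within_block_pcorr target absolute partial correlation in (0, 1)
#'   for within-community pairs.
#' @param bridge_edges optional data.frame/list of cross-links with fields
#'   `from`, `to`, `pcorr`.
#' @param min_eigenvalue lower bound enforced on the spectrum before
#'   rescaling.
#' @return symmetric positive-definite precision matrix with the labels as
#'   dimnames and attribute `true_edges` (data.frame `from`/`to`).
#' @export
build_block_precision <- function(partition, within_block_pcorr,
                                  bridge_edges = NULL, min_eigenvalue = 0.1) {
  partition <- normalize_partition(partition)
  labels <- names(partition)
  p <- length(labels)
  stopifnot(p >= 1L)
  if (!(within_block_pcorr > 0 && within_block_pcorr < 1))
    stop("within_block_pcorr must be in (0, 1)")
  theta <- diag(p)
  dimnames(theta) <- list(labels, labels)
  for (cid in unique(partition[!is.na(partition)])) {
    members <- labels[!is.na(partition) & partition == cid]
    for (a in seq_along(members)) for (b in seq_len(a - 1L)) {
      theta[members[a], members[b]] <- -within_block_pcorr
      theta[members[b], members[a]] <- -within_block_pcorr
    }
  }
  if (!is.null(bridge_edges) && NROW(bridge_edges) > 0L) {
    be <- as.data.frame(bridge_edges, stringsAsFactors = FALSE)
    stopifnot(all(c("from", "to", "pcorr") %in% names(be)))
    for (i in seq_len(nrow(be))) {
      a <- be$from[i]; b <- be$to[i]
      if (!all(c(a, b) %in% labels)) stop("bridge edge uses unknown label")
      theta[a, b] <- -be$pcorr[i]
      theta[b, a] <- -be$pcorr[i]
    }
  }
  ev <- min(eigen(theta, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < min_eigenvalue) diag(theta) <- diag(theta) + (min_eigenvalue - ev)
  ev2 <- min(eigen(theta, symmetric = TRUE, only.values = TRUE)$values)
  if (ev2 <= 0)
    stop("precision matrix not positive definite after diagonal boosting ",
         "(blocks: ", paste(unique(stats::na.omit(partition)), collapse = ", "), ")")
  # rescale so the implied covariance (= solve(theta)) has unit diagonal;
  # a diagonal rescaling preserves both the zero pattern and all partial
  # correlations
  sigma <- solve(theta)
  d <- sqrt(diag(sigma))
  theta <- theta * outer(d, d)
  theta <- (theta + t(theta)) / 2
  idx <- which(upper.tri(theta) & abs(theta) > 1e-10, arr.ind = TRUE)
  attr(theta, "true_edges") <- data.frame(
    from = labels[idx[, 1L]], to = labels[idx[, 2L]],
    stringsAsFactors = FALSE)
  theta
}

#' Partial correlations implied by a precision matrix
#' @param theta symmetric positive-definite precision matrix.
#' @return matrix of partial correlations `-theta_ij / sqrt(theta_ii theta_jj)`
#'   with unit diagonal.
#' @export
partial_correlations_from_precision <- function(theta) {
  d <- sqrt(diag(theta))
  pc <- -theta / outer(d, d)
  diag(pc) <- 1
  pc
}

#' Specification of a synthetic HBM dataset
#'
#' Bundles everything the generator needs: sample size, panel, ground-truth
#' community structure and partial-correlation strengths, covariate effects
#' on the log scale, per-biomarker left-censoring level and missingness
#' rate, and a global seed. Covariates are drawn as maternal age
#' ~ Normal(30, 4^2) years, pre-pregnancy BMI ~ Normal(24, 4^2) kg/m^2,
#' smoking during pregnancy ~ Bernoulli(0.12), parity ~ Poisson(0.8),
#' multiples ~ Bernoulli(0.02) and blood lipid ~ logNormal(log 2.5, 0.25^2)
#' g/L, mirroring a realistic maternal cohort.
#'
#' @param n_samples number of newborns.
#' @param partition named label -> community map (see
#'   [partition_from_blocks()]).
#' @param within_block_pcorr target within-community partial correlation.
#' @param bridge_edges optional cross-community links (`from`, `to`, `pcorr`).
#' @param covariate_betas named list (by covariate) of per-biomarker effect
#'   vectors on the log-concentration scale; missing entries mean no effect.
#' @param lod_quantile per-biomarker fraction of the marginal concentration
#'   distribution below the limit of detection (recycled to the panel).
#' @param missing_rate missing-completely-at-random rate among non-censored
#'   cells.
#' @param lipid_adjusted named logical: which labels are expressed per gram
#'   blood lipid downstream (defaults to the organochlorines in the panel).
#' @param seed global integer seed; independent sub-streams are derived for
#'   covariates, noise and missingness.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples, partition, within_block_pcorr = 0.4,
                           bridge_edges = NULL, covariate_betas = list(),
                           lod_quantile = 0, missing_rate = 0,
                           lipid_adjusted = NULL, seed = 1L) {
  partition <- normalize_partition(partition)
  labels <- names(partition)
  p <- length(labels)
  lod_quantile <- rep_len(lod_quantile, p)
  names(lod_quantile) <- labels
  stopifnot(n_samples >= 1, all(lod_quantile >= 0), all(lod_quantile < 1),
            missing_rate >= 0, missing_rate < 1)
  if (any(missing_rate + lod_quantile >= 1))
    stop("missing_rate + lod_quantile must be < 1 for every biomarker")
  if (is.null(lipid_adjusted)) {
    lip <- grepl("^PCB|DDE|HCB", labels)
    lipid_adjusted <- stats::setNames(lip, labels)
  }
  structure(list(n_samples = as.integer(n_samples), labels = labels,
                 partition = partition,
                 within_block_pcorr = within_block_pcorr,
                 bridge_edges = bridge_edges,
                 covariate_betas = covariate_betas,
                 lod_quantile = lod_quantile, missing_rate = missing_rate,
                 lipid_adjusted = lipid_adjusted, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Default synthetic specification emulating the third-campaign panel
#'
#' Nineteen biomarkers in three communities — organochlorines (six PCB
#' congeners plus p,p'-DDE and the stand-in PCB156), PFAS (PFOS, PFOA,
#' PFHXS, PFNA) and the metals cadmium/copper/manganese — with HCB,
#' arsenic, thallium and lead as unconnected markers, and two bridge links
#' from PFNA into the PCB community. Modest covariate effects are planted
#' on the log scale: +0.02/yr of maternal age on the lipophilic
#' organochlorines, -0.015 per BMI unit on PFAS, +0.25 (smoking) on cadmium
#' and +0.10 on lead.
#'
#' @param n_samples sample size (default 281, a realistic campaign size).
#' @param within_block_pcorr target within-community partial correlation.
#' @param lod_quantile per-biomarker censoring fraction (default 0.2).
#' @param missing_rate MCAR rate (default 0.02).
#' @param seed global seed.
#' @return a `synthetic_spec`.
#' @export
default_synthetic_spec <- function(n_samples = 281, within_block_pcorr = 0.4,
                                   lod_quantile = 0.2, missing_rate = 0.02,
                                   seed = 1L) {
  panel <- flehs_panels()$flehs3
  pcbs <- c("PCB118", "PCB138", "PCB146", "PCB153", "PCB156", "PCB170",
            "PCB180", "ppDDE")
  pfas <- c("PFOS", "PFOA", "PFHXS", "PFNA")
  metals <- c("cadmium", "copper", "manganese")
  isolated <- c("HCB", "arsenic", "thallium", "lead")
  part <- partition_from_blocks(list(pcbs, pfas, metals), isolated)
  part <- part[panel]  # keep panel order
  labels <- names(part)
  beta0 <- function(on, value) {
    b <- stats::setNames(rep(0, length(labels)), labels)
    b[on] <- value
    b
  }
  betas <- list(
    age = beta0(c(pcbs, "HCB"), 0.02),
    bmi = beta0(pfas, -0.015),
    smoking = beta0("cadmium", 0.25) + beta0("lead", 0.10))
  bridges <- data.frame(from = c("PFNA", "PFNA"),
                        to = c("PCB138", "PCB153"),
                        pcorr = c(0.2, 0.2), stringsAsFactors = FALSE)
  synthetic_spec(n_samples, part, within_block_pcorr = within_block_pcorr,
                 bridge_edges = bridges, covariate_betas = betas,
                 lod_quantile = lod_quantile, missing_rate = missing_rate,
                 seed = seed)
}

#' Simulate a biomarker dataset with known ground truth
#'
#' Log-concentrations are multivariate normal with covariance equal to the
#' inverse of the block precision matrix (rescaled to unit variances),
#' shifted by linear covariate effects; concentrations are their
#' exponentials. Each biomarker's LOD is placed at the requested marginal
#' quantile of its simulated concentrations; values below it are flagged
#' censored and stored as the LOD. Additional cells are set missing
#' completely at random. The same spec and seed give bit-identical output.
#'
#' @param spec a [synthetic_spec()].
#' @return list with elements `dataset` (a [biomarker_dataset()]) and
#'   `truth` (class `ground_truth`: `precision`, `pcorr`, `true_edges`,
#'   `partition`, `lod_values`, `true_log_values`, `sigma`).
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  labels <- spec$labels
  n <- spec$n_samples
  p <- length(labels)
  if (n < p + 2L)
    warning("n_samples < number of biomarkers + 2: downstream estimation ",
            "will be ill-conditioned")
  theta <- build_block_precision(spec$partition, spec$within_block_pcorr,
                                 spec$bridge_edges)
  sigma <- solve(theta)
  sigma <- (sigma + t(sigma)) / 2

  seeds <- vapply(1:3, function(k) derive_seed(spec$seed, k), integer(1))

  set.seed(seeds[1])
  covariates <- data.frame(
    age = stats::rnorm(n, 30, 4),
    bmi = stats::rnorm(n, 24, 4),
    smoking = stats::rbinom(n, 1, 0.12),
    parity = stats::rpois(n, 0.8),
    multiples = stats::rbinom(n, 1, 0.02),
    lipid = stats::rlnorm(n, log(2.5), 0.25))

  shift <- matrix(0, n, p, dimnames = list(NULL, labels))
  for (cov_name in names(spec$covariate_betas)) {
    if (!cov_name %in% names(covariates))
      stop("unknown covariate in covariate_betas: ", cov_name)
    b <- rep_len(spec$covariate_betas[[cov_name]], p)
    shift <- shift + outer(covariates[[cov_name]], b)
  }

  set.seed(seeds[2])
  z <- MASS::mvrnorm(n, mu = rep(0, p), Sigma = sigma)
  logvals <- shift + z
  conc <- exp(logvals)
  colnames(conc) <- labels

  lod <- vapply(labels, function(lb) {
    q <- spec$lod_quantile[[lb]]
    if (q <= 0) min(conc[, lb]) / 2
    else as.numeric(stats::quantile(conc[, lb], probs = q, type = 7))
  }, numeric(1))

  censored <- sweep(conc, 2L, lod, `<`)

  set.seed(seeds[3])
  missing <- matrix(stats::runif(n * p) < spec$missing_rate, n, p)
  missing <- missing & !censored  # masks disjoint

  values <- conc
  values[censored] <- rep(lod, each = n)[as.vector(censored)]
  values[missing] <- NA_real_

  dataset <- biomarker_dataset(values = values, censored = censored,
                               missing = missing, lod = lod,
                               lipid_adjusted = spec$lipid_adjusted,
                               covariates = covariates)
  truth <- structure(list(
    precision = theta,
    pcorr = partial_correlations_from_precision(theta),
    true_edges = attr(theta, "true_edges"),
    partition = spec$partition,
    lod_values = lod,
    true_log_values = logvals,
    sigma = sigma), class = "ground_truth")
  list(dataset = dataset, truth = truth)
}

#' Write a simulated dataset and its ground truth to plain-text files
#'
#' Emits `data.csv` (one row per newborn: covariates, biomarker
#' concentrations with empty cells for missing values, and a
#' `<label>_censored` companion column per biomarker), `metadata.csv`
#' (label, lod, lipid_adjusted), `true_edges.tsv` and `true_partition.json`.
#'
#' @param sim output of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ds <- sim$dataset
  labels <- colnames(ds$values)
  cens <- as.data.frame(ds$censored * 1L)
  names(cens) <- paste0(labels, "_censored")
  df <- cbind(ds$covariates, as.data.frame(ds$values), cens)
  utils::write.csv(df, file.path(dir, "data.csv"), row.names = FALSE,
                   na = "")
  meta <- data.frame(label = labels, lod = ds$lod[labels],
                     lipid_adjusted = ds$lipid_adjusted[labels])
  utils::write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  utils::write.table(sim$truth$true_edges, file.path(dir, "true_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  part <- sim$truth$partition
  part_out <- ifelse(is.na(part), "unassigned", as.character(part))
  jsonlite::write_json(as.list(stats::setNames(part_out, names(part))),
                       file.path(dir, "true_partition.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Compact block-structured synthetic specification
#'
#' Generic panel with communities of the given sizes plus isolated
#' (unconnected) markers — the workhorse spec for validation studies of
#' edge and community recovery.
#'
#' @param n_samples sample size.
#' @param sizes integer vector of community sizes.
#' @param within_block_pcorr target within-community partial correlation.
#' @param n_isolated number of unconnected markers.
#' @param lod_quantile per-biomarker censoring fraction.
#' @param missing_rate MCAR rate.
#' @param seed global seed.
#' @return a `synthetic_spec` (labels `bm01`, `bm02`, ...; no covariate
#'   effects, no lipid adjustment).
#' @export
block_synthetic_spec <- function(n_samples, sizes = c(5L, 4L, 3L),
                                 within_block_pcorr = 0.4, n_isolated = 4L,
                                 lod_quantile = 0, missing_rate = 0,
                                 seed = 1L) {
  p <- sum(sizes) + n_isolated
  labels <- sprintf("bm%02d", seq_len(p))
  blocks <- split(labels[seq_len(sum(sizes))],
                  rep(seq_along(sizes), sizes))
  isolated <- if (n_isolated > 0) labels[sum(sizes) + seq_len(n_isolated)]
              else character()
  part <- partition_from_blocks(blocks, isolated)
  synthetic_spec(n_samples, part, within_block_pcorr = within_block_pcorr,
                 lod_quantile = lod_quantile, missing_rate = missing_rate,
                 lipid_adjusted = stats::setNames(rep(FALSE, p), labels),
                 seed = seed)
}

#' Read a biomarker dataset from the CSV dialect of [write_synthetic_dataset()]
#'
#' @param data_csv path to `data.csv` (covariates, concentrations with
#'   empty cells for missing values, `<label>_censored` companion columns).
#' @param meta_csv path to `metadata.csv` (label, lod, lipid_adjusted).
#' @return a `biomarker_dataset`.
#' @export
read_biomarker_dataset <- function(data_csv, meta_csv) {
  meta <- utils::read.csv(meta_csv, stringsAsFactors = FALSE)
  stopifnot(all(c("label", "lod", "lipid_adjusted") %in% names(meta)))
  df <- utils::read.csv(data_csv, stringsAsFactors = FALSE)
  labels <- meta$label
  values <- as.matrix(df[labels])
  cens_cols <- paste0(labels, "_censored")
  censored <- if (all(cens_cols %in% names(df)))
    as.matrix(df[cens_cols]) > 0 else matrix(FALSE, nrow(df), length(labels))
  censored[is.na(censored)] <- FALSE
  colnames(censored) <- labels
  covariates <- df[setdiff(names(df), c(labels, cens_cols))]
  biomarker_dataset(values = values, censored = censored,
                    missing = is.na(values) & !censored,
                    lod = stats::setNames(meta$lod, labels),
                    lipid_adjusted = stats::setNames(
                      as.logical(meta$lipid_adjusted), labels),
                    covariates = covariates)
}
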