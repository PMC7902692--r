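#' Pipeline run configuration
#'
#' Bundles every tunable of the end-to-end analysis with its default:
#' LOD inclusion threshold 0.6, a 10-point equally spaced penalty path down
#' to 10% of the maximum, StARS instability threshold 0.1 over 20
#' subsamples, EBIC gamma 0.5, 1,000 bootstrap iterations, walktrap walk
#' length 4, CNA minimum subnetwork size 6, and the BMI category cut at
#' 25 kg/m^2.
#'
#' @param lod_threshold detection-fraction rule for biomarker inclusion.
#' @param adjust covariates residualized out in the campaign analysis.
#' @param method network estimation: `"stars"` (unweighted),
#'   `"ebic"` or `"boot"` (weighted median network).
#' @param n_points,min_ratio StARS penalty-path shape.
#' @param beta StARS instability threshold.
#' @param n_subsamples StARS subsample count.
#' @param gamma EBIC tuning parameter.
#' @param n_boot parametric-bootstrap iterations.
#' @param t walktrap walk length.
#' @param min_community_size CNA community-detection threshold.
#' @param bmi_cut BMI stratification cut in kg/m^2.
#' @param seed global integer seed.
#' @return a list of class `run_config`.
#' @export
run_config <- function(lod_threshold = 0.6,
                       adjust = c("age", "bmi", "smoking"),
                       method = c("stars", "ebic", "boot"),
                       n_points = 10L, min_ratio = 0.1, beta = 0.1,
                       n_subsamples = 20L, gamma = 0.5, n_boot = 1000L,
                       t = 4L, min_community_size = 6L, bmi_cut = 25,
                       seed = 1L) {
  method <- match.arg(method)
  structure(list(lod_threshold = lod_threshold, adjust = adjust,
                 method = method, n_points = as.integer(n_points),
                 min_ratio = min_ratio, beta = beta,
                 n_subsamples = as.integer(n_subsamples), gamma = gamma,
                 n_boot = as.integer(n_boot), t = as.integer(t),
                 min_community_size = as.integer(min_community_size),
                 bmi_cut = bmi_cut, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#' @param path YAML file whose keys match the [run_config()] arguments.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

stage_msg <- function(manifest, stage, ...) {
  msg <- sprintf(...)
  message("[", stage, "] ", msg)
  manifest$stages[[stage]] <- msg
  manifest
}

#' Preprocess a raw dataset into an analysis-ready matrix
#'
#' Runs the fixed pipeline order: LOD inclusion filter, lipid adjustment
#' and log transform, conditional truncated-normal imputation of below-LOD
#' values, two-stage single imputation of missing values, then
#' residualization on the adjustment set.
#'
#' @param dataset a `biomarker_dataset` (concentration scale).
#' @param adjust covariate names to residualize on.
#' @param lod_threshold LOD inclusion threshold.
#' @param seed seed for (optional) stochastic imputation.
#' @return an `analytical_matrix`.
#' @export
preprocess_dataset <- function(dataset, adjust = c("age", "bmi", "smoking"),
                               lod_threshold = 0.6, seed = 1L) {
  ds <- apply_lod_filter(dataset, lod_threshold)
  ds <- prepare_concentrations(ds)
  ds <- impute_below_lod(ds)
  ds <- impute_missing(ds, seed = seed)
  residualize(ds, adjust_for = adjust)
}

estimate_network <- function(am, config) {
  switch(config$method,
    stars = {
      st <- stars_select(am, beta = config$beta,
                         n_subsamples = config$n_subsamples,
                         seed = config$seed, n_points = config$n_points,
                         min_ratio = config$min_ratio)
      list(network = st$selected_graph, detail = st)
    },
    ebic = {
      fit <- ebic_select(am, gamma = config$gamma)
      list(network = partial_correlations(fit), detail = fit)
    },
    boot = {
      net <- bootstrap_median_network(am, n_boot = config$n_boot,
                                      gamma = config$gamma,
                                      seed = config$seed)
      list(network = net, detail = attr(net, "full_fit"))
    })
}

#' Run a full single-campaign analysis
#'
#' Preprocess, correlate, estimate the network (method per config), detect
#' communities, render the three figures (heatmap, correlation globe,
#' community-colored network) and write all artifacts plus a
#' machine-readable run manifest. Any stage failure aborts with the stage
#' name after writing a partial manifest.
#'
#' @param dataset a `biomarker_dataset` (e.g. from [simulate_dataset()]).
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @return the manifest (list), invisibly; artifacts are written to
#'   `out_dir`.
#' @export
run_campaign_analysis <- function(dataset, config = run_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = unclass(config), stages = list())
  finish <- function(m) {
    jsonlite::write_json(m, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    m
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      manifest$error <<- list(stage = stage, message = conditionMessage(e))
      finish(manifest)
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  am <- run_stage("preprocess", {
    kept <- lod_inclusion_filter(dataset, config$lod_threshold)
    if (length(kept) == 0L)
      stop("no biomarker passes the LOD inclusion rule")
    manifest <- stage_msg(manifest, "preprocess",
                          "%d samples, %d/%d biomarkers retained",
                          nrow(dataset$values), length(kept),
                          ncol(dataset$values))
    manifest$n_samples <- nrow(dataset$values)
    manifest$n_biomarkers_retained <- length(kept)
    manifest$biomarkers <- kept
    preprocess_dataset(dataset, adjust = config$adjust,
                       lod_threshold = config$lod_threshold,
                       seed = config$seed)
  })
  manifest$adjusted_for <- config$adjust

  S <- run_stage("correlation", {
    write_analytical_tsv(am, file.path(out_dir, "residualized.tsv"))
    S <- correlation_matrix(am)
    utils::write.table(round(S, 6), file.path(out_dir, "correlation.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    S
  })

  est <- run_stage("network", {
    est <- estimate_network(am, config)
    manifest <- stage_msg(manifest, "network", "%s network: %d edges",
                          config$method, n_edges(est$network))
    manifest$n_edges <- n_edges(est$network)
    write_network_tsv(est$network, file.path(out_dir, "network.tsv"))
    write_network_graphml(est$network, file.path(out_dir, "network.graphml"))
    if (inherits(est$detail, "stars_result"))
      utils::write.table(stars_diagnostics(est$detail),
                         file.path(out_dir, "stars_diagnostics.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    est
  })

  partition <- run_stage("communities", {
    pt <- detect_communities(est$network, t = config$t)
    manifest <- stage_msg(manifest, "communities",
                          "%d communities, %d unassigned",
                          pt$n_communities, sum(is.na(pt$assignment)))
    manifest$n_communities <- pt$n_communities
    manifest$n_unassigned <- sum(is.na(pt$assignment))
    write_partition_tsv(pt, file.path(out_dir, "communities.tsv"))
    pt
  })

  run_stage("plots", {
    style <- plot_style(layout_seed = derive_seed(config$seed, 99L))
    plot_heatmap(S, file.path(out_dir, "heatmap.svg"))
    plot_circos(S, file.path(out_dir, "circos.svg"))
    plot_network(est$network, file.path(out_dir, "network.svg"),
                 partition = partition, style = style)
  })

  invisible(finish(manifest))
}

#' Run a stratified comparative network analysis
#'
#' Residualizes with the stratum-appropriate adjustment set (stratifying by
#' smoking adjusts for age and BMI; stratifying by BMI — cut at
#' `config$bmi_cut` kg/m^2 — adjusts for age and smoking), splits the data,
#' estimates a network per stratum and writes both-direction CNA artifacts
#' plus a manifest.
#'
#' @param dataset a `biomarker_dataset`.
#' @param stratify `"smoking"` or `"bmi"`.
#' @param config a [run_config()] (`method` must be `"stars"` or `"ebic"`).
#' @param out_dir output directory.
#' @return the manifest (list), invisibly.
#' @export
run_stratified_cna <- function(dataset, stratify = c("smoking", "bmi"),
                               config = run_config(), out_dir) {
  stratify <- match.arg(stratify)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  adjust <- if (stratify == "smoking") c("age", "bmi") else c("age", "smoking")
  am <- preprocess_dataset(dataset, adjust = adjust,
                           lod_threshold = config$lod_threshold,
                           seed = config$seed)
  covs <- dataset$covariates
  stratum <- if (stratify == "smoking") {
    factor(ifelse(covs$smoking > 0, "smoking", "non_smoking"),
           levels = c("non_smoking", "smoking"))
  } else {
    factor(ifelse(covs$bmi > config$bmi_cut, "high_bmi", "low_normal_bmi"),
           levels = c("low_normal_bmi", "high_bmi"))
  }
  method <- if (config$method == "boot") "ebic" else config$method
  res <- compare_strata(am, stratum, method = method, seed = config$seed,
                        beta = config$beta, gamma = config$gamma,
                        min_community_size = config$min_community_size,
                        t = config$t)
  for (lev in names(res$networks)) {
    write_network_tsv(res$networks[[lev]],
                      file.path(out_dir, paste0("network_", lev, ".tsv")))
    write_network_graphml(res$networks[[lev]],
                          file.path(out_dir, paste0("network_", lev, ".graphml")))
    plot_network(res$networks[[lev]],
                 file.path(out_dir, paste0("network_", lev, ".svg")),
                 partition = detect_communities(res$networks[[lev]],
                                                t = config$t),
                 style = plot_style(layout_seed = derive_seed(config$seed, 98L)))
  }
  write_cna_result(res$cna, out_dir)
  plot_network(res$cna$differential,
               file.path(out_dir, "differential_network.svg"),
               style = plot_style(layout_seed = derive_seed(config$seed, 97L)),
               cna_mode = TRUE)
  manifest <- list(config = unclass(config), stratify = stratify,
                   adjusted_for = adjust,
                   stratum_sizes = as.list(res$stratum_sizes),
                   n_edges = lapply(res$networks, n_edges),
                   n_conserved = n_edges(res$cna$conserved),
                   n_differential = n_edges(res$cna$differential))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
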