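#' Equally spaced penalty path for the graphical lasso
#'
#' The maximum penalty is the largest absolute off-diagonal entry of the
#' correlation matrix (any penalty at or above it yields the empty graph);
#' the path descends in equal steps to `min_ratio` times the maximum.
#'
#' @param correlation symmetric correlation matrix.
#' @param n_points number of penalties (default 10).
#' @param min_ratio smallest penalty as a fraction of the largest
#'   (default 0.1).
#' @return an object of class `lambda_path`: `lambdas` (descending),
#'   `lambda_max`, `lambda_min`.
#' @export
lambda_path <- function(correlation, n_points = 10L, min_ratio = 0.1) {
  stopifnot(n_points >= 2L, min_ratio > 0, min_ratio < 1)
  off <- abs(correlation[upper.tri(correlation)])
  lambda_max <- if (length(off)) max(off) else 0
  if (lambda_max <= 0) {
    warning("all off-diagonal correlations are zero; using lambda_max = 1 ",
            "(any positive penalty gives the empty graph)")
    lambda_max <- 1
  }
  lambdas <- seq(lambda_max, min_ratio * lambda_max, length.out = n_points)
  structure(list(lambdas = lambdas, lambda_max = lambda_max,
                 lambda_min = min_ratio * lambda_max),
            class = "lambda_path")
}

#' Graphical lasso fit at a single penalty
#'
#' Block coordinate-descent solution of the L1-penalized Gaussian
#' log-likelihood (diagonal unpenalized): the algorithm cycles through the
#' variables, solving a lasso regression for each column of the working
#' covariance. Convergence is declared when the average absolute change of
#' the off-diagonal working covariance in a sweep drops below `tol` times
#' the average absolute off-diagonal of the input.
#'
#' @param correlation symmetric positive semi-definite matrix with unit
#'   diagonal (networks are estimated on the standardized scale because
#'   biomarkers have incommensurable units).
#' @param lambda penalty (> 0).
#' @param tol convergence tolerance (default 1e-4).
#' @param max_iter maximum outer sweeps (default 200); if reached, the best
#'   iterate is returned flagged non-converged.
#' @param warm optional previous `glasso_fit` on the same variables (warm
#'   start along a path).
#' @param edge_tol absolute precision threshold for edge presence.
#' @return an object of class `glasso_fit`: `precision` (Theta),
#'   `covariance_estimate` (W), `S`, `lambda`, `edges` (data.frame),
#'   `loglik` (per-observation kernel `log det Theta - tr(S Theta)`),
#'   `converged`, `iterations`.
#' @export
glasso_fit <- function(correlation, lambda, tol = 1e-4, max_iter = 200L,
                       warm = NULL, edge_tol = 1e-8) {
  S <- as.matrix(correlation)
  stopifnot(nrow(S) == ncol(S), lambda > 0)
  labels <- colnames(S) %||% paste0("V", seq_len(ncol(S)))
  dimnames(S) <- list(labels, labels)
  W0 <- if (!is.null(warm)) warm$covariance_estimate else NULL
  B0 <- if (!is.null(warm)) warm$B else NULL
  out <- .glasso_cd(S, lambda, tol, as.integer(max_iter), W0, B0)
  theta <- out$Theta
  dimnames(theta) <- dimnames(S)
  W <- out$W
  dimnames(W) <- dimnames(S)
  if (!out$converged)
    warning("glasso_fit did not converge in ", max_iter, " iterations")
  idx <- which(upper.tri(theta) & abs(theta) > edge_tol, arr.ind = TRUE)
  edges <- data.frame(from = labels[idx[, 1L]], to = labels[idx[, 2L]],
                      stringsAsFactors = FALSE)
  ld <- determinant(theta, logarithm = TRUE)
  loglik <- as.numeric(ld$modulus) - sum(S * theta)
  structure(list(precision = theta, covariance_estimate = W, S = S,
                 lambda = lambda, edges = edges, loglik = loglik,
                 converged = out$converged, iterations = out$iterations,
                 edge_tol = edge_tol, B = out$B),
            class = "glasso_fit")
}

#' @export
print.glasso_fit <- function(x, ...) {
  cat(sprintf("glasso_fit: p = %d, lambda = %.4g, %d edges%s\n",
              ncol(x$precision), x$lambda, nrow(x$edges),
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Extended Bayesian information criterion of a graphical lasso fit
#'
#' `EBIC = -2 l(Theta) + |E| log n + 4 gamma |E| log p`, where `l` is the
#' unpenalized Gaussian log-likelihood at the estimate and `|E|` the number
#' of edges. `gamma = 0` reduces to the BIC; `gamma = 0.5` (default) adds
#' the sparsity-favouring extension used for network selection here.
#'
#' @param fit a `glasso_fit`.
#' @param n sample size behind the correlation matrix.
#' @param p number of variables (defaults to the fit's dimension).
#' @param gamma EBIC tuning parameter (default 0.5).
#' @return the EBIC score (smaller is better).
#' @export
ebic_score <- function(fit, n, p = ncol(fit$precision), gamma = 0.5) {
  stopifnot(inherits(fit, "glasso_fit"))
  n_edges <- nrow(fit$edges)
  ll <- (n / 2) * (fit$loglik - p * log(2 * pi))
  -2 * ll + n_edges * log(n) + 4 * gamma * n_edges * log(p)
}

#' EBIC-selected graphical lasso fit
#'
#' Fits a logarithmically spaced penalty path from the maximum penalty down
#' to `min_ratio` times it and returns the fit minimizing [ebic_score()].
#' Exact ties resolve toward the larger penalty (sparser graph).
#'
#' @param data an `analytical_matrix` or numeric data matrix.
#' @param gamma EBIC tuning parameter (default 0.5).
#' @param n_lambdas path length (default 100).
#' @param min_ratio smallest penalty as a fraction of the largest
#'   (default 0.01).
#' @param tol,max_iter passed to [glasso_fit()].
#' @return the selected `glasso_fit`, with attributes `lambdas` and
#'   `ebic` (the full score path).
#' @export
ebic_select <- function(data, gamma = 0.5, n_lambdas = 100L,
                        min_ratio = 0.01, tol = 1e-4, max_iter = 200L) {
  v <- am_values(data)
  n <- nrow(v)
  S <- correlation_matrix(v)
  off <- abs(S[upper.tri(S)])
  lambda_max <- max(off)
  if (lambda_max <= 0) lambda_max <- 1
  lambdas <- exp(seq(log(lambda_max), log(min_ratio * lambda_max),
                     length.out = n_lambdas))
  fits <- vector("list", n_lambdas)
  scores <- numeric(n_lambdas)
  warm <- NULL
  for (i in seq_len(n_lambdas)) {
    fits[[i]] <- suppressWarnings(
      glasso_fit(S, lambdas[i], tol = tol, max_iter = max_iter, warm = warm))
    warm <- fits[[i]]
    scores[i] <- ebic_score(fits[[i]], n = n, gamma = gamma)
  }
  best <- which(scores <= min(scores) + 1e-9)[1L]  # first = largest lambda
  fit <- fits[[best]]
  attr(fit, "lambdas") <- lambdas
  attr(fit, "ebic") <- scores
  attr(fit, "n") <- n
  fit
}

#' Weighted partial-correlation network of a graphical lasso fit
#'
#' Edge weights are the partial correlations implied by the estimated
#' precision matrix, `-Theta_ij / sqrt(Theta_ii Theta_jj)`; positive and
#' negative conditional dependencies keep their sign.
#'
#' @param fit a `glasso_fit`.
#' @return a weighted `sparse_network`.
#' @export
partial_correlations <- function(fit) {
  stopifnot(inherits(fit, "glasso_fit"))
  network_from_precision(fit$precision, edge_tol = fit$edge_tol,
                         weighted = TRUE)
}

#' StARS: stability selection of the graphical lasso penalty
#'
#' Draws `n_subsamples` subsamples of size `b = floor(10 sqrt(n))` (capped
#' at `n - 1`) without replacement, fits the full penalty path on each
#' subsample's correlation matrix, and measures for each penalty the total
#' edge instability `D(lambda)`: the mean over all node pairs of
#' `2 theta_hat (1 - theta_hat)`, where `theta_hat` is the fraction of
#' subsamples selecting that edge — equivalently, the expected fraction of
#' times two subsample graphs disagree on an edge (range 0–0.5). The
#' instability is monotonized by a running maximum from the sparse end of
#' the path, and the selected penalty is the smallest (densest graph) whose
#' monotonized instability stays at or below `beta`. The selected graph is
#' refit on the full data.
#'
#' @param data an `analytical_matrix` or numeric data matrix (n >= 20,
#'   p >= 2).
#' @param path optional [lambda_path()]; computed from the full-data
#'   correlation by default.
#' @param beta instability threshold (default 0.1).
#' @param n_subsamples number of subsamples (default 20).
#' @param seed integer seed making the subsampling reproducible.
#' @param n_points,min_ratio path shape when `path` is not supplied.
#' @return an object of class `stars_result`: `path`, `theta_hat`
#'   (pair x lambda selection frequencies), `instability`, `monotonized`,
#'   `selected_lambda`, `selected_fit`, `selected_graph` (unweighted
#'   `sparse_network`), `n_subsamples`, `subsample_size`, `beta`.
#' @export
stars_select <- function(data, path = NULL, beta = 0.1, n_subsamples = 20L,
                         seed = 1L, n_points = 10L, min_ratio = 0.1) {
  v <- am_values(data)
  n <- nrow(v); p <- ncol(v)
  stopifnot(n >= 20L, p >= 2L)
  S_full <- correlation_matrix(v)
  if (is.null(path)) path <- lambda_path(S_full, n_points, min_ratio)
  lambdas <- path$lambdas
  b <- min(floor(10 * sqrt(n)), n - 1L)
  set.seed(derive_seed(seed, 4L))
  n_pairs <- p * (p - 1L) / 2L
  counts <- matrix(0L, n_pairs, length(lambdas))
  ut <- upper.tri(S_full)
  for (s in seq_len(n_subsamples)) {
    rows <- sample.int(n, b)
    Ssub <- stats::cor(v[rows, , drop = FALSE])
    warm <- NULL
    for (i in seq_along(lambdas)) {
      fit <- suppressWarnings(glasso_fit(Ssub, lambdas[i], warm = warm))
      warm <- fit
      adj <- abs(fit$precision) > fit$edge_tol
      counts[, i] <- counts[, i] + as.integer(adj[ut])
    }
  }
  theta_hat <- counts / n_subsamples
  xi <- 2 * theta_hat * (1 - theta_hat)
  instability <- colMeans(xi)
  monotonized <- cummax(instability)  # lambdas descend: sparse -> dense
  ok <- which(monotonized <= beta)
  if (length(ok) == 0L) {
    warning("no penalty meets the instability threshold; selecting ",
            "lambda_max (sparsest graph)")
    sel <- 1L
  } else {
    sel <- max(ok)  # smallest lambda (densest graph) still under beta
  }
  selected_fit <- suppressWarnings(glasso_fit(S_full, lambdas[sel]))
  selected_graph <- network_from_precision(selected_fit$precision,
                                           edge_tol = selected_fit$edge_tol)
  structure(list(path = path, theta_hat = theta_hat,
                 instability = instability, monotonized = monotonized,
                 selected_lambda = lambdas[sel], selected_index = sel,
                 selected_fit = selected_fit,
                 selected_graph = selected_graph,
                 n_subsamples = as.integer(n_subsamples),
                 subsample_size = as.integer(b), beta = beta),
            class = "stars_result")
}

#' @export
print.stars_result <- function(x, ...) {
  cat(sprintf(paste0("stars_result: selected lambda %.4g (instability %.3f",
                     " <= beta %.2f), %d edges\n"),
              x$selected_lambda, x$monotonized[x$selected_index], x$beta,
              n_edges(x$selected_graph)))
  invisible(x)
}

#' StARS diagnostics as a table
#' @param stars a `stars_result`.
#' @return data.frame with columns `lambda`, `instability`, `monotonized`,
#'   `n_edges` (edge count of the full-data fit is not refit per penalty;
#'   `n_edges` counts pairs selected in more than half the subsamples).
#' @export
stars_diagnostics <- function(stars) {
  data.frame(lambda = stars$path$lambdas,
             instability = stars$instability,
             monotonized = stars$monotonized,
             n_edges = colSums(stars$theta_hat > 0.5))
}

#' Median network over a parametric bootstrap
#'
#' Fits the full data by [ebic_select()], simulates `n_boot` datasets of
#' the same size from a multivariate normal with the fitted covariance,
#' runs EBIC selection on each, and takes per node pair the median of the
#' partial-correlation weights over the bootstrap (an absent edge counts as
#' weight 0). An edge is present when its median weight is nonzero.
#'
#' @param data an `analytical_matrix` or numeric data matrix.
#' @param n_boot bootstrap iterations (default 1000).
#' @param gamma EBIC tuning parameter (default 0.5).
#' @param seed integer seed.
#' @param n_lambdas path length per fit (default 100).
#' @return a weighted `sparse_network` with attributes `full_fit` (the
#'   full-data `glasso_fit`) and `n_nonconverged` (bootstrap fits recorded
#'   as all-zero weights).
#' @export
bootstrap_median_network <- function(data, n_boot = 1000L, gamma = 0.5,
                                     seed = 1L, n_lambdas = 100L) {
  v <- am_values(data)
  n <- nrow(v); p <- ncol(v)
  labels <- colnames(v)
  full_fit <- ebic_select(v, gamma = gamma, n_lambdas = n_lambdas)
  sigma_hat <- full_fit$covariance_estimate
  sigma_hat <- (sigma_hat + t(sigma_hat)) / 2
  set.seed(derive_seed(seed, 5L))
  acc <- array(0, dim = c(p, p, n_boot))
  n_nonconv <- 0L
  for (bi in seq_len(n_boot)) {
    x <- MASS::mvrnorm(n, mu = rep(0, p), Sigma = sigma_hat)
    colnames(x) <- labels
    fit <- ebic_select(x, gamma = gamma, n_lambdas = n_lambdas)
    if (!fit$converged) {
      n_nonconv <- n_nonconv + 1L  # weights stay 0 for this iterate
      next
    }
    pc <- partial_correlations_from_precision(fit$precision)
    pc[abs(fit$precision) <= fit$edge_tol] <- 0
    diag(pc) <- 0
    acc[, , bi] <- pc
  }
  med <- apply(acc, c(1L, 2L), stats::median)
  dimnames(med) <- list(labels, labels)
  idx <- which(upper.tri(med) & med != 0, arr.ind = TRUE)
  net <- if (nrow(idx) == 0L) sparse_network(labels) else
    sparse_network(labels, cbind(labels[idx[, 1L]], labels[idx[, 2L]]),
                   weights = med[idx])
  attr(net, "full_fit") <- full_fit
  attr(net, "n_nonconverged") <- n_nonconv
  net
}
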