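# Sparse Gaussian graphical model estimation: graphical lasso over a
# log-spaced penalty path, extended-BIC model selection, and conversion of
# the selected precision matrix to partial correlations.

#' GGM estimation settings
#'
#' @param gamma extended-BIC hyperparameter (`>= 0`); 0.5 favours sparse,
#'   parsimonious networks, 0 recovers ordinary BIC.
#' @param n_lambda number of penalty values on the path.
#' @param lambda_min_ratio smallest penalty as a fraction of the largest.
#' @param convergence_tol absolute tolerance on covariance-estimate updates.
#' @param max_iter cap on full coordinate-descent sweeps per penalty.
#' @param edge_zero_tol magnitude below which an estimated partial
#'   correlation is reported as an exact zero (absent edge).
#' @param n_mode effective sample size entering the EBIC under pairwise
#'   deletion: `"complete"` counts listwise-complete rows (conservative),
#'   `"min_pairwise"` uses the smallest per-pair n.
#' @return A `ggm_config` list.
#' @export
ggm_config <- function(gamma = 0.5, n_lambda = 100L, lambda_min_ratio = 0.01,
                       convergence_tol = 1e-4, max_iter = 10000L,
                       edge_zero_tol = 1e-8,
                       n_mode = c("complete", "min_pairwise")) {
  stopifnot(gamma >= 0, n_lambda >= 1, lambda_min_ratio > 0,
            lambda_min_ratio <= 1, convergence_tol > 0, max_iter > 0,
            edge_zero_tol > 0)
  structure(list(gamma = gamma, n_lambda = as.integer(n_lambda),
                 lambda_min_ratio = lambda_min_ratio,
                 convergence_tol = convergence_tol,
                 max_iter = as.integer(max_iter),
                 edge_zero_tol = edge_zero_tol,
                 n_mode = match.arg(n_mode)),
            class = "ggm_config")
}

#' Penalty path for the graphical lasso
#'
#' Log-spaced sequence from `lambda_max` (the largest absolute off-diagonal
#' correlation, at and above which the estimated network is empty) down to
#' `lambda_max * lambda_min_ratio`. A matrix with no off-diagonal signal
#' yields a single nominal small penalty, since every penalty then gives the
#' same diagonal model.
#'
#' @param S symmetric unit-diagonal correlation matrix.
#' @param config a [ggm_config()].
#' @return Strictly decreasing vector of penalties.
#' @export
lambda_path <- function(S, config = ggm_config()) {
  lmax <- max(abs(S[upper.tri(S)]))
  if (lmax <= 0) return(1e-3)
  if (config$n_lambda == 1L) return(lmax)
  exp(seq(log(lmax), log(lmax * config$lambda_min_ratio),
          length.out = config$n_lambda))
}

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

#' Graphical lasso at a single penalty
#'
#' Maximizes the L1-penalized Gaussian log-likelihood
#' `log det K - trace(S K) - lambda * sum_{i != j} |K_ij|`
#' (diagonal unpenalized) by blockwise coordinate descent: each column of
#' the working covariance estimate is updated by solving a lasso regression
#' subproblem, itself by coordinate descent with exact soft-thresholding, so
#' absent edges come out as exact zeros. Warm starts are accepted for path
#' fitting.
#'
#' @param S symmetric positive-definite correlation matrix.
#' @param lambda penalty (`>= 0`).
#' @param config a [ggm_config()].
#' @param warm optional list with `W` and `B` from a previous fit.
#' @return List with precision `K` (symmetric PD, exact zeros), covariance
#'   estimate `W`, regression coefficients `B`, `iterations`, `converged`.
#' @export
glasso_fit <- function(S, lambda, config = ggm_config(), warm = NULL) {
  p <- ncol(S)
  stopifnot(isSymmetric(unname(S), tol = 1e-8), lambda >= 0)
  S <- (S + t(S)) / 2
  W <- if (!is.null(warm)) warm$W else S + lambda * diag(p)
  B <- if (!is.null(warm)) warm$B else matrix(0, p, p)
  diag(W) <- diag(S) + lambda
  inner_tol <- config$convergence_tol / 10
  converged <- FALSE
  for (it in seq_len(config$max_iter)) {
    W_old <- W
    for (j in seq_len(p)) {
      idx <- seq_len(p)[-j]
      W11 <- W[idx, idx, drop = FALSE]
      s12 <- S[idx, j]
      beta <- B[idx, j]
      repeat {
        delta <- 0
        for (l in seq_len(p - 1)) {
          r <- s12[l] - sum(W11[l, -l] * beta[-l])
          b_new <- soft_threshold(r, lambda) / W11[l, l]
          delta <- max(delta, abs(b_new - beta[l]))
          beta[l] <- b_new
        }
        if (delta < inner_tol) break
      }
      w12 <- as.vector(W11 %*% beta)
      W[idx, j] <- W[j, idx] <- w12
      B[idx, j] <- beta
    }
    if (max(abs(W - W_old)) < config$convergence_tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    convergence_error(sprintf(
      "graphical lasso did not converge at lambda = %.6g after %d sweeps (last update %.3g)",
      lambda, config$max_iter, max(abs(W - W_old))),
      lambda = lambda, iterations = config$max_iter)
  }
  K <- matrix(0, p, p)
  for (j in seq_len(p)) {
    idx <- seq_len(p)[-j]
    k22 <- 1 / (W[j, j] - sum(W[idx, j] * B[idx, j]))
    K[j, j] <- k22
    K[idx, j] <- -B[idx, j] * k22
  }
  K <- (K + t(K)) / 2
  dimnames(K) <- dimnames(W) <- dimnames(S)
  list(K = K, W = W, B = B, iterations = it, converged = converged)
}

#' Extended Bayesian Information Criterion of a fitted precision matrix
#'
#' `EBIC = -2 l + |E| log(n) + 4 gamma |E| log(p)` with Gaussian
#' log-likelihood `l = (n/2) (log det K - trace(S K))` and `|E|` the number
#' of nonzero upper-triangle precision entries. `gamma = 0` reduces to BIC.
#'
#' @param K symmetric positive-definite precision matrix.
#' @param S sample correlation matrix.
#' @param n effective sample size.
#' @param gamma EBIC hyperparameter.
#' @param edge_zero_tol zero threshold for counting edges.
#' @return Scalar EBIC (smaller is better).
#' @export
ebic <- function(K, S, n, gamma = 0.5, edge_zero_tol = 1e-8) {
  p <- ncol(K)
  ld <- determinant(K, logarithm = TRUE)
  if (ld$sign <= 0) config_error("ebic: precision matrix is not positive definite")
  ll <- (n / 2) * (as.numeric(ld$modulus) - sum(S * K))
  n_edges <- sum(abs(K[upper.tri(K)]) > edge_zero_tol)
  -2 * ll + n_edges * log(n) + 4 * gamma * n_edges * log(p)
}

#' Fit the penalty path and select the network by EBIC
#'
#' Fits the graphical lasso at every penalty on the path (warm-started from
#' sparser to denser), scores each fit by [ebic()], selects the minimizer
#' (ties go to the larger penalty, i.e. the sparser model), and converts the
#' selected precision matrix to partial correlations
#' `r_ij = -K_ij / sqrt(K_ii K_jj)`, reporting entries below
#' `edge_zero_tol` as exact zeros.
#'
#' @param S correlation matrix or a `correlation_result` from
#'   [mixed_correlation_matrix()].
#' @param n effective sample size; defaults, for a `correlation_result`, to
#'   the count implied by `config$n_mode`.
#' @param config a [ggm_config()].
#' @return A `ggm_fit`: `lambda_path`, `precision_per_lambda`,
#'   `ebic_per_lambda`, `selected_index`, `selected_lambda`, `precision`,
#'   `partial_matrix`, `edge_count`, `n_used`, `gamma`, and `graph`
#'   (a [network_graph()] of the selected partial correlations).
#' @export
ggm_select <- function(S, n = NULL, config = ggm_config()) {
  if (inherits(S, "correlation_result")) {
    if (is.null(n)) {
      n <- if (config$n_mode == "complete") S$n_complete else S$n_min_pairwise
    }
    S <- S$matrix
  }
  if (is.null(n) || n < 3) config_error("ggm_select needs an effective sample size n >= 3")
  p <- ncol(S)
  path <- lambda_path(S, config)
  fits <- vector("list", length(path))
  ebics <- numeric(length(path))
  warm <- NULL
  for (i in seq_along(path)) {
    fits[[i]] <- glasso_fit(S, path[i], config, warm = warm)
    warm <- fits[[i]]
    ebics[i] <- ebic(fits[[i]]$K, S, n, config$gamma, config$edge_zero_tol)
  }
  sel <- which.min(ebics)   # first minimum = largest penalty on ties
  K <- fits[[sel]]$K
  partial <- -K / sqrt(outer(diag(K), diag(K)))
  diag(partial) <- 0
  partial[abs(partial) < config$edge_zero_tol] <- 0
  dimnames(partial) <- dimnames(S)
  labels <- colnames(S) %||% sprintf("v%d", seq_len(p))
  structure(list(lambda_path = path,
                 precision_per_lambda = lapply(fits, `[[`, "K"),
                 ebic_per_lambda = ebics,
                 selected_index = sel,
                 selected_lambda = path[sel],
                 precision = K,
                 partial_matrix = partial,
                 edge_count = sum(abs(partial[upper.tri(partial)]) > 0),
                 n_used = n,
                 gamma = config$gamma,
                 graph = network_graph(labels, partial)),
            class = "ggm_fit")
}

#' @export
print.ggm_fit <- function(x, ...) {
  cat(sprintf("<ggm_fit> %d nodes, %d edges; gamma = %g, n = %d\n",
              ncol(x$partial_matrix), x$edge_count, x$gamma, x$n_used))
  cat(sprintf("  selected lambda = %.4g (index %d of %d)\n",
              x$selected_lambda, x$selected_index, length(x$lambda_path)))
  invisible(x)
}

#' Weighted signed network
#'
#' A labelled undirected network whose edge weights are partial correlations:
#' symmetric adjacency, zero diagonal, weights in `(-1, 1)`. Positive weights
#' are conventionally drawn blue, negative red.
#'
#' @param labels node labels.
#' @param adjacency symmetric numeric matrix with zero diagonal.
#' @return A `network_graph` list with `labels` and `adjacency`.
#' @export
network_graph <- function(labels, adjacency) {
  adjacency <- as.matrix(adjacency)
  p <- ncol(adjacency)
  if (length(labels) != p) config_error("label count must match adjacency size")
  if (!isSymmetric(unname(adjacency), tol = 1e-8)) {
    data_error("network adjacency must be symmetric")
  }
  if (any(abs(diag(adjacency)) > 1e-12)) data_error("network must have no self-loops")
  if (any(abs(adjacency) > 1)) data_error("edge weights must lie in [-1, 1]")
  adjacency <- (adjacency + t(adjacency)) / 2
  diag(adjacency) <- 0
  dimnames(adjacency) <- list(labels, labels)
  structure(list(labels = as.character(labels), adjacency = adjacency),
            class = "network_graph")
}

#' @export
print.network_graph <- function(x, ...) {
  ne <- sum(abs(x$adjacency[upper.tri(x$adjacency)]) > 0)
  cat(sprintf("<network_graph> %d nodes, %d edges\n", length(x$labels), ne))
  invisible(x)
}

#' Edge list of a network
#'
#' @param g a [network_graph()].
#' @return Data frame with `node_a`, `node_b`, `weight` for nonzero edges,
#'   plus a `sign` column (`"positive"`/`"negative"`).
#' @export
edge_list <- function(g) {
  stopifnot(inherits(g, "network_graph"))
  A <- g$adjacency
  idx <- which(upper.tri(A) & abs(A) > 0, arr.ind = TRUE)
  out <- data.frame(node_a = g$labels[idx[, 1]], node_b = g$labels[idx[, 2]],
                    weight = A[idx])
  out$sign <- ifelse(out$weight > 0, "positive", "negative")
  out[order(-abs(out$weight)), , drop = FALSE]
}
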