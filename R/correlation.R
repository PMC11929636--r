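# Mixed-type correlation: Pearson for continuous pairs, polychoric for
# ordinal pairs, polyserial for mixed pairs, all under pairwise deletion,
# followed by positive-definite repair of the assembled matrix.

# cached Gauss-Legendre nodes for the bivariate-normal integral
.gl_cache <- new.env(parent = emptyenv())

gl_nodes <- function(n = 64L) {
  key <- as.character(n)
  if (is.null(.gl_cache[[key]])) {
    .gl_cache[[key]] <- pracma::gaussLegendre(n, 0, 1)
  }
  .gl_cache[[key]]
}

#' Standard bivariate normal CDF
#'
#' `P(X <= h, Y <= k)` for standard normal margins with correlation `rho`,
#' via the single integral
#' `Phi(h)Phi(k) + (1/2pi) * int_0^{asin(rho)} exp(-(h^2 + k^2 - 2hk sin t)/(2 cos^2 t)) dt`
#' evaluated by 64-point Gauss-Legendre quadrature. The angular substitution
#' keeps the integrand bounded as `|rho| -> 1`; absolute accuracy is well
#' below 1e-7 across `|rho| <= 0.999`. Vectorized over `h`, `k`; infinite
#' bounds reduce to the univariate CDF.
#'
#' @param h,k upper integration bounds (recycled to a common length).
#' @param rho scalar correlation in `[-1, 1]`.
#' @return Vector of probabilities.
#' @export
pbvnorm <- function(h, k, rho) {
  stopifnot(length(rho) == 1L, abs(rho) <= 1)
  n <- max(length(h), length(k))
  h <- rep_len(as.numeric(h), n)
  k <- rep_len(as.numeric(k), n)
  out <- numeric(n)
  hi_h <- h == Inf
  hi_k <- k == Inf
  lo <- h == -Inf | k == -Inf
  out[hi_h & !lo] <- stats::pnorm(k[hi_h & !lo])
  out[hi_k & !lo] <- stats::pnorm(h[hi_k & !lo])
  out[hi_h & hi_k] <- 1
  out[lo] <- 0
  fin <- !(hi_h | hi_k | lo)
  if (any(fin)) {
    hf <- h[fin]; kf <- k[fin]
    base <- stats::pnorm(hf) * stats::pnorm(kf)
    if (rho == 0) {
      out[fin] <- base
    } else {
      gl <- gl_nodes(64L)
      upper <- asin(rho)
      theta <- gl$x * upper            # nodes mapped to [0, asin(rho)]
      w <- gl$w * upper
      s <- sin(theta)
      c2 <- cos(theta)^2
      # integrand matrix: length(theta) x n_fin
      integ <- vapply(seq_along(theta), function(i) {
        exp(-(hf^2 + kf^2 - 2 * s[i] * hf * kf) / (2 * c2[i]))
      }, numeric(length(hf)))
      out[fin] <- base + as.vector(integ %*% w) / (2 * pi)
    }
  }
  pmin(pmax(out, 0), 1)
}

#' Classify a variable's measurement level
#'
#' A variable is treated as ordinal when all non-missing values are integers
#' with at most `max_levels` distinct values; otherwise continuous. A
#' [variable_spec()] override wins when supplied (its `binary` level maps to
#' ordinal for correlation purposes).
#'
#' @param values numeric vector (may contain `NA`).
#' @param spec optional [variable_spec()] override.
#' @param max_levels distinct-integer ceiling for the ordinal rule.
#' @return `"continuous"` or `"ordinal"`.
#' @export
classify_level <- function(values, spec = NULL, max_levels = 7L) {
  v <- values[!is.na(values)]
  if (length(v) < 10) data_error("classify_level needs >= 10 non-missing values")
  if (length(unique(v)) < 2) data_error("constant variable is unusable in a network")
  if (!is.null(spec)) {
    return(if (spec$level == "continuous") "continuous" else "ordinal")
  }
  is_int <- all(abs(v - round(v)) < 1e-8)
  if (is_int && length(unique(v)) <= max_levels) "ordinal" else "continuous"
}

#' Latent-normal thresholds of an ordinal variable
#'
#' Threshold `tau_k` is the normal quantile of the empirical cumulative
#' proportion at level `k`; levels carrying no observations are collapsed
#' away, so all returned thresholds are finite and strictly increasing.
#'
#' @param values ordinal observations (may contain `NA`).
#' @param n_levels optional declared number of levels (for validation only).
#' @return List with `levels` (observed, sorted) and `tau`
#'   (length `length(levels) - 1`).
#' @export
estimate_thresholds <- function(values, n_levels = NULL) {
  v <- values[!is.na(values)]
  lev <- sort(unique(v))
  if (length(lev) < 2) data_error("ordinal variable has fewer than 2 observed levels")
  if (!is.null(n_levels) && length(lev) > n_levels) {
    data_error("more observed levels than declared n_levels")
  }
  cum <- cumsum(tabulate(match(v, lev)))[-length(lev)] / length(v)
  list(levels = lev, tau = stats::qnorm(cum))
}

polychoric_loglik <- function(rho, counts, tau_x, tau_y) {
  ax <- c(-Inf, tau_x, Inf)
  ay <- c(-Inf, tau_y, Inf)
  H <- matrix(rep(ax, times = length(ay)), nrow = length(ax))
  K <- matrix(rep(ay, each = length(ax)), nrow = length(ax))
  C <- matrix(pbvnorm(as.vector(H), as.vector(K), rho), nrow = length(ax))
  P <- C[-1, -1, drop = FALSE] - C[-nrow(C), -1, drop = FALSE] -
    C[-1, -ncol(C), drop = FALSE] + C[-nrow(C), -ncol(C), drop = FALSE]
  P <- pmax(P, 1e-12)
  sum(counts * log(P))
}

#' Polychoric correlation (two-step)
#'
#' Latent-normal correlation between two ordinal variables: thresholds are
#' fixed at their univariate estimates, then `rho` maximizes the
#' contingency-table log-likelihood with bivariate-normal rectangle
#' probabilities, by bounded scalar search on `[-0.999, 0.999]`. Estimates
#' hitting the boundary (perfect association) are clamped with a warning.
#'
#' @param x,y ordinal vectors (pairwise-complete cases are used).
#' @param min_n minimum number of complete pairs.
#' @return Correlation estimate in `[-0.999, 0.999]`.
#' @export
polychoric <- function(x, y, min_n = 20L) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < min_n) data_error(sprintf("polychoric needs >= %d complete pairs", min_n))
  x <- x[ok]; y <- y[ok]
  tx <- estimate_thresholds(x)
  ty <- estimate_thresholds(y)
  counts <- table(factor(x, levels = tx$levels), factor(y, levels = ty$levels))
  opt <- tryCatch(
    stats::optimize(function(r) -polychoric_loglik(r, counts, tx$tau, ty$tau),
                    interval = c(-0.999, 0.999), tol = 1e-6),
    error = function(e) convergence_error(paste0("polychoric optimizer failed: ",
                                                 conditionMessage(e))))
  rho <- opt$minimum
  if (abs(rho) > 0.9985) {
    rho <- sign(rho) * 0.999
    warning("polychoric estimate at boundary; clamped to +/-0.999")
  }
  rho
}

#' Polyserial correlation (two-step)
#'
#' Latent-normal correlation between a continuous and an ordinal variable.
#' The continuous variable is standardized internally; thresholds come from
#' the ordinal margin; `rho` maximizes the conditional likelihood of the
#' observed categories given the continuous scores, by bounded scalar search.
#'
#' @param x continuous vector.
#' @param y ordinal vector.
#' @param min_n minimum number of complete pairs.
#' @return Correlation estimate in `[-0.999, 0.999]`.
#' @export
polyserial <- function(x, y, min_n = 20L) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < min_n) data_error(sprintf("polyserial needs >= %d complete pairs", min_n))
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0) data_error("constant continuous variable")
  z <- (x - mean(x)) / stats::sd(x)
  ty <- estimate_thresholds(y)
  yi <- match(y, ty$levels)
  lo <- c(-Inf, ty$tau)[yi]
  hi <- c(ty$tau, Inf)[yi]
  nll <- function(rho) {
    s <- sqrt(1 - rho^2)
    p <- stats::pnorm((hi - rho * z) / s) - stats::pnorm((lo - rho * z) / s)
    -sum(log(pmax(p, 1e-12)))
  }
  opt <- tryCatch(stats::optimize(nll, interval = c(-0.999, 0.999), tol = 1e-6),
                  error = function(e) convergence_error(
                    paste0("polyserial optimizer failed: ", conditionMessage(e))))
  rho <- opt$minimum
  if (abs(rho) > 0.9985) {
    rho <- sign(rho) * 0.999
    warning("polyserial estimate at boundary; clamped to +/-0.999")
  }
  rho
}

#' Repair a correlation matrix to positive definiteness
#'
#' Eigenvalue-clipping repair: eigenvalues below `clip` are raised to `clip`,
#' the matrix is reconstructed and rescaled back to unit diagonal, and the
#' cycle repeats until the smallest eigenvalue reaches `target`. Positive
#' definite input (smallest eigenvalue already `>= clip`) is returned
#' unchanged, making the repair idempotent there.
#'
#' @param m symmetric unit-diagonal matrix.
#' @param clip eigenvalue floor used during reconstruction.
#' @param target required smallest eigenvalue on exit.
#' @param max_iter iteration cap.
#' @return Repaired matrix with attribute `"iterations"`.
#' @export
nearest_pd <- function(m, clip = 1e-6, target = 1e-8, max_iter = 100L) {
  stopifnot(isSymmetric(unname(m), tol = 1e-10))
  x <- (m + t(m)) / 2
  if (min(eigen(x, symmetric = TRUE, only.values = TRUE)$values) >= clip) {
    attr(x, "iterations") <- 0L
    return(x)
  }
  for (it in seq_len(max_iter)) {
    e <- eigen(x, symmetric = TRUE)
    lam <- pmax(e$values, clip)
    x <- e$vectors %*% (lam * t(e$vectors))
    d <- sqrt(diag(x))
    x <- x / outer(d, d)
    diag(x) <- 1
    x <- (x + t(x)) / 2
    if (min(eigen(x, symmetric = TRUE, only.values = TRUE)$values) >= target) break
  }
  dimnames(x) <- dimnames(m)
  attr(x, "iterations") <- it
  x
}

#' Mixed-type correlation matrix with pairwise deletion
#'
#' For every variable pair the estimator follows the two measurement levels:
#' Pearson product-moment for continuous-continuous, polychoric for
#' ordinal-ordinal, polyserial for mixed. Each pair uses only its own
#' complete cases (pairwise deletion), the per-pair method and sample size
#' are recorded, and the assembled matrix is repaired to positive definite
#' when pairwise deletion has made it indefinite.
#'
#' @param node_table [survey_table()] or data frame of node variables.
#' @param specs optional named list of [variable_spec()] level overrides.
#' @param min_pair_n pairs with fewer complete cases raise an error.
#' @param pd_tol smallest eigenvalue below which repair is triggered.
#' @return A `correlation_result`: list with `matrix`, `pair_method`,
#'   `pair_n`, `levels`, `pd_repaired`, `min_eigen_before`, `n_complete`
#'   (listwise-complete rows) and `n_min_pairwise`.
#' @export
mixed_correlation_matrix <- function(node_table, specs = NULL,
                                     min_pair_n = 20L, pd_tol = 1e-6) {
  vals <- if (inherits(node_table, "survey_table")) survey_values(node_table)
          else as.data.frame(node_table)
  p <- ncol(vals)
  if (p < 3) config_error("need at least 3 variables for a network")
  vn <- names(vals)
  lev <- vapply(vn, function(nm) classify_level(vals[[nm]], specs[[nm]]),
                character(1))
  R <- diag(p); Nmat <- matrix(NA_integer_, p, p)
  meth <- matrix(NA_character_, p, p)
  dimnames(R) <- dimnames(Nmat) <- dimnames(meth) <- list(vn, vn)
  diag(Nmat) <- colSums(!is.na(vals))
  offenders <- character(0)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      x <- vals[[i]]; y <- vals[[j]]
      ok <- !is.na(x) & !is.na(y)
      n_ij <- sum(ok)
      if (n_ij < min_pair_n) {
        offenders <- c(offenders, sprintf("%s-%s (n=%d)", vn[i], vn[j], n_ij))
        next
      }
      pair_lev <- c(lev[i], lev[j])
      if (all(pair_lev == "continuous")) {
        r <- stats::cor(x[ok], y[ok]); m <- "pearson"
      } else if (all(pair_lev == "ordinal")) {
        r <- polychoric(x[ok], y[ok], min_n = min_pair_n); m <- "polychoric"
      } else {
        if (lev[i] == "continuous") {
          r <- polyserial(x[ok], y[ok], min_n = min_pair_n)
        } else {
          r <- polyserial(y[ok], x[ok], min_n = min_pair_n)
        }
        m <- "polyserial"
      }
      R[i, j] <- R[j, i] <- r
      Nmat[i, j] <- Nmat[j, i] <- n_ij
      meth[i, j] <- meth[j, i] <- m
    }
  }
  if (length(offenders)) {
    data_error(paste0("pairs with too few complete cases: ",
                      paste(offenders, collapse = "; ")))
  }
  min_eig <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  repaired <- FALSE
  if (min_eig < pd_tol) {
    R <- nearest_pd(R, clip = pd_tol, target = 1e-8)
    attr(R, "iterations") <- NULL
    repaired <- TRUE
  }
  structure(list(matrix = R, pair_method = meth, pair_n = Nmat, levels = lev,
                 pd_repaired = repaired, min_eigen_before = min_eig,
                 n_complete = sum(stats::complete.cases(vals)),
                 n_min_pairwise = min(Nmat[upper.tri(Nmat)])),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> %d variables; methods: %s\n",
              ncol(x$matrix),
              paste(names(table(x$pair_method[upper.tri(x$pair_method)])),
                    table(x$pair_method[upper.tri(x$pair_method)]),
                    sep = ":", collapse = ", ")))
  cat(sprintf("  listwise-complete n = %d, min pairwise n = %d; PD repaired: %s (min eigen %.3g)\n",
              x$n_complete, x$n_min_pairwise, x$pd_repaired, x$min_eigen_before))
  invisible(x)
}
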