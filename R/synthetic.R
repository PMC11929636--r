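# Seeded synthetic survey generator. Data are drawn from a latent
# multivariate normal whose sparse partial-correlation structure is known,
# then expanded into Likert items through a one-factor congeneric
# measurement model per scale and discretized, so every pipeline stage
# (scoring, mixed correlation, GGM, centrality) can be validated against a
# known truth without any real respondent data.

#' Build a true network from a partial-correlation matrix
#'
#' The implied precision matrix is unit-diagonal with `K_ij = -P_ij`. If it
#' is not positive definite the off-diagonal is shrunk toward zero by a
#' factor just below 1 until it is, and the shrunken partials become the
#' truth. The implied correlation matrix is the standardized inverse.
#'
#' @param partial symmetric zero-diagonal matrix of partial correlations.
#' @param labels optional node labels.
#' @return A `true_network`: `partial`, `precision`, `sigma`, `labels`,
#'   `shrunk` flag and applied `shrink_factor`.
#' @export
true_network <- function(partial, labels = NULL) {
  P <- as.matrix(partial)
  p <- ncol(P)
  stopifnot(isSymmetric(unname(P), tol = 1e-10), all(abs(diag(P)) < 1e-12))
  if (is.null(labels)) labels <- colnames(P) %||% sprintf("v%d", seq_len(p))
  shrink <- 1
  repeat {
    K <- diag(p) - shrink * P
    if (min(eigen(K, symmetric = TRUE, only.values = TRUE)$values) > 1e-6) break
    shrink <- shrink * 0.95
  }
  Sigma <- stats::cov2cor(solve(K))
  dimnames(K) <- dimnames(Sigma) <- list(labels, labels)
  Pout <- shrink * P
  dimnames(Pout) <- list(labels, labels)
  structure(list(partial = Pout, precision = K, sigma = Sigma,
                 labels = labels, shrunk = shrink < 1, shrink_factor = shrink),
            class = "true_network")
}

#' Random sparse true network
#'
#' Each upper-triangle edge is present independently with probability
#' `edge_prob`, with weight uniform on `weight_range`; positive definiteness
#' is enforced by diagonal-ward shrinkage (see [true_network()]). Fully
#' determined by `seed`.
#'
#' @param p number of nodes (`>= 3`).
#' @param edge_prob edge inclusion probability.
#' @param weight_range interval inside `(-1, 1)`.
#' @param seed integer seed.
#' @param labels optional node labels.
#' @return A [true_network()].
#' @export
random_sparse_network <- function(p, edge_prob = 0.2,
                                  weight_range = c(-0.4, 0.4),
                                  seed = 1L, labels = NULL) {
  stopifnot(p >= 3, edge_prob >= 0, edge_prob <= 1,
            all(abs(weight_range) < 1))
  set.seed(seed)
  P <- matrix(0, p, p)
  ut <- upper.tri(P)
  n_edges <- sum(ut)
  present <- stats::runif(n_edges) < edge_prob
  w <- stats::runif(n_edges, weight_range[1], weight_range[2])
  P[ut] <- ifelse(present, w, 0)
  P <- P + t(P)
  if (!is.null(labels)) dimnames(P) <- list(labels, labels)
  true_network(P, labels)
}

#' The bundled reference network as a simulation truth
#'
#' Wraps the published partial-correlation network shipped with the package
#' (see [load_fixture()]) into a [true_network()], so recovery experiments
#' can use a realistic psychosocial dependence structure as ground truth.
#'
#' @param which `"main"` (7 nodes) or `"posthoc"` (10 nodes).
#' @return A [true_network()].
#' @export
reference_truth <- function(which = c("main", "posthoc")) {
  g <- load_fixture(match.arg(which))
  true_network(g$adjacency, g$labels)
}

#' Default item blueprints for the bundled instruments
#'
#' One blueprint per network node: item count, number of response levels and
#' the lowest response value, mirroring the instruments' formats (support
#' subscales 4 items on 1-7; CES-D 20 on 0-3; PTSD/DTS frequency 17 on 0-4;
#' STSS 31 on 1-5). The composite risk node is generated separately from
#' three binary indicators.
#'
#' @return Named list of blueprints.
#' @export
default_item_blueprints <- function() {
  list(
    cesd    = list(prefix = "cesd", n_items = 20L, n_levels = 4L, min_value = 0),
    ptsd    = list(prefix = "ptsd", n_items = 17L, n_levels = 5L, min_value = 0),
    stss    = list(prefix = "stss", n_items = 31L, n_levels = 5L, min_value = 1),
    special = list(prefix = "special", n_items = 4L, n_levels = 7L, min_value = 1),
    family  = list(prefix = "family", n_items = 4L, n_levels = 7L, min_value = 1),
    friend  = list(prefix = "friend", n_items = 4L, n_levels = 7L, min_value = 1)
  )
}

discretize_items <- function(latent, n_levels, min_value) {
  # thresholds at equally spaced normal quantiles -> near-uniform margins
  tau <- stats::qnorm(seq_len(n_levels - 1) / n_levels)
  min_value + findInterval(latent, tau)
}

#' Draw latent node scores
#'
#' Continuous observations from `N(0, Sigma)` under the truth's implied
#' correlation matrix — the idealized, measurement-error-free view of the
#' network variables used by recovery benchmarks.
#'
#' @param truth a [true_network()].
#' @param n number of observations.
#' @param seed integer seed.
#' @return Data frame of node columns.
#' @export
sample_latent <- function(truth, n, seed = 1L) {
  stopifnot(inherits(truth, "true_network"))
  set.seed(seed)
  x <- MASS::mvrnorm(n, mu = rep(0, length(truth$labels)), Sigma = truth$sigma)
  colnames(x) <- truth$labels
  as.data.frame(x)
}

#' Generate a synthetic survey
#'
#' Latent node scores are drawn from `N(0, Sigma)`; every scale node is
#' expanded into its Likert items through a one-factor congeneric model
#' (`item latent = loading x node score + unique noise`) and discretized at
#' equally spaced normal quantiles. The composite-risk node is expanded into
#' three binary indicators (latent thresholded at the configured marginal
#' prevalences), emitted as a continuous adherence proportion calibrated so
#' that adherence `< 0.80` coincides with the first indicator, plus two 0/1
#' indicator columns. Missingness is injected completely at random at
#' `missing_rate` (optionally depending on the depressive latent when
#' `mar = TRUE`). Output is fully determined by `seed`.
#'
#' @param truth a [true_network()] whose labels match the blueprint names
#'   plus a `risk` node (default: [reference_truth()]).
#' @param n number of respondents.
#' @param missing_rate cell-level missingness probability in `[0, 1)`.
#' @param loading common item loading in `(0, 1)`.
#' @param prevalences marginal probabilities of the three risk indicators.
#' @param seed integer seed.
#' @param mar if `TRUE`, missingness probability increases with the
#'   depressive latent (logistic link) instead of being uniform.
#' @param blueprints item blueprints ([default_item_blueprints()]).
#' @return A [survey_table()] with item columns, `adherence_prop`,
#'   `detectable_vl_12mo`, `missed_visit_12mo`, and attributes `latent`
#'   (the generating node scores) and `truth`.
#' @export
sample_survey <- function(truth = reference_truth("main"), n = 119L,
                          missing_rate = 0, loading = 0.7,
                          prevalences = c(0.22, 0.22, 0.22), seed = 1L,
                          mar = FALSE, blueprints = default_item_blueprints()) {
  stopifnot(inherits(truth, "true_network"), missing_rate >= 0,
            missing_rate < 1, loading > 0, loading < 1,
            length(prevalences) == 3)
  scale_nodes <- setdiff(truth$labels, "risk")
  missing_bp <- setdiff(scale_nodes, names(blueprints))
  if (length(missing_bp)) {
    config_error(paste0("no item blueprint for node(s): ",
                        paste(missing_bp, collapse = ", ")))
  }
  if (!"risk" %in% truth$labels) config_error("truth must contain a 'risk' node")
  set.seed(seed)
  eta <- MASS::mvrnorm(n, mu = rep(0, length(truth$labels)),
                       Sigma = truth$sigma)
  colnames(eta) <- truth$labels
  cols <- list()
  for (nd in scale_nodes) {
    bp <- blueprints[[nd]]
    uniq_sd <- sqrt(1 - loading^2)
    for (i in seq_len(bp$n_items)) {
      lat <- loading * eta[, nd] + stats::rnorm(n, sd = uniq_sd)
      cols[[sprintf("%s_%d", bp$prefix, i)]] <-
        discretize_items(lat, bp$n_levels, bp$min_value)
    }
  }
  # risk indicators: correlated binary expansions of the risk latent
  ind_loading <- 0.7
  uniq_sd <- sqrt(1 - ind_loading^2)
  tau_ind <- stats::qnorm(1 - prevalences)
  ind_lat <- sapply(1:3, function(j) {
    ind_loading * eta[, "risk"] + stats::rnorm(n, sd = uniq_sd)
  })
  # adherence < 0.80 exactly when the first indicator latent crosses its
  # threshold: P(adh < .8) = prevalences[1]
  cols$adherence_prop <- stats::pnorm(stats::qnorm(0.80) + tau_ind[1] - ind_lat[, 1])
  cols$detectable_vl_12mo <- as.numeric(ind_lat[, 2] > tau_ind[2])
  cols$missed_visit_12mo <- as.numeric(ind_lat[, 3] > tau_ind[3])
  df <- as.data.frame(cols)
  if (missing_rate > 0) {
    prob <- if (mar && "cesd" %in% colnames(eta)) {
      # logistic in the depressive latent, calibrated to missing_rate on average
      pl <- stats::plogis(eta[, "cesd"])
      missing_rate * pl / mean(pl)
    } else {
      rep(missing_rate, n)
    }
    for (cn in names(df)) {
      drop <- stats::runif(n) < prob
      df[[cn]][drop] <- NA
    }
  }
  out <- survey_table(df)
  attr(out, "latent") <- as.data.frame(eta)
  attr(out, "truth") <- truth
  out
}

#' Write the generating truth alongside a synthetic survey
#'
#' @param truth a [true_network()].
#' @param path output JSON path.
#' @param seed the seed used for generation (recorded for provenance).
#' @export
write_truth <- function(truth, path, seed = NULL) {
  jsonlite::write_json(
    list(labels = truth$labels, partial = truth$partial,
         sigma = truth$sigma, shrunk = truth$shrunk,
         shrink_factor = truth$shrink_factor, seed = seed),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' End-to-end recovery experiment
#'
#' Repeatedly simulates data under a known truth, runs the estimation
#' pipeline (mixed correlation then EBIC graphical lasso), and scores the
#' selected network against the truth: per-edge sensitivity and specificity,
#' mean absolute error on true-edge weights, per-edge detection rates, and
#' the Spearman correlation of node strength with the truth's.
#'
#' @param truth a [true_network()].
#' @param n observations per replicate.
#' @param n_reps number of replicates.
#' @param seed base seed; replicate `r` uses `seed + r`.
#' @param mode `"latent"` simulates the node scores directly (continuous,
#'   no measurement model); `"survey"` generates full item-level surveys and
#'   scores them first.
#' @param config a [ggm_config()].
#' @param ... passed to [sample_survey()] in survey mode.
#' @return A `recovery_report` list with aggregate metrics and the per-edge
#'   detection matrix.
#' @export
recovery_experiment <- function(truth, n = 2000L, n_reps = 20L, seed = 1L,
                                mode = c("latent", "survey"),
                                config = ggm_config(), ...) {
  mode <- match.arg(mode)
  stopifnot(n_reps >= 1)
  P <- truth$partial
  ut <- upper.tri(P)
  true_edge <- abs(P[ut]) > 0
  detect <- matrix(NA, n_reps, sum(ut))
  mae <- sens <- spec <- rank_cor <- numeric(n_reps)
  true_strength <- rowSums(abs(P))
  for (r in seq_len(n_reps)) {
    rep_seed <- seed + r
    dat <- if (mode == "latent") {
      sample_latent(truth, n, seed = rep_seed)
    } else {
      surv <- sample_survey(truth, n = n, seed = rep_seed, ...)
      survey_values(build_node_table(surv))
    }
    cr <- mixed_correlation_matrix(dat)
    fit <- ggm_select(cr, config = config)
    Pe <- fit$partial_matrix[truth$labels, truth$labels]
    est_edge <- abs(Pe[ut]) > 0
    detect[r, ] <- est_edge
    sens[r] <- if (any(true_edge)) mean(est_edge[true_edge]) else NA_real_
    spec[r] <- if (any(!true_edge)) mean(!est_edge[!true_edge]) else NA_real_
    mae[r] <- if (any(true_edge)) {
      mean(abs(Pe[ut][true_edge] - P[ut][true_edge]))
    } else NA_real_
    rank_cor[r] <- suppressWarnings(
      stats::cor(rowSums(abs(Pe)), true_strength, method = "spearman"))
  }
  pair_names <- outer(truth$labels, truth$labels, paste, sep = "~")[ut]
  colnames(detect) <- pair_names
  structure(list(
    n = n, n_reps = n_reps, mode = mode, seed = seed,
    sensitivity = mean(sens), specificity = mean(spec),
    weight_mae = mean(mae), strength_rank_cor = mean(rank_cor, na.rm = TRUE),
    per_edge_detection = colMeans(detect),
    false_positive_rate = if (any(!true_edge)) {
      mean(detect[, !true_edge, drop = FALSE])
    } else NA_real_,
    true_edges = pair_names[true_edge]),
    class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> %d reps at n = %d (%s data)\n",
              x$n_reps, x$n, x$mode))
  cat(sprintf("  sensitivity %.3f | specificity %.3f | weight MAE %.4f | strength rank cor %.3f\n",
              x$sensitivity, x$specificity, x$weight_mae, x$strength_rank_cor))
  invisible(x)
}
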