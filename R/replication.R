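# Bundled reference networks and the end-to-end pipeline driver.
#
# The package ships, as plain-text fixtures, the two partial-correlation
# networks printed in a published cross-sectional network analysis of
# psychosocial variables among Black women living with HIV: a 7-node main
# network (depressive symptoms, PTSD symptoms, self-silencing total,
# composite viral non-suppression risk, and special-person / family /
# friend support) and a 10-node post-hoc network in which the self-silencing
# total is replaced by its four subscales. Printed absent edges are stored
# as structural zeros; where the source's running text and its tables
# disagree on a weight, the tables are authoritative.

#' Load a bundled reference network
#'
#' @param which `"main"` (7 nodes) or `"posthoc"` (10 nodes).
#' @return A [network_graph()].
#' @export
load_fixture <- function(which = c("main", "posthoc")) {
  which <- match.arg(which)
  path <- system.file("extdata", sprintf("network_%s.csv", which),
                      package = "supportnet", mustWork = TRUE)
  raw <- utils::read.csv(path, check.names = FALSE)
  labels <- raw$node
  A <- as.matrix(raw[, -1, drop = FALSE])
  rownames(A) <- labels
  network_graph(labels, A)
}

# In-text centrality claims for the main network. `reproducible` marks the
# two claims that agree with values recomputed from the printed matrix;
# the others do not reproduce under standard conventions (1/|w| distances,
# fractional-credit betweenness, within-component closeness) and are
# reported as documented discrepancies.
main_printed_claims <- function() {
  data.frame(
    node = c("cesd", "cesd", "cesd", "ptsd", "family", "family",
             "risk", "risk", "risk", "risk"),
    index = c("strength", "expected_influence", "betweenness", "betweenness",
              "betweenness", "closeness", "strength", "expected_influence",
              "betweenness", "closeness"),
    printed = c(1.02, 0.78, 4, 5, 5, 0.22, 0.31, -0.09, 1, 0.18),
    reproducible = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                     FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Replicate the published centrality results from a bundled network
#'
#' Recomputes all four centrality indices (raw and z-standardized) on the
#' requested reference network and, for the main network, compares them with
#' the centrality values reported in the source's text. Only the depressive
#' node's raw strength and expected influence reproduce from the printed
#' matrix (1.02 and 0.78 at two decimals); the remaining printed values do
#' not follow from it under standard conventions, and the report flags them
#' as documented discrepancies rather than confirming them.
#'
#' @param which `"main"` or `"posthoc"`.
#' @return A `replication_report` list: `which`, `graph`, `centrality` (a
#'   [centrality_table()]), and for the main network `concordance`, a table
#'   of printed vs recomputed values with a two-decimal `concordant` flag.
#' @export
replicate_report <- function(which = c("main", "posthoc")) {
  which <- match.arg(which)
  g <- load_fixture(which)
  ct <- centrality_table(g)
  conc <- NULL
  if (which == "main") {
    conc <- main_printed_claims()
    conc$recomputed <- mapply(function(nd, ix) {
      ct[ct$node == nd, ix]
    }, conc$node, conc$index)
    conc$concordant <- round(conc$recomputed, 2) == round(conc$printed, 2)
  }
  structure(list(which = which, graph = g, centrality = ct,
                 concordance = conc),
            class = "replication_report")
}

#' @export
print.replication_report <- function(x, ...) {
  cat(sprintf("<replication_report> %s network (%d nodes, %d edges)\n",
              x$which, length(x$graph$labels),
              sum(abs(x$graph$adjacency[upper.tri(x$graph$adjacency)]) > 0)))
  print(x$centrality, digits = 3)
  if (!is.null(x$concordance)) {
    cat("\nPrinted centrality claims vs recomputation:\n")
    print(x$concordance, digits = 3)
    n_bad <- sum(!x$concordance$concordant)
    if (n_bad) {
      cat(sprintf(paste0(
        "\n%d printed value(s) do not reproduce from the printed matrix under\n",
        "standard conventions; they are documented discrepancies, not errors\n",
        "in the recomputation.\n"), n_bad))
    }
  }
  invisible(x)
}

#' Run the full estimation pipeline and write its artifacts
#'
#' Executes scoring, mixed correlation, EBIC graphical lasso and centrality
#' end to end on a survey, writing every intermediate product to `out_dir`:
#' the scored node table, correlation / method / per-pair-n matrices, a JSON
#' fit report (penalty path, EBIC values, selected model, edge list), the
#' selected network adjacency, and the centrality table. Decision points
#' (per-pair estimator and n, PD repair, selected penalty, effective n) are
#' reported via `message()`.
#'
#' @param survey a [survey_table()] or path to a survey CSV.
#' @param out_dir output directory (created if absent).
#' @param network `"main"` or `"posthoc"` node configuration.
#' @param defns scale definitions ([default_scale_definitions()]).
#' @param specs optional [variable_spec()] overrides for the node variables.
#' @param config a [ggm_config()].
#' @param missing_marker missing marker used when `survey` is a path and
#'   for written output.
#' @return Invisibly, a list with `node_table`, `correlation`, `fit`,
#'   `centrality` and the written `paths`.
#' @export
run_pipeline <- function(survey, out_dir, network = c("main", "posthoc"),
                         defns = default_scale_definitions(), specs = NULL,
                         config = ggm_config(), missing_marker = "") {
  network <- match.arg(network)
  if (is.character(survey)) survey <- read_survey(survey, missing_marker)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  nodes <- build_node_table(survey, defns, network)
  message(sprintf("scored %d respondents into %d node variables",
                  nrow(nodes), ncol(nodes) - 1L))
  cr <- mixed_correlation_matrix(nodes, specs = specs)
  message(sprintf("correlation: listwise n = %d, min pairwise n = %d, PD repaired = %s",
                  cr$n_complete, cr$n_min_pairwise, cr$pd_repaired))
  fit <- ggm_select(cr, config = config)
  message(sprintf("selected lambda = %.4g (EBIC index %d/%d), %d edges, effective n = %d",
                  fit$selected_lambda, fit$selected_index,
                  length(fit$lambda_path), fit$edge_count, fit$n_used))
  ct <- centrality_table(fit$graph)

  paths <- list(
    node_table = file.path(out_dir, "node_table.csv"),
    correlation = file.path(out_dir, "correlation.csv"),
    pair_method = file.path(out_dir, "pair_method.csv"),
    pair_n = file.path(out_dir, "pair_n.csv"),
    network = file.path(out_dir, "network.csv"),
    edge_list = file.path(out_dir, "edges.csv"),
    centrality = file.path(out_dir, "centrality.csv"),
    fit_report = file.path(out_dir, "fit_report.json"),
    scale_report = file.path(out_dir, "scale_report.csv")
  )
  write_survey(nodes, paths$node_table, missing_marker)
  write_named_matrix(cr$matrix, paths$correlation)
  write_named_matrix(cr$pair_method, paths$pair_method)
  write_named_matrix(cr$pair_n, paths$pair_n)
  write_named_matrix(fit$partial_matrix, paths$network)
  utils::write.csv(edge_list(fit$graph), paths$edge_list, row.names = FALSE)
  utils::write.csv(as.data.frame(ct), paths$centrality, row.names = FALSE)
  utils::write.csv(attr(nodes, "scale_report"), paths$scale_report,
                   row.names = FALSE)
  jsonlite::write_json(
    list(lambda_path = fit$lambda_path, ebic = fit$ebic_per_lambda,
         selected_index = fit$selected_index,
         selected_lambda = fit$selected_lambda, gamma = fit$gamma,
         n_used = fit$n_used, edge_count = fit$edge_count,
         pd_repaired = cr$pd_repaired,
         min_eigen_before = cr$min_eigen_before,
         edges = edge_list(fit$graph)),
    paths$fit_report, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(list(node_table = nodes, correlation = cr, fit = fit,
                 centrality = ct, paths = paths))
}

write_named_matrix <- function(m, path) {
  df <- data.frame(node = rownames(m), as.data.frame(m, check.names = FALSE),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a labelled adjacency matrix written by [run_pipeline()]
#'
#' @param path CSV with a `node` label column and one column per node.
#' @return A [network_graph()].
#' @export
read_network <- function(path) {
  if (!file.exists(path)) data_error(paste0("network file not found: ", path))
  raw <- utils::read.csv(path, check.names = FALSE)
  labels <- raw$node
  A <- as.matrix(raw[, -1, drop = FALSE])
  rownames(A) <- labels
  network_graph(labels, A)
}
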