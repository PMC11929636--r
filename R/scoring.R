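#' Define a psychometric scale
#'
#' @param scale_name label for the scored variable.
#' @param item_names ordered item column names.
#' @param aggregation `"sum"` or `"mean"`.
#' @param item_range closed interval of legal item values `c(lo, hi)`.
#' @param min_prop_answered minimum fraction of items that must be answered
#'   for a respondent to receive a (prorated) score; in `(0, 1]`.
#' @return A `scale_definition` list.
#' @export
scale_definition <- function(scale_name, item_names,
                             aggregation = c("sum", "mean"),
                             item_range, min_prop_answered = 0.75) {
  aggregation <- match.arg(aggregation)
  if (!length(item_names)) config_error("scale needs at least one item")
  if (min_prop_answered <= 0 || min_prop_answered > 1) {
    config_error("min_prop_answered must lie in (0, 1]")
  }
  structure(list(scale_name = scale_name, item_names = as.character(item_names),
                 aggregation = aggregation, item_range = as.numeric(item_range),
                 min_prop_answered = min_prop_answered),
            class = "scale_definition")
}

#' Default instrument definitions
#'
#' Returns scale definitions for the five instruments the package scores:
#' the three MSPSS support subscales (special person, family, friend; 4 items
#' each on a 1-7 Likert metric, aggregated by mean), the CES-D (20 items,
#' 0-3, summed), the Davidson Trauma Scale frequency ratings for PTSD
#' symptoms (17 items, 0-4, summed), and the Silencing the Self Scale (31
#' items, 1-5, summed) with its four subscales (externalized self-perception
#' 6 items, care as self-sacrifice 9, silencing the self 9, divided self 7).
#' Item columns follow the `<scale>_<i>` naming used by [sample_survey()];
#' the subscale blocks are contiguous, a synthetic layout standing in for
#' the instrument's published item keying. No item is reverse coded.
#'
#' @param min_prop_answered proration threshold applied to every scale.
#' @return Named list of [scale_definition()] objects.
#' @export
default_scale_definitions <- function(min_prop_answered = 0.75) {
  mk <- function(name, prefix, k, agg, rng) {
    scale_definition(name, sprintf("%s_%d", prefix, seq_len(k)), agg, rng,
                     min_prop_answered)
  }
  list(
    special = mk("special", "special", 4L, "mean", c(1, 7)),
    family  = mk("family", "family", 4L, "mean", c(1, 7)),
    friend  = mk("friend", "friend", 4L, "mean", c(1, 7)),
    cesd    = mk("cesd", "cesd", 20L, "sum", c(0, 3)),
    ptsd    = mk("ptsd", "ptsd", 17L, "sum", c(0, 4)),
    stss    = mk("stss", "stss", 31L, "sum", c(1, 5)),
    ext_self_perception = scale_definition("ext_self_perception",
      sprintf("stss_%d", 1:6), "sum", c(1, 5), min_prop_answered),
    care_self_sacrifice = scale_definition("care_self_sacrifice",
      sprintf("stss_%d", 7:15), "sum", c(1, 5), min_prop_answered),
    silencing_self = scale_definition("silencing_self",
      sprintf("stss_%d", 16:24), "sum", c(1, 5), min_prop_answered),
    divided_self = scale_definition("divided_self",
      sprintf("stss_%d", 25:31), "sum", c(1, 5), min_prop_answered)
  )
}

#' Score one scale for every respondent
#'
#' Mean-aggregated scales return the mean of the answered items; sum-aggregated
#' scales return the prorated sum, i.e. (mean of answered items) x (number of
#' items). Either score is only issued when the fraction of answered items
#' reaches `min_prop_answered`; otherwise the respondent's score is missing.
#' With no missing items the prorated sum equals the plain sum exactly, and
#' every emitted score lies inside the scale's theoretical range.
#'
#' @param table a [survey_table()].
#' @param defn a [scale_definition()].
#' @return Named numeric vector of per-respondent scores (`NA` = not scorable).
#' @export
score_scale <- function(table, defn) {
  stopifnot(inherits(defn, "scale_definition"))
  vals <- survey_values(table)
  missing_items <- setdiff(defn$item_names, names(vals))
  if (length(missing_items)) {
    config_error(sprintf("scale '%s': unknown item(s) %s", defn$scale_name,
                         paste(missing_items, collapse = ", ")))
  }
  m <- as.matrix(vals[, defn$item_names, drop = FALSE])
  out_of_range <- !is.na(m) & (m < defn$item_range[1] | m > defn$item_range[2])
  if (any(out_of_range)) {
    idx <- which(out_of_range, arr.ind = TRUE)[1, ]
    data_error(sprintf(
      "scale '%s': value %g outside [%g, %g] at row %d, item '%s'",
      defn$scale_name, m[idx[1], idx[2]], defn$item_range[1],
      defn$item_range[2], idx[1], defn$item_names[idx[2]]))
  }
  k <- length(defn$item_names)
  answered <- rowSums(!is.na(m))
  item_mean <- rowMeans(m, na.rm = TRUE)
  score <- if (defn$aggregation == "mean") item_mean else item_mean * k
  score[answered < defn$min_prop_answered * k | answered == 0] <- NA_real_
  names(score) <- table$respondent_id %||% rownames(m)
  score
}

#' Composite viral non-suppression risk score
#'
#' Counts, per respondent, how many of three risk criteria hold: antiretroviral
#' adherence strictly below 80%, a detectable viral load in the past 12 months,
#' and at least one missed HIV-care visit in the past 12 months. Adherence of
#' exactly 80% does not count. A missing criterion contributes 0 and is
#' tallied in `n_missing_criteria`; a respondent missing all three criteria
#' gets a missing score.
#'
#' @param adherence_prop numeric adherence proportion in `[0, 1]` (or `NA`).
#' @param detectable_vl_12mo logical/0-1: detectable viral load (or `NA`).
#' @param missed_visit_12mo logical/0-1: missed an HIV-care visit (or `NA`).
#' @param adherence_cutoff criteria threshold; adherence `<` this counts.
#' @return Data frame with integer `score` in `0..3` (`NA` if unscorable) and
#'   `n_missing_criteria`.
#' @export
score_composite_risk <- function(adherence_prop, detectable_vl_12mo,
                                 missed_visit_12mo, adherence_cutoff = 0.80) {
  n <- max(length(adherence_prop), length(detectable_vl_12mo),
           length(missed_visit_12mo))
  a <- rep_len(as.numeric(adherence_prop), n)
  v <- rep_len(as.logical(detectable_vl_12mo), n)
  m <- rep_len(as.logical(missed_visit_12mo), n)
  crit <- cbind(a < adherence_cutoff, v, m)
  n_missing <- rowSums(is.na(crit))
  score <- rowSums(crit, na.rm = TRUE)
  score[n_missing == 3L] <- NA_integer_
  data.frame(score = as.integer(score), n_missing_criteria = n_missing)
}

#' Cronbach's alpha
#'
#' Internal-consistency coefficient
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(item sums))`,
#' computed on the rows complete for all items.
#'
#' @param item_matrix numeric matrix/data frame, respondents x items.
#' @return Scalar alpha (`<= 1`; can be negative for incoherent items).
#' @export
cronbach_alpha <- function(item_matrix) {
  m <- as.matrix(item_matrix)
  if (ncol(m) < 2) config_error("cronbach_alpha needs at least 2 items")
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 3) data_error("cronbach_alpha needs at least 3 complete rows")
  total_var <- stats::var(rowSums(m))
  if (total_var <= .Machine$double.eps) {
    data_error("cronbach_alpha undefined: total score has zero variance")
  }
  k <- ncol(m)
  k / (k - 1) * (1 - sum(apply(m, 2, stats::var)) / total_var)
}

#' Score all scales and assemble the network node table
#'
#' Scores each instrument and the composite risk score and returns the
#' variables entering the network. The main configuration yields seven nodes
#' (CES-D, PTSD symptoms, STSS total, composite risk, and the special-person
#' / family / friend support means); the post-hoc configuration replaces the
#' STSS total with its four subscales (ten nodes). Respondents missing a
#' score keep their row with a missing cell: deletion is handled pairwise
#' downstream, in the correlation stage.
#'
#' @param table a [survey_table()] holding the item columns and the three
#'   risk columns `adherence_prop`, `detectable_vl_12mo`, `missed_visit_12mo`.
#' @param defns named list of [scale_definition()]s
#'   (default [default_scale_definitions()]).
#' @param network `"main"` or `"posthoc"`.
#' @return A [survey_table()] of node variables, with a
#'   `"scale_report"` attribute holding per-scale alpha and complete-case
#'   counts (see [scale_score_report()]).
#' @export
build_node_table <- function(table, defns = default_scale_definitions(),
                             network = c("main", "posthoc")) {
  network <- match.arg(network)
  wanted <- if (network == "main") {
    c("cesd", "ptsd", "stss", "special", "family", "friend")
  } else {
    c("cesd", "ptsd", "special", "family", "friend",
      "ext_self_perception", "care_self_sacrifice", "silencing_self",
      "divided_self")
  }
  missing_defn <- setdiff(wanted, names(defns))
  if (length(missing_defn)) {
    config_error(paste0("missing scale definition(s): ",
                        paste(missing_defn, collapse = ", ")))
  }
  vals <- survey_values(table)
  risk_cols <- c("adherence_prop", "detectable_vl_12mo", "missed_visit_12mo")
  if (!all(risk_cols %in% names(vals))) {
    config_error(paste0("survey table lacks risk column(s): ",
                        paste(setdiff(risk_cols, names(vals)), collapse = ", ")))
  }
  scores <- lapply(defns[wanted], function(d) score_scale(table, d))
  risk <- score_composite_risk(vals$adherence_prop, vals$detectable_vl_12mo,
                               vals$missed_visit_12mo)
  node_order <- if (network == "main") {
    c("cesd", "ptsd", "stss", "risk", "special", "family", "friend")
  } else {
    c("cesd", "ptsd", "risk", "special", "family", "friend",
      "ext_self_perception", "care_self_sacrifice", "silencing_self",
      "divided_self")
  }
  df <- as.data.frame(scores)
  df$risk <- as.numeric(risk$score)
  df <- df[, node_order]
  out <- survey_table(df, respondent_id = table$respondent_id)
  attr(out, "scale_report") <- scale_score_report(table, defns[wanted])
  out
}

#' Per-scale scoring diagnostics
#'
#' @param table a [survey_table()].
#' @param defns named list of [scale_definition()]s.
#' @return Data frame with one row per scale: Cronbach's alpha on
#'   item-complete rows (`NA` when undefined) and the number of respondents
#'   receiving a score.
#' @export
scale_score_report <- function(table, defns = default_scale_definitions()) {
  vals <- survey_values(table)
  rows <- lapply(defns, function(d) {
    sc <- score_scale(table, d)
    a <- tryCatch(cronbach_alpha(vals[, d$item_names, drop = FALSE]),
                  supportnet_error = function(e) NA_real_)
    data.frame(scale = d$scale_name, n_items = length(d$item_names),
               alpha = a, n_scored = sum(!is.na(sc)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
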