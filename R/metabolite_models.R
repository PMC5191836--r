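# Trend-augmented rhythmicity analysis for metabolite time courses.
#
# Metabolite concentrations in developing larvae often drift over the
# sampling window independently of any diurnal oscillation; a linear
# time term per condition (or shared across conditions) absorbs that
# drift so it is not mistaken for — or does not mask — a rhythm.

#' Trend policy for metabolite model fitting
#'
#' `mode` controls the non-periodic time term added to every candidate
#' design: `"per_condition"` (default; one free slope per condition),
#' `"shared"` (a single slope), or `"none"` (reduces exactly to the
#' transcriptome pipeline). `candidate_set` is either `"full"` — the
#' complete enumeration of zero/shared harmonic structures from
#' [enumerate_models()] — or an explicit list of model assignment vectors
#' (which must include the all-flat model), for analyses that restrict the
#' space to a curated subset.
#'
#' @param mode trend mode.
#' @param candidate_set `"full"` or a list of assignment vectors.
#' @return A `trend_policy` object.
#' @export
trend_policy <- function(mode = c("per_condition", "shared", "none"),
                         candidate_set = "full") {
  mode <- match.arg(mode)
  if (!identical(candidate_set, "full")) {
    if (!is.list(candidate_set) || length(candidate_set) < 1L)
      stop("'candidate_set' must be \"full\" or a non-empty list of model specs")
    candidate_set <- lapply(candidate_set, check_spec)
    if (!any(vapply(candidate_set, function(s) all(s == 0L), logical(1))))
      stop("an explicit candidate set must include the all-flat model")
  }
  structure(list(mode = mode, candidate_set = candidate_set),
            class = "trend_policy")
}

#' Rhythmicity assessment for metabolite tables
#'
#' Same contract as [select_all()], but every candidate design carries the
#' trend term requested by the policy, and the result records the policy
#' used. When `alias` is supplied (a data.frame with columns `label` and
#' `alias`, e.g. roman numerals from a published model table), an alias
#' column is attached to the selection table for the labels present; no
#' alias is ever guessed.
#'
#' @param table metabolites x samples numeric matrix.
#' @param sheet a [sample_sheet()].
#' @param policy a [trend_policy()].
#' @param period oscillation period in hours.
#' @param threshold Schwarz-weight threshold; defaults to
#'   [default_bicw_threshold()].
#' @param alias optional label-to-alias mapping data.frame.
#' @param bic_n BIC sample-size convention, see [fit_feature()].
#' @return A `rhythm_selection` with a `policy` element (and a
#'   `model_alias` column in `$table` when `alias` was given).
#' @export
fit_metabolites <- function(table, sheet, policy = trend_policy(),
                            period = 24, threshold = NULL, alias = NULL,
                            bic_n = "timepoints") {
  if (!inherits(policy, "trend_policy"))
    stop("'policy' must come from trend_policy()")
  models <- if (identical(policy$candidate_set, "full")) NULL else
    policy$candidate_set
  sel <- select_all(table, sheet, models = models, period = period,
                    with_trend = policy$mode, threshold = threshold,
                    bic_n = bic_n)
  sel$policy <- policy
  if (!is.null(alias)) {
    stopifnot(is.data.frame(alias), all(c("label", "alias") %in% names(alias)))
    sel$table$model_alias <-
      alias$alias[match(sel$table$best_model, alias$label)]
  }
  sel
}
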