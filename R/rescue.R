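# Rescue classification: compare a feature's model assignment between an
# untreated multi-condition arm (reference genotype, one or more mutants)
# and a treated two-condition arm (reference + treatment, mutant +
# treatment), and decide whether the treatment restored the mutant's
# rhythm.
#
# Vocabulary: a feature is "affected" when the untreated reference is
# rhythmic but the designated mutant either lost the rhythm or oscillates
# with different parameters. In the treated arm, "both rhythmic with
# shared parameters" is the full-rescue pattern (model D in the conventional
# lettering) and "both rhythmic with distinct parameters" the partial
# pattern (model E); an E-type assignment whose phase/amplitude gap did
# not shrink relative to the untreated arm is the non-rescued E* class.

RESCUE_CATEGORIES <- c("rescued_full", "rescued_partial",
                       "not_rescued_Estar", "not_rescued_other",
                       "not_applicable")

#' Tolerances for "reduced difference" comparisons in rescue calls
#'
#' A phase or relative-amplitude gap between reference and mutant counts
#' as reduced by the treatment only when it shrinks by more than the
#' tolerance: `phase_h` hours for peak-phase distances and
#' `relative_amplitude` (dimensionless) for relative-amplitude gaps.
#'
#' @param phase_h phase tolerance in hours.
#' @param relative_amplitude relative-amplitude tolerance.
#' @return A named list used by [classify_rescue()].
#' @export
rescue_tolerances <- function(phase_h = 0.5, relative_amplitude = 0.05) {
  stopifnot(phase_h >= 0, relative_amplitude >= 0)
  list(phase_h = phase_h, relative_amplitude = relative_amplitude)
}

param_lookup <- function(sel, condition, column) {
  p <- sel$params[sel$params$condition == condition, ]
  p[match(sel$table$feature_id, p$feature_id), column]
}

#' Flag features affected in the untreated arm
#'
#' A feature is affected when (i) its untreated assignment is confident
#' (fittable and not ambiguous), (ii) the reference condition is rhythmic,
#' and (iii) the designated mutant is either non-rhythmic (loss) or
#' rhythmic in a different parameter group (altered phase/amplitude).
#'
#' The same difference tolerances that govern the rescue comparison also
#' act as an effect-size guard here: an "altered" call requires the fitted
#' peak-phase distance or the relative-amplitude gap between reference and
#' mutant to exceed its tolerance. A structural two-group assignment whose
#' fitted parameters are indistinguishable within tolerance is reported as
#' `split_below_tolerance` and not counted as affected. Set both
#' tolerances to 0 for the purely structural rule.
#'
#' @param untreated a `rhythm_selection` from the untreated arm.
#' @param reference,mutant condition names of the reference (wild-type)
#'   and mutant conditions.
#' @param tolerances a [rescue_tolerances()] list.
#' @return A data.frame with `feature_id`, logical `affected` and a
#'   `reason` in `{loss, altered, shared, split_below_tolerance,
#'   reference_not_rhythmic, ambiguous, unfittable}`.
#' @export
is_affected <- function(untreated, reference, mutant,
                        tolerances = rescue_tolerances()) {
  stopifnot(inherits(untreated, "rhythm_selection"))
  for (cc in c(reference, mutant))
    if (!cc %in% untreated$conditions)
      stop("condition '", cc, "' not present in the untreated selection")
  tab <- untreated$table
  ref_g <- param_lookup(untreated, reference, "group")
  mut_g <- param_lookup(untreated, mutant, "group")
  pd <- circular_phase_distance(param_lookup(untreated, reference, "phase"),
                                param_lookup(untreated, mutant, "phase"),
                                untreated$period)
  rd <- abs(param_lookup(untreated, reference, "relative_amplitude") -
              param_lookup(untreated, mutant, "relative_amplitude"))
  beyond <- (pd > tolerances$phase_h & !is.na(pd)) |
    (rd > tolerances$relative_amplitude & !is.na(rd))
  reason <- rep("shared", nrow(tab))
  reason[ref_g > 0 & mut_g == 0] <- "loss"
  altered <- ref_g > 0 & mut_g > 0 & mut_g != ref_g
  reason[altered & beyond] <- "altered"
  reason[altered & !beyond] <- "split_below_tolerance"
  reason[ref_g == 0] <- "reference_not_rhythmic"
  reason[!is.na(tab$ambiguous) & tab$ambiguous] <- "ambiguous"
  reason[!tab$fittable] <- "unfittable"
  data.frame(feature_id = tab$feature_id,
             affected = reason %in% c("loss", "altered"),
             reason = reason, stringsAsFactors = FALSE)
}

#' Assemble per-feature rescue evidence from two selection runs
#'
#' Joins the untreated and treated selections on feature id and extracts
#' everything the rescue rules need: model structure (rhythm-group codes of
#' reference and mutant in each arm), the between-genotype peak-phase
#' distances and relative-amplitude gaps in each arm, and the ambiguity
#' flags. The rules themselves are applied by [rescue_categories()].
#'
#' @inheritParams is_affected
#' @param treated a `rhythm_selection` from the treated two-condition arm.
#' @param reference_treated,mutant_treated condition names in the treated
#'   arm; default to the treated arm's declared condition order
#'   (reference first).
#' @param tolerances a [rescue_tolerances()] list, forwarded to
#'   [is_affected()].
#' @return A data.frame with one row per shared feature.
#' @export
rescue_evidence <- function(untreated, treated, reference, mutant,
                            reference_treated = NULL, mutant_treated = NULL,
                            tolerances = rescue_tolerances()) {
  stopifnot(inherits(untreated, "rhythm_selection"),
            inherits(treated, "rhythm_selection"))
  if (is.null(reference_treated)) reference_treated <- treated$conditions[1]
  if (is.null(mutant_treated)) mutant_treated <- treated$conditions[2]
  for (cc in c(reference_treated, mutant_treated))
    if (!cc %in% treated$conditions)
      stop("condition '", cc, "' not present in the treated selection")
  ids <- intersect(untreated$table$feature_id, treated$table$feature_id)
  if (!length(ids)) stop("no shared feature ids between the two arms")
  iu <- match(ids, untreated$table$feature_id)
  it <- match(ids, treated$table$feature_id)
  aff <- is_affected(untreated, reference, mutant, tolerances = tolerances)

  pick <- function(sel, cond, col, idx) param_lookup(sel, cond, col)[idx]
  pd_u <- circular_phase_distance(
    pick(untreated, reference, "phase", iu),
    pick(untreated, mutant, "phase", iu), untreated$period)
  pd_t <- circular_phase_distance(
    pick(treated, reference_treated, "phase", it),
    pick(treated, mutant_treated, "phase", it), treated$period)
  rd_u <- abs(pick(untreated, reference, "relative_amplitude", iu) -
                pick(untreated, mutant, "relative_amplitude", iu))
  rd_t <- abs(pick(treated, reference_treated, "relative_amplitude", it) -
                pick(treated, mutant_treated, "relative_amplitude", it))

  data.frame(
    feature_id = ids,
    affected = aff$affected[iu],
    affected_reason = aff$reason[iu],
    untreated_label = untreated$table$best_model[iu],
    treated_label = treated$table$best_model[it],
    untreated_ambiguous = !untreated$table$fittable[iu] |
      untreated$table$ambiguous[iu],
    treated_ambiguous = !treated$table$fittable[it] |
      treated$table$ambiguous[it],
    u_ref_group = pick(untreated, reference, "group", iu),
    u_mut_group = pick(untreated, mutant, "group", iu),
    t_ref_group = pick(treated, reference_treated, "group", it),
    t_mut_group = pick(treated, mutant_treated, "group", it),
    phase_diff_untreated = pd_u,
    phase_diff_treated = pd_t,
    relamp_diff_untreated = rd_u,
    relamp_diff_treated = rd_t,
    stringsAsFactors = FALSE
  )
}

#' Apply the rescue decision rules to an evidence table
#'
#' Decision rules per feature:
#' \itemize{
#' \item not affected in the untreated arm (or untreated ambiguous /
#'   unfittable) — `not_applicable`;
#' \item treated assignment ambiguous or unfittable —
#'   `not_rescued_other` with an "ambiguous" note;
#' \item treated arm both-rhythmic with shared parameters (model D) —
#'   `rescued_full`;
#' \item treated arm both-rhythmic with distinct parameters (model E):
#'   `rescued_partial` when the untreated mutant was non-rhythmic, or when
#'   the phase distance or the relative-amplitude gap shrank by more than
#'   its tolerance; otherwise `not_rescued_Estar`;
#' \item any other treated assignment — `not_rescued_other`.
#' }
#'
#' @param evidence a data.frame from [rescue_evidence()].
#' @param tolerances a [rescue_tolerances()] list.
#' @return `evidence` with `category` and `note` columns appended;
#'   class `rescue_calls`.
#' @export
rescue_categories <- function(evidence, tolerances = rescue_tolerances()) {
  ev <- evidence
  n <- nrow(ev)
  category <- rep("not_rescued_other", n)
  note <- rep("", n)

  t_shared <- ev$t_ref_group > 0 & ev$t_mut_group > 0 &
    ev$t_ref_group == ev$t_mut_group
  t_distinct <- ev$t_ref_group > 0 & ev$t_mut_group > 0 &
    ev$t_ref_group != ev$t_mut_group
  t_shared[is.na(t_shared)] <- FALSE
  t_distinct[is.na(t_distinct)] <- FALSE

  phase_reduced <- (ev$phase_diff_untreated - ev$phase_diff_treated) >
    tolerances$phase_h
  amp_reduced <- (ev$relamp_diff_untreated - ev$relamp_diff_treated) >
    tolerances$relative_amplitude
  reduced <- (phase_reduced & !is.na(phase_reduced)) |
    (amp_reduced & !is.na(amp_reduced))

  category[t_shared] <- "rescued_full"
  from_loss <- ev$u_mut_group == 0
  category[t_distinct & (from_loss | reduced)] <- "rescued_partial"
  category[t_distinct & !from_loss & !reduced] <- "not_rescued_Estar"
  note[t_distinct & from_loss] <- "rhythm restored with residual difference"
  note[t_distinct & !from_loss & reduced] <- "phase or amplitude gap reduced"
  note[t_distinct & !from_loss & !reduced] <- "no reduction of differences"

  tr_amb <- ev$treated_ambiguous
  tr_amb[is.na(tr_amb)] <- TRUE
  category[tr_amb] <- "not_rescued_other"
  note[tr_amb] <- "treated assignment ambiguous or unfittable"

  not_app <- !ev$affected
  category[not_app] <- "not_applicable"
  note[not_app] <- ev$affected_reason[not_app]

  ev$category <- factor(category, levels = RESCUE_CATEGORIES)
  ev$note <- note
  class(ev) <- c("rescue_calls", "data.frame")
  ev
}

#' Classify rescue status of every feature
#'
#' Convenience wrapper: [rescue_evidence()] followed by
#' [rescue_categories()].
#'
#' @inheritParams rescue_evidence
#' @param tolerances a [rescue_tolerances()] list.
#' @return A `rescue_calls` data.frame (evidence columns plus `category`
#'   and `note`).
#' @export
classify_rescue <- function(untreated, treated, reference, mutant,
                            reference_treated = NULL, mutant_treated = NULL,
                            tolerances = rescue_tolerances()) {
  ev <- rescue_evidence(untreated, treated, reference, mutant,
                        reference_treated, mutant_treated,
                        tolerances = tolerances)
  rescue_categories(ev, tolerances)
}

#' Summarize rescue calls, optionally per feature set
#'
#' Fractions are computed over the applicable features: confidently
#' affected in the untreated arm and with a confident treated assignment
#' (features ambiguous in either arm are excluded from the denominator and
#' reported in `n_excluded_ambiguous`). `rescued_fraction` is the share of
#' applicable features called `rescued_full` or `rescued_partial`. Feature
#' sets with no applicable members are dropped with a warning.
#'
#' @param calls a `rescue_calls` data.frame.
#' @param feature_sets optional: a data.frame with columns `set_id` and
#'   `feature_id`, or a named list of feature-id vectors.
#' @return A data.frame with one row per set (plus the row `all`).
#' @export
rescue_summary <- function(calls, feature_sets = NULL) {
  stopifnot(inherits(calls, "rescue_calls") || is.data.frame(calls))
  sets <- list(all = calls$feature_id)
  if (!is.null(feature_sets)) {
    if (is.data.frame(feature_sets)) {
      stopifnot(all(c("set_id", "feature_id") %in% names(feature_sets)))
      sets <- c(sets, split(as.character(feature_sets$feature_id),
                            feature_sets$set_id))
    } else if (is.list(feature_sets) && !is.null(names(feature_sets))) {
      sets <- c(sets, feature_sets)
    } else stop("'feature_sets' must be a data.frame or a named list")
  }
  tr_amb <- if ("treated_ambiguous" %in% names(calls))
    calls$treated_ambiguous & !is.na(calls$treated_ambiguous)
  else rep(FALSE, nrow(calls))
  rows <- lapply(names(sets), function(sid) {
    in_set <- calls$feature_id %in% sets[[sid]]
    sub <- calls[in_set & !tr_amb, ]
    app <- sub[sub$category != "not_applicable", ]
    if (sid != "all" && nrow(app) == 0) {
      warning("feature set '", sid, "' has no applicable features; omitted")
      return(NULL)
    }
    counts <- table(factor(app$category,
                           levels = setdiff(RESCUE_CATEGORIES,
                                            "not_applicable")))
    n_app <- nrow(app)
    out <- data.frame(set_id = sid, n_features = sum(in_set),
                      n_applicable = n_app,
                      n_excluded_ambiguous = sum(in_set & tr_amb),
                      stringsAsFactors = FALSE)
    for (cat in names(counts)) {
      out[[paste0("n_", cat)]] <- as.integer(counts[[cat]])
      out[[paste0("frac_", cat)]] <-
        if (n_app > 0) counts[[cat]] / n_app else NA_real_
    }
    out$rescued_fraction <- if (n_app > 0)
      (counts[["rescued_full"]] + counts[["rescued_partial"]]) / n_app
    else NA_real_
    out
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}
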