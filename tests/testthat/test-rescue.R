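# an evidence row as produced by rescue_evidence(), for driving the
# decision rules directly
ev_row <- function(affected = TRUE, reason = "altered",
                   u_ref = 1, u_mut = 2, t_ref = 1, t_mut = 2,
                   pd_u = 5, pd_t = 5, rd_u = 0.2, rd_t = 0.2,
                   t_amb = FALSE) {
  data.frame(feature_id = "f", affected = affected,
             affected_reason = reason,
             untreated_label = "u", treated_label = "t",
             untreated_ambiguous = FALSE, treated_ambiguous = t_amb,
             u_ref_group = u_ref, u_mut_group = u_mut,
             t_ref_group = t_ref, t_mut_group = t_mut,
             phase_diff_untreated = pd_u, phase_diff_treated = pd_t,
             relamp_diff_untreated = rd_u, relamp_diff_treated = rd_t,
             stringsAsFactors = FALSE)
}

cat_of <- function(ev) as.character(rescue_categories(ev)$category)

test_that("the rescue decision rules cover every branch", {
  # treated both-rhythmic shared (model D) -> full rescue
  expect_equal(cat_of(ev_row(u_mut = 0, t_mut = 1)), "rescued_full")
  expect_equal(cat_of(ev_row(t_mut = 1, pd_t = NA)), "rescued_full")
  # mutant rhythm restored but distinct (model E) after untreated loss
  expect_equal(cat_of(ev_row(u_mut = 0, pd_u = NA)), "rescued_partial")
  # altered untreated + treated E with clearly reduced phase gap
  expect_equal(cat_of(ev_row(pd_u = 5, pd_t = 2)), "rescued_partial")
  # reduction below tolerance does not count
  expect_equal(cat_of(ev_row(pd_u = 5, pd_t = 4.8)), "not_rescued_Estar")
  # unchanged differences -> E*
  expect_equal(cat_of(ev_row()), "not_rescued_Estar")
  # amplitude-gap reduction alone suffices (the rule is an OR)
  expect_equal(cat_of(ev_row(rd_u = 0.3, rd_t = 0.1)), "rescued_partial")
  # treated mutant still flat -> not rescued
  expect_equal(cat_of(ev_row(t_mut = 0, pd_t = NA)), "not_rescued_other")
  # ambiguous treated assignment -> not rescued, with a note
  amb <- rescue_categories(ev_row(t_amb = TRUE))
  expect_equal(as.character(amb$category), "not_rescued_other")
  expect_match(amb$note, "ambiguous")
  # unaffected features are out of scope
  expect_equal(cat_of(ev_row(affected = FALSE, reason = "shared")),
               "not_applicable")
})

test_that("custom tolerances change what counts as a reduction", {
  ev <- ev_row(pd_u = 5, pd_t = 3.5)
  expect_equal(cat_of(ev), "rescued_partial") # default 0.5 h
  strict <- rescue_categories(ev, rescue_tolerances(phase_h = 2))
  expect_equal(as.character(strict$category), "not_rescued_Estar")
})

test_that("shrinking the treated phase gap never moves a feature away from rescue", {
  rank <- c(rescued_full = 2, rescued_partial = 2, not_rescued_Estar = 0,
            not_rescued_other = 0)
  cats <- vapply(seq(5, 0, by = -0.5), function(pd_t)
    cat_of(ev_row(pd_u = 5, pd_t = pd_t)), character(1))
  expect_true(all(diff(rank[cats]) >= 0))
})

test_that("is_affected distinguishes loss, alteration and shared rhythms", {
  conds <- c("WT", "weak", "strong")
  sheet <- make_sheet(conds)
  t <- sheet$time
  curve <- function(phi) cos(2 * pi * (t - phi) / 24)
  rows <- list(
    loss = 7 + ifelse(sheet$condition == "strong", 0, curve(8)),
    shared = 7 + curve(8),
    altered = 7 + ifelse(sheet$condition == "strong", curve(16), curve(8)),
    allflat = rep(7, length(t)))
  set.seed(15)
  mat <- do.call(rbind, rows) + rnorm(4 * length(t), 0, 0.02)
  dimnames(mat) <- list(names(rows), sheet$sample_id)
  sel <- select_all(mat, sheet)
  aff <- is_affected(sel, "WT", "strong")
  expect_equal(aff$affected,
               c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(aff$reason,
               c("loss", "shared", "altered", "reference_not_rhythmic"))
  expect_error(is_affected(sel, "WT", "nosuch"), "not present")
})

test_that("every feature receives exactly one category", {
  study <- simulate_rescue_study(
    config_untreated = simulation_config(n_features = 80, seed = 5),
    rescue_fraction = 0.5, seed = 5)
  su <- select_all(study$untreated$matrix, study$untreated$sheet)
  st <- select_all(study$treated$matrix, study$treated$sheet)
  calls <- classify_rescue(su, st, study$reference, study$mutant)
  expect_equal(nrow(calls), 80)
  expect_false(any(is.na(calls$category)))
  counts <- table(calls$category)
  expect_equal(sum(counts), 80)
})

test_that("extreme planted rescue fractions are recovered at high SNR", {
  quiet <- simulation_config(n_features = 60, noise_sd = 0.02, seed = 71)
  for (rf in c(1, 0)) {
    study <- simulate_rescue_study(config_untreated = quiet,
                                   rescue_fraction = rf, seed = 71)
    su <- select_all(study$untreated$matrix, study$untreated$sheet)
    st <- select_all(study$treated$matrix, study$treated$sheet)
    calls <- classify_rescue(su, st, study$reference, study$mutant)
    est <- rescue_summary(calls)$rescued_fraction
    if (rf == 1) expect_gte(est, 0.95) else expect_lte(est, 0.05)
  }
})

test_that("rescue summaries partition counts across disjoint sets", {
  ev <- do.call(rbind, list(
    ev_row(u_mut = 0, t_mut = 1), ev_row(), ev_row(t_mut = 0, pd_t = NA),
    ev_row(affected = FALSE, reason = "shared")))
  ev$feature_id <- paste0("f", 1:4)
  calls <- rescue_categories(ev)
  sets <- data.frame(set_id = c("s1", "s1", "s2", "s2"),
                     feature_id = paste0("f", 1:4))
  sm <- rescue_summary(calls, sets)
  all_row <- sm[sm$set_id == "all", ]
  expect_equal(all_row$n_applicable, 3)
  expect_equal(all_row$rescued_fraction, 1 / 3)
  expect_equal(sum(sm$n_applicable[sm$set_id != "all"]),
               all_row$n_applicable)
  # fractions over applicable features sum to one
  frac_cols <- grep("^frac_", names(sm), value = TRUE)
  expect_equal(sum(all_row[, frac_cols]), 1)
  expect_warning(
    rescue_summary(calls, list(empty = "nonexistent_feature")),
    "no applicable")
})
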