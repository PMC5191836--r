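test_that("Schwarz weights normalize, favour the minimum BIC, and are stable", {
  expect_equal(schwarz_weights(rep(3, 5)), rep(0.2, 5))
  expect_equal(schwarz_weights(c(0, 2 * log(9))), c(0.9, 0.1))
  expect_equal(schwarz_weights(42), 1)
  # huge common offsets must not overflow
  w <- schwarz_weights(c(1e6, 1e6 + 2, 1e6 + 50))
  expect_equal(sum(w), 1)
  expect_equal(which.max(w), 1L)
  set.seed(5)
  for (i in 1:50) {
    b <- rnorm(sample(2:15, 1), sd = 10^sample(0:3, 1))
    w <- schwarz_weights(b)
    expect_equal(sum(w), 1, tolerance = 1e-9)
    expect_equal(which.max(w), which.min(b))
  }
  expect_error(schwarz_weights(c(NA_real_, Inf)), "non-finite")
})

test_that("assign_model applies the threshold and breaks ties to simpler models", {
  a <- assign_model(c(0.6, 0.4), 0.4)
  expect_equal(a$best_index, 1L)
  expect_false(a$ambiguous)
  expect_true(assign_model(rep(0.25, 4), 0.3)$ambiguous)
  expect_equal(assign_model(c(0.5, 0.5), 0.3)$best_index, 1L)
  expect_equal(assign_model(c(0.2, 0.8), 0.3)$threshold_used, 0.3)
})

test_that("default confidence thresholds track the number of conditions", {
  expect_equal(default_bicw_threshold(2), 0.3)
  expect_equal(default_bicw_threshold(3), 0.5)
  expect_equal(default_bicw_threshold(5), 0.5)
})

test_that("select_all recovers a planted shared rhythm in most features", {
  conds <- c("WT", "weak", "strong")
  lab <- spec_label(c(1, 1, 1), conds)
  cfg <- simulation_config(n_features = 150, seed = 202,
                           model_mix = stats::setNames(1, lab))
  sim <- simulate_matrix(cfg)
  sel <- select_all(sim$matrix, sim$sheet)
  tab <- sel$table
  ok <- tab$fittable & !tab$ambiguous
  expect_gte(mean(tab$best_model[ok] == lab), 0.9)
  expect_equal(tab$threshold_used[1], 0.5)
  # weights rows are proper distributions
  expect_equal(unname(rowSums(sel$weights)), rep(1, nrow(tab)),
               tolerance = 1e-9)
})

test_that("constant features always land on the flat model", {
  sheet <- make_sheet(c("a", "b"))
  mat <- matrix(5, 6, nrow(sheet),
                dimnames = list(paste0("f", 1:6), sheet$sample_id))
  sel <- select_all(mat, sheet)
  expect_true(all(sel$table$best_model == spec_label(c(0, 0), c("a", "b"))))
  expect_false(any(sel$table$ambiguous))
})

test_that("feature order only permutes output rows", {
  sheet <- make_sheet(c("a", "b"))
  set.seed(31)
  mat <- matrix(rnorm(10 * nrow(sheet), 6), 10,
                dimnames = list(paste0("f", 1:10), sheet$sample_id))
  sel1 <- select_all(mat, sheet)
  perm <- sample(10)
  sel2 <- select_all(mat[perm, ], sheet)
  reord <- match(sel1$table$feature_id, sel2$table$feature_id)
  expect_equal(sel2$table$best_model[reord], sel1$table$best_model)
  expect_equal(sel2$table$best_weight[reord], sel1$table$best_weight,
               tolerance = 1e-12)
})

test_that("false-rhythm calls on flat noise decrease with the threshold", {
  sheet <- make_sheet(c("a", "b"))
  set.seed(77)
  mat <- matrix(rnorm(400 * nrow(sheet), 7, 0.1), 400,
                dimnames = list(paste0("f", 1:400), sheet$sample_id))
  sel <- select_all(mat, sheet)
  flat_lab <- spec_label(c(0, 0), c("a", "b"))
  frac_rhythmic <- vapply(c(0.3, 0.5, 0.7, 0.9), function(thr)
    mean(sel$table$best_model != flat_lab & sel$table$best_weight >= thr),
    numeric(1))
  expect_true(all(diff(frac_rhythmic) <= 0))
  expect_lt(frac_rhythmic[length(frac_rhythmic)], frac_rhythmic[1] + 1e-12)
})

test_that("noise-free data give the generating model full confidence", {
  conds <- c("a", "b")
  lab <- spec_label(c(1, 2), conds)
  cfg <- simulation_config(conditions = conds, n_features = 5,
                           noise_sd = 0, seed = 9,
                           model_mix = stats::setNames(1, lab))
  sim <- simulate_matrix(cfg)
  sel <- select_all(sim$matrix, sim$sheet)
  expect_true(all(sel$table$best_model == lab))
  expect_true(all(sel$table$best_weight > 0.999))
})

test_that("schema mismatches raise errors instead of silent misalignment", {
  sheet <- make_sheet(c("a", "b"))
  mat <- matrix(rnorm(2 * nrow(sheet)), 2)
  rownames(mat) <- c("f1", "f2")
  colnames(mat) <- paste0("bogus", seq_len(ncol(mat)))
  expect_error(select_all(mat, sheet), "samples in sheet")
  mat2 <- matrix(rnorm(4), 2)
  expect_error(select_all(mat2, sheet), "columns")
})
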