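test_that("design matrices have the documented column layout", {
  sheet <- make_sheet(c("a", "b"))
  expect_equal(colnames(build_design(sheet, c(0, 0))), c("mu.a", "mu.b"))
  expect_equal(colnames(build_design(sheet, c(1, 1))),
               c("mu.a", "mu.b", "cos.g1", "sin.g1"))
  sheet3 <- make_sheet(c("a", "b", "c"))
  X <- build_design(sheet3, c(1, 1, 0))
  expect_equal(ncol(X), 5)
  # harmonic columns active only in member conditions
  expect_true(all(X[sheet3$condition == "c", c("cos.g1", "sin.g1")] == 0))
  expect_equal(ncol(build_design(sheet3, c(1, 1, 0),
                                 with_trend = "per_condition")), 8)
  expect_equal(ncol(build_design(sheet3, c(1, 1, 0),
                                 with_trend = "shared")), 6)
  expect_error(build_design(sheet, c(1, 1, 0)), "conditions")
})

test_that("noiseless harmonic data are interpolated exactly", {
  sheet <- make_sheet("a", reps = 2)
  y <- 5 + 2 * cos(2 * pi * sheet$time / 24)
  fit <- fit_feature(y, sheet, 1L)
  expect_true(fit$ok)
  expect_equal(unname(fit$mu), 5, tolerance = 1e-10)
  expect_equal(unname(fit$alpha), 2, tolerance = 1e-10)
  expect_equal(unname(fit$beta), 0, tolerance = 1e-10)
  expect_lt(fit$rss, 1e-18)
  expect_true(is.finite(fit$bic)) # RSS floor keeps the BIC finite
})

test_that("flat fit reduces to the mean and nested models lower the RSS", {
  sheet <- sample_sheet(paste0("s", 1:4), rep("a", 4), c(0, 6, 12, 18))
  y <- c(1, 2, 3, 4)
  flat <- fit_feature(y, sheet, 0L)
  expect_equal(unname(flat$mu), 2.5)
  expect_equal(flat$rss, 5)
  rhythmic <- fit_feature(y, sheet, 1L)
  expect_lt(rhythmic$rss, flat$rss)
})

test_that("bic_score evaluates n*ln(RSS/n) + k*ln(n) with an RSS floor", {
  expect_equal(bic_score(8, 8, 0), 0)     # rss = n, k = 0
  expect_equal(bic_score(2, 8, 3), 8 * log(0.25) + 3 * log(8))
  expect_equal(bic_score(2, 8, 3), -4.852, tolerance = 1e-3)
  expect_true(is.finite(bic_score(0, 8, 3)))
})

test_that("RSS is monotone over nested specs", {
  sheet <- make_sheet(c("a", "b"), reps = 2)
  set.seed(42)
  y <- rnorm(nrow(sheet), 6, 1)
  specs <- enumerate_models(2)
  rss <- vapply(specs, function(s) fit_feature(y, sheet, s)$rss, numeric(1))
  # flat vs each rhythmic model, and sharing vs distinct coefficients
  expect_true(all(rss[-1] <= rss[1] + 1e-12))
  shared <- which(vapply(specs, function(s) identical(s, c(1L, 1L)),
                         logical(1)))
  distinct <- which(vapply(specs, function(s) identical(s, c(1L, 2L)),
                           logical(1)))
  expect_lte(rss[distinct], rss[shared] + 1e-12)
})

test_that("fits agree with a normal-equations oracle on random instances", {
  set.seed(99)
  for (i in 1:60) {
    C <- sample(1:3, 1)
    conds <- letters[seq_len(C)]
    sheet <- make_sheet(conds, times = c(2, 8, 14, 20),
                        reps = sample(1:2, 1))
    specs <- enumerate_models(C)
    spec <- specs[[sample(length(specs), 1)]]
    y <- rnorm(nrow(sheet), 5, 1)
    fit <- fit_feature(y, sheet, spec)
    X <- build_design(sheet, spec)
    oracle <- normal_eq_fit(X, y)
    expect_equal(fit$rss, oracle$rss, tolerance = 1e-8)
    expect_equal(unname(fit$coefficients), unname(oracle$beta),
                 tolerance = 1e-8)
  }
})

test_that("fits are invariant to row order and signal shifts", {
  sheet <- make_sheet(c("a", "b"))
  set.seed(7)
  y <- rnorm(nrow(sheet), 6, 0.5)
  fit <- fit_feature(y, sheet, c(1L, 2L))
  perm <- sample(nrow(sheet))
  sheet_p <- sample_sheet(sheet$sample_id[perm], sheet$condition[perm],
                          sheet$time[perm], sheet$replicate[perm],
                          conditions = c("a", "b"))
  fit_p <- fit_feature(y[perm], sheet_p, c(1L, 2L))
  expect_equal(fit_p$rss, fit$rss, tolerance = 1e-10)
  expect_equal(fit_p$alpha, fit$alpha, tolerance = 1e-10)
  shifted <- fit_feature(y + 3, sheet, c(1L, 2L))
  expect_equal(unname(shifted$mu), unname(fit$mu) + 3, tolerance = 1e-10)
  expect_equal(shifted$alpha, fit$alpha, tolerance = 1e-10)
  expect_equal(shifted$rss, fit$rss, tolerance = 1e-10)
})

test_that("missing values shrink n and hopeless designs are flagged", {
  sheet <- make_sheet("a", reps = 2)
  y <- 5 + cos(2 * pi * sheet$time / 24) + 0.01 * seq_len(nrow(sheet))
  y[c(1, 5)] <- NA
  fit <- fit_feature(y, sheet, 1L)
  expect_true(fit$ok)
  expect_equal(fit$n, 6)
  # too few observations for the parameter count: flagged, not an error
  y2 <- y
  y2[2:7] <- NA
  flagged <- fit_feature(y2, sheet, 1L)
  expect_false(flagged$ok)
  expect_true(is.na(flagged$bic))
})

test_that("the BIC sample size follows the requested convention", {
  sheet <- make_sheet(c("a", "b"), reps = 3) # 8 cells, 24 observations
  y <- rnorm(nrow(sheet), 5, 0.3)
  tp <- fit_feature(y, sheet, c(1L, 1L), bic_n = "timepoints")
  ob <- fit_feature(y, sheet, c(1L, 1L), bic_n = "observations")
  expect_equal(tp$n_bic, 8)
  expect_equal(ob$n_bic, 24)
  expect_equal(tp$bic, bic_score(tp$rss, 8, tp$k,
                                 diffrhythm:::rss_floor_for(y, 24)))
  expect_equal(ob$bic, bic_score(ob$rss, 24, ob$k,
                                 diffrhythm:::rss_floor_for(y, 24)))
})
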