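test_that("the generator round-trips noiselessly through the fitting layer", {
  conds <- c("WT", "weak", "strong")
  lab <- spec_label(c(1, 1, 2), conds)
  cfg <- simulation_config(n_features = 3, noise_sd = 0, seed = 19,
                           amplitude_range = c(0.5, 3),
                           model_mix = stats::setNames(1, lab))
  sim <- simulate_matrix(cfg)
  for (f in seq_len(3)) {
    fit <- fit_feature(sim$matrix[f, ], sim$sheet, c(1L, 1L, 2L))
    for (cc in conds) {
      g <- sim$truth[[paste0("group.", cc)]][f]
      expect_equal(unname(amplitude(fit$alpha[g], fit$beta[g])),
                   sim$truth[[paste0("amplitude.", cc)]][f],
                   tolerance = 1e-8)
      expect_equal(unname(phase_hours(fit$alpha[g], fit$beta[g])),
                   sim$truth[[paste0("phase.", cc)]][f],
                   tolerance = 1e-8)
      expect_equal(unname(fit$mu[cc]), sim$truth[[paste0("mu.", cc)]][f],
                   tolerance = 1e-8)
    }
  }
})

test_that("identical seeds give identical data, down to written bytes", {
  cfg <- simulation_config(n_features = 10, seed = 123)
  sim1 <- simulate_matrix(cfg)
  sim2 <- simulate_matrix(cfg)
  expect_identical(sim1$matrix, sim2$matrix)
  expect_identical(sim1$truth, sim2$truth)
  f1 <- tempfile(); f2 <- tempfile()
  write_matrix(sim1$matrix, f1)
  write_matrix(sim2$matrix, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  sim3 <- simulate_matrix(simulation_config(n_features = 10, seed = 124))
  expect_false(identical(sim1$matrix, sim3$matrix))
  expect_error(simulation_config(n_features = 10), "seed")
})

test_that("noisy replicate means converge to the deterministic curve", {
  reps <- 4000 # ~1.2e4 observations over three time points
  cfg <- simulation_config(conditions = "a", time_points = c(3, 11, 19),
                           replicates = reps, n_features = 1,
                           model_mix = stats::setNames(1, spec_label(1, "a")),
                           seed = 909)
  sim <- simulate_matrix(cfg)
  tol <- 3 * cfg$noise_sd / sqrt(reps)
  for (tt in cfg$time_points) {
    idx <- sim$sheet$time == tt
    expected <- sim$truth$mu.a + sim$truth$amplitude.a / 2 *
      cos(2 * pi * (tt - sim$truth$phase.a) / 24)
    expect_equal(mean(sim$matrix[1, idx]), expected, tolerance = tol)
  }
})

test_that("flat features show no phase structure across the cohort", {
  conds <- "a"
  cfg <- simulation_config(conditions = conds, n_features = 300,
                           model_mix = stats::setNames(1, spec_label(0, "a")),
                           seed = 31)
  sim <- simulate_matrix(cfg)
  # force-fit the rhythmic model and inspect the fitted phases
  phases <- apply(sim$matrix, 1L, function(y) {
    fit <- fit_feature(y, sim$sheet, 1L)
    phase_hours(fit$alpha, fit$beta)
  })
  ang <- 2 * pi * phases / 24
  resultant <- sqrt(mean(cos(ang))^2 + mean(sin(ang))^2)
  expect_lt(resultant, 0.15) # uniform phases: resultant ~ 1/sqrt(n)
  # per-condition means track the generating baseline
  expect_equal(unname(rowMeans(sim$matrix)), sim$truth$mu.a,
               tolerance = 4 * cfg$noise_sd / sqrt(ncol(sim$matrix)) * 3)
})

test_that("rescue-study planting matches its declared truth labels", {
  study <- simulate_rescue_study(
    config_untreated = simulation_config(n_features = 300, seed = 77),
    rescue_fraction = 0.4, seed = 77)
  expect_equal(study$untreated$sheet$sample_id,
               colnames(study$untreated$matrix))
  expect_setequal(rownames(study$untreated$matrix),
                  rownames(study$treated$matrix))
  expect_equal(sort(unique(study$truth$category)),
               sort(c("not_applicable", "not_rescued_Estar",
                      "not_rescued_other", "rescued_full",
                      "rescued_partial")))
  expect_equal(study$truth$rescued,
               study$truth$category %in% c("rescued_full", "rescued_partial"))
  # planted proportions are near their multinomial expectations
  aff <- study$truth$category != "not_applicable"
  expect_equal(mean(aff), 0.6, tolerance = 0.1)
  expect_equal(mean(study$truth$rescued[aff]), 0.4, tolerance = 0.1)
})
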