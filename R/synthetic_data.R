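# Ground-truth synthetic data emulating the study design: a handful of
# Zeitgeber time points over 24 h, a few replicates, several conditions,
# each feature following one enumerated rhythmicity model. Signals are
# generated on the log2 scale as
#   y = mu_c + (A_g / 2) * cos(2 pi (t - phi_g) / 24) [+ gamma_c t] + noise,
# so the "amplitude" recorded in truth tables is the peak-trough amplitude,
# matching amplitude()/phase_hours() conventions exactly.

#' Configuration for the synthetic time-course generator
#'
#' Defaults emulate the transcriptome arm of the zebrafish glucocorticoid
#' study design: three conditions (wild-type and two mutant alleles),
#' four Zeitgeber time points over 24 h, duplicate samples, peak-trough
#' amplitude 2 on the log2 scale and Gaussian noise with sd 0.1. Distinct
#' rhythm groups within one feature are drawn with peak phases at least
#' `min_phase_sep` hours apart so that "distinct parameters" is a
#' recoverable truth rather than a coin flip.
#'
#' @param conditions condition labels.
#' @param time_points Zeitgeber sampling times in hours.
#' @param replicates replicates per condition and time point.
#' @param n_features number of features to simulate.
#' @param model_mix probability per candidate model (named by model label
#'   or aligned to enumeration order); default uniform over all models.
#' @param amplitude_range range of peak-trough amplitudes (log2 units).
#' @param phase_range phases are drawn uniformly from this interval (h).
#' @param baseline_range range of per-condition mean levels (log2 units).
#' @param noise_sd Gaussian noise standard deviation (log2 units).
#' @param trend when `TRUE` (metabolite mode) add a per-condition linear
#'   drift with slope drawn from `trend_slope_range` (log2 units per hour).
#' @param trend_slope_range slope range for the drift term.
#' @param min_phase_sep minimal circular separation between the peak
#'   phases of distinct rhythm groups within one feature (hours).
#' @param period oscillation period (hours).
#' @param seed integer seed; mandatory, all randomness flows from it.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(conditions = c("WT", "weak", "strong"),
                              time_points = c(3, 9, 15, 21),
                              replicates = 2,
                              n_features = 1000,
                              model_mix = NULL,
                              amplitude_range = c(2, 2),
                              phase_range = c(0, 24),
                              baseline_range = c(6, 10),
                              noise_sd = 0.1,
                              trend = FALSE,
                              trend_slope_range = c(-0.08, -0.02),
                              min_phase_sep = 4,
                              period = 24,
                              seed) {
  if (missing(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' is mandatory for reproducible simulation")
  stopifnot(length(conditions) >= 1, length(time_points) >= 3,
            replicates >= 1, n_features >= 1, noise_sd >= 0,
            length(amplitude_range) == 2, length(baseline_range) == 2,
            min_phase_sep >= 0, period > 0)
  cfg <- list(conditions = as.character(conditions),
              time_points = as.numeric(time_points),
              replicates = as.integer(replicates),
              n_features = as.integer(n_features),
              model_mix = model_mix,
              amplitude_range = as.numeric(amplitude_range),
              phase_range = as.numeric(phase_range),
              baseline_range = as.numeric(baseline_range),
              noise_sd = as.numeric(noise_sd),
              trend = isTRUE(trend),
              trend_slope_range = as.numeric(trend_slope_range),
              min_phase_sep = as.numeric(min_phase_sep),
              period = as.numeric(period),
              seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  cfg
}

#' Configuration emulating the metabolite arm
#'
#' Four conditions (genotype x treatment), five time points over 24 h,
#' triplicates, a declining per-condition drift, and a smaller feature
#' count, as typical for targeted metabolite panels.
#'
#' @param ... overrides passed to [simulation_config()].
#' @param seed integer seed (mandatory).
#' @return A `simulation_config`.
#' @export
metabolite_config <- function(..., seed) {
  defaults <- list(conditions = c("WT", "strong", "WT_DEX", "strong_DEX"),
                   time_points = c(3, 9, 15, 21, 27),
                   replicates = 3, n_features = 40, trend = TRUE,
                   seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}

sheet_from_config <- function(cfg) {
  grid <- expand.grid(replicate = seq_len(cfg$replicates),
                      time = cfg$time_points,
                      condition = cfg$conditions,
                      stringsAsFactors = FALSE)
  sample_sheet(
    sample_id = sprintf("%s_ZT%g_r%d", grid$condition, grid$time,
                        grid$replicate),
    condition = grid$condition, time = grid$time,
    replicate = grid$replicate, conditions = cfg$conditions)
}

# phases with pairwise circular separation >= min_sep
draw_phases <- function(G, phase_range, min_sep, period) {
  ph <- numeric(G)
  for (g in seq_len(G)) {
    for (try in 1:1000) {
      cand <- stats::runif(1, phase_range[1], phase_range[2]) %% period
      if (g == 1 || all(circular_phase_distance(cand, ph[seq_len(g - 1)],
                                                period) >= min_sep)) {
        ph[g] <- cand
        break
      }
      if (try == 1000) stop("cannot place ", G, " phases ", min_sep,
                            " h apart in a ", period, " h cycle")
    }
  }
  ph
}

# deterministic curve for one feature: per-condition mean, peak-trough
# amplitude, peak phase and slope (vectors named by condition)
curve_values <- function(sheet, period, mu, amp, phase, slope = NULL) {
  ci <- match(sheet$condition, names(mu))
  t <- sheet$time
  ph <- ifelse(is.na(phase[ci]), 0, phase[ci])
  y <- mu[ci] + (amp[ci] / 2) * cos(2 * pi * (t - ph) / period)
  if (!is.null(slope)) y <- y + slope[ci] * t
  unname(y)
}

#' Simulate an expression or metabolite matrix with known ground truth
#'
#' Each feature is assigned a candidate model drawn from `model_mix`;
#' rhythm-group amplitudes, phases, per-condition baselines (and, in trend
#' mode, drift slopes) are drawn from the configured ranges, and Gaussian
#' noise is added on the log2 scale. The same seed always yields the same
#' output.
#'
#' @param config a [simulation_config()].
#' @return A list with `matrix` (features x samples), `sheet`
#'   (a [sample_sheet()]) and `truth` — a data.frame with the generating
#'   model label and, per condition, the group code, baseline, peak-trough
#'   amplitude, peak phase and drift slope.
#' @export
simulate_matrix <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  set.seed(cfg$seed)
  sheet <- sheet_from_config(cfg)
  C <- length(cfg$conditions)
  models <- enumerate_models(C)
  labels <- vapply(models, spec_label, character(1), cfg$conditions)
  mix <- cfg$model_mix
  if (is.null(mix)) {
    mix <- rep(1 / length(models), length(models))
  } else if (!is.null(names(mix))) {
    if (!all(names(mix) %in% labels))
      stop("model_mix names must be model labels; unknown: ",
           paste(setdiff(names(mix), labels), collapse = ", "))
    full <- stats::setNames(numeric(length(models)), labels)
    full[names(mix)] <- mix
    mix <- unname(full)
  }
  if (length(mix) != length(models) || any(mix < 0) ||
      abs(sum(mix) - 1) > 1e-8)
    stop("model_mix must be probabilities over the candidate models summing to 1")

  nF <- cfg$n_features
  midx <- sample.int(length(models), nF, replace = TRUE, prob = mix)
  mat <- matrix(NA_real_, nF, nrow(sheet),
                dimnames = list(sprintf("feature%04d", seq_len(nF)),
                                sheet$sample_id))
  truth_rows <- vector("list", nF)
  for (f in seq_len(nF)) {
    spec <- models[[midx[f]]]
    G <- n_groups(spec)
    mu <- stats::setNames(stats::runif(C, cfg$baseline_range[1],
                                       cfg$baseline_range[2]),
                          cfg$conditions)
    gamp <- stats::runif(max(G, 1), cfg$amplitude_range[1],
                         cfg$amplitude_range[2])
    gphase <- draw_phases(max(G, 1), cfg$phase_range, cfg$min_phase_sep,
                          cfg$period)
    amp <- ifelse(spec > 0, gamp[pmax(spec, 1)], 0)
    phase <- ifelse(spec > 0, gphase[pmax(spec, 1)], NA_real_)
    names(amp) <- names(phase) <- cfg$conditions
    slope <- if (cfg$trend)
      stats::setNames(stats::runif(C, cfg$trend_slope_range[1],
                                   cfg$trend_slope_range[2]),
                      cfg$conditions)
    else NULL
    y <- curve_values(sheet, cfg$period, mu, amp, phase, slope)
    mat[f, ] <- y + stats::rnorm(nrow(sheet), 0, cfg$noise_sd)
    tr <- data.frame(feature_id = rownames(mat)[f], model = labels[midx[f]],
                     stringsAsFactors = FALSE)
    for (ci in seq_len(C)) {
      cc <- cfg$conditions[ci]
      tr[[paste0("group.", cc)]] <- spec[ci]
      tr[[paste0("mu.", cc)]] <- unname(mu[ci])
      tr[[paste0("amplitude.", cc)]] <- unname(amp[ci])
      tr[[paste0("phase.", cc)]] <- unname(phase[ci])
      if (cfg$trend) tr[[paste0("trend.", cc)]] <- unname(slope[ci])
    }
    truth_rows[[f]] <- tr
  }
  list(matrix = mat, sheet = sheet, truth = do.call(rbind, truth_rows))
}

#' Simulate a paired untreated/treated rescue study with planted truth
#'
#' Generates two datasets sharing feature ids: an untreated arm with a
#' reference condition (first condition), a control mutant sharing the
#' reference rhythm, and an affected mutant (last condition); and a
#' treated two-condition arm (reference + treatment, affected mutant +
#' treatment). Each feature is planted as one of
#' \itemize{
#' \item `not_applicable` — rhythmic everywhere with shared parameters
#'   (nothing to rescue);
#' \item `rescued_full` — mutant rhythm lost or altered untreated, both
#'   genotypes share parameters under treatment;
#' \item `rescued_partial` — mutant rhythm lost untreated, both rhythmic
#'   under treatment but with distinct parameters;
#' \item `not_rescued_Estar` — mutant rhythm phase-shifted untreated, and
#'   the same shift persists unreduced under treatment;
#' \item `not_rescued_other` — mutant rhythm lost or altered untreated and
#'   still non-rhythmic under treatment.
#' }
#' Per-genotype baselines and, for the E* class, amplitudes and phase
#' offsets are reused across the two arms so that "no reduction of
#' differences" holds exactly in the noise-free signal.
#'
#' @param config_untreated,config_treated [simulation_config()]s for the
#'   two arms; defaults emulate the study design (conditions WT / weak /
#'   strong untreated and WT_DEX / strong_DEX treated). The single `seed`
#'   argument drives all randomness in both arms.
#' @param rescue_fraction fraction of affected features that are rescued.
#' @param seed integer seed.
#' @param affected_fraction fraction of features planted as affected.
#' @param prop_full among rescued features, fraction rescued fully
#'   (treated arm shared) rather than partially.
#' @param prop_estar among non-rescued features, fraction planted as E*
#'   (persistent divergent rhythm) rather than still non-rhythmic.
#' @return A list with `untreated` and `treated` (each `matrix` + `sheet`),
#'   and `truth` (feature_id, planted `category`, logical `rescued`,
#'   generating model labels per arm).
#' @export
simulate_rescue_study <- function(config_untreated = NULL,
                                  config_treated = NULL,
                                  rescue_fraction = 0.4, seed,
                                  affected_fraction = 0.6,
                                  prop_full = 0.6, prop_estar = 0.3) {
  if (missing(seed)) stop("'seed' is mandatory")
  stopifnot(rescue_fraction >= 0, rescue_fraction <= 1,
            affected_fraction >= 0, affected_fraction <= 1)
  if (is.null(config_untreated))
    config_untreated <- simulation_config(seed = seed)
  if (is.null(config_treated))
    config_treated <- simulation_config(
      conditions = c("WT_DEX", "strong_DEX"),
      time_points = config_untreated$time_points,
      replicates = config_untreated$replicates,
      n_features = config_untreated$n_features,
      amplitude_range = config_untreated$amplitude_range,
      baseline_range = config_untreated$baseline_range,
      noise_sd = config_untreated$noise_sd,
      min_phase_sep = config_untreated$min_phase_sep,
      period = config_untreated$period, seed = seed)
  cu <- config_untreated; ct <- config_treated
  if (cu$n_features != ct$n_features)
    stop("both arms must simulate the same number of features")
  if (length(cu$conditions) < 3 || length(ct$conditions) != 2)
    stop("rescue simulation needs >= 3 untreated and exactly 2 treated conditions")
  set.seed(seed)
  sheet_u <- sheet_from_config(cu)
  sheet_t <- sheet_from_config(ct)
  ref <- cu$conditions[1]
  mut <- cu$conditions[length(cu$conditions)]
  ctl <- setdiff(cu$conditions, c(ref, mut)) # control mutants track reference
  nF <- cu$n_features
  p <- c(not_applicable = 1 - affected_fraction,
         rescued_full = affected_fraction * rescue_fraction * prop_full,
         rescued_partial = affected_fraction * rescue_fraction * (1 - prop_full),
         not_rescued_Estar = affected_fraction * (1 - rescue_fraction) * prop_estar,
         not_rescued_other = affected_fraction * (1 - rescue_fraction) * (1 - prop_estar))
  category <- sample(names(p), nF, replace = TRUE, prob = p)

  ids <- sprintf("feature%04d", seq_len(nF))
  mat_u <- matrix(NA_real_, nF, nrow(sheet_u),
                  dimnames = list(ids, sheet_u$sample_id))
  mat_t <- matrix(NA_real_, nF, nrow(sheet_t),
                  dimnames = list(ids, sheet_t$sample_id))
  truth <- vector("list", nF)
  for (f in seq_len(nF)) {
    cat_f <- category[f]
    mu_u <- stats::setNames(stats::runif(length(cu$conditions),
                                         cu$baseline_range[1],
                                         cu$baseline_range[2]),
                            cu$conditions)
    # treated arm keeps each genotype's baseline
    mu_t <- stats::setNames(mu_u[c(ref, mut)], ct$conditions)
    A <- stats::runif(1, cu$amplitude_range[1], cu$amplitude_range[2])
    A2 <- stats::runif(1, cu$amplitude_range[1], cu$amplitude_range[2])
    phi <- stats::runif(1, cu$phase_range[1], cu$phase_range[2]) %% cu$period
    delta <- sample(c(-1, 1), 1) *
      stats::runif(1, cu$min_phase_sep, cu$period / 2)
    phi2 <- (phi + delta) %% cu$period
    zero <- function(conds) stats::setNames(rep(0, length(conds)), conds)
    nap <- function(conds) stats::setNames(rep(NA_real_, length(conds)), conds)
    amp_u <- zero(cu$conditions); phase_u <- nap(cu$conditions)
    amp_t <- zero(ct$conditions); phase_t <- nap(ct$conditions)
    # reference (and control mutants) always rhythmic at (A, phi) untreated
    amp_u[c(ref, ctl)] <- A; phase_u[c(ref, ctl)] <- phi
    loss <- stats::runif(1) < 0.5 # for categories allowing either origin
    u_model <- t_model <- ""
    if (cat_f == "not_applicable") {
      amp_u[mut] <- A; phase_u[mut] <- phi
      amp_t[] <- A; phase_t[] <- phi
      u_model <- "shared"; t_model <- "shared"
    } else if (cat_f == "rescued_full") {
      if (!loss) { amp_u[mut] <- A2; phase_u[mut] <- phi2 }
      amp_t[] <- A; phase_t[] <- phi
      u_model <- if (loss) "loss" else "altered"; t_model <- "shared"
    } else if (cat_f == "rescued_partial") {
      # mutant non-rhythmic untreated; treated both rhythmic, distinct
      amp_t[1] <- A; phase_t[1] <- phi
      amp_t[2] <- A2; phase_t[2] <- phi2
      u_model <- "loss"; t_model <- "distinct"
    } else if (cat_f == "not_rescued_Estar") {
      # same amplitudes and the same phase offset in both arms
      amp_u[mut] <- A2; phase_u[mut] <- phi2
      amp_t[1] <- A; phase_t[1] <- phi
      amp_t[2] <- A2; phase_t[2] <- phi2
      u_model <- "altered"; t_model <- "distinct"
    } else { # not_rescued_other: treated mutant still flat
      if (!loss) { amp_u[mut] <- A2; phase_u[mut] <- phi2 }
      amp_t[1] <- A; phase_t[1] <- phi
      u_model <- if (loss) "loss" else "altered"; t_model <- "mutant_flat"
    }
    mat_u[f, ] <- curve_values(sheet_u, cu$period, mu_u, amp_u, phase_u) +
      stats::rnorm(nrow(sheet_u), 0, cu$noise_sd)
    mat_t[f, ] <- curve_values(sheet_t, ct$period, mu_t, amp_t, phase_t) +
      stats::rnorm(nrow(sheet_t), 0, ct$noise_sd)
    truth[[f]] <- data.frame(
      feature_id = ids[f], category = cat_f,
      rescued = cat_f %in% c("rescued_full", "rescued_partial"),
      untreated_pattern = u_model, treated_pattern = t_model,
      stringsAsFactors = FALSE)
  }
  list(untreated = list(matrix = mat_u, sheet = sheet_u),
       treated = list(matrix = mat_t, sheet = sheet_t),
       truth = do.call(rbind, truth),
       reference = ref, mutant = mut,
       reference_treated = ct$conditions[1],
       mutant_treated = ct$conditions[2])
}
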