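# Harmonic regression core: design construction, per-feature OLS and BIC.
#
# The working model for the signal of one feature in condition c is
#   y(t) = mu_c + alpha_g cos(2 pi t / period) + beta_g sin(2 pi t / period)
#          [+ gamma_c t] + noise,
# where g is the rhythm group condition c belongs to under a given model
# spec. Per-condition means are free parameters in every candidate model;
# the candidates differ only in which conditions carry a harmonic and how
# the (alpha, beta) pairs are shared. The optional linear term gamma_c t
# absorbs a non-periodic drift (used for metabolite series).

normalize_trend <- function(with_trend) {
  if (is.logical(with_trend))
    return(if (isTRUE(with_trend)) "per_condition" else "none")
  match.arg(with_trend, c("none", "shared", "per_condition"))
}

#' Build the design matrix implied by a model spec
#'
#' Column layout (stable and documented): one mean indicator per condition
#' in declared condition order (`mu.<condition>`), then for each rhythm
#' group `g` a cosine and a sine column active only in that group's
#' conditions (`cos.g<g>`, `sin.g<g>`), then — when a trend is requested —
#' either a single shared time column (`trend`) or one time column per
#' condition (`trend.<condition>`).
#'
#' @param sheet a [sample_sheet()].
#' @param spec integer model assignment (see [enumerate_models()]); its
#'   length must equal the number of declared conditions.
#' @param period oscillation period in hours (default 24).
#' @param with_trend `"none"`, `"shared"`, `"per_condition"`, or a logical
#'   (`TRUE` = per-condition trend).
#' @return A numeric design matrix with one row per sample.
#' @export
build_design <- function(sheet, spec, period = 24, with_trend = "none") {
  stopifnot(is.numeric(period), length(period) == 1L, period > 0)
  with_trend <- normalize_trend(with_trend)
  conds <- conditions_of(sheet)
  spec <- check_spec(spec)
  if (length(spec) != length(conds))
    stop("model spec has ", length(spec), " conditions but the sample sheet declares ",
         length(conds))
  fcond <- factor(sheet$condition, levels = conds)
  if (anyNA(fcond))
    stop("sample sheet contains conditions absent from the declared list")
  t <- sheet$time
  omega <- 2 * pi / period
  X <- sapply(conds, function(cc) as.numeric(fcond == cc))
  colnames(X) <- paste0("mu.", conds)
  G <- n_groups(spec)
  for (g in seq_len(G)) {
    member <- as.numeric(spec[as.integer(fcond)] == g)
    X <- cbind(X, member * cos(omega * t), member * sin(omega * t))
    colnames(X)[ncol(X) - 1:0] <- paste0(c("cos.g", "sin.g"), g)
  }
  if (with_trend == "shared") {
    X <- cbind(X, trend = t)
  } else if (with_trend == "per_condition") {
    Xt <- sapply(conds, function(cc) as.numeric(fcond == cc) * t)
    colnames(Xt) <- paste0("trend.", conds)
    X <- cbind(X, Xt)
  }
  rownames(X) <- sheet$sample_id
  X
}

#' Bayesian information criterion from a residual sum of squares
#'
#' Computes `n * log(RSS/n) + k * log(n)`, the BIC of a Gaussian linear
#' model up to an additive constant shared by all candidates. The fitting
#' routines pass as `n` the number of time points entering the fit — the
#' distinct condition-time cells, replicates being repeated measures at a
#' time point — or, when `bic_n = "observations"` is requested, every
#' replicate measurement; see the methods vignette for the trade-off.
#' A floor on the RSS (default `1e-12`) keeps the criterion finite on
#' perfect fits; fitting routines in this package scale the floor as
#' `1e-12 * (n * var(y) + 1)` so that noiseless synthetic data remain
#' comparable across candidates.
#'
#' @param rss residual sum of squares (vectorized).
#' @param n number of observations used in the fit.
#' @param k number of free parameters.
#' @param rss_floor lower bound applied to `rss` before taking the log.
#' @return The BIC value(s).
#' @examples
#' bic_score(2, 8, 3) # 8*log(0.25) + 3*log(8)
#' @export
bic_score <- function(rss, n, k, rss_floor = 1e-12) {
  stopifnot(all(n > 0), all(rss >= 0 | is.na(rss)), all(k >= 0))
  n * log(pmax(rss, rss_floor) / n) + k * log(n)
}

rss_floor_for <- function(y, n) {
  v <- if (length(y) >= 2) stats::var(y) else 0
  if (!is.finite(v)) v <- 0
  1e-12 * (n * v + 1)
}

# Effective sample size entering the BIC. "timepoints" counts the distinct
# (condition, time) cells with data — replicates are repeated measures at a
# time point, not extra time points; "observations" counts every replicate
# measurement.
bic_n_for <- function(sheet, use, bic_n = c("timepoints", "observations")) {
  bic_n <- match.arg(bic_n)
  if (bic_n == "observations") return(sum(use))
  length(unique(paste(sheet$condition, sheet$time)[use]))
}

#' Fit one feature's time course under a given model spec
#'
#' Ordinary least squares on the design from [build_design()]. Missing
#' values are dropped (with `n` adjusted); a design that is rank-deficient
#' on the remaining samples yields a flagged result (`ok = FALSE`) rather
#' than an error.
#'
#' @param y numeric vector of log2 signal aligned to the sample-sheet rows;
#'   `NA` allowed.
#' @inheritParams build_design
#' @param bic_n what to count as the BIC sample size: `"timepoints"`
#'   (default; the distinct condition-time cells with data, treating
#'   replicates as repeated measures at a time point) or `"observations"`
#'   (every replicate measurement).
#' @return An object of class `rhythm_fit`: a list with the per-condition
#'   means `mu`, per-group harmonic coefficients `alpha` and `beta`,
#'   optional per-condition (or shared) `trend` slopes, `rss`, parameter
#'   count `k`, observation count `n`, the BIC sample size `n_bic`, `bic`,
#'   `sigma2 = rss/n`, the raw `coefficients`, fitted `values` (NA where y
#'   was missing) and the flag `ok`.
#' @export
fit_feature <- function(y, sheet, spec, period = 24, with_trend = "none",
                        bic_n = "timepoints") {
  spec <- check_spec(spec)
  with_trend <- normalize_trend(with_trend)
  if (length(y) != nrow(sheet))
    stop("'y' must align with the sample sheet (one value per row)")
  X <- build_design(sheet, spec, period = period, with_trend = with_trend)
  use <- !is.na(y)
  conds <- conditions_of(sheet)
  obs_per_cond <- tapply(use, factor(sheet$condition, levels = conds), sum)
  nb <- bic_n_for(sheet, use, bic_n)
  fit <- structure(list(spec = spec, conditions = conds, period = period,
                        with_trend = with_trend, ok = FALSE,
                        mu = NULL, alpha = NULL, beta = NULL, trend = NULL,
                        rss = NA_real_, k = ncol(X), n = sum(use),
                        n_bic = nb, bic = NA_real_, sigma2 = NA_real_,
                        coefficients = NULL, values = rep(NA_real_, length(y))),
                   class = "rhythm_fit")
  if (any(obs_per_cond < 1) || sum(use) < ncol(X)) return(fit)
  Xu <- X[use, , drop = FALSE]
  qrX <- qr(Xu)
  if (qrX$rank < ncol(Xu)) return(fit)
  ls <- qr.coef(qrX, y[use])
  res <- y[use] - drop(Xu %*% ls)
  n <- sum(use)
  rss <- sum(res^2)
  fit$ok <- TRUE
  fit$coefficients <- ls
  fit$rss <- rss
  fit$n <- n
  fit$sigma2 <- rss / n
  fit$bic <- bic_score(rss, nb, ncol(X), rss_floor = rss_floor_for(y[use], n))
  fit$values[use] <- drop(Xu %*% ls)
  fit$mu <- stats::setNames(ls[paste0("mu.", conds)], conds)
  G <- n_groups(spec)
  fit$alpha <- if (G) stats::setNames(ls[paste0("cos.g", seq_len(G))],
                                      paste0("g", seq_len(G))) else numeric(0)
  fit$beta <- if (G) stats::setNames(ls[paste0("sin.g", seq_len(G))],
                                     paste0("g", seq_len(G))) else numeric(0)
  if (with_trend == "shared") {
    fit$trend <- stats::setNames(rep(ls[["trend"]], length(conds)), conds)
  } else if (with_trend == "per_condition") {
    fit$trend <- stats::setNames(ls[paste0("trend.", conds)], conds)
  }
  fit
}

#' @export
print.rhythm_fit <- function(x, ...) {
  cat("rhythm_fit:", spec_label(x$spec, x$conditions), "\n")
  if (!x$ok) {
    cat("  fit flagged as unavailable (rank-deficient or too few data)\n")
    return(invisible(x))
  }
  cat(sprintf("  n = %d, k = %d, RSS = %.6g, BIC = %.4f\n",
              x$n, x$k, x$rss, x$bic))
  invisible(x)
}
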