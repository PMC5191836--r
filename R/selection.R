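# Model selection: fit every candidate model per feature, turn BICs into
# Schwarz weights and call the best model or "ambiguous".

#' Schwarz weights from a vector of BIC values
#'
#' For candidate models j with criterion values BIC_j, the Schwarz weight
#' is `w_j = exp(-dBIC_j/2) / sum_m exp(-dBIC_m/2)` with
#' `dBIC_j = BIC_j - min_m BIC_m`. The minimum is subtracted before
#' exponentiation for numerical stability, so the minimum-BIC model always
#' carries the largest weight. `w_j` is interpreted as the confidence that
#' model j is optimal within the candidate set. Non-finite BICs (models
#' that could not be fitted) receive weight 0.
#'
#' @param bics numeric vector of BIC values, at least one finite.
#' @return Weights in `[0, 1]` summing to 1.
#' @export
schwarz_weights <- function(bics) {
  if (!is.numeric(bics) || length(bics) < 1L)
    stop("'bics' must be a non-empty numeric vector")
  fin <- is.finite(bics)
  if (!any(fin)) stop("all BIC values are non-finite")
  w <- numeric(length(bics))
  e <- exp(-(bics[fin] - min(bics[fin])) / 2)
  w[fin] <- e / sum(e)
  names(w) <- names(bics)
  w
}

#' Default Schwarz-weight confidence threshold by number of conditions
#'
#' Features whose best-model weight falls below the threshold are called
#' "ambiguous" and excluded from model-based categories. The default grows
#' with the number of conditions because the candidate set grows and
#' spurious coefficient splits become more likely: 0.3 for up to two
#' conditions (5 candidate models) and 0.5 for three or more (15+). All
#' entry points accept an explicit threshold instead; the methods vignette
#' discusses the calibration.
#'
#' @param C number of conditions.
#' @return A single threshold in (0, 1].
#' @export
default_bicw_threshold <- function(C) {
  stopifnot(C >= 1)
  if (C <= 2) 0.3 else 0.5
}

#' Pick the best model from Schwarz weights
#'
#' The best model is the argmax of the weights; ties are broken toward the
#' earlier model in enumeration order (simpler models first). The feature
#' is ambiguous when the best weight does not reach the threshold.
#'
#' @param weights Schwarz weights as from [schwarz_weights()].
#' @param threshold confidence threshold in (0, 1].
#' @return A list with `best_index`, `best_weight`, `ambiguous` and
#'   `threshold_used`.
#' @export
assign_model <- function(weights, threshold) {
  stopifnot(is.numeric(weights), length(weights) >= 1L,
            is.numeric(threshold), length(threshold) == 1L,
            threshold > 0, threshold <= 1)
  best <- which.max(weights) # first maximum = earlier model
  list(best_index = best, best_weight = weights[[best]],
       ambiguous = weights[[best]] < threshold,
       threshold_used = threshold)
}

#' Fit all candidate models to every feature and select per feature
#'
#' The central routine of the package: for each feature (row of `mat`),
#' every candidate model is fitted by least squares, BICs are converted to
#' Schwarz weights, and the best-supported model is recorded together with
#' per-condition rhythm parameters (fitted mean, harmonic coefficients,
#' peak-trough amplitude, peak phase, and the data-based relative
#' amplitude). Features whose best weight stays below the threshold are
#' flagged `ambiguous`; features for which no candidate could be fitted are
#' flagged unfittable instead of aborting the run.
#'
#' Features with complete data are fitted in one batched least-squares pass
#' per model; features with missing values fall back to a per-feature fit
#' with `n` adjusted.
#'
#' @param mat numeric features x samples matrix; rownames are feature ids,
#'   colnames (when present) must match the sample sheet's `sample_id`.
#' @param sheet a [sample_sheet()].
#' @param models list of model assignment vectors; defaults to
#'   [enumerate_models()] over the declared conditions.
#' @param period oscillation period in hours.
#' @param with_trend trend mode passed to [build_design()].
#' @param threshold Schwarz-weight confidence threshold; defaults to
#'   [default_bicw_threshold()].
#' @param bic_n BIC sample-size convention, see [fit_feature()].
#' @return An object of class `rhythm_selection`; see
#'   [as.data.frame.rhythm_selection()] for the flat table export.
#' @export
select_all <- function(mat, sheet, models = NULL, period = 24,
                       with_trend = "none", threshold = NULL,
                       bic_n = "timepoints") {
  with_trend <- normalize_trend(with_trend)
  conds <- conditions_of(sheet)
  C <- length(conds)
  mat <- align_matrix(mat, sheet)
  if (is.null(models)) models <- enumerate_models(C)
  models <- lapply(models, check_spec)
  if (any(vapply(models, length, integer(1)) != C))
    stop("every model spec must cover the ", C, " declared conditions")
  if (is.null(threshold)) threshold <- default_bicw_threshold(C)
  stopifnot(threshold > 0, threshold <= 1)

  labels <- vapply(models, spec_label, character(1),
                   condition_names = conds)
  nF <- nrow(mat); nM <- length(models)
  feature_id <- rownames(mat)
  bics <- matrix(NA_real_, nF, nM, dimnames = list(feature_id, labels))
  coef_store <- vector("list", nM)

  complete <- !apply(is.na(mat), 1L, any)
  Yc <- t(mat[complete, , drop = FALSE])
  n_all <- nrow(sheet)
  nb_all <- bic_n_for(sheet, rep(TRUE, n_all), bic_n)
  floor_c <- if (any(complete))
    1e-12 * (n_all * apply(mat[complete, , drop = FALSE], 1L, stats::var) + 1)
  else numeric(0)

  for (m in seq_len(nM)) {
    X <- build_design(sheet, models[[m]], period = period,
                      with_trend = with_trend)
    k <- ncol(X)
    qrX <- qr(X)
    cs <- matrix(NA_real_, k, nF,
                 dimnames = list(colnames(X), feature_id))
    if (qrX$rank == k && any(complete)) {
      res <- qr.resid(qrX, Yc)
      rss <- colSums(res^2)
      bics[complete, m] <- nb_all * log(pmax(rss, floor_c) / nb_all) +
        k * log(nb_all)
      cs[, complete] <- qr.coef(qrX, Yc)
    }
    if (any(!complete)) {
      for (f in which(!complete)) {
        ft <- fit_feature(mat[f, ], sheet, models[[m]], period = period,
                          with_trend = with_trend, bic_n = bic_n)
        if (ft$ok) {
          bics[f, m] <- ft$bic
          cs[, f] <- ft$coefficients
        }
      }
    }
    coef_store[[m]] <- cs
  }

  fittable <- rowSums(is.finite(bics)) > 0
  weights <- matrix(NA_real_, nF, nM, dimnames = dimnames(bics))
  if (any(fittable)) {
    B <- bics[fittable, , drop = FALSE]
    Bmin <- apply(B, 1L, min, na.rm = TRUE)
    E <- exp(-(B - Bmin) / 2)
    E[!is.finite(E)] <- 0
    weights[fittable, ] <- E / rowSums(E)
  }
  wsafe <- weights
  wsafe[is.na(wsafe)] <- -Inf
  best_idx <- ifelse(fittable, max.col(wsafe, ties.method = "first"), NA_integer_)
  best_weight <- ifelse(fittable, weights[cbind(seq_len(nF), best_idx)], NA_real_)
  ambiguous <- ifelse(fittable, best_weight < threshold, NA)

  table <- data.frame(
    feature_id = feature_id,
    best_model = ifelse(fittable, labels[best_idx], NA_character_),
    best_weight = best_weight,
    ambiguous = ambiguous,
    fittable = fittable,
    threshold_used = threshold,
    stringsAsFactors = FALSE
  )

  params <- best_model_params(mat, sheet, models, coef_store, best_idx,
                              fittable, period, with_trend)

  structure(list(table = table, weights = weights, bics = bics,
                 models = models, labels = labels, params = params,
                 conditions = conds, period = period,
                 with_trend = with_trend, threshold = threshold,
                 bic_n = bic_n),
            class = "rhythm_selection")
}

align_matrix <- function(mat, sheet) {
  mat <- as.matrix(mat)
  if (!is.numeric(mat)) stop("expression matrix must be numeric")
  if (is.null(rownames(mat)))
    rownames(mat) <- paste0("feature", seq_len(nrow(mat)))
  if (!is.null(colnames(mat))) {
    missing <- setdiff(sheet$sample_id, colnames(mat))
    if (length(missing))
      stop("samples in sheet but not in matrix: ",
           paste(missing, collapse = ", "))
    mat <- mat[, sheet$sample_id, drop = FALSE]
  } else if (ncol(mat) != nrow(sheet)) {
    stop("matrix has ", ncol(mat), " columns but the sheet describes ",
         nrow(sheet), " samples")
  }
  mat
}

# Per-condition parameters of each feature's best model, plus the
# data-based relative amplitude (per-time-point condition means).
best_model_params <- function(mat, sheet, models, coef_store, best_idx,
                              fittable, period, with_trend) {
  conds <- conditions_of(sheet)
  nF <- nrow(mat)
  feature_id <- rownames(mat)
  relamp <- matrix(NA_real_, nF, length(conds))
  for (ci in seq_along(conds)) {
    rows <- which(sheet$condition == conds[ci])
    times <- sort(unique(sheet$time[rows]))
    prof <- sapply(times, function(tt)
      rowMeans(mat[, rows[sheet$time[rows] == tt], drop = FALSE],
               na.rm = TRUE))
    if (is.null(dim(prof))) prof <- matrix(prof, nrow = nF)
    pm <- rowMeans(prof)
    ra <- (apply(prof, 1L, max) - apply(prof, 1L, min)) / pm
    ra[pm == 0 | !is.finite(ra)] <- NA_real_
    relamp[, ci] <- ra
  }
  out <- vector("list", length(conds))
  MU <- ALPHA <- BETA <- TREND <- matrix(NA_real_, nF, length(conds))
  GROUP <- matrix(NA_integer_, nF, length(conds))
  for (m in unique(best_idx[fittable])) {
    rows <- which(fittable & best_idx == m)
    spec <- models[[m]]
    cs <- coef_store[[m]]
    for (ci in seq_along(conds)) {
      GROUP[rows, ci] <- spec[ci]
      MU[rows, ci] <- cs[paste0("mu.", conds[ci]), rows]
      if (spec[ci] > 0L) {
        ALPHA[rows, ci] <- cs[paste0("cos.g", spec[ci]), rows]
        BETA[rows, ci] <- cs[paste0("sin.g", spec[ci]), rows]
      } else {
        ALPHA[rows, ci] <- 0
        BETA[rows, ci] <- 0
      }
      if (with_trend == "shared") {
        TREND[rows, ci] <- cs["trend", rows]
      } else if (with_trend == "per_condition") {
        TREND[rows, ci] <- cs[paste0("trend.", conds[ci]), rows]
      }
    }
  }
  data.frame(
    feature_id = rep(feature_id, times = length(conds)),
    condition = rep(conds, each = nF),
    group = as.vector(GROUP),
    mu = as.vector(MU),
    alpha = as.vector(ALPHA),
    beta = as.vector(BETA),
    amplitude = amplitude(as.vector(ALPHA), as.vector(BETA)),
    phase = phase_hours(as.vector(ALPHA), as.vector(BETA), period = period),
    relative_amplitude = as.vector(relamp),
    trend = as.vector(TREND),
    stringsAsFactors = FALSE
  )
}

#' @export
print.rhythm_selection <- function(x, ...) {
  tab <- x$table
  cat("rhythm_selection:", nrow(tab), "features,",
      length(x$models), "candidate models,",
      length(x$conditions), "conditions\n")
  cat(sprintf("  period = %g h, trend = %s, BICW threshold = %g\n",
              x$period, x$with_trend, x$threshold))
  ok <- tab$fittable
  cat(sprintf("  ambiguous: %d, unfittable: %d\n",
              sum(tab$ambiguous[ok], na.rm = TRUE), sum(!ok)))
  bm <- sort(table(tab$best_model[ok & !tab$ambiguous]), decreasing = TRUE)
  print(utils::head(bm, 10))
  invisible(x)
}

#' Flatten a selection object into one row per feature
#'
#' Columns: `feature_id`, `best_model`, `best_weight`, `ambiguous`, the
#' per-condition rhythm parameters (`amplitude.<cond>`, `phase.<cond>`,
#' `relative_amplitude.<cond>`, plus `trend.<cond>` when trends were
#' fitted), then one Schwarz-weight column per candidate model
#' (`bicw.<label>`).
#'
#' @param x a `rhythm_selection`.
#' @param row.names,optional,... ignored (data.frame method signature).
#' @param include_weights include the per-model weight columns.
#' @return A data.frame with one row per feature.
#' @export
as.data.frame.rhythm_selection <- function(x, row.names = NULL,
                                           optional = FALSE,
                                           include_weights = TRUE, ...) {
  out <- x$table
  for (cc in x$conditions) {
    p <- x$params[x$params$condition == cc, ]
    p <- p[match(out$feature_id, p$feature_id), ]
    out[[paste0("amplitude.", cc)]] <- p$amplitude
    out[[paste0("phase.", cc)]] <- p$phase
    out[[paste0("relative_amplitude.", cc)]] <- p$relative_amplitude
    if (x$with_trend != "none") out[[paste0("trend.", cc)]] <- p$trend
  }
  if (include_weights) {
    w <- x$weights
    colnames(w) <- paste0("bicw.", colnames(w))
    out <- cbind(out, as.data.frame(w, optional = TRUE))
  }
  rownames(out) <- NULL
  out
}
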