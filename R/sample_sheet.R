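#' Construct a validated sample sheet
#'
#' A sample sheet describes one sample per row: its id, experimental
#' condition, Zeitgeber time in hours (real numbers; ZT0 = lights on) and
#' replicate index. The declared condition order — not the row order of the
#' file — fixes the condition order used by model assignments, design
#' matrices and all output tables.
#'
#' Every condition must be observed at three or more distinct time points,
#' otherwise the harmonic fit (per-condition mean plus cosine and sine) is
#' underdetermined.
#'
#' @param sample_id character vector of unique sample names.
#' @param condition condition label per sample.
#' @param time Zeitgeber time in hours per sample (>= 0).
#' @param replicate replicate index per sample (integer >= 1).
#' @param conditions optional character vector declaring the condition
#'   order; defaults to order of first appearance.
#' @return A `sample_sheet` data.frame with a `conditions` attribute.
#' @export
sample_sheet <- function(sample_id, condition, time, replicate = NULL,
                         conditions = NULL) {
  sample_id <- as.character(sample_id)
  condition <- as.character(condition)
  time <- as.numeric(time)
  if (is.null(replicate)) {
    replicate <- stats::ave(time, condition, time, FUN = seq_along)
  }
  replicate <- as.integer(replicate)
  n <- length(sample_id)
  if (length(condition) != n || length(time) != n || length(replicate) != n)
    stop("sample_id, condition, time and replicate must have equal length")
  if (anyDuplicated(sample_id))
    stop("duplicated sample_id: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  if (anyNA(time) || any(time < 0))
    stop("'time' must be non-negative Zeitgeber hours")
  if (anyNA(replicate) || any(replicate < 1))
    stop("'replicate' must be a positive integer")
  key <- paste(condition, time, replicate, sep = "\r")
  if (anyDuplicated(key))
    stop("(condition, time, replicate) triples must be unique")
  if (is.null(conditions)) conditions <- unique(condition)
  conditions <- as.character(conditions)
  if (!all(condition %in% conditions))
    stop("samples carry conditions absent from the declared condition list: ",
         paste(setdiff(condition, conditions), collapse = ", "))
  if (!all(conditions %in% condition))
    stop("declared conditions never observed: ",
         paste(setdiff(conditions, condition), collapse = ", "))
  ntp <- tapply(time, factor(condition, levels = conditions),
                function(t) length(unique(t)))
  if (any(ntp < 3))
    stop("every condition needs >= 3 distinct time points; offending: ",
         paste(names(ntp)[ntp < 3], collapse = ", "))
  out <- data.frame(sample_id = sample_id, condition = condition,
                    time = time, replicate = replicate,
                    stringsAsFactors = FALSE)
  attr(out, "conditions") <- conditions
  class(out) <- c("sample_sheet", "data.frame")
  out
}

#' @export
print.sample_sheet <- function(x, ...) {
  cat("sample_sheet:", nrow(x), "samples,",
      length(conditions_of(x)), "conditions (",
      paste(conditions_of(x), collapse = ", "), ")\n")
  print(as.data.frame(x), ...)
  invisible(x)
}

conditions_of <- function(sheet) {
  cond <- attr(sheet, "conditions")
  if (is.null(cond)) unique(sheet$condition) else cond
}
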