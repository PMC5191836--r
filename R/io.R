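# TSV readers and writers. All tables are UTF-8 tab-separated text;
# writers prepend '#'-prefixed header comments recording the package
# version and a hash of the run configuration, and readers skip such
# comments.

pkg_version <- function() {
  as.character(utils::packageVersion("diffrhythm"))
}

# Polynomial rolling hash (mod 2^31 - 1) over the UTF-8 bytes of the
# deparsed object; enough to fingerprint a run configuration in output
# headers.
config_hash <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(deparse(x), collapse = "\n")))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

header_comments <- function(config = NULL, extra = character()) {
  c(paste0("# diffrhythm ", pkg_version()),
    if (!is.null(config)) paste0("# config_hash=", config_hash(config)),
    if (length(extra)) paste0("# ", extra))
}

#' Read a features-by-samples matrix from TSV
#'
#' Expects a header line with `feature_id` (or any name) in the first
#' column followed by sample ids, one feature per row. Blank cells become
#' `NA`; any other non-numeric cell is a parse error reported with its row
#' and column; duplicated feature or sample ids are errors. Lines starting
#' with `#` and Windows line endings are handled transparently.
#'
#' @param path TSV file path.
#' @return A numeric matrix with feature ids as rownames and sample ids as
#'   colnames.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "#", check.names = FALSE,
                          colClasses = "character",
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (ncol(df) < 2) stop("matrix file needs a feature id column plus samples")
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop("duplicated feature ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  samples <- colnames(df)[-1]
  if (anyDuplicated(samples))
    stop("duplicated sample columns: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  mat <- matrix(NA_real_, length(ids), length(samples),
                dimnames = list(ids, samples))
  for (j in seq_along(samples)) {
    raw <- trimws(df[[j + 1]])
    blank <- raw == "" | raw == "NA" | is.na(raw)
    val <- suppressWarnings(as.numeric(raw))
    bad <- !blank & is.na(val)
    if (any(bad)) {
      i <- which(bad)[1]
      stop("non-numeric value '", raw[i], "' at feature '", ids[i],
           "', sample column '", samples[j], "'")
    }
    mat[, j] <- val
  }
  mat
}

#' Write a matrix as TSV
#'
#' @param mat numeric matrix with rownames (feature ids) and colnames
#'   (sample ids).
#' @param path output file path.
#' @param config optional configuration object; when given, a
#'   `config_hash` header comment is emitted.
#' @param comments extra header comment lines (without the leading `#`).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(mat, path, config = NULL, comments = character()) {
  con <- file(path, "wb") # binary mode: identical bytes on every platform
  on.exit(close(con))
  writeLines(header_comments(config, comments), con)
  header <- paste(c("feature_id", colnames(mat)), collapse = "\t")
  body <- vapply(seq_len(nrow(mat)), function(i)
    paste(c(rownames(mat)[i],
            formatC(mat[i, ], format = "g", digits = 15)), collapse = "\t"),
    character(1))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Read a sample sheet from TSV
#'
#' Requires columns `sample_id`, `condition`, `time` and (optionally)
#' `replicate`.
#'
#' @param path TSV file path.
#' @param conditions optional declared condition order (defaults to first
#'   appearance in the file).
#' @return A [sample_sheet()].
#' @export
read_sample_sheet <- function(path, conditions = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("sample_id", "condition", "time")
  if (!all(need %in% names(df)))
    stop("sample sheet needs columns: ", paste(need, collapse = ", "))
  sample_sheet(df$sample_id, df$condition, df$time,
               replicate = if ("replicate" %in% names(df)) df$replicate,
               conditions = conditions)
}

#' Write a data.frame (sample sheet, selection table, calls, ...) as TSV
#'
#' @param df a data.frame.
#' @param path output file path.
#' @inheritParams write_matrix
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path, config = NULL, comments = character()) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header_comments(config, comments), con)
  fmt <- vapply(df, function(col) {
    if (is.numeric(col) && !is.integer(col))
      formatC(col, format = "g", digits = 15)
    else as.character(col)
  }, FUN.VALUE = character(nrow(df)))
  if (nrow(df) == 1L) fmt <- matrix(fmt, nrow = 1L)
  fmt[is.na(fmt) | fmt == "NA"] <- "NA"
  writeLines(c(paste(names(df), collapse = "\t"),
               apply(fmt, 1L, paste, collapse = "\t")), con)
  invisible(path)
}

#' Write a selection result as TSV
#'
#' Flattens the selection with [as.data.frame.rhythm_selection()] and
#' records the period, trend mode and the Schwarz-weight threshold in the
#' header comments.
#'
#' @param sel a `rhythm_selection`.
#' @param path output file path.
#' @param config optional configuration for the `config_hash` comment.
#' @return `path`, invisibly.
#' @export
write_selection <- function(sel, path, config = NULL) {
  stopifnot(inherits(sel, "rhythm_selection"))
  write_table(as.data.frame(sel), path, config = config,
              comments = sprintf(
                "period=%g trend=%s bicw_threshold=%g",
                sel$period, sel$with_trend, sel$threshold))
}
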