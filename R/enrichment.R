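# Hypergeometric over-representation statistics with Benjamini-Hochberg
# correction, for gene-set enrichment and motif co-occurrence tests.

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of
#' drawing at least `k` marked features when `n` features are drawn
#' without replacement from a universe of `N` features of which `K` are
#' marked. Exact, via [stats::phyper()].
#'
#' @param k observed hits in the selection.
#' @param K marked features in the universe.
#' @param n selection size.
#' @param N universe size.
#' @return The exact p-value in `(0, 1]` (vectorized).
#' @examples
#' hypergeom_upper_tail(5, 5, 5, 10) # 1/choose(10, 5)
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  bad <- is.na(k) | is.na(K) | is.na(n) | is.na(N) |
    k < 0 | K < 0 | n < 0 | N < 0 | k > n | k > K | n > N | K > N
  if (any(bad))
    stop("inconsistent hypergeometric counts: need 0 <= k <= min(K, n), ",
         "n <= N, K <= N")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment (via
#' [stats::p.adjust()]), capped at 1.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length.
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values < 0 | p_values > 1))
    stop("'p_values' must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Hypergeometric enrichment of feature sets in a selection
#'
#' One upper-tail hypergeometric test per set, Benjamini-Hochberg
#' corrected across sets; sets with adjusted p below `alpha` are flagged
#' significant.
#'
#' @param selection_ids feature ids in the selection (e.g. rescued genes).
#' @param universe_ids feature ids of the universe; must contain the
#'   selection.
#' @param sets a data.frame with columns `set_id` and `feature_id`, or a
#'   named list of feature-id vectors. Memberships outside the universe
#'   are ignored.
#' @param alpha significance level applied to the adjusted p-values.
#' @return A data.frame with `set_id`, `k`, `K`, `n`, `N`, `p_value`,
#'   `adjusted_p` and `significant`.
#' @export
enrich_sets <- function(selection_ids, universe_ids, sets, alpha = 0.05) {
  selection_ids <- unique(as.character(selection_ids))
  universe_ids <- unique(as.character(universe_ids))
  if (!all(selection_ids %in% universe_ids))
    stop("selection contains ids absent from the universe")
  if (is.data.frame(sets)) {
    stopifnot(all(c("set_id", "feature_id") %in% names(sets)))
    sets <- split(as.character(sets$feature_id), sets$set_id)
  }
  stopifnot(is.list(sets), !is.null(names(sets)))
  N <- length(universe_ids)
  n <- length(selection_ids)
  rows <- lapply(names(sets), function(sid) {
    members <- intersect(unique(as.character(sets[[sid]])), universe_ids)
    K <- length(members)
    k <- length(intersect(members, selection_ids))
    data.frame(set_id = sid, k = k, K = K, n = n, N = N,
               p_value = hypergeom_upper_tail(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- bh_adjust(out$p_value)
  out$significant <- out$adjusted_p < alpha
  out
}

#' Co-occurrence enrichment of two motif classes
#'
#' A feature counts as a co-occurrence hit when it carries at least one
#' hit of every motif class in `classes` (e.g. an E-box and a
#' glucocorticoid response element in its promoter). The test asks whether
#' such double-positive features are over-represented in the selection
#' relative to the universe, with an upper-tail hypergeometric p-value.
#'
#' @param selection_ids feature ids of the selection.
#' @param universe_ids feature ids of the universe (superset of the
#'   selection). Features absent from `hit_table` count as motif-free.
#' @param hit_table data.frame with a `feature_id` column and one
#'   logical/numeric column per motif class (TRUE/nonzero = at least one
#'   hit).
#' @param classes motif-class column names to combine; default all
#'   non-id columns.
#' @return A one-row data.frame with `k`, `K`, `n`, `N` and `p_value`,
#'   where `K` counts co-occurrence hits in the universe and `k` in the
#'   selection.
#' @export
cooccurrence_enrichment <- function(selection_ids, universe_ids, hit_table,
                                    classes = NULL) {
  stopifnot(is.data.frame(hit_table), "feature_id" %in% names(hit_table))
  selection_ids <- unique(as.character(selection_ids))
  universe_ids <- unique(as.character(universe_ids))
  if (!all(selection_ids %in% universe_ids))
    stop("selection contains ids absent from the universe")
  if (is.null(classes)) classes <- setdiff(names(hit_table), "feature_id")
  if (!all(classes %in% names(hit_table)))
    stop("unknown motif classes: ",
         paste(setdiff(classes, names(hit_table)), collapse = ", "))
  if (length(classes) < 1L) stop("need at least one motif class")
  hit <- rep(TRUE, nrow(hit_table))
  for (cl in classes) {
    v <- hit_table[[cl]]
    hit <- hit & !is.na(v) & (as.numeric(v) != 0)
  }
  carriers <- as.character(hit_table$feature_id[hit])
  K <- length(intersect(carriers, universe_ids))
  k <- length(intersect(carriers, selection_ids))
  n <- length(selection_ids)
  N <- length(universe_ids)
  data.frame(k = k, K = K, n = n, N = N,
             p_value = hypergeom_upper_tail(k, K, n, N))
}
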