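# Shared fixtures and independent oracles, built in code.

# sample sheet with every condition sampled at the same times
make_sheet <- function(conditions = c("a", "b"),
                       times = c(3, 9, 15, 21), reps = 2) {
  grid <- expand.grid(replicate = seq_len(reps), time = times,
                      condition = conditions, stringsAsFactors = FALSE)
  sample_sheet(sprintf("%s_t%g_r%d", grid$condition, grid$time,
                       grid$replicate),
               grid$condition, grid$time, grid$replicate,
               conditions = conditions)
}

# Brute-force model enumeration: every function conditions -> {0..C},
# reduced to canonical first-use group labels, deduplicated.
brute_force_models <- function(C) {
  grids <- do.call(expand.grid, rep(list(0:C), C))
  canon <- apply(grids, 1L, function(a) {
    groups <- unique(a[a > 0])
    paste(ifelse(a == 0, 0L, match(a, groups)), collapse = ",")
  })
  unique(canon)
}

# Normal-equations least squares, independent of the qr path used by the
# package.
normal_eq_fit <- function(X, y) {
  beta <- solve(crossprod(X), crossprod(X, y))
  rss <- sum((y - X %*% beta)^2)
  list(beta = drop(beta), rss = rss)
}

# Exhaustive upper-tail hypergeometric probability by enumerating every
# size-n subset of a universe with K marked elements.
enumeration_hypergeom <- function(k, K, n, N) {
  if (n == 0) return(as.numeric(k <= 0))
  sel <- utils::combn(N, n)
  hits <- colSums(sel <= K)
  mean(hits >= k)
}
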