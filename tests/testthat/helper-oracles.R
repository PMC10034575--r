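# Independent brute-force oracles used by the tests. These deliberately
# re-derive each quantity from first principles, not through the package's
# own code paths.

# Two-sided exact signed-rank p by full enumeration over all 2^n sign
# assignments (midranks for tied magnitudes).
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  obs <- sum(r[d > 0])
  w <- vapply(0:(2^n - 1), function(m)
    sum(r[bitwAnd(m, 2^(0:(n - 1))) > 0]), numeric(1))
  min(1, 2 * min(mean(w <= obs + 1e-9), mean(w >= obs - 1e-9)))
}

# Two-sided exact Mann-Whitney p by enumeration over all C(n+m, n) group
# labelings (no ties assumed).
oracle_mann_whitney_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  u_of <- function(xi, yi) sum(outer(xi, yi, `>`)) + 0.5 * sum(outer(xi, yi, `==`))
  obs <- u_of(x, y)
  labelings <- utils::combn(length(pooled), n)
  u <- apply(labelings, 2, function(ix) u_of(pooled[ix], pooled[-ix]))
  min(1, 2 * min(mean(u <= obs + 1e-9), mean(u >= obs - 1e-9)))
}

# Literal re-reading of the switching rule, re-evaluated from scratch on
# every prefix (no incremental state).
oracle_switch <- function(dev, cutpoint = -7, window = 9, prop = 0.20) {
  for (t in seq_along(dev)) {
    viol <- which(dev[1:t] < cutpoint)
    if (t <= window && length(viol) >= 2 && sort(viol)[2] == t)
      return(list(switched = TRUE, after = t, trigger = "second_violation_early"))
    if (t > window && length(viol) / t > prop)
      return(list(switched = TRUE, after = t, trigger = "proportion_late"))
  }
  list(switched = FALSE, after = NA_integer_, trigger = "none")
}

# Dx% by sorting voxel doses: dose received by the hottest x% of voxels.
oracle_dx <- function(doses, x) {
  k <- ceiling(x / 100 * length(doses))
  sort(doses, decreasing = TRUE)[k]
}

# Margin expansion by brute-force neighbourhood enumeration.
oracle_expand <- function(mask, spacing, margin) {
  sh <- dim(mask)
  src <- which(mask, arr.ind = TRUE)
  src_mm <- sweep(src - 1, 2, spacing, `*`)
  out <- array(FALSE, dim = sh)
  for (i in 1:sh[1]) for (j in 1:sh[2]) for (k in 1:sh[3]) {
    p <- (c(i, j, k) - 1) * spacing
    if (min(colSums((t(src_mm) - p)^2)) <= margin^2 + 1e-9)
      out[i, j, k] <- TRUE
  }
  out
}
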