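# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: explicit loops, full-grid scans, exhaustive
# enumeration.

# Third standardized moment by explicit summation (divide-by-Np).
brute_skewness <- function(x) {
  n <- length(x)
  xbar <- sum(x) / n
  s2 <- 0
  s3 <- 0
  for (v in x) {
    s2 <- s2 + (v - xbar)^2
    s3 <- s3 + (v - xbar)^3
  }
  (s3 / n) / (sqrt(s2 / n))^3
}

# Full-grid center-in-sphere membership test (no bounding box shortcut).
brute_sphere_mask <- function(center, radius, dims, affine) {
  out <- array(FALSE, dim = dims)
  for (k in seq_len(dims[3])) for (j in seq_len(dims[2])) for (i in seq_len(dims[1])) {
    w <- affine %*% c(i - 1, j - 1, k - 1, 1)
    d2 <- sum((w[1:3] - center)^2)
    out[i, j, k] <- d2 <= radius^2
  }
  out
}

# Exact two-sided rank-sum p by exhaustive enumeration of rank assignments.
ranksum_exact_p <- function(a, b) {
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  n <- length(pooled)
  na <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(n, na)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(1, p)
}

# Best empirical Youden index over all midpoints between adjacent sorted
# values (plus outer cuts), calling the higher-mean group positive.
max_youden_midpoints <- function(values, groups) {
  levels <- sort(unique(groups))
  means <- vapply(levels, function(g) mean(values[groups == g]), numeric(1))
  pos <- levels[which.max(means)]
  sv <- sort(unique(values))
  cuts <- c(sv[1] - 1, (sv[-1] + sv[-length(sv)]) / 2, sv[length(sv)] + 1)
  best <- -Inf
  for (cut in cuts) {
    sens <- mean(values[groups == pos] > cut)
    spec <- mean(values[groups != pos] <= cut)
    best <- max(best, sens + spec - 1)
  }
  best
}

# Local maxima of a kernel density estimate, ignoring bumps under 10% of the
# tallest peak.
count_modes <- function(values) {
  d <- stats::density(values, n = 512)
  y <- d$y
  peaks <- which(diff(sign(diff(y))) == -2) + 1
  sum(y[peaks] > 0.1 * max(y))
}

# Sampling from an intensity law (internal routine, used as a fixture source).
draw_law_for_test <- function(law, n) suvhist:::draw_law(law, n)

# Quick constructors for small fixtures.
toy_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  aff <- diag(4)
  diag(aff)[1:3] <- spacing
  aff[1:3, 4] <- origin
  suv_volume(data, aff)
}

ramp_volume <- function(dims = c(3, 3, 3), spacing = c(1, 1, 1)) {
  toy_volume(array(seq_len(prod(dims)), dim = dims), spacing = spacing)
}
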