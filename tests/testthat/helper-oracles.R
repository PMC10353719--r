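# Naive double-loop reference implementations of every distance statistic,
# kept deliberately independent of the package's vectorized code paths.

o_dist <- function(x) {
  n <- length(x)
  d <- matrix(0, n, n)
  for (j in seq_len(n)) for (k in seq_len(n)) d[j, k] <- abs(x[j] - x[k])
  d
}

o_joint_dist <- function(block) {
  block <- as.matrix(block)
  n <- nrow(block)
  d <- matrix(0, n, n)
  for (j in seq_len(n)) for (k in seq_len(n)) {
    s <- 0
    for (col in seq_len(ncol(block))) s <- s + (block[j, col] - block[k, col])^2
    d[j, k] <- sqrt(s)
  }
  d
}

o_center <- function(d) {
  n <- nrow(d)
  rm <- numeric(n); cm <- numeric(n)
  for (j in seq_len(n)) rm[j] <- sum(d[j, ]) / n
  for (k in seq_len(n)) cm[k] <- sum(d[, k]) / n
  gm <- sum(d) / n^2
  a <- matrix(0, n, n)
  for (j in seq_len(n)) for (k in seq_len(n)) {
    a[j, k] <- d[j, k] - rm[j] - cm[k] + gm
  }
  a
}

o_dcov2 <- function(A, B) {
  n <- nrow(A)
  s <- 0
  for (j in seq_len(n)) for (k in seq_len(n)) s <- s + A[j, k] * B[j, k]
  s / n^2
}

o_dcor <- function(x, y) {
  A <- o_center(o_dist(x))
  B <- o_center(o_dist(y))
  v <- o_dcov2(A, B)
  sqrt(max(v, 0) / sqrt(o_dcov2(A, A) * o_dcov2(B, B)))
}

o_dcor_one_to_all <- function(values, i) {
  A <- o_center(o_dist(values[, i]))
  B <- o_center(o_joint_dist(values[, -i, drop = FALSE]))
  v <- o_dcov2(A, B)
  sqrt(max(v, 0) / sqrt(o_dcov2(A, A) * o_dcov2(B, B)))
}

# Textbook product-moment correlation by explicit summation.
o_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxy / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# CDF oracles by numerical integration of the density (independent of
# stats::pt / stats::pnorm).
o_pt_upper <- function(q, df) {
  stats::integrate(function(u) stats::dt(u, df), q, Inf,
                   rel.tol = 1e-12)$value
}

o_pnorm_upper <- function(q) {
  stats::integrate(stats::dnorm, q, Inf, rel.tol = 1e-12)$value
}

# Convenience: a seeded, z-scored feature_matrix of standard-normal noise.
random_fm <- function(n, m, seed) {
  rt <- simulate_scenario("independent", n_samples = n, n_features = m,
                          seed = seed)
  zscore(validate_features(rt))
}

# Write a raw_table to a temporary CSV shaped like user input.
write_raw_csv <- function(rt, path = tempfile(fileext = ".csv")) {
  df <- data.frame(sample_id = rt$sample_ids, rt$values, check.names = FALSE)
  readr::write_csv(df, path, progress = FALSE)
  path
}
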