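#' Simulate a feature table with known dependence structure
#'
#' Generates seeded samples-by-features tables realizing a named dependence
#' scenario, so every analysis mode can be exercised against a known ground
#' truth ([scenario_truth()]). Scenarios:
#' \describe{
#'   \item{independent}{all features i.i.d. standard normal.}
#'   \item{linear}{feature 2 = feature 1 + noise; remaining features i.i.d.}
#'   \item{quadratic}{feature 1 on a symmetric grid about 0, feature 2 =
#'     feature1^2 + noise (Pearson-blind, dCor-visible).}
#'   \item{sinusoidal}{feature 2 = sin(2*pi*feature1) + noise, feature 1
#'     uniform on [0, 1].}
#'   \item{circular}{(feature1, feature2) on the unit circle + noise.}
#'   \item{gaussian_chain}{multivariate normal Markov chain
#'     X1 -> X2 -> ... with adjacent correlation `chain_rho`, unit variances.}
#'   \item{hub}{feature 1 is a hub driving every other feature with
#'     correlation `chain_rho`; leaves are conditionally independent.}
#' }
#' Defects (for error-path testing) are injected last at seeded positions:
#' `missing_cells` empties random cells, `constant_features` overwrites
#' trailing columns with the constant 7.
#'
#' The generator pins the Mersenne-Twister / Inversion RNG so fixtures are
#' bit-reproducible across platforms for a given seed.
#'
#' @param scenario One of the scenario names above.
#' @param n_samples Number of rows (samples).
#' @param n_features Number of columns (features); scenarios with a
#'   structural pair fill the remaining columns with independent noise.
#' @param noise_sd Standard deviation of additive Gaussian noise on the
#'   structural relationship (default 0.1; 0 gives exact dependence).
#' @param seed Integer seed; fully determines the output.
#' @param chain_rho Adjacent (or hub-leaf) correlation for the graph
#'   scenarios (default 0.7).
#' @param missing_cells,constant_features Defect counts (default 0).
#' @return A `raw_table` (see [read_feature_table()]); sample IDs are
#'   `S1..Sn`, feature names `F1..Fm`.
#' @export
simulate_scenario <- function(scenario = c("independent", "linear",
                                           "quadratic", "sinusoidal",
                                           "circular", "gaussian_chain",
                                           "hub"),
                              n_samples = 50, n_features = 5,
                              noise_sd = 0.1, seed = 1, chain_rho = 0.7,
                              missing_cells = 0, constant_features = 0) {
  scenario <- match.arg(scenario)
  stopifnot(n_samples >= 3, n_features >= 2, noise_sd >= 0,
            missing_cells >= 0, constant_features >= 0)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")

  n <- n_samples; m <- n_features
  noise <- function(k = n) stats::rnorm(k, sd = noise_sd)
  v <- switch(scenario,
    independent = matrix(stats::rnorm(n * m), n, m),
    linear = {
      x <- stats::rnorm(n)
      cbind(x, x + noise(), filler(n, m - 2L))
    },
    quadratic = {
      x <- seq(-1, 1, length.out = n)
      cbind(x, x^2 + noise(), filler(n, m - 2L))
    },
    sinusoidal = {
      x <- stats::runif(n)
      cbind(x, sin(2 * pi * x) + noise(), filler(n, m - 2L))
    },
    circular = {
      th <- stats::runif(n, 0, 2 * pi)
      cbind(cos(th) + noise(), sin(th) + noise(), filler(n, m - 2L))
    },
    gaussian_chain = rmvn_chol(n, chain_covariance(m, chain_rho)),
    hub = rmvn_chol(n, hub_covariance(m, chain_rho))
  )
  v <- unname(v)

  if (constant_features > 0) {
    if (constant_features >= m) {
      stop("constant_features (", constant_features,
           ") must be smaller than n_features (", m, ")", call. = FALSE)
    }
    v[, seq.int(m - constant_features + 1L, m)] <- 7
  }
  if (missing_cells > 0) {
    if (missing_cells > n * m) {
      stop("missing_cells (", missing_cells, ") exceeds cell count (",
           n * m, ")", call. = FALSE)
    }
    v[sample.int(n * m, missing_cells)] <- NA_real_
  }
  new_raw_table(sample_ids = paste0("S", seq_len(n)),
                feature_names = paste0("F", seq_len(m)),
                values = v)
}

filler <- function(n, k) {
  if (k <= 0) return(matrix(numeric(0), n, 0))
  matrix(stats::rnorm(n * k), n, k)
}

# Markov chain: cov[i,j] = rho^|i-j|, unit variances.
chain_covariance <- function(m, rho) rho^abs(outer(seq_len(m), seq_len(m), "-"))

# Hub at feature 1: cov[1,j] = rho, leaves share only the hub pathway
# (cov[i,j] = rho^2 for leaves i != j), unit variances.
hub_covariance <- function(m, rho) {
  s <- matrix(rho^2, m, m)
  s[1, ] <- rho
  s[, 1] <- rho
  diag(s) <- 1
  s
}

# Deterministic multivariate normal draw via Cholesky (fixed algorithm so a
# seed pins the fixture bit-for-bit).
rmvn_chol <- function(n, sigma) {
  z <- matrix(stats::rnorm(n * ncol(sigma)), n, ncol(sigma))
  z %*% chol(sigma)
}

#' Ground truth of a simulated scenario
#'
#' Returns the true dependence structure a scenario realizes, for assertion
#' in structure-recovery tests: the edge set over features `F1..Fm` and the
#' generating parameters.
#'
#' @inheritParams simulate_scenario
#' @return A list with `edges` (two-column character matrix, zero rows for
#'   `independent`), `non_edges` where informative, and `params`.
#' @export
scenario_truth <- function(scenario, n_features = 5, chain_rho = 0.7) {
  scenario <- match.arg(scenario, c("independent", "linear", "quadratic",
                                    "sinusoidal", "circular",
                                    "gaussian_chain", "hub"))
  f <- paste0("F", seq_len(n_features))
  pair <- function(a, b) matrix(c(a, b), ncol = 2,
                                dimnames = list(NULL, c("a", "b")))
  edges <- switch(scenario,
    independent = pair(character(0), character(0)),
    gaussian_chain = pair(f[-n_features], f[-1]),
    hub = pair(rep(f[1], n_features - 1L), f[-1]),
    pair(f[1], f[2]))
  non_edges <- switch(scenario,
    gaussian_chain = if (n_features >= 3) pair(f[1], f[3]),
    hub = if (n_features >= 3) pair(f[2], f[3]))
  list(edges = edges, non_edges = non_edges,
       params = list(scenario = scenario, chain_rho = chain_rho))
}
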