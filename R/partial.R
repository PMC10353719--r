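#' Distance covariance matrix of a feature matrix
#'
#' Builds the m x m matrix Sigma with `Sigma[i,j] = dCov(X_i, X_j)` (the
#' square root of the clamped squared distance covariance) and
#' `Sigma[i,i] = dVar(X_i)`. This is the input to the Gaussian-graphical-model
#' route to partial correlations. Reliable partials need more samples than
#' features, so the computation refuses to run with m >= n unless explicitly
#' overridden.
#'
#' @param fm A `feature_matrix` with at least 3 usable features.
#' @param override_feature_guard Proceed (with a warning) when the number of
#'   features is >= the number of samples.
#' @return Symmetric m x m matrix, dimnames = usable feature names.
#' @export
dcov_matrix <- function(fm, override_feature_guard = FALSE) {
  stopifnot(inherits(fm, "feature_matrix"))
  feats <- usable_features(fm)
  m <- length(feats)
  if (m < 3L) {
    stop("partial correlations need at least 3 non-constant features, got ",
         m, call. = FALSE)
  }
  n <- n_samples(fm)
  if (m >= n) {
    msg <- paste0("number of features (", m, ") is not smaller than number ",
                  "of samples (", n, "); the distance covariance matrix is ",
                  "rank deficient and partial correlations are unreliable")
    if (!override_feature_guard) {
      stop(msg, "; pass override_feature_guard = TRUE to proceed anyway",
           call. = FALSE)
    }
    warning(msg, call. = FALSE)
  }
  cen <- centered_by_feature(fm)
  sigma <- matrix(0, m, m, dimnames = list(feats, feats))
  for (i in seq_len(m)) {
    for (j in i:m) {
      v <- sqrt(dcov2(cen[[i]], cen[[j]]))
      sigma[i, j] <- v
      sigma[j, i] <- v
    }
  }
  sigma
}

#' Precision matrix by Moore-Penrose pseudo-inversion
#'
#' `omega = Sigma^+`, the Moore-Penrose pseudo-inverse, which equals the
#' ordinary inverse for non-singular Sigma and is the least-squares
#' generalized inverse otherwise. Singular values below
#' `tol * max(singular value)` are truncated.
#'
#' @param sigma Symmetric matrix (distance covariance matrix).
#' @param tol Relative singular-value cutoff (default 1e-12).
#' @param verbose Report the condition number via [message()].
#' @return The precision matrix omega, same dimnames as `sigma`.
#' @export
precision <- function(sigma, tol = 1e-12, verbose = FALSE) {
  sigma <- as.matrix(sigma)
  stopifnot(isSymmetric(sigma, tol = 1e-8))
  if (verbose) {
    sv <- svd(sigma, nu = 0, nv = 0)$d
    message("Sigma condition number: ",
            format(sv[1] / max(sv[length(sv)], .Machine$double.xmin),
                   digits = 4))
  }
  omega <- MASS::ginv(sigma, tol = tol)
  dimnames(omega) <- dimnames(sigma)
  # ginv of a symmetric matrix is symmetric up to rounding; enforce exactly
  (omega + t(omega)) / 2
}

#' Partial correlations from a precision matrix
#'
#' `rho[i,j] = -omega[i,j] / sqrt(omega[i,i] * omega[j,j])` for i != j; the
#' diagonal is set to 1 by convention. Features whose precision diagonal is
#' not positive (a rank-deficiency artifact) are excluded with a warning and
#' reported as `NA`.
#'
#' @param omega Precision matrix from [precision()].
#' @return Symmetric matrix of partial correlations.
#' @export
partial_rho <- function(omega) {
  omega <- as.matrix(omega)
  d <- diag(omega)
  bad <- d <= 0
  if (any(bad)) {
    nm <- if (!is.null(rownames(omega))) rownames(omega)[bad] else which(bad)
    warning("non-positive precision diagonal; excluding feature(s): ",
            paste(nm, collapse = ", "), call. = FALSE)
  }
  d[bad] <- NA_real_
  rho <- -omega / sqrt(outer(d, d))
  diag(rho) <- 1
  rho
}

#' Fisher-z p-values for partial correlations
#'
#' `z = 0.5 * log((1 + rho) / (1 - rho))` (arctanh); the two-sided p-value is
#' `2 * (1 - Phi(|z| * (N - M - 1)^e))` with `e = 0.5` by default (the Fisher
#' approximation uses the square root of the degrees of freedom). `|rho| = 1`
#' yields p = 0.
#'
#' @param rho Partial correlation(s), `|rho| <= 1` (vectorized; NA passes
#'   through).
#' @param N Number of samples.
#' @param M Total number of features in the matrix.
#' @param df_exponent Exponent applied to `N - M - 1` (default 0.5; 1 gives
#'   the literal un-rooted product, retained as a sensitivity switch).
#' @return A list with `z` and `p_value`.
#' @export
fisher_pvalue <- function(rho, N, M, df_exponent = 0.5) {
  df <- N - M - 1
  if (df < 1) {
    stop("N - M - 1 = ", df, " < 1: too many features for ", N,
         " samples; see the features-smaller-than-samples guard",
         call. = FALSE)
  }
  stopifnot(all(abs(rho) <= 1 + 1e-10, na.rm = TRUE))
  rho <- pmin(pmax(rho, -1), 1)
  z <- atanh(rho)
  p <- 2 * (1 - stats::pnorm(abs(z) * df^df_exponent))
  p[is.infinite(z)] <- 0
  list(z = z, p_value = pmin(pmax(p, 0), 1))
}

#' Full partial-correlation model for a feature matrix
#'
#' Chains [dcov_matrix()], [precision()], [partial_rho()] and
#' [fisher_pvalue()] into the complete Gaussian-graphical-model analysis:
#' pairwise distance covariances, pseudo-inverse precision matrix, partial
#' correlations and Fisher-z p-values.
#'
#' @inheritParams dcov_matrix
#' @inheritParams precision
#' @inheritParams fisher_pvalue
#' @param use_dcor If `TRUE`, invert the distance correlation matrix instead
#'   of the distance covariance matrix (sensitivity option; the covariance
#'   route is the default contract).
#' @return A `partial_model` list: `sigma`, `omega`, `rho`, `z`, `p`, `N`, `M`.
#' @export
partial_model <- function(fm, override_feature_guard = FALSE, tol = 1e-12,
                          df_exponent = 0.5, use_dcor = FALSE) {
  sigma <- dcov_matrix(fm, override_feature_guard = override_feature_guard)
  if (use_dcor) sigma <- dcor_matrix(fm)
  omega <- precision(sigma, tol = tol)
  rho <- partial_rho(omega)
  fz <- fisher_pvalue(rho[upper.tri(rho)], N = n_samples(fm),
                      M = ncol(sigma), df_exponent = df_exponent)
  z <- p <- matrix(NA_real_, ncol(rho), ncol(rho), dimnames = dimnames(rho))
  z[upper.tri(z)] <- fz$z
  p[upper.tri(p)] <- fz$p_value
  z[lower.tri(z)] <- t(z)[lower.tri(z)]
  p[lower.tri(p)] <- t(p)[lower.tri(p)]
  structure(list(sigma = sigma, omega = omega, rho = rho, z = z, p = p,
                 N = n_samples(fm), M = ncol(sigma)),
            class = "partial_model")
}

#' @export
print.partial_model <- function(x, ...) {
  cat("<partial_model> ", x$M, " features, ", x$N, " samples\n", sep = "")
  cat("partial correlations (rho):\n")
  print(round(x$rho, 4))
  invisible(x)
}
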