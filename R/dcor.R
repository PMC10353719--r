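#' Pairwise Euclidean distance matrix of a single feature
#'
#' For a length-n value vector the Euclidean distance between samples j and k
#' reduces to `|x_j - x_k|`.
#'
#' @param x Numeric vector, length >= 2, no missing values.
#' @return An n x n symmetric matrix with zero diagonal.
#' @export
pairwise_distance <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 2L, !anyNA(x))
  abs(outer(x, x, "-"))
}

#' Joint Euclidean distance matrix of a feature block
#'
#' Distance between samples j and k is the Euclidean norm of the difference
#' of their rows across all columns of the block: this is the n x (m-1)
#' dimensional distance used by the one-to-all mode.
#'
#' @param block Numeric matrix (samples x features), >= 1 column.
#' @return An n x n symmetric matrix with zero diagonal.
#' @export
joint_distance <- function(block) {
  block <- as.matrix(block)
  stopifnot(ncol(block) >= 1L, nrow(block) >= 2L, !anyNA(block))
  as.matrix(stats::dist(block, method = "euclidean"))
}

#' Doubly center a distance matrix
#'
#' Subtracts row means and column means and adds back the grand mean:
#' `A[j,k] = d[j,k] - rowmean_j - colmean_k + grandmean`. All row and column
#' sums of the result vanish. The means are retained as attributes
#' (`row_means`, `col_means`, `grand_mean`) for audit.
#'
#' @param d Symmetric non-negative distance matrix with zero diagonal.
#' @return The centered matrix, class `centered_distance`.
#' @export
double_center <- function(d) {
  d <- unname(as.matrix(d))
  stopifnot(nrow(d) == ncol(d))
  rm <- rowMeans(d)
  cm <- colMeans(d)
  gm <- mean(d)
  a <- d - outer(rm, rep(1, length(cm))) - outer(rep(1, length(rm)), cm) + gm
  structure(a, class = c("centered_distance", class(a)),
            row_means = rm, col_means = cm, grand_mean = gm)
}

#' Squared distance covariance of two centered matrices
#'
#' `dCov^2(X,Y) = (1/n^2) * sum_jk A[j,k] * B[j,k]`. Floating point can make
#' the self-product marginally negative; magnitudes below 1e-12 are clamped
#' to zero, anything more negative signals an internal inconsistency.
#'
#' @param A,B Doubly centered distance matrices of identical dimension.
#' @return Scalar squared distance covariance (>= 0 after clamping).
#' @export
dcov2 <- function(A, B) {
  if (!all(dim(A) == dim(B))) {
    stop("centered matrices have mismatched dimensions: ",
         nrow(A), "x", ncol(A), " vs ", nrow(B), "x", ncol(B), call. = FALSE)
  }
  v <- mean(unclass(A) * unclass(B))
  if (v < 0) {
    if (v > -1e-12) v <- 0
    else stop("squared distance covariance is negative (", v,
              "); inputs are not valid centered distance matrices",
              call. = FALSE)
  }
  v
}

#' Distance variance of a centered matrix
#'
#' `dVar(X) = dCov(X,X)` (on the squared scale, the mean of the squared
#' centered entries); returned on the same squared scale as [dcov2()].
#'
#' @param A Doubly centered distance matrix.
#' @return Scalar squared distance variance (>= 0).
#' @export
dvar2 <- function(A) dcov2(A, A)

#' Distance correlation from its components
#'
#' `dCor(X,Y) = dCov(X,Y) / sqrt(dVar(X) dVar(Y))` on the correlation scale,
#' i.e. `dCor^2 = dCov^2 / sqrt(dVarX * dVarY)`; the result is clamped into
#' `[0, 1]` (clamping never exceeds 1e-12 for valid inputs).
#'
#' @param dcov2 Squared distance covariance.
#' @param dvar_x,dvar_y Squared distance variances of the two inputs.
#' @return Scalar dCor in `[0, 1]`.
#' @export
dcor_from_stats <- function(dcov2, dvar_x, dvar_y) {
  if (dvar_x <= 0 || dvar_y <= 0) {
    stop("distance correlation undefined: zero distance variance ",
         "(constant feature)", call. = FALSE)
  }
  r2 <- dcov2 / sqrt(dvar_x * dvar_y)
  r <- sqrt(max(r2, 0))
  min(max(r, 0), 1)
}

#' Distance correlation of two value vectors
#'
#' Runs the full pipeline (pairwise distances, double centering, distance
#' covariance and variances) for a single pair of features.
#'
#' @param x,y Numeric vectors of equal length n >= 2, non-constant.
#' @return A list with `dcov2`, `dvar_x`, `dvar_y` (squared scale) and `dcor`.
#' @export
dcor_pair <- function(x, y) {
  stopifnot(length(x) == length(y))
  A <- double_center(pairwise_distance(x))
  B <- double_center(pairwise_distance(y))
  v <- dcov2(A, B)
  vx <- dvar2(A)
  vy <- dvar2(B)
  list(dcov2 = v, dvar_x = vx, dvar_y = vy,
       dcor = dcor_from_stats(v, vx, vy))
}

# Centered pairwise-distance matrices for every usable feature, computed once
# and reused across all pairs (contract: identical to uncached computation).
centered_by_feature <- function(fm) {
  feats <- usable_features(fm)
  out <- lapply(feats, function(f) double_center(pairwise_distance(fm$values[, f])))
  names(out) <- feats
  out
}

#' One-to-one distance correlation matrix
#'
#' Distance correlation between every pair of usable (non-constant) features.
#' The diagonal is 1 by convention.
#'
#' @param fm A `feature_matrix` (normally z-scored).
#' @return A symmetric m x m matrix of dCor values, dimnames = feature names.
#' @export
dcor_matrix <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  feats <- usable_features(fm)
  if (length(feats) < 2L) {
    stop("need at least 2 non-constant features, got ", length(feats),
         call. = FALSE)
  }
  cen <- centered_by_feature(fm)
  dv <- vapply(cen, dvar2, numeric(1))
  m <- length(feats)
  out <- diag(1, m)
  dimnames(out) <- list(feats, feats)
  for (i in seq_len(m - 1L)) {
    for (j in seq.int(i + 1L, m)) {
      r <- dcor_from_stats(dcov2(cen[[i]], cen[[j]]), dv[i], dv[j])
      out[i, j] <- r
      out[j, i] <- r
    }
  }
  out
}

#' One-to-all distance correlation of a single feature
#'
#' Distance correlation between feature `i`'s pairwise distance structure and
#' the joint Euclidean distance structure of all remaining usable features
#' taken together in (m-1)-dimensional space.
#'
#' @param fm A `feature_matrix`.
#' @param feature Feature name (or index into the usable features).
#' @return A list with `dcov2`, `dvar_x`, `dvar_y`, `dcor` and `n_covariates`.
#' @export
dcor_one_to_all <- function(fm, feature) {
  stopifnot(inherits(fm, "feature_matrix"))
  feats <- usable_features(fm)
  if (length(feats) < 2L) {
    stop("need at least 2 non-constant features", call. = FALSE)
  }
  if (is.numeric(feature)) feature <- feats[feature]
  if (!feature %in% feats) {
    stop("feature '", feature, "' is constant or absent; ",
         "distance correlation undefined", call. = FALSE)
  }
  others <- setdiff(feats, feature)
  A <- double_center(pairwise_distance(fm$values[, feature]))
  B <- double_center(joint_distance(fm$values[, others, drop = FALSE]))
  v <- dcov2(A, B)
  vx <- dvar2(A)
  vy <- dvar2(B)
  list(dcov2 = v, dvar_x = vx, dvar_y = vy,
       dcor = dcor_from_stats(v, vx, vy),
       n_covariates = length(others))
}
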