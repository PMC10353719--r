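#' Build the one-to-one edge table
#'
#' One row per unordered pair of usable features: distance correlation with
#' its sign (from Pearson), t-based p-value, and companion Pearson/Spearman
#' statistics.
#'
#' @param fm A z-scored `feature_matrix`.
#' @return A tibble with columns `feature_a`, `feature_b`, `dcor`, `sign`,
#'   `signed_dcor`, `p_dcor`, `pearson_r`, `p_pearson`, `spearman_rho`,
#'   `p_spearman`, `n_covariates`, `mode`.
#' @export
one_to_one_edges <- function(fm) {
  dm <- dcor_matrix(fm)
  feats <- colnames(dm)
  n <- n_samples(fm)
  idx <- which(upper.tri(dm), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  rows <- lapply(seq_len(nrow(idx)), function(k) {
    i <- idx[k, 1]; j <- idx[k, 2]
    r <- dm[i, j]
    tp <- dcor_t_pvalue(r, n)
    ps <- pearson_spearman(fm$values[, feats[i]], fm$values[, feats[j]])
    sg <- attach_sign(r, ps$pearson_r)
    tibble::tibble(feature_a = feats[i], feature_b = feats[j],
                   dcor = r, sign = sg$sign, signed_dcor = sg$signed_dcor,
                   p_dcor = tp$p_value,
                   pearson_r = ps$pearson_r, p_pearson = ps$pearson_p,
                   spearman_rho = ps$spearman_rho, p_spearman = ps$spearman_p,
                   n_covariates = 0L, mode = "one_to_one")
  })
  do.call(rbind, rows)
}

#' Build the one-to-all edge table
#'
#' One row per usable feature: distance correlation between that feature and
#' all remaining features combined (`feature_b = "ALL_OTHERS"`). The sign is
#' taken, by convention, from the Pearson correlation between the feature and
#' the per-sample mean of the other features; the unsigned `dcor` column is
#' always present.
#'
#' @inheritParams one_to_one_edges
#' @return A tibble with the same columns as [one_to_one_edges()]
#'   (`spearman` columns are `NA` in this mode; `n_covariates` = m - 1).
#' @export
one_to_all_edges <- function(fm) {
  feats <- usable_features(fm)
  n <- n_samples(fm)
  rows <- lapply(feats, function(f) {
    res <- dcor_one_to_all(fm, f)
    others_mean <- rowMeans(fm$values[, setdiff(feats, f), drop = FALSE])
    r_trend <- if (stats::sd(others_mean) == 0) 0 else
      stats::cor(fm$values[, f], others_mean)
    tp <- dcor_t_pvalue(res$dcor, n)
    sg <- attach_sign(res$dcor, r_trend)
    tibble::tibble(feature_a = f, feature_b = "ALL_OTHERS",
                   dcor = res$dcor, sign = sg$sign,
                   signed_dcor = sg$signed_dcor, p_dcor = tp$p_value,
                   pearson_r = r_trend, p_pearson = NA_real_,
                   spearman_rho = NA_real_, p_spearman = NA_real_,
                   n_covariates = res$n_covariates, mode = "one_to_all")
  })
  do.call(rbind, rows)
}

#' Build the partial-correlation edge table
#'
#' One row per unordered pair: partial distance correlation (from the
#' pseudo-inverted distance covariance matrix), Fisher-z value and p-value.
#'
#' @inheritParams partial_model
#' @return A tibble with columns `feature_a`, `feature_b`, `partial_rho`,
#'   `z`, `p_partial`, `mode`.
#' @export
partial_edges <- function(fm, override_feature_guard = FALSE,
                          df_exponent = 0.5, tol = 1e-12) {
  pm <- partial_model(fm, override_feature_guard = override_feature_guard,
                      df_exponent = df_exponent, tol = tol)
  feats <- colnames(pm$rho)
  idx <- which(upper.tri(pm$rho), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  tibble::tibble(feature_a = feats[idx[, 1]], feature_b = feats[idx[, 2]],
                 partial_rho = pm$rho[idx], z = pm$z[idx],
                 p_partial = pm$p[idx], mode = "partial")
}

#' Filter and order an edge table by user thresholds
#'
#' Retains rows with `|correlation| >= dcor_threshold` and (optionally
#' BH-adjusted) `p <= p_threshold`. The correlation column is `dcor` for the
#' distance-correlation modes and `partial_rho` for partial mode; the p
#' column is `p_dcor` / `p_partial` accordingly. Output order is
#' deterministic: descending `|correlation|`, ties broken by
#' (`feature_a`, `feature_b`) lexicographically.
#'
#' @param edges An edge tibble from one of the `*_edges()` builders.
#' @param dcor_threshold Minimum absolute correlation in `[0, 1]` (default 0).
#' @param p_threshold Maximum p-value in `[0, 1]` (default 1).
#' @param adjust `"none"` (raw p, default) or `"bh"`
#'   (Benjamini-Hochberg-adjusted p, applied before thresholding; the
#'   reported p column is then the adjusted one).
#' @return The filtered, ordered tibble.
#' @export
filter_edges <- function(edges, dcor_threshold = 0, p_threshold = 1,
                         adjust = c("none", "bh")) {
  adjust <- match.arg(adjust)
  if (dcor_threshold < 0 || dcor_threshold > 1) {
    stop("dcor_threshold must be in [0, 1], got ", dcor_threshold,
         call. = FALSE)
  }
  if (p_threshold < 0 || p_threshold > 1) {
    stop("p_threshold must be in [0, 1], got ", p_threshold, call. = FALSE)
  }
  cor_col <- if ("partial_rho" %in% names(edges)) "partial_rho" else "dcor"
  p_col <- if ("p_partial" %in% names(edges)) "p_partial" else "p_dcor"
  if (adjust == "bh") edges[[p_col]] <- bh_adjust(edges[[p_col]])
  mag <- abs(edges[[cor_col]])
  keep <- !is.na(mag) & mag >= dcor_threshold &
    !is.na(edges[[p_col]]) & edges[[p_col]] <= p_threshold
  out <- edges[keep, , drop = FALSE]
  out[order(-abs(out[[cor_col]]), out$feature_a, out$feature_b), ,
      drop = FALSE]
}

#' Run the full analysis pipeline
#'
#' Read, validate, z-score, analyse (one-to-one, one-to-all or partial),
#' attach significance, filter by thresholds and optionally write the edge
#' table to CSV. A log of dimensions, excluded constant features and config
#' is emitted via [message()] (suppress with `quiet = TRUE`).
#'
#' @param input Path to a CSV/XLSX table, or an already-parsed `raw_table`.
#' @param mode `"one_to_one"`, `"one_to_all"` or `"partial"`.
#' @param output Optional CSV output path.
#' @param dcor_threshold,p_threshold,adjust Edge filters, see
#'   [filter_edges()].
#' @param transpose Transpose the table on load (features-by-samples input).
#' @param override_feature_guard Allow partial mode with features >= samples.
#' @param df_exponent Partial-mode degrees-of-freedom exponent, see
#'   [fisher_pvalue()].
#' @param format Input file format, see [read_feature_table()].
#' @param quiet Suppress log messages.
#' @return The filtered edge tibble, invisibly when `output` is given.
#' @examples
#' rt <- simulate_scenario("linear", n_samples = 30, n_features = 4, seed = 7)
#' edges <- sidcor_run(rt, mode = "one_to_one", quiet = TRUE)
#' edges[1, c("feature_a", "feature_b", "signed_dcor", "p_dcor")]
#' @export
sidcor_run <- function(input,
                       mode = c("one_to_one", "one_to_all", "partial"),
                       output = NULL, dcor_threshold = 0, p_threshold = 1,
                       adjust = c("none", "bh"), transpose = FALSE,
                       override_feature_guard = FALSE, df_exponent = 0.5,
                       format = "auto", quiet = FALSE) {
  mode <- match.arg(mode)
  adjust <- match.arg(adjust)
  log <- function(...) if (!quiet) message("[sidcor] ", ...)
  raw <- if (inherits(input, "raw_table")) {
    if (transpose) transpose_raw(input) else input
  } else {
    read_feature_table(input, format = format, transpose = transpose)
  }
  fm <- validate_features(raw)
  log("input: ", n_samples(fm), " samples x ", ncol(fm$values), " features")
  if (length(fm$constant_features)) {
    warning("constant feature(s) excluded from correlations: ",
            paste(fm$constant_features, collapse = ", "), call. = FALSE)
  }
  fm <- zscore(fm)
  log("z-score normalization applied (per feature, n-1 denominator)")
  edges <- switch(mode,
    one_to_one = one_to_one_edges(fm),
    one_to_all = one_to_all_edges(fm),
    partial = partial_edges(fm,
                            override_feature_guard = override_feature_guard,
                            df_exponent = df_exponent))
  out <- filter_edges(edges, dcor_threshold = dcor_threshold,
                      p_threshold = p_threshold, adjust = adjust)
  log("mode = ", mode, "; thresholds: |cor| >= ", dcor_threshold,
      ", p <= ", p_threshold, " (adjust = ", adjust, "); retained ",
      nrow(out), " of ", nrow(edges), " pairs")
  if (!is.null(output)) {
    write_edges(out, output)
    log("wrote ", output)
    return(invisible(out))
  }
  out
}
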