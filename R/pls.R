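#' Partial least squares regression with a single response
#'
#' NIPALS-style PLS with deflation: each component's predictor weight vector
#' maximizes the covariance between the X-score and the (current) response,
#' X and y are deflated on the component score, and component signs are
#' oriented so every X-score correlates non-negatively with the original
#' response. `var_explained[k]` is the share of response variance captured
#' by regression on the first `k` scores minus that of the first `k - 1`
#' (scores are mutually orthogonal, so these are per-component increments).
#'
#' Inputs are expected already z-scored column-wise; [run_decoding()] takes
#' care of that in the full pipeline.
#'
#' @param x Parcel x predictor numeric matrix.
#' @param y Response vector, one value per parcel.
#' @param n_components Number of components (at most `min(nrow(x) - 1,
#'   ncol(x))`).
#' @return An object of class `pls_fit`: `x_weights` (predictor x
#'   component; the first column is the PLS1 weight vector used for gene
#'   ranking), `scores` (parcel x component), `x_loadings`, `y_loadings`,
#'   `var_explained`, `cum_var_explained`, `p_spatial` (`NULL` until
#'   [component_p_spatial()] is run).
#' @export
fit_pls <- function(x, y, n_components = 1) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  stopifnot(nrow(x) == length(y))
  if (sd(y) == 0) abort("response is constant")
  kmax <- min(nrow(x) - 1, ncol(x))
  if (n_components > kmax)
    abort(sprintf("n_components must be <= min(parcels - 1, predictors) = %d",
                  kmax))
  preds <- colnames(x) %||% paste0("x", seq_len(ncol(x)))

  y0 <- y - mean(y)
  ssy <- sum(y0^2)
  xc <- sweep(x, 2, colMeans(x))
  yc <- y0
  w_mat <- matrix(0, ncol(x), n_components,
                  dimnames = list(preds, paste0("comp", seq_len(n_components))))
  t_mat <- matrix(0, nrow(x), n_components,
                  dimnames = list(rownames(x), colnames(w_mat)))
  p_mat <- w_mat
  q_vec <- numeric(n_components)
  ve <- numeric(n_components)
  for (k in seq_len(n_components)) {
    w <- drop(crossprod(xc, yc))
    nw <- sqrt(sum(w^2))
    if (nw < .Machine$double.eps) break
    w <- w / nw
    tt <- drop(xc %*% w)
    if (sum(tt * y0) < 0) { w <- -w; tt <- -tt }
    tt2 <- sum(tt^2)
    p <- drop(crossprod(xc, tt)) / tt2
    q <- sum(yc * tt) / tt2
    xc <- xc - tcrossprod(tt, p)
    yc <- yc - tt * q
    w_mat[, k] <- w; t_mat[, k] <- tt; p_mat[, k] <- p; q_vec[k] <- q
    ve[k] <- sum(tt * y0)^2 / (tt2 * ssy)
  }
  structure(
    list(x_weights = w_mat, scores = t_mat, x_loadings = p_mat,
         y_loadings = q_vec, var_explained = ve,
         cum_var_explained = cumsum(ve), n_components = n_components,
         predictors = preds, n = nrow(x), p_spatial = NULL),
    class = "pls_fit")
}

#' @export
print.pls_fit <- function(x, ...) {
  cat(sprintf("<pls_fit> %d component(s), %d predictors, %d parcels\n",
              x$n_components, length(x$predictors), x$n))
  cat("  var explained:",
      paste(sprintf("%.3f", x$var_explained), collapse = " "), "\n")
  if (!is.null(x$p_spatial))
    cat("  spatial p:   ",
        paste(sprintf("%.4g", x$p_spatial), collapse = " "), "\n")
  invisible(x)
}

# Per-component variance explained for many permuted responses at once.
# Returns an n_components x n_perm matrix. Fast closed path for K = 1.
perm_var_explained_ <- function(x, y_perm, n_components) {
  if (n_components == 1) {
    xc <- sweep(x, 2, colMeans(x))
    yc <- sweep(y_perm, 2, colMeans(y_perm))
    w <- crossprod(xc, yc)
    tt <- xc %*% w
    num <- colSums(tt * yc)^2
    den <- colSums(tt^2) * colSums(yc^2)
    return(matrix(num / den, nrow = 1))
  }
  apply(y_perm, 2, function(yy)
    fit_pls(x, yy, n_components)$var_explained)
}

#' Spatial permutation p-values for PLS components
#'
#' The response map is permuted with a spin null and the model refit; the
#' p-value of component `k` is `(1 + #[var_explained_k(perm) >=
#' var_explained_k(obs)]) / (n_perm + 1)` (add-one estimator, never exactly
#' zero).
#'
#' @param x,y As in [fit_pls()] (z-scored, parcels aligned with `spin`).
#' @param spin A `spin_null` built over the same parcels.
#' @param n_components Components to test.
#' @return The `pls_fit` with `p_spatial` filled in.
#' @export
component_p_spatial <- function(x, y, spin, n_components = 1) {
  stopifnot(inherits(spin, "spin_null"), length(y) == ncol(spin$perm))
  fit <- fit_pls(x, y, n_components)
  # spin$perm is n_perm x n; build n x n_perm matrix of permuted maps
  y_perm <- apply(spin$perm, 1, function(p) y[p])
  ve_perm <- perm_var_explained_(x, y_perm, n_components)
  obs <- fit$var_explained
  fit$p_spatial <- vapply(seq_len(n_components), function(k)
    (1 + sum(ve_perm[k, ] >= obs[k])) / (spin$n_perm + 1), numeric(1))
  fit
}

#' Bootstrap Z-scores and ranking of PLS1 predictor weights
#'
#' Parcels are resampled with replacement and the first PLS component refit;
#' each bootstrap weight vector is sign-aligned to the original (flipped
#' when its correlation with the original weights is negative). A
#' predictor's Z is its original weight over the standard deviation of its
#' aligned bootstrap weights, its p the two-sided normal tail, its q the
#' Benjamini--Hochberg adjustment over all predictors in the run, and its
#' rank the position in decreasing Z. Weights enter the ratio on their raw
#' covariance scale (not unit-normalized): normalizing each bootstrap
#' vector couples the coordinates through the shared norm and deflates the
#' standard error and overdisperses null Z-scores.
#'
#' @param x,y As in [fit_pls()] (z-scored).
#' @param n_boot Number of bootstrap resamples (at least 100).
#' @param seed Integer seed.
#' @return A tibble of class `predictor_report`, one row per predictor in
#'   input order: `predictor`, `weight`, `boot_se`, `z`, `rank`, `p`, `q`.
#' @export
bootstrap_predictor_z <- function(x, y, n_boot = 1000, seed = 1) {
  x <- as.matrix(x)
  stopifnot(n_boot >= 100)
  fit <- fit_pls(x, y, 1)
  xc <- sweep(x, 2, colMeans(x))
  w0 <- drop(crossprod(xc, y - mean(y)))  # raw PLS1 covariance weights
  n <- nrow(x)
  with_seed_(seed, {
    wb <- matrix(0, length(w0), n_boot)
    b <- 1L; redraws <- 0L
    while (b <= n_boot) {
      idx <- sample.int(n, n, replace = TRUE)
      if (sd(y[idx]) == 0) {
        redraws <- redraws + 1L
        if (redraws > 100L) abort("too many degenerate bootstrap draws")
        next
      }
      w <- drop(crossprod(sweep(x[idx, , drop = FALSE], 2,
                                colMeans(x[idx, , drop = FALSE])),
                          y[idx] - mean(y[idx])))
      if (sum(w * w0) < 0) w <- -w
      wb[, b] <- w
      b <- b + 1L
    }
    se <- apply(wb, 1, sd)
    z <- w0 / se
    p <- 2 * pnorm(-abs(z))
    out <- tibble(
      predictor = fit$predictors,
      weight = unname(w0), boot_se = unname(se), z = unname(z),
      rank = rank(-z, ties.method = "first"),
      p = unname(p), q = fdr_bh(unname(p)))
    class(out) <- c("predictor_report", class(out))
    out
  })
}

#' Benjamini--Hochberg FDR adjustment
#'
#' Step-up adjusted q-values over one family of p-values.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return The adjusted values (same length and order).
#' @export
fdr_bh <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Decode a tracer map against expression or module eigengenes
#'
#' Full decoding run: restricts parcels (by default to the left hemisphere,
#' with the brainstem counted as left), aligns and z-scores the predictor
#' matrix and the tracer map, fits PLS across `n_components` components,
#' attaches spin-permutation p-values per component, and bootstrap-ranks the
#' PLS1 predictor weights.
#'
#' @param predictors A `region_expression`, a `module_set` (its eigengenes
#'   are used), or a parcel x predictor matrix with parcel ids as row names.
#' @param tracer A `tracer_map` tibble (`parcel_id`, `value`).
#' @param atlas A `parcel_atlas`.
#' @param hemisphere `"L"`, `"R"` or `"both"`.
#' @param include_brainstem Count the brainstem with the selected
#'   hemisphere.
#' @param n_components Components scanned for variance explained.
#' @param n_perm Spin permutations (0 disables spatial p-values).
#' @param n_boot Bootstrap resamples for predictor Z.
#' @param seed Integer seed for the spin null and the bootstrap.
#' @return An object of class `decoding_result`: `fit` (`pls_fit`),
#'   `report` (`predictor_report`, bootstrap ranking on PLS1), `parcel_ids`,
#'   `tracer_name`, `config`.
#' @export
run_decoding <- function(predictors, tracer, atlas, hemisphere = "L",
                         include_brainstem = TRUE, n_components = 15,
                         n_perm = 1000, n_boot = 1000, seed = 1) {
  xm <- if (inherits(predictors, "module_set")) predictors$eigengenes
        else expr_matrix_(predictors)
  stopifnot(!is.null(rownames(xm)))
  keep <- if (hemisphere == "both") atlas$parcel_id else
    atlas$parcel_id[atlas$hemisphere == hemisphere |
                      (include_brainstem & atlas$hemisphere == "none")]
  keep <- intersect(keep, as.integer(rownames(xm)))
  missing_tr <- setdiff(keep, tracer$parcel_id)
  if (length(missing_tr))
    abort(paste0("tracer map missing parcel(s): ",
                 paste(head(missing_tr, 10), collapse = ", ")))
  x <- xm[as.character(keep), , drop = FALSE]
  y <- tracer$value[match(keep, tracer$parcel_id)]

  const <- apply(x, 2, sd) == 0
  if (any(const)) {
    warn(sprintf("dropping %d constant predictor column(s)", sum(const)))
    x <- x[, !const, drop = FALSE]
  }
  x <- scale(x)
  y <- drop(scale(y))
  k <- min(n_components, nrow(x) - 1, ncol(x))

  if (n_perm > 0) {
    spin <- build_spin_null(atlas, keep, n_perm = n_perm, seed = seed)
    fit <- component_p_spatial(x, y, spin, k)
  } else {
    spin <- NULL
    fit <- fit_pls(x, y, k)
  }
  report <- bootstrap_predictor_z(x, y, n_boot = n_boot, seed = seed)
  structure(
    list(fit = fit, report = report, parcel_ids = keep,
         tracer_name = attr(tracer, "tracer_name") %||% "tracer",
         spin = spin,
         config = list(hemisphere = hemisphere,
                       include_brainstem = include_brainstem,
                       n_components = k, n_perm = n_perm, n_boot = n_boot,
                       seed = seed)),
    class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result> tracer '%s', %d parcels, %d predictors\n",
              x$tracer_name, length(x$parcel_ids), nrow(x$report)))
  cat(sprintf("  PLS1 var explained %.3f", x$fit$var_explained[1]))
  if (!is.null(x$fit$p_spatial))
    cat(sprintf(" (spatial p = %.4g)", x$fit$p_spatial[1]))
  cat("\n  top predictors:",
      paste(head(x$report$predictor[order(x$report$rank)], 5),
            collapse = ", "), "\n")
  invisible(x)
}
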