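#' Signed co-expression adjacency
#'
#' Transforms the gene--gene Pearson correlation matrix (over parcels) with
#' the signed soft-thresholding map `a_ij = ((1 + cor_ij) / 2)^power`, so
#' anticorrelated genes receive near-zero connection strength. Constant gene
#' columns are dropped with a warning.
#'
#' @param expr A `region_expression` or a parcel x gene matrix.
#' @param power Soft-threshold power beta (positive integer).
#' @return A gene x gene adjacency matrix in `[0, 1]` with unit diagonal.
#' @export
signed_adjacency <- function(expr, power = 14) {
  m <- expr_matrix_(expr)
  if (power < 1) abort("power must be >= 1")
  stopifnot(nrow(m) >= 3)
  con <- apply(m, 2, sd) == 0
  if (any(con)) {
    warn(sprintf("dropping %d constant gene column(s)", sum(con)))
    m <- m[, !con, drop = FALSE]
  }
  a <- ((1 + cor(m)) / 2)^power
  diag(a) <- 1
  a
}

expr_matrix_ <- function(expr) {
  if (inherits(expr, "region_expression")) expr$values else as.matrix(expr)
}

# Scale-free topology fit for one adjacency: connectivity k is binned
# (equal-width bins on k), and R^2 of log10(freq) vs log10(mean k) is signed
# by the negated slope so positively sloped (non-scale-free) fits score
# negative.
scale_free_fit_ <- function(adjacency, n_bins = 10) {
  k <- colSums(adjacency) - 1
  brk <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, brk, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  mk <- tapply(k, bin, mean)
  ok <- !is.na(freq) & freq > 0 & mk > 0
  if (sum(ok) < 3) return(list(r2 = NA_real_, slope = NA_real_,
                               mean_k = mean(k)))
  fit <- lm(log10(freq[ok]) ~ log10(mk[ok]))
  r2 <- summary(fit)$r.squared
  slope <- unname(coef(fit)[2])
  list(r2 = -sign(slope) * r2, slope = slope, mean_k = mean(k))
}

#' Choose the soft-threshold power by the scale-free topology criterion
#'
#' Scans candidate powers and returns the smallest one whose signed
#' scale-free model fit exceeds `r2_target` (R^2 of the log--log regression
#' of connectivity-bin frequency on mean binned connectivity, signed so that
#' positively sloped degree distributions are penalized). If no candidate
#' reaches the target, the power with the best fit is returned with
#' `reached = FALSE` and a warning.
#'
#' @param expr A `region_expression` or parcel x gene matrix.
#' @param powers Increasing candidate powers.
#' @param r2_target Fit threshold in (0, 1); the default 0.8 mirrors common
#'   practice for whole-transcriptome networks.
#' @param n_bins Connectivity bins for the fit.
#' @return A list with `power`, `reached`, and `fit` (tibble: power,
#'   `r2_signed`, `slope`, `mean_connectivity`).
#' @export
select_soft_threshold <- function(expr, powers = 1:20, r2_target = 0.8,
                                  n_bins = 10) {
  stopifnot(all(diff(powers) > 0), r2_target > 0, r2_target < 1)
  m <- expr_matrix_(expr)
  rows <- map(powers, function(p) {
    f <- scale_free_fit_(signed_adjacency(m, p), n_bins)
    tibble(power = p, r2_signed = f$r2, slope = f$slope,
           mean_connectivity = f$mean_k)
  })
  fit <- bind_rows(rows)
  hit <- which(fit$r2_signed > r2_target)
  if (length(hit)) {
    list(power = fit$power[hit[1]], reached = TRUE, fit = fit)
  } else {
    warn("no candidate power reached the scale-free fit target; using best fit")
    list(power = fit$power[which.max(fit$r2_signed)], reached = FALSE,
         fit = fit)
  }
}

#' Topological overlap matrix
#'
#' The standard (unsigned) topological overlap of a symmetric adjacency:
#' `tom_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for
#' `i != j`, where the sum runs over `u != i, j` and `k_i = sum_{u != i}
#' a_iu`; the diagonal is 1. `1 - tom` is the clustering dissimilarity.
#'
#' @param adjacency Symmetric gene x gene matrix in `[0, 1]`.
#' @return The TOM matrix, same dimnames, diagonal 1.
#' @export
topological_overlap <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (!isSymmetric(unname(a), tol = 1e-10)) abort("adjacency must be symmetric")
  stopifnot(min(a) >= 0, max(a) <= 1)
  diag(a) <- 1
  k <- colSums(a) - 1
  l <- a %*% a - 2 * a           # sum over u != i, j (diagonal of a is 1)
  num <- l + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Detect modules by average-linkage clustering with a static branch cut
#'
#' Average-linkage hierarchical clustering of the dissimilarity, cut at a
#' fixed height; branches smaller than `min_module_size` are labelled 0
#' (unassigned). Surviving modules are renumbered in decreasing size order
#' (1 = largest; size ties broken by first occurrence for determinism).
#'
#' @param dissimilarity Square matrix in `[0, 1]`, typically `1 - tom`.
#' @param cut_height Static cut height on the dendrogram.
#' @param min_module_size Minimum branch size to keep as a module.
#' @return A tibble: `gene`, `module` (0 = unassigned).
#' @export
detect_modules <- function(dissimilarity, cut_height = 0.99,
                           min_module_size = 30) {
  d <- as.matrix(dissimilarity)
  stopifnot(min(d) >= -1e-12, max(d) <= 1 + 1e-12)
  genes <- colnames(d) %||% as.character(seq_len(ncol(d)))
  if (min_module_size > ncol(d)) {
    warn("min_module_size exceeds gene count; all genes unassigned")
    return(tibble(gene = genes, module = 0L))
  }
  hc <- hclust(stats::as.dist(d), method = "average")
  raw <- cutree(hc, h = cut_height)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_module_size]
  # renumber by decreasing size; ties by first occurrence in `raw`
  keep <- keep[order(-sizes[keep], match(keep, unique(as.character(raw))))]
  module <- integer(length(raw))
  for (i in seq_along(keep)) module[raw == keep[i]] <- i
  tibble(gene = genes, module = module)
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' member-gene expression across parcels: member columns are standardized,
#' the leading left singular vector of the resulting matrix is taken as the
#' parcel score vector, normalized to unit Euclidean norm, and its sign
#' oriented so the mean correlation with member-gene expression is
#' non-negative. Size-1 modules use the gene's standardized profile.
#'
#' @param expr A `region_expression` or parcel x gene matrix.
#' @param labels Tibble `gene`, `module` as from [detect_modules()]; label 0
#'   is ignored.
#' @return A parcel x module matrix with columns `ME1`, `ME2`, ... and unit
#'   column norms.
#' @export
module_eigengenes <- function(expr, labels) {
  m <- expr_matrix_(expr)
  mods <- sort(unique(labels$module[labels$module > 0]))
  if (!length(mods)) abort("no modules to summarise (all genes unassigned)")
  eg <- matrix(NA_real_, nrow(m), length(mods),
               dimnames = list(rownames(m), paste0("ME", mods)))
  for (i in seq_along(mods)) {
    members <- labels$gene[labels$module == mods[i]]
    sub <- m[, members, drop = FALSE]
    sds <- apply(sub, 2, sd)
    if (all(sds == 0))
      abort(sprintf("module %d has only constant genes", mods[i]))
    sub <- sub[, sds > 0, drop = FALSE]
    z <- scale(sub)
    v <- if (ncol(z) == 1) z[, 1] else svd(z, nu = 1, nv = 0)$u[, 1]
    v <- v / sqrt(sum(v^2))
    if (mean(cor(v, sub)) < 0) v <- -v
    eg[, i] <- v
  }
  eg
}

#' Build the co-expression network and modules in one call
#'
#' Convenience orchestrator: selects (or accepts) the soft-threshold power,
#' computes the signed adjacency and TOM, clusters `1 - tom`, and computes
#' module eigengenes.
#'
#' @inheritParams select_soft_threshold
#' @inheritParams detect_modules
#' @param power Fixed soft-threshold power; if `NULL`, chosen by
#'   [select_soft_threshold()].
#' @return A list of class `module_set`: `labels` (gene, module),
#'   `eigengenes` (parcel x module, unit norms), `module_sizes`, `power`,
#'   `fit` (soft-threshold diagnostics), `tom`.
#' @export
detect_coexpression_modules <- function(expr, power = NULL, powers = 1:20,
                                        r2_target = 0.8, cut_height = 0.99,
                                        min_module_size = 30) {
  sel <- NULL
  if (is.null(power)) {
    sel <- select_soft_threshold(expr, powers, r2_target)
    power <- sel$power
  }
  adj <- signed_adjacency(expr, power)
  tom <- topological_overlap(adj)
  labels <- detect_modules(1 - tom, cut_height, min_module_size)
  eg <- module_eigengenes(expr_matrix_(expr)[, labels$gene, drop = FALSE],
                          labels)
  structure(
    list(labels = labels, eigengenes = eg,
         module_sizes = table(labels$module[labels$module > 0]),
         power = power, fit = sel$fit, tom = tom),
    class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  cat(sprintf("<module_set> %d modules over %d genes (power %d); %d unassigned\n",
              ncol(x$eigengenes), nrow(x$labels), x$power,
              sum(x$labels$module == 0)))
  invisible(x)
}

#' Pairwise correlations among marker genes of interest
#'
#' Pearson correlations across parcels between selected genes, with
#' two-sided p-values from the t distribution on `n - 2` degrees of freedom
#' (uncorrected), and the list of "strong" pairs (`|r| > 0.5`, `p < 0.05`).
#'
#' @param expr A `region_expression` or parcel x gene matrix.
#' @param genes Gene symbols of interest; genes absent from `expr` are
#'   reported and skipped.
#' @param r_threshold,p_threshold Thresholds defining a strong pair.
#' @return A tibble of unordered pairs (`gene1`, `gene2`, `r`, `p`,
#'   `strong`), with the full `r` and `p` matrices and any `missing` genes
#'   as attributes.
#' @export
pairwise_marker_correlations <- function(expr, genes, r_threshold = 0.5,
                                         p_threshold = 0.05) {
  m <- expr_matrix_(expr)
  if (nrow(m) < 3) abort("need at least 3 parcels for correlation p-values")
  missing <- setdiff(genes, colnames(m))
  if (length(missing))
    warn(paste0("gene(s) not in expression matrix, skipped: ",
                paste(missing, collapse = ", ")))
  genes <- intersect(genes, colnames(m))
  stopifnot(length(genes) >= 2)
  sub <- m[, genes, drop = FALSE]
  n <- nrow(sub)
  r <- cor(sub)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  diag(p) <- 0
  idx <- which(upper.tri(r), arr.ind = TRUE)
  out <- tibble(
    gene1 = genes[idx[, 1]], gene2 = genes[idx[, 2]],
    r = r[idx], p = p[idx]) %>%
    mutate(strong = abs(.data$r) > r_threshold & .data$p < p_threshold) %>%
    arrange(desc(abs(.data$r)))
  attr(out, "r_matrix") <- r
  attr(out, "p_matrix") <- p
  attr(out, "missing") <- missing
  class(out) <- c("gene_correlation_report", class(out))
  out
}
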