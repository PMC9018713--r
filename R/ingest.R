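#' Filter probes by above-background intensity
#'
#' A probe is retained when the fraction of samples in which its intensity
#' fell below the background level is strictly less than
#' `max_below_fraction`; with the default 0.5 this discards probes below
#' background in at least half of the samples.
#'
#' @param above_background Logical matrix, probes x samples, with probe ids
#'   as row names (`TRUE` = intensity above background), or a
#'   `donor_expression_set`.
#' @param max_below_fraction Threshold on the below-background fraction.
#' @return A tibble with one row per probe, in input order: `probe_id`,
#'   `n_samples`, `frac_below`, `retained`.
#' @export
filter_probes_by_intensity <- function(above_background,
                                       max_below_fraction = 0.5) {
  if (inherits(above_background, "donor_expression_set"))
    above_background <- above_background$above_background
  stopifnot(is.matrix(above_background),
            max_below_fraction >= 0, max_below_fraction <= 1)
  if (nrow(above_background) == 0) {
    warn("no probes supplied; returning an empty filter report")
    return(tibble(probe_id = character(), n_samples = integer(),
                  frac_below = double(), retained = logical()))
  }
  if (anyNA(above_background)) {
    bad <- rownames(above_background)[apply(is.na(above_background), 1, any)]
    abort(paste0("missing above-background flags for probe(s): ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  frac_below <- rowMeans(!above_background)
  tibble(
    probe_id = rownames(above_background),
    n_samples = ncol(above_background),
    frac_below = unname(frac_below),
    retained = unname(frac_below < max_below_fraction)
  )
}

# Spearman rho between two profiles; NA (constant input) handled by caller.
spearman_ <- function(a, b) suppressWarnings(cor(a, b, method = "spearman"))

#' Differential stability of a regional expression profile
#'
#' The mean Spearman rank correlation of one probe's regional profile over
#' all unordered pairs of donor brains. A donor pair in which either profile
#' is constant has an undefined rank correlation; such a pair contributes 0,
#' with a warning.
#'
#' @param profiles A region x donor numeric matrix (or data frame) of one
#'   probe's expression, columns being donors aligned on the same ordered
#'   region set. Regions missing in a donor may be `NA`; each pair is
#'   correlated over its complete regions.
#' @return A single value in `[-1, 1]`.
#' @export
differential_stability <- function(profiles) {
  profiles <- as.matrix(profiles)
  nd <- ncol(profiles)
  stopifnot(nd >= 2)
  pairs <- utils::combn(nd, 2)
  rho <- apply(pairs, 2, function(ij) {
    ok <- complete.cases(profiles[, ij])
    spearman_(profiles[ok, ij[1]], profiles[ok, ij[2]])
  })
  if (anyNA(rho)) {
    warn("constant donor profile(s): undefined Spearman pair(s) counted as 0")
    rho[is.na(rho)] <- 0
  }
  mean(rho)
}

# Differential stability for many probes at once. `donor_profiles` is a list
# of region x probe matrices (one per donor, aligned rows and columns, NA for
# regions a donor does not cover). Returns a named vector of DS per probe.
probe_differential_stability_ <- function(donor_profiles) {
  nd <- length(donor_profiles)
  stopifnot(nd >= 2)
  probes <- colnames(donor_profiles[[1]])
  pairs <- utils::combn(nd, 2)
  acc <- numeric(length(probes))
  n_undef <- 0L
  for (k in seq_len(ncol(pairs))) {
    a <- donor_profiles[[pairs[1, k]]]
    b <- donor_profiles[[pairs[2, k]]]
    rho <- vapply(seq_along(probes), function(j) {
      ok <- !is.na(a[, j]) & !is.na(b[, j])
      spearman_(a[ok, j], b[ok, j])
    }, numeric(1))
    n_undef <- n_undef + sum(is.na(rho))
    rho[is.na(rho)] <- 0
    acc <- acc + rho
  }
  if (n_undef > 0)
    warn(sprintf("%d undefined Spearman pair(s) (constant profiles) counted as 0",
                 n_undef))
  setNames(acc / ncol(pairs), probes)
}

#' Select one representative probe per gene by differential stability
#'
#' @param probe_ds A tibble (or data frame) with columns `probe_id`,
#'   `gene_symbol` and `ds`.
#' @return A tibble with one row per gene: `gene_symbol`, `probe_id`, `ds`,
#'   and `tie` flagging genes whose maximal DS was shared by several probes
#'   (resolved to the lexicographically smallest probe id).
#' @export
select_representative_probe <- function(probe_ds) {
  stopifnot(all(c("probe_id", "gene_symbol", "ds") %in% names(probe_ds)))
  out <- probe_ds %>%
    as_tibble() %>%
    group_by(.data$gene_symbol) %>%
    mutate(tie = sum(.data$ds == max(.data$ds)) > 1) %>%
    filter(.data$ds == max(.data$ds)) %>%
    arrange(.data$probe_id, .by_group = TRUE) %>%
    dplyr::slice(1) %>%
    ungroup() %>%
    select("gene_symbol", "probe_id", "ds", "tie") %>%
    arrange(.data$gene_symbol)
  if (any(out$tie))
    inform(sprintf(
      "%d gene(s) had tied differential stability; smallest probe_id kept",
      sum(out$tie)))
  out
}

#' Assign tissue samples of one donor to atlas parcels
#'
#' Each sample is assigned to the nearest parcel centroid within
#' `radius_mm`, considering only parcels whose tissue class matches the
#' sample and whose hemisphere matches (parcels with hemisphere `"none"`
#' accept either). Samples with no eligible parcel in range stay unassigned.
#' Afterwards every eligible-but-empty parcel is assigned the single nearest
#' eligible sample to its centroid, so that a donor covers every parcel its
#' samples could in principle reach. Distance ties (within 1e-9 mm) are
#' broken toward the lower parcel id.
#'
#' @param samples Tibble of one donor's samples: `sample_id`, `x`, `y`, `z`,
#'   `hemisphere` (`"L"`/`"R"`), `tissue_class`.
#' @param atlas A `parcel_atlas`.
#' @param radius_mm Assignment radius in mm (default 2).
#' @return A list with `assignment` (tibble: `sample_id`, `parcel_id`,
#'   `distance`, `method` = `"radius"`/`"centroid_fallback"`; unassigned
#'   samples have `NA` parcel) and `fallback` (the subset of fallback rows).
#' @export
assign_samples_to_parcels <- function(samples, atlas, radius_mm = 2) {
  stopifnot(radius_mm > 0,
            all(c("sample_id", "x", "y", "z", "hemisphere", "tissue_class")
                %in% names(samples)))
  xyz_s <- as.matrix(samples[, c("x", "y", "z")])
  stopifnot(all(is.finite(xyz_s)))
  xyz_p <- as.matrix(atlas[, c("x", "y", "z")])
  ns <- nrow(samples); np <- nrow(atlas)

  elig <- matrix(FALSE, ns, np)
  for (j in seq_len(np)) {
    elig[, j] <- samples$tissue_class == atlas$tissue_class[j] &
      (atlas$hemisphere[j] == "none" | samples$hemisphere == atlas$hemisphere[j])
  }
  d <- sqrt(outer(rowSums(xyz_s^2), rep(1, np)) +
            outer(rep(1, ns), rowSums(xyz_p^2)) -
            2 * xyz_s %*% t(xyz_p))

  # ties within 1e-9 break towards the smallest id (parcel_id for
  # sample->parcel lookups, sample_id for the centroid fallback)
  pick_min <- function(dist_vec, ok, ids) {
    ok <- ok & is.finite(dist_vec)
    if (!any(ok)) return(NA_integer_)
    dmin <- min(dist_vec[ok])
    cand <- which(ok & dist_vec <= dmin + 1e-9)
    cand[which.min(ids[cand])]
  }
  sample_rank <- match(samples$sample_id, sort(samples$sample_id))

  assigned <- rep(NA_integer_, ns)
  dists <- rep(NA_real_, ns)
  for (i in seq_len(ns)) {
    j <- pick_min(d[i, ], elig[i, ] & d[i, ] <= radius_mm, atlas$parcel_id)
    if (!is.na(j)) { assigned[i] <- j; dists[i] <- d[i, j] }
  }

  method <- ifelse(is.na(assigned), NA_character_, "radius")
  # centroid fallback: empty but reachable parcels take their nearest sample
  empty <- setdiff(which(colSums(elig) > 0), unique(assigned[!is.na(assigned)]))
  fb_rows <- list()
  for (j in empty) {
    i <- pick_min(d[, j], elig[, j], sample_rank)
    fb_rows[[length(fb_rows) + 1L]] <- tibble(
      sample_id = samples$sample_id[i], parcel_id = atlas$parcel_id[j],
      distance = d[i, j], method = "centroid_fallback")
  }
  fallback <- if (length(fb_rows)) bind_rows(fb_rows) else
    tibble(sample_id = character(), parcel_id = integer(),
           distance = double(), method = character())

  assignment <- tibble(
    sample_id = samples$sample_id,
    parcel_id = ifelse(is.na(assigned), NA_integer_, atlas$parcel_id[assigned]),
    distance = dists, method = method)
  # a fallback row may re-use a sample already assigned elsewhere; it is an
  # additional parcel assignment, appended after the radius-based rows
  assignment <- bind_rows(assignment, fallback)
  list(assignment = assignment, fallback = fallback)
}

#' Robust sigmoid normalization of a donor expression matrix
#'
#' Each gene column is passed through the scaled robust sigmoid
#' `s(x) = 1 / (1 + exp(-(x - median) / (IQR / 1.35)))` (median and
#' interquartile range taken across parcels) and then min--max rescaled to
#' span exactly `[0, 1]`. Genes constant across parcels (IQR = 0) map to a
#' flat 0.5 and are not rescaled. `NA` entries (parcels a donor does not
#' cover) pass through as `NA`.
#'
#' @param m A parcel x gene numeric matrix.
#' @return A matrix of the same shape with values in `[0, 1]` (or `NA`).
#' @export
normalize_robust_sigmoid <- function(m) {
  m <- as.matrix(m)
  all_na <- colSums(!is.na(m)) == 0
  if (any(all_na))
    abort(paste0("gene column(s) entirely missing: ",
                 paste(head(colnames(m)[all_na], 5), collapse = ", ")))
  out <- m
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    ok <- !is.na(x)
    med <- median(x[ok])
    iqr <- IQR(x[ok])
    if (iqr == 0) {
      out[ok, j] <- 0.5
    } else {
      s <- 1 / (1 + exp(-(x[ok] - med) / (iqr / 1.35)))
      out[ok, j] <- (s - min(s)) / (max(s) - min(s))
    }
  }
  out
}

#' Average per-donor expression matrices into one regional matrix
#'
#' Entrywise mean across donors, ignoring donors that do not cover a parcel
#' (all-`NA` row for that donor). Every parcel must be covered by at least
#' one donor.
#'
#' @param per_donor Named list of parcel x gene matrices with identical
#'   dimnames (parcels and genes aligned).
#' @return A `region_expression` object; see [region_expression()].
#' @export
aggregate_donors <- function(per_donor) {
  stopifnot(is.list(per_donor), length(per_donor) >= 1)
  dn <- dimnames(per_donor[[1]])
  for (m in per_donor)
    if (!identical(dimnames(m), dn))
      abort("per-donor matrices must share parcel and gene ordering")
  arr <- array(unlist(per_donor), dim = c(dim(per_donor[[1]]),
                                          length(per_donor)))
  cover <- apply(!is.na(arr), c(1, 3), any)
  if (any(rowSums(cover) == 0))
    abort(paste0("parcel(s) covered by no donor: ",
                 paste(head(dn[[1]][rowSums(cover) == 0], 5), collapse = ", ")))
  values <- apply(arr, c(1, 2), function(v) mean(v, na.rm = TRUE))
  dimnames(values) <- dn
  region_expression(values, per_donor = per_donor)
}

#' Construct a regional expression object
#'
#' The pipeline's central container: a parcel x gene matrix of expression
#' values on the unit interval, with parcel ids as row names and gene
#' symbols as column names.
#'
#' @param values Parcel x gene numeric matrix (row names: parcel ids,
#'   column names: gene symbols). No missing entries.
#' @param per_donor Optional named list of the per-donor matrices that were
#'   averaged.
#' @return An object of class `region_expression`.
#' @export
region_expression <- function(values, per_donor = NULL) {
  values <- as.matrix(values)
  stopifnot(!is.null(rownames(values)), !is.null(colnames(values)),
            !anyNA(values))
  structure(list(values = values,
                 parcel_ids = as.integer(rownames(values)),
                 gene_symbols = colnames(values),
                 per_donor = per_donor),
            class = "region_expression")
}

#' @export
print.region_expression <- function(x, ...) {
  cat(sprintf("<region_expression> %d parcels x %d genes, range [%.3f, %.3f]\n",
              nrow(x$values), ncol(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as_tibble.region_expression <- function(x, ...) {
  out <- as_tibble(x$values)
  tibble(parcel_id = x$parcel_ids, out)
}

#' Ingest multi-donor probe-level data into a regional expression matrix
#'
#' Runs the full pre-processing chain: intensity-based probe filtering,
#' sample-to-parcel assignment with centroid fallback (per donor), averaging
#' of samples within parcel and donor, differential-stability probe
#' selection (one probe per gene), robust-sigmoid normalization per donor,
#' and averaging across donors.
#'
#' @param dataset A `donor_expression_set` (from [generate_expression()] or
#'   [read_donor_dataset()]).
#' @param radius_mm Sample-to-parcel assignment radius in mm.
#' @param max_below_fraction Probe filter threshold; see
#'   [filter_probes_by_intensity()].
#' @return A `region_expression` whose `report` attribute records the probe
#'   filter table, the DS score and selected probe per gene, and the
#'   centroid-fallback assignments per donor.
#' @export
ingest_expression <- function(dataset, radius_mm = 2, max_below_fraction = 0.5) {
  stopifnot(inherits(dataset, "donor_expression_set"))
  atlas <- dataset$atlas
  filt <- filter_probes_by_intensity(dataset$above_background,
                                     max_below_fraction)
  kept <- filt$probe_id[filt$retained]
  if (length(kept) == 0) abort("all probes removed by the intensity filter")
  intens <- dataset$intensities[kept, , drop = FALSE]
  pmap <- dataset$probe_map[match(kept, dataset$probe_map$probe_id), ]

  donors <- unique(dataset$samples$donor_id)
  donor_mats <- list()
  fallbacks <- list()
  for (d in donors) {
    smp <- dataset$samples[dataset$samples$donor_id == d, ]
    asg <- assign_samples_to_parcels(smp, atlas, radius_mm)
    fallbacks[[d]] <- asg$fallback
    a <- asg$assignment[!is.na(asg$assignment$parcel_id), ]
    m <- matrix(NA_real_, nrow(atlas), length(kept),
                dimnames = list(atlas$parcel_id, kept))
    for (p in unique(a$parcel_id)) {
      sids <- a$sample_id[a$parcel_id == p]
      m[as.character(p), ] <-
        rowMeans(intens[, sids, drop = FALSE])
    }
    donor_mats[[d]] <- m
  }

  ds <- probe_differential_stability_(donor_mats)
  sel <- select_representative_probe(
    tibble(probe_id = kept, gene_symbol = pmap$gene_symbol, ds = unname(ds)))

  per_donor <- map(donor_mats, function(m) {
    mm <- m[, sel$probe_id, drop = FALSE]
    colnames(mm) <- sel$gene_symbol
    normalize_robust_sigmoid(mm)
  })
  expr <- aggregate_donors(per_donor)
  attr(expr, "report") <- list(
    probe_filter = filt,
    probe_selection = sel,
    fallback_assignments = fallbacks
  )
  expr
}
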