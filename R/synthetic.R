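#' Specification of planted co-expression structure
#'
#' Describes the ground-truth module structure used by
#' [generate_expression()]: `n_modules` latent spatial factors, each with
#' `genes_per_module` member genes whose regional profile is
#' `loading * factor + noise`, plus `n_background_genes` genes tied to no
#' factor. The noise budget is split between a gene-private regional pattern
#' shared across donors and donor-specific measurement noise, so that every
#' gene (background genes included) has a reproducible cross-donor profile
#' for differential-stability probe selection to latch onto.
#'
#' @param n_modules Number of planted modules.
#' @param genes_per_module Member genes per module.
#' @param n_background_genes Genes belonging to no module.
#' @param loading Member-gene loading on the module's latent factor, in (0, 1].
#' @param noise_sd Standard deviation of the non-factor part of a member
#'   gene's profile.
#' @param private_share Fraction of the noise variance carried by the
#'   gene-private pattern shared across donors (the rest is donor noise).
#' @return A list of class `module_spec`.
#' @export
module_spec <- function(n_modules = 5, genes_per_module = 20,
                        n_background_genes = 100, loading = 0.8,
                        noise_sd = 0.4, private_share = 0.5) {
  stopifnot(n_modules >= 1, genes_per_module >= 2, n_background_genes >= 0,
            loading > 0, loading <= 1, noise_sd >= 0,
            private_share >= 0, private_share <= 1)
  structure(
    list(n_modules = n_modules, genes_per_module = genes_per_module,
         n_background_genes = n_background_genes, loading = loading,
         noise_sd = noise_sd, private_share = private_share,
         n_genes = n_modules * genes_per_module + n_background_genes),
    class = "module_spec"
  )
}

#' Specification of a synthetic tracer map
#'
#' @param target_r2 Fraction of map variance carried by the target signal,
#'   in `[0, 1)`. `0` yields a map of pure spatially smooth noise.
#' @param smoothness_fwhm Full width at half maximum of the angular smoothing
#'   kernel for the noise field, in degrees of arc on the hemisphere sphere.
#' @param gradient If `TRUE` the signal is the anterior--posterior coordinate
#'   of each parcel rather than a supplied factor or eigengene.
#' @return A list of class `map_spec`.
#' @export
map_spec <- function(target_r2 = 0.6, smoothness_fwhm = 25, gradient = FALSE) {
  stopifnot(target_r2 >= 0, target_r2 < 1, smoothness_fwhm > 0)
  structure(list(target_r2 = target_r2, smoothness_fwhm = smoothness_fwhm,
                 gradient = gradient),
            class = "map_spec")
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed_ <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Quasi-uniform Fibonacci lattice of n points on the unit sphere.
fibonacci_sphere_ <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  golden <- pi * (3 - sqrt(5))
  phi <- golden * (seq_len(n) - 1)
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

# Uniform random 3x3 rotation (Haar measure) via QR with sign correction.
random_rotation_ <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  q <- q %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Generate a synthetic parcel atlas
#'
#' Builds a Desikan--Killiany-like atlas: cortical parcels as a jittered
#' Fibonacci lattice on per-hemisphere unit spheres (scaled to mm and offset
#' laterally), subcortical parcels inside a medial ellipsoid, and optionally
#' a single brainstem parcel. The default configuration (34 cortical and 7
#' subcortical parcels per hemisphere plus brainstem) yields 83 parcels, of
#' which 42 are left-hemisphere when the brainstem is counted as left.
#'
#' @param n_cortical_per_hemi Cortical parcels per hemisphere (at least 2).
#' @param n_subcortical_per_hemi Subcortical parcels per hemisphere.
#' @param include_brainstem Add a single brainstem parcel with hemisphere
#'   `"none"`.
#' @param seed Integer seed; the same seed gives a bit-identical atlas.
#' @return A tibble of class `parcel_atlas` with columns `parcel_id`, `name`,
#'   `hemisphere` (`"L"`, `"R"`, `"none"`), `tissue_class` (`"cortical"`,
#'   `"subcortical"`, `"brainstem"`), centroid coordinates `x`, `y`, `z` (mm)
#'   and unit-sphere coordinates `sx`, `sy`, `sz` (`NA` for non-cortical
#'   parcels).
#' @export
generate_atlas <- function(n_cortical_per_hemi = 34, n_subcortical_per_hemi = 7,
                           include_brainstem = TRUE, seed = 1) {
  stopifnot(n_cortical_per_hemi >= 2, n_subcortical_per_hemi >= 0)
  with_seed_(seed, {
    lat <- fibonacci_sphere_(n_cortical_per_hemi)
    lat <- lat %*% t(random_rotation_())  # seed-dependent jitter
    colnames(lat) <- c("x", "y", "z")
    radius <- 33
    mk_ctx <- function(sphere, hemi) {
      offset <- c(if (hemi == "L") -36 else 36, -18, 18)
      cent <- sweep(sphere * radius, 2, offset, "+")
      tibble(
        name = sprintf("ctx_%s_%02d", tolower(hemi), seq_len(nrow(sphere))),
        hemisphere = hemi, tissue_class = "cortical",
        x = cent[, 1], y = cent[, 2], z = cent[, 3],
        sx = sphere[, 1], sy = sphere[, 2], sz = sphere[, 3]
      )
    }
    # Right-hemisphere lattice mirrors the left in x, like homologous cortex.
    lat_r <- lat
    lat_r[, 1] <- -lat_r[, 1]
    mk_sub <- function(n, hemi) {
      if (n == 0) return(NULL)
      sgn <- if (hemi == "L") -1 else 1
      tibble(
        name = sprintf("sub_%s_%02d", tolower(hemi), seq_len(n)),
        hemisphere = hemi, tissue_class = "subcortical",
        x = sgn * runif(n, 4, 16), y = rnorm(n, -18, 7), z = rnorm(n, 2, 6),
        sx = NA_real_, sy = NA_real_, sz = NA_real_
      )
    }
    parts <- list(
      mk_ctx(lat, "L"), mk_sub(n_subcortical_per_hemi, "L"),
      mk_ctx(lat_r, "R"), mk_sub(n_subcortical_per_hemi, "R")
    )
    if (include_brainstem) {
      parts <- c(parts, list(tibble(
        name = "brainstem", hemisphere = "none", tissue_class = "brainstem",
        x = 0, y = -28, z = -38, sx = NA_real_, sy = NA_real_, sz = NA_real_
      )))
    }
    atlas <- bind_rows(parts)
    atlas <- tibble(parcel_id = seq_len(nrow(atlas)), atlas)
    class(atlas) <- c("parcel_atlas", class(atlas))
    atlas
  })
}

# Pairwise parcel distances on a common angular scale (radians): great-circle
# distance between cortical parcels (right-hemisphere sphere coordinates
# mirrored into the left frame so homologous parcels coincide), centroid
# Euclidean distance divided by the cortical radius otherwise.
parcel_angular_dist_ <- function(atlas) {
  n <- nrow(atlas)
  s <- as.matrix(atlas[, c("sx", "sy", "sz")])
  s[atlas$hemisphere == "R", 1] <- -s[atlas$hemisphere == "R", 1]
  ctx <- atlas$tissue_class == "cortical"
  d <- as.matrix(dist(as.matrix(atlas[, c("x", "y", "z")]))) / 33
  if (any(ctx)) {
    g <- s[ctx, , drop = FALSE] %*% t(s[ctx, , drop = FALSE])
    d[ctx, ctx] <- acos(pmin(1, pmax(-1, g)))
  }
  d
}

# n spatially smooth, standardized noise fields over parcels: white noise
# kernel-smoothed with a Gaussian of the given angular FWHM (degrees). The
# sphere-distance kernel is defined on the cortical sheet only; subcortical
# and brainstem parcels are anatomically distinct nuclei and keep
# independent white noise.
smooth_parcel_noise_ <- function(atlas, n = 1, fwhm_deg = 25) {
  d <- parcel_angular_dist_(atlas)
  sigma <- (fwhm_deg * pi / 180) / (2 * sqrt(2 * log(2)))
  k <- exp(-d^2 / (2 * sigma^2))
  ctx <- atlas$tissue_class == "cortical"
  k[!ctx, ] <- 0
  k[, !ctx] <- 0
  diag(k)[!ctx] <- 1
  f <- k %*% matrix(rnorm(nrow(atlas) * n), nrow(atlas), n)
  scale(f)[, , drop = FALSE]
}

#' Generate synthetic multi-donor probe-level expression data
#'
#' Emulates the inputs of an Allen-atlas-style ingestion: several donors with
#' tissue samples jittered around parcel centroids, probe-level intensities
#' for genes organised into planted co-expression modules, redundant probes
#' per gene with inflated noise (so differential-stability selection has a
#' ground-truth best probe), and a planted fraction of probes flagged below
#' background in at least half of all samples. All donors sample the left
#' hemisphere and brainstem; only the first two donors sample the right
#' hemisphere, mirroring the lateralised sampling of the donor cohort the
#' pipeline is designed for.
#'
#' @param atlas A `parcel_atlas`, e.g. from [generate_atlas()].
#' @param spec A [module_spec()].
#' @param n_donors Number of donors (at least 2).
#' @param samples_per_parcel_mean Poisson mean of samples per parcel and donor.
#' @param probes_per_gene_mean Mean probes per gene (each gene gets at least
#'   one; extra probes have inflated noise).
#' @param background_probe_rate Fraction of probes planted as
#'   below-background in >= 50% of samples (drawn from non-best probes).
#' @param factor_fwhm Angular FWHM (degrees) of the latent module factors.
#' @param seed Integer seed.
#' @return A list of class `donor_expression_set` with elements `samples`
#'   (tibble: sample_id, donor_id, x, y, z, hemisphere, tissue_class),
#'   `intensities` and `above_background` (probe x sample matrices),
#'   `probe_map` (tibble: probe_id, gene_symbol), `atlas`, and `truth`
#'   (planted gene->module labels, latent factors, best probe per gene,
#'   planted background probes).
#' @export
generate_expression <- function(atlas, spec = module_spec(), n_donors = 3,
                                samples_per_parcel_mean = 1.5,
                                probes_per_gene_mean = 1.5,
                                background_probe_rate = 0.1,
                                factor_fwhm = 40, seed = 1) {
  stopifnot(inherits(atlas, "parcel_atlas"), n_donors >= 2,
            samples_per_parcel_mean > 0, probes_per_gene_mean >= 1,
            background_probe_rate >= 0, background_probe_rate < 1)
  with_seed_(seed, {
    np <- nrow(atlas)
    ng <- spec$n_genes
    genes <- sprintf("GENE%04d", seq_len(ng))
    labels <- c(rep(seq_len(spec$n_modules), each = spec$genes_per_module),
                rep(0L, spec$n_background_genes))

    factors <- smooth_parcel_noise_(atlas, spec$n_modules, factor_fwhm)
    colnames(factors) <- sprintf("factor_%d", seq_len(spec$n_modules))
    rownames(factors) <- atlas$parcel_id

    sd_tot <- sqrt(spec$loading^2 + spec$noise_sd^2)
    private <- matrix(rnorm(np * ng), np, ng)
    base <- matrix(0, np, ng, dimnames = list(atlas$parcel_id, genes))
    a_priv <- sqrt(spec$private_share)
    a_don <- sqrt(1 - spec$private_share)
    for (g in seq_len(ng)) {
      base[, g] <- if (labels[g] > 0)
        spec$loading * factors[, labels[g]] + a_priv * spec$noise_sd * private[, g]
      else
        sd_tot * a_priv * private[, g]
    }
    donor_sd <- ifelse(labels > 0, a_don * spec$noise_sd, a_don * sd_tot)

    # probes: probe 1 per gene is the low-noise ground-truth best
    n_probes_per_gene <- 1L + rpois(ng, max(0, probes_per_gene_mean - 1))
    probe_gene <- rep(seq_len(ng), n_probes_per_gene)
    n_probes <- length(probe_gene)
    probe_ids <- sprintf("probe_%04d", seq_len(n_probes))
    is_best <- !duplicated(probe_gene)
    # redundant probes carry strongly inflated noise, so the designated best
    # probe is a clear differential-stability ground truth
    probe_noise <- ifelse(is_best, 0.1, runif(n_probes, 1.5, 2.5))

    # donor samples
    hemis_for <- function(d) if (d <= 2) c("L", "R", "none") else c("L", "none")
    samples <- list()
    for (d in seq_len(n_donors)) {
      elig <- atlas[atlas$hemisphere %in% hemis_for(d), ]
      ns <- rpois(nrow(elig), samples_per_parcel_mean)
      if (sum(ns) == 0) ns[1] <- 1L
      idx <- rep(seq_len(nrow(elig)), ns)
      samples[[d]] <- tibble(
        donor_id = sprintf("donor%d", d),
        parcel_id = elig$parcel_id[idx],
        x = elig$x[idx] + rnorm(length(idx), 0, 0.8),
        y = elig$y[idx] + rnorm(length(idx), 0, 0.8),
        z = elig$z[idx] + rnorm(length(idx), 0, 0.8),
        hemisphere = ifelse(elig$hemisphere[idx] == "none", "L",
                            elig$hemisphere[idx]),
        tissue_class = elig$tissue_class[idx]
      )
    }
    samples <- bind_rows(samples)
    samples <- tibble(sample_id = sprintf("s%04d", seq_len(nrow(samples))),
                      samples)

    # probe intensities: log2 scale value = donor gene value + measurement
    # noise + probe noise, mapped through 2^(8 + value)
    ns_tot <- nrow(samples)
    pidx <- match(samples$parcel_id, atlas$parcel_id)
    didx <- as.integer(sub("donor", "", samples$donor_id))
    donor_eps <- array(rnorm(np * ng * n_donors), c(np, ng, n_donors))
    logval <- matrix(0, n_probes, ns_tot,
                     dimnames = list(probe_ids, samples$sample_id))
    for (s in seq_len(ns_tot)) {
      gval <- base[pidx[s], ] + donor_sd * donor_eps[pidx[s], , didx[s]] +
        rnorm(ng, 0, 0.1)
      logval[, s] <- gval[probe_gene] + probe_noise * rnorm(n_probes)
    }
    intensities <- 2^(8 + logval)

    # planted background probes: below background in >= 50% of samples
    extra <- which(!is_best)
    n_bg <- min(length(extra), round(background_probe_rate * n_probes))
    bg_probes <- sort(sample(extra, n_bg))
    frac_below <- runif(n_probes, 0, 0.3)
    frac_below[bg_probes] <- runif(n_bg, 0.55, 0.85)
    above <- matrix(TRUE, n_probes, ns_tot,
                    dimnames = dimnames(logval))
    for (p in seq_len(n_probes)) {
      nb <- if (p %in% bg_probes) max(ceiling(frac_below[p] * ns_tot),
                                      ceiling(ns_tot / 2))
            else min(floor(frac_below[p] * ns_tot), ceiling(ns_tot / 2) - 1L)
      if (nb > 0) above[p, sample(ns_tot, nb)] <- FALSE
    }

    structure(
      list(
        samples = samples[, c("sample_id", "donor_id", "x", "y", "z",
                              "hemisphere", "tissue_class")],
        sample_parcels = samples[, c("sample_id", "donor_id", "parcel_id")],
        intensities = intensities,
        above_background = above,
        probe_map = tibble(probe_id = probe_ids, gene_symbol = genes[probe_gene]),
        atlas = atlas,
        truth = list(
          gene_module = tibble(gene_symbol = genes, module = labels),
          factors = factors,
          best_probe = tibble(gene_symbol = genes,
                              probe_id = probe_ids[is_best]),
          background_probes = probe_ids[bg_probes]
        ),
        spec = spec, seed = seed
      ),
      class = "donor_expression_set"
    )
  })
}

#' @export
print.donor_expression_set <- function(x, ...) {
  cat(sprintf(
    "<donor_expression_set> %d donors, %d samples, %d probes / %d genes, %d parcels\n",
    length(unique(x$samples$donor_id)), nrow(x$samples),
    nrow(x$intensities), nrow(x$truth$gene_module), nrow(x$atlas)))
  invisible(x)
}

#' Generate a synthetic parcellated tracer map
#'
#' Constructs a parcel-level radiotracer binding map as
#' `sqrt(r2) * signal + sqrt(1 - r2) * noise`, where the noise field is
#' spatially autocorrelated (white noise smoothed over angular parcel
#' distance) and orthogonalised against the signal so the in-sample variance
#' share of the signal equals `target_r2` exactly. With `target_r2 = 0` (or a
#' `NULL` signal) the map is pure smooth noise, independent of any expression
#' factor. With `gradient = TRUE` in the map spec, the signal is the
#' anterior--posterior (y) coordinate of the parcel centroids.
#'
#' @param atlas A `parcel_atlas`.
#' @param signal Numeric vector over the atlas parcels (e.g. a latent factor
#'   or module eigengene), or `NULL` for a pure-noise map. Ignored when the
#'   map spec requests a gradient.
#' @param spec A [map_spec()].
#' @param tracer_name Name stored with the map.
#' @param seed Integer seed.
#' @return A tibble of class `tracer_map` with columns `parcel_id`, `value`
#'   and attributes `tracer_name`, `zscored` and `truth` (target and realized
#'   in-sample R^2).
#' @export
generate_tracer_map <- function(atlas, signal = NULL, spec = map_spec(),
                                tracer_name = "synthetic_tracer", seed = 1) {
  stopifnot(inherits(atlas, "parcel_atlas"))
  with_seed_(seed, {
    np <- nrow(atlas)
    if (isTRUE(spec$gradient)) signal <- atlas$y
    use_signal <- spec$target_r2 > 0
    if (use_signal && is.null(signal))
      abort("target_r2 > 0 requires a signal (factor, eigengene or gradient)")
    if (!is.null(signal) && length(signal) != np)
      abort("signal length must equal the number of atlas parcels")
    noise <- drop(smooth_parcel_noise_(atlas, 1, spec$smoothness_fwhm))
    if (use_signal) {
      s <- drop(scale(signal))
      e <- stats::residuals(lm(noise ~ s))
      e <- drop(scale(e))
      value <- sqrt(spec$target_r2) * s + sqrt(1 - spec$target_r2) * e
      realized <- summary(lm(value ~ s))$r.squared
    } else {
      value <- drop(scale(noise))
      realized <- 0
    }
    out <- tibble(parcel_id = atlas$parcel_id, value = as.numeric(value))
    attr(out, "tracer_name") <- tracer_name
    attr(out, "zscored") <- FALSE
    attr(out, "truth") <- list(target_r2 = spec$target_r2,
                               realized_r2 = realized)
    class(out) <- c("tracer_map", class(out))
    out
  })
}
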