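#' Build a spatial-autocorrelation-preserving permutation null
#'
#' For each permutation, cortical parcels are permuted by a random rotation
#' of their unit-sphere coordinates: a uniform rotation is drawn for the
#' left hemisphere (its x-mirrored image is applied to the right), parcels
#' are rotated, and each original parcel slot takes the value of a rotated
#' parcel via a greedy one-to-one nearest-neighbour matching (pairs accepted
#' in increasing distance, forcing a bijection). Subcortical and brainstem
#' parcels, which have no spherical embedding, receive an independent
#' uniform shuffle among themselves. The result is a set of bijections on
#' the included parcels that preserve the spatial autocorrelation of
#' cortical maps.
#'
#' @param atlas A `parcel_atlas`.
#' @param included_parcels Parcel ids to permute over (default: all).
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @param rotations Optional list of `n_perm` fixed 3x3 rotation matrices
#'   for the left hemisphere (a test hook; the identity matrix with
#'   `shuffle_noncortical = FALSE` yields identity permutations).
#' @param shuffle_noncortical Shuffle non-cortical parcels (default `TRUE`).
#' @return An object of class `spin_null`: list with `perm` (n_perm x
#'   n_included index matrix: row `b`, entry `j` gives the included-parcel
#'   position whose value parcel `j` receives in permutation `b`),
#'   `parcel_ids`, `n_perm`, `seed`.
#' @export
build_spin_null <- function(atlas, included_parcels = atlas$parcel_id,
                            n_perm = 1000, seed = 1, rotations = NULL,
                            shuffle_noncortical = TRUE) {
  stopifnot(inherits(atlas, "parcel_atlas"), n_perm >= 1)
  sub <- atlas[match(included_parcels, atlas$parcel_id), ]
  if (anyNA(sub$parcel_id)) abort("included_parcels not all present in atlas")
  n <- nrow(sub)
  ctx <- which(sub$tissue_class == "cortical")
  rest <- setdiff(seq_len(n), ctx)
  do_rotate <- length(ctx) >= 2
  if (!do_rotate && length(ctx) > 0)
    warn("fewer than 2 cortical parcels: rotations skipped, all shuffled")
  if (!do_rotate) { rest <- seq_len(n); ctx <- integer() }

  hemi <- sub$hemisphere[ctx]
  s <- as.matrix(sub[ctx, c("sx", "sy", "sz")])
  mirror <- diag(c(-1, 1, 1))

  with_seed_(seed, {
    perm <- matrix(0L, n_perm, n)
    for (b in seq_len(n_perm)) {
      pi_b <- seq_len(n)
      if (do_rotate) {
        rot_l <- if (!is.null(rotations)) rotations[[b]] else random_rotation_()
        for (h in c("L", "R")) {
          ih <- ctx[hemi == h]
          if (length(ih) < 2) next
          rot <- if (h == "L") rot_l else mirror %*% rot_l %*% mirror
          sh <- s[hemi == h, , drop = FALSE]
          rotated <- sh %*% t(rot)
          pi_b[ih] <- ih[greedy_match_(rotated, sh)]
        }
      }
      if (shuffle_noncortical && length(rest) > 1)
        pi_b[rest] <- rest[sample(length(rest))]
      perm[b, ] <- pi_b
    }
    structure(list(perm = perm, parcel_ids = sub$parcel_id,
                   n_perm = n_perm, seed = seed),
              class = "spin_null")
  })
}

# Greedy bijective nearest-neighbour matching between rotated and original
# points. Returns g with g[j] = index of the rotated point whose value the
# original slot j receives: pairs (rotated i, original j) are accepted in
# order of increasing distance, each side used once.
greedy_match_ <- function(rotated, original) {
  n <- nrow(original)
  d2 <- outer(rowSums(rotated^2), rep(1, n)) +
    outer(rep(1, n), rowSums(original^2)) - 2 * rotated %*% t(original)
  ord <- order(d2)
  g <- integer(n)
  used_i <- logical(n); used_j <- logical(n)
  left <- n
  for (k in ord) {
    i <- (k - 1) %% n + 1
    j <- (k - 1) %/% n + 1
    if (used_i[i] || used_j[j]) next
    g[j] <- i
    used_i[i] <- TRUE; used_j[j] <- TRUE
    left <- left - 1
    if (left == 0) break
  }
  g
}

#' Apply a spin permutation to a parcel map
#'
#' @param spin A `spin_null`.
#' @param values Numeric vector aligned to `spin$parcel_ids`.
#' @param b Permutation index in `1..n_perm`.
#' @return The permuted vector.
#' @export
spin_permute <- function(spin, values, b) {
  stopifnot(inherits(spin, "spin_null"), length(values) == ncol(spin$perm),
            b >= 1, b <= spin$n_perm)
  values[spin$perm[b, ]]
}

#' @export
print.spin_null <- function(x, ...) {
  cat(sprintf("<spin_null> %d permutations over %d parcels (seed %d)\n",
              x$n_perm, length(x$parcel_ids), x$seed))
  invisible(x)
}
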