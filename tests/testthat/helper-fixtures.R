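# Shared fixtures and small independent oracles used across test files.

# Tiny atlas for fast tests: 8 cortical + 2 subcortical per hemisphere +
# brainstem = 21 parcels.
tiny_atlas <- function(seed = 42) {
  generate_atlas(n_cortical_per_hemi = 8, n_subcortical_per_hemi = 2,
                 include_brainstem = TRUE, seed = seed)
}

# Brute-force differential stability: explicit enumeration of donor pairs.
ds_oracle <- function(profiles) {
  profiles <- as.matrix(profiles)
  nd <- ncol(profiles)
  rhos <- c()
  for (i in seq_len(nd - 1)) {
    for (j in (i + 1):nd) {
      r <- suppressWarnings(
        cor(profiles[, i], profiles[, j], method = "spearman"))
      rhos <- c(rhos, if (is.na(r)) 0 else r)
    }
  }
  mean(rhos)
}

# Triple-loop topological overlap, straight from the definition.
tom_oracle <- function(a) {
  n <- nrow(a)
  diag(a) <- 1
  k <- colSums(a) - 1
  tom <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      s <- 0
      for (u in seq_len(n)) if (u != i && u != j) s <- s + a[i, u] * a[u, j]
      tom[i, j] <- (s + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  dimnames(tom) <- dimnames(a)
  tom
}

# Random symmetric adjacency in [0, 1] with unit diagonal.
random_adjacency <- function(n) {
  a <- matrix(runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  a
}

# Textbook PLS by explicit deflation, written independently of the package
# implementation: returns per-component fraction of response variance
# explained by regression on the accumulated (orthogonal) scores.
pls_deflation_oracle <- function(x, y, k) {
  x <- sweep(as.matrix(x), 2, colMeans(x))
  y0 <- y - mean(y)
  yc <- y0
  scores <- matrix(0, nrow(x), k)
  for (comp in seq_len(k)) {
    w <- t(x) %*% yc
    w <- w / sqrt(sum(w^2))
    tt <- x %*% w
    scores[, comp] <- tt
    p <- t(x) %*% tt / sum(tt^2)
    x <- x - tt %*% t(p)
    yc <- yc - tt * drop(crossprod(yc, tt)) / sum(tt^2)
  }
  r2 <- numeric(k)
  for (comp in seq_len(k)) {
    fit <- lm(y0 ~ scores[, seq_len(comp), drop = FALSE])
    r2[comp] <- summary(fit)$r.squared
  }
  diff(c(0, r2))
}

# Benjamini-Hochberg step-up from its definition: find the largest i with
# p_(i) <= i/m * alpha; adjusted value = min over j >= i of m * p_(j) / j.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  sorted <- p[o]
  run <- rev(cummin(rev(m * sorted / seq_len(m))))
  adj[o] <- pmin(run, 1)
  adj
}

# Adjusted Rand index between two labelings (mclust provides the
# independent implementation).
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# A deterministic spatially smooth parcel signal (anterior-posterior plus
# dorsoventral trend with a seeded ripple), independent of package internals.
smooth_field_for_test <- function(atlas, seed = 1) {
  set.seed(seed)
  ph <- runif(1, 0, 2 * pi)
  drop(scale(atlas$y / 40 + atlas$z / 60 + 0.3 * sin(atlas$x / 25 + ph)))
}

# Moran's I of a parcel map under inverse-distance weights.
morans_i <- function(values, coords) {
  n <- length(values)
  d <- as.matrix(dist(coords))
  w <- 1 / d
  diag(w) <- 0
  z <- values - mean(values)
  (n / sum(w)) * sum(w * outer(z, z)) / sum(z^2)
}
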