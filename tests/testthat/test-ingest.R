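test_that("probe filtering retains a probe iff its below-background fraction is under threshold", {
  flags <- rbind(
    half = c(rep(FALSE, 5), rep(TRUE, 5)),      # 5/10 below -> discarded
    clean = rep(TRUE, 10),                      # 0/10 below -> retained
    four = c(rep(FALSE, 4), rep(TRUE, 6))       # 4/10 below -> retained
  )
  out <- filter_probes_by_intensity(flags, 0.5)
  expect_equal(out$retained, c(FALSE, TRUE, TRUE))
  expect_equal(out$probe_id, rownames(flags))  # order preserved
  expect_equal(out$frac_below, c(0.5, 0, 0.4))
})

test_that("probe filtering edge cases: empty input warns, missing flags abort", {
  expect_warning(
    out <- filter_probes_by_intensity(matrix(TRUE, 0, 5)), "no probes")
  expect_equal(nrow(out), 0)
  bad <- matrix(c(TRUE, NA, TRUE, TRUE), 2, 2,
                dimnames = list(c("pA", "pB"), NULL))
  expect_error(filter_probes_by_intensity(bad), "pB")
})

test_that("differential stability equals the brute-force pairwise Spearman mean", {
  # trivial anchors
  prof <- cbind(1:5, 1:5)
  expect_equal(differential_stability(prof), 1.0)
  expect_equal(differential_stability(cbind(1:5, 5:1)), -1.0)

  # three donors, mean over explicitly enumerated pairs
  abc <- cbind(A = c(1, 2, 3, 4, 5), B = c(1, 2, 3, 5, 4), C = c(5, 4, 3, 2, 1))
  expect_equal(differential_stability(abc), ds_oracle(abc), tolerance = 1e-12)

  # random instances
  set.seed(11)
  for (rep in 1:20) {
    m <- matrix(rnorm(8 * 4), 8, 4)
    expect_equal(differential_stability(m), ds_oracle(m), tolerance = 1e-12)
  }
})

test_that("a constant donor profile contributes rho = 0 with a warning", {
  m <- cbind(c(1, 1, 1, 1), c(1, 2, 3, 4), c(4, 3, 2, 1))
  # pairs: (const, up) -> 0, (const, down) -> 0, (up, down) -> -1
  expect_warning(out <- differential_stability(m), "constant")
  expect_equal(out, -1 / 3)
})

test_that("probe selection takes the max-DS probe, ties to smallest probe id, invariant to order", {
  tb <- tibble::tibble(
    probe_id = c("p3", "p1", "p2", "p9"),
    gene_symbol = c("G1", "G1", "G2", "G2"),
    ds = c(0.3, 0.8, 0.5, 0.5))
  out <- select_representative_probe(tb)
  expect_equal(out$probe_id[out$gene_symbol == "G1"], "p1")   # argmax
  expect_equal(out$probe_id[out$gene_symbol == "G2"], "p2")   # tie -> lexicographic
  expect_true(out$tie[out$gene_symbol == "G2"])
  for (perm in list(4:1, c(2, 4, 1, 3))) {
    expect_equal(select_representative_probe(tb[perm, ]), out)
  }
})

test_that("samples map to the nearest eligible parcel within the radius", {
  atlas <- tiny_atlas()
  target <- atlas[atlas$tissue_class == "cortical" & atlas$hemisphere == "L", ][1, ]
  samples <- tibble::tibble(
    sample_id = c("in_range", "out_of_range", "wrong_hemi"),
    x = target$x + c(1.5, 5, 1), y = target$y, z = target$z,
    hemisphere = c("L", "L", "R"),
    tissue_class = "cortical")
  res <- assign_samples_to_parcels(samples, atlas, radius_mm = 2)
  a <- res$assignment
  expect_equal(a$parcel_id[a$sample_id == "in_range" & a$method == "radius"],
               target$parcel_id)
  expect_true(is.na(a$parcel_id[a$sample_id == "out_of_range" &
                                  is.na(a$method)]))
  radius_rows <- a[!is.na(a$method) & a$method == "radius", ]
  expect_false("wrong_hemi" %in% radius_rows$sample_id)
})

test_that("empty parcels receive their centroid-nearest eligible sample", {
  atlas <- tiny_atlas()
  left_ctx <- atlas[atlas$tissue_class == "cortical" & atlas$hemisphere == "L", ]
  # one sample near one parcel; all other left-cortical parcels are empty
  samples <- tibble::tibble(
    sample_id = "s1", x = left_ctx$x[1] + 0.5, y = left_ctx$y[1],
    z = left_ctx$z[1], hemisphere = "L", tissue_class = "cortical")
  res <- assign_samples_to_parcels(samples, atlas, radius_mm = 2)
  fb <- res$fallback
  expect_setequal(fb$parcel_id, left_ctx$parcel_id[-1])
  expect_true(all(fb$sample_id == "s1"))
  expect_true(all(fb$method == "centroid_fallback"))
})

test_that("assignment is deterministic under equidistant ties and permuted sample order", {
  atlas <- tibble::tibble(
    parcel_id = c(7L, 3L), name = c("a", "b"), hemisphere = "L",
    tissue_class = "cortical", x = c(1, -1), y = 0, z = 0,
    sx = c(1, -1), sy = 0, sz = 0)
  class(atlas) <- c("parcel_atlas", class(atlas))
  samples <- tibble::tibble(sample_id = c("sA", "sB"), x = 0, y = c(0, 0.5),
                            z = 0, hemisphere = "L", tissue_class = "cortical")
  res <- assign_samples_to_parcels(samples, atlas, radius_mm = 2)
  # equidistant from parcels 7 and 3 -> lower parcel_id wins
  expect_equal(res$assignment$parcel_id[1:2], c(3L, 3L))
  res2 <- assign_samples_to_parcels(samples[2:1, ], atlas[2:1, ], radius_mm = 2)
  joined <- merge(res$assignment[res$assignment$method == "radius", ],
                  res2$assignment[res2$assignment$method == "radius", ],
                  by = "sample_id")
  expect_equal(joined$parcel_id.x, joined$parcel_id.y)
})

test_that("robust sigmoid normalization matches the scalar formula and spans [0, 1]", {
  x <- c(1, 2, 3, 4, 100)
  m <- matrix(x, ncol = 1, dimnames = list(NULL, "g"))
  out <- normalize_robust_sigmoid(m)[, 1]
  # independent scalar evaluation
  s <- 1 / (1 + exp(-(x - median(x)) / (IQR(x) / 1.35)))
  expected <- (s - min(s)) / (max(s) - min(s))
  expect_equal(out, expected, tolerance = 1e-12)
  expect_equal(min(out), 0)
  expect_equal(max(out), 1)
  expect_equal(order(out), order(x))  # rank order preserved

  # s(median) = 0.5 before rescaling
  expect_equal(1 / (1 + exp(-(median(x) - median(x)) / (IQR(x) / 1.35))), 0.5)

  # monotonicity on strictly increasing inputs
  inc <- matrix(sort(rnorm(20)), ncol = 1, dimnames = list(NULL, "g"))
  expect_true(all(diff(normalize_robust_sigmoid(inc)[, 1]) > 0))
})

test_that("constant genes map to 0.5 and all-missing genes abort", {
  m <- matrix(c(rep(2, 5), 1:5), 5, 2, dimnames = list(NULL, c("flat", "ok")))
  out <- normalize_robust_sigmoid(m)
  expect_equal(out[, "flat"], rep(0.5, 5))
  m[, 2] <- NA
  expect_error(normalize_robust_sigmoid(m), "ok")
})

test_that("donor aggregation averages entrywise and ignores missing donors", {
  dn <- list(c("1", "2"), c("gA", "gB"))
  m1 <- matrix(c(0.2, 0.4, 0.6, 0.8), 2, 2, dimnames = dn)
  # single donor -> identity
  expect_equal(aggregate_donors(list(d1 = m1))$values, m1)
  m2 <- matrix(c(0.6, 0.4, 0.2, 0.0), 2, 2, dimnames = dn)
  agg <- aggregate_donors(list(d1 = m1, d2 = m2))
  expect_equal(agg$values[1, 1], 0.4)
  # donor missing a parcel: masked-mean oracle
  m2[1, ] <- NA
  agg <- aggregate_donors(list(d1 = m1, d2 = m2))
  expect_equal(agg$values[1, ], m1[1, ])
  expect_equal(agg$values[2, ], (m1[2, ] + m2[2, ]) / 2)
  # zero donors covering a parcel -> error
  m1[1, ] <- NA
  expect_error(aggregate_donors(list(d1 = m1, d2 = m2)), "no donor")
})

test_that("full ingestion yields a complete matrix on [0, 1] and drops planted background probes", {
  atlas <- tiny_atlas()
  ds <- generate_expression(atlas, module_spec(2, 5, 10), n_donors = 3,
                            seed = 7)
  expr <- ingest_expression(ds)
  expect_false(anyNA(expr$values))
  expect_true(all(expr$values >= 0 & expr$values <= 1))
  expect_equal(nrow(expr$values), nrow(atlas))
  rep_ <- attr(expr, "report")
  dropped <- rep_$probe_filter$probe_id[!rep_$probe_filter$retained]
  expect_setequal(dropped, ds$truth$background_probes)
})

test_that("region expression round-trips through TSV bit-identically", {
  atlas <- tiny_atlas()
  ds <- generate_expression(atlas, module_spec(2, 5, 6), seed = 3)
  expr <- ingest_expression(ds)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_region_expression(expr, path)
  back <- read_region_expression(path)
  expect_identical(back$values, expr$values)
  expect_identical(back$parcel_ids, expr$parcel_ids)
})
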