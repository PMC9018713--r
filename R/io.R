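#' Read and write pipeline tables
#'
#' Tab-separated readers and writers for every table the pipeline consumes
#' or emits. Doubles are written with round-trip precision, so a write
#' followed by a read reproduces values bit-identically.
#'
#' @param x Object to write.
#' @param path File path.
#' @name imagingtx-io
NULL

tsv_read_ <- function(path, ...) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE, ...)
}

# Exact-precision read: parse everything as character and convert numeric
# columns with strtod (as.numeric), which recovers %.17g output
# bit-identically (fast float parsers can be off by one ulp).
tsv_read_exact_ <- function(path, numeric_cols = NULL) {
  tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  if (is.null(numeric_cols)) numeric_cols <- setdiff(names(tb), names(tb)[1])
  for (nm in intersect(numeric_cols, names(tb))) tb[[nm]] <- as.numeric(tb[[nm]])
  tb
}

# Write a tibble with doubles rendered at full (17 significant digit)
# precision so that read_tsv() recovers them bit-identically.
tsv_write_exact_ <- function(tb, path) {
  tb <- dplyr::mutate(tb, dplyr::across(
    dplyr::where(is.double), ~ sprintf("%.17g", .x)))
  readr::write_tsv(tb, path)
  invisible(path)
}

#' @rdname imagingtx-io
#' @export
write_atlas <- function(x, path) {
  tsv_write_exact_(as_tibble(x), path)
}

#' @rdname imagingtx-io
#' @export
read_atlas <- function(path) {
  out <- tsv_read_exact_(path, c("x", "y", "z", "sx", "sy", "sz"))
  need <- c("parcel_id", "name", "hemisphere", "tissue_class",
            "x", "y", "z", "sx", "sy", "sz")
  stopifnot(all(need %in% names(out)))
  out$parcel_id <- as.integer(out$parcel_id)
  stopifnot(!anyDuplicated(out$parcel_id),
            all(out$hemisphere %in% c("L", "R", "none")),
            all(out$tissue_class %in% c("cortical", "subcortical", "brainstem")))
  ctx <- out$tissue_class == "cortical"
  nrm <- sqrt(out$sx^2 + out$sy^2 + out$sz^2)
  stopifnot(all(abs(nrm[ctx] - 1) < 1e-9))
  class(out) <- c("parcel_atlas", class(out))
  out
}

#' @rdname imagingtx-io
#' @export
write_region_expression <- function(x, path) {
  stopifnot(inherits(x, "region_expression"))
  tsv_write_exact_(as_tibble(x), path)
}

#' @rdname imagingtx-io
#' @export
read_region_expression <- function(path) {
  tb <- tsv_read_exact_(path)
  stopifnot(names(tb)[1] == "parcel_id")
  m <- as.matrix(tb[, -1])
  rownames(m) <- as.character(tb$parcel_id)
  region_expression(m)
}

#' @rdname imagingtx-io
#' @param tracer_name Stored tracer name (read side: overrides the file
#'   name stem).
#' @export
write_tracer_map <- function(x, path) {
  tsv_write_exact_(tibble(parcel_id = x$parcel_id, value = x$value), path)
}

#' @rdname imagingtx-io
#' @export
read_tracer_map <- function(path, tracer_name = NULL) {
  tb <- tsv_read_exact_(path, "value")
  stopifnot(all(c("parcel_id", "value") %in% names(tb)),
            all(is.finite(tb$value)))
  out <- tibble(parcel_id = as.integer(tb$parcel_id), value = tb$value)
  attr(out, "tracer_name") <- tracer_name %||%
    sub("\\.[^.]*$", "", basename(path))
  attr(out, "zscored") <- FALSE
  class(out) <- c("tracer_map", class(out))
  out
}

# matrix <-> TSV with an id first column
matrix_write_ <- function(m, path, id_col) {
  tb <- as_tibble(m)
  tsv_write_exact_(tibble(!!id_col := rownames(m), tb), path)
}

matrix_read_ <- function(path) {
  tb <- tsv_read_exact_(path)
  m <- as.matrix(tb[, -1])
  rownames(m) <- as.character(tb[[1]])
  m
}

#' Write a donor-level dataset to a directory of TSV files
#'
#' Emits `samples.tsv` (sample metadata), `intensities.tsv` (probe x
#' sample), `above_background.tsv` (0/1, same shape), `probe_map.tsv`
#' (probe_id, gene_symbol) and `atlas.tsv`.
#'
#' @param dataset A `donor_expression_set`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_donor_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "donor_expression_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv_write_exact_(dataset$samples, file.path(dir, "samples.tsv"))
  matrix_write_(dataset$intensities, file.path(dir, "intensities.tsv"),
                "probe_id")
  flags <- dataset$above_background * 1L
  matrix_write_(flags, file.path(dir, "above_background.tsv"), "probe_id")
  readr::write_tsv(dataset$probe_map, file.path(dir, "probe_map.tsv"))
  write_atlas(dataset$atlas, file.path(dir, "atlas.tsv"))
  invisible(dir)
}

#' Read a donor-level dataset from a directory of TSV files
#'
#' Inverse of [write_donor_dataset()] (planted ground truth is not part of
#' the file format and is absent after a round trip).
#'
#' @param dir Directory holding the five TSV files.
#' @return A `donor_expression_set`.
#' @export
read_donor_dataset <- function(dir) {
  samples <- tsv_read_exact_(file.path(dir, "samples.tsv"),
                             c("x", "y", "z"))
  intens <- matrix_read_(file.path(dir, "intensities.tsv"))
  flags <- matrix_read_(file.path(dir, "above_background.tsv")) == 1
  structure(
    list(samples = samples,
         intensities = intens,
         above_background = flags,
         probe_map = tsv_read_(file.path(dir, "probe_map.tsv")),
         atlas = read_atlas(file.path(dir, "atlas.tsv")),
         truth = NULL),
    class = "donor_expression_set")
}

#' @rdname imagingtx-io
#' @export
write_module_labels <- function(x, path) {
  labels <- if (inherits(x, "module_set")) x$labels else x
  readr::write_tsv(labels, path)
  invisible(path)
}

#' @rdname imagingtx-io
#' @export
write_eigengenes <- function(x, path) {
  eg <- if (inherits(x, "module_set")) x$eigengenes else x
  matrix_write_(eg, path, "parcel_id")
  invisible(path)
}

#' @rdname imagingtx-io
#' @export
read_eigengenes <- function(path) matrix_read_(path)
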