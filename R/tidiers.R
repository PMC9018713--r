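#' Tidy a PLS fit
#'
#' One row per component: variance explained, cumulative variance explained
#' and (when computed) the spin-permutation p-value.
#'
#' @param x A `pls_fit`.
#' @param ... Unused.
#' @return A tibble: `component`, `var_explained`, `cum_var_explained`,
#'   `p_spatial`.
#' @export
tidy.pls_fit <- function(x, ...) {
  tibble(component = seq_len(x$n_components),
         var_explained = x$var_explained,
         cum_var_explained = x$cum_var_explained,
         p_spatial = x$p_spatial %||% rep(NA_real_, x$n_components))
}

#' @rdname tidy.pls_fit
#' @export
glance.pls_fit <- function(x, ...) {
  tibble(n_parcels = x$n, n_predictors = length(x$predictors),
         n_components = x$n_components,
         total_var_explained = x$cum_var_explained[x$n_components],
         min_p_spatial = if (is.null(x$p_spatial)) NA_real_
                         else min(x$p_spatial))
}

#' Tidy a decoding result
#'
#' The bootstrap-ranked predictor table of the run, ordered by rank
#' (publication-table style: predictor, PLS1 weight, bootstrap Z, rank,
#' p and FDR-adjusted q).
#'
#' @param x A `decoding_result`.
#' @param ... Unused.
#' @export
tidy.decoding_result <- function(x, ...) {
  as_tibble(x$report) %>% arrange(.data$rank)
}

#' @rdname tidy.decoding_result
#' @export
glance.decoding_result <- function(x, ...) {
  dplyr::bind_cols(tibble(tracer = x$tracer_name), glance(x$fit),
                   tibble(n_significant_q05 = sum(x$report$q < 0.05)))
}

#' Tidy a module set
#'
#' @param x A `module_set`.
#' @param ... Unused.
#' @return Gene-to-module assignments (module 0 = unassigned).
#' @export
tidy.module_set <- function(x, ...) as_tibble(x$labels)

#' @rdname tidy.module_set
#' @export
glance.module_set <- function(x, ...) {
  tibble(n_modules = ncol(x$eigengenes), n_genes = nrow(x$labels),
         n_unassigned = sum(x$labels$module == 0), power = x$power,
         largest_module = max(as.integer(x$module_sizes)))
}
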