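#' Plot variance explained across PLS components
#'
#' Bar chart of per-component variance explained, annotated with spin
#' permutation p-values when present.
#'
#' @param object A `pls_fit`.
#' @param ... Unused.
#' @export
autoplot.pls_fit <- function(object, ...) {
  tb <- tidy(object)
  p <- ggplot(tb, aes(x = factor(.data$component), y = .data$var_explained)) +
    geom_col(fill = "steelblue4") +
    labs(x = "PLS component", y = "Variance explained",
         title = "Response variance explained per PLS component") +
    theme_minimal()
  if (!all(is.na(tb$p_spatial)))
    p <- p + geom_text(aes(label = sprintf("p=%.3g", .data$p_spatial)),
                       vjust = -0.4, size = 3)
  p
}

#' Plot the bootstrap Z distribution of a decoding run
#'
#' Density of predictor Z-scores with the top-ranked predictors marked,
#' mirroring the weight-distribution panels of imaging-transcriptomics
#' reports.
#'
#' @param object A `decoding_result`.
#' @param highlight Predictors to label (default: the top 5 by rank).
#' @param ... Unused.
#' @export
autoplot.decoding_result <- function(object, highlight = NULL, ...) {
  tb <- tidy(object)
  if (is.null(highlight)) highlight <- head(tb$predictor, 5)
  marks <- tb %>% filter(.data$predictor %in% highlight)
  ggplot(tb, aes(x = .data$z)) +
    geom_density(fill = "grey85") +
    geom_vline(data = marks, aes(xintercept = .data$z),
               colour = "firebrick", linetype = 2) +
    geom_text(data = marks,
              aes(x = .data$z, y = 0, label = .data$predictor),
              angle = 90, hjust = -0.1, vjust = -0.4, size = 3) +
    labs(x = "Bootstrap Z of PLS1 weight", y = "Density",
         title = sprintf("Predictor weights for %s", object$tracer_name)) +
    theme_minimal()
}

#' Plot module sizes
#'
#' @param object A `module_set`.
#' @param ... Unused.
#' @export
autoplot.module_set <- function(object, ...) {
  tb <- tibble(module = factor(names(object$module_sizes),
                               levels = names(object$module_sizes)),
               size = as.integer(object$module_sizes))
  ggplot(tb, aes(x = .data$module, y = .data$size)) +
    geom_col(fill = "darkseagreen4") +
    labs(x = "Module", y = "Genes",
         title = "Co-expression module sizes") +
    theme_minimal()
}

#' Plot a tracer map along the anterior--posterior axis
#'
#' Scatter of parcel binding values against the y (anterior--posterior)
#' centroid coordinate, the axis along which GABAergic tracer binding
#' typically shows its dominant gradient.
#'
#' @param object A `tracer_map`.
#' @param atlas The `parcel_atlas` the map is aligned to.
#' @param ... Unused.
#' @export
autoplot.tracer_map <- function(object, atlas, ...) {
  tb <- dplyr::inner_join(as_tibble(object),
                          as_tibble(atlas)[, c("parcel_id", "y",
                                               "tissue_class")],
                          by = "parcel_id")
  ggplot(tb, aes(x = .data$y, y = .data$value,
                 colour = .data$tissue_class)) +
    geom_point() +
    geom_smooth(aes(group = 1), method = "lm", formula = y ~ x,
                se = FALSE, colour = "grey40") +
    labs(x = "Posterior < y (mm) > Anterior", y = "Binding (a.u.)",
         colour = NULL,
         title = attr(object, "tracer_name") %||% "tracer map") +
    theme_minimal()
}

#' Plot gene-set enrichment results
#'
#' @param object An `enrichment_result`.
#' @param ... Unused.
#' @export
autoplot.enrichment_result <- function(object, ...) {
  tb <- as_tibble(object) %>% arrange(.data$nes) %>%
    mutate(set = factor(.data$set, levels = .data$set))
  ggplot(tb, aes(x = .data$nes, y = .data$set,
                 colour = .data$q < 0.05, size = .data$size)) +
    geom_point() +
    scale_colour_manual(values = c(`TRUE` = "firebrick",
                                   `FALSE` = "grey55"),
                        name = "q < 0.05") +
    labs(x = "Normalized enrichment score", y = NULL,
         title = "Weighted gene-set enrichment") +
    theme_minimal()
}
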