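#' Weighted preranked gene-set enrichment
#'
#' GSEA-style running-sum enrichment of gene sets in a ranked, weighted gene
#' list (e.g. bootstrap Z-scores from a decoding run). Genes are ordered by
#' decreasing weight; walking down the list, hits advance the running sum by
#' `|w|^exponent` (normalized over the set) and misses retreat by
#' `1 / (N - set size)`. The enrichment score (ES) is the maximum deviation
#' from zero, signed. The null distribution comes from random gene-label
#' sets of matched size; the p-value is the add-one tail among null scores
#' of matching sign, the normalized score (NES) divides the ES by the mean
#' magnitude of same-sign null scores, and q is Benjamini--Hochberg across
#' the tested sets.
#'
#' @param ranked Named numeric vector of gene weights (names = gene
#'   symbols), or a `predictor_report` (its `z` column is used).
#' @param sets Named list of gene-symbol vectors, e.g. from [read_gmt()].
#' @param n_perm Gene-label permutations per set family.
#' @param seed Integer seed.
#' @param min_size,max_size Set-size bounds after intersection with the
#'   ranked universe; sets outside are skipped and reported.
#' @param exponent Weight exponent of the running sum.
#' @return A tibble of class `enrichment_result`: `set`, `size`, `es`,
#'   `nes`, `p`, `q`; skipped sets in the `skipped` attribute.
#' @export
preranked_enrichment <- function(ranked, sets, n_perm = 1000, seed = 1,
                                 min_size = 5, max_size = 500, exponent = 1) {
  if (inherits(ranked, "predictor_report"))
    ranked <- setNames(ranked$z, ranked$predictor)
  stopifnot(is.numeric(ranked), !is.null(names(ranked)), length(ranked) >= 10)
  ord <- order(ranked, decreasing = TRUE)
  w <- ranked[ord]
  universe <- names(w)
  n <- length(universe)

  sizes <- map_int(sets, ~ length(intersect(.x, universe)))
  keep <- sizes >= min_size & sizes <= max_size
  skipped <- tibble(set = names(sets)[!keep], size = sizes[!keep])
  sets <- sets[keep]
  if (!length(sets)) abort("no gene set passed the size bounds")

  es_for <- function(hit_idx) {
    hit <- logical(n); hit[hit_idx] <- TRUE
    inc <- abs(w)^exponent * hit
    tot <- sum(inc)
    if (tot == 0) inc[hit] <- 1 / sum(hit) else inc <- inc / tot
    dec <- (!hit) / (n - sum(hit))
    rs <- cumsum(inc - dec)
    unname(rs[which.max(abs(rs))])
  }

  with_seed_(seed, {
    rows <- imap(sets, function(genes, nm) {
      idx <- which(universe %in% genes)
      es <- es_for(idx)
      null_es <- vapply(seq_len(n_perm), function(b)
        es_for(sample.int(n, length(idx))), numeric(1))
      same <- null_es[sign(null_es) == sign(es) | null_es == 0]
      p <- (1 + sum(abs(same) >= abs(es))) / (length(same) + 1)
      nes <- if (length(same) && mean(abs(same)) > 0)
        es / mean(abs(same)) else NA_real_
      tibble(set = nm, size = length(idx), es = es, nes = nes, p = p)
    })
    out <- bind_rows(rows) %>% mutate(q = fdr_bh(.data$p)) %>%
      arrange(.data$p)
    attr(out, "skipped") <- skipped
    class(out) <- c("enrichment_result", class(out))
    out
  })
}

#' Hypergeometric over-representation of gene sets in a module
#'
#' One-sided hypergeometric tail for the overlap between a module's genes
#' and each set, within a fixed universe; q by Benjamini--Hochberg across
#' sets.
#'
#' @param module_genes Character vector (must be contained in `universe`).
#' @param sets Named list of gene-symbol vectors.
#' @param universe Character vector of all eligible genes.
#' @return A tibble: `set`, `overlap`, `set_size`, `module_size`, `p`, `q`.
#' @export
module_overrepresentation <- function(module_genes, sets, universe) {
  stopifnot(all(module_genes %in% universe))
  module_genes <- unique(module_genes)
  universe <- unique(universe)
  rows <- imap(sets, function(genes, nm) {
    s <- intersect(genes, universe)
    k <- length(intersect(module_genes, s))
    tibble(set = nm, overlap = k, set_size = length(s),
           module_size = length(module_genes),
           p = phyper(k - 1, length(s), length(universe) - length(s),
                      length(module_genes), lower.tail = FALSE))
  })
  bind_rows(rows) %>% mutate(q = fdr_bh(.data$p)) %>% arrange(.data$p)
}

#' Read a GMT gene-set file
#'
#' Standard tab-separated gene-set format: one set per line as
#' `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path File path.
#' @return Named list of gene-symbol vectors; descriptions in the
#'   `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- map(parts, ~ unique(.x[-(1:2)]))
  names(sets) <- map_chr(parts, 1)
  attr(sets, "descriptions") <- setNames(map_chr(parts, 2), names(sets))
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets Named list of gene-symbol vectors.
#' @param path File path.
#' @param descriptions Optional named character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  lines <- imap(sets, function(genes, nm) {
    desc <- descriptions[nm] %||% "na"
    paste(c(nm, desc, genes), collapse = "\t")
  })
  writeLines(unlist(lines), path)
  invisible(path)
}
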