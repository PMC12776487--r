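# Over-representation analysis: one-sided hypergeometric tail tests of a
# query gene list against a gene-set collection, Benjamini-Hochberg
# corrected.

#' One-sided hypergeometric over-representation test
#'
#' Computes the upper-tail probability \eqn{P(X \ge k)} of observing at
#' least the realised overlap \eqn{k = |query \cap target|} when drawing
#' \eqn{n = |query|} genes without replacement from a universe of size
#' \eqn{N} containing \eqn{K = |target|} successes. Equivalent to a
#' one-sided Fisher exact test on the 2x2 overlap table.
#'
#' @param query,target Character vectors of gene symbols; both must be
#'   subsets of `universe`.
#' @param universe Character vector: the background gene universe.
#' @return A single p-value in \eqn{(0, 1]}.
#' @export
ora_test <- function(query, target, universe) {
  universe <- unique(universe)
  query <- unique(query); target <- unique(target)
  if (length(universe) == 0) stop_universe("universe must be nonempty")
  if (!all(query %in% universe)) {
    stop_universe("query genes must be a subset of the universe")
  }
  if (!all(target %in% universe)) {
    stop_universe("target set genes must be a subset of the universe")
  }
  k <- length(intersect(query, target))
  stats::phyper(k - 1, length(target), length(universe) - length(target),
                length(query), lower.tail = FALSE)
}

#' Multiple-testing adjustment
#'
#' Benjamini-Hochberg step-up adjustment (the package's correction of
#' record for enrichment tables).
#'
#' @param p_values Numeric vector of p-values in \eqn{(0, 1]}.
#' @param method Adjustment method; only `"BH"` is offered.
#' @return Adjusted p-values, capped at 1.
#' @export
adjust_pvalues <- function(p_values, method = c("BH")) {
  method <- match.arg(method)
  if (length(p_values) == 0) return(numeric(0))
  if (any(p_values <= 0 | p_values > 1)) {
    stop_usage("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p_values, method = method)
}

#' Run over-representation analysis against a gene-set collection
#'
#' Tests the query list against every set with at least one overlapping
#' gene (zero-overlap sets carry no enrichment information and would only
#' inflate the correction burden), adjusts with Benjamini-Hochberg across
#' the tested sets and flags sets with adjusted p below `alpha`.
#'
#' @param query Character vector of gene symbols; must lie inside the
#'   collection's universe.
#' @param collection A [gene_set_collection()].
#' @param alpha Significance threshold on the adjusted p-value.
#' @return A tibble of class `enrichment_result`, one row per overlapping
#'   set, sorted by adjusted then raw p-value: `set_id`, `set_name`, `k`
#'   (overlap), `K` (set size), `n` (query size), `N` (universe size),
#'   `p_value`, `p_adjusted`, `significant`, `genes` (comma-joined
#'   overlap).
#' @export
run_enrichment <- function(query, collection, alpha = 0.05) {
  stopifnot(inherits(collection, "gene_set_collection"))
  query <- unique(query)
  if (!all(query %in% collection$universe)) {
    stop_universe("query genes must be a subset of the collection universe")
  }
  N <- length(collection$universe)
  n <- length(query)
  rows <- purrr::imap_dfr(collection$sets, function(genes, id) {
    hit <- intersect(query, genes)
    if (length(hit) == 0) return(NULL)
    tibble(set_id = id,
           set_name = unname(collection$names[[id]]),
           k = length(hit), K = length(genes), n = n, N = N,
           p_value = ora_test(query, genes, collection$universe),
           genes = paste(sort(hit), collapse = ","))
  })
  if (nrow(rows) == 0) {
    rows <- tibble(set_id = character(), set_name = character(),
                   k = integer(), K = integer(), n = integer(), N = integer(),
                   p_value = numeric(), p_adjusted = numeric(),
                   significant = logical(), genes = character())
  } else {
    rows <- rows %>%
      mutate(p_adjusted = adjust_pvalues(.data$p_value),
             significant = .data$p_adjusted < alpha) %>%
      arrange(.data$p_adjusted, .data$p_value, .data$set_id) %>%
      select("set_id", "set_name", "k", "K", "n", "N", "p_value",
             "p_adjusted", "significant", "genes")
  }
  attr(rows, "alpha") <- alpha
  class(rows) <- c("enrichment_result", class(rows))
  rows
}

#' One-row summary of an enrichment table
#'
#' @param x An `enrichment_result`.
#' @param ... Unused.
#' @method glance enrichment_result
#' @export
glance.enrichment_result <- function(x, ...) {
  tibble(n_sets_tested = nrow(x), n_significant = sum(x$significant),
         alpha = attr(x, "alpha") %||% NA_real_,
         min_p_adjusted = if (nrow(x) > 0) min(x$p_adjusted) else NA_real_)
}

#' Dot plot of enrichment results
#'
#' @param object An `enrichment_result`.
#' @param top Number of top sets to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot enrichment_result
#' @export
autoplot.enrichment_result <- function(object, top = 15, ...) {
  d <- as_tibble(head(object, top))
  d$set_id <- factor(d$set_id, levels = rev(d$set_id))
  ggplot2::ggplot(d, ggplot2::aes(x = -log10(.data$p_adjusted),
                                  y = .data$set_id,
                                  size = .data$k,
                                  colour = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey50")) +
    ggplot2::labs(x = expression(-log[10](P[adj])), y = NULL,
                  size = "overlap", colour = "significant",
                  title = "Over-representation analysis") +
    ggplot2::theme_minimal()
}
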