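# Thresholded protein-interaction graphs and maximal-clique-centrality
# hub ranking.

#' Build a thresholded protein-interaction graph
#'
#' Constructs an undirected weighted graph over a queried gene set: edges
#' with confidence score at or above the threshold are retained, and every
#' queried gene is a node whether or not it is connected (sparse networks
#' over small candidate lists leave most genes isolated). Edges touching a
#' gene outside the query set are dropped with a warning.
#'
#' @param genes Character vector of queried gene symbols (the node set).
#' @param edges Edge tibble from [read_edge_list()].
#' @param threshold Confidence threshold on \eqn{[0, 1]}; default 0.150,
#'   the permissive exploratory cutoff for small candidate lists.
#' @return An object of class `ppi_graph`: list with the `igraph` object,
#'   `nodes`, the retained `edges` and the `threshold`. Has [tidy()],
#'   [glance()] and [autoplot()] methods.
#' @export
build_ppi_graph <- function(genes, edges, threshold = 0.150) {
  if (threshold < 0 || threshold > 1) stop_config("threshold must lie in [0, 1]")
  genes <- unique(as.character(genes))
  outside <- !(edges$gene_a %in% genes & edges$gene_b %in% genes)
  if (any(outside)) {
    warn(sprintf("dropped %d edge(s) with endpoints outside the queried gene set",
                 sum(outside)), class = "triofunnel_unknown_gene")
    edges <- edges[!outside, ]
  }
  kept <- edges %>%
    filter(.data$score >= threshold) %>%
    mutate(pair = purrr::map2_chr(.data$gene_a, .data$gene_b,
                                  ~ paste(sort(c(.x, .y)), collapse = "|"))) %>%
    distinct(.data$pair, .keep_all = TRUE) %>%
    select("gene_a", "gene_b", "score")
  g <- igraph::graph_from_data_frame(kept, directed = FALSE,
                                     vertices = data.frame(name = genes))
  structure(list(graph = g, nodes = genes, edges = kept, threshold = threshold),
            class = "ppi_graph")
}

#' @export
print.ppi_graph <- function(x, ...) {
  cat(sprintf("<ppi_graph> %d nodes, %d edges (score >= %.3f)\n",
              length(x$nodes), nrow(x$edges), x$threshold))
  invisible(x)
}

#' Network summary statistics
#'
#' `average_degree()` returns the mean node degree `2 |E| / |N|` of the
#' graph (isolated nodes included).
#'
#' @param g A `ppi_graph`.
#' @return A single number.
#' @export
average_degree <- function(g) {
  n <- length(g$nodes)
  if (n == 0) stop_usage("average degree of an empty graph is undefined")
  2 * nrow(g$edges) / n
}

#' Enumerate maximal cliques
#'
#' Returns exactly the inclusion-maximal cliques of the graph; isolated
#' nodes appear as singleton cliques. Each clique is a sorted character
#' vector and the list is ordered deterministically.
#'
#' @param g A `ppi_graph`.
#' @return A list of character vectors.
#' @export
maximal_cliques <- function(g) {
  cl <- igraph::max_cliques(g$graph)
  cl <- lapply(cl, function(v) sort(igraph::V(g$graph)$name[v]))
  cl[order(vapply(cl, paste, character(1), collapse = "|"))]
}

#' Maximal clique centrality (MCC) hub scores
#'
#' Scores every node by the sum of \eqn{(|C| - 1)!} over the maximal
#' cliques \eqn{C} of size at least 2 that contain it; a node belonging to
#' no such clique (an isolated node) scores 1 by the standard singleton
#' convention. The returned ranking is sorted by MCC descending, then
#' degree descending, then symbol -- a deterministic tie-break.
#'
#' @param g A `ppi_graph`.
#' @return A tibble of class `hub_ranking` with columns `gene`, `mcc`,
#'   `degree`, `rank`.
#' @export
mcc_scores <- function(g) {
  score <- setNames(numeric(length(g$nodes)), g$nodes)
  for (cl in maximal_cliques(g)) {
    if (length(cl) >= 2) score[cl] <- score[cl] + factorial(length(cl) - 1)
  }
  score[score == 0] <- 1
  deg <- igraph::degree(g$graph)[g$nodes]
  out <- tibble(gene = g$nodes, mcc = unname(score), degree = unname(deg)) %>%
    arrange(dplyr::desc(.data$mcc), dplyr::desc(.data$degree), .data$gene) %>%
    mutate(rank = row_number())
  class(out) <- c("hub_ranking", class(out))
  out
}

#' Top hub genes
#'
#' @param scores A `hub_ranking` from [mcc_scores()].
#' @param k Number of hubs to return; if larger than the node count the
#'   full ranking is returned.
#' @return A character vector of gene symbols in rank order.
#' @export
top_hubs <- function(scores, k) {
  if (k < 1) stop_usage("k must be at least 1")
  head(scores$gene, k)
}

#' Tidiers for PPI graphs
#'
#' `tidy()` returns the retained edge table; `glance()` the node/edge
#' counts, threshold and mean degree.
#'
#' @param x A `ppi_graph`.
#' @param ... Unused.
#' @method tidy ppi_graph
#' @export
tidy.ppi_graph <- function(x, ...) as_tibble(x$edges)

#' @rdname tidy.ppi_graph
#' @method glance ppi_graph
#' @export
glance.ppi_graph <- function(x, ...) {
  tibble(n_nodes = length(x$nodes), n_edges = nrow(x$edges),
         threshold = x$threshold, avg_degree = average_degree(x))
}

#' Network plot of a PPI graph
#'
#' Simple force-directed ggplot rendering; isolated nodes are laid out on
#' the periphery.
#'
#' @param object A `ppi_graph`.
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ppi_graph
#' @export
autoplot.ppi_graph <- function(object, seed = 1L, ...) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()),
          add = TRUE)
  set.seed(seed)
  xy <- igraph::layout_with_fr(object$graph)
  nodes <- tibble(gene = igraph::V(object$graph)$name,
                  x = xy[, 1], y = xy[, 2])
  seg <- object$edges %>%
    left_join(nodes, by = c(gene_a = "gene")) %>%
    rename(xa = "x", ya = "y") %>%
    left_join(nodes, by = c(gene_b = "gene")) %>%
    rename(xb = "x", yb = "y")
  ggplot2::ggplot(nodes, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$xa, y = .data$ya,
                                       xend = .data$xb, yend = .data$yb),
                          colour = "grey60") +
    ggplot2::geom_point(size = 3, colour = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$gene), vjust = -1, size = 3) +
    ggplot2::theme_void() +
    ggplot2::labs(title = sprintf("PPI network (score >= %.3f)", object$threshold))
}

#' Lollipop plot of hub scores
#'
#' @param object A `hub_ranking`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hub_ranking
#' @export
autoplot.hub_ranking <- function(object, ...) {
  d <- as_tibble(object)
  d$gene <- factor(d$gene, levels = rev(d$gene))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mcc, y = .data$gene)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$mcc,
                                       yend = .data$gene), colour = "grey70") +
    ggplot2::geom_point(colour = "firebrick", size = 3) +
    ggplot2::labs(x = "maximal clique centrality", y = NULL,
                  title = "Hub-gene ranking") +
    ggplot2::theme_minimal()
}
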