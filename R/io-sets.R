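# Gene-set collections (GMT) and protein-interaction edge lists.

#' Build a gene-set collection
#'
#' Wraps named gene sets with a background universe. By default the universe
#' is the union of all member genes; a custom background can be supplied.
#' After harmonisation every set is a subset of the universe; empty sets are
#' rejected.
#'
#' @param sets Named list of character vectors of gene symbols.
#' @param names Optional named character vector of human-readable set names
#'   (defaults to the set ids).
#' @param universe Optional character vector overriding the background.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, names = NULL, universe = NULL) {
  if (length(sets) == 0 || is.null(base::names(sets))) {
    stop_format("sets must be a non-empty named list")
  }
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (is.null(universe)) {
    universe <- sort(unique(unlist(sets, use.names = FALSE)))
  } else {
    universe <- sort(unique(as.character(universe)))
    sets <- lapply(sets, intersect, y = universe)
  }
  if (any(lengths(sets) == 0)) {
    stop_format("empty gene sets (after harmonisation with the universe) are rejected")
  }
  if (is.null(names)) names <- setNames(base::names(sets), base::names(sets))
  structure(list(sets = sets, names = names, universe = universe),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets over a universe of %d genes\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

#' Read gene sets in GMT format
#'
#' Parses the tab-separated GMT dialect (set id, description, member
#' genes...). Lines with fewer than three fields raise a format error.
#'
#' @param path Path to a `.gmt` file.
#' @param universe Optional custom background passed to
#'   [gene_set_collection()].
#' @return A `gene_set_collection`.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad) > 0) {
    stop_format(sprintf("malformed GMT line %d: need id, description and at least one gene", bad[[1]]))
  }
  ids <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(ids)) stop_format("duplicated set ids in GMT")
  descs <- vapply(fields, `[[`, character(1), 2)
  sets <- setNames(lapply(fields, function(f) unique(f[-(1:2)])), ids)
  gene_set_collection(sets, names = setNames(descs, ids), universe = universe)
}

#' Read a protein-interaction edge list
#'
#' Accepts either the STRING export dialect (header
#' `protein1 protein2 combined_score`, scores on a 0--1000 integer scale) or
#' a headerless three-column table. Scores are always returned on
#' \eqn{[0, 1]}: `score_scale = "milli"` divides by 1000, `"unit"` keeps
#' values as-is, and `"auto"` (default) rescales when any score exceeds 1.
#' Self-loops are dropped with a warning.
#'
#' @param path Path to a whitespace- or tab-delimited edge list.
#' @param score_scale One of `"auto"`, `"unit"`, `"milli"`.
#' @return A tibble with columns `gene_a`, `gene_b`, `score`.
#' @export
read_edge_list <- function(path, score_scale = c("auto", "unit", "milli")) {
  score_scale <- match.arg(score_scale)
  first <- readLines(path, n = 1)
  has_header <- grepl("protein1", first, fixed = TRUE) ||
    grepl("gene_a", first, fixed = TRUE)
  raw <- utils::read.table(path, header = has_header, stringsAsFactors = FALSE)
  if (ncol(raw) != 3) stop_format("edge list must have exactly 3 columns")
  names(raw) <- c("gene_a", "gene_b", "score")
  edges <- as_tibble(raw) %>%
    mutate(gene_a = as.character(.data$gene_a),
           gene_b = as.character(.data$gene_b),
           score = as.numeric(.data$score))
  if (score_scale == "milli" ||
      (score_scale == "auto" && any(edges$score > 1))) {
    edges$score <- edges$score / 1000
  }
  if (any(edges$score < 0 | edges$score > 1)) {
    stop_format("edge scores must lie in [0, 1] after rescaling")
  }
  loops <- edges$gene_a == edges$gene_b
  if (any(loops)) {
    warn(sprintf("dropped %d self-loop edge(s)", sum(loops)),
         class = "triofunnel_self_loop")
    edges <- edges[!loops, ]
  }
  edges
}
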