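# Independent oracles, written as plain enumeration/lookup so they share no
# code path with the package implementation.

# --- segregation decision table -----------------------------------------
# Nested-lookup reimplementation of the classification contract. Absent
# parents are passed as genotype "missing".
oracle_classify <- function(p, m, f, m_aff = FALSE, f_aff = FALSE,
                            x_hemi = FALSE, tolerate = FALSE) {
  carrier <- function(g) g == "het" || g == "hom_alt"
  dom <- function(aff) if (aff) "ad_inherited_affected_parent" else "ad_incomplete_penetrance"
  if (x_hemi) {
    if (p == "het") return("mendelian_inconsistent")
    if (carrier(m)) return("x_linked")
    if (m == "hom_ref") return("de_novo")
    return("unknown_missing_parent")
  }
  if (p == "het") {
    if (m == "hom_ref" && f == "hom_ref") return("de_novo")
    if (carrier(m) && carrier(f)) return(dom(m_aff || f_aff))
    if (carrier(m)) return(dom(m_aff))
    if (carrier(f)) return(dom(f_aff))
    return("unknown_missing_parent")
  }
  if (p == "hom_alt") {
    if (carrier(m) && carrier(f)) return("ar_homozygous")
    if (m == "hom_ref" && f == "hom_ref") return("de_novo_homozygous_flagged")
    if ((m == "hom_ref" && carrier(f)) || (carrier(m) && f == "hom_ref")) {
      return(if (tolerate) "ar_homozygous" else "mendelian_inconsistent")
    }
    if ((m == "hom_ref" && f == "missing") || (f == "hom_ref" && m == "missing")) {
      return(if (tolerate) "unknown_missing_parent" else "mendelian_inconsistent")
    }
    return("unknown_missing_parent")
  }
  stop("oracle: proband must be a carrier")
}

# --- maximal cliques by exhaustive subset search ------------------------
# adj: symmetric 0/1 matrix with named rows/cols
oracle_max_cliques <- function(adj) {
  n <- nrow(adj)
  nodes <- rownames(adj)
  subsets <- lapply(seq_len(2^n - 1), function(code) {
    which(bitwAnd(code, 2^(seq_len(n) - 1)) > 0)
  })
  is_clique <- function(idx) {
    if (length(idx) <= 1) return(TRUE)
    s <- adj[idx, idx, drop = FALSE]
    all(s[upper.tri(s)] == 1)
  }
  cliques <- Filter(is_clique, subsets)
  maximal <- Filter(function(idx) {
    outside <- setdiff(seq_len(n), idx)
    !any(vapply(outside, function(v) all(adj[v, idx] == 1), logical(1)))
  }, cliques)
  cl <- lapply(maximal, function(idx) sort(nodes[idx]))
  cl[order(vapply(cl, paste, character(1), collapse = "|"))]
}

oracle_mcc <- function(adj) {
  cl <- oracle_max_cliques(adj)
  score <- stats::setNames(numeric(nrow(adj)), rownames(adj))
  for (s in cl) if (length(s) >= 2) score[s] <- score[s] + factorial(length(s) - 1)
  score[score == 0] <- 1
  score
}

random_adjacency <- function(n, p_edge = 0.4) {
  adj <- matrix(0L, n, n, dimnames = list(LETTERS[seq_len(n)], LETTERS[seq_len(n)]))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (stats::runif(1) < p_edge) adj[i, j] <- adj[j, i] <- 1L
  }
  adj
}

graph_from_adjacency <- function(adj, threshold = 0.5) {
  nodes <- rownames(adj)
  idx <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
  edges <- tibble::tibble(gene_a = nodes[idx[, 1]], gene_b = nodes[idx[, 2]],
                          score = 0.9)
  build_ppi_graph(nodes, edges, threshold = threshold)
}

# --- hypergeometric upper tail by direct combinatorial sum --------------
oracle_hyper_tail <- function(k, K, n, N) {
  upper <- min(K, n)
  if (k > upper) return(0)
  sum(vapply(k:upper, function(i) {
    exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n))
  }, numeric(1)))
}
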