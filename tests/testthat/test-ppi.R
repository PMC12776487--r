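# Thresholded interaction graphs and MCC hub ranking.

test_that("graph construction keeps all queried genes and thresholds edges", {
  fx <- load_table1_fixture()
  genes <- unique(fx$variants$gene)
  edges <- read_edge_list(synthetic_edge_file())
  g <- build_ppi_graph(genes, edges, threshold = 0.150)
  expect_equal(length(g$nodes), 13)
  expect_equal(nrow(g$edges), 5)
  # the stricter default interaction cutoff leaves a single edge
  g40 <- build_ppi_graph(genes, edges, threshold = 0.400)
  expect_equal(nrow(g40$edges), 1)
  expect_equal(length(g40$nodes), 13)
  # threshold 1.0: no edges survive, node count unchanged
  g100 <- build_ppi_graph(genes, edges, threshold = 1.0)
  expect_equal(nrow(g100$edges), 0)
  expect_equal(length(g100$nodes), 13)
  # an edge to a gene outside the query set is dropped with a warning
  extra <- dplyr::bind_rows(edges, tibble::tibble(gene_a = "TP63",
                                                  gene_b = "NOT_QUERIED",
                                                  score = 0.9))
  expect_warning(g2 <- build_ppi_graph(genes, extra, 0.15),
                 class = "triofunnel_unknown_gene")
  expect_equal(nrow(g2$edges), 5)
})

test_that("average degree is 2E/N with closed-form checks", {
  fx <- load_table1_fixture()
  g <- build_ppi_graph(unique(fx$variants$gene),
                       read_edge_list(synthetic_edge_file()), 0.150)
  expect_equal(round(average_degree(g), 3), 0.769)
  single <- build_ppi_graph("A", tibble::tibble(gene_a = character(),
                                                gene_b = character(),
                                                score = numeric()), 0.5)
  expect_equal(average_degree(single), 0)
  k4 <- graph_from_adjacency(matrix(1, 4, 4,
                                    dimnames = list(LETTERS[1:4], LETTERS[1:4]))
                             - diag(4))
  expect_equal(average_degree(k4), 3)
  empty <- build_ppi_graph(character(0),
                           tibble::tibble(gene_a = character(),
                                          gene_b = character(),
                                          score = numeric()), 0.5)
  expect_error(average_degree(empty), class = "triofunnel_usage_error")
})

test_that("maximal cliques on canonical small graphs", {
  tri <- matrix(1, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  diag(tri) <- 0
  g <- graph_from_adjacency(tri)
  expect_equal(maximal_cliques(g), list(c("a", "b", "c")))
  path <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  path["a", "b"] <- path["b", "a"] <- path["b", "c"] <- path["c", "b"] <- 1
  gp <- graph_from_adjacency(path)
  expect_equal(maximal_cliques(gp), list(c("a", "b"), c("b", "c")))
})

test_that("clique enumeration and MCC match brute force on random graphs", {
  set.seed(101)
  for (i in 1:40) {
    n <- sample(3:8, 1)
    adj <- random_adjacency(n, p_edge = runif(1, 0.2, 0.7))
    g <- graph_from_adjacency(adj)
    expect_equal(maximal_cliques(g), oracle_max_cliques(adj))
    want <- oracle_mcc(adj)
    got <- mcc_scores(g)
    expect_equal(setNames(got$mcc, got$gene)[names(want)], want)
  }
})

test_that("MCC follows the factorial convention with singleton fallback", {
  tri <- matrix(1, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  diag(tri) <- 0
  expect_equal(unname(mcc_scores(graph_from_adjacency(tri))$mcc), c(2, 2, 2))
  path <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  path["a", "b"] <- path["b", "a"] <- path["b", "c"] <- path["c", "b"] <- 1
  s <- mcc_scores(graph_from_adjacency(path))
  expect_equal(setNames(s$mcc, s$gene)[c("a", "b", "c")],
               c(a = 1, b = 2, c = 1))
  iso <- build_ppi_graph(c("x", "y"),
                         tibble::tibble(gene_a = character(),
                                        gene_b = character(), score = numeric()),
                         0.5)
  expect_equal(mcc_scores(iso)$mcc, c(1, 1))
})

test_that("MCC is additive over disjoint components", {
  set.seed(7)
  a1 <- random_adjacency(4, 0.6); a2 <- random_adjacency(4, 0.6)
  rownames(a2) <- colnames(a2) <- letters[1:4]
  joint <- rbind(cbind(a1, matrix(0L, 4, 4)), cbind(matrix(0L, 4, 4), a2))
  rownames(joint) <- colnames(joint) <- c(rownames(a1), rownames(a2))
  s_joint <- mcc_scores(graph_from_adjacency(joint))
  s1 <- mcc_scores(graph_from_adjacency(a1))
  s2 <- mcc_scores(graph_from_adjacency(a2))
  sep <- c(setNames(s1$mcc, s1$gene), setNames(s2$mcc, s2$gene))
  expect_equal(setNames(s_joint$mcc, s_joint$gene)[names(sep)], sep)
})

test_that("raising the threshold never adds edges or MCC mass", {
  fx <- load_table1_fixture()
  genes <- unique(fx$variants$gene)
  edges <- read_edge_list(synthetic_edge_file())
  thresholds <- c(0.1, 0.15, 0.2, 0.3, 0.5, 0.9)
  n_edges <- integer(0); total_mcc <- numeric(0)
  for (t in thresholds) {
    g <- build_ppi_graph(genes, edges, t)
    n_edges <- c(n_edges, nrow(g$edges))
    total_mcc <- c(total_mcc, sum(mcc_scores(g)$mcc))
  }
  expect_true(all(diff(n_edges) <= 0))
  expect_true(all(total_mcc <= length(genes) * factorial(length(genes) - 1)))
})

test_that("hub ranking breaks ties by degree then symbol, deterministically", {
  # star on b plus pendant: degrees differ under equal MCC
  edges <- tibble::tibble(gene_a = c("B", "B", "C"),
                          gene_b = c("A", "C", "D"), score = 0.9)
  g <- build_ppi_graph(c("A", "B", "C", "D", "E"), edges, 0.5)
  s <- mcc_scores(g)
  expect_equal(top_hubs(s, 2), c("B", "C"))  # MCC 2,2 then degree 2 > ...
  # all-isolated: alphabetical order
  iso <- build_ppi_graph(c("Z", "M", "A"),
                         tibble::tibble(gene_a = character(),
                                        gene_b = character(), score = numeric()),
                         0.5)
  expect_equal(top_hubs(mcc_scores(iso), 3), c("A", "M", "Z"))
  # k beyond the node count returns the full stable ranking
  expect_equal(top_hubs(mcc_scores(iso), 10), c("A", "M", "Z"))
  expect_identical(mcc_scores(g), mcc_scores(g))
})
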