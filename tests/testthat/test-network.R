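unit_triangle <- function() {
  g <- igraph::make_full_graph(3)
  igraph::V(g)$name <- c("a", "b", "c")
  igraph::E(g)$weight <- 1
  g
}

test_that("functional network edges are Jaccard similarities thresholded at tau", {
  sets <- tibble::tibble(
    set_id = c("t1", "t2", "t3", "t1", "t2", "t3", "t4", "t9"),
    namespace = "BP",
    gene_id = c("a", "a", "a", "b", "b", "b", "b", "c")
  )
  # ann(a) = {t1,t2,t3}; ann(b) = {t1,t2,t3,t4}: Jaccard 3/4
  g <- build_functional_network(sets, c("a", "b", "c", "d"), tau = 0.5)
  expect_equal(igraph::vcount(g), 4L)           # isolated nodes kept
  expect_equal(igraph::ecount(g), 1L)
  e <- igraph::as_data_frame(g)
  expect_equal(sort(c(e$from, e$to)), c("a", "b"))
  expect_equal(e$weight, 3 / 4)
  # identical annotation sets -> weight 1; disjoint -> no edge
  sets2 <- tibble::tibble(set_id = c("t1", "t1", "t2"), namespace = "BP",
                          gene_id = c("x", "y", "z"))
  g2 <- build_functional_network(sets2, c("x", "y", "z"), tau = 0.5)
  e2 <- igraph::as_data_frame(g2)
  expect_equal(nrow(e2), 1L)
  expect_equal(e2$weight, 1)
  # ann(a)={g1,g2,g3}, ann(b)={g2,g3,g4}: Jaccard exactly 0.5 kept at tau 0.5
  sets3 <- tibble::tibble(
    set_id = c("g1", "g2", "g3", "g2", "g3", "g4"), namespace = "BP",
    gene_id = rep(c("a", "b"), each = 3))
  g3 <- build_functional_network(sets3, c("a", "b"), tau = 0.5)
  expect_equal(igraph::as_data_frame(g3)$weight, 0.5)
  expect_error(build_functional_network(sets, c("a"), tau = 1.5), "tau")
})

test_that("interaction network applies the confidence threshold and collapses duplicates", {
  edges <- tibble::tibble(
    gene_a = c("a", "a", "b", "c", "d"),
    gene_b = c("b", "b", "c", "d", "d"),
    weight = c(0.85, 0.6, 0.95, 0.7, 0.9),
    source = c("string", "mentha", "string", "bioplex", "mentha")
  )
  g <- build_interaction_network(edges)
  e <- igraph::as_data_frame(g)
  # string 0.85 dropped, mentha 0.6 kept for a-b (max of survivors)
  expect_equal(e$weight[e$from == "a" | e$to == "a"], 0.6)
  # self-loop d-d dropped
  expect_false(any(e$from == e$to))
  # node restriction removes incident edges
  g2 <- build_interaction_network(edges, expressed = c("a", "b"))
  expect_equal(igraph::vcount(g2), 2L)
  expect_equal(igraph::ecount(g2), 1L)
  expect_error(build_interaction_network(dplyr::mutate(edges, weight = -1)),
               "line 1")
})

test_that("cohesiveness matches direct evaluation", {
  tri <- unit_triangle()
  expect_equal(cohesiveness(tri, c("a", "b", "c"), penalty = 0), 1)
  expect_equal(cohesiveness(tri, c("a", "b", "c"), penalty = 2), 1 / 3)
  # single node with one incident unit edge, p = 0: 0 / (0 + 1)
  path <- igraph::make_graph(~ x - y)
  igraph::E(path)$weight <- 1
  expect_equal(cohesiveness(path, "x", penalty = 0), 0)
  expect_error(cohesiveness(tri, character(0)), "non-empty")
  # adding an isolated vertex strictly decreases the score when p > 0
  tri_iso <- igraph::add_vertices(tri, 1, name = "z")
  expect_lt(cohesiveness(tri_iso, c("a", "b", "c", "z"), penalty = 2),
            cohesiveness(tri_iso, c("a", "b", "c"), penalty = 2))
})

test_that("greedy clustering recovers planted cliques joined by a bridge", {
  set.seed(1)
  k1 <- paste0("p", 1:6); k2 <- paste0("q", 1:6)
  cl <- function(v) {
    p <- t(utils::combn(v, 2))
    tibble::tibble(gene_a = p[, 1], gene_b = p[, 2], weight = 1, source = "x")
  }
  bridge <- tibble::tibble(gene_a = "p1", gene_b = "q1", weight = 1, source = "x")
  g <- build_interaction_network(dplyr::bind_rows(cl(k1), cl(k2), bridge))
  mods <- cluster_graph(g, min_size = 4, overlap_merge = 0.8)
  expect_equal(nrow(mods), 2L)
  expect_setequal(mods$members[[1]], sort(k1))
  expect_setequal(mods$members[[2]], sort(k2))
})

test_that("clustering degenerate graphs behaves sensibly", {
  # complete graph: one module containing every node
  g <- igraph::make_full_graph(6)
  igraph::V(g)$name <- paste0("n", 1:6)
  igraph::E(g)$weight <- 1
  mods <- cluster_graph(g, min_size = 4)
  expect_equal(nrow(mods), 1L)
  expect_setequal(mods$members[[1]], paste0("n", 1:6))
  # empty edge set: no modules
  g0 <- igraph::make_empty_graph(n = 5, directed = FALSE)
  igraph::V(g0)$name <- paste0("n", 1:5)
  expect_equal(nrow(cluster_graph(g0)), 0L)
  # determinism: two runs identical
  set.seed(2)
  edges <- tibble::tibble(gene_a = sample(letters[1:15], 40, TRUE),
                          gene_b = sample(letters[1:15], 40, TRUE),
                          weight = runif(40, 0.5, 1), source = "x") |>
    dplyr::filter(gene_a != gene_b)
  gr <- build_interaction_network(edges)
  expect_identical(cluster_graph(gr, min_size = 3, min_density = 0.3),
                   cluster_graph(gr, min_size = 3, min_density = 0.3))
})

test_that("module merging takes the transitive closure of the overlap relation", {
  g <- igraph::make_full_graph(10)
  igraph::V(g)$name <- paste0("v", sprintf("%02d", 1:10))
  igraph::E(g)$weight <- 1
  mk_mods <- function(sets) {
    cardiomir:::score_modules(sets, igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE) |>
                                (\(A) {dimnames(A) <- list(igraph::V(g)$name, igraph::V(g)$name); A})(),
                              penalty = 2)
  }
  v <- igraph::V(g)$name
  # disjoint modules unchanged
  mods_d <- mk_mods(list(v[1:4], v[6:9]))
  merged_d <- merge_modules(mods_d, g, threshold = 0.8)
  expect_equal(nrow(merged_d), 2L)
  # A subset of B collapses to B
  mods_s <- mk_mods(list(v[1:4], v[1:5]))
  # omega = 16/20 = 0.8 >= 0.8
  merged_s <- merge_modules(mods_s, g, threshold = 0.8)
  expect_equal(nrow(merged_s), 1L)
  expect_setequal(merged_s$members[[1]], v[1:5])
  # chain A~B, B~C merges into one even if A and C barely overlap
  mods_c <- mk_mods(list(v[1:5], v[2:6], v[3:7]))
  merged_c <- merge_modules(mods_c, g, threshold = 0.6)
  expect_equal(nrow(merged_c), 1L)
  expect_setequal(merged_c$members[[1]], v[1:7])
})

test_that("module annotation finds the planted category against the network background", {
  set.seed(4)
  genes <- paste0("g", 1:30)
  sets <- dplyr::bind_rows(
    tibble::tibble(set_id = "planted", namespace = "BP", gene_id = genes[1:6]),
    tibble::tibble(set_id = "noise", namespace = "BP", gene_id = sample(genes, 12))
  )
  cl <- t(utils::combn(genes[1:6], 2))
  edges <- tibble::tibble(gene_a = cl[, 1], gene_b = cl[, 2], weight = 1,
                          source = "x")
  sparse <- tibble::tibble(gene_a = genes[7:29], gene_b = genes[8:30],
                           weight = 0.5, source = "x")
  g <- build_interaction_network(dplyr::bind_rows(edges, sparse))
  mods <- cluster_graph(g, min_size = 4)
  ann <- annotate_modules(mods, sets, g)
  planted_row <- which(purrr::map_lgl(ann$members, ~setequal(.x, genes[1:6])))
  expect_length(planted_row, 1L)
  expect_equal(ann$top_category[planted_row], "planted")
  # module with no annotated member gets no enrichment
  mods_un <- mods[purrr::map_lgl(mods$members, ~!any(.x %in% sets$gene_id)), ]
  if (nrow(mods_un)) {
    ann_un <- annotate_modules(mods_un, sets, g)
    expect_true(all(is.na(ann_un$top_category)))
  }
})

test_that("node attributes mark DE, target, variant and expressed genes", {
  g <- unit_triangle()
  g2 <- annotate_network_nodes(g, de_genes = "a", target_genes = c("a", "b"),
                               variant_genes = "c", expressed_genes = c("a", "b", "c"))
  expect_equal(igraph::V(g2)$is_de, c(TRUE, FALSE, FALSE))
  expect_equal(igraph::V(g2)$is_target, c(TRUE, TRUE, FALSE))
  expect_equal(igraph::V(g2)$is_acm_variant_gene, c(FALSE, FALSE, TRUE))
  expect_true(all(igraph::V(g2)$expressed))
})
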