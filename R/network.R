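#' Build a functional-similarity gene network
#'
#' Connects genes by the similarity of their biological-process annotation
#' profiles: the edge weight between two genes is the Jaccard index of
#' their annotation-term sets, and an edge is kept when the weight reaches
#' `tau` (default 0.5). Genes without annotations remain isolated nodes.
#'
#' @param gene_sets Long annotation tibble (`set_id`, `namespace`,
#'   `gene_id`); typically the BP namespace of a GMT collection.
#' @param genes Character vector of genes to include as nodes.
#' @param tau Jaccard threshold in (0, 1].
#' @param namespace Namespace to use from `gene_sets` (default `"BP"`;
#'   `NULL` for all).
#' @return An [igraph::graph] with a `weight` edge attribute and a `kind`
#'   graph attribute `"functional"`.
#' @export
build_functional_network <- function(gene_sets, genes, tau = 0.5,
                                     namespace = "BP") {
  if (!is.numeric(tau) || tau <= 0 || tau > 1) {
    abort("tau must be in (0, 1].")
  }
  ann <- gene_sets
  if (!is.null(namespace)) ann <- ann |> filter(.data$namespace == !!namespace)
  ann <- ann |> filter(.data$gene_id %in% genes) |> distinct()

  genes <- sort(unique(genes))
  sets <- sort(unique(ann$set_id))
  edges <- tibble(gene_a = character(), gene_b = character(), weight = numeric())
  if (length(sets) && nrow(ann)) {
    A <- matrix(0L, length(genes), length(sets),
                dimnames = list(genes, sets))
    A[cbind(match(ann$gene_id, genes), match(ann$set_id, sets))] <- 1L
    inter <- tcrossprod(A)
    n_ann <- rowSums(A)
    uni <- outer(n_ann, n_ann, `+`) - inter
    jac <- ifelse(uni > 0, inter / uni, 0)
    diag(jac) <- 0
    idx <- which(upper.tri(jac) & jac >= tau, arr.ind = TRUE)
    edges <- tibble(gene_a = genes[idx[, 1]], gene_b = genes[idx[, 2]],
                    weight = jac[idx])
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = tibble(name = genes))
  igraph::graph_attr(g, "kind") <- "functional"
  g
}

#' Build a merged interaction network from tagged edge lists
#'
#' Combines protein-interaction and functional-association edge lists into
#' one weighted undirected network. Edges tagged with the `"string"` source
#' are kept only when their confidence score (the `weight` column) reaches
#' `min_string_score` (default 0.9). Nodes are restricted to the expressed
#' (or heart-expressed) gene set when given; duplicate edges are collapsed
#' keeping the maximum weight, and self-loops are dropped.
#'
#' @param edges Edge tibble (`gene_a`, `gene_b`, `weight`, `source`), e.g.
#'   from [read_edge_list()] or [simulate_knowledge()].
#' @param min_string_score Confidence threshold for `"string"` edges.
#' @param expressed Optional character vector restricting the node set.
#' @return An [igraph::graph] with `weight` edge attribute and `kind`
#'   attribute `"interaction"`.
#' @export
build_interaction_network <- function(edges, min_string_score = 0.9,
                                      expressed = NULL) {
  needed <- c("gene_a", "gene_b", "weight")
  if (!all(needed %in% names(edges))) {
    abort("edges must have columns gene_a, gene_b, weight (and optionally source).")
  }
  if (!"source" %in% names(edges)) edges$source <- "unknown"
  bad <- which(!is.finite(edges$weight) | edges$weight <= 0)
  if (length(bad)) {
    abort(sprintf("Malformed edge weight at line %d.", bad[1]))
  }
  kept <- edges |>
    filter(.data$source != "string" | .data$weight >= min_string_score) |>
    filter(.data$gene_a != .data$gene_b)
  if (!is.null(expressed)) {
    kept <- kept |>
      filter(.data$gene_a %in% expressed, .data$gene_b %in% expressed)
  }
  kept <- kept |>
    mutate(a = pmin(.data$gene_a, .data$gene_b),
           b = pmax(.data$gene_a, .data$gene_b)) |>
    group_by(.data$a, .data$b) |>
    summarise(weight = max(.data$weight), .groups = "drop") |>
    rename(gene_a = "a", gene_b = "b")
  nodes <- sort(unique(c(kept$gene_a, kept$gene_b)))
  g <- igraph::graph_from_data_frame(kept, directed = FALSE,
                                     vertices = tibble(name = nodes))
  igraph::graph_attr(g, "kind") <- "interaction"
  g
}

#' Attach analysis status attributes to network nodes
#'
#' Marks each node as differentially expressed, miRNA target, carrier of a
#' disease-associated variant, and/or expressed. The variant gene list is
#' user-supplied; none is bundled.
#'
#' @param graph An igraph network.
#' @param de_genes,target_genes,variant_genes,expressed_genes Character
#'   vectors of gene ids.
#' @return The graph with logical vertex attributes `is_de`, `is_target`,
#'   `is_acm_variant_gene`, `expressed`.
#' @export
annotate_network_nodes <- function(graph, de_genes = character(),
                                   target_genes = character(),
                                   variant_genes = character(),
                                   expressed_genes = character()) {
  nm <- igraph::V(graph)$name
  graph <- igraph::set_vertex_attr(graph, "is_de", value = nm %in% de_genes)
  graph <- igraph::set_vertex_attr(graph, "is_target", value = nm %in% target_genes)
  graph <- igraph::set_vertex_attr(graph, "is_acm_variant_gene",
                                   value = nm %in% variant_genes)
  igraph::set_vertex_attr(graph, "expressed", value = nm %in% expressed_genes)
}

#' Cohesiveness of a node set
#'
#' The cluster quality score used by greedy cohesive clustering:
#' \eqn{f(C) = w_{in} / (w_{in} + w_{bound} + p \cdot |C|)} where
#' \eqn{w_{in}} is the total weight of edges inside `cluster`,
#' \eqn{w_{bound}} the total weight of edges with exactly one endpoint in
#' `cluster`, and `p` a per-node penalty modelling unobserved interactions.
#'
#' @param graph A weighted igraph network.
#' @param cluster Character vector of member node names (non-empty).
#' @param penalty Per-node penalty `p` (default 2).
#' @return The cohesiveness score in \[0, 1\].
#' @examples
#' tri <- igraph::make_full_graph(3)
#' igraph::V(tri)$name <- c("a", "b", "c")
#' igraph::E(tri)$weight <- 1
#' cohesiveness(tri, c("a", "b", "c"), penalty = 2)  # 3/9
#' @export
cohesiveness <- function(graph, cluster, penalty = 2) {
  if (length(cluster) == 0) abort("cluster must be non-empty.")
  nm <- igraph::V(graph)$name
  if (!all(cluster %in% nm)) abort("cluster contains nodes absent from the graph.")
  w <- igraph::E(graph)$weight %||% rep(1, igraph::ecount(graph))
  ends <- igraph::ends(graph, igraph::E(graph), names = TRUE)
  a_in <- ends[, 1] %in% cluster
  b_in <- ends[, 2] %in% cluster
  w_in <- sum(w[a_in & b_in])
  w_bound <- sum(w[xor(a_in, b_in)])
  denom <- w_in + w_bound + penalty * length(cluster)
  if (denom == 0) return(0)
  w_in / denom
}

#' Discover cohesive clusters by greedy growth
#'
#' Greedy cohesiveness-based clustering in the style of ClusterOne:
#' clusters are seeded from the highest-weighted-degree node not yet in any
#' cluster and grown by repeatedly applying the single vertex addition or
#' removal that most increases the cohesiveness score (strict improvement;
#' ties broken by lexicographic node name). Grown clusters below `min_size`
#' members or `min_density` weighted density are discarded, and remaining
#' clusters whose overlap score \eqn{\omega(A,B) = |A \cap B|^2 / (|A||B|)}
#' reaches `overlap_merge` are merged transitively.
#'
#' @param graph A weighted igraph network.
#' @param min_size Minimum cluster size (4 for interaction networks, 5 for
#'   functional networks).
#' @param penalty Cohesiveness penalty `p` (default 2).
#' @param min_density Minimum weighted density `2 w_in / (k (k-1))`.
#' @param overlap_merge Overlap-score threshold for merging (default 0.8);
#'   `NULL` to skip merging.
#' @return A tibble of modules: `module_id`, `members` (list column,
#'   sorted), `size`, `cohesiveness`, `density`.
#' @export
cluster_graph <- function(graph, min_size = 4L, penalty = 2,
                          min_density = 0.5, overlap_merge = 0.8) {
  if (igraph::vcount(graph) == 0) {
    return(empty_modules())
  }
  A <- igraph::as_adjacency_matrix(graph, attr = if (!is.null(igraph::E(graph)$weight)) "weight" else NULL,
                                   sparse = FALSE)
  ids <- igraph::V(graph)$name
  dimnames(A) <- list(ids, ids)
  n <- length(ids)
  deg <- rowSums(A)

  unclustered <- rep(TRUE, n)
  clusters <- list()
  f_of <- function(w_in, w_bound, k) {
    d <- w_in + w_bound + penalty * k
    if (d == 0) 0 else w_in / d
  }

  # seeds: decreasing weighted degree, name as tie-break
  for (s in order(-deg, ids)) {
    if (!unclustered[s] || deg[s] == 0) next
    in_c <- logical(n); in_c[s] <- TRUE
    wtoC <- A[, s]
    w_in <- 0; w_bound <- deg[s]
    f <- f_of(w_in, w_bound, 1)
    repeat {
      k <- sum(in_c)
      best_f <- f; best_v <- NA_integer_; best_op <- ""
      add_cand <- which(!in_c & wtoC > 0)
      if (length(add_cand)) {
        f_add <- vapply(add_cand, function(v) {
          f_of(w_in + wtoC[v],
               w_bound - wtoC[v] + (deg[v] - wtoC[v]),
               k + 1)
        }, numeric(1))
        o <- order(-f_add, ids[add_cand])
        if (f_add[o[1]] > best_f + 1e-12) {
          best_f <- f_add[o[1]]; best_v <- add_cand[o[1]]; best_op <- "add"
        }
      }
      if (k > 1) {
        rem_cand <- which(in_c)
        f_rem <- vapply(rem_cand, function(v) {
          f_of(w_in - wtoC[v],
               w_bound + wtoC[v] - (deg[v] - wtoC[v]),
               k - 1)
        }, numeric(1))
        o <- order(-f_rem, ids[rem_cand])
        if (f_rem[o[1]] > best_f + 1e-12) {
          best_f <- f_rem[o[1]]; best_v <- rem_cand[o[1]]; best_op <- "remove"
        }
      }
      if (is.na(best_v)) break
      if (best_op == "add") {
        in_c[best_v] <- TRUE
        w_in <- w_in + wtoC[best_v]
        w_bound <- w_bound - wtoC[best_v] + (deg[best_v] - wtoC[best_v])
        wtoC <- wtoC + A[, best_v]
      } else {
        in_c[best_v] <- FALSE
        wtoC <- wtoC - A[, best_v]
        w_in <- w_in - wtoC[best_v]
        w_bound <- w_bound + wtoC[best_v] - (deg[best_v] - wtoC[best_v])
      }
      f <- best_f
    }
    members <- ids[in_c]
    clusters <- c(clusters, list(members))
    unclustered[in_c] <- FALSE
  }

  mods <- score_modules(clusters, A, penalty) |>
    filter(.data$size >= min_size, .data$density >= min_density)
  if (!is.null(overlap_merge) && nrow(mods) > 1) {
    mods <- merge_modules(mods, graph, threshold = overlap_merge,
                          penalty = penalty)
  }
  mods |> mutate(module_id = sprintf("M%02d", row_number()))
}

empty_modules <- function() {
  tibble(module_id = character(), members = list(), size = integer(),
         cohesiveness = numeric(), density = numeric())
}

score_modules <- function(member_list, A, penalty) {
  if (!length(member_list)) return(empty_modules())
  purrr::map(member_list, function(mem) {
    mem <- sort(unique(mem))
    k <- length(mem)
    sub <- A[mem, mem, drop = FALSE]
    w_in <- sum(sub) / 2
    w_tot <- sum(A[mem, , drop = FALSE])
    w_bound <- w_tot - 2 * w_in
    tibble(module_id = NA_character_, members = list(mem), size = k,
           cohesiveness = if (w_in + w_bound + penalty * k > 0) {
             w_in / (w_in + w_bound + penalty * k)
           } else 0,
           density = if (k > 1) 2 * w_in / (k * (k - 1)) else 0)
  }) |> list_rbind()
}

#' Merge overlapping modules into functional modules
#'
#' Computes the pairwise overlap score
#' \eqn{\omega(A,B) = |A \cap B|^2 / (|A| |B|)} between modules and merges
#' every group connected by overlaps at or above `threshold` (transitive
#' closure) into one module whose members are the union; merged modules are
#' re-scored on the graph.
#'
#' @param modules Module tibble from [cluster_graph()].
#' @param graph The network the modules were discovered in.
#' @param threshold Overlap-score threshold (default 0.8).
#' @param penalty Cohesiveness penalty used for re-scoring.
#' @return A module tibble of the same shape.
#' @export
merge_modules <- function(modules, graph, threshold = 0.8, penalty = 2) {
  if (nrow(modules) <= 1) return(modules)
  sets <- modules$members
  nm <- length(sets)
  pairs <- t(utils::combn(nm, 2))
  om <- apply(pairs, 1, function(ij) {
    a <- sets[[ij[1]]]; b <- sets[[ij[2]]]
    length(intersect(a, b))^2 / (length(a) * length(b))
  })
  g_all <- igraph::make_empty_graph(n = nm, directed = FALSE)
  if (any(om >= threshold)) {
    g_all <- igraph::add_edges(g_all, t(pairs[om >= threshold, , drop = FALSE]))
  }
  comp <- igraph::components(g_all)$membership
  merged <- split(seq_len(nm), comp) |>
    purrr::map(function(idx) sort(unique(unlist(sets[idx]))))

  A <- igraph::as_adjacency_matrix(graph, attr = if (!is.null(igraph::E(graph)$weight)) "weight" else NULL,
                                   sparse = FALSE)
  dimnames(A) <- list(igraph::V(graph)$name, igraph::V(graph)$name)
  score_modules(unname(merged), A, penalty) |>
    mutate(module_id = sprintf("FM%02d", row_number()))
}

#' Annotate modules with enriched categories
#'
#' Runs a BH-adjusted hypergeometric over-representation test for each
#' module against the full network node set as background and attaches
#' categories with adjusted p below `alpha`.
#'
#' @param modules Module tibble from [cluster_graph()] or [merge_modules()].
#' @param gene_sets Long annotation tibble (`set_id`, `namespace`,
#'   `gene_id`).
#' @param graph The network (its nodes form the background).
#' @param alpha FDR threshold for attached categories (default 0.05).
#' @return The module tibble with list column `enriched` (per-module
#'   enrichment rows) and `top_category`.
#' @export
annotate_modules <- function(modules, gene_sets, graph, alpha = 0.05) {
  background <- igraph::V(graph)$name
  enr <- purrr::map(modules$members, function(mem) {
    res <- hypergeom_enrich(intersect(mem, background), background,
                            gene_sets, adjust = "bh")
    res |> filter(.data$p_adj < alpha)
  })
  modules |>
    mutate(enriched = enr,
           top_category = purrr::map_chr(enr, function(e) {
             if (nrow(e)) e$set_id[1] else NA_character_
           }))
}
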