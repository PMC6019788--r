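#' Simulate annotation knowledge with planted structure
#'
#' Generates the external knowledge the integrative stages consume, all
#' consistent with the gene universe of [simulate_count_experiment()] under
#' the same config: a validated miRNA-target map with strong/weak evidence
#' labels, gene-set collections (biological-process-like and pathway-like)
#' with one category planted inside the DE genes, a weighted interaction
#' edge list with two planted dense subgraphs over a sparse background, and
#' toy miRNA loci / host gene models covering intronic, intergenic,
#' antisense, and doubly-hosted placements.
#'
#' @param config A [sim_config()] object.
#' @return A list with tibbles `targets` (mirna_id, gene_id, evidence),
#'   `gene_sets` (set_id, namespace, gene_id), `edges`
#'   (gene_a, gene_b, weight, source), `mirna_loci`, `host_models` (exon
#'   table), plus a `truth` list recording the planted enriched set, dense
#'   subgraphs, repressed miRNAs and host assignments.
#' @export
simulate_knowledge <- function(config = sim_config()) {
  validate_sim_config(config)
  counts_sim <- simulate_count_experiment(config)
  gene_ids <- counts_sim$truth$gene_id
  de_up <- counts_sim$truth$gene_id[counts_sim$truth$log2fc > 0]
  de_down <- counts_sim$truth$gene_id[counts_sim$truth$log2fc < 0]
  null_genes <- counts_sim$truth$gene_id[!counts_sim$truth$is_de]

  cq_truth <- simulate_cq_experiment(config)$truth

  set.seed(sub_seed(config, 37L))

  ## miRNA-target map ------------------------------------------------------
  # The repressed miRNAs are the very assays the Cq generator plants as
  # differentially expressed, so the integrated stages line up end to end.
  n_mirnas <- 30L
  mirna_ids <- sprintf("mir-%04d", seq_len(config$n_assays))
  repressed <- if (nrow(cq_truth)) cq_truth$assay_id else mirna_ids[1]
  expressed_mirnas <- union(repressed,
                            sample(mirna_ids, min(n_mirnas, length(mirna_ids))))

  targets <- purrr::map(expressed_mirnas, function(m) {
    n_t <- sample(5:40, 1)
    if (m %in% repressed && length(de_down) > 0) {
      # planted repression: a fifth of the targets sit among down genes
      n_down <- max(1L, round(0.2 * n_t))
      g <- c(sample(de_down, min(n_down, length(de_down))),
             sample(null_genes, n_t - min(n_down, length(de_down))))
    } else {
      g <- sample(gene_ids, n_t)
    }
    tibble(mirna_id = m, gene_id = unique(g),
           evidence = sample(c("strong", "weak"), length(unique(g)),
                             replace = TRUE, prob = c(0.7, 0.3)))
  }) |> list_rbind()

  ## gene sets --------------------------------------------------------------
  de_genes <- counts_sim$truth$gene_id[counts_sim$truth$is_de]
  planted_set <- "BP:planted_adhesion"
  planted_members <- sample(de_genes, min(15L, length(de_genes)))
  sets <- purrr::map(seq_len(19L), function(i) {
    ns <- if (i <= 12) "BP" else "pathway"
    tibble(set_id = sprintf("%s:set%02d", ns, i), namespace = ns,
           gene_id = sample(gene_ids, sample(10:40, 1)))
  }) |> list_rbind()
  gene_sets <- bind_rows(
    tibble(set_id = planted_set, namespace = "BP", gene_id = planted_members),
    sets
  )

  ## interaction edges -------------------------------------------------------
  net_genes <- sample(gene_ids, min(120L, length(gene_ids)))
  clique1 <- paste0("cliq1_", letters[1:6])
  clique2 <- paste0("cliq2_", letters[1:6])
  all_nodes <- c(net_genes, clique1, clique2)

  bg_pairs <- t(utils::combn(net_genes, 2))
  keep <- runif(nrow(bg_pairs)) < 0.02
  bg <- tibble(gene_a = bg_pairs[keep, 1], gene_b = bg_pairs[keep, 2],
               weight = round(runif(sum(keep), 0.4, 0.95), 3),
               source = sample(c("mentha", "string"), sum(keep), replace = TRUE))
  cl_edges <- function(nodes) {
    p <- t(utils::combn(nodes, 2))
    tibble(gene_a = p[, 1], gene_b = p[, 2], weight = 1.0, source = "bioplex")
  }
  # a couple of weak spokes connecting the cliques to the background
  spokes <- tibble(
    gene_a = c(clique1[1], clique2[1]),
    gene_b = sample(net_genes, 2),
    weight = 0.5, source = "mentha"
  )
  edges <- bind_rows(bg, cl_edges(clique1), cl_edges(clique2), spokes)

  ## miRNA loci and host gene models ----------------------------------------
  host_models <- tibble(
    gene_id = c("hostG1", "hostG1", "hostG2", "hostG2"),
    seqnames = "chr9",
    start = c(1001, 5001, 1501, 6001),
    end   = c(1200, 5200, 1700, 6200),
    strand = c("+", "+", "+", "+")
  )
  mirna_loci <- tibble(
    mirna_id = c("mirH_intronic", "mirH_intergenic", "mirH_antisense"),
    seqnames = "chr9",
    start = c(2001, 8001, 2101),
    end   = c(2085, 8085, 2185),
    strand = c("+", "+", "-")
  )

  list(
    targets = targets,
    gene_sets = gene_sets,
    edges = edges,
    mirna_loci = mirna_loci,
    host_models = host_models,
    expressed_mirnas = expressed_mirnas,
    truth = list(
      planted_enriched_set = planted_set,
      planted_cliques = list(clique1, clique2),
      network_nodes = all_nodes,
      repressed_mirnas = repressed,
      # mirH_intronic sits in the introns of both hostG1 and hostG2 spans;
      # the antisense locus is inside hostG1's span on the opposite strand.
      planted_hosts = tibble(
        mirna_id = c("mirH_intronic", "mirH_intronic"),
        gene_id = c("hostG1", "hostG2"),
        placement = c("intronic", "intronic")
      )
    )
  )
}
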