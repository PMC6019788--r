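#' Published miRNA screen summary values
#'
#' Group-mean normalized delta-Cq values and adjusted p-values of the three
#' miRNAs reported as significantly differentially expressed (ACM vs
#' control cardiac stromal cells) in the published TaqMan-array screen.
#' Useful as a worked input for [delta_cq_to_m()].
#'
#' @return A tibble (`mirna`, `dcq_case`, `dcq_control`, `p_adj`).
#' @examples
#' screen <- acm_mirna_screen()
#' delta_cq_to_m(screen$dcq_case, screen$dcq_control)
#' @export
acm_mirna_screen <- function() {
  readr::read_tsv(system.file("extdata", "acm_mirna_screen.tsv",
                              package = "cardiomir"),
                  show_col_types = FALSE)
}

#' Run the integrative pipeline end to end on synthetic data
#'
#' Orchestrates all stages on data from the synthetic generators under one
#' [sim_config()]: the miRNA Cq screen (global-mean normalization,
#' replicate averaging, detection filter, moderated t-test), the RNA-seq
#' stage (size factors, low-count filter, PCA confounder, NB Wald test),
#' gene-set enrichment of the DE genes, the target-repression permutation
#' analysis and host-gene detection, and network module discovery. Result
#' tables are written as TSV under `out_dir` together with a JSON manifest
#' (seed, per-stage row counts, file checksums). Runs are deterministic
#' given the config.
#'
#' @param config A [sim_config()]; its seed drives every random draw.
#' @param out_dir Output directory (created if needed).
#' @param stages Character subset of
#'   `c("qpcr", "rnaseq", "enrichment", "integration", "network")`.
#' @param inputs Optional named list of precomputed stage outputs, used when
#'   a required upstream stage is toggled off: `de_mirna`, `de_genes`
#'   (`cm_de_table`-shaped tibbles), `expressed_genes` (character).
#' @param n_perm Permutations for the repression test (default 1000).
#' @param alpha Significance level for all adjusted-p calls.
#' @return A list with per-stage results (`de_mirna`, `detection_report`,
#'   `de_genes`, `pca`, `enrichment`, `repression`, `host_genes`,
#'   `modules_interaction`, `modules_functional`, `truth`) and the manifest,
#'   invisibly also written to `out_dir`.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = tempfile("cardiomir_"),
                         stages = c("qpcr", "rnaseq", "enrichment",
                                    "integration", "network"),
                         inputs = list(), n_perm = 1000L, alpha = 0.05) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  outputs <- character(0)

  need <- function(what, stage) {
    if (!is.null(res[[what]])) return(res[[what]])
    if (!is.null(inputs[[what]])) return(inputs[[what]])
    abort(sprintf("Stage '%s' needs artifact '%s': run its upstream stage or supply it via `inputs`.",
                  stage, what))
  }
  save_tsv <- function(x, name) {
    p <- file.path(out_dir, name)
    readr::write_tsv(x, p)
    outputs <<- c(outputs, p)
  }

  ## miRNA screen -----------------------------------------------------------
  if ("qpcr" %in% stages) {
    sim <- simulate_cq_experiment(config)
    filtered <- sim$cq |>
      normalize_cq_global_mean() |>
      average_replicates(sim$samples) |>
      filter_detection(sim$samples)
    de_mirna <- moderated_t_test(filtered, sim$samples, alpha = alpha)
    res$de_mirna <- de_mirna
    res$detection_report <- filter_report(filtered)
    res$truth$mirna <- sim$truth
    save_tsv(tidy(de_mirna), "de_mirna.tsv")
  }

  ## RNA-seq ----------------------------------------------------------------
  if ("rnaseq" %in% stages) {
    sim <- simulate_count_experiment(config)
    sf <- size_factors_median_ratio(sim$counts)
    filtered <- low_count_filter(sim$counts, sim$samples, sf)
    pca <- pca_confounder(filtered, sf)
    # When the PC1 sign coincides with the condition there is no separate
    # confounder to absorb; adding it would only alias the condition effect.
    grp <- sim$samples$group[match(pca$sample_id, sim$samples$sample_id)]
    aliased <- dplyr::n_distinct(paste(pca$covariate, grp)) <= 2
    if (aliased) {
      inform("PC1 sign coincides with the condition; fitting without the covariate.")
    }
    de_genes <- nb_wald_test(filtered, sim$samples, sf,
                             covariate = if (aliased) NULL else pca,
                             alpha = alpha)
    res$de_genes <- de_genes
    res$pca <- pca
    res$count_filter_report <- filter_report(filtered)
    res$expressed_genes <- filtered$gene_id
    res$truth$genes <- sim$truth
    save_tsv(tidy(de_genes), "de_genes.tsv")
    save_tsv(pca, "pca_scores.tsv")
  }

  needs_knowledge <- any(c("enrichment", "integration", "network") %in% stages)
  if (needs_knowledge) {
    kn <- simulate_knowledge(config)
    res$knowledge <- kn
    save_tsv(kn$targets, "target_map.tsv")
    save_tsv(kn$edges, "edges.tsv")
    p_gmt <- file.path(out_dir, "gene_sets.gmt")
    write_gmt(kn$gene_sets, p_gmt)
    outputs <- c(outputs, p_gmt)
  }

  ## enrichment -------------------------------------------------------------
  if ("enrichment" %in% stages) {
    de_genes <- need("de_genes", "enrichment")
    expressed <- need("expressed_genes", "enrichment")
    query <- de_genes$feature_id[de_genes$significant %in% TRUE]
    res$enrichment <- hypergeom_enrich(query, expressed, res$knowledge$gene_sets,
                                       adjust = "bonferroni")
    save_tsv(res$enrichment, "enrichment.tsv")
  }

  ## integration ------------------------------------------------------------
  if ("integration" %in% stages) {
    de_mirna <- need("de_mirna", "integration")
    de_genes <- need("de_genes", "integration")
    expressed <- need("expressed_genes", "integration")
    kn <- res$knowledge
    sig_mirnas <- de_mirna$feature_id[de_mirna$significant %in% TRUE]
    detected <- de_mirna$feature_id[de_mirna$tested %in% TRUE]
    universe <- mirna_target_background(kn$targets,
                                        union(detected, kn$expressed_mirnas),
                                        expressed)
    sets <- suppressWarnings(
      select_targets(kn$targets, sig_mirnas, expressed, evidence = "strong")
    )
    res$target_sets <- sets
    if (length(universe) && any(lengths(sets) > 0)) {
      res$repression <- repression_table(de_genes, sets, universe,
                                         n_perm = n_perm,
                                         seed = sub_seed(config, 71L))
      save_tsv(res$repression, "repression.tsv")
    }
    res$host_genes <- find_host_genes(kn$mirna_loci, kn$host_models)
    save_tsv(res$host_genes, "host_genes.tsv")
  }

  ## network ----------------------------------------------------------------
  if ("network" %in% stages) {
    kn <- res$knowledge
    g_int <- build_interaction_network(kn$edges,
                                       expressed = kn$truth$network_nodes)
    res$modules_interaction <- cluster_graph(g_int, min_size = 4L)
    fun_genes <- unique(kn$gene_sets$gene_id[kn$gene_sets$namespace == "BP"])
    g_fun <- build_functional_network(kn$gene_sets, fun_genes, tau = 0.5)
    mods_fun <- cluster_graph(g_fun, min_size = 5L)
    res$modules_functional <- annotate_modules(mods_fun, kn$gene_sets, g_fun,
                                               alpha = alpha)
    save_tsv(res$modules_interaction |>
               mutate(members = purrr::map_chr(.data$members, paste, collapse = ",")),
             "modules_interaction.tsv")
    save_tsv(res$modules_functional |>
               select(-"enriched") |>
               mutate(members = purrr::map_chr(.data$members, paste, collapse = ",")),
             "modules_functional.tsv")
  }

  ## manifest ---------------------------------------------------------------
  manifest <- list(
    package = "cardiomir",
    version = as.character(utils::packageVersion("cardiomir")),
    seed = config$seed,
    stages = stages,
    files = lapply(setNames(outputs, basename(outputs)), function(p) {
      list(md5 = unname(tools::md5sum(p)),
           rows = length(readLines(p)) - 1L)
    })
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  res$manifest <- manifest
  res$out_dir <- out_dir
  res
}
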