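#' Hypergeometric gene-set over-representation analysis
#'
#' For each category, tests whether the query gene set overlaps the category
#' more than expected when drawing `|query|` genes from the background
#' universe: the one-sided upper-tail hypergeometric probability
#' \eqn{P[X \ge count]} with population = background size, successes =
#' category size in the background, draws = query size. Categories are
#' intersected with the background before testing; categories with fewer
#' than 2 background members are skipped. Adjustment is Bonferroni (for
#' category screens) or Benjamini-Hochberg (for module annotation).
#'
#' @param query Character vector of query gene ids (must be a subset of
#'   `background`).
#' @param background Character vector: the expressed-gene universe.
#' @param gene_sets Long tibble (`set_id`, `namespace`, `gene_id`) as read
#'   by [read_gmt()].
#' @param adjust `"bonferroni"` or `"bh"`.
#' @param min_size Minimum category size within the background (default 2).
#' @return A tibble sorted by adjusted p: `set_id`, `namespace`, `p`,
#'   `p_adj`, `count` (query hits), `size` (background hits), `query_size`,
#'   `background_size`, `significant`.
#' @examples
#' sets <- tibble::tibble(set_id = "s1", namespace = "BP",
#'                        gene_id = paste0("g", 1:5))
#' hypergeom_enrich(paste0("g", 1:4), paste0("g", 1:10), sets)
#' @export
hypergeom_enrich <- function(query, background, gene_sets,
                             adjust = c("bonferroni", "bh"), min_size = 2L) {
  adjust <- match.arg(adjust)
  query <- unique(query)
  background <- unique(background)
  offenders <- setdiff(query, background)
  if (length(offenders)) {
    abort(sprintf("Query gene(s) not in the background: %s%s.",
                  paste(head(offenders, 5), collapse = ", "),
                  if (length(offenders) > 5) ", ..." else ""))
  }
  n_bg <- length(background)
  n_q <- length(query)

  rows <- gene_sets |>
    filter(.data$gene_id %in% background) |>
    group_by(.data$set_id) |>
    summarise(
      namespace = first(.data$namespace),
      size = dplyr::n_distinct(.data$gene_id),
      count = sum(unique(.data$gene_id) %in% query),
      .groups = "drop"
    ) |>
    filter(.data$size >= min_size)

  if (nrow(rows) == 0) {
    return(tibble(set_id = character(), namespace = character(),
                  p = numeric(), p_adj = numeric(), count = integer(),
                  size = integer(), query_size = integer(),
                  background_size = integer(), significant = logical()))
  }

  p <- phyper(rows$count - 1L, rows$size, n_bg - rows$size, n_q,
              lower.tail = FALSE)
  p_adj <- if (adjust == "bonferroni") adjust_bonferroni(p) else adjust_bh(p)
  rows |>
    mutate(p = p, p_adj = p_adj,
           query_size = n_q, background_size = n_bg,
           significant = p_adj < 0.05) |>
    select("set_id", "namespace", "p", "p_adj", "count", "size",
           "query_size", "background_size", "significant") |>
    arrange(.data$p_adj, .data$p, .data$set_id)
}

#' Build the expressed miRNA-target background universe
#'
#' The universe against which target-set repression and enrichment are
#' evaluated: the union of validated target genes of all expressed miRNAs,
#' intersected with the expressed genes.
#'
#' @param targets Target map tibble (`mirna_id`, `gene_id`, `evidence`).
#' @param expressed_mirnas Character vector of detected miRNA ids.
#' @param expressed_genes Character vector of expressed gene ids.
#' @return Character vector of background gene ids (sorted, unique).
#' @export
mirna_target_background <- function(targets, expressed_mirnas, expressed_genes) {
  targets |>
    filter(.data$mirna_id %in% expressed_mirnas,
           .data$gene_id %in% expressed_genes) |>
    pull("gene_id") |>
    unique() |>
    sort()
}
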