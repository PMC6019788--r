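#' Select expressed target genes per miRNA
#'
#' Filters a validated miRNA-target map to the requested evidence level and
#' intersects each miRNA's targets with the expressed genes. miRNAs with no
#' remaining targets (including miRNAs absent from the map, which triggers a
#' warning) are reported with empty sets rather than dropped.
#'
#' @param targets Target map tibble (`mirna_id`, `gene_id`, `evidence`).
#' @param mirnas Character vector of miRNA ids of interest.
#' @param expressed_genes Character vector of expressed gene ids.
#' @param evidence `"strong"` (high-confidence pairs only) or `"any"`.
#' @return A named list of character vectors, one per requested miRNA.
#' @export
select_targets <- function(targets, mirnas, expressed_genes,
                           evidence = c("strong", "any")) {
  evidence <- match.arg(evidence)
  unknown <- setdiff(mirnas, unique(targets$mirna_id))
  if (length(unknown)) {
    warn(sprintf("No target genes reported for: %s.", paste(unknown, collapse = ", ")))
  }
  kept <- targets |>
    filter(.data$mirna_id %in% mirnas,
           .data$gene_id %in% expressed_genes)
  if (evidence == "strong") kept <- kept |> filter(.data$evidence == "strong")
  sets <- split(kept$gene_id, factor(kept$mirna_id, levels = mirnas))
  lapply(sets, function(g) sort(unique(g)))
}

#' Permutation test for coordinate repression of a target set
#'
#' Tests whether the observed average M-value (log2 fold change) of a
#' miRNA's target genes is lower than expected for a random target set: the
#' observed mean M is compared with the mean M of `n_perm` randomly drawn
#' same-sized subsets of the target universe (validated, expressed target
#' genes of expressed miRNAs). The one-tailed p-value is the fraction of
#' random sets whose average M is less than or equal to the observed
#' average. By default the p-value is the plain fraction over `n_perm`
#' draws; `plus_one = TRUE` applies the (k+1)/(n+1) correction.
#'
#' @param de A DE table (e.g. from [nb_wald_test()]) with `feature_id` and
#'   `m` columns.
#' @param target_set Character vector of target gene ids (subset of
#'   `universe`).
#' @param universe Character vector: the sampling universe of target genes.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed for the draws.
#' @param plus_one Apply the (k+1)/(n+1) finite-sample correction.
#' @param mirna Label for the output row.
#' @return A one-row tibble: `mirna`, `average_m`, `p_perm`, `p_t`,
#'   `gene_count`, `n_permutations`.
#' @export
target_repression_test <- function(de, target_set, universe,
                                   n_perm = 1000L, seed = 1L,
                                   plus_one = FALSE, mirna = "miRNA") {
  m_lookup <- setNames(de$m, de$feature_id)
  target_set <- unique(target_set)
  universe <- unique(universe)
  if (length(target_set) < 1) abort("target_set must contain at least one gene.")
  if (length(target_set) > length(universe)) {
    abort("target_set is larger than the sampling universe.")
  }
  bad <- setdiff(universe, de$feature_id)
  if (length(bad)) {
    abort(sprintf("Universe gene(s) missing from the DE table: %s%s.",
                  paste(head(bad, 5), collapse = ", "),
                  if (length(bad) > 5) ", ..." else ""))
  }
  if (!all(target_set %in% universe)) {
    abort("target_set must be a subset of the universe.")
  }

  m_u <- m_lookup[universe]
  observed <- mean(m_lookup[target_set])
  k <- length(target_set)

  set.seed(seed)
  null_means <- vapply(seq_len(n_perm), function(i) mean(sample(m_u, k)),
                       numeric(1))
  n_le <- sum(null_means <= observed)
  p_perm <- if (plus_one) (n_le + 1) / (n_perm + 1) else n_le / n_perm

  tibble(
    mirna = mirna,
    average_m = observed,
    p_perm = p_perm,
    p_t = target_repression_ttest(de, target_set),
    gene_count = k,
    n_permutations = as.integer(n_perm)
  )
}

#' One-sample t-test for average target repression
#'
#' One-sided (less) one-sample Student's t-test of the target genes'
#' M-values against zero: the alternative hypothesis is an average M < 0,
#' i.e. the targets are on average lower expressed in cases.
#'
#' @inheritParams target_repression_test
#' @return The one-sided p-value (NA with a warning if the M-values are
#'   degenerate).
#' @export
target_repression_ttest <- function(de, target_set) {
  mv <- de$m[match(unique(target_set), de$feature_id)]
  mv <- mv[!is.na(mv)]
  if (length(mv) < 2) {
    warn("Fewer than 2 target M-values; t-test not performed.")
    return(NA_real_)
  }
  if (sd(mv) == 0) {
    warn("Degenerate (zero-variance) target M-values; t-test undefined.")
    return(NA_real_)
  }
  stats::t.test(mv, mu = 0, alternative = "less")$p.value
}

#' Repression test for each miRNA and for the combined target set
#'
#' Runs [target_repression_test()] for every miRNA's target set and once
#' for the union of all sets (reported as `"All"`), mirroring the combined
#' analysis row of an integrated screen.
#'
#' @inheritParams target_repression_test
#' @param target_sets Named list of per-miRNA target gene vectors (from
#'   [select_targets()]). Empty sets are skipped with a note in the output.
#' @return A tibble with one row per miRNA plus the `"All"` row.
#' @export
repression_table <- function(de, target_sets, universe,
                             n_perm = 1000L, seed = 1L, plus_one = FALSE) {
  nonempty <- target_sets[vapply(target_sets, length, integer(1)) > 0]
  rows <- purrr::imap(nonempty, function(g, nm) {
    target_repression_test(de, g, universe, n_perm = n_perm,
                           seed = seed, plus_one = plus_one, mirna = nm)
  }) |> list_rbind()
  all_set <- sort(unique(unlist(target_sets)))
  if (length(all_set)) {
    rows <- bind_rows(
      rows,
      target_repression_test(de, all_set, universe, n_perm = n_perm,
                             seed = seed, plus_one = plus_one, mirna = "All")
    )
  }
  rows
}

#' Find host genes of miRNA loci
#'
#' A gene hosts a miRNA when its transcription-unit span (minimum start to
#' maximum end over its exons) fully contains the miRNA locus on the same
#' strand — the primary-transcript logic behind intronic miRNA biogenesis.
#' Multiple hosts are allowed (overlapping genes). Containment within the
#' host's exon union is tagged `"exonic"`, otherwise `"intronic"`.
#' Antisense hosts (span contains the locus on the opposite strand) are
#' only reported with `include_antisense = TRUE`, tagged `"antisense"`.
#'
#' @param loci Tibble of miRNA loci (`mirna_id`, `seqnames`, `start`,
#'   `end`, `strand`; 1-based closed).
#' @param models Gene models: either an exon tibble (`gene_id`, `seqnames`,
#'   `start`, `end`, `strand`) or a path to a GFF3 file with exon features.
#' @param include_antisense Also report opposite-strand hosts.
#' @return A tibble (`mirna_id`, `gene_id`, `placement`); miRNAs without a
#'   host are absent. A warning is raised for loci on chromosomes missing
#'   from the models.
#' @export
find_host_genes <- function(loci, models, include_antisense = FALSE) {
  exons <- if (is.character(models)) {
    gr <- read_exons_by_gene(models)
    fl <- unlist(gr, use.names = FALSE)
    tibble(gene_id = rep(names(gr), S4Vectors::elementNROWS(gr)),
           seqnames = as.character(GenomicRanges::seqnames(fl)),
           start = GenomicRanges::start(fl), end = GenomicRanges::end(fl),
           strand = as.character(GenomicRanges::strand(fl)))
  } else {
    models
  }
  if (any(exons$end < exons$start) || any(loci$end < loci$start)) {
    abort("Interval with end < start in the gene models or loci.")
  }
  missing_chr <- setdiff(unique(loci$seqnames), unique(exons$seqnames))
  if (length(missing_chr)) {
    warn(sprintf("Chromosome(s) absent from the gene models: %s.",
                 paste(missing_chr, collapse = ", ")))
  }

  spans <- exons |>
    group_by(.data$gene_id) |>
    summarise(seqnames = first(.data$seqnames), start = min(.data$start),
              end = max(.data$end), strand = first(.data$strand),
              .groups = "drop")

  hits <- loci |>
    inner_join(spans, by = "seqnames", suffix = c("", "_gene"),
               relationship = "many-to-many") |>
    filter(.data$start >= .data$start_gene, .data$end <= .data$end_gene)

  hits <- hits |>
    mutate(same_strand = .data$strand == .data$strand_gene) |>
    filter(.data$same_strand | include_antisense)

  if (nrow(hits) == 0) {
    return(tibble(mirna_id = character(), gene_id = character(),
                  placement = character()))
  }

  exonic <- purrr::pmap_lgl(
    hits |> select("mirna_id", "gene_id", "start", "end"),
    function(mirna_id, gene_id, start, end) {
      ex <- exons |> filter(.data$gene_id == !!gene_id)
      red <- IRanges::reduce(IRanges::IRanges(ex$start, ex$end))
      any(IRanges::start(red) <= start & IRanges::end(red) >= end)
    }
  )
  hits |>
    mutate(placement = dplyr::case_when(
      !.data$same_strand ~ "antisense",
      exonic ~ "exonic",
      TRUE ~ "intronic"
    )) |>
    select("mirna_id", "gene_id", "placement") |>
    arrange(.data$mirna_id, .data$gene_id)
}
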