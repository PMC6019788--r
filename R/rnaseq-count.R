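#' Count read pairs fully contained in gene exons
#'
#' Gene-level quantification by strict exon containment: a read pair is
#' counted for a gene if and only if every aligned base of both mates lies
#' within the union of that gene's exons (junction reads whose N-gap matches
#' an intron therefore count). Pairs with alignment quality below `min_mapq`
#' (default 30), multi-mapping pairs (`NH` tag > 1 or secondary flag), and
#' pairs compatible with more than one gene are not counted. Counting is
#' unstranded.
#'
#' @param sam_files Named character vector of SAM (or BAM) paths, one per
#'   sample; names become sample ids.
#' @param gff3 Path to gene models in GFF3 (1-based closed coordinates,
#'   `exon` features carrying a `gene_id` attribute).
#' @param min_mapq Minimum alignment quality (default 30).
#' @param paired `TRUE` (default) to count at fragment level.
#' @return A counts tibble (`gene_id` + one column per sample) with a
#'   per-sample accounting `"report"` attribute whose categories
#'   (counted, ambiguous, low_mapq, multimapped, not_contained) sum to the
#'   total number of alignments processed.
#' @export
count_exon_contained <- function(sam_files, gff3, min_mapq = 30L, paired = TRUE) {
  if (is.null(names(sam_files)) || any(!nzchar(names(sam_files)))) {
    names(sam_files) <- tools::file_path_sans_ext(basename(sam_files))
  }
  exons_by_gene <- read_exons_by_gene(gff3)
  gene_ids <- sort(names(exons_by_gene))
  exu <- GenomicRanges::reduce(exons_by_gene)
  exu_flat <- unlist(exu, use.names = FALSE)
  exu_gene <- rep(names(exu), S4Vectors::elementNROWS(exu))

  per_sample <- purrr::imap(sam_files, function(path, sample) {
    aln <- read_alignments(path, paired = paired)
    n_total <- length(aln$blocks)

    multim <- aln$nh > 1L | aln$secondary
    lowq <- !multim & aln$mapq < min_mapq
    usable <- !multim & !lowq

    blocks <- aln$blocks[usable]
    n_usable <- length(blocks)
    assigned <- character(0)
    n_amb <- 0L
    if (n_usable > 0) {
      flat <- unlist(blocks, use.names = FALSE)
      block_of <- rep(seq_len(n_usable), S4Vectors::elementNROWS(blocks))
      hits <- GenomicRanges::findOverlaps(flat, exu_flat, type = "within",
                                          ignore.strand = TRUE)
      if (length(hits)) {
        hit_tbl <- tibble(
          read = block_of[S4Vectors::queryHits(hits)],
          block = S4Vectors::queryHits(hits),
          gene = exu_gene[S4Vectors::subjectHits(hits)]
        ) |> distinct()
        nblocks <- S4Vectors::elementNROWS(blocks)
        full <- hit_tbl |>
          group_by(.data$read, .data$gene) |>
          summarise(n_in = dplyr::n_distinct(.data$block), .groups = "drop") |>
          filter(.data$n_in == nblocks[.data$read])
        genes_per_read <- full |> dplyr::count(.data$read)
        uniq <- genes_per_read$read[genes_per_read$n == 1L]
        n_amb <- sum(genes_per_read$n > 1L)
        assigned <- full$gene[full$read %in% uniq]
      }
    }
    counts <- table(factor(assigned, levels = gene_ids))
    n_counted <- length(assigned)
    list(
      counts = as.integer(counts),
      report = tibble(
        sample_id = sample,
        total = n_total,
        counted = n_counted,
        ambiguous = n_amb,
        low_mapq = sum(lowq),
        multimapped = sum(multim),
        not_contained = n_usable - n_counted - n_amb
      )
    )
  })

  mat <- vapply(per_sample, `[[`, integer(length(gene_ids)), "counts")
  out <- bind_cols(tibble(gene_id = gene_ids), as_tibble(mat))
  attr(out, "report") <- purrr::map(per_sample, "report") |> list_rbind()
  out
}

read_exons_by_gene <- function(gff3) {
  gr <- tryCatch(
    rtracklayer::import(gff3, format = "gff3"),
    error = function(e) abort(sprintf("GFF3 validation error in %s: %s",
                                      gff3, conditionMessage(e)))
  )
  ex <- gr[gr$type == "exon"]
  if (length(ex) == 0) abort("No exon features found in the gene models.")
  if (is.null(ex$gene_id) || anyNA(ex$gene_id)) {
    abort("Exon features must carry a gene_id attribute.")
  }
  GenomicRanges::split(ex, ex$gene_id)
}

# Parse SAM/BAM into per-fragment aligned blocks plus MAPQ/NH metadata.
read_alignments <- function(path, paired = TRUE) {
  bam <- if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    Rsamtools::asBam(path, destination = tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
  } else {
    path
  }
  param <- Rsamtools::ScanBamParam(what = c("mapq", "flag"), tag = "NH")
  if (paired) {
    ga <- GenomicAlignments::readGAlignmentPairs(bam, param = param)
    f <- GenomicAlignments::first(ga)
    l <- GenomicAlignments::second(ga)
    nh1 <- S4Vectors::mcols(f)$NH %||% rep(1L, length(ga))
    nh2 <- S4Vectors::mcols(l)$NH %||% rep(1L, length(ga))
    nh1[is.na(nh1)] <- 1L; nh2[is.na(nh2)] <- 1L
    list(
      blocks = GenomicAlignments::grglist(ga),
      mapq = pmin(S4Vectors::mcols(f)$mapq, S4Vectors::mcols(l)$mapq),
      nh = pmax(nh1, nh2),
      secondary = (bitwAnd(S4Vectors::mcols(f)$flag, 256L) > 0) |
        (bitwAnd(S4Vectors::mcols(l)$flag, 256L) > 0)
    )
  } else {
    ga <- GenomicAlignments::readGAlignments(bam, param = param)
    nh <- S4Vectors::mcols(ga)$NH %||% rep(1L, length(ga))
    nh[is.na(nh)] <- 1L
    list(
      blocks = GenomicAlignments::grglist(ga),
      mapq = S4Vectors::mcols(ga)$mapq,
      nh = nh,
      secondary = bitwAnd(S4Vectors::mcols(ga)$flag, 256L) > 0
    )
  }
}

#' Median-of-ratios size factors
#'
#' The standard library-size normalization for count matrices: per sample,
#' the median ratio of counts to the per-gene geometric mean over all
#' samples, taken across genes with nonzero counts everywhere, rescaled so
#' the factors have geometric mean 1.
#'
#' @param counts Counts tibble (`gene_id` + sample columns) or matrix.
#' @return A tibble (`sample_id`, `size_factor`).
#' @export
size_factors_median_ratio <- function(counts) {
  m <- counts_to_matrix(counts)
  all_nonzero <- rowSums(m == 0) == 0
  if (!any(all_nonzero)) {
    abort(paste("No gene has nonzero counts in every sample;",
                "size factors need a pseudo-reference fallback."))
  }
  ref <- m[all_nonzero, , drop = FALSE]
  geo <- exp(rowMeans(log(ref)))
  sf <- apply(ref / geo, 2, median)
  sf <- sf / geometric_mean(sf)
  tibble(sample_id = colnames(m), size_factor = unname(sf))
}

sf_vector <- function(size_factors, sample_ids) {
  if (is.null(size_factors)) return(setNames(rep(1, length(sample_ids)), sample_ids))
  if (is.data.frame(size_factors)) {
    sf <- setNames(size_factors$size_factor, size_factors$sample_id)
  } else {
    sf <- size_factors
  }
  missing <- setdiff(sample_ids, names(sf))
  if (length(missing)) {
    abort(sprintf("Missing size factors for sample(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  sf[sample_ids]
}

#' Remove genes with low normalized counts in both groups
#'
#' Keeps a gene if its mean normalized count (count / size factor) reaches
#' `threshold` in at least one of the two groups; genes below the threshold
#' in both groups are removed.
#'
#' @param counts Counts tibble (`gene_id` + sample columns).
#' @param samples Sample sheet mapping `sample_id` to `group`.
#' @param size_factors Tibble from [size_factors_median_ratio()] (computed
#'   if `NULL`).
#' @param threshold Normalized-count threshold (default 10).
#' @return The filtered counts tibble with a `"report"` attribute
#'   (`n_before`, `n_after`).
#' @export
low_count_filter <- function(counts, samples, size_factors = NULL, threshold = 10) {
  m <- counts_to_matrix(counts)
  assert_sample_sheet(samples)
  if (is.null(size_factors)) size_factors <- size_factors_median_ratio(counts)
  sf <- sf_vector(size_factors, colnames(m))
  z <- sweep(m, 2, sf, `/`)
  grp <- samples$group[match(colnames(m), samples$sample_id)]
  mean_case <- rowMeans(z[, grp == "case", drop = FALSE])
  mean_ctrl <- rowMeans(z[, grp == "control", drop = FALSE])
  keep <- mean_case >= threshold | mean_ctrl >= threshold
  out <- matrix_to_counts(m[keep, , drop = FALSE])
  attr(out, "report") <- tibble(n_before = nrow(m), n_after = sum(keep),
                                threshold = threshold)
  out
}
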