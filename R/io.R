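#' Read and write pipeline tables
#'
#' Thin TSV readers/writers for the tabular formats the pipeline exchanges:
#' Cq tables (`assay_id`, `sample_id`, `cq`, `flag`), sample sheets
#' (`sample_id`, `individual`, `group`, `replicate`), count matrices
#' (`gene_id` + one column per sample), miRNA-target maps
#' (`mirna_id`, `gene_id`, `evidence`) and weighted edge lists
#' (`gene_a`, `gene_b`, `weight`, `source`).
#'
#' @param path File path.
#' @param x Table to write.
#' @return Readers return a tibble; writers return `path` invisibly.
#' @name pipeline-io
NULL

#' @rdname pipeline-io
#' @export
read_cq_tsv <- function(path) {
  cq <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          assay_id = "c", sample_id = "c",
                          cq = "d", flag = "c"))
  assert_cq_tbl(cq)
  cq
}

#' @rdname pipeline-io
#' @export
write_cq_tsv <- function(x, path) {
  assert_cq_tbl(x)
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname pipeline-io
#' @export
read_sample_sheet <- function(path) {
  s <- readr::read_tsv(path, show_col_types = FALSE)
  assert_sample_sheet(s)
  s
}

#' @rdname pipeline-io
#' @export
read_counts_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname pipeline-io
#' @export
read_target_map <- function(path) {
  t <- readr::read_tsv(path, show_col_types = FALSE)
  needed <- c("mirna_id", "gene_id", "evidence")
  if (!all(needed %in% names(t))) {
    abort("Target map must have columns mirna_id, gene_id, evidence.")
  }
  t
}

#' @rdname pipeline-io
#' @export
read_edge_list <- function(path) {
  e <- readr::read_tsv(path, show_col_types = FALSE)
  needed <- c("gene_a", "gene_b", "weight")
  if (!all(needed %in% names(e))) {
    bad <- setdiff(needed, names(e))
    abort(sprintf("Edge list %s is missing column(s): %s.",
                  path, paste(bad, collapse = ", ")))
  }
  if (!"source" %in% names(e)) e$source <- "unknown"
  e
}

#' Read and write GMT gene-set collections
#'
#' GMT is the tab-separated gene-set format: one set per line, fields
#' `set_id`, `description`, then member gene ids. `read_gmt()` returns the
#' collection in long form; the `description` field is stored in the
#' `namespace` column (the writers put the namespace tag there).
#'
#' @param path GMT file path.
#' @param gene_sets Long tibble with columns `set_id`, `namespace`, `gene_id`.
#' @return `read_gmt()`: tibble (`set_id`, `namespace`, `gene_id`);
#'   `write_gmt()`: `path`, invisibly.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  purrr::map(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) abort(sprintf("Malformed GMT line: %s", substr(l, 1, 60)))
    tibble(set_id = f[1], namespace = f[2], gene_id = unique(f[-(1:2)]))
  }) |> list_rbind()
}

#' @rdname read_gmt
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- gene_sets |>
    group_by(.data$set_id) |>
    summarise(namespace = first(.data$namespace),
              genes = paste(unique(.data$gene_id), collapse = "\t"),
              .groups = "drop") |>
    mutate(line = paste(.data$set_id, .data$namespace, .data$genes, sep = "\t")) |>
    pull("line")
  writeLines(lines, path)
  invisible(path)
}
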