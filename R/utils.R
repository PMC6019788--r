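# Internal helpers shared across modules.

# Validity flags a Cq cell can carry. "valid" cells have a finite positive Cq;
# the two failure flags mirror what array software reports for failed wells.
CQ_FLAGS <- c("valid", "undetermined", "no_amplification")

assert_cq_tbl <- function(cq, arg = "cq") {
  if (!is.data.frame(cq)) {
    abort(sprintf("`%s` must be a data frame with columns assay_id, sample_id, cq, flag.", arg))
  }
  needed <- c("assay_id", "sample_id", "cq", "flag")
  missing <- setdiff(needed, names(cq))
  if (length(missing)) {
    abort(sprintf("`%s` is missing column(s): %s.", arg, paste(missing, collapse = ", ")))
  }
  bad_flag <- setdiff(unique(cq$flag), CQ_FLAGS)
  if (length(bad_flag)) {
    abort(sprintf("`%s` has unknown flag(s): %s.", arg, paste(bad_flag, collapse = ", ")))
  }
  ok <- cq$flag != "valid" | (is.finite(cq$cq) & !is.na(cq$cq))
  if (!all(ok)) {
    abort(sprintf("`%s` has cells flagged valid without a finite Cq value.", arg))
  }
  invisible(cq)
}

assert_sample_sheet <- function(samples, arg = "samples") {
  if (!is.data.frame(samples)) {
    abort(sprintf("`%s` must be a data frame.", arg))
  }
  needed <- c("sample_id", "individual", "group")
  missing <- setdiff(needed, names(samples))
  if (length(missing)) {
    abort(sprintf("`%s` is missing column(s): %s.", arg, paste(missing, collapse = ", ")))
  }
  bad <- setdiff(unique(samples$group), c("case", "control"))
  if (length(bad)) {
    abort(sprintf("`%s`$group must be 'case' or 'control'; found: %s.",
                  arg, paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(samples$sample_id)) {
    abort(sprintf("`%s`$sample_id contains duplicates.", arg))
  }
  invisible(samples)
}

assert_probability <- function(p, arg = "p") {
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1)) {
    abort(sprintf("`%s` must be numeric in [0, 1] without NA.", arg))
  }
  invisible(p)
}

# Long (assay_id, sample_id, cq) -> assays x samples matrix; invalid cells NA.
cq_to_matrix <- function(cq) {
  valid <- cq |>
    mutate(cq = if_else(.data$flag == "valid", .data$cq, NA_real_))
  wide <- valid |>
    select("assay_id", "sample_id", "cq") |>
    pivot_wider(names_from = "sample_id", values_from = "cq")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$assay_id
  m
}

counts_to_matrix <- function(counts) {
  if (is.matrix(counts)) return(counts)
  if (!is.data.frame(counts) || !"gene_id" %in% names(counts)) {
    abort("`counts` must be a matrix or a data frame with a gene_id column.")
  }
  m <- as.matrix(counts[setdiff(names(counts), "gene_id")])
  rownames(m) <- counts$gene_id
  storage.mode(m) <- "double"
  m
}

matrix_to_counts <- function(m) {
  bind_cols(tibble(gene_id = rownames(m)), as_tibble(m))
}

geometric_mean <- function(x) exp(mean(log(x)))

# Inverse of the trigamma function by Newton iteration on 1/x scale;
# used when fitting the scaled inverse-chi-square variance prior.
trigamma_inverse <- function(y) {
  if (!is.finite(y) || y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in seq_len(50)) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}
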