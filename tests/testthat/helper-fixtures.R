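# Small in-code fixtures shared across test files.

# Long Cq tibble from a named matrix (NA cells become "undetermined").
cq_from_matrix <- function(m, flags = NULL) {
  tb <- tidyr::expand_grid(
    assay_id = rownames(m),
    sample_id = colnames(m)
  )
  tb$cq <- m[cbind(tb$assay_id, tb$sample_id)]
  tb$flag <- ifelse(is.na(tb$cq), "undetermined", "valid")
  if (!is.null(flags)) tb$flag[match(names(flags), paste(tb$assay_id, tb$sample_id))] <- flags
  tibble::as_tibble(tb)
}

# Sample sheet for k case + k control individuals, one replicate each.
sheet_1rep <- function(k) {
  ids <- c(sprintf("case%02d", seq_len(k)), sprintf("ctrl%02d", seq_len(k)))
  tibble::tibble(sample_id = ids, individual = ids,
                 group = rep(c("case", "control"), each = k),
                 replicate = "r1")
}

# Gaussian null Cq matrix (features x 2k samples) as a long tibble.
null_cq <- function(n_features, k, sd = 1, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_features * 2 * k, mean = 25, sd = sd), n_features,
              dimnames = list(sprintf("f%04d", seq_len(n_features)),
                              sheet_1rep(k)$sample_id))
  cq_from_matrix(m)
}

expect_tbl_equal <- function(a, b, tol = 1e-12) {
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = tol)
}
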