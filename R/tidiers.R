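#' Tidy a differential-expression table
#'
#' Returns the per-feature results as a plain tibble (the table is already
#' tidy; this drops the class and attributes for downstream manipulation).
#'
#' @param x A `cm_de_table` from [moderated_t_test()], [plain_t_test()] or
#'   [nb_wald_test()].
#' @param ... Unused.
#' @return A tibble with one row per feature.
#' @export
tidy.cm_de_table <- function(x, ...) {
  as_tibble(unclass(x)[!vapply(unclass(x), is.null, logical(1))])
}

#' Summarise a differential-expression analysis in one row
#'
#' @inheritParams tidy.cm_de_table
#' @return A one-row tibble: `method`, `n_features`, `n_tested`,
#'   `n_significant`, `alpha`, and for moderated tests the estimated prior
#'   degrees of freedom `d0` and prior variance `s0_sq`.
#' @export
glance.cm_de_table <- function(x, ...) {
  tibble(
    method = attr(x, "method") %||% NA_character_,
    n_features = nrow(x),
    n_tested = sum(x$tested %in% TRUE),
    n_significant = sum(x$significant %in% TRUE),
    alpha = attr(x, "alpha") %||% NA_real_,
    d0 = attr(x, "d0") %||% NA_real_,
    s0_sq = attr(x, "s0_sq") %||% NA_real_
  )
}

#' @export
print.cm_de_table <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<cm_de_table> %s: %d features, %d tested, %d significant (alpha %.3g)\n",
              g$method, g$n_features, g$n_tested, g$n_significant, g$alpha))
  print(tidy(x), ...)
  invisible(x)
}
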