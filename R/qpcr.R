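#' Normalize Cq values by the per-sample global mean
#'
#' Global geometric-mean scaling for array-scale qPCR screens: on the Cq
#' (log2) scale this is the arithmetic mean, so each sample's valid Cq values
#' are centred by subtracting their mean, yielding delta-Cq values that are
#' comparable across samples. Invalid cells (flags `undetermined`,
#' `no_amplification`) are excluded from the mean and preserved unchanged.
#' The operation is idempotent: re-normalizing a centred sample changes
#' nothing.
#'
#' @param cq Long Cq tibble (`assay_id`, `sample_id`, `cq`, `flag`).
#' @return The tibble with `cq` replaced by delta-Cq values.
#' @examples
#' cq <- tibble::tibble(assay_id = c("a", "b"), sample_id = "s1",
#'                      cq = c(20, 30), flag = "valid")
#' normalize_cq_global_mean(cq)$cq   # -5, +5
#' @export
normalize_cq_global_mean <- function(cq) {
  assert_cq_tbl(cq)
  n_valid <- cq |>
    group_by(.data$sample_id) |>
    summarise(n = sum(.data$flag == "valid"), .groups = "drop")
  bad <- n_valid$sample_id[n_valid$n == 0]
  if (length(bad)) {
    abort(sprintf("Sample(s) with no valid Cq measurement: %s.",
                  paste(bad, collapse = ", ")))
  }
  out <- cq |>
    group_by(.data$sample_id) |>
    mutate(cq = .data$cq - mean(.data$cq[.data$flag == "valid"])) |>
    ungroup()
  attr(out, "cm_normalized") <- "global-mean"
  out
}

#' Normalize Cq values against a reference assay
#'
#' Classic delta-Cq normalization against a housekeeping control (e.g. TBP
#' for genes, a stably expressed miRNA for miRNA panels):
#' \eqn{\Delta Cq_{ij} = Cq_{ij} - Cq_{ref,j}}. The reference assay must be
#' valid in every sample.
#'
#' @inheritParams normalize_cq_global_mean
#' @param reference_assay Assay id of the housekeeping control.
#' @return The tibble with `cq` replaced by delta-Cq values; the reference
#'   assay rows are kept (their delta-Cq is 0).
#' @export
normalize_cq_reference <- function(cq, reference_assay) {
  assert_cq_tbl(cq)
  ref <- cq |> filter(.data$assay_id == reference_assay)
  if (nrow(ref) == 0) {
    abort(sprintf("Reference assay '%s' not found.", reference_assay))
  }
  bad <- ref$sample_id[ref$flag != "valid"]
  missing <- setdiff(unique(cq$sample_id), ref$sample_id)
  if (length(c(bad, missing))) {
    abort(sprintf("Reference assay '%s' is not valid in sample(s): %s.",
                  reference_assay, paste(unique(c(bad, missing)), collapse = ", ")))
  }
  out <- cq |>
    left_join(ref |> select("sample_id", ref_cq = "cq"), by = "sample_id") |>
    mutate(cq = .data$cq - .data$ref_cq) |>
    select(-"ref_cq")
  attr(out, "cm_normalized") <- paste0("reference:", reference_assay)
  out
}

#' Average technical replicates per individual
#'
#' Collapses replicate measurements of each individual to their mean. A cell
#' is valid after averaging if at least one replicate was valid (the mean is
#' over valid replicates only); it is invalid only when every replicate
#' failed. The returned table has one column per individual
#' (`sample_id` = individual id).
#'
#' @inheritParams normalize_cq_global_mean
#' @param samples Sample sheet with columns `sample_id`, `individual`,
#'   `group` (and `replicate`).
#' @return A Cq tibble keyed by individual.
#' @export
average_replicates <- function(cq, samples) {
  assert_cq_tbl(cq)
  assert_sample_sheet(samples)
  norm_attr <- attr(cq, "cm_normalized")
  out <- cq |>
    inner_join(samples |> select("sample_id", "individual"), by = "sample_id") |>
    group_by(.data$assay_id, .data$individual) |>
    summarise(
      n_ok = sum(.data$flag == "valid"),
      cq = if (sum(.data$flag == "valid") > 0) {
        mean(.data$cq[.data$flag == "valid"])
      } else NA_real_,
      worst_flag = .data$flag[which.max(.data$flag != "valid")][1],
      .groups = "drop"
    ) |>
    mutate(
      flag = if_else(.data$n_ok > 0, "valid", .data$worst_flag),
      sample_id = .data$individual
    ) |>
    select("assay_id", "sample_id", "cq", "flag")
  attr(out, "cm_normalized") <- norm_attr
  out
}

# Map Cq columns to case/control groups, accepting either replicate-level
# sample ids or individual ids (after average_replicates()).
resolve_groups <- function(cq, samples) {
  assert_sample_sheet(samples)
  ids <- unique(cq$sample_id)
  if (all(ids %in% samples$sample_id)) {
    samples |> select("sample_id", "group") |> distinct()
  } else if (all(ids %in% samples$individual)) {
    samples |> select(sample_id = "individual", "group") |> distinct()
  } else {
    abort("Cq sample ids match neither sample_id nor individual in the sample sheet.")
  }
}

#' Filter assays by detection rate
#'
#' Applies the screen's detection rule on the per-individual table: an assay
#' is kept if it has at least `min_valid` valid measurements in one group
#' (`mode = "any-group"`, the default) or in both groups
#' (`mode = "both-groups"`). The published rule "at least 2 valid out of 3
#' individuals" corresponds to `min_valid = ceiling(2/3 * group size)`,
#' which is the default for general group sizes.
#'
#' @inheritParams average_replicates
#' @param min_valid Minimum valid measurements per group; default
#'   `ceiling(2/3 * group size)`.
#' @param mode `"any-group"` or `"both-groups"` (see Details).
#' @return The filtered Cq tibble; the numbers of assays before and after
#'   and the rule used are attached as the `"report"` attribute (see
#'   [filter_report()]).
#' @export
filter_detection <- function(cq, samples, min_valid = NULL,
                             mode = c("any-group", "both-groups")) {
  assert_cq_tbl(cq)
  mode <- match.arg(mode)
  grp <- resolve_groups(cq, samples)
  group_sizes <- grp |> dplyr::count(.data$group) |> pull("n")
  if (is.null(min_valid)) min_valid <- ceiling(2 / 3 * min(group_sizes))
  if (min_valid > min(group_sizes)) {
    abort(sprintf("min_valid (%d) exceeds the smallest group size (%d).",
                  min_valid, min(group_sizes)))
  }
  tallies <- cq |>
    inner_join(grp, by = "sample_id") |>
    group_by(.data$assay_id, .data$group) |>
    summarise(n_valid = sum(.data$flag == "valid"), .groups = "drop") |>
    pivot_wider(names_from = "group", values_from = "n_valid", values_fill = 0L)
  keep <- if (mode == "any-group") {
    tallies$assay_id[tallies$case >= min_valid | tallies$control >= min_valid]
  } else {
    tallies$assay_id[tallies$case >= min_valid & tallies$control >= min_valid]
  }
  out <- cq |> filter(.data$assay_id %in% keep)
  attr(out, "cm_normalized") <- attr(cq, "cm_normalized")
  attr(out, "report") <- tibble(
    n_before = dplyr::n_distinct(cq$assay_id),
    n_after = length(unique(keep)),
    min_valid = as.integer(min_valid),
    mode = mode
  )
  out
}

#' Retrieve the report attached to a filtering step
#'
#' @param x An object returned by [filter_detection()], [low_count_filter()]
#'   or [filter_and_trim_reads()].
#' @return A tibble of per-rule counts.
#' @export
filter_report <- function(x) attr(x, "report")

#' Empirical-Bayes moderated t-test on Cq (or log2) features
#'
#' Two-sample comparison of case versus control with variance moderation:
#' per-feature pooled variances \eqn{s_g^2} (with \eqn{d_g} degrees of
#' freedom) are shrunk toward a common prior by fitting a scaled
#' inverse-chi-square distribution \eqn{s_0^2, d_0} to the observed
#' variances via moments of \eqn{\log s_g^2}; the posterior variance
#' \eqn{\tilde s^2 = (d_0 s_0^2 + d_g s_g^2) / (d_0 + d_g)} replaces
#' \eqn{s_g^2} in the t statistic, which then has \eqn{d_0 + d_g} degrees
#' of freedom. With `d0 = 0` this is the ordinary pooled two-sample t-test;
#' with `d0 = Inf` all features share the prior variance.
#'
#' The effect size follows the qPCR sign convention for delta-Cq input:
#' \eqn{M = \overline{\Delta Cq}_{control} - \overline{\Delta Cq}_{case}},
#' positive when expression is higher in cases (lower Cq = more abundant).
#' M is the log2 fold change because PCR amplification is base 2.
#'
#' Features with fewer than 2 valid values in either group are reported with
#' `tested = FALSE` and NA statistics.
#'
#' @inheritParams average_replicates
#' @param alpha Adjusted-p significance threshold (default 0.05).
#' @param d0 Optional override of the prior degrees of freedom (0 forces the
#'   ordinary t-test; `Inf` full shrinkage). Default: estimated from the data.
#' @return A `cm_de_table` tibble: `feature_id`, `m`, `mean_case`,
#'   `mean_control`, `t`, `df`, `p`, `p_adj`, `significant`, `n_case`,
#'   `n_control`, `tested`. Prior estimates are attached as attributes and
#'   surfaced by [glance.cm_de_table()].
#' @export
moderated_t_test <- function(cq, samples, alpha = 0.05, d0 = NULL) {
  assert_cq_tbl(cq)
  m <- cq_to_matrix(cq)
  grp <- resolve_groups(cq, samples)
  g <- grp$group[match(colnames(m), grp$sample_id)]

  de <- moderated_t_matrix(m, g, alpha = alpha, d0 = d0)
  de
}

# Matrix-level engine shared by the qPCR and RNA-seq paths.
# x: feature x sample matrix (NA = missing); g: "case"/"control" per column.
moderated_t_matrix <- function(x, g, alpha = 0.05, d0 = NULL,
                               method = "moderated-t") {
  case <- x[, g == "case", drop = FALSE]
  ctrl <- x[, g == "control", drop = FALSE]
  n1 <- rowSums(!is.na(case))
  n2 <- rowSums(!is.na(ctrl))
  mean1 <- rowMeans(case, na.rm = TRUE)
  mean2 <- rowMeans(ctrl, na.rm = TRUE)
  ss1 <- rowSums((case - mean1)^2, na.rm = TRUE)
  ss2 <- rowSums((ctrl - mean2)^2, na.rm = TRUE)
  dg <- n1 + n2 - 2
  tested <- n1 >= 2 & n2 >= 2
  s2 <- ifelse(tested, (ss1 + ss2) / pmax(dg, 1), NA_real_)

  if (sum(tested) < 2 && is.null(d0)) {
    warn("Fewer than 2 testable features; falling back to the ordinary t-test.")
    d0 <- 0
  }
  if (is.null(d0)) {
    prior <- fit_variance_prior(s2[tested], dg[tested])
    d0 <- prior$d0
    s0_sq <- prior$s0_sq
  } else {
    s0_sq <- if (d0 > 0) exp(mean(log(s2[tested & s2 > 0]))) else NA_real_
  }

  post_s2 <- if (is.infinite(d0)) {
    rep(s0_sq, length(s2))
  } else if (d0 == 0) {
    s2
  } else {
    (d0 * s0_sq + dg * s2) / (d0 + dg)
  }

  m_val <- mean2 - mean1   # positive = up in case (lower Cq in case)
  se <- sqrt(post_s2 * (1 / n1 + 1 / n2))
  tstat <- m_val / se
  df_total <- d0 + dg
  p <- 2 * pt(-abs(tstat), df = df_total)
  p[!tested] <- NA_real_
  tstat[!tested] <- NA_real_

  p_adj <- rep(NA_real_, length(p))
  p_adj[tested] <- adjust_bh(p[tested])

  out <- tibble(
    feature_id = rownames(x),
    m = unname(ifelse(tested, m_val, NA_real_)),
    mean_case = unname(mean1),
    mean_control = unname(mean2),
    t = unname(tstat),
    df = unname(ifelse(tested, df_total, NA_real_)),
    p = unname(p),
    p_adj = unname(p_adj),
    significant = unname(!is.na(p_adj) & p_adj < alpha),
    n_case = unname(n1),
    n_control = unname(n2),
    tested = unname(tested)
  )
  structure(out,
            class = c("cm_de_table", class(out)),
            method = method, alpha = alpha,
            d0 = d0, s0_sq = s0_sq)
}

# Method-of-moments fit of the scaled inverse-chi-square variance prior
# using the log-variance representation: for s2 ~ s0^2 * chisq_d0-inverse
# mixture, e_g = log s2_g - digamma(d_g/2) + log(d_g/2) has
# mean log s0^2 + digamma(d0/2) - log(d0/2) and excess variance
# trigamma(d0/2) beyond trigamma(d_g/2).
fit_variance_prior <- function(s2, dg) {
  ok <- is.finite(s2) & s2 > 0 & dg > 0
  s2 <- s2[ok]; dg <- dg[ok]
  if (length(s2) < 2) return(list(d0 = 0, s0_sq = NA_real_))
  z <- log(s2)
  e <- z - digamma(dg / 2) + log(dg / 2)
  e_bar <- mean(e)
  e_var <- var(e) * (length(e) - 1) / length(e) - mean(trigamma(dg / 2))
  if (!is.finite(e_var) || e_var <= 0) {
    return(list(d0 = Inf, s0_sq = exp(e_bar)))
  }
  d0 <- 2 * trigamma_inverse(e_var)
  s0_sq <- exp(e_bar + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0_sq)
}

#' Ordinary Student's t-test on Cq (or log2) features
#'
#' The validation-experiment test: identical to [moderated_t_test()] with the
#' prior degrees of freedom fixed at zero, i.e. a pooled-variance two-sample
#' Student's t-test per feature.
#'
#' @inheritParams moderated_t_test
#' @return A `cm_de_table` tibble; see [moderated_t_test()].
#' @export
plain_t_test <- function(cq, samples, alpha = 0.05) {
  out <- moderated_t_test(cq, samples, alpha = alpha, d0 = 0)
  attr(out, "method") <- "student-t"
  out
}

#' Benjamini-Hochberg and Bonferroni adjustment
#'
#' Step-up FDR adjustment (BH) with monotonicity enforcement, and the
#' family-wise Bonferroni adjustment `min(1, m * p)`. Thin validated wrappers
#' around [stats::p.adjust()]; both are order-preserving.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @examples
#' adjust_bh(c(0.01, 0.02, 0.03, 0.04))
#' @export
adjust_bh <- function(p) {
  assert_probability(p)
  p.adjust(p, method = "BH")
}

#' @rdname adjust_bh
#' @export
adjust_bonferroni <- function(p) {
  assert_probability(p)
  p.adjust(p, method = "bonferroni")
}

#' Convert group-mean delta-Cq values to M and linear fold change
#'
#' \eqn{M = \overline{\Delta Cq}_{control} - \overline{\Delta Cq}_{case}}
#' (log2 fold change, positive = higher in cases) and the linear fold change
#' \eqn{2^M}.
#'
#' @param mean_dcq_case,mean_dcq_control Group-mean delta-Cq values
#'   (vectorized).
#' @return A tibble with columns `m` and `fold`.
#' @examples
#' delta_cq_to_m(29.9, 36.7)   # m = 6.8, fold = 2^6.8
#' @export
delta_cq_to_m <- function(mean_dcq_case, mean_dcq_control) {
  if (anyNA(mean_dcq_case) || anyNA(mean_dcq_control) ||
      any(!is.finite(mean_dcq_case)) || any(!is.finite(mean_dcq_control))) {
    abort("delta-Cq inputs must be finite.")
  }
  m <- mean_dcq_control - mean_dcq_case
  tibble(m = m, fold = 2^m)
}
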