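#' Detect a sample-level confounder with PCA
#'
#' Principal component analysis on gene-centred log2(normalized count + 1)
#' values. In small case-control designs the first component often captures
#' a technical factor (batch, passage, library preparation) rather than the
#' condition; its sign provides a two-level covariate that can be added to
#' the differential-expression design to absorb that factor.
#'
#' @inheritParams low_count_filter
#' @return A tibble of per-sample scores (`sample_id`, `PC1`, `PC2`, ...,
#'   `covariate` = factor of the PC1 sign) with the per-component variance
#'   share attached as attribute `"variance_explained"`.
#' @export
pca_confounder <- function(counts, size_factors = NULL) {
  m <- counts_to_matrix(counts)
  if (ncol(m) < 3) abort("PCA-based confounder detection needs at least 3 samples.")
  if (is.null(size_factors)) size_factors <- size_factors_median_ratio(counts)
  sf <- sf_vector(size_factors, colnames(m))
  x <- log2(sweep(m, 2, sf, `/`) + 1)
  x <- x - rowMeans(x)
  pc <- prcomp(t(x), center = FALSE, scale. = FALSE)
  k <- min(ncol(pc$x), ncol(m) - 1L)
  scores <- as_tibble(pc$x[, seq_len(k), drop = FALSE])
  out <- bind_cols(tibble(sample_id = colnames(m)), scores) |>
    mutate(covariate = factor(if_else(.data$PC1 >= 0, "pos", "neg")))
  attr(out, "variance_explained") <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
  out
}

#' Negative-binomial Wald test for differential expression
#'
#' A simplified count-based differential-expression test: per gene, a
#' negative-binomial generalized linear model with log link,
#' \eqn{\mu_{gj} = s_j q_g \exp(x_j^T \beta_g)} and
#' \eqn{Var = \mu + \alpha \mu^2}, is fit by iteratively reweighted least
#' squares with a fixed gene-wise dispersion. Dispersions are estimated by
#' the method of moments on normalized counts within condition groups and
#' shrunk toward their across-gene mean on the log scale (weight
#' `dispersion_shrink`). The Wald statistic on the condition coefficient
#' gives the p-value; BH adjustment and the significance call
#' (`p_adj < alpha`) follow, and the reported DE call additionally requires
#' `|M| > min_abs_m` (default 1, i.e. more than two-fold).
#'
#' The design is intercept + condition (+ the optional covariate, e.g. the
#' PC1 factor from [pca_confounder()], either as the two-level sign factor
#' or as the continuous score).
#'
#' @inheritParams low_count_filter
#' @param covariate Optional per-sample covariate: a tibble with
#'   `sample_id` and either a `covariate` factor column (as returned by
#'   [pca_confounder()]) or a numeric `PC1` column when
#'   `covariate_type = "continuous"`; or a vector named by sample id.
#' @param covariate_type `"factor"` (default) or `"continuous"`.
#' @param alpha Adjusted-p significance level.
#' @param min_abs_m Minimum |log2 fold change| for the reported DE call.
#' @param dispersion_shrink Weight in \[0, 1\] pulling log dispersions toward
#'   their mean (default 0.5).
#' @param max_iter,tol IRLS iteration cap and convergence tolerance.
#' @return A `cm_de_table` tibble with columns `feature_id`, `m` (log2 fold
#'   change case vs control), `mean_case`, `mean_control` (mean normalized
#'   counts), `t` (Wald statistic), `p`, `p_adj`, `significant`, `de_call`,
#'   `dispersion`, `converged`.
#' @export
nb_wald_test <- function(counts, samples, size_factors = NULL,
                         covariate = NULL, covariate_type = c("factor", "continuous"),
                         alpha = 0.05, min_abs_m = 1,
                         dispersion_shrink = 0.5,
                         max_iter = 50L, tol = 1e-8) {
  covariate_type <- match.arg(covariate_type)
  m <- counts_to_matrix(counts)
  assert_sample_sheet(samples)
  if (is.null(size_factors)) size_factors <- size_factors_median_ratio(counts)
  sf <- sf_vector(size_factors, colnames(m))
  grp <- samples$group[match(colnames(m), samples$sample_id)]
  x_cond <- as.numeric(grp == "case")

  X <- cbind(intercept = 1, condition = x_cond)
  if (!is.null(covariate)) {
    v <- resolve_covariate(covariate, colnames(m), covariate_type)
    X <- cbind(X, covariate = v)
  }
  if (qr(X)$rank < ncol(X)) {
    abort("Design matrix is rank deficient (is the covariate confounded with the condition?).")
  }

  z <- sweep(m, 2, sf, `/`)
  mean_case <- rowMeans(z[, grp == "case", drop = FALSE])
  mean_ctrl <- rowMeans(z[, grp == "control", drop = FALSE])

  disp <- estimate_dispersion_mom(m, sf, grp, shrink = dispersion_shrink)

  offs <- log(sf)
  ngene <- nrow(m)
  beta_m <- se <- rep(NA_real_, ngene)
  conv <- rep(FALSE, ngene)
  j_cond <- 2L

  for (g in seq_len(ngene)) {
    y <- m[g, ]
    if (all(y == 0)) next
    fit <- nb_irls(y, X, offs, disp[g], max_iter = max_iter, tol = tol)
    if (is.null(fit)) next
    beta_m[g] <- fit$beta[j_cond]
    se[g] <- fit$se[j_cond]
    conv[g] <- fit$converged
  }

  # Standard normal Wald reference: dispersions are pooled across genes, so
  # the coefficient SE behaves as if the dispersion were known. Calibration
  # is checked on simulated nulls; at very small n (3 per group) the test
  # remains mildly anticonservative, as count-based Wald tests are.
  wald <- beta_m / se
  df_resid <- ncol(m) - ncol(X)
  p <- 2 * pnorm(-abs(wald))
  p[!conv] <- NA_real_
  p_adj <- rep(NA_real_, ngene)
  p_adj[conv] <- adjust_bh(p[conv])
  m_log2 <- beta_m / log(2)

  out <- tibble(
    feature_id = rownames(m),
    m = unname(m_log2),
    mean_case = unname(mean_case),
    mean_control = unname(mean_ctrl),
    t = wald,
    df = df_resid,
    p = p,
    p_adj = p_adj,
    significant = !is.na(p_adj) & p_adj < alpha,
    de_call = !is.na(p_adj) & p_adj < alpha & abs(m_log2) > min_abs_m,
    dispersion = disp,
    converged = conv,
    tested = conv
  )
  structure(out, class = c("cm_de_table", class(out)),
            method = "nb-wald", alpha = alpha, min_abs_m = min_abs_m)
}

resolve_covariate <- function(covariate, sample_ids, covariate_type) {
  if (is.data.frame(covariate)) {
    i <- match(sample_ids, covariate$sample_id)
    if (anyNA(i)) abort("Covariate table is missing samples.")
    v <- if (covariate_type == "continuous") covariate$PC1[i] else covariate$covariate[i]
  } else {
    v <- covariate[sample_ids]
    if (anyNA(v) && !is.numeric(covariate)) abort("Covariate vector is missing samples.")
  }
  if (is.factor(v) || is.character(v)) v <- as.numeric(factor(v)) - 1
  as.numeric(v)
}

# Method-of-moments dispersion per gene, pooled over condition groups, with
# log-scale shrinkage toward the across-gene mean.
estimate_dispersion_mom <- function(m, sf, grp, shrink = 0.5,
                                    min_disp = 1e-8, max_disp = 10) {
  z <- sweep(m, 2, sf, `/`)
  xim <- mean(1 / sf)
  per_group <- function(sel) {
    zz <- z[, sel, drop = FALSE]
    mu <- rowMeans(zz)
    v <- apply(zz, 1, var)
    list(mu = mu, v = v, n = sum(sel))
  }
  a <- per_group(grp == "case")
  b <- per_group(grp == "control")
  # pooled within-group variance and overall mean of normalized counts
  v_pool <- ((a$n - 1) * a$v + (b$n - 1) * b$v) / pmax(a$n + b$n - 2, 1)
  mu_bar <- (a$n * a$mu + b$n * b$mu) / (a$n + b$n)
  raw <- (v_pool - mu_bar * xim) / mu_bar^2
  raw[!is.finite(raw)] <- 0
  raw <- pmin(raw, max_disp)
  # trend = arithmetic mean of the raw moment estimates: under-dispersed
  # genes legitimately pull it down, but a log-scale mean would be dominated
  # by the floor applied to non-positive estimates
  trend <- max(mean(pmax(raw, 0)), min_disp)
  floor_disp <- max(trend / 50, min_disp)
  raw <- pmax(raw, floor_disp)
  if (shrink > 0 && nrow(m) > 1) {
    exp((1 - shrink) * log(raw) + shrink * log(trend))
  } else {
    raw
  }
}

# IRLS for one NB GLM with log link, fixed dispersion, offset log(sf).
nb_irls <- function(y, X, offs, alpha_disp, max_iter = 50L, tol = 1e-8) {
  beta <- tryCatch(
    qr.solve(X, log(y / exp(offs) + 0.5)),
    error = function(e) NULL
  )
  if (is.null(beta)) return(NULL)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta) + offs
    mu <- pmin(exp(eta), 1e12)
    w <- mu / (1 + alpha_disp * mu)
    zwork <- (eta - offs) + (y - mu) / mu
    XtW <- t(X * w)
    upd <- tryCatch(solve(XtW %*% X, XtW %*% zwork), error = function(e) NULL)
    if (is.null(upd)) return(list(beta = beta, se = rep(NA_real_, length(beta)),
                                  converged = FALSE))
    delta <- drop(upd) - beta
    beta <- drop(upd)
    if (max(abs(delta)) < tol) { converged <- TRUE; break }
  }
  eta <- drop(X %*% beta) + offs
  mu <- pmin(exp(eta), 1e12)
  w <- mu / (1 + alpha_disp * mu)
  info <- t(X * w) %*% X
  se <- tryCatch(sqrt(diag(solve(info))), error = function(e) rep(NA_real_, length(beta)))
  list(beta = beta, se = se, converged = converged)
}
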