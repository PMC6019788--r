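test_that("global-mean normalization centres each sample on its valid cells", {
  cq <- tibble::tibble(assay_id = c("a", "b"), sample_id = "s1",
                       cq = c(20, 30), flag = "valid")
  out <- normalize_cq_global_mean(cq)
  expect_equal(out$cq, c(-5, 5))

  # all assays equal within a sample -> all delta-Cq zero
  cq2 <- tibble::tibble(assay_id = c("a", "b", "c"), sample_id = "s1",
                        cq = 27.3, flag = "valid")
  expect_equal(normalize_cq_global_mean(cq2)$cq, rep(0, 3))
})

test_that("global-mean normalization on a 3x3 matrix with an invalid cell matches the cellwise oracle", {
  m <- matrix(c(20, 25, 30,
                22, NA, 28,
                24, 26, 31), 3, byrow = TRUE,
              dimnames = list(c("a1", "a2", "a3"), c("s1", "s2", "s3")))
  cq <- cq_from_matrix(m)
  out <- normalize_cq_global_mean(cq)
  # oracle: per-column mean over valid cells only, subtracted cellwise
  col_means <- apply(m, 2, mean, na.rm = TRUE)
  oracle <- sweep(m, 2, col_means)
  got <- cardiomir:::cq_to_matrix(out)[rownames(m), colnames(m)]
  expect_equal(got, oracle)
  # invalid cell stays flagged
  expect_equal(out$flag[out$assay_id == "a2" & out$sample_id == "s2"],
               "undetermined")
})

test_that("global-mean normalization is idempotent and errors on all-invalid samples", {
  cq <- null_cq(10, 2, seed = 3)
  once <- normalize_cq_global_mean(cq)
  twice <- normalize_cq_global_mean(once)
  expect_equal(once$cq, twice$cq)

  bad <- cq
  bad$flag[bad$sample_id == "case01"] <- "no_amplification"
  bad$cq[bad$sample_id == "case01"] <- NA_real_
  expect_error(normalize_cq_global_mean(bad), "case01")
})

test_that("reference normalization subtracts the housekeeping assay cellwise", {
  m <- matrix(c(25, 26, 27, 24,
                20, 21, 19, 22,
                30, 29, 31, 28), 3, byrow = TRUE,
              dimnames = list(c("tgt", "ref", "oth"),
                              c("s1", "s2", "s3", "s4")))
  cq <- cq_from_matrix(m)
  out <- normalize_cq_reference(cq, "ref")
  oracle <- sweep(m, 2, m["ref", ])
  expect_equal(cardiomir:::cq_to_matrix(out)[rownames(m), colnames(m)], oracle)
  expect_equal(out$cq[out$assay_id == "ref"], rep(0, 4))

  bad <- cq
  bad$flag[bad$assay_id == "ref" & bad$sample_id == "s2"] <- "undetermined"
  expect_error(normalize_cq_reference(bad, "ref"), "s2")
  expect_error(normalize_cq_reference(cq, "nope"), "not found")
})

test_that("replicate averaging keeps a cell valid when at least one replicate is valid", {
  samples <- tibble::tibble(
    sample_id = c("i1_r1", "i1_r2", "i2_r1", "i2_r2"),
    individual = rep(c("i1", "i2"), each = 2),
    group = rep(c("case", "control"), each = 2),
    replicate = rep(c("r1", "r2"), 2)
  )
  cq <- tibble::tibble(
    assay_id = "a",
    sample_id = samples$sample_id,
    cq = c(28, 30, 27.5, NA),
    flag = c("valid", "valid", "valid", "undetermined")
  )
  out <- average_replicates(cq, samples)
  expect_equal(out$cq[out$sample_id == "i1"], 29)
  expect_equal(out$cq[out$sample_id == "i2"], 27.5)
  expect_equal(out$flag[out$sample_id == "i2"], "valid")

  cq$flag[3] <- "no_amplification"; cq$cq[3] <- NA
  out2 <- average_replicates(cq, samples)
  expect_true(is.na(out2$cq[out2$sample_id == "i2"]))
  expect_false(out2$flag[out2$sample_id == "i2"] == "valid")
})

test_that("detection filter implements both group rules", {
  samples <- sheet_1rep(3)
  mk <- function(valid_case, valid_ctrl) {
    tibble::tibble(
      assay_id = "a",
      sample_id = samples$sample_id,
      cq = ifelse(c(seq_len(3) <= valid_case, seq_len(3) <= valid_ctrl), 25, NA),
      flag = ifelse(c(seq_len(3) <= valid_case, seq_len(3) <= valid_ctrl),
                    "valid", "undetermined")
    )
  }
  kept <- function(cq, mode) {
    nrow(filter_detection(cq, samples, min_valid = 2, mode = mode)) > 0
  }
  # valid in 3/3 cases, 0/3 controls: group-specific expression
  expect_true(kept(mk(3, 0), "any-group"))
  expect_false(kept(mk(3, 0), "both-groups"))
  # 1/3 and 1/3 excluded under both rules; 2/3 and 2/3 kept under both
  expect_false(kept(mk(1, 1), "any-group"))
  expect_false(kept(mk(1, 1), "both-groups"))
  expect_true(kept(mk(2, 2), "any-group"))
  expect_true(kept(mk(2, 2), "both-groups"))
  # impossible rule errors
  expect_error(filter_detection(mk(2, 2), samples, min_valid = 4), "group size")
  # report records before/after
  rep <- filter_report(filter_detection(mk(1, 1), samples, min_valid = 2))
  expect_equal(rep$n_before, 1L)
  expect_equal(rep$n_after, 0L)
})

test_that("moderated t with d0 = 0 equals the pooled two-sample t-test", {
  cq <- null_cq(30, 3, seed = 7)
  samples <- sheet_1rep(3)
  de <- moderated_t_test(cq, samples, d0 = 0)
  m <- cardiomir:::cq_to_matrix(cq)
  for (i in c(1, 11, 30)) {
    tt <- t.test(m[i, 4:6], m[i, 1:3], var.equal = TRUE)
    expect_equal(unname(de$t[i]), unname(tt$statistic), tolerance = 1e-10)
    expect_equal(de$p[i], tt$p.value, tolerance = 1e-10)
  }
  # and equals plain_t_test on the same fixture
  de2 <- plain_t_test(cq, samples)
  expect_equal(de$t, de2$t)
})

test_that("2-vs-2 hand example gives the closed-form pooled t", {
  samples <- sheet_1rep(2)
  cq <- tibble::tibble(assay_id = "a", sample_id = samples$sample_id,
                       cq = c(1, 2, 3, 4), flag = "valid")
  de <- plain_t_test(cq, samples)
  # M = mean(control) - mean(case) = 2; se = sqrt(0.5 * (1/2 + 1/2))
  expect_equal(de$m, 2)
  expect_equal(abs(de$t), 2.8284271, tolerance = 1e-6)
  expect_equal(de$p, 2 * pt(-2.8284271, df = 2), tolerance = 1e-6)
})

test_that("moderated t with d0 = Inf shares the prior variance across features", {
  cq <- null_cq(20, 3, seed = 9)
  samples <- sheet_1rep(3)
  de <- moderated_t_test(cq, samples, d0 = Inf)
  m <- cardiomir:::cq_to_matrix(cq)
  md <- unname(rowMeans(m[, 4:6]) - rowMeans(m[, 1:3]))
  # all features divided by the same constant: t proportional to M
  expect_equal(de$t, md / (de$m / de$t)[1], tolerance = 1e-8)
})

test_that("moderated t matches the empirical-Bayes reference implementation", {
  set.seed(42)
  n <- 200
  x <- matrix(rnorm(n * 6, sd = rep(sqrt(1 / rgamma(n, 4, 4)), 6)), n,
              dimnames = list(paste0("f", 1:n), sheet_1rep(3)$sample_id))
  x[1:10, 1:3] <- x[1:10, 1:3] + 2
  de <- cardiomir:::moderated_t_matrix(x, rep(c("case", "control"), each = 3))
  fit <- limma::eBayes(limma::lmFit(
    x, stats::model.matrix(~rep(c(1, 0), each = 3))))
  expect_equal(attr(de, "d0"), fit$df.prior, tolerance = 0.05)
  expect_equal(attr(de, "s0_sq"), fit$s2.prior, tolerance = 0.01)
  # my M is control - case; limma's coefficient is case - control
  expect_lt(max(abs(-de$t - fit$t[, 2])), 0.05)
})

test_that("features with fewer than 2 valid values per group are reported untested", {
  samples <- sheet_1rep(3)
  cq <- null_cq(5, 3, seed = 11)
  cq$flag[cq$assay_id == "f0002" & grepl("case", cq$sample_id)] <- "undetermined"
  cq$cq[cq$flag != "valid"] <- NA
  de <- moderated_t_test(cq, samples)
  expect_false(de$tested[de$feature_id == "f0002"])
  expect_true(is.na(de$p[de$feature_id == "f0002"]))
  expect_true(all(de$tested[de$feature_id != "f0002"]))
})

test_that("BH and Bonferroni adjustments match their brute-force definitions", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(0.37), 0.37)
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(1)
  for (i in 1:10) {
    p <- runif(sample(3:50, 1))
    # brute-force step-up BH: sort, p_(i) * m / i, cumulative min from top
    o <- order(p)
    m <- length(p)
    stepup <- rev(cummin(rev(p[o] * m / seq_len(m))))
    bh_oracle <- pmin(1, stepup)[order(o)]
    expect_equal(adjust_bh(p), bh_oracle)
    expect_equal(adjust_bonferroni(p), pmin(1, p * m))
  }
})

test_that("delta-Cq arithmetic reproduces printed screen M-values", {
  screen <- acm_mirna_screen()
  res <- delta_cq_to_m(screen$dcq_case, screen$dcq_control)
  expect_equal(res$m, c(6.8, 3.0, 4.0), tolerance = 0.05 / 6.8)
  expect_equal(res$fold, 2^res$m)
  expect_equal(delta_cq_to_m(25, 25)$m, 0)
  expect_equal(delta_cq_to_m(25, 25)$fold, 1)
  expect_error(delta_cq_to_m(NA, 3), "finite")
})

test_that("moderated t type-I error is near nominal on null data", {
  cq <- null_cq(2000, 3, seed = 101)
  de <- moderated_t_test(cq, sheet_1rep(3))
  rate <- mean(de$p < 0.05, na.rm = TRUE)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
  # and the p distribution is approximately uniform
  expect_lt(suppressWarnings(ks.test(de$p, "punif")$statistic), 0.05)
})
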