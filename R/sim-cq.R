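#' Simulate a TaqMan-array miRNA Cq screen with planted effects
#'
#' Generates raw quantification-cycle (Cq) values for `n_assays` miRNA assays
#' measured in `n_per_group` case and control individuals, two technical
#' replicates each, emulating a TaqMan Low Density Array screen. A chosen set
#' of assays is planted as differentially expressed: their case-group Cq is
#' lowered (lower Cq = higher abundance) by a delta-delta-Cq effect drawn
#' from `ddcq_effect_range`, so the planted log2 fold change (M-value) equals
#' that effect. Detection failure is simulated logistically in the true Cq:
#' wells far above `dropout_midpoint` tend to come back flagged
#' `"undetermined"` or `"no_amplification"`, as weakly expressed miRNAs do on
#' real cards.
#'
#' Planted DE assays are placed in the well-detected (low-Cq) range so that a
#' screen at the simulated depth can in principle recover them.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements
#'   * `cq`: long tibble (`assay_id`, `sample_id`, `cq`, `flag`),
#'   * `samples`: sample sheet (`sample_id`, `individual`, `group`, `replicate`),
#'   * `truth`: tibble of planted assays (`assay_id`, `ddcq`, `direction`).
#' @examples
#' sim <- simulate_cq_experiment(sim_config(seed = 7, n_assays = 48))
#' dplyr::count(sim$cq, flag)
#' @export
simulate_cq_experiment <- function(config = sim_config()) {
  validate_sim_config(config)
  set.seed(sub_seed(config, 11L))

  n <- config$n_per_group
  individuals <- c(sprintf("case%02d", seq_len(n)), sprintf("ctrl%02d", seq_len(n)))
  groups <- rep(c("case", "control"), each = n)
  samples <- tidyr::crossing(
    tibble(individual = individuals),
    tibble(replicate = c("r1", "r2"))
  ) |>
    left_join(tibble(individual = individuals, group = groups), by = "individual") |>
    mutate(sample_id = paste(.data$individual, .data$replicate, sep = "_")) |>
    select("sample_id", "individual", "group", "replicate") |>
    arrange(.data$sample_id)

  assay_ids <- sprintf("mir-%04d", seq_len(config$n_assays))

  # Baseline abundance per assay; a long right tail of weak assays feeds the
  # dropout model so that, at the default midpoint, roughly a quarter to a
  # third of the card survives detection filtering, as in real screens.
  base_cq <- runif(config$n_assays, min = 24, max = 40)

  de_idx <- integer(0)
  truth <- tibble(assay_id = character(), ddcq = numeric(), direction = character())
  if (config$n_de_mirnas > 0) {
    detectable <- which(base_cq <= config$dropout_midpoint - 1)
    if (length(detectable) < config$n_de_mirnas) detectable <- order(base_cq)[seq_len(config$n_de_mirnas)]
    de_idx <- sort(sample(detectable, config$n_de_mirnas))
    ddcq <- runif(config$n_de_mirnas, config$ddcq_effect_range[1], config$ddcq_effect_range[2])
    truth <- tibble(assay_id = assay_ids[de_idx], ddcq = ddcq, direction = "up_in_case")
  }

  effect <- numeric(config$n_assays)
  effect[de_idx] <- truth$ddcq

  grid <- tidyr::crossing(
    tibble(assay_id = assay_ids, base_cq = base_cq, effect = effect),
    samples |> select("sample_id", "group")
  ) |>
    mutate(true_cq = .data$base_cq - if_else(.data$group == "case", .data$effect, 0))

  noise <- if (config$cq_noise_sd > 0) rnorm(nrow(grid), 0, config$cq_noise_sd) else 0
  p_drop <- if (is.finite(config$dropout_midpoint)) {
    stats::plogis((grid$true_cq - config$dropout_midpoint) / config$dropout_scale)
  } else {
    0
  }
  dropped <- runif(nrow(grid)) < p_drop
  flag <- if_else(dropped,
                  if_else(runif(nrow(grid)) < 0.5, "undetermined", "no_amplification"),
                  "valid")

  cq <- grid |>
    mutate(
      cq = if_else(flag == "valid", .data$true_cq + noise, NA_real_),
      flag = flag
    ) |>
    select("assay_id", "sample_id", "cq", "flag") |>
    arrange(.data$assay_id, .data$sample_id)

  list(cq = cq, samples = samples, truth = truth)
}
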