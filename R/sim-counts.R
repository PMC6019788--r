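#' Simulate an RNA-seq count matrix with planted effects and a confounder
#'
#' Draws gene-level read counts from a negative-binomial model
#' \eqn{K_{gj} \sim NB(\mu_{gj}, \alpha)} with
#' \eqn{\mu_{gj} = s_j q_g 2^{x_j \beta_g + b_j \gamma_g}}: per-sample size
#' factors \eqn{s_j} from unequal library sizes, log-normal baseline
#' abundances \eqn{q_g}, planted condition effects \eqn{\beta_g} (log2 fold
#' changes, random sign) on `n_de_genes` genes, and a two-level batch shift
#' \eqn{\gamma_g} on a `confounder_fraction` of genes. The batch factor is
#' assigned as orthogonally to condition as the group sizes allow, emulating
#' a technical confounder that dominates the first principal component
#' rather than the case-control axis.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements
#'   * `counts`: tibble `gene_id` + one integer column per sample,
#'   * `samples`: tibble (`sample_id`, `individual`, `group`, `batch`),
#'   * `truth`: per-gene tibble (`gene_id`, `log2fc`, `is_de`, `in_batch`),
#'   * `size_factors_true`: named numeric vector used in the simulation.
#' @examples
#' sim <- simulate_count_experiment(sim_config(seed = 3, n_genes = 100))
#' head(sim$counts)
#' @export
simulate_count_experiment <- function(config = sim_config()) {
  validate_sim_config(config)
  set.seed(sub_seed(config, 23L))

  n <- config$n_per_group
  sample_ids <- c(sprintf("case%02d", seq_len(n)), sprintf("ctrl%02d", seq_len(n)))
  group <- rep(c("case", "control"), each = n)
  # Alternate batch within each group: with equal group sizes this is the
  # most balanced (closest to orthogonal) two-level assignment available.
  batch_lvl <- c(rep_len(c("b1", "b2"), n), rep_len(c("b2", "b1"), n))
  samples <- tibble(sample_id = sample_ids, individual = sample_ids,
                    group = group, batch = batch_lvl)

  gene_ids <- sprintf("gene%05d", seq_len(config$n_genes))

  lib <- runif(2 * n, config$library_size_range[1], config$library_size_range[2])
  sf <- lib / geometric_mean(lib)

  # Baseline relative abundance; heavy-tailed as in real transcriptomes.
  q <- rlnorm(config$n_genes, meanlog = 0, sdlog = 1.2)
  q <- q / sum(q) * mean(lib)   # scale so counts total ~ library size

  log2fc <- numeric(config$n_genes)
  if (config$n_de_genes > 0) {
    de_idx <- sort(sample.int(config$n_genes, config$n_de_genes))
    mag <- runif(config$n_de_genes, config$log2fc_range[1], config$log2fc_range[2])
    sgn <- sample(c(-1, 1), config$n_de_genes, replace = TRUE)
    log2fc[de_idx] <- mag * sgn
  }

  gamma <- numeric(config$n_genes)
  in_batch <- rep(FALSE, config$n_genes)
  if (config$confounder_fraction > 0) {
    nb <- round(config$confounder_fraction * config$n_genes)
    b_idx <- sort(sample.int(config$n_genes, nb))
    in_batch[b_idx] <- TRUE
    gamma[b_idx] <- config$confounder_log2fc
  }

  x <- as.numeric(group == "case")
  b <- as.numeric(batch_lvl == "b2")
  log2_mu <- outer(log2fc, x) + outer(gamma, b) + log2(q)
  mu <- sweep(2^log2_mu, 2, sf, `*`)

  counts <- matrix(
    rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion),
    nrow = config$n_genes, dimnames = list(gene_ids, sample_ids)
  )

  list(
    counts = matrix_to_counts(counts),
    samples = samples,
    truth = tibble(gene_id = gene_ids, log2fc = log2fc,
                   is_de = log2fc != 0, in_batch = in_batch),
    size_factors_true = setNames(sf, sample_ids)
  )
}
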