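#' Simulation configuration for the synthetic study
#'
#' Bundles every knob of the synthetic-data generators into one validated
#' object. Defaults reproduce the design of a small case-control cardiac
#' stromal cell study: 3 individuals per group, a 768-assay miRNA array
#' screen with two technical replicates per sample, and a 2000-gene RNA-seq
#' experiment with a batch-like confounder orthogonal to the condition.
#'
#' @param seed Integer seed; the same config and seed give bit-identical data.
#' @param n_per_group Individuals per condition group (default 3).
#' @param n_assays Number of miRNA assays on the array (default 768).
#' @param n_genes Number of genes in the count simulation (default 2000).
#' @param n_de_mirnas Number of planted differentially expressed miRNA assays.
#' @param ddcq_effect_range Range (Cq units) of planted delta-delta-Cq effects;
#'   the default 3--7 spans log2 fold changes seen in ACM screens.
#' @param cq_noise_sd Measurement noise SD in Cq units per technical replicate.
#' @param dropout_midpoint Cq value at which a well fails detection with
#'   probability 1/2; failure probability rises logistically with true Cq.
#'   `Inf` disables dropout.
#' @param dropout_scale Logistic scale (Cq units) of the dropout curve.
#' @param n_de_genes Number of planted DE genes in the count simulation.
#' @param log2fc_range Range of |log2 fold change| for planted DE genes
#'   (signs random). Default 1--4: at least two-fold.
#' @param nb_dispersion Negative-binomial dispersion alpha (Var = mu + alpha mu^2).
#' @param confounder_fraction Fraction of genes shifted by a two-level batch
#'   factor assigned orthogonally to condition.
#' @param confounder_log2fc Size of the batch shift in log2 units.
#' @param library_size_range Range of per-sample library sizes (total counts).
#'
#' @return A list of class `cm_sim_config`.
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 200)
#' cfg$n_per_group
#' @export
sim_config <- function(seed = 1L,
                       n_per_group = 3L,
                       n_assays = 768L,
                       n_genes = 2000L,
                       n_de_mirnas = 3L,
                       ddcq_effect_range = c(3, 7),
                       cq_noise_sd = 0.5,
                       dropout_midpoint = 26,
                       dropout_scale = 1.5,
                       n_de_genes = 100L,
                       log2fc_range = c(1, 4),
                       nb_dispersion = 0.05,
                       confounder_fraction = 0.3,
                       confounder_log2fc = 1.5,
                       library_size_range = c(5e5, 1.5e6)) {
  cfg <- list(
    seed = as.integer(seed),
    n_per_group = as.integer(n_per_group),
    n_assays = as.integer(n_assays),
    n_genes = as.integer(n_genes),
    n_de_mirnas = as.integer(n_de_mirnas),
    ddcq_effect_range = as.numeric(ddcq_effect_range),
    cq_noise_sd = as.numeric(cq_noise_sd),
    dropout_midpoint = as.numeric(dropout_midpoint),
    dropout_scale = as.numeric(dropout_scale),
    n_de_genes = as.integer(n_de_genes),
    log2fc_range = as.numeric(log2fc_range),
    nb_dispersion = as.numeric(nb_dispersion),
    confounder_fraction = as.numeric(confounder_fraction),
    confounder_log2fc = as.numeric(confounder_log2fc),
    library_size_range = as.numeric(library_size_range)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "cm_sim_config")
}

validate_sim_config <- function(cfg) {
  stop_cfg <- function(msg) abort(paste0("Invalid simulation config: ", msg))
  if (cfg$n_per_group < 1L) stop_cfg("n_per_group must be >= 1.")
  if (cfg$n_assays < 1L || cfg$n_genes < 1L) stop_cfg("n_assays and n_genes must be >= 1.")
  if (cfg$n_de_mirnas > cfg$n_assays) stop_cfg("n_de_mirnas exceeds n_assays.")
  if (cfg$n_de_genes > cfg$n_genes) stop_cfg("n_de_genes exceeds n_genes.")
  for (nm in c("ddcq_effect_range", "log2fc_range", "library_size_range")) {
    r <- cfg[[nm]]
    if (length(r) != 2L || anyNA(r) || r[1] > r[2]) {
      stop_cfg(sprintf("%s must be an ordered pair low <= high.", nm))
    }
  }
  if (cfg$cq_noise_sd < 0) stop_cfg("cq_noise_sd must be >= 0.")
  if (cfg$dropout_scale <= 0) stop_cfg("dropout_scale must be > 0.")
  if (cfg$nb_dispersion <= 0) stop_cfg("nb_dispersion must be > 0.")
  if (cfg$confounder_fraction < 0 || cfg$confounder_fraction > 1) {
    stop_cfg("confounder_fraction must be in [0, 1].")
  }
  if (any(cfg$library_size_range <= 0)) stop_cfg("library sizes must be positive.")
  invisible(cfg)
}

# Derive a reproducible sub-seed so each generator draws from its own stream.
sub_seed <- function(cfg, offset) {
  (cfg$seed * 1013L + as.integer(offset)) %% .Machine$integer.max
}
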