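#' Simulation configuration
#'
#' Builds and validates the configuration object shared by all synthetic-data
#' generators. Defaults emulate a cord-blood 450k-style study of a bounded
#' parent-report trait score: a batch-structured beta matrix (slides, plates,
#' two sample types, six-or-seven cell fractions), a 0--24 count phenotype with
#' mean 14.65 causally linked to a chosen CpG subset, an mQTL map in which each
#' CpG maps to a variable number of SNPs, block-structured LD, and GWAS
#' p-values with a tunable chi-square inflation for mQTLs of causal CpGs.
#'
#' A negative binomial cannot be under-dispersed, so `nb_dispersion` defaults
#' to a large size parameter (near-Poisson counts, SD about 3.9 at mean 14.65),
#' the closest achievable spread to the questionnaire's reported SD.
#'
#' @param n_samples number of samples.
#' @param n_cpgs number of CpG probes.
#' @param n_causal number of CpGs with a causal effect on the phenotype.
#' @param effect_sd_units causal effect on the log-mean of the phenotype per
#'   standard deviation of technically residualized methylation.
#' @param nb_dispersion negative-binomial size (theta) of the phenotype.
#' @param score_max questionnaire ceiling; counts are censored at this value.
#' @param pheno_mean target marginal mean of the phenotype before censoring.
#' @param n_slides,n_plates numbers of array slides and processing plates.
#'   Defaults scale with `n_samples` (12 arrays per slide, 96 per plate).
#' @param batch_sd SD, on the logit(beta) scale, of slide/plate/sample-type
#'   effects (plate effects use half this SD).
#' @param cell_effect_sd SD of per-CpG cell-composition loadings.
#' @param noise_sd residual logit-scale measurement noise SD.
#' @param n_snps number of SNPs on the synthetic map.
#' @param mqtl_per_cpg_dist probability weights over mQTL counts 1..40 per CpG;
#'   `NULL` uses a right-skewed default (most CpGs map to few SNPs).
#' @param gwas_enrich_shift non-centrality added to the 1-df association
#'   chi-square of SNPs that are mQTLs of causal CpGs (mean chi-square
#'   becomes `1 + gwas_enrich_shift`).
#' @param ld_block_size SNPs per LD block.
#' @param ld_r2 pairwise r-squared within an LD block (zero across blocks).
#' @param include_nrbc include a nucleated-red-blood-cell fraction (zero for
#'   most samples) so the extended-cell-set first-stage model is exercised.
#' @param seed master seed; each generator derives its own stream from it.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 700L,
                       n_cpgs = 1000L,
                       n_causal = 0L,
                       effect_sd_units = 0.5,
                       nb_dispersion = 100,
                       score_max = 24L,
                       pheno_mean = 14.65,
                       n_slides = NULL,
                       n_plates = NULL,
                       batch_sd = 0.25,
                       cell_effect_sd = 0.2,
                       noise_sd = 0.3,
                       n_snps = 5000L,
                       mqtl_per_cpg_dist = NULL,
                       gwas_enrich_shift = 0,
                       ld_block_size = 5L,
                       ld_r2 = 0.9,
                       include_nrbc = TRUE,
                       seed = 1L) {
  if (is.null(n_slides)) n_slides <- max(2L, ceiling(n_samples / 12))
  if (is.null(n_plates)) n_plates <- max(2L, ceiling(n_samples / 96))
  if (is.null(mqtl_per_cpg_dist)) {
    # right-skewed: most CpGs have few mQTLs, a thin tail reaches past 25
    mqtl_per_cpg_dist <- stats::dnbinom(0:39, size = 1.2, mu = 5)
  }
  cfg <- list(
    n_samples = as.integer(n_samples), n_cpgs = as.integer(n_cpgs),
    n_causal = as.integer(n_causal), effect_sd_units = effect_sd_units,
    nb_dispersion = nb_dispersion, score_max = as.integer(score_max),
    pheno_mean = pheno_mean,
    n_slides = as.integer(n_slides), n_plates = as.integer(n_plates),
    batch_sd = batch_sd, cell_effect_sd = cell_effect_sd, noise_sd = noise_sd,
    n_snps = as.integer(n_snps), mqtl_per_cpg_dist = mqtl_per_cpg_dist,
    gwas_enrich_shift = gwas_enrich_shift,
    ld_block_size = as.integer(ld_block_size), ld_r2 = ld_r2,
    include_nrbc = isTRUE(include_nrbc), seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_samples < 1L || cfg$n_cpgs < 1L || cfg$n_snps < 1L ||
      cfg$n_slides < 1L || cfg$n_plates < 1L || cfg$ld_block_size < 1L) {
    stop("sim_config: dimensions must be positive", call. = FALSE)
  }
  if (cfg$n_causal < 0L || cfg$n_causal > cfg$n_cpgs) {
    stop("sim_config: n_causal must lie in [0, n_cpgs]", call. = FALSE)
  }
  if (cfg$score_max < 1L) stop("sim_config: score_max must be >= 1", call. = FALSE)
  if (cfg$batch_sd < 0 || cfg$noise_sd < 0 || cfg$cell_effect_sd < 0 ||
      cfg$gwas_enrich_shift < 0) {
    stop("sim_config: SDs and shifts must be non-negative", call. = FALSE)
  }
  if (cfg$nb_dispersion <= 0) stop("sim_config: nb_dispersion must be positive", call. = FALSE)
  d <- cfg$mqtl_per_cpg_dist
  if (length(d) != 40L || any(d < 0) || sum(d) <= 0) {
    stop("sim_config: mqtl_per_cpg_dist must be 40 non-negative weights over 1..40",
         call. = FALSE)
  }
  if (cfg$ld_r2 < 0 || cfg$ld_r2 > 1) stop("sim_config: ld_r2 must lie in [0,1]", call. = FALSE)
  invisible(cfg)
}

# Independent RNG stream per generator: fixed offsets from the master seed,
# kept below 2^31 so the result is a valid R integer seed.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset * 10007) %% 2147483647)
}
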