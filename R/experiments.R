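#' @name experiments
#' @title Calibration, recovery and detection experiments
#' @description Canned simulation experiments that validate the pipeline
#'   against its own synthetic ground truth: null calibration of the MWAS
#'   p-value distribution and of the downstream shift and permutation tests,
#'   recovery of a single generating effect, and detection of simulated
#'   trait-linked mQTL enrichment against a negative-control GWAS. These are
#'   the experiments the acceptance checks and the analysis scripts run; sizes
#'   are documented in the methods vignette.
NULL

#' @describeIn experiments One large null MWAS: with no causal CpGs, fits the
#'   two-step NB model and returns the p-values, their Kolmogorov-Smirnov
#'   distance from the uniform, and the genomic inflation factor.
#' @param seed master seed.
#' @param n_samples,n_cpgs simulation size.
#' @export
null_mwas_experiment <- function(seed = 1L, n_samples = 700L, n_cpgs = 2000L) {
  cfg <- sim_config(n_samples = n_samples, n_cpgs = n_cpgs, n_causal = 0L,
                    seed = seed)
  gm <- gen_methylation(cfg)
  gp <- gen_phenotype(gm$meth, gm$covars, cfg)
  res <- residualize(gm$meth, gm$covars, model = 1L)
  mw <- fit_nb_mwas(res, gp$pheno, gm$covars)
  ks <- suppressWarnings(stats::ks.test(mw$p, "punif"))
  list(mwas = mw, ks_distance = unname(ks$statistic),
       lambda = genomic_inflation(mw$p))
}

#' @describeIn experiments Type-I error of the p-value shift test and the
#'   bin-matched permutation test over independent null replicates. Each
#'   replicate runs a small end-to-end null MWAS (no causal CpGs) for the
#'   testing-side p-values and a null mQTL/GWAS draw (no chi-square shift);
#'   the discovery-side p-values are drawn from their uniform null at the
#'   summary level.
#' @param n_seeds number of replicates.
#' @param n_perm permutations per replicate.
#' @param alpha nominal level whose rejection rate is tracked.
#' @export
calibration_experiment <- function(seed = 1L, n_seeds = 200L,
                                   n_samples = 120L, n_cpgs = 200L,
                                   n_perm = 500L, alpha = 0.05) {
  shift_rej <- logical(n_seeds)
  perm_rej <- logical(n_seeds)
  for (k in seq_len(n_seeds)) {
    sk <- derive_seed(seed, 2000L + k)
    cfg <- sim_config(n_samples = n_samples, n_cpgs = n_cpgs, n_causal = 0L,
                      gwas_enrich_shift = 0, n_snps = 1500L, seed = sk)
    gm <- gen_methylation(cfg)
    gp <- gen_phenotype(gm$meth, gm$covars, cfg)
    res <- residualize(gm$meth, gm$covars, model = 1L)
    mw <- fit_nb_mwas(res, gp$pheno, gm$covars)

    set.seed(derive_seed(sk, 7L))
    discovery <- data.frame(cpg = mw$cpg, p = stats::runif(nrow(mw)))
    st <- pvalue_shift_test(discovery, mw, selection_threshold = 0.05)
    shift_rej[k] <- !st$flagged && st$p_one_sided <= alpha

    gq <- gen_mqtl_gwas(mw$cpg, cfg, gp$truth)
    map <- dedup_pairs(clump_mqtls(gq$mqtl, gq$gwas, gq$ld))
    pe <- permutation_enrichment(map, mw, gq$gwas, threshold = 0.05,
                                 n_perm = n_perm, seed = derive_seed(sk, 8L))
    perm_rej[k] <- !pe$flagged && pe$empirical_p <= alpha
  }
  list(n_seeds = n_seeds, alpha = alpha,
       shift_type1 = mean(shift_rej), perm_type1 = mean(perm_rej),
       binom_bounds = alpha + c(-1, 1) * 1.96 *
         sqrt(alpha * (1 - alpha) / n_seeds))
}

#' @describeIn experiments Parameter recovery: one causal CpG with a known
#'   per-SD effect, re-estimated by the two-step NB fit over independent
#'   replicates. Runs in a regime where the questionnaire ceiling is inactive
#'   (low phenotype mean) so the generating effect is the estimand; returns
#'   the per-SD estimates, their mean bias and the Monte-Carlo SE.
#' @param effect generating effect per SD of residualized methylation.
#' @export
recovery_experiment <- function(seed = 1L, n_seeds = 50L, n_samples = 700L,
                                effect = 0.3) {
  est <- numeric(n_seeds)
  for (k in seq_len(n_seeds)) {
    cfg <- sim_config(n_samples = n_samples, n_cpgs = 30L, n_causal = 1L,
                      pheno_mean = 6, seed = derive_seed(seed, 3000L + k))
    gm <- gen_methylation(cfg)
    gp <- gen_phenotype(gm$meth, gm$covars, cfg, effects = effect)
    res <- residualize(gm$meth, gm$covars, model = 1L)
    cid <- gp$truth$causal_cpg_ids
    mw <- fit_nb_mwas(res[cid, , drop = FALSE], gp$pheno, gm$covars)
    # the fit uses the raw residual; convert to per-SD units
    est[k] <- mw$effect[1L] * stats::sd(res[cid, ])
  }
  mc_se <- stats::sd(est) / sqrt(n_seeds)
  list(effect = effect, estimates = est, mean_estimate = mean(est),
       bias = mean(est) - effect, mc_se = mc_se,
       bias_in_mc_se = (mean(est) - effect) / mc_se)
}

#' @describeIn experiments Signal detection: simulations with causal CpGs and
#'   a chi-square shift for their mQTLs in the trait GWAS, alongside a
#'   negative-control GWAS drawn from the null on the same mQTL map. Returns
#'   the fraction of replicates where the trait GWAS reaches FDR < 0.05 at
#'   MWAS threshold 0.01 or 0.005, and the fraction where the control GWAS is
#'   significant at any threshold.
#' @param n_causal number of causal CpGs.
#' @param gwas_enrich_shift chi-square non-centrality for enriched mQTLs.
#' @export
detection_experiment <- function(seed = 1L, n_seeds = 20L, n_samples = 700L,
                                 n_cpgs = 600L, n_causal = 50L,
                                 effect_sd_units = 0.1,
                                 gwas_enrich_shift = 1.0, n_perm = 1000L) {
  detected <- logical(n_seeds)
  control_sig <- logical(n_seeds)
  for (k in seq_len(n_seeds)) {
    sk <- derive_seed(seed, 4000L + k)
    # polyepigenetic regime: many CpGs, each with a small per-SD effect, so
    # the bounded questionnaire is not saturated by the combined signal
    cfg <- sim_config(n_samples = n_samples, n_cpgs = n_cpgs,
                      n_causal = n_causal,
                      effect_sd_units = effect_sd_units,
                      gwas_enrich_shift = gwas_enrich_shift,
                      n_snps = 12000L, seed = sk)
    gm <- gen_methylation(cfg)
    gp <- gen_phenotype(gm$meth, gm$covars, cfg)
    res <- residualize(gm$meth, gm$covars, model = 1L)
    mw <- fit_nb_mwas(res, gp$pheno, gm$covars)

    gq <- gen_mqtl_gwas(mw$cpg, cfg, gp$truth)
    ctrl <- gen_mqtl_gwas(mw$cpg, cfg, truth = NULL, seed_offset = 50L,
                          mqtl_map = gq$mqtl)

    er <- run_enrichment(mw, gq$mqtl, gq$gwas, gq$ld,
                         seed = derive_seed(sk, 9L), n_perm = n_perm)
    ec <- run_enrichment(mw, ctrl$mqtl, ctrl$gwas, ctrl$ld,
                         seed = derive_seed(sk, 10L), n_perm = n_perm)
    mid <- er$threshold %in% c(0.01, 0.005)
    detected[k] <- any(er$fdr_p[mid] < 0.05, na.rm = TRUE)
    control_sig[k] <- any(ec$fdr_p < 0.05, na.rm = TRUE)
  }
  list(n_seeds = n_seeds, detection_rate = mean(detected),
       control_significant_rate = mean(control_sig))
}
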