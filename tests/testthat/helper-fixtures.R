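# small in-code fixtures shared across test files

# a compact simulated dataset: methylation + covariates + phenotype
tiny_dataset <- function(seed = 11L, n_samples = 60L, n_cpgs = 20L,
                         n_causal = 0L, ...) {
  cfg <- sim_config(n_samples = n_samples, n_cpgs = n_cpgs,
                    n_causal = n_causal, seed = seed, ...)
  gm <- gen_methylation(cfg)
  gp <- gen_phenotype(gm$meth, gm$covars, cfg)
  c(gm, gp, list(config = cfg))
}

# an MWAS-shaped summary table built directly (no model fitting)
mwas_table <- function(cpg, effect, p, se = NULL, z = NULL) {
  if (is.null(se)) se <- rep(1, length(cpg))
  if (is.null(z)) z <- effect / se
  data.frame(cpg = cpg, effect = effect, se = se, z = z, p = p,
             n = NA_integer_, converged = TRUE, stringsAsFactors = FALSE)
}

# covariate table where every technical covariate is constant
constant_covars <- function(n) {
  data.frame(sample_id = sprintf("s%04d", seq_len(n)),
             slide = factor(rep("slide01", n)),
             plate = factor(rep("plate01", n)),
             sample_type = factor(rep("whitecell", n)),
             sex = factor(rep(c("F", "M"), length.out = n)),
             pc1 = rnorm(n), pc2 = rnorm(n),
             cell_a = rep(0.5, n), cell_b = rep(0.5, n),
             stringsAsFactors = FALSE)
}
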