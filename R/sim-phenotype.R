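#' Generate a bounded skewed count phenotype linked to chosen CpGs
#'
#' Draws, per sample, a negative-binomial count whose log-mean is an intercept
#' plus the sum of per-CpG effects times the standardized technically
#' residualized methylation of the causal CpGs, plus a small sex term; counts
#' are censored at the questionnaire ceiling `score_max`. Effects act on the
#' first-stage residual (not the raw beta) so the two-step association
#' estimator targets the generating effect. The intercept is chosen so the
#' pre-censoring marginal mean is `config$pheno_mean`.
#'
#' @param meth,covars output of [gen_methylation()].
#' @param config a [sim_config()] object.
#' @param causal_ids optional CpG ids to use as causal sites (overrides random
#'   selection of `config$n_causal` sites).
#' @param effects optional per-causal-CpG effects in per-SD units; default is
#'   `config$effect_sd_units` with random signs.
#' @param seed_offset offset added to the derived stream, letting callers draw
#'   several independent phenotypes from one methylation matrix.
#' @return list with `pheno` (data.frame `sample_id`, `score`) and `truth`
#'   (list `causal_cpg_ids`, `effects`, `enriched_snp_ids` — the latter filled
#'   in by [gen_mqtl_gwas()]).
#' @export
gen_phenotype <- function(meth, covars, config, causal_ids = NULL,
                          effects = NULL, seed_offset = 0L) {
  validate_sim_config(config)
  if (!identical(colnames(meth), covars$sample_id)) {
    stop("gen_phenotype: sample identifiers of meth and covars do not match",
         call. = FALSE)
  }
  n <- ncol(meth)
  set.seed(derive_seed(config$seed, 2L + seed_offset))

  if (is.null(causal_ids)) {
    causal_ids <- if (config$n_causal > 0L) {
      sort(sample(rownames(meth), config$n_causal))
    } else character(0)
  }
  stopifnot(all(causal_ids %in% rownames(meth)))
  if (is.null(effects)) {
    effects <- config$effect_sd_units *
      sample(c(-1, 1), length(causal_ids), replace = TRUE)
  }
  stopifnot(length(effects) == length(causal_ids))

  eta <- rep(0, n)
  if (length(causal_ids) > 0L) {
    res <- residualize(meth[causal_ids, , drop = FALSE], covars, model = 1L)
    z <- t(apply(res, 1L, function(r) (r - mean(r)) / stats::sd(r)))
    eta <- as.numeric(crossprod(z, effects))
  }
  sex_coef <- 0.05
  is_m <- as.numeric(covars$sex == "M")
  # intercept calibrated so E[exp(eta + sex term)] ~ pheno_mean (lognormal
  # correction for the causal sum; exact average over the sex indicator)
  intercept <- log(config$pheno_mean) - 0.5 * sum(effects^2) -
    log(mean(exp(sex_coef * is_m)))
  mu <- exp(intercept + eta + sex_coef * is_m)
  score <- stats::rnbinom(n, size = config$nb_dispersion, mu = mu)
  score <- pmin(score, config$score_max)

  list(
    pheno = data.frame(sample_id = covars$sample_id, score = as.integer(score),
                       stringsAsFactors = FALSE),
    truth = list(causal_cpg_ids = causal_ids, effects = effects,
                 enriched_snp_ids = character(0))
  )
}
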