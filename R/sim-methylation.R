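#' Generate a batch-structured methylation beta matrix with covariates
#'
#' Simulates a CpG x sample matrix of beta values as the inverse logit of a
#' CpG-specific baseline plus slide, plate and sample-type effects, weighted
#' cell-composition loadings, and measurement noise. Baselines are drawn from a
#' three-component mixture so the marginal beta distribution is bimodal, as on
#' real arrays. The covariate table carries slide, plate, sample type
#' (white-cell vs blood-spot), cell proportions summing to one per sample, sex
#' and two ancestry principal components.
#'
#' @param config a [sim_config()] object.
#' @return list with `meth` (numeric matrix, CpGs x samples, values strictly in
#'   (0,1), dimnames = CpG/sample ids) and `covars` (data.frame keyed by
#'   `sample_id`).
#' @export
gen_methylation <- function(config) {
  validate_sim_config(config)
  n <- config$n_samples
  m <- config$n_cpgs
  set.seed(derive_seed(config$seed, 1L))

  sample_ids <- sprintf("s%04d", seq_len(n))
  cpg_ids <- sprintf("cg%07d", seq_len(m))

  # independent shuffles: processing order is scrambled, so slide and plate
  # are crossed rather than nested (keeps the joint design full rank)
  slide <- factor(sample(sprintf("slide%02d",
                                 rep_len(seq_len(config$n_slides), n))))
  plate <- factor(sample(sprintf("plate%02d",
                                 rep_len(seq_len(config$n_plates), n))))
  sample_type <- factor(ifelse(stats::runif(n) < 0.22, "bloodspot", "whitecell"),
                        levels = c("whitecell", "bloodspot"))
  sex <- factor(ifelse(stats::runif(n) < 0.5, "F", "M"), levels = c("F", "M"))
  pc1 <- stats::rnorm(n)
  pc2 <- stats::rnorm(n)

  # cord-blood-like composition, granulocyte-dominated; Dirichlet via gammas
  alpha <- c(cd4t = 4.0, cd8t = 2.5, bcell = 2.0, nk = 1.2, mono = 1.8, gran = 14.0)
  cells <- matrix(stats::rgamma(n * length(alpha), shape = rep(alpha, each = n)),
                  nrow = n, dimnames = list(sample_ids, paste0("cell_", names(alpha))))
  if (config$include_nrbc) {
    # present in a minority of samples only
    nrbc <- ifelse(stats::runif(n) < 0.25, stats::rgamma(n, shape = 0.8), 0)
    cells <- cbind(cells, cell_nrbc = nrbc)
  }
  cells <- cells / rowSums(cells)

  # CpG-specific pieces
  comp <- sample.int(3L, m, replace = TRUE, prob = c(0.4, 0.4, 0.2))
  baseline <- c(-2.5, 2.5, 0)[comp] + stats::rnorm(m, sd = c(1, 1, 1.5)[comp])
  slide_eff <- matrix(stats::rnorm(m * config$n_slides, sd = config$batch_sd),
                      nrow = m, dimnames = list(NULL, levels(slide)))
  plate_eff <- matrix(stats::rnorm(m * config$n_plates, sd = config$batch_sd / 2),
                      nrow = m, dimnames = list(NULL, levels(plate)))
  type_eff <- stats::rnorm(m, sd = config$batch_sd)
  cell_load <- matrix(stats::rnorm(m * ncol(cells), sd = config$cell_effect_sd),
                      nrow = m)
  # center loadings so the sum-to-one constraint does not shift the baseline
  cell_load <- cell_load - rowMeans(cell_load)

  logit <- matrix(baseline, nrow = m, ncol = n)
  logit <- logit + slide_eff[, as.integer(slide), drop = FALSE]
  logit <- logit + plate_eff[, as.integer(plate), drop = FALSE]
  logit <- logit + outer(type_eff, as.numeric(sample_type == "bloodspot"))
  logit <- logit + cell_load %*% t(cells)
  if (config$noise_sd > 0) {
    logit <- logit + matrix(stats::rnorm(m * n, sd = config$noise_sd), nrow = m)
  }
  meth <- stats::plogis(logit)
  dimnames(meth) <- list(cpg_ids, sample_ids)

  covars <- data.frame(
    sample_id = sample_ids, slide = slide, plate = plate,
    sample_type = sample_type, sex = sex, pc1 = pc1, pc2 = pc2,
    cells, stringsAsFactors = FALSE, row.names = NULL
  )
  list(meth = meth, covars = covars)
}
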