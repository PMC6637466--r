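#' Remove blacklisted probes from a methylation matrix
#'
#' Excludes CpGs whose probe or single-base extension overlaps a common SNP,
#' and cross-reactive probes, both supplied as externally curated identifier
#' sets (the MAF screen itself happens upstream of this package). Unknown
#' identifiers in either list are ignored.
#'
#' @param meth CpG x sample beta matrix with CpG rownames.
#' @param snp_overlap_list,cross_reactive_list character vectors of CpG ids.
#' @return the filtered matrix, with attribute `filter_counts` recording the
#'   number removed per list (counted among probes actually present) and the
#'   number remaining. Warns if nothing remains.
#' @export
filter_probes <- function(meth, snp_overlap_list = character(0),
                          cross_reactive_list = character(0)) {
  stopifnot(is.matrix(meth), !is.null(rownames(meth)))
  present <- rownames(meth)
  drop_snp <- intersect(present, snp_overlap_list)
  drop_xr <- intersect(present, cross_reactive_list)
  drop <- union(drop_snp, drop_xr)
  out <- meth[setdiff(present, drop), , drop = FALSE]
  attr(out, "filter_counts") <- c(
    snp_overlap = length(drop_snp), cross_reactive = length(drop_xr),
    removed = length(drop), remaining = nrow(out),
    unknown_ids = length(setdiff(union(snp_overlap_list, cross_reactive_list),
                                 present))
  )
  if (nrow(out) == 0L) {
    warning("filter_probes: no CpGs remain after filtering", call. = FALSE)
  }
  out
}

#' Beta-value to M-value conversion
#'
#' `M = log2(b / (1 - b))` with the beta clipped into
#' `[clip_eps, 1 - clip_eps]` so boundary values stay finite.
#'
#' @param beta numeric vector or matrix of beta values in \[0, 1\].
#' @param clip_eps positive clipping bound.
#' @return M-values with the shape of the input.
#' @export
beta_to_m <- function(beta, clip_eps = 1e-6) {
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) {
    stop("beta_to_m: beta values must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(clip_eps > 0, clip_eps < 0.5)
  b <- pmin(pmax(beta, clip_eps), 1 - clip_eps)
  out <- log2(b / (1 - b))
  if (is.matrix(beta)) dim(out) <- dim(beta)
  if (is.matrix(beta)) dimnames(out) <- dimnames(beta)
  out
}

# First-stage design: intercept + slide + sample type + plate indicators +
# cell-proportion columns (last cell column dropped: proportions sum to one).
# Model 2 uses the extended cell set (including nRBC when present); model 1
# uses the six standard fractions.
first_stage_design <- function(covars, model = 1L) {
  cell_cols <- grep("^cell_", names(covars), value = TRUE)
  if (model == 1L) {
    cell_cols <- setdiff(cell_cols, "cell_nrbc")
  } else {
    # extended cell set: keep nRBC in the design, so it is never the
    # sum-to-one column that gets dropped
    cell_cols <- c(intersect("cell_nrbc", cell_cols),
                   setdiff(cell_cols, "cell_nrbc"))
  }
  if (length(cell_cols) > 0L) cell_cols <- cell_cols[-length(cell_cols)]
  fixed <- intersect(c("slide", "sample_type", "plate"), names(covars))
  # constant columns carry no information; keep the design full rank
  fixed <- fixed[vapply(covars[fixed], function(x) length(unique(x)) > 1L, TRUE)]
  cell_cols <- cell_cols[vapply(covars[cell_cols],
                                function(x) length(unique(x)) > 1L, TRUE)]
  terms <- c(fixed, cell_cols)
  f <- if (length(terms) == 0L) ~ 1 else
    stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  X <- stats::model.matrix(f, data = covars)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("residualize: first-stage design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  qrX
}

#' First-stage residualization against technical covariates
#'
#' Per CpG, ordinary-least-squares residuals of the methylation values against
#' the technical design (intercept + slide + sample-type + plate indicators +
#' cell proportions, one cell column dropped to break the sum-to-one
#' collinearity). Model 1 residualizes beta values with the standard cell set;
#' model 2 first converts betas to M-values and uses the extended cell set
#' (including the nucleated-RBC fraction when present).
#'
#' @param meth CpG x sample beta matrix.
#' @param covars covariate data.frame (see [gen_methylation()] for the schema).
#' @param model `1` (betas, standard cells) or `2` (M-values, extended cells).
#' @param clip_eps boundary clipping for the M-value conversion (model 2).
#' @return residual matrix, same shape and dimnames as `meth`; each row is
#'   orthogonal to every first-stage design column.
#' @export
residualize <- function(meth, covars, model = 1L, clip_eps = 1e-6) {
  stopifnot(is.matrix(meth), model %in% c(1L, 2L))
  if (!identical(colnames(meth), covars$sample_id)) {
    stop("residualize: sample identifiers of meth and covars do not match",
         call. = FALSE)
  }
  vals <- if (model == 2L) beta_to_m(meth, clip_eps) else meth
  qrX <- first_stage_design(covars, model)
  if (ncol(meth) < qrX$rank + 2L) {
    stop("residualize: need at least ", qrX$rank + 2L, " samples", call. = FALSE)
  }
  res <- t(qr.resid(qrX, t(vals)))
  dimnames(res) <- dimnames(meth)
  res
}

#' Two-step residualized negative-binomial MWAS
#'
#' Per CpG, a maximum-likelihood negative-binomial regression (log link) of
#' the count phenotype on the first-stage methylation residual, sex and two
#' ancestry principal components. The dispersion is estimated by alternating
#' coefficient and theta updates ([MASS::glm.nb()]); CpGs where that fit fails
#' to converge are refit as Poisson and flagged `converged = FALSE`. The
#' per-CpG p-value is two-sided Wald from the standard-normal reference by
#' default; `p_type = "lrt"` uses the likelihood-ratio test against the model
#' without the methylation term.
#'
#' @param resid residual matrix from [residualize()].
#' @param pheno data.frame with `sample_id` and non-negative integer `score`.
#' @param covars covariate data.frame with `sex`, `pc1`, `pc2`.
#' @param p_type `"wald"` (default) or `"lrt"`.
#' @return data.frame with one row per CpG: `cpg`, `effect`, `se`, `z`, `p`,
#'   `n`, `converged`.
#' @export
fit_nb_mwas <- function(resid, pheno, covars, p_type = c("wald", "lrt")) {
  p_type <- match.arg(p_type)
  stopifnot(is.matrix(resid))
  if (!identical(colnames(resid), covars$sample_id)) {
    stop("fit_nb_mwas: sample identifiers of resid and covars do not match",
         call. = FALSE)
  }
  ix <- match(colnames(resid), pheno$sample_id)
  if (anyNA(ix)) stop("fit_nb_mwas: phenotype missing for some samples", call. = FALSE)
  y <- pheno$score[ix]
  if (any(y < 0)) stop("fit_nb_mwas: negative counts", call. = FALSE)
  if (length(unique(y)) < 2L) stop("fit_nb_mwas: phenotype is constant", call. = FALSE)

  df <- data.frame(score = y, sex = covars$sex, pc1 = covars$pc1,
                   pc2 = covars$pc2, r = 0)
  n <- nrow(df)
  cpgs <- rownames(resid)
  out <- data.frame(cpg = cpgs, effect = NA_real_, se = NA_real_, z = NA_real_,
                    p = NA_real_, n = n, converged = NA,
                    stringsAsFactors = FALSE)

  for (i in seq_along(cpgs)) {
    df$r <- resid[i, ]
    # theta iteration warnings at the Poisson limit are expected; only an
    # error or a non-converged IRLS triggers the Poisson fallback
    fit <- tryCatch(
      suppressWarnings(MASS::glm.nb(score ~ r + sex + pc1 + pc2, data = df)),
      error = function(e) NULL
    )
    ok <- !is.null(fit) && isTRUE(fit$converged)
    if (!ok) {
      fit <- stats::glm(score ~ r + sex + pc1 + pc2, data = df,
                        family = stats::poisson())
    }
    cf <- summary(fit)$coefficients
    eff <- cf["r", 1L]
    se <- cf["r", 2L]
    z <- eff / se
    p <- if (p_type == "wald") {
      2 * stats::pnorm(-abs(z))
    } else {
      fit0 <- if (inherits(fit, "negbin")) {
        tryCatch(MASS::glm.nb(score ~ sex + pc1 + pc2, data = df),
                 error = function(e) NULL)
      } else {
        stats::glm(score ~ sex + pc1 + pc2, data = df, family = stats::poisson())
      }
      if (is.null(fit0)) 2 * stats::pnorm(-abs(z)) else {
        lr <- as.numeric(2 * (stats::logLik(fit) - stats::logLik(fit0)))
        stats::pchisq(max(lr, 0), df = 1, lower.tail = FALSE)
      }
    }
    out$effect[i] <- eff
    out$se[i] <- se
    out$z[i] <- z
    out$p[i] <- max(p, .Machine$double.xmin)
    out$converged[i] <- ok
  }
  out
}

#' Epigenome-wide significant CpGs
#'
#' Subsets an MWAS result table at the Bonferroni-corrected epigenome-wide
#' threshold of 1e-7.
#'
#' @param mwas MWAS result data.frame.
#' @param alpha significance threshold (default `1e-7`).
#' @return rows of `mwas` with `p < alpha`.
#' @export
mwas_significant <- function(mwas, alpha = 1e-7) {
  mwas[mwas$p < alpha, , drop = FALSE]
}

#' Genomic inflation factor
#'
#' `lambda` = median of the 1-df chi-squares implied by the p-values divided
#' by the 1-df chi-square median (0.4549364): the standard test-statistic
#' calibration diagnostic; 1 under a well-calibrated null.
#'
#' @param pvalues numeric vector of p-values in (0, 1\].
#' @return lambda as a single number.
#' @export
genomic_inflation <- function(pvalues) {
  if (length(pvalues) == 0L) stop("genomic_inflation: empty p-value list", call. = FALSE)
  if (any(pvalues <= 0 | pvalues > 1)) {
    stop("genomic_inflation: p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::median(stats::qchisq(pvalues, df = 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1)
}

#' Effect size in phenotype standard-deviation units
#'
#' @param effect regression coefficient (count-scale effect of the top CpG).
#' @param phenotype_sd standard deviation of the phenotype.
#' @return `abs(effect) / phenotype_sd`.
#' @export
standardized_effect <- function(effect, phenotype_sd) {
  if (phenotype_sd <= 0) stop("standardized_effect: phenotype_sd must be positive",
                              call. = FALSE)
  abs(effect) / phenotype_sd
}

#' Agreement between two MWAS result tables
#'
#' Pearson correlation of z-scores and of effects over shared CpGs, with
#' Fisher-z 95% confidence intervals and two-sided p-values. Used to compare
#' the beta-value and M-value models, or two phenotypes' MWAS.
#'
#' @param res_a,res_b MWAS result data.frames.
#' @return list with components `z` and `effect`, each holding `r`, `ci`
#'   (length 2), `p` and `n`.
#' @export
compare_models <- function(res_a, res_b) {
  shared <- merge(res_a, res_b, by = "cpg", suffixes = c("_a", "_b"))
  if (nrow(shared) < 3L) stop("compare_models: fewer than 3 shared CpGs", call. = FALSE)
  one <- function(x, y) {
    ct <- stats::cor.test(x, y)
    list(r = unname(ct$estimate), ci = as.numeric(ct$conf.int),
         p = ct$p.value, n = length(x))
  }
  list(z = one(shared$z_a, shared$z_b),
       effect = one(shared$effect_a, shared$effect_b))
}
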