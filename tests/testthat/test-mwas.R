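test_that("probe filtering removes the union of the blacklists", {
  m <- matrix(runif(20), nrow = 10,
              dimnames = list(paste0("cg", 1:10), c("a", "b")))
  expect_identical(filter_probes(m), m, ignore_attr = TRUE)
  out <- filter_probes(m, snp_overlap_list = c("cg1", "cg2", "cg3"),
                       cross_reactive_list = c("cg3", "cg4", "cgZZ"))
  expect_equal(nrow(out), 6)
  counts <- attr(out, "filter_counts")
  expect_equal(unname(counts[c("snp_overlap", "cross_reactive", "removed")]),
               c(3, 2, 4))
  expect_equal(unname(counts["unknown_ids"]), 1)
  expect_warning(filter_probes(m, paste0("cg", 1:10)), "no CpGs remain")
})

test_that("beta to M-value conversion matches the clipped log2 odds", {
  expect_equal(beta_to_m(0.5), 0)
  expect_equal(beta_to_m(0.8), 2)
  expect_equal(beta_to_m(0, clip_eps = 1e-6), log2(1e-6 / (1 - 1e-6)))
  expect_equal(beta_to_m(0, clip_eps = 1e-6), -19.93157, tolerance = 1e-6)
  expect_error(beta_to_m(1.2), "\\[0, 1\\]")
  expect_error(beta_to_m(-0.1), "\\[0, 1\\]")
  m <- matrix(c(0.2, 0.5, 0.8, 0.9), 2, dimnames = list(c("x", "y"), c("a", "b")))
  expect_equal(dimnames(beta_to_m(m)), dimnames(m))
})

test_that("residuals are orthogonal to every first-stage design column", {
  d <- tiny_dataset(seed = 8, n_samples = 50, n_cpgs = 12)
  for (model in 1:2) {
    res <- residualize(d$meth, d$covars, model = model)
    X <- model.matrix(~ slide + sample_type + plate + cell_cd4t + cell_cd8t,
                      data = d$covars)
    ip <- abs(res %*% X)
    expect_lt(max(ip), 1e-8 * ncol(d$meth))
  }
})

test_that("with constant covariates residualization just centers each CpG", {
  n <- 30
  covars <- constant_covars(n)
  m <- matrix(runif(5 * n), nrow = 5,
              dimnames = list(paste0("cg", 1:5), covars$sample_id))
  res <- residualize(m, covars, model = 1)
  expect_equal(res, m - rowMeans(m), ignore_attr = TRUE)
})

test_that("one-factor residualization equals per-slide mean subtraction", {
  n <- 20
  covars <- constant_covars(n)
  covars$slide <- factor(rep(c("s1", "s2"), each = 10))
  m <- matrix(runif(5 * n), nrow = 5,
              dimnames = list(paste0("cg", 1:5), covars$sample_id))
  res <- residualize(m, covars, model = 1)
  oracle <- t(apply(m, 1, function(y) y - ave(y, covars$slide)))
  expect_equal(res, oracle, ignore_attr = TRUE)
})

test_that("rank-deficient designs fail with the collinear column named", {
  n <- 30
  covars <- constant_covars(n)
  covars$slide <- factor(rep(c("s1", "s2"), each = 15))
  covars$plate <- covars$slide  # perfectly aliased
  levels(covars$plate) <- c("p1", "p2")
  m <- matrix(runif(2 * n), nrow = 2,
              dimnames = list(paste0("cg", 1:2), covars$sample_id))
  expect_error(residualize(m, covars), "collinear")
})

test_that("NB effect estimates rescale as 1/c when the residual is scaled by c", {
  d <- tiny_dataset(seed = 13, n_samples = 80, n_cpgs = 3)
  res <- residualize(d$meth, d$covars)
  fit1 <- fit_nb_mwas(res, d$pheno, d$covars)
  fit2 <- fit_nb_mwas(res * 10, d$pheno, d$covars)
  expect_equal(fit2$effect, fit1$effect / 10, tolerance = 1e-6)
  expect_equal(fit2$z, fit1$z, tolerance = 1e-6)
  expect_equal(fit2$p, fit1$p, tolerance = 1e-6)
})

test_that("per-CpG fits are unchanged by adding unrelated noise CpGs", {
  d <- tiny_dataset(seed = 17, n_samples = 60, n_cpgs = 10)
  res <- residualize(d$meth, d$covars)
  full <- fit_nb_mwas(res, d$pheno, d$covars)
  sub <- fit_nb_mwas(res[3:5, , drop = FALSE], d$pheno, d$covars)
  expect_equal(sub, full[3:5, ], ignore_attr = TRUE)
})

test_that("NB fit rejects degenerate phenotypes", {
  d <- tiny_dataset(seed = 19, n_samples = 40, n_cpgs = 2)
  res <- residualize(d$meth, d$covars)
  ph_const <- d$pheno; ph_const$score <- 5L
  expect_error(fit_nb_mwas(res, ph_const, d$covars), "constant")
  ph_neg <- d$pheno; ph_neg$score[1] <- -1L
  expect_error(fit_nb_mwas(res, ph_neg, d$covars), "negative")
})

test_that("Wald and likelihood-ratio p-values agree at moderate sample size", {
  d <- tiny_dataset(seed = 23, n_samples = 150, n_cpgs = 4)
  res <- residualize(d$meth, d$covars)
  w <- fit_nb_mwas(res, d$pheno, d$covars, p_type = "wald")
  l <- fit_nb_mwas(res, d$pheno, d$covars, p_type = "lrt")
  expect_true(all(l$p > 0 & l$p <= 1))
  expect_equal(w$effect, l$effect)  # same point estimates, different p
  expect_equal(log(w$p), log(l$p), tolerance = 0.2)
})

test_that("two-step estimate agrees with a one-step joint NB fit on a small instance", {
  # documents the two-step approximation: the joint model regresses the count
  # on raw methylation plus the technical covariates directly
  cfg <- sim_config(n_samples = 30, n_cpgs = 3, n_causal = 1, n_slides = 2,
                    n_plates = 2, include_nrbc = FALSE, pheno_mean = 8,
                    seed = 77)
  gm <- gen_methylation(cfg)
  gp <- gen_phenotype(gm$meth, gm$covars, cfg, effects = 0.8)
  res <- residualize(gm$meth, gm$covars)
  two_step <- fit_nb_mwas(res, gp$pheno, gm$covars)
  cid <- gp$truth$causal_cpg_ids
  df <- data.frame(score = gp$pheno$score, beta_meth = gm$meth[cid, ],
                   gm$covars)
  joint <- suppressWarnings(MASS::glm.nb(
    score ~ beta_meth + slide + sample_type + plate + cell_cd4t + cell_cd8t +
      cell_bcell + cell_nk + cell_mono + sex + pc1 + pc2, data = df))
  b_joint <- coef(joint)[["beta_meth"]]
  b_two <- two_step$effect[two_step$cpg == cid]
  expect_lt(abs(b_two - b_joint) / abs(b_joint), 0.10)
})

test_that("the epigenome-wide significance caller thresholds at 1e-7", {
  tab <- mwas_table(c("a", "b", "c"), c(1, 1, 1), c(9.9e-8, 1e-7, 0.5))
  expect_equal(mwas_significant(tab)$cpg, "a")
})

test_that("genomic inflation equals 1 at the null median and on uniform p-values", {
  expect_equal(genomic_inflation(rep(0.5, 11)), 1.0)
  set.seed(1)
  expect_equal(genomic_inflation(runif(1e5)), 1.0, tolerance = 0.02)
  expect_error(genomic_inflation(numeric(0)), "empty")
  expect_error(genomic_inflation(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("standardized effects reproduce the published SD-unit conversions", {
  # printed values truncate trailing digits (1.78/3.44 = 0.517 -> 0.51)
  expect_equal(standardized_effect(-1.78, 3.44), 0.51, tolerance = 0.02)
  expect_equal(standardized_effect(-3.73, 6.77), 0.55, tolerance = 0.02)
  expect_equal(standardized_effect(0, 5), 0)
  expect_error(standardized_effect(1, 0), "positive")
})

test_that("model comparison recovers perfect, inverted and cross-model agreement", {
  tab <- mwas_table(paste0("cg", 1:50), rnorm(50), runif(50))
  expect_equal(compare_models(tab, tab)$z$r, 1)
  flip <- tab; flip$z <- -flip$z; flip$effect <- -flip$effect
  expect_equal(compare_models(tab, flip)$z$r, -1)
  expect_error(compare_models(tab[1:2, ], tab[1:2, ]), "3 shared")

  d <- tiny_dataset(seed = 29, n_samples = 200, n_cpgs = 120)
  r1 <- fit_nb_mwas(residualize(d$meth, d$covars, model = 1), d$pheno, d$covars)
  r2 <- fit_nb_mwas(residualize(d$meth, d$covars, model = 2), d$pheno, d$covars)
  expect_gt(compare_models(r1, r2)$z$r, 0.8)
})
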