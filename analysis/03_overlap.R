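#!/usr/bin/env Rscript
# Cross-phenotype concordance and shift analyses: simulates a second,
# correlated trait (sharing the causal CpGs, like a communication checklist
# alongside a social-communication score), runs its MWAS, and computes sign
# concordance at top loci, the one-sided p-value shift test, z-score
# correlations, and a gene-set shift enrichment for the causal CpGs' genes.

suppressMessages(library(mwasenrich))

seed <- 2026L
data_dir <- "results/data"

meth <- read_matrix(file.path(data_dir, "methylation.tsv"))
covars <- read_covariates(file.path(data_dir, "covariates.tsv"))
m1 <- read_mwas("results/mwas_model1.tsv")
truth <- utils::read.delim(file.path(data_dir, "ground_truth.tsv"),
                           comment.char = "#")
causal <- truth$id[truth$role == "causal_cpg"]
effects <- truth$effect[truth$role == "causal_cpg"]

cfg <- sim_config(n_samples = ncol(meth), n_cpgs = nrow(meth), n_causal = 50,
                  effect_sd_units = 0.1, seed = seed)
second <- gen_phenotype(meth, covars, cfg, causal_ids = causal,
                        effects = effects, seed_offset = 17L)
m_second <- fit_nb_mwas(residualize(meth, covars), second$pheno, covars)
write_mwas(m_second, "results/mwas_second_trait.tsv", seed)

cc <- sign_concordance(m1, m_second, threshold = 1e-4)
cat(sprintf("sign concordance at p < 1e-4: %d of %d concordant, binomial p = %.3g\n",
            cc$n_concordant, cc$n_total, cc$p))

sh <- pvalue_shift_test(m1, m_second, selection_threshold = 0.01)
cat(sprintf("shift test (discovery p < 0.01, n = %d vs %d): one-sided p = %.3g\n",
            sh$n_selected, sh$n_rest, sh$p_one_sided))

zc_all <- zscore_correlation(m1, m_second)
zc_top <- zscore_correlation(m1, m_second, restrict_threshold = 0.01,
                             restrict_side = "a")
cat(sprintf("z-score correlation: all CpGs r = %.3f (n = %d); top CpGs r = %.3f (n = %d)\n",
            zc_all$r, zc_all$n, zc_top$r, zc_top$n))

# gene-set shift: one synthetic gene per CpG, set = genes of causal CpGs
map <- data.frame(cpg = m1$cpg, gene = paste0("G_", m1$cpg))
set <- list(name = "causal_genes", genes = paste0("G_", causal),
            universe = paste0("G_", m1$cpg))
ge <- gene_set_shift_test(m1, map, set)
cat(sprintf("gene-set shift (causal genes, %d vs %d CpGs): one-sided p = %.3g\n",
            ge$n_selected, ge$n_rest, ge$p_one_sided))

report <- data.frame(
  analysis = c("sign_concordance", "pvalue_shift", "zcor_all", "zcor_top",
               "gene_set_shift"),
  statistic = c(cc$n_concordant / cc$n_total, sh$w_statistic, zc_all$r,
                zc_top$r, ge$w_statistic),
  p = c(cc$p, sh$p_one_sided, zc_all$p, zc_top$p, ge$p_one_sided)
)
write_tsv <- function(df, path) utils::write.table(df, path, sep = "\t",
                                                   quote = FALSE,
                                                   row.names = FALSE)
write_tsv(report, "results/overlap_report.tsv")
cat("report written to results/overlap_report.tsv\n")
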