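#!/usr/bin/env Rscript
# Generates the synthetic study dataset used by the downstream analyses:
# a batch-structured cord-blood-style beta matrix for 700 samples x 1,000
# CpGs, a bounded count phenotype (mean ~14.65, ceiling 24) causally linked
# to 50 CpGs with small per-SD effects, an mQTL map, block-LD table, a trait
# GWAS whose enriched mQTLs carry a chi-square shift of 1.0, and a
# negative-control GWAS drawn from the null on the same map.

suppressMessages(library(mwasenrich))

seed <- 2026L
out_dir <- "results/data"

cfg <- sim_config(n_samples = 700, n_cpgs = 1000, n_causal = 50,
                  effect_sd_units = 0.1, gwas_enrich_shift = 1.0,
                  n_snps = 12000, seed = seed)
obj <- write_sim_dataset(out_dir, cfg)

# negative-control GWAS: same mQTL map, association p-values from the null
ctrl <- gen_mqtl_gwas(rownames(obj$meth), cfg, truth = NULL,
                      seed_offset = 50L, mqtl_map = obj$mqtl)
write_gwas(ctrl$gwas, file.path(out_dir, "gwas_control.tsv"), seed)

cat(sprintf("dataset written to %s\n", out_dir))
cat(sprintf("  %d CpGs x %d samples; %d causal CpGs\n",
            nrow(obj$meth), ncol(obj$meth),
            length(obj$truth$causal_cpg_ids)))
cat(sprintf("  phenotype: mean %.2f, sd %.2f, range %d-%d\n",
            mean(obj$pheno$score), sd(obj$pheno$score),
            min(obj$pheno$score), max(obj$pheno$score)))
cat(sprintf("  mQTL map: %d pairs, %d SNPs; %d enriched SNPs in the trait GWAS\n",
            nrow(obj$mqtl), length(unique(obj$mqtl$snp)),
            length(obj$truth$enriched_snp_ids)))
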