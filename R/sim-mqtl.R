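#' Generate an mQTL map, GWAS summary statistics and a block LD table
#'
#' Each CpG is assigned k SNPs, k drawn from `config$mqtl_per_cpg_dist`
#' (support 1..40); SNPs live on a synthetic single-chromosome coordinate map
#' in LD blocks of `ld_block_size` consecutive SNPs with constant high
#' within-block r-squared and zero across blocks. GWAS p-values come from a
#' 1-df chi-square (uniform under the null); SNPs that are mQTLs of causal
#' CpGs get a non-central chi-square with non-centrality
#' `config$gwas_enrich_shift`, i.e. a downward shift in p.
#'
#' @param cpg_ids CpG identifiers to map.
#' @param config a [sim_config()] object.
#' @param truth ground-truth list from [gen_phenotype()]; its
#'   `enriched_snp_ids` field is filled in.
#' @param seed_offset offset for the derived RNG stream, so several GWAS
#'   analogues (e.g. a negative control) can be drawn for one map.
#' @param mqtl_map optional existing map to reuse (only the GWAS p-values are
#'   redrawn); used for negative-control GWAS analogues on the same map.
#' @return list with `mqtl` (data.frame `cpg`, `snp`), `gwas` (data.frame
#'   `snp`, `chr`, `pos`, `p`, `maf`), `ld` (data.frame `snp_a`, `snp_b`,
#'   `r2`, `pos_a`, `pos_b`) and the updated `truth`.
#' @export
gen_mqtl_gwas <- function(cpg_ids, config, truth = NULL, seed_offset = 0L,
                          mqtl_map = NULL) {
  validate_sim_config(config)
  if (length(cpg_ids) == 0L) stop("gen_mqtl_gwas: cpg_ids is empty", call. = FALSE)
  if (sum(config$mqtl_per_cpg_dist > 0) == 0L) {
    stop("gen_mqtl_gwas: mqtl count distribution has empty support", call. = FALSE)
  }
  set.seed(derive_seed(config$seed, 3L + seed_offset))

  n_snps <- config$n_snps
  snp_ids <- sprintf("rs%06d", seq_len(n_snps))
  bs <- config$ld_block_size
  block <- 1L + (seq_len(n_snps) - 1L) %/% bs
  within <- (seq_len(n_snps) - 1L) %% bs
  # 2 kb spacing inside a block, 200 kb between block starts
  pos <- (block - 1L) * 200000L + within * 2000L + 1L

  if (is.null(mqtl_map)) {
    k <- sample(1:40, length(cpg_ids), replace = TRUE,
                prob = config$mqtl_per_cpg_dist)
    k <- pmin(k, n_snps)
    mqtl <- data.frame(
      cpg = rep(cpg_ids, k),
      snp = snp_ids[unlist(lapply(k, function(ki) sample.int(n_snps, ki)))],
      stringsAsFactors = FALSE
    )
  } else {
    mqtl <- mqtl_map[, c("cpg", "snp")]
  }

  enriched <- character(0)
  if (!is.null(truth) && length(truth$causal_cpg_ids) > 0L) {
    enriched <- sort(unique(mqtl$snp[mqtl$cpg %in% truth$causal_cpg_ids]))
  }
  ncp <- ifelse(snp_ids %in% enriched, config$gwas_enrich_shift, 0)
  chisq <- stats::rchisq(n_snps, df = 1, ncp = ncp)
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  p <- pmax(p, .Machine$double.xmin)

  gwas <- data.frame(snp = snp_ids, chr = 1L, pos = pos, p = p,
                     maf = stats::runif(n_snps, 0.01, 0.5),
                     stringsAsFactors = FALSE)

  # all within-block pairs at constant r2
  pair_i <- unlist(lapply(split(seq_len(n_snps), block), function(ix) {
    if (length(ix) < 2L) return(integer(0))
    cmb <- utils::combn(ix, 2L)
    as.integer(cmb)
  }))
  if (length(pair_i) > 0L) {
    pm <- matrix(pair_i, nrow = 2L)
    ld <- data.frame(snp_a = snp_ids[pm[1L, ]], snp_b = snp_ids[pm[2L, ]],
                     r2 = config$ld_r2,
                     pos_a = pos[pm[1L, ]], pos_b = pos[pm[2L, ]],
                     stringsAsFactors = FALSE)
  } else {
    ld <- data.frame(snp_a = character(0), snp_b = character(0), r2 = numeric(0),
                     pos_a = integer(0), pos_b = integer(0))
  }

  if (!is.null(truth)) truth$enriched_snp_ids <- enriched
  list(mqtl = mqtl, gwas = gwas, ld = ld, truth = truth)
}
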