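#' Collapse duplicate CpG-SNP pairs
#'
#' A single SNP can be an mQTL of several CpGs and an mQTL list can repeat
#' pairs; exact duplicate (CpG, SNP) pairs are collapsed to one before
#' enrichment. Idempotent.
#'
#' @param map data.frame with columns `cpg`, `snp`.
#' @return the deduplicated map with attribute `deduplicated = TRUE`.
#' @export
dedup_pairs <- function(map) {
  out <- unique(map[, c("cpg", "snp"), drop = FALSE])
  rownames(out) <- NULL
  attr(out, "deduplicated") <- TRUE
  attr(out, "clumped") <- isTRUE(attr(map, "clumped"))
  out
}

#' Greedy LD clumping of an mQTL SNP list
#'
#' Orders the map's SNPs by ascending GWAS p-value and greedily retains index
#' SNPs, removing every not-yet-retained SNP within `window_kb` of an index
#' whose r-squared with it is at least `r2_max`. Returns the map restricted to
#' retained SNPs. SNP pairs absent from the LD table are treated as r2 = 0;
#' SNPs without a GWAS position cannot be window-checked and are counted in
#' the `missing_info` attribute (also treated as unlinked).
#'
#' @param map data.frame with columns `cpg`, `snp`.
#' @param gwas data.frame with columns `snp`, `p` and (for clumping) `chr`,
#'   `pos`.
#' @param ld data.frame with columns `snp_a`, `snp_b`, `r2` (symmetric on
#'   lookup).
#' @param r2_max clumping r-squared threshold (default 0.6).
#' @param window_kb clumping window in kilobases (default 1000).
#' @return the clumped map, attributes `clumped = TRUE` and `missing_info`.
#' @export
clump_mqtls <- function(map, gwas, ld, r2_max = 0.6, window_kb = 1000L) {
  snps <- unique(map$snp)
  gi <- match(snps, gwas$snp)
  keep_known <- !is.na(gi)
  n_missing <- sum(!keep_known)
  snps <- snps[keep_known]
  gi <- gi[keep_known]
  p <- gwas$p[gi]
  chr <- if ("chr" %in% names(gwas)) gwas$chr[gi] else rep(1L, length(gi))
  pos <- if ("pos" %in% names(gwas)) gwas$pos[gi] else rep(NA_integer_, length(gi))
  n_missing <- n_missing + sum(is.na(pos))

  # symmetric high-LD adjacency restricted to the candidate SNPs
  ld2 <- ld[ld$r2 >= r2_max & ld$snp_a %in% snps & ld$snp_b %in% snps, ,
            drop = FALSE]
  nbr <- split(c(ld2$snp_b, ld2$snp_a), c(ld2$snp_a, ld2$snp_b))

  ord <- order(p)
  removed <- structure(logical(length(snps)), names = snps)
  retained <- character(0)
  pos_by_snp <- structure(pos, names = snps)
  chr_by_snp <- structure(chr, names = snps)
  win <- window_kb * 1000
  for (s in snps[ord]) {
    if (removed[[s]]) next
    retained <- c(retained, s)
    cand <- setdiff(nbr[[s]], retained)
    if (length(cand) == 0L) next
    same_chr <- chr_by_snp[cand] == chr_by_snp[[s]]
    dist_ok <- abs(pos_by_snp[cand] - pos_by_snp[[s]]) <= win
    drop <- cand[!is.na(same_chr) & same_chr & !is.na(dist_ok) & dist_ok]
    removed[drop] <- TRUE
  }
  out <- map[map$snp %in% retained, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "clumped") <- TRUE
  attr(out, "deduplicated") <- isTRUE(attr(map, "deduplicated"))
  attr(out, "missing_info") <- n_missing
  out
}

#' Bin CpGs by mQTL count
#'
#' Bins each CpG by the number of SNPs it maps to, into six groups: 1-5, 6-10,
#' 11-15, 16-20, 21-25, and 26 or more. The permutation null is matched on
#' these bins. CpGs with zero mQTLs (absent from the map) are simply not
#' binned.
#'
#' @param map deduplicated data.frame with columns `cpg`, `snp`.
#' @return named integer vector, CpG id -> bin index in 1..6.
#' @export
bin_cpgs <- function(map) {
  counts <- table(map$cpg)
  bins <- cut(as.integer(counts), breaks = c(0, 5, 10, 15, 20, 25, Inf),
              labels = FALSE)
  structure(as.integer(bins), names = names(counts))
}

#' Mean GWAS p-value difference between mQTLs of top and remaining CpGs
#'
#' Restricts the map to pairs whose CpG has an MWAS result and whose SNP has a
#' GWAS p-value, partitions pairs by the MWAS p-value of their CpG (below vs
#' at-or-above `threshold`), and returns mean(GWAS p of above-set) minus
#' mean(GWAS p of below-set): positive values mean the mQTLs of top CpGs are
#' shifted toward lower GWAS p-values.
#'
#' @param map data.frame with columns `cpg`, `snp` (clumped + deduplicated).
#' @param mwas MWAS result data.frame (`cpg`, `p`).
#' @param gwas GWAS summary data.frame (`snp`, `p`).
#' @param threshold MWAS p-value threshold defining the top CpG set.
#' @return list `statistic`, `n_below`, `n_above`, `flagged` (TRUE with NA
#'   statistic when either partition is empty).
#' @export
enrichment_statistic <- function(map, mwas, gwas, threshold) {
  pr <- restrict_pairs(map, mwas, gwas)
  below <- pr$mwas_p < threshold
  n_below <- sum(below)
  n_above <- sum(!below)
  if (n_below == 0L || n_above == 0L) {
    return(list(statistic = NA_real_, n_below = n_below, n_above = n_above,
                flagged = TRUE))
  }
  list(statistic = mean(pr$gwas_p[!below]) - mean(pr$gwas_p[below]),
       n_below = n_below, n_above = n_above, flagged = FALSE)
}

# restrict to pairs testable in both summary tables; annotate each pair with
# its CpG's MWAS p and its SNP's GWAS p
restrict_pairs <- function(map, mwas, gwas) {
  mi <- match(map$cpg, mwas$cpg)
  gi <- match(map$snp, gwas$snp)
  keep <- !is.na(mi) & !is.na(gi)
  data.frame(cpg = map$cpg[keep], snp = map$snp[keep],
             mwas_p = mwas$p[mi[keep]], gwas_p = gwas$p[gi[keep]],
             stringsAsFactors = FALSE)
}

#' Bin-matched permutation test for mQTL-GWAS enrichment
#'
#' Computes the observed [enrichment_statistic()], then builds `n_perm` null
#' sets: within each mQTL-count bin, as many CpGs as the observed
#' below-threshold set contains in that bin are sampled uniformly without
#' replacement from all CpGs of that bin; the sampled CpGs carry all their
#' pairs into the null below-set and the statistic is recomputed. The
#' one-sided empirical p-value is `(1 + #{null >= observed}) / (n_perm + 1)`,
#' so it is never exactly zero.
#'
#' @param map clumped, deduplicated data.frame with columns `cpg`, `snp`.
#' @param mwas MWAS result data.frame (`cpg`, `p`).
#' @param gwas GWAS summary data.frame (`snp`, `p`).
#' @param threshold MWAS p-value threshold defining the top CpG set.
#' @param n_perm number of null sets (default 10000).
#' @param seed RNG seed for the permutation stream.
#' @param check_bins assert, for every null set, that its per-bin CpG counts
#'   equal the observed ones (test mode).
#' @return list: `statistic`, `n_below`, `n_above`, `empirical_p`, `n_perm`,
#'   `seed`, `null_mean`, `flagged`.
#' @export
permutation_enrichment <- function(map, mwas, gwas, threshold,
                                   n_perm = 10000L, seed = 1L,
                                   check_bins = FALSE) {
  pr <- restrict_pairs(map, mwas, gwas)
  bins <- bin_cpgs(pr)
  obs <- enrichment_statistic(pr[, c("cpg", "snp")],
                              data.frame(cpg = pr$cpg, p = pr$mwas_p),
                              data.frame(snp = pr$snp, p = pr$gwas_p),
                              threshold)
  if (obs$flagged) {
    return(c(obs, list(empirical_p = NA_real_, n_perm = as.integer(n_perm),
                       seed = as.integer(seed), null_mean = NA_real_)))
  }

  # per-CpG sufficient statistics: the below-set mean only needs each sampled
  # CpG's pair count and GWAS p sum
  cpg_levels <- names(bins)
  ci <- match(pr$cpg, cpg_levels)
  pair_n <- tabulate(ci, nbins = length(cpg_levels))
  pair_sum <- as.numeric(rowsum(pr$gwas_p, ci, reorder = TRUE))
  tot_n <- sum(pair_n)
  tot_sum <- sum(pair_sum)

  below_cpgs <- unique(pr$cpg[pr$mwas_p < threshold])
  demand <- table(factor(bins[below_cpgs], levels = sort(unique(bins))))
  members <- split(seq_along(bins), bins)
  for (b in names(demand)) {
    if (demand[[b]] > length(members[[b]])) {
      stop("permutation_enrichment: bin ", b, " demands ", demand[[b]],
           " CpGs but only has ", length(members[[b]]), call. = FALSE)
    }
  }

  set.seed(seed)
  null_stats <- numeric(n_perm)
  for (k in seq_len(n_perm)) {
    pick <- unlist(lapply(names(demand), function(b) {
      m <- members[[b]]
      d <- demand[[b]]
      if (d == 0L) integer(0) else m[sample.int(length(m), d)]
    }), use.names = FALSE)
    if (check_bins) {
      got <- table(factor(bins[pick], levels = names(demand)))
      stopifnot(all(as.integer(got) == as.integer(demand)))
    }
    nb <- sum(pair_n[pick])
    sb <- sum(pair_sum[pick])
    null_stats[k] <- (tot_sum - sb) / (tot_n - nb) - sb / nb
  }
  list(statistic = obs$statistic, n_below = obs$n_below, n_above = obs$n_above,
       empirical_p = (1 + sum(null_stats >= obs$statistic)) / (n_perm + 1),
       n_perm = as.integer(n_perm), seed = as.integer(seed),
       null_mean = mean(null_stats), flagged = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, capped at one, monotone non-decreasing in rank.
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return adjusted p-values in the input order.
#' @export
fdr_correct <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(pvalues <= 0 | pvalues > 1)) {
    stop("fdr_correct: p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Full mQTL-GWAS enrichment pipeline
#'
#' Restrict -> clump -> deduplicate -> bin -> per MWAS threshold in
#' `thresholds`: observed statistic and bin-matched permutation p -> BH-FDR
#' over the thresholds. One result row per threshold.
#'
#' @param mwas MWAS result data.frame (`cpg`, `p`).
#' @param map mQTL map data.frame (`cpg`, `snp`).
#' @param gwas GWAS summary data.frame (`snp`, `chr`, `pos`, `p`).
#' @param ld LD table data.frame (`snp_a`, `snp_b`, `r2`).
#' @param seed RNG seed for the permutation streams.
#' @param thresholds MWAS p-value thresholds (default 0.05, 0.01, 0.005,
#'   0.001).
#' @param n_perm permutations per threshold (default 10000).
#' @param r2_max,window_kb clumping parameters (defaults 0.6 and 1000 kb).
#' @return data.frame with one row per threshold: `threshold`, `n_below`,
#'   `n_above`, `mean_difference`, `empirical_p`, `fdr_p`, `n_perm`, `seed`.
#' @export
run_enrichment <- function(mwas, map, gwas, ld, seed = 1L,
                           thresholds = c(0.05, 0.01, 0.005, 0.001),
                           n_perm = 10000L, r2_max = 0.6, window_kb = 1000L) {
  map <- map[map$cpg %in% mwas$cpg & map$snp %in% gwas$snp, , drop = FALSE]
  map <- clump_mqtls(map, gwas, ld, r2_max = r2_max, window_kb = window_kb)
  map <- dedup_pairs(map)
  out <- data.frame(threshold = thresholds, n_below = NA_integer_,
                    n_above = NA_integer_, mean_difference = NA_real_,
                    empirical_p = NA_real_, fdr_p = NA_real_,
                    n_perm = as.integer(n_perm), seed = as.integer(seed))
  for (i in seq_along(thresholds)) {
    pe <- permutation_enrichment(map, mwas, gwas, thresholds[i],
                                 n_perm = n_perm,
                                 seed = derive_seed(seed, 100L + i))
    out$n_below[i] <- pe$n_below
    out$n_above[i] <- pe$n_above
    out$mean_difference[i] <- pe$statistic
    out$empirical_p[i] <- pe$empirical_p
  }
  ok <- !is.na(out$empirical_p)
  out$fdr_p[ok] <- fdr_correct(out$empirical_p[ok])
  out
}
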