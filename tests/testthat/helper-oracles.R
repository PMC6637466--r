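# independent oracles, kept deliberately naive

# exact two-sided binomial p at 1/2 by full enumeration:
# sum of P(x) over all outcomes no more likely than the observed one
enum_binom_two_sided <- function(k, n) {
  d <- dbinom(0:n, n, 0.5)
  sum(d[d <= d[k + 1L] * (1 + 1e-7)])
}

# brute-force greedy index-SNP selection by ascending p: repeatedly take the
# smallest-p remaining SNP, discard everything linked to it (r2 >= r2_max and
# within window); quadratic lookups on a dense pair list
brute_force_clump <- function(snps, p, chr, pos, ld, r2_max = 0.6,
                              window_kb = 1000) {
  key <- function(a, b) paste(a, b, sep = "|")
  r2 <- c(structure(ld$r2, names = key(ld$snp_a, ld$snp_b)),
          structure(ld$r2, names = key(ld$snp_b, ld$snp_a)))
  names(p) <- names(chr) <- names(pos) <- snps
  remaining <- snps
  retained <- character(0)
  while (length(remaining) > 0L) {
    idx <- remaining[which.min(p[remaining])]
    retained <- c(retained, idx)
    remaining <- setdiff(remaining, idx)
    linked <- vapply(remaining, function(s) {
      r <- r2[key(idx, s)]
      !is.na(r) && r >= r2_max && chr[s] == chr[idx] &&
        abs(pos[s] - pos[idx]) <= window_kb * 1000
    }, TRUE)
    remaining <- remaining[!linked]
  }
  sort(retained)
}

# hand Benjamini-Hochberg: p(i) * m / i with a running minimum from the
# largest rank, capped at 1
hand_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# enumeration of the bin-matched permutation null on a one-bin instance:
# every below-set choice of size m from the CpG pool, equally weighted
enum_perm_null <- function(pair_cpg, pair_gwas_p, m) {
  cpgs <- unique(pair_cpg)
  combs <- utils::combn(cpgs, m, simplify = FALSE)
  vapply(combs, function(set) {
    below <- pair_cpg %in% set
    mean(pair_gwas_p[!below]) - mean(pair_gwas_p[below])
  }, numeric(1))
}
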