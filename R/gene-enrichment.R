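#' Gene-set p-value shift enrichment over CpG-to-gene mappings
#'
#' Maps CpGs to genes through a many-to-many annotation, restricts to CpGs
#' mapped to any gene in the testing universe (the genes actually assayed for
#' differential expression), then compares the MWAS p-values of CpGs mapped to
#' at least one set gene (group A) against those of the remaining restricted
#' CpGs (group B) with a one-sided rank-sum test (alternative: group A has
#' lower p-values). A CpG mapping to both a set gene and a non-set gene lands
#' in group A. CpGs mapped only to genes outside the universe never enter
#' either group.
#'
#' @param mwas MWAS result data.frame (`cpg`, `p`).
#' @param map data.frame with columns `cpg`, `gene` (duplicate pairs are
#'   collapsed).
#' @param set list with `name`, `genes` (character) and `universe`
#'   (character, superset of `genes`).
#' @return a `shift_result` list as in [pvalue_shift_test()], plus
#'   `n_set_genes` and `set_name`; `flagged = TRUE` when either group is
#'   empty.
#' @export
gene_set_shift_test <- function(mwas, map, set) {
  stopifnot(all(c("cpg", "gene") %in% names(map)))
  if (length(set$universe) == 0L) {
    stop("gene_set_shift_test: empty gene universe", call. = FALSE)
  }
  if (!all(set$genes %in% set$universe)) {
    stop("gene_set_shift_test: set genes must be contained in the universe",
         call. = FALSE)
  }
  map <- unique(map[, c("cpg", "gene")])
  map <- map[map$gene %in% set$universe, , drop = FALSE]   # restriction first
  map <- map[map$cpg %in% mwas$cpg, , drop = FALSE]
  in_set <- tapply(map$gene %in% set$genes, map$cpg, any)
  a_cpgs <- names(in_set)[in_set]
  b_cpgs <- names(in_set)[!in_set]
  p <- mwas$p[match(names(in_set), mwas$cpg)]
  names(p) <- names(in_set)
  if (length(a_cpgs) == 0L || length(b_cpgs) == 0L) {
    res <- list(selection_threshold = NA_real_, n_selected = length(a_cpgs),
                n_rest = length(b_cpgs), w_statistic = NA_real_,
                p_one_sided = NA_real_, flagged = TRUE)
  } else {
    res <- rank_sum_shift(p[a_cpgs], p[b_cpgs], NA_real_)
  }
  res$n_set_genes <- length(set$genes)
  res$set_name <- set$name
  class(res) <- "shift_result"
  res
}
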