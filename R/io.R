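#' @name io
#' @title Tab-delimited readers and writers
#' @description All pipeline tables are plain TSV with one header line;
#'   writers prepend comment lines (`#`) recording the package version, the
#'   seed and a content hash, and readers skip them. Coordinates are 1-based
#'   inclusive; p-values of exactly zero are clamped to the smallest positive
#'   double on read, with a warning. Scientific notation is accepted on read
#'   and written with six significant digits.
NULL

pkg_version <- function() {
  as.character(utils::packageVersion("mwasenrich"))
}

# small FNV-1a content hash so re-runs with identical content are verifiable
content_hash <- function(df) {
  bytes <- as.integer(charToRaw(paste(
    utils::capture.output(utils::write.table(df, sep = "\t", row.names = FALSE)),
    collapse = "\n")))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

write_tsv_with_header <- function(df, path, seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mwasenrich %s; seed=%s; hash=%s", pkg_version(),
                     as.character(seed), content_hash(df)), con)
  num <- vapply(df, function(x) is.numeric(x) && !is.integer(x), TRUE)
  df[num] <- lapply(df[num], signif, digits = 6)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_table <- function(path, required, aliases = list()) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE)
  for (canon in names(aliases)) {
    if (!canon %in% names(df)) {
      hit <- intersect(aliases[[canon]], names(df))
      if (length(hit) > 0L) names(df)[names(df) == hit[1L]] <- canon
    }
  }
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("schema error reading ", path, ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

clamp_p <- function(p, what) {
  if (any(p == 0, na.rm = TRUE)) {
    warning(what, ": p-values of exactly 0 clamped to smallest positive double",
            call. = FALSE)
    p[p == 0] <- .Machine$double.xmin
  }
  p
}

#' @rdname io
#' @param path file path.
#' @export
read_mwas <- function(path) {
  df <- read_tsv_table(path, c("cpg", "effect", "se", "p"),
                       aliases = list(effect = c("beta", "b"),
                                      p = c("pvalue", "p_value", "P")))
  if (anyDuplicated(df$cpg)) {
    stop("read_mwas: duplicate CpG ids: ",
         paste(utils::head(df$cpg[duplicated(df$cpg)], 5L), collapse = ", "),
         call. = FALSE)
  }
  df$p <- clamp_p(df$p, "read_mwas")
  if (!"z" %in% names(df)) df$z <- df$effect / df$se
  if (!"n" %in% names(df)) df$n <- NA_integer_
  if (!"converged" %in% names(df)) df$converged <- NA
  df[, c("cpg", "effect", "se", "z", "p", "n", "converged")]
}

#' @rdname io
#' @param mwas MWAS result data.frame.
#' @param seed seed recorded in the header comment.
#' @export
write_mwas <- function(mwas, path, seed = NA) {
  write_tsv_with_header(
    mwas[, c("cpg", "effect", "se", "z", "p", "n", "converged")], path, seed)
}

#' @rdname io
#' @export
read_gwas <- function(path) {
  df <- read_tsv_table(path, c("snp", "p"),
                       aliases = list(p = c("pvalue", "p_value", "P"),
                                      pos = c("bp", "position")))
  if (anyDuplicated(df$snp)) {
    stop("read_gwas: duplicate SNP ids: ",
         paste(utils::head(df$snp[duplicated(df$snp)], 5L), collapse = ", "),
         call. = FALSE)
  }
  df$p <- clamp_p(df$p, "read_gwas")
  df
}

#' @rdname io
#' @param gwas GWAS summary data.frame.
#' @export
write_gwas <- function(gwas, path, seed = NA) {
  write_tsv_with_header(gwas, path, seed)
}

#' @rdname io
#' @export
read_mqtl <- function(path) {
  # duplicate pairs are preserved on read; dedup_pairs() is a separate step
  read_tsv_table(path, c("snp", "cpg"))
}

#' @rdname io
#' @param map mQTL map data.frame.
#' @export
write_mqtl <- function(map, path, seed = NA) {
  write_tsv_with_header(map, path, seed)
}

#' @rdname io
#' @export
read_ld <- function(path) {
  df <- read_tsv_table(path, c("snp_a", "snp_b", "r2"))
  if (any(df$r2 < 0 | df$r2 > 1)) {
    stop("read_ld: r2 values outside [0, 1]", call. = FALSE)
  }
  df
}

#' @rdname io
#' @param ld LD table data.frame.
#' @export
write_ld <- function(ld, path, seed = NA) {
  write_tsv_with_header(ld, path, seed)
}

#' @rdname io
#' @export
read_matrix <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (anyDuplicated(df[[1L]])) stop("read_matrix: duplicate CpG ids", call. = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  if (any(m < 0 | m > 1, na.rm = TRUE)) {
    stop("read_matrix: beta values outside [0, 1]", call. = FALSE)
  }
  m
}

#' @rdname io
#' @param meth beta matrix (CpG x sample).
#' @export
write_matrix <- function(meth, path, seed = NA) {
  df <- data.frame(cpg = rownames(meth), meth, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_with_header(df, path, seed)
}

#' @rdname io
#' @export
read_covariates <- function(path) {
  df <- read_tsv_table(path, c("sample_id", "sex", "pc1", "pc2"))
  for (col in intersect(c("slide", "plate", "sample_type", "sex"), names(df))) {
    df[[col]] <- factor(df[[col]])
  }
  df
}

#' @rdname io
#' @param covars covariate data.frame.
#' @export
write_covariates <- function(covars, path, seed = NA) {
  write_tsv_with_header(covars, path, seed)
}

#' @rdname io
#' @export
read_phenotype <- function(path) {
  df <- read_tsv_table(path, c("sample_id", "score"))
  if (any(df$score < 0)) stop("read_phenotype: negative scores", call. = FALSE)
  df$score <- as.integer(df$score)
  df
}

#' @rdname io
#' @param pheno phenotype data.frame.
#' @export
write_phenotype <- function(pheno, path, seed = NA) {
  write_tsv_with_header(pheno, path, seed)
}

#' Write a complete simulated dataset directory
#'
#' Emits every pipeline input generated from one configuration (beta matrix,
#' covariates, phenotype, mQTL map, GWAS, LD table) plus a ground-truth
#' sidecar TSV of causal CpGs and enriched SNPs.
#'
#' @param dir output directory (created if needed).
#' @param config a [sim_config()] object.
#' @return invisibly, the list of generated objects.
#' @export
write_sim_dataset <- function(dir, config) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gm <- gen_methylation(config)
  gp <- gen_phenotype(gm$meth, gm$covars, config)
  gq <- gen_mqtl_gwas(rownames(gm$meth), config, gp$truth)
  s <- config$seed
  write_matrix(gm$meth, file.path(dir, "methylation.tsv"), s)
  write_covariates(gm$covars, file.path(dir, "covariates.tsv"), s)
  write_phenotype(gp$pheno, file.path(dir, "phenotype.tsv"), s)
  write_mqtl(gq$mqtl, file.path(dir, "mqtl.tsv"), s)
  write_gwas(gq$gwas, file.path(dir, "gwas.tsv"), s)
  write_ld(gq$ld, file.path(dir, "ld.tsv"), s)
  truth <- data.frame(
    id = c(gq$truth$causal_cpg_ids, gq$truth$enriched_snp_ids),
    role = c(rep("causal_cpg", length(gq$truth$causal_cpg_ids)),
             rep("enriched_snp", length(gq$truth$enriched_snp_ids))),
    effect = c(gq$truth$effects, rep(NA_real_, length(gq$truth$enriched_snp_ids))),
    stringsAsFactors = FALSE
  )
  write_tsv_with_header(truth, file.path(dir, "ground_truth.tsv"), s)
  invisible(list(meth = gm$meth, covars = gm$covars, pheno = gp$pheno,
                 mqtl = gq$mqtl, gwas = gq$gwas, ld = gq$ld, truth = gq$truth))
}
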