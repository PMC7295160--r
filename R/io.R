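# Plain-text input/output -----------------------------------------------------
#
# All tables travel as TSV.  Genomic coordinates are 0-based half-open
# throughout the package.

#' Write / read a gene x sample count (or expression) matrix as TSV
#'
#' The first column holds gene ids; remaining columns are samples.
#'
#' @param mat Genes x samples matrix.
#' @param path File path.
#' @return `read_matrix_tsv` returns a numeric matrix with dimnames.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write / read a sample metadata table as TSV
#'
#' @param sample_table Sample table (see [simulate_samples()]).
#' @param path File path.
#' @export
write_samples_tsv <- function(sample_table, path) {
  write.table(sample_table, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_samples_tsv
#' @export
read_samples_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read genotype dosages as TSV
#'
#' Variant metadata columns first, then one dosage column per sample.
#'
#' @param genotypes List with `variants` and `dosage`
#'   (see [simulate_genotypes()]).
#' @param path File path.
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  df <- cbind(genotypes$variants,
              as.data.frame(genotypes$dosage, check.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @param sample_ids Sample ids identifying the dosage columns.
#' @export
read_genotypes_tsv <- function(path, sample_ids) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- setdiff(names(df), sample_ids)
  dosage <- as.matrix(df[, sample_ids, drop = FALSE])
  rownames(dosage) <- df$variant_id
  list(variants = df[, meta, drop = FALSE], dosage = dosage)
}

#' Write / read GWAS summary statistics as TSV
#'
#' @param gwas data.frame from [simulate_gwas()] (columns `variant_id`,
#'   `chrom`, `pos`, `beta`, `se`, `p`, `n`).
#' @param path File path.
#' @export
write_gwas_tsv <- function(gwas, path) {
  write.table(gwas, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gwas_tsv
#' @export
read_gwas_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
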