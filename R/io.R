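#' Write a matrix as TSV with a leading identifier column
#'
#' @param mat matrix with row names.
#' @param path output path.
#' @param id_col name of the identifier column (default "gene").
#' @export
write_tsv_matrix <- function(mat, path, id_col = "gene") {
  df <- data.frame(rownames(mat), as.data.frame(unclass(mat)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV matrix written by \code{\link{write_tsv_matrix}}
#'
#' @param path input path.
#' @return numeric matrix with row names from the first column.
#' @export
read_tsv_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write a single-cell reference as MTX plus annotation TSVs
#'
#' Writes \code{<prefix>.mtx} (sparse counts), \code{<prefix>_genes.tsv}
#' (gene, mito_flag) and \code{<prefix>_cells.tsv} (cell, cell_type).
#'
#' @param reference an \code{nd_reference}.
#' @param prefix output path prefix.
#' @export
write_reference_mtx <- function(reference, prefix) {
  m <- Matrix::Matrix(reference$counts, sparse = TRUE)
  Matrix::writeMM(m, paste0(prefix, ".mtx"))
  write.table(data.frame(gene = rownames(reference$counts),
                         mito_flag = reference$mito_flag),
              paste0(prefix, "_genes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(cell = colnames(reference$counts),
                         cell_type = reference$cell_type),
              paste0(prefix, "_cells.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(prefix)
}

#' Write a bulk cohort (counts, metadata, truth) as TSVs
#'
#' @param bulk an \code{nd_bulk}.
#' @param prefix output path prefix.
#' @export
write_bulk_tsv <- function(bulk, prefix) {
  write_tsv_matrix(bulk$counts, paste0(prefix, "_counts.tsv"))
  write.table(bulk$metadata, paste0(prefix, "_metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(bulk$true_fractions))
    write_tsv_matrix(bulk$true_fractions,
                     paste0(prefix, "_true_fractions.tsv"), id_col = "sample")
  if (!is.null(bulk$truth))
    write.table(bulk$truth, paste0(prefix, "_truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' Write a simulation configuration as YAML
#'
#' Scalar and small-vector fields only; the materialised per-gene tables are
#' reproducible from the seed.
#'
#' @param config an \code{nd_config}.
#' @param path output path.
#' @export
write_config_yaml <- function(config, path) {
  keep <- c("n_genes", "cell_types", "n_cells_per_type", "mrna_content",
            "dispersion", "composition_concentration", "sc_depth",
            "bulk_depth", "frac_degenerate", "n_mislabeled", "seed")
  yaml::write_yaml(lapply(config[keep], function(x)
    if (is.numeric(x)) unname(x) else x), path)
  invisible(path)
}
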