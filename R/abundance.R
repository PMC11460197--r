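#' Protein-by-sample abundance matrix
#'
#' The central container of the package: a numeric matrix of protein
#' intensities (rows = proteins, columns = samples) with explicit missing
#' values (`NA`), a per-protein gene symbol annotation, and a scale state
#' recording which transformations have been applied.
#'
#' @param values Numeric matrix. Row names are protein identifiers (e.g.
#'   UniProt accessions) and must be unique; column names are sample
#'   identifiers and must be unique. Missing measurements are `NA`.
#' @param gene_symbols Character vector of gene symbols, one per row.
#'   Symbols may repeat (proteoforms such as APOE4 are distinct rows).
#'   Defaults to the row names.
#' @param scale One of `"raw"`, `"scaled"`, `"log2"`, `"corrected"`.
#'   Raw and scaled values must be non-negative where observed.
#'
#' @return An object of class `AbundanceMatrix`: a list with elements
#'   `values`, `gene_symbols` (named by protein id) and `scale`.
#' @export
abundance_matrix <- function(values, gene_symbols = NULL,
                             scale = c("raw", "scaled", "log2", "corrected")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have row (protein) and column (sample) names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate protein ids in matrix rows")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids in matrix columns")
  if (is.null(gene_symbols)) gene_symbols <- rownames(values)
  if (length(gene_symbols) != nrow(values))
    stop("`gene_symbols` must have one entry per protein row")
  gene_symbols <- stats::setNames(as.character(gene_symbols), rownames(values))
  if (scale %in% c("raw", "scaled")) {
    v <- values[!is.na(values)]
    if (length(v) && any(v < 0))
      stop("raw/scaled intensities must be non-negative")
  }
  structure(list(values = values, gene_symbols = gene_symbols, scale = scale),
            class = "AbundanceMatrix")
}

#' @export
print.AbundanceMatrix <- function(x, ...) {
  cat(sprintf("AbundanceMatrix: %d proteins x %d samples [%s scale], %.1f%% missing\n",
              nrow(x$values), ncol(x$values), x$scale,
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @rdname abundance_matrix
#' @param x An `AbundanceMatrix`.
#' @export
is_abundance_matrix <- function(x) inherits(x, "AbundanceMatrix")

#' Subset an AbundanceMatrix by proteins and/or samples
#'
#' @param x An `AbundanceMatrix`.
#' @param proteins,samples Character or logical/integer indices; `NULL`
#'   keeps everything.
#' @return An `AbundanceMatrix` on the same scale.
#' @export
am_subset <- function(x, proteins = NULL, samples = NULL) {
  stopifnot(is_abundance_matrix(x))
  v <- x$values
  if (!is.null(proteins)) v <- v[proteins, , drop = FALSE]
  if (!is.null(samples))  v <- v[, samples, drop = FALSE]
  abundance_matrix(v, x$gene_symbols[rownames(v)], scale = x$scale)
}

# internal: replace the value matrix, optionally moving to a new scale
am_with_values <- function(x, values, scale = x$scale) {
  abundance_matrix(values, x$gene_symbols[rownames(values)], scale = scale)
}

#' Validate that metadata covers a matrix
#'
#' Checks that every sample column of `matrix` has a metadata row and that
#' required columns exist.
#'
#' @param matrix An `AbundanceMatrix`.
#' @param metadata A data frame with at least a `sample_id` column.
#' @param required Character vector of metadata columns that must exist.
#' @return Invisibly, the metadata rows aligned to the matrix columns.
#' @export
check_metadata <- function(matrix, metadata,
                           required = c("sample_id", "set", "batch", "is_gis",
                                        "diagnosis")) {
  missing_cols <- setdiff(required, names(metadata))
  if (length(missing_cols))
    stop("metadata lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  idx <- match(colnames(matrix$values), metadata$sample_id)
  if (anyNA(idx))
    stop("samples missing from metadata: ",
         paste(colnames(matrix$values)[is.na(idx)], collapse = ", "))
  invisible(metadata[idx, , drop = FALSE])
}
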