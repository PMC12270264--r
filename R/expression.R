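#' Construct an expression dataset
#'
#' Bundles a genes-by-samples expression matrix with a phenotype label per
#' sample. This is the input container for network estimation and the full
#' enrichment pipeline.
#'
#' @param values Numeric matrix, rows = genes, columns = samples. Row names
#'   (gene identifiers) and column names (sample identifiers) are required
#'   unless given explicitly.
#' @param phenotype Character or factor vector of phenotype labels, one per
#'   sample (column).
#' @param gene_ids,sample_ids Optional identifier vectors overriding the
#'   dimnames of `values`.
#'
#' @return An object of class `"gbnea_expression"`: a list with elements
#'   `values` (matrix with dimnames), `gene_ids`, `sample_ids`, `phenotype`
#'   (character, named by sample).
#' @export
expression_dataset <- function(values, phenotype, gene_ids = NULL,
                               sample_ids = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (is.null(gene_ids)) gene_ids <- rownames(values)
  if (is.null(sample_ids)) sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("gene and sample identifiers are required")
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values))
    stop("length of gene_ids must equal the number of rows")
  if (length(sample_ids) != ncol(values))
    stop("length of sample_ids must equal the number of columns")
  if (anyDuplicated(gene_ids)) stop("gene identifiers must be unique")
  if (anyDuplicated(sample_ids)) stop("sample identifiers must be unique")
  if (any(!is.finite(values)))
    stop("expression values must be finite (no NA/NaN/Inf)")
  phenotype <- as.character(phenotype)
  if (length(phenotype) != length(sample_ids))
    stop("one phenotype label per sample is required")
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(list(values = values, gene_ids = gene_ids,
                 sample_ids = sample_ids,
                 phenotype = setNames(phenotype, sample_ids)),
            class = "gbnea_expression")
}

#' @export
print.gbnea_expression <- function(x, ...) {
  cat("Expression dataset:", length(x$gene_ids), "genes x",
      length(x$sample_ids), "samples\n")
  tab <- table(x$phenotype)
  cat("Phenotypes:", paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
                           collapse = ", "), "\n")
  invisible(x)
}

# Columns of the expression matrix belonging to one phenotype.
phenotype_samples <- function(data, label) {
  stopifnot(inherits(data, "gbnea_expression"))
  idx <- which(data$phenotype == label)
  if (length(idx) == 0L)
    stop(sprintf("phenotype '%s' not present in the dataset", label))
  idx
}

#' Per-gene mean expression within one phenotype
#'
#' Arithmetic mean over the samples carrying `label`, on the same expression
#' scale used for network fitting. These means enter the regulatory-effect
#' statistic.
#'
#' @param data A [expression_dataset()].
#' @param label Phenotype label.
#' @return Named numeric vector over the gene universe.
#' @export
phenotype_means <- function(data, label) {
  idx <- phenotype_samples(data, label)
  rowMeans(data$values[, idx, drop = FALSE])
}
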