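#' Expression study container
#'
#' Genes x samples matrix of positive expression values (linear scale, as
#' produced by RMA summarization and exponentiation) plus per-gene
#' annotation flags and per-sample metadata: hybridization plate, sample
#' type, replicate group and baseline designation.
#'
#' @param expression Numeric matrix, genes x samples, strictly positive,
#'   with gene ids as row names and sample ids as column names.
#' @param samples Data frame with columns `sample_id`, `plate` (1 or 2),
#'   `sample_type` (one of `"baseline_GFP"`, `"baseline_mCh"`, `"MFP"`,
#'   `"AxLN"`, `"AxLN_LuM"` by default, but any labels are accepted),
#'   `replicate_group`, `is_baseline` (logical).
#' @param genes Optional data frame with columns `gene_id`,
#'   `symbol_present`, `protein_coding`; defaults to all-`TRUE` flags.
#' @return An object of class `"expression_study"`.
#' @export
expression_study <- function(expression, samples, genes = NULL) {
  expression <- as.matrix(expression)
  if (is.null(rownames(expression)) || is.null(colnames(expression)))
    stop("'expression' needs gene row names and sample column names")
  if (!is.numeric(expression) || any(!is.finite(expression)) ||
      any(expression <= 0))
    stop("expression values must be finite and strictly positive")
  req <- c("sample_id", "plate", "sample_type", "replicate_group",
           "is_baseline")
  if (!all(req %in% names(samples)))
    stop("'samples' must have columns: ", paste(req, collapse = ", "))
  if (!setequal(samples$sample_id, colnames(expression)))
    stop("sample ids in metadata and expression matrix differ")
  samples <- samples[match(colnames(expression), samples$sample_id), ]
  rownames(samples) <- NULL
  if (is.null(genes))
    genes <- data.frame(gene_id = rownames(expression),
                        symbol_present = TRUE, protein_coding = TRUE,
                        stringsAsFactors = FALSE)
  if (!setequal(genes$gene_id, rownames(expression)))
    stop("gene ids in annotation and expression matrix differ")
  genes <- genes[match(rownames(expression), genes$gene_id), ]
  rownames(genes) <- NULL
  structure(list(expression = expression, samples = samples, genes = genes),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat("<expression_study>", nrow(x$expression), "genes x",
      ncol(x$expression), "samples\n")
  print(table(plate = x$samples$plate, type = x$samples$sample_type))
  invisible(x)
}

# sample ids of one sample type (experimental samples only unless told
# otherwise)
.type_samples <- function(study, type) {
  study$samples$sample_id[study$samples$sample_type == type]
}

.baseline_samples <- function(study) {
  study$samples$sample_id[study$samples$is_baseline]
}
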