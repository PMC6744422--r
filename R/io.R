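#' Write / read a mutation profile table as TSV
#'
#' Canonical interchange format for one patient's mutation calls: a
#' tab-delimited table with variant ids in the first column, one column per
#' sample, and a second header line (prefixed `#roles`) carrying the sample
#' roles.
#'
#' @param mp A [mutation_profile_set()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_mutation_tsv <- function(mp, path) {
  stopifnot(inherits(mp, "mutation_profile_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("variant_id", colnames(mp$weights)), collapse = "\t"),
             con)
  writeLines(paste(c("#roles", mp$samples$role), collapse = "\t"), con)
  utils::write.table(
    cbind(variant_id = rownames(mp$weights), as.data.frame(mp$weights)),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' @param path TSV file as written by [write_mutation_tsv()], or any TSV
#'   with a `variant_id` column and sample columns.
#' @param roles Named character vector or data frame
#'   (`sample_id`, `role`, optionally `site_label`, `purity_ok`) supplying
#'   roles when the file has no `#roles` line.
#' @param patient_id Patient id to record.
#' @rdname write_mutation_tsv
#' @export
read_mutation_table <- function(path, roles = NULL, patient_id = NULL) {
  lines <- readLines(path, n = 2L)
  if (!length(lines)) stop("empty file: ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (header[1] != "variant_id")
    stop("line 1: expected 'variant_id' as first column, got '",
         header[1], "'")
  sample_ids <- header[-1]
  skip <- 1L
  file_roles <- NULL
  if (length(lines) > 1L && startsWith(lines[2], "#roles")) {
    rl <- strsplit(lines[2], "\t", fixed = TRUE)[[1]][-1]
    if (length(rl) != length(sample_ids))
      stop("line 2: #roles line has ", length(rl), " entries for ",
           length(sample_ids), " samples")
    file_roles <- stats::setNames(rl, sample_ids)
    skip <- 2L
  }
  tab <- utils::read.delim(path, skip = skip, header = FALSE,
                           col.names = header, check.names = FALSE,
                           colClasses = c("character",
                                          rep("numeric",
                                              length(sample_ids))))
  if (anyDuplicated(tab$variant_id)) {
    dup <- which(duplicated(tab$variant_id))[1]
    stop("line ", dup + skip, ": duplicate variant id '",
         tab$variant_id[dup], "'")
  }
  w <- as.matrix(tab[, -1, drop = FALSE])
  rownames(w) <- tab$variant_id
  info <- .resolve_roles(file_roles, roles, sample_ids)
  if (is.null(patient_id))
    patient_id <- sub("\\.[^.]*$", "", basename(path))
  mutation_profile_set(patient_id, w, info$roles,
                       site_label = info$site_label,
                       purity_ok = info$purity_ok)
}

.resolve_roles <- function(file_roles, roles, sample_ids) {
  site_label <- NULL
  purity_ok <- NULL
  if (is.data.frame(roles)) {
    if (!all(c("sample_id", "role") %in% names(roles)))
      stop("roles data frame needs 'sample_id' and 'role' columns")
    if ("site_label" %in% names(roles))
      site_label <- stats::setNames(roles$site_label, roles$sample_id)
    if ("purity_ok" %in% names(roles))
      purity_ok <- stats::setNames(as.logical(roles$purity_ok),
                                   roles$sample_id)
    roles <- stats::setNames(roles$role, roles$sample_id)
  }
  if (is.null(roles)) roles <- file_roles
  if (is.null(roles))
    stop("no sample roles: file carries no #roles line and none supplied")
  list(roles = roles, site_label = site_label, purity_ok = purity_ok)
}

#' Read / write sample-role metadata TSV
#'
#' @param mp A [mutation_profile_set()].
#' @param path TSV with columns `sample_id`, `role`, and optionally
#'   `site_label`, `purity_ok`.
#' @return For the reader, the metadata data frame; for the writer, `path`.
#' @export
read_roles_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "role") %in% names(df)))
    stop("roles TSV needs 'sample_id' and 'role' columns")
  df
}

#' @rdname read_roles_tsv
#' @export
write_roles_tsv <- function(mp, path) {
  utils::write.table(mp$samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write / read a minimal VCF of binary mutation calls
#'
#' Deliberately minimal VCF support: one patient per file, samples as
#' genotype columns, placeholder contig/position/alleles, genotype `0/1`
#' for a present call and `./.` for absence. Reading maps any genotype
#' containing a `1` allele to presence (weight 1) and everything else
#' (including `./.`) to 0. Roles are not representable in VCF and must be
#' supplied separately when reading.
#'
#' @param mp A [mutation_profile_set()] with binary weights.
#' @param path File path (uncompressed `.vcf`).
#' @return `path`, invisibly.
#' @export
write_mutation_vcf <- function(mp, path) {
  stopifnot(inherits(mp, "mutation_profile_set"))
  w <- mp$weights
  gt <- ifelse(w > 0, "0/1", "./.")
  body <- cbind("chr1", seq_len(nrow(w)), rownames(w), "A", "T", ".",
                "PASS", ".", "GT", gt)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(w)), collapse = "\t")
  ), con)
  utils::write.table(body, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @param roles Sample roles (named vector or roles data frame), required.
#' @inheritParams read_mutation_table
#' @rdname write_mutation_vcf
#' @export
read_mutation_vcf <- function(path, roles, patient_id = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt) || !ncol(gt)) stop("VCF has no genotype columns")
  ids <- vcfR::getID(v)
  if (anyNA(ids) || anyDuplicated(ids))
    ids <- sprintf("%s_%s", vcfR::getCHROM(v), vcfR::getPOS(v))
  w <- matrix(0, nrow(gt), ncol(gt), dimnames = list(ids, colnames(gt)))
  w[!is.na(gt) & grepl("1", gt)] <- 1
  info <- .resolve_roles(NULL, roles, colnames(gt))
  if (is.null(patient_id))
    patient_id <- sub("\\.[^.]*$", "", basename(path))
  mutation_profile_set(patient_id, w, info$roles,
                       site_label = info$site_label,
                       purity_ok = info$purity_ok)
}

#' Write / read an expression study as TSV files
#'
#' Three tab-delimited files: the expression matrix (first column
#' `gene_id`), the sample metadata (`sample_id`, `plate`, `sample_type`,
#' `replicate_group`, `is_baseline`), and optionally the gene annotation
#' flags (`gene_id`, `symbol_present`, `protein_coding`).
#'
#' @param study An [expression_study()].
#' @param expr_path,meta_path,genes_path File paths; `genes_path` may be
#'   `NULL`.
#' @return The expression-file path, invisibly.
#' @export
write_expression_study <- function(study, expr_path, meta_path,
                                   genes_path = NULL) {
  stopifnot(inherits(study, "expression_study"))
  utils::write.table(
    cbind(gene_id = rownames(study$expression),
          as.data.frame(study$expression)),
    expr_path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(study$samples, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(genes_path))
    utils::write.table(study$genes, genes_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(expr_path)
}

#' @param log2_input Declare the expression file to be on the log2 scale;
#'   values are exponentiated (`2^x`) on read. Without this flag,
#'   non-positive values are an error.
#' @rdname write_expression_study
#' @export
read_expression_study <- function(expr_path, meta_path, genes_path = NULL,
                                  log2_input = FALSE) {
  tab <- utils::read.delim(expr_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(tab)[1] != "gene_id")
    stop("expression TSV must start with a 'gene_id' column")
  x <- as.matrix(tab[, -1, drop = FALSE])
  rownames(x) <- tab$gene_id
  if (log2_input) x <- 2^x
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  missing <- setdiff(colnames(x), meta$sample_id)
  extra <- setdiff(meta$sample_id, colnames(x))
  if (length(missing) || length(extra))
    stop("sample id mismatch between expression and metadata; ",
         if (length(missing)) paste("missing from metadata:",
                                    paste(missing, collapse = ", ")),
         if (length(extra)) paste(" absent from matrix:",
                                  paste(extra, collapse = ", ")))
  genes <- if (!is.null(genes_path))
    utils::read.delim(genes_path, stringsAsFactors = FALSE) else NULL
  expression_study(x, meta, genes)
}

#' Write a seeding call as JSON
#'
#' Serializes the classification, per-sample distance ratios, bootstrap
#' confidence and seed. Ratios and confidence are written with 6
#' significant digits.
#'
#' @param call A `"seeding_call"`.
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_seeding_call <- function(call, path) {
  stopifnot(inherits(call, "seeding_call"))
  obj <- list(
    patient_id = call$patient_id,
    classification = call$classification,
    ln_ratios = as.list(signif(call$ln_ratios, 6)),
    met_ratios = as.list(signif(call$met_ratios, 6)),
    confidence = if (is.na(call$confidence)) NULL
                 else signif(call$confidence, 6),
    n_bootstrap = call$n_bootstrap,
    seed = call$seed
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Write trees in newick format
#'
#' @param call A `"seeding_call"` (carries the unrooted and rooted trees).
#' @param unrooted_path,rooted_path Output files; either may be `NULL`.
#' @return Invisibly, the paths written.
#' @export
write_trees <- function(call, unrooted_path = NULL, rooted_path = NULL) {
  stopifnot(inherits(call, "seeding_call"))
  if (!is.null(unrooted_path)) ape::write.tree(call$tree, unrooted_path)
  if (!is.null(rooted_path)) ape::write.tree(call$rooted, rooted_path)
  invisible(c(unrooted_path, rooted_path))
}

#' Write a pattern table (and the clustered matrix) as TSV
#'
#' @param pattern_table A `"pattern_table"`.
#' @param path Output TSV. P-values are written at full precision.
#' @return `path`, invisibly.
#' @export
write_pattern_table <- function(pattern_table, path) {
  utils::write.table(as.data.frame(pattern_table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a clustered, centered submatrix in a CDT-like layout
#'
#' @param split_result Output of [cluster_and_split()].
#' @param path Output TSV: gene, pattern, half, then the log2 centered
#'   values in clustered row order.
#' @return `path`, invisibly.
#' @export
write_cdt <- function(split_result, path) {
  x <- attr(split_result, "centered")
  out <- cbind(split_result[, c("gene", "pattern", "half")],
               as.data.frame(signif(x, 6)))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one term per line, tab-delimited, `term<TAB>description`
#' then member genes.
#'
#' @param path GMT file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE))
    return(fgsea::gmtPathways(path))
  lines <- strsplit(readLines(path), "\t", fixed = TRUE)
  stats::setNames(lapply(lines, function(x) x[-(1:2)]),
                  vapply(lines, `[`, "", 1L))
}
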