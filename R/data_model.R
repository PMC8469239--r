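# ---- ExpressionMatrix ------------------------------------------------------

#' Construct a validated FPKM expression matrix
#'
#' Container for a non-negative gene-by-sample FPKM matrix. All downstream
#' stages (embedding, random-forest ranking, group comparisons) consume this
#' type rather than bare matrices, so validation happens once, at the edge.
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#' @param gene_ids character vector of unique gene (or transcript) ids,
#'   one per row. Ids are treated as opaque strings; Ensembl version
#'   suffixes are kept unless `strip_versions = TRUE`.
#' @param sample_ids character vector of unique sample ids, one per column.
#' @param log_transformed logical flag recording whether `values` are
#'   already on the log2(FPKM + 1) scale. [log_transform()] refuses to run
#'   twice on the same object.
#' @param strip_versions drop a trailing ".N" Ensembl version from gene ids.
#' @return an object of class `ExpressionMatrix` (list with `values`,
#'   `gene_ids`, `sample_ids`, `log_transformed`).
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values),
                              log_transformed = FALSE,
                              strip_versions = FALSE) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("gene_ids and sample_ids are required (rownames/colnames or explicit)")
  }
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (strip_versions) gene_ids <- sub("\\.\\d+$", "", gene_ids)
  if (length(gene_ids) != nrow(values)) {
    stop("length(gene_ids) != nrow(values)")
  }
  if (length(sample_ids) != ncol(values)) {
    stop("length(sample_ids) != ncol(values)")
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene ids: ", paste(unique(gene_ids[duplicated(gene_ids)])[1:3], collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ", paste(unique(sample_ids[duplicated(sample_ids)])[1:3], collapse = ", "))
  }
  bad <- which(!is.finite(values) | values < 0)
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(values))
    stop(sprintf(
      "invalid expression value %s at gene '%s', sample '%s' (must be finite and >= 0)",
      format(values[bad[1]]), gene_ids[i[1]], sample_ids[i[2]]
    ))
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(
    list(values = values, gene_ids = gene_ids, sample_ids = sample_ids,
         log_transformed = isTRUE(log_transformed)),
    class = "ExpressionMatrix"
  )
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf(
    "ExpressionMatrix: %d genes x %d samples (%s scale)\n",
    nrow(x$values), ncol(x$values),
    if (x$log_transformed) "log2(FPKM+1)" else "FPKM"
  ))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Read an FPKM expression table from TSV
#'
#' Expects a strict dialect: tab-separated, UTF-8, "." decimal, one header
#' row of ids and a first id column. Any negative, missing or non-numeric
#' cell is an error naming the offending row and column — no silent
#' coercion.
#'
#' @param path TSV file path.
#' @param orientation `"genes_in_rows"` (default) or `"samples_in_rows"`;
#'   the returned object is always genes x samples.
#' @param strip_versions see [expression_matrix()].
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path,
                            orientation = c("genes_in_rows", "samples_in_rows"),
                            strip_versions = FALSE) {
  orientation <- match.arg(orientation)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", fileEncoding = "UTF-8")
  if (ncol(df) < 2) stop("expression TSV needs an id column plus >= 1 data column: ", path)
  row_ids <- df[[1]]
  mat <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(mat), dim = dim(mat)))
  bad <- which(is.na(num) & !is.na(mat))
  if (length(bad) || anyNA(num)) {
    first <- if (length(bad)) bad[1] else which(is.na(num))[1]
    i <- arrayInd(first, dim(num))
    stop(sprintf("non-numeric or missing value '%s' at row '%s', column '%s' in %s",
                 mat[first], row_ids[i[1]], colnames(mat)[i[2]], path))
  }
  dimnames(num) <- list(row_ids, colnames(mat))
  if (orientation == "samples_in_rows") num <- t(num)
  expression_matrix(num, strip_versions = strip_versions)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression()]: `read(write(x))` round-trips ids exactly
#' and values to full double precision.
#'
#' @param x an `ExpressionMatrix`.
#' @param path output path.
#' @param id_column header name of the id column.
#' @export
write_expression <- function(x, path, id_column = "gene_id") {
  stopifnot(inherits(x, "ExpressionMatrix"))
  df <- data.frame(id = x$gene_ids, x$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

# ---- ClinicalTable and MutationTable ---------------------------------------

.clinical_groups <- c("NAG", "EIA", "MACS-CPA", "CS-CPA", "ACC", "UNKNOWN")

#' Construct a clinical table
#'
#' One row per sample: overall-survival time in years, a binary death
#' indicator, and a tissue group label (normal adrenal gland, the benign
#' adenoma entities, carcinoma, or UNKNOWN).
#'
#' @param sample_id unique sample ids.
#' @param os_time overall survival (or follow-up) time, years, > 0; NA allowed.
#' @param event 1 = death observed, 0 = censored; NA allowed.
#' @param group tissue group, one of NAG, EIA, MACS-CPA, CS-CPA, ACC, UNKNOWN.
#' @return a `data.frame` of class `ClinicalTable`.
#' @export
clinical_table <- function(sample_id, os_time, event,
                           group = rep("UNKNOWN", length(sample_id))) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) stop("duplicate sample ids in clinical table")
  os_time <- as.numeric(os_time)
  event <- as.numeric(event)
  if (any(!is.na(os_time) & (os_time <= 0 | !is.finite(os_time)))) {
    stop("os_time must be finite and > 0 where present")
  }
  if (any(!is.na(event) & !event %in% c(0, 1))) stop("event must be 0 or 1")
  group <- as.character(group)
  bad <- setdiff(unique(group), .clinical_groups)
  if (length(bad)) stop("unknown tissue group(s): ", paste(bad, collapse = ", "))
  structure(
    data.frame(sample_id = sample_id, os_time = os_time, event = event,
               group = group, stringsAsFactors = FALSE),
    class = c("ClinicalTable", "data.frame")
  )
}

#' Read a clinical TSV (sample_id, os_time, event, group)
#' @param path TSV path with header columns `sample_id`, `os_time`, `event`,
#'   `group`.
#' @return a [clinical_table()].
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("sample_id", "os_time", "event", "group")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("clinical TSV missing column(s): ", paste(miss, collapse = ", "))
  clinical_table(df$sample_id, df$os_time, df$event, df$group)
}

#' Write a clinical table as TSV
#' @param x a `ClinicalTable`. @param path output path.
#' @export
write_clinical <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Construct a long-format binary mutation table
#'
#' @param sample_id,gene id columns; the (sample, gene) pair must be unique.
#' @param mutated 0/1 mutation status.
#' @return a `data.frame` of class `MutationTable`.
#' @export
mutation_table <- function(sample_id, gene, mutated) {
  sample_id <- as.character(sample_id); gene <- as.character(gene)
  mutated <- as.numeric(mutated)
  if (any(!mutated %in% c(0, 1))) stop("mutated must be 0 or 1")
  if (anyDuplicated(paste(sample_id, gene, sep = "\r"))) {
    stop("duplicate (sample_id, gene) pairs in mutation table")
  }
  structure(
    data.frame(sample_id = sample_id, gene = gene, mutated = mutated,
               stringsAsFactors = FALSE),
    class = c("MutationTable", "data.frame")
  )
}

#' Read a mutation-status TSV (sample_id, gene, mutated)
#' @param path TSV path.
#' @return a [mutation_table()].
#' @export
read_mutations <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("sample_id", "gene", "mutated")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("mutation TSV missing column(s): ", paste(miss, collapse = ", "))
  mutation_table(df$sample_id, df$gene, df$mutated)
}

#' Write a mutation table as TSV
#' @param x a `MutationTable`. @param path output path.
#' @export
write_mutations <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

# ---- transforms and alignment ----------------------------------------------

#' log2(FPKM + 1) transform
#'
#' The embedding stage consumes log-scale expression while the
#' random-forest stage consumes raw FPKM; this function performs the
#' conventional bulk RNA-seq log2(v + 1) transform and marks the object so
#' an accidental second application is refused rather than silently
#' compounding.
#'
#' @param x an `ExpressionMatrix` on the FPKM scale.
#' @return an `ExpressionMatrix` with `log_transformed = TRUE`.
#' @export
log_transform <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (x$log_transformed) {
    stop("matrix is already log-transformed; refusing to apply log2(v+1) twice")
  }
  expression_matrix(log2(x$values + 1), x$gene_ids, x$sample_ids,
                    log_transformed = TRUE)
}

#' Align expression, clinical and mutation tables on shared samples
#'
#' Takes the intersection of sample ids across the inputs, preserving the
#' expression matrix's sample order, and reports every id dropped from each
#' table. Row order of the clinical and mutation inputs never affects the
#' result.
#'
#' @param x `ExpressionMatrix`.
#' @param clinical optional `ClinicalTable`.
#' @param mutations optional `MutationTable`.
#' @return list with the subset `expression`, `clinical`, `mutations`
#'   (NULL where not given), `sample_ids` (retained, in expression order)
#'   and `dropped` (named list of ids removed from each input).
#' @export
align_cohort <- function(x, clinical = NULL, mutations = NULL) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  keep <- x$sample_ids
  if (!is.null(clinical)) keep <- keep[keep %in% clinical$sample_id]
  if (!is.null(mutations)) keep <- keep[keep %in% unique(mutations$sample_id)]
  if (!length(keep)) stop("no sample ids shared across the supplied tables")
  dropped <- list(
    expression = setdiff(x$sample_ids, keep),
    clinical = if (is.null(clinical)) character(0) else setdiff(clinical$sample_id, keep),
    mutations = if (is.null(mutations)) character(0) else setdiff(unique(mutations$sample_id), keep)
  )
  expr <- expression_matrix(x$values[, keep, drop = FALSE], x$gene_ids, keep,
                            log_transformed = x$log_transformed)
  clin <- if (is.null(clinical)) NULL else {
    cl <- clinical[match(keep, clinical$sample_id), , drop = FALSE]
    rownames(cl) <- NULL
    cl
  }
  mut <- if (is.null(mutations)) NULL else {
    mt <- mutations[mutations$sample_id %in% keep, , drop = FALSE]
    mt <- mt[order(match(mt$sample_id, keep), mt$gene), , drop = FALSE]
    rownames(mt) <- NULL
    mt
  }
  list(expression = expr, clinical = clin, mutations = mut,
       sample_ids = keep, dropped = dropped)
}
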