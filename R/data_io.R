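#' Read a gene-by-sample expression matrix from TSV
#'
#' Expects a tab-separated file whose first row holds sample identifiers
#' (first column header is the gene-id column, conventionally `gene_id`)
#' and whose first column holds gene identifiers. Values must be numeric
#' on log scale (typically RMA-normalized). Duplicate gene rows are
#' collapsed by their mean with a warning; rows containing missing values
#' (`NA` or empty cells) are dropped and their count reported.
#'
#' @param path Path to a tab-separated expression file.
#' @return A numeric matrix, genes in rows, samples in columns, with
#'   gene/sample identifiers as dimnames.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L) stop("empty expression file: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0L || ncol(raw) < 2L) {
    stop("expression file has no data rows/samples: ", path, call. = FALSE)
  }
  gene_ids <- raw[[1L]]
  sample_ids <- colnames(raw)[-1L]
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample identifiers in header of ", path, call. = FALSE)
  }
  body <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body),
                                 dimnames = list(gene_ids, sample_ids)))
  # distinguish declared-missing cells (NA, empty) from unparsable tokens
  missing_token <- body == "" | toupper(body) == "NA"
  bad <- which(is.na(num) & !missing_token, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s' in %s",
                 body[bad[1L, 1L], bad[1L, 2L]], gene_ids[bad[1L, 1L]],
                 sample_ids[bad[1L, 2L]], path), call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) {
    warning(sprintf("collapsing %d duplicate gene rows by mean",
                    sum(duplicated(gene_ids))), call. = FALSE)
    num <- rowsum(num, group = gene_ids, reorder = FALSE) /
      as.vector(table(factor(gene_ids, levels = unique(gene_ids))))
    rownames(num) <- unique(gene_ids)
  }
  incomplete <- rowSums(is.na(num)) > 0L
  if (any(incomplete)) {
    message(sprintf("dropped %d gene rows with missing values",
                    sum(incomplete)))
    num <- num[!incomplete, , drop = FALSE]
  }
  assert_expression_matrix(num, "matrix")
  num
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression_matrix()]: first column `gene_id`, header
#' row of sample identifiers, full double precision.
#'
#' @param m Numeric gene-by-sample matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path) {
  assert_expression_matrix(m)
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample annotation table
#'
#' Tab-separated, with columns `sample_id` and `response` (values `CR`
#' for chemotherapy-sensitive, `NOCR` for resistant) and optional
#' `subtype` and `cohort` columns.
#'
#' @param path Path to annotation TSV.
#' @return A data frame with columns `sample_id`, `response`, `subtype`,
#'   `cohort`.
#' @export
read_sample_annotation <- function(path) {
  ann <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("sample_id", "response") %in% colnames(ann))) {
    stop("annotation must have sample_id and response columns", call. = FALSE)
  }
  if (anyDuplicated(ann$sample_id)) {
    stop("duplicate sample_id in annotation", call. = FALSE)
  }
  if (is.null(ann$subtype)) ann$subtype <- ""
  if (is.null(ann$cohort)) ann$cohort <- "discovery"
  ann[, c("sample_id", "response", "subtype", "cohort")]
}

#' Write a sample annotation table
#' @param ann Annotation data frame (see [read_sample_annotation()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_annotation <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Z-score expression rows across samples
#'
#' Centers and scales every gene row to mean 0 and unit sample standard
#' deviation (n - 1 denominator) across all samples of the matrix.
#' Zero-variance genes cannot be scaled and are dropped with a message.
#'
#' @param m Numeric gene-by-sample matrix.
#' @return The z-scored matrix (possibly with fewer rows).
#' @export
zscore_normalize <- function(m) {
  assert_expression_matrix(m)
  if (ncol(m) < 2L) stop("z-scoring needs at least 2 samples", call. = FALSE)
  sds <- row_sds(m)
  keep <- sds > 0
  if (!all(keep)) {
    message(sprintf("dropped %d zero-variance genes during z-scoring",
                    sum(!keep)))
  }
  m <- m[keep, , drop = FALSE]
  (m - rowMeans(m)) / sds[keep]
}

#' Read gene sets in GMT format
#'
#' Each line: set name, description, then one or more gene identifiers,
#' tab-separated. Genes are deduplicated within a set.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors (pathway name -> gene ids).
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop(sprintf("GMT line %d has fewer than 3 fields", which(nf < 3L)[1L]),
         call. = FALSE)
  }
  names_ <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(names_)) {
    stop("duplicate pathway names in GMT: ",
         paste(unique(names_[duplicated(names_)]), collapse = ", "),
         call. = FALSE)
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  stats::setNames(sets, names_)
}

#' Write gene sets to GMT format
#' @param pathways Named list of gene-id character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of descriptions.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(pathways, path, descriptions = NULL) {
  descriptions <- descriptions %||% rep("na", length(pathways))
  lines <- mapply(function(nm, desc, genes) {
    paste(c(nm, desc, genes), collapse = "\t")
  }, names(pathways), descriptions, pathways)
  writeLines(lines, path)
  invisible(path)
}

#' Read an undirected interaction edge list
#'
#' Two tab-separated gene-identifier columns per line. Self-loops are
#' removed; duplicate pairs (in either orientation) are collapsed, so the
#' result is orientation-invariant.
#'
#' @param path Path to the two-column TSV.
#' @param header Logical; skip a header line (default `FALSE`).
#' @return A two-column character matrix of unique unordered edges
#'   (columns `gene_a`, `gene_b`, with `gene_a` <= `gene_b`).
#' @export
read_interactions <- function(path, header = FALSE) {
  lines <- readLines(path, warn = FALSE)
  if (isTRUE(header) && length(lines) > 0L) lines <- lines[-1L]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(matrix(character(0), ncol = 2L,
                  dimnames = list(NULL, c("gene_a", "gene_b"))))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 2L)) {
    stop(sprintf("interaction line %d does not have exactly 2 fields",
                 which(nf != 2L)[1L] + as.integer(isTRUE(header))),
         call. = FALSE)
  }
  a <- vapply(fields, `[[`, "", 1L)
  b <- vapply(fields, `[[`, "", 2L)
  canonical_edges(a, b)
}

# canonical undirected edge matrix: sorted within pair, self-loops and
# duplicates removed
canonical_edges <- function(a, b) {
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  keep <- lo != hi & !duplicated(paste(lo, hi, sep = "\r"))
  matrix(c(lo[keep], hi[keep]), ncol = 2L,
         dimnames = list(NULL, c("gene_a", "gene_b")))
}

#' Write an interaction edge list to TSV
#' @param edges Two-column character matrix of edges.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
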