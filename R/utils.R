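# internal helpers shared across modules

# row-wise sample standard deviation (n - 1 denominator)
row_sds <- function(x) {
  n <- ncol(x)
  if (n < 2L) stop("row_sds() needs at least 2 columns", call. = FALSE)
  mu <- rowMeans(x)
  sqrt(rowSums((x - mu)^2) / (n - 1L))
}

# a numeric gene-by-sample matrix with unique dimnames
assert_expression_matrix <- function(m, arg = "m") {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop(sprintf("`%s` must be a numeric matrix (genes x samples)", arg),
         call. = FALSE)
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop(sprintf("`%s` must carry gene rownames and sample colnames", arg),
         call. = FALSE)
  }
  if (anyDuplicated(rownames(m))) {
    stop(sprintf("`%s` has duplicate gene identifiers", arg), call. = FALSE)
  }
  if (anyDuplicated(colnames(m))) {
    stop(sprintf("`%s` has duplicate sample identifiers", arg), call. = FALSE)
  }
  invisible(m)
}

# annotation lookup: one row per sample, response present where required
match_annotation <- function(sample_ids, annotation, require_response = TRUE) {
  idx <- match(sample_ids, annotation$sample_id)
  if (anyNA(idx)) {
    stop("samples without annotation: ",
         paste(sample_ids[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  ann <- annotation[idx, , drop = FALSE]
  if (require_response &&
      (anyNA(ann$response) || any(!ann$response %in% c("CR", "NOCR")))) {
    bad <- sample_ids[is.na(ann$response) | !ann$response %in% c("CR", "NOCR")]
    stop("missing or invalid response (expected CR/NOCR) for: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  ann
}

`%||%` <- function(a, b) if (is.null(a)) b else a
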