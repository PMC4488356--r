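# in-code fixtures shared across test files

# small deterministic expression matrix with dimnames
toy_matrix <- function(values, genes = NULL, samples = NULL) {
  m <- matrix(values$x, nrow = values$nrow, byrow = TRUE)
  rownames(m) <- genes %||% sprintf("g%d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("s%d", seq_len(ncol(m)))
  m
}
`%||%` <- function(a, b) if (is.null(a)) b else a

write_tsv_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# subgroup model built from the generator's planted subgroup labels
truth_model <- function(truth) {
  f <- factor(truth$sample_subgroup)
  assignment <- stats::setNames(as.integer(f), names(truth$sample_subgroup))
  structure(list(assignment = assignment, k = nlevels(f), tree = NULL),
            class = "subgroup_model")
}

# which model subgroup index corresponds to a planted subgroup label
model_group_of <- function(truth, label) {
  f <- factor(truth$sample_subgroup)
  which(levels(f) == label)
}
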