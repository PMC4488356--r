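#' Median-center an expression matrix
#'
#' Subtracts each gene row's median, then each sample column's median,
#' one pass each in that order (the Cluster 3.0 convention; the passes
#' are not iterated to convergence).
#'
#' @param m Gene-by-sample numeric matrix.
#' @return The double-centered matrix.
#' @export
median_center <- function(m) {
  assert_expression_matrix(m)
  m <- m - apply(m, 1L, stats::median)
  m - rep(apply(m, 2L, stats::median), each = nrow(m))
}

#' Centred-correlation distance between samples
#'
#' `d(a, b) = 1 - r(a, b)` where `r` is the Pearson correlation between
#' the two sample columns (vector means subtracted, i.e. the "centred
#' correlation" of Cluster 3.0).
#'
#' @param m Gene-by-sample numeric matrix (>= 2 samples, >= 2 genes).
#' @return A symmetric sample-by-sample distance matrix with zero
#'   diagonal; values lie in [0, 2].
#' @export
correlation_distance <- function(m) {
  assert_expression_matrix(m)
  if (ncol(m) < 2L) stop("need at least 2 samples", call. = FALSE)
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("constant sample column(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "), call. = FALSE)
  }
  d <- 1 - stats::cor(m)
  diag(d) <- 0
  d
}

#' Average-linkage (UPGMA) hierarchical clustering of samples
#'
#' @param d Symmetric distance matrix (e.g. from
#'   [correlation_distance()]).
#' @return An [stats::hclust] tree (merge history and heights).
#' @export
hierarchical_cluster <- function(d) {
  if (!is.matrix(d) || !isSymmetric(unname(d))) {
    stop("d must be a symmetric distance matrix", call. = FALSE)
  }
  if (any(diag(d) != 0) || any(d < 0)) {
    stop("d must have zero diagonal and non-negative entries",
         call. = FALSE)
  }
  stats::hclust(stats::as.dist(d), method = "average")
}

#' Cut a dendrogram into patient subgroups
#'
#' Cuts the tree into exactly `k` clusters; when `k` is `NULL`, `k` is
#' chosen from `2..min(10, n - 1)` by maximal mean silhouette width on
#' the supplied distance matrix.
#'
#' @param tree An [stats::hclust] tree.
#' @param k Number of subgroups, or `NULL` for silhouette-selected `k`.
#' @param d Distance matrix (required when `k` is `NULL`).
#' @return A list of class `subgroup_model` with `assignment` (named
#'   integer vector sample -> subgroup), `k`, and `tree`.
#' @export
cut_clusters <- function(tree, k = NULL, d = NULL) {
  stopifnot(inherits(tree, "hclust"))
  n <- length(tree$labels)
  if (is.null(k)) {
    if (is.null(d)) {
      stop("auto-k selection needs the distance matrix d", call. = FALSE)
    }
    ks <- seq(2L, min(10L, n - 1L))
    sil <- vapply(ks, function(kk) {
      cl <- stats::cutree(tree, k = kk)
      mean(cluster::silhouette(cl, stats::as.dist(d))[, "sil_width"])
    }, numeric(1))
    k <- ks[which.max(sil)]
  }
  if (k > n) stop("k cannot exceed the number of samples", call. = FALSE)
  assignment <- stats::cutree(tree, k = k)
  structure(list(assignment = assignment, k = as.integer(k), tree = tree),
            class = "subgroup_model")
}

#' Summarize phenotype composition of subgroups
#'
#' For each subgroup reports sample count, CR/NOCR counts, dominant
#' response and subtype labels (ties broken lexicographically with a
#' warning), and a resistant flag set when NOCR samples form a strict
#' majority (ties count as sensitive, with a warning).
#'
#' @param model A [cut_clusters()] `subgroup_model`.
#' @param annotation Sample annotation data frame.
#' @return A data frame with one row per subgroup: `subgroup`, `n`,
#'   `n_cr`, `n_nocr`, `dominant_response`, `dominant_subtype`,
#'   `resistant`.
#' @export
summarize_subgroups <- function(model, annotation) {
  stopifnot(inherits(model, "subgroup_model"))
  ids <- names(model$assignment)
  ann <- match_annotation(ids, annotation)
  dominant <- function(x) {
    x <- x[!is.na(x) & nzchar(x)]
    if (length(x) == 0L) return(NA_character_)
    tab <- table(x)
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1L) {
      warning("tied dominant label; breaking tie lexicographically",
              call. = FALSE)
    }
    sort(top)[1L]
  }
  rows <- lapply(sort(unique(model$assignment)), function(g) {
    in_g <- model$assignment == g
    resp <- ann$response[in_g]
    n_cr <- sum(resp == "CR")
    n_nocr <- sum(resp == "NOCR")
    if (n_cr == n_nocr) {
      warning(sprintf("subgroup %d has a CR/NOCR tie; flagged sensitive", g),
              call. = FALSE)
    }
    data.frame(subgroup = g, n = sum(in_g), n_cr = n_cr, n_nocr = n_nocr,
               dominant_response = dominant(resp),
               dominant_subtype = dominant(ann$subtype[in_g]),
               resistant = n_nocr > n_cr,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cluster samples into molecular subgroups from expression
#'
#' Convenience wrapper reproducing the full subgrouping protocol:
#' median centering, centred-correlation distance, UPGMA clustering and
#' tree cutting. Typically applied to the significant-DEG submatrix.
#'
#' @param m Gene-by-sample numeric matrix (e.g. restricted to
#'   significant genes).
#' @param k Number of subgroups, or `NULL` for silhouette selection.
#' @return A `subgroup_model` (see [cut_clusters()]).
#' @export
subgroup_samples <- function(m, k = NULL) {
  centered <- median_center(m)
  d <- correlation_distance(centered)
  tree <- hierarchical_cluster(d)
  cut_clusters(tree, k = k, d = d)
}
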