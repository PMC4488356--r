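#' Hypergeometric gene-set over-representation test
#'
#' For each pathway, tests whether the query gene set overlaps the
#' pathway more than expected under sampling without replacement from
#' the universe: the p-value is the hypergeometric upper tail
#' `P(X >= k)` with population size `|universe|`,
#' `|pathway intersect universe|` successes and `|query|` draws.
#' Benjamini-Hochberg q-values are computed across all tested pathways;
#' pathways are called significant at raw `p < alpha`.
#'
#' @param query Character vector of genes of interest (must be a subset
#'   of `universe`).
#' @param universe Character vector of all considered genes.
#' @param pathways Named list of gene-id vectors.
#' @param alpha Raw-p significance level (default 0.05).
#' @return A data frame with `pathway`, `count` (overlap size),
#'   `pathway_size` (within universe), `p_value`, `q_value`,
#'   `significant`, ordered by increasing p.
#' @export
hypergeom_enrichment <- function(query, universe, pathways, alpha = 0.05) {
  query <- unique(query)
  universe <- unique(universe)
  extra <- setdiff(query, universe)
  if (length(extra) > 0L) {
    stop("query genes outside the universe: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(pathways), function(nm) {
    pw <- intersect(unique(pathways[[nm]]), universe)
    K <- length(pw)
    k <- length(intersect(query, pw))
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway = nm, count = k, pathway_size = K, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_fdr(out$p_value)
  out$significant <- out$p_value < alpha
  out[order(out$p_value, out$pathway), , drop = FALSE]
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment; output is monotone in p-rank
#' and capped at 1.
#'
#' @param p_values Numeric vector of p-values in [0, 1].
#' @return Adjusted q-values, same length and order as the input.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Pathway deviation score of a subgroup
#'
#' For a pathway's genes, the deviation score is
#' `A = log10( mean_i (Xbar_i - Ybar_i)^2 )` where `Xbar_i` is gene i's
#' mean over the subgroup samples and `Ybar_i` its mean over the
#' sensitive samples. `variant = "cumsum"` drops the `1/N` factor and
#' scores `log10( sum_i (Xbar_i - Ybar_i)^2 )`. A zero mean-squared
#' deviation has no finite logarithm and is reported as `NA`.
#'
#' @param pathway_genes Character vector of the pathway's genes.
#' @param subgroup_samples,sensitive_samples Sample-id vectors.
#' @param m Gene-by-sample numeric matrix.
#' @param variant `"mean"` (default) or `"cumsum"`.
#' @return A list with `A` (score or `NA`), `n_genes` (N), and
#'   `deviations` (named vector of `Xbar_i - Ybar_i`).
#' @export
pathway_deviation_score <- function(pathway_genes, subgroup_samples,
                                    sensitive_samples, m,
                                    variant = c("mean", "cumsum")) {
  variant <- match.arg(variant)
  assert_expression_matrix(m)
  genes <- intersect(unique(pathway_genes), rownames(m))
  if (length(genes) == 0L) {
    stop("no pathway genes present in the expression matrix", call. = FALSE)
  }
  if (length(subgroup_samples) == 0L || length(sensitive_samples) == 0L) {
    stop("both sample sets must be nonempty", call. = FALSE)
  }
  xbar <- rowMeans(m[genes, subgroup_samples, drop = FALSE])
  ybar <- rowMeans(m[genes, sensitive_samples, drop = FALSE])
  dev <- xbar - ybar
  msd <- if (variant == "mean") mean(dev^2) else sum(dev^2)
  A <- if (msd > 0) log10(msd) else NA_real_
  list(A = A, n_genes = length(genes), deviations = dev)
}

#' Pathway-by-subgroup deviation score profile
#'
#' Scores the union of significantly enriched pathways (across all
#' supplied enrichment results) in every subgroup of the model,
#' resistant and sensitive alike. Each pathway is scored on its
#' significant differentially expressed genes (`degs`), with the
#' sensitive reference mean always taken over all CR samples.
#'
#' @param enrichments A list of data frames from
#'   [hypergeom_enrichment()] (e.g. one per subgroup gene set).
#' @param pathways Named list of gene-id vectors.
#' @param degs Character vector of significant gene ids.
#' @param model A `subgroup_model`.
#' @param annotation Sample annotation data frame.
#' @param m Gene-by-sample numeric matrix.
#' @param variant Passed to [pathway_deviation_score()].
#' @return A data frame, one row per scored pathway, one `subgroup_<g>`
#'   column per subgroup, plus `n_genes`.
#' @export
deviation_profile <- function(enrichments, pathways, degs, model,
                              annotation, m, variant = c("mean", "cumsum")) {
  variant <- match.arg(variant)
  stopifnot(inherits(model, "subgroup_model"))
  selected <- unique(unlist(lapply(enrichments, function(e) {
    e$pathway[e$significant]
  }), use.names = FALSE))
  if (length(selected) == 0L) {
    return(data.frame(pathway = character(0), n_genes = integer(0)))
  }
  ann <- match_annotation(names(model$assignment), annotation)
  sens_samples <- names(model$assignment)[ann$response == "CR"]
  groups <- sort(unique(model$assignment))
  rows <- lapply(selected, function(nm) {
    genes <- intersect(intersect(pathways[[nm]], degs), rownames(m))
    if (length(genes) == 0L) {
      return(cbind(data.frame(pathway = nm, n_genes = 0L),
                   stats::setNames(as.data.frame(as.list(rep(NA_real_,
                                                             length(groups)))),
                                   paste0("subgroup_", groups))))
    }
    scores <- vapply(groups, function(g) {
      ss <- names(model$assignment)[model$assignment == g]
      pathway_deviation_score(genes, ss, sens_samples, m,
                              variant = variant)$A
    }, numeric(1))
    cbind(data.frame(pathway = nm, n_genes = length(genes),
                     stringsAsFactors = FALSE),
          stats::setNames(as.data.frame(as.list(scores)),
                          paste0("subgroup_", groups)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
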