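#' Per-gene fluctuation range of a sample group
#'
#' The fluctuation range of a reference group is, per gene, the interval
#' mean +/- one sample standard deviation over the group's samples --
#' the same construction as the sensitive-group normal range used for
#' deviation scoring. An alternative reading (`method = "span"`) uses
#' the min/max span of per-subgroup means instead; it requires a
#' subgroup assignment for the reference samples.
#'
#' @param m Gene-by-sample numeric matrix.
#' @param samples Character vector of reference sample ids (>= 2).
#' @param method `"mean_sd"` (default) or `"span"`.
#' @param subgroups Named integer/character vector assigning reference
#'   samples to subgroups (required for `method = "span"`).
#' @return A data frame with columns `gene_id`, `low`, `high`.
#' @export
group_fluctuation_range <- function(m, samples, method = c("mean_sd", "span"),
                                    subgroups = NULL) {
  method <- match.arg(method)
  assert_expression_matrix(m)
  if (length(samples) < 2L) {
    stop("fluctuation range needs at least 2 samples", call. = FALSE)
  }
  if (!all(samples %in% colnames(m))) {
    stop("samples missing from matrix: ",
         paste(setdiff(samples, colnames(m)), collapse = ", "), call. = FALSE)
  }
  sub <- m[, samples, drop = FALSE]
  if (method == "mean_sd") {
    mu <- rowMeans(sub)
    s <- row_sds(sub)
    data.frame(gene_id = rownames(m), low = mu - s, high = mu + s,
               row.names = NULL, stringsAsFactors = FALSE)
  } else {
    if (is.null(subgroups)) {
      stop("method = 'span' needs a subgroup assignment", call. = FALSE)
    }
    groups <- split(samples, subgroups[samples])
    means <- matrix(unlist(lapply(groups, function(ss) {
      rowMeans(m[, ss, drop = FALSE])
    }), use.names = FALSE), nrow = nrow(m))
    data.frame(gene_id = rownames(m),
               low = apply(means, 1L, min), high = apply(means, 1L, max),
               row.names = NULL, stringsAsFactors = FALSE)
  }
}

#' Allocate significant genes to patient subgroups
#'
#' A significant gene is specific to a resistant subgroup when its mean
#' over that subgroup's samples falls outside the sensitive group's
#' fluctuation range; symmetrically, a gene is allocated to a sensitive
#' subgroup when its subgroup mean falls outside the pooled resistant
#' group's fluctuation range. Genes may be specific to several subgroups
#' at once; `common_resistant` is the intersection over all resistant
#' subgroups (`common_scope = "resistant"`, default) or over every
#' subgroup's allocation (`common_scope = "all"`).
#'
#' @param degs Character vector of significant gene ids.
#' @param m Gene-by-sample numeric matrix containing those genes.
#' @param model A `subgroup_model` from [cut_clusters()], or a named
#'   vector/list coercible to one sample -> subgroup assignment.
#' @param annotation Sample annotation data frame (defines CR/NOCR).
#' @param range_method Passed to [group_fluctuation_range()].
#' @param common_scope `"resistant"` or `"all"` (see above).
#' @return A list of class `gene_allocation` with
#'   `specific_to_resistant` (list subgroup -> gene vector),
#'   `allocated_to_sensitive`, `common_resistant`, and `summary` (the
#'   subgroup summary used to classify subgroups).
#' @export
allocate_genes <- function(degs, m, model, annotation,
                           range_method = c("mean_sd", "span"),
                           common_scope = c("resistant", "all")) {
  range_method <- match.arg(range_method)
  common_scope <- match.arg(common_scope)
  assert_expression_matrix(m)
  degs <- intersect(degs, rownames(m))
  if (length(degs) == 0L) stop("no significant genes present in matrix",
                               call. = FALSE)
  summary <- summarize_subgroups(model, annotation)
  if (!any(summary$resistant) || !any(!summary$resistant)) {
    stop("need at least one resistant and one sensitive subgroup",
         call. = FALSE)
  }
  ann <- match_annotation(names(model$assignment), annotation)
  sens_samples <- names(model$assignment)[ann$response == "CR"]
  res_samples <- names(model$assignment)[ann$response == "NOCR"]
  if (length(sens_samples) < 2L || length(res_samples) < 2L) {
    stop("need at least 2 samples in each phenotype group", call. = FALSE)
  }
  dm <- m[degs, , drop = FALSE]

  sub_assign <- model$assignment
  res_groups <- summary$subgroup[summary$resistant]
  sens_groups <- summary$subgroup[!summary$resistant]

  sens_range <- group_fluctuation_range(dm, sens_samples,
                                        method = range_method,
                                        subgroups = sub_assign)
  res_range <- group_fluctuation_range(dm, res_samples,
                                       method = range_method,
                                       subgroups = sub_assign)
  outside <- function(means, range) {
    means < range$low | means > range$high
  }
  alloc_for <- function(groups, range) {
    out <- lapply(groups, function(g) {
      ss <- names(sub_assign)[sub_assign == g]
      if (length(ss) < 1L) stop("empty subgroup", call. = FALSE)
      means <- rowMeans(dm[, ss, drop = FALSE])
      degs[outside(means, range)]
    })
    stats::setNames(out, paste0("subgroup_", groups))
  }
  specific <- alloc_for(res_groups, sens_range)
  sensitive <- alloc_for(sens_groups, res_range)
  common_pool <- if (common_scope == "resistant") specific
                 else c(specific, sensitive)
  common <- Reduce(intersect, common_pool)
  structure(list(specific_to_resistant = specific,
                 allocated_to_sensitive = sensitive,
                 common_resistant = common,
                 summary = summary),
            class = "gene_allocation")
}

#' Write a gene allocation to long-format TSV
#'
#' One row per (gene, subgroup) pair with the subgroup's phenotype side
#' and a flag for membership in the common resistant set.
#'
#' @param allocation A [allocate_genes()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_allocation <- function(allocation, path) {
  stopifnot(inherits(allocation, "gene_allocation"))
  long <- function(sets, side) {
    do.call(rbind, c(lapply(names(sets), function(nm) {
      if (length(sets[[nm]]) == 0L) return(NULL)
      data.frame(gene_id = sets[[nm]], subgroup = nm, side = side,
                 is_common = sets[[nm]] %in% allocation$common_resistant,
                 stringsAsFactors = FALSE)
    }), list(NULL)))
  }
  out <- rbind(long(allocation$specific_to_resistant, "resistant"),
               long(allocation$allocated_to_sensitive, "sensitive"))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
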