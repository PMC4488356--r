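#' Build the restricted interaction network
#'
#' Induced subgraph of the interaction table on `node_set`: only edges
#' with both endpoints inside the node set are kept. The graph is
#' simple, undirected and includes isolated nodes of the set.
#'
#' @param interactions Two-column character matrix of undirected edges
#'   (as returned by [read_interactions()]).
#' @param node_set Character vector of gene ids to restrict to.
#' @return An [igraph::graph] object.
#' @export
build_network <- function(interactions, node_set) {
  node_set <- unique(node_set)
  if (length(node_set) == 0L) stop("node_set must be nonempty", call. = FALSE)
  keep <- interactions[, 1L] %in% node_set & interactions[, 2L] %in% node_set
  g <- igraph::graph_from_data_frame(
    as.data.frame(interactions[keep, , drop = FALSE],
                  stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = node_set, stringsAsFactors = FALSE))
  igraph::simplify(g)
}

#' Degree table with base-2 log conversion
#'
#' Counts each node's distinct neighbours within the network and
#' converts degrees with the base-2 logarithm; isolated nodes (degree
#' 0) have no finite logarithm and carry `NA`.
#'
#' @param network An [igraph::graph] (from [build_network()]).
#' @return A data frame with `gene_id`, `degree`, `log2_degree`, ordered
#'   by decreasing degree then gene id.
#' @export
node_degrees <- function(network) {
  deg <- igraph::degree(network)
  out <- data.frame(gene_id = names(deg),
                    degree = as.integer(deg),
                    log2_degree = ifelse(deg >= 1, log2(deg), NA_real_),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select hub biomarkers by log2-degree threshold
#'
#' Genes whose log2 degree strictly exceeds the threshold (default 4.7,
#' i.e. at least 26 neighbours) are selected as hub biomarkers, sorted
#' by descending degree then gene id. Isolated nodes are never selected.
#'
#' @param degrees Degree table from [node_degrees()].
#' @param threshold Log2-degree cutoff (strict; default 4.7).
#' @return A data frame like `degrees` with an added `is_biomarker`
#'   column, biomarkers first.
#' @export
select_biomarkers <- function(degrees, threshold = 4.7) {
  sel <- !is.na(degrees$log2_degree) & degrees$log2_degree > threshold
  out <- degrees
  out$is_biomarker <- sel
  out <- out[order(-out$is_biomarker, -out$degree, out$gene_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
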