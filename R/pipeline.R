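#' Assemble a pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis in one validated
#' list. Inputs come either from files (`expression`, `annotation`,
#' `pathways`, `interactions` paths, with optional
#' `validation_expression`/`validation_annotation` for the classifier
#' stage) or from the synthetic generator (`simulate` = a
#' [synthetic_config()]; a validation cohort is then simulated under a
#' seed derived from the pipeline seed).
#'
#' @param simulate A [synthetic_config()], or `NULL` to read files.
#' @param expression,annotation,pathways,interactions Input file paths
#'   (ignored when `simulate` is given).
#' @param validation_expression,validation_annotation Optional
#'   validation-cohort file paths.
#' @param zscore Z-score the expression matrix first (default `TRUE`).
#' @param n_permutations,alpha,statistic Deviation-test settings (see
#'   [detect_degs()]).
#' @param k Subgroup count, or `NULL` for silhouette selection.
#' @param range_method,common_scope Allocation settings (see
#'   [allocate_genes()]).
#' @param enrichment_alpha Raw-p cutoff for pathway enrichment.
#' @param deviation_variant `"mean"` or `"cumsum"` (see
#'   [pathway_deviation_score()]).
#' @param biomarker_threshold Strict log2-degree cutoff (default 4.7).
#' @param seed Master seed; stage seeds derive from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL,
                            expression = NULL, annotation = NULL,
                            pathways = NULL, interactions = NULL,
                            validation_expression = NULL,
                            validation_annotation = NULL,
                            zscore = TRUE,
                            n_permutations = 10000L, alpha = 0.05,
                            statistic = "signed",
                            k = NULL,
                            range_method = "mean_sd",
                            common_scope = "resistant",
                            enrichment_alpha = 0.05,
                            deviation_variant = "mean",
                            biomarker_threshold = 4.7,
                            seed = 1L) {
  if (is.null(simulate)) {
    paths <- c(expression, annotation, pathways, interactions)
    if (length(paths) < 4L || !all(file.exists(paths))) {
      stop("without a simulate block, all four input paths must exist",
           call. = FALSE)
    }
  } else {
    stopifnot(inherits(simulate, "synthetic_config"))
  }
  structure(list(simulate = simulate, expression = expression,
                 annotation = annotation, pathways = pathways,
                 interactions = interactions,
                 validation_expression = validation_expression,
                 validation_annotation = validation_annotation,
                 zscore = isTRUE(zscore),
                 n_permutations = as.integer(n_permutations),
                 alpha = alpha, statistic = statistic, k = k,
                 range_method = range_method, common_scope = common_scope,
                 enrichment_alpha = enrichment_alpha,
                 deviation_variant = deviation_variant,
                 biomarker_threshold = biomarker_threshold,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full chemoresistance analysis pipeline
#'
#' Executes, in order: deviation-score DEG detection, subgroup
#' clustering on the significant-gene submatrix, subgroup gene
#' allocation, hypergeometric pathway enrichment per subgroup gene set,
#' pathway deviation profiling, hub-biomarker selection from the
#' restricted interaction network, and (when a validation cohort is
#' available) discretized decision-tree validation of the biomarkers.
#' Rerunning with an identical configuration reproduces identical
#' outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, every stage writes a
#'   TSV/JSON output plus a run manifest.
#' @return A list with elements `degs`, `model`, `subgroup_summary`,
#'   `allocation`, `enrichments`, `deviation_profile`, `biomarkers`,
#'   `validation` (NULL if no validation cohort) and `truth` (NULL for
#'   file inputs).
#' @export
run_full_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(out_dir)) {
        writeLines(paste(name, conditionMessage(e)),
                   file.path(out_dir, "FAILED"))
      }
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)

  # --- inputs -------------------------------------------------------------
  truth <- NULL
  validation <- NULL
  if (!is.null(config$simulate)) {
    study <- stage("simulate", generate_study(config$simulate))
    expr <- study$expression
    ann <- study$annotation
    pathways <- study$pathways
    edges <- study$edges
    truth <- study$truth
    vcohort <- stage("simulate_validation",
                     generate_cohort(config$simulate,
                                     noise_seed = config$simulate$seed + 500L,
                                     cohort = "validation"))
    validation <- list(expression = vcohort$expression,
                       annotation = vcohort$annotation)
  } else {
    expr <- stage("read_inputs", read_expression_matrix(config$expression))
    ann <- read_sample_annotation(config$annotation)
    pathways <- read_gene_sets(config$pathways)
    edges <- read_interactions(config$interactions)
    if (!is.null(config$validation_expression)) {
      validation <- list(
        expression = read_expression_matrix(config$validation_expression),
        annotation = read_sample_annotation(config$validation_annotation))
    }
  }
  raw_expr <- expr
  if (config$zscore) expr <- stage("zscore", zscore_normalize(expr))

  # --- DEG detection ------------------------------------------------------
  degs <- stage("detect_degs",
                detect_degs(expr, ann,
                            n_permutations = config$n_permutations,
                            alpha = config$alpha, seed = config$seed,
                            statistic = config$statistic))
  sig_genes <- degs$gene_id[degs$significant]
  message(sprintf("detect_degs: %d/%d genes significant at alpha = %g",
                  length(sig_genes), nrow(degs), config$alpha))
  if (length(sig_genes) < 2L) {
    stop("fewer than 2 significant genes; downstream stages undefined",
         call. = FALSE)
  }

  # --- subgrouping --------------------------------------------------------
  model <- stage("subgroup",
                 subgroup_samples(expr[sig_genes, , drop = FALSE],
                                  k = config$k))
  summary <- stage("subgroup", summarize_subgroups(model, ann))
  message(sprintf("subgroup: k = %d (%d resistant, %d sensitive)",
                  model$k, sum(summary$resistant), sum(!summary$resistant)))

  # --- allocation ---------------------------------------------------------
  allocation <- stage("allocate",
                      allocate_genes(sig_genes, expr, model, ann,
                                     range_method = config$range_method,
                                     common_scope = config$common_scope))

  # --- enrichment ---------------------------------------------------------
  universe <- intersect(rownames(expr),
                        unique(unlist(pathways, use.names = FALSE)))
  query_sets <- c(allocation$specific_to_resistant,
                  list(common = allocation$common_resistant))
  enrichments <- stage("enrich", lapply(query_sets, function(gs) {
    hypergeom_enrichment(intersect(gs, universe), universe, pathways,
                         alpha = config$enrichment_alpha)
  }))

  # --- pathway deviation profile -----------------------------------------
  profile <- stage("pathdev",
                   deviation_profile(enrichments, pathways, sig_genes,
                                     model, ann, expr,
                                     variant = config$deviation_variant))

  # --- network biomarkers -------------------------------------------------
  sig_pathways <- unique(unlist(lapply(enrichments, function(e) {
    e$pathway[e$significant]
  }), use.names = FALSE))
  candidates <- intersect(
    unique(unlist(pathways[sig_pathways], use.names = FALSE)), sig_genes)
  node_set <- union(candidates, allocation$common_resistant)
  biomarkers <- stage("biomarkers", {
    if (length(node_set) == 0L) {
      data.frame(gene_id = character(0), degree = integer(0),
                 log2_degree = numeric(0), is_biomarker = logical(0))
    } else {
      g <- build_network(edges, node_set)
      select_biomarkers(node_degrees(g),
                        threshold = config$biomarker_threshold)
    }
  })
  marker_genes <- biomarkers$gene_id[biomarkers$is_biomarker]
  message(sprintf("biomarkers: %d hub genes above log2-degree %g",
                  length(marker_genes), config$biomarker_threshold))

  # --- classifier validation ----------------------------------------------
  val_result <- NULL
  if (!is.null(validation) && length(marker_genes) > 0L) {
    val_result <- stage("classify",
                        validate_biomarkers(marker_genes, raw_expr, ann,
                                            validation$expression,
                                            validation$annotation,
                                            seed = config$seed))
  }

  result <- list(degs = degs, model = model, subgroup_summary = summary,
                 allocation = allocation, enrichments = enrichments,
                 deviation_profile = profile, biomarkers = biomarkers,
                 validation = val_result, truth = truth)
  if (!is.null(out_dir)) write_pipeline_outputs(result, config, out_dir)
  result
}

# serialize every stage output plus a manifest
write_pipeline_outputs <- function(result, config, out_dir) {
  wt <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(result$degs, "degs.tsv")
  wt(data.frame(sample_id = names(result$model$assignment),
                subgroup = unname(result$model$assignment)),
     "subgroups.tsv")
  wt(result$subgroup_summary, "subgroup_summary.tsv")
  write_allocation(result$allocation, file.path(out_dir, "allocation.tsv"))
  enr <- do.call(rbind, lapply(names(result$enrichments), function(nm) {
    cbind(gene_set = nm, result$enrichments[[nm]])
  }))
  wt(enr, "enrichment.tsv")
  wt(result$deviation_profile, "pathway_deviation.tsv")
  wt(result$biomarkers, "biomarkers.tsv")
  tree <- result$model$tree
  jsonlite::write_json(
    list(merge = tree$merge, height = tree$height, labels = tree$labels),
    file.path(out_dir, "linkage_tree.json"), auto_unbox = FALSE, digits = NA)
  if (!is.null(result$validation)) {
    rep <- result$validation$report
    jsonlite::write_json(
      list(per_class = rep$per_class,
           macro_avg = as.list(rep$macro_avg),
           weighted_avg = as.list(rep$weighted_avg),
           accuracy = rep$accuracy,
           features = result$validation$features),
      file.path(out_dir, "classification_report.json"),
      auto_unbox = TRUE, digits = NA)
  }
  manifest <- list(
    config = lapply(unclass(config), function(x) {
      if (inherits(x, "synthetic_config")) unclass(x) else x
    }),
    package_version = as.character(utils::packageVersion("chemodev")),
    counts = list(
      n_genes_tested = nrow(result$degs),
      n_significant = sum(result$degs$significant),
      k_subgroups = result$model$k,
      n_common_resistant = length(result$allocation$common_resistant),
      n_scored_pathways = nrow(result$deviation_profile),
      n_biomarkers = sum(result$biomarkers$is_biomarker)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}
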