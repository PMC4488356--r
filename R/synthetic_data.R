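#' Configuration for the synthetic chemoresistance cohort generator
#'
#' Builds a validated configuration for [generate_cohort()],
#' [generate_pathways()] and [generate_network()]. Default sample sizes
#' mirror a basal-like discovery cohort of 24 chemotherapy-sensitive (CR)
#' and 22 resistant (NOCR) patients, each phenotype carrying two latent
#' molecular subgroups. Signal genes are shifted by `effect_size` baseline
#' standard deviations, with a per-gene random sign so both up- and
#' downregulation occur.
#'
#' @param n_genes Total number of genes.
#' @param n_sensitive,n_resistant Sample counts per phenotype group.
#' @param k_resistant_subgroups,k_sensitive_subgroups Latent subgroups
#'   planted within each phenotype group.
#' @param n_common_de Genes shifted in every resistant sample.
#' @param n_specific_de_per_subgroup Genes shifted only in one resistant
#'   subgroup.
#' @param n_sensitive_markers_per_subgroup Genes shifted only in one
#'   sensitive subgroup (these give the sensitive samples their own
#'   cluster structure).
#' @param effect_size Shift magnitude in units of `noise_sd`.
#' @param noise_sd Baseline Gaussian noise standard deviation.
#' @param n_pathways Total pathways in the generated collection.
#' @param pathway_size Genes per pathway.
#' @param n_planted_pathways_per_subgroup Pathways drawn predominantly
#'   from one resistant subgroup's specific genes.
#' @param n_hubs Planted hub genes in the interaction network.
#' @param hub_degree Guaranteed hub degree (distinct signal-gene
#'   neighbours).
#' @param background_edge_prob Independent edge probability between
#'   non-hub pairs.
#' @param seed Integer seed; all generation is deterministic given it.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 600L,
                             n_sensitive = 24L,
                             n_resistant = 22L,
                             k_resistant_subgroups = 2L,
                             k_sensitive_subgroups = 2L,
                             n_common_de = 60L,
                             n_specific_de_per_subgroup = 60L,
                             n_sensitive_markers_per_subgroup = 60L,
                             effect_size = 2,
                             noise_sd = 1,
                             n_pathways = 20L,
                             pathway_size = 15L,
                             n_planted_pathways_per_subgroup = 1L,
                             n_hubs = 9L,
                             hub_degree = 32L,
                             background_edge_prob = 0.01,
                             seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_sensitive = as.integer(n_sensitive),
              n_resistant = as.integer(n_resistant),
              k_resistant_subgroups = as.integer(k_resistant_subgroups),
              k_sensitive_subgroups = as.integer(k_sensitive_subgroups),
              n_common_de = as.integer(n_common_de),
              n_specific_de_per_subgroup = as.integer(n_specific_de_per_subgroup),
              n_sensitive_markers_per_subgroup =
                as.integer(n_sensitive_markers_per_subgroup),
              effect_size = as.numeric(effect_size),
              noise_sd = as.numeric(noise_sd),
              n_pathways = as.integer(n_pathways),
              pathway_size = as.integer(pathway_size),
              n_planted_pathways_per_subgroup =
                as.integer(n_planted_pathways_per_subgroup),
              n_hubs = as.integer(n_hubs),
              hub_degree = as.integer(hub_degree),
              background_edge_prob = as.numeric(background_edge_prob),
              seed = as.integer(seed))
  counts <- cfg[c("n_genes", "n_sensitive", "n_resistant",
                  "k_resistant_subgroups", "k_sensitive_subgroups",
                  "n_common_de", "n_specific_de_per_subgroup",
                  "n_sensitive_markers_per_subgroup", "n_pathways",
                  "pathway_size", "n_planted_pathways_per_subgroup",
                  "n_hubs", "hub_degree")]
  if (any(vapply(counts, function(x) is.na(x) || x < 0L, TRUE))) {
    stop("all counts must be non-negative", call. = FALSE)
  }
  if (cfg$effect_size < 0) stop("effect_size must be >= 0", call. = FALSE)
  if (cfg$noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  if (cfg$background_edge_prob < 0 || cfg$background_edge_prob > 1) {
    stop("background_edge_prob must be in [0, 1]", call. = FALSE)
  }
  n_signal <- cfg$n_common_de +
    cfg$k_resistant_subgroups * cfg$n_specific_de_per_subgroup +
    cfg$k_sensitive_subgroups * cfg$n_sensitive_markers_per_subgroup
  if (n_signal > cfg$n_genes) {
    stop("planted signal genes exceed n_genes", call. = FALSE)
  }
  if (cfg$k_resistant_subgroups > cfg$n_resistant ||
      cfg$k_sensitive_subgroups > max(cfg$n_sensitive, 1L)) {
    stop("more subgroups than samples", call. = FALSE)
  }
  structure(cfg, class = "synthetic_config")
}

# round-robin partition of samples into k subgroups
split_subgroups <- function(ids, k) {
  if (k <= 0L || length(ids) == 0L) return(stats::setNames(integer(0), ids))
  stats::setNames(rep_len(seq_len(k), length(ids)), ids)
}

#' Generate a synthetic cohort with planted chemoresistance structure
#'
#' Draws baseline expression from N(0, `noise_sd`^2), then plants:
#' common resistance genes (shifted in all resistant samples),
#' subgroup-specific resistance genes (shifted only in one resistant
#' subgroup), and sensitive-subgroup marker genes (shifted only in one
#' sensitive subgroup). Shift direction is random per gene. Gene roles
#' and shift signs are the study's biology and derive only from
#' `cfg$seed`; the measurement noise derives from `noise_seed`, so a
#' validation cohort drawn with a different `noise_seed` shares the same
#' planted signal genes and directions but contains new patients.
#'
#' @param cfg A [synthetic_config()].
#' @param noise_seed Seed for the sampling noise (default `cfg$seed`,
#'   the discovery cohort).
#' @param cohort Cohort label written to the annotation.
#' @return A list with elements `expression` (gene-by-sample matrix),
#'   `annotation` (sample annotation data frame) and `truth` (planted
#'   ground truth: `common_de_genes`, `specific_de_genes`,
#'   `sensitive_marker_genes`, `shift_sign`, `sample_subgroup`,
#'   `hub_genes` filled in by [generate_network()]).
#' @export
generate_cohort <- function(cfg, noise_seed = NULL, cohort = "discovery") {
  stopifnot(inherits(cfg, "synthetic_config"))
  noise_seed <- as.integer(noise_seed %||% cfg$seed)
  n_samples <- cfg$n_sensitive + cfg$n_resistant
  gene_ids <- sprintf("g%04d", seq_len(cfg$n_genes))
  sens_ids <- sprintf("S%02d", seq_len(cfg$n_sensitive))
  res_ids <- sprintf("R%02d", seq_len(cfg$n_resistant))
  sample_ids <- c(sens_ids, res_ids)

  # --- study biology: gene roles and shift signs, fixed by cfg$seed ------
  set.seed(cfg$seed)
  shuffled <- sample(gene_ids)
  take <- function(n) {
    out <- shuffled[seq_len(n)]
    shuffled <<- shuffled[-seq_len(n)]
    out
  }
  common <- take(cfg$n_common_de)
  specific <- lapply(seq_len(cfg$k_resistant_subgroups),
                     function(j) take(cfg$n_specific_de_per_subgroup))
  names(specific) <- paste0("R", seq_len(cfg$k_resistant_subgroups))
  sens_markers <- lapply(seq_len(cfg$k_sensitive_subgroups),
                         function(j) take(cfg$n_sensitive_markers_per_subgroup))
  names(sens_markers) <- paste0("S", seq_len(cfg$k_sensitive_subgroups))
  signal_genes <- c(common, unlist(specific, use.names = FALSE),
                    unlist(sens_markers, use.names = FALSE))
  shift_sign <- stats::setNames(
    sample(c(-1, 1), length(signal_genes), replace = TRUE), signal_genes)

  res_sub <- split_subgroups(res_ids, cfg$k_resistant_subgroups)
  sens_sub <- split_subgroups(sens_ids, cfg$k_sensitive_subgroups)

  # --- measurement noise: cohort-specific --------------------------------
  set.seed(noise_seed)
  m <- matrix(stats::rnorm(cfg$n_genes * n_samples, 0, cfg$noise_sd),
              nrow = cfg$n_genes, dimnames = list(gene_ids, sample_ids))

  shift <- cfg$effect_size * cfg$noise_sd
  apply_shift <- function(m, genes, samples) {
    if (length(genes) == 0L || length(samples) == 0L) return(m)
    m[genes, samples] <- m[genes, samples] + shift_sign[genes] * shift
    m
  }
  m <- apply_shift(m, common, res_ids)
  for (j in seq_along(specific)) {
    m <- apply_shift(m, specific[[j]], res_ids[res_sub == j])
  }
  for (j in seq_along(sens_markers)) {
    m <- apply_shift(m, sens_markers[[j]], sens_ids[sens_sub == j])
  }

  annotation <- data.frame(
    sample_id = sample_ids,
    response = c(rep("CR", cfg$n_sensitive), rep("NOCR", cfg$n_resistant)),
    subtype = "basal",
    cohort = cohort,
    stringsAsFactors = FALSE)

  sample_subgroup <- c(
    stats::setNames(paste0("S", sens_sub), sens_ids),
    stats::setNames(paste0("R", res_sub), res_ids))

  truth <- list(common_de_genes = common,
                specific_de_genes = specific,
                sensitive_marker_genes = sens_markers,
                shift_sign = shift_sign,
                sample_subgroup = sample_subgroup,
                planted_pathways = NULL,
                hub_genes = character(0))
  list(expression = m, annotation = annotation, truth = truth)
}

#' Generate a pathway collection with planted enriched pathways
#'
#' For each resistant subgroup, plants
#' `n_planted_pathways_per_subgroup` pathways whose members are at least
#' 80% drawn from that subgroup's specific resistance genes (the
#' remainder from null genes). Remaining pathways are background sets
#' drawn uniformly from genes with no planted signal.
#'
#' @param cfg A [synthetic_config()].
#' @param cohort Output of [generate_cohort()] run under the same config.
#' @return A list with `pathways` (named list of gene vectors) and
#'   `truth` (the cohort truth with `planted_pathways` filled in).
#' @export
generate_pathways <- function(cfg, cohort) {
  stopifnot(inherits(cfg, "synthetic_config"))
  truth <- cohort$truth
  gene_ids <- rownames(cohort$expression)
  de_genes <- unique(c(truth$common_de_genes,
                       unlist(truth$specific_de_genes, use.names = FALSE)))
  null_genes <- setdiff(gene_ids,
                        c(de_genes,
                          unlist(truth$sensitive_marker_genes,
                                 use.names = FALSE)))
  if (cfg$pathway_size > length(null_genes)) {
    stop("pathway_size exceeds the available null gene pool", call. = FALSE)
  }
  set.seed(cfg$seed + 1L)
  pathways <- list()
  planted <- list()
  n_core <- ceiling(0.8 * cfg$pathway_size)
  for (j in seq_len(cfg$k_resistant_subgroups)) {
    sub <- names(truth$specific_de_genes)[j]
    pool <- truth$specific_de_genes[[j]]
    if (cfg$n_planted_pathways_per_subgroup > 0L && n_core > length(pool)) {
      stop("not enough subgroup-specific genes to plant a pathway",
           call. = FALSE)
    }
    for (i in seq_len(cfg$n_planted_pathways_per_subgroup)) {
      nm <- sprintf("planted_%s_%02d", sub, i)
      members <- c(sample(pool, n_core),
                   sample(null_genes, cfg$pathway_size - n_core))
      pathways[[nm]] <- members
      planted[[sub]] <- c(planted[[sub]], nm)
    }
  }
  n_background <- cfg$n_pathways - length(pathways)
  if (n_background < 0L) {
    stop("n_pathways smaller than the number of planted pathways",
         call. = FALSE)
  }
  for (i in seq_len(n_background)) {
    pathways[[sprintf("background_%02d", i)]] <-
      sample(null_genes, cfg$pathway_size)
  }
  truth$planted_pathways <- planted
  list(pathways = pathways, truth = truth)
}

#' Generate an interaction network with planted hubs
#'
#' Hub genes are drawn from the planted common resistance genes and each
#' connected to `hub_degree` distinct signal (DE) genes, preferring
#' common resistance genes as neighbours (hubs sit at the intersection
#' of the subgroups' resistance mechanisms, so their interactions
#' survive restriction to candidate + common node sets); all remaining
#' node pairs are connected independently with probability
#' `background_edge_prob`. The graph is simple and undirected.
#'
#' @param cfg A [synthetic_config()].
#' @param cohort Output of [generate_cohort()] (or of
#'   [generate_pathways()], whose updated `truth` is preserved).
#' @return A list with `edges` (two-column character matrix) and `truth`
#'   (with `hub_genes` filled in).
#' @export
generate_network <- function(cfg, cohort) {
  stopifnot(inherits(cfg, "synthetic_config"))
  truth <- cohort$truth
  gene_ids <- rownames(cohort$expression)
  de_genes <- unique(c(truth$common_de_genes,
                       unlist(truth$specific_de_genes, use.names = FALSE)))
  if (cfg$n_hubs > length(truth$common_de_genes)) {
    stop("n_hubs exceeds the number of common resistance genes",
         call. = FALSE)
  }
  set.seed(cfg$seed + 2L)
  hubs <- if (cfg$n_hubs > 0L) sample(truth$common_de_genes, cfg$n_hubs)
          else character(0)
  a <- character(0); b <- character(0)
  for (h in hubs) {
    primary <- setdiff(truth$common_de_genes, h)
    fallback <- setdiff(de_genes, c(h, primary))
    if (cfg$hub_degree > length(primary) + length(fallback)) {
      stop("hub_degree exceeds the number of available DE genes",
           call. = FALSE)
    }
    n_primary <- min(cfg$hub_degree, length(primary))
    nb <- c(sample(primary, n_primary),
            if (cfg$hub_degree > n_primary) {
              sample(fallback, cfg$hub_degree - n_primary)
            })
    a <- c(a, rep(h, length(nb)))
    b <- c(b, nb)
  }
  if (cfg$background_edge_prob > 0) {
    n <- length(gene_ids)
    # Bernoulli sampling over all unordered pairs via a draw of pair counts
    n_pairs <- n * (n - 1) / 2
    n_bg <- stats::rbinom(1L, n_pairs, cfg$background_edge_prob)
    if (n_bg > 0L) {
      pair_idx <- sample(n_pairs, n_bg)
      # map linear index to (i, j), i < j
      i <- floor((2 * n - 1 - sqrt((2 * n - 1)^2 - 8 * pair_idx)) / 2) + 1
      offset <- pair_idx - (i - 1) * (2 * n - i) / 2
      j <- i + offset
      a <- c(a, gene_ids[i])
      b <- c(b, gene_ids[j])
    }
  }
  edges <- canonical_edges(a, b)
  truth$hub_genes <- hubs
  list(edges = edges, truth = truth)
}

#' Generate a complete synthetic study (cohort, pathways, network)
#'
#' Convenience wrapper chaining [generate_cohort()],
#' [generate_pathways()] and [generate_network()] under one seed.
#'
#' @param cfg A [synthetic_config()].
#' @return A list with `expression`, `annotation`, `pathways`, `edges`
#'   and the fully populated `truth`.
#' @export
generate_study <- function(cfg) {
  cohort <- generate_cohort(cfg)
  pw <- generate_pathways(cfg, cohort)
  cohort$truth <- pw$truth
  nw <- generate_network(cfg, cohort)
  list(expression = cohort$expression,
       annotation = cohort$annotation,
       pathways = pw$pathways,
       edges = nw$edges,
       truth = nw$truth)
}

#' Write a synthetic study to disk in the pipeline's input formats
#'
#' Writes expression and annotation TSVs, a GMT pathway file, an
#' interaction edge list, a ground-truth gene-role TSV and a JSON
#' manifest holding the generating configuration.
#'
#' @param study Output of [generate_study()].
#' @param cfg The [synthetic_config()] used.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression_matrix(study$expression, file.path(dir, "expression.tsv"))
  write_sample_annotation(study$annotation, file.path(dir, "annotation.tsv"))
  write_gene_sets(study$pathways, file.path(dir, "pathways.gmt"))
  write_interactions(study$edges, file.path(dir, "interactions.tsv"))
  truth <- study$truth
  roles <- rbind(
    data.frame(gene_id = truth$common_de_genes, role = "common_de",
               subgroup = "", stringsAsFactors = FALSE),
    do.call(rbind, c(lapply(names(truth$specific_de_genes), function(s) {
      data.frame(gene_id = truth$specific_de_genes[[s]], role = "specific_de",
                 subgroup = s, stringsAsFactors = FALSE)
    }), list(NULL))),
    do.call(rbind, c(lapply(names(truth$sensitive_marker_genes), function(s) {
      data.frame(gene_id = truth$sensitive_marker_genes[[s]],
                 role = "sensitive_marker", subgroup = s,
                 stringsAsFactors = FALSE)
    }), list(NULL))),
    data.frame(gene_id = truth$hub_genes, role = "hub", subgroup = "",
               stringsAsFactors = FALSE))
  utils::write.table(roles, file.path(dir, "ground_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(cfg), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
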