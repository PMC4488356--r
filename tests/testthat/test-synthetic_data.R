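test_that("invalid configurations are rejected before generation", {
  expect_error(synthetic_config(n_genes = 100, n_common_de = 80,
                                n_specific_de_per_subgroup = 40),
               "exceed")
  expect_error(synthetic_config(effect_size = -1), "effect_size")
  expect_error(synthetic_config(background_edge_prob = 1.5),
               "background_edge_prob")
  expect_error(synthetic_config(n_resistant = 1, k_resistant_subgroups = 2),
               "subgroups")
})

test_that("generation is bitwise deterministic for a fixed seed", {
  cfg <- synthetic_config(n_genes = 80, n_common_de = 8,
                          n_specific_de_per_subgroup = 6,
                          n_sensitive_markers_per_subgroup = 6,
                          n_pathways = 5, pathway_size = 5,
                          n_hubs = 2, hub_degree = 5, seed = 11)
  s1 <- generate_study(cfg)
  s2 <- generate_study(cfg)
  expect_identical(s1$expression, s2$expression)
  expect_identical(s1$pathways, s2$pathways)
  expect_identical(s1$edges, s2$edges)
  expect_identical(s1$truth, s2$truth)
})

test_that("effect_size 0 yields a pure-noise null cohort", {
  cfg0 <- synthetic_config(n_genes = 50, n_common_de = 5,
                           n_specific_de_per_subgroup = 5,
                           n_sensitive_markers_per_subgroup = 5,
                           effect_size = 0, seed = 3)
  cfg_none <- synthetic_config(n_genes = 50, n_common_de = 0,
                               n_specific_de_per_subgroup = 0,
                               n_sensitive_markers_per_subgroup = 0,
                               effect_size = 0, seed = 3)
  # with no shift the planted roles leave no trace in the matrix
  expect_identical(generate_cohort(cfg0)$expression,
                   generate_cohort(cfg_none)$expression)
})

test_that("planted subgroup genes separate strongly at large effect size", {
  gaps <- unlist(lapply(1:5, function(s) {
    cfg <- synthetic_config(n_genes = 100, n_common_de = 10,
                            n_specific_de_per_subgroup = 10,
                            n_sensitive_markers_per_subgroup = 5,
                            effect_size = 10, noise_sd = 1, seed = s)
    cohort <- generate_cohort(cfg)
    ann <- cohort$annotation
    sens <- ann$sample_id[ann$response == "CR"]
    unlist(lapply(names(cohort$truth$specific_de_genes), function(sub) {
      ss <- names(cohort$truth$sample_subgroup)[
        cohort$truth$sample_subgroup == sub]
      genes <- cohort$truth$specific_de_genes[[sub]]
      abs(rowMeans(cohort$expression[genes, ss, drop = FALSE]) -
            rowMeans(cohort$expression[genes, sens, drop = FALSE]))
    }))
  }))
  expect_true(all(gaps >= 5))
})

test_that("a validation draw shares the study's biology but new noise", {
  cfg <- synthetic_config(n_genes = 60, n_common_de = 6,
                          n_specific_de_per_subgroup = 5,
                          n_sensitive_markers_per_subgroup = 5, seed = 9)
  disc <- generate_cohort(cfg)
  val <- generate_cohort(cfg, noise_seed = cfg$seed + 500L,
                         cohort = "validation")
  expect_identical(disc$truth$common_de_genes, val$truth$common_de_genes)
  expect_identical(disc$truth$shift_sign, val$truth$shift_sign)
  expect_false(identical(disc$expression, val$expression))
  expect_identical(unique(val$annotation$cohort), "validation")
})

test_that("ground-truth gene sets are pairwise disjoint", {
  cfg <- synthetic_config(seed = 5)
  truth <- generate_cohort(cfg)$truth
  sets <- c(list(truth$common_de_genes), truth$specific_de_genes,
            truth$sensitive_marker_genes)
  all_genes <- unlist(sets, use.names = FALSE)
  expect_identical(anyDuplicated(all_genes), 0L)
  expect_true(all(nzchar(truth$sample_subgroup)))
})

test_that("planted pathways are dominated by their subgroup's DE genes", {
  cfg <- synthetic_config(n_genes = 200, n_common_de = 20,
                          n_specific_de_per_subgroup = 20,
                          n_sensitive_markers_per_subgroup = 10,
                          n_pathways = 6, pathway_size = 10,
                          n_planted_pathways_per_subgroup = 1, seed = 2)
  cohort <- generate_cohort(cfg)
  pw <- generate_pathways(cfg, cohort)
  for (sub in names(pw$truth$planted_pathways)) {
    for (nm in pw$truth$planted_pathways[[sub]]) {
      overlap <- length(intersect(pw$pathways[[nm]],
                                  cohort$truth$specific_de_genes[[sub]]))
      expect_gte(overlap, ceiling(0.8 * cfg$pathway_size))
    }
  }
  # background pathways avoid every planted signal gene by construction
  signal <- c(cohort$truth$common_de_genes,
              unlist(cohort$truth$specific_de_genes, use.names = FALSE),
              unlist(cohort$truth$sensitive_marker_genes, use.names = FALSE))
  bg <- setdiff(names(pw$pathways),
                unlist(pw$truth$planted_pathways, use.names = FALSE))
  expect_length(bg, cfg$n_pathways - 2L)
  for (nm in bg) {
    expect_length(intersect(pw$pathways[[nm]], signal), 0L)
  }
})

test_that("planted hubs reach their guaranteed degree; no background gives exact counts", {
  cfg <- synthetic_config(n_genes = 150, n_common_de = 40,
                          n_specific_de_per_subgroup = 20,
                          n_sensitive_markers_per_subgroup = 5,
                          n_hubs = 1, hub_degree = 32,
                          background_edge_prob = 0, seed = 4)
  cohort <- generate_cohort(cfg)
  nw <- generate_network(cfg, cohort)
  expect_identical(nrow(nw$edges), 32L)
  deg <- oracle_degrees(nw$edges, rownames(cohort$expression))
  expect_identical(unname(deg[nw$truth$hub_genes]), 32L)

  cfg2 <- synthetic_config(n_genes = 150, n_common_de = 40,
                           n_specific_de_per_subgroup = 20,
                           n_sensitive_markers_per_subgroup = 5,
                           n_hubs = 3, hub_degree = 32,
                           background_edge_prob = 0.01, seed = 4)
  nw2 <- generate_network(cfg2, generate_cohort(cfg2))
  deg2 <- oracle_degrees(nw2$edges, rownames(cohort$expression))
  expect_true(all(deg2[nw2$truth$hub_genes] >= 32L))
  expect_identical(anyDuplicated(paste(nw2$edges[, 1], nw2$edges[, 2])), 0L)
  expect_true(all(nw2$edges[, 1] != nw2$edges[, 2]))
})

test_that("a written study round-trips through the readers", {
  cfg <- synthetic_config(n_genes = 60, n_common_de = 10,
                          n_specific_de_per_subgroup = 5,
                          n_sensitive_markers_per_subgroup = 5,
                          n_pathways = 4, pathway_size = 5,
                          n_hubs = 2, hub_degree = 8, seed = 6)
  study <- generate_study(cfg)
  dir <- withr::local_tempdir()
  write_study(study, cfg, dir)
  expect_equal(read_expression_matrix(file.path(dir, "expression.tsv")),
               study$expression, tolerance = 1e-12)
  expect_identical(read_gene_sets(file.path(dir, "pathways.gmt")),
                   study$pathways)
  expect_identical(read_interactions(file.path(dir, "interactions.tsv")),
                   study$edges)
  truth_tab <- read.delim(file.path(dir, "ground_truth.tsv"),
                          stringsAsFactors = FALSE)
  expect_setequal(truth_tab$gene_id[truth_tab$role == "hub"],
                  study$truth$hub_genes)
})
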