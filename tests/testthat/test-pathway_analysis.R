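test_that("hypergeometric p-values match the combinatorial oracle", {
  universe <- sprintf("u%02d", 1:20)
  pw <- list(full = universe, five = universe[1:5])
  res <- hypergeom_enrichment(universe[1:5], universe, pw)
  # complete overlap of a 5-gene pathway by a 5-gene query: p = 1/C(20,5)
  expect_equal(res$p_value[res$pathway == "five"], 1 / choose(20, 5),
               tolerance = 1e-12)
  expect_equal(res$p_value[res$pathway == "five"], 6.4499e-5,
               tolerance = 1e-4)
  # pathway == universe is a certain event
  expect_equal(res$p_value[res$pathway == "full"], 1)
  # zero overlap has upper tail 1 at k = 0
  res0 <- hypergeom_enrichment(universe[6:10], universe,
                               list(p = universe[1:5]))
  expect_equal(res0$p_value, 1)

  set.seed(22)
  for (i in 1:25) {
    N <- sample(10:30, 1)
    uni <- sprintf("u%02d", seq_len(N))
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    pws <- list(p = sample(uni, K))
    query <- sample(uni, n)
    got <- hypergeom_enrichment(query, uni, pws)
    k <- length(intersect(query, pws$p))
    expect_equal(got$p_value, oracle_hyper_upper(k, K, N, n),
                 tolerance = 1e-12)
  }
})

test_that("queries outside the universe are rejected by name", {
  expect_error(hypergeom_enrichment(c("a", "zz"), c("a", "b"),
                                    list(p = "a")), "zz")
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(1:100, 1))
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("pathway deviation scores reproduce the hand-worked values", {
  samples <- c("x1", "x2", "y1", "y2")
  # gene means: subgroup {x1,x2} minus sensitive {y1,y2}
  m <- rbind(gA = c(sqrt(10), sqrt(10), 0, 0),
             gB = c(1, 1, 0, 0),
             gC = c(3, 3, 0, 0),
             gD = c(0, 0, 0, 0))
  colnames(m) <- samples
  s1 <- pathway_deviation_score("gA", c("x1", "x2"), c("y1", "y2"), m)
  expect_equal(s1$A, 1.0, tolerance = 1e-12)
  s2 <- pathway_deviation_score(c("gB", "gC"), c("x1", "x2"),
                                c("y1", "y2"), m)
  expect_equal(s2$A, log10(5), tolerance = 1e-12)
  expect_identical(s2$n_genes, 2L)
  # zero deviation has no finite log
  expect_true(is.na(pathway_deviation_score("gD", c("x1", "x2"),
                                            c("y1", "y2"), m)$A))
  # doubling every deviation raises A by exactly log10(4)
  m2 <- m; m2[, c("x1", "x2")] <- 2 * m2[, c("x1", "x2")]
  s3 <- pathway_deviation_score(c("gB", "gC"), c("x1", "x2"),
                                c("y1", "y2"), m2)
  expect_equal(s3$A - s2$A, log10(4), tolerance = 1e-12)
  # the cumulative-sum variant drops the 1/N factor
  s4 <- pathway_deviation_score(c("gB", "gC"), c("x1", "x2"),
                                c("y1", "y2"), m, variant = "cumsum")
  expect_equal(s4$A, log10(10), tolerance = 1e-12)
  # recomputable from the stored per-gene deviations
  expect_equal(s2$A, log10(mean(s2$deviations^2)), tolerance = 1e-12)
  expect_error(pathway_deviation_score("missing", "x1", "y1", m),
               "no pathway genes")
})

test_that("A(P) increases with any per-gene deviation magnitude", {
  set.seed(12)
  base <- runif(6, 0.1, 2)
  A0 <- log10(mean(base^2))
  for (i in seq_along(base)) {
    bumped <- base
    bumped[i] <- bumped[i] + 0.5
    expect_gt(log10(mean(bumped^2)), A0)
  }
})

test_that("planted pathways score highest in their own subgroup", {
  cfg <- synthetic_config(seed = 33)
  study <- generate_study(cfg)
  model <- truth_model(study$truth)
  degs <- c(study$truth$common_de_genes,
            unlist(study$truth$specific_de_genes, use.names = FALSE))
  ann <- study$annotation
  sens <- ann$sample_id[ann$response == "CR"]
  for (sub in names(study$truth$planted_pathways)) {
    g_own <- model_group_of(study$truth, sub)
    own_samples <- names(model$assignment)[model$assignment == g_own]
    for (nm in study$truth$planted_pathways[[sub]]) {
      genes <- intersect(study$pathways[[nm]], degs)
      a_own <- pathway_deviation_score(genes, own_samples, sens,
                                       study$expression)$A
      for (sg in grep("^S", unique(study$truth$sample_subgroup),
                      value = TRUE)) {
        g_s <- model_group_of(study$truth, sg)
        ss <- names(model$assignment)[model$assignment == g_s]
        a_sens <- pathway_deviation_score(genes, ss, sens,
                                          study$expression)$A
        expect_gt(a_own, a_sens)
      }
    }
  }
})

test_that("the profile scores enriched pathways across every subgroup", {
  cfg <- synthetic_config(seed = 44)
  study <- generate_study(cfg)
  model <- truth_model(study$truth)
  degs <- c(study$truth$common_de_genes,
            unlist(study$truth$specific_de_genes, use.names = FALSE))
  universe <- intersect(rownames(study$expression),
                        unique(unlist(study$pathways, use.names = FALSE)))
  enr <- lapply(study$truth$specific_de_genes, function(gs) {
    hypergeom_enrichment(intersect(gs, universe), universe, study$pathways)
  })
  prof <- deviation_profile(enr, study$pathways, degs, model,
                            study$annotation, study$expression)
  expect_true(all(unlist(lapply(study$truth$planted_pathways, identity))
                  %in% prof$pathway))
  expect_identical(ncol(prof), 2L + model$k)
  # empty enrichment yields an empty profile
  none <- lapply(enr, function(e) { e$significant <- FALSE; e })
  expect_identical(nrow(deviation_profile(none, study$pathways, degs, model,
                                          study$annotation,
                                          study$expression)), 0L)
})
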