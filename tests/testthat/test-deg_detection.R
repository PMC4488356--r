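test_that("normal range is the sensitive mean +/- one sample sd", {
  r <- normal_range(c(1, 2, 3))
  expect_equal(c(r$x_min, r$x_max), c(1, 3))
  r2 <- normal_range(c(0, 2))
  expect_equal(c(r2$x_min, r2$x_max), c(1 - sqrt(2), 1 + sqrt(2)))
  expect_warning(r3 <- normal_range(c(5, 5, 5)), "degenerate")
  expect_equal(c(r3$x_min, r3$x_max), c(5, 5))
  expect_error(normal_range(1), "at least 2")
})

test_that("deviation score clamps to the range and tracks sign cancellation", {
  rng <- structure(list(x_min = 1, x_max = 3, n_sensitive = 3),
                   class = "normal_range")
  expect_equal(deviation_score(c(2, 2.5, 1.5), rng), c(raw = 0, abs = 0))
  expect_equal(deviation_score(c(4, 2, 0), rng), c(raw = 0, abs = 2))
  expect_equal(deviation_score(c(5, 3.5), rng), c(raw = 2.5, abs = 2.5))
  expect_error(deviation_score(numeric(0), rng), "empty")
})

test_that("deviation score equals the direct clamped-sum oracle", {
  set.seed(101)
  for (i in 1:200) {
    vals <- rnorm(sample(1:8, 1), sd = runif(1, 0.5, 3))
    lo <- rnorm(1)
    hi <- lo + runif(1, 0, 2)
    rng <- structure(list(x_min = lo, x_max = hi, n_sensitive = 2),
                     class = "normal_range")
    expect_equal(deviation_score(vals, rng),
                 oracle_deviation(vals, lo, hi), tolerance = 1e-12)
  }
})

test_that("scores are translation invariant and scale equivariant", {
  set.seed(7)
  vals <- rnorm(10)
  base <- oracle_score_split(vals, 1:6)
  shifted <- oracle_score_split(vals + 3.7, 1:6)
  scaled <- oracle_score_split(vals * 2.5, 1:6)
  expect_equal(base, shifted, tolerance = 1e-12)
  expect_equal(scaled, base * 2.5, tolerance = 1e-12)
  # and so are the package scores through detect_degs
  m <- rbind(vals, vals + 3.7, vals * 2.5)
  dimnames(m) <- list(c("base", "shift", "scale"), sprintf("s%d", 1:10))
  ann <- data.frame(sample_id = colnames(m),
                    response = c(rep("CR", 6), rep("NOCR", 4)))
  tab <- detect_degs(m, ann, n_permutations = 200, seed = 1)
  expect_equal(tab$raw_score[2], tab$raw_score[1], tolerance = 1e-12)
  expect_equal(tab$raw_score[3], 2.5 * tab$raw_score[1], tolerance = 1e-12)
  expect_equal(tab$p_value[2], tab$p_value[1])
  expect_equal(tab$p_value[3], tab$p_value[1])
})

test_that("permutation p-values honour degenerate and extreme cases", {
  # fully degenerate: every permuted score equals the observed zero
  expect_equal(permutation_pvalue(rep(2, 8), 4, 4, observed = 0,
                                  n_permutations = 50, seed = 1), 1)
  # an observed score larger than any permuted one hits the add-one bound
  p <- permutation_pvalue(c(rnorm(5), 100, 101), n1 = 5, n2 = 2,
                          observed = 1e6, n_permutations = 999, seed = 1)
  expect_equal(p, 1 / 1000)
})

test_that("Monte-Carlo p converges to the exhaustive-enumeration p", {
  set.seed(55)
  for (i in 1:3) {
    n1 <- sample(3:5, 1)
    n2 <- sample(2:4, 1)
    vals <- rnorm(n1 + n2) + c(rep(0, n1), rep(1.5, n2))
    obs <- oracle_score_split(vals, seq_len(n1))
    p_mc <- permutation_pvalue(vals, n1, n2, observed = obs[["raw"]],
                               n_permutations = 4000, seed = i)
    p_exact <- oracle_perm_exact(vals, n1)
    expect_lt(abs(p_mc - p_exact), 0.02)
  }
})

test_that("detect_degs reports directions and handles constant genes", {
  set.seed(31)
  n1 <- 10; n2 <- 8
  up <- c(rnorm(n1, 0, 0.3), rnorm(n2, 5, 0.3))
  down <- c(rnorm(n1, 0, 0.3), rnorm(n2, -5, 0.3))
  mixed <- c(rnorm(n1, 0, 0.3), rep(c(5, -5), length.out = n2))
  flat <- rep(1, n1 + n2)
  m <- rbind(up = up, down = down, mixed = mixed, flat = flat)
  colnames(m) <- sprintf("s%d", seq_len(n1 + n2))
  ann <- data.frame(sample_id = colnames(m),
                    response = c(rep("CR", n1), rep("NOCR", n2)))
  tab <- detect_degs(m, ann, n_permutations = 300, seed = 2)
  expect_identical(tab$direction,
                   c("up", "down", "mixed", "none"))
  expect_equal(tab$p_value[tab$gene_id == "flat"], 1)
  expect_false(tab$significant[tab$gene_id == "flat"])
  expect_true(all(tab$abs_score >= abs(tab$raw_score) - 1e-12))
  expect_identical(tab$significant, tab$p_value < 0.05)
})

test_that("detect_degs is deterministic given the seed and validates inputs", {
  cfg <- synthetic_config(n_genes = 30, n_sensitive = 6, n_resistant = 5,
                          n_common_de = 5, n_specific_de_per_subgroup = 2,
                          n_sensitive_markers_per_subgroup = 2, seed = 8)
  cohort <- generate_cohort(cfg)
  t1 <- detect_degs(cohort$expression, cohort$annotation,
                    n_permutations = 100, seed = 42)
  t2 <- detect_degs(cohort$expression, cohort$annotation,
                    n_permutations = 100, seed = 42)
  expect_identical(t1, t2)
  expect_error(detect_degs(cohort$expression,
                           cohort$annotation[-1, , drop = FALSE],
                           n_permutations = 10),
               "without annotation")
})

test_that("null p-values are super-uniform under exchangeability", {
  cfg <- synthetic_config(n_genes = 150, n_sensitive = 8, n_resistant = 7,
                          n_common_de = 0, n_specific_de_per_subgroup = 0,
                          n_sensitive_markers_per_subgroup = 0,
                          effect_size = 0, seed = 13)
  cohort <- generate_cohort(cfg)
  tab <- detect_degs(cohort$expression, cohort$annotation,
                     n_permutations = 400, seed = 13)
  for (a in c(0.05, 0.1, 0.25)) {
    se <- sqrt(a * (1 - a) / nrow(tab))
    expect_lte(mean(tab$p_value < a), a + 3 * se)
  }
})
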