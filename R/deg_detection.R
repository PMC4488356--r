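#' Normal range of a gene in the sensitive group
#'
#' The sensitive-group normal range is mean +/- one sample standard
#' deviation of the gene's expression in chemotherapy-sensitive (CR)
#' samples. Resistant expression outside this interval contributes to the
#' deviation score.
#'
#' @param sensitive_values Numeric vector of the gene's values in the
#'   sensitive group (length >= 2).
#' @return A list of class `normal_range` with `x_min`, `x_max`,
#'   `n_sensitive`.
#' @export
normal_range <- function(sensitive_values) {
  if (length(sensitive_values) < 2L) {
    stop("normal range needs at least 2 sensitive values", call. = FALSE)
  }
  mu <- mean(sensitive_values)
  s <- stats::sd(sensitive_values)
  if (s == 0) {
    warning("zero variance in sensitive group: degenerate normal range",
            call. = FALSE)
  }
  structure(list(x_min = mu - s, x_max = mu + s,
                 n_sensitive = length(sensitive_values)),
            class = "normal_range")
}

#' Deviation score of resistant samples against a normal range
#'
#' Each resistant value contributes its (signed) excess beyond the normal
#' range: `x - x_max` if above, `x - x_min` if below, 0 inside. The raw
#' score is the signed sum (up- and down-deviations can cancel); the
#' absolute score sums magnitudes and never cancels.
#'
#' @param resistant_values Numeric vector of resistant-group values.
#' @param range A [normal_range()].
#' @return Named numeric vector with `raw` and `abs` components.
#' @export
deviation_score <- function(resistant_values, range) {
  stopifnot(inherits(range, "normal_range"))
  if (length(resistant_values) == 0L) {
    stop("empty resistant vector", call. = FALSE)
  }
  over <- pmax(resistant_values - range$x_max, 0)
  under <- pmin(resistant_values - range$x_min, 0)
  c(raw = sum(over) + sum(under), abs = sum(over) - sum(under))
}

# vectorized scoring used by the permutation machinery:
# X is genes x samples; idx1 indexes the sensitive columns
score_matrix <- function(X, idx1) {
  S <- X[, idx1, drop = FALSE]
  R <- X[, -idx1, drop = FALSE]
  mu <- rowMeans(S)
  s <- sqrt(rowSums((S - mu)^2) / (ncol(S) - 1L))
  over <- pmax(R - (mu + s), 0)
  under <- pmin(R - (mu - s), 0)
  pos <- rowSums(over)
  neg <- rowSums(under)
  list(raw = pos + neg, abs = pos - neg, pos = pos, neg = neg)
}

#' Permutation p-value for a single gene's deviation score
#'
#' Randomly reassigns the pooled values to a sensitive group of size `n1`
#' and a resistant group of size `n2`, recomputes the normal range and
#' deviation score for each permutation, and reports the add-one
#' empirical p-value `(#{|score_b| >= |observed|} + 1) / (B + 1)` (for
#' the signed statistic; the absolute statistic compares the already
#' non-negative scores directly).
#'
#' @param all_values Numeric vector of length `n1 + n2` (sensitive values
#'   first in the observed labelling).
#' @param n1,n2 Sensitive and resistant group sizes.
#' @param observed Observed score (signed or absolute, matching
#'   `statistic`).
#' @param n_permutations Number of label permutations (default 10000).
#' @param seed Integer seed.
#' @param statistic `"signed"` (two-sided on the raw score) or
#'   `"absolute"`.
#' @return The permutation p-value in (0, 1].
#' @export
permutation_pvalue <- function(all_values, n1, n2, observed,
                               n_permutations = 10000L, seed = 1L,
                               statistic = c("signed", "absolute")) {
  statistic <- match.arg(statistic)
  if (length(all_values) != n1 + n2) {
    stop("length(all_values) must equal n1 + n2", call. = FALSE)
  }
  if (n1 < 2L) stop("n1 must be >= 2 (normal range undefined)", call. = FALSE)
  if (n_permutations < 1L) stop("need at least one permutation", call. = FALSE)
  X <- matrix(all_values, nrow = 1L)
  set.seed(seed)
  n <- n1 + n2
  count <- 0L
  target <- if (statistic == "signed") abs(observed) else observed
  for (b in seq_len(n_permutations)) {
    p <- sample.int(n)
    sc <- score_matrix(X[, p, drop = FALSE], seq_len(n1))
    stat_b <- if (statistic == "signed") abs(sc$raw) else sc$abs
    if (stat_b >= target) count <- count + 1L
  }
  (count + 1L) / (n_permutations + 1L)
}

#' Detect differentially expressed genes by permutation-tested deviation
#'
#' For every gene, builds the sensitive-group normal range, accumulates
#' the deviation score over resistant samples, and tests it against a
#' null distribution obtained by randomly re-labelling samples (one
#' shared, seeded sequence of label shuffles is reused across all genes).
#' A gene is called significant when its permutation p-value falls below
#' `alpha` (no multiple-testing correction, matching the raw P < 0.05
#' call; a Benjamini-Hochberg column is emitted for reference).
#'
#' @param m Gene-by-sample numeric matrix.
#' @param annotation Sample annotation data frame with `sample_id` and
#'   `response` (`CR` = sensitive, `NOCR` = resistant).
#' @param n_permutations Number of label permutations (default 10000).
#' @param alpha Significance level (default 0.05).
#' @param seed Integer seed for the shared permutation stream.
#' @param statistic `"signed"` (default; tested two-sided via absolute
#'   value) or `"absolute"` (sum of deviation magnitudes).
#' @return A data frame with columns `gene_id`, `raw_score`, `abs_score`,
#'   `p_value`, `p_adjust` (BH, reference only), `significant`,
#'   `direction` (`up`, `down`, `mixed`, `none`).
#' @export
detect_degs <- function(m, annotation, n_permutations = 10000L,
                        alpha = 0.05, seed = 1L,
                        statistic = c("signed", "absolute")) {
  statistic <- match.arg(statistic)
  assert_expression_matrix(m)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  ann <- match_annotation(colnames(m), annotation)
  sens <- colnames(m)[ann$response == "CR"]
  res <- colnames(m)[ann$response == "NOCR"]
  n1 <- length(sens)
  n2 <- length(res)
  if (n1 < 2L) stop("need at least 2 sensitive (CR) samples", call. = FALSE)
  if (n2 < 1L) stop("need at least 1 resistant (NOCR) sample", call. = FALSE)

  X <- m[, c(sens, res), drop = FALSE]
  obs <- score_matrix(X, seq_len(n1))
  obs_stat <- if (statistic == "signed") abs(obs$raw) else obs$abs

  set.seed(seed)
  n <- n1 + n2
  count <- integer(nrow(X))
  for (b in seq_len(n_permutations)) {
    p <- sample.int(n)
    sc <- score_matrix(X[, p, drop = FALSE], seq_len(n1))
    stat_b <- if (statistic == "signed") abs(sc$raw) else sc$abs
    count <- count + (stat_b >= obs_stat)
  }
  p_value <- (count + 1L) / (n_permutations + 1L)

  tol <- 1e-12
  direction <- rep("mixed", nrow(X))
  direction[obs$abs <= tol] <- "none"
  direction[obs$abs > tol & obs$neg >= -tol] <- "up"
  direction[obs$abs > tol & obs$pos <= tol] <- "down"

  data.frame(gene_id = rownames(X),
             raw_score = obs$raw,
             abs_score = obs$abs,
             p_value = p_value,
             p_adjust = stats::p.adjust(p_value, method = "BH"),
             significant = p_value < alpha,
             direction = direction,
             row.names = NULL,
             stringsAsFactors = FALSE)
}
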