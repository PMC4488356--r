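# independent brute-force oracles used to cross-check the implementation

# clamped-sum deviation score, one value at a time
oracle_deviation <- function(values, x_min, x_max) {
  raw <- 0
  abs_ <- 0
  for (v in values) {
    contrib <- if (v > x_max) v - x_max else if (v < x_min) v - x_min else 0
    raw <- raw + contrib
    abs_ <- abs_ + abs(contrib)
  }
  c(raw = raw, abs = abs_)
}

# exact permutation p: enumerate every split of the pooled values into a
# sensitive set of size n1, score the complement, and count extreme splits
oracle_perm_exact <- function(all_values, n1, statistic = "signed") {
  n <- length(all_values)
  obs <- oracle_score_split(all_values, seq_len(n1))
  obs_stat <- if (statistic == "signed") abs(obs[["raw"]]) else obs[["abs"]]
  combos <- utils::combn(n, n1)
  stats <- apply(combos, 2L, function(idx) {
    sc <- oracle_score_split(all_values, idx)
    if (statistic == "signed") abs(sc[["raw"]]) else sc[["abs"]]
  })
  mean(stats >= obs_stat - 1e-12)
}

oracle_score_split <- function(all_values, sens_idx) {
  s <- all_values[sens_idx]
  r <- all_values[-sens_idx]
  mu <- mean(s)
  sdev <- stats::sd(s)
  oracle_deviation(r, mu - sdev, mu + sdev)
}

# hypergeometric upper tail from explicit binomial coefficients
oracle_hyper_upper <- function(k, K, N, n) {
  ks <- seq(max(k, 0L), min(K, n))
  if (length(ks) == 0L) return(0)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# Benjamini-Hochberg step-up from its definition
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(ord == i)
    q[i] <- min(1, min(p[ord][rank_i:m] * m / (rank_i:m)))
  }
  q
}

# adjacency-list degree counting on an undirected simple edge matrix
oracle_degrees <- function(edges, nodes) {
  deg <- stats::setNames(integer(length(nodes)), nodes)
  seen <- character(0)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1L]; b <- edges[i, 2L]
    if (!(a %in% nodes) || !(b %in% nodes) || a == b) next
    key <- paste(sort(c(a, b)), collapse = "|")
    if (key %in% seen) next
    seen <- c(seen, key)
    deg[a] <- deg[a] + 1L
    deg[b] <- deg[b] + 1L
  }
  deg
}

# confusion-matrix classification metrics, counted label by label
oracle_report <- function(true, pred, labels) {
  out <- list()
  for (lb in labels) {
    tp <- 0; fp <- 0; fn <- 0
    for (i in seq_along(true)) {
      if (pred[i] == lb && true[i] == lb) tp <- tp + 1
      if (pred[i] == lb && true[i] != lb) fp <- fp + 1
      if (pred[i] != lb && true[i] == lb) fn <- fn + 1
    }
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
    out[[lb]] <- c(precision = precision, recall = recall, f1 = f1,
                   support = tp + fn)
  }
  out
}

# labels with an exact confusion matrix (tp/fp/fn/tn) for a binary task
make_labels <- function(tp, fp, fn, tn, pos = "pos", neg = "neg") {
  true <- c(rep(pos, tp), rep(neg, fp), rep(pos, fn), rep(neg, tn))
  pred <- c(rep(pos, tp), rep(pos, fp), rep(neg, fn), rep(neg, tn))
  list(true = true, pred = pred)
}
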