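# Independent oracles and small fixture builders shared across tests.
# Oracles are deliberately naive (double loops, grid search, exhaustive
# enumeration) and never call the implementation paths they check.

# small planted-structure cohort, cheap enough for unit tests
small_spec <- function(seed = 1L, fc = 4, n1 = 20, n2 = 20, n_benign = 0) {
  simulation_spec(
    n_per_cluster = c(n1, n2), n_genes = 200, n_informative = 20,
    log2_fold_change = fc, n_benign = n_benign, seed = seed
  )
}

# brute-force squared Euclidean distances, double loop
brute_sq_dist <- function(X) {
  n <- nrow(X)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d[i, j] <- sum((X[i, ] - X[j, ])^2)
  }
  d
}

# scalar double-loop cross-entropy
brute_cross_entropy <- function(P, Q, eps = 1e-12) {
  n <- nrow(P)
  ce <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    p <- P[i, j]; q <- Q[i, j]
    ce <- ce + p * log((p + eps) / (q + eps)) +
      (1 - p) * log((1 - p + eps) / (1 - q + eps))
  }
  ce
}

# central finite differences of the embedding objective
fd_gradient <- function(P, Y, kernel, h = 1e-5) {
  fd <- matrix(0, nrow(Y), ncol(Y))
  for (i in seq_len(nrow(Y))) for (j in seq_len(ncol(Y))) {
    Yp <- Y; Yp[i, j] <- Yp[i, j] + h
    Ym <- Y; Ym[i, j] <- Ym[i, j] - h
    fd[i, j] <- (cross_entropy(P, low_dim_probabilities(Yp, kernel)$Q) -
                   cross_entropy(P, low_dim_probabilities(Ym, kernel)$Q)) / (2 * h)
  }
  fd
}

# two-group log-rank chi-square statistic, computed from first principles
# (observed minus expected events over shared event times)
naive_logrank_chisq <- function(times, events, labels) {
  labels <- as.integer(factor(labels))
  ts <- sort(unique(times[events == 1]))
  o_minus_e <- 0; v <- 0
  for (t in ts) {
    at_risk <- times >= t
    n1 <- sum(at_risk & labels == 1); n2 <- sum(at_risk & labels == 2)
    d1 <- sum(times == t & events == 1 & labels == 1)
    d2 <- sum(times == t & events == 1 & labels == 2)
    d <- d1 + d2; n <- n1 + n2
    if (n < 2 || d == 0) next
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    v <- v + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  if (v == 0) return(0)
  o_minus_e^2 / v
}

# Breslow partial log-likelihood for a binary covariate at coefficient b
breslow_loglik <- function(beta, times, events, x) {
  ll <- 0
  for (t in sort(unique(times[events == 1]))) {
    dead <- which(times == t & events == 1)
    risk <- which(times >= t)
    ll <- ll + sum(beta * x[dead]) -
      length(dead) * log(sum(exp(beta * x[risk])))
  }
  ll
}

grid_cox_beta <- function(times, events, x, lo = -5, hi = 5, step = 1e-4) {
  grid <- seq(lo, hi, by = step)
  ll <- vapply(grid, breslow_loglik, numeric(1), times, events, x)
  grid[which.max(ll)]
}

# naive double-loop consensus counting over per-model top lists
naive_consensus <- function(top_lists, top_k) {
  genes <- sort(unique(unlist(top_lists)))
  count <- integer(length(genes)); rank_sum <- numeric(length(genes))
  for (gi in seq_along(genes)) {
    for (tl in top_lists) {
      pos <- match(genes[gi], tl)
      if (!is.na(pos)) {
        count[gi] <- count[gi] + 1
        rank_sum[gi] <- rank_sum[gi] + pos
      }
    }
  }
  mean_rank <- rank_sum / count
  ord <- order(-count, mean_rank, genes)
  data.frame(gene = genes[ord], count = count[ord],
             mean_rank = mean_rank[ord], stringsAsFactors = FALSE)
}

# fake ModelRun list from explicit top lists (for aggregation tests)
fake_runs <- function(top_lists) {
  lapply(seq_along(top_lists), function(i) {
    structure(list(model_seed = i, accuracy = 1,
                   top_genes = top_lists[[i]]), class = "ModelRun")
  })
}

# minimal mismatch between two binary labelings over both permutations
brute_mismatch <- function(a, b) {
  min(sum(a != b), sum(a == b))
}
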