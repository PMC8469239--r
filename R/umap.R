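# UMAP variant for two-cluster subtype discovery. Deliberate deviations from
# canonical UMAP, reproduced here as the method under study: squared Euclidean
# input distances; mean symmetrization (P_cond + t(P_cond)) / 2 instead of the
# fuzzy union; a globally normalized low-dimensional Q; full-batch gradient
# descent on the exact cross-entropy (no negative sampling, no spectral init).

# ---- high-dimensional graph -------------------------------------------------

#' Squared pairwise Euclidean distances between samples
#'
#' @param X numeric matrix, samples in rows, features in columns; all
#'   values finite.
#' @return symmetric n x n matrix of squared Euclidean distances with an
#'   exact zero diagonal.
#' @export
pairwise_sq_euclidean <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need >= 2 samples")
  if (!all(is.finite(X))) stop("non-finite values in input matrix")
  sq <- rowSums(X^2)
  d <- outer(sq, sq, "+") - 2 * tcrossprod(X)
  d[d < 0] <- 0            # clamp tiny negative round-off
  d <- (d + t(d)) / 2
  diag(d) <- 0
  dimnames(d) <- list(rownames(X), rownames(X))
  d
}

#' Per-sample local connectivity (distance to the first nearest neighbor)
#'
#' @param d squared distance matrix from [pairwise_sq_euclidean()].
#' @return numeric vector rho with rho_i = min over j != i of d[i, j].
#' @export
local_connectivity <- function(d) {
  n <- nrow(d)
  if (n < 2) stop("need >= 2 samples")
  vapply(seq_len(n), function(i) min(d[i, -i]), numeric(1))
}

#' Smooth effective neighbor count for one sample at a given bandwidth
#'
#' Row conditional probabilities are p_j|i = exp(-max(0, d_ij - rho_i) /
#' sigma); their sum plays the role of an entropy and 2^sum is the smooth
#' number of neighbors the bandwidth calibration drives to `n_neighbors`.
#'
#' @param d_row distances from sample i to the other samples (self
#'   excluded).
#' @param rho local connectivity of sample i.
#' @param sigma bandwidth > 0.
#' @return list with `p` (conditional probabilities) and `k` (= 2^sum(p)).
#' @export
neighbor_count <- function(d_row, rho, sigma) {
  if (sigma <= 0) stop("sigma must be > 0")
  p <- exp(-pmax(0, d_row - rho) / sigma)
  list(p = p, k = 2^sum(p))
}

#' Calibrate a per-sample bandwidth by binary search
#'
#' Finds sigma such that the smooth neighbor count 2^sum(p_j|i) equals
#' `k_target` (15 by default throughout the pipeline). The bracket upper
#' end doubles from 1 until the count reaches the target or a cap; rows
#' where the count cannot reach the target (e.g. every distance equal to
#' rho, making the count sigma-independent) are flagged non-converged and
#' returned with the bracket cap rather than aborting the run.
#'
#' @param d_row,rho as in [neighbor_count()].
#' @param k_target desired effective neighbor count; must satisfy
#'   k_target <= n - 1 to be reachable.
#' @param tol convergence tolerance on |k - k_target|.
#' @param max_iter bisection iterations.
#' @return list with `sigma`, `k` (achieved count), `converged` flag.
#' @export
calibrate_sigma <- function(d_row, rho, k_target, tol = 1e-5,
                            max_iter = 200L) {
  if (k_target > length(d_row) + 1) {
    stop("k_target exceeds n - 1: unreachable neighbor count")
  }
  cap <- 1e9
  hi <- 1
  while (neighbor_count(d_row, rho, hi)$k < k_target && hi < cap) hi <- hi * 2
  if (neighbor_count(d_row, rho, hi)$k < k_target - tol) {
    # count is (near) sigma-independent and below target: degenerate row
    return(list(sigma = hi, k = neighbor_count(d_row, rho, hi)$k,
                converged = FALSE))
  }
  lo <- 0
  sigma <- hi
  for (it in seq_len(max_iter)) {
    sigma <- (lo + hi) / 2
    k <- neighbor_count(d_row, rho, sigma)$k
    if (abs(k - k_target) <= tol) {
      return(list(sigma = sigma, k = k, converged = TRUE))
    }
    if (k > k_target) hi <- sigma else lo <- sigma
  }
  k <- neighbor_count(d_row, rho, sigma)$k
  list(sigma = sigma, k = k, converged = abs(k - k_target) <= tol)
}

#' Build the symmetric high-dimensional fuzzy graph
#'
#' Conditional probabilities use per-row calibrated bandwidths; the
#' symmetrization is the plain mean P = (P_cond + t(P_cond)) / 2 — not the
#' canonical fuzzy union P + t(P) - P * t(P).
#'
#' @param d squared distance matrix.
#' @param k_target effective neighbor count (default 15).
#' @param tol,max_iter passed to [calibrate_sigma()].
#' @return object of class `FuzzyGraph`: list with `P` (symmetric,
#'   zero-diagonal, entries in [0, 1]), `rho`, `sigma`, `converged` (per
#'   sample), `k_target`.
#' @export
fuzzy_graph <- function(d, k_target = 15, tol = 1e-5, max_iter = 200L) {
  n <- nrow(d)
  rho <- local_connectivity(d)
  sigma <- numeric(n); conv <- logical(n)
  P_cond <- matrix(0, n, n)
  for (i in seq_len(n)) {
    cal <- calibrate_sigma(d[i, -i], rho[i], k_target, tol, max_iter)
    sigma[i] <- cal$sigma
    conv[i] <- cal$converged
    P_cond[i, -i] <- neighbor_count(d[i, -i], rho[i], cal$sigma)$p
  }
  if (any(!conv)) {
    warning(sum(!conv), " sample(s) with degenerate bandwidth calibration; ",
            "bracket cap used")
  }
  P <- (P_cond + t(P_cond)) / 2
  diag(P) <- 0
  structure(list(P = P, rho = rho, sigma = sigma, converged = conv,
                 k_target = k_target),
            class = "FuzzyGraph")
}

# ---- low-dimensional kernel -------------------------------------------------

#' Fit the low-dimensional kernel parameters (a, b) from min_dist
#'
#' Least-squares fit of g(d) = 1 / (1 + a d^(2b)) to the target curve
#' h(d) = 1 for d <= min_dist and exp(-(d - min_dist)) beyond, over the
#' grid d in [0, 3] with step 0.01. Distances here are Euclidean (not
#' squared), matching the min_dist semantics.
#'
#' @param min_dist minimum-distance hyperparameter (> 0); the analysis
#'   default is 0.25.
#' @return object of class `LowDimKernel`: list with `a`, `b`, `min_dist`,
#'   `rmse` of the fit over the grid.
#' @export
fit_low_dim_kernel <- function(min_dist = 0.25) {
  if (min_dist <= 0) stop("min_dist must be > 0")
  d <- seq(0, 3, by = 0.01)
  h <- ifelse(d <= min_dist, 1, exp(-(d - min_dist)))
  obj <- function(par) {
    a <- exp(par[1]); b <- exp(par[2])
    g <- 1 / (1 + a * d^(2 * b))
    sum((g - h)^2)
  }
  fit <- stats::optim(c(0, 0), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  if (fit$convergence != 0) {
    stop("kernel curve fit failed to converge; residual SS = ",
         format(fit$value))
  }
  a <- exp(fit$par[1]); b <- exp(fit$par[2])
  structure(list(a = a, b = b, min_dist = min_dist,
                 rmse = sqrt(fit$value / length(d))),
            class = "LowDimKernel")
}

#' Normalized low-dimensional similarity matrix Q
#'
#' Raw similarities q_ij = 1 / (1 + a ||y_i - y_j||^(2b)) with zero
#' diagonal are normalized by their off-diagonal grand total, so that the
#' entries of Q sum to 1 — the "normalized Q" entering the cross-entropy.
#'
#' @param Y n x m embedding coordinates.
#' @param kernel a [fit_low_dim_kernel()] result.
#' @return list with `Q` (normalized), `w` (raw similarities), `S`
#'   (off-diagonal total of `w`), `dist` (Euclidean distance matrix).
#' @export
low_dim_probabilities <- function(Y, kernel) {
  Y <- as.matrix(Y)
  dist <- sqrt(pairwise_sq_euclidean(Y))
  w <- 1 / (1 + kernel$a * dist^(2 * kernel$b))
  diag(w) <- 0
  S <- sum(w)
  list(Q = w / S, w = w, S = S, dist = dist)
}

#' Fuzzy cross-entropy between the graphs P and Q
#'
#' CE = sum over i != j of P log((P + eps) / (Q + eps)) +
#' (1 - P) log((1 - P + eps) / (1 - Q + eps)), eps = 1e-12.
#'
#' @param P high-dimensional fuzzy graph matrix.
#' @param Q normalized low-dimensional matrix (same shape).
#' @param eps numerical guard.
#' @return scalar cross-entropy.
#' @export
cross_entropy <- function(P, Q, eps = 1e-12) {
  stopifnot(all(dim(P) == dim(Q)))
  off <- row(P) != col(P)
  p <- P[off]; q <- Q[off]
  sum(p * log((p + eps) / (q + eps)) +
        (1 - p) * log((1 - p + eps) / (1 - q + eps)))
}

#' Analytic gradient of the cross-entropy with respect to the embedding
#'
#' Differentiates cross_entropy(P, Q(Y)) including the coupling introduced
#' by the global normalization of Q (every coordinate moves every Q entry
#' through the grand total S).
#'
#' @param P fuzzy graph matrix.
#' @param Y n x m coordinates.
#' @param kernel [fit_low_dim_kernel()] result.
#' @param eps guard matching [cross_entropy()].
#' @return n x m gradient matrix.
#' @export
ce_gradient <- function(P, Y, kernel, eps = 1e-12) {
  Y <- as.matrix(Y)
  lq <- low_dim_probabilities(Y, kernel)
  Q <- lq$Q; w <- lq$w; S <- lq$S; dist <- lq$dist
  a <- kernel$a; b <- kernel$b

  G <- -P / (Q + eps) + (1 - P) / (1 - Q + eps)   # dCE/dQ, off-diagonal
  diag(G) <- 0
  # dQ_ij/dw_kl = delta_{ij,kl}/S - w_ij/S^2  =>  chain through the total
  M <- G / S - sum(G * w) / S^2
  diag(M) <- 0
  # dw_ij/dy_i = -2ab d^(2b-2) w^2 (y_i - y_j); guard d = 0 (w' -> finite
  # only for b >= 1; coincident points get zero force, consistent with the
  # symmetric limit)
  dpow <- dist
  dpow[dpow == 0] <- Inf
  K <- -2 * a * b * dpow^(2 * b - 2) * w^2
  K[!is.finite(K)] <- 0          # coincident pairs and the diagonal
  diag(K) <- 0
  coef <- (M + t(M)) * K
  grad <- rowSums(coef) * Y - coef %*% Y
  grad
}

# ---- optimization -----------------------------------------------------------

#' Embed samples by full-batch gradient descent on the cross-entropy
#'
#' Builds the fuzzy graph at `n_neighbors`, fits the low-dimensional
#' kernel from `min_dist`, initializes coordinates from a seeded standard
#' normal, and runs plain (non-stochastic) gradient descent with a
#' linearly decaying learning rate, recording the cross-entropy each
#' epoch.
#'
#' @param X numeric matrix, samples x features (log-scale expression for
#'   the subtype analysis).
#' @param n_neighbors effective neighbor count for bandwidth calibration
#'   (default 15).
#' @param min_dist kernel hyperparameter (default 0.25).
#' @param n_components embedding dimensionality (default 2).
#' @param n_epochs gradient-descent epochs (default 300).
#' @param learning_rate initial step size, decayed linearly to
#'   `learning_rate_final` (defaults 1.0 -> 0.1).
#' @param learning_rate_final final step size.
#' @param seed RNG seed for the initialization; same seed, same embedding.
#' @return object of class `Embedding`: list with `Y` (n x n_components,
#'   rownames = sample ids), `ce_trace` (length n_epochs + 1), `graph`
#'   (the `FuzzyGraph`), `kernel`, `config`, `seed`.
#' @export
umap_embed <- function(X, n_neighbors = 15, min_dist = 0.25,
                       n_components = 2, n_epochs = 300,
                       learning_rate = 1.0, learning_rate_final = 0.1,
                       seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n_neighbors < 2 || n_neighbors >= n) {
    stop("need 2 <= n_neighbors < n_samples")
  }
  d <- pairwise_sq_euclidean(X)
  graph <- fuzzy_graph(d, k_target = n_neighbors)
  kernel <- fit_low_dim_kernel(min_dist)

  set.seed(seed)
  Y <- matrix(stats::rnorm(n * n_components, sd = 1), n, n_components)
  rownames(Y) <- rownames(X)

  lr <- seq(learning_rate, learning_rate_final, length.out = max(n_epochs, 1))
  ce_trace <- numeric(n_epochs + 1)
  ce_trace[1] <- cross_entropy(graph$P, low_dim_probabilities(Y, kernel)$Q)
  for (e in seq_len(n_epochs)) {
    grad <- ce_gradient(graph$P, Y, kernel)
    Y <- Y - lr[e] * grad
    ce <- cross_entropy(graph$P, low_dim_probabilities(Y, kernel)$Q)
    if (!is.finite(ce)) {
      stop("non-finite cross-entropy at epoch ", e, "; descent diverged")
    }
    ce_trace[e + 1] <- ce
  }
  structure(
    list(Y = Y, ce_trace = ce_trace, graph = graph, kernel = kernel,
         config = list(n_neighbors = n_neighbors, min_dist = min_dist,
                       n_components = n_components, n_epochs = n_epochs,
                       learning_rate = learning_rate,
                       learning_rate_final = learning_rate_final),
         seed = seed),
    class = "Embedding"
  )
}

#' @export
print.Embedding <- function(x, ...) {
  cat(sprintf(
    "Embedding: %d samples in %d dims; CE %.4f -> %.4f over %d epochs\n",
    nrow(x$Y), ncol(x$Y), x$ce_trace[1], x$ce_trace[length(x$ce_trace)],
    x$config$n_epochs
  ))
  invisible(x)
}

#' Embed an expression matrix (samples as points)
#'
#' Thin wrapper over [umap_embed()]: log2(FPKM + 1)-transforms the matrix
#' unless it already is (or `log_transform = "none"`), then embeds the
#' transposed matrix so each sample becomes a point.
#'
#' @param x an `ExpressionMatrix`.
#' @param log_transform `"log2p1"` (default) or `"none"`.
#' @param ... passed to [umap_embed()].
#' @return an `Embedding`.
#' @export
embed_expression <- function(x, log_transform = c("log2p1", "none"), ...) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  log_transform <- match.arg(log_transform)
  if (log_transform == "log2p1" && !x$log_transformed) {
    x <- accumap::log_transform(x)
  }
  umap_embed(t(x$values), ...)
}
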