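test_that("Kaplan-Meier product-limit matches hand calculations", {
  # events at 1, 2, 3, no censoring
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(km$median, 2)

  # censor at 2: S(1) = 2/3, risk set shrinks, S(3) = 0
  km2 <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km2$surv[km2$time == 1], 2 / 3)
  expect_equal(km2$surv[km2$time == 3], 0)

  # all censored: S identically 1, median undefined
  km3 <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km3$surv == 1))
  expect_true(is.na(km3$median))

  expect_error(km_estimate(numeric(0), numeric(0)), "empty")
  expect_error(km_estimate(c(-1, 2), c(1, 1)), "> 0")
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(50)
  t <- round(stats::rexp(40, 0.2), 3)
  km <- km_estimate(t, rep(1, 40))
  emp <- vapply(km$time, function(u) mean(t > u), numeric(1))
  expect_equal(km$surv, emp, tolerance = 1e-12)
})

test_that("log-rank statistic is zero on duplicated groups and symmetric in labels", {
  t <- c(1, 2, 3, 4, 5); e <- c(1, 1, 0, 1, 1)
  res <- logrank_test(c(t, t), c(e, e), rep(c("A", "B"), each = 5))
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1)
  set.seed(51)
  tt <- stats::rexp(30); ee <- stats::rbinom(30, 1, 0.8)
  ll <- rep(c("A", "B"), 15)
  r1 <- logrank_test(tt, ee, ll)
  r2 <- logrank_test(tt, ee, ifelse(ll == "A", "B", "A"))
  expect_equal(r1$statistic, r2$statistic)
})

test_that("log-rank chi-square matches the first-principles oracle and its permutation null", {
  set.seed(52)
  times <- c(stats::rexp(10, 0.2), stats::rexp(10, 0.8))
  events <- stats::rbinom(20, 1, 0.9)
  labels <- rep(c("A", "B"), each = 10)
  res <- logrank_test(times, events, labels)
  expect_equal(res$statistic, naive_logrank_chisq(times, events, labels),
               tolerance = 1e-8)
  # permutation null of the same statistic: asymptotic p within the
  # combined Monte-Carlo + chi-square approximation error
  obs <- res$statistic
  perm <- vapply(1:2000, function(i) {
    naive_logrank_chisq(times, events, sample(labels))
  }, numeric(1))
  expect_lt(abs(mean(perm >= obs - 1e-12) - res$p_value), 0.05)
  # no events at all: warning and p = 1
  expect_warning(r0 <- logrank_test(c(1, 2), c(0, 0), c("A", "B")), "no events")
  expect_equal(r0$p_value, 1)
})

test_that("Cox estimate equals the grid-search Breslow oracle on toy data", {
  times <- c(1, 3, 2, 4); events <- c(1, 1, 1, 1)
  x <- c(0, 0, 1, 1)
  fit <- cox_univariate(times, events, x)
  oracle <- grid_cox_beta(times, events, x)
  expect_lt(abs(fit$beta - oracle), 1e-3)
  expect_equal(fit$hazard_ratio, exp(fit$beta))
  expect_true(fit$ci_lower <= fit$hazard_ratio &
                fit$hazard_ratio <= fit$ci_upper)

  set.seed(53)
  t2 <- stats::rexp(30, 0.3); e2 <- stats::rbinom(30, 1, 0.8)
  x2 <- rep(0:1, 15)
  fit2 <- cox_univariate(t2, e2, x2)
  expect_lt(abs(fit2$beta - grid_cox_beta(t2, e2, x2)), 1e-3)
})

test_that("Cox beta is zero for exchangeable groups and flags monotone likelihood", {
  t <- c(1, 2, 3, 4, 5)
  e <- c(1, 1, 0, 1, 1)
  fit <- cox_univariate(c(t, t), c(e, e), rep(0:1, each = 5))
  expect_lt(abs(fit$beta), 1e-6)
  # complete separation: all events in one group at the extremes
  sep <- suppressWarnings(
    cox_univariate(c(1, 2, 3, 10, 11, 12), c(1, 1, 1, 1, 1, 1),
                   c(1, 1, 1, 0, 0, 0)))
  expect_false(sep$converged)
})

test_that("Kruskal-Wallis reproduces the hand rank-sum value 27/7 and edge cases", {
  res <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(res$statistic, 27 / 7, tolerance = 1e-12)
  expect_equal(res$df, 1)

  same <- kruskal_wallis(list(c(2, 2, 2), c(2, 2, 2)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_true(same$degenerate)

  dup <- kruskal_wallis(list(c(1, 5, 9), c(1, 5, 9)))
  expect_equal(dup$statistic, 0, tolerance = 1e-12)
  expect_equal(dup$p_value, 1)

  expect_error(kruskal_wallis(list(1:3)), ">= 2 groups")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "non-empty")
})

test_that("Kruskal-Wallis tie correction matches the hand formula on binary data", {
  # tie-corrected H computed from first principles:
  # H = [12 / (N(N+1)) * sum R_j^2 / n_j - 3(N+1)] / [1 - sum(t^3 - t) / (N^3 - N)]
  hand_H <- function(groups) {
    vals <- unlist(groups)
    N <- length(vals)
    r <- rank(vals)
    Rj <- vapply(split(r, rep(seq_along(groups), lengths(groups))), sum,
                 numeric(1))
    H <- 12 / (N * (N + 1)) * sum(Rj^2 / lengths(groups)) - 3 * (N + 1)
    ties <- table(vals)
    H / (1 - sum(ties^3 - ties) / (N^3 - N))
  }
  g1 <- c(1, 1, 1, 1, 0); g2 <- c(0, 0, 0, 0, 1)
  res <- kruskal_wallis(list(g1, g2))
  expect_equal(res$statistic, hand_H(list(g1, g2)), tolerance = 1e-12)
  set.seed(61)
  for (rep in 1:5) {
    gs <- list(rbinom(8, 1, 0.4), rbinom(9, 1, 0.6), rbinom(7, 1, 0.5))
    expect_equal(kruskal_wallis(gs)$statistic, hand_H(gs), tolerance = 1e-10)
  }
})

test_that("Kruskal-Wallis p on tied binary data tracks its permutation null", {
  set.seed(62)
  v <- rbinom(30, 1, 0.5); v[1:10] <- pmin(v[1:10] + rbinom(10, 1, 0.5), 1)
  res <- kruskal_wallis(list(v[1:15], v[16:30]))
  perm <- vapply(1:4000, function(i) {
    pv <- sample(v)
    kruskal_wallis(list(pv[1:15], pv[16:30]))$statistic
  }, numeric(1))
  # binary data make the permutation distribution coarsely discrete: the
  # continuous chi-square p must fall between the strict and non-strict
  # permutation tails (with a Monte-Carlo margin)
  p_ge <- mean(perm >= res$statistic - 1e-12)
  p_gt <- mean(perm > res$statistic + 1e-12)
  expect_gte(res$p_value, p_gt - 0.03)
  expect_lte(res$p_value, p_ge + 0.03)
})

test_that("mutation association: degenerate, internally consistent, symmetric", {
  ids <- sprintf("s%02d", 1:76)
  lab <- stats::setNames(rep(c(1, 2), c(40, 36)), ids)

  zero <- mutation_table(ids, rep("APC", 76), rep(0, 76))
  r0 <- mutation_cluster_association(zero, lab)
  expect_equal(r0$kw_p, 1)

  # counts 1/40 vs 11/36, the scale of a strongly cluster-enriched driver
  mut <- mutation_table(ids, rep("TP53", 76),
                        c(1, rep(0, 39), rep(1, 11), rep(0, 25)))
  r <- mutation_cluster_association(mut, lab)
  expect_identical(r$mut1, 1L)
  expect_identical(r$mut2, 11L)
  # internal consistency: equals kruskal_wallis run on the expanded vectors
  kw <- kruskal_wallis(list(c(1, rep(0, 39)), c(rep(1, 11), rep(0, 25))))
  expect_equal(r$kw_p, kw$p_value)
  # permutation oracle on the binary indicator
  pool <- mut$mutated
  perm <- vapply(1:4000, function(i) {
    pp <- sample(pool)
    kruskal_wallis(list(pp[1:40], pp[41:76]))$statistic
  }, numeric(1))
  expect_lt(abs(mean(perm >= kw$statistic - 1e-12) - r$kw_p), 0.05)
  # swapping cluster labels leaves p unchanged
  r_sw <- mutation_cluster_association(mut, stats::setNames(3 - lab, ids))
  expect_equal(r_sw$kw_p, r$kw_p)
  # absent gene listed as missing, not fatal
  rm <- mutation_cluster_association(mut, lab, genes = c("TP53", "GNAS"))
  expect_true(rm$missing[rm$gene == "GNAS"])
})

test_that("significance tiers are a pure threshold function of p", {
  expect_identical(significance_tier(c(0.5, 0.05, 0.049, 0.01, 0.009,
                                       1e-4, 9e-5, NA)),
                   c("ns", "ns", "p<0.05", "p<0.05", "p<0.01",
                     "p<0.01", "p<0.0001", NA))
})

test_that("group expression comparison: degenerate ns, planted power, skipped pairs", {
  # literally identical values in all groups: every pair degenerate ns
  ids <- sprintf("s%02d", 1:30)
  x <- expression_matrix(matrix(7, 2, 30), c("gA", "gB"), ids)
  grp <- stats::setNames(rep(c("cluster1", "cluster2", "NAG"), each = 10), ids)
  res <- group_expression_comparison(x, grp, c("gA", "gB"))
  expect_true(all(res$tier == "ns"))

  # planted gene high in cluster2 only: cluster2-vs-NAG significant
  set.seed(60)
  vals <- matrix(2^(stats::rnorm(60, 3, 0.5)), 1)
  vals[1, 21:40] <- 2^(stats::rnorm(20, 7, 0.5))   # the cluster2 samples
  xx <- expression_matrix(rbind(vals, matrix(1, 1, 60)), c("hit", "flat"),
                          sprintf("t%02d", 1:60))
  gg <- stats::setNames(rep(c("cluster1", "cluster2", "NAG"), each = 20),
                        xx$sample_ids)
  rr <- group_expression_comparison(xx, gg, "hit")
  hit_pair <- rr[rr$group1 == "cluster2" & rr$group2 == "NAG" |
                   rr$group1 == "NAG" & rr$group2 == "cluster2", ]
  expect_lt(hit_pair$p, 0.05)

  # a group with < 2 samples is skipped with a note, not an error
  g3 <- stats::setNames(c("cluster1", rep(c("cluster1", "cluster2"), 14), "NAG"),
                        sprintf("t%02d", 1:30))
  x3 <- expression_matrix(matrix(stats::runif(30), 1), "g",
                          sprintf("t%02d", 1:30))
  r3 <- group_expression_comparison(x3, g3, "g")
  expect_true(all(r3$skipped[r3$group1 == "NAG" | r3$group2 == "NAG"]))
})
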