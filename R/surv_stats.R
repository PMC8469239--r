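# Survival and group statistics behind the subtype comparison. The
# estimators are the standard ones (survival::survfit / survdiff / coxph,
# stats::kruskal.test); this module fixes the conventions used throughout
# the analysis: median survival as the first time S(t) <= 0.5, Breslow tie
# handling in Cox, Kruskal-Wallis for binary mutation indicators, raw
# p-values by default with optional Benjamini-Hochberg.

#' Kaplan-Meier curve for one group
#'
#' Product-limit estimator; censored subjects leave the risk set after
#' their time. Median survival is the first observed time with
#' S(t) <= 0.5 (NA when the curve never reaches 0.5).
#'
#' @param times positive survival/follow-up times.
#' @param events 1 = event (death), 0 = censored.
#' @param group optional label stored on the result.
#' @return list of class `KMCurve`: `time` (ascending unique event/censor
#'   times), `surv`, `n_risk`, `n_event`, `median`, `group`.
#' @export
km_estimate <- function(times, events, group = NA_character_) {
  if (!length(times)) stop("empty group")
  if (any(!is.finite(times) | times <= 0)) stop("times must be finite and > 0")
  if (any(!events %in% c(0, 1))) stop("events must be 0/1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  s <- summary(fit, censored = TRUE)
  med <- {
    hit <- which(fit$surv <= 0.5 & fit$n.event > 0)
    if (length(hit)) fit$time[hit[1]] else NA_real_
  }
  structure(
    list(time = s$time, surv = s$surv, n_risk = s$n.risk,
         n_event = s$n.event, median = med, group = group),
    class = "KMCurve"
  )
}

#' Two-group log-rank test
#'
#' @param times,events as in [km_estimate()].
#' @param labels binary group labels.
#' @return list of class `TestResult`: `statistic` (chi-square, df 1),
#'   `df`, `p_value`, `method`.
#' @export
logrank_test <- function(times, events, labels) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop("labels must have exactly two levels")
  if (any(table(labels) == 0)) stop("both groups must be non-empty")
  if (sum(events) == 0) {
    warning("no events in either group; log-rank undefined, returning p = 1")
    return(structure(list(statistic = 0, df = 1L, p_value = 1,
                          method = "log-rank"), class = "TestResult"))
  }
  sd <- survival::survdiff(survival::Surv(times, events) ~ labels)
  structure(
    list(statistic = sd$chisq, df = 1L,
         p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
         method = "log-rank"),
    class = "TestResult"
  )
}

#' Univariate Cox proportional-hazards regression on a binary covariate
#'
#' Breslow partial likelihood maximized by Newton-Raphson (via
#' `survival::coxph(ties = "breslow")`), Wald confidence interval and
#' p-value. Monotone likelihood (e.g. all events in one group) is
#' reported through the convergence flag rather than fabricated numbers.
#'
#' @param times,events as in [km_estimate()].
#' @param x binary covariate (coded so the hazard ratio is level 2 vs
#'   level 1 of `factor(x)`).
#' @param conf_level Wald CI level (default 0.95).
#' @return list of class `CoxResult`: `beta`, `hazard_ratio`, `ci_lower`,
#'   `ci_upper`, `p_value`, `converged`.
#' @export
cox_univariate <- function(times, events, x, conf_level = 0.95) {
  xf <- as.factor(x)
  if (nlevels(xf) != 2) stop("covariate must be binary")
  xn <- as.numeric(xf) - 1
  fit <- tryCatch(
    survival::coxph(survival::Surv(times, events) ~ xn, ties = "breslow"),
    warning = function(w) {
      f <- suppressWarnings(
        survival::coxph(survival::Surv(times, events) ~ xn, ties = "breslow"))
      attr(f, "cox_warning") <- conditionMessage(w)
      f
    }
  )
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(diag(fit$var)))[1]
  monotone <- !is.null(attr(fit, "cox_warning")) &&
    grepl("infinite|converge", attr(fit, "cox_warning"))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(
    list(beta = beta, hazard_ratio = exp(beta),
         ci_lower = exp(beta - z * se), ci_upper = exp(beta + z * se),
         se = se,
         p_value = 2 * stats::pnorm(-abs(beta / se)),
         converged = !monotone),
    class = "CoxResult"
  )
}

#' Kruskal-Wallis rank test with tie correction
#'
#' @param groups list of >= 2 non-empty numeric vectors.
#' @return `TestResult` with `statistic` (H), `df`, `p_value`,
#'   `degenerate` flag (all values identical across groups => p = 1).
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("need >= 2 groups")
  if (any(!vapply(groups, length, integer(1)))) stop("groups must be non-empty")
  vals <- unlist(groups, use.names = FALSE)
  if (length(unique(vals)) == 1) {
    return(structure(list(statistic = 0, df = length(groups) - 1L,
                          p_value = 1, degenerate = TRUE,
                          method = "Kruskal-Wallis"),
                     class = "TestResult"))
  }
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(vals, g)
  structure(
    list(statistic = unname(kt$statistic), df = unname(kt$parameter),
         p_value = kt$p.value, degenerate = FALSE,
         method = "Kruskal-Wallis"),
    class = "TestResult"
  )
}

#' Mutation-status association with the cluster assignment
#'
#' For each requested gene, tabulates mutated counts per cluster and
#' tests the binary indicator across the two clusters with the
#' Kruskal-Wallis test (the convention used throughout this analysis for
#' clinical and mutation variables); a Fisher's exact column is emitted
#' alongside for reference, clearly not the primary test.
#'
#' @param mutations a `MutationTable`.
#' @param assignment `ClusterAssignment` or named binary labels.
#' @param genes genes to test (default: all in the table).
#' @return data.frame of class `MutationAssociation`: gene, n1, mut1,
#'   n2, mut2, kw_p, fisher_p, missing flag.
#' @export
mutation_cluster_association <- function(mutations, assignment,
                                         genes = NULL) {
  lab <- .rf_labels(NULL, assignment)
  if (is.null(genes)) genes <- sort(unique(mutations$gene))
  lv <- sort(unique(as.character(lab)))
  if (length(lv) != 2) stop("need exactly two clusters")
  out <- do.call(rbind, lapply(genes, function(g) {
    sub <- mutations[mutations$gene == g, , drop = FALSE]
    sub <- sub[sub$sample_id %in% names(lab), , drop = FALSE]
    if (!nrow(sub)) {
      return(data.frame(gene = g, n1 = 0L, mut1 = NA_integer_,
                        n2 = 0L, mut2 = NA_integer_, kw_p = NA_real_,
                        fisher_p = NA_real_, missing = TRUE,
                        stringsAsFactors = FALSE))
    }
    cl <- as.character(lab[sub$sample_id])
    v1 <- sub$mutated[cl == lv[1]]; v2 <- sub$mutated[cl == lv[2]]
    kw <- kruskal_wallis(list(v1, v2))
    fis <- if (length(v1) && length(v2)) {
      m <- matrix(c(sum(v1), length(v1) - sum(v1),
                    sum(v2), length(v2) - sum(v2)), 2)
      stats::fisher.test(m)$p.value
    } else NA_real_
    data.frame(gene = g, n1 = length(v1), mut1 = as.integer(sum(v1)),
               n2 = length(v2), mut2 = as.integer(sum(v2)), kw_p = kw$p_value,
               fisher_p = fis, missing = FALSE, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("MutationAssociation", "data.frame")
  out
}

#' Significance tier used in the figure annotations
#'
#' Pure function of the p-value: `"p<0.0001"`, `"p<0.01"`, `"p<0.05"`,
#' else `"ns"` (boundaries are exclusive: p = 0.05 is ns).
#'
#' @param p p-value(s).
#' @return character vector of tiers.
#' @export
significance_tier <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 1e-4, "p<0.0001",
                ifelse(p < 0.01, "p<0.01",
                       ifelse(p < 0.05, "p<0.05", "ns"))))
}

#' Per-gene pairwise expression comparison across tissue groups
#'
#' For each gene and each pair of groups (e.g. cluster 1, cluster 2,
#' normal adrenal, adenoma), a two-group Kruskal-Wallis test with the
#' significance tier annotation; pairs where a group has fewer than two
#' samples are skipped with a note. Raw p-values by default; an optional
#' Benjamini-Hochberg column across all tests.
#'
#' @param x `ExpressionMatrix`.
#' @param groups named vector (sample id -> group label).
#' @param genes genes to test.
#' @param bh add a BH-adjusted column (default TRUE).
#' @return data.frame: gene, group1, group2, n1, n2, p, tier, skipped
#'   (+ p_bh).
#' @export
group_expression_comparison <- function(x, groups, genes, bh = TRUE) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  ids <- intersect(x$sample_ids, names(groups))
  groups <- groups[ids]
  lv <- sort(unique(as.character(groups)))
  if (length(lv) < 2) stop("need >= 2 groups present")
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  rows <- list()
  for (g in genes) {
    present <- g %in% x$gene_ids
    for (pr in pairs) {
      i1 <- ids[groups == pr[1]]; i2 <- ids[groups == pr[2]]
      if (!present || length(i1) < 2 || length(i2) < 2) {
        rows[[length(rows) + 1]] <- data.frame(
          gene = g, group1 = pr[1], group2 = pr[2],
          n1 = length(i1), n2 = length(i2), p = NA_real_,
          tier = NA_character_, skipped = TRUE, stringsAsFactors = FALSE)
        next
      }
      kw <- kruskal_wallis(list(x$values[g, i1], x$values[g, i2]))
      rows[[length(rows) + 1]] <- data.frame(
        gene = g, group1 = pr[1], group2 = pr[2],
        n1 = length(i1), n2 = length(i2), p = kw$p_value,
        tier = significance_tier(kw$p_value), skipped = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (bh) out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out
}
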