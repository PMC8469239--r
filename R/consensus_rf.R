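# Stability-selection-style marker ranking: many random forests on
# independent stratified 50/50 splits of the raw FPKM matrix, per-model
# top-k importance lists, then aggregation by occurrence count and mean
# rank. Classifiers are `ranger` forests (impurity importance, single
# thread for determinism); the aggregation logic is the method itself.

.rf_labels <- function(x, labels) {
  if (inherits(labels, "ClusterAssignment")) {
    keep <- !labels$outlier & !is.na(labels$cluster)
    stats::setNames(labels$cluster[keep], labels$sample_id[keep])
  } else labels
}

#' Train one random-forest model on a stratified 50/50 split
#'
#' @param x `ExpressionMatrix` of raw (unprocessed) FPKM values — the
#'   classifier deliberately consumes the untransformed matrix even though
#'   the embedding upstream used log-scale values.
#' @param labels a `ClusterAssignment` or named vector of binary cluster
#'   labels; outliers are excluded.
#' @param n_trees trees per forest (default 1000).
#' @param train_fraction fraction of each class placed in the training
#'   split (default 0.5).
#' @param top_k length of the per-model importance list (default 100).
#' @param stratified stratify the split by class (default TRUE).
#' @param model_seed seed controlling both the split and the forest.
#' @return object of class `ModelRun`: list with `model_seed`,
#'   `train_ids`, `test_ids`, `accuracy`, `importance` (named,
#'   non-negative, sums to 1), `top_genes` (ordered, ties broken by gene
#'   id).
#' @export
train_single_model <- function(x, labels, n_trees = 1000,
                               train_fraction = 0.5, top_k = 100,
                               stratified = TRUE, model_seed = 1L) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  lab <- .rf_labels(x, labels)
  ids <- intersect(x$sample_ids, names(lab))
  lab <- factor(lab[ids])
  if (nlevels(lab) != 2) stop("need exactly two classes among labeled samples")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)")
  }
  set.seed(model_seed)
  if (stratified) {
    train_idx <- unlist(lapply(levels(lab), function(lv) {
      pool <- which(lab == lv)
      sample(pool, max(1, round(train_fraction * length(pool))))
    }), use.names = FALSE)
  } else {
    train_idx <- sample(seq_along(ids), max(2, round(train_fraction * length(ids))))
  }
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_along(ids), train_idx)
  if (length(unique(lab[train_idx])) < 2) {
    stop("a class is absent from the training split")
  }
  feats <- t(x$values[, ids, drop = FALSE])
  df_train <- data.frame(feats[train_idx, , drop = FALSE], check.names = FALSE)
  df_train$.cluster <- lab[train_idx]
  fit <- ranger::ranger(
    dependent.variable.name = ".cluster", data = df_train,
    num.trees = n_trees, importance = "impurity",
    seed = model_seed, num.threads = 1
  )
  pred <- stats::predict(fit,
                         data = data.frame(feats[test_idx, , drop = FALSE],
                                           check.names = FALSE),
                         num.threads = 1)$predictions
  acc <- mean(pred == lab[test_idx])
  imp <- fit$variable.importance
  tot <- sum(imp)
  imp <- if (tot > 0) imp / tot else imp
  ord <- order(-imp, names(imp))
  top <- names(imp)[ord][seq_len(min(top_k, length(imp)))]
  structure(
    list(model_seed = model_seed, train_ids = ids[train_idx],
         test_ids = ids[test_idx], accuracy = acc,
         importance = imp, top_genes = top),
    class = "ModelRun"
  )
}

#' Run the model ensemble
#'
#' Trains `n_models` forests on splits whose seeds derive
#' deterministically from `seed`, and summarizes their test accuracies
#' (min / max / mean — the headline bookkeeping of the consensus
#' procedure).
#'
#' @inheritParams train_single_model
#' @param n_models ensemble size (default 100).
#' @param seed base seed; model i uses `seed + i`.
#' @return list of class `EnsembleRuns`: `runs` (list of `ModelRun`),
#'   `accuracy` (vector), `accuracy_summary` (min, max, mean, n_perfect).
#' @export
run_ensemble <- function(x, labels, n_models = 100, n_trees = 1000,
                         train_fraction = 0.5, top_k = 100,
                         stratified = TRUE, seed = 1L) {
  runs <- lapply(seq_len(n_models), function(i) {
    train_single_model(x, labels, n_trees = n_trees,
                       train_fraction = train_fraction, top_k = top_k,
                       stratified = stratified, model_seed = seed + i)
  })
  acc <- vapply(runs, `[[`, numeric(1), "accuracy")
  structure(
    list(runs = runs, accuracy = acc,
         accuracy_summary = c(min = min(acc), max = max(acc),
                              mean = mean(acc),
                              n_perfect = sum(acc == 1))),
    class = "EnsembleRuns"
  )
}

#' Aggregate per-model top lists into a consensus ranking
#'
#' For every gene, counts in how many models it entered the per-model
#' top-k importance list and averages its rank over those models only
#' (rank 1 = most important). The consensus order is occurrence count
#' descending, mean rank ascending, then gene id — and the final list is
#' the first `top_k` genes under that order.
#'
#' @param runs an `EnsembleRuns` or plain list of `ModelRun`s.
#' @param top_k consensus list length (default 100).
#' @param absent_rank_penalty if TRUE, genes absent from a model's top
#'   list contribute rank top_k + 1 to the mean instead of being skipped.
#' @return data.frame of class `ConsensusRanking`: `gene`, `count`,
#'   `mean_rank`, `final_rank` (NA beyond top_k), ordered by the
#'   consensus order; attribute `accuracy_summary` when available.
#' @export
aggregate_consensus <- function(runs, top_k = 100,
                                absent_rank_penalty = FALSE) {
  acc_sum <- NULL
  if (inherits(runs, "EnsembleRuns")) {
    acc_sum <- runs$accuracy_summary
    runs <- runs$runs
  }
  if (!length(runs)) stop("need >= 1 model run")
  per_model_k <- length(runs[[1]]$top_genes)
  tallies <- new.env(parent = emptyenv())
  for (r in runs) {
    tg <- r$top_genes
    for (j in seq_along(tg)) {
      cur <- tallies[[tg[j]]]
      if (is.null(cur)) cur <- c(0, 0)
      tallies[[tg[j]]] <- cur + c(1, j)
    }
  }
  genes <- ls(tallies)
  count <- vapply(genes, function(g) tallies[[g]][1], numeric(1))
  rank_sum <- vapply(genes, function(g) tallies[[g]][2], numeric(1))
  mean_rank <- if (absent_rank_penalty) {
    (rank_sum + (length(runs) - count) * (per_model_k + 1)) / length(runs)
  } else {
    rank_sum / count
  }
  ord <- order(-count, mean_rank, genes)
  out <- data.frame(gene = genes[ord], count = count[ord],
                    mean_rank = mean_rank[ord], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out$final_rank <- ifelse(seq_len(nrow(out)) <= top_k,
                           seq_len(nrow(out)), NA_integer_)
  attr(out, "accuracy_summary") <- acc_sum
  attr(out, "top_k") <- top_k
  class(out) <- c("ConsensusRanking", "data.frame")
  out
}

#' Consensus gene list (the first top_k genes of a ranking)
#' @param consensus a `ConsensusRanking`.
#' @return character vector of genes with a final rank.
#' @export
consensus_genes <- function(consensus) {
  consensus$gene[!is.na(consensus$final_rank)]
}

#' Stratified k-fold cross-validated accuracy
#'
#' @inheritParams train_single_model
#' @param n_folds folds (default 5).
#' @param seed RNG seed for the fold assignment.
#' @return list with `fold_accuracy`, `mean`, `sd`.
#' @export
cross_validate <- function(x, labels, n_folds = 5, n_trees = 1000,
                           seed = 1L) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  lab <- .rf_labels(x, labels)
  ids <- intersect(x$sample_ids, names(lab))
  lab <- factor(lab[ids])
  if (min(table(lab)) < n_folds && n_folds < length(ids)) {
    stop("need >= n_folds samples per class for stratified folds")
  }
  set.seed(seed)
  fold <- integer(length(ids))
  if (n_folds >= length(ids)) {       # leave-one-out
    n_folds <- length(ids)
    fold <- seq_along(ids)
  } else {
    for (lv in levels(lab)) {
      pool <- which(lab == lv)
      fold[pool] <- sample(rep_len(seq_len(n_folds), length(pool)))
    }
  }
  feats <- t(x$values[, ids, drop = FALSE])
  acc <- vapply(seq_len(n_folds), function(f) {
    tr <- fold != f; te <- !tr
    if (length(unique(lab[tr])) < 2) stop("fold ", f, " lacks both classes in training")
    df <- data.frame(feats[tr, , drop = FALSE], check.names = FALSE)
    df$.cluster <- lab[tr]
    fit <- ranger::ranger(dependent.variable.name = ".cluster", data = df,
                          num.trees = n_trees, seed = seed + f,
                          num.threads = 1)
    pred <- stats::predict(fit, data = data.frame(feats[te, , drop = FALSE],
                                                  check.names = FALSE),
                           num.threads = 1)$predictions
    mean(pred == lab[te])
  }, numeric(1))
  list(fold_accuracy = acc, mean = mean(acc), sd = stats::sd(acc))
}

#' Audit expression direction of consensus genes between clusters
#'
#' For each consensus gene, compares the per-cluster FPKM medians and
#' tags the gene up_in_2 / up_in_1 / tied, with a Kruskal-Wallis p-value
#' across the two clusters. On the real cohort this is the check that
#' found nearly all consensus markers overexpressed in the poor-prognosis
#' cluster.
#'
#' @param x raw-FPKM `ExpressionMatrix`.
#' @param labels `ClusterAssignment` or named binary labels.
#' @param consensus `ConsensusRanking` or character vector of genes.
#' @return data.frame of class `DirectionAudit`: gene, median_cluster1,
#'   median_cluster2, direction, kw_p.
#' @export
direction_audit <- function(x, labels, consensus) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  genes <- if (inherits(consensus, "ConsensusRanking")) {
    consensus_genes(consensus)
  } else as.character(consensus)
  if (!length(genes)) stop("empty consensus list")
  lab <- .rf_labels(x, labels)
  ids <- intersect(x$sample_ids, names(lab))
  lab <- lab[ids]
  lv <- sort(unique(as.character(lab)))
  if (length(lv) != 2) stop("need exactly two clusters")
  out <- do.call(rbind, lapply(genes, function(g) {
    if (!g %in% x$gene_ids) {
      return(data.frame(gene = g, median_cluster1 = NA_real_,
                        median_cluster2 = NA_real_, direction = NA_character_,
                        kw_p = NA_real_, stringsAsFactors = FALSE))
    }
    v <- x$values[g, ids]
    m1 <- stats::median(v[lab == lv[1]]); m2 <- stats::median(v[lab == lv[2]])
    dir <- if (m2 > m1) "up_in_2" else if (m1 > m2) "up_in_1" else "tied"
    kw <- kruskal_wallis(list(v[lab == lv[1]], v[lab == lv[2]]))
    data.frame(gene = g, median_cluster1 = m1, median_cluster2 = m2,
               direction = dir, kw_p = kw$p_value, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("DirectionAudit", "data.frame")
  out
}
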