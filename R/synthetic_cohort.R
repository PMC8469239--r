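# ---- simulation spec -------------------------------------------------------

#' Specify a synthetic adrenocortical-like cohort
#'
#' Defines the statistical structure the downstream analysis assumes: a
#' log-normal FPKM matrix with two latent tumor clusters driven by a subset
#' of differentially expressed genes, cluster-dependent exponential
#' survival with uniform censoring, cluster-dependent per-gene mutation
#' frequencies, and an optional benign/normal group positioned
#' transcriptionally near cluster 1.
#'
#' @param n_per_cluster integer pair: tumor samples in cluster 1 and 2.
#' @param n_genes total number of genes.
#' @param n_informative number of genes whose log2 mean differs between
#'   the clusters (all shifted up in cluster 2).
#' @param log2_fold_change log2-space mean shift of informative genes
#'   (cluster 2 minus cluster 1).
#' @param baseline_log_mean,baseline_log_sd mean and gene-to-gene SD of
#'   per-gene baseline expression on the log2 scale.
#' @param noise_sd residual (sample-to-sample) SD on the log2 scale.
#' @param hazard_baseline exponential death hazard for cluster 1, events
#'   per year.
#' @param hazard_ratio cluster-2 vs cluster-1 hazard ratio (> 0).
#' @param censor_time_max censoring times drawn uniform on
#'   (0, censor_time_max] years, independent of survival.
#' @param mutation_rates named list; each element a length-2 numeric
#'   c(rate_cluster1, rate_cluster2) of Bernoulli mutation rates for that
#'   gene.
#' @param n_benign number of benign/normal samples (tissue group NAG).
#' @param benign_shift in [0, 1]: 0 places the benign centroid on the
#'   cluster-1 centroid; 1 displaces it along a benign-specific direction
#'   by the full inter-cluster effect magnitude.
#' @param seed integer RNG seed; identical specs give bit-identical cohorts.
#' @return a `SimulationSpec` list.
#' @export
simulation_spec <- function(n_per_cluster = c(40, 36),
                            n_genes = 2000,
                            n_informative = 40,
                            log2_fold_change = 2,
                            baseline_log_mean = 3,
                            baseline_log_sd = 1.5,
                            noise_sd = 0.5,
                            hazard_baseline = 0.055,
                            hazard_ratio = 6,
                            censor_time_max = 20,
                            mutation_rates = NULL,
                            n_benign = 0,
                            benign_shift = 0.5,
                            seed = 1L) {
  spec <- list(
    n_per_cluster = as.integer(n_per_cluster), n_genes = as.integer(n_genes),
    n_informative = as.integer(n_informative),
    log2_fold_change = log2_fold_change,
    baseline_log_mean = baseline_log_mean, baseline_log_sd = baseline_log_sd,
    noise_sd = noise_sd, hazard_baseline = hazard_baseline,
    hazard_ratio = hazard_ratio, censor_time_max = censor_time_max,
    mutation_rates = mutation_rates, n_benign = as.integer(n_benign),
    benign_shift = benign_shift, seed = as.integer(seed)
  )
  with(spec, {
    if (length(n_per_cluster) != 2 || any(n_per_cluster < 0)) {
      stop("n_per_cluster must be two non-negative integers")
    }
    if (n_informative > n_genes) stop("n_informative must be <= n_genes")
    if (hazard_ratio <= 0) stop("hazard_ratio must be > 0")
    if (hazard_baseline <= 0) stop("hazard_baseline must be > 0")
    if (censor_time_max <= 0) stop("censor_time_max must be > 0")
    if (noise_sd < 0 || baseline_log_sd < 0) stop("sds must be >= 0")
    if (benign_shift < 0 || benign_shift > 1) stop("benign_shift must be in [0, 1]")
    if (n_benign < 0) stop("n_benign must be >= 0")
  })
  if (!is.null(mutation_rates)) {
    ok <- vapply(mutation_rates, function(r) {
      length(r) == 2 && all(is.finite(r)) && all(r >= 0) && all(r <= 1)
    }, logical(1))
    if (!all(ok) || is.null(names(mutation_rates))) {
      stop("mutation_rates must be a named list of c(rate1, rate2) in [0, 1]")
    }
  }
  structure(spec, class = "SimulationSpec")
}

#' Default cohort specification at desk scale
#'
#' Mirrors the structure of the TCGA adrenocortical cohort the pipeline was
#' designed around, scaled down to 2,000 genes: 40 + 36 tumor samples (the
#' two subtype clusters), 40 informative genes at log2 fold change 2, a
#' cluster-2 vs cluster-1 death hazard ratio of 6, 20 benign/normal
#' samples adjacent to cluster 1, and mutation rates for the eight
#' recurrently mutated driver genes (TP53, CTNNB1, NF1, APC, ZNRF3, MEN1,
#' GNAS, ATRX) with TP53 and CTNNB1 strongly enriched in cluster 2.
#'
#' @param seed RNG seed (default 20210917).
#' @return a [simulation_spec()].
#' @export
default_paper_like_spec <- function(seed = 20210917L) {
  simulation_spec(
    n_per_cluster = c(40L, 36L),
    n_genes = 2000L,
    n_informative = 40L,
    log2_fold_change = 2,
    hazard_ratio = 6,
    n_benign = 20L,
    benign_shift = 0.5,
    mutation_rates = list(
      TP53   = c(1 / 40, 11 / 36),
      CTNNB1 = c(1 / 40, 12 / 36),
      NF1    = c(3 / 40, 4 / 36),
      APC    = c(2 / 40, 2 / 36),
      ZNRF3  = c(8 / 40, 7 / 36),
      MEN1   = c(1 / 40, 5 / 36),
      GNAS   = c(2 / 40, 2 / 36),
      ATRX   = c(2 / 40, 3 / 36)
    ),
    seed = seed
  )
}

# ---- generator --------------------------------------------------------------

#' Simulate a cohort with planted subtype structure
#'
#' Expression: per-gene baselines mu_g ~ N(baseline_log_mean,
#' baseline_log_sd) on the log2 scale; informative genes gain
#' `log2_fold_change` in cluster 2; benign samples sit at the cluster-1
#' profile displaced by `benign_shift` along a benign-specific direction
#' (a disjoint gene set with the same effect magnitude). FPKM = 2^log2
#' expression, so values are strictly positive log-normals. Survival:
#' exponential with hazard `hazard_baseline` (clusters 1 and benign) and
#' `hazard_baseline * hazard_ratio` (cluster 2), censored by an
#' independent Uniform(0, censor_time_max] time. Mutations: Bernoulli per
#' gene with cluster-specific rates (benign samples use cluster-1 rates).
#'
#' @param spec a [simulation_spec()].
#' @return list with `expression` (FPKM `ExpressionMatrix`), `clinical`
#'   (`ClinicalTable`, groups ACC/NAG), `mutations` (`MutationTable` or
#'   NULL), and `truth` (per-sample latent label in {1, 2, "benign"},
#'   informative gene ids, benign-direction gene ids, true hazard ratio
#'   and mutation rates).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "SimulationSpec"))
  set.seed(spec$seed)
  n1 <- spec$n_per_cluster[1]; n2 <- spec$n_per_cluster[2]
  nb <- spec$n_benign
  n <- n1 + n2 + nb
  if (n < 1) stop("spec yields an empty cohort")
  g <- spec$n_genes

  gene_ids <- sprintf("G%04d", seq_len(g))
  sample_ids <- c(sprintf("S1-%03d", seq_len(n1)),
                  sprintf("S2-%03d", seq_len(n2)),
                  if (nb) sprintf("SB-%03d", seq_len(nb)) else character(0))
  label <- c(rep("1", n1), rep("2", n2), rep("benign", nb))

  informative <- gene_ids[seq_len(spec$n_informative)]
  # benign displacement uses its own disjoint gene set so the benign group
  # is near cluster 1 but not on the tumor-subtype axis
  n_dir <- min(spec$n_informative, g - spec$n_informative)
  benign_dir <- if (nb && n_dir > 0) {
    gene_ids[spec$n_informative + seq_len(n_dir)]
  } else character(0)

  mu <- stats::rnorm(g, spec$baseline_log_mean, spec$baseline_log_sd)
  M <- matrix(mu, nrow = g, ncol = n)
  M[match(informative, gene_ids), label == "2"] <-
    M[match(informative, gene_ids), label == "2"] + spec$log2_fold_change
  if (length(benign_dir)) {
    M[match(benign_dir, gene_ids), label == "benign"] <-
      M[match(benign_dir, gene_ids), label == "benign"] +
      spec$benign_shift * spec$log2_fold_change
  }
  L <- M + matrix(stats::rnorm(g * n, 0, spec$noise_sd), g, n)
  fpkm <- 2^L

  expr <- expression_matrix(fpkm, gene_ids, sample_ids)

  hazard <- ifelse(label == "2",
                   spec$hazard_baseline * spec$hazard_ratio,
                   spec$hazard_baseline)
  death <- stats::rexp(n, rate = hazard)
  censor <- stats::runif(n, 0, spec$censor_time_max)
  os_time <- pmin(death, censor)
  event <- as.numeric(death <= censor)
  clin <- clinical_table(sample_ids, os_time, event,
                         group = ifelse(label == "benign", "NAG", "ACC"))

  mut <- NULL
  if (!is.null(spec$mutation_rates)) {
    genes <- names(spec$mutation_rates)
    rows <- lapply(genes, function(gn) {
      r <- spec$mutation_rates[[gn]]
      p <- ifelse(label == "2", r[2], r[1])
      data.frame(sample_id = sample_ids, gene = gn,
                 mutated = stats::rbinom(n, 1, p), stringsAsFactors = FALSE)
    })
    all <- do.call(rbind, rows)
    mut <- mutation_table(all$sample_id, all$gene, all$mutated)
  }

  truth <- list(cluster_label = stats::setNames(label, sample_ids),
                informative_gene_ids = informative,
                benign_direction_gene_ids = benign_dir,
                hazard_ratio = spec$hazard_ratio,
                mutation_rates = spec$mutation_rates)
  list(expression = expr, clinical = clin, mutations = mut, truth = truth)
}

#' Write a simulated cohort to a directory as TSV + truth JSON
#'
#' Emits exactly the three tables the readers in this package consume,
#' plus `truth.json` with the latent labels and planted gene ids.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if missing).
#' @return invisibly, the named vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             clinical = file.path(dir, "clinical.tsv"),
             truth = file.path(dir, "truth.json"))
  write_expression(cohort$expression, paths[["expression"]])
  write_clinical(cohort$clinical, paths[["clinical"]])
  if (!is.null(cohort$mutations)) {
    paths[["mutations"]] <- file.path(dir, "mutations.tsv")
    write_mutations(cohort$mutations, paths[["mutations"]])
  }
  jsonlite::write_json(
    list(cluster_label = as.list(cohort$truth$cluster_label),
         informative_gene_ids = cohort$truth$informative_gene_ids,
         benign_direction_gene_ids = cohort$truth$benign_direction_gene_ids,
         hazard_ratio = cohort$truth$hazard_ratio),
    paths[["truth"]], auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}
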