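#' Define a two-phenotype simulation scenario
#'
#' Describes a gene universe in which a designated "pathway" subset carries
#' phenotype-specific directed regulatory structure (edges present in
#' phenotype C, absent or rewired in N) against a background of edges shared
#' between the phenotypes. Data are drawn from the implied linear
#' structural-equation model. Defaults mirror a cancer-versus-normal cell-line
#' study at full scale (500 genes, an 87-gene pathway, 85 vs 103 samples); all
#' sizes scale down freely for desk-scale benchmarking.
#'
#' @param n_genes Universe size p.
#' @param pathway_size Number of pathway member genes.
#' @param pathway_genes Optional explicit member identifiers (must be a subset
#'   of the generated universe `g0001 ...`); default: the first
#'   `pathway_size` genes.
#' @param pathway_fraction_in_negative Fraction of pathway genes retained in
#'   the true-negative universe (default 0.05).
#' @param n_samples_C,n_samples_N Group sizes.
#' @param effect_size Coefficient magnitude of the phenotype-specific pathway
#'   edges; 0 makes the two phenotypes identical (null scenario).
#' @param background_density Edge probability among non-pathway gene pairs
#'   (shared between phenotypes).
#' @param noise_sd Residual standard deviation of non-root genes.
#' @param topology Pathway wiring in phenotype C: `"chain"` (m-1 edges along
#'   the member order) or `"random"` (random DAG of comparable density).
#' @param pathway_in_N `"absent"` (default; pathway genes isolated in N) or
#'   `"rewired"` (an independently drawn pathway DAG in N).
#' @param seed Seed fixing the planted structures (drawn from the current RNG
#'   when omitted, then stored, so a scenario object is always reproducible).
#' @return A list of class `"gbnea_scenario"`.
#' @export
simulation_scenario <- function(n_genes = 500L, pathway_size = 87L,
                                pathway_genes = NULL,
                                pathway_fraction_in_negative = 0.05,
                                n_samples_C = 85L, n_samples_N = 103L,
                                effect_size = 1, background_density = 0.02,
                                noise_sd = 0.2,
                                topology = c("chain", "random"),
                                pathway_in_N = c("absent", "rewired"),
                                seed = NULL) {
  topology <- match.arg(topology)
  pathway_in_N <- match.arg(pathway_in_N)
  n_genes <- as.integer(n_genes)
  pathway_size <- as.integer(pathway_size)
  if (n_genes < 2L || pathway_size < 1L ||
      n_samples_C < 1L || n_samples_N < 1L)
    stop("all counts must be positive (and n_genes >= 2)")
  if (pathway_size > n_genes)
    stop("the pathway cannot be larger than the gene universe")
  if (pathway_fraction_in_negative <= 0 || pathway_fraction_in_negative > 1)
    stop("pathway_fraction_in_negative must be in (0, 1]")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (background_density < 0 || background_density > 1)
    stop("background_density must be in [0, 1]")
  if (effect_size < 0) stop("effect_size must be nonnegative")
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  if (is.null(pathway_genes)) {
    pathway_genes <- gene_ids[seq_len(pathway_size)]
  } else {
    pathway_genes <- as.character(pathway_genes)
    if (!all(pathway_genes %in% gene_ids))
      stop("pathway_genes must belong to the generated universe")
    pathway_size <- length(pathway_genes)
  }
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max - 1L, 1L)
  structure(list(n_genes = n_genes, gene_ids = gene_ids,
                 pathway_genes = pathway_genes, pathway_size = pathway_size,
                 pathway_fraction_in_negative = pathway_fraction_in_negative,
                 n_samples_C = as.integer(n_samples_C),
                 n_samples_N = as.integer(n_samples_N),
                 effect_size = effect_size,
                 background_density = background_density,
                 noise_sd = noise_sd, topology = topology,
                 pathway_in_N = pathway_in_N, seed = as.integer(seed)),
            class = "gbnea_scenario")
}

#' @export
print.gbnea_scenario <- function(x, ...) {
  cat("Simulation scenario:", x$n_genes, "genes,",
      x$pathway_size, "pathway genes (", x$topology, "topology )\n")
  cat(sprintf("  samples: %d (C) + %d (N); effect %.3g, noise sd %.3g, background density %.3g\n",
              x$n_samples_C, x$n_samples_N, x$effect_size, x$noise_sd,
              x$background_density))
  invisible(x)
}

# Deterministic sub-seeds for a scenario's structural draws.
scenario_seeds <- function(scenario) {
  with_seed(scenario$seed, setNames(derive_seeds(3L),
                                    c("background", "pathwayC", "pathwayN")))
}

#' Planted directed coefficient structure for one phenotype
#'
#' Builds the directed acyclic coefficient structure of a scenario phenotype:
#' shared background edges among non-pathway genes (identical in C and N) plus
#' phenotype-specific pathway edges (weight `effect_size` in C; absent or
#' rewired in N). Edges always point from lower to higher gene index, so the
#' structure is acyclic by construction.
#'
#' @param scenario A [simulation_scenario()].
#' @param phenotype `"C"` or `"N"`.
#' @return A [directed_network()] over the scenario universe.
#' @export
generate_planted_network <- function(scenario, phenotype = c("C", "N")) {
  stopifnot(inherits(scenario, "gbnea_scenario"))
  phenotype <- match.arg(phenotype)
  seeds <- scenario_seeds(scenario)
  genes <- scenario$gene_ids
  bg_genes <- setdiff(genes, scenario$pathway_genes)
  edges <- with_seed(seeds["background"],
                     random_dag_edges(bg_genes, scenario$background_density))

  if (scenario$effect_size > 0) {
    pw <- scenario$pathway_genes[order(match(scenario$pathway_genes, genes))]
    if (phenotype == "C") {
      pe <- pathway_edges(pw, scenario$topology, scenario$effect_size,
                          seeds["pathwayC"])
    } else {
      pe <- switch(scenario$pathway_in_N,
                   absent = NULL,
                   rewired = pathway_edges(pw, "random",
                                           scenario$effect_size,
                                           seeds["pathwayN"]))
    }
    edges <- rbind(edges, pe)
  }
  directed_network(edges, genes, phenotype_label = phenotype)
}

# Random DAG among `genes` (edges low index -> high index), weights of
# moderate magnitude and random sign.
random_dag_edges <- function(genes, density) {
  m <- length(genes)
  if (m < 2L || density <= 0)
    return(data.frame(regulator = character(0), target = character(0),
                      weight = numeric(0)))
  pairs <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  keep <- stats::runif(nrow(pairs)) < density
  pairs <- pairs[keep, , drop = FALSE]
  if (nrow(pairs) == 0L)
    return(data.frame(regulator = character(0), target = character(0),
                      weight = numeric(0)))
  w <- stats::runif(nrow(pairs), 0.25, 0.75) *
    sample(c(-1, 1), nrow(pairs), replace = TRUE)
  data.frame(regulator = genes[pairs[, 1L]], target = genes[pairs[, 2L]],
             weight = w, stringsAsFactors = FALSE)
}

pathway_edges <- function(pw, topology, effect_size, seed) {
  m <- length(pw)
  if (m < 2L)
    return(NULL)
  if (topology == "chain") {
    data.frame(regulator = pw[-m], target = pw[-1L],
               weight = rep(effect_size, m - 1L), stringsAsFactors = FALSE)
  } else {
    with_seed(seed, {
      ed <- random_dag_edges(pw, min(1, 2 / m))
      if (nrow(ed) == 0L)  # guarantee at least the first->last edge
        ed <- data.frame(regulator = pw[1L], target = pw[m], weight = 1)
      ed$weight <- effect_size * sign(ed$weight)
      ed
    })
  }
}

#' Sample expression data from a directed acyclic coefficient structure
#'
#' Linear structural-equation sampling: root genes (no regulators) are drawn
#' standard normal; every downstream gene is the coefficient-weighted sum of
#' its parents plus Gaussian noise with standard deviation `noise_sd`,
#' evaluated in topological order.
#'
#' @param network A [directed_network()]; must be acyclic.
#' @param n_samples Number of samples to draw.
#' @param noise_sd Residual standard deviation for non-root genes.
#' @param sample_prefix Prefix for generated sample identifiers.
#' @return Numeric genes x samples matrix with dimnames.
#' @export
simulate_expression <- function(network, n_samples, noise_sd = 0.2,
                                sample_prefix = "s") {
  stopifnot(inherits(network, "gbnea_network"))
  n_samples <- as.integer(n_samples)
  if (n_samples < 1L) stop("n_samples must be positive")
  beta <- network$beta
  p <- length(network$gene_ids)
  ord <- topological_order(beta)
  x <- matrix(0, p, n_samples,
              dimnames = list(network$gene_ids,
                              sprintf("%s%04d", sample_prefix,
                                      seq_len(n_samples))))
  for (g in ord) {
    parents <- which(beta[, g] != 0)
    if (length(parents) == 0L) {
      x[g, ] <- stats::rnorm(n_samples)
    } else {
      x[g, ] <- drop(crossprod(as.matrix(beta[parents, g, drop = FALSE]),
                               x[parents, , drop = FALSE])) +
        stats::rnorm(n_samples, sd = noise_sd)
    }
  }
  x
}

# Kahn topological sort of the regulator -> target structure; errors on cycles.
topological_order <- function(beta) {
  p <- nrow(beta)
  adj <- beta != 0
  indeg <- Matrix::colSums(adj)
  queue <- which(indeg == 0)
  ord <- integer(0)
  while (length(queue)) {
    g <- queue[1L]
    queue <- queue[-1L]
    ord <- c(ord, g)
    kids <- which(adj[g, ])
    for (kid in kids) {
      indeg[kid] <- indeg[kid] - 1L
      if (indeg[kid] == 0L) queue <- c(queue, kid)
    }
  }
  if (length(ord) != p) stop("the coefficient structure contains a cycle")
  ord
}

#' Build the full two-phenotype dataset of a scenario
#'
#' Draws `n_samples_C` samples from the phenotype-C structure and
#' `n_samples_N` from the phenotype-N structure and assembles them into one
#' labeled [expression_dataset()].
#'
#' @param scenario A [simulation_scenario()].
#' @param seed Optional seed for the expression draw (the planted structures
#'   are already fixed by the scenario's own seed).
#' @param labels Phenotype labels for the two groups.
#' @return An [expression_dataset()].
#' @export
simulate_scenario_dataset <- function(scenario, seed = NULL,
                                      labels = c("C", "N")) {
  stopifnot(inherits(scenario, "gbnea_scenario"))
  netC <- generate_planted_network(scenario, "C")
  netN <- generate_planted_network(scenario, "N")
  draw <- function() {
    xc <- simulate_expression(netC, scenario$n_samples_C, scenario$noise_sd,
                              sample_prefix = "c")
    xn <- simulate_expression(netN, scenario$n_samples_N, scenario$noise_sd,
                              sample_prefix = "n")
    cbind(xc, xn)
  }
  values <- if (is.null(seed)) draw() else with_seed(seed, draw())
  phen <- c(rep(labels[1L], scenario$n_samples_C),
            rep(labels[2L], scenario$n_samples_N))
  expression_dataset(values, phen)
}

#' Confusion-matrix performance measures
#'
#' Accuracy, Precision, Recall, F1 and the true-negative rate from raw
#' confusion counts. Precision is `NA` ("--" when printed) when no positives
#' were called; F1 is 0 when nothing true was recovered.
#'
#' @param tp,fp,tn,fn Confusion counts.
#' @return One-row data frame with the five measures and the counts.
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  total <- tp + fp + tn + fn
  if (total <= 0) stop("at least one decision is required")
  precision <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  recall <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  tnr <- if (tn + fp == 0) NA_real_ else tn / (tn + fp)
  f1 <- if (is.na(precision) || is.na(recall) || tp == 0) {
    if (tp == 0) 0 else NA_real_
  } else 2 * precision * recall / (precision + recall)
  data.frame(accuracy = (tp + tn) / total, precision = precision,
             recall = recall, f1 = f1, tnr = tnr,
             tp = tp, fp = fp, tn = tn, fn = fn)
}

variant_name <- function(stat) {
  c(d1 = "GbNEA1R", Wd1 = "GbNEA1RJ", d2 = "GbNEA2R", Wd2 = "GbNEA2RJ")[stat]
}

#' Benchmark the method on planted true-positive/true-negative scenario pairs
#'
#' For each iteration, draws a true-positive dataset (pathway structure
#' planted in phenotype C) and a true-negative dataset (no phenotype effect;
#' only `pathway_fraction_in_negative` of the pathway's genes are present in
#' the tested universe, mirroring a network built off-pathway) and runs the
#' full enrichment pipeline for each requested statistic. Calling the pathway
#' significant counts as a true positive in the first arm and a false positive
#' in the second.
#'
#' @param scenario A [simulation_scenario()].
#' @param stats Statistics (method variants) to evaluate.
#' @param n_iterations Iterations per arm.
#' @param n_perm Permutations per test.
#' @param alpha Significance level.
#' @param k Enrichment weighting exponent.
#' @param regression A [regression_config()].
#' @param seed Master seed.
#' @param n_workers Workers for the permutation loops.
#' @return Data frame of class `"gbnea_simstudy"`: one row per statistic with
#'   the confusion-based performance measures.
#' @export
run_simulation_study <- function(scenario, stats = "Wd1",
                                 n_iterations = 50L, n_perm = 200L,
                                 alpha = 0.05, k = 0,
                                 regression = regression_config(),
                                 seed = NULL, n_workers = 1L) {
  stopifnot(inherits(scenario, "gbnea_scenario"))
  n_iterations <- as.integer(n_iterations)
  if (n_iterations < 1L) stop("at least one iteration is required")
  stats <- match.arg(stats, c("Wd1", "Wd2", "d1", "d2"), several.ok = TRUE)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max - 1L, 1L)
  iter_seeds <- with_seed(seed, derive_seeds(4L * n_iterations))

  # true-negative arm: a null universe in which only a small fraction of the
  # pathway is present (the remaining members fall outside the universe)
  retained <- max(1L, ceiling(scenario$pathway_fraction_in_negative *
                              scenario$pathway_size))
  null_scenario <- scenario
  null_scenario$effect_size <- 0
  tn_set <- c(scenario$pathway_genes[seq_len(retained)],
              sprintf("offuniverse%04d", seq_len(scenario$pathway_size -
                                                 retained)))

  counts <- matrix(0L, length(stats), 4L,
                   dimnames = list(stats, c("tp", "fn", "fp", "tn")))
  for (i in seq_len(n_iterations)) {
    s4 <- iter_seeds[(4L * (i - 1L) + 1L):(4L * i)]
    # true-positive arm
    dat <- simulate_scenario_dataset(scenario, seed = s4[1L])
    p_tp <- multi_stat_pvalues(dat, c("C", "N"), regression,
                               list(pathway = scenario$pathway_genes),
                               stats, k, n_perm, s4[2L], n_workers)
    # true-negative arm
    dat0 <- simulate_scenario_dataset(null_scenario, seed = s4[3L])
    p_tn <- multi_stat_pvalues(dat0, c("C", "N"), regression,
                               list(pathway = tn_set), stats, k, n_perm,
                               s4[4L], n_workers)
    for (s in stats) {
      if (!is.na(p_tp[s, 1L]) && p_tp[s, 1L] < alpha) {
        counts[s, "tp"] <- counts[s, "tp"] + 1L
      } else counts[s, "fn"] <- counts[s, "fn"] + 1L
      if (!is.na(p_tn[s, 1L]) && p_tn[s, 1L] < alpha) {
        counts[s, "fp"] <- counts[s, "fp"] + 1L
      } else counts[s, "tn"] <- counts[s, "tn"] + 1L
    }
  }

  out <- do.call(rbind, lapply(stats, function(s) {
    cbind(data.frame(method = unname(variant_name(s)), stat = s),
          confusion_metrics(counts[s, "tp"], counts[s, "fp"],
                            counts[s, "tn"], counts[s, "fn"]))
  }))
  rownames(out) <- NULL
  class(out) <- c("gbnea_simstudy", "data.frame")
  out
}

# p-values of each (statistic, set) pair for one dataset, sharing the
# estimated networks across statistics.
multi_stat_pvalues <- function(data, labels, config, sets, stats, k, n_perm,
                               seed, n_workers = 1L) {
  members <- lapply(sets, intersect, data$gene_ids)
  if (any(lengths(members) == 0L)) stop("a tested set has no overlap")
  obs <- pair_es(data$values, data$gene_ids, data$phenotype, labels, config,
                 members, stats, k)
  pc <- permutation_config(n_perm = n_perm, seed = seed,
                           n_workers = n_workers)
  arr <- null_es_array(data, labels, config, members, stats, k, pc)
  p <- matrix(NA_real_, length(stats), length(members),
              dimnames = list(stats, names(members)))
  for (s in seq_along(stats)) {
    nullm <- matrix(arr[, s, , drop = FALSE], nrow = n_perm)
    nrm <- normalize_scores(obs[s, ], nullm)
    for (m in seq_along(members)) {
      p[s, m] <- if (is.na(nrm$nES_obs[m])) 1 / (n_perm + 1)
        else pvalue_primary(nrm$nES_obs[m], nrm$nES_null[, m])
    }
  }
  p
}

#' @export
print.gbnea_simstudy <- function(x, ...) {
  cat("Planted-pathway benchmark (", x$tp[1L] + x$fn[1L],
      "iterations per arm )\n")
  y <- as.data.frame(x)
  y$precision <- ifelse(is.na(y$precision), "-",
                        formatC(y$precision, digits = 3, format = "f"))
  print.data.frame(y, digits = 3)
  invisible(x)
}
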