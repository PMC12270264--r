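#' Permutation-test configuration
#'
#' @param n_perm Number of label permutations (default 200).
#' @param seed Integer seed; all permutation randomness derives from it.
#' @param alpha Significance level in (0, 1).
#' @param n_workers Parallelism hint for the permutation loop. Results are
#'   identical for any worker count: every permutation's sub-seed is derived
#'   up front from `seed`, so scheduling cannot change the draw.
#' @return A list of class `"gbnea_perm_config"`.
#' @export
permutation_config <- function(n_perm = 200L, seed = NULL, alpha = 0.05,
                               n_workers = 1L) {
  n_perm <- as.integer(n_perm)
  if (is.na(n_perm) || n_perm < 1L) stop("n_perm must be >= 1")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  structure(list(n_perm = n_perm, seed = seed, alpha = alpha,
                 n_workers = max(1L, as.integer(n_workers))),
            class = "gbnea_perm_config")
}

#' Randomly reassign phenotype labels
#'
#' Draws a uniformly random reassignment of the given labels to the samples,
#' preserving the original group sizes. Uses the current RNG state.
#'
#' @param phenotypes Vector of sample labels containing exactly the two
#'   phenotype levels under comparison.
#' @return Permuted label vector (same names/order of samples).
#' @export
permute_labels <- function(phenotypes) {
  lv <- unique(phenotypes)
  if (length(lv) != 2L)
    stop("exactly two phenotype levels are required")
  if (!all(table(phenotypes) > 0L)) stop("both groups must be non-empty")
  out <- sample(phenotypes)
  names(out) <- names(phenotypes)
  out
}

#' Normalize enrichment scores against their permutation null
#'
#' Positive scores are divided by the mean of the positive permuted scores of
#' that pathway; negative scores by the absolute mean of the negative permuted
#' scores. Applied to both the observed score and the permuted scores
#' themselves, so same-sign null values cluster near +-1.
#'
#' @param ES_obs Named numeric vector of observed scores (one per pathway).
#' @param ES_null Matrix of permuted scores, `n_perm` rows, one column per
#'   pathway (column order matching `ES_obs`).
#' @return List with `nES_obs` (NA where no same-sign permuted score exists)
#'   and `nES_null` (same shape as `ES_null`).
#' @export
normalize_scores <- function(ES_obs, ES_null) {
  ES_null <- as.matrix(ES_null)
  if (length(ES_obs) != ncol(ES_null))
    stop("one null column per observed score is required")
  nES_obs <- numeric(length(ES_obs))
  nES_null <- ES_null
  for (j in seq_along(ES_obs)) {
    v <- ES_null[, j]
    mpos <- mean(v[v > 0])
    mneg <- abs(mean(v[v < 0]))
    scale_by <- function(x) {
      out <- x
      out[x > 0] <- x[x > 0] / mpos
      out[x < 0] <- x[x < 0] / mneg
      out
    }
    nES_null[, j] <- scale_by(v)
    o <- ES_obs[j]
    nES_obs[j] <- if (o > 0) o / mpos else if (o < 0) -abs(o) / mneg else 0
  }
  names(nES_obs) <- names(ES_obs)
  list(nES_obs = nES_obs, nES_null = nES_null)
}

#' Permutation p-value of a normalized enrichment score
#'
#' Sign-matched tail test: for a nonnegative observed score, the fraction of
#' permuted scores at least as large; for a negative one, the fraction at most
#' as small. With `denominator = "same_sign"` (default) the fraction is taken
#' over the same-sign permuted scores, the convention that keeps the test
#' calibrated; `"all"` divides the same count by the total number of
#' permutations (the literal printed rule, which can understate p by about a
#' factor of two).
#'
#' @param nES_obs Observed normalized score (single value).
#' @param nES_null Vector of permuted normalized scores.
#' @param denominator `"same_sign"` or `"all"`.
#' @return p-value in `[0, 1]`; `NA` when no same-sign permuted score exists.
#' @export
permutation_pvalue <- function(nES_obs, nES_null,
                               denominator = c("same_sign", "all")) {
  denominator <- match.arg(denominator)
  if (length(nES_null) == 0L) stop("empty permutation null")
  if (is.na(nES_obs)) return(NA_real_)
  if (nES_obs >= 0) {
    count <- sum(nES_null >= nES_obs)
    m <- sum(nES_null >= 0)
  } else {
    count <- sum(nES_null <= nES_obs)
    m <- sum(nES_null < 0)
  }
  denom <- if (denominator == "same_sign") m else length(nES_null)
  if (denom == 0L) return(NA_real_)
  min(1, count / denom)
}

#' Benjamini-Hochberg adjusted values
#'
#' Standard step-up FDR adjustment across the pathways tested in one run.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return Vector of q-values in `[0, 1]`.
#' @export
bh_correction <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Permutation null distribution of enrichment scores
#'
#' For each permutation: reassigns the phenotype labels, re-estimates both
#' networks, recomputes the behavior statistics, the ranking and the
#' enrichment score of every pathway. Pathways with no overlap with the gene
#' universe are excluded (with a notice).
#'
#' @param data A two-phenotype [expression_dataset()].
#' @param config A [regression_config()].
#' @param perm_config A [permutation_config()].
#' @param gene_sets A [gene_set_collection()].
#' @param stat_name Behavior statistic to rank by.
#' @param k Enrichment weighting exponent.
#' @param labels Length-2 character vector naming the (C, N) phenotype pair;
#'   defaults to the two levels present in `data`.
#' @return Matrix with `n_perm` rows and one named column per scored pathway.
#' @export
null_distribution <- function(data, config, perm_config, gene_sets,
                              stat_name = "Wd1", k = 0, labels = NULL) {
  labels <- resolve_labels(data, labels)
  members <- resolve_members(gene_sets, data$gene_ids)
  if (length(members) == 0L) stop("no gene set overlaps the gene universe")
  arr <- null_es_array(data, labels, config, members, stat_name, k,
                       perm_config)
  matrix(arr[, 1L, , drop = FALSE], nrow = perm_config$n_perm,
         dimnames = list(NULL, names(members)))
}

resolve_labels <- function(data, labels) {
  lv <- unique(data$phenotype)
  if (is.null(labels)) {
    if (length(lv) != 2L)
      stop("data must contain exactly two phenotypes, or pass `labels`")
    return(lv)
  }
  if (length(labels) != 2L || labels[1L] == labels[2L])
    stop("labels must be two distinct phenotype levels")
  miss <- setdiff(labels, lv)
  if (length(miss))
    stop("phenotype level(s) absent from the data: ",
         paste(miss, collapse = ", "))
  labels
}

# Intersect each set with the universe; drop (and report) empty overlaps.
resolve_members <- function(gene_sets, universe) {
  stopifnot(inherits(gene_sets, "gbnea_gene_sets"))
  members <- lapply(gene_sets$sets, intersect, universe)
  empty <- lengths(members) == 0L
  if (any(empty))
    message("excluding ", sum(empty),
            " gene set(s) with no overlap with the gene universe: ",
            paste(names(members)[empty], collapse = ", "))
  members[!empty]
}

# Estimate both phenotype networks under a label assignment and return the
# ES of every set for every requested statistic:  matrix [stat x set].
pair_es <- function(values, gene_ids, phen, labels, config, members, stats,
                    k) {
  data <- expression_dataset(values, phen, gene_ids = gene_ids)
  netC <- estimate_network(data, labels[1L], config)
  netN <- estimate_network(data, labels[2L], config)
  sc <- behavior_scores(netC, netN,
                        phenotype_means(data, labels[1L]),
                        phenotype_means(data, labels[2L]))
  es <- matrix(NA_real_, length(stats), length(members),
               dimnames = list(stats, names(members)))
  for (s in stats) {
    rk <- rank_genes(sc, s)
    for (m in seq_along(members))
      es[s, m] <- enrichment_score(rk, members[[m]], k)$ES
  }
  es
}

# Permutation null for possibly several statistics at once (networks are
# shared across statistics within a permutation).
# Returns array [n_perm x stat x set].
null_es_array <- function(data, labels, config, members, stats, k,
                          perm_config) {
  n_perm <- perm_config$n_perm
  seeds <- if (!is.null(perm_config$seed)) {
    with_seed(perm_config$seed, derive_seeds(2L * n_perm))
  } else derive_seeds(2L * n_perm)
  retry_seeds <- seeds[(n_perm + 1L):(2L * n_perm)]
  seeds <- seeds[seq_len(n_perm)]

  one_perm <- function(i) {
    run <- function(sd) {
      perm <- with_seed(sd, permute_labels(data$phenotype))
      pair_es(data$values, data$gene_ids, perm, labels, config, members,
              stats, k)
    }
    tryCatch(run(seeds[i]), error = function(e) {
      message("permutation ", i, " failed (", conditionMessage(e),
              "); redrawing")
      tryCatch(run(retry_seeds[i]), error = function(e2) NULL)
    })
  }

  res <- if (perm_config$n_workers > 1L) {
    parallel::mclapply(seq_len(n_perm), one_perm,
                       mc.cores = perm_config$n_workers)
  } else {
    lapply(seq_len(n_perm), one_perm)
  }
  failed <- vapply(res, is.null, logical(1L))
  if (sum(failed) > 0.1 * n_perm)
    stop("more than 10% of permutations failed")
  if (any(failed)) {
    ok <- which(!failed)[1L]
    for (i in which(failed)) res[[i]] <- res[[ok]] * NA_real_
  }
  arr <- array(NA_real_, dim = c(n_perm, length(stats), length(members)),
               dimnames = list(NULL, stats, names(members)))
  for (i in seq_len(n_perm)) arr[i, , ] <- res[[i]]
  arr
}
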