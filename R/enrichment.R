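#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors (pathway name -> member gene
#'   identifiers). Names must be unique, every set non-empty; duplicate
#'   members within a set are collapsed.
#' @param provenance Free-text source tag (e.g. the GMT file the sets came
#'   from).
#' @return An object of class `"gbnea_gene_sets"`.
#' @export
gene_set_collection <- function(sets, provenance = "") {
  if (!is.list(sets)) stop("sets must be a named list of character vectors")
  if (length(sets)) {
    if (is.null(names(sets)) || any(names(sets) == "") ||
        anyDuplicated(names(sets)))
      stop("set names must be present and unique")
    sets <- lapply(sets, function(s) unique(as.character(s)))
    if (any(lengths(sets) == 0L)) stop("every gene set must be non-empty")
  }
  structure(list(sets = sets, provenance = provenance),
            class = "gbnea_gene_sets")
}

#' @export
print.gbnea_gene_sets <- function(x, ...) {
  cat("Gene-set collection:", length(x$sets), "sets")
  if (nzchar(x$provenance)) cat(" [", x$provenance, "]", sep = "")
  cat("\n")
  if (length(x$sets)) {
    sz <- lengths(x$sets)
    cat("  set sizes:", min(sz), "-", max(sz), "\n")
  }
  invisible(x)
}

#' Rank genes by a behavior statistic
#'
#' Sorts the gene universe by the signed statistic in descending order. Ties
#' are broken deterministically by lexicographic gene identifier.
#'
#' @param scores A [behavior_scores()] table.
#' @param stat_name One of `"d1"`, `"d2"`, `"Wd1"`, `"Wd2"`.
#' @return A list of class `"gbnea_ranking"` with elements `order` (gene
#'   identifiers, best first), `stat_values` (statistic in ranked order) and
#'   `stat_name`.
#' @export
rank_genes <- function(scores, stat_name = c("Wd1", "Wd2", "d1", "d2")) {
  stat_name <- match.arg(stat_name)
  if (!stat_name %in% names(scores))
    stop("unknown statistic: ", stat_name)
  v <- scores[[stat_name]]
  g <- as.character(scores$gene)
  o <- order(-v, g, method = "radix")
  structure(list(order = g[o], stat_values = v[o], stat_name = stat_name),
            class = "gbnea_ranking")
}

#' @export
print.gbnea_ranking <- function(x, ...) {
  cat("Gene ranking by", x$stat_name, "(", length(x$order), "genes )\n")
  k <- min(5L, length(x$order))
  cat("  top:", paste(sprintf("%s=%.3g", x$order[seq_len(k)],
                              x$stat_values[seq_len(k)]), collapse = ", "),
      "\n")
  invisible(x)
}

#' Weighted Kolmogorov-Smirnov-like enrichment score of a gene set
#'
#' Walks the ranked gene list accumulating a running sum: each gene-set member
#' ("hit") adds its weight `|stat|^k / VR` (with `VR` the sum of `|stat|^k`
#' over all in-universe members), each non-member ("miss") subtracts
#' `1 / (|V| - |V_T|)`. The enrichment score is the running-sum value of
#' maximal absolute deviation from zero, keeping its sign. With `k = 0` this
#' is the classical unweighted two-sample Kolmogorov-Smirnov statistic; with
#' `k = 1` members are weighted by their normalized statistic.
#'
#' @param ranking A [rank_genes()] result.
#' @param gene_set Character vector of member gene identifiers. Members absent
#'   from the ranking universe are dropped (the effective set size is
#'   reported as `n_hits`).
#' @param k Nonnegative weighting exponent (default 0).
#' @return A list of class `"gbnea_es"` with `ES`, `running_sum`,
#'   `peak_position`, `k`, `n_hits`, and `no_overlap` (TRUE when the set does
#'   not intersect the universe; such results are excluded from testing).
#' @export
enrichment_score <- function(ranking, gene_set, k = 0) {
  stopifnot(inherits(ranking, "gbnea_ranking"))
  if (!is.numeric(k) || length(k) != 1L || k < 0)
    stop("k must be a single nonnegative number")
  hit <- ranking$order %in% gene_set
  n_hits <- sum(hit)
  p <- length(ranking$order)
  if (n_hits == 0L)
    return(structure(list(ES = NA_real_, running_sum = NULL,
                          peak_position = NA_integer_, k = k, n_hits = 0L,
                          no_overlap = TRUE),
                     class = "gbnea_es"))
  if (n_hits == p)
    stop("the gene set covers the whole universe; the miss fraction is undefined")
  w <- numeric(p)
  w[hit] <- abs(ranking$stat_values[hit])^k
  vr <- sum(w)
  if (vr == 0)
    stop("all in-set statistics are zero at this k (VR = 0); use k = 0")
  inc <- w / vr
  inc[!hit] <- -1 / (p - n_hits)
  rs <- cumsum(inc)
  # maximal |deviation|; when the positive and negative extremes tie (to
  # within accumulation error) the positive one is taken
  hi <- max(rs)
  lo <- min(rs)
  peak <- if (hi >= -lo - 1e-12) which.max(rs) else which.min(rs)
  structure(list(ES = rs[peak], running_sum = rs,
                 peak_position = peak, k = k, n_hits = n_hits,
                 no_overlap = FALSE),
            class = "gbnea_es")
}

#' @export
print.gbnea_es <- function(x, ...) {
  if (x$no_overlap) {
    cat("Enrichment score: no overlap with the gene universe\n")
  } else {
    cat(sprintf("Enrichment score: ES = %.4f at position %d (k = %g, %d hits)\n",
                x$ES, x$peak_position, x$k, x$n_hits))
  }
  invisible(x)
}
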