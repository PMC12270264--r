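#' Regulatory effect of each gene in a network
#'
#' The regulatory effect of gene j is the summed absolute product of its
#' outgoing edge weights and its mean expression in the phenotype the network
#' was estimated from: `r_j = sum_l |beta_lj * xbar_j|`. Genes that regulate
#' nothing get 0.
#'
#' @param network A [directed_network()] / output of [estimate_network()].
#' @param mean_expr Named per-gene mean expression covering the network's
#'   gene universe (see [phenotype_means()]).
#' @return Named nonnegative numeric vector over the gene universe.
#' @export
regulatory_effect <- function(network, mean_expr) {
  stopifnot(inherits(network, "gbnea_network"))
  miss <- setdiff(network$gene_ids, names(mean_expr))
  if (length(miss))
    stop("mean expression missing for gene(s): ",
         paste(head(miss, 5L), collapse = ", "))
  xbar <- mean_expr[network$gene_ids]
  r <- abs(xbar) * Matrix::rowSums(abs(network$beta))
  setNames(as.numeric(r), network$gene_ids)
}

# Undirected adjacency: a gene's neighbors are its regulators and its targets.
adjacency_undirected <- function(network) {
  a <- network$beta != 0
  a | Matrix::t(a)
}

#' Direct neighbors of a gene in a directed network
#'
#' "Directly connected" is read direction-agnostically: the neighborhood of a
#' gene is the union of its regulators and its targets (never the gene
#' itself).
#'
#' @param network A `"gbnea_network"`.
#' @param gene Gene identifier.
#' @return Character vector of neighbor identifiers (possibly empty).
#' @export
neighborhood <- function(network, gene) {
  stopifnot(inherits(network, "gbnea_network"))
  j <- match(gene, network$gene_ids)
  if (is.na(j)) stop(sprintf("gene '%s' is not in the network", gene))
  adj <- (network$beta[, j] != 0) | (network$beta[j, ] != 0)
  adj[j] <- FALSE
  network$gene_ids[as.logical(adj)]
}

#' Jaccard distance between a gene's neighborhoods in two networks
#'
#' `1 - |N_C v N_N| / |N_C u N_N|` over the direction-agnostic neighborhoods;
#' 0 means identical wiring across phenotypes, 1 fully phenotype-specific
#' wiring. A gene isolated in both networks gets distance 0 (no
#' phenotype-specific interplay).
#'
#' @param netC,netN Networks over identical gene universes.
#' @param gene Gene identifier.
#' @return A value in `[0, 1]`.
#' @export
jaccard_distance <- function(netC, netN, gene) {
  check_universes(netC, netN)
  nc <- neighborhood(netC, gene)
  nn <- neighborhood(netN, gene)
  u <- length(union(nc, nn))
  if (u == 0L) return(0)
  1 - length(intersect(nc, nn)) / u
}

check_universes <- function(netC, netN) {
  stopifnot(inherits(netC, "gbnea_network"), inherits(netN, "gbnea_network"))
  if (!identical(netC$gene_ids, netN$gene_ids))
    stop("the two networks must share an identical gene universe")
}

#' Per-gene phenotype-distinction statistics from a network pair
#'
#' Computes, for every gene j over the shared universe:
#' regulatory effects `r_C`, `r_N`; the Jaccard neighborhood distance `d_JI`;
#' the regulatory-effect difference `d1 = r_C - r_N`; the signed-profile
#' discrepancy `d2 = sum_l (betaC_lj * xbarC_j - betaN_lj * xbarN_j)^2`
#' (absent coefficients counting as 0); and the Jaccard-weighted versions
#' `Wd1 = d_JI * d1`, `Wd2 = d_JI * d2`.
#'
#' @param netC,netN Phenotype-specific networks over identical gene universes.
#' @param meanC,meanN Named per-gene mean expression for each phenotype.
#' @return Data frame of class `"gbnea_scores"` with columns `gene`, `r_C`,
#'   `r_N`, `d_JI`, `d1`, `d2`, `Wd1`, `Wd2`.
#' @export
behavior_scores <- function(netC, netN, meanC, meanN) {
  check_universes(netC, netN)
  genes <- netC$gene_ids
  rC <- regulatory_effect(netC, meanC)
  rN <- regulatory_effect(netN, meanN)

  aC <- adjacency_undirected(netC)
  aN <- adjacency_undirected(netN)
  inter <- Matrix::rowSums(aC & aN)
  uni <- Matrix::rowSums(aC | aN)
  d_JI <- ifelse(uni == 0, 0, 1 - inter / uni)

  d1 <- rC - rN
  # weighted outgoing profiles: rows = regulators, columns = targets
  pc <- Matrix::Diagonal(x = as.numeric(meanC[genes])) %*% netC$beta
  pn <- Matrix::Diagonal(x = as.numeric(meanN[genes])) %*% netN$beta
  d2 <- Matrix::rowSums((pc - pn)^2)

  out <- data.frame(gene = genes,
                    r_C = as.numeric(rC), r_N = as.numeric(rN),
                    d_JI = as.numeric(d_JI),
                    d1 = as.numeric(d1), d2 = as.numeric(d2),
                    Wd1 = as.numeric(d_JI * d1),
                    Wd2 = as.numeric(d_JI * d2),
                    stringsAsFactors = FALSE)
  class(out) <- c("gbnea_scores", "data.frame")
  out
}

#' @export
print.gbnea_scores <- function(x, ...) {
  cat("Gene behavior statistics for", nrow(x), "genes\n")
  print.data.frame(head(as.data.frame(x), 10L), digits = 4)
  if (nrow(x) > 10L) cat("... (", nrow(x) - 10L, " more genes)\n", sep = "")
  invisible(x)
}
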