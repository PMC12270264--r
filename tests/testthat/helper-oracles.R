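# Independent brute-force oracles used to cross-check the implementation.
# These recompute results from first principles and never call the package's
# own computational path.

# Two-sample Kolmogorov-Smirnov running sum: difference between the empirical
# CDF of the hit positions and that of the miss positions along the ranking.
ks_running_sum_oracle <- function(ranked_genes, gene_set) {
  hit <- ranked_genes %in% gene_set
  n_hit <- sum(hit)
  n_miss <- length(ranked_genes) - n_hit
  stopifnot(n_hit > 0, n_miss > 0)
  cumsum(hit) / n_hit - cumsum(!hit) / n_miss
}

ks_es_oracle <- function(ranked_genes, gene_set) {
  d <- ks_running_sum_oracle(ranked_genes, gene_set)
  if (max(d) >= -min(d) - 1e-12) max(d) else min(d)
}

# Karush-Kuhn-Tucker optimality residual for the elastic-net objective
# 1/2 ||y - X b||^2 + lam [(1-delta)/2 ||b||^2 + delta ||b||_1]:
# zero iff b is the exact minimizer.
elnet_kkt_residual <- function(y, X, b, lam, delta) {
  r <- drop(crossprod(X, y - X %*% b))
  viol <- numeric(length(b))
  act <- b != 0
  viol[act] <- abs(r[act] - lam * (1 - delta) * b[act] -
                     lam * delta * sign(b[act]))
  viol[!act] <- pmax(abs(r[!act]) - lam * delta, 0)
  max(viol)
}

# Benjamini-Hochberg step-up, written from the definition:
# q_(i) = min_{j >= i} min(1, m * p_(j) / j).
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, m * p[o] / seq_len(m))
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Lasso solution under an orthonormal design (X'X = I): soft thresholding.
soft_threshold_oracle <- function(xty, lam) {
  sign(xty) * pmax(abs(xty) - lam, 0)
}

# Orthonormal design matrix (n x p, columns orthonormal).
orthonormal_design <- function(n, p) {
  qr.Q(qr(matrix(rnorm(n * p), n, p)))[, seq_len(p), drop = FALSE]
}

# A scores table with controlled statistic values (all four columns filled).
make_scores <- function(genes, values) {
  data.frame(gene = genes, r_C = abs(values), r_N = 0,
             d_JI = rep(1, length(genes)),
             d1 = values, d2 = abs(values),
             Wd1 = values, Wd2 = abs(values),
             stringsAsFactors = FALSE)
}

# A small network from a compact edge specification.
net_from_edges <- function(genes, ..., label = NA_character_) {
  ed <- list(...)
  if (length(ed)) {
    df <- do.call(rbind, lapply(ed, function(e)
      data.frame(regulator = e[[1L]], target = e[[2L]],
                 weight = as.numeric(e[[3L]]), stringsAsFactors = FALSE)))
  } else {
    df <- data.frame(regulator = character(0), target = character(0),
                     weight = numeric(0))
  }
  directed_network(df, genes, phenotype_label = label)
}

# Random sparse network over `genes` for property checks.
random_network <- function(genes, density = 0.2) {
  p <- length(genes)
  pairs <- expand.grid(i = seq_len(p), j = seq_len(p))
  pairs <- pairs[pairs$i != pairs$j, ]
  keep <- runif(nrow(pairs)) < density
  pairs <- pairs[keep, , drop = FALSE]
  if (nrow(pairs) == 0L) return(net_from_edges(genes))
  directed_network(data.frame(regulator = genes[pairs$i],
                              target = genes[pairs$j],
                              weight = rnorm(nrow(pairs)) +
                                sign(rnorm(nrow(pairs))) * 0.1,
                              stringsAsFactors = FALSE), genes)
}
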