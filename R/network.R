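#' Regression configuration for network estimation
#'
#' Settings for the per-target sparse regressions that define the directed
#' network: each gene is regressed on all other genes with an elastic-net
#' penalty, and the regularization strength is selected per target by BIC.
#'
#' @param delta Mixing parameter in `[0, 1]` between the L2 (ridge, `delta =
#'   0`) and L1 (lasso, `delta = 1`) penalties. Default 1 (pure lasso).
#' @param lambda_grid Either `"auto"` (default) or a numeric vector of
#'   candidate regularization values. Under `"auto"` the relative grid
#'   `lambda_rel` is scaled per target by `max(|X'y|)`, the smallest value at
#'   which the lasso solution is identically zero; 0 (unpenalized least
#'   squares) is appended when the number of usable regulators is below the
#'   sample count. An explicit grid must be positive; the value 0 is permitted
#'   only when regulators < samples.
#' @param sigma2_estimator Rule for the noise-variance plug-in of the BIC:
#'   `"least_penalized"` (default) uses the residual variance
#'   `RSS/(n - df)` of the least-penalized model on the grid, falling back to
#'   the sample variance of the target when that fit is saturated or
#'   degenerate; `"var_y"` always uses the sample variance of the target.
#' @param standardize If `TRUE` (default), regulators are standardized to unit
#'   variance and the target is centered before fitting; coefficients are
#'   reported on the original scale. Penalization is scale-sensitive, so this
#'   is the recommended default.
#' @param lambda_rel Relative grid used by `lambda_grid = "auto"`.
#' @param tol Coordinate-descent convergence tolerance: a sweep converges when
#'   the largest variance-weighted squared coefficient change falls below
#'   `tol * y'y` (scale-free, as in standard coordinate-descent solvers).
#' @param maxit Maximum coordinate-descent sweeps per regularization value.
#'
#' @return A list of class `"gbnea_regression_config"`.
#' @export
regression_config <- function(delta = 1,
                              lambda_grid = "auto",
                              sigma2_estimator = c("least_penalized", "var_y"),
                              standardize = TRUE,
                              lambda_rel = c(0.001, 0.01, 0.1, 0.5, 1),
                              tol = 1e-5, maxit = 5000L) {
  sigma2_estimator <- match.arg(sigma2_estimator)
  if (!is.numeric(delta) || length(delta) != 1L || delta < 0 || delta > 1)
    stop("delta must be a single value in [0, 1]")
  if (is.character(lambda_grid)) {
    if (!identical(lambda_grid, "auto"))
      stop("lambda_grid must be \"auto\" or a numeric vector")
  } else {
    lambda_grid <- as.numeric(lambda_grid)
    if (length(lambda_grid) == 0L || any(!is.finite(lambda_grid)) ||
        any(lambda_grid < 0))
      stop("lambda_grid must be non-empty with all values >= 0")
  }
  if (any(!is.finite(lambda_rel)) || any(lambda_rel <= 0))
    stop("lambda_rel values must be positive")
  structure(list(delta = delta, lambda_grid = lambda_grid,
                 sigma2_estimator = sigma2_estimator,
                 standardize = isTRUE(standardize),
                 lambda_rel = sort(unique(as.numeric(lambda_rel))),
                 tol = tol, maxit = as.integer(maxit)),
            class = "gbnea_regression_config")
}

#' Bayesian information criterion for a penalized fit
#'
#' `BIC = ||y - y_hat||^2 / (n * sigma2) + log(n) * df / n`, where `df` is the
#' model degrees of freedom (for the lasso, the number of nonzero
#' coefficients) and `sigma2` a plug-in noise variance.
#'
#' @param y Observed response vector.
#' @param y_hat Fitted values (same length as `y`).
#' @param df Model degrees of freedom (>= 0).
#' @param sigma2 Noise-variance estimate (> 0).
#' @param n Sample count (> 0).
#' @return The BIC value (single numeric).
#' @export
compute_bic <- function(y, y_hat, df, sigma2, n) {
  if (length(y) != length(y_hat))
    stop("y and y_hat must have equal length")
  if (!is.finite(n) || n <= 0) stop("n must be positive")
  if (!is.finite(df) || df < 0) stop("df must be nonnegative")
  if (!is.finite(sigma2) || sigma2 <= 0)
    stop("sigma2 must be positive; use the sigma2_estimator fallback ",
         "(sample variance of y) for degenerate residual-variance estimates")
  bic_from_rss(sum((y - y_hat)^2), df, sigma2, n)
}

bic_from_rss <- function(rss, df, sigma2, n) {
  rss / (n * sigma2) + log(n) * df / n
}

#' Fit a single penalized target regression
#'
#' Minimizes `1/2 ||y - X b||^2 + lam * sum_j [(1-delta)/2 b_j^2 +
#' delta |b_j|]` by coordinate descent. With `delta = 1` this is the lasso;
#' coefficients shrunk out by the penalty are exactly zero.
#'
#' @param y Target expression vector (length n).
#' @param X Regulator expression matrix (n x p).
#' @param config A [regression_config()] (supplies `delta`, standardization
#'   and solver settings; the grid is ignored here).
#' @param lam Regularization value; `lam = 0` (least squares) requires
#'   `p < n`.
#' @return Numeric coefficient vector of length `ncol(X)` on the original
#'   scale of `X`, named by the columns of `X` when present.
#' @export
fit_target_regression <- function(y, X, config = regression_config(), lam) {
  X <- as.matrix(X)
  if (!is.numeric(y) || !is.numeric(X))
    stop("y and X must be numeric")
  if (length(y) != nrow(X))
    stop("length(y) must equal nrow(X)")
  if (any(!is.finite(y)) || any(!is.finite(X)))
    stop("non-finite values in y or X")
  if (!is.finite(lam) || lam < 0) stop("lam must be >= 0")
  if (lam == 0 && ncol(X) >= nrow(X))
    stop("lam = 0 requires fewer regulators than samples")

  sds <- rep(1, ncol(X))
  if (config$standardize) {
    y <- y - mean(y)
    xm <- colMeans(X)
    sds <- apply(X, 2L, sd)
    zero <- !is.finite(sds) | sds == 0
    sds[zero] <- 1
    X <- sweep(sweep(X, 2L, xm, "-"), 2L, sds, "/")
    X[, zero] <- 0
  } else {
    zero <- apply(X, 2L, function(col) all(col == col[1L]) && col[1L] == 0)
  }
  G <- crossprod(X)
  cvec <- drop(crossprod(X, y))
  fit <- .cd_elnet_path(G, cvec, sum(y^2), lam, config$delta,
                        zero, config$tol, config$maxit)
  if (!fit$converged[1L])
    warning("coordinate descent did not converge; returning the all-zero ",
            "solution for this target")
  beta <- fit$beta[, 1L] / sds
  names(beta) <- colnames(X)
  beta
}

#' Estimate a phenotype-specific directed gene network
#'
#' For every target gene, fits a sparse regression of its expression on all
#' other genes over a grid of regularization values and keeps the fit with
#' minimal BIC. The nonzero coefficients are the directed, weighted edges
#' (regulator -> target) of the phenotype's network.
#'
#' @param data A [expression_dataset()].
#' @param phenotype Phenotype label selecting the samples (>= 2 required).
#' @param config A [regression_config()].
#' @param verbose Print a progress note per 100 targets.
#' @return A [directed_network()] object over the full gene universe, with
#'   the selected regularization value per target in `$lambda_selected`.
#' @export
estimate_network <- function(data, phenotype, config = regression_config(),
                             verbose = FALSE) {
  stopifnot(inherits(data, "gbnea_expression"))
  if (!inherits(config, "gbnea_regression_config"))
    stop("config must be a regression_config()")
  idx <- phenotype_samples(data, phenotype)
  n <- length(idx)
  if (n < 2L)
    stop(sprintf("phenotype '%s' has fewer than 2 samples", phenotype))
  p <- length(data$gene_ids)
  if (p < 2L) stop("at least 2 genes are required")

  X <- t(data$values[, idx, drop = FALSE])  # n x p
  vars <- apply(X, 2L, var)
  zero_var <- !is.finite(vars) | vars == 0
  if (config$standardize) {
    sds <- sqrt(vars)
    Z <- sweep(sweep(X, 2L, colMeans(X), "-"), 2L,
               ifelse(zero_var, 1, sds), "/")
    Z[, zero_var] <- 0
    yscale <- ifelse(zero_var, 0, sds)   # y_l = yscale_l * Z[, l]
  } else {
    Z <- X
    yscale <- rep(1, p)
  }
  G <- crossprod(Z)

  reg_i <- vector("list", p)
  tgt_j <- vector("list", p)
  wts <- vector("list", p)
  lambda_sel <- setNames(rep(NA_real_, p), data$gene_ids)
  failed <- character(0)

  for (l in seq_len(p)) {
    if (verbose && l %% 100L == 0L)
      message("  target ", l, "/", p)
    if (zero_var[l] || yscale[l] == 0) next  # constant target: no edges
    exclude <- zero_var
    exclude[l] <- TRUE
    p_eff <- sum(!exclude)
    if (p_eff == 0L) next
    cvec <- yscale[l] * G[, l]
    cvec[exclude] <- 0
    yty <- yscale[l]^2 * G[l, l]

    grid <- target_lambda_grid(config, cvec, exclude, p_eff, n)
    if (is.null(grid)) next

    fit <- .cd_elnet_path(G, cvec, yty, grid, config$delta, exclude,
                          config$tol, config$maxit)

    sigma2 <- target_sigma2(config, fit, grid, yty, n,
                            var_y = if (config$standardize) vars[l]
                                    else var(X[, l]))
    if (!is.finite(sigma2) || sigma2 <= 0) next  # flat target, keep empty
    bic <- bic_from_rss(fit$rss, fit$df, sigma2, n)
    s <- which.min(bic)  # grid is decreasing: first minimum = larger lambda
    if (!fit$converged[s]) failed <- c(failed, data$gene_ids[l])
    beta <- fit$beta[, s]
    if (config$standardize) beta <- beta / ifelse(zero_var, 1, sds)
    nz <- which(beta != 0)
    lambda_sel[l] <- grid[s]
    if (length(nz)) {
      reg_i[[l]] <- nz
      tgt_j[[l]] <- rep.int(l, length(nz))
      wts[[l]] <- beta[nz]
    }
  }
  if (length(failed))
    warning("coordinate descent fell back to the all-zero solution for ",
            "target(s): ", paste(failed, collapse = ", "))

  ri <- unlist(reg_i); tj <- unlist(tgt_j); w <- unlist(wts)
  beta <- Matrix::sparseMatrix(i = if (is.null(ri)) integer(0) else ri,
                               j = if (is.null(tj)) integer(0) else tj,
                               x = if (is.null(w)) numeric(0) else w,
                               dims = c(p, p),
                               dimnames = list(data$gene_ids, data$gene_ids))
  new_network(beta, data$gene_ids, phenotype_label = phenotype,
              lambda_selected = lambda_sel)
}

# Candidate grid for one target, sorted decreasing, 0 (if any) last.
target_lambda_grid <- function(config, cvec, exclude, p_eff, n) {
  if (identical(config$lambda_grid, "auto")) {
    lam_max <- max(abs(cvec[!exclude]))
    if (lam_max == 0) return(NULL)
    grid <- config$lambda_rel * lam_max
    if (p_eff < n) grid <- c(grid, 0)
  } else {
    grid <- config$lambda_grid
    if (any(grid == 0) && p_eff >= n)
      stop("lambda = 0 in the grid requires fewer regulators than samples")
  }
  sort(unique(grid), decreasing = TRUE)
}

target_sigma2 <- function(config, fit, grid, yty, n, var_y) {
  if (config$sigma2_estimator == "var_y") return(var_y)
  s <- length(grid)  # smallest lambda (grid decreasing)
  dof <- n - fit$df[s]
  sigma2 <- if (dof >= 2) fit$rss[s] / dof else NA_real_
  if (!is.finite(sigma2) || sigma2 <= 1e-10 * max(var_y, .Machine$double.eps))
    sigma2 <- var_y
  sigma2
}

new_network <- function(beta, gene_ids, phenotype_label = NA_character_,
                        lambda_selected = NULL) {
  structure(list(beta = methods::as(methods::as(beta, "CsparseMatrix"),
                                    "generalMatrix"),
                 gene_ids = gene_ids,
                 phenotype_label = phenotype_label,
                 lambda_selected = lambda_selected),
            class = "gbnea_network")
}

#' Construct a directed weighted gene network from an edge table
#'
#' @param edges Data frame with columns `regulator`, `target`, `weight`
#'   (nonzero). Self-edges and duplicate (regulator, target) pairs are
#'   rejected.
#' @param gene_ids Gene universe; must contain all edge endpoints. Genes
#'   without edges are kept as isolated nodes.
#' @param phenotype_label Optional label recording which phenotype the network
#'   describes.
#' @return An object of class `"gbnea_network"` with a sparse coefficient
#'   matrix `$beta` (rows = regulators, columns = targets).
#' @export
directed_network <- function(edges, gene_ids,
                             phenotype_label = NA_character_) {
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(gene_ids)) stop("gene identifiers must be unique")
  if (nrow(edges) > 0) {
    req <- c("regulator", "target", "weight")
    if (!all(req %in% names(edges)))
      stop("edges must have columns regulator, target, weight")
    reg <- as.character(edges$regulator)
    tgt <- as.character(edges$target)
    w <- as.numeric(edges$weight)
    if (any(!is.finite(w)) || any(w == 0))
      stop("edge weights must be finite and nonzero")
    if (any(reg == tgt)) stop("self-edges are not allowed")
    if (!all(c(reg, tgt) %in% gene_ids))
      stop("all edge endpoints must belong to gene_ids")
    if (anyDuplicated(paste0(reg, "\r", tgt)))
      stop("duplicate (regulator, target) pairs")
    beta <- Matrix::sparseMatrix(i = match(reg, gene_ids),
                                 j = match(tgt, gene_ids), x = w,
                                 dims = rep(length(gene_ids), 2L),
                                 dimnames = list(gene_ids, gene_ids))
  } else {
    beta <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                 x = numeric(0),
                                 dims = rep(length(gene_ids), 2L),
                                 dimnames = list(gene_ids, gene_ids))
  }
  new_network(beta, gene_ids, phenotype_label)
}

#' Edge table of a directed network
#'
#' @param network A `"gbnea_network"`.
#' @return Data frame with columns `regulator`, `target`, `weight`, sorted
#'   canonically (regulator, then target, lexicographically).
#' @export
network_edges <- function(network) {
  stopifnot(inherits(network, "gbnea_network"))
  tri <- Matrix::summary(network$beta)
  tri <- tri[tri$x != 0, , drop = FALSE]
  out <- data.frame(regulator = network$gene_ids[tri$i],
                    target = network$gene_ids[tri$j],
                    weight = tri$x, stringsAsFactors = FALSE)
  out[order(out$regulator, out$target, method = "radix"), , drop = FALSE] |>
    `rownames<-`(NULL)
}

#' @export
print.gbnea_network <- function(x, ...) {
  ne <- Matrix::nnzero(x$beta)
  cat("Directed gene network",
      if (!is.na(x$phenotype_label))
        sprintf("(phenotype '%s')", x$phenotype_label) else "", "\n")
  cat(" ", length(x$gene_ids), "genes,", ne, "edges\n")
  invisible(x)
}
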