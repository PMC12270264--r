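test_that("lasso matches the soft-thresholding closed form under an orthonormal design", {
  set.seed(11)
  cfg <- regression_config(standardize = FALSE, tol = 1e-13)
  X <- orthonormal_design(40, 10)
  beta_true <- c(3, -2, 0, 0, 1.5, rep(0, 5))
  y <- drop(X %*% beta_true) + rnorm(40, sd = 0.1)
  xty <- drop(crossprod(X, y))
  for (lam in c(0.05, 0.3, 1, 2.5)) {
    got <- fit_target_regression(y, X, cfg, lam)
    expect_lt(max(abs(got - soft_threshold_oracle(xty, lam))), 1e-6)
  }
})

test_that("single dominant coefficient survives shrunk by the threshold amount", {
  set.seed(3)
  X <- orthonormal_design(30, 6)
  y <- drop(X %*% c(5, 0, 0, 0, 0, 0))
  got <- fit_target_regression(y, X, regression_config(standardize = FALSE,
                                                       tol = 1e-13),
                               lam = 0.4)
  expect_equal(unname(got[1L]), 5 - 0.4, tolerance = 1e-8)
  expect_true(all(got[-1L] == 0))
})

test_that("lasso fits agree with glmnet on random designs", {
  set.seed(21)
  n <- 60; p <- 15
  X <- matrix(rnorm(n * p), n, p)
  y <- drop(X %*% c(2, -1.5, rep(0, p - 2))) + rnorm(n)
  cfg <- regression_config(standardize = FALSE, tol = 1e-14, maxit = 1e5)
  for (lam in c(2, 10, 40)) {
    ours <- fit_target_regression(y, X, cfg, lam)
    gfit <- glmnet::glmnet(X, y, alpha = 1, lambda = lam / n,
                           standardize = FALSE, intercept = FALSE,
                           thresh = 1e-14, maxit = 1e7)
    theirs <- as.numeric(coef(gfit))[-1L]
    expect_lt(max(abs(ours - theirs)), 1e-6)
  }
})

test_that("elastic-net fits satisfy the optimality conditions exactly", {
  set.seed(22)
  n <- 60; p <- 15
  X <- matrix(rnorm(n * p), n, p)
  y <- drop(X %*% c(2, -1.5, rep(0, p - 2))) + rnorm(n)
  cfg0 <- regression_config(standardize = FALSE, tol = 1e-14, maxit = 1e5)
  for (delta in c(1, 0.5, 0.2)) {
    cfg <- cfg0; cfg$delta <- delta
    for (lam in c(2, 10, 40)) {
      b <- fit_target_regression(y, X, cfg, lam)
      expect_lt(elnet_kkt_residual(y, X, b, lam, delta), 1e-5)
    }
  }
})

test_that("degenerate inputs are rejected and handled", {
  X <- matrix(rnorm(40), 20, 2)
  expect_error(fit_target_regression(c(rnorm(19), NA), X,
                                     regression_config(), 0.1),
               "non-finite")
  expect_error(fit_target_regression(rnorm(20), cbind(X, Inf),
                                     regression_config(), 0.1),
               "non-finite")
  expect_error(fit_target_regression(rnorm(2), matrix(rnorm(6), 2, 3),
                                     regression_config(), 0),
               "fewer regulators")
  # zero response -> zero solution
  z <- fit_target_regression(rep(0, 20), X, regression_config(), 0.1)
  expect_true(all(z == 0))
  # enormous penalty -> full shrinkage
  y <- rnorm(20)
  lam_huge <- 1e6 * max(abs(crossprod(X, y)))
  expect_true(all(fit_target_regression(y, X, regression_config(), lam_huge)
                  == 0))
})

test_that("lam = 0 with p < n reproduces least squares", {
  set.seed(5)
  X <- matrix(rnorm(200), 50, 4)
  y <- rnorm(50)
  got <- fit_target_regression(y, X, regression_config(standardize = FALSE),
                               0)
  expect_equal(unname(got), unname(coef(lm(y ~ X - 1))), tolerance = 1e-8)
})

test_that("BIC arithmetic matches hand evaluation", {
  y <- rnorm(100)
  expect_equal(compute_bic(y, y, df = 3, sigma2 = 1, n = 100),
               log(100) * 3 / 100)
  y2 <- c(rep(1, 50)); yh2 <- rep(0, 50)  # rss = 50
  expect_equal(compute_bic(y2, yh2, df = 0, sigma2 = 1, n = 50), 1.0)
  # identical residuals, larger df -> strictly larger BIC
  y3 <- rnorm(30); yh3 <- y3 + rnorm(30, sd = 0.5)
  expect_gt(compute_bic(y3, yh3, df = 5, sigma2 = 1, n = 30),
            compute_bic(y3, yh3, df = 2, sigma2 = 1, n = 30))
  expect_error(compute_bic(y3, yh3, df = 2, sigma2 = 0, n = 30),
               "fallback")
  expect_error(compute_bic(y3, yh3, df = -1, sigma2 = 1, n = 30))
})

test_that("planted 3-gene structure is recovered by BIC-selected lasso", {
  set.seed(7)
  n <- 60
  g1 <- rnorm(n)
  g2 <- 2 * g1 + rnorm(n, sd = 0.1)
  g3 <- rnorm(n)
  dat <- expression_dataset(rbind(g1 = g1, g2 = g2, g3 = g3),
                            rep("C", n),
                            sample_ids = sprintf("s%02d", 1:n))
  net <- estimate_network(dat, "C")
  ed <- network_edges(net)
  e12 <- ed[ed$regulator == "g1" & ed$target == "g2", ]
  expect_equal(nrow(e12), 1L)
  expect_gt(e12$weight, 1.5)
  g3_edges <- ed[ed$regulator == "g3" | ed$target == "g3", ]
  expect_true(nrow(g3_edges) == 0L || all(abs(g3_edges$weight) < 0.2))
})

test_that("network estimation preconditions and degenerate grids", {
  set.seed(8)
  vals <- matrix(rnorm(40), 4, 10,
                 dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  dat <- expression_dataset(vals, c(rep("C", 9), "N"))
  expect_error(estimate_network(dat, "N"), "fewer than 2")
  expect_error(estimate_network(dat, "missing"), "not present")
  # a grid with only an enormous value yields an empty network
  net <- estimate_network(dat, "C",
                          regression_config(lambda_grid = 1e6))
  expect_equal(nrow(network_edges(net)), 0L)
})

test_that("network estimation is deterministic and structurally valid", {
  set.seed(9)
  sc <- simulation_scenario(n_genes = 25, pathway_size = 6,
                            n_samples_C = 30, n_samples_N = 30, seed = 4)
  dat <- simulate_scenario_dataset(sc, seed = 10)
  n1 <- estimate_network(dat, "C")
  n2 <- estimate_network(dat, "C")
  expect_identical(network_edges(n1), network_edges(n2))
  ed <- network_edges(n1)
  expect_true(all(ed$regulator != ed$target))
  expect_true(all(ed$weight != 0))
  expect_true(all(c(ed$regulator, ed$target) %in% dat$gene_ids))
  expect_identical(n1$phenotype_label, "C")
})

test_that("zero-variance regulators never receive an edge", {
  set.seed(12)
  vals <- matrix(rnorm(150), 5, 30,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:30)))
  vals["g3", ] <- 7  # constant gene
  dat <- expression_dataset(vals, rep("C", 30))
  ed <- network_edges(estimate_network(dat, "C"))
  expect_false("g3" %in% ed$regulator)
  expect_false("g3" %in% ed$target)  # constant target: centered y is zero
})

test_that("increasing lambda never increases the nonzero count along a path", {
  set.seed(13)
  n <- 40; p <- 12
  X <- matrix(rnorm(n * p), n, p)
  y <- drop(X %*% rnorm(p)) + rnorm(n)
  cfg <- regression_config(standardize = FALSE, tol = 1e-12)
  lam_max <- max(abs(crossprod(X, y)))
  grid <- lam_max * c(1, 0.5, 0.1, 0.01, 0.001)
  nnz <- vapply(grid, function(l)
    sum(fit_target_regression(y, X, cfg, l) != 0), numeric(1L))
  expect_true(all(diff(nnz) >= 0))  # grid is decreasing, support grows
})

test_that("the network matches per-target refits at the selected lambda", {
  set.seed(14)
  sc <- simulation_scenario(n_genes = 12, pathway_size = 4,
                            n_samples_C = 40, n_samples_N = 30, seed = 6)
  dat <- simulate_scenario_dataset(sc, seed = 15)
  cfg <- regression_config(tol = 1e-12)
  net <- estimate_network(dat, "C", cfg)
  idx <- which(dat$phenotype == "C")
  X <- t(dat$values[, idx])
  for (l in c(1L, 5L, 9L)) {
    lam <- net$lambda_selected[l]
    refit <- fit_target_regression(X[, l], X[, -l, drop = FALSE], cfg, lam)
    stored <- as.numeric(net$beta[-l, l])
    expect_lt(max(abs(refit - stored)), 1e-6)
  }
})
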