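test_that("label permutation preserves group sizes and is seed-reproducible", {
  labs <- setNames(c(rep("C", 7), rep("N", 5)), sprintf("s%02d", 1:12))
  set.seed(51)
  perm <- permute_labels(labs)
  expect_identical(as.vector(table(perm)[c("C", "N")]), c(7L, 5L))
  expect_identical(names(perm), names(labs))
  set.seed(99); a <- permute_labels(labs)
  set.seed(99); b <- permute_labels(labs)
  expect_identical(a, b)
  expect_error(permute_labels(rep("C", 4)), "two phenotype levels")
})

test_that("two-sample permutation is identity or swap with equal chance", {
  labs <- c(s1 = "C", s2 = "N")
  set.seed(52)
  draws <- replicate(2000, paste(permute_labels(labs), collapse = ""))
  tab <- table(draws)
  expect_setequal(names(tab), c("CN", "NC"))
  expect_gt(min(tab), 2000 * 0.5 - 3 * sqrt(2000 * 0.25))  # ~3 sd band
})

test_that("score normalization rescales by sign-specific null means", {
  null <- cbind(c(0.3, 0.3, -0.2, -0.4))
  got <- normalize_scores(c(pw = 0.6), null)
  expect_equal(unname(got$nES_obs), 2.0)        # 0.6 / mean(0.3, 0.3)
  expect_equal(got$nES_null[, 1L], c(1, 1, -2 / 3, -4 / 3))
  # all null equal to the observation: everything normalizes to 1
  got2 <- normalize_scores(c(pw = 0.5), cbind(rep(0.5, 10)))
  expect_equal(unname(got2$nES_obs), 1)
  expect_true(all(got2$nES_null == 1))
  # sign is preserved
  got3 <- normalize_scores(c(pw = -0.6), cbind(c(0.2, -0.3, -0.1)))
  expect_lt(got3$nES_obs, 0)
})

test_that("permutation p-values equal direct counting over the null", {
  set.seed(53)
  for (i in 1:1000) {
    nullv <- rnorm(sample(5:50, 1L))
    obs <- rnorm(1)
    p_same <- permutation_pvalue(obs, nullv)
    p_all <- permutation_pvalue(obs, nullv, denominator = "all")
    if (obs >= 0) {
      count <- sum(nullv >= obs); m <- sum(nullv >= 0)
    } else {
      count <- sum(nullv <= obs); m <- sum(nullv < 0)
    }
    expect_identical(p_all, min(1, count / length(nullv)))
    expect_identical(p_same, if (m == 0) NA_real_ else min(1, count / m))
  }
})

test_that("p-value landmarks: exceedance, median, resolution", {
  nullv <- seq(0.1, 2, length.out = 200)
  expect_equal(permutation_pvalue(3, nullv, denominator = "all"), 0)
  med <- stats::median(nullv)
  expect_equal(permutation_pvalue(med, nullv, denominator = "all"),
               sum(nullv >= med) / 200)  # ~ 0.5
  expect_lt(abs(permutation_pvalue(med, nullv, denominator = "all") - 0.5),
            0.01)
  # minimum attainable nonzero p under literal counting is 1/n_perm
  expect_equal(permutation_pvalue(max(nullv), nullv, denominator = "all"),
               1 / 200)
  expect_error(permutation_pvalue(1, numeric(0)), "empty")
})

test_that("BH correction agrees with the step-up oracle", {
  expect_equal(bh_correction(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_correction(0.2), 0.2)
  expect_equal(bh_correction(rep(1, 5)), rep(1, 5))
  set.seed(54)
  for (i in 1:1000) {
    p <- runif(sample(1:40, 1L))
    expect_lt(max(abs(bh_correction(p) - bh_oracle(p))), 1e-12)
  }
  expect_error(bh_correction(c(0.1, 1.2)), "0, 1")
})

test_that("null distributions are reproducible and worker-independent", {
  sc <- simulation_scenario(n_genes = 15, pathway_size = 5,
                            n_samples_C = 15, n_samples_N = 15, seed = 55)
  dat <- simulate_scenario_dataset(sc, seed = 56)
  gs <- gene_set_collection(list(pw = sc$pathway_genes))
  pc1 <- permutation_config(n_perm = 3L, seed = 77)
  m1 <- null_distribution(dat, regression_config(), pc1, gs)
  m2 <- null_distribution(dat, regression_config(), pc1, gs)
  expect_identical(m1, m2)
  pc2 <- permutation_config(n_perm = 3L, seed = 77, n_workers = 2L)
  m3 <- null_distribution(dat, regression_config(), pc2, gs)
  expect_identical(m1, m3)
  expect_identical(dim(m1), c(3L, 1L))
})

test_that("gene sets without overlap are excluded from the null", {
  sc <- simulation_scenario(n_genes = 12, pathway_size = 4,
                            n_samples_C = 12, n_samples_N = 12, seed = 57)
  dat <- simulate_scenario_dataset(sc, seed = 58)
  gs <- gene_set_collection(list(pw = sc$pathway_genes,
                                 alien = c("x1", "x2")))
  pc <- permutation_config(n_perm = 2L, seed = 78)
  expect_message(m <- null_distribution(dat, regression_config(), pc, gs),
                 "no overlap")
  expect_identical(colnames(m), "pw")
})
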