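test_that("scenario construction validates its fields", {
  expect_error(simulation_scenario(n_genes = 10, pathway_size = 11), "larger")
  expect_error(simulation_scenario(noise_sd = 0), "noise_sd")
  expect_error(simulation_scenario(pathway_fraction_in_negative = 0),
               "fraction")
  sc <- simulation_scenario(n_genes = 20, pathway_size = 5, seed = 1)
  expect_length(sc$pathway_genes, 5L)
  expect_true(all(sc$pathway_genes %in% sc$gene_ids))
})

test_that("zero effect size gives identical phenotype structures", {
  sc <- simulation_scenario(n_genes = 30, pathway_size = 8, effect_size = 0,
                            background_density = 0.1, seed = 61)
  nc <- generate_planted_network(sc, "C")
  nn <- generate_planted_network(sc, "N")
  expect_identical(network_edges(nc), network_edges(nn))
})

test_that("a chain pathway plants exactly m - 1 phenotype-specific edges", {
  sc <- simulation_scenario(n_genes = 25, pathway_size = 7,
                            background_density = 0, effect_size = 1.5,
                            topology = "chain", seed = 62)
  edC <- network_edges(generate_planted_network(sc, "C"))
  edN <- network_edges(generate_planted_network(sc, "N"))
  expect_equal(nrow(edC), 6L)
  expect_equal(nrow(edN), 0L)
  expect_true(all(edC$weight == 1.5))
  expect_true(all(edC$regulator %in% sc$pathway_genes))
  expect_true(all(edC$target %in% sc$pathway_genes))
})

test_that("planted structures are acyclic without self-edges", {
  for (s in 63:66) {
    sc <- simulation_scenario(n_genes = 40, pathway_size = 10,
                              background_density = 0.1,
                              topology = "random", pathway_in_N = "rewired",
                              seed = s)
    for (ph in c("C", "N")) {
      net <- generate_planted_network(sc, ph)
      ed <- network_edges(net)
      expect_true(all(ed$regulator != ed$target))
      # topological_order errors on cycles; reaching here means acyclic
      expect_length(gbnea:::topological_order(net$beta), 40L)
    }
  }
})

test_that("cyclic structures are rejected by the sampler", {
  net <- directed_network(data.frame(regulator = c("a", "b"),
                                     target = c("b", "a"),
                                     weight = c(1, 1)),
                          c("a", "b"))
  expect_error(simulate_expression(net, 10), "cycle")
})

test_that("structural-equation sampling follows the planted coefficients", {
  net <- net_from_edges(c("g1", "g2"), list("g1", "g2", 2))
  set.seed(67)
  x <- simulate_expression(net, 4000, noise_sd = 0.01)
  expect_gt(cor(x["g1", ], x["g2", ]), 0.999)
  slope <- coef(lm(x["g2", ] ~ x["g1", ]))[2L]
  expect_equal(unname(slope), 2, tolerance = 0.01)
  # empty structure: independent noise
  net0 <- net_from_edges(sprintf("g%d", 1:6))
  set.seed(68)
  x0 <- simulate_expression(net0, 800)
  cm <- cor(t(x0))
  expect_lt(max(abs(cm[upper.tri(cm)])), 0.15)
  # reproducibility under an outer seed
  sc <- simulation_scenario(n_genes = 10, pathway_size = 3, seed = 69)
  d1 <- simulate_scenario_dataset(sc, seed = 70)
  d2 <- simulate_scenario_dataset(sc, seed = 70)
  expect_identical(d1$values, d2$values)
})

test_that("generated datasets satisfy the container invariants", {
  sc <- simulation_scenario(n_genes = 18, pathway_size = 6,
                            n_samples_C = 9, n_samples_N = 7, seed = 71)
  dat <- simulate_scenario_dataset(sc, seed = 72)
  expect_s3_class(dat, "gbnea_expression")
  expect_equal(dim(dat$values), c(18L, 16L))
  expect_identical(as.vector(table(dat$phenotype)[c("C", "N")]), c(9L, 7L))
  expect_true(all(is.finite(dat$values)))
})

test_that("confusion metrics cover the perfect and never-reject classifiers", {
  perfect <- confusion_metrics(tp = 20, fp = 0, tn = 20, fn = 0)
  expect_equal(unlist(perfect[c("accuracy", "precision", "recall", "f1",
                                "tnr")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1, tnr = 1))
  never <- confusion_metrics(tp = 0, fp = 0, tn = 20, fn = 20)
  expect_true(is.na(never$precision))   # printed as "-"
  expect_equal(never$recall, 0)
  expect_equal(never$f1, 0)
  expect_equal(never$tnr, 1)
  expect_equal(never$accuracy, 0.5)
  expect_error(confusion_metrics(0, 0, 0, 0), "at least one")
})

test_that("the simulation study conserves confusion counts", {
  sc <- simulation_scenario(n_genes = 16, pathway_size = 5,
                            n_samples_C = 12, n_samples_N = 12,
                            effect_size = 1, noise_sd = 0.2, seed = 73)
  st <- run_simulation_study(sc, stats = c("Wd1", "d1"), n_iterations = 2,
                             n_perm = 4, seed = 74)
  expect_equal(st$tp + st$fn, rep(2, 2))
  expect_equal(st$fp + st$tn, rep(2, 2))
  expect_identical(st$method, c("GbNEA1RJ", "GbNEA1R"))
  expect_error(run_simulation_study(sc, n_iterations = 0), "iteration")
})
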