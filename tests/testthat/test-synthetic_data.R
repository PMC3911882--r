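test_that("generated interaction matrices honour density, diagonal and spectral radius", {
  cfg <- simulation_config(p = 50, n_train = 10, density = 0.05,
                           spectral_target = 0.5, seed = 1)
  net <- generate_interaction_matrix(cfg)
  expect_true(all(diag(net$B) == 0))
  rho <- max(Mod(eigen(net$B, only.values = TRUE)$values))
  expect_equal(rho, 0.5, tolerance = 1e-6)
  n_off <- 50 * 49
  expect_equal(sum(net$B != 0), round(0.05 * n_off), tolerance = 1)

  # zero density gives the zero matrix
  cfg0 <- simulation_config(p = 10, n_train = 5, density = 0, seed = 2)
  expect_true(all(generate_interaction_matrix(cfg0)$B == 0))

  # diagonal is zero at any density
  for (d in c(0.02, 0.3, 0.9)) {
    cfg_d <- simulation_config(p = 12, n_train = 5, density = d, seed = 3)
    expect_true(all(diag(generate_interaction_matrix(cfg_d)$B) == 0))
  }
})

test_that("simulation config rejects invalid parameter values", {
  expect_error(simulation_config(p = 2, n_train = 5, seed = 1), "at least 3")
  expect_error(simulation_config(p = 5, n_train = 1, seed = 1), "at least 2")
  expect_error(simulation_config(p = 5, n_train = 5, density = 1.2, seed = 1),
               "density")
  expect_error(simulation_config(p = 5, n_train = 5, spectral_target = 1,
                                 seed = 1), "spectral_target")
  expect_error(simulation_config(p = 5, n_train = 5, noise_sd = -1, seed = 1),
               "noise_sd")
  expect_error(simulation_config(p = 5, n_train = 5, noise_sd = Inf, seed = 1),
               "finite")
  expect_error(simulation_config(p = 5, n_train = 5), "seed")
})

test_that("noise-free samples solve the structural system exactly", {
  cfg <- simulation_config(p = 5, n_train = 3, density = 0, seed = 4)
  net <- generate_interaction_matrix(cfg)

  # B = 0, no noise, no perturbation: every column is the baseline
  comp <- simulate_samples(net, 3, noise_sd = 0, seed = 5)
  expect_equal(comp$values, matrix(net$baseline, 5, 3,
                                   dimnames = dimnames(comp$values)))

  # B = 0, single target shifted by delta: only that gene moves
  pert <- perturbation_spec(net$genes[3], 1.5, "shift3")
  comp2 <- simulate_samples(net, 2, noise_sd = 0, pert = pert, seed = 6)
  expected <- net$baseline
  expected[3] <- expected[3] + 1.5
  expect_equal(comp2$values[, 1], setNames(expected, net$genes))

  # hand-solved 3-gene chain: B[1,2] = 0.5, shift +2 on gene 2 propagates +1
  # to gene 1 through (I - B)^{-1}
  cfg3 <- simulation_config(p = 3, n_train = 2, density = 0, seed = 7)
  net3 <- generate_interaction_matrix(cfg3)
  net3$B[1, 2] <- 0.5
  comp3 <- simulate_samples(net3, 1, noise_sd = 0,
                            pert = perturbation_spec(net3$genes[2], 2), seed = 8)
  shift <- comp3$values[, 1] - net3$baseline
  expect_equal(unname(shift), c(1, 2, 0))
})

test_that("scenario generation is reproducible and carries ground truth", {
  cfg <- simulation_config(p = 8, n_train = 20, density = 0.1, replicates = 2,
                           seed = 9)
  sc1 <- generate_scenario(cfg)
  sc2 <- generate_scenario(cfg)
  expect_identical(sc1$train$values, sc2$train$values)
  expect_identical(sc1$network$B, sc2$network$B)
  expect_identical(sc1$tests[[1]]$compendium$values,
                   sc2$tests[[1]]$compendium$values)
  expect_equal(n_samples(sc1$tests[[1]]$compendium), 2)
  expect_equal(n_samples(sc1$train), 20)

  # a different seed gives different draws
  sc3 <- generate_scenario(simulation_config(p = 8, n_train = 20,
                                             density = 0.1, replicates = 2,
                                             seed = 10))
  expect_false(identical(sc1$train$values, sc3$train$values))

  # noise-free, B = 0: the target is the unique gene differing from the
  # training mean
  cfg0 <- simulation_config(p = 6, n_train = 10, density = 0, noise_sd = 0,
                            replicates = 1, seed = 11)
  net0 <- generate_interaction_matrix(cfg0)
  sc0 <- generate_scenario(cfg0, list(perturbation_spec(net0$genes[2], 1.5,
                                                        "single")))
  diffs <- abs(sc0$tests[[1]]$compendium$values[, 1] -
                 rowMeans(sc0$train$values))
  expect_identical(names(which(diffs > 1e-12)), sc0$tests[[1]]$pert$targets)
})

test_that("singular structural systems are rejected with a spectral-radius message", {
  cfg <- simulation_config(p = 3, n_train = 2, density = 0, seed = 12)
  net <- generate_interaction_matrix(cfg)
  net$B[1, 2] <- 2; net$B[2, 1] <- 2    # spectral radius 2
  expect_error(simulate_samples(net, 1, 0.1, seed = 13), "spectral radius")
})

test_that("sample means converge to baselines and covariance matches the model", {
  cfg <- simulation_config(p = 10, n_train = 5, density = 0.1,
                           spectral_target = 0.5, seed = 14)
  net <- generate_interaction_matrix(cfg)
  n <- 10000; noise_sd <- 0.25
  comp <- simulate_samples(net, n, noise_sd, seed = 15)
  expect_true(all(abs(rowMeans(comp$values) - net$baseline) <
                    4 * noise_sd / sqrt(n)))

  cfg2 <- simulation_config(p = 15, n_train = 5, density = 0.15, seed = 16)
  net2 <- generate_interaction_matrix(cfg2)
  big <- simulate_samples(net2, 50000, 0.3, seed = 17)
  M <- solve(diag(15) - net2$B)
  target_cov <- M %*% (0.3^2 * diag(15)) %*% t(M)
  emp_cov <- cov(t(big$values))
  expect_lt(norm(emp_cov - target_cov, "F") / norm(target_cov, "F"), 0.1)
})

test_that("ground truth files round-trip the network and targets as plain text", {
  cfg <- simulation_config(p = 6, n_train = 5, density = 0.2, seed = 18)
  sc <- generate_scenario(cfg)
  dir <- withr::local_tempdir()
  write_ground_truth(sc, dir)
  edges <- read.delim(file.path(dir, "true_network_edges.tsv"))
  B_rebuilt <- matrix(0, 6, 6, dimnames = dimnames(sc$network$B))
  B_rebuilt[cbind(match(edges$target, sc$network$genes),
                  match(edges$source, sc$network$genes))] <- edges$coefficient
  expect_equal(B_rebuilt, sc$network$B, tolerance = 1e-12)
  truth <- read.delim(file.path(dir, "truth_test1.tsv"))
  expect_identical(truth$gene[truth$true_target == 1],
                   sc$tests[[1]]$pert$targets)
})
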