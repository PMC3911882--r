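make_identity_network <- function(p, means = NULL, seed = 1) {
  genes <- sprintf("g%02d", seq_len(p))
  if (is.null(means)) means <- setNames(rep(0, p), genes)
  structure(list(genes = genes,
                 B_hat = matrix(0, p, p, dimnames = list(genes, genes)),
                 train_means = setNames(means, genes), lasso_report = NULL),
            class = "interaction_network")
}

test_that("residuals reduce to the centered test vector for an empty network", {
  net <- make_identity_network(4, means = c(1, 2, 3, 4))
  y <- setNames(c(1.5, 2, 2.5, 8), net$genes)
  prof <- compute_residuals(net, y)
  expect_equal(unname(prof$residuals), c(0.5, 0, -0.5, 4))

  # a test vector equal to the training means has all-zero residuals
  prof0 <- compute_residuals(net, setNames(net$train_means, net$genes))
  expect_true(all(prof0$residuals == 0))
})

test_that("residuals subtract inferred interaction effects (hand-computed case)", {
  net <- make_identity_network(3)
  net$B_hat[1, 2] <- 0.5
  y <- setNames(c(1, 2, 0), net$genes)   # already centered (means are zero)
  prof <- compute_residuals(net, y)
  expect_equal(unname(prof$residuals), c(1 - 0.5 * 2, 2, 0))
})

test_that("gene universe mismatches are rejected naming the offenders", {
  net <- make_identity_network(3)
  y <- setNames(c(1, 2, 3), c("g01", "g02", "bad"))
  expect_error(compute_residuals(net, y), "bad")
  expect_error(compute_residuals(net, y), "g03")
})

test_that("ranking assigns rank 1 to the largest absolute residual with stable ties", {
  net <- make_identity_network(3)
  prof <- compute_residuals(net, setNames(c(0.1, -5, 2), net$genes))
  rk <- rank_genes(prof)
  expect_equal(rk$rank, c(3, 1, 2))

  # all-equal residuals: gene order breaks ties
  prof_tie <- compute_residuals(net, setNames(c(1, -1, 1), net$genes))
  expect_equal(rank_genes(prof_tie)$rank, c(1, 2, 3))
})

test_that("ranks are a permutation agreeing with an independent argsort", {
  p <- 1000
  net <- make_identity_network(p)
  y <- withr::with_seed(1, setNames(rnorm(p), net$genes))
  rk <- rank_genes(compute_residuals(net, y))
  expect_setequal(rk$rank, seq_len(p))
  oracle <- order(order(-abs(y - net$train_means)))
  expect_equal(rk$rank, oracle)
})

test_that("permuting gene order permutes residuals and preserves ranks", {
  p <- 30
  net <- make_identity_network(p)
  net$B_hat[] <- withr::with_seed(2, matrix(rnorm(p * p, sd = 0.05), p, p))
  diag(net$B_hat) <- 0
  y <- withr::with_seed(3, setNames(rnorm(p), net$genes))
  rk <- rank_genes(compute_residuals(net, y))

  perm <- withr::with_seed(4, sample(p))
  net_p <- net
  net_p$genes <- net$genes[perm]
  net_p$B_hat <- net$B_hat[perm, perm]
  net_p$train_means <- net$train_means[perm]
  rk_p <- rank_genes(compute_residuals(net_p, y[perm]))
  # residuals are equivariant; ranks match gene-by-gene (no ties here)
  expect_equal(rk_p$rank[match(net$genes, rk_p$genes)], rk$rank)
})

test_that("replicate rank averaging follows the stated arithmetic and rounding", {
  net <- make_identity_network(4)
  r1 <- rank_genes(compute_residuals(net, setNames(c(4, 3, 2, 1), net$genes)))
  r2 <- rank_genes(compute_residuals(net, setNames(c(4, 3, 2, 1), net$genes)))
  avg <- average_rankings(list(r1, r2))
  expect_equal(avg$mean_rank, r1$rank)         # idempotent on identical inputs

  r3 <- rank_genes(compute_residuals(net, setNames(c(1, 2, 3, 4), net$genes)))
  avg2 <- average_rankings(list(r1, r3))
  expect_equal(avg2$mean_rank, rep(2.5, 4))

  # half-up display rounding: mean of ranks 3 and 4 prints as 4
  fake1 <- r1; fake1$rank <- c(3, 1, 2, 4)
  fake2 <- r1; fake2$rank <- c(4, 2, 1, 3)
  expect_equal(average_rankings(list(fake1, fake2))$display_rank[1], 4)

  bad <- r1; bad$genes <- rev(bad$genes)
  expect_error(average_rankings(list(r1, bad)), "universe")
})

test_that("z-score baseline matches a direct recomputation", {
  comp <- noise_compendium(50, 40, seed = 5)
  y <- withr::with_seed(6,
    setNames(rnorm(50, mean = rowMeans(comp$values)), compendium_genes(comp)))
  zr <- zscore_ranking(comp, y)
  mu <- rowMeans(comp$values)
  s <- apply(comp$values, 1, sd)
  z_oracle <- abs((y - mu) / s)
  expect_equal(zr$abs_residual, unname(z_oracle))
  expect_equal(zr$rank, order(order(-z_oracle)))

  # test vector at the training means: all z zero, ranks in gene order
  z0 <- zscore_ranking(comp, setNames(mu, names(mu)))
  expect_equal(z0$rank, 1:50)

  # a 10-SD spike wins rank 1
  y_spike <- mu; y_spike[27] <- mu[27] + 10 * s[27]
  expect_equal(zscore_ranking(comp, setNames(y_spike, names(mu)))$rank[27], 1)

  # zero-variance genes score zero with a warning
  flat <- comp
  flat$values[3, ] <- 5
  expect_warning(zf <- zscore_ranking(expression_compendium(flat$values),
                                      setNames(mu, names(mu))), "zero training SD")
  expect_equal(zf$abs_residual[3], 0)
})

test_that("network residual ranking resolves the target at least as well as z-scores", {
  # correlated genes, single target shifted by 5 * noise_sd, several seeds
  ssem_rank <- c(); z_rank <- c()
  for (s in 1:8) {
    cfg <- simulation_config(p = 15, n_train = 120, density = 0.15,
                             spectral_target = 0.5, noise_sd = 0.25,
                             replicates = 1, seed = 100 + s)
    sc <- generate_scenario(cfg)
    net <- fit_network(sc$train, lasso_config(seed = s))
    y <- setNames(sc$tests[[1]]$compendium$values[, 1], sc$network$genes)
    tgt <- sc$tests[[1]]$pert$targets
    ssem_rank <- c(ssem_rank,
                   rank_genes(compute_residuals(net, y))$rank[
                     match(tgt, sc$network$genes)])
    z_rank <- c(z_rank, zscore_ranking(sc$train, y)$rank[
      match(tgt, sc$network$genes)])
  }
  expect_lte(median(ssem_rank), median(z_rank))
  expect_gte(mean(ssem_rank <= 1), 0.8)  # top gene in most seeds
})
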