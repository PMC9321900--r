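test_that("a data-free chain recovers its prior marginals", {
  net <- network_preset("A01-B", 0.0025)
  map <- sample_map(net, 2)
  pr <- prior_for_theta(0.0025)     # tau0 ~ IG(3, 0.025), theta ~ IG(3, 0.005)
  ch <- run_a00(NULL, net, map, pr,
                mcmc_settings(burnin = 400, nsamples = 4000, seed = 1,
                              validate = TRUE))
  sm <- summarize_posterior(ch)$params
  tau0 <- ch$params[, "tau_R"]
  mu <- pr$tau_beta / (pr$tau_alpha - 1)
  se <- stats::sd(tau0) / sqrt(mscrecomb:::ess(tau0))
  expect_lt(abs(mean(tau0) - mu), 4 * se)
  # thinned KS against the inverse-gamma law itself
  thin <- tau0[seq(1, length(tau0), by = 20)]
  ks <- stats::ks.test(thin, function(q)
    stats::pgamma(1 / q, shape = pr$tau_alpha, rate = pr$tau_beta,
                  lower.tail = FALSE))
  expect_gt(ks$p.value, 0.01)
  # every theta at its prior mean
  th_cols <- grep("^theta_", colnames(ch$params))
  th_means <- colMeans(ch$params[, th_cols])
  expect_true(all(abs(th_means - 0.0025) < 0.0004))
})

test_that("a data-free MSci chain recovers uniform phi", {
  net <- network_preset("A00-B", 0.01)
  map <- sample_map(net, 2)
  ch <- run_a00(NULL, net, map, prior_for_theta(0.01),
                mcmc_settings(burnin = 300, nsamples = 3000, seed = 2,
                              validate = TRUE))
  phis <- ch$params[, c("phi_Y", "phi_W")]
  expect_true(all(abs(colMeans(phis) - 0.5) < 0.08))
  expect_true(all(apply(phis, 2, stats::sd) > 0.2))  # spread, not stuck
})

test_that("posterior summaries compute means, HPDs and tree probabilities", {
  x <- matrix(rep(3.5, 100), ncol = 1, dimnames = list(NULL, "v"))
  s <- summarize_posterior(x)
  expect_equal(s$params$mean, 3.5)
  expect_equal(c(s$params$lower, s$params$upper), c(3.5, 3.5))

  set.seed(4)
  z <- stats::rnorm(1e6)
  h <- hpd_interval(z)
  # sample HPD endpoints carry the shortest-window selection bias on top of
  # quantile Monte-Carlo error
  expect_lt(abs(h[1] + 1.96), 0.03)
  expect_lt(abs(h[2] - 1.96), 0.03)

  fake <- structure(list(
    params = matrix(stats::rnorm(100), ncol = 1,
                    dimnames = list(NULL, "x")),
    topology = c(rep("((A,B),C)", 70), rep("((A,C),B)", 30))),
    class = "msc_chain")
  s2 <- summarize_posterior(fake)
  expect_equal(s2$trees$prob[s2$trees$topology == "((A,B),C)"], 0.7)
  expect_equal(s2$map_tree, "((A,B),C)")
  expect_equal(s2$clades$prob[s2$clades$clade == "A,B"], 0.7)
  expect_error(summarize_posterior(structure(list(params = NULL),
                                             class = "msc_chain")),
               "empty")
})

test_that("acceptance rates land in a workable band after autotuning", {
  net <- three_species_net()
  map <- sample_map(net, 2)
  d <- sim_design(S = 2, L = 10, rho = 0, theta_base = 0.0025, R = 1,
                  seed = 3)
  alns <- simulate_alignments(net, map, d)
  ch <- run_a00(alns, net, map, prior_for_theta(0.0025),
                mcmc_settings(burnin = 400, nsamples = 600, seed = 5))
  rates <- ch$acceptance
  for (mv in c("gene_age", "tau", "rescale")) {
    r <- rates$rate[rates$move == mv]
    expect_gte(r, 0.15)
    expect_lte(r, 0.6)
  }
})

test_that("two species leave a single topology with posterior one", {
  net <- two_species_net(0.0025, 0.005)
  map <- sample_map(net, 2)
  d <- sim_design(S = 2, L = 8, rho = 0, theta_base = 0.0025, R = 1,
                  seed = 6)
  alns <- simulate_alignments(net, map, d)
  ch <- run_a01(alns, net, map, prior_for_theta(0.0025, TRUE),
                mcmc_settings(burnin = 150, nsamples = 400, seed = 7))
  s <- summarize_posterior(ch)
  expect_equal(nrow(s$trees), 1L)
  expect_equal(s$trees$prob, 1)
  expect_equal(s$map_tree, "(A,B)")
})

test_that("theta-integrated and theta-sampled runs agree on the posterior", {
  # same data, both theta treatments: clade/topology posteriors and tau
  # estimates should agree within Monte-Carlo error
  net <- three_species_net(theta = 0.0025, tau_s = 0.004, tau_r = 0.0075)
  map <- sample_map(net, 2)
  d <- sim_design(S = 2, L = 15, rho = 0, theta_base = 0.0025, R = 1,
                  seed = 8)
  alns <- simulate_alignments(net, map, d)
  chs <- run_a00(alns, net, map, prior_for_theta(0.0025),
                 mcmc_settings(burnin = 400, nsamples = 1500, seed = 9))
  # integrated-theta path exercised through the A01 machinery on the fixed
  # tree (species moves still proposed, but the data dominate)
  chi <- run_a01(alns, net, map, prior_for_theta(0.0025, TRUE),
                 mcmc_settings(burnin = 400, nsamples = 1500, seed = 10))
  ms <- colMeans(chs$params)
  mi <- colMeans(chi$params)
  for (p in c("tau_R", "tau_S"))
    expect_lt(abs(ms[p] - mi[p]) / ms[p], 0.15)
})

test_that("independent chains are screened for convergence", {
  net <- three_species_net()
  map <- sample_map(net, 2)
  d <- sim_design(S = 2, L = 8, rho = 0, theta_base = 0.0025, R = 1,
                  seed = 11)
  alns <- simulate_alignments(net, map, d)
  ch1 <- run_a00(alns, net, map, prior_for_theta(0.0025),
                 mcmc_settings(burnin = 300, nsamples = 800, seed = 12))
  ch2 <- run_a00(alns, net, map, prior_for_theta(0.0025),
                 mcmc_settings(burnin = 300, nsamples = 800, seed = 13))
  cv <- check_convergence(ch1, ch2, tol = 0.3)
  expect_false(cv$flagged)
  expect_true(is.finite(cv$max_discrepancy))
})
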