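test_that("no recombination gives a single segment and zero events", {
  net <- network_preset("A01-B", 0.0025)
  map <- sample_map(net, 2)
  d <- sim_design(S = 2, L = 1, rho = 0, theta_base = 0.0025)
  g <- simulate_locus(net, map, d, seed = 1)
  expect_equal(count_recombination_events(g), 0L)
  expect_equal(count_distinct_breakpoints(g), 0L)
  expect_equal(g$breakpoints, c(0L, 500L))
  t0 <- marginal_tree_at(g, 0)
  t499 <- marginal_tree_at(g, 499)
  expect_identical(t0, t499)
  expect_error(marginal_tree_at(g, 500), "range")
})

test_that("segment lengths partition the locus and trees are dated", {
  net <- network_preset("A01-B", 0.0025)
  map <- sample_map(net, 2)
  d <- sim_design(S = 2, L = 1, rho = 5, theta_base = 0.0025)
  for (seed in 1:5) {
    g <- simulate_locus(net, map, d, seed = seed)
    st <- segment_trees(g)
    expect_equal(sum(st$lengths), 500L)
    expect_gte(count_recombination_events(g),
               length(g$breakpoints) - 2L)   # m-1 <= event count
    for (tr in st$trees) {
      expect_true(ape::is.rooted(tr))
      expect_equal(length(tr$tip.label), 10L)
      expect_true(all(tr$edge.length >= 0))
    }
  }
})

test_that("event counting follows the executed-event definition", {
  net <- network_preset("A01-B", 0.0025)
  map <- sample_map(net, 2)
  d <- sim_design(S = 2, L = 1, rho = 2, theta_base = 0.0025)
  g <- simulate_locus(net, map, d, seed = 42)
  expect_equal(count_recombination_events(g), nrow(g$events))
  # repeat links count each time for events, once for breakpoints
  expect_gte(count_recombination_events(g), count_distinct_breakpoints(g))
})

test_that("segment trees round-trip through length-prefixed Newick", {
  net <- network_preset("A01-B", 0.0025)
  map <- sample_map(net, 2)
  d <- sim_design(S = 2, L = 1, rho = 1, theta_base = 0.0025)
  g <- simulate_locus(net, map, d, seed = 3)
  f <- tempfile()
  write_segment_trees(g, f)
  back <- read_segment_trees(f)
  st <- segment_trees(g)
  expect_equal(back$lengths, unclass(st$lengths))
  expect_equal(sum(back$lengths), 500L)
  for (j in seq_along(back$trees)) {
    d1 <- ape::cophenetic.phylo(st$trees[[j]])
    d2 <- ape::cophenetic.phylo(back$trees[[j]])
    expect_equal(d2[rownames(d1), colnames(d1)], d1, tolerance = 1e-6)
  }
})

test_that("pairwise coalescent times match the single-population theory", {
  # 2 lineages in one population of size theta: TMRCA ~ Exp(2/theta),
  # mean theta/2
  theta <- 0.01
  net <- one_pop_net(theta)
  tab <- sim_loci(net, S = 2, rho = 0, theta_base = theta, nloc = 3000,
                  seed = 7, trees = TRUE)
  ages <- vapply(attr(tab, "genealogies"), function(g) g$records$age[1], 0)
  se <- stats::sd(ages) / sqrt(length(ages))
  expect_lt(abs(mean(ages) - theta / 2), 3 * se)
  ks <- stats::ks.test(ages, stats::pexp, rate = 2 / theta)
  expect_gt(ks$p.value, 0.01)
})

test_that("gene-tree discordance follows the MSC closed form", {
  # ((A,B)S,C)R with internal branch dt: each discordant rooted topology
  # has probability (1/3) exp(-2 dt / theta)
  theta <- 0.01
  dt <- 0.005
  net <- three_species_net(theta = theta, tau_s = 0.004, tau_r = 0.004 + dt)
  tab <- sim_loci(net, S = 1, rho = 0, theta_base = theta, nloc = 4000,
                  seed = 11, trees = TRUE)
  topo <- vapply(attr(tab, "genealogies"), function(g)
    mscrecomb:::rooted_topology_id(marginal_tree_at(g, 0)), "")
  p_expect <- exp(-2 * dt / theta) / 3
  p_ac <- mean(topo == "((A1,C1),B1)")
  p_bc <- mean(topo == "((B1,C1),A1)")
  se <- sqrt(p_expect * (1 - p_expect) / length(topo))
  expect_lt(abs(p_ac - p_expect), 4 * se)
  expect_lt(abs(p_bc - p_expect), 4 * se)
})

test_that("recombination events are rho-dependent but theta-invariant", {
  # tau proportional to theta: the event-count distribution depends on rho
  # (and S) but not on the mutation rate
  n1 <- sim_loci(network_preset("A01-B", 0.0025), S = 2, rho = 0.5,
                 theta_base = 0.0025, nloc = 4000, seed = 21)
  n2 <- sim_loci(network_preset("A01-B", 0.01), S = 2, rho = 0.5,
                 theta_base = 0.01, nloc = 4000, seed = 22)
  bins <- c(-0.5, 1.5, 3.5, 5.5, 7.5, 9.5, 12.5, Inf)
  h1 <- table(cut(n1$events, bins))
  h2 <- table(cut(n2$events, bins))
  suppressWarnings(
    chi <- stats::chisq.test(rbind(as.integer(h1), as.integer(h2))))
  expect_gt(chi$p.value, 0.01)

  # monotone in S at fixed rho and in rho at fixed S
  nS8 <- sim_loci(network_preset("A01-B", 0.0025), S = 8, rho = 0.5,
                  theta_base = 0.0025, nloc = 1500, seed = 23)
  expect_gt(mean(nS8$events), mean(n1$events))
  nr5 <- sim_loci(network_preset("A01-B", 0.0025), S = 2, rho = 5,
                  theta_base = 0.0025, nloc = 1500, seed = 24)
  expect_gt(mean(nr5$events), mean(n1$events))
})

test_that("hybrid routing sends lineages to the donor with probability phi", {
  net <- tiny_msci_net(phi = 0.3)
  map <- data.frame(sequence = "B1", species = "B")
  d <- sim_design(S = 1, L = 1, rho = 0, theta_base = 0.01)
  # a second sample in A so the locus has 2 sequences
  map <- rbind(map, data.frame(sequence = "A1", species = "A"))
  set.seed(31)
  alt <- total <- 0
  for (i in 1:2000) {
    g <- simulate_locus(net, map, d)
    hy <- g$route[g$route$hybrid == "Y", ]
    alt <- alt + hy$routed_alt
    total <- total + hy$routed_total
  }
  p <- alt / total
  se <- sqrt(0.3 * 0.7 / total)
  expect_lt(abs(p - 0.3), 4 * se)
})

test_that("study settings reproduce the independent-simulator tabulation", {
  # Frozen oracle values from an independent coalescent simulator (msprime,
  # 3000 replicates) for the delimitation trees at theta=0.0025, S=2,
  # rho=0.05: deep tree (tau_R=5theta) mean 0.497 events, 0.608 zero
  # fraction; shallow tree (tau_R=theta) mean 0.161, 0.854.
  deep <- sim_loci(network_preset("A11-deep", 0.0025), S = 2, rho = 0.05,
                   theta_base = 0.0025, nloc = 6000, seed = 41)
  expect_lt(abs(mean(deep$events) - 0.497), 0.05)
  expect_lt(abs(mean(deep$events == 0) - 0.608), 0.03)
  shallow <- sim_loci(network_preset("A11-shallow", 0.0025), S = 2,
                      rho = 0.05, theta_base = 0.0025, nloc = 6000,
                      seed = 42)
  expect_lt(abs(mean(shallow$events) - 0.161), 0.03)
  expect_lt(abs(mean(shallow$events == 0) - 0.854), 0.02)
})

test_that("joint ARG law matches msprime on a two-population model", {
  skip_if(Sys.which("python") == "", "python not on PATH")
  theta <- 0.01; tau <- 0.005; rho <- 0.5; nrep <- 10000
  ours <- sim_loci(two_species_net(theta, tau), S = 1, rho = rho,
                   theta_base = theta, nloc = nrep, seed = 51,
                   trees = TRUE)
  gl <- attr(ours, "genealogies")
  tmrca <- vapply(gl, function(g) {
    r <- g$records
    r$age[r$start <= 0 & r$end >= 1][1]
  }, 0)
  out <- system2("python",
                 c(oracle_script("msprime_twopop.py"), theta, tau, rho,
                   500, 1, nrep, 123), stdout = TRUE)
  oracle <- utils::read.csv(text = out, header = FALSE,
                            col.names = c("tmrca", "events"))
  ks <- suppressWarnings(stats::ks.test(tmrca, oracle$tmrca))
  expect_gt(ks$p.value, 0.01)
  bins <- c(-0.5, 0.5, 1.5, 2.5, 3.5, Inf)
  h1 <- table(cut(ours$events, bins))
  h2 <- table(cut(oracle$events, bins))
  suppressWarnings(
    chi <- stats::chisq.test(rbind(as.integer(h1), as.integer(h2))))
  expect_gt(chi$p.value, 0.01)
})

test_that("per-locus seed streams are reproducible and independent", {
  net <- network_preset("A01-B", 0.0025)
  map <- sample_map(net, 2)
  d <- sim_design(S = 2, L = 3, rho = 0.5, theta_base = 0.0025, R = 2,
                  seed = 99)
  t1 <- simulate_replicates(net, map, d)
  t2 <- simulate_replicates(net, map, d)
  expect_identical(t1, t2)
  # regenerating one locus in isolation matches the batch
  g <- simulate_locus(net, map, d, seed = 99 + 1 * 3 + 2)
  expect_equal(g$n_events, t1$events[t1$replicate == 1 & t1$locus == 2])
})
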