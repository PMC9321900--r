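test_that("rrmse matches hand computations", {
  expect_equal(rrmse(rep(1.1 * 7, 5), 7), 0.1, tolerance = 1e-12)
  expect_equal(rrmse(rep(0.42, 9), 0.42), 0)
  expect_equal(rrmse(c(1, 3), 2), 0.5)
  expect_error(rrmse(c(1, 2), 0), "positive")
  expect_error(rrmse(numeric(0), 1), "at least one")
})

test_that("coverage is simple counting", {
  expect_equal(ci_coverage(c(0, 0, 0), c(1, 1, 1), 0.5), 1)
  expect_equal(ci_coverage(c(2, 2), c(3, 3), 0.5), 0)
  expect_equal(ci_coverage(c(0, 0, 0.9), c(1, 1, 1), 0.5), 2 / 3)
  expect_error(ci_coverage(numeric(0), numeric(0), 1), "non-empty")
})

fake_summary <- function(map_tree, clades = NULL, params = NULL) {
  structure(list(params = params, map_tree = map_tree,
                 clades = clades,
                 trees = data.frame(topology = map_tree, prob = 1)),
            class = "posterior_summary")
}

test_that("recovery statistics count MAP trees and clades", {
  truth <- three_species_net()
  true_topo <- "((A,B),C)"
  s1 <- fake_summary(true_topo,
                     data.frame(clade = c("A,B,C", "A,B"),
                                prob = c(1, 0.5)))
  s2 <- fake_summary("((A,C),B)",
                     data.frame(clade = c("A,B,C", "A,C"),
                                prob = c(1, 0.9)))
  rs <- recovery_stats(list(s1, s2), truth)
  expect_equal(rs$recovery, 0.5)
  ab <- rs$clades[rs$clades$clade == "A,B", ]
  expect_equal(ab$map_recovery, 0.5)
  expect_equal(ab$mean_posterior, 0.25)   # (0.5 + 0) / 2
  # all MAP = truth -> all ones
  rs2 <- recovery_stats(list(s1, s1), truth)
  expect_equal(rs2$recovery, 1)
  expect_true(all(rs2$clades$map_recovery == 1))
  # averaging over {0.5, 0.7}
  s3 <- fake_summary(true_topo,
                     data.frame(clade = c("A,B,C", "A,B"),
                                prob = c(1, 0.7)))
  rs3 <- recovery_stats(list(s1, s3), truth)
  expect_equal(rs3$clades$mean_posterior[rs3$clades$clade == "A,B"], 0.6)
})

test_that("recombination summaries count means and zeros", {
  expect_equal(recombination_summary(c(0L, 0L, 3L)),
               list(mean_events = 1, fraction_zero = 2 / 3))
  expect_equal(recombination_summary(c(0L, 0L)),
               list(mean_events = 0, fraction_zero = 1))
  tab <- data.frame(events = c(2L, 0L), breakpoints = c(1L, 0L))
  expect_equal(recombination_summary(tab)$mean_events, 0.5)
  expect_equal(recombination_summary(tab, "events")$mean_events, 1)
  expect_error(recombination_summary(integer(0)), "no loci")
})

test_that("segment-tree comparison matches a brute-force classification", {
  net <- network_preset("A01-B", 0.0025)
  map <- sample_map(net, 2)
  d <- sim_design(S = 2, L = 1, rho = 3, theta_base = 0.0025)
  found_multi <- FALSE
  for (seed in 1:8) {
    g <- simulate_locus(net, map, d, seed = seed)
    cmp <- compare_segment_trees(g)
    st <- segment_trees(g)
    m <- length(st$trees)
    # brute-force distinct count by all-pairs topology comparison
    ids <- vapply(st$trees, mscrecomb:::rooted_topology_id, "")
    brute <- 0
    for (i in seq_len(m))
      if (!any(ids[seq_len(i - 1)] == ids[i])) brute <- brute + 1
    expect_equal(cmp$n_distinct_topologies, brute)
    expect_equal(nrow(cmp$breakpoints), m - 1L)
    if (m > 1) found_multi <- TRUE
    expect_true(all(cmp$breakpoints$class %in%
                      c("none", "lengths", "topology")))
    # class consistency: "topology" iff the flanking ids differ
    if (m > 1) {
      differs <- ids[-m] != ids[-1]
      expect_equal(cmp$breakpoints$class == "topology", unname(differs))
    }
  }
  expect_true(found_multi)
  # rho = 0: one topology, no breakpoints
  d0 <- sim_design(S = 2, L = 1, rho = 0, theta_base = 0.0025)
  g0 <- simulate_locus(net, map, d0, seed = 1)
  cmp0 <- compare_segment_trees(g0)
  expect_equal(cmp0$n_distinct_topologies, 1L)
  expect_equal(nrow(cmp0$breakpoints), 0L)
})

test_that("estimation reports assemble bias, coverage and rrmse", {
  mk <- function(m, lo, hi) structure(list(
    params = data.frame(parameter = "tau_R", mean = m, lower = lo,
                        upper = hi)), class = "posterior_summary")
  sums <- list(mk(0.011, 0.009, 0.013), mk(0.013, 0.012, 0.014),
               mk(0.009, 0.007, 0.011))
  rep <- estimation_report(sums, c(tau_R = 0.01))
  expect_equal(rep$coverage, 2 / 3)
  expect_equal(rep$mean_estimate, mean(c(0.011, 0.013, 0.009)))
  expect_equal(rep$rrmse,
               rrmse(c(0.011, 0.013, 0.009), 0.01))
  expect_gte(rep$rrmse^2 + 1e-12, rep$rel_bias^2)  # variance decomposition
})
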