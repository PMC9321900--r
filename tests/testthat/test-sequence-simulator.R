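test_that("zero branch lengths copy the root state to every tip", {
  net <- one_pop_net(0.01)
  map <- data.frame(sequence = c("A1", "A2"), species = c("A", "A"))
  d <- sim_design(S = 2, L = 1, rho = 0, theta_base = 0.01, n = 50)
  g <- simulate_locus(net, map, d, seed = 1)
  g$records$age <- 0
  aln <- evolve_jc(g, seed = 2)
  expect_identical(aln[1, ], aln[2, ])
})

test_that("pairwise differences follow the JC saturation curve", {
  # fixed 2-tip tree at total path distance d: differing fraction
  # -> (3/4)(1 - exp(-4d/3))
  net <- one_pop_net(0.01)
  map <- data.frame(sequence = c("A1", "A2"), species = c("A", "A"))
  d <- sim_design(S = 2, L = 1, rho = 0, theta_base = 0.01, n = 50000)
  g <- simulate_locus(net, map, d, seed = 5)
  for (dist in c(0.01, 0.2)) {
    g$records$age <- dist / 2
    aln <- evolve_jc(g, seed = 7)
    p_hat <- mean(aln[1, ] != aln[2, ])
    p_exp <- 0.75 * (1 - exp(-4 * dist / 3))
    se <- sqrt(p_exp * (1 - p_exp) / ncol(aln))
    expect_lt(abs(p_hat - p_exp), 3 * se)
  }
  # saturation limit
  g$records$age <- 50
  aln <- evolve_jc(g, seed = 8)
  expect_lt(abs(mean(aln[1, ] != aln[2, ]) - 0.75), 0.01)
})

test_that("two half-length steps equal one full JC jump (Markov property)", {
  # a 2-tip genealogy with root age t/2 evolves each lineage in one t/2
  # step from a common state, so tip-to-tip differences traverse two
  # independent steps; the count per locus must be Binomial(n, p(t)) with
  # the single-jump probability p(t) = (3/4)(1 - exp(-4t/3))
  net <- one_pop_net(0.01)
  map <- data.frame(sequence = c("A1", "A2"), species = c("A", "A"))
  n <- 100; dist <- 0.1
  d <- sim_design(S = 2, L = 1, rho = 0, theta_base = 0.01, n = n)
  g <- simulate_locus(net, map, d, seed = 9)
  g$records$age <- dist / 2
  set.seed(10)
  counts <- replicate(4000, { a <- evolve_jc(g); sum(a[1, ] != a[2, ]) })
  p <- 0.75 * (1 - exp(-4 * dist / 3))
  br <- unique(c(-0.5, stats::qbinom(seq(0.1, 0.9, 0.1), n, p) + 0.5, Inf))
  obs <- table(cut(counts, br))
  expc <- diff(stats::pbinom(br, n, p)) * length(counts)
  suppressWarnings(chi <- stats::chisq.test(as.integer(obs),
                                            p = expc / sum(expc)))
  expect_gt(chi$p.value, 0.01)
})

test_that("base composition is uniform", {
  net <- one_pop_net(0.01)
  map <- data.frame(sequence = c("A1", "A2"), species = c("A", "A"))
  d <- sim_design(S = 2, L = 1, rho = 0, theta_base = 0.01, n = 20000)
  g <- simulate_locus(net, map, d, seed = 14)
  aln <- evolve_jc(g, seed = 15)
  freq <- table(aln) / length(aln)
  expect_true(all(abs(freq - 0.25) < 0.02))
  expect_equal(sort(names(freq)), c("A", "C", "G", "T"))
})

test_that("PHYLIP and FASTA round-trip exactly, multilocus included", {
  net <- network_preset("A01-B", 0.01)
  map <- sample_map(net, 2)
  d <- sim_design(S = 2, L = 2, rho = 0, theta_base = 0.01, n = 40)
  alns <- simulate_alignments(net, map, d)
  fp <- tempfile()
  write_alignment(alns[[1]], fp, "phylip")
  write_alignment(alns[[2]], fp, "phylip", append = TRUE)
  back <- read_alignment(fp, "phylip")
  expect_length(back, 2L)
  expect_equal(unclass(back[[1]]), unclass(alns[[1]]))
  expect_equal(unclass(back[[2]]), unclass(alns[[2]]))
  hdr <- readLines(fp, n = 1)
  expect_equal(hdr, "10 40")

  ff <- tempfile()
  write_alignment(alns[[1]], ff, "fasta")
  backf <- read_alignment(ff, "fasta")
  expect_equal(unclass(backf), unclass(alns[[1]]))
})
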