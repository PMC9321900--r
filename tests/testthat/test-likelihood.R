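# brute-force JC likelihood by summing over all internal states
brute_jc <- function(tree, states) {
  jc_p <- function(x, y, t) {
    e <- exp(-4 * t / 3)
    if (x == y) 0.25 + 0.75 * e else 0.25 - 0.25 * e
  }
  nt <- length(tree$tip.label)
  nn <- tree$Nnode
  total <- 0
  grid <- expand.grid(rep(list(0:3), nn))
  for (r in seq_len(nrow(grid))) {
    st <- c(states, as.integer(grid[r, ]))
    pr <- 0.25   # root state
    for (e in seq_len(nrow(tree$edge)))
      pr <- pr * jc_p(st[tree$edge[e, 1]], st[tree$edge[e, 2]],
                      tree$edge.length[e])
    total <- total + pr
  }
  log(total)
}

test_that("pruning equals brute-force enumeration on a 3-tip tree", {
  tree <- ape::read.tree(text = "((A:0.02,B:0.05):0.03,C:0.08);")
  set.seed(1)
  for (i in 1:5) {
    states <- sample(0:3, 3, replace = TRUE)
    a <- matrix(c("T", "C", "A", "G")[states + 1], nrow = 3,
                dimnames = list(c("A", "B", "C"), NULL))
    expect_equal(jc_pruning_loglik(a, tree), brute_jc(tree, states),
                 tolerance = 1e-10)
  }
})

test_that("identical sequences on a zero-length tree give n log 1/4", {
  tree <- ape::read.tree(text = "(A:0,B:0);")
  n <- 17
  a <- matrix("G", 2, n, dimnames = list(c("A", "B"), NULL))
  expect_equal(jc_pruning_loglik(a, tree), n * log(0.25))
})

test_that("the likelihood is invariant to root placement", {
  set.seed(2)
  tree <- ape::rtree(6)
  tree$edge.length <- stats::runif(nrow(tree$edge), 0.01, 0.1)
  a <- matrix(sample(c("T", "C", "A", "G"), 6 * 30, replace = TRUE), 6, 30,
              dimnames = list(tree$tip.label, NULL))
  l0 <- jc_pruning_loglik(a, tree)
  for (node in c(2, 4)) {
    rr <- ape::root(ape::unroot(tree), outgroup = tree$tip.label[node],
                    resolve.root = TRUE)
    expect_lt(abs(jc_pruning_loglik(a, rr) - l0), 1e-9)
  }
  expect_error(jc_pruning_loglik(a[1:3, ], tree), "missing")
})

test_that("single-population MSC density matches the exponential law", {
  # 2 lineages, coalescence at age t: log(2/theta) - 2t/theta
  theta <- 0.01
  net <- one_pop_net(theta)
  map <- data.frame(sequence = c("A1", "A2"), species = c("A", "A"))
  for (t in c(0.001, 0.02)) {
    tr <- ape::read.tree(text = sprintf("(A1:%g,A2:%g);", t, t))
    expect_equal(msc_logdensity(tr, net, map),
                 log(2 / theta) - 2 * t / theta, tolerance = 1e-10)
  }
  # density integrates to 1 over the coalescence age
  f <- Vectorize(function(t) {
    tr <- ape::read.tree(text = sprintf("(A1:%g,A2:%g);", t, t))
    exp(msc_logdensity(tr, net, map))
  })
  expect_equal(stats::integrate(f, 0, 1)$value, 1, tolerance = 1e-5)
})

test_that("species divergences truncate coalescence correctly", {
  # two species, one sequence each: coalescence must predate the split
  theta <- 0.01; tau <- 0.005
  net <- two_species_net(theta, tau)
  map <- data.frame(sequence = c("A1", "B1"), species = c("A", "B"))
  t <- 0.008
  tr <- ape::read.tree(text = sprintf("(A1:%g,B1:%g);", t, t))
  expect_equal(msc_logdensity(tr, net, map),
               log(2 / theta) - 2 * (t - tau) / theta, tolerance = 1e-10)
  too_young <- ape::read.tree(text = "(A1:0.004,B1:0.004);")
  expect_identical(msc_logdensity(too_young, net, map), -Inf)
})

test_that("hybrid path indicators contribute their phi factors", {
  phi <- 0.3
  net <- tiny_msci_net(theta = 0.01, tau_h = 0.002, tau_r = 0.01,
                       phi = phi)
  map <- data.frame(sequence = c("B1", "B2"), species = c("B", "B"))
  # two B lineages cross hybrid Y at 0.002 and coalesce at 0.006, which is
  # valid when both take the same parent; populations X and Y span the
  # same interval with equal theta, so the densities differ only in the
  # routing factors: phi^2 (donor side) versus (1-phi)^2
  tr <- ape::read.tree(text = "(B1:0.006,B2:0.006);")
  ind_main <- data.frame(node = c(1L, 2L), hybrid = "Y",
                         choice = "main")
  ind_alt <- data.frame(node = c(1L, 2L), hybrid = "Y", choice = "alt")
  lm <- msc_logdensity(tr, net, map, ind_main)
  la <- msc_logdensity(tr, net, map, ind_alt)
  expect_true(is.finite(lm) && is.finite(la))
  expect_equal(la - lm, 2 * (log(phi) - log(1 - phi)), tolerance = 1e-10)
  # with phi = 1 the routing factor disappears: the density changes by
  # -2 log phi relative to the alt path
  net1 <- tiny_msci_net(theta = 0.01, tau_h = 0.002, tau_r = 0.01,
                        phi = 1)
  l1 <- msc_logdensity(tr, net1, map, ind_alt)
  expect_equal(l1 - la, -2 * log(phi), tolerance = 1e-10)
  # opposite parents orphan the coalescence below the root population
  ind_mix <- data.frame(node = c(1L, 2L), hybrid = "Y",
                        choice = c("main", "alt"))
  expect_identical(msc_logdensity(tr, net, map, ind_mix), -Inf)
})

test_that("theta-integrated contributions reduce to closed forms", {
  expect_equal(theta_integrated_factor(0, 0, 3, 0.005), 0)
  a <- 3; b <- 0.004; cc <- 0.002
  expect_equal(theta_integrated_factor(0, cc, a, b),
               a * log(b / (b + 2 * cc)), tolerance = 1e-12)
  expect_error(theta_integrated_factor(1, 0.1, 1, 0.01), "alpha")
})

test_that("theta-integrated density matches numerical quadrature", {
  set.seed(3)
  for (i in 1:6) {
    k <- sample(0:5, 1)
    cc <- stats::runif(1, 0, 0.02)
    a <- stats::runif(1, 2, 5)
    b <- stats::runif(1, 0.002, 0.05)
    f <- function(th)
      (2 / th)^k * exp(-2 * cc / th) *
        b^a / gamma(a) * th^(-a - 1) * exp(-b / th)
    quad <- stats::integrate(f, 0, Inf, rel.tol = 1e-10)$value
    expect_equal(theta_integrated_factor(k, cc, a, b), log(quad),
                 tolerance = 1e-6)
  }
})

test_that("integrated and closed-form densities agree through msc_stats", {
  # one population, 2 lineages coalescing at t: k=1, c=t
  theta <- 0.01; t <- 0.004
  net <- one_pop_net(theta)
  map <- data.frame(sequence = c("A1", "A2"), species = c("A", "A"))
  tr <- ape::read.tree(text = sprintf("(A1:%g,A2:%g);", t, t))
  pr <- prior_spec(theta_alpha = 3, theta_beta = 0.005)
  got <- msc_logdensity_theta_integrated(tr, net, map, pr)
  expect_equal(got, theta_integrated_factor(1, t, 3, 0.005),
               tolerance = 1e-12)
})

test_that("msc density is invariant under locus relabeling", {
  theta <- 0.01
  net <- two_species_net(theta, 0.005)
  map <- data.frame(sequence = c("A1", "B1"), species = c("A", "B"))
  t1 <- ape::read.tree(text = "(A1:0.007,B1:0.007);")
  t2 <- ape::read.tree(text = "(A1:0.012,B1:0.012);")
  expect_equal(msc_logdensity(list(t1, t2), net, map),
               msc_logdensity(list(t2, t1), net, map))
})
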