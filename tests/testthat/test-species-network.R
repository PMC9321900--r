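test_that("model presets encode the factorial-study trees", {
  th <- 0.0025
  b <- network_preset("A01-B", th)
  expect_equal(sort(b$nodes$label[network_tips(b)]),
               c("A", "B", "C", "D", "E"))
  ages <- setNames(b$nodes$age, b$nodes$label)
  expect_equal(unname(ages[c("R", "S", "T", "U")]),
               c(5, 4.8, 4.7, 4.8) * th)
  expect_equal(network_topology(b), "(((A,B),C),(D,E))")

  u <- network_preset("A01-U", th)
  expect_equal(network_topology(u), "((((A,B),C),D),E)")
  expect_equal(sort(u$nodes$age), sort(c(0, 0, 0, 0, 0,
                                         c(4.4, 4.6, 4.8, 5) * th)))

  deep <- network_preset("A11-deep", 0.01)
  ad <- setNames(deep$nodes$age, deep$nodes$label)
  expect_equal(unname(ad["R"]), 0.05)
  expect_equal(unname(ad["S"]), 0.048)
  expect_equal(unname(ad[c("T", "U")]), rep(1e-50 * 0.01, 2))

  msci <- network_preset("A00-B", 0.01)
  phis <- setNames(msci$nodes$phi, msci$nodes$label)
  expect_equal(unname(phis["Y"]), 0.3)
  expect_equal(unname(phis["W"]), 0.2)
  # 21 parameters: 6 tau classes, 13 thetas, 2 phis
  expect_equal(max(mscrecomb:::age_classes(msci)) + 1L, 6L)
  expect_equal(nrow(msci$nodes), 13L)
  expect_equal(sum(!is.na(msci$nodes$parent2)), 2L)
})

test_that("tau scales linearly in theta across presets", {
  for (nm in c("A01-B", "A01-U", "A11-shallow", "A11-deep", "A00-B",
               "A00-U")) {
    n1 <- network_preset(nm, 0.0025)
    n2 <- network_preset(nm, 0.005)
    expect_equal(n2$nodes$age, 2 * n1$nodes$age, info = nm)
    expect_silent(validate_species_network(n1))
  }
})

test_that("validation rejects malformed networks", {
  expect_error(species_network(c("A", "B"), c(0, 0), c(0.01, 0.01),
                               c(NA, NA)), "exactly one root")
  expect_error(species_network(c("A", "R"), c(0, 0.01), c(0.01, -1),
                               c(2L, NA)), "theta")
  expect_error(species_network(c("A", "R"), c(0.02, 0.01), c(0.01, 0.01),
                               c(2L, NA)), "parent age")
  net <- tiny_msci_net()
  net$nodes$phi[4] <- 1.5
  expect_error(validate_species_network(net), "phi")
})

test_that("extended-Newick writing and parsing round-trips", {
  for (nm in c("A01-B", "A11-shallow", "A00-B", "A00-U")) {
    net <- network_preset(nm, 0.01)
    txt <- write_species_network(net)
    back <- parse_species_network(txt)
    expect_identical(write_species_network(back), txt, info = nm)
    expect_equal(sort(back$nodes$label), sort(net$nodes$label))
    expect_equal(setNames(back$nodes$age, back$nodes$label)[net$nodes$label],
                 setNames(net$nodes$age, net$nodes$label))
  }
  # plain Newick with ultrametric branch lengths and theta attributes
  txt <- paste0("((A[&theta=0.01]:0.004,B[&theta=0.01]:0.004)",
                "S[&theta=0.01]:0.006,C[&theta=0.01]:0.01)R[&theta=0.01];")
  net <- parse_species_network(txt)
  a <- setNames(net$nodes$age, net$nodes$label)
  expect_equal(unname(a[c("S", "R")]), c(0.004, 0.01))
})

test_that("parser reports syntax and semantic errors", {
  expect_error(parse_species_network("((A,B;"), "parenthes|syntax")
  expect_error(parse_species_network(""), "syntax")
  # hybrid tag appearing once: not two parents
  expect_error(parse_species_network(
    "((A[&age=0,theta=1],(B[&age=0,theta=1])Y#H1[&age=0.1,theta=1,phi=0.2])R[&age=0.2,theta=1]);"),
    "2 parents|exactly")
  # phi outside [0,1]
  net <- tiny_msci_net()
  txt <- write_species_network(net)
  bad <- sub("phi=0.3", "phi=1.4", txt, fixed = TRUE)
  expect_error(parse_species_network(bad), "phi")
})

test_that("event schedules carry the right merges and routings", {
  th <- 0.0025
  b <- network_preset("A01-B", th)
  ev <- event_schedule(b)
  expect_equal(nrow(ev), 4L)
  expect_true(all(ev$type == "MERGE"))
  expect_equal(sort(ev$time), c(4.7, 4.8, 4.8, 5) * th)
  expect_true(!is.unsorted(ev$time))

  msci <- network_preset("A00-B", th)
  evm <- event_schedule(msci)
  routes <- evm[evm$type == "ROUTE", ]
  expect_equal(nrow(routes), 2L)
  expect_equal(routes$time, rep(th, 2))
  expect_equal(sort(routes$prob), c(0.2, 0.3))
  # merges = non-hybrid internal nodes (R,S,T,U plus donor points X,Z)
  expect_equal(sum(evm$type == "MERGE"), 6L)

  single <- one_pop_net()
  expect_equal(nrow(event_schedule(single)), 0L)
})

test_that("tree-model schedules reduce populations by one per merge", {
  for (nm in c("A01-B", "A01-U")) {
    net <- network_preset(nm, 0.01)
    ev <- event_schedule(net)
    npop <- length(network_tips(net))
    for (i in seq_len(nrow(ev))) {
      nsrc <- length(strsplit(ev$src[i], ",")[[1]])
      npop <- npop - nsrc + 1L
      expect_gte(npop, 1L)
    }
    expect_equal(npop, 1L)
  }
})

test_that("sample maps validate against the network and round-trip", {
  net <- network_preset("A01-B", 0.01)
  map <- sample_map(net, 2)
  expect_equal(nrow(map), 10L)
  expect_equal(as.vector(table(map$species)), rep(2L, 5))
  f <- tempfile()
  write_sample_map(map, f)
  expect_equal(read_sample_map(f), map)
  bad <- rbind(map, data.frame(sequence = "Z1", species = "Z"))
  expect_error(validate_sample_map(net, bad), "not tips")
})
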