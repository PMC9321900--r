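# Small fixture networks built in code.

one_pop_net <- function(theta = 0.01) {
  species_network("A", 0, theta, NA_integer_)
}

two_species_net <- function(theta = 0.01, tau = 0.005) {
  species_network(c("A", "B", "R"), c(0, 0, tau), rep(theta, 3),
                  c(3L, 3L, NA))
}

# asymmetric rooted 3-species tree ((A,B)S,C)R
three_species_net <- function(theta = 0.0025, tau_s = 0.005,
                              tau_r = 0.01) {
  species_network(c("A", "B", "C", "S", "R"), c(0, 0, 0, tau_s, tau_r),
                  rep(theta, 5), c(4L, 4L, 5L, 5L, NA))
}

# minimal MSci network: recipient hybrid Y on B's branch, donor X on A's
# branch, both at age tau_h; phi routes to the donor side
tiny_msci_net <- function(theta = 0.01, tau_h = 0.002, tau_r = 0.01,
                          phi = 0.3) {
  species_network(
    label = c("A", "B", "X", "Y", "R"),
    age = c(0, 0, tau_h, tau_h, tau_r),
    theta = rep(theta, 5),
    parent = c(3L, 4L, 5L, 5L, NA),
    parent2 = c(NA, NA, NA, 3L, NA),
    phi = c(NA, NA, NA, phi, NA))
}

map_for <- function(net, S) sample_map(net, S)

# batch of per-locus genealogies at fixed seed
sim_loci <- function(net, S, rho, theta_base, nloc, seed = 1,
                     trees = FALSE, n = 500) {
  d <- sim_design(S = S, L = nloc, rho = rho, theta_base = theta_base,
                  n = n, R = 1, seed = seed)
  simulate_replicates(net, sample_map(net, S), d, trees = trees)
}

oracle_script <- function(name) {
  f <- system.file("oracle", name, package = "mscrecomb")
  stopifnot(nzchar(f))
  f
}
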