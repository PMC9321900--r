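#' Prior specification for MSC/MSci inference
#'
#' Inverse-gamma priors on the root age (tau0) and the per-branch population
#' sizes (theta), and a uniform prior on each introgression probability.
#' The inverse-gamma IG(alpha, beta) has mean `beta/(alpha - 1)`; alpha = 3
#' gives a diffuse prior.  Non-root divergence times are uniform given tau0
#' and the node-order constraints.
#'
#' @param tau_alpha,tau_beta IG parameters of the root-age prior.
#' @param theta_alpha,theta_beta IG parameters of the shared theta prior.
#' @param integrate_theta integrate the thetas analytically (the species-
#'   tree-search configuration) instead of sampling them.
#' @return an object of class `prior_spec`.
#' @export
prior_spec <- function(tau_alpha = 3, tau_beta = 0.025,
                       theta_alpha = 3, theta_beta = 0.005,
                       integrate_theta = FALSE) {
  stopifnot(tau_alpha > 1, theta_alpha > 1, tau_beta > 0, theta_beta > 0)
  structure(list(tau_alpha = tau_alpha, tau_beta = tau_beta,
                 theta_alpha = theta_alpha, theta_beta = theta_beta,
                 integrate_theta = isTRUE(integrate_theta)),
            class = "prior_spec")
}

#' Study priors matched to the simulated heterozygosity
#'
#' The factorial study pairs its priors with the generating theta:
#' `tau0 ~ IG(3, 10 * theta)` and `theta ~ IG(3, 2 * theta)`, i.e.
#' IG(3, 0.025)/IG(3, 0.005) at theta = 0.0025 and IG(3, 0.1)/IG(3, 0.02)
#' at theta = 0.01 (prior means 5*theta and theta).
#'
#' @param theta_base the generating per-site theta.
#' @inheritParams prior_spec
#' @export
prior_for_theta <- function(theta_base, integrate_theta = FALSE) {
  prior_spec(3, 10 * theta_base, 3, 2 * theta_base,
             integrate_theta = integrate_theta)
}

#' MCMC run settings
#'
#' One iteration is a full sweep: an age move for every internal gene-tree
#' node of every locus, `n_spr` subtree-regraft attempts per locus, hybrid
#' path-indicator flips, a sliding-window move for every tau (with the
#' rubber-band deformation of gene-node ages), Gibbs draws for every theta
#' and phi, species-tree NNI moves where enabled, and one whole-model
#' rescale.  Step sizes are autotuned toward ~30% acceptance during burn-in,
#' then frozen.
#'
#' @param burnin discarded initial sweeps.
#' @param nsamples recorded samples.
#' @param thin record every `thin`-th sweep.
#' @param n_spr subtree-regraft attempts per locus per sweep (default: one
#'   per internal node).
#' @param w_age initial age-move window (absolute, substitutions/site).
#' @param w_tau initial tau window.
#' @param eps_mix log-scale width of the rescale move.
#' @param autotune adapt step sizes during burn-in.
#' @param seed optional integer seed.
#' @return an object of class `mcmc_settings`.
#' @export
mcmc_settings <- function(burnin = 500L, nsamples = 1500L, thin = 1L,
                          n_spr = NULL, w_age = NULL, w_tau = NULL,
                          eps_mix = 0.5, autotune = TRUE, seed = NULL,
                          validate = FALSE) {
  stopifnot(burnin >= 0, nsamples > 0, thin > 0)
  structure(list(burnin = as.integer(burnin),
                 nsamples = as.integer(nsamples), thin = as.integer(thin),
                 n_spr = n_spr, w_age = w_age, w_tau = w_tau,
                 eps_mix = eps_mix, autotune = isTRUE(autotune),
                 seed = seed, validate = isTRUE(validate)),
            class = "mcmc_settings")
}

# tau age classes: each internal node its own parameter; a hybrid node is
# tied to its (equal-age) second parent
age_classes <- function(net) {
  nd <- net$nodes
  n <- nrow(nd)
  tips <- network_tips(net)
  cls <- rep(NA_integer_, n)
  nxt <- 0L
  for (i in setdiff(seq_len(n), tips)) {
    if (!is.na(cls[i])) next
    cls[i] <- nxt
    if (!is.na(nd$parent2[i])) cls[nd$parent2[i]] <- nxt
    nxt <- nxt + 1L
  }
  # a second parent that precedes its hybrid in node order
  for (i in setdiff(seq_len(n), tips))
    if (!is.na(nd$parent2[i]) && cls[nd$parent2[i]] != cls[i]) {
      cls[cls == cls[nd$parent2[i]]] <- cls[i]
    }
  # renumber densely
  u <- sort(unique(cls[!is.na(cls)]))
  cls <- match(cls, u) - 1L
  cls[is.na(cls)] <- -1L
  cls
}

compress_alignment <- function(a, labels) {
  mat <- a[labels, , drop = FALSE]
  code <- matrix(match(mat, c("T", "C", "A", "G")) - 1L, nrow = nrow(mat))
  key <- apply(code, 2L, paste, collapse = ",")
  tab <- table(key)
  list(tip_pat = code[, match(names(tab), key), drop = FALSE],
       weights = as.numeric(tab))
}

run_chain <- function(alns, net, map, prior, settings, species_tree_move) {
  validate_species_network(net)
  validate_sample_map(net, map)
  nd <- net$nodes
  data_free <- is.null(alns)
  if (!data_free && inherits(alns, "locus_alignment")) alns <- list(alns)
  cls <- age_classes(net)
  ntau <- max(cls) + 1L
  # initial state: root age at its prior mean, inner ages keeping the input
  # network's relative shape; theta at the prior mean; phi at 1/2
  tau0_mean <- prior$tau_beta / (prior$tau_alpha - 1)
  root <- which(is.na(nd$parent))
  scale0 <- tau0_mean / nd$age[root]
  theta_mean <- prior$theta_beta / (prior$theta_alpha - 1)
  net_in <- list(age = nd$age * scale0,
                 parent = ifelse(is.na(nd$parent), -1L, nd$parent - 1L),
                 parent2 = ifelse(is.na(nd$parent2), -1L, nd$parent2 - 1L),
                 phi = rep(0.5, nrow(nd)),
                 age_class = cls,
                 theta = rep(theta_mean, nrow(nd)),
                 label = nd$label)
  loci_in <- list()
  nl <- if (data_free) 1L else length(alns)
  for (l in seq_len(nl)) {
    if (data_free) {
      labels <- map$sequence
      li <- list(tip_pop = match(map$species, nd$label) - 1L)
    } else {
      labels <- rownames(alns[[l]])
      sp <- map$species[match(labels, map$sequence)]
      if (anyNA(sp)) stop("locus ", l, ": sequence labels not in sample map")
      cmp <- compress_alignment(alns[[l]], labels)
      li <- list(tip_pop = match(sp, nd$label) - 1L,
                 tip_pat = cmp$tip_pat, weights = cmp$weights)
    }
    loci_in[[l]] <- li
  }
  if (!is.null(settings$seed)) set.seed(settings$seed)
  w_age <- if (is.null(settings$w_age)) tau0_mean / 5 else settings$w_age
  w_tau <- if (is.null(settings$w_tau)) tau0_mean / 10 else settings$w_tau
  m <- length(loci_in[[1]]$tip_pop)
  n_spr <- if (is.null(settings$n_spr)) m - 1L else settings$n_spr
  set_in <- list(data_free = data_free,
                 species_tree_move = isTRUE(species_tree_move),
                 burnin = settings$burnin, nsamples = settings$nsamples,
                 thin = settings$thin, autotune = settings$autotune,
                 w_age = w_age, w_tau = w_tau, eps_mix = settings$eps_mix,
                 n_spr = as.integer(n_spr),
                 validate = isTRUE(settings$validate))
  prior_in <- list(tau_alpha = prior$tau_alpha, tau_beta = prior$tau_beta,
                   theta_alpha = prior$theta_alpha,
                   theta_beta = prior$theta_beta,
                   integrate_theta = prior$integrate_theta)
  res <- .run_mcmc_cpp(net_in, loci_in, prior_in, set_in)
  cls_labels <- vapply(0:(ntau - 1L), function(k)
    paste(sort(nd$label[which(cls == k)]), collapse = "."), "")
  cn <- paste0("tau_", cls_labels)
  if (!prior$integrate_theta) cn <- c(cn, paste0("theta_", nd$label))
  hyb <- which(!is.na(nd$parent2))
  if (length(hyb)) cn <- c(cn, paste0("phi_", nd$label[hyb]))
  cn <- c(cn, "loglik")
  colnames(res$samples) <- cn
  structure(list(params = res$samples,
                 topology = if (species_tree_move) as.character(res$topology)
                            else NULL,
                 acceptance = acceptance_table(res$acceptance),
                 prior = prior, settings = settings, net = net, map = map),
            class = "msc_chain")
}

acceptance_table <- function(m) {
  out <- data.frame(
    move = c("gene_age", "gene_spr", "hybrid_flip", "tau", "rescale",
             "species_nni"),
    accepted = m[, 1], tried = m[, 2])
  out$rate <- ifelse(out$tried > 0, out$accepted / out$tried, NA)
  out
}

#' A00: posterior sampling of tau, theta and phi on a fixed model
#'
#' Metropolis-within-Gibbs sampling of the MSC/MSci posterior for a fixed
#' species tree or network topology: gene-tree ages, gene-tree topologies
#' (subtree regrafts), hybrid path indicators, tau (sliding windows with the
#' rubber-band gene-age deformation), theta (conjugate inverse-gamma Gibbs
#' draws), phi (Beta Gibbs draws) and a whole-model rescale move.
#'
#' @param alns a list of `locus_alignment` objects (or `NULL` for a
#'   data-free run, which samples from the prior and is useful for
#'   validating the sampler).
#' @param net the species network giving the (fixed) topology; its ages are
#'   used only to shape the initial state.
#' @param map sample map.
#' @param prior a [prior_spec()]; thetas are sampled, so
#'   `integrate_theta = FALSE` is required.
#' @param settings an [mcmc_settings()].
#' @return an `msc_chain`: `params` (samples x parameters matrix; tau by
#'   age-class label, theta by branch, phi by hybrid node, and the total
#'   log-likelihood) plus acceptance statistics.
#' @export
run_a00 <- function(alns, net, map, prior = prior_spec(),
                    settings = mcmc_settings()) {
  if (prior$integrate_theta)
    stop("A00 reports theta estimates; use integrate_theta = FALSE")
  run_chain(alns, net, map, prior, settings, species_tree_move = FALSE)
}

#' A01: joint posterior over species trees and parameters
#'
#' Augments the A00 moves with rooted nearest-neighbour-interchange moves on
#' the species tree (gene trees held fixed with their population
#' assignments re-derived; proposals that orphan a coalescence are
#' rejected).  Thetas are integrated analytically through the conjugate
#' inverse-gamma prior, the configuration used for species-tree search.
#'
#' @inheritParams run_a00
#' @param net a starting species tree over the candidate tips (no
#'   hybridization nodes).
#' @return an `msc_chain` whose `topology` field holds one canonical
#'   (topology-only) Newick string per sample.
#' @export
run_a01 <- function(alns, net, map,
                    prior = prior_spec(integrate_theta = TRUE),
                    settings = mcmc_settings()) {
  if (any(!is.na(net$nodes$parent2)))
    stop("species-tree search runs on trees, not networks")
  if (!prior$integrate_theta)
    prior$integrate_theta <- TRUE
  run_chain(alns, net, map, prior, settings, species_tree_move = TRUE)
}

#' Shortest 95% highest-posterior-density interval
#'
#' The shortest contiguous interval containing `ceiling(prob * N)` of the
#' sorted samples.
#'
#' @param x numeric samples.
#' @param prob interval mass (default 0.95).
#' @return `c(lower, upper)`.
#' @export
hpd_interval <- function(x, prob = 0.95) {
  x <- sort(x)
  n <- length(x)
  k <- min(n, max(1L, ceiling(prob * n)))
  if (k == n) return(c(x[1], x[n]))
  width <- x[(k):n] - x[seq_len(n - k + 1L)]
  i <- which.min(width)
  c(x[i], x[i + k - 1L])
}

# effective sample size via the initial positive sequence of autocovariances
ess <- function(x) {
  n <- length(x)
  if (n < 10 || stats::var(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 1, 2000), plot = FALSE,
                   demean = TRUE)$acf[-1]
  s <- 0
  for (i in seq_along(ac)) {
    if (ac[i] < 0) break
    s <- s + ac[i]
  }
  max(1, n / (1 + 2 * s))
}

# clades (as sorted tip-label strings) of a canonical topology newick
topology_clades <- function(txt) {
  out <- character(0)
  stack <- list()
  buf <- ""
  flush_tip <- function() {
    if (nzchar(buf)) {
      for (j in seq_along(stack)) stack[[j]] <<- c(stack[[j]], buf)
      buf <<- ""
    }
  }
  for (ch in strsplit(txt, "")[[1]]) {
    if (ch == "(") stack[[length(stack) + 1L]] <- character(0)
    else if (ch == ",") flush_tip()
    else if (ch == ")") {
      flush_tip()
      out <- c(out, paste(sort(stack[[length(stack)]]), collapse = ","))
      stack[length(stack)] <- NULL
    } else if (ch != ";") buf <- paste0(buf, ch)
  }
  out
}

#' Summarize a posterior sample
#'
#' Posterior means, shortest 95% HPD intervals and effective sample sizes
#' for every parameter; for species-tree searches, posterior probabilities
#' of the sampled topologies and of their clades, and the MAP tree (ties
#' broken lexicographically by Newick string).
#'
#' @param chain an `msc_chain` (or a plain numeric matrix of samples).
#' @param prob HPD mass.
#' @return a `posterior_summary`: data.frame `params` (mean, lower, upper,
#'   ess), plus `trees` (topology, prob), `clades` (clade, prob) and
#'   `map_tree` when topologies were sampled.
#' @export
summarize_posterior <- function(chain, prob = 0.95) {
  par <- if (is.matrix(chain)) chain else chain$params
  if (is.null(par) || nrow(par) == 0) stop("empty chain")
  sm <- data.frame(
    parameter = colnames(par),
    mean = colMeans(par),
    lower = apply(par, 2, function(x) hpd_interval(x, prob)[1]),
    upper = apply(par, 2, function(x) hpd_interval(x, prob)[2]),
    ess = apply(par, 2, ess),
    row.names = NULL)
  out <- list(params = sm, trees = NULL, clades = NULL, map_tree = NULL)
  topo <- if (is.matrix(chain)) NULL else chain$topology
  if (!is.null(topo)) {
    tf <- sort(table(topo), decreasing = TRUE)
    probs <- as.numeric(tf) / length(topo)
    out$trees <- data.frame(topology = names(tf), prob = probs,
                            row.names = NULL)
    best <- probs == max(probs)
    out$map_tree <- sort(names(tf)[best])[1]
    cl <- table(unlist(lapply(topo, topology_clades)))
    out$clades <- data.frame(clade = names(cl),
                             prob = as.numeric(cl) / length(topo),
                             row.names = NULL)
    out$clades <- out$clades[order(-out$clades$prob), , drop = FALSE]
  }
  class(out) <- "posterior_summary"
  out
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat("posterior_summary\n")
  print(x$params, digits = 4)
  if (!is.null(x$map_tree)) {
    cat("MAP tree:", x$map_tree, "\n")
    print(utils::head(x$trees, 5), digits = 3)
  }
  invisible(x)
}

#' Compare two independent chains
#'
#' Convergence screen in the spirit of running the same analysis twice:
#' flags the pair when clade posterior probabilities (species-tree search)
#' or scaled posterior means disagree beyond `tol`.
#'
#' @param chain1,chain2 two `msc_chain`s from independent seeds.
#' @param tol maximum tolerated discrepancy (default 0.05).
#' @return list with `flagged` (logical) and `max_discrepancy`.
#' @export
check_convergence <- function(chain1, chain2, tol = 0.05) {
  if (!is.null(chain1$topology) && !is.null(chain2$topology)) {
    c1 <- summarize_posterior(chain1)$clades
    c2 <- summarize_posterior(chain2)$clades
    all_cl <- union(c1$clade, c2$clade)
    p1 <- c1$prob[match(all_cl, c1$clade)]; p1[is.na(p1)] <- 0
    p2 <- c2$prob[match(all_cl, c2$clade)]; p2[is.na(p2)] <- 0
    d <- max(abs(p1 - p2))
  } else {
    m1 <- colMeans(chain1$params); m2 <- colMeans(chain2$params)
    keep <- colnames(chain1$params) != "loglik"
    d <- max(abs(m1[keep] - m2[keep]) / pmax((abs(m1[keep]) +
                                              abs(m2[keep])) / 2, 1e-12))
  }
  list(flagged = d > tol, max_discrepancy = d)
}
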