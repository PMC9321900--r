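#' JC69 pruning log-likelihood of an alignment on a gene tree
#'
#' Felsenstein pruning with uniform root frequencies under JC69.  The value
#' is invariant to root placement of the unrooted topology (reversibility).
#'
#' @param a a `locus_alignment` (character matrix, rows named by sequence).
#' @param tree an `ape::phylo` with branch lengths in expected
#'   substitutions per site; tip labels must match the rows of `a`.
#' @return the log-likelihood (natural log).
#' @export
jc_pruning_loglik <- function(a, tree) {
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (!all(tree$tip.label %in% rownames(a)))
    stop("tip labels missing from the alignment: ",
         paste(setdiff(tree$tip.label, rownames(a)), collapse = ", "))
  if (any(tree$edge.length < 0)) stop("negative branch length")
  mat <- a[tree$tip.label, , drop = FALSE]
  code <- matrix(match(mat, c("T", "C", "A", "G")) - 1L, nrow = nrow(mat))
  key <- apply(code, 2L, paste, collapse = ",")
  tab <- table(key)
  pat <- code[, match(names(tab), key), drop = FALSE]
  tr <- stats::reorder(tree, "postorder")
  .jc_loglik_cpp(tr$edge[, 1], tr$edge[, 2], tr$edge.length,
                 length(tr$tip.label), length(tr$tip.label) + tr$Nnode,
                 pat, as.numeric(tab))
}

# node ages of an ultrametric phylo (tips at 0)
phylo_ages <- function(tree) {
  if (!is.null(attr(tree, "ages"))) return(attr(tree, "ages"))
  nt <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  ages <- max(depth) - depth
  ages[seq_len(nt)][abs(ages[seq_len(nt)]) < 1e-12] <- 0
  ages
}

# walk one gene-tree edge through the network from (pop, t0) to t1.
# ind_of(hybrid_label) -> "main"/"alt" for this edge, or NULL
walk_pops <- function(net, pop, t0, t1, ind_of) {
  nd <- net$nodes
  segs <- list()
  phi_main <- character(0)
  phi_alt <- character(0)
  repeat {
    par <- nd$parent[pop]
    top <- if (is.na(par)) Inf else nd$age[par]
    if (top >= t1) {
      segs[[length(segs) + 1L]] <- c(pop, t0, t1)
      break
    }
    segs[[length(segs) + 1L]] <- c(pop, t0, top)
    if (!is.na(nd$parent2[par])) {
      choice <- ind_of(nd$label[par])
      if (is.null(choice))
        stop("lineage crosses hybrid node ", nd$label[par],
             " but no path indicator was supplied")
      if (choice == "alt") {
        phi_alt <- c(phi_alt, nd$label[par])
        pop <- nd$parent2[par]
      } else {
        phi_main <- c(phi_main, nd$label[par])
        pop <- par
      }
    } else {
      pop <- par
    }
    t0 <- top
  }
  list(segs = segs, phi_main = phi_main, phi_alt = phi_alt)
}

# per-population sufficient statistics of one dated gene tree inside net:
# k (coalescences), c (sum of C(n,2) dt), and hybrid routing counts
msc_stats <- function(tree, net, map, indicators = NULL) {
  nd <- net$nodes
  nt <- length(tree$tip.label)
  ages <- phylo_ages(tree)
  M <- nt + tree$Nnode
  sp <- map$species[match(tree$tip.label, map$sequence)]
  if (anyNA(sp)) stop("tip labels missing from the sample map")
  pop <- integer(M)
  pop[seq_len(nt)] <- match(sp, nd$label)
  parent <- integer(M); parent[] <- NA_integer_
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  ind_of <- function(node_id) {
    function(hlab) {
      if (is.null(indicators)) return(NULL)
      hit <- indicators$node == node_id & indicators$hybrid == hlab
      if (!any(hit)) return(NULL)
      indicators$choice[which(hit)[1]]
    }
  }
  k <- integer(nrow(nd)); cc <- numeric(nrow(nd))
  nmain <- nalt <- stats::setNames(integer(nrow(nd)), nd$label)
  # resolve populations bottom-up (increasing age)
  ord <- order(ages)
  present <- list()  # per-pop presence intervals
  for (u in ord) {
    if (u <= nt) next
    ch <- kids[[as.character(u)]]
    pops_at <- vapply(ch, function(v) {
      w <- walk_pops(net, pop[v], ages[v], ages[u], ind_of(v))
      w$segs[[length(w$segs)]][1]
    }, 0)
    if (length(unique(pops_at)) != 1L)
      stop("gene tree incompatible with the network: children of node ", u,
           " meet in different populations")
    pop[u] <- pops_at[1]
    k[pop[u]] <- k[pop[u]] + 1L
  }
  for (v in seq_len(M)) {
    if (is.na(parent[v])) next
    w <- walk_pops(net, pop[v], ages[v], ages[parent[v]], ind_of(v))
    for (s in w$segs)
      present[[length(present) + 1L]] <- s
    for (h in w$phi_main) nmain[h] <- nmain[h] + 1L
    for (h in w$phi_alt) nalt[h] <- nalt[h] + 1L
  }
  # event sweep per population
  if (length(present)) {
    mat <- do.call(rbind, present)
    for (p in unique(mat[, 1])) {
      iv <- mat[mat[, 1] == p, , drop = FALSE]
      ev <- rbind(cbind(iv[, 2], 1), cbind(iv[, 3], -1))
      ev <- ev[order(ev[, 1], ev[, 2]), , drop = FALSE]
      n <- 0; tprev <- 0
      for (r in seq_len(nrow(ev))) {
        tt <- ev[r, 1]
        if (tt > tprev && n >= 2)
          cc[p] <- cc[p] + 0.5 * n * (n - 1) * (tt - tprev)
        if (tt > tprev) tprev <- tt
        n <- n + ev[r, 2]
      }
    }
  }
  list(k = k, c = cc, nmain = nmain, nalt = nalt, pop = pop)
}

#' MSC / MSci log-density of dated gene trees
#'
#' The coalescent density of one or more dated gene trees embedded in a
#' species network: each population of size theta contributes
#' `(2/theta)^k * exp(-(2/theta) * c)` where `k` is the number of
#' coalescences in the population and `c` sums `choose(n,2) * dt` over the
#' inter-event intervals; each lineage routed at a hybridization node
#' contributes a factor `phi` (second-parent path) or `1 - phi`.
#'
#' @param trees a single `ape::phylo` (ultrametric, or carrying an `ages`
#'   attribute) or a list of them.
#' @param net a `species_network` holding tau, theta and phi.
#' @param map sample map linking tip labels to species.
#' @param indicators optional data.frame with columns `node` (gene-tree node
#'   id whose parent edge crosses the hybrid), `hybrid` (hybrid node label)
#'   and `choice` (`"main"` or `"alt"`); required whenever a lineage crosses
#'   a hybridization node.
#' @return the log-density (sum over trees); `-Inf` if a gene tree is
#'   incompatible with the network ages.
#' @export
msc_logdensity <- function(trees, net, map, indicators = NULL) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  nd <- net$nodes
  ld <- 0
  for (tr in trees) {
    st <- tryCatch(msc_stats(tr, net, map, indicators),
                   error = function(e) NULL)
    if (is.null(st)) return(-Inf)
    ld <- ld + sum(st$k * log(2 / nd$theta)) - sum(2 * st$c / nd$theta)
    hyb <- which(!is.na(nd$parent2))
    for (h in hyb) {
      lab <- nd$label[h]
      if (st$nalt[lab]) ld <- ld + st$nalt[lab] * log(nd$phi[h])
      if (st$nmain[lab]) ld <- ld + st$nmain[lab] * log(1 - nd$phi[h])
    }
  }
  as.numeric(ld)
}

#' Per-population contribution with theta integrated analytically
#'
#' With the conjugate inverse-gamma prior IG(alpha, beta) on a population's
#' theta, the coalescent factor `(2/theta)^k exp(-2c/theta)` integrates to
#' `2^k beta^alpha Gamma(alpha + k) / (Gamma(alpha) (beta + 2c)^(alpha+k))`.
#'
#' @param k number of coalescences in the population (summed over loci).
#' @param c coalescent sufficient statistic (summed over loci).
#' @param alpha,beta inverse-gamma prior parameters (`alpha > 1`).
#' @return the log contribution.
#' @export
theta_integrated_factor <- function(k, c, alpha, beta) {
  if (alpha <= 1) stop("alpha must exceed 1 (finite prior mean)")
  k * log(2) + alpha * log(beta) + lgamma(alpha + k) - lgamma(alpha) -
    (alpha + k) * log(beta + 2 * c)
}

#' MSC log-density with population sizes integrated out
#'
#' As [msc_logdensity()], but the per-branch thetas are integrated
#' analytically under a shared inverse-gamma prior, coupling the loci
#' through each population's totals.
#'
#' @inheritParams msc_logdensity
#' @param prior a [prior_spec()] (fields `theta_alpha`, `theta_beta`).
#' @return the log-density.
#' @export
msc_logdensity_theta_integrated <- function(trees, net, map, prior,
                                            indicators = NULL) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  nd <- net$nodes
  K <- integer(nrow(nd)); C <- numeric(nrow(nd))
  lphi <- 0
  for (tr in trees) {
    st <- msc_stats(tr, net, map, indicators)
    K <- K + st$k; C <- C + st$c
    hyb <- which(!is.na(nd$parent2))
    for (h in hyb) {
      lab <- nd$label[h]
      if (st$nalt[lab]) lphi <- lphi + st$nalt[lab] * log(nd$phi[h])
      if (st$nmain[lab]) lphi <- lphi + st$nmain[lab] * log(1 - nd$phi[h])
    }
  }
  as.numeric(
    sum(theta_integrated_factor(K, C, prior$theta_alpha,
                                prior$theta_beta)) + lphi)
}
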