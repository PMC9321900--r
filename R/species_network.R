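#' Species trees and introgression (MSci) networks
#'
#' A `species_network` represents a rooted species tree or an MSC-with-
#' introgression (MSci) network.  Node ages (tau) and population sizes
#' (theta = 4*Ne*mu) are both measured in expected substitutions per site.
#' Every node owns the population on the branch between itself and its main
#' parent (the root node owns the root population), so theta is attached to
#' every branch including tips.  A hybridization node has a second parent of
#' equal age reached with inheritance probability `phi`; the main parent is
#' reached with probability `1 - phi`.
#'
#' @param label character vector of node labels (unique).
#' @param age numeric node ages; tips must be 0.
#' @param theta numeric per-branch population sizes, all finite and > 0.
#' @param parent integer index of each node's main parent (`NA` for the root).
#' @param parent2 integer index of the second parent for hybrid nodes
#'   (`NA` elsewhere).  The second parent must have the same age as the
#'   hybrid node (horizontal introgression).
#' @param phi numeric inheritance probability of the *second* parent edge
#'   (`NA` for non-hybrid nodes).
#' @return an object of class `species_network`.
#' @examples
#' net <- network_preset("A01-B", theta = 0.0025)
#' net
#' @export
species_network <- function(label, age, theta, parent,
                            parent2 = rep(NA_integer_, length(label)),
                            phi = rep(NA_real_, length(label))) {
  nodes <- data.frame(
    label = as.character(label),
    age = as.numeric(age),
    theta = as.numeric(theta),
    parent = as.integer(parent),
    parent2 = as.integer(parent2),
    phi = as.numeric(phi),
    stringsAsFactors = FALSE
  )
  net <- structure(list(nodes = nodes), class = "species_network")
  validate_species_network(net)
  net
}

#' Validate a species network
#'
#' Checks the structural invariants: a single root, parent ages >= child
#' ages, zero tip ages, positive finite theta on every branch, phi in [0,1]
#' with equal-age second parents, and a tree structure on the main edges.
#'
#' @param net a `species_network`.
#' @return `net`, invisibly; signals an error describing the first violated
#'   invariant otherwise.
#' @export
validate_species_network <- function(net) {
  stopifnot(inherits(net, "species_network"))
  nd <- net$nodes
  n <- nrow(nd)
  if (n < 1L) stop("network has no nodes")
  if (anyDuplicated(nd$label)) stop("node labels must be unique")
  root <- which(is.na(nd$parent))
  if (length(root) != 1L) stop("network must have exactly one root")
  if (any(!is.finite(nd$theta)) || any(nd$theta <= 0))
    stop("every branch must carry a finite theta > 0")
  if (any(nd$age < 0)) stop("node ages must be nonnegative")
  ok <- !is.na(nd$parent)
  if (any(nd$age[nd$parent[ok]] < nd$age[ok]))
    stop("every parent age must be >= child age")
  ok2 <- !is.na(nd$parent2)
  if (any(ok2)) {
    if (any(is.na(nd$phi[ok2])))
      stop("hybrid nodes must carry an inheritance probability phi")
    if (any(nd$phi[ok2] < 0 | nd$phi[ok2] > 1))
      stop("phi must lie in [0, 1]")
    if (any(abs(nd$age[nd$parent2[ok2]] - nd$age[ok2]) >
            1e-12 * pmax(1, nd$age[ok2])))
      stop("second-parent age must equal the hybrid node age")
    nch <- tabulate(nd$parent[ok], nbins = n)
    if (any(nch[which(ok2)] != 1L))
      stop("hybrid nodes must have exactly one child")
  }
  if (any(!is.na(nd$phi) & is.na(nd$parent2)))
    stop("phi given for a node without a second parent")
  # main-parent graph must be a tree: walk to root from every node
  for (i in seq_len(n)) {
    seen <- logical(n); j <- i
    while (!is.na(nd$parent[j])) {
      if (seen[j]) stop("cycle in main-parent edges")
      seen[j] <- TRUE
      j <- nd$parent[j]
    }
  }
  tips <- network_tips(net)
  if (any(abs(nd$age[tips]) > 1e-12))
    stop("tip ages must be 0 (contemporaneous tips)")
  invisible(net)
}

#' @return integer indices of tip nodes (no children on main or hybrid edges).
#' @rdname species_network
#' @export
network_tips <- function(net) {
  nd <- net$nodes
  has_child <- rep(FALSE, nrow(nd))
  has_child[stats::na.omit(nd$parent)] <- TRUE
  has_child[stats::na.omit(nd$parent2)] <- TRUE
  which(!has_child)
}

#' @export
print.species_network <- function(x, ...) {
  nd <- x$nodes
  tips <- network_tips(x)
  nhyb <- sum(!is.na(nd$parent2))
  cat(sprintf("species_network: %d tips (%s), %d nodes, %d hybridization node%s\n",
              length(tips), paste(sort(nd$label[tips]), collapse = ", "),
              nrow(nd), nhyb, if (nhyb == 1) "" else "s"))
  cat(write_species_network(x), "\n")
  invisible(x)
}

## ---------------------------------------------------------------------------
## Presets: the standard 5-species study designs
## ---------------------------------------------------------------------------

#' Standard simulation-study species models
#'
#' Builds the named species tree or MSci network with all divergence times
#' proportional to `theta`:
#' \describe{
#'   \item{`A01-B`}{balanced 5-species tree `(((A,B)T,C)S,(D,E)U)R` with
#'     `tau_R=5*theta`, `tau_S=4.8`, `tau_T=4.7`, `tau_U=4.8` (in units of
#'     `theta`); a hard species-tree problem with very short internal
#'     branches.}
#'   \item{`A01-U`}{unbalanced (caterpillar) tree `((((A,B)U,C)T,D)S,E)R`
#'     with ages `4.4, 4.6, 4.8, 5` times `theta`.}
#'   \item{`A11-shallow`}{the `A01-B` topology with `tau_R=theta`,
#'     `tau_S=0.5*theta` and `tau_T=tau_U=1e-50*theta`: three species
#'     (AB, C, DE) sampled as five populations.}
#'   \item{`A11-deep`}{as `A11-shallow` but `tau_R=5*theta`,
#'     `tau_S=4.8*theta`.}
#'   \item{`A00-B`}{MSci network on the balanced tree
#'     (`tau_R=5, tau_S=4, tau_T=3, tau_U=4.5` times `theta`) with two
#'     horizontal introgression events at age `theta`: donor X on B's branch
#'     into recipient Y on C's branch with probability `phi_Y = 0.3`, and
#'     donor Z on D's branch into recipient W on E's branch with
#'     `phi_W = 0.2`.  21 parameters: 6 tau, 13 theta, 2 phi.}
#'   \item{`A00-U`}{the MSci network on the caterpillar tree
#'     (`tau_U = 2.5*theta`), same two introgression events.}
#' }
#' Every branch receives the same population size `theta`.
#'
#' @param name one of `"A01-B"`, `"A01-U"`, `"A11-shallow"`, `"A11-deep"`,
#'   `"A00-B"`, `"A00-U"`.
#' @param theta per-site population size parameter, > 0.
#' @return a validated `species_network`.
#' @export
network_preset <- function(name, theta) {
  stopifnot(is.numeric(theta), length(theta) == 1L, theta > 0)
  th <- theta
  build_tree <- function(label, rel_age, parent) {
    species_network(label = label, age = rel_age * th,
                    theta = rep(th, length(label)), parent = parent)
  }
  switch(name,
    "A01-B" = build_tree(
      label = c("A", "B", "C", "D", "E", "T", "S", "U", "R"),
      rel_age = c(0, 0, 0, 0, 0, 4.7, 4.8, 4.8, 5),
      parent = c(6L, 6L, 7L, 8L, 8L, 7L, 9L, 9L, NA)),
    "A01-U" = build_tree(
      label = c("A", "B", "C", "D", "E", "U", "T", "S", "R"),
      rel_age = c(0, 0, 0, 0, 0, 4.4, 4.6, 4.8, 5),
      parent = c(6L, 6L, 7L, 8L, 9L, 7L, 8L, 9L, NA)),
    "A11-shallow" = build_tree(
      label = c("A", "B", "C", "D", "E", "T", "S", "U", "R"),
      rel_age = c(0, 0, 0, 0, 0, 1e-50, 0.5, 1e-50, 1),
      parent = c(6L, 6L, 7L, 8L, 8L, 7L, 9L, 9L, NA)),
    "A11-deep" = build_tree(
      label = c("A", "B", "C", "D", "E", "T", "S", "U", "R"),
      rel_age = c(0, 0, 0, 0, 0, 1e-50, 4.8, 1e-50, 5),
      parent = c(6L, 6L, 7L, 8L, 8L, 7L, 9L, 9L, NA)),
    "A00-B" = {
      lab <- c("A", "B", "C", "D", "E", "X", "Y", "Z", "W",
               "T", "S", "U", "R")
      rel <- c(0, 0, 0, 0, 0, 1, 1, 1, 1, 3, 4, 4.5, 5)
      par <- c(10L, 6L, 7L, 8L, 9L, 10L, 11L, 12L, 12L, 11L, 13L, 13L, NA)
      par2 <- rep(NA_integer_, 13L); phi <- rep(NA_real_, 13L)
      par2[7L] <- 6L; phi[7L] <- 0.3  # Y routed to X with prob 0.3
      par2[9L] <- 8L; phi[9L] <- 0.2  # W routed to Z with prob 0.2
      species_network(lab, rel * th, rep(th, 13L), par, par2, phi)
    },
    "A00-U" = {
      lab <- c("A", "B", "C", "D", "E", "X", "Y", "Z", "W",
               "U", "T", "S", "R")
      rel <- c(0, 0, 0, 0, 0, 1, 1, 1, 1, 2.5, 3, 4, 5)
      par <- c(10L, 6L, 7L, 8L, 9L, 10L, 11L, 12L, 13L, 11L, 12L, 13L, NA)
      par2 <- rep(NA_integer_, 13L); phi <- rep(NA_real_, 13L)
      par2[7L] <- 6L; phi[7L] <- 0.3
      par2[9L] <- 8L; phi[9L] <- 0.2
      species_network(lab, rel * th, rep(th, 13L), par, par2, phi)
    },
    stop("unknown model name: ", name)
  )
}

## ---------------------------------------------------------------------------
## Backward-time event schedule
## ---------------------------------------------------------------------------

#' Compile a network into a backward-time event schedule
#'
#' Each non-hybrid internal node contributes one MERGE event at its age
#' (lineages of its main-edge children transfer into its population); each
#' hybridization node contributes one ROUTE event at its age (lineages of its
#' child population move to the second parent's population with probability
#' `phi`, else into the hybrid node's own population).
#'
#' @param net a `species_network`.
#' @return a data.frame with columns `time`, `type` (`"MERGE"`/`"ROUTE"`),
#'   `dest` (destination node label), `src` (comma-separated source labels),
#'   `alt` (ROUTE only: alternative destination), and `prob` (ROUTE only:
#'   probability of the alternative destination), sorted by nondecreasing
#'   time.
#' @export
event_schedule <- function(net) {
  validate_species_network(net)
  nd <- net$nodes
  n <- nrow(nd)
  is_hyb <- !is.na(nd$parent2)
  tips <- network_tips(net)
  internal <- setdiff(seq_len(n), tips)
  ev <- list()
  for (i in internal) {
    kids <- which(!is.na(nd$parent) & nd$parent == i)
    if (is_hyb[i]) {
      ev[[length(ev) + 1L]] <- data.frame(
        time = nd$age[i], type = "ROUTE", dest = nd$label[i],
        src = nd$label[kids], alt = nd$label[nd$parent2[i]],
        prob = nd$phi[i], stringsAsFactors = FALSE)
    } else {
      ev[[length(ev) + 1L]] <- data.frame(
        time = nd$age[i], type = "MERGE", dest = nd$label[i],
        src = paste(nd$label[kids], collapse = ","), alt = NA_character_,
        prob = NA_real_, stringsAsFactors = FALSE)
    }
  }
  if (!length(ev)) {
    return(data.frame(time = numeric(), type = character(),
                      dest = character(), src = character(),
                      alt = character(), prob = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, ev)
  out <- out[order(out$time, out$type, out$dest), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## ---------------------------------------------------------------------------
## Sample maps
## ---------------------------------------------------------------------------

#' Sequence-to-species sample maps
#'
#' `sample_map()` builds the standard map with `S` sequences per species,
#' labelled `<species>1 ... <species>S`.  `write_sample_map()` and
#' `read_sample_map()` exchange the two-column tab-delimited (Imap-style)
#' format: sequence label, species label.
#'
#' @param net a `species_network`.
#' @param S sequences sampled per species (>= 1), recycled over tips.
#' @return a data.frame with columns `sequence` and `species`.
#' @export
sample_map <- function(net, S) {
  stopifnot(all(S >= 1))
  tips <- network_tips(net)
  sp <- sort(net$nodes$label[tips])
  S <- rep_len(as.integer(S), length(sp))
  data.frame(
    sequence = unlist(lapply(seq_along(sp),
                             function(i) paste0(sp[i], seq_len(S[i])))),
    species = rep(sp, S),
    stringsAsFactors = FALSE
  )
}

#' @param map a sample map data.frame.
#' @param file path of the tab-delimited map file.
#' @rdname sample_map
#' @export
write_sample_map <- function(map, file) {
  utils::write.table(map[, c("sequence", "species")], file,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(file)
}

#' @rdname sample_map
#' @export
read_sample_map <- function(file) {
  df <- utils::read.table(file, sep = "\t", header = FALSE,
                          col.names = c("sequence", "species"),
                          colClasses = "character")
  df
}

#' Check a sample map against a network
#'
#' Every mapped species must be a tip of the network and every species must
#' receive at least one sequence.
#' @param net a `species_network`.
#' @param map a sample map data.frame.
#' @return the map, invisibly.
#' @export
validate_sample_map <- function(net, map) {
  tips <- net$nodes$label[network_tips(net)]
  if (!all(map$species %in% tips))
    stop("sample map refers to species that are not tips of the network: ",
         paste(setdiff(map$species, tips), collapse = ", "))
  if (anyDuplicated(map$sequence)) stop("duplicate sequence labels in map")
  invisible(map)
}
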