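#' Simulation designs
#'
#' Bundles the per-locus simulation settings of the factorial study: `S`
#' sequences per species, `L` loci per replicate, `n` sites per locus,
#' the population recombination rate `rho` (4*Ne*r per kb per generation),
#' the design's base heterozygosity `theta_base` (used to convert `rho` to
#' mutation-scaled time), and `R` replicates.
#'
#' Rate conversion: time is measured in expected substitutions per site, and
#' one unit of 4N generations equals `theta_base` mutation units, so a
#' lineage spanning `b` links recombines at rate `b * (rho/1000) /
#' theta_base` per mutation unit.  This makes the distribution of
#' recombination-event counts depend on `rho` (and `S`) but not on the
#' mutation rate when divergence times are proportional to theta.
#'
#' @param S sequences per species.
#' @param L loci per replicate.
#' @param rho population recombination rate, per kb per generation; >= 0.
#' @param theta_base the design's per-site theta used for rate scaling.
#' @param n sites per locus (default 500).
#' @param R number of replicates (default 100).
#' @param seed base seed; per-locus streams are derived as
#'   `seed + replicate_index * L + locus_index` (0-based indices).
#' @return an object of class `sim_design`.
#' @export
sim_design <- function(S, L, rho, theta_base, n = 500L, R = 100L,
                       seed = 1L) {
  stopifnot(n >= 2, rho >= 0, theta_base > 0, S >= 1, L >= 1, R >= 1)
  structure(list(S = as.integer(S), L = as.integer(L), n = as.integer(n),
                 rho = rho, theta_base = theta_base, R = as.integer(R),
                 seed = as.integer(seed)),
            class = "sim_design")
}

#' @export
print.sim_design <- function(x, ...) {
  cat(sprintf(
    "sim_design: S=%d seqs/species, L=%d loci, n=%d sites, rho=%g /kb, theta_base=%g, R=%d replicates, seed=%d\n",
    x$S, x$L, x$n, x$rho, x$theta_base, x$R, x$seed))
  invisible(x)
}

# Flatten a species network into the population/event arrays the C++
# simulator consumes.  Populations are network nodes (0-based); each
# non-root node transfers into its parent population at the parent's age
# (MERGE), except children of hybridization nodes, which are routed at the
# hybrid age to the second parent's population with probability phi.
compile_demography <- function(net, map) {
  validate_species_network(net)
  validate_sample_map(net, map)
  nd <- net$nodes
  is_hyb <- !is.na(nd$parent2)
  child <- which(!is.na(nd$parent))
  par <- nd$parent[child]
  hy <- is_hyb[par]
  ev <- data.frame(
    time = nd$age[par],
    type = ifelse(hy, 2L, 1L),
    src = child - 1L,
    dest = par - 1L,
    alt = ifelse(hy, nd$parent2[par] - 1L, -1L),
    prob = ifelse(hy, nd$phi[par], 0))
  # routes before merges at tied times, so routed lineages catch same-time
  # merges of their destination population
  ev <- ev[order(ev$time, ev$type, ev$src), , drop = FALSE]
  idx <- match(map$species, nd$label)
  list(theta = nd$theta, events = ev, sample_pop = idx - 1L,
       labels = map$sequence, species = map$species,
       hybrid_labels = nd$label[is_hyb])
}

#' Simulate the coalescent with recombination for one locus
#'
#' Runs an exact (non-Markovian-approximation-free) Hudson-style ancestral
#' recombination graph backward in time, constrained by the species network:
#' within a population of size theta each lineage pair coalesces at rate
#' 2/theta per mutation-scaled time unit; each lineage recombines at rate
#' `(rho/1000)/theta_base` per link spanned by its ancestral breadth;
#' lineages transfer between populations at speciation (merge) times, and at
#' a hybridization node each lineage moves to the second parent with
#' probability phi.  The locus ends when every site has reached its marginal
#' most recent common ancestor.
#'
#' @param net a `species_network`.
#' @param map a sample map (see [sample_map()]).
#' @param design a [sim_design()] (fields `n`, `rho`, `theta_base` are used).
#' @param seed optional integer; when given, `set.seed(seed)` is called so
#'   the locus is reproducible in isolation.
#' @param trees if `FALSE`, only recombination-event counts and routing
#'   tallies are returned (the genealogical process is simulated
#'   identically; segment-tree bookkeeping is skipped).
#' @return an object of class `locus_genealogy`: breakpoints
#'   `0 = b_0 < ... < b_m = n`, a `records` data.frame of dated marginal
#'   coalescences (`age`, `child1`, `child2`, `start`, `end`; node ids are
#'   0-based with tips `0..ns-1` and record `i` owning id `ns + i`), the
#'   recombination-event records (`time`, `link`), and per-hybrid routing
#'   tallies.
#' @export
simulate_locus <- function(net, map, design, seed = NULL, trees = TRUE) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  dem <- compile_demography(net, map)
  res <- .arg_simulate_cpp(dem$theta, dem$sample_pop, design$n,
                           (design$rho / 1000) / design$theta_base,
                           dem$events$time, dem$events$type, dem$events$src,
                           dem$events$dest, dem$events$alt, dem$events$prob,
                           trees)
  route <- NULL
  if (length(dem$hybrid_labels)) {
    hyb_rows <- dem$events$type == 2L
    route <- data.frame(
      hybrid = net$nodes$label[dem$events$dest[hyb_rows] + 1L],
      alt = net$nodes$label[dem$events$alt[hyb_rows] + 1L],
      routed_alt = res$route_alt[hyb_rows],
      routed_total = res$route_tot[hyb_rows],
      stringsAsFactors = FALSE)
  }
  g <- list(
    n = design$n,
    labels = dem$labels,
    species = dem$species,
    n_events = res$n_events,
    n_breakpoints = res$n_breakpoints,
    events = data.frame(time = res$event_time, link = res$event_link),
    route = route,
    breakpoints = if (trees) res$breakpoints else NULL,
    records = if (trees) res$records else NULL
  )
  class(g) <- "locus_genealogy"
  g
}

#' @export
print.locus_genealogy <- function(x, ...) {
  m <- if (is.null(x$breakpoints)) NA_integer_ else length(x$breakpoints) - 1L
  cat(sprintf(
    "locus_genealogy: %d sequences, %d sites, %d recombination event(s), %s segment(s)\n",
    length(x$labels), x$n, x$n_events,
    if (is.na(m)) "untracked" else as.character(m)))
  invisible(x)
}

#' Number of recombination events executed at a locus
#'
#' Counts the executed breadth-splitting recombination events (repeat links
#' count each time); some events need not change the marginal trees.
#'
#' @param g a `locus_genealogy`.
#' @return integer count.
#' @export
count_recombination_events <- function(g) {
  stopifnot(inherits(g, "locus_genealogy"))
  g$n_events
}

#' Number of distinct breakpoint links at a locus
#'
#' Counts the distinct links at which an executed recombination event split
#' a lineage's ancestral material proper (events whose breakpoint fell in a
#' trapped gap between material, and repeat events at an already-split link,
#' add nothing).  This equals the ms-style segment count minus one — the
#' per-locus recombination statistic that segment-tree output tabulates.  At
#' low rates it coincides with [count_recombination_events()]; at high rates
#' link collisions and trapped-gap events make it smaller.
#'
#' @param g a `locus_genealogy`.
#' @return integer count.
#' @export
count_distinct_breakpoints <- function(g) {
  stopifnot(inherits(g, "locus_genealogy"))
  g$n_breakpoints
}

#' Simulate all loci of a replicated design
#'
#' Runs [simulate_locus()] for every (replicate, locus) pair of the design,
#' with one reproducible RNG stream per locus seeded as
#' `design$seed + replicate * L + locus` (0-based indices), so any subset of
#' loci can be regenerated independently and in any order.
#'
#' @param net a `species_network`.
#' @param map a sample map.
#' @param design a [sim_design()].
#' @param trees keep full segment genealogies (memory-heavy for large runs);
#'   when `FALSE` only event counts and routing tallies are collected.
#' @return a data.frame with one row per locus: `replicate`, `locus`
#'   (both 0-based), `events` (executed recombination events), `breakpoints`
#'   (distinct split links); when `trees = TRUE` the genealogies are
#'   attached as the list attribute `"genealogies"` (in row order).
#' @export
simulate_replicates <- function(net, map, design, trees = FALSE) {
  dem <- compile_demography(net, map)
  rl <- (design$rho / 1000) / design$theta_base
  nloc <- design$R * design$L
  events <- integer(nloc)
  brk <- integer(nloc)
  gl <- if (trees) vector("list", nloc) else NULL
  k <- 0L
  for (rep in 0:(design$R - 1L)) {
    for (locus in 0:(design$L - 1L)) {
      k <- k + 1L
      set.seed(design$seed + rep * design$L + locus)
      res <- .arg_simulate_cpp(dem$theta, dem$sample_pop, design$n, rl,
                               dem$events$time, dem$events$type,
                               dem$events$src, dem$events$dest,
                               dem$events$alt, dem$events$prob, trees)
      events[k] <- res$n_events
      brk[k] <- res$n_breakpoints
      if (trees) {
        g <- list(n = design$n, labels = dem$labels, species = dem$species,
                  n_events = res$n_events,
                  events = data.frame(time = res$event_time,
                                      link = res$event_link),
                  route = NULL, breakpoints = res$breakpoints,
                  records = res$records)
        class(g) <- "locus_genealogy"
        gl[[k]] <- g
      }
    }
  }
  out <- data.frame(replicate = rep(0:(design$R - 1L), each = design$L),
                    locus = rep(0:(design$L - 1L), times = design$R),
                    events = events, breakpoints = brk)
  if (trees) attr(out, "genealogies") <- gl
  out
}

#' Write the per-locus recombination-event table
#'
#' Tab-delimited table (replicate, locus, events, breakpoints), the
#' simulator's standard sidecar output.
#'
#' @param tab the data.frame returned by [simulate_replicates()].
#' @param file path.
#' @return `file`, invisibly.
#' @export
write_event_table <- function(tab, file) {
  utils::write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

# Build an ape phylo for the segment [lo, hi).
segment_phylo <- function(g, lo, hi) {
  rec <- g$records
  ns <- length(g$labels)
  cov <- which(rec$start <= lo & rec$end >= hi)
  if (length(cov) != ns - 1L)
    stop("malformed genealogy: segment not covered by ", ns - 1L, " records")
  # ape ids: tips 1..ns; internal by decreasing age so the root is ns+1
  ord <- cov[order(rec$age[cov], decreasing = TRUE)]
  # 0-based node id k lives in slot k+1; record row i owns node id ns+i-1
  ape_id <- integer(ns + nrow(rec))
  ape_id[seq_len(ns)] <- seq_len(ns)
  ape_id[ns + ord] <- ns + seq_along(ord)
  node_age <- c(rep(0, ns), rec$age[ord])
  edge <- matrix(0L, 2L * (ns - 1L), 2L)
  elen <- numeric(2L * (ns - 1L))
  k <- 0L
  for (i in ord) {
    par <- ape_id[ns + i]
    for (ch0 in c(rec$child1[i], rec$child2[i])) {
      k <- k + 1L
      ch <- ape_id[ch0 + 1L]
      edge[k, ] <- c(par, ch)
      elen[k] <- rec$age[i] - node_age[ch]
    }
  }
  phy <- structure(list(edge = edge, edge.length = elen,
                        tip.label = g$labels, Nnode = ns - 1L),
                   class = "phylo", order = "cladewise")
  attr(phy, "ages") <- node_age
  phy
}

#' Marginal gene tree at a site
#'
#' @param g a `locus_genealogy` simulated with `trees = TRUE`.
#' @param site 0-based site index, `0 <= site < n`.
#' @return the rooted, dated segment tree containing the site, as an
#'   `ape::phylo` with an `ages` attribute (tip ages first, then internal
#'   node ages in ape node order).
#' @export
marginal_tree_at <- function(g, site) {
  stopifnot(inherits(g, "locus_genealogy"), !is.null(g$breakpoints))
  if (site < 0 || site >= g$n) stop("site out of range [0, ", g$n - 1, "]")
  bp <- g$breakpoints
  j <- findInterval(site, bp, rightmost.closed = FALSE)
  segment_phylo(g, bp[j], bp[j + 1L])
}

#' Segment trees of a locus
#'
#' @param g a `locus_genealogy`.
#' @return a list with one `phylo` per segment plus the segment lengths.
#' @export
segment_trees <- function(g) {
  stopifnot(inherits(g, "locus_genealogy"), !is.null(g$breakpoints))
  bp <- g$breakpoints
  m <- length(bp) - 1L
  list(lengths = diff(bp),
       trees = lapply(seq_len(m),
                      function(j) segment_phylo(g, bp[j], bp[j + 1L])))
}

#' Write segment trees in length-prefixed Newick
#'
#' One line per segment, `[len](...);` with `len` the segment length in
#' sites (lengths sum to `n`), in the style of ms's tree output.
#'
#' @param g a `locus_genealogy`.
#' @param file a path or connection.
#' @return `file`, invisibly.
#' @export
write_segment_trees <- function(g, file) {
  st <- segment_trees(g)
  lines <- vapply(seq_along(st$lengths), function(j)
    paste0("[", st$lengths[j], "]",
           ape::write.tree(st$trees[[j]], digits = 12)), "")
  writeLines(lines, file)
  invisible(file)
}

#' Read length-prefixed segment trees
#'
#' @param file a path or connection holding lines written by
#'   [write_segment_trees()].
#' @return a list with `lengths` (integer vector) and `trees`
#'   (list of `phylo`).
#' @export
read_segment_trees <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines)]
  m <- regmatches(lines, regexec("^\\[([0-9]+)\\](.*)$", lines))
  if (any(vapply(m, length, 1L) != 3L))
    stop("malformed segment-tree line")
  list(lengths = as.integer(vapply(m, `[`, "", 2L)),
       trees = lapply(m, function(x) ape::read.tree(text = x[3])))
}
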