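#' Relative root-mean-square error
#'
#' `rrmse = (1/truth) * sqrt(mean((estimates - truth)^2))`: an rRMSE of 0.1
#' means the root mean square error is 10% of the true value.  It reflects
#' both the bias and the variance of the estimator.
#'
#' @param estimates numeric vector of per-replicate point estimates.
#' @param truth the true parameter value (> 0).
#' @return a nonnegative scalar.
#' @export
rrmse <- function(estimates, truth) {
  if (!is.numeric(truth) || length(truth) != 1L || truth <= 0)
    stop("truth must be a positive scalar")
  if (!length(estimates)) stop("need at least one estimate")
  sqrt(mean((estimates - truth)^2)) / truth
}

#' Credible-interval coverage
#'
#' The proportion of replicates whose interval contains the true value.
#'
#' @param lower,upper numeric vectors of interval bounds (one per
#'   replicate).
#' @param truth the true parameter value.
#' @return a proportion in [0, 1].
#' @export
ci_coverage <- function(lower, upper, truth) {
  if (!length(lower) || length(lower) != length(upper))
    stop("need matching non-empty lower/upper bounds")
  mean(lower <= truth & truth <= upper)
}

#' Canonical topology string of a species tree
#'
#' Topology-only Newick with children sorted lexicographically, matching the
#' strings recorded by species-tree searches; hybrid edges are ignored.
#'
#' @param net a `species_network`.
#' @return a character scalar like `"(((A,B),C),(D,E))"`.
#' @export
network_topology <- function(net) {
  nd <- net$nodes
  kids <- lapply(seq_len(nrow(nd)), function(i)
    which(!is.na(nd$parent) & nd$parent == i))
  rec <- function(i) {
    if (!length(kids[[i]])) return(nd$label[i])
    parts <- sort(vapply(kids[[i]], rec, ""))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  rec(which(is.na(nd$parent)))
}

#' Species-tree recovery statistics
#'
#' Given per-replicate posterior summaries from species-tree searches and
#' the true species tree: the proportion of replicates whose MAP tree is the
#' true tree; for each clade of the true tree, the proportion of replicates
#' whose MAP tree contains it ("recovered" means present in the MAP tree);
#' and the mean posterior probability of each true clade across all
#' replicates.
#'
#' @param summaries a list of `posterior_summary` objects with tree samples.
#' @param truth the true `species_network` (a tree).
#' @return a list with `recovery` (P(MAP = truth)), and a data.frame
#'   `clades` (clade, map_recovery, mean_posterior), clades ordered from
#'   the root down.
#' @export
recovery_stats <- function(summaries, truth) {
  if (!length(summaries)) stop("no replicate summaries")
  if (any(vapply(summaries, function(s) is.null(s$map_tree), TRUE)))
    stop("summaries lack species-tree samples")
  true_topo <- network_topology(truth)
  true_clades <- topology_clades(true_topo)
  # order clades large -> small (root first)
  true_clades <- true_clades[order(-nchar(true_clades))]
  maps <- vapply(summaries, function(s) s$map_tree, "")
  recovery <- mean(maps == true_topo)
  map_cl <- lapply(maps, topology_clades)
  rec_cl <- vapply(true_clades, function(cl)
    mean(vapply(map_cl, function(x) cl %in% x, TRUE)), 0)
  mean_post <- vapply(true_clades, function(cl)
    mean(vapply(summaries, function(s) {
      i <- match(cl, s$clades$clade)
      if (is.na(i)) 0 else s$clades$prob[i]
    }, 0)), 0)
  list(recovery = recovery,
       clades = data.frame(clade = true_clades, map_recovery = rec_cl,
                           mean_posterior = mean_post, row.names = NULL))
}

#' Per-setting recombination summary
#'
#' The two statistics tabulated per simulation setting: the mean number of
#' recombination events per locus and the proportion of loci with none.  By
#' default events are counted as distinct breakpoint links in the final
#' segment partition (`"breakpoints"`, the statistic ms-style segment
#' output shows); `"events"` counts every executed breadth-splitting event.
#'
#' @param tab a data.frame from [simulate_replicates()] (columns `events`
#'   and `breakpoints`), or an integer vector of per-locus counts.
#' @param counting `"breakpoints"` or `"events"`.
#' @return a list with `mean_events` and `fraction_zero`.
#' @export
recombination_summary <- function(tab, counting = c("breakpoints",
                                                    "events")) {
  counting <- match.arg(counting)
  x <- if (is.data.frame(tab)) tab[[counting]] else tab
  if (!length(x)) stop("no loci")
  list(mean_events = mean(x), fraction_zero = mean(x == 0))
}

# rooted labelled topology id of a phylo, ignoring branch lengths
rooted_topology_id <- function(phy) {
  nt <- length(phy$tip.label)
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  rec <- function(i) {
    if (i <= nt) return(phy$tip.label[i])
    parts <- sort(vapply(kids[[as.character(i)]], rec, ""))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  rec(nt + 1L)
}

#' Compare the segment trees of one locus
#'
#' Classifies each breakpoint by what changes between the flanking marginal
#' trees — `"none"` (identical topology and branch lengths, an "invisible"
#' recombination), `"lengths"` (same rooted topology, different coalescent
#' times) or `"topology"` — and counts the distinct rooted labelled
#' topologies among the segment trees.
#'
#' @param g a `locus_genealogy` simulated with `trees = TRUE`.
#' @param tol absolute age tolerance when calling branch lengths equal.
#' @return a list with `n_distinct_topologies` and a data.frame
#'   `breakpoints` (`link`, `class`).
#' @export
compare_segment_trees <- function(g, tol = 1e-12) {
  st <- segment_trees(g)
  m <- length(st$trees)
  ids <- vapply(st$trees, rooted_topology_id, "")
  n_distinct <- length(unique(ids))
  cls <- character(max(m - 1L, 0L))
  bp <- g$breakpoints[-c(1L, length(g$breakpoints))]
  for (j in seq_len(m - 1L)) {
    if (ids[j] != ids[j + 1L]) {
      cls[j] <- "topology"
    } else {
      a1 <- sort(attr(st$trees[[j]], "ages"))
      a2 <- sort(attr(st$trees[[j + 1L]], "ages"))
      cls[j] <- if (all(abs(a1 - a2) <= tol)) "none" else "lengths"
    }
  }
  list(n_distinct_topologies = n_distinct,
       breakpoints = data.frame(link = bp, class = cls))
}

#' Parameter-estimation report across replicates
#'
#' Collects, for each parameter, the mean posterior-mean estimate, absolute
#' and relative bias, mean credible-interval width, coverage and rRMSE.
#'
#' @param summaries list of `posterior_summary` objects (one per replicate).
#' @param truth named numeric vector of true values (names matching the
#'   parameter column of the summaries).
#' @return a data.frame with one row per parameter.
#' @export
estimation_report <- function(summaries, truth) {
  if (!length(summaries)) stop("no replicate summaries")
  pars <- names(truth)
  rows <- lapply(pars, function(p) {
    est <- vapply(summaries, function(s)
      s$params$mean[match(p, s$params$parameter)], 0)
    lo <- vapply(summaries, function(s)
      s$params$lower[match(p, s$params$parameter)], 0)
    hi <- vapply(summaries, function(s)
      s$params$upper[match(p, s$params$parameter)], 0)
    data.frame(parameter = p, truth = truth[[p]],
               mean_estimate = mean(est),
               bias = mean(est) - truth[[p]],
               rel_bias = (mean(est) - truth[[p]]) / truth[[p]],
               ci_width = mean(hi - lo),
               coverage = ci_coverage(lo, hi, truth[[p]]),
               rrmse = rrmse(est, truth[[p]]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
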