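#' Factorial experiment configuration
#'
#' Describes one of the study's factorial experiments: an analysis mode
#' (`"sim"` tabulates recombination only; `"A00"` fixes the model and
#' estimates parameters; `"A01"` searches species trees), the model presets,
#' and the grid over sequences per species (S), loci (L), heterozygosity
#' (theta) and recombination rate (rho), with `R` replicates per setting.
#'
#' `scale` shrinks a full-size experiment for desk runs: `R`, `L` and the
#' MCMC lengths are multiplied by `scale` (minimum 1 replicate / 10 loci).
#'
#' @param analysis `"sim"`, `"A00"` or `"A01"`.
#' @param models character vector of [network_preset()] names.
#' @param S_grid,L_grid,theta_grid,rho_grid the factorial grid.
#' @param R replicates per setting.
#' @param n sites per locus.
#' @param seed base seed; per-job seeds are derived deterministically.
#' @param scale desk-run scale factor in (0, 1].
#' @param mcmc an [mcmc_settings()] template for inference analyses.
#' @return an `experiment_config`.
#' @export
experiment_config <- function(analysis = c("sim", "A00", "A01"),
                              models, S_grid = c(2L, 8L),
                              L_grid = c(40L, 160L),
                              theta_grid = c(0.0025, 0.01),
                              rho_grid = c(0.05, 0.5, 5),
                              R = 100L, n = 500L, seed = 1L, scale = 1,
                              mcmc = mcmc_settings()) {
  analysis <- match.arg(analysis)
  stopifnot(length(models) >= 1, scale > 0, scale <= 1, R >= 1)
  structure(list(analysis = analysis, models = models,
                 S_grid = as.integer(S_grid), L_grid = as.integer(L_grid),
                 theta_grid = theta_grid, rho_grid = rho_grid,
                 R = as.integer(R), n = as.integer(n),
                 seed = as.integer(seed), scale = scale, mcmc = mcmc),
            class = "experiment_config")
}

#' Enumerate the jobs of an experiment
#'
#' Deterministic expansion of the factorial grid into one job per
#' (setting, replicate), with reproducible per-job seeds.  Repeated
#' expansion yields identical seed assignment.
#'
#' @param config an [experiment_config()].
#' @return a data.frame with columns `job`, `model`, `S`, `L`, `theta`,
#'   `rho`, `replicate` (0-based) and `seed`.
#' @export
expand_grid_jobs <- function(config) {
  R <- max(1L, as.integer(round(config$R * config$scale)))
  L <- pmax(10L, as.integer(round(config$L_grid * config$scale)))
  grid <- expand.grid(model = config$models, S = config$S_grid, L = L,
                      theta = config$theta_grid, rho = config$rho_grid,
                      stringsAsFactors = FALSE)
  njob <- nrow(grid) * R
  out <- grid[rep(seq_len(nrow(grid)), each = R), , drop = FALSE]
  out$replicate <- rep(0:(R - 1L), times = nrow(grid))
  out$job <- seq_len(njob)
  # spacing leaves room for the per-locus streams (seed + rep*L + locus)
  out$seed <- config$seed + (out$job - 1L) * 100000L
  rownames(out) <- NULL
  out[, c("job", "model", "S", "L", "theta", "rho", "replicate", "seed")]
}

run_one_job <- function(job, config) {
  net <- network_preset(job$model, job$theta)
  map <- sample_map(net, job$S)
  design <- sim_design(S = job$S, L = job$L, rho = job$rho,
                       theta_base = job$theta, n = config$n, R = 1L,
                       seed = job$seed)
  if (config$analysis == "sim") {
    tab <- simulate_replicates(net, map, design)
    rs <- recombination_summary(tab)
    return(list(mean_events = rs$mean_events,
                fraction_zero = rs$fraction_zero,
                loci = nrow(tab)))
  }
  alns <- simulate_alignments(net, map, design)
  tab <- data.frame(
    events = vapply(attr(alns, "genealogies"), count_recombination_events, 0L),
    breakpoints = vapply(attr(alns, "genealogies"),
                         count_distinct_breakpoints, 0L))
  mcmc <- config$mcmc
  mcmc$burnin <- max(50L, as.integer(round(mcmc$burnin * config$scale)))
  mcmc$nsamples <- max(200L, as.integer(round(mcmc$nsamples * config$scale)))
  mcmc$seed <- job$seed + 1L
  prior <- prior_for_theta(job$theta,
                           integrate_theta = config$analysis == "A01")
  ch <- if (config$analysis == "A00")
    run_a00(alns, net, map, prior, mcmc)
  else
    run_a01(alns, net, map, prior, mcmc)
  sm <- summarize_posterior(ch)
  rs <- recombination_summary(tab)
  list(summary = sm, mean_events = rs$mean_events,
       fraction_zero = rs$fraction_zero, loci = nrow(tab))
}

#' Run an experiment and aggregate the evaluation report
#'
#' Simulates (and for inference analyses, analyses) every job of the
#' config, then aggregates per setting: recombination summaries always; MAP
#' recovery and clade statistics for species-tree searches; bias, coverage
#' and rRMSE for parameter estimation.  With a run directory the per-job
#' progress is checkpointed in a manifest and completed jobs are skipped on
#' resume.
#'
#' @param config an [experiment_config()].
#' @param dir optional run directory for the resumable manifest.
#' @return an `evaluation_report`: data.frame `settings` with one row per
#'   grid setting (recombination means, and analysis-specific columns),
#'   plus `details` holding the per-setting objects.
#' @export
run_experiment <- function(config, dir = NULL) {
  jobs <- expand_grid_jobs(config)
  done <- rep(FALSE, nrow(jobs))
  manifest <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    manifest <- file.path(dir, "manifest.tsv")
    if (file.exists(manifest)) {
      m <- utils::read.table(manifest, header = TRUE, sep = "\t")
      done[jobs$job %in% m$job] <- TRUE
    }
  }
  results <- vector("list", nrow(jobs))
  if (!is.null(dir)) {
    for (i in which(done)) {
      f <- file.path(dir, sprintf("job%06d.json", jobs$job[i]))
      if (file.exists(f))
        results[[i]] <- jsonlite::fromJSON(f, simplifyVector = FALSE)
      else done[i] <- FALSE
    }
  }
  for (i in seq_len(nrow(jobs))) {
    if (done[i]) next
    res <- tryCatch(run_one_job(jobs[i, ], config), error = function(e)
      stop("job ", jobs$job[i], " (", jobs$model[i], " S=", jobs$S[i],
           " L=", jobs$L[i], " theta=", jobs$theta[i], " rho=",
           jobs$rho[i], " rep=", jobs$replicate[i], ") failed: ",
           conditionMessage(e)))
    results[[i]] <- res
    if (!is.null(dir)) {
      jf <- file.path(dir, sprintf("job%06d.json", jobs$job[i]))
      jsonlite::write_json(serialize_job(res), jf, auto_unbox = TRUE,
                           digits = NA)
      have <- file.exists(manifest)
      utils::write.table(jobs[i, c("job", "seed")], manifest, sep = "\t",
                         quote = FALSE, row.names = FALSE,
                         col.names = !have, append = have)
      results[[i]] <- jsonlite::fromJSON(jf, simplifyVector = FALSE)
    }
  }
  aggregate_report(jobs, results, config)
}

# flatten a job result into JSON-serializable form
serialize_job <- function(res) {
  out <- list(mean_events = res$mean_events,
              fraction_zero = res$fraction_zero, loci = res$loci)
  if (!is.null(res$summary)) {
    sm <- res$summary
    out$params <- sm$params
    if (!is.null(sm$map_tree)) {
      out$map_tree <- sm$map_tree
      out$clades <- sm$clades
    }
  }
  out
}

job_params <- function(res) {
  if (!is.null(res$summary)) return(res$summary$params)
  do.call(rbind, lapply(res$params, function(r) as.data.frame(r)))
}

aggregate_report <- function(jobs, results, config) {
  key <- interaction(jobs$model, jobs$S, jobs$L, jobs$theta, jobs$rho,
                     drop = TRUE)
  settings <- unique(jobs[, c("model", "S", "L", "theta", "rho")])
  rownames(settings) <- NULL
  details <- list()
  rows <- list()
  for (si in seq_len(nrow(settings))) {
    st <- settings[si, ]
    sel <- which(jobs$model == st$model & jobs$S == st$S & jobs$L == st$L &
                 jobs$theta == st$theta & jobs$rho == st$rho)
    res <- results[sel]
    row <- st
    row$replicates <- length(sel)
    row$mean_events <- mean(vapply(res, function(r) r$mean_events, 0))
    row$fraction_zero <- mean(vapply(res, function(r) r$fraction_zero, 0))
    det <- list()
    if (config$analysis == "A01") {
      truth <- network_preset(st$model, st$theta)
      true_topo <- network_topology(truth)
      maps <- vapply(res, function(r) {
        if (!is.null(r$summary)) r$summary$map_tree else r$map_tree
      }, "")
      row$recovery <- mean(maps == true_topo)
      det$maps <- maps
      det$true_topology <- true_topo
    }
    if (config$analysis == "A00") {
      truth <- network_preset(st$model, st$theta)
      tv <- truth_params(truth)
      pars <- lapply(res, job_params)
      est <- function(p, what) vapply(pars, function(d)
        d[[what]][match(p, d$parameter)], 0)
      rep_rows <- lapply(names(tv), function(p) {
        e <- est(p, "mean")
        data.frame(parameter = p, truth = tv[[p]],
                   mean_estimate = mean(e),
                   rel_bias = (mean(e) - tv[[p]]) / tv[[p]],
                   coverage = ci_coverage(est(p, "lower"), est(p, "upper"),
                                          tv[[p]]),
                   rrmse = rrmse(e, tv[[p]]))
      })
      det$params <- do.call(rbind, rep_rows)
    }
    details[[si]] <- det
    rows[[si]] <- row
  }
  structure(list(settings = do.call(rbind, rows), details = details,
                 config = config),
            class = "evaluation_report")
}

# true (tau, theta, phi) values of a preset network, named like chain columns
truth_params <- function(net) {
  nd <- net$nodes
  cls <- age_classes(net)
  out <- list()
  for (k in 0:max(cls)) {
    lab <- paste(sort(nd$label[which(cls == k)]), collapse = ".")
    out[[paste0("tau_", lab)]] <- nd$age[which(cls == k)[1]]
  }
  for (i in seq_len(nrow(nd)))
    out[[paste0("theta_", nd$label[i])]] <- nd$theta[i]
  for (i in which(!is.na(nd$parent2)))
    out[[paste0("phi_", nd$label[i])]] <- nd$phi[i]
  out
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation_report (", x$config$analysis, " analysis )\n", sep = "")
  print(x$settings, digits = 3)
  invisible(x)
}

#' Write an evaluation report as TSV
#'
#' Deterministic (byte-identical on rerun) tab-delimited export of the
#' per-setting table.
#'
#' @param report an `evaluation_report`.
#' @param file path.
#' @return `file`, invisibly.
#' @export
write_report <- function(report, file) {
  df <- report$settings
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) signif(x, 10))
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Reproduction presets
#'
#' Ready-made configs for the study's three factorial experiments.
#' `table3_preset()` is the simulator-only tabulation of recombination
#' events (all eight model presets, L = 160, the full S x theta x rho
#' grid); `a01_preset()` and `a00_preset()` are the species-tree-search and
#' parameter-estimation experiments.  At `scale = 1` each expands to the
#' full 2x2x2x2x3x100 = 4800-job grid of its experiment; smaller scales
#' shrink R, L and the MCMC lengths for desk runs.
#'
#' @param scale desk-run scale in (0, 1].
#' @param seed base seed.
#' @return an [experiment_config()].
#' @export
table3_preset <- function(scale = 1, seed = 1L) {
  experiment_config("sim",
                    models = c("A01-B", "A01-U", "A11-shallow", "A11-deep",
                               "A00-B", "A00-U"),
                    L_grid = 160L, R = 100L, seed = seed, scale = scale)
}

#' @rdname table3_preset
#' @export
a01_preset <- function(scale = 1, seed = 1L) {
  experiment_config("A01", models = c("A01-B", "A01-U"), R = 100L,
                    seed = seed, scale = scale,
                    mcmc = mcmc_settings(burnin = 1000L, nsamples = 2000L))
}

#' @rdname table3_preset
#' @export
a00_preset <- function(scale = 1, seed = 1L) {
  experiment_config("A00", models = c("A00-B", "A00-U"), R = 100L,
                    seed = seed, scale = scale,
                    mcmc = mcmc_settings(burnin = 1000L, nsamples = 2000L))
}
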