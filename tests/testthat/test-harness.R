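test_that("the full species-tree experiment expands to 4800 jobs", {
  cfg <- a01_preset()
  jobs <- expand_grid_jobs(cfg)
  expect_equal(nrow(jobs), 4800L)       # 2 x 2 x 2 x 2 x 3 x 100
  expect_identical(jobs, expand_grid_jobs(cfg))  # deterministic seeds
  expect_equal(anyDuplicated(jobs$seed), 0L)
  expect_true(all(jobs$seed < 2^31))
  cfg1 <- experiment_config("sim", "A01-B", S_grid = 2L, L_grid = 40L,
                            theta_grid = 0.0025, rho_grid = 0.05, R = 1L)
  expect_equal(nrow(expand_grid_jobs(cfg1)), 1L)
  expect_error(experiment_config("sim", "A01-B", scale = 0), "scale")
})

test_that("scaled presets shrink replicates and loci for desk runs", {
  cfg <- a00_preset(scale = 0.1)
  jobs <- expand_grid_jobs(cfg)
  expect_equal(max(jobs$replicate) + 1L, 10L)
  expect_true(all(jobs$L %in% c(10L, 16L)))
})

test_that("a zero-recombination run reports zero events everywhere", {
  cfg <- experiment_config("sim", "A01-B", S_grid = 2L, L_grid = 15L,
                           theta_grid = 0.0025, rho_grid = 0, R = 2L,
                           seed = 3L)
  rep <- run_experiment(cfg)
  expect_equal(rep$settings$mean_events, 0)
  expect_equal(rep$settings$fraction_zero, 1)
})

test_that("runs are resumable and reports byte-identical", {
  cfg <- experiment_config("sim", c("A01-B", "A11-shallow"), S_grid = 2L,
                           L_grid = 12L, theta_grid = 0.0025,
                           rho_grid = c(0.05, 0.5), R = 2L, seed = 7L)
  dir <- file.path(tempdir(), "harness-resume")
  unlink(dir, recursive = TRUE)
  r1 <- run_experiment(cfg, dir)
  manifest <- file.path(dir, "manifest.tsv")
  expect_true(file.exists(manifest))
  n_done <- nrow(utils::read.table(manifest, header = TRUE))
  expect_equal(n_done, nrow(expand_grid_jobs(cfg)))
  r2 <- run_experiment(cfg, dir)   # all jobs cached
  expect_identical(r1$settings, r2$settings)
  f1 <- tempfile(); f2 <- tempfile()
  write_report(r1, f1); write_report(r2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("a scaled inference experiment emits all report fields", {
  cfg <- experiment_config("A01", "A01-B", S_grid = 2L, L_grid = 10L,
                           theta_grid = 0.01, rho_grid = 0.05, R = 2L,
                           seed = 21L,
                           mcmc = mcmc_settings(burnin = 100,
                                                nsamples = 250))
  rep <- run_experiment(cfg)
  expect_true(all(c("recovery", "mean_events", "fraction_zero") %in%
                    names(rep$settings)))
  expect_gte(rep$settings$recovery, 0)
  expect_lte(rep$settings$recovery, 1)
  expect_equal(rep$details[[1]]$true_topology, "(((A,B),C),(D,E))")
})
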