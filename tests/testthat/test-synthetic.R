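sc <- ccScenario()

test_that("zero noise returns the clean MIDs exactly", {
  ms <- noiselessMeasurements(sc)
  pred <- predictMids(sc$model, sc$fluxes, sc$tracer)
  for (m in names(mids(ms)))
    expect_identical(mids(ms)[[m]], pred[[m]])
  # any replicate count, still exact
  ms3 <- generateExperiment(sc$model, sc$fluxes, sc$tracer, sigma = 0,
                            n_replicates = 3L, seed = 9L)@measurements
  for (m in names(mids(ms3)))
    expect_equal(mids(ms3)[[m]], pred[[m]], tolerance = 1e-15)
})

test_that("noise generation is deterministic under a fixed seed", {
  e1 <- generateExperiment(sc$model, sc$fluxes, sc$tracer, sigma = 0.01,
                           n_replicates = 3L, seed = 7L)
  e2 <- generateExperiment(sc$model, sc$fluxes, sc$tracer, sigma = 0.01,
                           n_replicates = 3L, seed = 7L)
  expect_identical(e1@measurements@replicates, e2@measurements@replicates)
  e3 <- generateExperiment(sc$model, sc$fluxes, sc$tracer, sigma = 0.01,
                           n_replicates = 3L, seed = 8L)
  expect_false(identical(e1@measurements@replicates,
                         e3@measurements@replicates))
})

test_that("noise magnitude matches sigma before renormalization", {
  # a flat MID keeps clipping and renormalization effects negligible
  clean <- measurementSet(mids = list(X = rep(0.25, 4)))
  noisy <- addMeasurementNoise(clean, sigma = 0.01, n_replicates = 1000,
                               seed = 2)
  draws <- noisy@replicates$X
  sds <- apply(draws, 2, sd)
  expect_true(all(abs(sds - 0.01) / 0.01 < 0.2))
})

test_that("invalid noise parameters are rejected", {
  clean <- measurementSet(mids = list(X = c(0.5, 0.5)))
  expect_error(addMeasurementNoise(clean, -0.1, 3, 1), "non-negative")
  expect_error(addMeasurementNoise(clean, 0.1, 0, 1), "at least 1")
})

test_that("written experiments round-trip through the table reader", {
  dir <- withr::local_tempdir()
  exp <- generateExperiment(sc$model, sc$fluxes, sc$tracer, sigma = 0.01,
                            n_replicates = 3L, seed = 7L, dir = dir,
                            condition = "ctl")
  raw <- readMeasurementTable(file.path(dir, "measurements.csv"))
  expect_named(raw, "ctl")
  expect_setequal(names(raw$ctl), measuredPools(sc$model))
  for (m in names(raw$ctl)) {
    expect_equal(nrow(raw$ctl[[m]]), 3L)
    expect_equal(unname(raw$ctl[[m]]), unname(exp@measurements@replicates[[m]]),
                 tolerance = 1e-12)
  }
  ms <- averageReplicates(raw$ctl, condition = "ctl")
  for (m in names(mids(ms)))
    expect_equal(mids(ms)[[m]], mids(exp@measurements)[[m]], tolerance = 1e-9)

  # sidecar carries seed, sigma and the true fluxes
  meta <- yaml::read_yaml(file.path(dir, "experiment.yaml"))
  expect_equal(meta$seed, 7L)
  expect_equal(meta$sigma, 0.01)
  expect_equal(unlist(meta$true_fluxes), sc$fluxes)
})

test_that("regenerating with the same seed reproduces the file bytes", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generateExperiment(sc$model, sc$fluxes, sc$tracer, 0.01, 3L, 7L, dir = d1)
  generateExperiment(sc$model, sc$fluxes, sc$tracer, 0.01, 3L, 7L, dir = d2)
  expect_identical(readLines(file.path(d1, "measurements.csv")),
                   readLines(file.path(d2, "measurements.csv")))
})

test_that("the reference scenario satisfies its own constraints", {
  expect_equal(balanceResidual(sc$model, sc$fluxes), 0)
  expect_true(validateFluxVector(sc$model, sc$fluxes))
  # hexose uptake normalization and fixed dietary inflows hold
  expect_equal(unname(sc$fluxes["r_glc"] + sc$fluxes["r_frc"]), 100)
  expect_equal(unname(sc$fluxes["r_serin"]), 10)
  expect_equal(unname(sc$fluxes["r_acein"]), 10)
})
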