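sc <- ccScenario()
ms0 <- noiselessMeasurements(sc)

test_that("the loss is zero at the generating fluxes and matches a naive
           double-loop evaluation", {
  expect_lt(totalLoss(sc$model, sc$fluxes, ms0, sc$tracer), 1e-16)

  # hand value: one 1-carbon pool, predicted (0.6, 0.4) vs observed (0.5, 0.5)
  m <- buildNetwork("
pools:
  - {id: U, carbons: 1, role: source, measured: false}
  - {id: L, carbons: 1, role: source, measured: false}
  - {id: M, carbons: 1, role: sink, measured: true}
reactions:
  - {id: ru, substrates: [U], product: M, carbon_map: [[1,1]]}
  - {id: rl, substrates: [L], product: M, carbon_map: [[1,1]]}
")
  obs <- measurementSet(mids = list(M = c(0.5, 0.5)))
  L <- totalLoss(m, c(ru = 0.6, rl = 0.4), obs, tracerSpec("L", 1))
  expect_equal(L, 0.02, tolerance = 1e-12)

  # random instance vs an independently coded double loop
  set.seed(21)
  v <- sc$fluxes * 1  # perturb within the constraint null space
  msn <- generateExperiment(sc$model, sc$fluxes, sc$tracer, sigma = 0.02,
                            n_replicates = 2L, seed = 31L)@measurements
  pred <- predictMids(sc$model, v, sc$tracer)
  L2 <- 0
  for (met in names(mids(msn))) {
    for (j in seq_along(mids(msn)[[met]])) {
      L2 <- L2 + (pred[[met]][j] - mids(msn)[[met]][j])^2
    }
  }
  expect_equal(totalLoss(sc$model, v, msn, sc$tracer), L2, tolerance = 1e-12)
})

test_that("a measured metabolite missing from the model is an error", {
  obs <- measurementSet(mids = list(NOPE = c(0.5, 0.5)))
  expect_error(totalLoss(sc$model, sc$fluxes, obs, sc$tracer),
               "missing from the model")
})

test_that("single fits recover noiseless data and are deterministic", {
  f1 <- fitSingle(sc$model, ms0, sc$tracer, seed = 5L)
  expect_true(f1@converged)
  expect_lt(f1@loss, 1e-8)
  expect_lt(f1@residual, 1e-6)
  expect_true(all(f1@fluxes >= fluxBounds(sc$model)[, 1]))
  expect_true(all(f1@fluxes <= fluxBounds(sc$model)[, 2]))
  f2 <- fitSingle(sc$model, ms0, sc$tracer, seed = 5L)
  expect_identical(f1@fluxes, f2@fluxes)
  expect_identical(f1@loss, f2@loss)
})

test_that("ratio-identifiable chains recover the true flux ratio", {
  # U and L feed M; only the ratio rB/(rA+rB) is observable. No uptake
  # constraint here: absolute scale is free, the ratio must still be exact.
  m <- buildNetwork("
pools:
  - {id: U, carbons: 1, role: source, measured: false}
  - {id: L, carbons: 1, role: source, measured: false}
  - {id: M, carbons: 1, role: internal, measured: true}
  - {id: S, carbons: 1, role: sink, measured: false}
reactions:
  - {id: rA, substrates: [U], product: M, carbon_map: [[1,1]]}
  - {id: rB, substrates: [L], product: M, carbon_map: [[1,1]]}
  - {id: rC, substrates: [M], product: S, carbon_map: [[1,1]]}
bounds:
  default: [0, 2]
")
  tr <- tracerSpec("L", 1)
  truth <- c(rA = 0.9, rB = 0.3, rC = 1.2)
  obs <- generateExperiment(m, truth, tr, sigma = 0, n_replicates = 1L,
                            seed = 1L)@measurements
  f <- fitSingle(m, obs, tr, seed = 11L)
  got <- f@fluxes["rB"] / (f@fluxes["rA"] + f@fluxes["rB"])
  expect_equal(unname(got), 0.25, tolerance = 1e-4)
})

test_that("the ensemble selection rule is honored", {
  ens <- fitEnsemble(sc$model, ms0, sc$tracer, n_restarts = 30, keep = 8,
                     base_seed = 3L)
  expect_equal(ens@nRestarts, 30L)
  expect_equal(nrow(fluxMatrix(ens)), 8L)
  expect_false(is.unsorted(losses(ens)))
  tr <- restartTrace(ens)
  expect_equal(nrow(tr), 30L)
  expect_identical(tr$seed, 3L + 0:29)
  conv_losses <- sort(tr$L_total[tr$converged])
  # retained set = the keep smallest converged losses; max retained <= min discarded
  expect_equal(losses(ens), conv_losses[1:8], tolerance = 0)
  expect_lte(max(losses(ens)), min(conv_losses[-(1:8)]))
  # keep = n_restarts retains everything converged, sorted
  ens_all <- fitEnsemble(sc$model, ms0, sc$tracer, n_restarts = 10, keep = 10,
                         base_seed = 3L)
  expect_equal(nrow(fluxMatrix(ens_all)), sum(restartTrace(ens_all)$converged))
  # best-of-k is monotone non-increasing in k
  expect_true(all(diff(cummin(tr$L_total)) <= 0))
})

test_that("every retained solution is feasible", {
  ens <- fitEnsemble(sc$model, ms0, sc$tracer, n_restarts = 25, keep = 10,
                     base_seed = 17L)
  bd <- fluxBounds(sc$model)
  for (i in seq_len(nrow(fluxMatrix(ens)))) {
    v <- fluxMatrix(ens)[i, ]
    expect_lte(balanceResidual(sc$model, v), 1e-6)
    expect_true(all(v >= bd[, 1] & v <= bd[, 2]))
  }
})

test_that("paper-fidelity defaults request 10000 restarts keeping 50", {
  # contract check on the configuration plumbing (not a full-scale run)
  expect_error(fitEnsemble(sc$model, ms0, sc$tracer, n_restarts = 5, keep = 10),
               "at least keep")
  ens <- fitEnsemble(sc$model, ms0, sc$tracer, n_restarts = 20, keep = 5,
                     base_seed = 1L, profile = "paper")
  expect_equal(ens@keep, 5L)  # explicit values override the profile
})

test_that("ensemble summaries match independent column statistics", {
  ens <- fitEnsemble(sc$model, ms0, sc$tracer, n_restarts = 20, keep = 6,
                     base_seed = 2L)
  s <- summarizeEnsemble(ens)
  fm <- fluxMatrix(ens)
  expect_equal(s$reaction, reactionIds(sc$model))
  for (j in seq_len(ncol(fm))) {
    expect_equal(s$mean_flux[j], sum(fm[, j]) / nrow(fm), tolerance = 1e-12)
    expect_equal(s$sd_flux[j],
                 sqrt(sum((fm[, j] - mean(fm[, j]))^2) / (nrow(fm) - 1)),
                 tolerance = 1e-12)
  }
  expect_equal(unique(s$n_retained), 6L)
  expect_equal(unique(s$min_loss), min(losses(ens)))
})

test_that("condition comparison handles identical, degenerate and random
           ensembles", {
  ens <- fitEnsemble(sc$model, ms0, sc$tracer, n_restarts = 12, keep = 5,
                     base_seed = 2L)
  self <- compareConditions(ens, ens)
  expect_true(all(self$p[!self$degenerate] == 1))
  expect_true(all(self$t[!self$degenerate] == 0))
  # all-equal ensembles with different constants: flagged sentinel, not NaN
  ens_a <- ens; ens_b <- ens
  ens_a@fluxes[] <- 1
  ens_b@fluxes[] <- 2
  cmp <- compareConditions(ens_a, ens_b)
  expect_true(all(cmp$degenerate))
  expect_true(all(cmp$p == 0))
  expect_true(all(is.infinite(cmp$t)))

  # random Gaussian ensembles vs the closed-form Welch statistic
  set.seed(8)
  ga <- ens; gb <- ens
  ga@fluxes <- matrix(rnorm(5 * ncol(ens@fluxes), 10, 1), nrow = 5,
                      dimnames = dimnames(ens@fluxes))
  gb@fluxes <- matrix(rnorm(5 * ncol(ens@fluxes), 11, 2), nrow = 5,
                      dimnames = dimnames(ens@fluxes))
  cmp2 <- compareConditions(ga, gb)
  for (j in seq_along(cmp2$reaction)) {
    a <- ga@fluxes[, j]; b <- gb@fluxes[, j]
    tw <- (mean(a) - mean(b)) / sqrt(var(a) / 5 + var(b) / 5)
    expect_equal(cmp2$t[j], tw, tolerance = 1e-10)
  }
  expect_equal(cmp2$p_adj, p.adjust(cmp2$p, "BH"))
})

test_that("identifiability analysis flags the weakly determined exchange", {
  fi <- fluxIdentifiability(sc$model, sc$fluxes, sc$tracer, sigma = 0.01)
  expect_equal(fi$reaction, reactionIds(sc$model))
  # fixed-by-constraint fluxes are perfectly determined
  expect_lt(fi$rel_sd[fi$reaction == "r_serin"], 1e-8)
  # hexose split is sharply determined; lactate exchange is the loosest
  expect_lt(fi$rel_sd[fi$reaction == "r_frc"], 0.02)
  expect_equal(fi$reaction[which.max(fi$rel_sd)], "r_ldh")
})
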