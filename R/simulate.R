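## Synthetic experiments: forward-simulated MIDs with replicate noise.

#' Construct a MeasurementSet from MIDs or replicate matrices
#'
#' @param mids named list of MIDs (replicate-averaged), or `NULL` to derive
#'   the averages from `replicates` by [averageReplicates()] semantics.
#' @param condition condition label.
#' @param replicates optional named list of replicate x mass-level matrices.
#' @return a [MeasurementSet].
#' @export
measurementSet <- function(mids = NULL, condition = "default",
                           replicates = list()) {
  if (is.null(mids)) {
    if (!length(replicates)) stop("either mids or replicates must be given")
    return(averageReplicates(replicates, condition = condition))
  }
  mids <- lapply(mids, normalizeMid)
  dispersion <- lapply(replicates, function(m) apply(m, 2, sd))
  new("MeasurementSet", condition = condition, mids = mids,
      replicates = replicates, dispersion = dispersion)
}

setValidity("MeasurementSet", function(object) {
  msg <- character()
  if (length(object@condition) != 1L)
    msg <- c(msg, "condition must be a single label")
  bad <- names(object@mids)[!vapply(object@mids, validMid, logical(1))]
  if (length(bad))
    msg <- c(msg, sprintf("invalid MID for: %s", paste(bad, collapse = ", ")))
  if (is.null(names(object@mids)) && length(object@mids))
    msg <- c(msg, "mids must be a named list")
  if (length(msg)) msg else TRUE
})

#' Add replicate measurement noise to clean MIDs
#'
#' Each replicate MID is the clean MID plus independent Gaussian noise of
#' standard deviation `sigma` per mass level, clipped at zero and
#' renormalized (the simplest simplex-respecting noise model). The
#' replicate-averaged MID is then recomputed as the arithmetic mean across
#' replicates, renormalized. Per-replicate random streams are derived from
#' `seed` by fixed offsets, so regeneration is deterministic and stable
#' under partial changes of `n_replicates`.
#'
#' @param ms a [MeasurementSet] holding the clean (noise-free) MIDs.
#' @param sigma noise standard deviation per mass level (`>= 0`).
#' @param n_replicates number of replicates (`>= 1`).
#' @param seed integer base seed.
#' @return a [MeasurementSet] with per-replicate MIDs and recomputed
#'   averages. With `sigma = 0` the averages equal the input exactly.
#' @export
addMeasurementNoise <- function(ms, sigma, n_replicates, seed) {
  if (sigma < 0) stop("sigma must be non-negative")
  if (n_replicates < 1) stop("n_replicates must be at least 1")
  mets <- names(ms@mids)
  reps <- lapply(ms@mids, function(x)
    matrix(0, nrow = n_replicates, ncol = length(x)))
  for (r in seq_len(n_replicates)) {
    .withSeed(seed + r - 1L, {
      for (m in mets) {
        clean <- ms@mids[[m]]
        if (sigma == 0) {  # exact: no renormalization round-off
          reps[[m]][r, ] <- clean
        } else {
          noisy <- clean + rnorm(length(clean), 0, sigma)
          reps[[m]][r, ] <- normalizeMid(pmax(noisy, 0))
        }
      }
    })
  }
  avg <- if (sigma == 0) ms@mids else
    lapply(reps, function(x) normalizeMid(colMeans(x)))
  new("MeasurementSet", condition = ms@condition, mids = avg,
      replicates = reps,
      dispersion = lapply(reps, function(x) apply(x, 2, sd)))
}

#' Generate a complete synthetic tracing experiment
#'
#' Runs the forward simulator at the given true fluxes, restricts the
#' predicted MIDs to the model's measured pools, adds replicate noise, and
#' (optionally) writes the measurement table plus a metadata sidecar so the
#' experiment can be re-ingested and the truth recovered by the fitting
#' stage.
#'
#' @param model a [NetworkModel].
#' @param true_fluxes named flux vector satisfying bounds and balance.
#' @param tracer a [TracerSpec].
#' @param sigma per-mass-level noise standard deviation.
#' @param n_replicates number of replicates.
#' @param seed integer base seed (drives the noise only).
#' @param dir optional output directory; when given, writes
#'   `measurements.csv` (schema `metabolite, mass_level, value, replicate,
#'   condition`) and `experiment.yaml` (seed, sigma, tracer, true fluxes).
#' @param condition condition label for the emitted table.
#' @return a [SyntheticExperiment].
#' @seealso [readMeasurementTable()], [fitEnsemble()]
#' @export
generateExperiment <- function(model, true_fluxes, tracer, sigma = 0.01,
                               n_replicates = 3L, seed = 1L, dir = NULL,
                               condition = "synthetic") {
  validateFluxVector(model, true_fluxes)
  pred <- predictMids(model, true_fluxes, tracer)
  meas <- pred[measuredPools(model)]
  clean <- new("MeasurementSet", condition = condition, mids = meas,
               replicates = list(), dispersion = list())
  noisy <- addMeasurementNoise(clean, sigma, n_replicates, seed)
  exp <- new("SyntheticExperiment",
             model = model,
             trueFluxes = setNames(.orderFluxes(model, true_fluxes),
                                   reactionIds(model)),
             tracer = tracer, sigma = as.numeric(sigma),
             nReplicates = as.integer(n_replicates), seed = as.integer(seed),
             measurements = noisy)
  if (!is.null(dir)) writeExperiment(exp, dir)
  exp
}

#' Write a synthetic experiment to disk
#'
#' @param exp a [SyntheticExperiment].
#' @param dir output directory (created if needed).
#' @return the paths of the written files, invisibly.
#' @export
writeExperiment <- function(exp, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ms <- exp@measurements
  rows <- list()
  for (m in names(ms@replicates)) {
    mat <- ms@replicates[[m]]
    for (r in seq_len(nrow(mat))) {
      rows[[length(rows) + 1L]] <- data.frame(
        metabolite = m, mass_level = seq_len(ncol(mat)) - 1L,
        value = mat[r, ], replicate = r, condition = ms@condition,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab_path <- file.path(dir, "measurements.csv")
  write.csv(tab, tab_path, row.names = FALSE, quote = FALSE)
  meta <- list(
    seed = exp@seed, sigma = exp@sigma, n_replicates = exp@nReplicates,
    condition = ms@condition,
    tracer = list(pool = exp@tracer@pool, purity = exp@tracer@purity,
                  isotopologue = if (is.na(exp@tracer@isotopologue)) "uniform"
                                 else exp@tracer@isotopologue),
    true_fluxes = as.list(exp@trueFluxes))
  meta_path <- file.path(dir, "experiment.yaml")
  yaml::write_yaml(meta, meta_path)
  invisible(c(measurements = tab_path, metadata = meta_path))
}

#' The bundled central-carbon network and its reference flux scenario
#'
#' Loads the fixture network shipped with the package — glycolysis from
#' glucose/fructose sources, the pyruvate node (lactate efflux, pyruvate
#' dehydrogenase, pyruvate carboxylase), the TCA cycle with malic-enzyme
#' cataplerosis, and the 3PG-serine-glycine branch — together with a
#' reference flux vector that satisfies all balance constraints (hexose
#' uptake normalized to 100 relative units) and the default tracer
#' (uniformly 13C-labeled fructose at purity 0.99). The scenario is fully
#' identifiable from the measured pools: the fixed dietary inflows and the
#' uptake normalization pin the absolute scale.
#'
#' @return `list(model = NetworkModel, fluxes = named numeric,
#'   tracer = TracerSpec)`.
#' @examples
#' sc <- centralCarbonNetwork()
#' balanceResidual(sc$model, sc$fluxes)  # 0
#' @export
centralCarbonNetwork <- function() {
  path <- system.file("extdata", "central_carbon.yaml", package = "isoflux",
                      mustWork = TRUE)
  model <- buildNetwork(path)
  fluxes <- c(
    r_glc = 40, r_frc = 60, r_gapdh = 100, r_eno = 85, r_pk = 85,
    r_ldh = 25, r_pgser = 15, r_serin = 10, r_shmt = 25, r_pdh = 60,
    r_acein = 10, r_cs = 70, r_idh = 70, r_kgdh = 70, r_sdh = 70,
    r_mdh = 55, r_pc = 15, r_me = 15)
  list(model = model, fluxes = fluxes[reactionIds(model)],
       tracer = tracerSpec("FRC", purity = 0.99))
}
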