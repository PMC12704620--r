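## Central S4 classes. MIDs themselves are bare numeric vectors of length
## n_carbons + 1 on the probability simplex (see validMid()); the classes
## below are the containers that carry them through the pipeline.

#' Reaction: a carbon-mapped metabolic reaction
#'
#' A single irreversible reaction converting one or two substrate pools into
#' one product pool, with an explicit atom map: every product carbon position
#' is assigned the (substrate index, substrate carbon position) it derives
#' from, and every substrate carbon not retained (e.g. the carbon released as
#' CO2 by a decarboxylation) is listed as lost. Reversible steps are declared
#' once in a network config with `reversible: true` and expanded into a
#' forward/backward pair of irreversible reactions.
#'
#' @slot id character(1), unique reaction identifier.
#' @slot substrates character vector of substrate pool ids (ordered).
#' @slot product character(1), product pool id.
#' @slot carbonMap integer matrix with one row per product carbon and two
#'   columns, `substrate` (index into `substrates`) and `carbon`
#'   (1-based carbon position within that substrate).
#' @slot lost integer matrix, same two columns, listing substrate carbons
#'   not retained in the product (0 rows if none).
#' @slot reversible logical(1), whether this reaction was declared as one
#'   direction of a reversible pair.
#'
#' @export
setClass("Reaction",
  representation(
    id = "character",
    substrates = "character",
    product = "character",
    carbonMap = "matrix",
    lost = "matrix",
    reversible = "logical"
  )
)

#' NetworkModel: a carbon-mapped metabolic network with balance constraints
#'
#' Holds the metabolite pools (with tracked carbon counts and roles), the
#' carbon-mapped reactions, the steady-state balance matrix over internal
#' pools, optional extra linear equality constraints, and per-reaction flux
#' bounds. Source pools carry a fixed input MID (unlabeled, or set by a
#' [TracerSpec] at prediction time) and have no balance row; sink pools are
#' produced but not balanced.
#'
#' @slot pools data.frame with columns `id`, `n_carbons`, `role`
#'   (one of `"source"`, `"internal"`, `"sink"`) and `measured` (logical).
#' @slot reactions list of [Reaction] objects, in declaration order.
#' @slot A numeric balance matrix, one row per internal pool, one column per
#'   reaction; entries are +1 (production), -1 (consumption) or 0.
#' @slot b numeric right-hand side for the balance rows (all zeros at strict
#'   steady state).
#' @slot extraA numeric matrix of additional equality-constraint rows
#'   (same column order as `A`; 0 rows if none).
#' @slot extraB numeric right-hand side for the extra rows.
#' @slot bounds numeric matrix, one row per reaction, columns `lower` and
#'   `upper`, with `0 <= lower <= upper < Inf`.
#'
#' @seealso [buildNetwork()], [assembleBalance()], [balanceResidual()]
#' @export
setClass("NetworkModel",
  representation(
    pools = "data.frame",
    reactions = "list",
    A = "matrix",
    b = "numeric",
    extraA = "matrix",
    extraB = "numeric",
    bounds = "matrix"
  )
)

#' TracerSpec: which source pool is labeled, and how
#'
#' @slot pool character(1), id of the labeled source pool.
#' @slot purity numeric(1) in \[0, 1\]: fraction of source molecules that are
#'   tracer; the remainder is unlabeled.
#' @slot isotopologue integer(1), mass level of the tracer species
#'   (`NA` means fully labeled, i.e. mass level = carbon count of the pool).
#'
#' @export
setClass("TracerSpec",
  representation(
    pool = "character",
    purity = "numeric",
    isotopologue = "integer"
  )
)

#' MeasurementSet: observed MIDs for one experimental condition
#'
#' Replicate-averaged mass isotopomer distributions for the measured
#' metabolites of a network, with the per-replicate MIDs and per-mass-level
#' dispersion retained for diagnostics.
#'
#' @slot condition character(1) condition label.
#' @slot mids named list; one replicate-averaged MID (numeric vector of
#'   length n_carbons + 1, summing to 1) per measured metabolite.
#' @slot replicates named list of numeric matrices (replicate x mass level),
#'   possibly empty when only averages are available.
#' @slot dispersion named list of per-mass-level standard deviations across
#'   replicates (numeric vectors; empty when replicates are unavailable).
#'
#' @export
setClass("MeasurementSet",
  representation(
    condition = "character",
    mids = "list",
    replicates = "list",
    dispersion = "list"
  )
)

#' SyntheticExperiment: a simulated tracing experiment with known truth
#'
#' @slot model the [NetworkModel] used for simulation.
#' @slot trueFluxes named numeric, the generating flux vector.
#' @slot tracer the [TracerSpec].
#' @slot sigma numeric(1), per-mass-level Gaussian noise standard deviation.
#' @slot nReplicates integer(1).
#' @slot seed integer(1) base seed; regeneration with the same seed
#'   reproduces the measurement table exactly.
#' @slot measurements the emitted [MeasurementSet].
#'
#' @export
setClass("SyntheticExperiment",
  representation(
    model = "NetworkModel",
    trueFluxes = "numeric",
    tracer = "TracerSpec",
    sigma = "numeric",
    nReplicates = "integer",
    seed = "integer",
    measurements = "MeasurementSet"
  )
)

#' FitResult: one constrained local optimization from a random start
#'
#' @slot fluxes named numeric flux vector at the optimum.
#' @slot loss numeric(1), total sum-of-squared-error over measured MIDs.
#' @slot seed integer(1), restart seed.
#' @slot converged logical(1); optimizer failure is reported here, never
#'   raised.
#' @slot residual numeric(1), infinity-norm equality-constraint residual at
#'   the returned point.
#'
#' @export
setClass("FitResult",
  representation(
    fluxes = "numeric",
    loss = "numeric",
    seed = "integer",
    converged = "logical",
    residual = "numeric"
  )
)

#' EnsembleSolution: retained best-of-restarts flux vectors
#'
#' The result of the multi-start fitting procedure: the `keep` converged
#' restarts with the lowest total loss, sorted ascending, together with the
#' full restart trace for auditing the selection rule.
#'
#' @slot fluxes numeric matrix, one row per retained solution, one column per
#'   reaction (model order), rows sorted by ascending loss.
#' @slot losses numeric vector of retained losses (non-decreasing).
#' @slot seeds integer vector of the retained restart seeds.
#' @slot residuals numeric vector of retained constraint residuals.
#' @slot nRestarts integer(1), restarts attempted.
#' @slot keep integer(1), requested retention count.
#' @slot shortfall logical(1), TRUE when fewer than `keep` restarts
#'   converged (all converged results are then retained).
#' @slot trace data.frame with columns `restart`, `seed`, `L_total`,
#'   `converged` for every attempted restart.
#'
#' @seealso [fitEnsemble()], [summarizeEnsemble()], [compareConditions()]
#' @export
setClass("EnsembleSolution",
  representation(
    fluxes = "matrix",
    losses = "numeric",
    seeds = "integer",
    residuals = "numeric",
    nRestarts = "integer",
    keep = "integer",
    shortfall = "logical",
    trace = "data.frame"
  )
)
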