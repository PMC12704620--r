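## Accessors and show methods.

#' @rdname NetworkModel-accessors
#' @export
setGeneric("pools", function(x) standardGeneric("pools"))
#' @rdname NetworkModel-accessors
#' @export
setGeneric("reactions", function(x) standardGeneric("reactions"))
#' @rdname NetworkModel-accessors
#' @export
setGeneric("reactionIds", function(x) standardGeneric("reactionIds"))
#' @rdname NetworkModel-accessors
#' @export
setGeneric("poolIds", function(x) standardGeneric("poolIds"))
#' @rdname NetworkModel-accessors
#' @export
setGeneric("measuredPools", function(x) standardGeneric("measuredPools"))
#' @rdname NetworkModel-accessors
#' @export
setGeneric("nCarbons", function(x, pool) standardGeneric("nCarbons"))
#' @rdname NetworkModel-accessors
#' @export
setGeneric("fluxBounds", function(x) standardGeneric("fluxBounds"))

#' Accessors for NetworkModel
#'
#' @param x a [NetworkModel].
#' @param pool optional pool id (for `nCarbons`); when missing, the full
#'   named vector of tracked carbon counts is returned.
#' @return `pools`: the pool data.frame; `reactions`: the list of
#'   [Reaction] objects; `reactionIds`/`poolIds`: character vectors in
#'   declaration order; `measuredPools`: ids of pools with observed MIDs;
#'   `nCarbons`: integer carbon count(s); `fluxBounds`: the per-reaction
#'   bounds matrix.
#' @name NetworkModel-accessors
#' @aliases pools reactions reactionIds poolIds measuredPools nCarbons
#'   fluxBounds
NULL

#' @rdname NetworkModel-accessors
setMethod("pools", "NetworkModel", function(x) x@pools)
#' @rdname NetworkModel-accessors
setMethod("reactions", "NetworkModel", function(x) x@reactions)
#' @rdname NetworkModel-accessors
setMethod("reactionIds", "NetworkModel",
          function(x) vapply(x@reactions, function(r) r@id, character(1)))
#' @rdname NetworkModel-accessors
setMethod("poolIds", "NetworkModel", function(x) x@pools$id)
#' @rdname NetworkModel-accessors
setMethod("measuredPools", "NetworkModel",
          function(x) x@pools$id[x@pools$measured])
#' @rdname NetworkModel-accessors
setMethod("nCarbons", "NetworkModel", function(x, pool) {
  nc <- setNames(x@pools$n_carbons, x@pools$id)
  if (missing(pool)) nc else unname(nc[pool])
})
#' @rdname NetworkModel-accessors
setMethod("fluxBounds", "NetworkModel", function(x) x@bounds)

#' @rdname EnsembleSolution-accessors
#' @export
setGeneric("fluxMatrix", function(x) standardGeneric("fluxMatrix"))
#' @rdname EnsembleSolution-accessors
#' @export
setGeneric("losses", function(x) standardGeneric("losses"))
#' @rdname EnsembleSolution-accessors
#' @export
setGeneric("restartTrace", function(x) standardGeneric("restartTrace"))

#' Accessors for EnsembleSolution
#'
#' @param x an [EnsembleSolution].
#' @return `fluxMatrix`: retained solutions (rows, sorted by ascending
#'   loss) by reactions (columns); `losses`: the retained loss values;
#'   `restartTrace`: per-restart audit table (`restart`, `seed`,
#'   `L_total`, `converged`).
#' @name EnsembleSolution-accessors
#' @aliases fluxMatrix losses restartTrace
NULL

#' @rdname EnsembleSolution-accessors
setMethod("fluxMatrix", "EnsembleSolution", function(x) x@fluxes)
#' @rdname EnsembleSolution-accessors
setMethod("losses", "EnsembleSolution", function(x) x@losses)
#' @rdname EnsembleSolution-accessors
setMethod("restartTrace", "EnsembleSolution", function(x) x@trace)

#' @rdname MeasurementSet-accessors
#' @export
setGeneric("condition", function(x) standardGeneric("condition"))
#' @rdname MeasurementSet-accessors
#' @export
setGeneric("mids", function(x) standardGeneric("mids"))

#' Accessors for MeasurementSet
#'
#' @param x a [MeasurementSet].
#' @return `condition`: the condition label; `mids`: the named list of
#'   replicate-averaged MIDs.
#' @name MeasurementSet-accessors
#' @aliases condition mids
NULL

#' @rdname MeasurementSet-accessors
setMethod("condition", "MeasurementSet", function(x) x@condition)
#' @rdname MeasurementSet-accessors
setMethod("mids", "MeasurementSet", function(x) x@mids)

setMethod("show", "NetworkModel", function(object) {
  p <- object@pools
  cat(sprintf("NetworkModel: %d pools (%d source, %d internal, %d sink), %d reactions\n",
              nrow(p), sum(p$role == "source"), sum(p$role == "internal"),
              sum(p$role == "sink"), length(object@reactions)))
  cat(sprintf("  balance rows: %d (+%d extra equality constraints)\n",
              nrow(object@A), nrow(object@extraA)))
  cat(sprintf("  measured pools: %s\n",
              paste(p$id[p$measured], collapse = ", ")))
})

setMethod("show", "Reaction", function(object) {
  lost <- if (nrow(object@lost)) sprintf(" (%d carbon(s) lost)", nrow(object@lost)) else ""
  cat(sprintf("Reaction %s: %s -> %s%s\n", object@id,
              paste(object@substrates, collapse = " + "), object@product, lost))
})

setMethod("show", "TracerSpec", function(object) {
  iso <- if (is.na(object@isotopologue)) "U-13C" else paste0("M+", object@isotopologue)
  cat(sprintf("TracerSpec: %s in pool %s at purity %.3f\n",
              iso, object@pool, object@purity))
})

setMethod("show", "MeasurementSet", function(object) {
  cat(sprintf("MeasurementSet '%s': %d measured metabolites\n",
              object@condition, length(object@mids)))
  if (length(object@replicates))
    cat(sprintf("  replicates retained: %d\n", nrow(object@replicates[[1]])))
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult (seed %d): L_total = %.4g, converged = %s, residual = %.2g\n",
              object@seed, object@loss, object@converged, object@residual))
})

setMethod("show", "EnsembleSolution", function(object) {
  cat(sprintf("EnsembleSolution: %d/%d restarts retained (attempted %d)\n",
              length(object@losses), object@keep, object@nRestarts))
  if (length(object@losses))
    cat(sprintf("  L_total range: %.4g .. %.4g\n",
                min(object@losses), max(object@losses)))
  if (object@shortfall)
    cat("  warning: fewer converged restarts than requested keep\n")
})

setMethod("show", "SyntheticExperiment", function(object) {
  cat(sprintf("SyntheticExperiment (seed %d): sigma = %.3g, %d replicate(s), %d measured pools\n",
              object@seed, object@sigma, object@nReplicates,
              length(object@measurements@mids)))
})
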