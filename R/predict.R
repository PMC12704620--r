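## Forward label propagation: steady-state MIDs implied by a flux vector.

#' Construct a tracer specification
#'
#' @param pool id of the labeled source pool.
#' @param purity fraction of source molecules that are tracer (the rest is
#'   unlabeled). The bundled fixture defaults to 0.99, a stand-in for a
#'   vendor-reported tracer purity that users should replace with their own
#'   value.
#' @param isotopologue mass level of the tracer species; `NA` (default)
#'   means uniformly labeled, i.e. mass level = the pool's carbon count.
#' @return a [TracerSpec].
#' @examples
#' tracerSpec("FRC", purity = 0.99)
#' @export
tracerSpec <- function(pool, purity = 0.99, isotopologue = NA_integer_) {
  if (purity < 0 || purity > 1) stop("tracer purity must lie in [0, 1]")
  new("TracerSpec", pool = as.character(pool), purity = as.numeric(purity),
      isotopologue = as.integer(isotopologue))
}

## Compile a model + tracer into the flat plan consumed by the C routines.
## Source pools get their fixed MIDs here: unlabeled, except the tracer
## pool which is a purity-weighted mixture of the tracer isotopologue and
## the unlabeled species.
.compilePlan <- function(model, tracer) {
  p <- model@pools
  if (!tracer@pool %in% p$id[p$role == "source"])
    stop(sprintf("tracer pool %s is not a source pool of the model", tracer@pool))
  nidx <- setNames(seq_len(nrow(p)), p$id)
  nC <- setNames(p$n_carbons, p$id)

  smids <- vector("list", nrow(p))
  for (i in seq_len(nrow(p))) {
    if (p$role[i] != "source") next
    mid <- c(1, rep(0, p$n_carbons[i]))
    if (p$id[i] == tracer@pool) {
      lvl <- if (is.na(tracer@isotopologue)) p$n_carbons[i] else tracer@isotopologue
      if (lvl < 0 || lvl > p$n_carbons[i])
        stop("tracer isotopologue outside the pool's mass range")
      mid <- (1 - tracer@purity) * mid
      mid[lvl + 1] <- mid[lvl + 1] + tracer@purity
    }
    smids[[i]] <- mid
  }

  rxns <- lapply(model@reactions, function(r) {
    margs <- vector("list", length(r@substrates))
    for (k in seq_along(r@substrates)) {
      n_sub <- nC[[r@substrates[k]]]
      n_keep <- sum(r@carbonMap[, 1] == k)
      if (n_keep == n_sub) next  # identity, left NULL
      margs[[k]] <- if (n_keep == 0)
        matrix(c(1, rep(0, n_sub)), nrow = 1) else .margMatrix(n_sub, n_keep)
    }
    list(prod = unname(nidx[r@product]) - 1L,
         subs = as.integer(nidx[r@substrates]) - 1L,
         margs = margs)
  })

  list(n_carbons = as.integer(p$n_carbons),
       is_source = as.integer(p$role == "source"),
       source_mids = smids,
       reactions = rxns,
       pool_ids = p$id)
}

#' Predict steady-state MIDs from a flux vector
#'
#' Implements the precursor-averaging recursion: the MID of every non-source
#' pool is the flux-weighted average of the MIDs contributed by its producing
#' reactions, where a reaction's contribution is built from its substrate
#' MIDs through the carbon map — convolution for condensations,
#' hypergeometric marginalization for carbon losses. Because cyclic
#' pathways (the TCA loop) admit no acyclic evaluation order, the recursion
#' is closed by fixed-point iteration (Jacobi sweeps from an unlabeled
#' initialization) until the largest per-entry change falls below `tol`.
#'
#' The result depends only on flux ratios: rescaling all fluxes by a common
#' factor leaves every predicted MID unchanged.
#'
#' @param model a [NetworkModel].
#' @param v flux vector (one non-negative entry per reaction; named vectors
#'   are matched by reaction id).
#' @param tracer a [TracerSpec] fixing the labeled source pool.
#' @param tol fixed-point tolerance on the sup-norm change per sweep
#'   (default `1e-12`).
#' @param maxit iteration cap (default 20000).
#' @param damping fraction of the fresh sweep used in each update
#'   (1 = undamped).
#' @return named list of MIDs, one per pool.
#' @seealso [totalLoss()], [generateExperiment()]
#' @export
predictMids <- function(model, v, tracer, tol = 1e-12, maxit = 20000L,
                        damping = 1) {
  v <- .orderFluxes(model, v)
  if (any(v < 0)) stop("fluxes must be non-negative")
  plan <- .compilePlan(model, tracer)
  res <- .c_predict_mids(plan, as.numeric(v), tol, as.integer(maxit),
                         as.numeric(damping))
  if (!res$converged)
    stop(sprintf("label propagation did not converge within %d sweeps", maxit))
  setNames(res$mids, plan$pool_ids)
}
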