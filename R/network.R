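## Network declaration, validation and the linear constraint system.

.POOL_ROLES <- c("source", "internal", "sink")

setValidity("Reaction", function(object) {
  msg <- character()
  if (length(object@id) != 1L || !nzchar(object@id))
    msg <- c(msg, "reaction id must be a non-empty string")
  if (length(object@substrates) < 1L)
    msg <- c(msg, "reaction needs at least one substrate")
  if (length(object@product) != 1L)
    msg <- c(msg, "reaction must have exactly one product")
  for (nm in c("carbonMap", "lost")) {
    m <- slot(object, nm)
    if (ncol(m) != 2L)
      msg <- c(msg, sprintf("%s must have two columns (substrate, carbon)", nm))
  }
  cm <- object@carbonMap
  if (nrow(cm) > 0 &&
      (any(cm[, 1] < 1) || any(cm[, 1] > length(object@substrates))))
    msg <- c(msg, "carbonMap references a substrate index out of range")
  if (length(msg)) msg else TRUE
})

setValidity("NetworkModel", function(object) {
  p <- object@pools
  msg <- character()
  need <- c("id", "n_carbons", "role", "measured")
  if (!all(need %in% names(p)))
    return(sprintf("pools must have columns %s", paste(need, collapse = ", ")))
  if (anyDuplicated(p$id))
    msg <- c(msg, sprintf("duplicate pool id: %s",
                          paste(unique(p$id[duplicated(p$id)]), collapse = ", ")))
  if (any(p$n_carbons < 1))
    msg <- c(msg, "every pool must track at least one carbon")
  if (!all(p$role %in% .POOL_ROLES))
    msg <- c(msg, "pool role must be one of source/internal/sink")

  rids <- vapply(object@reactions, function(r) r@id, character(1))
  if (anyDuplicated(rids))
    msg <- c(msg, sprintf("duplicate reaction id: %s",
                          paste(unique(rids[duplicated(rids)]), collapse = ", ")))

  nC <- setNames(p$n_carbons, p$id)
  for (r in object@reactions) {
    bad <- setdiff(c(r@substrates, r@product), p$id)
    if (length(bad)) {
      msg <- c(msg, sprintf("reaction %s references unknown pool(s): %s",
                            r@id, paste(bad, collapse = ", ")))
      next
    }
    if (nrow(r@carbonMap) != nC[[r@product]])
      msg <- c(msg, sprintf(
        "reaction %s: carbon map assigns %d product carbons but %s has %d",
        r@id, nrow(r@carbonMap), r@product, nC[[r@product]]))
    # every substrate carbon either mapped or explicitly lost, exactly once
    for (k in seq_along(r@substrates)) {
      used <- sort(c(r@carbonMap[r@carbonMap[, 1] == k, 2],
                     r@lost[r@lost[, 1] == k, 2]))
      want <- seq_len(nC[[r@substrates[k]]])
      if (!identical(as.integer(used), as.integer(want)))
        msg <- c(msg, sprintf(
          "reaction %s: substrate %s carbons must each be mapped or lost exactly once",
          r@id, r@substrates[k]))
    }
  }

  internal <- p$id[p$role == "internal"]
  producers <- unlist(lapply(object@reactions, function(r) r@product))
  consumers <- unlist(lapply(object@reactions, function(r) r@substrates))
  for (pid in internal) {
    if (!pid %in% producers)
      msg <- c(msg, sprintf("internal pool %s has no producing reaction", pid))
    if (!pid %in% consumers)
      msg <- c(msg, sprintf("internal pool %s has no consuming reaction", pid))
  }

  nr <- length(object@reactions)
  if (!identical(dim(object@A), c(length(internal), nr)))
    msg <- c(msg, "balance matrix A must be (internal pools) x (reactions)")
  if (length(object@b) != nrow(object@A))
    msg <- c(msg, "b must have one entry per balance row")
  if (ncol(object@extraA) != nr && nrow(object@extraA) > 0)
    msg <- c(msg, "extra constraint rows must have one column per reaction")
  if (length(object@extraB) != nrow(object@extraA))
    msg <- c(msg, "extraB must have one entry per extra constraint row")
  bd <- object@bounds
  if (!identical(dim(bd), c(nr, 2L)))
    msg <- c(msg, "bounds must be a (reactions) x 2 matrix")
  else {
    if (any(!is.finite(bd)))
      msg <- c(msg, "flux bounds must be finite")
    if (any(bd[, 1] < 0))
      msg <- c(msg, "lower flux bounds must be non-negative")
    if (any(bd[, 1] > bd[, 2]))
      msg <- c(msg, sprintf("bounds with v_min > v_max for reaction(s): %s",
                            paste(rids[bd[, 1] > bd[, 2]], collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Build and validate a network model from a structured declaration
#'
#' Parses a YAML network configuration (text, file path, or an equivalent
#' nested list), expands reversible reactions into irreversible pairs,
#' assembles the steady-state balance matrix over internal pools plus any
#' declared extra equality constraints, and validates every structural
#' invariant (unique ids, complete carbon maps, produced-and-consumed
#' internal pools, ordered finite bounds). Pool and reaction order follows
#' declaration order, so the constraint system is deterministic.
#'
#' The schema (see the bundled `central_carbon.yaml` for a complete example):
#' \preformatted{
#' pools:
#'   - {id: GLC, carbons: 6, role: source, measured: false}
#' reactions:
#'   - id: r_glc
#'     substrates: [GLC]
#'     product: GAP
#'     carbon_map: [[1, 1], [1, 2], [1, 3]]   # product carbon k <- (substrate, carbon)
#'     lost: [[1, 4], [1, 5], [1, 6]]
#' bounds:
#'   default: [0, 200]
#' extra_constraints:
#'   - {reactions: [r_glc, r_frc], coefficients: [1, 1], rhs: 100}
#' }
#'
#' @param config a YAML string, a path to a YAML file, or a list with
#'   elements `pools`, `reactions` and optionally `bounds`,
#'   `extra_constraints`.
#' @return a validated [NetworkModel].
#' @examples
#' cfg <- "
#' pools:
#'   - {id: A, carbons: 3, role: source, measured: false}
#'   - {id: B, carbons: 3, role: internal, measured: true}
#'   - {id: C, carbons: 3, role: sink, measured: true}
#' reactions:
#'   - {id: r1, substrates: [A], product: B, carbon_map: [[1,1],[1,2],[1,3]]}
#'   - {id: r2, substrates: [B], product: C, carbon_map: [[1,1],[1,2],[1,3]]}
#' "
#' m <- buildNetwork(cfg)
#' assembleBalance(m)
#' @export
buildNetwork <- function(config) {
  cfg <- .readConfig(config)
  if (is.null(cfg$pools) || is.null(cfg$reactions))
    stop("network config must declare 'pools' and 'reactions'")

  pools <- do.call(rbind, lapply(cfg$pools, function(p) {
    data.frame(
      id = as.character(p$id),
      n_carbons = as.integer(p$carbons),
      role = as.character(p$role %||% "internal"),
      measured = isTRUE(p$measured),
      stringsAsFactors = FALSE
    )
  }))
  rownames(pools) <- NULL
  if (sum(pools$role == "source") < 1L)
    stop("network must declare at least one source pool")

  reactions <- list()
  for (rx in cfg$reactions) {
    r <- .parseReaction(rx)
    reactions <- c(reactions, list(r))
    if (isTRUE(rx$reversible)) {
      reactions <- c(reactions, list(.reverseReaction(r, pools)))
    }
  }
  if (length(reactions) < 1L) stop("network must declare at least one reaction")
  rids <- vapply(reactions, function(r) r@id, character(1))

  bounds <- .parseBounds(cfg$bounds, rids)
  ab <- .balanceSystem(pools, reactions)
  ex <- .extraConstraints(cfg$extra_constraints, rids)

  new("NetworkModel",
      pools = pools, reactions = reactions,
      A = ab$A, b = ab$b, extraA = ex$A, extraB = ex$b, bounds = bounds)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.readConfig <- function(config) {
  if (is.list(config)) return(config)
  stopifnot(is.character(config), length(config) == 1L)
  if (file.exists(config) && !grepl("\n", config)) {
    yaml::read_yaml(config)
  } else {
    yaml::yaml.load(config)
  }
}

.intPairs <- function(x, what) {
  if (is.null(x) || length(x) == 0)
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("substrate", "carbon"))))
  if (is.matrix(x)) {
    m <- x
  } else {
    bad <- !vapply(x, function(e) length(e) == 2L, logical(1))
    if (any(bad)) stop(sprintf("%s entries must be (substrate, carbon) pairs", what))
    m <- do.call(rbind, lapply(x, as.integer))
  }
  storage.mode(m) <- "integer"
  colnames(m) <- c("substrate", "carbon")
  m
}

.parseReaction <- function(rx) {
  new("Reaction",
      id = as.character(rx$id),
      substrates = as.character(unlist(rx$substrates)),
      product = as.character(rx$product),
      carbonMap = .intPairs(rx$carbon_map, sprintf("reaction %s carbon_map", rx$id)),
      lost = .intPairs(rx$lost, sprintf("reaction %s lost", rx$id)),
      reversible = isTRUE(rx$reversible))
}

## Reverse of a reversible step. Only loss-free single-substrate reactions
## (a bijective atom map) have a well-defined reverse.
.reverseReaction <- function(r, pools) {
  if (length(r@substrates) != 1L || nrow(r@lost) > 0L)
    stop(sprintf(
      "reaction %s: only single-substrate reactions without carbon loss can be reversible",
      r@id))
  inv <- r@carbonMap
  inv[, 2] <- order(r@carbonMap[, 2])
  ## product carbon j of the reverse comes from product carbon position of
  ## the forward reaction that consumed substrate carbon j
  m <- cbind(substrate = rep(1L, nrow(inv)),
             carbon = match(seq_len(nrow(inv)), r@carbonMap[, 2]))
  storage.mode(m) <- "integer"
  new("Reaction",
      id = paste0(r@id, "_rev"),
      substrates = r@product,
      product = r@substrates,
      carbonMap = m,
      lost = .intPairs(NULL, "lost"),
      reversible = TRUE)
}

.parseBounds <- function(bcfg, rids) {
  def <- c(0, 1000)
  if (!is.null(bcfg$default)) def <- as.numeric(unlist(bcfg$default))
  b <- matrix(rep(def, each = length(rids)), ncol = 2,
              dimnames = list(rids, c("lower", "upper")))
  for (nm in setdiff(names(bcfg), "default")) {
    if (!nm %in% rids) stop(sprintf("bounds given for unknown reaction: %s", nm))
    b[nm, ] <- as.numeric(unlist(bcfg[[nm]]))
  }
  b
}

.balanceSystem <- function(pools, reactions) {
  internal <- pools$id[pools$role == "internal"]
  rids <- vapply(reactions, function(r) r@id, character(1))
  A <- matrix(0, nrow = length(internal), ncol = length(reactions),
              dimnames = list(internal, rids))
  for (j in seq_along(reactions)) {
    r <- reactions[[j]]
    if (r@product %in% internal) A[r@product, j] <- A[r@product, j] + 1
    for (s in r@substrates)
      if (s %in% internal) A[s, j] <- A[s, j] - 1
  }
  list(A = A, b = rep(0, length(internal)))
}

.extraConstraints <- function(ecfg, rids) {
  if (is.null(ecfg) || length(ecfg) == 0)
    return(list(A = matrix(numeric(0), nrow = 0, ncol = length(rids),
                           dimnames = list(NULL, rids)),
                b = numeric(0)))
  A <- matrix(0, nrow = length(ecfg), ncol = length(rids),
              dimnames = list(NULL, rids))
  b <- numeric(length(ecfg))
  for (i in seq_along(ecfg)) {
    e <- ecfg[[i]]
    rs <- as.character(unlist(e$reactions))
    co <- as.numeric(unlist(e$coefficients %||% rep(1, length(rs))))
    bad <- setdiff(rs, rids)
    if (length(bad))
      stop(sprintf("extra constraint references unknown reaction(s): %s",
                   paste(bad, collapse = ", ")))
    A[i, rs] <- co
    b[i] <- as.numeric(e$rhs)
  }
  list(A = A, b = b)
}

#' Serialize a network model back to its YAML declaration
#'
#' Round-trips with [buildNetwork()]: re-parsing the emitted text yields a
#' model with identical pools, carbon maps, balance matrix and bounds.
#' Reactions generated by expansion of `reversible: true` declarations are
#' re-collapsed into their declared form.
#'
#' @param model a [NetworkModel].
#' @param path optional file path; when `NULL` the YAML text is returned.
#' @return the YAML text (invisibly, when written to `path`).
#' @export
writeNetworkConfig <- function(model, path = NULL) {
  pools <- lapply(seq_len(nrow(model@pools)), function(i) {
    p <- model@pools[i, ]
    list(id = p$id, carbons = p$n_carbons, role = p$role, measured = p$measured)
  })
  keep <- vapply(model@reactions, function(r) !grepl("_rev$", r@id) || !r@reversible,
                 logical(1))
  reactions <- lapply(model@reactions[keep], function(r) {
    out <- list(
      id = r@id,
      substrates = as.list(r@substrates),
      product = r@product,
      carbon_map = lapply(seq_len(nrow(r@carbonMap)),
                          function(i) as.list(as.integer(r@carbonMap[i, ])))
    )
    if (nrow(r@lost) > 0)
      out$lost <- lapply(seq_len(nrow(r@lost)),
                         function(i) as.list(as.integer(r@lost[i, ])))
    if (r@reversible) out$reversible <- TRUE
    out
  })
  bounds <- list()
  for (i in seq_len(nrow(model@bounds)))
    bounds[[rownames(model@bounds)[i]]] <- as.list(as.numeric(model@bounds[i, ]))
  extras <- NULL
  if (nrow(model@extraA) > 0) {
    extras <- lapply(seq_len(nrow(model@extraA)), function(i) {
      nz <- which(model@extraA[i, ] != 0)
      list(reactions = as.list(colnames(model@extraA)[nz]),
           coefficients = as.list(as.numeric(model@extraA[i, nz])),
           rhs = model@extraB[i])
    })
  }
  cfg <- list(pools = pools, reactions = reactions, bounds = bounds)
  if (!is.null(extras)) cfg$extra_constraints <- extras
  txt <- yaml::as.yaml(cfg)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Assemble the flux-balance constraint system A v = b
#'
#' Entry (p, r) of `A` is +1 if reaction `r` produces internal pool `p`,
#' -1 if it consumes it, and 0 otherwise; `b` is all zeros (strict steady
#' state). With `constraints = "all"` any extra equality rows declared in
#' the config (e.g. a fixed total uptake) are appended, which is the system
#' the fitting stage enforces.
#'
#' @param model a [NetworkModel].
#' @param constraints `"balance"` for the steady-state rows only (default),
#'   `"all"` to append the extra equality rows.
#' @return `list(A = matrix, b = numeric)`.
#' @export
assembleBalance <- function(model, constraints = c("balance", "all")) {
  constraints <- match.arg(constraints)
  if (constraints == "all")
    list(A = rbind(model@A, model@extraA), b = c(model@b, model@extraB))
  else
    list(A = model@A, b = model@b)
}

#' Infinity-norm residual of the equality constraints at a flux vector
#'
#' @param model a [NetworkModel].
#' @param v numeric flux vector, one entry per reaction (model order; a
#'   named vector is reordered by reaction id).
#' @param constraints which equality rows to include; `"all"` (default)
#'   covers the steady-state balance and any extra declared constraints.
#' @return max absolute violation, a non-negative scalar.
#' @export
balanceResidual <- function(model, v, constraints = c("all", "balance")) {
  constraints <- match.arg(constraints)
  v <- .orderFluxes(model, v)
  sys <- assembleBalance(model, if (constraints == "all") "all" else "balance")
  if (nrow(sys$A) == 0) return(0)
  max(abs(as.numeric(sys$A %*% v) - sys$b))
}

.orderFluxes <- function(model, v) {
  rids <- reactionIds(model)
  if (length(v) != length(rids))
    stop(sprintf("flux vector has %d entries but the model has %d reactions",
                 length(v), length(rids)))
  if (!is.null(names(v))) {
    if (!setequal(names(v), rids))
      stop("flux vector names do not match the model's reaction ids")
    v <- v[rids]
  }
  unname(v)
}

#' Validate a flux vector against a model
#'
#' Checks bounds element-wise and the equality-constraint residual against
#' `tol` (infinity norm).
#'
#' @param model a [NetworkModel].
#' @param v flux vector.
#' @param tol balance tolerance (default `1e-6`).
#' @return `TRUE` invisibly; otherwise an error describing the violation.
#' @export
validateFluxVector <- function(model, v, tol = 1e-6) {
  v <- .orderFluxes(model, v)
  bd <- model@bounds
  if (any(v < bd[, 1]) || any(v > bd[, 2]))
    stop("flux vector violates bounds for reaction(s): ",
         paste(rownames(bd)[v < bd[, 1] | v > bd[, 2]], collapse = ", "))
  r <- balanceResidual(model, v)
  if (r > tol)
    stop(sprintf("flux vector violates balance constraints (residual %.3g > %.3g)",
                 r, tol))
  invisible(TRUE)
}
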