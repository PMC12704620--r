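## The inverse problem: constrained least-squares fitting of fluxes to
## measured MIDs, repeated from random starts, with best-of-restarts
## selection.

#' Total sum-of-squared-error between predicted and observed MIDs
#'
#' For every measured metabolite i, `L_i = sum_j (pred_ij - obs_ij)^2`
#' where `pred` comes from [predictMids()] at the candidate fluxes;
#' `L_total` is the sum of `L_i` over all measured (target) metabolites.
#' Which metabolites enter the loss is decided by the model's `measured`
#' flags intersected with the metabolites present in `ms`.
#'
#' @param model a [NetworkModel].
#' @param v candidate flux vector.
#' @param ms a [MeasurementSet] of observed, replicate-averaged MIDs.
#' @param tracer a [TracerSpec].
#' @param tol,maxit fixed-point controls passed to the label propagation.
#' @return non-negative scalar.
#' @export
totalLoss <- function(model, v, ms, tracer, tol = 1e-12, maxit = 20000L) {
  ctx <- .fitContext(model, ms, tracer, tol = tol, maxit = maxit)
  v <- .orderFluxes(model, v)
  .c_total_loss(ctx$plan, as.numeric(v), ctx$obs_pool, ctx$obs_mids,
                tol, as.integer(maxit), 1.0)
}

## Precompute everything shared across restarts: the compiled propagation
## plan, the observed-MID index, the equality system, a null-space
## parameterization v = v_p + N z, and a strictly interior reference point.
.fitContext <- function(model, ms, tracer, tol = 1e-12, maxit = 20000L) {
  plan <- .compilePlan(model, tracer)
  mets <- intersect(measuredPools(model), names(ms@mids))
  missing <- setdiff(names(ms@mids), poolIds(model))
  if (length(missing))
    stop(sprintf("measured metabolite(s) missing from the model: %s",
                 paste(missing, collapse = ", ")))
  if (!length(mets)) stop("no measured metabolites in common with the model")
  nC <- nCarbons(model)
  for (m in mets) {
    if (length(ms@mids[[m]]) != nC[match(m, poolIds(model))] + 1L)
      stop(sprintf("observed MID for %s has the wrong number of mass levels", m))
  }
  sys <- assembleBalance(model, "all")
  nr <- length(model@reactions)
  lb <- model@bounds[, 1]
  ub <- model@bounds[, 2]

  if (nrow(sys$A) == 0) {
    N <- diag(nr)
    vp <- rep(0, nr)
  } else {
    s <- svd(sys$A, nu = nrow(sys$A), nv = ncol(sys$A))
    rtol <- max(dim(sys$A)) * max(s$d) * .Machine$double.eps
    rank <- sum(s$d > rtol)
    if (rank == ncol(sys$A))
      stop("equality constraints leave no free flux directions")
    N <- s$v[, (rank + 1L):ncol(sys$A), drop = FALSE]
    ## minimum-norm particular solution
    dinv <- ifelse(s$d > rtol, 1 / s$d, 0)
    vp <- as.numeric(s$v[, seq_len(length(s$d)), drop = FALSE] %*%
                       (dinv * (t(s$u) %*% sys$b)))
  }

  ctx <- list(model = model, plan = plan, cplan = .c_compile_plan(plan),
              tracer = tracer,
              obs_pool = match(mets, plan$pool_ids) - 1L,
              obs_mids = unname(ms@mids[mets]),
              A = sys$A, b = sys$b, N = N, vp = vp, lb = lb, ub = ub,
              tol = tol, maxit = as.integer(maxit))
  ctx$center <- .interiorPoint(ctx)
  ctx
}

## Phase-1: a strictly interior feasible point, found by minimizing squared
## box violations (plus a pull toward the box center) over the equality
## null space.
.interiorPoint <- function(ctx) {
  margin <- 0.05 * (ctx$ub - ctx$lb)
  lo <- ctx$lb + margin
  hi <- ctx$ub - margin
  pen <- function(z) {
    v <- ctx$vp + as.numeric(ctx$N %*% z)
    sum(pmax(lo - v, 0)^2 + pmax(v - hi, 0)^2)
  }
  gpen <- function(z) {
    v <- ctx$vp + as.numeric(ctx$N %*% z)
    g <- -2 * pmax(lo - v, 0) + 2 * pmax(v - hi, 0)
    as.numeric(crossprod(ctx$N, g))
  }
  z0 <- as.numeric(crossprod(ctx$N, (ctx$lb + ctx$ub) / 2 - ctx$vp))
  opt <- optim(z0, pen, gpen, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  v <- ctx$vp + as.numeric(ctx$N %*% opt$par)
  if (any(v < ctx$lb) || any(v > ctx$ub))
    stop("could not find a feasible interior flux vector; check bounds and constraints")
  v
}

## Draw a random start: uniform within the box, least-squares projected
## onto the equality affine set; if the projection leaves the box, retry,
## then blend toward the interior reference point.
.randomStart <- function(ctx, margin_frac = 1e-6) {
  eps <- margin_frac * (ctx$ub - ctx$lb)
  for (try in 1:10) {
    vu <- runif(length(ctx$lb), ctx$lb, ctx$ub)
    z <- as.numeric(crossprod(ctx$N, vu - ctx$vp))
    v <- ctx$vp + as.numeric(ctx$N %*% z)
    if (all(v >= ctx$lb + eps) && all(v <= ctx$ub - eps)) return(v)
  }
  for (alpha in seq(0.1, 1, by = 0.1)) {
    vb <- (1 - alpha) * v + alpha * ctx$center
    if (all(vb >= ctx$lb + eps) && all(vb <= ctx$ub - eps)) return(vb)
  }
  ctx$center
}

.residFun <- function(ctx) {
  force(ctx)
  function(z) {
    v <- ctx$vp + as.numeric(ctx$N %*% z)
    .c_residuals(ctx$cplan, v, ctx$obs_pool, ctx$obs_mids, ctx$tol, ctx$maxit)
  }
}

## Constrained nonlinear least squares on the equality null space:
## Levenberg-Marquardt with a finite-difference Jacobian; trial steps that
## would leave the flux box are backtracked (halved) so every iterate is
## feasible. Equality constraints hold to numerical precision through the
## v = vp + N z parameterization.
.lmFit <- function(ctx, z0, maxit = 200L, ftol = 1e-12, gtol = 1e-10) {
  rf <- .residFun(ctx)
  d <- length(z0)
  inBox <- function(z) {
    v <- ctx$vp + as.numeric(ctx$N %*% z)
    all(v >= ctx$lb) && all(v <= ctx$ub)
  }
  z <- z0
  r <- rf(z)
  L <- sum(r * r)
  lambda <- 1e-3
  conv <- FALSE
  for (it in seq_len(maxit)) {
    J <- matrix(0, nrow = length(r), ncol = d)
    for (j in seq_len(d)) {
      h <- 1e-6 * (1 + abs(z[j]))
      zp <- z; zp[j] <- z[j] + h
      zm <- z; zm[j] <- z[j] - h
      J[, j] <- (rf(zp) - rf(zm)) / (2 * h)
    }
    g <- as.numeric(crossprod(J, r))
    if (max(abs(g)) < gtol * (1 + L)) { conv <- TRUE; break }
    JtJ <- crossprod(J)
    dscale <- pmax(diag(JtJ), 1e-12)
    improved <- FALSE
    for (try in 1:25) {
      step <- tryCatch(
        -solve(JtJ + lambda * diag(dscale, d), g),
        error = function(e) NULL)
      if (!is.null(step)) {
        znew <- z + step
        halved <- 0
        while (!inBox(znew) && halved < 40) {
          step <- step / 2
          znew <- z + step
          halved <- halved + 1
        }
        if (inBox(znew)) {
          rnew <- rf(znew)
          Lnew <- sum(rnew * rnew)
          if (Lnew < L) {
            if (L - Lnew < ftol * (1 + L)) conv <- TRUE
            z <- znew; r <- rnew; L <- Lnew
            lambda <- max(lambda / 3, 1e-12)
            improved <- TRUE
            break
          }
        }
      }
      lambda <- lambda * 5
      if (lambda > 1e12) break
    }
    if (!improved) {
      ## stalled: accept as converged only if the gradient is essentially flat
      conv <- max(abs(g)) < 1e-6 * (1 + L)
      break
    }
    if (conv) break
  }
  list(z = z, loss = L, converged = conv)
}

.fitOne <- function(ctx, seed) {
  v0 <- .withSeed(seed, .randomStart(ctx))
  z0 <- as.numeric(crossprod(ctx$N, v0 - ctx$vp))
  f0 <- sum(.residFun(ctx)(z0)^2)

  res <- tryCatch(.lmFit(ctx, z0), error = function(e) NULL)
  if (is.null(res)) {
    v <- v0; L <- f0; conv <- FALSE
  } else {
    v <- ctx$vp + as.numeric(ctx$N %*% res$z)
    L <- res$loss
    conv <- res$converged
    if (L > f0) { v <- v0; L <- f0 }  # never worse than the feasible start
  }
  resid <- if (nrow(ctx$A)) max(abs(as.numeric(ctx$A %*% v) - ctx$b)) else 0
  new("FitResult",
      fluxes = setNames(v, reactionIds(ctx$model)),
      loss = L, seed = as.integer(seed),
      converged = isTRUE(conv) && resid <= 1e-6,
      residual = resid)
}

#' One constrained local fit from a random start
#'
#' Draws a start uniformly within the flux bounds, projects it onto the
#' equality-constraint affine set (retrying, then blending toward a strictly
#' interior point, if the projection leaves the box), and runs a
#' gradient-based constrained nonlinear least-squares optimizer:
#' Levenberg-Marquardt on `L_total` restricted to the constraint null
#' space, with finite-difference Jacobians, and trial steps backtracked so
#' every iterate respects the flux bounds. Equality constraints hold to
#' numerical precision by construction of the null-space parameterization.
#'
#' Optimizer failure is reported as `converged = FALSE`, never raised.
#' Repeated calls with the same seed are bit-identical.
#'
#' @param model a [NetworkModel].
#' @param ms observed [MeasurementSet].
#' @param tracer a [TracerSpec].
#' @param seed integer restart seed.
#' @return a [FitResult].
#' @export
fitSingle <- function(model, ms, tracer, seed = 1L) {
  ctx <- .fitContext(model, ms, tracer)
  .fitOne(ctx, seed)
}

#' Multi-start ensemble fitting with best-of-restarts selection
#'
#' Repeats the constrained local optimization from `n_restarts` independent
#' random starts (restart r uses seed `base_seed + r - 1`) and retains the
#' `keep` converged solutions with the lowest `L_total`, sorted ascending.
#' The defaults (10,000 restarts, keep 50) reproduce the full published
#' procedure; `profile = "desk"` switches to 200/20, a scale suited to
#' interactive work and continuous testing, and documented as such.
#'
#' When fewer than `keep` restarts converge, all converged results are
#' returned and the `shortfall` flag is set (with a warning).
#'
#' @param model a [NetworkModel].
#' @param ms observed [MeasurementSet].
#' @param tracer a [TracerSpec].
#' @param n_restarts number of restarts (`>= keep`).
#' @param keep number of lowest-loss solutions to retain.
#' @param base_seed integer; restart seeds are `base_seed .. base_seed +
#'   n_restarts - 1`.
#' @param profile `"paper"` (10,000/50, the default) or `"desk"` (200/20);
#'   explicit `n_restarts`/`keep` override the profile.
#' @return an [EnsembleSolution].
#' @seealso [summarizeEnsemble()], [compareConditions()]
#' @export
fitEnsemble <- function(model, ms, tracer, n_restarts = NULL, keep = NULL,
                        base_seed = 1L, profile = c("paper", "desk")) {
  profile <- match.arg(profile)
  defaults <- if (profile == "paper") c(10000L, 50L) else c(200L, 20L)
  if (is.null(n_restarts)) n_restarts <- defaults[1]
  if (is.null(keep)) keep <- defaults[2]
  n_restarts <- as.integer(n_restarts)
  keep <- as.integer(keep)
  if (keep < 1L) stop("keep must be at least 1")
  if (n_restarts < keep) stop("n_restarts must be at least keep")

  ctx <- .fitContext(model, ms, tracer)
  seeds <- base_seed + seq_len(n_restarts) - 1L
  fits <- lapply(seeds, function(s) .fitOne(ctx, s))

  loss_all <- vapply(fits, function(f) f@loss, numeric(1))
  conv_all <- vapply(fits, function(f) f@converged, logical(1))
  trace <- data.frame(restart = seq_len(n_restarts), seed = as.integer(seeds),
                      L_total = loss_all, converged = conv_all)

  idx <- which(conv_all)
  shortfall <- length(idx) < keep
  if (shortfall)
    warning(sprintf("only %d of %d restarts converged (requested keep = %d)",
                    length(idx), n_restarts, keep))
  sel <- idx[order(loss_all[idx])][seq_len(min(keep, length(idx)))]
  flux <- do.call(rbind, lapply(fits[sel], function(f) unname(f@fluxes)))
  if (is.null(flux)) flux <- matrix(numeric(0), nrow = 0,
                                    ncol = length(reactionIds(model)))
  colnames(flux) <- reactionIds(model)

  new("EnsembleSolution",
      fluxes = flux,
      losses = loss_all[sel],
      seeds = as.integer(seeds[sel]),
      residuals = vapply(fits[sel], function(f) f@residual, numeric(1)),
      nRestarts = n_restarts, keep = keep,
      shortfall = shortfall, trace = trace)
}

setValidity("EnsembleSolution", function(object) {
  msg <- character()
  if (length(object@losses) && is.unsorted(object@losses))
    msg <- c(msg, "retained losses must be non-decreasing")
  if (nrow(object@fluxes) != length(object@losses))
    msg <- c(msg, "one flux row per retained loss required")
  if (length(msg)) msg else TRUE
})

#' Per-flux summary of a retained ensemble
#'
#' The reported flux value for each reaction is the arithmetic mean across
#' the retained lowest-loss solutions; the spread across the ensemble
#' (sample standard deviation) measures how well the data pin that flux
#' down.
#'
#' @param ens an [EnsembleSolution].
#' @return data.frame with columns `reaction`, `mean_flux`, `sd_flux`,
#'   `n_retained`, `min_loss`, in model reaction order.
#' @export
summarizeEnsemble <- function(ens) {
  if (!nrow(ens@fluxes)) stop("empty ensemble")
  data.frame(
    reaction = colnames(ens@fluxes),
    mean_flux = unname(colMeans(ens@fluxes)),
    sd_flux = unname(apply(ens@fluxes, 2, sd)),
    n_retained = nrow(ens@fluxes),
    min_loss = min(ens@losses),
    stringsAsFactors = FALSE)
}

#' Cross-condition flux comparison by unpaired two-tailed t-tests
#'
#' Treats the retained ensemble solutions of each condition as the
#' replicate values of every flux and applies an unpaired two-tailed t-test
#' per reaction (Welch by default). Raw p-values are primary; a
#' Benjamini-Hochberg-adjusted column is included. Note this tests the
#' spread of the fitted solution sets, an interpretation of how published
#' tracing studies attach significance stars to flux bars, not a claim of
#' biological replication.
#'
#' Degenerate variance (both ensembles constant for a flux, as happens with
#' noiseless data) is handled by a documented rule instead of a crash:
#' equal constants give `t = 0, p = 1`; different constants give
#' `t = +/-Inf, p = 0`, flagged in the `degenerate` column.
#'
#' @param ens_a,ens_b [EnsembleSolution] objects fitted on the same model.
#' @param var_equal use the pooled-variance (Student) form instead of Welch.
#' @return data.frame with columns `reaction`, `mean_a`, `mean_b`, `t`,
#'   `p`, `p_adj`, `degenerate`.
#' @export
compareConditions <- function(ens_a, ens_b, var_equal = FALSE) {
  if (!identical(colnames(ens_a@fluxes), colnames(ens_b@fluxes)))
    stop("ensembles were fitted on different reaction sets")
  rids <- colnames(ens_a@fluxes)
  out <- lapply(rids, function(r) {
    a <- ens_a@fluxes[, r]
    b <- ens_b@fluxes[, r]
    if (sd(a) == 0 && sd(b) == 0) {
      same <- isTRUE(all.equal(mean(a), mean(b)))
      data.frame(reaction = r, mean_a = mean(a), mean_b = mean(b),
                 t = if (same) 0 else sign(mean(a) - mean(b)) * Inf,
                 p = if (same) 1 else 0,
                 degenerate = TRUE, stringsAsFactors = FALSE)
    } else {
      tt <- t.test(a, b, var.equal = var_equal)
      data.frame(reaction = r, mean_a = mean(a), mean_b = mean(b),
                 t = unname(tt$statistic), p = tt$p.value,
                 degenerate = FALSE, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, out)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out[, c("reaction", "mean_a", "mean_b", "t", "p", "p_adj", "degenerate")]
}

#' Linearized identifiability analysis of a flux scenario
#'
#' Numerically differentiates the stacked measured MIDs with respect to the
#' free flux directions (the equality-constraint null space) at a reference
#' flux vector, and propagates an assumed per-mass-level measurement noise
#' through the Gauss-Newton covariance `sigma^2 (J'J)^-1` back to flux
#' space. The returned predicted standard deviations classify which fluxes
#' the experiment can determine: a flux whose predicted relative sd is
#' large sits on a poorly constrained direction of the model.
#'
#' @param model a [NetworkModel].
#' @param v reference flux vector.
#' @param tracer a [TracerSpec].
#' @param sigma assumed per-mass-level noise sd on the averaged MIDs.
#' @param h finite-difference step on the free coordinates.
#' @return data.frame with columns `reaction`, `flux`, `pred_sd`,
#'   `rel_sd`.
#' @export
fluxIdentifiability <- function(model, v, tracer, sigma = 0.01, h = 1e-4) {
  v <- .orderFluxes(model, v)
  sys <- assembleBalance(model, "all")
  s <- svd(sys$A, nv = ncol(sys$A))
  rtol <- max(dim(sys$A)) * max(s$d) * .Machine$double.eps
  rank <- sum(s$d > rtol)
  N <- s$v[, (rank + 1L):ncol(sys$A), drop = FALSE]
  mets <- measuredPools(model)
  stack <- function(vv) {
    pred <- predictMids(model, vv, tracer)
    unlist(pred[mets], use.names = FALSE)
  }
  J <- matrix(0, nrow = length(stack(v)), ncol = ncol(N))
  for (j in seq_len(ncol(N))) {
    J[, j] <- (stack(v + h * N[, j]) - stack(v - h * N[, j])) / (2 * h)
  }
  covz <- tryCatch(sigma^2 * solve(crossprod(J)), error = function(e) {
    sigma^2 * pracma::pinv(crossprod(J))
  })
  covv <- N %*% covz %*% t(N)
  sdv <- sqrt(pmax(diag(covv), 0))
  data.frame(reaction = reactionIds(model), flux = v, pred_sd = sdv,
             rel_sd = ifelse(v > 0, sdv / v, Inf),
             stringsAsFactors = FALSE)
}
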