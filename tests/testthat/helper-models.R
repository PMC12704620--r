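# Small models and independent oracles shared across tests.

# linear chain: A (3C source, tracer) -> B -> C, identity carbon maps
chainConfig <- function(sink_c = TRUE) {
  sprintf("
pools:
  - {id: A, carbons: 3, role: source, measured: false}
  - {id: B, carbons: 3, role: internal, measured: true}
  - {id: C, carbons: 3, role: %s, measured: true}
reactions:
  - {id: r1, substrates: [A], product: B, carbon_map: [[1,1],[1,2],[1,3]]}
  - {id: r2, substrates: [B], product: C, carbon_map: [[1,1],[1,2],[1,3]]}
bounds:
  default: [0, 10]
", if (sink_c) "sink" else "internal")
}

chainModel <- function(sink_c = TRUE) buildNetwork(chainConfig(sink_c))

# two independent 1-carbon mixing nodes, each fed by an unlabeled (U) and a
# fully labeled (L) source with total inflow pinned at 1: exactly two free,
# fully identifiable flux directions (rB and rE)
mixingModel <- function() {
  buildNetwork("
pools:
  - {id: U,  carbons: 1, role: source, measured: false}
  - {id: L,  carbons: 1, role: source, measured: false}
  - {id: M1, carbons: 1, role: internal, measured: true}
  - {id: M2, carbons: 1, role: internal, measured: true}
  - {id: S1, carbons: 1, role: sink, measured: false}
  - {id: S2, carbons: 1, role: sink, measured: false}
reactions:
  - {id: rA, substrates: [U], product: M1, carbon_map: [[1,1]]}
  - {id: rB, substrates: [L], product: M1, carbon_map: [[1,1]]}
  - {id: rC, substrates: [M1], product: S1, carbon_map: [[1,1]]}
  - {id: rD, substrates: [U], product: M2, carbon_map: [[1,1]]}
  - {id: rE, substrates: [L], product: M2, carbon_map: [[1,1]]}
  - {id: rF, substrates: [M2], product: S2, carbon_map: [[1,1]]}
bounds:
  default: [0, 2]
extra_constraints:
  - {reactions: [rA, rB], coefficients: [1, 1], rhs: 1}
  - {reactions: [rD, rE], coefficients: [1, 1], rhs: 1}
")
}

# minimal cyclic network: label enters B and recycles through C
loopModel <- function() {
  buildNetwork("
pools:
  - {id: A, carbons: 2, role: source, measured: false}
  - {id: B, carbons: 2, role: internal, measured: true}
  - {id: C, carbons: 2, role: internal, measured: true}
  - {id: D, carbons: 2, role: sink, measured: false}
reactions:
  - {id: rin,  substrates: [A], product: B, carbon_map: [[1,1],[1,2]]}
  - {id: rbc,  substrates: [B], product: C, carbon_map: [[1,1],[1,2]]}
  - {id: rcb,  substrates: [C], product: B, carbon_map: [[1,1],[1,2]]}
  - {id: rout, substrates: [C], product: D, carbon_map: [[1,1],[1,2]]}
bounds:
  default: [0, 100]
")
}

# brute-force convolution: enumerate all isotopologue pairings
bruteConvolve <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      out[i + j - 1L] <- out[i + j - 1L] + a[i] * b[j]
    }
  }
  out
}

# brute-force carbon-loss marginalization: enumerate every subset of kept
# carbon positions and every placement of the m labels (positions
# exchangeable), count labels retained
bruteMarginalize <- function(x, n_keep) {
  n <- length(x) - 1L
  out <- numeric(n_keep + 1L)
  keep_sets <- utils::combn(n, n_keep, simplify = FALSE)
  for (m in 0:n) {
    if (x[m + 1L] == 0) next
    lab_sets <- if (m == 0) list(integer(0)) else
      utils::combn(n, m, simplify = FALSE)
    for (ks in keep_sets) {
      for (ls in lab_sets) {
        j <- length(intersect(ks, ls))
        out[j + 1L] <- out[j + 1L] +
          x[m + 1L] / (length(keep_sets) * length(lab_sets))
      }
    }
  }
  out
}

# independent long-run Jacobi sweep in plain R, built directly from the
# model's reaction slots (uses the separately verified MID primitives)
jacobiOracle <- function(model, v, tracer, sweeps = 10000) {
  p <- pools(model)
  nC <- stats::setNames(p$n_carbons, p$id)
  v <- stats::setNames(as.numeric(v), reactionIds(model))
  mids <- list()
  for (i in seq_len(nrow(p))) {
    mid <- c(1, rep(0, p$n_carbons[i]))
    if (p$role[i] == "source" && p$id[i] == tracer@pool) {
      lvl <- if (is.na(tracer@isotopologue)) p$n_carbons[i] else tracer@isotopologue
      mid <- (1 - tracer@purity) * mid
      mid[lvl + 1] <- mid[lvl + 1] + tracer@purity
    }
    mids[[p$id[i]]] <- mid
  }
  nonsource <- p$id[p$role != "source"]
  for (s in seq_len(sweeps)) {
    num <- lapply(stats::setNames(nonsource, nonsource),
                  function(id) rep(0, nC[[id]] + 1))
    den <- stats::setNames(rep(0, length(nonsource)), nonsource)
    for (r in reactions(model)) {
      if (!r@product %in% nonsource) next
      contrib <- 1
      for (k in seq_along(r@substrates)) {
        x <- mids[[r@substrates[k]]]
        n_keep <- sum(r@carbonMap[, 1] == k)
        y <- if (n_keep == length(x) - 1L) x
             else if (n_keep == 0) 1
             else marginalizeCarbons(x, n_keep)
        contrib <- bruteConvolve(contrib, y)
      }
      num[[r@product]] <- num[[r@product]] + v[[r@id]] * contrib
      den[[r@product]] <- den[[r@product]] + v[[r@id]]
    }
    for (id in nonsource) mids[[id]] <- num[[id]] / den[[id]]
  }
  mids
}

# reference scenario, loaded once per test file
ccScenario <- function() centralCarbonNetwork()

noiselessMeasurements <- function(sc = ccScenario()) {
  generateExperiment(sc$model, sc$fluxes, sc$tracer, sigma = 0,
                     n_replicates = 1L, seed = 1L)@measurements
}

randomMid <- function(n) {
  x <- stats::runif(n + 1)
  x / sum(x)
}
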