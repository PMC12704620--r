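test_that("a linear chain builds with the expected balance structure", {
  m <- chainModel(sink_c = TRUE)
  expect_s4_class(m, "NetworkModel")
  expect_equal(length(reactions(m)), 2L)
  sys <- assembleBalance(m)
  # C declared sink -> only B is balanced
  expect_equal(dim(sys$A), c(1L, 2L))
  expect_equal(unname(sys$A["B", ]), c(1, -1))
  expect_equal(sys$b, 0)
})

test_that("an internal pool without a consumer is rejected", {
  expect_error(chainModel(sink_c = FALSE), "no consuming reaction")
})

test_that("carbon-map arity mismatches are rejected", {
  cfg <- "
pools:
  - {id: A, carbons: 3, role: source, measured: false}
  - {id: B, carbons: 2, role: sink, measured: true}
reactions:
  - {id: r1, substrates: [A], product: B, carbon_map: [[1,1],[1,2]]}
"
  # carbon 3 of A neither mapped nor lost
  expect_error(buildNetwork(cfg), "mapped or lost")
  ok <- sub("carbon_map: \\[\\[1,1\\],\\[1,2\\]\\]",
            "carbon_map: [[1,1],[1,2]], lost: [[1,3]]", cfg)
  expect_s4_class(buildNetwork(ok), "NetworkModel")
})

test_that("duplicate ids and inverted bounds are rejected", {
  dup <- "
pools:
  - {id: A, carbons: 1, role: source, measured: false}
  - {id: A, carbons: 1, role: sink, measured: false}
reactions:
  - {id: r1, substrates: [A], product: A, carbon_map: [[1,1]]}
"
  expect_error(buildNetwork(dup), "duplicate pool id")
  bad_bounds <- paste0(chainConfig(), "  r1: [5, 2]\n")
  expect_error(buildNetwork(bad_bounds), "v_min > v_max")
})

test_that("a 3-pool cycle yields rows summing to zero", {
  cfg <- "
pools:
  - {id: S, carbons: 1, role: source, measured: false}
  - {id: X, carbons: 1, role: internal, measured: true}
  - {id: Y, carbons: 1, role: internal, measured: true}
  - {id: Z, carbons: 1, role: internal, measured: true}
  - {id: W, carbons: 1, role: sink, measured: false}
reactions:
  - {id: rin, substrates: [S], product: X, carbon_map: [[1,1]]}
  - {id: rxy, substrates: [X], product: Y, carbon_map: [[1,1]]}
  - {id: ryz, substrates: [Y], product: Z, carbon_map: [[1,1]]}
  - {id: rzx, substrates: [Z], product: X, carbon_map: [[1,1]]}
  - {id: rout, substrates: [X], product: W, carbon_map: [[1,1]]}
"
  m <- buildNetwork(cfg)
  sys <- assembleBalance(m)
  expect_equal(dim(sys$A), c(3L, 5L))
  # pure-cycle columns (no source/sink involvement) sum to zero
  expect_equal(unname(colSums(sys$A[, c("rxy", "ryz", "rzx")])), rep(0, 3))
})

test_that("an extra efflux adds a -1 consumption entry to its pool row", {
  base <- chainConfig(sink_c = TRUE)
  extended <- sub("bounds:",
                  "  - {id: r3, substrates: [B], product: C, carbon_map: [[1,1],[1,2],[1,3]]}\nbounds:",
                  base, fixed = TRUE)
  m <- buildNetwork(extended)
  sys <- assembleBalance(m)
  expect_equal(unname(sys$A["B", "r3"]), -1)
})

test_that("balance residual matches an independent matrix product", {
  m <- chainModel()
  expect_equal(balanceResidual(m, c(2, 2)), 0)
  expect_equal(balanceResidual(m, c(2, 1)), 1)

  sc <- ccScenario()
  sys <- assembleBalance(sc$model, "all")
  v <- sc$fluxes
  # independent double loop
  res <- 0
  for (i in seq_len(nrow(sys$A))) {
    acc <- -sys$b[i]
    for (j in seq_len(ncol(sys$A))) acc <- acc + sys$A[i, j] * v[[j]]
    res <- max(res, abs(acc))
  }
  expect_equal(balanceResidual(sc$model, v), res)
  expect_equal(res, 0)
})

test_that("columns of A correspond 1:1, in order, to the reactions", {
  sc <- ccScenario()
  m <- sc$model
  sys <- assembleBalance(m)
  expect_identical(colnames(sys$A), reactionIds(m))
  # reconstruct A with an independent loop over reaction slots
  internal <- pools(m)$id[pools(m)$role == "internal"]
  A2 <- matrix(0, length(internal), length(reactions(m)),
               dimnames = list(internal, reactionIds(m)))
  for (r in reactions(m)) {
    if (r@product %in% internal) A2[r@product, r@id] <- A2[r@product, r@id] + 1
    for (s in r@substrates)
      if (s %in% internal) A2[s, r@id] <- A2[s, r@id] - 1
  }
  expect_equal(sys$A, A2)
})

test_that("the bundled fixture loads, is connected, and round-trips", {
  sc <- ccScenario()
  m <- sc$model
  expect_setequal(
    poolIds(m),
    c("GLC", "FRC", "CO2", "SERX", "ACE", "GAP", "3PG", "PEP", "PYR", "SER",
      "ACCOA", "CIT", "AKG", "SUC", "MAL", "OAC", "LAC", "GLY"))
  # connectivity: every pool reachable from some source via reactions
  edges <- do.call(rbind, lapply(reactions(m), function(r)
    cbind(r@substrates, r@product)))
  reach <- pools(m)$id[pools(m)$role == "source"]
  repeat {
    nxt <- unique(c(reach, edges[edges[, 1] %in% reach, 2]))
    if (setequal(nxt, reach)) break
    reach <- nxt
  }
  expect_setequal(reach, poolIds(m))

  # serialize -> re-parse: identical constraint system and carbon maps
  m2 <- buildNetwork(writeNetworkConfig(m))
  expect_equal(assembleBalance(m2, "all"), assembleBalance(m, "all"))
  expect_equal(fluxBounds(m2), fluxBounds(m))
  for (k in seq_along(reactions(m)))
    expect_equal(reactions(m2)[[k]]@carbonMap, reactions(m)[[k]]@carbonMap)
})

test_that("reversible reactions expand into a forward/backward pair", {
  cfg <- "
pools:
  - {id: A, carbons: 2, role: source, measured: false}
  - {id: B, carbons: 2, role: internal, measured: true}
  - {id: C, carbons: 2, role: sink, measured: false}
reactions:
  - {id: rab, substrates: [A], product: B, carbon_map: [[1,1],[1,2]]}
  - {id: rbc, substrates: [B], product: C, carbon_map: [[1,2],[1,1]], reversible: true}
"
  m <- buildNetwork(cfg)
  expect_setequal(reactionIds(m), c("rab", "rbc", "rbc_rev"))
  rev <- reactions(m)[[which(reactionIds(m) == "rbc_rev")]]
  expect_equal(rev@substrates, "C")
  expect_equal(rev@product, "B")
  # inverse of the swap map is the swap map
  expect_equal(unname(rev@carbonMap[, 2]), c(2L, 1L))
})

test_that("flux vectors violating bounds or balance are rejected", {
  m <- chainModel()
  expect_error(validateFluxVector(m, c(20, 20)), "bounds")
  expect_error(validateFluxVector(m, c(2, 1)), "balance")
  expect_true(validateFluxVector(m, c(2, 2)))
})
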