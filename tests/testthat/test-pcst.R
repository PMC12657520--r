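test_that("exact solver reproduces enumerable optima", {
  ## keep only the higher-prize node when the edge is too expensive
  net <- twoNodeNet(3, 4, 10)
  sol <- solvePCSTExact(net)
  expect_equal(selectedNodes(sol), "B")
  expect_equal(solutionObjective(sol), 3)

  ## connect both when the edge is cheap
  net2 <- twoNodeNet(5, 5, 1)
  sol2 <- solvePCSTExact(net2)
  expect_setequal(selectedNodes(sol2), c("A", "B"))
  expect_equal(solutionObjective(sol2), 1)

  ## star: hub prize 0, three leaves prize 2, edge costs 1 -> take all
  star <- new("RegulatoryNetwork",
    nodes = data.frame(id = c("H", "L1", "L2", "L3"),
                       gene = c("H", "L1", "L2", "L3"),
                       node_class = "Protein", prize = c(0, 2, 2, 2),
                       stringsAsFactors = FALSE),
    edges = data.frame(u = "H", v = c("L1", "L2", "L3"), cost = 1,
                       edge_class = "PPI", stringsAsFactors = FALSE),
    metadata = list())
  sol3 <- solvePCSTExact(star)
  expect_setequal(selectedNodes(sol3), c("H", "L1", "L2", "L3"))
  expect_equal(solutionObjective(sol3), 3)

  expect_error(solvePCSTExact(randomConnectedNet(16, 1)), "heuristic")
})

test_that("heuristic matches the exact optimum on small random instances", {
  agree <- 0L
  for (s in 1:60) {
    net <- randomConnectedNet(4 + (s %% 7), seed = 1000 + s)
    eo <- solutionObjective(solvePCSTExact(net))
    ho <- solutionObjective(solvePCST(net))
    expect_gte(ho, eo - 1e-9)   # never better than the optimum
    if (abs(ho - eo) <= 1e-9) agree <- agree + 1L
  }
  expect_gte(agree / 60, 0.95)
})

test_that("solutions are valid forests with conserved objectives", {
  for (s in 1:25) {
    net <- randomConnectedNet(4 + (s %% 8), seed = 2000 + s)
    sol <- solvePCST(net, beta = 1)
    nn <- length(selectedNodes(sol))
    k <- if (nn) length(unique(sol@components)) else 0L
    expect_equal(nrow(selectedEdges(sol)), nn - k)
    expect_true(all(c(selectedEdges(sol)$u, selectedEdges(sol)$v)
                    %in% selectedNodes(sol)))
    expect_lte(k, 1L)
    expect_equal(solutionObjective(sol), recomputedObjective(sol, net, 1),
                 tolerance = 1e-9)
    ## never worse than doing nothing
    expect_lte(solutionObjective(sol),
               sum(networkNodes(net)$prize) + 1e-9)
  }
})

test_that("heuristic and exact agree on the documented toy cascade", {
  net <- exampleToyNetwork()
  expect_equal(solutionObjective(solvePCST(net)),
               solutionObjective(solvePCSTExact(net)))
  expect_equal(selectedNodes(solvePCST(net)),
               selectedNodes(solvePCSTExact(net)))
})

test_that("selection grows monotonically with beta", {
  net <- randomConnectedNet(9, seed = 42)
  sizes <- vapply(c(0.25, 0.5, 1, 2, 4), function(b)
    length(selectedNodes(solvePCSTExact(net, beta = b))), integer(1))
  expect_true(all(diff(sizes) >= 0))
  sizesH <- vapply(c(0.25, 0.5, 1, 2, 4), function(b)
    length(selectedNodes(solvePCST(exampleToyNetwork(), beta = b))),
    integer(1))
  expect_true(all(diff(sizesH) >= 0))
})

test_that("pruning removes uneconomical leaves and is idempotent", {
  ## leaf with prize 0 hanging on a cost-1 edge
  net <- new("RegulatoryNetwork",
    nodes = data.frame(id = c("A", "B", "C"), gene = c("A", "B", "C"),
                       node_class = "Protein", prize = c(5, 5, 0),
                       stringsAsFactors = FALSE),
    edges = data.frame(u = c("A", "B"), v = c("B", "C"), cost = c(0.5, 1),
                       edge_class = "PPI", stringsAsFactors = FALSE),
    metadata = list())
  full <- new("PCSTSolution", nodes = c("A", "B", "C"),
              edges = networkEdges(net), objective = 1.5,
              components = rep(1L, 3), params = list(beta = 1))
  pruned <- pruneSolution(full, net)
  expect_setequal(selectedNodes(pruned), c("A", "B"))
  expect_equal(solutionObjective(pruned), solutionObjective(full) - 1)
  again <- pruneSolution(pruned, net)
  expect_equal(selectedNodes(again), selectedNodes(pruned))
  expect_equal(solutionObjective(again), solutionObjective(pruned))
})

test_that("pruning never increases the objective on random instances", {
  for (s in 1:15) {
    net <- randomConnectedNet(4 + (s %% 7), seed = 3000 + s)
    sol <- solvePCST(net)
    pruned <- pruneSolution(sol, net)
    expect_lte(solutionObjective(pruned), solutionObjective(sol) + 1e-9)
  }
})

test_that("the planted cascade is recovered on the default benchmark", {
  run <- runBenchmarkPipeline(seed = 7)
  gt <- run$bench$groundTruth
  selN <- selectedNodes(run$sol)
  expect_true(gt$hub %in% selN)
  expect_true(all(gt$plantedTFs %in% selN))
  ## all planted TF -> RNA regulatory edges are part of the solution
  ce <- gt$cascadeEdges
  tfrna <- ce[grepl(":rna$", ce$v), ]
  se <- selectedEdges(run$sol)
  expect_true(all(paste(tfrna$u, tfrna$v) %in% paste(se$u, se$v)))
})
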