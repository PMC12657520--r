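## a hand-built network + solution: TF T regulating g1..g3, kinase K
toySolvedNet <- function() {
  ppi <- data.frame(gene_a = "K", gene_b = "T", score = 1000)
  tft <- data.frame(tf = "T", target = c("g1", "g2", "g3"))
  net <- buildNetwork(ppi, tft, c(g1 = 1, g2 = 1, g3 = 1), c(K = 2))
  sol <- solvePCST(net)
  list(net = net, sol = sol)
}

test_that("target counts are taken within the optimized solution", {
  ts <- toySolvedNet()
  expect_equal(countTFTargets(ts$sol, ts$net), c(T = 3L))
  ## a solution without TF nodes yields an empty map
  soloK <- new("PCSTSolution", nodes = "K",
               edges = ts$net@edges[0, ], objective = 0,
               components = 1L, params = list(beta = 1))
  expect_length(countTFTargets(soloK, ts$net), 0L)
})

test_that("benchmark target counts equal the planted regulon sizes", {
  run <- runBenchmarkPipeline(seed = 7)
  gt <- run$bench$groundTruth
  expect_true(all(gt$plantedTFs %in% names(run$counts)))
  expect_equal(unname(run$counts[gt$plantedTFs]),
               rep(gt$nTargetsPerTF, length(gt$plantedTFs)))
})

test_that("ranking orders by target count, then |expression change|", {
  counts <- c(A = 5L, B = 5L)
  rk <- rankTFs(counts, c(A = 1, B = -2))
  expect_equal(rk$tf, c("B", "A"))
  rk2 <- rankTFs(c(A = 5L, B = 2L), c(A = 0.1, B = 9))
  expect_equal(rk2$tf, c("A", "B"))
  ## permutation property: no row invented or dropped
  counts3 <- c(X = 1L, Y = 4L, Z = 0L)
  rk3 <- rankTFs(counts3, degList = c("Y"))
  expect_setequal(rk3$tf, names(counts3))
  expect_equal(setNames(rk3$n_targets, rk3$tf)[names(counts3)], counts3)
  expect_equal(rk3$in_deg_list, rk3$tf == "Y")
  ## TFs missing an expression value sort after measured ones on ties
  rk4 <- rankTFs(c(A = 2L, B = 2L), c(B = 0.5))
  expect_equal(rk4$tf, c("B", "A"))
})

test_that("planted TFs outrank everything else across seeds", {
  ok <- 0L
  for (s in 1:10) {
    run <- runBenchmarkPipeline(seed = 300 + s)
    planted <- run$bench$groundTruth$plantedTFs
    rk <- run$ranking
    pos <- match(planted, rk$tf)
    if (!anyNA(pos) &&
        (nrow(rk) == length(planted) ||
         max(pos) < min(setdiff(seq_len(nrow(rk)), pos))))
      ok <- ok + 1L
  }
  expect_gte(ok, 9L)
})

test_that("hypergeometric enrichment matches closed form and permutations", {
  universe <- sprintf("g%02d", 1:10)
  regulons <- list(TF1 = universe[1:5])
  res <- enrichTFTargets(regulons, query = universe[1:5],
                         universe = universe)
  expect_equal(res$p_value, 1 / choose(10, 5))
  expect_equal(res$overlap, 5L)

  ## empty regulon: p = 1
  res0 <- enrichTFTargets(list(TF0 = character(0)), universe[1:3], universe)
  expect_equal(res0$p_value, 1)
  expect_equal(res0$overlap, 0L)
  expect_error(enrichTFTargets(regulons, "g01", character(0)), "universe")

  ## permutation oracle for an intermediate overlap
  reg <- universe[1:4]
  query <- universe[c(1, 2, 5, 6, 7)]
  res1 <- enrichTFTargets(list(A = reg), query, universe)
  obs <- res1$overlap
  perm <- withr::with_seed(99, replicate(4000, {
    q <- sample(universe, length(query))
    length(intersect(q, reg)) >= obs
  }))
  pEmp <- mean(perm)
  mcSd <- sqrt(pEmp * (1 - pEmp) / 4000)
  expect_lt(abs(pEmp - res1$p_value), 4 * mcSd + 1e-6)
})

test_that("BH adjustment is monotone and bounded below by p", {
  universe <- sprintf("g%03d", 1:60)
  regs <- withr::with_seed(7, lapply(setNames(1:8, paste0("TF", 1:8)),
    function(i) sample(universe, 10)))
  query <- universe[1:15]
  res <- enrichTFTargets(regs, query, universe)
  expect_true(all(res$adjusted_p >= res$p_value - 1e-12))
  expect_equal(order(res$p_value), order(res$adjusted_p, res$p_value))
})
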