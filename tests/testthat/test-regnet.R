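test_that("target selection applies the intersection rule and prize formula", {
  up <- data.frame(gene = c("A", "B"), log2fc = c(2, 1),
                   padj = c(0.01, 0.01))
  dn <- data.frame(gene = c("A", "C"), log2fc = c(-1, -3),
                   padj = c(0.01, 0.01))
  expect_equal(selectTargetGenes(up, dn), c(A = 1.5))

  dn2 <- data.frame(gene = "A", log2fc = 0.5, padj = 0.01)
  expect_warning(res <- selectTargetGenes(up, dn2), "no gene")
  expect_length(res, 0L)

  ## significance threshold is honoured on both sides
  up3 <- data.frame(gene = "A", log2fc = 2, padj = 0.2)
  dn3 <- data.frame(gene = "A", log2fc = -1, padj = 0.01)
  expect_warning(expect_length(selectTargetGenes(up3, dn3), 0L))
})

test_that("node values keep only significantly upregulated genes", {
  up <- data.frame(gene = c("A", "B"), log2fc = c(2, -1),
                   padj = c(0.01, 0.01))
  expect_equal(assignNodeValues(up), c(A = 2))
  expect_length(assignNodeValues(data.frame(gene = character(),
                                            log2fc = numeric(),
                                            padj = numeric())), 0L)
  ## 50 planted up genes among noise
  planted <- data.frame(gene = sprintf("UP%02d", 1:50),
                        log2fc = runif(50, 1, 3), padj = runif(50, 0, 0.04))
  noise <- data.frame(gene = sprintf("NS%02d", 1:30),
                      log2fc = rnorm(30), padj = runif(30, 0.06, 1))
  got <- assignNodeValues(rbind(planted, noise))
  expect_length(got, 50L)
  expect_true(all(got > 0))
})

test_that("edge costs follow -log(score/1000)", {
  expect_equal(edgeCost(1000), 0)
  expect_equal(edgeCost(100), 1)
  expect_equal(edgeCost(500), 0.30103, tolerance = 1e-5)
  expect_equal(edgeCost(500, logBase = exp(1)), log(2))
  s <- seq(10, 1000, by = 10)
  expect_true(all(diff(edgeCost(s)) < 0))
  expect_error(edgeCost(0), "positive")
  expect_error(edgeCost(1500), "range")
})

test_that("buildNetwork creates the tripartite structure", {
  ppi <- data.frame(gene_a = "K", gene_b = "T", score = 1000)
  tft <- data.frame(tf = "T", target = "g")
  net <- buildNetwork(ppi, tft, c(g = 1.5), c(K = 2))
  nd <- networkNodes(net)
  expect_setequal(nd$id, c("K", "T", "g:rna"))
  expect_equal(nd$node_class[match(c("K", "T", "g:rna"), nd$id)],
               c("Protein", "TF", "RNA"))
  expect_equal(nd$prize[match(c("K", "T", "g:rna"), nd$id)], c(2, 0, 1.5))
  ed <- networkEdges(net)
  expect_equal(nrow(ed), 2L)
  expect_equal(ed$cost[ed$edge_class == "PPI"], 0)
  expect_equal(ed$cost[ed$edge_class == "TF_target"], 0)

  ## a regulator without PPI information cannot form a TF node
  expect_message(net2 <- buildNetwork(ppi, data.frame(tf = "X", target = "g"),
                                      c(g = 1.5), c(K = 2)),
                 "without PPI")
  expect_equal(nrow(networkNodes(net2)), 2L)
  expect_equal(nrow(networkEdges(net2)), 1L)
  expect_true("X" %in% net2@metadata$unusable_tfs)
})

test_that("buildNetwork is deterministic and input-order independent", {
  bench <- generateNetworkBenchmark(seed = 7)
  prizes <- selectTargetGenes(bench$deUp, bench$deDown)
  vals <- assignNodeValues(bench$deUp)
  n1 <- buildNetwork(bench$ppi, bench$tfTargets, prizes, vals)
  shuf <- withr::with_seed(1, bench$ppi[sample(nrow(bench$ppi)), ])
  shufT <- withr::with_seed(2, bench$tfTargets[sample(nrow(bench$tfTargets)), ])
  n2 <- buildNetwork(shuf, shufT, prizes, vals)
  expect_equal(networkNodes(n1), networkNodes(n2))
  expect_equal(networkEdges(n1), networkEdges(n2))
})

test_that("benchmark network matches generator bookkeeping", {
  bench <- generateNetworkBenchmark(seed = 7)
  gt <- bench$groundTruth
  prizes <- selectTargetGenes(bench$deUp, bench$deDown)
  vals <- assignNodeValues(bench$deUp)
  net <- suppressMessages(
    buildNetwork(bench$ppi, bench$tfTargets, prizes, vals))
  nd <- networkNodes(net)
  ppiGenes <- unique(c(bench$ppi$gene_a, bench$ppi$gene_b))
  expect_equal(sum(nd$node_class != "RNA"), length(ppiGenes))
  ## every planted target that is regulated shows up as an RNA node
  expect_true(all(paste0(gt$plantedTargets, ":rna") %in% nd$id))
  ed <- networkEdges(net)
  expect_equal(sum(ed$edge_class == "PPI"), nrow(bench$ppi))
  ## invariants
  expect_true(all(ed$cost[ed$edge_class == "TF_target"] == 0))
  expect_true(all(ed$cost >= 0))
  expect_true(all(nd$prize >= 0))
  ## RNA prizes equal the average-absolute-log2fc formula
  up <- setNames(bench$deUp$log2fc, bench$deUp$gene)
  dn <- setNames(bench$deDown$log2fc, bench$deDown$gene)
  rna <- nd[nd$node_class == "RNA", ]
  expect_equal(rna$prize,
               (abs(up[rna$gene]) + abs(dn[rna$gene])) / 2,
               ignore_attr = TRUE)
})
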