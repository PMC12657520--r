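## Independent oracles and fixture builders used across the suite.

## brute-force Otsu: tries every distinct value as a cut (classes <= cut vs
## > cut) and returns the logical foreground partition with maximal
## between-class variance (lowest cut on ties)
naiveOtsuPartition <- function(values) {
  v <- sort(unique(values))
  stopifnot(length(v) >= 2L)
  bestVar <- -Inf
  bestCut <- v[1L]
  for (cut in v[-length(v)]) {
    lo <- values[values <= cut]
    hi <- values[values > cut]
    w0 <- length(lo) / length(values)
    sb <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (sb > bestVar + 1e-12) {
      bestVar <- sb
      bestCut <- cut
    }
  }
  values > bestCut
}

## closed-form pooled-variance two-sample t
pooledT <- function(a, b) {
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
         (length(a) + length(b) - 2)
  tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  df <- length(a) + length(b) - 2
  list(t = tt, df = df, p = 2 * pt(-abs(tt), df))
}

## a random connected prize/cost instance wrapped as a RegulatoryNetwork
## (all nodes Protein class; PCST is class-agnostic)
randomConnectedNet <- function(n, seed, maxPrize = 3, maxCost = 2) {
  withr::with_seed(seed, {
    ids <- sprintf("N%02d", seq_len(n))
    m <- matrix(runif(n * n) < 0.4, n, n)
    eu <- c(row(m)[upper.tri(m) & m], seq_len(n - 1L))
    ev <- c(col(m)[upper.tri(m) & m], seq(2L, n))
    a <- pmin(eu, ev); b <- pmax(eu, ev)
    d <- !duplicated(paste(a, b))
    edges <- data.frame(u = ids[a[d]], v = ids[b[d]],
                        cost = runif(sum(d), 0, maxCost),
                        edge_class = "PPI", stringsAsFactors = FALSE)
    nodes <- data.frame(id = ids, gene = ids, node_class = "Protein",
                        prize = runif(n, 0, maxPrize),
                        stringsAsFactors = FALSE)
    new("RegulatoryNetwork", nodes = nodes, edges = edges,
        metadata = list())
  })
}

## a two-node instance: prizes p1, p2 and one edge of given cost
twoNodeNet <- function(p1, p2, cost) {
  new("RegulatoryNetwork",
      nodes = data.frame(id = c("A", "B"), gene = c("A", "B"),
                         node_class = "Protein", prize = c(p1, p2),
                         stringsAsFactors = FALSE),
      edges = data.frame(u = "A", v = "B", cost = cost,
                         edge_class = "PPI", stringsAsFactors = FALSE),
      metadata = list())
}

## recompute a solution objective from its selected sets
recomputedObjective <- function(sol, net, beta) {
  keep <- networkNodes(net)$id %in% selectedNodes(sol)
  sum(selectedEdges(sol)$cost) +
    beta * sum(networkNodes(net)$prize[!keep])
}

## run the full planted-benchmark pipeline for one seed
runBenchmarkPipeline <- function(seed) {
  bench <- generateNetworkBenchmark(seed = seed)
  prizes <- suppressWarnings(selectTargetGenes(bench$deUp, bench$deDown))
  vals <- assignNodeValues(bench$deUp)
  net <- suppressMessages(
    buildNetwork(bench$ppi, bench$tfTargets, prizes, vals))
  sol <- solvePCST(net, beta = 1)
  counts <- countTFTargets(sol, net)
  list(bench = bench, prizes = prizes, vals = vals, net = net, sol = sol,
       counts = counts,
       ranking = rankTFs(counts, vals, degList = names(prizes)))
}
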