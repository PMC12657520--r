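## Prize-Collecting Steiner Tree solver.
##
## Objective (Goemans-Williamson prize-collecting form, unrooted):
##   minimize  sum(cost of selected edges) + beta * sum(prize of EXCLUDED nodes)
## over forests with at most `numComponents` trees.  Equivalently, maximize
## the net value beta*prize(selected) - cost(selected), since
## beta * totalPrize is constant.

.EPS <- 1e-12

## union-find root lookup (no compression; instances are small)
.ufFind <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

## minimum spanning forest (Kruskal) restricted to node subset `keep`
## (logical).  Edges must be pre-sorted by cost (ties by index).
## Returns list(edges = integer indices, nComp = components within subset).
.kruskalMSF <- function(nKeep, eu, ev, ord, keep) {
  parent <- seq_len(length(keep))
  chosen <- integer(0)
  merges <- 0L
  for (i in ord) {
    a <- eu[i]; b <- ev[i]
    if (!keep[a] || !keep[b]) next
    ra <- .ufFind(parent, a)
    rb <- .ufFind(parent, b)
    if (ra != rb) {
      parent[ra] <- rb
      chosen <- c(chosen, i)
      merges <- merges + 1L
      if (merges == nKeep - 1L) break
    }
  }
  list(edges = chosen, nComp = nKeep - merges)
}

.netIndex <- function(net) {
  ids <- net@nodes$id
  eu <- match(net@edges$u, ids)
  ev <- match(net@edges$v, ids)
  list(ids = ids, prize = net@nodes$prize, eu = eu, ev = ev,
       cost = net@edges$cost,
       ord = order(net@edges$cost, net@edges$u, net@edges$v))
}

.componentsOf <- function(nodes, edgesDF) {
  parent <- seq_along(nodes)
  if (nrow(edgesDF)) {
    eu <- match(edgesDF$u, nodes)
    ev <- match(edgesDF$v, nodes)
    for (i in seq_along(eu)) {
      ra <- .ufFind(parent, eu[i])
      rb <- .ufFind(parent, ev[i])
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_along(nodes), function(i) .ufFind(parent, i), integer(1))
  match(roots, unique(roots))
}

.makeSolution <- function(net, nodeIdx, edgeIdx, beta, params) {
  idx <- .netIndex(net)
  ids <- sort(idx$ids[nodeIdx])
  edges <- net@edges[sort(edgeIdx), , drop = FALSE]
  rownames(edges) <- NULL
  obj <- sum(edges$cost) +
    beta * (sum(net@nodes$prize) - sum(net@nodes$prize[nodeIdx]))
  comps <- if (length(ids)) .componentsOf(ids, edges) else integer(0)
  new("PCSTSolution", nodes = ids, edges = edges, objective = obj,
      components = comps, params = params)
}

#' Exact Prize-Collecting Steiner Tree solver (enumeration oracle)
#'
#' Enumerates every node subset, connects each with a minimum spanning
#' forest of the induced subgraph, and returns the global optimum of
#' \code{sum(edge costs) + beta * sum(excluded prizes)} over forests with
#' at most \code{numComponents} trees.  Guarded to at most \code{maxNodes}
#' nodes; use [solvePCST()] for realistic networks.  Ties are broken toward
#' fewer nodes, then the lexicographically smallest node-id set.
#'
#' @param net a [RegulatoryNetwork-class]
#' @param beta prize-scaling multiplier (>= 0)
#' @param numComponents maximum number of trees in the forest
#' @param maxNodes enumeration guard (default 15)
#' @return a [PCSTSolution-class]
#' @export
solvePCSTExact <- function(net, beta = 1, numComponents = 1L,
                           maxNodes = 15L) {
  stopifnot(beta >= 0, numComponents >= 1L)
  n <- nrow(net@nodes)
  if (n > maxNodes)
    stop("exact solver is limited to ", maxNodes,
         " nodes; use solvePCST(mode = 'heuristic')")
  idx <- .netIndex(net)
  total <- sum(idx$prize)
  bestObj <- beta * total          # empty solution
  bestMask <- logical(n)
  bestEdges <- integer(0)
  bestKey <- ""
  if (n) for (mask in seq_len(2^n - 1L)) {
    keep <- as.logical(bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)))
    nKeep <- sum(keep)
    msf <- .kruskalMSF(nKeep, idx$eu, idx$ev, idx$ord, keep)
    if (msf$nComp > numComponents) next
    obj <- sum(idx$cost[msf$edges]) + beta * sum(idx$prize[!keep])
    better <- obj < bestObj - .EPS
    if (!better && obj < bestObj + .EPS) {
      key <- paste(sort(idx$ids[keep]), collapse = "\r")
      better <- nKeep < sum(bestMask) ||
        (nKeep == sum(bestMask) && key < bestKey)
    }
    if (better) {
      bestObj <- obj
      bestMask <- keep
      bestEdges <- msf$edges
      bestKey <- paste(sort(idx$ids[keep]), collapse = "\r")
    }
  }
  .makeSolution(net, which(bestMask), bestEdges, beta,
                list(beta = beta, numComponents = numComponents,
                     mode = "exact"))
}

## Goemans-Williamson moat growing on an indexed graph.
## pb = beta * prize per node.  Returns integer indices of forest edges.
.gwForest <- function(n, eu, ev, cost, pb) {
  if (!n) return(integer(0))
  parent <- seq_len(n)
  surplus <- pb
  active <- pb > .EPS
  slack <- cost
  forest <- integer(0)
  m <- length(eu)
  repeat {
    roots <- vapply(seq_len(n), function(i) .ufFind(parent, i), integer(1))
    aroots <- unique(roots[active[roots]])
    ## a cluster is active while its root carries surplus
    aroots <- aroots[surplus[aroots] > .EPS]
    if (!length(aroots)) break
    isActive <- logical(n)
    isActive[aroots] <- TRUE
    ## edge events
    dtEdge <- Inf
    eHit <- 0L
    if (m) for (i in seq_len(m)) {
      ru <- roots[eu[i]]; rv <- roots[ev[i]]
      if (ru == rv) next
      r <- isActive[ru] + isActive[rv]
      if (r == 0L) next
      t <- slack[i] / r
      if (t < dtEdge - .EPS) { dtEdge <- t; eHit <- i }
    }
    ## deactivation events
    dtDeact <- min(surplus[aroots])
    dHit <- aroots[which.min(surplus[aroots])]
    dt <- min(dtEdge, dtDeact)
    if (!is.finite(dt)) break
    surplus[aroots] <- surplus[aroots] - dt
    if (m) for (i in seq_len(m)) {
      ru <- roots[eu[i]]; rv <- roots[ev[i]]
      if (ru == rv) next
      r <- isActive[ru] + isActive[rv]
      if (r) slack[i] <- slack[i] - dt * r
    }
    if (dtEdge <= dtDeact + .EPS && eHit) {
      ru <- roots[eu[eHit]]; rv <- roots[ev[eHit]]
      parent[ru] <- rv
      surplus[rv] <- surplus[rv] + surplus[ru]
      surplus[ru] <- 0
      active[rv] <- surplus[rv] > .EPS
      forest <- c(forest, eHit)
    } else {
      active[dHit] <- FALSE
      surplus[dHit] <- 0
    }
  }
  forest
}

## Strong pruning of one tree.  treeNodes: integer node indices;
## treeEdges: indices into (eu, ev, cost).  Returns the best (max net)
## pruned subtree over all roots: list(nodes, edges, net).
.strongPrune <- function(treeNodes, treeEdges, eu, ev, cost, pb, ids) {
  nt <- length(treeNodes)
  local <- match(seq_along(pb), treeNodes)  # global -> local (NA outside)
  adj <- vector("list", nt)
  for (e in treeEdges) {
    a <- local[eu[e]]; b <- local[ev[e]]
    adj[[a]] <- rbind(adj[[a]], c(b, e))
    adj[[b]] <- rbind(adj[[b]], c(a, e))
  }
  best <- list(nodes = integer(0), edges = integer(0), net = -Inf)
  for (rloc in seq_len(nt)) {
    ## iterative DFS order from root
    order <- integer(nt); parentLoc <- integer(nt); parentEdge <- integer(nt)
    seen <- logical(nt)
    stack <- rloc; seen[rloc] <- TRUE; k <- 0L
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      k <- k + 1L; order[k] <- v
      nb <- adj[[v]]
      if (!is.null(nb)) for (j in seq_len(nrow(nb))) {
        w <- nb[j, 1L]
        if (!seen[w]) {
          seen[w] <- TRUE
          parentLoc[w] <- v
          parentEdge[w] <- nb[j, 2L]
          stack <- c(stack, w)
        }
      }
    }
    payoff <- pb[treeNodes]
    keepEdge <- logical(nt)   # keep link to parent?
    for (v in rev(order[seq_len(k)])) {
      if (v == rloc) next
      gain <- payoff[v] - cost[parentEdge[v]]
      if (gain > .EPS) {
        keepEdge[v] <- TRUE
        payoff[parentLoc[v]] <- payoff[parentLoc[v]] + gain
      }
    }
    ## collect retained subtree from root
    keepNode <- logical(nt); keepNode[rloc] <- TRUE
    for (v in order[seq_len(k)]) {
      if (v == rloc) next
      keepNode[v] <- keepEdge[v] && keepNode[parentLoc[v]]
    }
    nodesG <- treeNodes[keepNode]
    edgesG <- parentEdge[keepNode & seq_len(nt) != rloc]
    net <- payoff[rloc] - 0  # payoff at root = net value of retained subtree
    better <- net > best$net + .EPS
    if (!better && net > best$net - .EPS) {
      if (length(nodesG) < length(best$nodes)) better <- TRUE
      else if (length(nodesG) == length(best$nodes) &&
               paste(sort(ids[nodesG]), collapse = "\r") <
               paste(sort(ids[best$nodes]), collapse = "\r")) better <- TRUE
    }
    if (better) best <- list(nodes = nodesG, edges = edgesG, net = net)
  }
  best
}

## split a forest (edge index set) into trees over n nodes; singletons kept
.forestTrees <- function(n, eu, ev, forest) {
  parent <- seq_len(n)
  for (i in forest) {
    ra <- .ufFind(parent, eu[i])
    rb <- .ufFind(parent, ev[i])
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(seq_len(n), function(i) .ufFind(parent, i), integer(1))
  nodesBy <- split(seq_len(n), roots)
  edgesBy <- split(forest, vapply(forest, function(i)
    .ufFind(parent, eu[i]), integer(1)))
  lapply(names(nodesBy), function(r)
    list(nodes = nodesBy[[r]],
         edges = if (r %in% names(edgesBy)) edgesBy[[r]] else integer(0)))
}

#' Solve the Prize-Collecting Steiner Tree problem
#'
#' Scalable heuristic solver: Goemans-Williamson moat growing produces a
#' candidate forest, each tree of which is strong-pruned (exact dynamic
#' program on the tree, evaluated from every root); minimum-spanning-tree
#' backbones of each graph component are pruned the same way as additional
#' candidates.  The best \code{numComponents} disjoint positive-value trees
#' are returned, or the empty solution when nothing has positive net value.
#' Fully deterministic; \code{seed} is accepted for interface stability.
#'
#' @param net a [RegulatoryNetwork-class]
#' @param beta prize-scaling multiplier (>= 0); larger beta selects more
#'   nodes.
#' @param numComponents maximum number of trees (default 1, a single
#'   connected regulatory network)
#' @param mode \code{"heuristic"} (default) or \code{"exact"} (delegates to
#'   [solvePCSTExact()], small networks only)
#' @param seed integer, kept in the solution parameters
#' @return a [PCSTSolution-class]
#' @examples
#' net <- exampleToyNetwork()
#' sol <- solvePCST(net, beta = 1)
#' selectedNodes(sol)
#' @export
solvePCST <- function(net, beta = 1, numComponents = 1L,
                      mode = c("heuristic", "exact"), seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(beta >= 0, numComponents >= 1L)
  if (mode == "exact")
    return(solvePCSTExact(net, beta = beta, numComponents = numComponents))
  idx <- .netIndex(net)
  n <- length(idx$ids)
  params <- list(beta = beta, numComponents = as.integer(numComponents),
                 mode = "heuristic", seed = as.integer(seed))
  if (!n) return(.makeSolution(net, integer(0), integer(0), beta, params))
  pb <- beta * idx$prize
  candidates <- list()
  ## GW candidate forest
  gw <- .gwForest(n, idx$eu, idx$ev, idx$cost, pb)
  for (tr in .forestTrees(n, idx$eu, idx$ev, gw))
    candidates <- c(candidates, list(
      .strongPrune(tr$nodes, tr$edges, idx$eu, idx$ev, idx$cost, pb,
                   idx$ids)))
  ## MST backbone of every graph component
  comp <- .componentsOf(idx$ids, net@edges)
  for (cc in unique(comp)) {
    keep <- comp == cc
    msf <- .kruskalMSF(sum(keep), idx$eu, idx$ev, idx$ord, keep)
    candidates <- c(candidates, list(
      .strongPrune(which(keep), msf$edges, idx$eu, idx$ev, idx$cost, pb,
                   idx$ids)))
  }
  ## order candidates by net value (desc), nodes (asc), id key (asc)
  nets <- vapply(candidates, `[[`, numeric(1), "net")
  sizes <- vapply(candidates, function(c) length(c$nodes), integer(1))
  keys <- vapply(candidates, function(c)
    paste(sort(idx$ids[c$nodes]), collapse = "\r"), character(1))
  ordC <- order(-nets, sizes, keys)
  chosenN <- integer(0)
  chosenE <- integer(0)
  used <- logical(n)
  kTaken <- 0L
  for (i in ordC) {
    cand <- candidates[[i]]
    if (kTaken >= numComponents) break
    if (cand$net <= .EPS) break
    if (any(used[cand$nodes])) next
    used[cand$nodes] <- TRUE
    chosenN <- c(chosenN, cand$nodes)
    chosenE <- c(chosenE, cand$edges)
    kTaken <- kTaken + 1L
  }
  .makeSolution(net, chosenN, chosenE, beta, params)
}

#' Prune uneconomical leaves from a PCST solution
#'
#' Iteratively removes leaf nodes whose scaled prize (\code{beta * prize})
#' is smaller than the cost of their attaching edge.  The objective never
#' increases and the operation is idempotent.
#'
#' @param sol a [PCSTSolution-class]
#' @param net the [RegulatoryNetwork-class] it was solved on
#' @param beta prize multiplier (defaults to the one stored in \code{sol})
#' @return a pruned [PCSTSolution-class]
#' @export
pruneSolution <- function(sol, net, beta = NULL) {
  if (is.null(beta)) beta <- sol@params$beta
  if (is.null(beta)) beta <- 1
  nodes <- sol@nodes
  edges <- sol@edges
  prize <- setNames(net@nodes$prize, net@nodes$id)
  repeat {
    if (!length(nodes)) break
    deg <- table(factor(c(edges$u, edges$v), levels = nodes))
    leaves <- nodes[deg == 1L]
    drop <- character(0)
    for (lf in leaves) {
      ei <- which(edges$u == lf | edges$v == lf)
      if (length(ei) == 1L && beta * prize[lf] < edges$cost[ei] - .EPS)
        drop <- c(drop, lf)
    }
    if (!length(drop)) break
    ## remove one leaf at a time so shared neighbours re-evaluate
    lf <- drop[1L]
    ei <- which(edges$u == lf | edges$v == lf)
    edges <- edges[-ei, , drop = FALSE]
    nodes <- setdiff(nodes, lf)
  }
  idx <- match(nodes, net@nodes$id)
  eIdx <- which(paste(net@edges$u, net@edges$v) %in% paste(edges$u, edges$v))
  .makeSolution(net, idx, eIdx, beta, sol@params)
}

#' A small worked-example network
#'
#' A toy kinase-TF-target cascade used in documentation examples: one
#' upstream kinase linked to a TF through a high-confidence PPI edge, the
#' TF regulating three prized targets, plus a weakly connected bystander
#' protein.
#'
#' @return a [RegulatoryNetwork-class]
#' @export
exampleToyNetwork <- function() {
  ppi <- data.frame(gene_a = c("KIN1", "KIN1"),
                    gene_b = c("TFX", "BYST"),
                    score = c(950, 200), stringsAsFactors = FALSE)
  tft <- data.frame(tf = "TFX", target = c("G1", "G2", "G3"),
                    stringsAsFactors = FALSE)
  prizes <- c(G1 = 1.5, G2 = 2.0, G3 = 1.2)
  values <- c(KIN1 = 1.0)
  buildNetwork(ppi, tft, prizes, values)
}
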