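#' @import methods
NULL

NODE_CLASSES <- c("Protein", "TF", "RNA")
EDGE_CLASSES <- c("PPI", "TF_target")

#' RegulatoryNetwork: a tripartite Protein-TF-RNA prize/cost graph
#'
#' The pre-optimization superset network on which the Prize-Collecting
#' Steiner Tree is solved.  Nodes belong to one of three classes:
#' \describe{
#'   \item{Protein}{proteins from the PPI table that are not transcriptional
#'     regulators; carry a non-negative value (prize) taken from the
#'     load-upregulated log2 fold change when available.}
#'   \item{TF}{transcriptional regulators that have PPI information; same
#'     prize rule as Protein nodes.}
#'   \item{RNA}{target-gene transcripts; their prize is the averaged
#'     absolute log2 fold change across the two differential-expression
#'     comparisons.  RNA node ids carry a \code{":rna"} suffix so that a
#'     gene present both as a protein and as a regulated transcript yields
#'     two distinct nodes.}
#' }
#' PPI edges carry cost \code{-log(score/1000)}; TF-to-RNA edges carry cost
#' zero.
#'
#' @slot nodes data.frame with columns \code{id}, \code{gene},
#'   \code{node_class}, \code{prize}.
#' @slot edges data.frame with columns \code{u}, \code{v}, \code{cost},
#'   \code{edge_class}.
#' @slot metadata list of bookkeeping values (filter counts, parameters).
#'
#' @seealso [buildNetwork()], [solvePCST()]
#' @export
setClass("RegulatoryNetwork",
  representation(nodes = "data.frame", edges = "data.frame",
                 metadata = "list"),
  prototype(
    nodes = data.frame(id = character(), gene = character(),
                       node_class = character(), prize = numeric(),
                       stringsAsFactors = FALSE),
    edges = data.frame(u = character(), v = character(), cost = numeric(),
                       edge_class = character(), stringsAsFactors = FALSE),
    metadata = list()))

setValidity("RegulatoryNetwork", function(object) {
  nd <- object@nodes
  ed <- object@edges
  msgs <- character()
  need_n <- c("id", "gene", "node_class", "prize")
  need_e <- c("u", "v", "cost", "edge_class")
  if (!all(need_n %in% names(nd)))
    return(sprintf("nodes must have columns %s", paste(need_n, collapse = ", ")))
  if (!all(need_e %in% names(ed)))
    return(sprintf("edges must have columns %s", paste(need_e, collapse = ", ")))
  if (anyDuplicated(nd$id))
    msgs <- c(msgs, "duplicate node ids")
  if (!all(nd$node_class %in% NODE_CLASSES))
    msgs <- c(msgs, "node_class must be Protein, TF or RNA")
  if (any(nd$prize < 0))
    msgs <- c(msgs, "prizes must be non-negative")
  if (nrow(ed)) {
    if (!all(ed$edge_class %in% EDGE_CLASSES))
      msgs <- c(msgs, "edge_class must be PPI or TF_target")
    if (!all(c(ed$u, ed$v) %in% nd$id))
      msgs <- c(msgs, "dangling edge endpoint")
    if (any(ed$cost < 0))
      msgs <- c(msgs, "edge costs must be non-negative")
    if (any(ed$edge_class == "TF_target" & ed$cost != 0))
      msgs <- c(msgs, "TF_target edges must have cost 0")
    key <- paste(pmin(ed$u, ed$v), pmax(ed$u, ed$v))
    if (anyDuplicated(key))
      msgs <- c(msgs, "duplicate edges")
    cls <- setNames(nd$node_class, nd$id)
    ppi <- ed$edge_class == "PPI"
    if (any(cls[ed$u[ppi]] == "RNA") || any(cls[ed$v[ppi]] == "RNA"))
      msgs <- c(msgs, "PPI edges cannot touch RNA nodes")
    tft <- ed$edge_class == "TF_target"
    if (any(cls[ed$u[tft]] != "TF") || any(cls[ed$v[tft]] != "RNA"))
      msgs <- c(msgs, "TF_target edges must run TF -> RNA")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' PCSTSolution: a selected prize-collecting forest
#'
#' @slot nodes character vector of selected node ids.
#' @slot edges data.frame (\code{u}, \code{v}, \code{cost},
#'   \code{edge_class}) of selected edges; they induce a forest spanning
#'   exactly the selected nodes.
#' @slot objective numeric; sum of selected edge costs plus \code{beta}
#'   times the prizes of unselected nodes.
#' @slot components integer vector parallel to \code{nodes} giving the tree
#'   membership of each selected node.
#' @slot params list of solver parameters (\code{beta},
#'   \code{numComponents}, \code{mode}, \code{seed}).
#'
#' @seealso [solvePCST()], [solvePCSTExact()], [pruneSolution()]
#' @export
setClass("PCSTSolution",
  representation(nodes = "character", edges = "data.frame",
                 objective = "numeric", components = "integer",
                 params = "list"),
  prototype(nodes = character(),
            edges = data.frame(u = character(), v = character(),
                               cost = numeric(), edge_class = character(),
                               stringsAsFactors = FALSE),
            objective = NA_real_, components = integer(), params = list()))

setValidity("PCSTSolution", function(object) {
  msgs <- character()
  nn <- length(object@nodes)
  ne <- nrow(object@edges)
  if (anyDuplicated(object@nodes))
    msgs <- c(msgs, "duplicate selected nodes")
  if (ne && !all(c(object@edges$u, object@edges$v) %in% object@nodes))
    msgs <- c(msgs, "selected edge touches unselected node")
  if (length(object@components) != nn)
    msgs <- c(msgs, "components must be parallel to nodes")
  k <- if (nn) length(unique(object@components)) else 0L
  if (nn && ne != nn - k)
    msgs <- c(msgs, "selected edges do not form a spanning forest")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' @describeIn RegulatoryNetwork-class compact display
#' @param object a \code{RegulatoryNetwork}
#' @export
setMethod("show", "RegulatoryNetwork", function(object) {
  tab <- table(factor(object@nodes$node_class, levels = NODE_CLASSES))
  cat("RegulatoryNetwork with", nrow(object@nodes), "nodes (",
      paste(sprintf("%s: %d", names(tab), as.integer(tab)), collapse = ", "),
      ") and", nrow(object@edges), "edges\n")
  cat("  total prize:", format(sum(object@nodes$prize)), "\n")
  invisible(NULL)
})

#' @describeIn PCSTSolution-class compact display
#' @param object a \code{PCSTSolution}
#' @export
setMethod("show", "PCSTSolution", function(object) {
  k <- if (length(object@nodes)) length(unique(object@components)) else 0L
  cat("PCSTSolution:", length(object@nodes), "nodes,",
      nrow(object@edges), "edges in", k, "tree(s); objective =",
      format(object@objective), "\n")
  invisible(NULL)
})

#' Accessors for network and solution objects
#'
#' \code{networkNodes} and \code{networkEdges} return the node and edge
#' tables of a [RegulatoryNetwork-class]; \code{selectedNodes} and
#' \code{selectedEdges} the selected sets of a [PCSTSolution-class];
#' \code{solutionObjective} its objective value.
#'
#' @param x a \code{RegulatoryNetwork} or \code{PCSTSolution}
#' @return a data.frame, character vector or numeric scalar as appropriate.
#' @name accessors
NULL

#' @rdname accessors
#' @export
networkNodes <- function(x) {
  stopifnot(is(x, "RegulatoryNetwork"))
  x@nodes
}

#' @rdname accessors
#' @export
networkEdges <- function(x) {
  stopifnot(is(x, "RegulatoryNetwork"))
  x@edges
}

#' @rdname accessors
#' @export
selectedNodes <- function(x) {
  stopifnot(is(x, "PCSTSolution"))
  x@nodes
}

#' @rdname accessors
#' @export
selectedEdges <- function(x) {
  stopifnot(is(x, "PCSTSolution"))
  x@edges
}

#' @rdname accessors
#' @export
solutionObjective <- function(x) {
  stopifnot(is(x, "PCSTSolution"))
  x@objective
}
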