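#' Select target genes and compute RNA-node prizes
#'
#' A gene becomes a target (RNA node) when it is significantly upregulated
#' under load (positive log2 fold change, adjusted p below threshold in
#' \code{upLoad}) and significantly downregulated under ERK inhibition of
#' the loaded condition (negative log2 fold change in \code{downInhibitor}).
#' Its prize is the average of the two absolute log2 fold changes.
#'
#' @param upLoad DE table (data.frame \code{gene}, \code{log2fc},
#'   \code{padj}) for the load-vs-control comparison.
#' @param downInhibitor DE table for the inhibitor+load vs load comparison.
#' @param padjThreshold adjusted-p cutoff applied to both tables.
#' @param lfcThreshold minimum absolute log2 fold change (default 0, i.e.
#'   any up/down change passing \code{padjThreshold}).
#' @return named numeric vector mapping gene symbol to prize; empty (with a
#'   warning) when the intersection is empty.
#' @examples
#' up <- data.frame(gene = c("A", "B"), log2fc = c(2, 1), padj = c(0.01, 0.01))
#' dn <- data.frame(gene = c("A", "C"), log2fc = c(-1, -3), padj = c(0.01, 0.01))
#' selectTargetGenes(up, dn)  # A: 1.5
#' @export
selectTargetGenes <- function(upLoad, downInhibitor, padjThreshold = 0.05,
                              lfcThreshold = 0) {
  up <- upLoad[upLoad$log2fc > lfcThreshold &
               upLoad$padj < padjThreshold, , drop = FALSE]
  dn <- downInhibitor[downInhibitor$log2fc < -lfcThreshold &
                      downInhibitor$padj < padjThreshold, , drop = FALSE]
  common <- intersect(up$gene, dn$gene)
  if (!length(common)) {
    warning("no gene is both load-upregulated and inhibitor-downregulated")
    return(setNames(numeric(0), character(0)))
  }
  upfc <- setNames(up$log2fc, up$gene)[common]
  dnfc <- setNames(dn$log2fc, dn$gene)[common]
  setNames((abs(upfc) + abs(dnfc)) / 2, common)
}

#' Assign Protein/TF node values from the load-upregulated genes
#'
#' @inheritParams selectTargetGenes
#' @return named numeric vector mapping gene to its (positive) log2 fold
#'   change for genes significantly upregulated under load.
#' @export
assignNodeValues <- function(upLoad, padjThreshold = 0.05,
                             lfcThreshold = 0) {
  up <- upLoad[upLoad$log2fc > lfcThreshold &
               upLoad$padj < padjThreshold, , drop = FALSE]
  setNames(up$log2fc, up$gene)
}

#' Transform STRING confidence scores into edge costs
#'
#' STRING stores link confidences as integers in [0, 1000] (probabilities
#' scaled by 1000).  The cost of a PPI edge is \code{-log(score/1000)},
#' so full-confidence links (score 1000) are free and weak links are
#' expensive.
#'
#' @param score integer vector of confidences in (0, 1000].
#' @param logBase base of the logarithm (10 or \code{exp(1)}); a common
#'   rescaling of all PPI costs, compensated by the prize scaling
#'   \code{beta}.
#' @return numeric vector of non-negative costs.
#' @examples
#' edgeCost(c(1000, 100, 500))
#' @export
edgeCost <- function(score, logBase = 10) {
  if (any(score <= 0))
    stop("score must be positive (score 0 implies infinite cost)")
  if (any(score > 1000)) stop("score out of range [0, 1000]")
  -log(score / 1000, base = logBase) + 0  # "+ 0" normalizes -0 at score 1000
}

#' Build the tripartite Protein-TF-RNA regulatory network
#'
#' Genes of the TF-target table that have PPI information become TF nodes;
#' all other PPI genes become Protein nodes; target genes carrying a prize
#' become RNA nodes (id suffixed \code{":rna"}), attached to their
#' regulating TF nodes by cost-zero edges.  TFs absent from the PPI table
#' cannot form a TF node and are logged as unusable; RNA nodes with no
#' usable regulator are omitted.
#'
#' @param ppi PPI edge table ([readEdgeTable()] output).
#' @param tfTargets TF-target table ([readTFTargetTable()] output).
#' @param targetPrizes named numeric vector from [selectTargetGenes()].
#' @param nodeValues named numeric vector from [assignNodeValues()];
#'   Protein/TF nodes absent from it get prize 0.
#' @param logBase log base for [edgeCost()].
#' @return a [RegulatoryNetwork-class].
#' @export
buildNetwork <- function(ppi, tfTargets, targetPrizes,
                         nodeValues = numeric(0), logBase = 10) {
  ppiGenes <- sort(unique(c(ppi$gene_a, ppi$gene_b)))
  tfs <- sort(unique(tfTargets$tf))
  usable <- tfs[tfs %in% ppiGenes]
  unusable <- setdiff(tfs, usable)
  if (length(unusable))
    message("buildNetwork: ", length(unusable),
            " TF(s) without PPI information dropped: ",
            paste(utils::head(unusable, 5L), collapse = ", "),
            if (length(unusable) > 5L) ", ..." else "")
  tft <- tfTargets[tfTargets$tf %in% usable &
                   tfTargets$target %in% names(targetPrizes), , drop = FALSE]
  rnaGenes <- sort(unique(tft$target))
  rnaIds <- if (length(rnaGenes)) paste0(rnaGenes, ":rna") else character(0)
  nodeClass <- ifelse(ppiGenes %in% usable, "TF", "Protein")
  val <- rep(0, length(ppiGenes))
  hit <- ppiGenes %in% names(nodeValues)
  val[hit] <- nodeValues[ppiGenes[hit]]
  nodes <- data.frame(
    id = c(ppiGenes, rnaIds),
    gene = c(ppiGenes, rnaGenes),
    node_class = c(nodeClass, rep("RNA", length(rnaGenes))),
    prize = c(val, unname(targetPrizes[rnaGenes])),
    stringsAsFactors = FALSE)
  ppiEdges <- data.frame(
    u = pmin(ppi$gene_a, ppi$gene_b),
    v = pmax(ppi$gene_a, ppi$gene_b),
    cost = edgeCost(ppi$score, logBase = logBase),
    edge_class = "PPI", stringsAsFactors = FALSE)
  tftEdges <- if (nrow(tft)) data.frame(
    u = tft$tf, v = paste0(tft$target, ":rna"),
    cost = 0, edge_class = "TF_target", stringsAsFactors = FALSE)
  else ppiEdges[0, , drop = FALSE]
  edges <- rbind(ppiEdges, tftEdges)
  edges <- edges[order(edges$u, edges$v), , drop = FALSE]
  rownames(edges) <- NULL
  rownames(nodes) <- NULL
  new("RegulatoryNetwork", nodes = nodes, edges = edges,
      metadata = list(unusable_tfs = unusable, log_base = logBase,
                      n_ppi_edges = nrow(ppiEdges),
                      n_tf_target_edges = nrow(tftEdges)))
}
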