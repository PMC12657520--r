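#' Count regulated targets per TF in a PCST solution
#'
#' For each selected TF node, counts the selected RNA nodes attached to it
#' through selected TF-target edges — the number of differentially
#' expressed targets the TF can regulate within the optimized network.
#' With \code{withinSolution = FALSE} the count is taken against the full
#' network instead (all TF-target edges towards prized RNA nodes).
#'
#' @param sol a [PCSTSolution-class]
#' @param net the [RegulatoryNetwork-class] it was solved on
#' @param withinSolution count only selected edges/nodes (default TRUE)
#' @return named integer vector, TF gene symbol -> target count.
#' @export
countTFTargets <- function(sol, net, withinSolution = TRUE) {
  cls <- setNames(net@nodes$node_class, net@nodes$id)
  gene <- setNames(net@nodes$gene, net@nodes$id)
  tfIds <- sol@nodes[cls[sol@nodes] == "TF"]
  if (!length(tfIds)) return(setNames(integer(0), character(0)))
  ed <- if (withinSolution) sol@edges else net@edges
  ed <- ed[ed$edge_class == "TF_target", , drop = FALSE]
  ed <- ed[ed$u %in% tfIds, , drop = FALSE]
  counts <- setNames(integer(length(tfIds)), gene[tfIds])
  if (nrow(ed)) {
    tab <- table(gene[ed$u])
    counts[names(tab)] <- as.integer(tab)
  }
  counts
}

#' Rank transcription factors
#'
#' Orders TFs by the number of targets they can regulate (descending), then
#' by the absolute expression change under compression (descending, missing
#' last), then alphabetically.  Flags membership of the differentially
#' expressed gene list.
#'
#' @param counts named integer vector from [countTFTargets()]
#' @param expressionValues named numeric vector from [assignNodeValues()]
#'   (load-vs-control log2 fold change); TFs absent from it get \code{NA}.
#' @param degList optional character vector of DEG symbols.
#' @return data.frame with columns \code{tf}, \code{n_targets},
#'   \code{expression_change}, \code{in_deg_list}, one row per input TF.
#' @export
rankTFs <- function(counts, expressionValues = numeric(0),
                    degList = character(0)) {
  tf <- names(counts)
  expr <- rep(NA_real_, length(tf))
  hit <- tf %in% names(expressionValues)
  expr[hit] <- expressionValues[tf[hit]]
  out <- data.frame(tf = tf, n_targets = as.integer(counts),
                    expression_change = expr,
                    in_deg_list = tf %in% degList,
                    stringsAsFactors = FALSE)
  absExpr <- abs(out$expression_change)
  absExpr[is.na(absExpr)] <- -Inf
  out <- out[order(-out$n_targets, -absExpr, out$tf), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hypergeometric regulon enrichment
#'
#' A transparent set-overlap enrichment of TF regulons against a query gene
#' set: upper-tail hypergeometric p-value (probability of observing at
#' least the overlap under random draws from the universe),
#' Benjamini-Hochberg adjustment across TFs, and the z-score of the overlap
#' under the hypergeometric null.  This is a simple stand-in for
#' motif-based regulon tools (e.g. iRegulon) and is labelled as such in the
#' \code{method} column; it does not compute motif-based normalized
#' enrichment scores.
#'
#' @param regulons named list of character vectors (TF -> target set)
#' @param query character vector of query genes (subset of universe)
#' @param universe character vector of all genes under consideration
#' @return data.frame with columns \code{tf}, \code{overlap},
#'   \code{regulon_size}, \code{p_value}, \code{adjusted_p},
#'   \code{z_score}, \code{method}, sorted by p-value.
#' @export
enrichTFTargets <- function(regulons, query, universe) {
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  query <- unique(intersect(query, universe))
  N <- length(universe)
  k <- length(query)
  rows <- lapply(names(regulons), function(tf) {
    reg <- unique(intersect(regulons[[tf]], universe))
    K <- length(reg)
    ov <- length(intersect(reg, query))
    p <- if (K == 0L || k == 0L) 1.0 else
      stats::phyper(ov - 1L, K, N - K, k, lower.tail = FALSE)
    mu <- k * K / N
    v <- k * (K / N) * (1 - K / N) * (N - k) / (N - 1)
    z <- if (v > 0) (ov - mu) / sqrt(v) else 0
    data.frame(tf = tf, overlap = ov, regulon_size = K, p_value = p,
               z_score = z, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- stats::p.adjust(out$p_value, method = "BH")
  out$method <- "hypergeometric set overlap (not motif-based NES)"
  out <- out[order(out$p_value, out$tf),
             c("tf", "overlap", "regulon_size", "p_value", "adjusted_p",
               "z_score", "method")]
  rownames(out) <- NULL
  out
}
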