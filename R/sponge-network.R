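# Final sponge-network assembly: intersect PCIT-significant negative
# co-abundance edges with sequence-predicted target sites.

#' Build the circRNA-miRNA sponge network
#'
#' Stabilizes both abundance matrices with `log2(x + 1)`, runs all-pairs
#' Pearson correlation and PCIT on the combined circRNA + miRNA matrix, then
#' restricts to circRNA-miRNA pairs and intersects with the target-site
#' predictions: a final edge must be PCIT-significant, negatively
#' correlated, and carry at least one predicted target site.
#'
#' @param circAbundance circRNA abundance matrix (circRNAs x samples), e.g.
#'   the CPM assay of a [CircCatalog-class].
#' @param mirAbundance miRNA abundance matrix (miRNAs x samples), on the
#'   same samples.
#' @param targetHits data.frame from [scanTargets()].
#' @param stabilized set `TRUE` if the matrices are already log2-stabilized.
#' @return a [SpongeNetwork-class].
#' @export
buildSpongeNetwork <- function(circAbundance, mirAbundance, targetHits,
                               stabilized = FALSE) {
  circAbundance <- as.matrix(circAbundance)
  mirAbundance <- as.matrix(mirAbundance)
  if (is.null(rownames(circAbundance)) || is.null(rownames(mirAbundance)))
    stop("abundance matrices must have feature rownames")
  if (ncol(circAbundance) != ncol(mirAbundance))
    stop("circRNA and miRNA matrices must share samples")
  if (!is.null(colnames(circAbundance)) && !is.null(colnames(mirAbundance)))
    mirAbundance <- mirAbundance[, colnames(circAbundance), drop = FALSE]
  x <- rbind(circAbundance, mirAbundance)
  if (!stabilized) x <- stabilizeAbundance(x)
  x <- dropZeroVariance(x)
  circIds <- intersect(rownames(circAbundance), rownames(x))
  mirIds <- intersect(rownames(mirAbundance), rownames(x))
  r <- pearsonAllPairs(x)
  keep <- pcit(r)

  edges <- expand.grid(circ_id = circIds, mirna_id = mirIds,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  edges$pearson_r <- r[cbind(edges$circ_id, edges$mirna_id)]
  edges$pcit_kept <- keep[cbind(edges$circ_id, edges$mirna_id)]
  th <- targetHits
  if (nrow(th)) {
    agg <- stats::aggregate(score ~ circ_id + mirna_id, data = th,
                            FUN = function(s) c(n = length(s), best = max(s)))
    agg <- data.frame(circ_id = agg$circ_id, mirna_id = agg$mirna_id,
                      n_sites = agg$score[, "n"],
                      best_target_score = agg$score[, "best"])
  } else {
    agg <- data.frame(circ_id = character(0), mirna_id = character(0),
                      n_sites = numeric(0), best_target_score = numeric(0))
  }
  edges <- merge(edges, agg, by = c("circ_id", "mirna_id"), all.x = TRUE)
  edges$n_sites[is.na(edges$n_sites)] <- 0
  edges$in_final_network <- edges$pcit_kept & edges$pearson_r < 0 &
    edges$n_sites > 0
  edges <- edges[order(edges$circ_id, edges$mirna_id), , drop = FALSE]
  rownames(edges) <- NULL

  fin <- edges[edges$in_final_network, , drop = FALSE]
  deg <- data.frame(node = c(circIds, mirIds),
                    kind = rep(c("circRNA", "miRNA"),
                               c(length(circIds), length(mirIds))))
  deg$degree <- vapply(deg$node, function(nd)
    sum(fin$circ_id == nd | fin$mirna_id == nd), 0L)
  methods::new("SpongeNetwork", edges = edges, degrees = deg)
}

#' Convert a sponge network to an igraph graph
#'
#' Nodes carry `kind` (circRNA/miRNA) and `degree` attributes; only final
#' edges are included (set `all = TRUE` for every screened pair).
#'
#' @param net a [SpongeNetwork-class].
#' @param all include non-final edges too.
#' @return an [igraph::graph] object.
#' @export
asSpongeGraph <- function(net, all = FALSE) {
  e <- if (all) spongeEdges(net) else finalNetwork(net)
  d <- nodeDegrees(net)
  used <- if (all) d else d[d$node %in% c(e$circ_id, e$mirna_id), ,
                            drop = FALSE]
  g <- igraph::graph_from_data_frame(
    e[, c("circ_id", "mirna_id", "pearson_r", "n_sites")],
    directed = FALSE, vertices = used[, c("node", "kind", "degree")])
  g
}
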