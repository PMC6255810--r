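#' Build a directed signaling network from an edge list
#'
#' Nodes are uppercase gene symbols; duplicate edges are removed; isolated
#' nodes are permitted (pass them via `nodes`). The walk-transition contract
#' is that the out-edges of a node receive equal probability.
#'
#' @param edge_list data.frame with columns `source`, `target` and optionally
#'   `sign` (carried as an edge attribute, ignored by the walk). See
#'   [read_sif()].
#' @param nodes optional character vector of additional (possibly isolated)
#'   node symbols.
#' @return object of class `signaling_network` wrapping a directed igraph
#'   graph, with `nodes`, `n_nodes`, `n_edges`.
#' @export
build_signaling_network <- function(edge_list, nodes = NULL) {
  if (nrow(edge_list) == 0) {
    warning("empty edge list; building an empty network")
  } else {
    stopifnot(all(c("source", "target") %in% names(edge_list)))
  }
  src <- normalize_symbols(edge_list$source)
  tgt <- normalize_symbols(edge_list$target)
  dup <- duplicated(paste(src, tgt, sep = "\r"))
  src <- src[!dup]; tgt <- tgt[!dup]
  all_nodes <- sort(unique(c(src, tgt, normalize_symbols(nodes))))
  g <- igraph::graph_from_data_frame(
    data.frame(from = src, to = tgt),
    directed = TRUE, vertices = all_nodes)
  if ("sign" %in% names(edge_list)) {
    igraph::E(g)$sign <- edge_list$sign[!dup]
  }
  message("signaling network: ", length(all_nodes), " nodes, ",
          length(src), " edges")
  structure(list(graph = g, nodes = all_nodes,
                 n_nodes = length(all_nodes), n_edges = length(src)),
            class = "signaling_network")
}

#' @export
print.signaling_network <- function(x, ...) {
  cat("Directed signaling network:", x$n_nodes, "nodes,", x$n_edges,
      "edges\n")
  invisible(x)
}

# column-stochastic out-edge transition operator; dangling columns are zero
# (their mass is returned to the seed inside the iteration)
transition_operator <- function(net) {
  g <- net$graph
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  outdeg <- igraph::degree(g, mode = "out")
  inv <- ifelse(outdeg > 0, 1 / outdeg, 0)
  W <- Matrix::t(Matrix::Diagonal(x = inv) %*% A)
  list(W = W, dangling = outdeg == 0, nodes = net$nodes)
}

#' Random-walk-with-return visiting probabilities
#'
#' Iterates the update p_{t+1} = (1 - r) W p_t + r e_seed for `iterations`
#' steps from p_0 = e_seed, where W is the column-stochastic out-edge
#' transition operator. Mass sitting on dangling (out-degree 0) nodes is
#' returned to the seed, so the result is a probability vector at every step.
#'
#' @param net a `signaling_network`.
#' @param seed seed node symbol (must be a network node).
#' @param r return (restart) probability in (0, 1]; default 0.5.
#' @param iterations number of update applications; default 15.
#' @param op optional precomputed transition operator (internal reuse).
#' @return named probability vector over all nodes (sums to 1).
#' @export
rwr_visiting_probabilities <- function(net, seed, r = 0.5, iterations = 15,
                                       op = NULL) {
  stopifnot(r > 0, r <= 1, iterations >= 1)
  seed <- normalize_symbols(seed)
  if (is.null(op)) op <- transition_operator(net)
  if (!seed %in% op$nodes) stop("seed node not in network: ", seed)
  n <- length(op$nodes)
  e <- numeric(n); names(e) <- op$nodes
  e[seed] <- 1
  p <- e
  for (t in seq_len(iterations)) {
    flow <- as.numeric(op$W %*% p)
    flow <- flow + e * sum(p[op$dangling])
    p <- (1 - r) * flow + r * e
  }
  names(p) <- op$nodes
  p
}

#' Proximity of seed proteins to transcription factors
#'
#' Runs the random walk with return from every seed protein and restricts the
#' visiting probabilities to the given TFs. Distance is the negative log10
#' probability ("log scale proximity"); unreachable TFs get probability 0 and
#' distance Inf.
#'
#' @param net a `signaling_network`.
#' @param seeds,tfs character vectors of node symbols; symbols absent from
#'   the network are dropped with a warning.
#' @param r,iterations walk parameters (defaults 0.5 and 15).
#' @return object of class `proximity_matrix`: list with `probability` and
#'   `distance` matrices (rows seeds, columns TFs) and the walk parameters.
#' @export
proximity_matrix <- function(net, seeds, tfs, r = 0.5, iterations = 15) {
  seeds <- sort(unique(normalize_symbols(seeds)))
  tfs <- sort(unique(normalize_symbols(tfs)))
  drop_s <- setdiff(seeds, net$nodes)
  drop_t <- setdiff(tfs, net$nodes)
  if (length(drop_s) > 0) {
    warning(length(drop_s), " seed protein(s) absent from network, dropped")
  }
  if (length(drop_t) > 0) {
    warning(length(drop_t), " TF(s) absent from network, dropped")
  }
  seeds <- setdiff(seeds, drop_s)
  tfs <- setdiff(tfs, drop_t)
  if (length(seeds) == 0 || length(tfs) == 0) {
    stop("no seeds or no TFs left after dropping absent symbols")
  }
  op <- transition_operator(net)
  prob <- matrix(0, length(seeds), length(tfs),
                 dimnames = list(seeds, tfs))
  for (s in seeds) {
    p <- rwr_visiting_probabilities(net, s, r = r, iterations = iterations,
                                    op = op)
    prob[s, ] <- p[tfs]
  }
  dist <- -log10(prob)  # probability 0 -> Inf by IEEE semantics
  structure(list(probability = prob, distance = dist, r = r,
                 iterations = iterations),
            class = "proximity_matrix")
}

#' @export
print.proximity_matrix <- function(x, ...) {
  cat("RWR proximity:", nrow(x$probability), "seed(s) x",
      ncol(x$probability), "TF(s); r =", x$r, ", iterations =",
      x$iterations, "\n")
  invisible(x)
}

# TFs whose (filtered) regulon contains the gene
gene_tfs <- function(gene, regulons) {
  gene <- normalize_symbols(gene)
  sort(unique(regulons$tf[regulons$target == gene]))
}

#' Network distance from a protein to a gene via its transcription factors
#'
#' A gene's distance is an aggregate (default minimum: one strong route
#' suffices) of the protein's walk distances to the TFs that regulate the
#' gene.
#'
#' @param protein seed protein symbol (a row of `prox`).
#' @param gene regulated gene symbol.
#' @param regulons regulon table (see [build_regulons()]).
#' @param prox a `proximity_matrix`.
#' @param aggregate "min" (default) or "mean".
#' @return distance scalar (Inf when every TF is unreachable).
#' @export
gene_distance <- function(protein, gene, regulons, prox,
                          aggregate = c("min", "mean")) {
  aggregate <- match.arg(aggregate)
  protein <- normalize_symbols(protein)
  tfs <- intersect(gene_tfs(gene, regulons), colnames(prox$distance))
  if (length(tfs) == 0) {
    stop("gene ", gene, " has no TFs in the regulons/proximity matrix")
  }
  if (!protein %in% rownames(prox$distance)) {
    stop("protein not in proximity matrix: ", protein)
  }
  d <- prox$distance[protein, tfs]
  if (aggregate == "min") min(d) else mean(d)
}

#' Rank assay proteins by network proximity to a gene
#'
#' Orders the proteins of the proximity matrix by ascending aggregated
#' distance to the gene's TFs and attaches each protein's representative-site
#' phosphorylation fold change (ratio scale, 1 = no change).
#'
#' @param gene gene symbol of interest.
#' @param prox a `proximity_matrix`.
#' @param regulons regulon table naming the gene's TFs.
#' @param k number of proteins to keep (default 30); all if fewer.
#' @param fcs optional fold-change table for a single treatment used to
#'   attach the representative-site fold change.
#' @param aggregate passed to [gene_distance()].
#' @return data.frame `protein`, `distance`, `fold_change` (NA when `fcs` is
#'   absent or lacks the protein), ascending by distance with lexicographic
#'   tie-break.
#' @export
rank_proteins_by_gene_proximity <- function(gene, prox, regulons, k = 30,
                                            fcs = NULL,
                                            aggregate = c("min", "mean")) {
  if (k <= 0) stop("k must be positive")
  aggregate <- match.arg(aggregate)
  proteins <- rownames(prox$distance)
  d <- vapply(proteins, function(p)
    gene_distance(p, gene, regulons, prox, aggregate), 0.0)
  out <- data.frame(protein = proteins, distance = as.numeric(d))
  out$fold_change <- NA_real_
  if (!is.null(fcs) && nrow(fcs) > 0) {
    rep_site <- representative_site_per_protein(fcs)
    fc_map <- stats::setNames(2^rep_site$log2fc, rep_site$protein)
    hit <- out$protein %in% names(fc_map)
    out$fold_change[hit] <- fc_map[out$protein[hit]]
  }
  out <- out[order_lex(out$distance, out$protein), , drop = FALSE]
  out <- utils::head(out, k)
  rownames(out) <- NULL
  out
}

#' Are phospho-altered proteins closer to a TF set than unaltered ones?
#'
#' Splits the proximity-matrix proteins into those with any phosphosite fold
#' change above `fold_threshold` (ratio scale) and the rest, aggregates each
#' protein's distance to the given TFs (minimum), and compares the two
#' distance samples with a Mann-Whitney (Wilcoxon rank-sum) test, one-sided
#' by default: altered distances lower.
#'
#' @param prox a `proximity_matrix`.
#' @param fcs fold-change table with `log2fc` (raw, unsigned scale).
#' @param tfs character vector of TF symbols defining the target set;
#'   defaults to all columns of `prox`.
#' @param fold_threshold ratio cutoff for "altered" (default 1.5).
#' @param alternative "less" (default, altered < unaltered) or "two.sided".
#' @return list with `statistic` (U), `p.value`, `n_altered`, `n_unaltered`,
#'   `alternative`.
#' @export
compare_altered_vs_unaltered_distances <- function(prox, fcs, tfs = NULL,
                                                   fold_threshold = 1.5,
                                                   alternative = c("less",
                                                                   "two.sided")) {
  alternative <- match.arg(alternative)
  if (is.null(tfs)) tfs <- colnames(prox$distance)
  tfs <- intersect(normalize_symbols(tfs), colnames(prox$distance))
  if (length(tfs) == 0) stop("none of the TFs are in the proximity matrix")
  altered_prot <- unique(fcs$protein[2^fcs$log2fc > fold_threshold])
  proteins <- rownames(prox$distance)
  grp_alt <- intersect(proteins, altered_prot)
  grp_un <- setdiff(proteins, altered_prot)
  if (length(grp_alt) == 0) stop("altered group is empty")
  if (length(grp_un) == 0) stop("unaltered group is empty")
  dsub <- prox$distance[, tfs, drop = FALSE]
  agg <- apply(dsub, 1, min)
  x <- agg[grp_alt]; y <- agg[grp_un]
  exact <- length(x) <= 20 && length(y) <= 20 &&
    !any(duplicated(c(x, y)))
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = alternative,
                                            exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p.value = wt$p.value,
       n_altered = length(x), n_unaltered = length(y),
       alternative = alternative)
}
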