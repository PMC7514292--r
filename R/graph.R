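#' Convert NTE weights to shortest-path distances
#'
#' Stronger flow means a shorter path: `distance = 1/weight` (the
#' default) or `-log(weight)` for weights in `(0, 1]`. Zero-weight edges
#' are absent (`Inf`); the diagonal is 0.
#'
#' @param cm a `connectivity_matrix` (or a bare nonnegative matrix).
#' @param mapping `"reciprocal"` or `"neglog"`.
#' @return An object of class `distance_matrix`: list with `distances`
#'   (N x N, `Inf` for absent edges) and `mapping`.
#' @export
weight_to_distance <- function(cm, mapping = c("reciprocal", "neglog")) {
  mapping <- match.arg(mapping)
  w <- if (inherits(cm, "connectivity_matrix")) cm$weights else as.matrix(cm)
  if (any(w < 0)) stop("weights must be nonnegative")
  d <- matrix(Inf, nrow(w), ncol(w), dimnames = dimnames(w))
  pos <- w > 0
  d[pos] <- if (mapping == "reciprocal") 1 / w[pos] else -log(w[pos])
  diag(d) <- 0
  structure(list(distances = d, mapping = mapping), class = "distance_matrix")
}

dist_graph <- function(dm) {
  d <- dm$distances
  adj <- ifelse(is.finite(d) & d > 0, d, 0)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "directed",
                                           weighted = TRUE, diag = FALSE)
  g
}

#' Betweenness centrality of every node
#'
#' Fraction of all shortest paths that pass through each node, counting
#' tied shortest paths, normalized by `(n-1)(n-2)` so values lie in
#' `[0, 1]`. Pairs with no connecting path contribute nothing.
#'
#' @param dm a `distance_matrix` (see [weight_to_distance()]), or a
#'   `connectivity_matrix` (converted with the default mapping).
#' @return Named numeric vector of centralities in `[0, 1]`.
#' @export
betweenness_centrality <- function(dm) {
  if (inherits(dm, "connectivity_matrix")) dm <- weight_to_distance(dm)
  n <- nrow(dm$distances)
  if (n < 3) stop("betweenness normalization requires at least 3 nodes")
  g <- dist_graph(dm)
  bc <- igraph::betweenness(g, directed = TRUE,
                            weights = igraph::E(g)$weight)
  stats::setNames(as.numeric(bc) / ((n - 1) * (n - 2)),
                  rownames(dm$distances))
}

#' Characteristic path length
#'
#' Mean shortest-path distance over ordered node pairs. Unreachable
#' pairs are excluded from the average (with a message) so the measure
#' stays finite after node removal; an entirely disconnected graph is an
#' error.
#'
#' @inheritParams betweenness_centrality
#' @return A single nonnegative number.
#' @export
characteristic_path_length <- function(dm) {
  if (inherits(dm, "connectivity_matrix")) dm <- weight_to_distance(dm)
  n <- nrow(dm$distances)
  if (n < 2) stop("need at least 2 nodes")
  g <- dist_graph(dm)
  sp <- igraph::distances(g, mode = "out", weights = igraph::E(g)$weight)
  off <- sp[row(sp) != col(sp)]
  reachable <- is.finite(off)
  if (!any(reachable)) stop("graph is fully disconnected: no reachable pairs")
  if (!all(reachable))
    message(sum(!reachable), " of ", length(off),
            " ordered pairs unreachable; excluded from the average")
  mean(off[reachable])
}

#' Identify hubs from windowed betweenness-centrality samples
#'
#' A node is a hub when its per-window betweenness-centrality values are
#' statistically higher than the pooled values of all remaining nodes
#' (one-sided Mann-Whitney test at level `alpha`). No multiple-testing
#' correction is applied by default, matching the per-node 5% test of
#' the reference methodology; `correct = "bonferroni"` is available.
#'
#' @param bc matrix of betweenness values, windows x nodes, with column
#'   names (see [windowed_connectivity()] and [bc_samples()]).
#' @param alpha significance level in `(0, 1)`.
#' @param correct `"none"` (default) or `"bonferroni"`.
#' @return A data frame with columns `node`, `is_hub`, `p_value`,
#'   `median_bc`.
#' @export
identify_hubs <- function(bc, alpha = 0.05, correct = c("none", "bonferroni")) {
  correct <- match.arg(correct)
  bc <- as.matrix(bc)
  if (nrow(bc) < 2)
    stop("need at least 2 betweenness samples per node; run windowed BC first")
  if (is.null(colnames(bc))) colnames(bc) <- sprintf("Ch%d", seq_len(ncol(bc)))
  stopifnot(alpha > 0, alpha < 1)
  p <- vapply(seq_len(ncol(bc)), function(i) {
    suppressWarnings(
      wilcox.test(bc[, i], as.vector(bc[, -i]),
                  alternative = "greater", exact = FALSE)$p.value)
  }, 0)
  if (correct == "bonferroni") p <- pmin(1, p * ncol(bc))
  data.frame(node = colnames(bc), is_hub = p < alpha, p_value = p,
             median_bc = apply(bc, 2, median), row.names = NULL)
}

#' Percent impact of node removal on the characteristic path length
#'
#' Removes the named nodes (rows and columns) from the connectivity
#' matrix and reports `100 * (l_after - l_before) / l_before`, the
#' percent variation of the characteristic path length with the complete
#' network as benchmark. Positive values mean the removal lengthened the
#' remaining shortest paths (the network got less efficient).
#'
#' @param cm a `connectivity_matrix`.
#' @param nodes character vector of channel labels, a proper subset.
#' @param mapping weight-to-distance mapping, see [weight_to_distance()].
#' @return Percent change (a single number).
#' @export
removal_impact <- function(cm, nodes, mapping = "reciprocal") {
  labels <- cm$channel_labels
  if (!all(nodes %in% labels))
    stop("unknown node label(s): ",
         paste(setdiff(nodes, labels), collapse = ", "))
  keep <- setdiff(labels, nodes)
  if (length(keep) < 2)
    stop("removal must leave at least 2 nodes")
  l_before <- characteristic_path_length(weight_to_distance(cm, mapping))
  sub <- cm$weights[keep, keep, drop = FALSE]
  l_after <- tryCatch(
    characteristic_path_length(weight_to_distance(sub, mapping)),
    error = function(e)
      stop("removing {", paste(nodes, collapse = ", "),
           "} disconnects the remaining graph entirely"))
  100 * (l_after - l_before) / l_before
}
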