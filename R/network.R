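# Community detection (multilevel modularity optimisation) and eigenvector
# centrality on the estimated partial-correlation network. Isolated nodes are
# excluded from detection and score 0 centrality.

#' Louvain (multilevel) community detection
#'
#' Runs multilevel modularity optimisation on the subgraph of non-isolated
#' nodes, with edge weights `|rho_ij|` (default) or 1. The node visit order is
#' shuffled by `seed`, making the partition deterministic for a fixed seed.
#' Community ids are relabelled 1..K by first appearance in node order.
#'
#' @param net a `"pcor_network"` (see [to_network()]).
#' @param weight_mode `"abs"` uses `|partial correlation|` weights; `"binary"`
#'   uses unit weights.
#' @param seed integer seed for the node-visit shuffle.
#' @return Object of class `"community_partition"`: `membership` (named
#'   integer over non-isolated nodes), `isolated`, `modularity`,
#'   `weight_mode`, `n_communities`.
#' @export
louvain_communities <- function(net, weight_mode = c("abs", "binary"),
                                seed = 1L) {
  weight_mode <- match.arg(weight_mode)
  if (!nrow(net$edges))
    stop("the network has no edges among non-isolated nodes; nothing to cluster",
         call. = FALSE)
  g <- net_igraph(net, weight_mode)
  vn <- igraph::V(g)$name
  memb <- with_seed(seed, {
    perm <- sample(seq_along(vn))
    gp <- igraph::permute(g, perm)
    cl <- igraph::cluster_louvain(gp, weights = igraph::E(gp)$weight)
    m <- igraph::membership(cl)
    m[match(vn, names(m))]
  })
  # canonical labels: 1..K in order of first appearance along the node order
  lab <- match(memb, unique(memb))
  names(lab) <- vn
  q <- modularity_q(net, lab, weight_mode)
  out <- list(membership = lab, isolated = net$isolated, modularity = q,
              weight_mode = weight_mode, n_communities = max(lab),
              seed = seed)
  class(out) <- "community_partition"
  out
}

#' @export
print.community_partition <- function(x, ...) {
  sizes <- table(x$membership)
  cat(sprintf("Community partition: %d communities (sizes %s), %d isolated, Q = %.3f\n",
              x$n_communities, paste(sizes, collapse = "/"),
              length(x$isolated), x$modularity))
  invisible(x)
}

#' Weighted Newman-Girvan modularity
#'
#' `Q = sum_c (e_c / m - (d_c / 2m)^2)` where `e_c` is the within-community
#' edge weight, `d_c` the total strength of community `c`, and `m` the total
#' edge weight.
#'
#' @param net a `"pcor_network"`, or a data frame with columns `from`, `to`,
#'   `weight`.
#' @param membership named vector of community labels covering the
#'   non-isolated nodes.
#' @param weight_mode `"abs"` or `"binary"` (ignored when `net` is an edge
#'   data frame with its own weights).
#' @return Modularity Q in `[-0.5, 1]`.
#' @export
modularity_q <- function(net, membership, weight_mode = c("abs", "binary")) {
  weight_mode <- match.arg(weight_mode)
  if (is.data.frame(net)) {
    edges <- net
    w <- edges$weight %||% rep(1, nrow(edges))
  } else {
    edges <- net$edges
    w <- if (weight_mode == "abs") abs(edges$pcor) else rep(1, nrow(edges))
  }
  ci <- membership[edges$from]
  cj <- membership[edges$to]
  if (anyNA(ci) || anyNA(cj))
    stop("membership does not cover all edge endpoints", call. = FALSE)
  m <- sum(w)
  ec <- tapply(w[ci == cj], ci[ci == cj], sum)
  strength <- tapply(c(w, w), c(ci, cj), sum)  # d_c
  comms <- unique(membership)
  e_c <- ec[as.character(comms)]
  e_c[is.na(e_c)] <- 0
  d_c <- strength[as.character(comms)]
  d_c[is.na(d_c)] <- 0
  sum(e_c / m - (d_c / (2 * m))^2)
}

#' Eigenvector centrality with per-component max-1 normalisation
#'
#' Power iteration on the weighted adjacency of each connected component of
#' the non-isolated subgraph (tolerance 1e-10, at most 1e4 iterations). Scores
#' are non-negative and rescaled so that each component's maximum is 1;
#' isolated nodes score 0.
#'
#' @param net a `"pcor_network"`.
#' @param weight_mode `"abs"` or `"binary"` edge weights.
#' @param normalization `"component_max"` (default) or `"l2"` (unit Euclidean
#'   norm per component).
#' @param tol convergence tolerance on the max absolute change.
#' @param max_iter iteration cap; non-convergence is an error.
#' @return Named numeric vector over all nodes (class-free).
#' @export
eigenvector_centrality <- function(net, weight_mode = c("abs", "binary"),
                                   normalization = c("component_max", "l2"),
                                   tol = 1e-10, max_iter = 10000) {
  weight_mode <- match.arg(weight_mode)
  normalization <- match.arg(normalization)
  if (!nrow(net$edges)) stop("the network has no edges", call. = FALSE)
  A <- net_adjacency(net, weight_mode)
  nodes <- net$nodes
  scores <- setNames(numeric(length(nodes)), nodes)
  g <- net_igraph(net, weight_mode)
  comp <- igraph::components(g)
  for (k in seq_len(comp$no)) {
    members <- names(comp$membership)[comp$membership == k]
    if (length(members) < 2) next
    Ak <- A[members, members, drop = FALSE]
    # spectral shift: A + sI has the same eigenvectors but a strictly
    # dominant Perron root even on bipartite components (where |lambda_min|
    # equals lambda_max and unshifted power iteration oscillates)
    shift <- max(rowSums(Ak))
    diag(Ak) <- diag(Ak) + shift
    v <- rep(1 / sqrt(length(members)), length(members))
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      v_new <- Ak %*% v
      nrm <- sqrt(sum(v_new^2))
      if (nrm == 0) stop("zero adjacency in component ", k, call. = FALSE)
      v_new <- as.vector(v_new) / nrm
      if (max(abs(v_new - v)) < tol) { v <- v_new; converged <- TRUE; break }
      v <- v_new
    }
    if (!converged)
      stop(sprintf("power iteration did not converge in %d iterations", max_iter),
           call. = FALSE)
    v <- abs(v)  # Perron vector is entrywise non-negative
    if (normalization == "component_max") v <- v / max(v)
    scores[members] <- v
  }
  scores
}

#' Most central node of each community
#'
#' @param partition a `"community_partition"`.
#' @param centrality named centrality vector from [eigenvector_centrality()].
#' @return Named character vector, one node per community; lexicographic
#'   tie-break with a warning.
#' @export
central_nodes <- function(partition, centrality) {
  memb <- partition$membership
  out <- character(partition$n_communities)
  for (c in seq_len(partition$n_communities)) {
    members <- sort(names(memb)[memb == c])
    sc <- centrality[members]
    top <- members[sc == max(sc)]
    if (length(top) > 1)
      warning("centrality tie in community ", c, "; breaking lexicographically",
              call. = FALSE)
    out[c] <- top[1]
  }
  names(out) <- paste0("c", seq_len(partition$n_communities))
  out
}

#' Write partition and centrality as TSV
#'
#' One row per node: node, community (`NA` for isolated), centrality,
#' is_isolated.
#'
#' @param net a `"pcor_network"`.
#' @param partition a `"community_partition"`.
#' @param centrality named centrality vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_partition <- function(net, partition, centrality, path) {
  df <- data.frame(
    node = net$nodes,
    community = unname(partition$membership[net$nodes]),
    centrality = unname(centrality[net$nodes]),
    is_isolated = net$nodes %in% partition$isolated)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
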