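#' Fit a dietary network model
#'
#' The central estimator: from a participants-by-food-groups intake matrix it
#' (1) applies the `log10(1 + g/day)` transform, (2) computes the divisor-n
#' sample covariance, (3) selects the graphical-lasso penalty by StARS unless
#' `lambda` is given, (4) estimates the sparse precision matrix, (5) converts
#' it to a signed partial-correlation network, and (6) detects communities
#' (multilevel modularity optimisation) and eigenvector centralities on the
#' non-isolated subgraph.
#'
#' @param x numeric matrix, participants in rows, food groups in columns. Raw
#'   grams/day by default; a matrix already carrying
#'   `attr(x, "transform") == "log10p1"` is used as-is.
#' @param lambda fixed penalty; `NULL` (default) selects it by StARS.
#' @param stars a [stars_control()] used when `lambda` is `NULL`.
#' @param scale fit on the correlation (`"cor"`, default) or covariance
#'   (`"cov"`) of the transformed intakes. The correlation scale applies the
#'   same effective penalty to every partial correlation regardless of the
#'   food group's variance; covariance-scale fitting is available for
#'   sensitivity analysis.
#' @param weight_mode `"abs"` (default) or `"binary"` edge weights for
#'   community detection and centrality.
#' @param zero_tol edge-calling tolerance on `|Theta_ij|`.
#' @param seed integer seed driving StARS subsampling and the community
#'   detection visit order.
#' @return Object of class `"dietary_network"` with components `S`, `lambda`,
#'   `stars` (profile or `NULL`), `precision`, `network`, `communities`,
#'   `centrality`, `central_nodes`, `modularity`, `mu` (means of the
#'   transformed intakes), `n`, `call`.
#' @seealso [predict.dietary_network()] for per-person community scores,
#'   [simulate.dietary_network()] for draws from the fitted model.
#' @export
#' @examples
#' spec <- cohort_spec(n = 400, network = planted_network_spec(
#'   p = 12, community_sizes = c(4, 4), seed = 7), seed = 7)
#' cohort <- simulate_cohort(spec)
#' fit <- dietary_network(cohort$intakes, lambda = 0.01, seed = 7)
#' print(fit)
dietary_network <- function(x, lambda = NULL, stars = stars_control(),
                            scale = c("cor", "cov"),
                            weight_mode = c("abs", "binary"),
                            zero_tol = 1e-6, seed = 1L) {
  scale <- match.arg(scale)
  weight_mode <- match.arg(weight_mode)
  cl <- match.call()
  if (!is.matrix(x)) x <- as.matrix(x)
  xlog <- if (intake_state(x) == "log10p1") x else log_transform(x)
  S <- sample_covariance(xlog, scale = scale)
  profile <- NULL
  if (is.null(lambda)) {
    profile <- stars_select(xlog, control = stars, scale = scale,
                            seed = derive_seed(seed, 1L))
    lambda <- profile$lambda
  }
  prec <- graphical_lasso(S, lambda)
  net <- to_network(prec, zero_tol = zero_tol)
  communities <- NULL
  centrality <- setNames(numeric(length(net$nodes)), net$nodes)
  centers <- NULL
  modularity <- NA_real_
  if (nrow(net$edges)) {
    communities <- louvain_communities(net, weight_mode = weight_mode,
                                       seed = derive_seed(seed, 2L))
    centrality <- eigenvector_centrality(net, weight_mode = weight_mode)
    centers <- central_nodes(communities, centrality)
    modularity <- communities$modularity
  }
  out <- list(S = S, lambda = lambda, stars = profile, precision = prec,
              network = net, communities = communities,
              centrality = centrality, central_nodes = centers,
              modularity = modularity, mu = colMeans(xlog),
              n = nrow(xlog), weight_mode = weight_mode, scale = scale,
              seed = seed, call = cl)
  class(out) <- "dietary_network"
  out
}

#' @export
print.dietary_network <- function(x, ...) {
  cat("Dietary network model\n")
  cat(sprintf("  %d food groups, %d participants\n",
              length(x$network$nodes), x$n))
  cat(sprintf("  lambda = %.4f (%s), %d edges, %d isolated nodes\n",
              x$lambda, if (is.null(x$stars)) "fixed" else "StARS",
              nrow(x$network$edges), length(x$network$isolated)))
  if (!is.null(x$communities)) {
    sizes <- table(x$communities$membership)
    cat(sprintf("  %d communities (sizes %s), modularity Q = %.3f\n",
                x$communities$n_communities, paste(sizes, collapse = "/"),
                x$modularity))
  } else cat("  no communities (empty graph)\n")
  invisible(x)
}

#' @export
summary.dietary_network <- function(object, ...) {
  comm <- NULL
  if (!is.null(object$communities)) {
    memb <- object$communities$membership
    comm <- data.frame(
      community = paste0("c", seq_len(object$communities$n_communities)),
      size = as.integer(table(memb)),
      central_node = unname(object$central_nodes),
      stringsAsFactors = FALSE)
  }
  out <- list(fit = object, communities = comm,
              edges = object$network$edges,
              isolated = object$network$isolated,
              centrality = sort(object$centrality, decreasing = TRUE))
  class(out) <- "summary.dietary_network"
  out
}

#' @export
print.summary.dietary_network <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$communities)) {
    cat("\nCommunities:\n")
    print(x$communities, row.names = FALSE)
  }
  if (length(x$isolated))
    cat("\nIsolated nodes:", paste(x$isolated, collapse = ", "), "\n")
  cat("\nStrongest conditional dependencies:\n")
  e <- x$edges[order(-abs(x$edges$pcor)), ]
  print(head(e, 10), row.names = FALSE)
  invisible(x)
}

#' Partial-correlation matrix of a fitted dietary network
#'
#' @param object a `"dietary_network"`.
#' @param ... unused.
#' @return The p x p signed partial-correlation matrix.
#' @export
coef.dietary_network <- function(object, ...) object$network$pcor

#' Community scores for new participants
#'
#' Applies the fitted partition and centralities to raw intakes, returning
#' the per-person community network-based scores (and quintiles).
#'
#' @param object a `"dietary_network"`.
#' @param newdata raw intake matrix (grams/day) covering the fitted food
#'   groups.
#' @param type `"table"` (scores + quintiles, default), `"scores"`, or
#'   `"quintiles"`.
#' @param ... unused.
#' @return See `type`.
#' @export
predict.dietary_network <- function(object, newdata,
                                    type = c("table", "scores", "quintiles"),
                                    ...) {
  type <- match.arg(type)
  if (is.null(object$communities))
    stop("the fitted network has no communities; no scores to compute",
         call. = FALSE)
  switch(type,
         scores = community_scores(newdata, object$communities,
                                   object$centrality),
         quintiles = assign_quintiles(
           community_scores(newdata, object$communities, object$centrality)),
         table = score_table(newdata, object$communities, object$centrality))
}

#' Simulate intakes from a fitted dietary network
#'
#' Draws transformed intakes from `N(mu, Theta^-1)` at the fitted precision
#' and back-transforms to grams/day (`10^y - 1`, clipped at 0).
#'
#' @param object a `"dietary_network"`.
#' @param nsim number of datasets.
#' @param seed integer seed.
#' @param n rows per dataset (default: the fitted n).
#' @param ... unused.
#' @return A raw intake matrix, or a list of `nsim` matrices.
#' @export
simulate.dietary_network <- function(object, nsim = 1, seed = 1L, n = NULL,
                                     ...) {
  n <- n %||% object$n
  one <- function(s) {
    x <- sample_intakes(n, object$precision$theta, zero_inflation = 0,
                        location = object$mu, scale = 1, seed = s)
    x
  }
  if (nsim == 1) return(one(seed))
  lapply(seq_len(nsim), function(i) one(derive_seed(seed, i)))
}

#' Plot a fitted dietary network
#'
#' Non-isolated subgraph with nodes coloured by community, edge width
#' proportional to `|partial correlation|`, solid edges for positive and
#' dashed for negative conditional dependencies.
#'
#' @param x a `"dietary_network"`.
#' @param vertex_cex label scaling.
#' @param ... passed to `igraph::plot.igraph`.
#' @return `x`, invisibly.
#' @export
plot.dietary_network <- function(x, vertex_cex = 0.7, ...) {
  if (!nrow(x$network$edges)) {
    warning("empty network; nothing to plot", call. = FALSE)
    return(invisible(x))
  }
  g <- net_igraph(x$network, x$weight_mode)
  memb <- x$communities$membership[igraph::V(g)$name]
  pal <- grDevices::hcl.colors(max(memb), "Dark 3")
  sign_pos <- x$network$edges$pcor >= 0
  igraph::plot.igraph(
    g,
    vertex.color = pal[memb],
    vertex.size = 6 + 14 * x$centrality[igraph::V(g)$name],
    vertex.label.cex = vertex_cex,
    edge.width = 1 + 6 * abs(x$network$edges$pcor),
    edge.lty = ifelse(sign_pos, 1, 2),
    layout = with_seed(x$seed, igraph::layout_with_fr(g)), ...)
  invisible(x)
}
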