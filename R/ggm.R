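# Sparse Gaussian graphical model estimation: sample covariance, graphical
# lasso (off-diagonal L1 penalty), and conversion to a signed
# partial-correlation network.

#' Sample covariance of log-transformed intakes
#'
#' Computes the divisor-`n` sample covariance `S = (1/n) * crossprod(X - xbar)`
#' used by the penalised-likelihood estimator. Intakes must already be on the
#' `log10(1 + g/day)` scale (see [log_transform()]).
#'
#' @param x numeric matrix, participants in rows, food groups in columns.
#' @param scale `"cov"` (default) fits on the covariance; `"cor"` rescales to
#'   the correlation matrix.
#' @return A `p x p` symmetric matrix with attribute `n`.
#' @export
sample_covariance <- function(x, scale = c("cov", "cor")) {
  scale <- match.arg(scale)
  if (!is.matrix(x)) x <- as.matrix(x)
  if (intake_state(x) == "raw")
    stop("intakes are on the raw grams/day scale; apply log_transform() first",
         call. = FALSE)
  n <- nrow(x)
  p <- ncol(x)
  if (n <= p)
    warning(sprintf("n (%d) <= p (%d): covariance is singular or near-singular",
                    n, p), call. = FALSE)
  v <- apply(x, 2, var)
  if (any(v == 0)) {
    bad <- colnames(x)[v == 0] %||% which(v == 0)
    stop("constant column(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  xc <- sweep(x, 2, colMeans(x))
  S <- crossprod(xc) / n
  if (scale == "cor") S <- stats::cov2cor(S)
  S <- (S + t(S)) / 2
  dimnames(S) <- list(colnames(x), colnames(x))
  attr(S, "n") <- n
  S
}

#' Graphical lasso precision estimate
#'
#' Maximises `log det(Theta) - tr(S Theta) - lambda * sum_{i != j} |Theta_ij|`
#' (penalty on off-diagonal entries only) by blockwise coordinate descent,
#' stopping when the duality gap `tr(S Theta) + lambda*||Theta||_1,off - p`
#' falls below `tol`. At `lambda = 0` the unpenalised maximum-likelihood
#' inverse is returned directly.
#'
#' @param S symmetric covariance matrix with positive diagonal.
#' @param lambda non-negative penalty.
#' @param tol duality-gap stopping tolerance.
#' @param max_sweeps maximum full coordinate-descent sweeps.
#' @param warm optional previous `"precision_estimate"` used as a warm start
#'   (speeds up descending-lambda paths).
#' @return An object of class `"precision_estimate"`: list with `theta`
#'   (precision matrix), `w` (its inverse, the covariance estimate),
#'   `lambda`, `gap`, `sweeps`, `converged`.
#' @export
graphical_lasso <- function(S, lambda, tol = 1e-6, max_sweeps = 500,
                            warm = NULL) {
  check_square_symmetric(S, "S")
  if (any(diag(S) <= 0)) stop("S must have a positive diagonal", call. = FALSE)
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda < 0)
    stop("'lambda' must be a single non-negative number", call. = FALSE)
  nms <- colnames(S)
  p <- ncol(S)

  if (lambda == 0) {
    ch <- tryCatch(chol(S), error = function(e)
      stop("S is singular: the unpenalised estimate requires lambda > 0",
           call. = FALSE))
    theta <- chol2inv(ch)
    dimnames(theta) <- dimnames(S) <- list(nms, nms)
    out <- list(theta = theta, w = S, lambda = 0, gap = 0, sweeps = 0L,
                converged = TRUE)
    class(out) <- "precision_estimate"
    return(out)
  }

  w0 <- if (!is.null(warm)) warm$w else NULL
  b0 <- if (!is.null(warm)) warm$beta else NULL
  fit <- glasso_cd(unname(S), lambda, tol, as.integer(max_sweeps), w0, b0)
  if (!fit$converged)
    stop(sprintf(
      "graphical lasso did not converge in %d sweeps (duality gap %.3e)",
      max_sweeps, fit$gap), call. = FALSE)
  theta <- (fit$theta + t(fit$theta)) / 2
  dimnames(theta) <- list(nms, nms)
  w <- fit$w
  dimnames(w) <- list(nms, nms)
  out <- list(theta = theta, w = w, beta = fit$beta, lambda = lambda,
              gap = fit$gap, sweeps = fit$sweeps, converged = TRUE)
  class(out) <- "precision_estimate"
  out
}

#' @export
print.precision_estimate <- function(x, ...) {
  p <- ncol(x$theta)
  ne <- sum(abs(x$theta[upper.tri(x$theta)]) > 1e-6)
  cat(sprintf(
    "Penalised precision estimate: %d nodes, %d edges, lambda = %.4g (gap %.1e, %d sweeps)\n",
    p, ne, x$lambda, x$gap, x$sweeps))
  invisible(x)
}

# penalised Gaussian log-likelihood (the objective being maximised)
penalised_loglik <- function(theta, S, lambda) {
  determinant(theta, logarithm = TRUE)$modulus[1] - sum(S * theta) -
    lambda * sum(abs(theta[row(theta) != col(theta)]))
}

#' Signed partial-correlation network from a precision matrix
#'
#' Edge `(i, j)` is present when `|Theta_ij| > zero_tol`, with weight
#' `rho_ij = -Theta_ij / sqrt(Theta_ii * Theta_jj)` (sign retained: positive
#' rho is a positive conditional dependency). All nodes are kept; nodes with
#' no edges are flagged as isolated.
#'
#' @param theta a `"precision_estimate"` or a symmetric positive-definite
#'   matrix.
#' @param zero_tol absolute threshold on `|Theta_ij|` for edge calling.
#' @return An object of class `"pcor_network"`: list with `nodes`, `edges`
#'   (data frame `from`, `to`, `pcor`), `pcor` (full matrix), `isolated`.
#' @export
to_network <- function(theta, zero_tol = 1e-6) {
  if (inherits(theta, "precision_estimate")) theta <- theta$theta
  check_square_symmetric(theta, "theta")
  p <- ncol(theta)
  nodes <- colnames(theta) %||% sprintf("v%02d", seq_len(p))
  d <- diag(theta)
  if (any(d <= 0)) stop("theta must have a positive diagonal", call. = FALSE)
  pc <- -theta / sqrt(outer(d, d))
  diag(pc) <- 1
  dimnames(pc) <- list(nodes, nodes)
  sel <- which(upper.tri(theta) & abs(theta) > zero_tol, arr.ind = TRUE)
  edges <- data.frame(from = nodes[sel[, 1]], to = nodes[sel[, 2]],
                      pcor = pc[sel], stringsAsFactors = FALSE)
  deg <- tabulate(match(c(edges$from, edges$to), nodes), nbins = p)
  out <- list(nodes = nodes, edges = edges, pcor = pc,
              isolated = nodes[deg == 0])
  class(out) <- "pcor_network"
  out
}

#' @export
print.pcor_network <- function(x, ...) {
  cat(sprintf("Partial-correlation network: %d nodes, %d edges, %d isolated\n",
              length(x$nodes), nrow(x$edges), length(x$isolated)))
  invisible(x)
}

# weighted adjacency on the full node set
net_adjacency <- function(net, weight_mode = c("abs", "binary")) {
  weight_mode <- match.arg(weight_mode)
  p <- length(net$nodes)
  A <- matrix(0, p, p, dimnames = list(net$nodes, net$nodes))
  if (nrow(net$edges)) {
    i <- match(net$edges$from, net$nodes)
    j <- match(net$edges$to, net$nodes)
    w <- if (weight_mode == "abs") abs(net$edges$pcor) else rep(1, nrow(net$edges))
    A[cbind(i, j)] <- w
    A[cbind(j, i)] <- w
  }
  A
}

# igraph view of the non-isolated subgraph
net_igraph <- function(net, weight_mode = c("abs", "binary")) {
  weight_mode <- match.arg(weight_mode)
  keep <- setdiff(net$nodes, net$isolated)
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = data.frame(name = keep))
  igraph::E(g)$weight <- if (weight_mode == "abs") abs(net$edges$pcor)
                         else rep(1, nrow(net$edges))
  g
}

#' Write a network as an edge-list TSV
#'
#' @param net a `"pcor_network"`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  e <- net$edges
  names(e) <- c("source", "target", "partial_correlation")
  write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
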