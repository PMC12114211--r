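# Independent oracles used to validate the package's estimators. These are
# deliberately slow, simple implementations that share no code with the
# package internals.

# Penalised Gaussian log-likelihood (objective being maximised); local copy so
# oracle checks do not depend on package internals.
oracle_objective <- function(theta, S, lambda) {
  determinant(theta, logarithm = TRUE)$modulus[1] - sum(S * theta) -
    lambda * sum(abs(theta[row(theta) != col(theta)]))
}

# Proximal-gradient (FISTA) minimiser of the penalised negative
# log-likelihood: gradient step on S - theta^-1, soft-threshold of the
# off-diagonal, momentum acceleration, step halving to stay positive
# definite.
ista_glasso <- function(S, lambda, max_iter = 20000, tol = 1e-12) {
  p <- ncol(S)
  soft <- function(m, t) {
    off <- sign(m) * pmax(abs(m) - t, 0)
    diag(off) <- diag(m)
    off
  }
  theta <- diag(1 / diag(S))
  y <- theta
  tk <- 1
  step <- 1 / max(eigen(S, symmetric = TRUE, only.values = TRUE)$values)^2
  obj_old <- -oracle_objective(theta, S, lambda)
  for (it in seq_len(max_iter)) {
    inv_y <- solve(y)
    cand <- soft(y - step * (S - inv_y), step * lambda)
    cand <- (cand + t(cand)) / 2
    ok <- inherits(try(chol(cand), silent = TRUE), "matrix")
    if (!ok) { step <- step / 2; tk <- 1; y <- theta; next }
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    y <- cand + ((tk - 1) / t_new) * (cand - theta)
    if (inherits(try(chol(y), silent = TRUE), "try-error")) y <- cand
    theta_new <- cand
    obj <- -oracle_objective(theta_new, S, lambda)
    if (obj > obj_old + 1e-10) { step <- step / 2; tk <- 1; y <- theta; next }
    conv <- abs(obj_old - obj) < tol * (abs(obj) + 1)
    theta <- theta_new
    obj_old <- obj
    tk <- t_new
    if (conv) break
  }
  theta
}

# random positive-definite covariance with non-trivial off-diagonal structure
random_cov <- function(p, seed) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(4 * p * p), 4 * p, p)
    crossprod(X) / (4 * p)
  })
}

# All set partitions of 1..n (Bell number of blocks), as membership vectors.
set_partitions <- function(n) {
  out <- list(rep(1L, 1))
  if (n == 1) return(out)
  for (k in 2:n) {
    new <- list()
    for (part in out) {
      mx <- max(part)
      for (b in seq_len(mx + 1))
        new[[length(new) + 1]] <- c(part, b)
    }
    out <- new
  }
  out
}

# Independent weighted modularity from the adjacency matrix:
# Q = (1/2m) * sum_ij (A_ij - d_i d_j / 2m) [c_i == c_j]
oracle_modularity <- function(A, membership) {
  m2 <- sum(A)
  d <- rowSums(A)
  same <- outer(membership, membership, `==`)
  sum((A - outer(d, d) / m2) * same) / m2
}

edges_to_adjacency <- function(edges, nodes) {
  A <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  w <- edges$weight %||% rep(1, nrow(edges))
  i <- match(edges$from, nodes)
  j <- match(edges$to, nodes)
  A[cbind(i, j)] <- w
  A[cbind(j, i)] <- w
  A
}

# Exhaustive-search maximum modularity over every partition of the node set.
brute_force_modularity <- function(edges, nodes) {
  A <- edges_to_adjacency(edges, nodes)
  parts <- set_partitions(length(nodes))
  qs <- vapply(parts, function(pp) oracle_modularity(A, pp), numeric(1))
  list(q = max(qs), partition = setNames(parts[[which.max(qs)]], nodes))
}

# Hand-written Cox partial log-likelihood for a single covariate, no ties.
cox_partial_loglik <- function(beta, time, event, x) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  eta <- beta * x
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + eta[i] - log(sum(exp(eta[risk])))
  }
  ll
}

cox_brute_force <- function(time, event, x) {
  stats::optimize(function(b) -cox_partial_loglik(b, time, event, x),
                  c(-10, 10), tol = 1e-10)$minimum
}

# Empirical partial correlation of two columns given all others, from the
# inverse of the sample covariance.
empirical_pcor <- function(x) {
  Ominv <- solve(stats::cov(x))
  d <- diag(Ominv)
  pc <- -Ominv / sqrt(outer(d, d))
  diag(pc) <- 1
  pc
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Map each detected community label to estimated labels on the true
# community nodes, giving estimated-isolated nodes their own singleton
# labels (for ARI against the planted partition).
estimated_labels_on <- function(true_nodes, fit) {
  est <- fit$communities$membership
  lab <- ifelse(true_nodes %in% names(est), est[true_nodes], NA)
  nmiss <- sum(is.na(lab))
  if (nmiss) lab[is.na(lab)] <- max(est) + seq_len(nmiss)
  lab
}
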