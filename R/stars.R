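# Penalty selection by the Stability Approach to Regularization Selection
# (StARS): refit the graphical lasso on subsamples, measure per-edge
# selection instability, and pick the least regularisation whose monotonised
# total instability stays below a threshold.

#' StARS settings
#'
#' Defaults follow the original StARS recommendation: `n_sub = 20` subsamples
#' of size `floor(10 * sqrt(n))` (capped at `n`), instability threshold
#' `beta = 0.05`, and a 30-point log-spaced penalty grid from
#' `lambda_max = max_{i != j} |S_ij|` down to `0.1 * lambda_max`.
#'
#' @param n_grid grid length.
#' @param grid_ratio smallest grid value as a fraction of `lambda_max`.
#' @param n_sub number of subsamples.
#' @param sub_size subsample size; `NULL` means `floor(10 * sqrt(n))`.
#' @param beta instability threshold in (0, 1).
#' @param zero_tol edge-calling tolerance passed to [to_network()].
#' @return A list of class `"stars_control"`.
#' @export
stars_control <- function(n_grid = 30, grid_ratio = 0.1, n_sub = 20,
                          sub_size = NULL, beta = 0.05, zero_tol = 1e-6) {
  stopifnot(n_grid >= 2, grid_ratio > 0, grid_ratio < 1, n_sub >= 2,
            beta > 0, beta < 1)
  structure(list(n_grid = n_grid, grid_ratio = grid_ratio, n_sub = n_sub,
                 sub_size = sub_size, beta = beta, zero_tol = zero_tol),
            class = "stars_control")
}

#' Default penalty grid
#'
#' Log-spaced descending grid from `lambda_max = max_{i != j} |S_ij|` (the
#' smallest penalty yielding an empty graph) down to `grid_ratio * lambda_max`.
#'
#' @param S covariance matrix.
#' @param n_grid grid length.
#' @param grid_ratio ratio of smallest to largest grid value.
#' @return Strictly descending numeric vector.
#' @export
stars_grid <- function(S, n_grid = 30, grid_ratio = 0.1) {
  check_square_symmetric(S, "S")
  off <- abs(S[row(S) != col(S)])
  lmax <- max(off)
  if (lmax == 0)
    stop("S is already diagonal (max off-diagonal 0); no grid to build",
         call. = FALSE)
  exp(seq(log(lmax), log(grid_ratio * lmax), length.out = n_grid))
}

#' Subsampling edge-selection instability
#'
#' For each of `n_sub` seeded subsamples (without replacement) fits the
#' graphical lasso along the descending penalty grid (warm starts) and records
#' edge indicators. The per-edge instability is `2 * f * (1 - f)` where `f` is
#' the selection frequency; `D(lambda)` averages it over the `p(p-1)/2` pairs.
#'
#' @param x log-transformed intake matrix (n x p).
#' @param grid descending penalty grid; `NULL` builds [stars_grid()] from the
#'   full-sample covariance.
#' @param control a [stars_control()].
#' @param seed integer; spawns one sub-seed per subsample.
#' @param scale covariance (`"cov"`) or correlation (`"cor"`) fitting scale.
#' @return Object of class `"stars_profile"`: `grid`, `D`, `D_bar`
#'   (monotonised), `edge_count` (mean over subsamples), `freq` (p x p x G
#'   selection frequencies), `n_sub_used`, `sub_size`, `failures`.
#' @export
edge_instability <- function(x, grid = NULL, control = stars_control(),
                             seed = 1L, scale = c("cor", "cov")) {
  scale <- match.arg(scale)
  if (!is.matrix(x)) x <- as.matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  b <- control$sub_size %||% min(n, floor(10 * sqrt(n)))
  if (b < 1 || b > n) stop("subsample size must be in [1, n]", call. = FALSE)
  if (is.null(grid)) {
    S_full <- sample_covariance(x, scale = scale)
    grid <- stars_grid(S_full, control$n_grid, control$grid_ratio)
  }
  if (is.unsorted(rev(grid), strictly = FALSE))
    stop("'grid' must be descending", call. = FALSE)
  G <- length(grid)

  counts <- array(0L, dim = c(p, p, G))
  used <- 0L
  failures <- 0L
  for (i in seq_len(control$n_sub)) {
    idx <- with_seed(derive_seed(seed, i), sample.int(n, b))
    ok <- tryCatch({
      xsub <- x[idx, , drop = FALSE]
      attr(xsub, "transform") <- intake_state(x)
      Ssub <- sample_covariance(xsub, scale = scale)
      warm <- NULL
      for (g in seq_len(G)) {
        fit <- graphical_lasso(Ssub, grid[g], warm = warm)
        warm <- fit
        adj <- abs(fit$theta) > control$zero_tol
        diag(adj) <- FALSE
        counts[, , g] <- counts[, , g] + adj
      }
      TRUE
    }, error = function(e) {
      warning("subsample ", i, " dropped: ", conditionMessage(e),
              call. = FALSE)
      FALSE
    })
    if (ok) used <- used + 1L else failures <- failures + 1L
  }
  if (failures > 0.2 * control$n_sub)
    stop(sprintf("%d of %d StARS subsample fits failed", failures,
                 control$n_sub), call. = FALSE)

  freq <- counts / used
  ut <- upper.tri(matrix(0, p, p))
  npairs <- p * (p - 1) / 2
  D <- vapply(seq_len(G), function(g) {
    f <- freq[, , g][ut]
    mean(2 * f * (1 - f))
  }, numeric(1))
  edge_count <- vapply(seq_len(G), function(g) sum(freq[, , g][ut]), numeric(1))
  # sup-monotonisation from the sparse (large-lambda) end:
  # D_bar(lambda) = max over lambda' >= lambda of D(lambda')
  D_bar <- cummax(D)
  out <- list(grid = grid, D = D, D_bar = D_bar, edge_count = edge_count,
              freq = freq, n = n, n_sub_used = used, sub_size = b,
              failures = failures, npairs = npairs)
  class(out) <- "stars_profile"
  out
}

#' Select the StARS penalty from a stability profile
#'
#' `lambda_hat` is the smallest grid penalty whose monotonised instability
#' `D_bar` does not exceed `beta`; if no grid point qualifies the largest
#' (sparsest) grid value is returned with a warning.
#'
#' @param profile a `"stars_profile"`.
#' @param beta instability threshold.
#' @return List with `lambda`, `index`, `feasible`.
#' @export
select_lambda <- function(profile, beta = 0.05) {
  stopifnot(inherits(profile, "stars_profile"))
  ok <- which(profile$D_bar <= beta)
  if (!length(ok)) {
    warning("no grid penalty meets the instability threshold; ",
            "returning the largest (sparsest) grid value", call. = FALSE)
    return(list(lambda = profile$grid[1], index = 1L, feasible = FALSE))
  }
  i <- max(ok)  # grid is descending: largest index = smallest lambda
  list(lambda = profile$grid[i], index = i, feasible = TRUE)
}

#' One-call StARS selection
#'
#' @inheritParams edge_instability
#' @return The `"stars_profile"` with `lambda`, `lambda_index`, `beta` filled
#'   in.
#' @export
stars_select <- function(x, grid = NULL, control = stars_control(),
                         seed = 1L, scale = c("cor", "cov")) {
  profile <- edge_instability(x, grid = grid, control = control, seed = seed,
                              scale = scale)
  sel <- select_lambda(profile, control$beta)
  profile$lambda <- sel$lambda
  profile$lambda_index <- sel$index
  profile$feasible <- sel$feasible
  profile$beta <- control$beta
  profile
}

#' @export
print.stars_profile <- function(x, ...) {
  cat(sprintf("StARS stability profile: %d penalties, %d subsamples of %d\n",
              length(x$grid), x$n_sub_used, x$sub_size))
  if (!is.null(x$lambda))
    cat(sprintf("  selected lambda = %.4f (grid point %d, beta = %.2f)\n",
                x$lambda, x$lambda_index, x$beta))
  invisible(x)
}

#' Write a stability profile as TSV
#'
#' Columns: lambda, instability D, monotonised D_bar, mean edge count, and a
#' selected flag — ready for plotting.
#'
#' @param profile a `"stars_profile"`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_stability_profile <- function(profile, path) {
  df <- data.frame(lambda = profile$grid, D = profile$D,
                   D_bar = profile$D_bar, edge_count = profile$edge_count,
                   selected = seq_along(profile$grid) ==
                     (profile$lambda_index %||% NA_integer_))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
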