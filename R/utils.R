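`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded internals never disturb user-level randomness.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# One global seed spawns per-stage/per-subsample seeds by fixed offsets,
# kept inside the 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 7919 + as.double(offset) * 104729) %% 2147483647L) + 1L
}

check_square_symmetric <- function(m, name = deparse(substitute(m)), tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop(sprintf("'%s' must be a square matrix", name), call. = FALSE)
  if (max(abs(m - t(m))) > tol)
    stop(sprintf("'%s' must be symmetric (max asymmetry %.2e)", name,
                 max(abs(m - t(m)))), call. = FALSE)
  invisible(m)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 means identical partitions, ~0 means agreement no better than random.
#' Used to compare a detected community partition with a planted one.
#'
#' @param a,b vectors of cluster labels of equal length.
#' @return Numeric scalar in \[-1, 1\].
#' @export
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b"))
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  mx <- (si + sj) / 2
  if (mx == expected) return(1)
  (sij - expected) / (mx - expected)
}

# transform state of an intake matrix; "unknown" when unmarked (e.g. after
# subsetting, which drops attributes) — state checks only fire on marked
# matrices
intake_state <- function(x) attr(x, "transform") %||% "unknown"
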