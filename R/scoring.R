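# Per-person community network-based scores: centrality-weighted sums of raw
# grams/day intakes over each community's food groups, plus population
# quintile assignment.

#' Community network-based scores
#'
#' `score(i, c) = sum_{j in community c} centrality(j) * intake_raw(i, j)`,
#' with intakes in raw grams/day (the actual daily intake, not the
#' log-transformed value used for network estimation). Isolated nodes
#' contribute to no score.
#'
#' @param intakes raw intake matrix (n x p, grams/day), participants in rows.
#' @param partition a `"community_partition"` (or a named membership vector).
#' @param centrality named eigenvector-centrality vector.
#' @return n x K matrix, columns `c1..cK`, with attribute `communities`
#'   (member list per community).
#' @export
community_scores <- function(intakes, partition, centrality) {
  if (!is.matrix(intakes)) intakes <- as.matrix(intakes)
  if (intake_state(intakes) == "log10p1")
    stop("community scores use the actual (raw grams/day) intake, ",
         "not the log-transformed matrix", call. = FALSE)
  memb <- if (inherits(partition, "community_partition"))
    partition$membership else partition
  K <- max(memb)
  n <- nrow(intakes)
  scores <- matrix(0, n, K,
                   dimnames = list(rownames(intakes), paste0("c", seq_len(K))))
  members_list <- vector("list", K)
  for (c in seq_len(K)) {
    members <- names(memb)[memb == c]
    missing_cols <- setdiff(members, colnames(intakes))
    if (length(missing_cols))
      stop("intake matrix lacks food group(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    w <- centrality[members]
    if (sum(w) == 0)
      stop("community c", c, " has zero total centrality; scores undefined",
           call. = FALSE)
    scores[, c] <- intakes[, members, drop = FALSE] %*% w
    members_list[[c]] <- members
  }
  names(members_list) <- colnames(scores)
  attr(scores, "communities") <- members_list
  scores
}

#' Population quintiles of community scores
#'
#' Rank-based split of each score column into five groups on the total
#' population (Q1 = lowest fifth, the Cox reference). Ties are resolved by
#' stable participant order; group sizes differ by at most one.
#'
#' @param scores matrix (or vector) of community scores.
#' @param max_tie_frac error threshold: if more than this fraction of a
#'   column's values are identical, quintiles are meaningless.
#' @return Integer matrix of quintile labels 1..5, same shape as `scores`.
#' @export
assign_quintiles <- function(scores, max_tie_frac = 0.8) {
  vec_in <- is.null(dim(scores))
  if (vec_in) scores <- matrix(scores, ncol = 1, dimnames = list(NULL, "c1"))
  n <- nrow(scores)
  if (n < 5) stop("need at least 5 participants for quintiles", call. = FALSE)
  q <- matrix(NA_integer_, n, ncol(scores), dimnames = dimnames(scores))
  for (c in seq_len(ncol(scores))) {
    s <- scores[, c]
    tf <- max(table(s)) / n
    if (tf > max_tie_frac)
      stop(sprintf(
        "%.0f%% of community %s scores are identical; quintiles are meaningless - use the continuous score",
        100 * tf, colnames(scores)[c]), call. = FALSE)
    r <- rank(s, ties.method = "first")  # stable: participant order breaks ties
    qc <- as.integer(floor((r - 1) * 5 / n) + 1L)
    # warn when a tied score value straddles a quintile boundary
    straddle <- tapply(qc, s, function(z) length(unique(z)) > 1)
    if (any(straddle))
      warning("tied scores straddle a quintile boundary in ",
              colnames(scores)[c], "; assignment follows participant order",
              call. = FALSE)
    q[, c] <- qc
  }
  if (vec_in) q[, 1] else q
}

#' Combined score/quintile table
#'
#' @inheritParams community_scores
#' @return Data frame with `id`, one `score_*` and one `quintile_*` column
#'   per community; per-community median scores in attribute `medians`.
#' @export
score_table <- function(intakes, partition, centrality) {
  s <- community_scores(intakes, partition, centrality)
  q <- assign_quintiles(s)
  df <- data.frame(id = rownames(s) %||% as.character(seq_len(nrow(s))),
                   stringsAsFactors = FALSE)
  for (c in colnames(s)) {
    df[[paste0("score_", c)]] <- s[, c]
    df[[paste0("quintile_", c)]] <- q[, c]
  }
  attr(df, "medians") <- apply(s, 2, median)
  attr(df, "communities") <- attr(s, "communities")
  df
}

#' Write the score table as delimited text
#'
#' @param tab a [score_table()] data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
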