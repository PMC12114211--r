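# Hand-enumerable micro-fixtures shared by the test suites.  Each fixture is
# an inline literal with its expected output and a provenance tag; DERIVED
# fixtures name the executable oracle that produced the expectation.

fixture_registry <- function() {
  list(
    energy_thresholds = list(
      tag = "PAPER",
      oracle = NULL,
      inputs = data.frame(
        id = c("m_low", "m_lo_edge", "m_hi_edge", "m_high",
               "f_low", "f_lo_edge", "f_hi_edge", "f_high"),
        sex = rep(c("male", "female"), each = 4),
        total_energy = c(750, 800, 4000, 4100, 450, 500, 3500, 3600),
        stringsAsFactors = FALSE),
      # strict inequalities: exactly-at-bound intakes are retained
      expected_retained = c("m_lo_edge", "m_hi_edge", "f_lo_edge", "f_hi_edge")),

    baseline_prevalence = list(
      tag = "PAPER",
      oracle = NULL,
      inputs = data.frame(
        id = c("prev_stroke", "prev_mi", "clean", "missing_stroke"),
        stroke_response = c("yes", "no", "no", NA),
        mi_response = c("no", "yes", "no", "no"),
        stringsAsFactors = FALSE),
      # a missing baseline response is treated as "no" (not prevalent)
      expected_excluded = c("prev_stroke", "prev_mi")),

    outcome_waves = list(
      tag = "PAPER",
      oracle = NULL,
      waves = data.frame(
        id = c("s2", "s2", "s2",
               "nc", "nc",
               "am", "am",
               "both1",
               "mixed", "mixed",
               "mi3", "mi3", "mi3"),
        wave = c(1L, 2L, 3L, 1L, 2L, 1L, 2L, 1L, 1L, 2L, 1L, 2L, 3L),
        stroke_response = c("no", "yes", NA, "no", "no", NA, NA, "yes",
                            NA, "no", "no", "no", "no"),
        mi_response = c("no", "no", NA, "no", "no", NA, NA, "yes",
                        NA, "no", "no", "no", "yes"),
        stringsAsFactors = FALSE),
      expected = data.frame(
        id = c("s2", "nc", "am", "both1", "mixed", "mi3"),
        status = c("stroke", "non_case", "excluded_all_missing", "both",
                   "non_case", "mi"),
        event_wave = c(2L, NA, NA, 1L, NA, 3L),
        stringsAsFactors = FALSE)),

    person_years_dates = list(
      tag = "TRIVIAL",
      oracle = "date arithmetic at 365.25 days/year",
      cases = data.frame(
        baseline = as.Date(c("2005-01-01", "2005-07-01")),
        end = as.Date(c("2009-01-01", "2010-07-02")),
        expected_years = c(4.00, 5.00),
        tol = c(0.01, 0.01))),

    aggregation_toy = list(
      tag = "DERIVED",
      oracle = "hand-computed column sums",
      items = matrix(c(3, 4, 1, 0, 2, 5,
                       1, 1, 1, 1, 1, 1),
                     nrow = 2, byrow = TRUE,
                     dimnames = list(c("p1", "p2"),
                                     c("i1", "i2", "i3", "i4", "i5", "i6"))),
      map = data.frame(
        item = c("i1", "i2", "i3", "i4", "i5", "i6"),
        group = c("g1", "g1", "g2", "g2", "g3", "g3"),
        stringsAsFactors = FALSE),
      expected = matrix(c(7, 1, 7,
                          2, 2, 2),
                        nrow = 2, byrow = TRUE,
                        dimnames = list(c("p1", "p2"), c("g1", "g2", "g3")))),

    glasso_3x3 = list(
      tag = "DERIVED",
      oracle = "proximal-gradient (ISTA) minimiser of the penalised likelihood",
      S = matrix(c(1, 0.5, 0,
                   0.5, 1, 0,
                   0, 0, 1), 3, 3),
      lambda = 0.1),

    two_cliques_bridge = list(
      tag = "DERIVED",
      oracle = "exhaustive modularity search over all partitions of 8 nodes",
      edges = {
        cl1 <- t(utils::combn(1:4, 2))
        cl2 <- t(utils::combn(5:8, 2))
        e <- rbind(cl1, cl2, c(4, 5))
        data.frame(from = paste0("n", e[, 1]), to = paste0("n", e[, 2]),
                   weight = 1, stringsAsFactors = FALSE)
      },
      expected_partition = setNames(rep(1:2, each = 4), paste0("n", 1:8)),
      expected_q = 12 / 13 - 1 / 2),  # 2*(6/13 - (13/26)^2)

    star4_centrality = list(
      tag = "DERIVED",
      oracle = "closed-form leading eigenvector of a star graph",
      edges = data.frame(from = c("hub", "hub", "hub"),
                         to = c("l1", "l2", "l3"),
                         weight = 1, stringsAsFactors = FALSE),
      expected = c(hub = 1, l1 = 1 / sqrt(3), l2 = 1 / sqrt(3),
                   l3 = 1 / sqrt(3))),

    score_worked_example = list(
      tag = "TRIVIAL",
      oracle = NULL,
      centrality = c(A = 1, B = 0.5),
      intakes = c(A = 10, B = 4),
      expected_score = 12.0),

    quintile_toy = list(
      tag = "TRIVIAL",
      oracle = NULL,
      scores = 1:10,
      expected = c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L, 5L, 5L))
  )
}

#' Load a named test fixture
#'
#' Returns one of the package's inline micro-fixtures (tiny graphs, boundary
#' cohort cases, worked scoring examples) used across the test suites.
#' Fixtures are immutable literals; `DERIVED` fixtures name the oracle that
#' produced their expected values.
#'
#' @param name fixture name.
#' @return A list with the fixture's inputs, expectations and provenance tag.
#' @export
#' @examples
#' load_fixture("star4_centrality")$expected
load_fixture <- function(name) {
  reg <- fixture_registry()
  if (!name %in% names(reg))
    stop("unknown fixture '", name, "'; available: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  reg[[name]]
}
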