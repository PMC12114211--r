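test_that("survival rows: event coding per outcome and quintile encoding", {
  co <- simulate_cohort(cohort_spec(n = 500, network = planted_network_spec(
    p = 8, community_sizes = c(3, 3), seed = 51), baseline_hazard = 0.03,
    seed = 51))
  b <- build_cohort(co$intakes, co$covariates, co$waves, co$baseline)
  fit <- dietary_network(b$intakes, lambda = 0.05, seed = 2)
  tab <- predict(fit, b$intakes)
  d <- survival_data(b, scores = tab)
  # non-cases carry event 0 everywhere
  nc <- d$status == "non_case"
  expect_true(all(d$event_stroke_or_mi[nc] == 0))
  expect_true(all(d$event_stroke[nc] == 0))
  # a "both" participant is an event for stroke, MI and the combined outcome
  if (any(d$status == "both")) {
    bt <- d$status == "both"
    expect_true(all(d$event_stroke[bt] == 1 & d$event_mi[bt] == 1 &
                      d$event_stroke_or_mi[bt] == 1))
  }
  # quintile exposure is a 5-level factor with Q1 as the reference: 4 terms
  f <- suppressWarnings(fit_cox(d, "quintile_c1", model = 1,
                                exposure_type = "quintile"))
  expect_equal(f$terms$term,
               paste0("quintile_c1", c("Q2", "Q3", "Q4", "Q5")))
  # HR ordering matches beta ordering (encoding consistency)
  expect_equal(order(f$terms$hr), order(f$terms$beta))
  # id mismatch between tables errors
  expect_error(survival_data(b, scores = tab[-1, ]), "cover")
})

test_that("small-sample fit matches brute-force partial likelihood", {
  set.seed(31)
  n <- 18
  x <- rbinom(n, 1, 0.5)
  t <- rexp(n, 0.1 * exp(0.7 * x))
  t <- t + seq_len(n) * 1e-6            # ensure no ties
  d <- data.frame(py_stroke_or_mi = t, event_stroke_or_mi = 1, exposure = x)
  f <- suppressWarnings(fit_cox(d, "exposure", model = 1))
  expect_equal(f$terms$beta, cox_brute_force(t, rep(1, n), x),
               tolerance = 1e-6)
})

test_that("a planted log-hazard of 0.5 is recovered within 3 SE at n = 2000", {
  set.seed(32)
  n <- 2000
  x <- rbinom(n, 1, 0.5)
  t <- rexp(n, 0.2 * exp(0.5 * x))
  d <- data.frame(py_stroke_or_mi = t, event_stroke_or_mi = 1, exposure = x)
  f <- fit_cox(d, "exposure", model = 1)
  expect_lt(abs(f$terms$beta - 0.5), 3 * f$terms$se)
})

test_that("hazard ratios are invariant to the time unit", {
  set.seed(33)
  n <- 300
  x <- rnorm(n)
  t <- rexp(n, 0.2 * exp(0.3 * x))
  ev <- rbinom(n, 1, 0.8)
  d1 <- data.frame(py_stroke_or_mi = t, event_stroke_or_mi = ev, exposure = x)
  d2 <- transform(d1, py_stroke_or_mi = py_stroke_or_mi * 365.25)
  f1 <- fit_cox(d1, "exposure", model = 1)
  f2 <- fit_cox(d2, "exposure", model = 1)
  expect_equal(f1$terms$hr, f2$terms$hr, tolerance = 1e-8)
})

test_that("degenerate inputs are errors, not fits", {
  d <- data.frame(py_stroke_or_mi = c(1, 2), event_stroke_or_mi = c(1, 0),
                  exposure = c(0, 1))
  expect_error(fit_cox(d, "exposure", model = 1), "too few|fewer than")
  d2 <- data.frame(py_stroke_or_mi = rexp(50), event_stroke_or_mi =
                     rbinom(50, 1, 0.5), exposure = 1)
  expect_error(suppressWarnings(fit_cox(d2, "exposure", model = 1)),
               "constant")
  # interaction needs both sexes
  d3 <- data.frame(py_stroke_or_mi = rexp(60),
                   event_stroke_or_mi = rbinom(60, 1, 0.5),
                   exposure = rnorm(60), sex = "male")
  expect_error(suppressWarnings(
    fit_cox(d3, "exposure", model = 1, interaction = TRUE)), "both sexes")
})

test_that("sex interaction is detected when planted and its p is valid", {
  set.seed(34)
  n <- 4000
  sex <- sample(c("male", "female"), n, TRUE)
  x <- rnorm(n)
  beta <- ifelse(sex == "male", 0.5, 0)
  t <- rexp(n, 0.1 * exp(beta * x))
  d <- data.frame(py_stroke_or_mi = t, event_stroke_or_mi = 1,
                  exposure = x, sex = sex)
  f <- fit_cox(d, "exposure", model = 1, interaction = TRUE)
  expect_lt(f$interaction_p, 0.05)
  expect_true(f$interaction_p >= 0 && f$interaction_p <= 1)
})

test_that("isolated-group models produce the contracted fit count", {
  co <- simulate_cohort(cohort_spec(n = 600, network = planted_network_spec(
    p = 10, community_sizes = c(4, 3), seed = 52), baseline_hazard = 0.05,
    seed = 52))
  b <- build_cohort(co$intakes, co$covariates, co$waves, co$baseline)
  iso <- co$truth$isolated            # 3 isolated groups planted
  d <- survival_data(b, intake_groups = iso)
  res <- suppressWarnings(isolated_group_models(d, iso))
  expect_equal(nrow(res), length(iso) * 3)      # 3 strata per group
  expect_equal(sum(!is.na(res$interaction_p)), length(iso))
  expect_true(all(res$hr > 0))
  expect_true(all(res$ci_lo <= res$hr & res$hr <= res$ci_hi))
})
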