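test_that("energy exclusion applies the sex-specific kcal bounds strictly", {
  fx <- load_fixture("energy_thresholds")
  res <- apply_energy_exclusion(fx$inputs)
  expect_setequal(res$retained$id, fx$expected_retained)
  expect_equal(sum(res$counts), 4)
  # missing energy is its own reason
  res2 <- apply_energy_exclusion(
    data.frame(id = "x", sex = "male", total_energy = NA))
  expect_equal(res2$excluded$reason, "missing_energy")
})

test_that("baseline prevalent cases are removed; missing responses are not", {
  fx <- load_fixture("baseline_prevalence")
  cov <- data.frame(id = fx$inputs$id)
  res <- exclude_baseline_prevalent(cov, fx$inputs)
  expect_setequal(res$excluded$id, fx$expected_excluded)
  expect_true("missing_stroke" %in% res$retained$id)
  expect_equal(res$n_missing_treated_as_no, 1)
})

test_that("outcome definition: first report, both-in-wave, all-missing", {
  fx <- load_fixture("outcome_waves")
  out <- define_outcomes(fx$waves)
  m <- merge(out, fx$expected, by = "id", suffixes = c("", "_exp"))
  expect_equal(m$status, m$status_exp)
  expect_equal(m$event_wave, m$event_wave_exp)
  # idempotent and local: recomputing a single participant matches
  one <- define_outcomes(fx$waves[fx$waves$id == "s2", ])
  expect_equal(one$status, "stroke")
  expect_equal(one$event_wave, 2L)
  # duplicated wave index is rejected
  bad <- data.frame(id = "z", wave = c(1L, 1L),
                    stroke_response = c("no", "no"),
                    mi_response = c("no", "no"))
  expect_error(define_outcomes(bad), "duplicated wave")
})

test_that("person-years follow the date arithmetic and conserve on summation", {
  fx <- load_fixture("person_years_dates")
  waves <- data.frame(id = c("a", "b"), wave = 1L,
                      wave_date = fx$cases$end,
                      stroke_response = c("yes", "no"),
                      mi_response = c("no", "no"))
  out <- define_outcomes(waves)
  bl <- data.frame(id = c("a", "b"), baseline_date = fx$cases$baseline)
  py <- person_years(out, waves, bl)
  expect_equal(py$py_stroke_or_mi[py$id == "a"], 4.00, tolerance = 0.01)
  expect_equal(py$py_stroke_or_mi[py$id == "b"], 5.00, tolerance = 0.01)
  # conservation on a synthetic cohort: total equals the sum of parts
  co <- simulate_cohort(cohort_spec(n = 400, network = planted_network_spec(
    p = 8, community_sizes = c(3, 3), seed = 21), seed = 21))
  b <- build_cohort(co$intakes, co$covariates, co$waves, co$baseline)
  expect_equal(sum(b$data$py_stroke_or_mi),
               sum(vapply(split(b$data$py_stroke_or_mi, b$data$id), sum,
                          numeric(1))))
  expect_true(all(b$data$py_stroke_or_mi > 0))
  # non-positive duration errors
  waves_bad <- transform(waves, wave_date = fx$cases$baseline - 1)
  expect_error(person_years(out, waves_bad, bl), "non-positive")
})

test_that("imputation: sex-stratified median below 5%, unknown category above", {
  set.seed(1)
  n <- 200
  df <- data.frame(id = as.character(1:n),
                   sex = rep(c("male", "female"), each = n / 2),
                   bmi = rnorm(n, 24, 2),
                   income = sample(c("low", "high"), n, TRUE))
  df$bmi[c(1, 2)] <- NA                    # 1% missing, both males
  df$income[1:30] <- NA                    # 15% missing
  male_med <- median(df$bmi[df$sex == "male"], na.rm = TRUE)
  imp <- impute_covariates(df, cols = c("bmi", "income"))
  expect_equal(imp$data$bmi[1], male_med)
  expect_equal(imp$log$bmi$strategy, "sex_median")
  expect_true(all(imp$data$income[1:30] == "unknown"))
  expect_equal(imp$log$income$strategy, "unknown_category")
  # 0% missing: identity
  clean <- impute_covariates(df[complete.cases(df), ],
                             cols = c("bmi", "income"))
  expect_identical(clean$data$bmi, df$bmi[complete.cases(df)])
  # a stratum with everything missing is an error
  df2 <- df
  df2$bmi[df2$sex == "female"] <- NA
  expect_error(impute_covariates(df2, cols = "bmi"), "entirely missing")
  # categorical below threshold: sex-stratified mode
  df3 <- df
  df3$income <- c(NA, rep(c("low", "low", "high"), length.out = n - 1))
  imp3 <- impute_covariates(df3, cols = "income")
  expect_equal(imp3$log$income$strategy, "sex_mode")
  expect_equal(imp3$data$income[1], "low")
})

test_that("item aggregation sums to groups and conserves total grams", {
  fx <- load_fixture("aggregation_toy")
  agg <- aggregate_items(fx$items, fx$map)
  expect_equal(unname(agg), unname(fx$expected), ignore_attr = TRUE)
  expect_equal(colnames(agg), colnames(fx$expected))
  expect_equal(rowSums(agg), rowSums(fx$items))     # conservation
  # identity when one item per group (up to reordering)
  map1 <- data.frame(item = c("i2", "i1"), group = c("g2", "g1"))
  one <- aggregate_items(fx$items[, c("i1", "i2")], map1)
  expect_equal(unname(one[, "g1"]), unname(fx$items[, "i1"]))
  expect_error(aggregate_items(fx$items, fx$map[-1, ]), "i1")
})

test_that("log transform matches closed-form values and round-trips", {
  x <- matrix(c(0, 9, 99, 999), 1)
  attr(x, "transform") <- "raw"
  y <- log_transform(x)
  expect_equal(as.vector(y), c(0, 1, 2, 3))
  expect_identical(attr(y, "transform"), "log10p1")
  expect_equal(10^y - 1, unclass(x), ignore_attr = TRUE)
  expect_error(log_transform(y), "already")
  expect_error(log_transform(matrix(-1)), "negative")
})

test_that("exclusion steps commute and duplicate ids are rejected", {
  co <- simulate_cohort(cohort_spec(n = 300, network = planted_network_spec(
    p = 8, community_sizes = c(3, 3), seed = 31), seed = 31))
  en_first <- apply_energy_exclusion(co$covariates)$retained
  ab <- exclude_baseline_prevalent(en_first, co$baseline)$retained
  bp_first <- exclude_baseline_prevalent(co$covariates, co$baseline)$retained
  ba <- apply_energy_exclusion(bp_first)$retained
  expect_setequal(ab$id, ba$id)
  cov_dup <- rbind(co$covariates, co$covariates[1, ])
  expect_error(build_cohort(co$intakes, cov_dup, co$waves), "duplicate")
})

test_that("the shipped example composition map drives item aggregation", {
  path <- system.file("extdata", "composition_map_example.tsv",
                      package = "dietnet")
  map <- read_composition_map(path)
  expect_length(unique(map$group), 45)
  expect_true(all(table(map$group) >= 1))
  set.seed(77)
  items <- matrix(rexp(3 * nrow(map), 0.05), 3, nrow(map),
                  dimnames = list(paste0("p", 1:3), map$item))
  agg <- aggregate_items(items, map)
  expect_equal(dim(agg), c(3L, 45L))
  expect_equal(rowSums(agg), rowSums(items))
})
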