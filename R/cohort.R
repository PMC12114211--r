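# Cohort construction: energy-intake exclusions, baseline-prevalence
# exclusion, outcome definition across unequal follow-up waves, person-years,
# sex-stratified covariate imputation, item-to-group aggregation and the
# log10(1 + g/day) transform.

DAYS_PER_YEAR <- 365.25

#' Implausible-energy exclusion
#'
#' Retains males with 800-4000 kcal/day and females with 500-3500 kcal/day
#' (bounds inclusive: the exclusion rule is "fewer than" / "more than").
#' Missing energy is its own exclusion reason.
#'
#' @param covariates data frame with `id`, `sex` (`"male"`/`"female"`) and
#'   `total_energy` (kcal/day).
#' @return List: `retained` (data frame), `excluded` (data frame with a
#'   `reason` column), `counts` (named exclusion tally).
#' @export
apply_energy_exclusion <- function(covariates) {
  stopifnot(all(c("id", "sex", "total_energy") %in% names(covariates)))
  e <- covariates$total_energy
  male <- covariates$sex == "male"
  reason <- rep(NA_character_, nrow(covariates))
  reason[is.na(e)] <- "missing_energy"
  low <- ifelse(male, 800, 500)
  high <- ifelse(male, 4000, 3500)
  reason[!is.na(e) & e < low] <- "energy_too_low"
  reason[!is.na(e) & e > high] <- "energy_too_high"
  keep <- is.na(reason)
  excluded <- covariates[!keep, , drop = FALSE]
  excluded$reason <- reason[!keep]
  list(retained = covariates[keep, , drop = FALSE],
       excluded = excluded,
       counts = c(table(reason[!keep])))
}

#' Baseline prevalent-case exclusion
#'
#' Removes participants answering "yes" to either the stroke or the MI
#' question at baseline. A missing baseline response is treated as "no"
#' (counted in the log, not excluded).
#'
#' @param covariates data frame with `id`.
#' @param baseline data frame with `id`, `stroke_response`, `mi_response`
#'   (values `"yes"`, `"no"` or `NA`).
#' @return List: `retained`, `excluded`, `n_missing_treated_as_no`.
#' @export
exclude_baseline_prevalent <- function(covariates, baseline) {
  stopifnot(all(c("id", "stroke_response", "mi_response") %in% names(baseline)))
  m <- baseline[match(covariates$id, baseline$id), ]
  prev <- (!is.na(m$stroke_response) & m$stroke_response == "yes") |
          (!is.na(m$mi_response) & m$mi_response == "yes")
  prev[is.na(prev)] <- FALSE
  excluded <- covariates[prev, , drop = FALSE]
  if (nrow(excluded)) excluded$reason <- "baseline_prevalent"
  list(retained = covariates[!prev, , drop = FALSE],
       excluded = excluded,
       n_missing_treated_as_no = sum(is.na(m$stroke_response) |
                                       is.na(m$mi_response)))
}

#' Define outcomes from follow-up wave responses
#'
#' The first wave with any "yes" fixes the status (`stroke`, `mi`, or `both`
#' when both are "yes" in that wave) and the event wave. All-"no" (possibly
#' with interspersed missing) responses give `non_case`; responses missing at
#' every wave give `excluded_all_missing`. Also records the first
#' type-specific "yes" wave and the last wave with any non-missing response
#' (the censoring wave for non-cases).
#'
#' @param waves data frame with `id`, `wave` (integer, strictly increasing per
#'   participant), `stroke_response`, `mi_response` (`"yes"`/`"no"`/`NA`).
#' @return Data frame: `id`, `status`, `event_wave`, `stroke_wave`, `mi_wave`,
#'   `last_wave`, `n_waves`.
#' @export
define_outcomes <- function(waves) {
  stopifnot(all(c("id", "wave", "stroke_response", "mi_response") %in%
                  names(waves)))
  waves <- waves[order(waves$id, waves$wave), ]
  rows <- split(seq_len(nrow(waves)), waves$id)
  one <- function(ix) {
    w <- waves[ix, ]
    if (!nrow(w)) stop("participant with zero waves", call. = FALSE)
    if (any(duplicated(w$wave)))
      stop("duplicated wave index for participant ", w$id[1], call. = FALSE)
    sy <- !is.na(w$stroke_response) & w$stroke_response == "yes"
    my <- !is.na(w$mi_response) & w$mi_response == "yes"
    observed <- !is.na(w$stroke_response) | !is.na(w$mi_response)
    if (!any(observed))
      return(list(status = "excluded_all_missing", event_wave = NA_integer_,
                  stroke_wave = NA_integer_, mi_wave = NA_integer_,
                  last_wave = NA_integer_, n_waves = nrow(w)))
    any_yes <- sy | my
    last_wave <- max(w$wave[observed])
    if (!any(any_yes))
      return(list(status = "non_case", event_wave = NA_integer_,
                  stroke_wave = NA_integer_, mi_wave = NA_integer_,
                  last_wave = last_wave, n_waves = nrow(w)))
    k <- which(any_yes)[1]
    status <- if (sy[k] && my[k]) "both" else if (sy[k]) "stroke" else "mi"
    list(status = status, event_wave = w$wave[k],
         stroke_wave = if (any(sy)) w$wave[which(sy)[1]] else NA_integer_,
         mi_wave = if (any(my)) w$wave[which(my)[1]] else NA_integer_,
         last_wave = last_wave, n_waves = nrow(w))
  }
  res <- lapply(rows, one)
  data.frame(id = names(rows),
             status = vapply(res, `[[`, "", "status"),
             event_wave = vapply(res, function(r) as.integer(r$event_wave), 1L),
             stroke_wave = vapply(res, function(r) as.integer(r$stroke_wave), 1L),
             mi_wave = vapply(res, function(r) as.integer(r$mi_wave), 1L),
             last_wave = vapply(res, function(r) as.integer(r$last_wave), 1L),
             n_waves = vapply(res, function(r) as.integer(r$n_waves), 1L),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Person-years of follow-up
#'
#' Years (365.25-day) between the baseline survey date and the wave where the
#' outcome was defined (cases) or the last responded wave (non-cases),
#' computed separately for the combined and the type-specific analyses. For a
#' type-specific analysis, a participant whose only event is the other type is
#' censored at their last observed wave.
#'
#' @param outcomes data frame from [define_outcomes()].
#' @param waves wave data frame including `wave_date` (Date).
#' @param baseline_dates data frame with `id`, `baseline_date` (Date).
#' @return `outcomes` with columns `py_stroke_or_mi`, `py_stroke`, `py_mi`
#'   and event indicators `event_stroke_or_mi`, `event_stroke`, `event_mi`.
#' @export
person_years <- function(outcomes, waves, baseline_dates) {
  stopifnot("wave_date" %in% names(waves),
            all(c("id", "baseline_date") %in% names(baseline_dates)))
  key <- paste(waves$id, waves$wave, sep = "\r")
  wave_date <- function(id, wv) waves$wave_date[match(paste(id, wv, sep = "\r"), key)]
  b <- baseline_dates$baseline_date[match(outcomes$id, baseline_dates$id)]
  if (anyNA(b)) stop("missing baseline date for some participants", call. = FALSE)

  py <- function(end_wave) {
    d <- wave_date(outcomes$id, end_wave)
    as.numeric(d - b) / DAYS_PER_YEAR
  }
  out <- outcomes
  kept <- !out$status %in% c("excluded_all_missing")
  end_combined <- ifelse(is.na(out$event_wave), out$last_wave, out$event_wave)
  end_stroke <- ifelse(is.na(out$stroke_wave), out$last_wave, out$stroke_wave)
  end_mi <- ifelse(is.na(out$mi_wave), out$last_wave, out$mi_wave)
  out$py_stroke_or_mi <- py(end_combined)
  out$py_stroke <- py(end_stroke)
  out$py_mi <- py(end_mi)
  bad <- kept & (is.na(out$py_stroke_or_mi) | out$py_stroke_or_mi <= 0)
  if (any(bad))
    stop("non-positive follow-up time for participant(s): ",
         paste(head(out$id[bad], 5), collapse = ", "), call. = FALSE)
  out$event_stroke_or_mi <- as.integer(out$status %in% c("stroke", "mi", "both"))
  out$event_stroke <- as.integer(!is.na(out$stroke_wave))
  out$event_mi <- as.integer(!is.na(out$mi_wave))
  out
}

#' Sex-stratified covariate imputation
#'
#' Covariates with less than `threshold` missingness are filled with the
#' sex-stratified median (numeric) or mode (categorical). At or above the
#' threshold, categorical covariates gain an explicit `"unknown"` category;
#' numeric covariates are median-imputed and a `<name>_missing` indicator
#' column is added (the numeric analogue of the unknown category).
#'
#' @param covariates data frame including `sex`.
#' @param cols covariate columns to process (default: all except `id`, `sex`,
#'   `baseline_date`).
#' @param threshold missingness proportion switching strategies (default 5%).
#' @return List: `data` (imputed data frame), `log` (per-covariate strategy
#'   and missing counts).
#' @export
impute_covariates <- function(covariates, cols = NULL, threshold = 0.05) {
  stopifnot("sex" %in% names(covariates))
  cols <- cols %||% setdiff(names(covariates), c("id", "sex", "baseline_date"))
  df <- covariates
  log <- list()
  for (cl in cols) {
    x <- df[[cl]]
    miss <- is.na(x)
    frac <- mean(miss)
    strategy <- "none"
    if (frac > 0) {
      for (s in unique(df$sex)) {
        in_s <- df$sex == s
        if (all(is.na(x[in_s])))
          stop(sprintf("covariate '%s' is entirely missing for sex '%s'",
                       cl, s), call. = FALSE)
      }
      if (is.numeric(x)) {
        for (s in unique(df$sex)) {
          in_s <- df$sex == s
          x[in_s & miss] <- median(x[in_s], na.rm = TRUE)
        }
        strategy <- "sex_median"
        if (frac >= threshold) {
          df[[paste0(cl, "_missing")]] <- miss
          strategy <- "sex_median_plus_indicator"
        }
      } else {
        if (frac >= threshold) {
          x <- as.character(x)
          x[miss] <- "unknown"
          strategy <- "unknown_category"
        } else {
          for (s in unique(df$sex)) {
            in_s <- df$sex == s
            tab <- table(x[in_s & !miss])
            x[in_s & miss] <- names(tab)[which.max(tab)]
          }
          strategy <- "sex_mode"
        }
      }
      df[[cl]] <- x
    }
    log[[cl]] <- list(n_missing = sum(miss), frac = frac, strategy = strategy)
  }
  list(data = df, log = log)
}

#' Aggregate food items to food groups
#'
#' Group intake is the sum of member-item grams/day; output columns follow the
#' composition map's group order. Item columns not named in the map are an
#' error.
#'
#' @param items numeric matrix/data frame of per-item intakes (columns =
#'   items).
#' @param map composition map: data frame with columns `item`, `group`.
#' @return Raw intake matrix (one column per group).
#' @export
aggregate_items <- function(items, map) {
  stopifnot(all(c("item", "group") %in% names(map)))
  if (!is.matrix(items)) items <- as.matrix(items)
  unmapped <- setdiff(colnames(items), map$item)
  if (length(unmapped))
    stop("item column(s) not in the composition map: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  groups <- unique(map$group)
  out <- matrix(0, nrow(items), length(groups),
                dimnames = list(rownames(items), groups))
  for (g in groups) {
    members <- intersect(map$item[map$group == g], colnames(items))
    if (length(members))
      out[, g] <- rowSums(items[, members, drop = FALSE])
  }
  attr(out, "transform") <- "raw"
  out
}

#' Log-transform intakes
#'
#' Elementwise `log10(1 + grams/day)`, the normalising transform applied
#' before covariance estimation. Invertible via `10^y - 1`.
#'
#' @param x raw intake matrix (all entries `>= 0`).
#' @return Matrix with attribute `transform = "log10p1"`.
#' @export
log_transform <- function(x) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (intake_state(x) == "log10p1")
    stop("intakes are already log-transformed", call. = FALSE)
  if (any(x < 0, na.rm = TRUE))
    stop("negative intake values cannot be log-transformed", call. = FALSE)
  y <- log10(1 + x)
  attr(y, "transform") <- "log10p1"
  y
}

#' Read a composition map
#'
#' Two-column TSV (item, group).
#'
#' @param path file path.
#' @return Data frame with columns `item`, `group`.
#' @export
read_composition_map <- function(path) {
  map <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("item", "group") %in% names(map)))
    stop("composition map needs columns 'item' and 'group'", call. = FALSE)
  if (any(duplicated(map$item)))
    stop("composition map assigns some items to more than one group",
         call. = FALSE)
  map
}

#' Build the analysis cohort
#'
#' Applies, in order: optional id-list exclusion (e.g. invalid recruitment
#' sites), the energy-intake exclusion, the baseline prevalent-case
#' exclusion, outcome definition (dropping all-missing responders),
#' person-years, and sex-stratified covariate imputation.
#'
#' @param intakes raw intake matrix with participant ids as row names.
#' @param covariates covariate data frame (`id`, `sex`, `total_energy`,
#'   `baseline_date`, ...).
#' @param waves follow-up wave responses (`id`, `wave`, `wave_date`,
#'   `stroke_response`, `mi_response`).
#' @param baseline optional baseline responses for the prevalence exclusion.
#' @param exclude_ids optional ids excluded up front.
#' @param impute apply [impute_covariates()]?
#' @return List: `data` (one row per retained participant: imputed
#'   covariates + outcome + person-years), `intakes` (matching rows),
#'   `exclusions` (named counts), `imputation_log`.
#' @export
build_cohort <- function(intakes, covariates, waves, baseline = NULL,
                         exclude_ids = NULL, impute = TRUE) {
  if (any(duplicated(covariates$id)))
    stop("duplicate participant ids in covariates", call. = FALSE)
  if (any(duplicated(rownames(intakes))))
    stop("duplicate participant ids in intakes", call. = FALSE)
  excl <- c()
  cov <- covariates
  if (!is.null(exclude_ids)) {
    excl["invalid_site"] <- sum(cov$id %in% exclude_ids)
    cov <- cov[!cov$id %in% exclude_ids, ]
  }
  en <- apply_energy_exclusion(cov)
  excl <- c(excl, en$counts)
  cov <- en$retained
  if (!is.null(baseline)) {
    bp <- exclude_baseline_prevalent(cov, baseline)
    excl["baseline_prevalent"] <- nrow(bp$excluded)
    cov <- bp$retained
  }
  out <- define_outcomes(waves[waves$id %in% cov$id, ])
  excl["all_missing_responses"] <- sum(out$status == "excluded_all_missing")
  excl["no_followup"] <- sum(!cov$id %in% out$id)
  out <- out[out$status != "excluded_all_missing", ]
  cov <- cov[cov$id %in% out$id, ]
  out <- person_years(out, waves, cov[, c("id", "baseline_date")])
  imp_log <- NULL
  if (impute) {
    imp <- impute_covariates(cov)
    cov <- imp$data
    imp_log <- imp$log
  }
  data <- merge(cov, out, by = "id", sort = FALSE)
  keep <- intersect(rownames(intakes), data$id)
  data <- data[match(keep, data$id), ]
  ik <- intakes[keep, , drop = FALSE]
  attr(ik, "transform") <- intake_state(intakes)
  list(data = data, intakes = ik, exclusions = excl,
       imputation_log = imp_log)
}

#' Waist-circumference category with sex-specific cut-offs
#'
#' Above-normal is `>= 90` cm for males and `>= 80` cm for females.
#'
#' @param waist numeric waist circumference (cm).
#' @param sex `"male"`/`"female"`.
#' @return Character vector, `"normal"` / `"above_normal"`.
#' @export
waist_category <- function(waist, sex) {
  cut_off <- ifelse(sex == "male", 90, 80)
  ifelse(is.na(waist), NA_character_,
         ifelse(waist < cut_off, "normal", "above_normal"))
}
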