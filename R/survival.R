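# Cox proportional-hazards association models: community scores (continuous
# and quintile) and isolated food groups vs self-reported stroke / MI, with
# three nested covariate-adjustment levels, sex strata and a sex-by-exposure
# interaction at the fullest adjustment.

cox_covariate_sets <- function(model, stratum) {
  m1 <- "age"
  m2 <- c(m1, "education", "income", "city", "marriage", "job",
          "comorbidity", "bmi", "waist_group")
  m3 <- c(m2, "drinking", "smoking", "total_energy", "exercise")
  covs <- switch(as.character(model), "1" = m1, "2" = m2, "3" = m3,
                 stop("model must be 1, 2 or 3", call. = FALSE))
  if (stratum == "total") covs <- c("sex", covs)
  covs
}

#' Assemble the survival analysis table
#'
#' Joins the built cohort (covariates + outcomes + person-years) with
#' community scores/quintiles and, optionally, raw intakes of selected food
#' groups (columns prefixed `intake_`). Adds the `waist_group` category.
#'
#' @param cohort list from [build_cohort()].
#' @param scores optional [score_table()] data frame.
#' @param intake_groups optional food-group names whose raw intakes become
#'   `intake_<group>` columns (for isolated-node models).
#' @return Data frame keyed by `id`, one row per retained participant.
#' @export
survival_data <- function(cohort, scores = NULL, intake_groups = NULL) {
  df <- cohort$data
  if (!"waist_group" %in% names(df) && "waist" %in% names(df))
    df$waist_group <- waist_category(df$waist, df$sex)
  if (!is.null(scores)) {
    if (!all(df$id %in% scores$id))
      stop("score table does not cover all cohort ids", call. = FALSE)
    df <- merge(df, scores, by = "id", sort = FALSE)
  }
  if (!is.null(intake_groups)) {
    ik <- cohort$intakes
    missing_g <- setdiff(intake_groups, colnames(ik))
    if (length(missing_g))
      stop("intake matrix lacks group(s): ", paste(missing_g, collapse = ", "),
           call. = FALSE)
    if (!all(df$id %in% rownames(ik)))
      stop("intake matrix does not cover all cohort ids", call. = FALSE)
    for (g in intake_groups)
      df[[paste0("intake_", g)]] <- ik[df$id, g]
  }
  df
}

wald_test <- function(fit, terms) {
  b <- coef(fit)[terms]
  V <- stats::vcov(fit)[terms, terms, drop = FALSE]
  stat <- as.numeric(t(b) %*% solve(V, b))
  c(stat = stat, df = length(terms), p = pchisq(stat, length(terms),
                                                lower.tail = FALSE))
}

#' Fit one Cox association model
#'
#' Partial-likelihood estimation (Efron tie correction) of the hazard of the
#' requested outcome on the exposure, adjusted by the covariate set of the
#' requested model level; optionally sex-stratified or with a sex-by-exposure
#' interaction (Wald test; only meaningful in the total stratum at the
#' fullest adjustment).
#'
#' @param data a [survival_data()] frame.
#' @param exposure column name: a continuous score (`score_c1`), a quintile
#'   column (`quintile_c1`), or a raw intake (`intake_coffee`).
#' @param outcome `"stroke_or_mi"`, `"stroke"` or `"mi"`.
#' @param model adjustment level 1, 2 or 3.
#' @param stratum `"total"`, `"male"` or `"female"`.
#' @param exposure_type `"continuous"` or `"quintile"` (quintile columns are
#'   coded as a 5-level factor with Q1 as reference).
#' @param interaction add a sex-by-exposure interaction and report its Wald
#'   p-value (requires both sexes).
#' @param standardize divide a continuous exposure by its SD before fitting.
#' @return Object of class `"dietnet_cox"`: tidy data frame `terms` (term,
#'   hr, ci_lo, ci_hi, p), `n`, `events`, `interaction_p`, the fitted
#'   `coxph` object, and the model descriptors.
#' @export
fit_cox <- function(data, exposure, outcome = "stroke_or_mi", model = 3,
                    stratum = c("total", "male", "female"),
                    exposure_type = c("continuous", "quintile"),
                    interaction = FALSE, standardize = FALSE) {
  stratum <- match.arg(stratum)
  exposure_type <- match.arg(exposure_type)
  outcome <- match.arg(outcome, c("stroke_or_mi", "stroke", "mi"))
  if (stratum != "total") data <- data[data$sex == stratum, , drop = FALSE]
  tcol <- paste0("py_", outcome)
  ecol <- paste0("event_", outcome)
  if (!all(c(tcol, ecol, exposure) %in% names(data)))
    stop("survival table lacks column(s): ",
         paste(setdiff(c(tcol, ecol, exposure), names(data)), collapse = ", "),
         call. = FALSE)
  covs <- cox_covariate_sets(model, stratum)
  covs <- covs[covs %in% names(data)]
  d <- data
  d$.time <- d[[tcol]]
  d$.event <- d[[ecol]]
  if (exposure_type == "quintile") {
    d$.exposure <- factor(paste0("Q", d[[exposure]]),
                          levels = paste0("Q", 1:5))
  } else {
    d$.exposure <- d[[exposure]]
    if (standardize) d$.exposure <- d$.exposure / sd(d$.exposure)
  }
  if (nrow(d) < 3) stop("too few observations for a Cox fit", call. = FALSE)
  ev <- sum(d$.event)
  if (ev < 2) stop("fewer than 2 events; model not estimable", call. = FALSE)
  if (ev < 10) warning("fewer than 10 events; estimates will be unstable",
                       call. = FALSE)
  if (exposure_type == "continuous" && sd(d$.exposure) == 0)
    stop("exposure '", exposure, "' is constant; no estimable term",
         call. = FALSE)
  rhs <- c(".exposure", covs)
  if (interaction) {
    if (length(unique(d$sex)) < 2)
      stop("sex interaction requires both sexes in the data", call. = FALSE)
    rhs <- c(rhs, ".exposure:sex")
  }
  fml <- as.formula(paste("survival::Surv(.time, .event) ~",
                          paste(rhs, collapse = " + ")))
  fit <- tryCatch(
    survival::coxph(fml, data = d, ties = "efron"),
    error = function(e) stop("Cox fit failed: ", conditionMessage(e),
                             call. = FALSE))
  if (!is.null(fit$info) && any(grepl("did not converge", fit$info)))
    stop("Cox fit did not converge", call. = FALSE)
  sm <- summary(fit)
  cf <- sm$coefficients
  ci <- sm$conf.int
  is_exp <- grepl("^\\.exposure", rownames(cf)) &
    !grepl(":", rownames(cf))
  term_names <- rownames(cf)[is_exp]
  pretty <- sub("^\\.exposure", exposure, term_names)
  terms <- data.frame(term = pretty,
                      beta = cf[is_exp, "coef"],
                      se = cf[is_exp, "se(coef)"],
                      hr = ci[is_exp, "exp(coef)"],
                      ci_lo = ci[is_exp, "lower .95"],
                      ci_hi = ci[is_exp, "upper .95"],
                      p = cf[is_exp, "Pr(>|z|)"],
                      row.names = NULL, stringsAsFactors = FALSE)
  interaction_p <- NA_real_
  if (interaction) {
    iterms <- rownames(cf)[grepl("^\\.exposure.*:sex", rownames(cf))]
    interaction_p <- unname(wald_test(fit, iterms)["p"])
  }
  out <- list(terms = terms, n = nrow(d), events = ev,
              interaction_p = interaction_p, fit = fit, exposure = exposure,
              exposure_type = exposure_type, outcome = outcome,
              model = model, stratum = stratum)
  class(out) <- "dietnet_cox"
  out
}

#' @export
print.dietnet_cox <- function(x, ...) {
  cat(sprintf("Cox model %d, outcome %s, stratum %s (%d participants, %d events)\n",
              x$model, x$outcome, x$stratum, x$n, x$events))
  tt <- x$terms
  tt$hr <- sprintf("%.3f", tt$hr)
  tt$ci <- sprintf("(%.3f, %.3f)", x$terms$ci_lo, x$terms$ci_hi)
  tt$p <- format.pval(x$terms$p, digits = 3)
  print(tt[, c("term", "hr", "ci", "p")], row.names = FALSE)
  if (!is.na(x$interaction_p))
    cat(sprintf("sex-interaction p = %s\n", format.pval(x$interaction_p, 3)))
  invisible(x)
}

#' Full association table across communities, models and strata
#'
#' Fits every requested combination of exposure x outcome x model x stratum
#' (continuous and quintile exposures), adding the sex-interaction p at the
#' fullest adjustment in the total stratum.
#'
#' @param data a [survival_data()] frame.
#' @param communities community labels (e.g. `c("c1", "c2")`); exposures are
#'   `score_<c>` / `quintile_<c>`.
#' @param outcomes,models,strata,exposure_types combinations to fit.
#' @param interaction add the sex-interaction test (Model 3, total stratum).
#' @return Data frame in tidy layout: outcome, community, stratum, model,
#'   exposure_type, term, hr, ci_lo, ci_hi, p, interaction_p, n, events.
#' @export
association_table <- function(data, communities,
                              outcomes = "stroke_or_mi", models = 1:3,
                              strata = c("total", "male", "female"),
                              exposure_types = c("continuous", "quintile"),
                              interaction = TRUE) {
  rows <- list()
  for (oc in outcomes) for (cm in communities) for (st in strata)
    for (md in models) for (ty in exposure_types) {
      expo <- paste0(if (ty == "continuous") "score_" else "quintile_", cm)
      want_int <- interaction && md == 3 && st == "total"
      f <- fit_cox(data, expo, outcome = oc, model = md, stratum = st,
                   exposure_type = ty, interaction = want_int)
      tt <- f$terms
      rows[[length(rows) + 1]] <- data.frame(
        outcome = oc, community = cm, stratum = st, model = md,
        exposure_type = ty, term = tt$term, hr = tt$hr, ci_lo = tt$ci_lo,
        ci_hi = tt$ci_hi, p = tt$p, interaction_p = f$interaction_p,
        n = f$n, events = f$events, stringsAsFactors = FALSE)
    }
  do.call(rbind, rows)
}

#' Per-food-group models for isolated nodes
#'
#' One fully adjusted (Model 3) continuous-intake Cox fit per isolated food
#' group and stratum, plus the sex-interaction p per group.
#'
#' @param data a [survival_data()] frame containing `intake_<group>` columns
#'   (see [survival_data()]).
#' @param isolated character vector of isolated food-group names.
#' @param outcome outcome to model.
#' @param strata strata to fit.
#' @param model adjustment level (default 3).
#' @return Tidy data frame, one row per group x stratum.
#' @export
isolated_group_models <- function(data, isolated, outcome = "stroke_or_mi",
                                  strata = c("total", "male", "female"),
                                  model = 3) {
  rows <- list()
  for (g in isolated) {
    expo <- paste0("intake_", g)
    int_p <- NA_real_
    for (st in strata) {
      want_int <- st == "total"
      f <- fit_cox(data, expo, outcome = outcome, model = model,
                   stratum = st, exposure_type = "continuous",
                   interaction = want_int)
      if (want_int) int_p <- f$interaction_p
      rows[[length(rows) + 1]] <- data.frame(
        group = g, stratum = st, model = model, outcome = outcome,
        hr = f$terms$hr, ci_lo = f$terms$ci_lo, ci_hi = f$terms$ci_hi,
        p = f$terms$p, interaction_p = if (want_int) int_p else NA_real_,
        n = f$n, events = f$events, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Write an association table as TSV
#'
#' @param tab data frame from [association_table()] or
#'   [isolated_group_models()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_association_table <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
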