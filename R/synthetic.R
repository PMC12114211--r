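# Synthetic FFQ cohort generator: planted block-structured sparse precision
# matrices, zero-inflated lognormal intakes, covariates with missingness, and
# multi-wave self-reported outcomes from a proportional-hazards model. Every
# downstream stage can be validated against the recorded ground truth.

# 45 food-group labels used as default node names (realistic labels only; the
# planted community membership is random per seed).
food_group_names <- function(p = 45) {
  nm <- c("breads", "chocolate_sweets", "eggs", "blue_fish", "white_fish",
          "soybean_products", "milk", "pizza_hamburger",
          "yellow_orange_fruit", "white_fruit", "purple_fruit",
          "red_pink_fruit", "red_vegetables", "dairy",
          "white_meat", "sushi", "meat_soup", "unprocessed_red_meat",
          "noodles", "green_tea",
          "soda", "other_drinks", "rice_cake", "white_rice", "mixed_rice",
          "mushrooms", "other_vegetables", "kimchi", "carrots",
          "brown_vegetables", "cruciferous_vegetables", "pumpkin",
          "radishes", "allium_vegetables", "green_vegetables",
          "potatoes_starch",
          "cereal", "crustacean", "legumes", "mollusks", "coffee",
          "seaweed", "processed_red_meat", "processed_seafood", "nuts")
  if (p == length(nm)) nm else sprintf("fg%02d", seq_len(p))
}

#' Planted-network specification
#'
#' Describes the ground-truth conditional-dependency structure: `K`
#' communities of the given sizes (each generated connected), remaining nodes
#' isolated, within-community edges added at `within_edge_prob` on top of a
#' random spanning path, planted partial-correlation magnitudes drawn from
#' `magnitude`, a fraction `negative_edge_frac` with negative sign.
#'
#' @param p node count.
#' @param community_sizes integer sizes (each `>= 2`) summing to `<= p`.
#' @param within_edge_prob extra-edge probability in `[0, 1]`.
#' @param magnitude range of planted `|partial correlation|`.
#' @param negative_edge_frac fraction of planted edges with negative sign.
#' @param seed integer seed.
#' @return Object of class `"planted_network_spec"`.
#' @export
planted_network_spec <- function(p = 45, community_sizes = c(8, 6, 6, 5, 11),
                                 within_edge_prob = 0.2,
                                 magnitude = c(0.15, 0.3),
                                 negative_edge_frac = 0.2, seed = 1L) {
  community_sizes <- as.integer(community_sizes)
  if (length(community_sizes) && any(community_sizes < 2))
    stop("each community needs at least 2 nodes", call. = FALSE)
  if (sum(community_sizes) > p)
    stop("community sizes exceed p", call. = FALSE)
  stopifnot(within_edge_prob >= 0, within_edge_prob <= 1,
            length(magnitude) == 2, magnitude[1] <= magnitude[2],
            magnitude[1] >= 0, magnitude[2] < 1,
            negative_edge_frac >= 0, negative_edge_frac <= 1)
  structure(list(p = as.integer(p), community_sizes = community_sizes,
                 K = length(community_sizes),
                 n_isolated = p - sum(community_sizes),
                 within_edge_prob = within_edge_prob, magnitude = magnitude,
                 negative_edge_frac = negative_edge_frac,
                 seed = as.integer(seed)),
            class = "planted_network_spec")
}

# Sample one community block of signed partial correlations: random spanning
# cycle ("ring + random chords", so every member has degree >= 2 and the
# block is connected) plus Bernoulli extras; rejection on the minimum
# eigenvalue of I - R so the full precision matrix is positive definite while
# keeping the requested magnitudes exactly.
sample_block <- function(size, spec, min_eig = 0.08, max_tries = 500) {
  for (try in seq_len(max_tries)) {
    R <- matrix(0, size, size)
    ord <- sample(size)
    pairs <- if (size == 2) cbind(ord[1], ord[2]) else
      cbind(ord, ord[c(2:size, 1)])               # spanning cycle
    if (size > 3) {
      all_pairs <- t(utils::combn(size, 2))
      on_cycle <- paste(pmin(pairs[, 1], pairs[, 2]),
                        pmax(pairs[, 1], pairs[, 2]))
      rest <- all_pairs[!paste(all_pairs[, 1], all_pairs[, 2]) %in% on_cycle, ,
                        drop = FALSE]
      extra <- rest[runif(nrow(rest)) < spec$within_edge_prob, , drop = FALSE]
      pairs <- rbind(pairs, extra)
    }
    mag <- runif(nrow(pairs), spec$magnitude[1], spec$magnitude[2])
    sgn <- ifelse(runif(nrow(pairs)) < spec$negative_edge_frac, -1, 1)
    rho <- mag * sgn
    R[cbind(pairs[, 1], pairs[, 2])] <- rho
    R[cbind(pairs[, 2], pairs[, 1])] <- rho
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (1 - max(ev) >= min_eig) return(R)
  }
  stop(sprintf(
    paste("cannot achieve positive definiteness: after %d draws no %d-node",
          "community satisfied min eigenvalue(I - R) >= %.2f; reduce",
          "within_edge_prob or the magnitude range"),
    max_tries, size, min_eig), call. = FALSE)
}

#' Planted precision matrix and true partition
#'
#' Builds `Theta = I - R` with `R` block-diagonal over the planted
#' communities, so planted edges have partial correlation exactly equal to the
#' drawn signed magnitudes, communities are connected components of the
#' support graph, and isolated nodes have no off-diagonal entries.
#'
#' @param spec a [planted_network_spec()].
#' @return List: `theta` (p x p precision), `pcor` (partial correlations),
#'   `membership` (named integer, `NA` for isolated), `isolated`, `nodes`.
#' @export
make_planted_precision <- function(spec) {
  stopifnot(inherits(spec, "planted_network_spec"))
  p <- spec$p
  nodes <- food_group_names(p)
  with_seed(spec$seed, {
    perm <- sample(p)  # random assignment of nodes to blocks
    theta <- diag(p)
    membership <- rep(NA_integer_, p)
    offset <- 0
    for (k in seq_along(spec$community_sizes)) {
      size <- spec$community_sizes[k]
      idx <- perm[(offset + 1):(offset + size)]
      R <- sample_block(size, spec)
      theta[idx, idx] <- diag(size) - R
      membership[idx] <- k
      offset <- offset + size
    }
    ev <- eigen(theta, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0)
      stop("planted precision is not positive definite", call. = FALSE)
    dimnames(theta) <- list(nodes, nodes)
    names(membership) <- nodes
    pc <- -theta / sqrt(outer(diag(theta), diag(theta)))
    diag(pc) <- 1
    list(theta = theta, pcor = pc, membership = membership,
         isolated = nodes[is.na(membership)], nodes = nodes)
  })
}

#' Sample raw intakes from a planted precision matrix
#'
#' Draws `Z ~ N(0, Theta^-1)`, maps to grams/day by
#' `x = max(0, 10^(location + scale * Z) - 1)` (a zero-inflated lognormal on
#' the log10 scale), then zeroes each cell independently with the per-node
#' zero-inflation probability. The `log10(1 + x)` transform therefore
#' recovers (clipped) Gaussians with the planted partial-correlation
#' structure.
#'
#' @param n participants.
#' @param theta positive-definite precision matrix.
#' @param zero_inflation per-node zero probability in `[0, 1)` (recycled).
#' @param location,scale per-node location/scale on the log10 scale
#'   (recycled).
#' @param seed integer seed.
#' @return Raw intake matrix (attribute `transform = "raw"`), rows named
#'   `p000001...`.
#' @export
sample_intakes <- function(n, theta, zero_inflation = 0, location = 1.4,
                           scale = 0.35, seed = 1L) {
  check_square_symmetric(theta, "theta")
  p <- ncol(theta)
  U <- tryCatch(chol(theta), error = function(e)
    stop("theta is not positive definite", call. = FALSE))
  zero_inflation <- rep_len(zero_inflation, p)
  if (any(zero_inflation < 0 | zero_inflation >= 1))
    stop("zero_inflation must be in [0, 1)", call. = FALSE)
  location <- rep_len(location, p)
  scale <- rep_len(scale, p)
  with_seed(seed, {
    E <- matrix(rnorm(n * p), p, n)
    Z <- t(backsolve(U, E))                       # rows ~ N(0, theta^-1)
    Y <- sweep(sweep(Z, 2, scale, `*`), 2, location, `+`)
    X <- pmax(10^Y - 1, 0)
    zero <- matrix(runif(n * p), n, p) <
      matrix(zero_inflation, n, p, byrow = TRUE)
    X[zero] <- 0
    dimnames(X) <- list(sprintf("p%06d", seq_len(n)),
                        colnames(theta) %||% sprintf("v%02d", seq_len(p)))
    attr(X, "transform") <- "raw"
    X
  })
}

#' Synthetic-cohort specification
#'
#' Bundles every generator setting: the planted network, the zero-inflated
#' lognormal intake model, covariate and community log-hazard effects, the
#' exponential baseline hazard and the follow-up wave design.
#'
#' Community effects are log hazard ratios per standard deviation of the true
#' community score; numeric covariate effects are per unit above the cohort
#' mean, so `baseline_hazard` is the event rate (events/person-year) at mean
#' covariates and average scores.
#'
#' @param n participants.
#' @param network a [planted_network_spec()].
#' @param zero_inflation per-node zero-intake probability.
#' @param location,scale per-node log10-scale intake parameters; `NULL` draws
#'   them once from U(0.8, 2.0) and U(0.25, 0.45).
#' @param community_effects named log-HR per SD of true score (`c1..cK`).
#' @param covariate_effects named log-HR per covariate unit/indicator.
#' @param baseline_hazard events per person-year (> 0).
#' @param n_waves follow-up waves (>= 1).
#' @param wave_spacing_years years between waves.
#' @param missing_response_prob probability a non-event response is missing.
#' @param baseline_prevalence_prob probability of a prevalent case at
#'   baseline.
#' @param seed integer master seed.
#' @return Object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n = 5000, network = planted_network_spec(),
                        zero_inflation = 0, location = NULL, scale = NULL,
                        community_effects = c(c1 = 0, c2 = -0.12, c3 = -0.2,
                                              c4 = 0.12, c5 = 0.08),
                        covariate_effects = c(age = 0.05, sex_male = 0.4,
                                              smoking_current = 0.3,
                                              exercise_yes = -0.2,
                                              comorbidity_yes = 0.5,
                                              bmi = 0.04),
                        baseline_hazard = 0.006, n_waves = 4,
                        wave_spacing_years = 2, missing_response_prob = 0.05,
                        baseline_prevalence_prob = 0.02, seed = 1L) {
  stopifnot(inherits(network, "planted_network_spec"), n >= 1,
            baseline_hazard > 0, n_waves >= 1, wave_spacing_years > 0,
            missing_response_prob >= 0, missing_response_prob < 1,
            baseline_prevalence_prob >= 0, baseline_prevalence_prob < 1)
  structure(list(n = as.integer(n), network = network,
                 zero_inflation = zero_inflation, location = location,
                 scale = scale, community_effects = community_effects,
                 covariate_effects = covariate_effects,
                 baseline_hazard = baseline_hazard,
                 n_waves = as.integer(n_waves),
                 wave_spacing_years = wave_spacing_years,
                 missing_response_prob = missing_response_prob,
                 baseline_prevalence_prob = baseline_prevalence_prob,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Demographic / lifestyle covariates with injected missingness (income >= 5%
# so the unknown-category path is exercised; bmi/education below it).
simulate_covariates <- function(n, seed,
                                missing_prob = c(income = 0.08, bmi = 0.02,
                                                 education = 0.02)) {
  with_seed(seed, {
    sex <- ifelse(runif(n) < 0.4, "male", "female")
    age <- pmin(pmax(round(rnorm(n, 54.5, 8)), 40), 79)
    total_energy <- round(rnorm(n, 1800, 520))
    bmi <- round(rnorm(n, 24, 3), 1)
    waist <- round(ifelse(sex == "male", rnorm(n, 86, 8), rnorm(n, 78, 9)), 1)
    df <- data.frame(
      id = sprintf("p%06d", seq_len(n)),
      sex = sex, age = age, total_energy = total_energy,
      education = sample(c("middle_school_or_less", "high_school",
                           "college_or_more"), n, TRUE, c(0.3, 0.4, 0.3)),
      income = sample(c("low", "middle", "high"), n, TRUE, c(0.35, 0.4, 0.25)),
      city = sample(c("urban", "rural"), n, TRUE, c(0.7, 0.3)),
      marriage = sample(c("married", "single"), n, TRUE, c(0.85, 0.15)),
      job = sample(c("office", "labor_agriculture", "unemployed_housekeeping"),
                   n, TRUE, c(0.35, 0.3, 0.35)),
      comorbidity = sample(c("no", "yes"), n, TRUE, c(0.75, 0.25)),
      bmi = bmi, waist = waist,
      smoking = sample(c("never", "past", "current"), n, TRUE,
                       c(0.6, 0.2, 0.2)),
      drinking = sample(c("never", "past", "current"), n, TRUE,
                        c(0.4, 0.1, 0.5)),
      exercise = sample(c("no", "yes"), n, TRUE, c(0.5, 0.5)),
      baseline_date = as.Date("2005-01-01") + sample.int(365, n, TRUE) - 1L,
      stringsAsFactors = FALSE)
    for (cl in names(missing_prob))
      df[[cl]][runif(n) < missing_prob[cl]] <- NA
    df
  })
}

# linear predictor from named covariate effects (numeric: centred at the
# cohort mean; "name_level": indicator for that level)
covariate_lp <- function(covariates, effects) {
  lp <- numeric(nrow(covariates))
  for (nm in names(effects)) {
    if (nm %in% names(covariates) && is.numeric(covariates[[nm]])) {
      x <- covariates[[nm]]
      x[is.na(x)] <- mean(x, na.rm = TRUE)
      lp <- lp + effects[[nm]] * (x - mean(x))
    } else {
      parts <- regmatches(nm, regexpr("_[^_]+$", nm))
      var <- sub("_[^_]+$", "", nm)
      lev <- sub("^_", "", parts)
      if (!var %in% names(covariates))
        stop("covariate effect '", nm, "' matches no covariate", call. = FALSE)
      lp <- lp + effects[[nm]] *
        as.numeric(!is.na(covariates[[var]]) & covariates[[var]] == lev)
    }
  }
  lp
}

#' Simulate multi-wave self-reported outcomes
#'
#' Event times are exponential with rate
#' `baseline_hazard * exp(linear predictor)`; the first follow-up wave whose
#' date reaches the event time records "yes" (stroke / MI / both split
#' 0.330 / 0.652 / 0.018) and later waves are omitted for that participant.
#' Missingness is injected into non-event ("no") responses only, so planted
#' events are never erased. True event times are retained for oracle checks.
#'
#' @param scores true community-score matrix (raw scale, rows = participants).
#' @param covariates covariate data frame including `baseline_date`.
#' @param community_effects log-HR per SD of each score column.
#' @param covariate_effects named covariate log-HRs.
#' @param baseline_hazard events/person-year.
#' @param n_waves,wave_spacing_years follow-up design.
#' @param missing_response_prob per-response missingness for non-events.
#' @param baseline_prevalence_prob probability of a "yes" at baseline.
#' @param seed integer seed.
#' @return List: `waves`, `baseline` (response data frames), `truth`
#'   (per-participant event time, linear predictor), `score_center`,
#'   `score_scale`.
#' @export
simulate_outcomes <- function(scores, covariates, community_effects,
                              covariate_effects, baseline_hazard,
                              n_waves = 4, wave_spacing_years = 2,
                              missing_response_prob = 0.05,
                              baseline_prevalence_prob = 0.02, seed = 1L) {
  n <- nrow(covariates)
  lp <- covariate_lp(covariates, covariate_effects)
  center <- scale_ <- NULL
  if (!is.null(scores) && length(community_effects)) {
    center <- colMeans(scores)
    scale_ <- apply(scores, 2, sd)
    zs <- sweep(sweep(scores, 2, center), 2, scale_, `/`)
    use <- intersect(names(community_effects), colnames(zs))
    lp <- lp + as.vector(zs[, use, drop = FALSE] %*%
                           community_effects[use])
  }
  with_seed(seed, {
    event_time <- rexp(n, rate = baseline_hazard * exp(lp))
    type <- sample(c("stroke", "mi", "both"), n, TRUE,
                   prob = c(0.330, 0.652, 0.018))
    prevalent <- runif(n) < baseline_prevalence_prob
    baseline <- data.frame(
      id = covariates$id,
      stroke_response = ifelse(prevalent & type != "mi", "yes", "no"),
      mi_response = ifelse(prevalent & type != "stroke", "yes", "no"),
      stringsAsFactors = FALSE)
    wave_offset_days <- round(seq_len(n_waves) * wave_spacing_years *
                                DAYS_PER_YEAR)
    rows <- vector("list", n_waves)
    for (k in seq_len(n_waves)) {
      wave_date <- covariates$baseline_date + wave_offset_days[k]
      t_wave <- wave_offset_days[k] / DAYS_PER_YEAR
      event_now <- event_time <= t_wave
      event_before <- if (k == 1) rep(FALSE, n) else
        event_time <= wave_offset_days[k - 1] / DAYS_PER_YEAR
      include <- !event_before         # cases are not carried forward
      sr <- ifelse(event_now & type %in% c("stroke", "both"), "yes", "no")
      mr <- ifelse(event_now & type %in% c("mi", "both"), "yes", "no")
      miss <- runif(n) < missing_response_prob
      sr[miss & sr == "no"] <- NA
      mr[miss & mr == "no"] <- NA
      rows[[k]] <- data.frame(id = covariates$id[include],
                              wave = rep.int(k, sum(include)),
                              wave_date = wave_date[include],
                              stroke_response = sr[include],
                              mi_response = mr[include],
                              stringsAsFactors = FALSE)
    }
    waves <- do.call(rbind, rows)
    waves <- waves[order(waves$id, waves$wave), ]
    rownames(waves) <- NULL
    list(waves = waves, baseline = baseline,
         truth = data.frame(id = covariates$id, event_time = event_time,
                            lp = lp, type = type,
                            stringsAsFactors = FALSE),
         score_center = center, score_scale = scale_)
  })
}

#' Generate a complete synthetic cohort
#'
#' Composes the planted precision, intake sampling, true centralities and
#' scores (eigenvector centrality of the planted network), covariates, and
#' proportional-hazards outcomes. All ground truth is returned alongside the
#' observable data.
#'
#' @param spec a [cohort_spec()].
#' @return Object of class `"dietnet_cohort"`: `intakes`, `covariates`,
#'   `waves`, `baseline`, `truth` (planted theta/pcor/membership/centrality/
#'   scores/event times/effects), `spec`.
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  net_spec <- spec$network
  net_spec$seed <- derive_seed(spec$seed, 11L)
  planted <- make_planted_precision(net_spec)
  p <- net_spec$p
  loc <- spec$location %||%
    with_seed(derive_seed(spec$seed, 12L), runif(p, 0.8, 2.0))
  sc <- spec$scale %||%
    with_seed(derive_seed(spec$seed, 13L), runif(p, 0.25, 0.45))
  intakes <- sample_intakes(spec$n, planted$theta, spec$zero_inflation,
                            loc, sc, seed = derive_seed(spec$seed, 14L))
  true_net <- to_network(planted$theta)
  centrality <- eigenvector_centrality(true_net)
  memb <- planted$membership[!is.na(planted$membership)]
  part <- list(membership = memb, isolated = planted$isolated,
               n_communities = max(memb))
  class(part) <- "community_partition"
  true_scores <- community_scores(intakes, part, centrality)
  covariates <- simulate_covariates(spec$n, derive_seed(spec$seed, 15L))
  oc <- simulate_outcomes(true_scores, covariates, spec$community_effects,
                          spec$covariate_effects, spec$baseline_hazard,
                          spec$n_waves, spec$wave_spacing_years,
                          spec$missing_response_prob,
                          spec$baseline_prevalence_prob,
                          seed = derive_seed(spec$seed, 16L))
  out <- list(intakes = intakes, covariates = covariates, waves = oc$waves,
              baseline = oc$baseline,
              truth = list(theta = planted$theta, pcor = planted$pcor,
                           membership = planted$membership,
                           isolated = planted$isolated,
                           centrality = centrality, scores = true_scores,
                           score_center = oc$score_center,
                           score_scale = oc$score_scale,
                           event = oc$truth, location = loc, scale = sc,
                           community_effects = spec$community_effects,
                           covariate_effects = spec$covariate_effects),
              spec = spec)
  class(out) <- "dietnet_cohort"
  out
}

#' @export
print.dietnet_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic FFQ cohort: %d participants x %d food groups, %d planted communities, %d isolated nodes\n",
    nrow(x$intakes), ncol(x$intakes), x$spec$network$K,
    x$spec$network$n_isolated))
  invisible(x)
}

#' Write a synthetic cohort as delimited text + ground-truth JSON
#'
#' Writes `intakes.tsv`, `covariates.tsv`, `waves.tsv`, `baseline.tsv` and a
#' `ground_truth.json` sidecar (precision matrix, partition, centralities,
#' true coefficients, event times).
#'
#' @param cohort a `"dietnet_cohort"`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ik <- data.frame(id = rownames(cohort$intakes), cohort$intakes,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(ik, file.path(dir, "intakes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(cohort$covariates, file.path(dir, "covariates.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cohort$waves, file.path(dir, "waves.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(cohort$baseline, file.path(dir, "baseline.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  tr <- cohort$truth
  gt <- list(theta = tr$theta, membership = as.list(tr$membership),
             isolated = tr$isolated, centrality = as.list(tr$centrality),
             score_center = tr$score_center, score_scale = tr$score_scale,
             community_effects = as.list(tr$community_effects),
             covariate_effects = as.list(tr$covariate_effects),
             event_time = tr$event$event_time, seed = cohort$spec$seed)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing the delimited files.
#' @return List with `intakes` (raw matrix), `covariates`, `waves`,
#'   `baseline`; duplicate participant ids are rejected.
#' @export
read_cohort <- function(dir) {
  ik <- read.delim(file.path(dir, "intakes.tsv"), check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (any(duplicated(ik$id)))
    stop("duplicate participant ids in intakes.tsv", call. = FALSE)
  m <- as.matrix(ik[, -1, drop = FALSE])
  rownames(m) <- ik$id
  attr(m, "transform") <- "raw"
  cov <- read.delim(file.path(dir, "covariates.tsv"), stringsAsFactors = FALSE)
  if (any(duplicated(cov$id)))
    stop("duplicate participant ids in covariates.tsv", call. = FALSE)
  cov$baseline_date <- as.Date(cov$baseline_date)
  waves <- read.delim(file.path(dir, "waves.tsv"), stringsAsFactors = FALSE)
  waves$wave_date <- as.Date(waves$wave_date)
  bl_path <- file.path(dir, "baseline.tsv")
  baseline <- if (file.exists(bl_path))
    read.delim(bl_path, stringsAsFactors = FALSE) else NULL
  list(intakes = m, covariates = cov, waves = waves, baseline = baseline)
}
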