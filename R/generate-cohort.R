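## --- internal samplers -------------------------------------------------------

## trajectory label -> (childhood, education, adult) low/high triple
trajectory_triple <- function(label) {
  map <- list(stable_high = c("high", "high", "high"),
              education_downward = c("high", "low", "high"),
              material_downward = c("high", "high", "low"),
              education_and_material_downward = c("high", "low", "low"),
              education_and_material_upward = c("low", "high", "high"),
              material_upward = c("low", "low", "high"),
              education_upward = c("low", "high", "low"),
              stable_low = c("low", "low", "low"))
  t(vapply(map[label], identity, character(3)))
}

## sample childhood indicator values consistent with a given low/high class,
## so that re-scoring round-trips exactly
sample_childhood_indicators <- function(class) {
  n <- length(class)
  combos <- expand.grid(tenure = 0:1, hot_water = 0:1, crowd = 0:1)
  base <- with(combos, ifelse(tenure == 1, 0.90, 0.10) *
                 ifelse(hot_water == 1, 0.85, 0.15) *
                 ifelse(crowd == 1, 0.60, 0.40))
  total <- rowSums(combos)
  pick_combo <- function(cls) {
    keep <- if (cls == "high") total >= 2 else total < 2
    w <- base * keep
    sample(nrow(combos), 1, prob = w)
  }
  idx <- vapply(class, pick_combo, integer(1))
  pts <- combos[idx, ]
  tenure <- ifelse(pts$tenure == 1,
                   ifelse(stats::runif(n) < 0.9, "one_dwelling", "multi_dwelling"),
                   "rented")
  persons <- sample(2:7, n, replace = TRUE)
  rooms <- integer(n)
  hi <- pts$crowd == 1
  rooms[hi] <- ceiling(0.6 * persons[hi]) + sample(0:2, sum(hi), replace = TRUE)
  lo <- !hi
  max_lo <- ceiling(0.6 * persons[lo]) - 1L
  rooms[lo] <- 1L + floor(stats::runif(sum(lo)) * pmax(max_lo, 1L))
  rooms[lo] <- pmin(rooms[lo], max_lo)
  rooms[lo] <- pmax(rooms[lo], 1L)
  ## persons with max_lo < 1 cannot be under-crowded; bump household size
  bad <- lo & (ceiling(0.6 * persons) - 1L < 1L)
  if (any(bad)) {
    persons[bad] <- 4L
    rooms[bad] <- 1L
  }
  data.frame(housing_tenure_childhood = tenure,
             hot_water = pts$hot_water == 1,
             rooms_childhood = rooms, persons_childhood = persons,
             stringsAsFactors = FALSE)
}

sample_education <- function(class) {
  n <- length(class)
  out <- character(n)
  hi <- class == "high"
  out[hi] <- ifelse(stats::runif(sum(hi)) < 0.746, "upper_secondary", "post_secondary")
  out[!hi] <- ifelse(stats::runif(sum(!hi)) < 0.45, "primary", "lower_secondary")
  out
}

sample_adult_indicators <- function(class) {
  n <- length(class)
  combos <- expand.grid(tenure = 0:2, occ = 0:3, crowd = 0:1)
  base <- with(combos,
               c(0.095, 0.814, 0.089)[tenure + 1] *
                 c(0.25, 0.35, 0.25, 0.15)[occ + 1] *
                 c(0.45, 0.55)[crowd + 1])
  total <- rowSums(combos)
  pick_combo <- function(cls) {
    keep <- if (cls == "high") total > 3 else total <= 3
    sample(nrow(combos), 1, prob = base * keep)
  }
  idx <- vapply(class, pick_combo, integer(1))
  pts <- combos[idx, ]
  tenure <- childhood_tenure_levels()[pts$tenure + 1]
  occupation <- rev(occupation_levels())[pts$occ + 1]
  persons <- integer(n); rooms <- integer(n)
  hi <- pts$crowd == 1
  persons[hi] <- sample(1:5, sum(hi), replace = TRUE)
  rooms[hi] <- persons[hi] + sample(0:3, sum(hi), replace = TRUE)
  persons[!hi] <- sample(2:7, sum(!hi), replace = TRUE)
  rooms[!hi] <- pmax(1L, persons[!hi] - 1L - sample(0:2, sum(!hi), replace = TRUE))
  data.frame(housing_tenure_adult = tenure, occupational_class = occupation,
             rooms_adult = rooms, persons_adult = persons,
             stringsAsFactors = FALSE)
}

## --- generator ---------------------------------------------------------------

#' Generate a synthetic cohort with known ground truth
#'
#' Draws a seeded cohort with the statistical structure the downstream
#' analysis assumes: 8-level socioeconomic trajectories sampled first and then
#' materialized as consistent childhood/education/adult indicators (so SES
#' scoring round-trips exactly); chronological age, sex and center;
#' trajectory-graded mediators (lifestyle and dietary inflammation scores,
#' Mediterranean diet score, physical activity, BMI, SF-36 physical/mental
#' wellbeing, smoking and drinking); a delta-age signal following a linear
#' structural model (direct trajectory effect plus mediator loadings plus
#' noise); 40 blood markers drifting with biological age (4 of them near
#' collinear combinations of the others); synthetic inflammatory biomarkers
#' driven by the pro-inflammatory lifestyle components; and item-level MCAR
#' missingness.
#'
#' @param config A [cohort_config()] object.
#' @return A list of class `synthetic_cohort` with elements `table` (the
#'   cohort data.frame) and `truth` (a `cohort_truth` object holding
#'   per-participant expected delta age and the analytic per-trajectory
#'   direct, indirect and proportion-mediated decomposition).
#' @examples
#' cohort <- generate_cohort(cohort_config(n_participants = 200, seed = 7))
#' table(cohort$table$trajectory_true)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config"))
    stop_config("config", "must be created by cohort_config()")
  set.seed(config$seed)
  n <- config$n_participants
  lv <- trajectory_levels()

  trajectory <- sample(lv, n, replace = TRUE, prob = config$trajectory_probs)
  triple <- trajectory_triple(trajectory)

  tab <- data.frame(participant_id = sprintf("P%06d", seq_len(n)),
                    stringsAsFactors = FALSE)
  tab <- cbind(tab, sample_childhood_indicators(triple[, 1]))
  tab$education_level <- sample_education(triple[, 2])
  tab <- cbind(tab, sample_adult_indicators(triple[, 3]))

  ## location solved so the truncated distribution has the target mean
  trunc_mean <- function(mu) {
    a <- (config$age_range[1] - mu) / config$age_sd
    b <- (config$age_range[2] - mu) / config$age_sd
    mu + config$age_sd * (stats::dnorm(a) - stats::dnorm(b)) /
      (stats::pnorm(b) - stats::pnorm(a))
  }
  loc <- stats::uniroot(function(mu) trunc_mean(mu) - config$age_mean,
                        config$age_mean + c(-10, 1))$root
  tab$ca <- rtruncnorm(n, loc, config$age_sd,
                       config$age_range[1], config$age_range[2])
  tab$sex <- ifelse(stats::runif(n) < config$sex_fraction_male, "male", "female")
  tab$center <- paste0("C", sample(config$n_centers, n, replace = TRUE))

  ## continuous mediators (dis is built from the food groups below)
  med <- config$mediator_means
  sds <- config$mediator_sds
  mu_ref <- med["stable_high", ]
  lat <- sapply(continuous_mediators(), function(j)
    med[trajectory, j] + sds[j] * stats::rnorm(n))
  tab$lis <- lat[, "lis"]
  tab$mds <- as.integer(pmin(9, pmax(0, round(lat[, "mds"]))))
  tab$physical_activity <- pmax(0, lat[, "physical_activity"])
  tab$bmi <- lat[, "bmi"]
  tab$sf36_physical <- lat[, "sf36_physical"]
  tab$sf36_mental <- lat[, "sf36_mental"]

  ## 19 standardized food-group components whose weighted sum IS the dietary
  ## inflammation score, with per-trajectory mean exactly med[T, "dis"]
  w <- config$dis_weights
  wss <- sum(w^2)
  intakes <- sapply(names(w), function(g)
    w[g] * med[trajectory, "dis"] / wss + stats::rnorm(n))
  colnames(intakes) <- paste0("intake_", names(w))
  tab <- cbind(tab, as.data.frame(intakes))
  tab$dis <- as.vector(intakes %*% w)

  ## 9 Mediterranean-diet component flags consistent with the integer score
  flags <- matrix(FALSE, n, 9, dimnames = list(NULL, paste0("mds_", mds_components())))
  for (k in sort(unique(tab$mds))) {
    rows <- which(tab$mds == k)
    if (k > 0) for (i in rows) flags[i, sample(9, k)] <- TRUE
  }
  tab <- cbind(tab, as.data.frame(flags))

  ## smoking and drinking compositions by trajectory
  tab$smoking <- sample_categorical(config$smoking_probs[trajectory, , drop = FALSE],
                                    colnames(config$smoking_probs))
  tab$drinking5 <- sample_categorical(config$drinking_probs[trajectory, , drop = FALSE],
                                      colnames(config$drinking_probs))
  tab$alcohol_responded <- tab$drinking5 != "non_responder"
  tab$drinker_history <- ifelse(tab$drinking5 %in% c("moderate", "heavy"), "current",
                                ifelse(tab$drinking5 == "non_responder", NA,
                                       tab$drinking5))
  tab$alcohol_g_day <- 0
  mod <- tab$drinking5 == "moderate"
  tab$alcohol_g_day[mod] <- rtruncnorm(sum(mod), 20, 12, 0.1, 48)
  hv <- tab$drinking5 == "heavy"
  tab$alcohol_g_day[hv] <- 48 + stats::rexp(sum(hv), rate = 1 / 12)
  tab$alcohol_g_day[!tab$alcohol_responded] <- NA

  ## delta-age structural model
  th <- config$outcome_loadings
  mds_ref <- expected_rounded_normal(med["stable_high", "mds"], sds["mds"], 9)
  contrib <- th["lis"] * (tab$lis - mu_ref["lis"]) +
    th["dis"] * (tab$dis - mu_ref["dis"]) +
    th["mds"] * (tab$mds - mds_ref) +
    th["physical_activity"] * (tab$physical_activity - mu_ref["physical_activity"]) +
    th["bmi"] * (tab$bmi - mu_ref["bmi"]) +
    th["sf36_physical"] * (tab$sf36_physical - mu_ref["sf36_physical"]) +
    th["sf36_mental"] * (tab$sf36_mental - mu_ref["sf36_mental"]) +
    th["smoking_current"] * ((tab$smoking == "current") -
                               config$smoking_probs["stable_high", "current"]) +
    th["smoking_former"] * ((tab$smoking == "former") -
                              config$smoking_probs["stable_high", "former"]) +
    th["drinking_heavy"] * ((tab$drinking5 == "heavy") -
                              config$drinking_probs["stable_high", "heavy"]) +
    th["drinking_former"] * ((tab$drinking5 == "former_drinker") -
                               config$drinking_probs["stable_high", "former_drinker"])
  direct <- config$direct_effects[trajectory]
  if (!is.null(config$direct_effects_male)) {
    male <- tab$sex == "male"
    direct[male] <- config$direct_effects_male[trajectory[male]]
  }
  if (!is.null(config$interaction_effects)) {
    ie <- config$interaction_effects
    nonref <- trajectory != "stable_high"
    for (j in names(ie)) {
      ref_j <- if (j == "mds") mds_ref else mu_ref[j]
      contrib <- contrib + ie[j] * (tab[[j]] - ref_j) * nonref
    }
  }
  expected_delta <- unname(direct + contrib)
  tab$delta_age <- expected_delta + stats::rnorm(n, 0, config$delta_noise_sd)

  ## blood markers drift with biological age = ca + delta_age
  panel <- marker_panel()
  ba_true <- tab$ca + tab$delta_age
  for (i in which(!panel$collinear)) {
    p <- panel[i, ]
    tab[[p$marker]] <- p$location + p$age_slope * (ba_true - config$age_mean) +
      p$sd * config$marker_age_noise_inflation * stats::rnorm(n)
  }
  csd <- panel$sd[match(c("cholesterol", "plateletcrit", "hematocrit",
                          "mean_corpuscular_hemoglobin"), panel$marker)]
  tab$cholesterol <- tab$hdl_cholesterol + tab$ldl_cholesterol +
    tab$triglycerides / 5 + csd[1] * stats::rnorm(n)
  tab$plateletcrit <- tab$platelets * tab$mpv / 1e4 + csd[2] * stats::rnorm(n)
  tab$hematocrit <- tab$rbc * tab$mcv / 10 + csd[3] * stats::rnorm(n)
  tab$mean_corpuscular_hemoglobin <- tab$hemoglobin / tab$rbc * 10 +
    csd[4] * stats::rnorm(n)

  ## synthetic inflammatory biomarkers from the pro-inflammatory lifestyle
  ## components (weights recoverable by derive_inflammation_weights)
  lw <- config$lis_weights
  comp <- cbind(smoking_current = as.numeric(tab$smoking == "current"),
                physical_activity = (tab$physical_activity - 3.5) / 3.9,
                alcohol_heavy = as.numeric(!is.na(tab$alcohol_g_day) &
                  ((tab$sex == "female" & tab$alcohol_g_day > 14) |
                     (tab$sex == "male" & tab$alcohol_g_day > 28))),
                bmi = (tab$bmi - 28.3) / 4.8)
  infl_signal <- as.vector(comp %*% lw)
  for (b in c("hscrp", "il6", "il8", "il10"))
    tab[[b]] <- infl_signal + stats::rnorm(n, 0, config$inflammation_noise_sd)

  ## SF-36 domain scores around the physical/mental latents
  for (d in sf36_domains()[1:4])
    tab[[paste0("sf36_", d)]] <- pmin(100, pmax(0,
      70 + 2.0 * (tab$sf36_physical - 46.6) + stats::rnorm(n, 0, 8)))
  for (d in sf36_domains()[5:8])
    tab[[paste0("sf36_", d)]] <- pmin(100, pmax(0,
      68 + 1.5 * (tab$sf36_mental - 46.9) + stats::rnorm(n, 0, 9)))

  ## prevalent conditions with a mild age gradient, independent of trajectory
  prev <- c(cvd = 0.058, cancer = 0.032, diabetes = 0.049,
            hypertension = 0.299, hyperlipidemia = 0.081)
  for (dz in names(prev)) {
    p <- stats::plogis(stats::qlogis(prev[dz]) + 0.06 * (tab$ca - config$age_mean))
    tab[[dz]] <- stats::runif(n) < p
  }

  tab$trajectory_true <- factor(trajectory, levels = lv)

  ## item-level MCAR missingness (seed fanned out from the config seed)
  if (length(config$missingness_rates))
    tab <- inject_missingness(tab, config$missingness_rates,
                              seed = (config$seed + 999983L) %% .Machine$integer.max)

  truth <- build_ground_truth(config, tab$participant_id, trajectory,
                              expected_delta, mds_ref)
  structure(list(table = tab, truth = truth), class = "synthetic_cohort")
}

## analytic per-trajectory effect decomposition implied by the config
build_ground_truth <- function(config, ids, trajectory, expected_delta, mds_ref) {
  lv <- trajectory_levels()
  med <- config$mediator_means
  sds <- config$mediator_sds
  th <- config$outcome_loadings
  mu_ref <- med["stable_high", ]
  indirect <- sapply(lv, function(tr) {
    c(lis = unname(th["lis"] * (med[tr, "lis"] - mu_ref["lis"])),
      dis = unname(th["dis"] * (med[tr, "dis"] - mu_ref["dis"])),
      mds = unname(th["mds"] *
        (expected_rounded_normal(med[tr, "mds"], sds["mds"], 9) - mds_ref)),
      physical_activity = unname(th["physical_activity"] *
        (med[tr, "physical_activity"] - mu_ref["physical_activity"])),
      bmi = unname(th["bmi"] * (med[tr, "bmi"] - mu_ref["bmi"])),
      sf36_physical = unname(th["sf36_physical"] *
        (med[tr, "sf36_physical"] - mu_ref["sf36_physical"])),
      sf36_mental = unname(th["sf36_mental"] *
        (med[tr, "sf36_mental"] - mu_ref["sf36_mental"])),
      smoking = unname(th["smoking_current"] *
        (config$smoking_probs[tr, "current"] - config$smoking_probs["stable_high", "current"]) +
        th["smoking_former"] *
        (config$smoking_probs[tr, "former"] - config$smoking_probs["stable_high", "former"])),
      drinking = unname(th["drinking_heavy"] *
        (config$drinking_probs[tr, "heavy"] - config$drinking_probs["stable_high", "heavy"]) +
        th["drinking_former"] *
        (config$drinking_probs[tr, "former_drinker"] - config$drinking_probs["stable_high", "former_drinker"])))
  })
  total_indirect <- colSums(indirect)
  direct <- config$direct_effects
  total <- direct + total_indirect
  pm <- ifelse(total != 0, total_indirect / total, NA_real_)
  structure(list(
    participants = data.frame(participant_id = ids,
                              trajectory = factor(trajectory, levels = lv),
                              expected_delta_age = expected_delta,
                              stringsAsFactors = FALSE),
    direct_effect = direct,
    indirect_contributions = t(indirect),
    total_effect = total,
    proportion_mediated = pm), class = "cohort_truth")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d participants, %d columns\n",
              nrow(x$table), ncol(x$table)))
  cat("Trajectory prevalences:\n")
  print(round(prop.table(table(x$table$trajectory_true)), 3))
  invisible(x)
}

#' @export
print.cohort_truth <- function(x, ...) {
  cat("Ground truth per trajectory (years of delta age):\n")
  print(round(cbind(direct = x$direct_effect, indirect = rowSums(x$indirect_contributions),
                    total = x$total_effect, pm = x$proportion_mediated), 3))
  invisible(x)
}

#' Inject missing-completely-at-random values
#'
#' Blanks each listed column independently at its configured rate. Observed
#' values are never altered and `participant_id` can never be made missing.
#'
#' @param table A cohort data.frame.
#' @param rates Named per-column rates in [0, 1).
#' @param seed Integer seed for the masking draws.
#' @return The table with `NA`s injected.
#' @export
inject_missingness <- function(table, rates, seed = 1L) {
  assert_that(!is.null(names(rates)) && all(nzchar(names(rates))),
              "rates must be a named vector")
  if (any(rates < 0 | rates >= 1))
    stop("missingness rates must lie in [0, 1)", call. = FALSE)
  if ("participant_id" %in% names(rates))
    stop("participant_id is an identifier and cannot be made missing",
         call. = FALSE)
  unknown <- setdiff(names(rates), names(table))
  if (length(unknown))
    warning("ignoring missingness rates for absent column(s): ",
            paste(unknown, collapse = ", "))
  set.seed(seed)
  for (col in intersect(names(rates), names(table))) {
    mask <- stats::runif(nrow(table)) < rates[col]
    table[[col]][mask] <- NA
  }
  table
}
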