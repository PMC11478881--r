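#' Eight life-course socioeconomic trajectory labels
#'
#' Ordered labels for the 2 x 2 x 2 combination of dichotomized childhood SES,
#' educational attainment, and adult material SES, anchored at `stable_high`
#' (high at all three stages) and `stable_low` (low at all three stages).
#'
#' @return Character vector of the 8 trajectory labels, in reporting order.
#' @export
trajectory_levels <- function() {
  c("stable_high", "education_downward", "material_downward",
    "education_and_material_downward", "education_and_material_upward",
    "material_upward", "education_upward", "stable_low")
}

## continuous mediators carried by the generator's structural model
continuous_mediators <- function() {
  c("lis", "dis", "mds", "physical_activity", "bmi",
    "sf36_physical", "sf36_mental")
}

## per-trajectory mediator means emulating the published cohort gradients
default_mediator_means <- function() {
  m <- rbind(
    lis               = c(0.43, 0.68, 0.47, 0.63, 0.52, 0.63, 0.56, 0.71),
    dis               = c(-0.37, -0.01, 0.03, 0.20, -0.23, -0.18, -0.03, 0.20),
    mds               = c(4.5, 4.5, 4.3, 4.3, 4.5, 4.3, 4.5, 4.2),
    physical_activity = c(3.2, 3.9, 3.2, 3.4, 3.2, 3.7, 3.3, 3.8),
    bmi               = c(27.1, 28.6, 27.4, 28.8, 27.8, 28.7, 27.7, 29.2),
    sf36_physical     = c(48.5, 46.3, 47.6, 45.1, 47.7, 45.8, 47.3, 44.6),
    sf36_mental       = c(47.1, 47.1, 46.9, 47.3, 46.9, 47.6, 46.5, 46.5))
  colnames(m) <- trajectory_levels()
  t(m)
}

default_mediator_sds <- function() {
  c(lis = 0.75, dis = 2.1, mds = 1.6, physical_activity = 3.9,
    bmi = 4.7, sf36_physical = 5.5, sf36_mental = 9.1)
}

## years of delta-age per unit of mediator: calibrated once so that, with the
## default gradients, the downward and stably-low total effects and mediated
## shares resemble the published cohort (see the methods vignette)
default_outcome_loadings <- function() {
  c(lis = 0.5, dis = 0.09, mds = -0.12, physical_activity = 0,
    bmi = 0.07, sf36_physical = -0.045, sf36_mental = 0,
    smoking_current = 0, smoking_former = 0,
    drinking_heavy = 0, drinking_former = 0)
}

## unmediated (direct) delta-age shift per trajectory vs stable_high, years
default_direct_effects <- function() {
  stats::setNames(c(0, 0.45, 0.25, 0.83, 0.20, 0.40, 0.30, 0.20),
                  trajectory_levels())
}

## smoking status composition by trajectory (never / current / former)
default_smoking_probs <- function() {
  p <- rbind(
    never   = c(0.471, 0.429, 0.510, 0.506, 0.422, 0.484, 0.397, 0.575),
    current = c(0.273, 0.323, 0.232, 0.235, 0.347, 0.363, 0.298, 0.261),
    former  = c(0.256, 0.247, 0.258, 0.259, 0.230, 0.152, 0.305, 0.164))
  colnames(p) <- trajectory_levels()
  sweep(t(p), 1, rowSums(t(p)), "/")
}

## five-level drinking composition by trajectory
default_drinking_probs <- function() {
  p <- rbind(
    non_responder     = c(0.013, 0.025, 0.020, 0.043, 0.021, 0.041, 0.032, 0.080),
    former_drinker    = c(0.044, 0.061, 0.027, 0.045, 0.047, 0.073, 0.025, 0.055),
    lifetime_abstainer = c(0.327, 0.409, 0.359, 0.387, 0.268, 0.325, 0.386, 0.334),
    moderate          = c(0.543, 0.298, 0.483, 0.277, 0.545, 0.384, 0.351, 0.281),
    heavy             = c(0.073, 0.207, 0.110, 0.247, 0.120, 0.176, 0.206, 0.251))
  colnames(p) <- trajectory_levels()
  sweep(t(p), 1, rowSums(t(p)), "/")
}

#' Names of the 19 dietary inflammation score food groups
#'
#' Eighteen whole-food/beverage groups plus one composite supplement group.
#' @return Character vector of length 19.
#' @export
dis_food_groups <- function() {
  c("leafy_greens", "other_vegetables", "fruit", "legumes", "whole_grains",
    "refined_grains", "red_meat", "processed_meat", "poultry", "fish",
    "low_fat_dairy", "high_fat_dairy", "nuts_seeds", "olive_oil", "other_fats",
    "sweets", "sugar_beverages", "coffee_tea", "supplements")
}

#' Names of the 9 Mediterranean diet score components
#' @return Character vector of length 9.
#' @export
mds_components <- function() {
  c("vegetables", "legumes", "fruit_nuts", "cereals", "fish",
    "meat", "dairy", "alcohol_moderate", "fat_ratio")
}

#' Names of the 8 SF-36 health domains
#' @return Character vector, physical domains first.
#' @export
sf36_domains <- function() {
  c("physical_functioning", "role_physical", "bodily_pain", "general_health",
    "vitality", "social_functioning", "role_emotional", "mental_health")
}

## synthetic dietary-inflammation weights: signed, sum of squares ~ DIS SD^2,
## so that the standardized food-group panel reproduces the DIS gradient
default_dis_weights <- function() {
  sign <- c(-1, -1, -1, -1, -1, 1, 1, 1, -1, -1, -1, 1, -1, -1, 1, 1, 1, -1, -1)
  stats::setNames(sign * 0.48, dis_food_groups())
}

## synthetic lifestyle-inflammation weights (pro-inflammatory direction)
default_lis_weights <- function() {
  c(smoking_current = 0.47, physical_activity = -0.12,
    alcohol_heavy = 0.28, bmi = 0.30)
}

#' Reference blood-marker panel of the synthetic cohort
#'
#' Forty routine circulating markers (cell counts and biochemistry analogues)
#' with the synthetic generative parameters (location at the cohort mean age,
#' age slope per year of biological age, residual SD) and plausible QC ranges.
#' Four markers (`cholesterol`, `plateletcrit`, `hematocrit`,
#' `mean_corpuscular_hemoglobin`) are generated as near-linear combinations of
#' other panel members and form the default collinear drop list.
#'
#' @return A data.frame with columns `marker`, `location`, `age_slope`, `sd`,
#'   `qc_min`, `qc_max`, `collinear`.
#' @export
marker_panel <- function() {
  m <- read.csv(text = "marker,location,age_slope,sd,qc_min,qc_max
glucose,95,0.35,11,40,400
insulin,10,0.05,4,0.5,80
hdl_cholesterol,55,-0.10,12,10,150
ldl_cholesterol,125,0.45,28,20,350
triglycerides,120,0.70,45,20,800
creatinine,0.85,0.004,0.16,0.2,6
urea,36,0.25,9,5,150
uric_acid,5.0,0.015,1.2,1,15
alt,24,0.06,10,2,300
ast,23,0.05,8,2,300
ggt,26,0.12,14,2,500
alkaline_phosphatase,70,0.30,18,10,400
total_bilirubin,0.7,0.001,0.25,0.05,8
albumin,4.4,-0.010,0.32,2,6
total_protein,7.2,-0.006,0.45,4,10
c_reactive_protein,2.2,0.030,1.8,0.01,120
fibrinogen,320,1.20,60,80,900
wbc,6.4,0.010,1.6,1.5,30
rbc,4.8,-0.006,0.42,2,8
hemoglobin,14.1,-0.020,1.3,6,20
mcv,89,0.10,4.6,60,120
mchc,33.5,-0.012,1.1,28,40
rdw,13.4,0.022,1.0,10,25
platelets,250,-0.40,58,50,900
mpv,10.4,0.008,0.9,6,15
lymphocytes,2.1,-0.008,0.6,0.3,10
neutrophils,3.7,0.010,1.2,0.5,20
monocytes,0.50,0.002,0.15,0.05,3
eosinophils,0.20,0.0005,0.12,0,2
basophils,0.04,0.0001,0.025,0,0.5
sodium,141,0.005,2.2,120,160
potassium,4.3,0.003,0.36,2.5,7
calcium,9.5,-0.004,0.42,7,13
iron,95,-0.20,32,10,300
ferritin,110,0.80,75,2,1500
tsh,1.9,0.006,1.0,0.01,40
cholesterol,205,0,16,50,500
plateletcrit,0.26,0,0.018,0.05,1
hematocrit,42.7,0,1.2,18,65
mean_corpuscular_hemoglobin,29.4,0,0.9,20,40
", stringsAsFactors = FALSE)
  ## age slopes are calibrated jointly so the default panel carries enough
  ## aging signal for a held-out clock accuracy near the published operating
  ## point (MAE ~6 y, r ~0.76); per-marker slopes are still individually small
  m$age_slope <- m$age_slope * 1.8
  m$collinear <- m$marker %in% c("cholesterol", "plateletcrit", "hematocrit",
                                 "mean_corpuscular_hemoglobin")
  m
}

## per-variable MCAR missingness rates emulating the published item totals
default_missingness_rates <- function() {
  food <- stats::setNames(rep(0.052, 19), paste0("intake_", dis_food_groups()))
  sf36 <- stats::setNames(rep(0.219, 8), paste0("sf36_", sf36_domains()))
  markers <- stats::setNames(rep(0.01, 40), marker_panel()$marker)
  c(c(education_level = 0.0015, housing_tenure_adult = 0.0017,
      smoking = 0.002, bmi = 0.0013, physical_activity = 0.011,
      alcohol_g_day = 0.0042, cvd = 0.016, cancer = 0.006,
      diabetes = 0.014, hypertension = 0.009, hyperlipidemia = 0.011),
    food, sf36, markers)
}

#' Configuration for the synthetic cohort generator
#'
#' Bundles every knob of the generator: sample size, seed, trajectory
#' prevalences, demographic distributions, per-trajectory mediator means,
#' the linear structural model linking trajectory and mediators to the
#' delta-age signal, the blood-marker model, and item-level missingness.
#' Defaults emulate the published cohort: trajectory prevalences from the
#' 4772-participant trajectory table, chronological age 55.9 (SD 11.9) years
#' truncated to 35-100, 48.2% men, mediator gradients from the by-trajectory
#' characteristics table, and item missingness from the sample
#' characteristics table.
#'
#' @param n_participants Number of participants to generate.
#' @param seed Integer seed; the generator is a pure function of the config.
#' @param trajectory_probs Named vector of 8 probabilities summing to 1.
#' @param age_range Two-element vector, minimum and maximum age in years.
#' @param age_mean,age_sd Mean and SD of the (truncated) age distribution.
#' @param sex_fraction_male Proportion of men.
#' @param n_centers Number of recruitment centers.
#' @param direct_effects Named 8-vector: unmediated delta-age shift (years)
#'   per trajectory vs `stable_high`.
#' @param mediator_means 8 x 7 matrix of per-trajectory means for the
#'   continuous mediators (lis, dis, mds, physical_activity, bmi,
#'   sf36_physical, sf36_mental).
#' @param mediator_sds Named SDs of the continuous mediators.
#' @param outcome_loadings Named vector: years of delta-age per unit of each
#'   mediator (categorical mediators enter through level indicators such as
#'   `smoking_current`).
#' @param direct_effects_male Optional named 8-vector of male-specific direct
#'   effects; when supplied, men receive these and women `direct_effects`
#'   (sex effect modification). Default `NULL`: both sexes share
#'   `direct_effects`.
#' @param smoking_probs,drinking_probs Per-trajectory composition matrices.
#' @param interaction_effects Optional named vector of exposure-by-mediator
#'   interaction loadings (years per mediator unit, applied on top of
#'   `outcome_loadings` for all non-reference trajectories); default none.
#' @param delta_noise_sd Residual SD (years) of the delta-age signal.
#' @param marker_age_noise_inflation Multiplier on marker residual SDs.
#' @param dis_weights,lis_weights Synthetic inflammation weights used to build
#'   food-group gradients and inflammatory biomarkers.
#' @param inflammation_noise_sd Residual SD of each synthetic inflammatory
#'   biomarker around its lifestyle/diet-driven signal.
#' @param missingness_rates Named per-variable MCAR rates in [0, 1); use
#'   `missingness_rates = 0` for a complete-data cohort.
#' @param alcohol_nonresponse_prob Unused when `drinking_probs` is supplied in
#'   full; retained as a convenience override of the non-responder column.
#'
#' @return An object of class `cohort_config` (a validated list).
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_participants = 4772,
                          seed = 1L,
                          trajectory_probs = NULL,
                          age_range = c(35, 100),
                          age_mean = 55.9,
                          age_sd = 11.9,
                          sex_fraction_male = 0.482,
                          n_centers = 3L,
                          direct_effects = default_direct_effects(),
                          direct_effects_male = NULL,
                          mediator_means = default_mediator_means(),
                          mediator_sds = default_mediator_sds(),
                          outcome_loadings = default_outcome_loadings(),
                          smoking_probs = default_smoking_probs(),
                          drinking_probs = default_drinking_probs(),
                          interaction_effects = NULL,
                          delta_noise_sd = 7.4,
                          marker_age_noise_inflation = 1,
                          dis_weights = default_dis_weights(),
                          lis_weights = default_lis_weights(),
                          inflammation_noise_sd = 0.5,
                          missingness_rates = default_missingness_rates(),
                          alcohol_nonresponse_prob = NULL) {
  lv <- trajectory_levels()
  if (is.null(trajectory_probs)) {
    counts <- c(891, 198, 590, 703, 426, 289, 282, 1393)
    trajectory_probs <- stats::setNames(counts / sum(counts), lv)
  }
  if (length(n_participants) != 1 || is.na(n_participants) || n_participants < 1)
    stop_config("n_participants", "must be a positive count")
  n_participants <- as.integer(n_participants)
  if (length(trajectory_probs) != 8)
    stop_config("trajectory_probs", "must have 8 entries")
  if (is.null(names(trajectory_probs))) names(trajectory_probs) <- lv
  trajectory_probs <- trajectory_probs[lv]
  if (anyNA(trajectory_probs))
    stop_config("trajectory_probs", "must be named by the 8 trajectory labels")
  if (abs(sum(trajectory_probs) - 1) > 1e-9)
    stop_config("trajectory_probs", "must sum to 1 (tolerance 1e-9)")
  if (any(trajectory_probs < 0))
    stop_config("trajectory_probs", "must be nonnegative")
  if (age_sd <= 0) stop_config("age_sd", "must be positive")
  if (delta_noise_sd <= 0) stop_config("delta_noise_sd", "must be positive")
  if (any(mediator_sds <= 0)) stop_config("mediator_sds", "must all be positive")
  if (sex_fraction_male < 0 || sex_fraction_male > 1)
    stop_config("sex_fraction_male", "must be a proportion")
  if (!is.matrix(mediator_means) ||
      !identical(dim(mediator_means), c(8L, length(continuous_mediators()))))
    stop_config("mediator_means", "must be an 8 x 7 trajectory-by-mediator matrix")
  if (is.null(names(direct_effects))) names(direct_effects) <- lv
  direct_effects <- direct_effects[lv]
  if (anyNA(direct_effects))
    stop_config("direct_effects", "must be named by the 8 trajectory labels")
  if (!is.null(direct_effects_male)) {
    if (is.null(names(direct_effects_male))) names(direct_effects_male) <- lv
    direct_effects_male <- direct_effects_male[lv]
    if (anyNA(direct_effects_male))
      stop_config("direct_effects_male", "must be named by the 8 trajectory labels")
  }
  ol <- default_outcome_loadings()
  if (is.null(names(outcome_loadings)) && length(outcome_loadings) != length(ol))
    stop_config("outcome_loadings", "must be a named vector")
  if (is.null(names(outcome_loadings))) names(outcome_loadings) <- names(ol)
  bad_ol <- setdiff(names(outcome_loadings), names(ol))
  if (length(bad_ol))
    stop_config("outcome_loadings",
                paste("unknown mediator name(s):", paste(bad_ol, collapse = ", ")))
  ol[names(outcome_loadings)] <- outcome_loadings
  outcome_loadings <- ol
  if (length(missingness_rates) == 1 && missingness_rates == 0)
    missingness_rates <- stats::setNames(numeric(0), character(0))
  if (length(missingness_rates) &&
      (any(missingness_rates < 0) || any(missingness_rates >= 1)))
    stop_config("missingness_rates", "must lie in [0, 1)")
  if (!is.null(alcohol_nonresponse_prob)) {
    if (alcohol_nonresponse_prob < 0 || alcohol_nonresponse_prob >= 1)
      stop_config("alcohol_nonresponse_prob", "must lie in [0, 1)")
    drinking_probs[, "non_responder"] <- alcohol_nonresponse_prob
    drinking_probs <- sweep(drinking_probs, 1, rowSums(drinking_probs), "/")
  }
  if (!is.null(interaction_effects)) {
    bad_ie <- setdiff(names(interaction_effects), continuous_mediators())
    if (is.null(names(interaction_effects)) || length(bad_ie))
      stop_config("interaction_effects",
                  "must be named by continuous mediators (lis, dis, mds, ...)")
  }
  cfg <- list(
    n_participants = n_participants, seed = as.integer(seed),
    trajectory_probs = trajectory_probs, age_range = age_range,
    age_mean = age_mean, age_sd = age_sd,
    sex_fraction_male = sex_fraction_male, n_centers = as.integer(n_centers),
    direct_effects = direct_effects, direct_effects_male = direct_effects_male,
    mediator_means = mediator_means,
    mediator_sds = mediator_sds, outcome_loadings = outcome_loadings,
    smoking_probs = smoking_probs, drinking_probs = drinking_probs,
    interaction_effects = interaction_effects,
    delta_noise_sd = delta_noise_sd,
    marker_age_noise_inflation = marker_age_noise_inflation,
    dis_weights = dis_weights, lis_weights = lis_weights,
    inflammation_noise_sd = inflammation_noise_sd,
    missingness_rates = missingness_rates)
  class(cfg) <- "cohort_config"
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  participants: %d   seed: %d\n", x$n_participants, x$seed))
  cat(sprintf("  age: %.1f (SD %.1f), range %g-%g;  men: %.1f%%\n",
              x$age_mean, x$age_sd, x$age_range[1], x$age_range[2],
              100 * x$sex_fraction_male))
  cat("  trajectory prevalences:\n")
  print(round(x$trajectory_probs, 3))
  invisible(x)
}
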