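#' Mediterranean diet adherence score (0-9)
#'
#' One point per favorable component (healthy food groups at or above the
#' sex-specific sample median, detrimental groups below it, moderate alcohol,
#' favorable fat ratio), summed over the nine components.
#'
#' @param component_flags Logical vector of 9 component indicators, or a
#'   matrix/data.frame with 9 columns (one row per participant).
#' @return Integer score(s) in 0-9.
#' @examples
#' compute_mds(rep(TRUE, 9)) # 9
#' @export
compute_mds <- function(component_flags) {
  if (is.data.frame(component_flags)) component_flags <- as.matrix(component_flags)
  if (is.matrix(component_flags)) {
    if (ncol(component_flags) != 9)
      stop("the Mediterranean diet score has exactly 9 components, got ",
           ncol(component_flags), call. = FALSE)
    return(as.integer(rowSums(component_flags)))
  }
  if (length(component_flags) != 9)
    stop("the Mediterranean diet score has exactly 9 components, got ",
         length(component_flags), call. = FALSE)
  as.integer(sum(component_flags))
}

#' Derive inflammation weights from a biomarker panel
#'
#' Collapses a panel of circulating inflammatory biomarkers (e.g. hsCRP and
#' interleukins 6, 8, 10) into a single standardized composite (the unweighted
#' mean of biomarker z-scores) and regresses it jointly on all candidate
#' components, adjusted for any supplied covariates. The component
#' coefficients are the score weights.
#'
#' @param components data.frame/matrix of component values (rows =
#'   participants).
#' @param biomarkers data.frame/matrix with at least 2 biomarker columns on
#'   the same rows.
#' @param covariates Optional data.frame of adjustment covariates.
#' @return A `weight_table`: data.frame with `component`, `weight`, `se`,
#'   `provenance = "derived"`.
#' @export
derive_inflammation_weights <- function(components, biomarkers,
                                        covariates = NULL) {
  components <- as.data.frame(components)
  biomarkers <- as.data.frame(biomarkers)
  assert_that(nrow(components) == nrow(biomarkers),
              "components and biomarkers must cover the same rows")
  assert_that(ncol(biomarkers) >= 2,
              "the inflammation panel needs at least 2 biomarkers")
  composite <- rowMeans(scale(biomarkers))
  dat <- cbind(data.frame(.composite = composite), components)
  form <- stats::as.formula(paste(".composite ~",
                                  paste(names(components), collapse = " + ")))
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    dat <- cbind(dat, covariates)
    form <- stats::update(form, stats::as.formula(
      paste("~ . +", paste(names(covariates), collapse = " + "))))
  }
  fit <- stats::lm(form, data = dat)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("singular design; collinear column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  sm <- summary(fit)$coefficients
  keep <- intersect(rownames(sm), names(components))
  structure(data.frame(component = keep,
                       weight = unname(sm[keep, "Estimate"]),
                       se = unname(sm[keep, "Std. Error"]),
                       provenance = "derived",
                       stringsAsFactors = FALSE),
            class = c("weight_table", "data.frame"))
}

#' Assemble a weight table from user-supplied weights
#'
#' @param weights Named numeric vector of component weights (for example
#'   published dietary/lifestyle inflammation weights).
#' @param provenance Label recorded with the weights.
#' @return A `weight_table` data.frame.
#' @export
weight_table <- function(weights, provenance = "user_supplied") {
  assert_that(!is.null(names(weights)), "weights must be named by component")
  assert_that(all(is.finite(weights)), "weights must be finite")
  structure(data.frame(component = names(weights), weight = unname(weights),
                       se = NA_real_, provenance = provenance,
                       stringsAsFactors = FALSE),
            class = c("weight_table", "data.frame"))
}

weights_as_vector <- function(weights) {
  if (inherits(weights, "weight_table") || is.data.frame(weights))
    return(stats::setNames(weights$weight, weights$component))
  assert_that(!is.null(names(weights)), "weights must be named by component")
  weights
}

#' Dietary inflammation score
#'
#' Weighted sum of the 19 standardized food-group components.
#'
#' @param food_group_intakes Named vector of 19 component values, or a matrix/
#'   data.frame with 19 named columns (one row per participant).
#' @param weights A `weight_table` or named vector covering the 19 components.
#' @return Numeric score(s).
#' @export
compute_dis <- function(food_group_intakes, weights) {
  w <- weights_as_vector(weights)
  if (length(w) != 19)
    stop("the dietary inflammation score has exactly 19 components, got ",
         length(w), " weights", call. = FALSE)
  if (is.data.frame(food_group_intakes))
    food_group_intakes <- as.matrix(food_group_intakes)
  if (!is.matrix(food_group_intakes))
    food_group_intakes <- matrix(food_group_intakes, nrow = 1,
                                 dimnames = list(NULL, names(food_group_intakes)))
  cols <- colnames(food_group_intakes)
  if (is.null(cols)) stop("food-group components must be named", call. = FALSE)
  cols <- sub("^intake_", "", cols)
  unmatched <- c(setdiff(names(w), cols), setdiff(cols, names(w)))
  if (length(unmatched))
    stop("component/weight name mismatch: ",
         paste(unique(unmatched), collapse = ", "), call. = FALSE)
  colnames(food_group_intakes) <- cols
  drop(food_group_intakes[, names(w), drop = FALSE] %*% w)
}

#' Dichotomize alcohol intake for the lifestyle inflammation score
#'
#' Heavy consumption is more than one drink (14 g ethanol) per day for women
#' and more than two (28 g) for men; anything lower is moderate.
#'
#' @param grams_per_day Nonnegative ethanol intake.
#' @param sex `"male"` or `"female"`, vectorized.
#' @return `"heavy"` or `"moderate"`.
#' @export
classify_alcohol_lis <- function(grams_per_day, sex) {
  assert_that(all(grams_per_day >= 0, na.rm = TRUE),
              "alcohol intake cannot be negative")
  check_levels(sex, c("male", "female"), "sex")
  threshold <- ifelse(sex == "female", 14, 28)
  ifelse(is.na(grams_per_day), NA_character_,
         ifelse(grams_per_day > threshold, "heavy", "moderate"))
}

#' Lifestyle inflammation score
#'
#' Weighted sum of four components: smoking (current vs former/never),
#' leisure-time physical activity, alcohol intake (heavy vs moderate) and
#' BMI. Categorical components enter as indicators of the pro-inflammatory
#' level; continuous components are standardized before weighting, so a
#' participant at every reference level scores 0.
#'
#' @param smoking_lis `"current"` or `"former_never"` (3-level smoking status
#'   is also accepted and collapsed).
#' @param physical_activity MET-h/day; standardized internally unless
#'   `standardize = FALSE`.
#' @param alcohol_lis `"heavy"` or `"moderate"` (see [classify_alcohol_lis()]).
#' @param bmi kg/m2; standardized internally unless `standardize = FALSE`.
#' @param weights `weight_table` or named vector with components
#'   `smoking_current`, `physical_activity`, `alcohol_heavy`, `bmi`.
#' @param standardize Standardize the continuous components to sample z-scores
#'   (default). With `FALSE` they are used as given (useful when already
#'   centered).
#' @param activity_as_category If `TRUE`, physical activity enters as a
#'   sedentary indicator (below the sample median) rather than a continuous
#'   term.
#' @return Numeric score(s).
#' @export
compute_lis <- function(smoking_lis, physical_activity, alcohol_lis, bmi,
                        weights = NULL, standardize = TRUE,
                        activity_as_category = FALSE) {
  w <- weights_as_vector(weights %||% default_lis_weights())
  need <- c("smoking_current", "physical_activity", "alcohol_heavy", "bmi")
  if (!setequal(names(w), need))
    stop("the lifestyle inflammation score has exactly 4 components: ",
         paste(need, collapse = ", "), call. = FALSE)
  smoking_lis <- as.character(smoking_lis)
  smoking_lis[smoking_lis %in% c("never", "former")] <- "former_never"
  check_levels(smoking_lis, c("current", "former_never"), "LIS smoking status")
  check_levels(alcohol_lis, c("heavy", "moderate"), "LIS alcohol category")
  if (anyNA(smoking_lis) || anyNA(physical_activity) || anyNA(alcohol_lis) ||
      anyNA(bmi))
    stop("all four LIS components must be resolved (impute upstream)",
         call. = FALSE)
  zs <- function(x) if (standardize && stats::sd(x) > 0) (x - mean(x)) / stats::sd(x) else x
  pa <- if (activity_as_category)
    as.numeric(physical_activity < stats::median(physical_activity))
  else zs(physical_activity)
  unname(w["smoking_current"] * (smoking_lis == "current") +
           w["physical_activity"] * pa +
           w["alcohol_heavy"] * (alcohol_lis == "heavy") +
           w["bmi"] * zs(bmi))
}

#' Five-level drinking classification
#'
#' Non-response dominates; then lifetime abstainers and former drinkers by
#' history; current drinkers split at 48 g ethanol/day into moderate and
#' heavy.
#'
#' @param history `"lifetime_abstainer"`, `"former_drinker"` or `"current"`.
#' @param grams_per_day Daily ethanol intake for current drinkers.
#' @param responded Logical; `FALSE` marks alcohol non-response.
#' @return One of `"lifetime_abstainer"`, `"former_drinker"`, `"moderate"`,
#'   `"heavy"`, `"non_responder"`.
#' @export
classify_drinking5 <- function(history, grams_per_day, responded = TRUE) {
  n <- max(length(history), length(grams_per_day), length(responded))
  history <- rep_len(as.character(history), n)
  grams_per_day <- rep_len(grams_per_day, n)
  responded <- rep_len(responded, n)
  check_levels(history[responded],
               c("lifetime_abstainer", "former_drinker", "current"),
               "drinking history")
  bad <- responded & history == "lifetime_abstainer" &
    !is.na(grams_per_day) & grams_per_day > 0
  if (any(bad))
    stop("contradictory input: lifetime abstainer with positive alcohol intake",
         call. = FALSE)
  cur <- responded & history == "current"
  if (any(cur & (is.na(grams_per_day) | grams_per_day < 0)))
    stop("current drinkers need a nonnegative g/day intake", call. = FALSE)
  out <- character(n)
  out[!responded] <- "non_responder"
  out[responded & history != "current"] <- history[responded & history != "current"]
  out[cur] <- ifelse(grams_per_day[cur] > 48, "heavy", "moderate")
  out
}

#' SF-36 physical and mental global components
#'
#' Domain scores (0-100, higher = better health) are transformed to sample
#' z-scores, combined into two global scores through weighted means whose
#' weights are the loadings of the two leading principal components of the
#' 8-domain correlation matrix (sign-aligned so physical-domain loadings are
#' positive on the physical component), and finally standardized to sample
#' mean 50 and SD 10.
#'
#' @param domain_scores Matrix/data.frame with the 8 domain columns of
#'   [sf36_domains()] (rows = participants, at least 2).
#' @return A list with `scores` (data.frame `physical`, `mental`),
#'   `loadings` (8 x 2), and `explained_variance`.
#' @export
score_sf36 <- function(domain_scores) {
  domain_scores <- as.data.frame(domain_scores)
  doms <- sf36_domains()
  if (!all(doms %in% names(domain_scores))) {
    pref <- paste0("sf36_", doms)
    if (all(pref %in% names(domain_scores))) {
      domain_scores <- domain_scores[pref]
      names(domain_scores) <- doms
    } else {
      stop("need all 8 SF-36 domain columns: ", paste(doms, collapse = ", "),
           call. = FALSE)
    }
  }
  x <- as.matrix(domain_scores[doms])
  assert_that(nrow(x) >= 2, "need at least 2 participants to standardize")
  assert_that(!anyNA(x), "domain scores must be complete (impute upstream)")
  if (any(x < 0 | x > 100))
    stop("SF-36 domain scores must lie in [0, 100]", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance SF-36 domain(s): ",
         paste(doms[sds == 0], collapse = ", "), call. = FALSE)
  z <- scale(x)
  pca <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  load <- pca$rotation[, 1:2, drop = FALSE]
  phys_idx <- doms[1:4]
  ## the component loading more on the physical domains is the physical one
  phys_share <- colSums(abs(load[phys_idx, ])) / colSums(abs(load))
  ord <- order(phys_share, decreasing = TRUE)
  load <- load[, ord, drop = FALSE]
  colnames(load) <- c("physical", "mental")
  if (sum(load[phys_idx, "physical"]) < 0) load[, "physical"] <- -load[, "physical"]
  if (sum(load[doms[5:8], "mental"]) < 0) load[, "mental"] <- -load[, "mental"]
  global <- z %*% sweep(load, 2, colSums(abs(load)), "/")
  std <- function(g) 50 + 10 * (g - mean(g)) / stats::sd(g)
  list(scores = data.frame(physical = std(global[, "physical"]),
                           mental = std(global[, "mental"])),
       loadings = load,
       explained_variance = (pca$sdev^2 / sum(pca$sdev^2))[ord])
}

#' Simple item-mean fallback for an SF-36 domain score
#'
#' Averages a domain's items after rescaling each to 0-100. This is NOT the
#' instrument's standard scoring (which uses licensed item weights); it is a
#' clearly non-standard fallback for data delivered at item level. Prefer
#' properly scored domain scores whenever available.
#'
#' @param items Matrix/data.frame of one domain's items (rows = participants).
#' @param item_min,item_max The items' response scale bounds (recycled).
#' @return Numeric domain score in [0, 100] per participant.
#' @export
sf36_domain_from_items <- function(items, item_min = 1, item_max = 5) {
  items <- as.matrix(items)
  item_min <- rep_len(item_min, ncol(items))
  item_max <- rep_len(item_max, ncol(items))
  if (any(item_max <= item_min))
    stop("item_max must exceed item_min", call. = FALSE)
  scaled <- sweep(sweep(items, 2, item_min), 2, item_max - item_min, "/") * 100
  if (any(scaled < 0 | scaled > 100, na.rm = TRUE))
    stop("item responses outside their declared scale", call. = FALSE)
  rowMeans(scaled, na.rm = TRUE)
}

#' Compute the full mediator panel of a cohort table
#'
#' Appends/overwrites the candidate mediators: the Mediterranean diet score
#' from its 9 component flags, the dietary inflammation score from the 19
#' food-group components, the lifestyle inflammation score, the LIS smoking
#' and alcohol dichotomies, the 5-level drinking classification, and the
#' SF-36 physical/mental global components recomputed from the 8 domains.
#'
#' @param table Cohort data.frame (post-imputation).
#' @param dis_weights,lis_weights `weight_table`s or named vectors; defaults
#'   are the package's synthetic weights (provenance `"default"`), which real
#'   analyses should replace with published or freshly derived weights.
#' @param standardize_dis Standardize the food-group columns to sample
#'   z-scores before weighting (the synthetic generator's groups are already
#'   standardized, for which the default `FALSE` reproduces its score
#'   exactly).
#' @param overwrite If `FALSE` (default) mediator columns already present are
#'   kept as-is (synthetic cohorts carry the structural scores that generated
#'   the outcome); with `TRUE` every score is recomputed from its components.
#' @return The table with mediator columns `mds`, `dis`, `lis`,
#'   `smoking_lis`, `alcohol_lis`, `drinking5`, and recomputed SF-36 global
#'   components `sf36_physical_component`, `sf36_mental_component`.
#' @export
compute_mediator_panel <- function(table, dis_weights = NULL,
                                   lis_weights = NULL,
                                   standardize_dis = FALSE,
                                   overwrite = FALSE) {
  put <- function(tab, name, value) {
    if (overwrite || is.null(tab[[name]])) tab[[name]] <- value
    tab
  }
  dw <- weights_as_vector(dis_weights %||% default_dis_weights())
  flags <- table[paste0("mds_", mds_components())]
  table <- put(table, "mds", compute_mds(flags))
  intakes <- as.matrix(table[paste0("intake_", dis_food_groups())])
  if (standardize_dis) intakes <- scale(intakes)
  table <- put(table, "dis", compute_dis(intakes, dw))
  table$smoking_lis <- ifelse(table$smoking == "current", "current", "former_never")
  table$alcohol_lis <- classify_alcohol_lis(
    ifelse(is.na(table$alcohol_g_day), 0, table$alcohol_g_day), table$sex)
  table <- put(table, "drinking5", classify_drinking5(
    ifelse(is.na(table$drinker_history), "current", table$drinker_history),
    ifelse(is.na(table$alcohol_g_day), 0, table$alcohol_g_day),
    table$alcohol_responded))
  table <- put(table, "lis", compute_lis(
    table$smoking_lis, table$physical_activity, table$alcohol_lis, table$bmi,
    weights = lis_weights %||% default_lis_weights()))
  sf <- score_sf36(table[paste0("sf36_", sf36_domains())])
  table$sf36_physical_component <- sf$scores$physical
  table$sf36_mental_component <- sf$scores$mental
  table
}
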