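# shared fixtures built in code

## complete-data cohort with the default study conditions
complete_cohort <- function(n, seed) {
  generate_cohort(cohort_config(n_participants = n, seed = seed,
                                missingness_rates = 0))
}

## generator with no trajectory effects at all: flat mediator means, zero
## direct effects and zero outcome loadings
null_config <- function(n, seed, ...) {
  mm <- default_mediator_means()
  mm[] <- rep(colMeans(mm), each = 8)
  zero <- default_outcome_loadings(); zero[] <- 0
  cohort_config(n_participants = n, seed = seed,
                direct_effects = stats::setNames(rep(0, 8), trajectory_levels()),
                mediator_means = mm, outcome_loadings = zero,
                missingness_rates = 0, ...)
}

## single-pathway generator: one continuous mediator (lis) carries the whole
## indirect effect; known direct, indirect and proportion mediated
single_pathway_config <- function(n, seed, direct = 0.75, indirect = 0.25,
                                  contrast = "stable_low", theta = 1,
                                  delta_noise_sd = 7.4) {
  mm <- default_mediator_means()
  mm[] <- rep(colMeans(mm), each = 8)
  mm[contrast, "lis"] <- mm[contrast, "lis"] + indirect / theta
  zero <- default_outcome_loadings(); zero[] <- 0
  zero["lis"] <- theta
  de <- stats::setNames(rep(0, 8), trajectory_levels())
  de[contrast] <- direct
  cohort_config(n_participants = n, seed = seed, direct_effects = de,
                mediator_means = mm, outcome_loadings = zero,
                missingness_rates = 0, delta_noise_sd = delta_noise_sd)
}

## small mixed-type table with a few missing cells, for imputation tests
mixed_missing_table <- function(n = 40, seed = 1, na_cells = 5) {
  set.seed(seed)
  tab <- data.frame(participant_id = sprintf("x%02d", seq_len(n)),
                    a = rnorm(n), b = runif(n, 0, 10),
                    c = rnorm(n, 100, 20),
                    g = sample(c("u", "v", "w"), n, replace = TRUE),
                    stringsAsFactors = FALSE)
  for (col in sample(c("a", "b", "c", "g"), na_cells, replace = TRUE))
    tab[[col]][sample(n, 1)] <- NA
  tab
}

## brute-force Gower knn imputation oracle: full pairwise scan, same
## donor-selection and aggregation rules, distances recomputed from scratch
oracle_knn_impute <- function(tab, k, exclude = "participant_id") {
  vars <- setdiff(names(tab), exclude)
  num <- vars[vapply(tab[vars], is.numeric, logical(1))]
  cat <- setdiff(vars, num)
  rng <- vapply(tab[num], function(x) diff(range(x, na.rm = TRUE)), numeric(1))
  n <- nrow(tab)
  gower <- function(i, j) {
    num_d <- vapply(num, function(v) {
      xi <- tab[[v]][i]; xj <- tab[[v]][j]
      if (is.na(xi) || is.na(xj) || rng[v] == 0) NA_real_
      else abs(xi - xj) / rng[v]
    }, numeric(1))
    cat_d <- vapply(cat, function(v) {
      xi <- tab[[v]][i]; xj <- tab[[v]][j]
      if (is.na(xi) || is.na(xj)) NA_real_ else as.numeric(xi != xj)
    }, numeric(1))
    d <- c(num_d, cat_d)
    if (all(is.na(d))) Inf else mean(d, na.rm = TRUE)
  }
  out <- tab
  for (v in vars) {
    for (i in which(is.na(tab[[v]]))) {
      d <- vapply(seq_len(n), function(j) if (j == i) Inf else gower(i, j),
                  numeric(1))
      donors <- setdiff(order(d), which(is.na(tab[[v]]) | is.infinite(d)))
      donors <- donors[!is.na(tab[[v]][donors])][seq_len(k)]
      out[[v]][i] <- if (v %in% num) mean(tab[[v]][donors])
      else names(which.max(table(tab[[v]][donors])))
    }
  }
  out
}
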