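med_cohort <- function(n, seed, ...) {
  score_ses(generate_cohort(single_pathway_config(n, seed, ...))$table)
}

test_that("spec validation and mediator-name mapping", {
  s <- mediation_spec(mediators = "ALL")
  expect_length(s$mediators, 9)
  s2 <- mediation_spec(mediators = c("LIS", "bmi"))
  expect_equal(s2$mediators, c("lis", "bmi"))
  expect_error(mediation_spec(mediators = character(0)), "mediators")
  expect_error(mediation_spec(n_boot_main = 0), "n_boot_main")
})

test_that("additivity and product-difference equivalence hold per replicate", {
  tab <- med_cohort(1500, 201)
  spec <- mediation_spec(contrast = "stable_low", mediators = "lis",
                         n_boot_main = 60, seed = 17)
  res <- estimate_effects(tab, spec)
  reps <- res$replicates
  ## TE = PNDE + PNIE exactly, on the point estimate and every replicate
  expect_lt(abs(res$point$te - (res$point$pnde + res$point$pnie)), 1e-8)
  expect_true(all(abs(reps[, 1, "te"] -
                        (reps[, 1, "pnde"] + reps[, 1, "pnie"])) < 1e-8))
  ## product method == difference method in the linear no-interaction case
  expect_true(all(abs(reps[, 1, "te"] - reps[, 1, "te_diff"]) < 1e-8))
  expect_lt(abs(res$point$te - res$point$te_difference), 1e-8)
})

test_that("known generator coefficients are recovered (theta1 1.0, theta2 0.5, beta1 0.5)", {
  ## direct = 1.0; mediator shift 0.5 with loading 0.5 -> indirect 0.25
  tab <- med_cohort(5000, 211, direct = 1.0, indirect = 0.25, theta = 0.5)
  spec <- mediation_spec(contrast = "stable_low", mediators = "lis",
                         n_boot_main = 150, seed = 23)
  res <- estimate_effects(tab, spec)
  e <- res$estimates
  se_te <- stats::sd(res$replicates[, 1, "te"])
  se_nie <- stats::sd(res$replicates[, 1, "pnie"])
  expect_lt(abs(e$te - 1.25), 3 * se_te)
  expect_lt(abs(e$pnie - 0.25), 3 * se_nie)
  expect_true(e$te_lower <= e$te & e$te <= e$te_upper)
  expect_true(e$pnie_lower <= e$pnie & e$pnie <= e$pnie_upper)
})

test_that("no mediator-outcome path or no exposure-mediator path kills PNIE", {
  ## theta2 = 0: lis shifts with trajectory but does not load on the outcome
  mm <- default_mediator_means()
  mm[] <- rep(colMeans(mm), each = 8)
  mm["stable_low", "lis"] <- mm["stable_low", "lis"] + 0.5
  zero <- default_outcome_loadings(); zero[] <- 0
  de <- stats::setNames(rep(0, 8), trajectory_levels()); de["stable_low"] <- 1
  cfg <- cohort_config(n_participants = 3000, seed = 221, direct_effects = de,
                       mediator_means = mm, outcome_loadings = zero,
                       missingness_rates = 0)
  tab <- score_ses(generate_cohort(cfg)$table)
  res <- estimate_effects(tab, mediation_spec(contrast = "stable_low",
                                              mediators = "lis",
                                              n_boot_main = 80, seed = 3))
  expect_true(res$estimates$pnie_lower <= 0 & 0 <= res$estimates$pnie_upper)
  ## beta1 = 0: lis loads on the outcome but is flat across trajectories
  zero2 <- default_outcome_loadings(); zero2[] <- 0; zero2["lis"] <- 0.8
  cfg2 <- cohort_config(n_participants = 3000, seed = 231, direct_effects = de,
                        mediator_means = {
                          m2 <- default_mediator_means()
                          m2[] <- rep(colMeans(m2), each = 8); m2
                        },
                        outcome_loadings = zero2, missingness_rates = 0)
  tab2 <- score_ses(generate_cohort(cfg2)$table)
  res2 <- estimate_effects(tab2, mediation_spec(contrast = "stable_low",
                                                mediators = "lis",
                                                n_boot_main = 80, seed = 3))
  expect_true(res2$estimates$pnie_lower <= 0 & 0 <= res2$estimates$pnie_upper)
})

test_that("shifting the mediator-outcome loading moves PNIE by exactly c * beta1", {
  tab <- med_cohort(2000, 241, direct = 0.5, indirect = 0.4, theta = 1)
  spec <- mediation_spec(contrast = "stable_low", mediators = "lis",
                         n_boot_main = 1, seed = 5)
  base <- estimate_effects(tab, spec)$point
  ## rebuilding the outcome as delta + c * lis moves the fitted mediator
  ## loading by exactly c, hence PNIE by exactly c * beta1 (refit check)
  bt <- stats::coef(stats::lm(lis ~ trajectory + ca + sex + cvd + cancer +
                                diabetes + hypertension + hyperlipidemia,
                              data = tab))[["trajectorystable_low"]]
  tab3 <- tab
  tab3$delta_age <- tab$delta_age + 2 * tab$lis
  scaled <- estimate_effects(tab3, spec)$point
  expect_equal(scaled$pnie - base$pnie, 2 * bt, tolerance = 1e-8)
  expect_equal(scaled$pnde, base$pnde, tolerance = 1e-8)
})

test_that("categorical mediators go through the multinomial pathway", {
  ## smoking prevalence differs by trajectory and current smoking ages people
  sp <- default_smoking_probs()
  sp["stable_low", ] <- c(never = 0.30, current = 0.55, former = 0.15)
  zero <- default_outcome_loadings(); zero[] <- 0
  zero["smoking_current"] <- 1.5
  de <- stats::setNames(rep(0, 8), trajectory_levels()); de["stable_low"] <- 0.5
  mm <- default_mediator_means(); mm[] <- rep(colMeans(mm), each = 8)
  cfg <- cohort_config(n_participants = 4000, seed = 251, direct_effects = de,
                       mediator_means = mm, outcome_loadings = zero,
                       smoking_probs = sp, missingness_rates = 0)
  co <- generate_cohort(cfg)
  tab <- score_ses(co$table)
  res <- estimate_effects(tab, mediation_spec(contrast = "stable_low",
                                              mediators = "smoking",
                                              n_boot_main = 60, seed = 7))
  truth <- co$truth$indirect_contributions["stable_low", "smoking"]
  expect_gt(truth, 0.3)  # configured pathway is material
  se <- stats::sd(res$replicates[, 1, "pnie"])
  expect_lt(abs(res$estimates$pnie - truth), 3 * se)
  expect_lt(abs(res$point$te - (res$point$pnde + res$point$pnie)), 1e-8)
})

test_that("joint mediation decomposes TE via the difference method", {
  tab <- med_cohort(3000, 261, direct = 0.75, indirect = 0.25)
  res <- estimate_effects(tab, mediation_spec(
    contrast = "stable_low", mediators = "ALL", n_boot_main = 40, seed = 11))
  p <- res$point
  expect_lt(abs(p$te - (p$pnde + p$pnie)), 1e-8)
  expect_lt(abs(p$te - p$te_difference), 1e-12)
})

test_that("interaction pretest is calibrated under the null and powered under signal", {
  ## null calibration: the per-term false-positive rate stays near nominal
  hits <- vapply(1:20, function(r) {
    tab <- med_cohort(1200, 270 + r)
    pre <- pretest_interaction(tab, mediation_spec(
      contrast = "stable_low", mediators = "lis", n_boot_pretest = 40,
      seed = r))
    pre$p_values[["stable_low"]] <= 0.05
  }, logical(1))
  expect_lte(mean(hits), 0.05 + 3 * sqrt(0.05 * 0.95 / 20))
  ## strong exposure-by-mediator modification (0.5 y per mediator SD) is seen
  ## (outcome noise kept moderate so the n = 5000 power check is decisive)
  cfg <- single_pathway_config(5000, 281, direct = 0.75, indirect = 0.25,
                               delta_noise_sd = 3)
  cfg$interaction_effects <- c(lis = 0.5 / default_mediator_sds()[["lis"]])
  tabi <- score_ses(generate_cohort(cfg)$table)
  prei <- pretest_interaction(tabi, mediation_spec(
    contrast = "stable_low", mediators = "lis", n_boot_pretest = 60, seed = 37))
  expect_lt(prei$p_values[["stable_low"]], 0.05)
  expect_true(prei$interaction_assumed)
  tab <- med_cohort(400, 271)
  expect_error(pretest_interaction(tab, mediation_spec(
    contrast = "stable_low", mediators = "lis", n_boot_pretest = 1)),
    "fewer than 2")
  tabc <- tab; tabc$lis <- 1
  expect_error(pretest_interaction(tabc, mediation_spec(
    contrast = "stable_low", mediators = "lis", n_boot_pretest = 10)),
    "constant")
})

test_that("proportion mediated reports PNIE/TE with the ratio formula behind a flag", {
  tab <- med_cohort(3000, 291, direct = 0.75, indirect = 0.25)
  res <- estimate_effects(tab, mediation_spec(contrast = "stable_low",
                                              mediators = "lis",
                                              n_boot_main = 60, seed = 13))
  pm <- proportion_mediated(res)
  expect_equal(pm$pm_percent, 100 * res$point$pnie / res$point$te)
  expect_true(pm$pm_lower <= pm$pm_percent & pm$pm_percent <= pm$pm_upper)
  alt <- proportion_mediated(res, formula = "ratio_scale")
  expect_equal(alt$pm_percent,
               100 * res$point$pnde * (res$point$pnie - 1) / (res$point$te - 1))
})

test_that("the suite runs per contrast and mediator set, deterministically", {
  tab <- med_cohort(1200, 301)
  sets <- list("lis", "bmi", "ALL")
  suite <- run_mediation_suite(tab, c("education_and_material_downward",
                                      "stable_low"),
                               mediator_sets = sets, n_boot = 10, seed = 19)
  expect_equal(nrow(suite), 6)  # 3 sets x 2 contrasts
  expect_setequal(unique(suite$mediators), c("lis", "bmi", "ALL"))
  suite2 <- run_mediation_suite(tab, c("education_and_material_downward",
                                       "stable_low"),
                                mediator_sets = sets, n_boot = 10, seed = 19)
  expect_identical(suite, suite2)
  ## failures are reported per row while the suite continues
  tabc <- tab; tabc$bmi <- 1
  suite3 <- run_mediation_suite(tabc, "stable_low",
                                mediator_sets = list("lis", "bmi"),
                                n_boot = 5, seed = 19)
  expect_equal(suite3$error[1], "")
  expect_match(suite3$error[2], "singular|collinear")
})

test_that("degenerate resamples and absent contrast levels error clearly", {
  tab <- med_cohort(300, 311)
  expect_error(estimate_effects(tab[tab$trajectory != "stable_low", ],
                                mediation_spec(contrast = "stable_low",
                                               mediators = "lis",
                                               n_boot_main = 5)),
               "absent")
})
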