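test_that("MDS sums nine 0/1 components and moves by one per flip", {
  expect_equal(compute_mds(rep(TRUE, 9)), 9L)
  expect_equal(compute_mds(rep(FALSE, 9)), 0L)
  flags <- c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE)
  base <- compute_mds(flags)
  for (i in 1:9) {
    flipped <- flags; flipped[i] <- !flipped[i]
    expect_equal(abs(compute_mds(flipped) - base), 1L)
  }
  expect_error(compute_mds(rep(TRUE, 8)), "9 components")
  m <- matrix(TRUE, 3, 9)
  expect_equal(compute_mds(m), c(9L, 9L, 9L))
})

test_that("inflammation weight derivation recovers generating coefficients", {
  set.seed(100)
  n <- 5000
  X <- as.data.frame(matrix(rnorm(n * 4), n, 4,
                            dimnames = list(NULL, c("smk", "act", "alc", "adi"))))
  w <- c(smk = 0.5, act = -0.35, alc = 0.55, adi = 0)
  noise_sd <- 0.5
  signal <- as.matrix(X) %*% w
  bio <- sapply(1:4, function(i) signal + rnorm(n, 0, noise_sd))
  wt <- derive_inflammation_weights(X, bio)
  ## each biomarker z-score shrinks the slope by its marginal sd, known in
  ## closed form under the generating model
  shrink <- sqrt(sum(w^2) + noise_sd^2)
  for (i in seq_along(w)) {
    expect_lt(abs(wt$weight[wt$component == names(w)[i]] - w[i] / shrink),
              3 * wt$se[wt$component == names(w)[i]])
  }
  ## the null component's CI covers zero
  row <- wt[wt$component == "adi", ]
  expect_lt(abs(row$weight), 2.5 * row$se)
  ## permuting input column order permutes nothing per name
  wt2 <- derive_inflammation_weights(X[, c(3, 1, 4, 2)], bio)
  expect_equal(wt2$weight[match(wt$component, wt2$component)], wt$weight)
})

test_that("weight derivation rejects a singular design naming the culprit", {
  set.seed(2)
  X <- data.frame(a = rnorm(50))
  X$b <- 2 * X$a
  bio <- cbind(rnorm(50), rnorm(50))
  expect_error(derive_inflammation_weights(X, bio), "collinear.*b")
  expect_error(derive_inflammation_weights(X["a"], matrix(rnorm(50), 50, 1)),
               "at least 2")
})

test_that("DIS is the name-matched weighted sum of 19 components", {
  w <- default_dis_weights()
  x <- stats::setNames(rep(0, 19), dis_food_groups())
  expect_equal(compute_dis(x, w), 0)
  ## hand case verified against an independent dot product
  x[] <- rnorm(19)
  expect_equal(compute_dis(x, w), sum(w[names(x)] * x))
  ## homogeneity in the weights
  expect_equal(compute_dis(x, w * 2), 2 * compute_dis(x, w))
  ## additivity in the components
  y <- x; y[] <- rnorm(19)
  expect_equal(compute_dis(x + y, w), compute_dis(x, w) + compute_dis(y, w))
  names(x)[1] <- "pizza"
  expect_error(compute_dis(x, w), "mismatch.*pizza|pizza")
  expect_error(compute_dis(stats::setNames(rep(0, 4), letters[1:4]),
                           c(a = 1, b = 1, c = 1, d = 1)), "19 components")
})

test_that("LIS alcohol dichotomy uses sex-specific thresholds", {
  expect_equal(classify_alcohol_lis(20, "female"), "heavy")
  expect_equal(classify_alcohol_lis(20, "male"), "moderate")
  expect_equal(classify_alcohol_lis(0, "female"), "moderate")
  expect_equal(classify_alcohol_lis(0, "male"), "moderate")
  ## thresholds are strict
  expect_equal(classify_alcohol_lis(14, "female"), "moderate")
  expect_equal(classify_alcohol_lis(28, "male"), "moderate")
  expect_error(classify_alcohol_lis(-1, "male"), "negative")
})

test_that("LIS is the weighted sum of its four components", {
  w <- c(smoking_current = 0.47, physical_activity = -0.12,
         alcohol_heavy = 0.28, bmi = 0.30)
  ## all at reference with centered continuous terms: exactly zero
  expect_equal(compute_lis("former_never", 0, "moderate", 0, w,
                           standardize = FALSE), 0)
  ## one pro-inflammatory indicator contributes exactly its weight
  expect_equal(compute_lis("current", 0, "moderate", 0, w, standardize = FALSE),
               unname(w["smoking_current"]))
  ## hand-constructed case equals the independent weighted sum
  got <- compute_lis("current", 1.5, "heavy", -0.5, w, standardize = FALSE)
  expect_equal(got, unname(w["smoking_current"] + 1.5 * w["physical_activity"] +
                             w["alcohol_heavy"] - 0.5 * w["bmi"]))
  ## three-level smoking collapses to the LIS dichotomy
  expect_equal(compute_lis("never", 0, "moderate", 0, w, standardize = FALSE), 0)
  expect_error(compute_lis("current", NA, "moderate", 0, w), "resolved")
  ## optional sedentary dichotomy for activity
  v <- compute_lis(rep("former_never", 4), c(0, 1, 5, 9), rep("moderate", 4),
                   rep(0, 4), w, standardize = FALSE,
                   activity_as_category = TRUE)
  expect_equal(v, w[["physical_activity"]] * c(1, 1, 0, 0))
})

test_that("five-level drinking classification follows the stated precedence", {
  expect_equal(classify_drinking5("current", 50), "heavy")
  expect_equal(classify_drinking5("current", 30), "moderate")
  expect_equal(classify_drinking5("current", 48), "moderate")
  expect_equal(classify_drinking5("lifetime_abstainer", 0), "lifetime_abstainer")
  expect_equal(classify_drinking5("former_drinker", 0), "former_drinker")
  expect_equal(classify_drinking5("current", 10, responded = FALSE),
               "non_responder")
  expect_error(classify_drinking5("lifetime_abstainer", 5), "contradictory")
})

test_that("SF-36 global components standardize to mean 50, sd 10", {
  set.seed(7)
  dom <- matrix(runif(400 * 8, 0, 100), 400, 8,
                dimnames = list(NULL, sf36_domains()))
  sf <- score_sf36(dom)
  expect_equal(mean(sf$scores$physical), 50, tolerance = 1e-9)
  expect_equal(stats::sd(sf$scores$physical), 10, tolerance = 1e-9)
  expect_equal(mean(sf$scores$mental), 50, tolerance = 1e-9)
  expect_equal(stats::sd(sf$scores$mental), 10, tolerance = 1e-9)
})

test_that("SF-36 scoring validates its domain inputs", {
  dom <- matrix(runif(50 * 8, 0, 100), 50, 8,
                dimnames = list(NULL, sf36_domains()))
  bad <- dom; bad[1, 1] <- 101
  expect_error(score_sf36(bad), "\\[0, 100\\]")
  con <- dom; con[, 3] <- 50
  expect_error(score_sf36(con), "zero-variance")
  expect_error(score_sf36(dom[, 1:7]), "8")
})

test_that("raising a participant's physical domains raises their physical rank", {
  co <- complete_cohort(300, 65)
  dom <- co$table[paste0("sf36_", sf36_domains())]
  base <- score_sf36(dom)$scores$physical
  shifted <- dom
  i <- which.min(base)
  shifted[i, 1:4] <- pmin(100, shifted[i, 1:4] + 30)
  new <- score_sf36(shifted)$scores$physical
  expect_gt(rank(new)[i], rank(base)[i])
})

test_that("SF-36 components are invariant to common affine rescaling", {
  set.seed(8)
  dom <- matrix(runif(200 * 8, 10, 90), 200, 8,
                dimnames = list(NULL, sf36_domains()))
  a <- score_sf36(dom)$scores
  b <- score_sf36(dom * 0.5 + 25)$scores
  expect_equal(a$physical, b$physical, tolerance = 1e-8)
  expect_equal(a$mental, b$mental, tolerance = 1e-8)
})

test_that("the item-mean domain fallback rescales and averages", {
  items <- cbind(c(1, 5, 3), c(1, 5, 3), c(1, 5, 3))
  expect_equal(sf36_domain_from_items(items), c(0, 100, 50))
  ## mixed response scales per item
  items2 <- cbind(a = c(1, 3), b = c(0, 100))
  got <- sf36_domain_from_items(items2, item_min = c(1, 0),
                                item_max = c(3, 100))
  expect_equal(got, c(0, 100))
  expect_error(sf36_domain_from_items(cbind(c(0, 6))), "scale")
  expect_error(sf36_domain_from_items(items, item_min = 5, item_max = 5),
               "exceed")
})

test_that("the cohort-level mediator panel is complete and reproduces scores", {
  co <- complete_cohort(500, 75)
  tab <- compute_mediator_panel(co$table)
  ## structural scores are preserved (not clobbered) without overwrite
  expect_identical(tab$lis, co$table$lis)
  expect_identical(tab$dis, co$table$dis)
  ## the generator's dis is exactly the weighted sum of its food groups
  tab2 <- compute_mediator_panel(co$table, overwrite = TRUE)
  expect_equal(tab2$dis, co$table$dis, tolerance = 1e-10)
  expect_equal(tab2$mds, co$table$mds)
  expect_true(all(tab$smoking_lis %in% c("current", "former_never")))
  expect_equal(mean(tab$sf36_physical_component), 50, tolerance = 1e-9)
})
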