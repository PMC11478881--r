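test_that("QC drops the 4 collinear markers and blanks out-of-range values", {
  co <- complete_cohort(300, 5)
  tab <- co$table
  tab$glucose[1] <- 5000           # far above any plausible range
  tab$sodium[2] <- -10
  qc <- qc_markers(tab, clock_config())
  left <- intersect(marker_panel()$marker, names(qc))
  expect_length(left, 36)
  expect_false(any(c("cholesterol", "plateletcrit", "hematocrit",
                     "mean_corpuscular_hemoglobin") %in% names(qc)))
  expect_true(is.na(qc$glucose[1]))
  expect_true(is.na(qc$sodium[2]))
  rep <- attr(qc, "qc_report")
  expect_gte(rep$blanked["glucose"], 1)
  expect_setequal(rep$dropped, clock_config()$collinear_drop_list)
})

test_that("QC with an empty drop list and in-range values is the identity", {
  co <- complete_cohort(100, 6)
  cfg <- clock_config(collinear_drop_list = character(0),
                      marker_ranges = data.frame(marker = "glucose",
                                                 qc_min = -Inf, qc_max = Inf))
  qc <- qc_markers(co$table, cfg)
  attr(qc, "qc_report") <- NULL
  expect_identical(qc, co$table)
  expect_warning(qc_markers(co$table, clock_config(collinear_drop_list = "no_such")),
                 "absent")
})

test_that("knn imputation equals the exhaustive-search oracle on small tables", {
  for (seed in 1:3) {
    tab <- mixed_missing_table(n = 60, seed = seed, na_cells = 6)
    got <- impute_knn(tab, k = 10)
    want <- oracle_knn_impute(tab, k = 10)
    expect_equal(got, want, tolerance = 1e-12)
  }
  ## larger table, still exhaustive
  tab <- mixed_missing_table(n = 200, seed = 9, na_cells = 12)
  expect_equal(impute_knn(tab, k = 10), oracle_knn_impute(tab, k = 10),
               tolerance = 1e-12)
})

test_that("oracle Gower distances agree with an independent implementation", {
  skip_if_not_installed("cluster")
  tab <- mixed_missing_table(n = 25, seed = 7, na_cells = 3)
  tab$g <- factor(tab$g)
  d_ref <- as.matrix(cluster::daisy(tab[c("a", "b", "c", "g")],
                                    metric = "gower"))
  ## recompute with the brute-force oracle's pairwise rule
  num <- c("a", "b", "c")
  rng <- vapply(tab[num], function(x) diff(range(x, na.rm = TRUE)), numeric(1))
  for (i in 1:5) for (j in 6:10) {
    parts <- c(vapply(num, function(v) {
      if (is.na(tab[[v]][i]) || is.na(tab[[v]][j])) NA_real_
      else abs(tab[[v]][i] - tab[[v]][j]) / rng[v]
    }, numeric(1)),
    if (is.na(tab$g[i]) || is.na(tab$g[j])) NA_real_
    else as.numeric(tab$g[i] != tab$g[j]))
    expect_equal(unname(d_ref[i, j]), mean(parts, na.rm = TRUE),
                 tolerance = 1e-10)
  }
})

test_that("knn imputation contract: identity, donors, observed cells", {
  tab <- mixed_missing_table(n = 30, seed = 4, na_cells = 0)
  expect_identical(impute_knn(tab, k = 5), tab)
  tab2 <- mixed_missing_table(n = 12, seed = 4, na_cells = 3)
  expect_error(impute_knn(tab2, k = 12), "fewer than k")
  tab3 <- mixed_missing_table(n = 20, seed = 5, na_cells = 4)
  out <- impute_knn(tab3, k = 5)
  expect_false(anyNA(out[c("a", "b", "c", "g")]))
  obs <- !is.na(tab3$a)
  expect_identical(out$a[obs], tab3$a[obs])
  tab3$all_gone <- NA_real_
  expect_error(impute_knn(tab3, k = 5), "every row")
})

test_that("training is deterministic and splits by the configured fraction", {
  co <- complete_cohort(400, 15)
  tab <- score_ses(co$table)
  cfg <- clock_config(epochs = 8, seed = 42, hidden_layers = c(8, 4))
  qc <- impute_knn(qc_markers(tab, cfg),
                   exclude = c("participant_id", "delta_age", "trajectory_true"))
  m1 <- train_clock(qc, cfg)
  m2 <- train_clock(qc, cfg)
  expect_identical(predict(m1, qc), predict(m2, qc))
  expect_equal(sum(m1$split == "train"), floor(0.8 * 400))
  expect_equal(sum(m1$split == "test"), 400 - floor(0.8 * 400))
  ## training loss is recorded per epoch
  expect_length(m1$training_loss, 8)
})

test_that("delta age identity and split-pure metrics", {
  co <- complete_cohort(350, 25)
  cfg <- clock_config(epochs = 6, seed = 2, hidden_layers = c(8, 4))
  qc <- impute_knn(qc_markers(co$table, cfg),
                   exclude = c("participant_id", "delta_age", "trajectory_true"))
  m <- train_clock(qc, cfg)
  res <- compute_delta_age(m, qc)
  expect_equal(res$delta_age, res$ba - res$ca)
  ## metrics depend only on test rows: recompute from scratch
  ti <- res$split == "test"
  expect_equal(unname(attr(res, "metrics")["mae"]),
               mean(abs(res$ba[ti] - res$ca[ti])))
  ## shifting every CA by +c with predictions fixed shifts every delta by -c
  qc2 <- qc
  qc2$ca <- qc$ca + 3
  res2 <- compute_delta_age(m, qc2)
  expect_equal(res2$ba, res$ba)
  expect_equal(res2$delta_age, res$delta_age - 3)
  expect_error(compute_delta_age(list(), qc), "clock_model")
})

test_that("the clock beats the constant-mean baseline on age-informative markers", {
  co <- complete_cohort(1200, 35)
  cfg <- clock_config(epochs = 40, seed = 7, hidden_layers = c(32, 16))
  qc <- impute_knn(qc_markers(co$table, cfg),
                   exclude = c("participant_id", "delta_age", "trajectory_true"))
  m <- train_clock(qc, cfg)
  res <- compute_delta_age(m, qc)
  ti <- res$split == "test"
  baseline <- mean(abs(mean(qc$ca[!ti]) - qc$ca[ti]))
  expect_lt(attr(res, "metrics")["mae"], baseline)
})

test_that("test MAE does not degrade as marker noise shrinks", {
  maes <- vapply(c(2, 1, 0.4), function(infl) {
    co <- generate_cohort(cohort_config(n_participants = 900, seed = 55,
                                        missingness_rates = 0,
                                        marker_age_noise_inflation = infl))
    cfg <- clock_config(epochs = 30, seed = 3, hidden_layers = c(16, 8))
    qc <- impute_knn(qc_markers(co$table, cfg),
                     exclude = c("participant_id", "delta_age", "trajectory_true"))
    res <- compute_delta_age(train_clock(qc, cfg), qc)
    unname(attr(res, "metrics")["mae"])
  }, numeric(1))
  expect_true(maes[2] <= maes[1] + 0.3 && maes[3] <= maes[2] + 0.3)
  expect_lt(maes[3], maes[1])
})
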