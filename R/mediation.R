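#' Canonical mediator set of the trajectory-aging analysis
#'
#' @return Named character vector mapping mediator names to cohort columns;
#'   `smoking` and `drinking` are categorical, the rest continuous.
#' @export
mediator_columns <- function() {
  c(lis = "lis", dis = "dis", mds = "mds", smoking = "smoking",
    physical_activity = "physical_activity", drinking = "drinking5",
    bmi = "bmi", sf36_physical = "sf36_physical", sf36_mental = "sf36_mental")
}

categorical_mediators <- function() c(smoking = "smoking", drinking = "drinking5")

#' Specification of one counterfactual mediation analysis
#'
#' @param contrast Trajectory level(s) contrasted against `stable_high`;
#'   default: every non-reference level.
#' @param mediators Mediator set: names from [mediator_columns()], raw column
#'   names, or `"ALL"` for the joint analysis of all nine.
#' @param covariates Adjustment set; default the fully adjusted Model 2
#'   covariates (chronological age, sex and the five prevalent conditions).
#' @param n_boot_main Bootstrap resamples for effect CIs (default 1000).
#' @param n_boot_pretest Resamples for the exposure-mediator interaction
#'   pretest (default 100).
#' @param seed Integer seed for all resampling.
#' @param interaction_assumed Carry exposure-mediator interaction terms in the
#'   estimator (default `FALSE`, as adopted when the pretest finds none).
#' @param ci_level Confidence level of percentile intervals.
#' @return An object of class `mediation_spec`.
#' @export
mediation_spec <- function(contrast = NULL, mediators = "ALL",
                           covariates = c("ca", "sex", disease_flags()),
                           n_boot_main = 1000L, n_boot_pretest = 100L,
                           seed = 1L, interaction_assumed = FALSE,
                           ci_level = 0.95) {
  if (!length(mediators)) stop_config("mediators", "must be nonempty")
  if (n_boot_main < 1) stop_config("n_boot_main", "must be >= 1")
  if (n_boot_pretest < 1) stop_config("n_boot_pretest", "must be >= 1")
  cols <- mediator_columns()
  if (length(mediators) == 1 && toupper(mediators) == "ALL") {
    mediators <- unname(cols)
  } else {
    ml <- tolower(mediators)
    mediators <- unname(ifelse(ml %in% names(cols), cols[ml], mediators))
  }
  structure(list(contrast = contrast, mediators = mediators,
                 covariates = covariates,
                 n_boot_main = as.integer(n_boot_main),
                 n_boot_pretest = as.integer(n_boot_pretest),
                 seed = as.integer(seed),
                 interaction_assumed = interaction_assumed,
                 ci_level = ci_level),
            class = "mediation_spec")
}

## --- design construction -----------------------------------------------------

## complete-case analysis frame with trajectory factor and design pieces
mediation_frame <- function(table, spec) {
  need <- unique(c("delta_age", "trajectory", spec$covariates, spec$mediators))
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("table lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  dat <- table[stats::complete.cases(table[need]), need, drop = FALSE]
  dat$trajectory <- droplevels(factor(dat$trajectory, levels = trajectory_levels()))
  for (m in spec$mediators)
    if (!is.numeric(dat[[m]])) dat[[m]] <- factor(dat[[m]])
  dat
}

## covariate model matrix without intercept
covariate_matrix <- function(dat, covariates) {
  if (!length(covariates)) return(matrix(numeric(0), nrow(dat), 0))
  mm <- stats::model.matrix(stats::reformulate(covariates), data = dat)
  mm[, -1, drop = FALSE]
}

## exposure dummy matrix (reference = stable_high)
exposure_matrix <- function(trajectory) {
  lv <- levels(trajectory)
  sapply(lv[-1], function(l) as.numeric(trajectory == l))
}

## mediator columns as a numeric matrix; categorical mediators expand to
## level dummies against their first level
mediator_matrix <- function(dat, mediators) {
  blocks <- lapply(mediators, function(m) {
    x <- dat[[m]]
    if (is.numeric(x)) {
      out <- matrix(x, ncol = 1, dimnames = list(NULL, m))
    } else {
      lv <- levels(x)
      out <- sapply(lv[-1], function(l) as.numeric(x == l))
      colnames(out) <- paste0(m, ".", lv[-1])
    }
    out
  })
  do.call(cbind, blocks)
}

ols_coef <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  cf <- fit$coefficients
  if (anyNA(cf))
    stop("singular fit; collinear column(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  cf
}

## point estimator on one (re)sample, by row index
mediation_point <- function(dat, spec, idx = seq_len(nrow(dat))) {
  d <- dat[idx, , drop = FALSE]
  A <- exposure_matrix(d$trajectory)
  C <- covariate_matrix(d, spec$covariates)
  M <- mediator_matrix(d, spec$mediators)
  y <- d$delta_age
  one <- matrix(1, nrow(d), 1, dimnames = list(NULL, "(Intercept)"))
  contrasts <- spec$contrast %||% colnames(A)

  ## outcome model without mediators: difference-method total effect
  cf_no_m <- ols_coef(cbind(one, A, C), y)
  te_diff <- cf_no_m[contrasts]

  joint <- length(spec$mediators) > 1
  if (spec$interaction_assumed && joint)
    stop("exposure-mediator interaction is supported for single mediators only",
         call. = FALSE)
  if (spec$interaction_assumed &&
      !is.numeric(d[[spec$mediators]]))
    stop("exposure-mediator interaction is supported for continuous mediators only",
         call. = FALSE)

  if (joint) {
    cf_m <- ols_coef(cbind(one, A, M, C), y)
    pnde <- cf_m[contrasts]
    te <- te_diff
    pnie <- te - pnde
  } else {
    m <- spec$mediators
    if (spec$interaction_assumed) {
      AM <- A * d[[m]]
      colnames(AM) <- paste0(colnames(A), ":", m)
      cf_m <- ols_coef(cbind(one, A, M, AM, C), y)
      th2 <- cf_m[m]
      th4 <- cf_m[paste0(contrasts, ":", m)]
      bt <- ols_coef(cbind(one, A, C), d[[m]])
      ## E[M | A = ref, C_i] averaged over the empirical covariate distribution
      m_ref <- mean(cbind(one, A * 0, C) %*% bt)
      pnde <- cf_m[contrasts] + th4 * m_ref
      pnie <- th2 * bt[contrasts]
      te <- pnde + (th2 + th4) * bt[contrasts]
      ## under interaction TE = PNDE + TNIE; report PNIE as the indirect part
      pnie <- te - pnde
    } else if (is.numeric(d[[m]])) {
      cf_m <- ols_coef(cbind(one, A, M, C), y)
      th2 <- cf_m[m]
      bt <- ols_coef(cbind(one, A, C), d[[m]])
      pnde <- cf_m[contrasts]
      pnie <- th2 * bt[contrasts]
      te <- pnde + pnie
    } else {
      cf_m <- ols_coef(cbind(one, A, M, C), y)
      th2 <- cf_m[colnames(M)]
      lv <- levels(d[[m]])
      mdat <- cbind(as.data.frame(A), d[c(m, spec$covariates)])
      fit <- nnet::multinom(
        stats::reformulate(c(colnames(A), spec$covariates), response = m),
        data = mdat, trace = FALSE, maxit = 300)
      p_ref <- counterfactual_level_probs(fit, mdat, colnames(A), NULL, lv)
      pnde <- cf_m[contrasts]
      pnie <- vapply(contrasts, function(k) {
        p_k <- counterfactual_level_probs(fit, mdat, colnames(A), k, lv)
        sum(th2[paste0(m, ".", lv[-1])] * (p_k - p_ref))
      }, numeric(1))
      te <- pnde + pnie
    }
  }
  te <- unname(te); pnde <- unname(pnde); pnie <- unname(pnie)
  pm <- ifelse(te != 0, pnie / te, NA_real_)
  list(te = te, pnde = pnde, pnie = pnie, pm = pm,
       te_difference = unname(te_diff),
       coefficients = list(outcome = cf_m, no_mediator = cf_no_m))
}

## mean counterfactual probability of each non-reference mediator level with
## the exposure set to level k (all rows), covariates at empirical values
counterfactual_level_probs <- function(fit, mdat, exposure_cols, k, lv) {
  nd <- mdat
  nd[exposure_cols] <- 0
  if (!is.null(k)) nd[[k]] <- 1
  pr <- stats::predict(fit, newdata = nd, type = "probs")
  if (is.null(dim(pr))) pr <- cbind(1 - pr, pr)  # 2-level mediator
  colnames(pr) <- fit$lev
  colMeans(pr)[lv[-1]]
}

## --- public operations -------------------------------------------------------

#' Pretest for exposure-mediator interaction
#'
#' Fits the fully adjusted outcome model enriched with
#' trajectory-by-mediator interaction terms on bootstrap resamples and forms
#' a bootstrap-normal two-sided p-value per interaction coefficient from the
#' resample distribution. The no-interaction estimator is adopted when every
#' p-value exceeds 0.05.
#'
#' @param table Analysis data.frame (complete cases are used).
#' @param spec A [mediation_spec()] with a single continuous mediator.
#' @return List with `p_values` (per contrast), `interaction_assumed`
#'   (the resulting decision) and the resampled coefficients.
#' @export
pretest_interaction <- function(table, spec) {
  if (spec$n_boot_pretest < 2)
    stop("cannot form a bootstrap distribution from fewer than 2 resamples",
         call. = FALSE)
  if (length(spec$mediators) != 1)
    stop("pretest one mediator at a time", call. = FALSE)
  dat <- mediation_frame(table, spec)
  m <- spec$mediators
  if (!is.numeric(dat[[m]]))
    dat[[m]] <- as.numeric(dat[[m]] != levels(dat[[m]])[1])
  if (stats::sd(dat[[m]]) == 0)
    stop("mediator '", m, "' is constant", call. = FALSE)
  contrasts <- spec$contrast %||% levels(dat$trajectory)[-1]
  set.seed(spec$seed)
  draws <- matrix(NA_real_, spec$n_boot_pretest, length(contrasts),
                  dimnames = list(NULL, contrasts))
  for (b in seq_len(spec$n_boot_pretest)) {
    idx <- resample_with_levels(dat$trajectory, max_tries = 100)
    d <- dat[idx, , drop = FALSE]
    A <- exposure_matrix(d$trajectory)
    C <- covariate_matrix(d, spec$covariates)
    one <- matrix(1, nrow(d), 1)
    AM <- A * d[[m]]
    colnames(AM) <- paste0(colnames(A), ":", m)
    cf <- ols_coef(cbind(one, A, d[[m]], AM, C), d$delta_age)
    draws[b, ] <- cf[paste0(contrasts, ":", m)]
  }
  z <- colMeans(draws) / apply(draws, 2, stats::sd)
  p <- 2 * stats::pnorm(-abs(z))
  list(p_values = p, interaction_assumed = any(p <= 0.05), draws = draws)
}

## one resample preserving >= 2 rows of every trajectory level
resample_with_levels <- function(trajectory, max_tries = 100) {
  n <- length(trajectory)
  for (t in seq_len(max_tries)) {
    idx <- sample.int(n, replace = TRUE)
    if (all(table(trajectory[idx]) >= 2)) {
      attr(idx, "redraws") <- t - 1L
      return(idx)
    }
  }
  stop("could not draw a bootstrap resample with >= 2 rows per trajectory",
       call. = FALSE)
}

#' Counterfactual mediation effects with bootstrap inference
#'
#' Regression-based estimator of the total effect (TE), pure natural direct
#' effect (PNDE) and pure natural indirect effect (PNIE) of each trajectory
#' contrast on delta age, through a single mediator or the joint mediator
#' set. In the default no-interaction linear case: continuous mediator —
#' PNDE is the exposure coefficient of the mediator-adjusted outcome model,
#' PNIE the product of the mediator's outcome coefficient and the exposure
#' coefficient of the mediator model, TE their sum; categorical mediator —
#' the mediator model is multinomial logistic and PNIE averages the
#' counterfactual level-probability shifts over the empirical covariate
#' distribution; joint set — TE comes from the mediator-free outcome model,
#' PNDE from the fully mediator-adjusted one, and PNIE is their difference.
#' Percentile confidence intervals and p-values come from participant
#' bootstrap resamples (resamples leaving any trajectory level with fewer
#' than 2 rows are redrawn and counted).
#'
#' @param table Analysis data.frame.
#' @param spec A [mediation_spec()].
#' @return A `mediation_result`: `estimates` data.frame (one row per
#'   contrast), bootstrap `replicates`, and `diagnostics`.
#' @export
estimate_effects <- function(table, spec) {
  dat <- mediation_frame(table, spec)
  contrasts <- spec$contrast %||% levels(dat$trajectory)[-1]
  bad <- setdiff(contrasts, levels(dat$trajectory))
  if (length(bad))
    stop("contrast level(s) absent from data: ", paste(bad, collapse = ", "),
         call. = FALSE)
  spec$contrast <- contrasts
  point <- mediation_point(dat, spec)
  set.seed(spec$seed)
  B <- spec$n_boot_main
  reps <- array(NA_real_, c(B, length(contrasts), 5),
                dimnames = list(NULL, contrasts,
                                c("te", "pnde", "pnie", "pm", "te_diff")))
  redraws <- 0L
  for (b in seq_len(B)) {
    idx <- resample_with_levels(dat$trajectory)
    redraws <- redraws + attr(idx, "redraws")
    pb <- mediation_point(dat, spec, idx)
    reps[b, , ] <- cbind(pb$te, pb$pnde, pb$pnie, pb$pm, pb$te_difference)
  }
  est <- do.call(rbind, lapply(seq_along(contrasts), function(i) {
    ci <- apply(reps[, i, , drop = FALSE], 3, percentile_ci, level = spec$ci_level)
    data.frame(contrast = contrasts[i],
               mediators = paste(spec$mediators, collapse = "+"),
               te = point$te[i], te_lower = ci[1, "te"], te_upper = ci[2, "te"],
               pnde = point$pnde[i], pnde_lower = ci[1, "pnde"],
               pnde_upper = ci[2, "pnde"],
               pnie = point$pnie[i], pnie_lower = ci[1, "pnie"],
               pnie_upper = ci[2, "pnie"],
               pnie_p = boot_p_value(reps[, i, "pnie"]),
               pm_percent = 100 * point$pm[i],
               pm_lower = 100 * ci[1, "pm"], pm_upper = 100 * ci[2, "pm"],
               pm_p = boot_p_value(reps[, i, "pm"]),
               stringsAsFactors = FALSE)
  }))
  structure(list(estimates = est, replicates = reps, point = point,
                 spec = spec,
                 diagnostics = list(n = nrow(dat), n_boot = B,
                                    redraws = redraws, ci_level = spec$ci_level)),
            class = "mediation_result")
}

#' Proportion mediated
#'
#' Share of the total effect transmitted through the mediator(s). The primary
#' definition is the linear-scale ratio PNIE/TE (in percent); the ratio-scale
#' formula `direct x (indirect - 1) / (total - 1)` used for odds-ratio
#' effects is available for comparison.
#'
#' @param result A `mediation_result`.
#' @param formula `"linear"` (PNIE/TE, default) or `"ratio_scale"`.
#' @return data.frame with `pm_percent`, percentile CI and bootstrap p per
#'   contrast.
#' @export
proportion_mediated <- function(result, formula = c("linear", "ratio_scale")) {
  formula <- match.arg(formula)
  stopifnot(inherits(result, "mediation_result"))
  point <- result$point
  reps <- result$replicates
  lv <- dimnames(reps)[[2]]
  out <- lapply(seq_along(lv), function(i) {
    if (formula == "linear") {
      if (point$te[i] == 0)
        return(data.frame(contrast = lv[i], pm_percent = NA_real_,
                          pm_lower = NA_real_, pm_upper = NA_real_,
                          pm_p = NA_real_, note = "undefined: total effect is 0"))
      pmr <- reps[, i, "pm"]
      pt <- 100 * point$pm[i]
    } else {
      pmr <- reps[, i, "pnde"] * (reps[, i, "pnie"] - 1) / (reps[, i, "te"] - 1)
      pt <- point$pnde[i] * (point$pnie[i] - 1) / (point$te[i] - 1)
      pmr <- 100 * pmr
      pt <- 100 * pt
    }
    ci <- percentile_ci(if (formula == "linear") 100 * pmr else pmr,
                        result$diagnostics$ci_level)
    data.frame(contrast = lv[i], pm_percent = pt,
               pm_lower = ci[1], pm_upper = ci[2],
               pm_p = boot_p_value(if (formula == "linear") pmr else pmr),
               note = "", stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Run a suite of mediation analyses
#'
#' One [estimate_effects()] per (contrast, mediator set) pair, collected into
#' a machine-readable table shaped like a published mediation summary (TE,
#' PNDE, PNIE, percent mediated, CIs, p). Failing rows are reported and the
#' suite continues.
#'
#' @param table Analysis data.frame.
#' @param contrasts Trajectory levels to contrast against `stable_high`.
#' @param mediator_sets List of mediator sets (each a character vector or
#'   `"ALL"`); default: each of the nine single mediators, then `"ALL"`.
#' @param n_boot,seed,covariates Passed to [mediation_spec()].
#' @return data.frame with one row per (contrast, mediator set).
#' @export
run_mediation_suite <- function(table, contrasts,
                                mediator_sets = c(as.list(names(mediator_columns())),
                                                  list("ALL")),
                                n_boot = 1000L, seed = 1L,
                                covariates = c("ca", "sex", disease_flags())) {
  rows <- list()
  for (ms in mediator_sets) {
    label <- if (length(ms) == 1 && toupper(ms) == "ALL") "ALL"
    else paste(ms, collapse = "+")
    res <- tryCatch({
      spec <- mediation_spec(contrast = contrasts, mediators = ms,
                             covariates = covariates, n_boot_main = n_boot,
                             seed = seed)
      fit <- estimate_effects(table, spec)
      est <- fit$estimates
      est$mediators <- label
      est$error <- ""
      est
    }, error = function(e) {
      data.frame(contrast = contrasts, mediators = label, te = NA_real_,
                 te_lower = NA, te_upper = NA, pnde = NA, pnde_lower = NA,
                 pnde_upper = NA, pnie = NA, pnie_lower = NA, pnie_upper = NA,
                 pnie_p = NA, pm_percent = NA, pm_lower = NA, pm_upper = NA,
                 pm_p = NA, error = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
    rows[[length(rows) + 1]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.mediation_result <- function(x, digits = 2, ...) {
  cat(sprintf("Counterfactual mediation (%s; %d bootstraps, n = %d)\n",
              x$estimates$mediators[1], x$diagnostics$n_boot,
              x$diagnostics$n))
  e <- x$estimates
  df <- data.frame(contrast = e$contrast,
                   TE = sprintf("%.*f [%.*f; %.*f]", digits, e$te, digits,
                                e$te_lower, digits, e$te_upper),
                   PNDE = sprintf("%.*f [%.*f; %.*f]", digits, e$pnde, digits,
                                  e$pnde_lower, digits, e$pnde_upper),
                   PNIE = sprintf("%.*f [%.*f; %.*f]", digits, e$pnie, digits,
                                  e$pnie_lower, digits, e$pnie_upper),
                   PM = sprintf("%.1f%% (%.1f; %.1f) p=%.3g", e$pm_percent,
                                e$pm_lower, e$pm_upper, e$pm_p))
  print(df, row.names = FALSE)
  invisible(x)
}
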