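disease_flags <- function() c("cvd", "cancer", "diabetes", "hypertension", "hyperlipidemia")

## shared engine for the incrementally adjusted trajectory models
fit_trajectory_model <- function(table, covariates, model_tag,
                                 interaction = FALSE, outcome = "delta_age") {
  need <- c(outcome, "trajectory", covariates)
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("table lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  dat <- table[stats::complete.cases(table[need]), need, drop = FALSE]
  dat$trajectory <- factor(dat$trajectory, levels = trajectory_levels())
  present <- levels(droplevels(dat$trajectory))
  absent <- setdiff(trajectory_levels(), present)
  if (length(absent)) {
    warning("trajectory level(s) absent from data, dropped: ",
            paste(absent, collapse = ", "))
    dat$trajectory <- droplevels(dat$trajectory)
  }
  ## degenerate (constant) covariates cannot be estimated
  for (cv in intersect(covariates, disease_flags())) {
    if (length(unique(dat[[cv]])) < 2) {
      warning("covariate '", cv, "' is constant, dropped")
      covariates <- setdiff(covariates, cv)
    }
  }
  rhs <- c("trajectory", covariates)
  if (interaction) rhs <- c(rhs, "sex:trajectory")
  form <- stats::reformulate(rhs, response = outcome)
  fit <- stats::lm(form, data = dat)
  sm <- summary(fit)$coefficients
  ci <- stats::confint(fit)
  keep <- if (interaction) grep("^trajectory.*:sex|^sex.*:trajectory",
                                rownames(sm), value = TRUE)
  else grep("^trajectory[^:]*$", rownames(sm), value = TRUE)
  res <- data.frame(
    term = sub(":sex(male|female)$", "",
               sub("^sex(male|female):", "", sub("trajectory", "", keep))),
    beta = unname(sm[keep, "Estimate"]),
    ci_lower = unname(ci[keep, 1]), ci_upper = unname(ci[keep, 2]),
    se = unname(sm[keep, "Std. Error"]),
    p_value = unname(sm[keep, "Pr(>|t|)"]),
    model = model_tag, n = nrow(dat),
    stringsAsFactors = FALSE)
  names(res)[1] <- "trajectory"
  attr(res, "fit") <- fit
  class(res) <- c("assoc_result", "data.frame")
  res
}

#' Model 1: trajectory association adjusted for age and sex
#'
#' Ordinary least squares of delta age on the 8-level SES trajectory
#' (reference `stable_high`) with chronological age and sex as covariates
#' (`delta_age ~ trajectory + ca + sex`). Wald 95% confidence intervals and
#' two-sided p-values per non-reference trajectory.
#'
#' @param table data.frame with `delta_age`, `trajectory`, `ca`, `sex`
#'   complete (impute upstream).
#' @return An `assoc_result` data.frame, one row per non-reference trajectory.
#' @export
fit_model1 <- function(table) {
  fit_trajectory_model(table, c("ca", "sex"), "model1")
}

#' Model 2: additionally adjusted for prevalent health conditions
#'
#' Model 1 plus prevalent cardiovascular disease, cancer, diabetes,
#' hypertension and hyperlipidemia
#' (`delta_age ~ trajectory + ca + sex + cvd + cancer + diabetes +
#' hypertension + hyperlipidemia`).
#'
#' @inheritParams fit_model1
#' @return An `assoc_result` data.frame.
#' @export
fit_model2 <- function(table) {
  fit_trajectory_model(table, c("ca", "sex", disease_flags()), "model2")
}

#' Sex-by-trajectory interaction model
#'
#' Model 2 enriched with sex-by-trajectory interaction terms; returns the
#' interaction coefficients (the sex-specific deviation of each trajectory
#' contrast).
#'
#' @inheritParams fit_model1
#' @return An `assoc_result` data.frame of the interaction terms.
#' @export
fit_sex_interaction <- function(table) {
  if (length(unique(table$sex[!is.na(table$sex)])) < 2)
    stop("only one sex present; use fit_stratified() instead", call. = FALSE)
  fit_trajectory_model(table, c("ca", "sex", disease_flags()),
                       "interaction", interaction = TRUE)
}

#' Sex-stratified Model 2
#'
#' @inheritParams fit_model1
#' @param sex Stratum to analyze, `"male"` or `"female"`.
#' @return An `assoc_result` data.frame for the stratum.
#' @export
fit_stratified <- function(table, sex) {
  check_levels(sex, c("male", "female"), "sex")
  sub <- table[!is.na(table$sex) & table$sex == sex, , drop = FALSE]
  if (!nrow(sub)) stop("empty stratum: ", sex, call. = FALSE)
  fit_trajectory_model(sub, c("ca", disease_flags()),
                       paste0("stratified_", sex))
}

#' @export
print.assoc_result <- function(x, digits = 3, ...) {
  cat(sprintf("Trajectory-delta age association (%s, n = %d)\n",
              x$model[1], x$n[1]))
  df <- data.frame(trajectory = x$trajectory,
                   beta = round(x$beta, digits),
                   ci = sprintf("(%.*f to %.*f)", digits, x$ci_lower,
                                digits, x$ci_upper),
                   p = signif(x$p_value, 2))
  print(df, row.names = FALSE)
  invisible(x)
}
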