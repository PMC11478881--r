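#' Write / read a cohort table
#'
#' CSV by default; Parquet when the path ends in `.parquet` (requires the
#' arrow package).
#'
#' @param table Cohort data.frame.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path) {
  if (grepl("\\.parquet$", path)) {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop("the arrow package is needed for Parquet output", call. = FALSE)
    arrow::write_parquet(table, path)
  } else {
    utils::write.csv(table, path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (grepl("\\.parquet$", path)) {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop("the arrow package is needed for Parquet input", call. = FALSE)
    as.data.frame(arrow::read_parquet(path))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
}

#' Descriptive cohort report
#'
#' Per-variable mean/SD for numeric variables and category percentages for
#' categorical ones, overall and by trajectory, plus per-variable
#' missingness — the shape of a cohort characteristics table.
#'
#' @param table Scored cohort data.frame (a `trajectory` or `trajectory_true`
#'   column defines the strata).
#' @param variables Columns to describe; default: a standard panel of
#'   demographics, mediators and delta age present in the table.
#' @return List with `continuous` (variable, stratum, n, mean, sd),
#'   `categorical` (variable, stratum, level, n, percent) and `missingness`.
#' @export
describe_cohort <- function(table, variables = NULL) {
  strat_col <- if (!is.null(table$trajectory)) "trajectory" else "trajectory_true"
  if (is.null(table[[strat_col]]))
    stop("table carries no trajectory column; run score_ses() first",
         call. = FALSE)
  if (is.null(variables)) {
    std <- c("ca", "delta_age", "sex", "education_level", "bmi",
             "physical_activity", "smoking", "lis", "mds", "dis",
             "alcohol_g_day", "drinking5", "sf36_physical", "sf36_mental",
             disease_flags())
    variables <- intersect(std, names(table))
  }
  strata <- c(list(overall = rep(TRUE, nrow(table))),
              lapply(stats::setNames(trajectory_levels(), trajectory_levels()),
                     function(l) !is.na(table[[strat_col]]) & table[[strat_col]] == l))
  cont <- list(); catg <- list()
  for (v in variables) {
    x <- table[[v]]
    for (s in names(strata)) {
      xs <- x[strata[[s]]]
      if (is.numeric(x)) {
        cont[[length(cont) + 1]] <- data.frame(
          variable = v, stratum = s, n = sum(!is.na(xs)),
          mean = mean(xs, na.rm = TRUE), sd = stats::sd(xs, na.rm = TRUE),
          stringsAsFactors = FALSE)
      } else {
        xs <- xs[!is.na(xs)]
        if (!length(xs)) next
        tab <- table(xs)
        catg[[length(catg) + 1]] <- data.frame(
          variable = v, stratum = s, level = names(tab),
          n = as.integer(tab), percent = 100 * as.numeric(tab) / length(xs),
          stringsAsFactors = FALSE)
      }
    }
  }
  miss <- data.frame(variable = variables,
                     n_missing = vapply(table[variables],
                                        function(x) sum(is.na(x)), integer(1)),
                     percent_missing = 100 * vapply(table[variables],
                                                    function(x) mean(is.na(x)),
                                                    numeric(1)),
                     stringsAsFactors = FALSE)
  list(continuous = do.call(rbind, cont), categorical = do.call(rbind, catg),
       missingness = miss)
}

#' End-to-end pipeline configuration
#'
#' @param workdir Output directory for stage artifacts and the manifest.
#' @param seed Global seed; per-stage seeds are fanned out deterministically
#'   (stage index added to the global seed) so stages are independently
#'   reproducible.
#' @param cohort A [cohort_config()] (its seed is overridden by the fan-out)
#'   or `NULL` with `input` pointing at an existing cohort file.
#' @param input Optional path of a cohort table to load instead of simulating.
#' @param clock A [clock_config()].
#' @param stages Character vector of enabled stages, in the fixed order
#'   `simulate`, `impute`, `score_ses`, `fit_clock`, `compute_scores`,
#'   `associate`, `mediate`, `describe`.
#' @param mediation_contrasts Contrasts passed to the mediation stage.
#' @param mediation_sets Mediator sets for the mediation stage.
#' @param n_boot Bootstrap resamples in the mediation stage.
#' @return An object of class `run_config`.
#' @export
run_config <- function(workdir = tempfile("trajage_run_"), seed = 1L,
                       cohort = cohort_config(seed = seed),
                       input = NULL,
                       clock = clock_config(seed = seed),
                       stages = c("simulate", "impute", "score_ses",
                                  "fit_clock", "compute_scores", "associate",
                                  "mediate", "describe"),
                       mediation_contrasts = c("education_and_material_downward",
                                               "stable_low"),
                       mediation_sets = list("ALL"),
                       n_boot = 200L) {
  all_stages <- c("simulate", "impute", "score_ses", "fit_clock",
                  "compute_scores", "associate", "mediate", "describe")
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop_config("stages", paste("unknown:", paste(bad, collapse = ", ")))
  stages <- all_stages[all_stages %in% stages]
  if (!"simulate" %in% stages && is.null(input))
    stop_config("input", "required when the simulate stage is disabled")
  structure(list(workdir = workdir, seed = as.integer(seed), cohort = cohort,
                 input = input, clock = clock, stages = stages,
                 mediation_contrasts = mediation_contrasts,
                 mediation_sets = mediation_sets, n_boot = as.integer(n_boot)),
            class = "run_config")
}

stage_seed <- function(config, stage) {
  (config$seed + 1000L * match(stage, c("simulate", "impute", "score_ses",
                                        "fit_clock", "compute_scores",
                                        "associate", "mediate", "describe"))) %%
    .Machine$integer.max
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in their fixed order — simulate (or load) the
#' cohort, impute missing items, score SES trajectories, fit the aging clock
#' and compute delta age, compute the mediator panel, fit the incrementally
#' adjusted association models, run the mediation suite, and write the
#' descriptive report — saving each stage's artifact under `workdir` and
#' returning a manifest with content hashes, seeds and row counts. Rerunning
#' an identical configuration reproduces identical outputs.
#'
#' @param config A [run_config()].
#' @return The manifest (list), invisibly; also written as
#'   `manifest.json` in `workdir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$workdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("trajage")),
                   seed = config$seed, stages = config$stages, files = list())
  log_stage <- function(name, msg) message(sprintf("[%s] %s", name, msg))
  save_artifact <- function(obj, file, stage) {
    path <- file.path(config$workdir, file)
    if (is.data.frame(obj)) write_cohort(obj, path)
    else jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, force = TRUE)
    manifest$files[[file]] <<- list(stage = stage,
                                    md5 = unname(tools::md5sum(path)),
                                    rows = if (is.data.frame(obj)) nrow(obj))
    path
  }
  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  ## pre-execution validation of the stage DAG against available inputs
  if (!"fit_clock" %in% config$stages && "associate" %in% config$stages &&
      "simulate" %in% config$stages == FALSE) {
    probe <- read_cohort(config$input)
    if (is.null(probe$delta_age))
      stop("validation: clock stage disabled but the input has no delta_age column",
           call. = FALSE)
  }

  tab <- NULL; truth <- NULL
  if ("simulate" %in% config$stages) {
    run_stage("simulate", function() {
      cfg <- config$cohort
      cfg$seed <- stage_seed(config, "simulate")
      cohort <- generate_cohort(cfg)
      tab <<- cohort$table
      truth <<- cohort$truth
      save_artifact(tab, "cohort.csv", "simulate")
      save_artifact(list(direct_effect = as.list(truth$direct_effect),
                         total_effect = as.list(truth$total_effect),
                         proportion_mediated = as.list(truth$proportion_mediated)),
                    "ground_truth.json", "simulate")
      log_stage("simulate", sprintf("%d participants", nrow(tab)))
    })
  } else {
    tab <- read_cohort(config$input)
    log_stage("load", sprintf("%d rows from %s", nrow(tab), config$input))
  }

  if ("impute" %in% config$stages) {
    run_stage("impute", function() {
      tab <<- impute_knn(tab, k = config$clock$knn_k,
                         exclude = c("participant_id", "delta_age",
                                     "trajectory_true"))
      save_artifact(tab, "cohort_imputed.csv", "impute")
      log_stage("impute", "knn imputation complete")
    })
  }

  if ("score_ses" %in% config$stages) {
    run_stage("score_ses", function() {
      tab <<- score_ses(tab)
      save_artifact(tab, "cohort_scored.csv", "score_ses")
      log_stage("score_ses", sprintf("%d trajectories assigned",
                                     sum(!is.na(tab$trajectory))))
    })
  }

  clock_metrics <- NULL
  if ("fit_clock" %in% config$stages) {
    run_stage("fit_clock", function() {
      ccfg <- config$clock
      ccfg$seed <- stage_seed(config, "fit_clock")
      qc <- qc_markers(tab, ccfg)
      if (anyNA(qc[intersect(marker_panel()$marker, names(qc))]))
        qc <- impute_knn(qc, k = ccfg$knn_k,
                         exclude = c("participant_id", "delta_age",
                                     "trajectory_true"))
      model <- train_clock(qc, ccfg)
      res <- compute_delta_age(model, qc)
      tab$ba <<- res$ba
      tab$delta_age <<- res$delta_age
      tab$split <<- res$split
      clock_metrics <<- as.list(attr(res, "metrics"))
      save_artifact(tab, "cohort_with_delta.csv", "fit_clock")
      save_artifact(clock_metrics, "clock_metrics.json", "fit_clock")
      log_stage("fit_clock", sprintf("test MAE %.2f y", clock_metrics$mae))
    })
  } else if (is.null(tab$delta_age)) {
    stop("validation: clock stage disabled but the cohort has no delta_age column",
         call. = FALSE)
  }

  if ("compute_scores" %in% config$stages) {
    run_stage("compute_scores", function() {
      tab <<- compute_mediator_panel(tab)
      save_artifact(tab, "cohort_mediators.csv", "compute_scores")
      log_stage("compute_scores", "mediator panel complete")
    })
  }

  if ("associate" %in% config$stages) {
    run_stage("associate", function() {
      m1 <- fit_model1(tab)
      m2 <- fit_model2(tab)
      save_artifact(rbind(as.data.frame(m1), as.data.frame(m2)),
                    "associations.csv", "associate")
      log_stage("associate", sprintf("%d contrasts per model", nrow(m2)))
    })
  }

  if ("mediate" %in% config$stages) {
    run_stage("mediate", function() {
      suite <- run_mediation_suite(tab, config$mediation_contrasts,
                                   config$mediation_sets,
                                   n_boot = config$n_boot,
                                   seed = stage_seed(config, "mediate"))
      save_artifact(suite, "mediation.csv", "mediate")
      log_stage("mediate", sprintf("%d result rows", nrow(suite)))
    })
  }

  if ("describe" %in% config$stages) {
    run_stage("describe", function() {
      rep <- describe_cohort(tab)
      save_artifact(rep$continuous, "describe_continuous.csv", "describe")
      save_artifact(rep$categorical, "describe_categorical.csv", "describe")
      save_artifact(rep$missingness, "describe_missingness.csv", "describe")
      log_stage("describe", "descriptive report written")
    })
  }

  manifest$n_rows <- nrow(tab)
  manifest$clock_metrics <- clock_metrics
  mpath <- file.path(config$workdir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(manifest)
}
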