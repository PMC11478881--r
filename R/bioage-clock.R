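## feature construction shared by training and prediction: standardized
## markers plus one-hot sex and recruitment center
clock_features <- function(table, marker_cols, center_stats = NULL) {
  X <- as.matrix(table[marker_cols])
  if (anyNA(X))
    stop("marker columns contain missing values; run impute_knn() first",
         call. = FALSE)
  sex_m <- matrix(as.numeric(table$sex == "male"), ncol = 1,
                  dimnames = list(NULL, "sex_male"))
  centers <- if (is.null(center_stats)) sort(unique(table$center))
  else center_stats$centers
  cen_m <- sapply(centers, function(l) as.numeric(table$center == l))
  if (is.null(dim(cen_m))) cen_m <- matrix(cen_m, ncol = length(centers))
  colnames(cen_m) <- paste0("center_", centers)
  X <- cbind(X, sex_m, cen_m)
  if (is.null(center_stats)) {
    mu <- colMeans(X)
    sdv <- apply(X, 2, stats::sd)
    sdv[sdv == 0] <- 1
    center_stats <- list(mean = mu, sd = sdv, centers = centers,
                         marker_cols = marker_cols)
  }
  Xs <- sweep(sweep(X, 2, center_stats$mean), 2, center_stats$sd, "/")
  if (any(!is.finite(Xs)))
    stop("non-finite features after standardization", call. = FALSE)
  list(X = Xs, stats = center_stats)
}

#' Train the blood-marker biological age clock
#'
#' Fits a feed-forward neural network regressing chronological age on the
#' QC'd, imputed circulating markers plus one-hot sex and recruitment center,
#' by minibatch Adam on mean squared error. The sample is split once into a
#' seeded random training fraction and a held-out remainder; standardization
#' statistics (features and the age label) come from the training split only.
#'
#' @param table QC'd, imputed cohort data.frame with `ca`, `sex`, `center`
#'   and marker columns.
#' @param config A [clock_config()].
#' @param marker_cols Marker column names; defaults to every non-collinear
#'   panel marker present in the table.
#' @return An object of class `clock_model` carrying the network weights,
#'   standardization statistics, split assignment and per-epoch losses.
#' @export
train_clock <- function(table, config = clock_config(), marker_cols = NULL) {
  if (is.null(marker_cols))
    marker_cols <- intersect(marker_panel()$marker, names(table))
  assert_that(length(marker_cols) > 0, "no marker columns found")
  assert_that(!anyNA(table$ca), "chronological age must be present for all rows")
  set.seed(config$seed)
  n <- nrow(table)
  n_train <- floor(config$train_fraction * n)
  train_idx <- sort(sample.int(n, n_train))
  split <- rep("test", n)
  split[train_idx] <- "train"

  ## optional early stopping monitors a validation carve-out of the training
  ## split (last 10% of the shuffled training rows), never the test split
  fit_idx <- train_idx
  valid <- NULL
  if (!is.null(config$early_stopping_patience)) {
    n_val <- max(1L, floor(0.1 * length(train_idx)))
    val_idx <- sample(train_idx, n_val)
    fit_idx <- setdiff(train_idx, val_idx)
  }
  feats <- clock_features(table[fit_idx, , drop = FALSE], marker_cols)
  y_mu <- mean(table$ca[fit_idx])
  y_sd <- stats::sd(table$ca[fit_idx])
  y <- (table$ca[fit_idx] - y_mu) / y_sd

  if (!is.null(config$early_stopping_patience)) {
    Xv <- clock_features(table[val_idx, , drop = FALSE], marker_cols,
                         feats$stats)$X
    valid <- list(X = Xv, y = (table$ca[val_idx] - y_mu) / y_sd)
  }
  fit <- mlp_train(feats$X, y, config$hidden_layers, config$epochs,
                   config$batch_size, config$learning_rate,
                   X_valid = valid$X, y_valid = valid$y,
                   patience = config$early_stopping_patience)
  structure(list(params = fit$params, feature_stats = feats$stats,
                 y_mean = y_mu, y_sd = y_sd, split = split,
                 marker_cols = marker_cols, config = config,
                 training_loss = fit$training_loss * y_sd^2,
                 validation_loss = fit$validation_loss * y_sd^2,
                 n = n), class = "clock_model")
}

#' Predict biological age
#'
#' @param object A trained [train_clock()] model.
#' @param newdata Cohort data.frame with the model's feature columns.
#' @param ... Unused.
#' @return Numeric vector of biological ages (years).
#' @export
predict.clock_model <- function(object, newdata, ...) {
  feats <- clock_features(newdata, object$marker_cols, object$feature_stats)
  mlp_predict(object$params, feats$X) * object$y_sd + object$y_mean
}

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf("Biological age clock: %d features -> [%s] -> 1, %d epochs\n",
              length(x$feature_stats$mean),
              paste(x$config$hidden_layers, collapse = ", "),
              length(x$training_loss)))
  cat(sprintf("  final training MSE: %.2f years^2\n",
              x$training_loss[length(x$training_loss)]))
  invisible(x)
}

#' Biological age, delta age and clock accuracy
#'
#' Applies a trained clock to a cohort, computing biological age (BA), the
#' aging gap delta age = BA - CA (positive values indicate accelerated,
#' unhealthy aging), and accuracy metrics (mean absolute error, Pearson r,
#' R-squared between BA and CA) on the held-out test split only.
#'
#' @param model A `clock_model`.
#' @param table The cohort the model was trained on (same rows), or any table
#'   with the feature columns plus `ca` — in that case all rows are treated
#'   as test rows unless `split` is supplied.
#' @param split Optional `"train"`/`"test"` assignment per row; defaults to
#'   the model's own split when row counts match.
#' @return A `bioage_result`: data.frame with `participant_id` (if present),
#'   `ba`, `ca`, `delta_age`, `split`; attribute `"metrics"` holds the
#'   test-split MAE, r and R2.
#' @export
compute_delta_age <- function(model, table, split = NULL) {
  if (!inherits(model, "clock_model"))
    stop("model must be a trained clock_model", call. = FALSE)
  ba <- predict(model, table)
  if (is.null(split)) {
    split <- if (nrow(table) == model$n) model$split else rep("test", nrow(table))
  }
  res <- data.frame(ba = ba, ca = table$ca, delta_age = ba - table$ca,
                    split = split, stringsAsFactors = FALSE)
  if (!is.null(table$participant_id))
    res <- cbind(data.frame(participant_id = table$participant_id,
                            stringsAsFactors = FALSE), res)
  ti <- split == "test"
  metrics <- c(mae = mean(abs(res$ba[ti] - res$ca[ti])),
               r = stats::cor(res$ba[ti], res$ca[ti]),
               r2 = 1 - sum((res$ca[ti] - res$ba[ti])^2) /
                 sum((res$ca[ti] - mean(res$ca[ti]))^2))
  attr(res, "metrics") <- metrics
  class(res) <- c("bioage_result", "data.frame")
  res
}

#' @export
print.bioage_result <- function(x, ...) {
  m <- attr(x, "metrics")
  cat(sprintf("Biological age for %d participants (%d test rows)\n",
              nrow(x), sum(x$split == "test")))
  cat(sprintf("  test accuracy: MAE %.2f y, r %.3f, R2 %.3f\n",
              m["mae"], m["r"], m["r2"]))
  cat(sprintf("  mean delta age: %.2f y\n", mean(x$delta_age)))
  invisible(x)
}
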