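#' Configuration for the biological age clock
#'
#' @param epochs Training epochs (default 1000).
#' @param batch_size Minibatch size (default 32).
#' @param train_fraction Fraction of rows in the training split (default 0.8).
#' @param knn_k Neighbours for imputation (default 10).
#' @param seed Integer seed controlling the split, weight initialization and
#'   minibatch order.
#' @param hidden_layers Hidden-layer widths of the feed-forward network.
#' @param learning_rate Adam step size.
#' @param marker_ranges data.frame with `marker`, `qc_min`, `qc_max`; defaults
#'   to the plausible ranges of [marker_panel()]. Review for real data.
#' @param collinear_drop_list Marker columns removed before training.
#' @param early_stopping_patience Optional epochs without held-out improvement
#'   before stopping; `NULL` (default) trains the full schedule.
#' @return An object of class `clock_config`.
#' @export
clock_config <- function(epochs = 1000L, batch_size = 32L,
                         train_fraction = 0.8, knn_k = 10L, seed = 1L,
                         hidden_layers = c(64L, 32L, 16L),
                         learning_rate = 1e-3,
                         marker_ranges = marker_panel()[, c("marker", "qc_min", "qc_max")],
                         collinear_drop_list = c("cholesterol", "plateletcrit",
                                                 "hematocrit",
                                                 "mean_corpuscular_hemoglobin"),
                         early_stopping_patience = NULL) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop_config("train_fraction", "must lie strictly between 0 and 1")
  if (epochs < 1) stop_config("epochs", "must be >= 1")
  if (batch_size < 1) stop_config("batch_size", "must be >= 1")
  if (knn_k < 1) stop_config("knn_k", "must be >= 1")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 train_fraction = train_fraction, knn_k = as.integer(knn_k),
                 seed = as.integer(seed), hidden_layers = as.integer(hidden_layers),
                 learning_rate = learning_rate, marker_ranges = marker_ranges,
                 collinear_drop_list = collinear_drop_list,
                 early_stopping_patience = early_stopping_patience),
            class = "clock_config")
}

#' Quality-control blood markers
#'
#' Blanks out-of-range marker values (they are later imputed, not row-dropped)
#' and removes the collinear marker columns.
#'
#' @param table Cohort data.frame containing marker columns.
#' @param config A [clock_config()].
#' @return The QC'd table; attribute `"qc_report"` holds per-marker blanked
#'   counts and the dropped columns.
#' @export
qc_markers <- function(table, config = clock_config()) {
  rng <- config$marker_ranges
  blanked <- integer(0)
  for (i in seq_len(nrow(rng))) {
    m <- rng$marker[i]
    if (!m %in% names(table)) next
    bad <- !is.na(table[[m]]) &
      (table[[m]] < rng$qc_min[i] | table[[m]] > rng$qc_max[i])
    if (any(bad)) table[[m]][bad] <- NA
    blanked[m] <- sum(bad)
  }
  absent <- setdiff(config$collinear_drop_list, names(table))
  if (length(absent))
    warning("collinear drop list names absent column(s): ",
            paste(absent, collapse = ", "))
  dropped <- intersect(config$collinear_drop_list, names(table))
  table <- table[setdiff(names(table), dropped)]
  attr(table, "qc_report") <- list(blanked = blanked, dropped = dropped)
  table
}

## --- Gower knn imputation ----------------------------------------------------

#' k-nearest-neighbour imputation under Gower distance
#'
#' Fills each missing cell from the k most similar donor rows observed on that
#' variable: numeric cells get the donor mean, categorical cells the donor
#' mode (ties broken by level order). Distances are Gower over the mixed-type
#' feature columns — range-normalized absolute differences for numeric
#' columns, 0/1 mismatches for categorical ones — averaged over the columns
#' observed in both rows. Observed cells are never changed.
#'
#' @param table data.frame to impute.
#' @param k Number of donors (default 10).
#' @param exclude Columns ignored both as features and as imputation targets
#'   (identifiers, outcomes); default `"participant_id"`.
#' @return The imputed table.
#' @export
impute_knn <- function(table, k = 10L, exclude = "participant_id") {
  k <- as.integer(k)
  assert_that(k >= 1, "k must be >= 1")
  n <- nrow(table)
  vars <- setdiff(names(table), exclude)
  is_num <- vapply(table[vars], is.numeric, logical(1))
  num_cols <- vars[is_num]
  cat_cols <- vars[!is_num]
  work <- table
  for (v in cat_cols) work[[v]] <- as.character(work[[v]])
  for (v in vars) {
    if (all(is.na(work[[v]])))
      stop("variable '", v, "' is missing in every row and cannot be imputed",
           call. = FALSE)
    nd <- sum(!is.na(work[[v]]))
    if (anyNA(work[[v]]) && nd < k)
      stop("variable '", v, "' has only ", nd,
           " donor rows, fewer than k = ", k, call. = FALSE)
  }
  ranges <- vapply(work[num_cols],
                   function(x) diff(range(x, na.rm = TRUE)), numeric(1))
  num_mat <- as.matrix(work[num_cols])
  incomplete <- which(rowSums(is.na(work[vars])) > 0)
  out <- work
  for (i in incomplete) {
    acc <- numeric(n)
    cnt <- numeric(n)
    for (j in seq_along(num_cols)) {
      tv <- num_mat[i, j]
      if (is.na(tv) || ranges[j] == 0) next
      dv <- num_mat[, j]
      ok <- !is.na(dv)
      acc[ok] <- acc[ok] + abs(dv[ok] - tv) / ranges[j]
      cnt[ok] <- cnt[ok] + 1
    }
    for (v in cat_cols) {
      tv <- work[[v]][i]
      if (is.na(tv)) next
      dv <- work[[v]]
      ok <- !is.na(dv)
      acc[ok] <- acc[ok] + (dv[ok] != tv)
      cnt[ok] <- cnt[ok] + 1
    }
    d <- ifelse(cnt > 0, acc / cnt, Inf)
    d[i] <- Inf
    o <- order(d)
    for (v in vars[is.na(work[i, vars])]) {
      donors <- o[!is.na(work[[v]][o]) & is.finite(d[o])]
      nn <- donors[seq_len(k)]
      out[[v]][i] <- if (v %in% num_cols) mean(work[[v]][nn])
      else stat_mode(work[[v]][nn])
    }
  }
  ## restore factor/logical types where the input had them
  for (v in cat_cols) {
    if (is.factor(table[[v]]))
      out[[v]] <- factor(out[[v]], levels = levels(table[[v]]))
    if (is.logical(table[[v]])) out[[v]] <- as.logical(out[[v]])
  }
  out
}
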