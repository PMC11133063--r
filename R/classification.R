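# Decision-making unit: a seeded random forest over the six-feature rows.
# Rows are classified independently - the temporal context lives entirely
# in the features - so training data can be balanced sample-wise without
# leaking information between train and test sets.

#' Default random-forest hyperparameters
#'
#' Pinned in the package (rather than left to library defaults) so that
#' "default settings" stays reproducible across library versions: 100
#' trees, mtry = floor(sqrt(6)) = 2, unlimited depth, node size 1.
#'
#' @return named list of hyperparameters.
#' @export
default_rf_params <- function() {
  list(ntree = 100L, mtry = 2L, nodesize = 1L)
}

#' Train the gaze-event classifier
#'
#' Fits a seeded random forest on the six-feature rows of a feature matrix.
#' Requires at least two classes and finite features.
#'
#' @param train feature matrix data.frame (columns of `FEATURE_ORDER` plus
#'   `label`), or a list of such matrices which are pooled.
#' @param seed integer seed (fixed-seed training is bit-reproducible).
#' @param params hyperparameters, see [default_rf_params()].
#' @return object of class `gaze_classifier` with the fitted ensemble,
#'   `class_set`, `feature_order`, `seed` and `params`.
#' @export
train_classifier <- function(train, seed = 1, params = default_rf_params()) {
  if (is.list(train) && !is.data.frame(train))
    train <- do.call(rbind, train)
  x <- as.matrix(train[, FEATURE_ORDER, drop = FALSE])
  bad <- which(!is.finite(x), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop_gz("gazevents_validation_error",
            "non-finite feature value at row %d", bad[1, 1])
  y <- factor(train$label)
  if (nlevels(y) < 2)
    stop_gz("gazevents_training_error",
            "training data contains a single class")
  set.seed(as.integer(seed) %% .Machine$integer.max)
  forest <- randomForest::randomForest(x = x, y = y,
                                       ntree = params$ntree,
                                       mtry = params$mtry,
                                       nodesize = params$nodesize,
                                       importance = FALSE)
  structure(list(forest = forest,
                 class_set = as.integer(levels(y)),
                 feature_order = FEATURE_ORDER,
                 seed = as.integer(seed),
                 params = params),
            class = "gaze_classifier")
}

#' @export
print.gaze_classifier <- function(x, ...) {
  cat(sprintf("<gaze_classifier: %d trees, classes {%s}, seed %d>\n",
              x$params$ntree, paste(x$class_set, collapse = ","), x$seed))
  invisible(x)
}

#' Predict per-sample gaze-event labels
#'
#' @param model a trained [train_classifier()] model.
#' @param test feature matrix data.frame with the model's feature columns.
#' @return list with integer `label` (one prediction per row) and `scores`
#'   (rows = samples, cols = classes; per-class tree-vote fractions summing
#'   to 1).
#' @export
predict_labels <- function(model, test) {
  miss <- setdiff(model$feature_order, names(test))
  if (length(miss) > 0)
    stop_gz("gazevents_validation_error", "test data missing feature(s): %s",
            paste(miss, collapse = ", "))
  x <- as.matrix(test[, model$feature_order, drop = FALSE])
  if (nrow(x) == 0) {
    return(list(label = integer(0),
                scores = matrix(0, 0, length(model$class_set),
                                dimnames = list(NULL, model$class_set))))
  }
  if (any(!is.finite(x)))
    stop_gz("gazevents_validation_error", "non-finite feature value in test data")
  votes <- predict(model$forest, newdata = x, type = "vote", norm.votes = TRUE)
  votes <- matrix(votes, nrow = nrow(x), dimnames = dimnames(votes))
  lab <- model$class_set[max.col(votes, ties.method = "first")]
  list(label = as.integer(lab), scores = votes)
}

#' Random-forest feature importances
#'
#' Mean decrease in Gini impurity per feature, normalized to sum to 1.
#'
#' @param model a trained [train_classifier()] model.
#' @return named numeric vector (one non-negative weight per feature,
#'   in feature order, summing to 1).
#' @export
feature_importances <- function(model) {
  if (!inherits(model, "gaze_classifier") || is.null(model$forest))
    stop_gz("gazevents_state_error", "model is not trained")
  imp <- randomForest::importance(model$forest, type = 2)[, 1]
  imp <- imp[model$feature_order]
  imp <- pmax(imp, 0)
  imp / sum(imp)
}

#' Save / load a trained classifier
#'
#' The artifact stores the fitted ensemble plus metadata (seed,
#' hyperparameters, feature order, class set); a round trip preserves
#' predictions exactly.
#'
#' @param model a `gaze_classifier`.
#' @param path file path (.rds).
#' @return `path` (save) or the restored model (load).
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path))
    stop_gz("gazevents_io_error", "file not found: %s", path)
  m <- readRDS(path)
  if (!inherits(m, "gaze_classifier"))
    stop_gz("gazevents_format_error", "not a gaze_classifier artifact")
  m
}
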