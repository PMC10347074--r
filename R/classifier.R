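#' Train the functional-use epoch classifier
#'
#' A retrainable surrogate for the pre-trained laboratory model: a random
#' forest (default) or a single decision tree over the 11 per-epoch
#' features, predicting functional (1) versus non-functional (0) arm use
#' per 4-s epoch. The min-max scaler is fitted on the training corpus here
#' and bundled with the model, so prediction-time data are scaled into the
#' training frame rather than leaking their own range.
#'
#' @param features Unscaled feature matrix from [epoch_features()]
#'   (training corpus).
#' @param labels Integer 0/1 vector, one per row of `features`.
#' @param learner `"random_forest"` (100 trees, default) or
#'   `"decision_tree"` (CART).
#' @param seed Integer seed making training deterministic.
#' @param ntree Number of trees for the forest.
#' @param class_weights Optional named weights `c("0" = , "1" = )` for the
#'   forest, exposed because free-living epoch labels are typically
#'   unbalanced; default none.
#' @return An object of class `functional_model` bundling the fitted
#'   learner, the scaler, the feature-order signature and the seed.
#' @export
train_functional_model <- function(features, labels,
                                   learner = c("random_forest",
                                               "decision_tree"),
                                   seed = 1L, ntree = 100,
                                   class_weights = NULL) {
  learner <- match.arg(learner)
  if (nrow(features) != length(labels))
    stop("features and labels must have one row/label per epoch")
  if (length(unique(labels)) < 2)
    stop("training set contains a single class; cannot train")
  scaler <- fit_minmax(features)
  x <- apply_minmax(scaler, features)
  y <- factor(labels, levels = c(0, 1))
  set.seed(seed)
  fit <- if (learner == "random_forest") {
    randomForest::randomForest(
      x = x, y = y, ntree = ntree,
      classwt = class_weights)
  } else {
    rpart::rpart(y ~ ., data = data.frame(y = y, x), method = "class")
  }
  structure(list(learner = learner, fit = fit, scaler = scaler,
                 signature = colnames(features), seed = as.integer(seed),
                 version = "1"),
            class = "functional_model")
}

#' @export
print.functional_model <- function(x, ...) {
  cat(sprintf("<functional_model> %s, %d features, seed %d (v%s)\n",
              x$learner, length(x$signature), x$seed, x$version))
  invisible(x)
}

#' Predict functional use per epoch
#'
#' One binary label per feature row, no temporal smoothing; predictions for
#' an epoch depend only on that epoch's features. The feature-order
#' signature must match the one the model was trained with.
#'
#' @param model A `functional_model`.
#' @param features Unscaled feature matrix.
#' @return Integer 0/1 vector of per-epoch predictions.
#' @export
predict_epochs <- function(model, features) {
  stopifnot(inherits(model, "functional_model"))
  if (nrow(features) == 0) return(integer(0))
  if (!identical(colnames(features), model$signature))
    stop("feature signature mismatch: model was trained on a different ",
         "feature order")
  x <- apply_minmax(model$scaler, features)
  pred <- if (model$learner == "random_forest") {
    stats::predict(model$fit, newdata = x)
  } else {
    stats::predict(model$fit, newdata = as.data.frame(x), type = "class")
  }
  as.integer(as.character(pred))
}

#' Functional minutes from predicted epoch labels
#'
#' The predicted number of functional 4-s blocks times 4 seconds, divided
#' by 60.
#'
#' @param labels Integer 0/1 predictions per epoch.
#' @param epoch_len_s Epoch length, default 4 s.
#' @return Minutes of predicted functional activity.
#' @export
predicted_functional_minutes <- function(labels, epoch_len_s = 4) {
  sum(labels == 1L) * epoch_len_s / 60
}

#' Save / load a functional model bundle
#'
#' Persists the model (learner, scaler, signature, seed, version) with
#' `saveRDS`.
#'
#' @param model A `functional_model`.
#' @param path File path.
#' @return `path` invisibly (`save_functional_model`); the model
#'   (`load_functional_model`).
#' @export
save_functional_model <- function(model, path) {
  stopifnot(inherits(model, "functional_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_functional_model
#' @export
load_functional_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "functional_model"))
    stop("not a functional_model bundle: ", path)
  model
}
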