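#' Fit a gradient-boosted tree classifier
#'
#' Small, dependency-free boosted-tree learner for binary targets using
#' second-order boosting on the logistic loss, exact greedy splits, row
#' subsampling, L1/L2 regularisation of leaf weights and an optional
#' positive-class weight. When a validation set is supplied, boosting stops
#' early on stalled validation log-loss and the model is truncated at the
#' best iteration.
#'
#' @param x numeric matrix of predictors (records x features), no missing
#'   values.
#' @param y binary vector (0/1) of length `nrow(x)`.
#' @param nrounds maximum number of boosting iterations.
#' @param max_depth maximum tree depth.
#' @param eta learning rate in (0, 1].
#' @param subsample fraction of rows sampled (without replacement) per tree.
#' @param lambda L2 penalty on leaf weights.
#' @param alpha L1 penalty on leaf weights.
#' @param pos_weight multiplicative weight on positive-class gradients.
#' @param min_child_weight minimum hessian sum per leaf.
#' @param valid optional list with elements `x` and `y` used for early
#'   stopping.
#' @param patience early-stopping patience (iterations without improvement);
#'   ignored without `valid`.
#'
#' @return an object of class `gbt_model` with elements `trees`,
#'   `best_iter`, `val_loss`, `feature_names` and the call parameters.
#'   Subsampling consumes R's RNG stream, so results are reproducible under
#'   `set.seed()`.
#' @export
gbt_fit <- function(x, y, nrounds = 50L, max_depth = 4L, eta = 0.1,
                    subsample = 1.0, lambda = 1.0, alpha = 0.0,
                    pos_weight = 1.0, min_child_weight = 1.0,
                    valid = NULL, patience = 8L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  stopifnot(nrow(x) == length(y), all(y %in% c(0, 1)))
  xv <- NULL
  yv <- NULL
  if (!is.null(valid)) {
    xv <- as.matrix(valid$x)
    storage.mode(xv) <- "double"
    yv <- as.numeric(valid$y)
  }
  fit <- cpp_gbt_train(x, as.numeric(y), as.integer(nrounds),
                       as.integer(max_depth), eta, subsample, lambda, alpha,
                       pos_weight, min_child_weight, xv, yv,
                       as.integer(patience))
  structure(list(trees = fit$trees, best_iter = fit$best_iter,
                 val_loss = fit$val_loss, feature_names = colnames(x),
                 params = list(max_depth = max_depth, eta = eta,
                               subsample = subsample, lambda = lambda,
                               alpha = alpha, pos_weight = pos_weight)),
            class = "gbt_model")
}

#' Predict from a gbt_model
#'
#' @param object a `gbt_model`.
#' @param x numeric matrix with the training feature columns in order.
#' @param type `"prob"` for P(y = 1), `"margin"` for the raw log-odds score.
#' @param ... unused.
#' @return numeric vector of scores.
#' @export
predict.gbt_model <- function(object, x, type = c("prob", "margin"), ...) {
  type <- match.arg(type)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  m <- cpp_gbt_margin(object$trees, x)
  if (type == "margin") m else 1 / (1 + exp(-m))
}

#' TreeSHAP attributions for a gbt_model
#'
#' Computes exact per-record, per-feature Shapley attributions for the
#' model margin using the polynomial-time path algorithm with
#' path-dependent (cover-weighted) expectations. Attributions satisfy
#' `rowSums(phi) + base_value = margin(x)` exactly.
#'
#' @param model a `gbt_model`.
#' @param x numeric matrix of records to explain.
#' @return matrix (records x features) of attributions with attribute
#'   `base_value`.
#' @export
gbt_shap <- function(model, x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  phi <- cpp_gbt_shap(model$trees, x)
  colnames(phi) <- model$feature_names
  phi
}
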