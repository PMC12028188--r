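# Leave-one-variable-out logistic-regression ablation of the consensus
# candidate variables, reported as train/validation/test AUROC per variant.

#' Stratified train/validation/test partition
#'
#' @param y binary target vector.
#' @param props length-3 proportions summing to 1.
#' @param seed integer seed.
#' @param max_tries redraw attempts to get both classes in every partition.
#' @return list with integer indices `train`, `validation`, `test`.
#' @export
make_eval_split <- function(y, props = c(0.6, 0.2, 0.2), seed = 1L,
                            max_tries = 100L) {
  stopifnot(length(props) == 3L, abs(sum(props) - 1) < 1e-8)
  set.seed(seed)
  n <- length(y)
  for (try in seq_len(max_tries)) {
    train <- .stratified_take(y, props[1])
    rest <- setdiff(seq_len(n), train)
    val_take <- .stratified_take(y[rest], props[2] / (props[2] + props[3]))
    validation <- rest[val_take]
    test <- setdiff(rest, validation)
    parts <- list(train, validation, test)
    if (all(vapply(parts, function(i) length(unique(y[i])) == 2L, logical(1))))
      return(list(train = train, validation = validation, test = test))
  }
  stop("could not produce a three-way split with both classes everywhere",
       call. = FALSE)
}

# TRUE when a fitted binomial glm shows symptoms of (quasi-)separation.
.separated <- function(fit) {
  !fit$converged ||
    any(abs(stats::coef(fit)[!is.na(stats::coef(fit))]) > 15) ||
    any(fit$fitted.values < 1e-8) || any(fit$fitted.values > 1 - 1e-8)
}

#' Fit a logistic model and report per-partition AUROC
#'
#' Maximum-likelihood logistic regression on the training partition only,
#' with AUROC reported on train, validation and test. On perfect or
#' quasi-perfect separation, the fit falls back to a ridge-stabilised
#' logistic regression (glmnet, alpha = 0, fixed small lambda) with a
#' warning.
#'
#' @param x numeric matrix of candidate features.
#' @param y binary target.
#' @param split three-way partition from [make_eval_split()].
#' @return list with `auroc` (named train/validation/test triple),
#'   `ridge_used`, and the fitted model.
#' @export
fit_logistic <- function(x, y, split) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y))
  df <- data.frame(y = y, x)
  fit <- suppressWarnings(
    stats::glm(y ~ ., family = stats::binomial(), data = df[split$train, ]))
  ridge_used <- FALSE
  if (.separated(fit)) {
    warning("separation detected; refitting with ridge stabilization",
            call. = FALSE)
    ridge_used <- TRUE
    # glmnet needs >= 2 columns; pad single-feature fits with an inert zero
    xr <- if (ncol(x) < 2L) cbind(x, .pad = 0) else x
    fit <- glmnet::glmnet(xr[split$train, , drop = FALSE], y[split$train],
                          family = "binomial", alpha = 0, lambda = 1e-2,
                          standardize = TRUE)
  }
  score <- function(idx) {
    if (ridge_used) {
      drop(stats::predict(fit, newx = xr[idx, , drop = FALSE], type = "link"))
    } else {
      suppressWarnings(
        stats::predict(fit, newdata = df[idx, , drop = FALSE], type = "link"))
    }
  }
  aucs <- vapply(split[c("train", "validation", "test")],
                 function(idx) auroc(score(idx), y[idx]), numeric(1))
  list(auroc = aucs, ridge_used = ridge_used, model = fit)
}

#' Leave-one-variable-out ablation scan
#'
#' Fits the complete logistic model and every variant omitting one
#' candidate variable, all on identical partitions so differences reflect
#' variables rather than splits. Rows report each omitted-variable variant
#' followed by the complete model; the omission with the largest test-AUROC
#' drop is flagged.
#'
#' @param x numeric matrix of the candidate variables (the consensus top
#'   cluster; the reference set has 4 columns, giving 5 report rows).
#' @param y binary target.
#' @param split optional partition from [make_eval_split()]; defaults to a
#'   seeded 60/20/20 stratified split.
#' @param seed seed for the default partition.
#' @return data.frame of class `ablation_report` with columns `model`,
#'   `omitted`, `train_auroc`, `validation_auroc`, `test_auroc`; attribute
#'   `worst_omission` names the variable whose removal cost the most test
#'   AUROC.
#' @export
ablation_scan <- function(x, y, split = NULL, seed = 1L) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("need at least 2 candidate variables", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (is.null(split)) split <- make_eval_split(y, seed = seed)
  variants <- c(as.list(colnames(x)), list(NA_character_))
  rows <- lapply(variants, function(omit) {
    keep <- if (is.na(omit)) colnames(x) else setdiff(colnames(x), omit)
    res <- fit_logistic(x[, keep, drop = FALSE], y, split)
    data.frame(model = if (is.na(omit)) "Complete Model"
               else paste0("Model-", omit),
               omitted = omit,
               train_auroc = unname(res$auroc["train"]),
               validation_auroc = unname(res$auroc["validation"]),
               test_auroc = unname(res$auroc["test"]),
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  complete_test <- report$test_auroc[is.na(report$omitted)]
  drops <- complete_test - report$test_auroc[!is.na(report$omitted)]
  attr(report, "worst_omission") <-
    report$omitted[!is.na(report$omitted)][which.max(drops)]
  class(report) <- c("ablation_report", "data.frame")
  report
}
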