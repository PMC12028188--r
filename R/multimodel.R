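# The multi-model procedure: repeated randomized 70:30 partitions of the
# training cohort, randomized gradient-boosted-tree hyperparameters, held-out
# AUROC on the internal test side and on external cohorts, and per-feature
# mean-|SHAP| importance per round. Rounds with internal-test AUROC above the
# retention threshold feed the corrected-importance ranking.

#' Default hyperparameter sampling space
#'
#' Seven dimensions: tree depth, learning rate, row-subsampling fraction,
#' L2 and L1 penalties, positive-class weight and the number of folds used
#' for in-training round selection. Learning rate and penalties are sampled
#' log-uniformly, depth and folds as uniform integers, the rest uniformly.
#'
#' @return named list of length-2 (min, max) ranges.
#' @export
default_hyperparam_space <- function() {
  list(tree_depth = c(2L, 8L),
       learning_rate = c(0.01, 0.3),
       subsample_fraction = c(0.5, 1.0),
       l2_penalty = c(1e-8, 10),
       l1_penalty = c(1e-8, 10),
       positive_class_weight = c(0.5, 4),
       cv_folds = c(3L, 10L))
}

#' Sample one hyperparameter configuration
#'
#' @param space named list of (min, max) ranges as in
#'   [default_hyperparam_space()]. A degenerate range (min == max) yields
#'   that exact value.
#' @return named list of class `hyperparams`.
#' @export
sample_hyperparams <- function(space = default_hyperparam_space()) {
  needed <- names(default_hyperparam_space())
  missing_dims <- setdiff(needed, names(space))
  if (length(missing_dims))
    stop(sprintf("hyperparameter space lacks dimension(s): %s",
                 paste(missing_dims, collapse = ", ")), call. = FALSE)
  for (d in needed) {
    rng <- space[[d]]
    if (length(rng) != 2L || any(is.na(rng)) || rng[2] < rng[1])
      stop(sprintf("invalid range for hyperparameter '%s'", d), call. = FALSE)
  }
  runif_log <- function(rng) exp(stats::runif(1, log(rng[1]), log(rng[2])))
  runif_int <- function(rng) {
    if (rng[1] == rng[2]) as.integer(rng[1]) else
      as.integer(sample(seq.int(rng[1], rng[2]), 1L))
  }
  structure(list(
    tree_depth = runif_int(space$tree_depth),
    learning_rate = runif_log(space$learning_rate),
    subsample_fraction = stats::runif(1, space$subsample_fraction[1],
                                      space$subsample_fraction[2]),
    l2_penalty = runif_log(space$l2_penalty),
    l1_penalty = runif_log(space$l1_penalty),
    positive_class_weight = stats::runif(1, space$positive_class_weight[1],
                                         space$positive_class_weight[2]),
    cv_folds = runif_int(space$cv_folds)), class = "hyperparams")
}

# Stratified index draw totalling round(frac * n), apportioned to classes
# by largest remainder and clamped so both classes appear on both sides.
.stratified_take <- function(y, frac) {
  n <- length(y)
  total <- round(frac * n)
  classes <- sort(unique(y))
  ns <- vapply(classes, function(cl) sum(y == cl), integer(1))
  base <- floor(frac * ns)
  rem <- total - sum(base)
  fracpart <- frac * ns - base
  if (rem > 0) {
    add <- order(-fracpart)[seq_len(rem)]
    base[add] <- base[add] + 1L
  } else if (rem < 0) {
    sub <- order(fracpart)[seq_len(-rem)]
    base[sub] <- base[sub] - 1L
  }
  base <- pmin(pmax(base, 1L), ns - 1L)
  take <- integer(0)
  for (k in seq_along(classes)) {
    idx <- which(y == classes[k])
    take <- c(take, sample(idx, base[k]))
  }
  sort(take)
}

#' Draw one randomized train/test partition of the training cohort
#'
#' Stratified so both target classes appear on each side; with
#' `groups` supplied (patient ids), whole patients are assigned to one side
#' so no patient's records straddle the split.
#'
#' @param y binary target vector of the training cohort's records.
#' @param ratio training fraction.
#' @param groups optional grouping vector (e.g. patient ids).
#' @param max_tries redraw attempts before failing the class-presence
#'   requirement.
#' @return list of class `split_plan` with `train`, `test`, `ratio`.
#' @export
make_split <- function(y, ratio = 0.7, groups = NULL, max_tries = 100L) {
  n <- length(y)
  if (n < 10L) stop("need at least 10 records to split", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("both target classes must be present", call. = FALSE)
  for (try in seq_len(max_tries)) {
    if (is.null(groups)) {
      train <- .stratified_take(y, ratio)
    } else {
      gids <- unique(groups)
      ord <- sample(gids)
      sizes <- cumsum(vapply(ord, function(g) sum(groups == g), integer(1)))
      n_train_groups <- which(sizes >= round(ratio * n))[1]
      if (is.na(n_train_groups)) n_train_groups <- length(ord) - 1L
      n_train_groups <- min(max(n_train_groups, 1L), length(ord) - 1L)
      train <- sort(which(groups %in% ord[seq_len(n_train_groups)]))
    }
    test <- setdiff(seq_len(n), train)
    if (length(unique(y[train])) == 2L && length(unique(y[test])) == 2L) {
      return(structure(list(train = train, test = test, ratio = ratio),
                       class = "split_plan"))
    }
  }
  stop(sprintf("could not produce a class-stratified split in %d attempts",
               max_tries), call. = FALSE)
}

#' Area under the ROC curve by rank statistic
#'
#' Equals the Mann-Whitney probability P(score+ > score-) + 0.5 P(tie).
#'
#' @param scores continuous classifier scores.
#' @param labels binary labels (0/1 or logical).
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("AUROC undefined: both classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Train and evaluate one ensemble round
#'
#' Fits a gradient-boosted tree classifier on the train side of `split`
#' with the sampled hyperparameters, then computes AUROC and per-feature
#' mean-|SHAP| importance on the internal test side and on each external
#' cohort. The round's `cv_folds` hyperparameter controls in-training round
#' selection: a stratified 1/cv_folds slice of the training side is held
#' out for early stopping, after which the model is refit on the full
#' training side at the selected iteration count. Test records are never
#' touched during fitting.
#'
#' @param dataset an `analysis_dataset` for the training cohort.
#' @param split a `split_plan` over `dataset`'s records.
#' @param external named list of `analysis_dataset`s sharing
#'   `feature_names` (order included) with `dataset`.
#' @param hp a `hyperparams` object.
#' @param seed optional integer; when given, `set.seed(seed)` is called so
#'   the round is reproducible in isolation. Leave `NULL` to consume the
#'   caller's RNG stream.
#' @param nrounds_max maximum boosting iterations.
#' @param round_selection `"holdout"` (early stopping on the held-out
#'   slice) or `"none"` (always `nrounds_max` iterations).
#' @return list of class `model_round` with `hyperparams`,
#'   `auroc_by_testset`, `shap_by_testset`, `n_trees`, `seed`.
#' @export
train_round <- function(dataset, split, external = list(), hp, seed = NULL,
                        nrounds_max = 50L,
                        round_selection = c("holdout", "none")) {
  round_selection <- match.arg(round_selection)
  if (!is.null(seed)) set.seed(seed)
  for (nm in names(external)) {
    ext <- external[[nm]]
    if (!identical(ext$feature_names, dataset$feature_names)) {
      diff <- c(setdiff(ext$feature_names, dataset$feature_names),
                setdiff(dataset$feature_names, ext$feature_names))
      stop(sprintf("feature names of external cohort '%s' differ: %s",
                   nm, paste(unique(diff), collapse = ", ")), call. = FALSE)
    }
  }
  xtr <- dataset$x[split$train, , drop = FALSE]
  ytr <- dataset$y[split$train]

  fit_args <- list(nrounds = nrounds_max, max_depth = hp$tree_depth,
                   eta = hp$learning_rate, subsample = hp$subsample_fraction,
                   lambda = hp$l2_penalty, alpha = hp$l1_penalty,
                   pos_weight = hp$positive_class_weight)
  n_trees <- nrounds_max
  if (round_selection == "holdout") {
    hold <- tryCatch(.stratified_take(ytr, 1 / hp$cv_folds),
                     error = function(e) integer(0))
    if (length(hold) >= 2L && length(hold) < length(ytr) &&
        length(unique(ytr[hold])) == 2L &&
        length(unique(ytr[-hold])) == 2L) {
      probe <- do.call(gbt_fit, c(list(x = xtr[-hold, , drop = FALSE],
                                       y = ytr[-hold],
                                       valid = list(x = xtr[hold, , drop = FALSE],
                                                    y = ytr[hold])),
                                  fit_args))
      n_trees <- probe$best_iter
    }
  }
  fit_args$nrounds <- n_trees
  model <- do.call(gbt_fit, c(list(x = xtr, y = ytr), fit_args))

  testsets <- c(list(internal = subset_dataset(dataset, split$test)), external)
  aucs <- list()
  shaps <- list()
  for (nm in names(testsets)) {
    ts <- testsets[[nm]]
    sc <- predict(model, ts$x, type = "margin")
    aucs[[nm]] <- if (length(unique(ts$y)) == 2L) auroc(sc, ts$y) else NA_real_
    phi <- gbt_shap(model, ts$x)
    shaps[[nm]] <- colMeans(abs(phi))
  }
  structure(list(hyperparams = hp,
                 auroc_by_testset = aucs,
                 shap_by_testset = shaps,
                 n_trees = n_trees,
                 seed = seed),
            class = "model_round")
}

#' Run the multi-model ensemble procedure
#'
#' Executes `n_rounds` of (fresh randomized stratified 70:30 split,
#' hyperparameter draw, gradient-boosted-tree fit, held-out evaluation) on
#' the training cohort, retaining rounds whose internal-test AUROC strictly
#' exceeds `auc_threshold`. Per-round seeds derive deterministically from
#' `master_seed`, so the full run is reproducible.
#'
#' @param dataset training-cohort `analysis_dataset`.
#' @param external named list of external-cohort `analysis_dataset`s.
#' @param n_rounds number of independent training rounds.
#' @param auc_threshold internal-test AUROC retention threshold.
#' @param space hyperparameter sampling space.
#' @param master_seed integer master seed.
#' @param grouped keep each patient's records on one side of every split.
#' @param ratio training fraction per split.
#' @param nrounds_max,round_selection passed to [train_round()].
#' @return list of class `multimodel_result` with `rounds` (retained
#'   `model_round`s), `retention` fraction, `status` (`"ok"` or
#'   `"empty"`), and the run settings.
#' @export
run_multimodel <- function(dataset, external = list(), n_rounds = 5000L,
                           auc_threshold = 0.7,
                           space = default_hyperparam_space(),
                           master_seed = 1L, grouped = FALSE, ratio = 0.7,
                           nrounds_max = 50L, round_selection = "holdout") {
  stopifnot(n_rounds >= 1L)
  groups <- if (grouped) dataset$patient_id else NULL
  retained <- vector("list", n_rounds)
  n_kept <- 0L
  for (i in seq_len(n_rounds)) {
    set.seed(derive_seed(master_seed, i))
    split <- make_split(dataset$y, ratio = ratio, groups = groups)
    hp <- sample_hyperparams(space)
    rnd <- train_round(dataset, split, external, hp, seed = NULL,
                       nrounds_max = nrounds_max,
                       round_selection = round_selection)
    rnd$round_id <- i
    if (!is.na(rnd$auroc_by_testset$internal) &&
        rnd$auroc_by_testset$internal > auc_threshold) {
      n_kept <- n_kept + 1L
      retained[[n_kept]] <- rnd
    }
  }
  retained <- retained[seq_len(n_kept)]
  structure(list(rounds = retained,
                 retention = n_kept / n_rounds,
                 status = if (n_kept == 0L) "empty" else "ok",
                 n_rounds = n_rounds,
                 auc_threshold = auc_threshold,
                 feature_names = dataset$feature_names,
                 master_seed = master_seed),
            class = "multimodel_result")
}

#' Serialize retained rounds as JSON lines
#'
#' One retained round per line: hyperparameters, per-testset AUROC and
#' mean-|SHAP| vectors, tree count and round id. Readable back with
#' [read_rounds_jsonl()].
#'
#' @param result a `multimodel_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_rounds_jsonl <- function(result, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (rnd in result$rounds) {
    line <- jsonlite::toJSON(list(
      round_id = rnd$round_id,
      hyperparams = unclass(rnd$hyperparams),
      n_trees = rnd$n_trees,
      auroc_by_testset = rnd$auroc_by_testset,
      shap_by_testset = lapply(rnd$shap_by_testset, as.list)),
      auto_unbox = TRUE, digits = NA, na = "null")
    writeLines(line, con)
  }
  invisible(path)
}

#' @rdname write_rounds_jsonl
#' @param feature_names feature order to restore for the SHAP vectors.
#' @export
read_rounds_jsonl <- function(path, feature_names = NULL) {
  lines <- readLines(path)
  rounds <- lapply(lines, function(ln) {
    obj <- jsonlite::fromJSON(ln, simplifyVector = TRUE)
    structure(list(hyperparams = structure(obj$hyperparams,
                                           class = "hyperparams"),
                   auroc_by_testset = as.list(obj$auroc_by_testset),
                   shap_by_testset = lapply(obj$shap_by_testset, unlist),
                   n_trees = obj$n_trees,
                   round_id = obj$round_id,
                   seed = NULL),
              class = "model_round")
  })
  structure(list(rounds = rounds,
                 retention = NA_real_,
                 status = if (length(rounds) == 0L) "empty" else "ok",
                 feature_names = feature_names),
            class = "multimodel_result")
}
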