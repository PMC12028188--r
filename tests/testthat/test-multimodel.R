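test_that("splits have the right sizes, are disjoint and stratified", {
  y <- rep(c(0, 1), each = 5)
  set.seed(1)
  s <- make_split(y, ratio = 0.7)
  expect_identical(length(s$train), 7L)
  expect_identical(length(s$test), 3L)
  expect_length(intersect(s$train, s$test), 0)
  expect_setequal(c(s$train, s$test), 1:10)
  expect_length(unique(y[s$train]), 2)
  expect_length(unique(y[s$test]), 2)
  s2 <- make_split(y, ratio = 0.7)
  expect_false(identical(s, s2))  # fresh randomized partition per draw
  expect_error(make_split(y[1:8]), "at least 10")
  expect_error(make_split(rep(1, 12)), "both target classes")
})

test_that("grouped splits keep each patient on one side", {
  y <- rep(c(0, 1, 0, 1), each = 5)
  groups <- rep(c("p1", "p2", "p3", "p4"), each = 5)
  set.seed(2)
  for (i in 1:10) {
    s <- make_split(y, ratio = 0.5, groups = groups)
    for (g in unique(groups)) {
      idx <- which(groups == g)
      expect_true(all(idx %in% s$train) || all(idx %in% s$test))
    }
  }
})

test_that("hyperparameter sampling respects ranges and covers discrete sets", {
  point <- list(tree_depth = c(3L, 3L), learning_rate = c(0.1, 0.1),
                subsample_fraction = c(0.8, 0.8), l2_penalty = c(1, 1),
                l1_penalty = c(0.5, 0.5), positive_class_weight = c(2, 2),
                cv_folds = c(5L, 5L))
  set.seed(3)
  hp <- sample_hyperparams(point)
  expect_identical(hp$tree_depth, 3L)
  expect_identical(hp$cv_folds, 5L)
  expect_equal(hp$learning_rate, 0.1)
  expect_equal(hp$positive_class_weight, 2)

  space <- default_hyperparam_space()
  space$tree_depth <- c(2L, 6L)
  set.seed(4)
  draws <- replicate(1000, sample_hyperparams(space), simplify = FALSE)
  depths <- vapply(draws, `[[`, integer(1), "tree_depth")
  expect_setequal(unique(depths), 2:6)
  lr <- vapply(draws, `[[`, numeric(1), "learning_rate")
  expect_true(all(lr > 0.01 & lr < 0.3))
  sub <- vapply(draws, `[[`, numeric(1), "subsample_fraction")
  expect_true(all(sub >= 0.5 & sub <= 1))

  bad <- space
  bad$learning_rate <- c(0.3, 0.01)
  expect_error(sample_hyperparams(bad), "invalid range")
  expect_error(sample_hyperparams(space[-1]), "tree_depth")
})

test_that("AUROC equals the Mann-Whitney pair-counting oracle", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(auroc(rep(0.5, 8), rep(c(0, 1), 4)), 0.5)
  expect_equal(auroc(c(1, 2, 3, 4, 5, 6), c(0, 0, 1, 0, 1, 1)),
               oracle_auroc(c(1, 2, 3, 4, 5, 6), c(0, 0, 1, 0, 1, 1)))
  expect_error(auroc(1:4, c(1, 1, 1, 1)), "both classes")
  set.seed(5)
  for (i in 1:20) {
    sc <- sample(seq(0, 1, 0.1), 15, replace = TRUE)  # force ties
    lb <- rbinom(15, 1, 0.5)
    if (length(unique(lb)) < 2) next
    a <- auroc(sc, lb)
    expect_equal(a, oracle_auroc(sc, lb), tolerance = 1e-12)
    # complement and monotone-transform invariances
    expect_equal(a, auroc(exp(3 * sc), lb), tolerance = 1e-12)
    if (!any(duplicated(sc))) expect_equal(auroc(sc, 1 - lb), 1 - a)
  }
})

make_toy_dataset <- function(n = 60, seed = 9) {
  set.seed(seed)
  x <- cbind(driver = stats::runif(n), other = stats::rnorm(n),
             extra = stats::rnorm(n))
  structure(list(x = x, y = as.integer(x[, "driver"] > 0.5),
                 feature_names = colnames(x),
                 cohort = rep("A", n),
                 patient_id = sprintf("P%02d", seq_len(n)),
                 hcc = rep(FALSE, n)),
            class = "analysis_dataset")
}

test_that("train_round on a separable dataset is perfect, attributed, deterministic", {
  ds <- make_toy_dataset()
  set.seed(11)
  split <- make_split(ds$y)
  hp <- structure(list(tree_depth = 3L, learning_rate = 0.2,
                       subsample_fraction = 0.9, l2_penalty = 1,
                       l1_penalty = 0, positive_class_weight = 1,
                       cv_folds = 5L), class = "hyperparams")
  r1 <- train_round(ds, split, hp = hp, seed = 77)
  r2 <- train_round(ds, split, hp = hp, seed = 77)
  expect_identical(r1, r2)
  expect_equal(r1$auroc_by_testset$internal, 1.0)
  shap <- r1$shap_by_testset$internal
  expect_identical(names(which.max(shap)), "driver")
  expect_true(all(shap >= 0))

  ext <- make_toy_dataset(40, seed = 12)
  ext$feature_names <- c("driver", "other", "renamed")
  colnames(ext$x) <- ext$feature_names
  expect_error(train_round(ds, split, external = list(B = ext), hp = hp),
               "renamed")
})

test_that("run_multimodel retains above-threshold rounds and flags empty results", {
  ds <- make_toy_dataset()
  res <- run_multimodel(ds, n_rounds = 1, master_seed = 5)
  expect_identical(res$status, "ok")
  expect_length(res$rounds, 1)

  res_none <- run_multimodel(ds, n_rounds = 3, auc_threshold = 1.01,
                             master_seed = 5)
  expect_identical(res_none$status, "empty")
  expect_length(res_none$rounds, 0)
  expect_error(corrected_importance(res_none), "no retained")

  # retained rounds never have internal AUROC at or below the threshold
  res2 <- run_multimodel(ds, n_rounds = 10, auc_threshold = 0.7,
                         master_seed = 6)
  aucs <- vapply(res2$rounds, function(r) r$auroc_by_testset$internal,
                 numeric(1))
  expect_true(all(aucs > 0.7))
})

test_that("a full run is reproducible from the master seed alone", {
  ds <- make_toy_dataset()
  r1 <- run_multimodel(ds, n_rounds = 8, master_seed = 21)
  r2 <- run_multimodel(ds, n_rounds = 8, master_seed = 21)
  expect_identical(r1, r2)
})

test_that("JSON-lines round files survive a round trip", {
  ds <- make_toy_dataset()
  res <- run_multimodel(ds, n_rounds = 6, master_seed = 8)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_rounds_jsonl(res, path)
  back <- read_rounds_jsonl(path, feature_names = ds$feature_names)
  expect_length(back$rounds, length(res$rounds))
  expect_equal(back$rounds[[1]]$auroc_by_testset$internal,
               res$rounds[[1]]$auroc_by_testset$internal, tolerance = 1e-12)
  expect_equal(unname(back$rounds[[1]]$shap_by_testset$internal),
               unname(res$rounds[[1]]$shap_by_testset$internal),
               tolerance = 1e-12)
  expect_equal(corrected_importance(back), corrected_importance(res),
               tolerance = 1e-12)
})
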