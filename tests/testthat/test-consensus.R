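vars4 <- c("alkp", "alt", "ntbc", "suac")

test_that("corrected importance is the mean of per-round SHAP x AUROC products", {
  r1 <- make_fake_round(c(a = 0.5), 0.8)
  expect_equal(unname(corrected_importance(fake_result(list(r1)))), 0.4)
  r2 <- make_fake_round(c(a = 0.25), 0.8)   # product 0.2
  two <- corrected_importance(fake_result(list(r1, r2)))
  expect_equal(unname(two), 0.3)
  expect_identical(names(two), "a")
})

test_that("corrected importance matches a loop-and-accumulate oracle", {
  set.seed(13)
  shaps <- replicate(50, stats::setNames(stats::runif(6), letters[1:6]),
                     simplify = FALSE)
  aucs <- stats::runif(50, 0.5, 1)
  rounds <- Map(make_fake_round, shaps, aucs)
  got <- corrected_importance(fake_result(rounds))
  expect_equal(unname(got), unname(oracle_corrected(shaps, aucs)),
               tolerance = 1e-12)
})

test_that("corrected importance is linear in SHAP and replication-idempotent", {
  set.seed(14)
  shaps <- replicate(10, stats::setNames(stats::runif(4), vars4),
                     simplify = FALSE)
  aucs <- stats::runif(10, 0.5, 1)
  rounds <- Map(make_fake_round, shaps, aucs)
  base <- corrected_importance(fake_result(rounds))
  doubled <- Map(make_fake_round, lapply(shaps, `*`, 2), aucs)
  expect_equal(corrected_importance(fake_result(doubled)), 2 * base,
               tolerance = 1e-12)
  tripled_set <- fake_result(c(rounds, rounds, rounds))
  expect_equal(corrected_importance(tripled_set), base, tolerance = 1e-12)
})

test_that("rankings sort descending with flagged alphabetical tie-breaks", {
  tab <- structure(cbind(internal = c(A = 0.4, B = 0.1, C = 0.3),
                         ext = c(0.2, 0.2, 0.2)),
                   class = c("importance_table", "matrix"))
  rk <- rank_variables(tab, "internal")
  expect_identical(rk$variable, c("A", "C", "B"))
  expect_identical(rk$rank, 1:3)
  expect_false(any(rk$tied))
  rk_t <- rank_variables(tab, "ext")
  expect_identical(rk_t$variable, c("A", "B", "C"))
  expect_true(all(rk_t$tied))
  expect_error(rank_variables(tab, "nope"), "not present")
  # invariant under positive rescaling of a cohort column
  tab2 <- tab
  tab2[, "internal"] <- tab2[, "internal"] * 17
  expect_identical(rank_variables(tab2, "internal")$variable, rk$variable)
})

test_that("pairwise importance-distribution tests behave at the extremes", {
  same <- lapply(1:20, function(i) {
    make_fake_round(c(a = 0.3, b = 0.3, c = stats::runif(1)), 1.0)
  })
  p <- compare_importance_distributions(fake_result(same))
  expect_equal(p["a", "b"], 1)
  expect_identical(p, t(p))
  disjoint <- lapply(1:20, function(i) {
    make_fake_round(c(a = stats::runif(1, 0.8, 1), b = stats::runif(1, 0, 0.2)),
                    1.0)
  })
  p2 <- compare_importance_distributions(fake_result(disjoint))
  expect_lt(p2["a", "b"], 0.01)
  single <- fake_result(list(make_fake_round(c(a = 1, b = 2), 0.9)))
  expect_error(compare_importance_distributions(single), "at least 2")
})

test_that("consensus clustering groups profiles and finds the top cluster", {
  tab <- structure(rbind(hi1 = c(0.9, 0.8, 0.85), hi2 = c(0.9, 0.8, 0.85),
                         lo1 = c(0.1, 0.05, 0.1), lo2 = c(0.12, 0.06, 0.11)),
                   dimnames = list(c("hi1", "hi2", "lo1", "lo2"),
                                   c("internal", "B", "C")),
                   class = c("importance_table", "matrix"))
  cl <- consensus_cluster(tab, k = 2)
  expect_setequal(cl$top_cluster, c("hi1", "hi2"))
  # identical profiles merge at height 0
  expect_equal(min(cl$hclust$height), 0)
  expect_identical(cl$flat_labels[["hi1"]], cl$flat_labels[["hi2"]])
  expect_match(cl$newick, "hi1")
  # pairwise distances agree with the brute-force Euclidean oracle
  expect_equal(as.matrix(stats::dist(unclass(tab))),
               oracle_euclidean(unclass(tab)), ignore_attr = TRUE,
               tolerance = 1e-12)
  zero <- tab
  zero[, ] <- 0
  expect_warning(cl0 <- consensus_cluster(zero), "all-zero")
  expect_length(unique(cl0$flat_labels), 1)
})
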