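test_that("eligibility filter enforces completeness and AFP/SUAC presence", {
  rec <- make_manual_records()
  expect_identical(nrow(filter_records(rec)), 3L)

  rec_afp_na <- rec
  rec_afp_na$afp[1] <- NA
  expect_identical(filter_records(rec_afp_na)$patient_id, c("P2", "P3"))

  rec_suac_na <- rec
  rec_suac_na$suac_detected[2] <- NA
  expect_identical(filter_records(rec_suac_na)$patient_id, c("P1", "P3"))

  # 8 of 15 modeled variables present (53%) with AFP+SUAC observed -> removed
  rec_sparse <- rec
  gone <- c("ntbc", "phe", "met", "tyr", "alt", "ast", "ggt")
  rec_sparse[1, gone] <- NA
  expect_identical(filter_records(rec_sparse)$patient_id, c("P2", "P3"))
  # 70% exactly (11/15 present; 10.5/15 rounds up) is retained
  rec_edge <- rec
  rec_edge[1, c("ntbc", "phe", "met", "tyr")] <- NA
  expect_identical(nrow(filter_records(rec_edge)), 3L)
})

test_that("filtering is idempotent, handles empty input, warns on wipeout", {
  r <- default_records()
  f1 <- filter_records(r)
  f2 <- filter_records(f1)
  expect_equal(f2, f1, ignore_attr = "n_removed")
  expect_identical(nrow(filter_records(r[0, ])), 0L)
  rec <- make_manual_records()
  rec$afp <- NA
  expect_warning(out <- filter_records(rec), "all records removed")
  expect_identical(nrow(out), 0L)
})

test_that("AFP binarization is a strict-threshold pure function", {
  expect_identical(binarize_afp(2.2), 0L)
  expect_identical(binarize_afp(61.1), 1L)
  expect_identical(binarize_afp(5.0), 0L)   # boundary -> normal
  expect_identical(binarize_afp(5.0001), 1L)
  expect_error(binarize_afp(0), "positive")
  expect_error(binarize_afp(NA_real_), "missing")
  # monotone in AFP
  v <- sort(stats::runif(50, 0.1, 20))
  expect_true(all(diff(binarize_afp(v)) >= 0))
})

test_that("imputation returns complete matrices unchanged and never touches observed cells", {
  set.seed(1)
  m <- matrix(stats::rlnorm(200), 40, 5)
  expect_identical(impute_missing(m), m)
  m2 <- m
  m2[cbind(sample(40, 8), sample(5, 8, replace = TRUE))] <- NA
  out <- impute_missing(m2)
  expect_false(any(is.na(out)))
  expect_identical(out[!is.na(m2)], m2[!is.na(m2)])
})

test_that("imputation recovers an exact linear relationship", {
  x <- seq(1, 20, length.out = 25)
  y <- 2 * x
  m <- cbind(x = x, y = y)
  m[7, "y"] <- NA
  out <- impute_missing(m)
  expect_equal(unname(out[7, "y"]), 2 * x[7], tolerance = 1e-6)
})

test_that("chained-equations imputation beats column-mean imputation under MCAR", {
  set.seed(99)
  n <- 200
  z <- stats::rnorm(n)
  truth <- cbind(a = z + stats::rnorm(n, 0, 0.3),
                 b = 2 * z + stats::rnorm(n, 0, 0.3),
                 c = -z + stats::rnorm(n, 0, 0.3),
                 d = stats::rnorm(n))
  masked <- truth
  mask <- matrix(stats::runif(length(truth)) < 0.05, n, 4)
  masked[mask] <- NA
  imp <- impute_missing(masked)
  mean_fill <- masked
  for (j in 1:4) mean_fill[is.na(masked[, j]), j] <-
      mean(masked[, j], na.rm = TRUE)
  err_chain <- mean(abs(imp[mask] - truth[mask]))
  err_mean <- mean(abs(mean_fill[mask] - truth[mask]))
  expect_lt(err_chain, err_mean)
})

test_that("imputation rejects near-empty columns by name", {
  m <- matrix(stats::rnorm(40), 20, 2, dimnames = list(NULL, c("ok", "bad")))
  m[, "bad"] <- NA
  m[1, "bad"] <- 1
  expect_error(impute_missing(m), "bad")
})

test_that("2-D embedding is deterministic and maps duplicates together", {
  set.seed(3)
  m <- matrix(stats::rnorm(40 * 6), 40, 6)
  m[2, ] <- m[1, ]   # exact duplicate rows
  c1 <- embed_2d(m, n_neighbors = 8)
  c2 <- embed_2d(m, n_neighbors = 8)
  expect_identical(c1, c2)
  expect_identical(dim(c1), c(40L, 2L))
  expect_lt(sqrt(sum((c1[1, ] - c1[2, ])^2)), 1e-6)
})

test_that("embedding separates well-separated blobs (silhouette > 0.5)", {
  set.seed(8)
  blob1 <- matrix(stats::rnorm(25 * 5, 0, 1), 25, 5)
  blob2 <- matrix(stats::rnorm(25 * 5, 12, 1), 25, 5)
  coords <- embed_2d(rbind(blob1, blob2), n_neighbors = 10)
  sil <- oracle_silhouette(coords, rep(1:2, each = 25))
  expect_gt(sil, 0.5)
})

test_that("embedding rejects degenerate inputs with actionable errors", {
  m <- matrix(stats::rnorm(30), 15, 2)
  expect_error(embed_2d(m[1:5, ]), "at least 10")
  expect_error(embed_2d(m, n_neighbors = 20), "smaller neighborhood")
  m[3, 1] <- NA
  expect_error(embed_2d(m), "completed")
})

test_that("analysis dataset assembly wires target, features and labels", {
  f <- filter_records(default_records())
  ds <- build_analysis_dataset(f)
  expect_s3_class(ds, "analysis_dataset")
  expect_identical(nrow(ds$x), nrow(f))
  expect_false(any(is.na(ds$x)))
  expect_identical(ds$y, as.integer(f$afp > 5))
  expect_false("afp" %in% colnames(ds$x))
  expect_true(all(c("age_at_diagnosis", "age_at_control") %in% colnames(ds$x)))
  ds2 <- build_analysis_dataset(f, include_age = FALSE)
  expect_false(any(c("age_at_diagnosis", "age_at_control") %in% colnames(ds2$x)))
  expect_identical(ncol(ds2$x), 12L)
})
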