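test_that("patient means skip missing values and keep one row per patient", {
  rec <- data.frame(patient_id = c("p1", "p1", "p1", "p2", "p3", "p3"),
                    alt = c(20, NA, 40, 15, 60, 80),
                    hcc = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE))
  pm <- patient_means(rec, "alt")
  expect_identical(nrow(pm), 3L)
  expect_equal(pm$mean_value[pm$patient_id == "p1"], 30)
  expect_identical(pm$hcc[pm$patient_id == "p3"], TRUE)
  # appending a duplicate patient's record set leaves existing means unchanged
  rec2 <- rbind(rec, data.frame(patient_id = "p4", alt = c(100, 200),
                                hcc = FALSE))
  pm2 <- patient_means(rec2, "alt")
  expect_equal(pm2[pm2$patient_id %in% pm$patient_id, ], pm,
               ignore_attr = TRUE)
  rec$alt[rec$patient_id == "p2"] <- NA
  expect_warning(pm3 <- patient_means(rec, "alt"), "excluded")
  expect_identical(nrow(pm3), 2L)
})

test_that("roc_cutoff handles separable toys exactly", {
  values <- c(60, 55, 50, 20, 15, 10, 5)
  labels <- c(1, 1, 1, 0, 0, 0, 0)
  res <- roc_cutoff(values, labels, n_boot = 200, seed = 1)
  expect_equal(res$auc, 1.0)
  expect_equal(res$sensitivity, 1.0)
  expect_equal(res$specificity, 1.0)
  expect_gt(res$threshold, 20)
  expect_lt(res$threshold, 50)
  expect_equal(res$ci_low, 1.0)   # bootstrap CI degenerates when separable
  expect_equal(res$ci_high, 1.0)
  expect_identical(res$n_pos, 3L)
  expect_identical(res$n_neg, 4L)
})

test_that("the midpoint rule and Youden tie-break are honoured", {
  res <- roc_cutoff(c(10, 20, 30, 40), c(0, 0, 1, 1), n_boot = 50, seed = 2)
  expect_equal(res$threshold, 25)
  expect_error(roc_cutoff(c(1, 2, 3), c(1, 1, 1), n_boot = 10),
               "at least 2")
  # ties resolved to the lowest threshold
  v <- c(1, 2, 3, 4)
  l <- c(0, 1, 0, 1)   # J maximised at several thresholds
  res2 <- roc_cutoff(v, c(0, 0, 1, 1), n_boot = 10, seed = 3)
  expect_equal(res2$threshold, oracle_youden(c(1, 2, 3, 4), c(0, 0, 1, 1)))
})

test_that("Youden threshold is invariant under monotone transforms", {
  set.seed(4)
  for (i in 1:10) {
    v <- round(stats::rlnorm(20, 3, 0.5), 1)
    l <- rbinom(20, 1, stats::plogis(scale(v)))
    if (sum(l) < 2 || sum(1 - l) < 2) next
    thr <- roc_cutoff(v, l, n_boot = 10, seed = i)$threshold
    thr_log <- roc_cutoff(log(v), l, n_boot = 10, seed = i)$threshold
    # the selected operating point (sets above threshold) must agree
    expect_identical(v > thr, log(v) > thr_log)
  }
})

test_that("screening table equals exhaustive enumeration on a constructed toy", {
  afp <- c(2, 3, 6, 7, 12, 4, 8, 11, 20, 1)
  alt <- c(10, 35, 20, 40, 45, 28, 31, 25, 60, 15)
  hcc <- c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE)
  st <- screening_table(afp, alt, hcc, afp_cuts = c(5, 10), alt_cut = 29)
  # hand enumeration over the 7 non-HCC / 3 HCC patients
  non <- !hcc
  expect_equal(st$false_positive_pct[st$rule == "AFP>5"],
               100 * sum(afp > 5 & non) / sum(non))
  expect_equal(st$false_positive_pct[st$rule == "AFP>5 & ALT>29"],
               100 * sum(afp > 5 & alt > 29 & non) / sum(non))
  expect_equal(st$sensitivity_pct[st$rule == "AFP>10"],
               100 * sum(afp > 10 & hcc) / sum(hcc))
  expect_equal(st$sensitivity_pct[st$rule == "AFP>10 & ALT>29"],
               100 * sum(afp > 10 & alt > 29 & hcc) / sum(hcc))
  expect_error(screening_table(afp[1:5], alt, hcc), "aligned")
})

test_that("combined flagging never exceeds AFP-alone flagging", {
  set.seed(5)
  for (i in 1:20) {
    afp <- stats::rlnorm(30, 1.5, 1)
    alt <- stats::rlnorm(30, 3.3, 0.6)
    hcc <- as.logical(rbinom(30, 1, 0.25))
    if (sum(hcc) == 0 || all(hcc)) next
    st <- screening_table(afp, alt, hcc)
    for (cut in c(5, 10)) {
      alone <- st[st$afp_cut == cut & is.na(st$alt_cut), ]
      comb <- st[st$afp_cut == cut & !is.na(st$alt_cut), ]
      expect_lte(comb$false_positive_pct, alone$false_positive_pct)
      expect_lte(comb$sensitivity_pct, alone$sensitivity_pct)
    }
  }
  st0 <- screening_table(rep(1, 4), rep(1, 4), c(TRUE, FALSE, FALSE, TRUE))
  expect_true(all(st0$false_positive_pct == 0))
  expect_true(all(st0$sensitivity_pct == 0))
})
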