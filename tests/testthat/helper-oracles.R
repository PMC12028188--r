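# Independent brute-force oracles and fixture builders shared across tests.
# Each oracle deliberately takes a different computational path from the
# package implementation it checks.

# O(n^2) pair-counting AUROC: P(score+ > score-) + 0.5 P(tie).
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Mid-ranks computed from sort positions (no call to rank()).
oracle_midrank <- function(x) {
  n <- length(x)
  ord <- order(x)
  r <- numeric(n)
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && x[ord[j + 1]] == x[ord[i]]) j <- j + 1
    r[ord[i:j]] <- mean(i:j)
    i <- j + 1
  }
  r
}

# Rank-then-Pearson Spearman via explicit sum formulas.
oracle_spearman <- function(x, y) {
  rx <- oracle_midrank(x)
  ry <- oracle_midrank(y)
  n <- length(x)
  num <- sum(rx * ry) - n * mean(rx) * mean(ry)
  den <- sqrt((sum(rx^2) - n * mean(rx)^2) * (sum(ry^2) - n * mean(ry)^2))
  num / den
}

# Tie-corrected Kruskal-Wallis H via the variance-ratio identity
# H = (N-1) * sum_i n_i (Rbar_i - Rbar)^2 / sum_ij (r_ij - Rbar)^2.
oracle_kruskal_h <- function(values, groups) {
  r <- oracle_midrank(values)
  rbar <- mean(r)
  num <- sum(tapply(r, groups, function(g) length(g) * (mean(g) - rbar)^2))
  den <- sum((r - rbar)^2)
  if (den == 0) 0 else (length(values) - 1) * num / den
}

# Exhaustive Youden scan over all strict thresholds (every midpoint plus
# sentinels), returning the lowest maximiser.
oracle_youden <- function(values, labels) {
  u <- sort(unique(values))
  cand <- if (length(u) > 1) (u[-length(u)] + u[-1]) / 2 else u
  js <- vapply(cand, function(thr) {
    mean(values[labels == 1] > thr) + mean(values[labels == 0] <= thr) - 1
  }, numeric(1))
  cand[which(js >= max(js) - 1e-12)][1]
}

# Loop-and-accumulate corrected importance.
oracle_corrected <- function(shaps, aucs) {
  acc <- numeric(length(shaps[[1]]))
  for (m in seq_along(shaps)) acc <- acc + shaps[[m]] * aucs[m]
  acc / length(shaps)
}

# Double-loop Euclidean distance matrix.
oracle_euclidean <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) d[i, j] <- sqrt(sum((m[i, ] - m[j, ])^2))
  }
  d
}

# Mean silhouette width for a 2-group labelling of points (rows).
oracle_silhouette <- function(coords, labels) {
  d <- oracle_euclidean(coords)
  n <- nrow(coords)
  s <- vapply(seq_len(n), function(i) {
    same <- labels == labels[i]
    a <- mean(d[i, same & seq_len(n) != i])
    b <- min(tapply(d[i, !same], labels[!same], mean))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

# Tiny hand-rolled visit-record table for filter/binarize tests.
make_manual_records <- function() {
  template <- function(id, co, afp = 3, suac = FALSE) {
    data.frame(patient_id = id, cohort = co, age_at_diagnosis = 10,
               age_at_control = 20, hcc = FALSE, ntbc = 30, afp = afp,
               phe = 50, met = 20, tyr = 300, alt = 25, ast = 30, ggt = 20,
               prothrombin_time = 1, total_bilirubin = 0.4,
               alkaline_phosphatase = 200, glycemia = 90,
               suac_detected = suac, stringsAsFactors = FALSE)
  }
  rbind(template("P1", "A"), template("P2", "A", afp = 8),
        template("P3", "B"))
}

# Synthetic model rounds with fixed SHAP/AUROC content.
make_fake_round <- function(shap, auc, cohort = "internal") {
  structure(list(hyperparams = structure(list(), class = "hyperparams"),
                 auroc_by_testset = stats::setNames(list(auc), cohort),
                 shap_by_testset = stats::setNames(list(shap), cohort),
                 n_trees = 1L, seed = NULL, round_id = 1L),
            class = "model_round")
}

fake_result <- function(rounds) {
  structure(list(rounds = rounds, retention = 1, status = "ok"),
            class = "multimodel_result")
}

# Default-config cohorts shared by several test files (generation is fast
# and deterministic, so each caller regenerates rather than caching).
default_records <- function(seed = 1L) {
  generate_cohorts(synthetic_config(seed = seed))
}
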