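# Univariate statistical screen: Spearman correlation against AFP,
# Kruskal-Wallis with Dunn's post hoc for cohort comparisons, and the
# Anderson-Darling normality check that motivates rank-based methods.

#' Spearman rank correlation with t-approximate p-value
#'
#' Mid-ranks (average ranks for ties) are correlated with Pearson's
#' formula; the two-sided p-value uses the t approximation with n - 2
#' degrees of freedom. Pairs with a missing value in either vector are
#' dropped (pairwise deletion).
#'
#' @param x,y numeric vectors of equal length.
#' @return list with `rho`, `p_value` and `n` (retained pairs).
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("Spearman correlation undefined for a constant vector", call. = FALSE)
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}

#' Univariate association screen of follow-up variables against AFP
#'
#' Computes the Spearman correlation of every continuous follow-up
#' variable (the 13 modeled variables minus AFP and the binary SUAC
#' indicator) with the AFP concentration, using pairwise deletion so each
#' row reports its own sample size. Rows are ordered by descending rho.
#'
#' @param records visit-record data.frame (pre-imputation values).
#' @param variables optional character vector overriding the screened set.
#' @return data.frame with columns `variable`, `rho`, `p_value`, `n` and a
#'   `significant` flag at alpha = 0.05.
#' @export
association_screen <- function(records, variables = NULL) {
  if (is.null(variables))
    variables <- setdiff(model_variables(), c("afp", "suac_detected"))
  rows <- lapply(variables, function(v) {
    r <- spearman_cor(records[[v]], records$afp)
    data.frame(variable = v, rho = r$rho, p_value = r$p_value, n = r$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p_value < 0.05
  out <- out[order(-out$rho), ]
  rownames(out) <- NULL
  out
}

#' Kruskal-Wallis omnibus test with Dunn's post hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square p-value, followed by
#' Dunn z-statistics for all group pairs with Bonferroni adjustment (the
#' conservative default).
#'
#' @param values numeric vector of observations.
#' @param groups group labels, at least 2 groups.
#' @param p_adjust multiplicity adjustment passed to [stats::p.adjust()].
#' @return list with `H`, `df`, `p_value` and a `posthoc` data.frame
#'   (`group1`, `group2`, `z`, `p_value`, `p_adjusted`).
#' @export
compare_groups <- function(values, groups, p_adjust = "bonferroni") {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- factor(groups[ok])
  k <- nlevels(groups)
  n <- length(values)
  stopifnot(k >= 2, n >= 5)
  r <- rank(values)
  ni <- tabulate(groups)
  rbar <- tapply(r, groups, mean)
  h_raw <- 12 / (n * (n + 1)) * sum(ni * rbar^2) - 3 * (n + 1)
  ties <- table(values)
  tie_sum <- sum(ties^3 - ties)
  corr <- 1 - tie_sum / (n^3 - n)
  if (corr <= 0) {  # every observation identical
    H <- 0
    p <- 1
  } else {
    H <- h_raw / corr
    if (abs(H) < 1e-12) H <- 0
    p <- stats::pchisq(H, df = k - 1, lower.tail = FALSE)
  }
  pairs <- utils::combn(levels(groups), 2)
  sigma2 <- n * (n + 1) / 12 - tie_sum / (12 * (n - 1))
  post <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt(sigma2 * (1 / ni[which(levels(groups) == i)] +
                         1 / ni[which(levels(groups) == j)]))
    z <- if (se > 0) (rbar[[i]] - rbar[[j]]) / se else 0
    c(z = z, p = 2 * stats::pnorm(-abs(z)))
  })
  posthoc <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                        z = post["z", ], p_value = post["p", ],
                        stringsAsFactors = FALSE)
  posthoc$p_adjusted <- stats::p.adjust(posthoc$p_value, method = p_adjust)
  list(H = H, df = k - 1, p_value = p, posthoc = posthoc)
}

#' Anderson-Darling normality check
#'
#' A-squared against the normal family with estimated mean and variance,
#' small-sample adjusted (A* = A^2 (1 + 0.75/n + 2.25/n^2)), with the
#' Stephens/D'Agostino piecewise p-value approximation. A failed check is
#' the signal to default to rank-based methods downstream.
#'
#' @param x numeric vector, n >= 8.
#' @param alpha significance level for the pass/fail verdict.
#' @return list with `A2` (adjusted statistic), `p_value` and `pass`.
#' @export
normality_check <- function(x, alpha = 0.05) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 8) stop("need at least 8 observations", call. = FALSE)
  s <- stats::sd(x)
  if (s == 0) stop("normality check undefined for a constant vector",
                   call. = FALSE)
  z <- sort((x - mean(x)) / s)
  u <- pmin(pmax(stats::pnorm(z), 1e-12), 1 - 1e-12)
  i <- seq_len(n)
  a2 <- -n - mean((2 * i - 1) * (log(u) + log(1 - rev(u))))
  a2s <- a2 * (1 + 0.75 / n + 2.25 / n^2)
  p <- if (a2s >= 0.6) {
    exp(1.2937 - 5.709 * a2s + 0.0186 * a2s^2)
  } else if (a2s >= 0.34) {
    exp(0.9177 - 4.279 * a2s - 1.38 * a2s^2)
  } else if (a2s > 0.2) {
    1 - exp(-8.318 + 42.796 * a2s - 59.938 * a2s^2)
  } else {
    1 - exp(-13.436 + 101.14 * a2s - 223.73 * a2s^2)
  }
  p <- min(max(p, 0), 1)
  list(A2 = a2s, p_value = p, pass = p > alpha)
}
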