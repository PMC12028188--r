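# Corrected importance (per-model mean-|SHAP| weighted by that model's
# test AUROC, averaged over retained models), per-cohort variable rankings,
# and cross-cohort hierarchical consensus clustering of importance profiles.

.retained_rounds <- function(result) {
  if (inherits(result, "multimodel_result")) {
    if (identical(result$status, "empty") || length(result$rounds) == 0L)
      stop("no retained model rounds: refusing to rank on an empty ensemble",
           call. = FALSE)
    result$rounds
  } else if (is.list(result)) {
    if (length(result) == 0L)
      stop("no retained model rounds: refusing to rank on an empty ensemble",
           call. = FALSE)
    result
  } else {
    stop("expected a multimodel_result or a list of model rounds",
         call. = FALSE)
  }
}

# rounds x variables matrix of per-round corrected importance for a cohort
.per_round_corrected <- function(rounds, cohort) {
  keep <- vapply(rounds, function(r) {
    !is.null(r$shap_by_testset[[cohort]]) &&
      !is.na(r$auroc_by_testset[[cohort]])
  }, logical(1))
  rounds <- rounds[keep]
  if (length(rounds) == 0L)
    stop(sprintf("no retained rounds carry results for cohort '%s'", cohort),
         call. = FALSE)
  p <- length(rounds[[1]]$shap_by_testset[[cohort]])
  vals <- vapply(rounds,
                 function(r) r$shap_by_testset[[cohort]] * r$auroc_by_testset[[cohort]],
                 numeric(p))
  mat <- if (p == 1L) matrix(vals, ncol = 1L) else t(vals)
  colnames(mat) <- names(rounds[[1]]$shap_by_testset[[cohort]])
  mat
}

#' Corrected importance of each variable for one cohort
#'
#' For each variable v, the mean over retained rounds m of
#' `shap(v, m, cohort) * auroc(m, cohort)`: SHAP importance discounted by
#' the performance of the model it came from.
#'
#' @param result a `multimodel_result` (or list of `model_round`s).
#' @param cohort test-set name (`"internal"` or an external cohort label).
#' @return named numeric vector of corrected importances (>= 0).
#' @export
corrected_importance <- function(result, cohort = "internal") {
  rounds <- .retained_rounds(result)
  colMeans(.per_round_corrected(rounds, cohort))
}

#' Corrected-importance table across cohorts
#'
#' @param result a `multimodel_result`.
#' @param cohorts test-set names; defaults to every test set present in the
#'   first retained round.
#' @return variables x cohorts matrix of class `importance_table` with an
#'   `n_models` attribute (retained-model count per cohort).
#' @export
importance_table <- function(result, cohorts = NULL) {
  rounds <- .retained_rounds(result)
  if (is.null(cohorts)) cohorts <- names(rounds[[1]]$shap_by_testset)
  cols <- lapply(cohorts, function(co) corrected_importance(rounds, co))
  n_models <- vapply(cohorts, function(co) {
    sum(vapply(rounds, function(r) !is.na(r$auroc_by_testset[[co]]),
               logical(1)))
  }, integer(1))
  tab <- do.call(cbind, cols)
  colnames(tab) <- cohorts
  structure(tab, n_models = n_models, class = c("importance_table", "matrix"))
}

#' Rank variables by corrected importance within a cohort
#'
#' Descending order; exact ties are broken alphabetically and flagged.
#'
#' @param table an `importance_table` (or plain matrix).
#' @param cohort column to rank on.
#' @return data.frame with `rank`, `variable`, `corrected_importance`,
#'   `tied`.
#' @export
rank_variables <- function(table, cohort = "internal") {
  if (!cohort %in% colnames(table))
    stop(sprintf("cohort '%s' not present in the importance table", cohort),
         call. = FALSE)
  v <- table[, cohort]
  ord <- order(-v, names(v))
  tied <- duplicated(v[ord]) | duplicated(v[ord], fromLast = TRUE)
  data.frame(rank = seq_along(ord),
             variable = names(v)[ord],
             corrected_importance = unname(v[ord]),
             tied = tied,
             stringsAsFactors = FALSE)
}

#' Pairwise tests on per-model corrected-importance distributions
#'
#' For every variable pair, a two-sided Mann-Whitney rank-sum test on the
#' per-retained-model corrected-importance samples, with multiplicity
#' adjustment (Bonferroni by default). The result is a symmetric matrix of
#' adjusted p-values.
#'
#' @param result a `multimodel_result` with >= 2 retained rounds.
#' @param cohort test-set name.
#' @param p_adjust adjustment method for [stats::p.adjust()].
#' @return symmetric variables x variables matrix of adjusted p-values
#'   (diagonal `NA`).
#' @export
compare_importance_distributions <- function(result, cohort = "internal",
                                             p_adjust = "bonferroni") {
  rounds <- .retained_rounds(result)
  samples <- .per_round_corrected(rounds, cohort)
  if (nrow(samples) < 2L)
    stop("need at least 2 retained rounds to compare distributions",
         call. = FALSE)
  vars <- colnames(samples)
  p <- ncol(samples)
  raw <- matrix(NA_real_, p, p, dimnames = list(vars, vars))
  for (i in seq_len(p - 1)) {
    for (j in seq.int(i + 1, p)) {
      pv <- if (isTRUE(all.equal(samples[, i], samples[, j]))) 1 else
        suppressWarnings(stats::wilcox.test(samples[, i], samples[, j],
                                            exact = FALSE)$p.value)
      raw[i, j] <- raw[j, i] <- pv
    }
  }
  adj <- raw
  upper <- upper.tri(raw)
  adj[upper] <- stats::p.adjust(raw[upper], method = p_adjust)
  adj[lower.tri(adj)] <- t(adj)[lower.tri(adj)]
  adj
}

#' Consensus clustering of variables on their cohort importance profiles
#'
#' Agglomerative clustering of the rows of the corrected-importance table
#' (Euclidean distance, average linkage by default), flat labels at a
#' configured cut, and the top cluster: the flat cluster with the greatest
#' mean corrected importance. Raw (unstandardised) importances are
#' clustered so that "highly important" forms a high-valued cluster.
#'
#' @param table an `importance_table` (variables x cohorts).
#' @param k number of flat clusters to cut.
#' @param linkage linkage method for [stats::hclust()].
#' @return list of class `consensus_clusters` with `hclust`, `flat_labels`,
#'   `top_cluster` (variable names), `newick`.
#' @export
consensus_cluster <- function(table, k = 2L, linkage = "average") {
  stopifnot(nrow(table) >= 2L, ncol(table) >= 2L)
  tab <- unclass(table)
  if (all(tab == 0)) {
    warning("degenerate all-zero importance table: single cluster",
            call. = FALSE)
    labels <- stats::setNames(rep(1L, nrow(tab)), rownames(tab))
    return(structure(list(hclust = NULL, flat_labels = labels,
                          top_cluster = rownames(tab), newick = NULL),
                     class = "consensus_clusters"))
  }
  hc <- stats::hclust(stats::dist(tab, method = "euclidean"),
                      method = linkage)
  k <- min(k, nrow(tab))
  labels <- stats::cutree(hc, k = k)
  means <- tapply(rowMeans(tab), labels, mean)
  top <- names(labels)[labels == as.integer(names(which.max(means)))]
  newick <- ape::write.tree(ape::as.phylo(hc))
  structure(list(hclust = hc, flat_labels = labels, top_cluster = top,
                 newick = newick),
            class = "consensus_clusters")
}
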