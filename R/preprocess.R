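# Record eligibility filtering, AFP binarization, chained-equations
# imputation, and 2-D embedding of cohorts.

#' Filter visit records for analysis eligibility
#'
#' A record is retained when it holds at least `min_completeness` of the 15
#' modeled variables (13 biochemical plus the two ages) and has observed
#' values for both AFP and SUAC.
#'
#' @param records visit-record data.frame.
#' @param min_completeness minimum fraction of modeled variables present,
#'   in (0, 1].
#' @return the retained records; filtering is idempotent and only removes
#'   rows. An empty input yields an empty output; removing every record
#'   raises a warning.
#' @export
filter_records <- function(records, min_completeness = 0.7) {
  stopifnot(min_completeness > 0, min_completeness <= 1)
  if (nrow(records) == 0L) return(records)
  vars <- intersect(model_variables(), names(records))
  present <- rowSums(!is.na(records[, vars, drop = FALSE]))
  keep <- present / length(vars) >= min_completeness &
    !is.na(records$afp) & !is.na(records$suac_detected)
  if (!any(keep))
    warning("all records removed by eligibility filtering", call. = FALSE)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "config") <- attr(records, "config")
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Binarize AFP into normal/altered status
#'
#' Status is altered (1) when AFP strictly exceeds the threshold and normal
#' (0) otherwise; a value exactly at the threshold is classed as normal.
#'
#' @param afp positive AFP concentration(s) in ng/mL.
#' @param threshold decision threshold in ng/mL.
#' @return integer vector of 0/1 statuses.
#' @export
binarize_afp <- function(afp, threshold = 5) {
  if (any(is.na(afp)))
    stop("missing AFP values cannot be binarized; filter records first",
         call. = FALSE)
  if (any(afp <= 0))
    stop("AFP must be strictly positive", call. = FALSE)
  as.integer(afp > threshold)
}

#' Impute missing cells by chained equations
#'
#' Round-robin iterative imputation: each incomplete column is regressed
#' (ridge-stabilised least squares with intercept, on standardised scale)
#' on all other columns, missing cells are replaced by predictions, and the
#' sweep repeats until the largest absolute change of an imputed cell on
#' the standardised scale falls below `tol` or `max_iter` sweeps are done.
#' Observed cells are returned bit-identical. The procedure involves no
#' randomness and is therefore trivially reproducible; `seed` is accepted
#' for interface stability.
#'
#' @param x numeric matrix (records x features) with `NA` for missing.
#' @param seed unused; kept so callers can treat imputation like the other
#'   seeded stages.
#' @param tol convergence tolerance on the standardised scale.
#' @param max_iter maximum number of round-robin sweeps.
#' @return completed numeric matrix.
#' @export
impute_missing <- function(x, seed = 1L, tol = 1e-3, max_iter = 10L) {
  x <- as.matrix(x)
  if (!any(is.na(x))) return(x)
  p <- ncol(x)
  obs <- !is.na(x)
  n_obs <- colSums(obs)
  if (any(n_obs < 2)) {
    bad <- colnames(x)[n_obs < 2] %||% which(n_obs < 2)
    stop(sprintf("column(s) with fewer than 2 observed values: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  mu <- colMeans(x, na.rm = TRUE)
  sd0 <- apply(x, 2, stats::sd, na.rm = TRUE)
  sd0[!is.finite(sd0) | sd0 == 0] <- 1
  z <- sweep(sweep(x, 2, mu), 2, sd0, "/")
  for (j in seq_len(p)) z[!obs[, j], j] <- 0  # mean-initialise

  incomplete <- order(colSums(!obs))
  incomplete <- incomplete[colSums(!obs)[incomplete] > 0]
  ridge <- 1e-6
  for (iter in seq_len(max_iter)) {
    delta <- 0
    for (j in incomplete) {
      miss <- !obs[, j]
      pred <- cbind(1, z[, -j, drop = FALSE])
      a <- pred[obs[, j], , drop = FALSE]
      xtx <- crossprod(a) + diag(ridge, ncol(a))
      beta <- solve(xtx, crossprod(a, z[obs[, j], j]))
      new_vals <- drop(pred[miss, , drop = FALSE] %*% beta)
      delta <- max(delta, max(abs(new_vals - z[miss, j])))
      z[miss, j] <- new_vals
    }
    if (delta < tol) break
  }
  out <- sweep(sweep(z, 2, sd0, "*"), 2, mu, "+")
  out[obs] <- x[obs]  # observed cells bit-identical
  out
}

#' Embed records in two dimensions for cohort visualization
#'
#' Deterministic nonlinear spectral embedding: a symmetrised k-nearest-
#' neighbour graph with self-tuning Gaussian affinities is built on the
#' standardised feature matrix, and the two non-trivial bottom eigenvectors
#' of its symmetric normalised Laplacian are returned as coordinates. A
#' linear PCA variant is available via `method = "pca"`. The output is for
#' visualising cohort overlap only and is never fed downstream.
#'
#' @param x completed numeric matrix, at least 10 records, no missing cells.
#' @param seed unused (the embedding is deterministic); kept for interface
#'   stability with stochastic embedders.
#' @param n_neighbors neighbourhood size of the kNN graph.
#' @param method `"spectral"` (default) or `"pca"`.
#' @return records x 2 coordinate matrix.
#' @export
embed_2d <- function(x, seed = 1L, n_neighbors = 15L,
                     method = c("spectral", "pca")) {
  method <- match.arg(method)
  x <- as.matrix(x)
  if (any(is.na(x))) stop("embedding requires a completed matrix", call. = FALSE)
  n <- nrow(x)
  if (n < 10L) stop("need at least 10 records to embed", call. = FALSE)
  if (n_neighbors >= n)
    stop(sprintf(paste("n_neighbors (%d) must be smaller than the record",
                       "count (%d); choose a smaller neighborhood"),
                 n_neighbors, n), call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  sds[sds == 0] <- 1
  z <- sweep(sweep(x, 2, colMeans(x)), 2, sds, "/")
  if (method == "pca") {
    pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
    coords <- pc$x[, 1:2, drop = FALSE]
  } else {
    d <- as.matrix(stats::dist(z))
    sigma <- apply(d, 1, function(r) sort(r)[n_neighbors + 1L])
    sigma <- pmax(sigma, 1e-8)
    w <- exp(-d^2 / outer(sigma, sigma))
    nn <- t(apply(d, 1, function(r) rank(r, ties.method = "first") <= n_neighbors + 1L))
    adj <- (nn | t(nn)) * w
    diag(adj) <- 0
    deg <- pmax(rowSums(adj), 1e-12)
    lsym <- diag(n) - sweep(sweep(adj, 1, sqrt(deg), "/"), 2, sqrt(deg), "/")
    eig <- eigen(lsym, symmetric = TRUE)
    coords <- eig$vectors[, c(n - 1L, n - 2L), drop = FALSE]
  }
  # deterministic sign convention: largest-magnitude entry positive
  for (k in 1:2) {
    i <- which.max(abs(coords[, k]))
    if (coords[i, k] < 0) coords[, k] <- -coords[, k]
  }
  colnames(coords) <- c("dim1", "dim2")
  coords
}

#' Assemble the modelling dataset from filtered records
#'
#' Builds the continuous feature matrix (imputing missing biomarker cells
#' by chained equations), appends the binary SUAC indicator, binarizes AFP
#' into the target, and carries cohort labels, patient ids and HCC flags.
#' AFP itself never enters the feature matrix.
#'
#' @param records filtered visit records (AFP and SUAC observed everywhere).
#' @param afp_threshold AFP binarization threshold in ng/mL.
#' @param include_age include the two age variables as features.
#' @param impute impute remaining missing biomarker cells.
#' @return an object of class `analysis_dataset`: list with `x`, `y`,
#'   `feature_names`, `cohort`, `patient_id`, `hcc`.
#' @export
build_analysis_dataset <- function(records, afp_threshold = 5,
                                   include_age = TRUE, impute = TRUE) {
  if (any(is.na(records$afp)) || any(is.na(records$suac_detected)))
    stop("records must be filtered before dataset assembly", call. = FALSE)
  cont <- setdiff(biomarker_variables(), c("afp", "suac_detected"))
  if (include_age) cont <- c(cont, "age_at_diagnosis", "age_at_control")
  x <- as.matrix(records[, cont, drop = FALSE])
  if (impute && any(is.na(x))) x <- impute_missing(x)
  x <- cbind(x, suac_detected = as.numeric(records$suac_detected))
  structure(list(x = x,
                 y = binarize_afp(records$afp, afp_threshold),
                 feature_names = colnames(x),
                 cohort = as.character(records$cohort),
                 patient_id = as.character(records$patient_id),
                 hcc = as.logical(records$hcc)),
            class = "analysis_dataset")
}

#' Restrict an analysis dataset to a subset of rows
#' @param dataset an `analysis_dataset`.
#' @param idx integer or logical row index.
#' @return the subsetted `analysis_dataset`.
#' @export
subset_dataset <- function(dataset, idx) {
  structure(list(x = dataset$x[idx, , drop = FALSE],
                 y = dataset$y[idx],
                 feature_names = dataset$feature_names,
                 cohort = dataset$cohort[idx],
                 patient_id = dataset$patient_id[idx],
                 hcc = dataset$hcc[idx]),
            class = "analysis_dataset")
}
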