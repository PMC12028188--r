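# Per-patient aggregation, ROC-derived biomarker cut-off for HCC
# discrimination with a bootstrap confidence interval, and the combined
# AFP+ALT screening table.

#' Per-patient mean of a follow-up variable
#'
#' Arithmetic mean of each patient's non-missing values of `variable`, one
#' row per patient, with the patient-level HCC label carried through.
#' Patients with no observed value are excluded with a warning.
#'
#' @param records visit-record data.frame.
#' @param variable column name to aggregate.
#' @return data.frame with `patient_id`, `mean_value`, `hcc`.
#' @export
patient_means <- function(records, variable = "alt") {
  stopifnot(variable %in% names(records))
  ids <- unique(records$patient_id)
  rows <- lapply(ids, function(pid) {
    sub <- records[records$patient_id == pid, ]
    v <- sub[[variable]]
    if (all(is.na(v))) return(NULL)
    data.frame(patient_id = pid, mean_value = mean(v, na.rm = TRUE),
               hcc = sub$hcc[1], stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0)
    warning(sprintf("%d patient(s) had no observed '%s' value and were excluded",
                    dropped, variable), call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Youden-optimal strict (>) threshold over midpoints of sorted unique values.
.youden_threshold <- function(values, labels) {
  u <- sort(unique(values))
  cand <- if (length(u) > 1) (u[-length(u)] + u[-1]) / 2 else u
  best <- c(threshold = cand[1], j = -Inf, sens = NA, spec = NA)
  for (thr in cand) {
    flag <- values > thr
    sens <- mean(flag[labels == 1])
    spec <- mean(!flag[labels == 0])
    j <- sens + spec - 1
    if (j > best["j"] + 1e-12) best <- c(threshold = thr, j = j,
                                         sens = sens, spec = spec)
  }
  best
}

#' ROC-derived optimal cut-off with bootstrap confidence interval
#'
#' AUROC by rank statistic; candidate thresholds are the midpoints between
#' consecutive sorted unique values; the optimal threshold maximises the
#' Youden index J = sensitivity + specificity - 1 (ties resolved to the
#' lowest threshold); the 95% CI for the AUC comes from a class-stratified
#' patient-level percentile bootstrap.
#'
#' @param values per-patient mean values of the biomarker.
#' @param labels patient-level outcome (e.g. HCC), both classes present
#'   with at least 2 patients each.
#' @param n_boot bootstrap resamples.
#' @param seed integer seed for the bootstrap.
#' @param conf confidence level.
#' @return list of class `cutoff_result`: `threshold`, `sensitivity`,
#'   `specificity`, `youden_j`, `auc`, `ci_low`, `ci_high`, `n_pos`,
#'   `n_neg`.
#' @export
roc_cutoff <- function(values, labels, n_boot = 2000L, seed = 1L,
                       conf = 0.95) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(values) == length(labels), !any(is.na(values)))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos < 2L || n_neg < 2L)
    stop("need at least 2 patients per class", call. = FALSE)
  auc <- auroc(values, labels)
  best <- .youden_threshold(values, labels)
  set.seed(seed)
  pos_idx <- which(labels == 1L)
  neg_idx <- which(labels == 0L)
  boots <- vapply(seq_len(n_boot), function(b) {
    idx <- c(sample(pos_idx, n_pos, replace = TRUE),
             sample(neg_idx, n_neg, replace = TRUE))
    auroc(values[idx], labels[idx])
  }, numeric(1))
  qs <- stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        names = FALSE, type = 7)
  structure(list(threshold = unname(best["threshold"]),
                 sensitivity = unname(best["sens"]),
                 specificity = unname(best["spec"]),
                 youden_j = unname(best["j"]),
                 auc = auc, ci_low = qs[1], ci_high = qs[2],
                 n_pos = n_pos, n_neg = n_neg, n_boot = n_boot),
            class = "cutoff_result")
}

#' Combined AFP+ALT screening table
#'
#' For each AFP cut-off, a patient is flagged by the AFP-alone rule when
#' mean AFP strictly exceeds the cut, and by the combined rule when mean
#' AFP exceeds the cut AND mean ALT strictly exceeds `alt_cut`. Reports the
#' flagged fraction among non-HCC patients (false-positive %) and among
#' HCC patients (sensitivity %) per rule.
#'
#' @param afp_means,alt_means aligned per-patient mean vectors.
#' @param labels patient-level HCC indicator, aligned.
#' @param afp_cuts AFP cut-offs in ng/mL.
#' @param alt_cut ALT cut-off in UI/L.
#' @return data.frame of class `screening_table` with one row per rule.
#' @export
screening_table <- function(afp_means, alt_means, labels,
                            afp_cuts = c(5, 10), alt_cut = 29) {
  if (length(afp_means) != length(alt_means) ||
      length(afp_means) != length(labels))
    stop("afp_means, alt_means and labels must be aligned", call. = FALSE)
  labels <- as.logical(labels)
  pct <- function(flag, sel) if (!any(sel)) NA_real_ else
    100 * mean(flag[sel])
  rows <- list()
  for (cut in afp_cuts) {
    afp_flag <- afp_means > cut
    comb_flag <- afp_flag & (alt_means > alt_cut)
    rows[[length(rows) + 1L]] <-
      data.frame(rule = sprintf("AFP>%g", cut), afp_cut = cut,
                 alt_cut = NA_real_,
                 false_positive_pct = pct(afp_flag, !labels),
                 sensitivity_pct = pct(afp_flag, labels))
    rows[[length(rows) + 1L]] <-
      data.frame(rule = sprintf("AFP>%g & ALT>%g", cut, alt_cut),
                 afp_cut = cut, alt_cut = alt_cut,
                 false_positive_pct = pct(comb_flag, !labels),
                 sensitivity_pct = pct(comb_flag, labels))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("screening_table", "data.frame")
  out
}
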