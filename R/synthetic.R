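# Synthetic longitudinal HT-1 follow-up cohorts.
#
# Three cohorts (A, B, C) emulate the structure of multicenter tyrosinemia
# type 1 follow-up data: cohort A is a symptomatically diagnosed cohort with
# quarterly visits, cohort B a late-diagnosed cohort with high HCC burden,
# cohort C a newborn-screening cohort diagnosed in the first days of life.
# Biomarkers are drawn from right-skewed log-normal distributions; a latent
# "AFP altered" state follows a logistic model on configurable covariate
# effects, and the AFP value is then drawn from the matching side of the
# 5 ng/mL threshold.

# Fixed generative scales (log-normal meanlog/sdlog) for the continuous
# biomarkers. Values bracket paediatric reference ranges; ALT/AST/GGT and
# alkaline phosphatase in UI/L, bilirubin mg/dL, glycemia mg/dL, amino acids
# umol/L, NTBC and prothrombin time unitless positive.
.biomarker_scales <- list(
  alt = c(log(30), 0.60),
  ast = c(log(35), 0.55),
  ggt = c(log(25), 0.70),
  alkaline_phosphatase = c(log(220), 0.45),
  prothrombin_time = c(log(1.05), 0.12),
  total_bilirubin = c(log(0.5), 0.50),
  glycemia = c(log(88), 0.10),
  phe = c(log(55), 0.35),
  tyr = c(log(350), 0.40),
  met = c(log(25), 0.45),
  ntbc = c(log(35), 0.50)
)

# Reference location/scale used to standardise log-ages in the latent model.
.age_scales <- list(age_at_diagnosis = c(log(12), 1.5),
                    age_at_control = c(log(60), 1.2))

#' Variable names of a visit record
#'
#' @return character vectors: `biomarker_variables()` the 13 biochemical
#'   variables (including AFP and SUAC), `model_variables()` the 15 modeled
#'   variables (biochemical plus the two age variables) used as the record
#'   completeness denominator.
#' @export
biomarker_variables <- function() {
  c("ntbc", "afp", "phe", "met", "tyr", "alt", "ast", "ggt",
    "prothrombin_time", "total_bilirubin", "alkaline_phosphatase",
    "glycemia", "suac_detected")
}

#' @rdname biomarker_variables
#' @export
model_variables <- function() {
  c(biomarker_variables(), "age_at_diagnosis", "age_at_control")
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults encode the stated world of the emulated study population:
#' 20/10/5 patients in cohorts A/B/C, diagnosis-age medians of roughly
#' 9 / 20 / 0.2 months, HCC prevalence 2/20, 6/10 and 0/5, per-cohort
#' missingness 3.05% / 4.62% / 7.07%, and succinylacetone detectable in
#' about 5% of visits. The default effect coefficients plant a positive
#' log-odds dependence of AFP alteration on ALT, alkaline phosphatase and
#' the two age variables, with all other biomarkers inert.
#'
#' @param cohort_sizes named integer vector, patients per cohort.
#' @param visits_per_patient named list of length-2 integer ranges
#'   (min, max) of visits per patient.
#' @param dx_age_params named list of c(meanlog, sdlog) for the log-normal
#'   diagnosis age in months.
#' @param effect_coefficients named numeric vector of log-odds weights on
#'   standardised log-scale covariates in the latent AFP-alteration model.
#' @param cohort_intercepts named numeric vector of per-cohort log-odds
#'   intercepts.
#' @param hcc_prevalence named numeric vector in [0, 1); the realised HCC
#'   patient count is `round(prevalence * size)`.
#' @param missingness_rates named numeric vector in [0, 1); fraction of
#'   biomarker cells masked completely at random per cohort.
#' @param suac_detect_prob probability in [0, 1] that SUAC is detected at a
#'   visit.
#' @param hcc_logodds_shift additive log-odds shift for records of HCC
#'   patients.
#' @param seed integer RNG seed; identical config and seed give
#'   bit-identical output.
#' @return a validated object of class `synthetic_config`.
#' @export
synthetic_config <- function(cohort_sizes = c(A = 20L, B = 10L, C = 5L),
                             visits_per_patient = list(A = c(5L, 9L),
                                                       B = c(4L, 7L),
                                                       C = c(6L, 9L)),
                             dx_age_params = list(A = c(log(9), 0.9),
                                                  B = c(log(20), 0.45),
                                                  C = c(log(0.25), 0.12)),
                             effect_coefficients = c(alt = 1.2,
                                                     alkaline_phosphatase = 1.0,
                                                     age_at_diagnosis = 0.8,
                                                     age_at_control = 0.4),
                             cohort_intercepts = c(A = 0.0, B = 1.0, C = -2.5),
                             hcc_prevalence = c(A = 0.10, B = 0.60, C = 0.0),
                             missingness_rates = c(A = 0.0305, B = 0.0462,
                                                   C = 0.0707),
                             suac_detect_prob = 0.05,
                             hcc_logodds_shift = 1.5,
                             seed = 1L) {
  cohorts <- c("A", "B", "C")
  fail <- function(field, why) {
    stop(sprintf("invalid synthetic_config field '%s': %s", field, why),
         call. = FALSE)
  }
  if (length(cohort_sizes) != 3L || any(cohort_sizes < 1L))
    fail("cohort_sizes", "need three cohorts with >= 1 patient each")
  names(cohort_sizes) <- cohorts
  for (co in cohorts) {
    rng <- visits_per_patient[[co]]
    if (is.null(rng) || length(rng) != 2L || rng[1] < 1L || rng[2] < rng[1])
      fail("visits_per_patient", sprintf("cohort %s needs a valid range", co))
  }
  coef_names <- setdiff(model_variables(), "afp")
  full_coefs <- stats::setNames(numeric(length(coef_names)), coef_names)
  if (length(effect_coefficients)) {
    unknown <- setdiff(names(effect_coefficients), coef_names)
    if (length(unknown))
      fail("effect_coefficients", paste("unknown variables:",
                                        paste(unknown, collapse = ", ")))
    full_coefs[names(effect_coefficients)] <- effect_coefficients
  }
  if (any(hcc_prevalence < 0 | hcc_prevalence >= 1))
    fail("hcc_prevalence", "must lie in [0, 1)")
  if (any(missingness_rates < 0 | missingness_rates >= 1))
    fail("missingness_rates", "must lie in [0, 1)")
  if (suac_detect_prob < 0 || suac_detect_prob > 1)
    fail("suac_detect_prob", "must lie in [0, 1]")
  if (length(seed) != 1L || is.na(seed))
    fail("seed", "must be a single integer")
  structure(list(cohort_sizes = cohort_sizes,
                 visits_per_patient = visits_per_patient,
                 dx_age_params = dx_age_params,
                 effect_coefficients = full_coefs,
                 cohort_intercepts = stats::setNames(cohort_intercepts, cohorts),
                 hcc_prevalence = stats::setNames(hcc_prevalence, cohorts),
                 missingness_rates = stats::setNames(missingness_rates, cohorts),
                 suac_detect_prob = suac_detect_prob,
                 hcc_logodds_shift = hcc_logodds_shift,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Truncated log-normal draw via inverse CDF, bounded to (lo, hi).
.rlnorm_trunc <- function(n, meanlog, sdlog, lo = 0, hi = Inf) {
  plo <- stats::plnorm(lo, meanlog, sdlog)
  phi <- stats::plnorm(hi, meanlog, sdlog)
  u <- stats::runif(n, plo, phi)
  stats::qlnorm(pmin(pmax(u, 1e-12), 1 - 1e-12), meanlog, sdlog)
}

#' Generate synthetic follow-up visit records
#'
#' Produces one row per outpatient visit across the three configured
#' cohorts. Covariates are drawn from right-skewed log-normal
#' distributions, a latent AFP-altered state from a logistic model with the
#' configured coefficients, and the AFP value conditionally below or above
#' 5 ng/mL. Missingness is applied completely at random to biomarker cells
#' (never to identifiers, ages, cohort or HCC flags) at the configured
#' per-cohort rate with an exact masked-cell count.
#'
#' @param config a [synthetic_config()].
#' @return a `data.frame` of visit records, one row per visit.
#' @export
generate_cohorts <- function(config) {
  if (!inherits(config, "synthetic_config"))
    config <- do.call(synthetic_config, as.list(config))
  set.seed(config$seed)
  cont_vars <- names(.biomarker_scales)
  out <- list()
  for (co in c("A", "B", "C")) {
    n_pat <- config$cohort_sizes[[co]]
    n_hcc <- round(config$hcc_prevalence[[co]] * n_pat)
    hcc_ids <- if (n_hcc > 0) sample.int(n_pat, n_hcc) else integer(0)
    vr <- config$visits_per_patient[[co]]
    dxp <- config$dx_age_params[[co]]
    rows <- list()
    for (i in seq_len(n_pat)) {
      n_vis <- if (vr[1] == vr[2]) vr[1] else
        sample(seq.int(vr[1], vr[2]), 1L)
      dx_age <- .rlnorm_trunc(1, dxp[1], dxp[2], lo = 0.2)
      rec <- data.frame(patient_id = sprintf("%s%02d", co, i),
                        cohort = co,
                        age_at_diagnosis = dx_age,
                        age_at_control = dx_age + 3 * seq_len(n_vis),
                        hcc = i %in% hcc_ids,
                        stringsAsFactors = FALSE)
      for (v in cont_vars) {
        sc <- .biomarker_scales[[v]]
        rec[[v]] <- stats::rlnorm(n_vis, sc[1], sc[2])
      }
      rec$suac_detected <- stats::runif(n_vis) < config$suac_detect_prob
      rows[[i]] <- rec
    }
    cohort_df <- do.call(rbind, rows)

    # latent AFP-altered status from the configured logistic model
    beta <- config$effect_coefficients
    lp <- rep(config$cohort_intercepts[[co]], nrow(cohort_df))
    for (v in cont_vars) {
      sc <- .biomarker_scales[[v]]
      lp <- lp + beta[[v]] * (log(cohort_df[[v]]) - sc[1]) / sc[2]
    }
    for (v in names(.age_scales)) {
      sc <- .age_scales[[v]]
      lp <- lp + beta[[v]] * (log(cohort_df[[v]]) - sc[1]) / sc[2]
    }
    lp <- lp + beta[["suac_detected"]] * (cohort_df$suac_detected - config$suac_detect_prob)
    lp <- lp + ifelse(cohort_df$hcc, config$hcc_logodds_shift, 0)
    altered <- stats::runif(nrow(cohort_df)) < stats::plogis(lp)

    afp <- numeric(nrow(cohort_df))
    n_alt <- sum(altered)
    if (n_alt) {
      ml <- ifelse(cohort_df$hcc[altered], log(55), log(15))
      afp[altered] <- 5 + stats::rlnorm(n_alt, ml, 1.0)
    }
    if (any(!altered))
      afp[!altered] <- .rlnorm_trunc(sum(!altered), log(2.6), 0.45, hi = 5)
    cohort_df$afp <- afp
    out[[co]] <- cohort_df
  }
  records <- do.call(rbind, out)
  rownames(records) <- NULL
  col_order <- c("patient_id", "cohort", "age_at_diagnosis", "age_at_control",
                 "hcc", biomarker_variables())
  records <- records[, col_order]

  # exact-count MCAR masking of biomarker cells, per cohort
  maskable <- biomarker_variables()
  for (co in c("A", "B", "C")) {
    idx <- which(records$cohort == co)
    n_cells <- length(idx) * length(maskable)
    n_mask <- round(config$missingness_rates[[co]] * n_cells)
    if (n_mask > 0) {
      cells <- sample.int(n_cells, n_mask)
      for (cell in cells) {
        r <- idx[((cell - 1) %% length(idx)) + 1]
        c <- maskable[((cell - 1) %/% length(idx)) + 1]
        records[r, c] <- NA
      }
    }
  }
  attr(records, "config") <- config
  records
}

#' Write visit records to CSV with a JSON config sidecar
#'
#' Empty cells encode missing values. If the records carry a generating
#' config, it is written to `<path>.json` alongside.
#'
#' @param records a visit-record data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  config <- attr(records, "config")
  if (!is.null(config)) {
    jsonlite::write_json(unclass(config), paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}
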