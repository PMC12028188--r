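# End-to-end orchestration: configuration, cohort CSV I/O, stage execution
# in the published order, artifact writing and a reproducibility manifest.

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis. With
#' `input_csv = NULL` the synthetic generator supplies the cohorts.
#'
#' @param input_csv path to a visit-record CSV, or `NULL` to simulate.
#' @param synthetic a [synthetic_config()] used when simulating.
#' @param afp_threshold AFP binarization threshold (ng/mL).
#' @param completeness_min record eligibility fraction.
#' @param n_rounds multi-model training rounds.
#' @param auc_threshold retention threshold on internal-test AUROC.
#' @param space hyperparameter sampling space.
#' @param grouped_splits keep patients on one side of each split.
#' @param nrounds_max maximum boosting iterations per round.
#' @param ablation_variables optional explicit candidate set overriding the
#'   consensus top cluster.
#' @param cutoff_variable biomarker for the per-patient ROC cut-off.
#' @param n_boot bootstrap resamples for the cut-off CI.
#' @param afp_cuts,alt_cut screening-table cut-offs.
#' @param master_seed master seed for every stochastic stage.
#' @param out_dir output directory for artifacts.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_csv = NULL,
                            synthetic = synthetic_config(),
                            afp_threshold = 5,
                            completeness_min = 0.7,
                            n_rounds = 5000L,
                            auc_threshold = 0.7,
                            space = default_hyperparam_space(),
                            grouped_splits = FALSE,
                            nrounds_max = 50L,
                            ablation_variables = NULL,
                            cutoff_variable = "alt",
                            n_boot = 2000L,
                            afp_cuts = c(5, 10),
                            alt_cut = 29,
                            master_seed = 1L,
                            out_dir = "afprank_out") {
  if (!is.null(input_csv) && !file.exists(input_csv))
    stop(sprintf("input_csv does not exist: %s", input_csv), call. = FALSE)
  structure(list(input_csv = input_csv, synthetic = synthetic,
                 afp_threshold = afp_threshold,
                 completeness_min = completeness_min,
                 n_rounds = as.integer(n_rounds),
                 auc_threshold = auc_threshold, space = space,
                 grouped_splits = grouped_splits,
                 nrounds_max = as.integer(nrounds_max),
                 ablation_variables = ablation_variables,
                 cutoff_variable = cutoff_variable,
                 n_boot = as.integer(n_boot),
                 afp_cuts = afp_cuts, alt_cut = alt_cut,
                 master_seed = as.integer(master_seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Load visit records from CSV
#'
#' Reads a visit-record CSV (the dialect written by [write_cohort_csv()],
#' or any CSV via `column_map`), typing each field and treating empty or
#' malformed numeric cells as missing with a counted warning. Row order is
#' preserved.
#'
#' @param path CSV path.
#' @param column_map optional named character vector mapping canonical
#'   field names to the file's column names.
#' @return visit-record data.frame.
#' @export
load_cohort_csv <- function(path, column_map = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(raw))
        stop(sprintf("column_map entry '%s' -> '%s' not found in CSV",
                     canon, src), call. = FALSE)
      names(raw)[names(raw) == src] <- canon
    }
  }
  required <- c("patient_id", "cohort", "age_at_diagnosis", "age_at_control",
                "hcc", biomarker_variables())
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop(sprintf("missing required columns: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  numeric_cols <- setdiff(required,
                          c("patient_id", "cohort", "hcc", "suac_detected"))
  n_bad <- 0L
  out <- raw[, required]
  for (col in numeric_cols) {
    v <- suppressWarnings(as.numeric(out[[col]]))
    n_bad <- n_bad + sum(!is.na(out[[col]]) & out[[col]] != "" & is.na(v))
    out[[col]] <- v
  }
  for (col in c("hcc", "suac_detected")) {
    v <- toupper(trimws(out[[col]]))
    out[[col]] <- ifelse(v %in% c("TRUE", "T", "1"), TRUE,
                         ifelse(v %in% c("FALSE", "F", "0"), FALSE, NA))
  }
  if (n_bad > 0)
    warning(sprintf("%d malformed numeric cell(s) treated as missing", n_bad),
            call. = FALSE)
  out
}

.write_csv_artifact <- function(x, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(x, path, row.names = FALSE, na = "")
  path
}

.write_json_artifact <- function(x, dir, name) {
  path <- file.path(dir, name)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  path
}

#' Run the full biomarker-ranking pipeline
#'
#' Orchestrates: cohort generation/loading, eligibility filtering, the
#' univariate association screen (pre-imputation), dataset assembly with
#' chained-equations imputation, 2-D embedding, the multi-model ensemble
#' run twice (with and without age variables), corrected-importance tables,
#' rankings and consensus clustering for both variants, logistic ablation
#' on the consensus top-cluster variables, and the per-patient biomarker
#' cut-off analysis with the combined screening table. All artifacts plus a
#' run manifest are written under `config$out_dir`.
#'
#' @param config a [pipeline_config()].
#' @param stages run a prefix of the pipeline: one of `"simulate"`,
#'   `"preprocess"`, `"associate"`, `"multimodel"`, `"rank"`, `"ablate"`,
#'   `"cutoff"`, `"all"`.
#' @param quiet suppress per-stage log lines.
#' @return (invisibly) a list with every stage result and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), stages = "all",
                         quiet = FALSE) {
  stage_order <- c("simulate", "preprocess", "associate", "multimodel",
                   "rank", "ablate", "cutoff", "all")
  stages <- match.arg(stages, stage_order)
  last <- if (stages == "all") Inf else match(stages, stage_order)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("afprank")),
                   master_seed = config$master_seed,
                   config = list(afp_threshold = config$afp_threshold,
                                 completeness_min = config$completeness_min,
                                 n_rounds = config$n_rounds,
                                 auc_threshold = config$auc_threshold,
                                 grouped_splits = config$grouped_splits,
                                 nrounds_max = config$nrounds_max,
                                 cutoff_variable = config$cutoff_variable,
                                 n_boot = config$n_boot,
                                 afp_cuts = config$afp_cuts,
                                 alt_cut = config$alt_cut))
  bundle <- list()

  # -- simulate / load -----------------------------------------------------
  if (is.null(config$input_csv)) {
    syn <- config$synthetic
    syn$seed <- derive_seed(config$master_seed, 1L)
    records <- generate_cohorts(syn)
    manifest$source <- list(kind = "synthetic", seed = syn$seed)
  } else {
    records <- load_cohort_csv(config$input_csv)
    manifest$source <- list(kind = "csv", path = config$input_csv)
  }
  write_cohort_csv(records, file.path(config$out_dir, "records.csv"))
  say("simulate: %d records, %d patients", nrow(records),
      length(unique(records$patient_id)))
  bundle$records <- records
  if (last < 2) return(invisible(c(bundle, list(manifest = manifest))))

  # -- preprocess ----------------------------------------------------------
  filtered <- filter_records(records, config$completeness_min)
  manifest$filter <- list(records_in = nrow(records),
                          records_out = nrow(filtered))
  say("preprocess: %d/%d records retained", nrow(filtered), nrow(records))
  bundle$filtered <- filtered

  # -- association screen (pre-imputation values) --------------------------
  if (last >= 3) {
    screen <- association_screen(filtered)
    .write_csv_artifact(screen, config$out_dir, "association_screen.csv")
    bundle$association <- screen
    say("associate: top variable %s (rho=%.3f)", screen$variable[1],
        screen$rho[1])
  }

  datasets <- list(
    with_age = build_analysis_dataset(filtered, config$afp_threshold,
                                      include_age = TRUE),
    no_age = build_analysis_dataset(filtered, config$afp_threshold,
                                    include_age = FALSE))
  coords <- embed_2d(datasets$with_age$x,
                     n_neighbors = min(15L, nrow(filtered) - 1L))
  .write_csv_artifact(data.frame(patient_id = filtered$patient_id,
                                 cohort = filtered$cohort, coords),
                      config$out_dir, "embedding.csv")
  bundle$embedding <- coords
  if (last < 4) return(invisible(c(bundle, list(manifest = manifest))))

  # -- multimodel (twice: with and without age variables) ------------------
  cohorts <- unique(datasets$with_age$cohort)
  train_cohort <- cohorts[1]
  results <- list()
  for (variant in names(datasets)) {
    ds <- datasets[[variant]]
    idx <- ds$cohort == train_cohort
    train_ds <- subset_dataset(ds, idx)
    external <- list()
    for (co in setdiff(cohorts, train_cohort)) {
      ext <- subset_dataset(ds, ds$cohort == co)
      if (length(unique(ext$y)) == 2L) external[[co]] <- ext
    }
    res <- run_multimodel(train_ds, external,
                          n_rounds = config$n_rounds,
                          auc_threshold = config$auc_threshold,
                          space = config$space,
                          master_seed = derive_seed(config$master_seed,
                                                    2L + match(variant, names(datasets))),
                          grouped = config$grouped_splits,
                          nrounds_max = config$nrounds_max)
    write_rounds_jsonl(res, file.path(config$out_dir,
                                      sprintf("rounds_%s.jsonl", variant)))
    say("multimodel[%s]: retained %d/%d rounds (%.1f%%)", variant,
        length(res$rounds), config$n_rounds, 100 * res$retention)
    results[[variant]] <- res
    manifest$multimodel[[variant]] <- list(retention = res$retention,
                                           retained = length(res$rounds))
  }
  bundle$multimodel <- results
  if (last < 5) return(invisible(c(bundle, list(manifest = manifest))))

  # -- corrected importance, rankings, consensus clustering ----------------
  tables <- list()
  clusters <- list()
  for (variant in names(results)) {
    if (identical(results[[variant]]$status, "empty")) {
      say("rank[%s]: skipped (no retained rounds)", variant)
      next
    }
    tab <- importance_table(results[[variant]])
    tables[[variant]] <- tab
    .write_csv_artifact(data.frame(variable = rownames(tab), unclass(tab)),
                        config$out_dir,
                        sprintf("importance_table_%s.csv", variant))
    rk <- rank_variables(tab, "internal")
    .write_csv_artifact(rk, config$out_dir,
                        sprintf("ranking_internal_%s.csv", variant))
    if (ncol(tab) >= 2L) {
      cl <- consensus_cluster(tab)
      clusters[[variant]] <- cl
      .write_json_artifact(list(flat_labels = as.list(cl$flat_labels),
                                top_cluster = cl$top_cluster,
                                newick = cl$newick),
                           config$out_dir,
                           sprintf("clusters_%s.json", variant))
    }
    say("rank[%s]: top variable %s", variant, rk$variable[1])
  }
  bundle$importance <- tables
  bundle$clusters <- clusters
  if (last < 6) return(invisible(c(bundle, list(manifest = manifest))))

  # -- ablation on the consensus candidate set -----------------------------
  candidates <- config$ablation_variables
  if (is.null(candidates) && !is.null(clusters$with_age))
    candidates <- clusters$with_age$top_cluster
  if (is.null(config$ablation_variables) && length(candidates) < 2L &&
      !is.null(tables$with_age)) {
    # degenerate top cluster: fall back to the four top-ranked variables
    candidates <- utils::head(rank_variables(tables$with_age,
                                             "internal")$variable, 4L)
  }
  if (!is.null(candidates) && length(candidates) >= 2L) {
    ds <- datasets$with_age
    idx <- ds$cohort == train_cohort
    abl <- ablation_scan(ds$x[idx, candidates, drop = FALSE], ds$y[idx],
                         seed = derive_seed(config$master_seed, 5L))
    .write_csv_artifact(abl, config$out_dir, "ablation_report.csv")
    bundle$ablation <- abl
    manifest$ablation <- list(candidates = candidates,
                              worst_omission = attr(abl, "worst_omission"))
    say("ablate: worst omission %s", attr(abl, "worst_omission"))
  } else {
    say("ablate: skipped (fewer than 2 candidate variables)")
  }
  if (last < 7) return(invisible(c(bundle, list(manifest = manifest))))

  # -- per-patient cut-off and screening table -----------------------------
  pm <- patient_means(filtered, config$cutoff_variable)
  if (sum(pm$hcc) >= 2L && sum(!pm$hcc) >= 2L) {
    cr <- roc_cutoff(pm$mean_value, pm$hcc, n_boot = config$n_boot,
                     seed = derive_seed(config$master_seed, 6L))
    .write_json_artifact(unclass(cr), config$out_dir, "cutoff_result.json")
    bundle$cutoff <- cr
    afp_pm <- patient_means(filtered, "afp")
    common <- intersect(pm$patient_id, afp_pm$patient_id)
    st <- screening_table(afp_pm$mean_value[match(common, afp_pm$patient_id)],
                          pm$mean_value[match(common, pm$patient_id)],
                          pm$hcc[match(common, pm$patient_id)],
                          afp_cuts = config$afp_cuts,
                          alt_cut = config$alt_cut)
    .write_csv_artifact(st, config$out_dir, "screening_table.csv")
    bundle$screening <- st
    say("cutoff: %s > %.3g (AUC %.3f, 95%% CI %.3f-%.3f)",
        config$cutoff_variable, cr$threshold, cr$auc, cr$ci_low, cr$ci_high)
  } else {
    say("cutoff: skipped (need >= 2 patients per outcome class)")
  }

  .write_json_artifact(manifest, config$out_dir, "manifest.json")
  invisible(c(bundle, list(manifest = manifest)))
}

#' Command-line entry point
#'
#' Subcommands mirror the pipeline stages: `simulate`, `preprocess`,
#' `associate`, `multimodel`, `rank`, `ablate`, `cutoff`, `all`. Options:
#' `--config <json>` (a JSON file of [pipeline_config()] overrides),
#' `--input <csv>`, `--rounds <n>`, `--auc-min <x>`, `--seed <n>`,
#' `--out <dir>`.
#'
#' @param args character vector of CLI arguments (default: the command
#'   line).
#' @return exit status, invisibly.
#' @export
afprank_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    message("usage: afprank <simulate|preprocess|associate|multimodel|rank|",
            "ablate|cutoff|all> [--config f.json] [--input f.csv] ",
            "[--rounds n] [--auc-min x] [--seed n] [--out dir]")
    return(invisible(1L))
  }
  stage <- args[1]
  opts <- list()
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    opts[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  cfg_args <- list()
  if (!is.null(opts$config))
    cfg_args <- jsonlite::fromJSON(opts$config, simplifyVector = TRUE)
  if (!is.null(opts$input)) cfg_args$input_csv <- opts$input
  if (!is.null(opts$rounds)) cfg_args$n_rounds <- as.integer(opts$rounds)
  if (!is.null(opts[["auc-min"]]))
    cfg_args$auc_threshold <- as.numeric(opts[["auc-min"]])
  if (!is.null(opts$seed)) cfg_args$master_seed <- as.integer(opts$seed)
  if (!is.null(opts$out)) cfg_args$out_dir <- opts$out
  config <- do.call(pipeline_config, cfg_args)
  run_pipeline(config, stages = stage)
  invisible(0L)
}
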