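#' Read / write the long-format claims tables
#'
#' Delimited (tab or comma) event and patient tables with a header row.
#' Events: `patient_id`, `day`, `kind`, `code`, `duration_days`, `quantity`;
#' patients: `patient_id`, `birth_year` (or `age`), `sex`, `region`, `plan`,
#' `first_day`, `last_day`.
#'
#' @param path file path (`.csv` comma, otherwise tab).
#' @return data.frame.
#' @export
read_events <- function(path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
}

#' @rdname read_events
#' @export
read_patients <- read_events

#' @rdname read_events
#' @param x data.frame to write.
#' @export
write_claims_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Bundles every input of [run_pipeline]. Tables can be passed as loaded
#' data.frames or as file paths (resolved lazily).
#'
#' @param events,patients claims tables or paths.
#' @param icd9_to_phewas diagnosis [mapping_table] (or path; the file needs
#'   `source`/`target` columns).
#' @param aed_codes AED prescription code set.
#' @param comorbidity a [comorbidity_definition].
#' @param output_dir artifact directory.
#' @param seed single integer feeding every random stage.
#' @param hp [hyperparams] for a plain fit, or `NULL` with `space` for
#'   tuning.
#' @param space optional [hp_space].
#' @param folds 0 = single train/test split, >= 2 = nested cross-validation.
#' @param n_trials tuning trials when `space` is given.
#' @param cohort a [cohort_config].
#' @param explain run the Shapley stage.
#' @param shap_fraction,shap_repeats subsampled-SHAP settings.
#' @param knowledge_tables optional list of extra [mapping_table]s.
#' @param epochs,patience training budget.
#' @return list of class `run_config`.
#' @export
run_config <- function(events, patients, icd9_to_phewas, aed_codes,
                       comorbidity, output_dir, seed,
                       hp = hyperparams(), space = NULL, folds = 0L,
                       n_trials = 10L, cohort = cohort_config(),
                       explain = FALSE, shap_fraction = 0.05,
                       shap_repeats = 5L, knowledge_tables = list(),
                       epochs = 40L, patience = 10L) {
  if (missing(seed)) stop("'seed' is mandatory")
  stopifnot(inherits(comorbidity, "comorbidity_definition"),
            inherits(cohort, "cohort_config"))
  structure(as.list(environment()), class = "run_config")
}

resolve_table <- function(x) if (is.character(x)) read_events(x) else x

#' Run the end-to-end pipeline
#'
#' Orchestrates cohort construction, featurization, model fitting (or
#' tuning / nested cross-validation), evaluation and explanation, writing
#' every artifact plus a manifest (software version, seed, config hash,
#' declared file list) into `output_dir`. A completed stage leaves its
#' artifacts on disk; rerunning with the same seed reproduces them, and
#' later stages can resume from stored artifacts of earlier ones.
#'
#' @param config a [run_config].
#' @param stages subset of
#'   `c("cohort", "featurize", "fit", "evaluate", "explain")` to run
#'   (earlier stages are loaded from disk when skipped).
#' @return list with the key in-memory artifacts (`cohort`, `labels`,
#'   `cubes`, `model`, `metrics`, `manifest`), invisibly.
#' @export
run_pipeline <- function(config,
                         stages = c("cohort", "featurize", "fit",
                                    "evaluate", "explain")) {
  stopifnot(inherits(config, "run_config"))
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  add <- function(p) { written <<- c(written, basename(p)); p }
  fail <- function(stage, e) {
    manifest <- list(status = "failed", stage = stage,
                     error = conditionMessage(e), files = written)
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  events <- resolve_table(config$events)
  patients <- resolve_table(config$patients)
  icd_map <- config$icd9_to_phewas
  if (is.character(icd_map))
    icd_map <- read_mapping_table(icd_map, target_subdomain = "phewas")

  art <- list()
  ## ---- cohort --------------------------------------------------------------
  if ("cohort" %in% stages) {
    tryCatch({
      cand <- identify_epilepsy_patients(events, config$aed_codes)
      cohort <- apply_cohort_filters(cand, patients, events, config$cohort,
                                     config$aed_codes)
      write_claims_table(as.data.frame(cohort), add(file.path(out, "cohort.tsv")))
      write_claims_table(attr(cohort, "exclusions"),
                         add(file.path(out, "cohort_exclusions.tsv")))
      art$cohort <- cohort
    }, error = function(e) fail("cohort", e))
  } else {
    cohort <- read_events(file.path(out, "cohort.tsv"))
    class(cohort) <- c("claims_cohort", "data.frame")
    art$cohort <- cohort
  }

  ## ---- featurize -----------------------------------------------------------
  if ("featurize" %in% stages) {
    tryCatch({
      concepts <- map_diagnoses(events, icd_map)
      labs <- build_comorbidity_labels(art$cohort, concepts,
                                       config$comorbidity, config$cohort)
      write_claims_table(as.data.frame(labs$labels),
                         add(file.path(out, "labels.tsv")))
      write_claims_table(labs$excluded,
                         add(file.path(out, "label_exclusions.tsv")))
      lcohort <- art$cohort[art$cohort$patient_id %in%
                              labs$labels$patient_id, , drop = FALSE]
      class(lcohort) <- c("claims_cohort", "data.frame")

      pf <- prefilter_codes(events, lcohort, config$cohort)
      concepts_f <- concepts  # concept vocabulary; raw-code prefilter below
      rx <- events[events$kind == "prescription" &
                     events$code %in% pf$vocabulary &
                     !events$code %in% config$aed_codes, , drop = FALSE]
      fe_dx <- data.frame(patient_id = concepts_f$patient_id,
                          day = concepts_f$day, code = concepts_f$code,
                          subdomain = "phewas")
      fe_rx <- data.frame(patient_id = rx$patient_id, day = rx$day,
                          code = rx$code, subdomain = "substance",
                          duration_days = rx$duration_days)
      fe_dx$duration_days <- NA_real_
      feats <- expand_knowledge(rbind(fe_dx, fe_rx), config$knowledge_tables)
      stat <- static_features(patients, lcohort)
      vocab <- list(phewas = setdiff(unique(fe_dx$code),
                                     config$comorbidity$phewas_codes))
      if (nrow(fe_rx)) vocab$substance <- unique(fe_rx$code)
      schema <- build_schema(vocab, config$knowledge_tables, stat$vocab)
      write_schema(schema, add(file.path(out, "schema.json")))
      scaling <- fit_static_scaling(stat$values, lcohort$patient_id)
      cubes <- assemble_cubes(feats, schema, lcohort, stat$values, scaling,
                              history_days = config$cohort$history_days,
                              month_days = config$cohort$month_days,
                              on_unknown = "drop")
      art$labels <- labs$labels[match(lcohort$patient_id,
                                      labs$labels$patient_id), , drop = FALSE]
      art$cubes <- cubes
    }, error = function(e) fail("featurize", e))
  }

  ## ---- fit -----------------------------------------------------------------
  if ("fit" %in% stages && config$folds < 2) {
    tryCatch({
      set.seed(config$seed)
      n <- n_patients(art$cubes)
      test_idx <- sample.int(n, max(2L, floor(0.2 * n)))
      train_idx <- setdiff(seq_len(n), test_idx)
      hp <- config$hp
      if (!is.null(config$space)) {
        tuned <- bayesian_hpo(config$space, subset_cubes(art$cubes, train_idx),
                              art$labels[train_idx, , drop = FALSE],
                              n_trials = config$n_trials, inner_folds = 2L,
                              seed = config$seed,
                              epochs = config$epochs, patience = config$patience)
        hp <- tuned$best_hp
        write_claims_table(tuned$trials, add(file.path(out, "tuning_log.tsv")))
      }
      set.seed(config$seed + 1L)
      model <- build_network(art$cubes$schema, hp, T_bins = art$cubes$T_bins,
                             seed = config$seed)
      model <- train(model, subset_cubes(art$cubes, train_idx),
                     art$labels[train_idx, , drop = FALSE],
                     epochs = config$epochs, patience = config$patience)
      model$scaling <- art$cubes$scaling
      save_checkpoint(model, add(file.path(out, "model.json")))
      art$model <- model
      art$test_idx <- test_idx
    }, error = function(e) fail("fit", e))
  }

  ## ---- evaluate ------------------------------------------------------------
  if ("evaluate" %in% stages) {
    tryCatch({
      if (config$folds >= 2) {
        cv <- nested_cv(art$cubes, art$labels, outer_folds = config$folds,
                        space = config$space, hp = config$hp,
                        n_trials = config$n_trials, seed = config$seed,
                        epochs = config$epochs, patience = config$patience)
        write_claims_table(cv$folds, add(file.path(out, "metrics_folds.tsv")))
        metrics <- list(mean_uno_c = cv$mean, sd_uno_c = cv$sd,
                        folds = config$folds)
        art$metrics <- cv
      } else {
        sc <- risk_score(art$model, art$cubes, idx = art$test_idx)
        te <- art$labels[art$test_idx, , drop = FALSE]
        uc <- uno_c(sc, te)
        grid <- stats::quantile(te$time[te$status == 1],
                                c(0.25, 0.5, 0.75), names = FALSE)
        auc <- auc_t(sc, te, grid)
        write_claims_table(auc, add(file.path(out, "auc_t.tsv")))
        h0 <- breslow_cumulative_hazard(
          risk_score(art$model, art$cubes,
                     idx = setdiff(seq_len(n_patients(art$cubes)),
                                   art$test_idx)),
          art$labels[setdiff(seq_len(n_patients(art$cubes)), art$test_idx), ,
                     drop = FALSE])
        write_step_function(h0, add(file.path(out, "baseline_hazard.tsv")))
        metrics <- list(uno_c = uc$estimate, tau = uc$tau,
                        harrell_c = as.numeric(
                          suppressWarnings(harrell_c(sc, te))),
                        n_test = length(art$test_idx))
        art$metrics <- metrics
      }
      jsonlite::write_json(metrics, add(file.path(out, "metrics.json")),
                           auto_unbox = TRUE, digits = NA)
    }, error = function(e) fail("evaluate", e))
  }

  ## ---- explain -------------------------------------------------------------
  if ("explain" %in% stages && isTRUE(config$explain)) {
    tryCatch({
      rep <- subsampled_shap(art$model, art$cubes,
                             fraction = config$shap_fraction,
                             repeats = config$shap_repeats,
                             seed = config$seed)
      write_claims_table(rep$feature, add(file.path(out, "shap_features.tsv")))
      write_claims_table(rep$subdomain,
                         add(file.path(out, "shap_subdomains.tsv")))
      write_claims_table(rep$domain, add(file.path(out, "shap_domains.tsv")))
      art$shap <- rep
    }, error = function(e) fail("explain", e))
  }

  manifest <- list(
    status = "ok",
    package_version = as.character(utils::packageVersion("claimrisk")),
    seed = config$seed,
    comorbidity = config$comorbidity$name,
    config_hash = config_hash(config),
    files = sort(unique(c(written, "manifest.json"))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  art$manifest <- manifest
  invisible(art)
}

## content hash of the run configuration (tables hashed by dimension)
config_hash <- function(config) {
  slim <- lapply(config, function(x) {
    if (is.data.frame(x)) c(nrow(x), ncol(x))
    else if (inherits(x, "mapping_table")) nrow(x$pairs)
    else if (is.function(x)) NULL
    else x
  })
  tf <- tempfile()
  on.exit(unlink(tf))
  jsonlite::write_json(slim, tf, auto_unbox = TRUE, force = TRUE)
  unname(tools::md5sum(tf))
}
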