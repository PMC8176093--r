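#' Synthetic claims simulation configuration
#'
#' The stated world of the bundled simulator: a cohort of epilepsy-like
#' claims histories with a planted proportional-hazards comorbidity risk.
#' Each patient gets an index date, qualifying epilepsy codes, AED
#' prescriptions, demographics, monthly Bernoulli code events over the
#' 456-day history window, and a comorbidity event time drawn (in days) from
#' an exponential proportional-hazards model with linear predictor
#' `beta . exposure` over the designated signal concepts, plus independent
#' exponential and administrative right censoring. Event times are generated
#' in days so the label pipeline — not the generator — controls monthly
#' rounding.
#'
#' @param n_patients cohort size.
#' @param n_phewas,n_substance vocabulary sizes (PheWAS concepts, substance
#'   codes).
#' @param icd_per_phewas ICD-9-style codes mapping onto each PheWAS concept
#'   (fan-in of the generated diagnosis mapping).
#' @param target_fanout fan-out of the generated substance-to-target
#'   knowledge table.
#' @param n_signal number of signal PheWAS concepts (the first
#'   `n_signal`).
#' @param beta planted log-hazard coefficients for the signal exposures
#'   (scalar recycled).
#' @param signal_propensity_max per-patient monthly presence probability of
#'   signal concepts is uniform on `[0, signal_propensity_max]`.
#' @param noise_propensity_max same for non-signal concepts.
#' @param rx_propensity_max same for substances.
#' @param baseline_hazard daily event hazard of a patient at the mean linear
#'   predictor.
#' @param censor_rate daily rate of the independent exponential censoring
#'   process.
#' @param censoring_target intended overall censored fraction under the
#'   defaults (documentation + invariant checks; not a fitted quantity).
#' @param coverage_days administrative coverage horizon per patient.
#' @param p_ineligible fraction of patients deliberately generated outside
#'   the age window (exercises cohort filters).
#' @param p_prior fraction with a comorbidity code planted in the history
#'   window (exercises prior-comorbidity exclusion).
#' @param p_lag fraction with the first comorbidity code planted inside the
#'   6-month lag window (exercises lag exclusion).
#' @param p_criterion4 fraction qualifying through the convulsions + AED
#'   rule instead of two epilepsy codes.
#' @param seed RNG seed (mandatory).
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 2000L,
                       n_phewas = 30L, n_substance = 15L,
                       icd_per_phewas = 2L, target_fanout = 3L,
                       n_signal = 5L, beta = 2.0,
                       signal_propensity_max = 0.6,
                       noise_propensity_max = 0.3,
                       rx_propensity_max = 0.25,
                       baseline_hazard = 1 / 400,
                       censor_rate = 1 / 700,
                       censoring_target = 0.30,
                       coverage_days = 2200L,
                       p_ineligible = 0.02, p_prior = 0.04, p_lag = 0.03,
                       p_criterion4 = 0.10,
                       seed) {
  if (missing(seed)) stop("'seed' is mandatory")
  if (n_signal > n_phewas)
    stop("signal features must be a subset of the PheWAS vocabulary")
  stopifnot(baseline_hazard > 0, n_patients >= 10,
            signal_propensity_max > 0, noise_propensity_max > 0,
            rx_propensity_max > 0)
  if (censor_rate <= 0 && !is.finite(coverage_days))
    stop("infeasible: no censoring process and infinite follow-up")
  beta <- rep_len(beta, n_signal)
  structure(as.list(environment()), class = "sim_config")
}

sim_vocab <- function(config) {
  list(phewas = sprintf("P%03d", seq_len(config$n_phewas)),
       icd = sprintf("%06.2f", 100 + seq_len(config$n_phewas *
                                               config$icd_per_phewas) / 100),
       substance = sprintf("S%03d", seq_len(config$n_substance)))
}

#' Generate synthetic mapping tables
#'
#' Deterministic (seeded) random many-to-many tables: the ICD-to-PheWAS
#' diagnosis map (each concept receives `icd_per_phewas` codes) and a
#' substance-to-target knowledge table with fan-out `target_fanout`.
#'
#' @param config a [sim_config].
#' @return named list of [mapping_table]s (`icd9_to_phewas`,
#'   `substance_targets`).
#' @export
generate_mappings <- function(config) {
  set.seed(config$seed + 1L)
  v <- sim_vocab(config)
  icd_map <- data.frame(
    source = c(v$icd,
               paste0("ICDCM.", seq_len(2))),
    target = c(rep(v$phewas, each = config$icd_per_phewas),
               rep("P_CM", 2)))
  out <- list(icd9_to_phewas = mapping_table("icd9_to_phewas", icd_map,
                                             target_subdomain = "phewas"))
  if (config$target_fanout > 0) {
    tgt <- data.frame(
      source = rep(v$substance, each = config$target_fanout),
      target = paste0("T", sample.int(config$n_substance * config$target_fanout)))
    out$substance_targets <- mapping_table("substance_targets", tgt,
                                           target_subdomain = "target_tissue")
  } else {
    warning("target_fanout = 0: empty knowledge table set")
  }
  out
}

#' Generate a synthetic claims cohort with known ground truth
#'
#' See [sim_config] for the generative model. The emitted tables use the
#' exact formats the cohort module reads (long event table + patient table),
#' and the true linear predictor and uncensored event day of every patient
#' are returned for oracle checks.
#'
#' @param config a [sim_config].
#' @return list: `events` (claim event table), `patients` (patient table),
#'   `truth` (data.frame `patient_id`, `lp` (linear predictor),
#'   `exposures` matrix attribute, `event_day` (possibly beyond coverage),
#'   `censor_day`), `mappings`, `aed_codes`, `defn`
#'   (the [comorbidity_definition] of the planted comorbidity), `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cfg <- cohort_config()
  v <- sim_vocab(config)
  n <- config$n_patients
  aed_codes <- c("AED001", "AED002")
  Tb <- 15L

  pid <- sprintf("pt%05d", seq_len(n))
  index_day <- sample(420:800, n, replace = TRUE)
  age <- runif(n, 18, 65)
  inel <- runif(n) < config$p_ineligible
  age[inel] <- sample(c(runif(sum(inel), 8, 17.5), runif(sum(inel), 66, 80)),
                      sum(inel))
  birth_year <- cfg$epoch_year + index_day / 365.25 - age
  patients <- data.frame(
    patient_id = pid,
    birth_year = birth_year,
    sex = sample(c("F", "M"), n, replace = TRUE),
    region = sample(paste0("R", 1:4), n, replace = TRUE),
    plan = sample(paste0("plan", 1:3), n, replace = TRUE),
    first_day = 0L,
    last_day = config$coverage_days)

  history_start <- index_day - cfg$lookback_days
  history_end <- index_day + cfg$diagnosis_period_days
  lag_end <- history_end + cfg$incident_lag_months * cfg$month_days

  ## exposures: per-patient monthly presence propensity per concept
  prop_sig <- matrix(runif(n * config$n_signal, 0, config$signal_propensity_max),
                     n, config$n_signal)
  n_noise <- config$n_phewas - config$n_signal
  prop_noise <- matrix(runif(n * n_noise, 0, config$noise_propensity_max),
                       n, n_noise)
  prop_dx <- cbind(prop_sig, prop_noise)
  prop_rx <- matrix(runif(n * config$n_substance, 0, config$rx_propensity_max),
                    n, config$n_substance)

  ## monthly presence draws over the 15 history bins
  pres_dx <- array(runif(n * config$n_phewas * Tb), c(n, config$n_phewas, Tb)) <
    array(rep(prop_dx, Tb), c(n, config$n_phewas, Tb))
  pres_rx <- array(runif(n * config$n_substance * Tb),
                   c(n, config$n_substance, Tb)) <
    array(rep(prop_rx, Tb), c(n, config$n_substance, Tb))

  exposures <- apply(pres_dx[, seq_len(config$n_signal), , drop = FALSE],
                     c(1, 2), mean)
  lp <- as.vector(exposures %*% config$beta)
  lp_center <- sum(config$beta) * config$signal_propensity_max / 2
  hz <- config$baseline_hazard * exp(lp - lp_center)

  event_gap <- rexp(n, hz)                     # days after the lag window
  event_day <- lag_end + event_gap
  cens_gap <- if (config$censor_rate > 0) rexp(n, config$censor_rate) else Inf
  censor_day <- pmin(config$coverage_days, lag_end + cens_gap)

  ## planted exclusions: prior-history or lag-window first diagnoses
  u <- runif(n)
  prior <- u < config$p_prior
  lagwin <- !prior & u < config$p_prior + config$p_lag

  ev <- list()
  emit <- function(p, day, kind, code, duration = NA_real_, qty = NA_real_) {
    ev[[length(ev) + 1L]] <<- data.frame(
      patient_id = p, day = round(day), kind = kind, code = code,
      duration_days = duration, quantity = qty)
  }

  crit4 <- runif(n) < config$p_criterion4
  i4 <- which(crit4); i1 <- which(!crit4)
  if (length(i4)) {
    emit(pid[i4], index_day[i4], "diagnosis", "780.39")
    emit(pid[i4], index_day[i4] + 25, "diagnosis", "780.39")
    emit(pid[i4], index_day[i4] + 30, "prescription", aed_codes[1], 30, 30)
  }
  if (length(i1)) {
    emit(pid[i1], index_day[i1], "diagnosis", "345.40")
    emit(pid[i1], index_day[i1] + sample(20:60, length(i1), replace = TRUE),
         "diagnosis", "345.41")
  }
  ## AED refills through follow-up (satisfies the AED filter)
  for (off in c(120, 240, 360))
    emit(pid, index_day + off, "prescription",
         aed_codes[sample.int(2, n, replace = TRUE)], 30, 30)

  ## history-window code events, one ICD code drawn per concept presence
  idx_dx <- which(pres_dx, arr.ind = TRUE)
  if (nrow(idx_dx)) {
    i <- idx_dx[, 1]; ci <- idx_dx[, 2]; t <- idx_dx[, 3]
    icd_choice <- (ci - 1L) * config$icd_per_phewas +
      sample.int(config$icd_per_phewas, nrow(idx_dx), replace = TRUE)
    ev[[length(ev) + 1L]] <- data.frame(
      patient_id = pid[i],
      day = history_start[i] + (t - 1L) * 30L +
        sample.int(30L, nrow(idx_dx), replace = TRUE) - 1L,
      kind = "diagnosis", code = v$icd[icd_choice],
      duration_days = NA_real_, quantity = NA_real_)
  }
  idx_rx <- which(pres_rx, arr.ind = TRUE)
  if (nrow(idx_rx)) {
    i <- idx_rx[, 1]; ci <- idx_rx[, 2]; t <- idx_rx[, 3]
    ev[[length(ev) + 1L]] <- data.frame(
      patient_id = pid[i],
      day = history_start[i] + (t - 1L) * 30L +
        sample.int(30L, nrow(idx_rx), replace = TRUE) - 1L,
      kind = "prescription", code = v$substance[ci],
      duration_days = sample(c(7, 30, 60), nrow(idx_rx), replace = TRUE),
      quantity = sample(10:90, nrow(idx_rx), replace = TRUE))
  }

  ## comorbidity diagnoses (ICD codes mapping to concept P_CM)
  cm_icd <- function(k) paste0("ICDCM.", sample.int(2, k, replace = TRUE))
  obs_event <- !prior & !lagwin & event_day <= censor_day
  last_day <- ifelse(!prior & !lagwin & !obs_event, censor_day,
                     config$coverage_days)
  if (any(prior))
    emit(pid[prior], history_start[prior] +
           sample.int(400, sum(prior), replace = TRUE),
         "diagnosis", cm_icd(sum(prior)))
  if (any(lagwin))
    emit(pid[lagwin], history_end[lagwin] +
           sample.int(175, sum(lagwin), replace = TRUE),
         "diagnosis", cm_icd(sum(lagwin)))
  if (any(obs_event))
    emit(pid[obs_event], event_day[obs_event], "diagnosis",
         cm_icd(sum(obs_event)))
  patients$last_day <- floor(last_day)

  events <- do.call(rbind, ev)
  events <- events[order(events$patient_id, events$day), , drop = FALSE]
  rownames(events) <- NULL

  truth <- data.frame(patient_id = pid, lp = lp, index_day = index_day,
                      event_day = event_day, censor_day = censor_day,
                      prior = prior, lagwin = lagwin)
  attr(truth, "exposures") <- exposures
  list(events = events, patients = patients, truth = truth,
       mappings = generate_mappings(config), aed_codes = aed_codes,
       defn = comorbidity_definition("synthetic_comorbidity", "P_CM"),
       config = config)
}

#' Synthetic cohort, featurized end-to-end
#'
#' Convenience wrapper chaining the full pipeline on a simulated cohort:
#' generation, inclusion rules, cohort filters, diagnosis mapping,
#' survival labelling, schema construction and cube assembly (claims-origin
#' subdomains: PheWAS, substance, demographics/region).
#'
#' @param config a [sim_config].
#' @return list: `cubes` (`cube_set`), `labels` ([survival_labels], aligned
#'   with `cubes$patient_ids`), `truth` (rows matched to the labelled
#'   cohort), `cohort`, `schema`, `sim` (the raw [generate_cohort] output).
#' @export
synthetic_training_data <- function(config) {
  sim <- generate_cohort(config)
  cc <- cohort_config()
  cand <- identify_epilepsy_patients(sim$events, sim$aed_codes)
  cohort <- apply_cohort_filters(cand, sim$patients, sim$events, cc,
                                 sim$aed_codes)
  concepts <- map_diagnoses(sim$events, sim$mappings$icd9_to_phewas)
  labs <- build_comorbidity_labels(cohort, concepts, sim$defn, cc)
  keep <- cohort$patient_id %in% labs$labels$patient_id
  lcoh <- cohort[keep, , drop = FALSE]
  class(lcoh) <- c("claims_cohort", "data.frame")
  labels <- labs$labels[match(lcoh$patient_id, labs$labels$patient_id), ,
                        drop = FALSE]
  rx <- sim$events[sim$events$kind == "prescription" &
                     !sim$events$code %in% sim$aed_codes, , drop = FALSE]
  fe <- rbind(
    data.frame(patient_id = concepts$patient_id, day = concepts$day,
               code = concepts$code, subdomain = "phewas",
               duration_days = NA_real_),
    data.frame(patient_id = rx$patient_id, day = rx$day, code = rx$code,
               subdomain = "substance", duration_days = rx$duration_days))
  feats <- expand_knowledge(fe)
  stat <- static_features(sim$patients, lcoh)
  schema <- build_schema(
    list(phewas = setdiff(unique(concepts$code), sim$defn$phewas_codes),
         substance = sort(unique(rx$code))),
    static = stat$vocab)
  scaling <- fit_static_scaling(stat$values, lcoh$patient_id)
  cubes <- assemble_cubes(feats, schema, lcoh, stat$values, scaling,
                          on_unknown = "drop")
  truth <- sim$truth[match(cubes$patient_ids, sim$truth$patient_id), ,
                     drop = FALSE]
  list(cubes = cubes, labels = labels, truth = truth, cohort = lcoh,
       schema = schema, sim = sim)
}
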