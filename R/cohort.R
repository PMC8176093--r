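#' Cohort construction configuration
#'
#' Parameters of cohort assembly and labelling. Defaults encode the standard
#' design: 365 days of medical history before the index date, a 91-day
#' diagnosis period after it (so the feature window spans 456 days), at least
#' 365 days of follow-up, ages 18-65 inclusive, 30-day months, a 6-month lag
#' before a comorbidity diagnosis counts as incident, and removal of codes
#' observed in <= 10 patients or with frequency <= 1%.
#'
#' @param lookback_days days of required history before the index date.
#' @param diagnosis_period_days length of the diagnosis period after the
#'   index date; features are collected through its end.
#' @param min_followup_days required follow-up after the index date.
#' @param age_range inclusive age bounds at the index date.
#' @param month_days days per month bin.
#' @param incident_lag_months months after the diagnosis period before a
#'   comorbidity diagnosis counts as incident.
#' @param min_patients_per_code codes carried by at most this many patients
#'   are removed.
#' @param min_code_freq codes with at most this patient frequency are removed.
#' @param epoch_year calendar year corresponding to day 0 of the study clock,
#'   used to compute age at index from `birth_year`.
#' @param aed_window window over which the "any AED treatment" filter is
#'   evaluated: the patient's full coverage interval (default) or the
#'   history-plus-follow-up study window.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(lookback_days = 365L,
                          diagnosis_period_days = 91L,
                          min_followup_days = 365L,
                          age_range = c(18L, 65L),
                          month_days = 30L,
                          incident_lag_months = 6L,
                          min_patients_per_code = 10L,
                          min_code_freq = 0.01,
                          epoch_year = 2011L,
                          aed_window = c("coverage", "study")) {
  cfg <- list(lookback_days = as.integer(lookback_days),
              diagnosis_period_days = as.integer(diagnosis_period_days),
              min_followup_days = as.integer(min_followup_days),
              age_range = as.integer(age_range),
              month_days = as.integer(month_days),
              incident_lag_months = as.integer(incident_lag_months),
              min_patients_per_code = as.integer(min_patients_per_code),
              min_code_freq = as.numeric(min_code_freq),
              epoch_year = as.integer(epoch_year),
              aed_window = match.arg(aed_window))
  with(cfg, {
    stopifnot(lookback_days > 0, diagnosis_period_days > 0,
              min_followup_days > 0, month_days > 0,
              incident_lag_months > 0, min_patients_per_code >= 0,
              min_code_freq >= 0, length(age_range) == 2,
              age_range[1] <= age_range[2])
  })
  cfg$history_days <- cfg$lookback_days + cfg$diagnosis_period_days
  class(cfg) <- "cohort_config"
  cfg
}

## ---- code classifiers (ICD-9-CM) ----------------------------------------
## 345.xx = epilepsy; 345.3 = grand mal status (excluded from the 345.xx
## criteria, handled by its own rule); 780.39 = convulsions
is_epilepsy_code <- function(code) startsWith(code, "345") & !startsWith(code, "345.3")
is_status_code <- function(code) startsWith(code, "345.3")
is_convulsion_code <- function(code) code == "780.39"

#' Validate a raw claims event table
#'
#' Checks the long-format event table contract: columns `patient_id`, `day`,
#' `kind`, `code` (plus `duration_days`, `quantity` for prescriptions),
#' nonnegative days, non-empty codes, and `duration_days` present on
#' prescriptions. Patients carrying any malformed row are rejected wholesale
#' with a diagnostic message.
#'
#' @param events data.frame of claim events.
#' @return The validated events (rows of rejected patients removed), with
#'   attribute `rejected`: a data.frame of `patient_id`, `reason`.
#' @export
validate_events <- function(events) {
  req <- c("patient_id", "day", "kind", "code")
  missing_cols <- setdiff(req, names(events))
  if (length(missing_cols))
    stop("event table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (!"duration_days" %in% names(events)) events$duration_days <- NA_real_
  bad <- rep(FALSE, nrow(events)); reason <- character(nrow(events))
  b <- !is.finite(events$day) | events$day < 0
  reason[b & !bad] <- "negative or missing day"; bad <- bad | b
  b <- is.na(events$code) | !nzchar(trimws(as.character(events$code)))
  reason[b & !bad] <- "empty code"; bad <- bad | b
  b <- events$kind == "prescription" &
    (is.na(events$duration_days) | events$duration_days < 0)
  reason[b & !bad] <- "prescription without duration"; bad <- bad | b
  rej <- unique(data.frame(patient_id = events$patient_id[bad],
                           reason = reason[bad]))
  if (nrow(rej) > 0)
    message("rejecting ", length(unique(rej$patient_id)),
            " patient(s) with malformed events")
  out <- events[!events$patient_id %in% rej$patient_id, , drop = FALSE]
  attr(out, "rejected") <- rej
  out
}

#' Identify epilepsy patients and their index dates
#'
#' Applies the five claims-based epilepsy inclusion criteria over separate
#' encounter dates (distinct calendar days):
#' 1. two or more 345.xx diagnoses (except 345.3) on separate days;
#' 2. one or more 345.xx plus one or more 780.39 (convulsions) on separate
#'    days;
#' 3. a single 345.xx plus an antiepileptic-drug (AED) prescription at least
#'    one day after it;
#' 4. two or more 780.39 on separate days plus an AED prescription at least
#'    one day after the second 780.39;
#' 5. grand-mal status (345.3): two 345.3 at least 30 days apart, or 345.3
#'    and 780.39 at least 30 days apart, or 345.3 plus any 345.xx on
#'    separate days.
#'
#' The index date is the day of the first qualifying epilepsy diagnosis; for
#' multi-code definitions, the first code of the qualifying set. When several
#' criteria hold, the earliest resulting index day wins.
#'
#' @param events validated claim event table (see [validate_events]); codes
#'   are ICD-9-CM style (apply [map_diagnoses] crosswalks first if needed).
#' @param aed_codes character set of prescription codes counting as AED.
#' @return data.frame `patient_id`, `index_day`, `criterion` (first criterion
#'   attaining the index). Empty input yields an empty data.frame.
#' @export
identify_epilepsy_patients <- function(events, aed_codes) {
  events <- validate_events(events)
  empty <- data.frame(patient_id = character(0), index_day = numeric(0),
                      criterion = integer(0))
  if (nrow(events) == 0) return(empty)
  dt <- data.table::as.data.table(events)
  dx <- dt[dt$kind == "diagnosis"]
  rx <- dt[dt$kind == "prescription" & dt$code %in% aed_codes]
  res <- lapply(split(seq_len(nrow(dx)), dx$patient_id), function(ix) {
    sub <- dx[ix]
    pid <- sub$patient_id[1]
    ep <- sort(unique(sub$day[is_epilepsy_code(sub$code)]))
    st <- sort(unique(sub$day[is_status_code(sub$code)]))
    cv <- sort(unique(sub$day[is_convulsion_code(sub$code)]))
    aed <- sort(unique(rx$day[rx$patient_id == pid]))
    cand <- rep(NA_real_, 5)
    if (length(ep) >= 2) cand[1] <- ep[1]
    if (length(ep) >= 1 && length(cv) >= 1 && any(outer(ep, cv, "!=")))
      cand[2] <- ep[1]
    if (length(ep) >= 1 && any(aed > ep[1])) cand[3] <- ep[1]
    if (length(cv) >= 2 && any(aed > cv[2])) cand[4] <- cv[1]
    if (length(st) >= 1) {
      c5 <- c(
        if (length(st) >= 2 && (st[length(st)] - st[1]) >= 30) st[1],
        if (length(cv) >= 1 && any(cv - st[1] >= 30)) st[1],
        if (length(cv) >= 1 && any(st - cv[1] >= 30)) cv[1],
        if (length(ep) >= 1 && any(outer(st, ep, "!=")))
          min(st[1], ep[1]))
      if (length(c5)) cand[5] <- min(c5)
    }
    if (all(is.na(cand))) return(NULL)
    data.frame(patient_id = pid, index_day = min(cand, na.rm = TRUE),
               criterion = which(cand == min(cand, na.rm = TRUE))[1])
  })
  res <- do.call(rbind, res)
  if (is.null(res)) return(empty)
  rownames(res) <- NULL
  attr(res, "rejected") <- attr(events, "rejected")
  res
}

#' Apply cohort-level filters
#'
#' Keeps candidate epilepsy patients who have (1) at least
#' `config$lookback_days` of history before and `config$min_followup_days`
#' of follow-up after the index date within their coverage interval, (2) an
#' age at index inside `config$age_range` (boundary inclusive), and (3) any
#' AED prescription within the configured window. Each surviving patient is
#' annotated with the feature-history window `[index - lookback,
#' index + diagnosis_period)` and follow-up start.
#'
#' @param candidates data.frame from [identify_epilepsy_patients].
#' @param patients patient table: `patient_id`, `birth_year` (or `age` at
#'   index), `sex`, `region`, `plan`, `first_day`, `last_day`.
#' @param events validated claim event table (for the AED filter).
#' @param config a [cohort_config].
#' @param aed_codes AED prescription code set.
#' @return data.frame `patient_id`, `index_day`, `criterion`, `age`,
#'   `history_start`, `history_end` (exclusive), `followup_start`,
#'   `coverage_end`; attribute `exclusions` lists dropped patients with
#'   reasons. Class `claims_cohort`.
#' @export
apply_cohort_filters <- function(candidates, patients, events, config, aed_codes) {
  stopifnot(inherits(config, "cohort_config"))
  m <- match(candidates$patient_id, patients$patient_id)
  excl <- list()
  drop <- function(ids, why) if (length(ids))
    excl[[length(excl) + 1L]] <<- data.frame(patient_id = ids, reason = why)

  unknown <- is.na(m)
  drop(candidates$patient_id[unknown], "no patient record")
  cand <- candidates[!unknown, , drop = FALSE]
  pat <- patients[m[!unknown], , drop = FALSE]

  if ("age" %in% names(pat)) {
    age <- pat$age
  } else if ("birth_year" %in% names(pat)) {
    index_year <- config$epoch_year + cand$index_day / 365.25
    age <- floor(index_year - pat$birth_year)
  } else {
    age <- rep(NA_real_, nrow(pat))
  }
  ok_hist <- (cand$index_day - pat$first_day) >= config$lookback_days
  ok_fup <- (pat$last_day - cand$index_day) >= config$min_followup_days
  ok_age <- !is.na(age) & age >= config$age_range[1] & age <= config$age_range[2]

  rx <- events[events$kind == "prescription" & events$code %in% aed_codes, ,
               drop = FALSE]
  if (config$aed_window == "coverage") {
    lo <- pat$first_day; hi <- pat$last_day
  } else {
    lo <- cand$index_day - config$lookback_days
    hi <- cand$index_day + config$min_followup_days
  }
  ok_aed <- vapply(seq_len(nrow(cand)), function(i) {
    di <- rx$day[rx$patient_id == cand$patient_id[i]]
    any(di >= lo[i] & di <= hi[i])
  }, logical(1))

  drop(cand$patient_id[!ok_hist], "insufficient history")
  drop(cand$patient_id[ok_hist & !ok_fup], "insufficient follow-up")
  drop(cand$patient_id[ok_hist & ok_fup & is.na(age)], "missing age")
  drop(cand$patient_id[ok_hist & ok_fup & !is.na(age) & !ok_age],
       "age outside range")
  drop(cand$patient_id[ok_hist & ok_fup & ok_age & !ok_aed], "no AED treatment")

  keep <- ok_hist & ok_fup & ok_age & ok_aed
  out <- data.frame(patient_id = cand$patient_id[keep],
                    index_day = cand$index_day[keep],
                    criterion = cand$criterion[keep],
                    age = age[keep],
                    history_start = cand$index_day[keep] - config$lookback_days,
                    history_end = cand$index_day[keep] + config$diagnosis_period_days,
                    followup_start = cand$index_day[keep] + config$diagnosis_period_days,
                    coverage_end = pat$last_day[keep])
  attr(out, "exclusions") <- if (length(excl)) do.call(rbind, excl)
    else data.frame(patient_id = character(0), reason = character(0))
  class(out) <- c("claims_cohort", "data.frame")
  out
}

#' Pre-filter the code vocabulary
#'
#' Removes rarely observed diagnosis and substance codes: a code survives iff
#' it is carried by strictly more than `min_patients_per_code` cohort
#' patients *and* its patient frequency strictly exceeds `min_code_freq`
#' (either rarity condition suffices for removal).
#'
#' @param events claim event table.
#' @param cohort a `claims_cohort` (defines the patient denominator).
#' @param config a [cohort_config].
#' @return list of class `code_prefilter`: `vocabulary` (surviving codes),
#'   `removed` (data.frame `code`, `n_patients`, `freq`), `n_patients`.
#'   An empty surviving vocabulary is allowed, with a warning.
#' @export
prefilter_codes <- function(events, cohort, config) {
  ev <- events[events$patient_id %in% cohort$patient_id &
                 events$kind %in% c("diagnosis", "prescription"), , drop = FALSE]
  n_total <- nrow(cohort)
  dt <- data.table::as.data.table(ev)
  counts <- dt[, list(n_patients = length(unique(patient_id))), by = "code"]
  counts$freq <- counts$n_patients / n_total
  keep <- counts$n_patients > config$min_patients_per_code &
    counts$freq > config$min_code_freq
  if (!any(keep)) warning("pre-filter removed every code")
  structure(list(vocabulary = sort(counts$code[keep]),
                 removed = as.data.frame(counts[!keep][order(code)]),
                 n_patients = n_total),
            class = "code_prefilter")
}

#' Comorbidity definition
#'
#' A named comorbidity defined by a set of PheWAS concept codes.
#'
#' @param name comorbidity name (e.g. `"anxiety"`).
#' @param phewas_codes non-empty character set of concept codes.
#' @return Object of class `comorbidity_definition`.
#' @export
comorbidity_definition <- function(name, phewas_codes) {
  phewas_codes <- unique(as.character(phewas_codes))
  if (length(phewas_codes) == 0 || any(!nzchar(phewas_codes)))
    stop("comorbidity '", name, "' needs a non-empty code set")
  structure(list(name = name, phewas_codes = phewas_codes),
            class = "comorbidity_definition")
}

#' Build incident-comorbidity survival labels
#'
#' Partitions the cohort, for one comorbidity, into exactly one of:
#' * **excluded / prior**: any defining concept observed before the end of
#'   the diagnosis period (no observation of the target comorbidity may
#'   appear in the medical history);
#' * **excluded / lag window**: first defining concept within
#'   `incident_lag_months` after the diagnosis period — neither a clean
#'   incident case nor safely censorable (keeping them censored would leak
#'   events);
#' * **incident**: first defining concept at least `incident_lag_months`
#'   after the diagnosis period; `status = 1`, `time` = months from index to
#'   that diagnosis, rounded up to whole 30-day months;
#' * **censored**: no defining concept through end of coverage; `status = 0`,
#'   `time` = months from index to coverage end, rounded up.
#'
#' @param cohort a `claims_cohort`.
#' @param concept_events diagnosis events mapped to PheWAS concepts
#'   (`patient_id`, `day`, `code`).
#' @param defn a [comorbidity_definition].
#' @param config a [cohort_config].
#' @return list: `labels` ([survival_labels] with `patient_id`), `excluded`
#'   (data.frame `patient_id`, `reason`).
#' @export
build_comorbidity_labels <- function(cohort, concept_events, defn, config) {
  stopifnot(inherits(defn, "comorbidity_definition"),
            inherits(config, "cohort_config"))
  hits <- concept_events[concept_events$code %in% defn$phewas_codes, ,
                         drop = FALSE]
  first_hit <- tapply(hits$day, hits$patient_id, min)
  lag_days <- config$incident_lag_months * config$month_days

  pid <- cohort$patient_id
  fh <- first_hit[match(pid, names(first_hit))]
  incident_from <- cohort$history_end + lag_days

  status <- integer(nrow(cohort)); time <- numeric(nrow(cohort))
  reason <- rep(NA_character_, nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    if (!is.na(fh[i]) && fh[i] < cohort$history_end[i]) {
      reason[i] <- "prior_comorbidity"
    } else if (!is.na(fh[i]) && fh[i] < incident_from[i]) {
      reason[i] <- "lag_window"
    } else if (!is.na(fh[i]) && fh[i] <= cohort$coverage_end[i]) {
      status[i] <- 1L
      time[i] <- ceiling((fh[i] - cohort$index_day[i]) / config$month_days)
    } else {
      status[i] <- 0L
      time[i] <- ceiling((cohort$coverage_end[i] - cohort$index_day[i]) /
                           config$month_days)
    }
  }
  keep <- is.na(reason)
  list(labels = survival_labels(time[keep], status[keep], patient_id = pid[keep]),
       excluded = data.frame(patient_id = pid[!keep], reason = reason[!keep]))
}
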