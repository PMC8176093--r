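## Shared fixtures, built in code and cached per test run.

.fixture_env <- new.env()

## small featurized synthetic cohort (~200 labelled patients)
small_data <- function() {
  if (is.null(.fixture_env$small)) {
    .fixture_env$small <- suppressWarnings(suppressMessages(
      synthetic_training_data(sim_config(n_patients = 250, seed = 73))))
  }
  .fixture_env$small
}

## random right-censored survival labels for metric oracles
random_labels <- function(n, event_rate = 1, censor_rate = 0.7,
                          round_months = TRUE) {
  ev <- rexp(n, event_rate)
  cs <- rexp(n, censor_rate)
  time <- pmin(ev, cs)
  if (round_months) time <- ceiling(time * 4) / 4  # induces ties
  survival_labels(time, as.integer(ev <= cs))
}

## hand-written long event table builder
ev_row <- function(patient_id, day, kind = "diagnosis", code,
                   duration_days = NA_real_, quantity = NA_real_) {
  data.frame(patient_id = patient_id, day = day, kind = kind, code = code,
             duration_days = duration_days, quantity = quantity)
}

## minimal single-subdomain schema + cube set built directly from a matrix
## (features x patients), optionally time-dependent with T bins
toy_cubes <- function(X, T_bins = 1L, subdomain = "phewas",
                      time_dependent = TRUE) {
  d <- nrow(X); n <- ncol(X)
  schema <- build_schema(
    stats::setNames(list(sprintf("f%02d", seq_len(d))), subdomain))
  a <- array(0, dim = c(d, T_bins, n))
  for (t in seq_len(T_bins)) a[, t, ] <- X
  structure(list(sub = stats::setNames(list(a), subdomain),
                 patient_ids = sprintf("p%03d", seq_len(n)),
                 T_bins = as.integer(T_bins), schema = schema,
                 scaling = NULL),
            class = "cube_set")
}
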