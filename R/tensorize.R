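#' Bin daily events onto the monthly grid
#'
#' Maps each event at day `d` to 30-day bin `floor((d - window_start) /
#' month_days)` (0-based). The number of bins is `T = floor(history_days /
#' month_days)` — 15 for the standard 456-day window; the few remainder days
#' at the window end are merged into the last bin, so events in the remainder
#' land in bin `T - 1` rather than being lost. Events at or beyond
#' `window_start + history_days` are discarded from the cube.
#'
#' @param events data.frame with at least `day`.
#' @param window_start first day of the history window; an event before it is
#'   a history violation and raises an error.
#' @param history_days window length in days (default 456).
#' @param month_days days per bin (default 30).
#' @return `events` restricted to the window, with an integer `bin` column
#'   and attribute `T_bins`.
#' @export
bin_events <- function(events, window_start, history_days = 456L,
                       month_days = 30L) {
  T_bins <- floor(history_days / month_days)
  rel <- events$day - window_start
  if (any(rel < 0))
    stop("event before window start (history violation): day ",
         events$day[which(rel < 0)[1]])
  keep <- rel < history_days
  out <- events[keep, , drop = FALSE]
  out$bin <- pmin(floor((out$day - window_start) / month_days), T_bins - 1L)
  attr(out, "T_bins") <- as.integer(T_bins)
  out
}

#' Static (general-domain) feature extraction
#'
#' Expands the patient table into the general domain's one-hot/continuous
#' feature layout: `age` (continuous, age at index), one indicator per
#' observed `sex`, `region` and `plan` level, and `hospital_days` when
#' present. Returns both the long-format values and the per-subdomain
#' vocabulary to feed [build_schema].
#'
#' @param patients patient table (`patient_id`, `sex`, `region`, `plan`,
#'   optionally `hospital_days`).
#' @param cohort a `claims_cohort` (supplies age at index).
#' @return list with `values` (data.frame `patient_id`, `subdomain`,
#'   `feature`, `value`) and `vocab` (named list subdomain -> features).
#' @export
static_features <- function(patients, cohort) {
  pat <- patients[match(cohort$patient_id, patients$patient_id), , drop = FALSE]
  rows <- list(data.frame(patient_id = cohort$patient_id,
                          subdomain = "demographics", feature = "age",
                          value = cohort$age))
  onehot <- function(col, prefix, subdomain) {
    if (!col %in% names(pat)) return(NULL)
    v <- as.character(pat[[col]])
    data.frame(patient_id = cohort$patient_id, subdomain = subdomain,
               feature = paste0(prefix, ":", v), value = 1)
  }
  rows <- c(rows, list(onehot("sex", "sex", "demographics"),
                       onehot("plan", "plan", "demographics"),
                       onehot("region", "region", "region")))
  if ("hospital_days" %in% names(pat))
    rows <- c(rows, list(data.frame(patient_id = cohort$patient_id,
                                    subdomain = "demographics",
                                    feature = "hospital_days",
                                    value = pat$hospital_days)))
  values <- do.call(rbind, rows)
  vocab <- lapply(split(values$feature, values$subdomain),
                  function(f) sort(unique(f)))
  list(values = values, vocab = vocab)
}

#' Fit min-max scaling constants for continuous static features
#'
#' Scaling is fitted on the training split only and persisted with the
#' model; one-hot features pass through unscaled.
#'
#' @param static_values long static values from [static_features].
#' @param train_ids patient ids of the training split.
#' @param continuous feature names to scale (default `age`,
#'   `hospital_days`).
#' @return named list feature -> `c(min, max)`.
#' @export
fit_static_scaling <- function(static_values, train_ids,
                               continuous = c("age", "hospital_days")) {
  tr <- static_values[static_values$patient_id %in% train_ids &
                        static_values$feature %in% continuous, , drop = FALSE]
  out <- lapply(split(tr$value, tr$feature), function(v)
    c(min = min(v), max = max(v)))
  out
}

apply_scaling <- function(feature, value, scaling) {
  if (is.null(scaling) || !feature %in% names(scaling)) return(value)
  r <- scaling[[feature]]
  if (r["max"] <= r["min"]) return(rep(0, length(value)))
  pmin(pmax((value - r["min"]) / (r["max"] - r["min"]), 0), 1)
}

#' Assemble multimodal patient data cubes
#'
#' Converts binned feature events plus static values into the model input:
#' one `d_s x T x n` binary (or weighted) array per time-dependent subdomain
#' and one `d_s x n` matrix per static subdomain, feature order taken from
#' the schema. Multiple occurrences of a feature within one bin collapse to
#' presence (weighted subdomains keep the maximum weight); prescriptions
#' spanning several bins via `duration_days` are marked present in every
#' covered bin. Assembly is independent of input event order.
#'
#' @param feature_events data.frame from [expand_knowledge] (`patient_id`,
#'   `day`, `subdomain`, `feature`, `weight`, `duration_days`).
#' @param schema a `feature_schema`.
#' @param cohort a `claims_cohort` (defines each patient's window).
#' @param static_values optional long static values from [static_features].
#' @param scaling optional constants from [fit_static_scaling].
#' @param history_days,month_days window geometry (defaults 456 / 30).
#' @param on_unknown what to do with feature events absent from the schema:
#'   `"error"` (schema drift guard, default) or `"drop"` (pre-filtered
#'   vocabularies make dropped codes expected in the pipeline).
#' @return Object of class `cube_set`: list with `sub` (named list of
#'   arrays/matrices), `patient_ids`, `T_bins`, `schema`, `scaling`.
#' @export
assemble_cubes <- function(feature_events, schema, cohort,
                           static_values = NULL, scaling = NULL,
                           history_days = 456L, month_days = 30L,
                           on_unknown = c("error", "drop")) {
  on_unknown <- match.arg(on_unknown)
  T_bins <- as.integer(floor(history_days / month_days))
  n <- nrow(cohort)
  pidx <- stats::setNames(seq_len(n), cohort$patient_id)

  fe <- feature_events[feature_events$patient_id %in% cohort$patient_id, ,
                       drop = FALSE]
  if (!"weight" %in% names(fe)) fe$weight <- 1
  if (!"duration_days" %in% names(fe)) fe$duration_days <- NA_real_
  pi <- pidx[as.character(fe$patient_id)]
  ws <- cohort$history_start[pi]
  rel <- fe$day - ws
  keep <- rel >= 0 & rel < history_days
  fe <- fe[keep, , drop = FALSE]; pi <- pi[keep]; rel <- rel[keep]

  sub <- list()
  for (s in schema$subdomains) {
    if (!s$time_dependent) next
    rows <- which(fe$subdomain == s$name)
    fidx <- match(fe$feature[rows], s$features)
    if (anyNA(fidx)) {
      if (on_unknown == "error")
        stop("feature(s) absent from schema subdomain '", s$name, "': ",
             paste(utils::head(unique(fe$feature[rows][is.na(fidx)]), 5),
                   collapse = ", "))
      rows <- rows[!is.na(fidx)]; fidx <- fidx[!is.na(fidx)]
    }
    arr <- array(0, dim = c(length(s$features), T_bins, n))
    if (length(rows)) {
      b0 <- floor(rel[rows] / month_days)
      dur <- fe$duration_days[rows]
      b1 <- ifelse(is.na(dur) | dur <= 0, b0,
                   floor((rel[rows] + dur - 1) / month_days))
      b0 <- pmin(b0, T_bins - 1L); b1 <- pmin(b1, T_bins - 1L)
      span <- b1 - b0 + 1L
      ii <- rep(fidx, span)
      bb <- unlist(lapply(seq_along(rows), function(k) b0[k]:b1[k]))
      pp <- rep(pi[rows], span)
      wwt <- rep(fe$weight[rows], span)
      flat <- ii + length(s$features) * (bb + T_bins * (pp - 1L))
      if (s$weighted) {
        o <- order(wwt)  # later assignments win; ascending keeps the max
        arr[flat[o]] <- wwt[o]
      } else {
        arr[flat] <- 1
      }
    }
    sub[[s$name]] <- arr
  }
  for (s in schema$subdomains) {
    if (s$time_dependent) next
    mat <- matrix(0, nrow = length(s$features), ncol = n)
    if (!is.null(static_values)) {
      sv <- static_values[static_values$subdomain == s$name &
                            static_values$patient_id %in% cohort$patient_id, ,
                          drop = FALSE]
      fidx <- match(sv$feature, s$features)
      if (anyNA(fidx)) {
        if (on_unknown == "error")
          stop("static feature(s) absent from schema subdomain '", s$name, "'")
        sv <- sv[!is.na(fidx), , drop = FALSE]; fidx <- fidx[!is.na(fidx)]
      }
      val <- sv$value
      for (f in unique(sv$feature))
        val[sv$feature == f] <- apply_scaling(f, val[sv$feature == f], scaling)
      mat[cbind(fidx, pidx[as.character(sv$patient_id)])] <- val
    }
    sub[[s$name]] <- mat
  }
  structure(list(sub = sub, patient_ids = cohort$patient_id, T_bins = T_bins,
                 schema = schema, scaling = scaling),
            class = "cube_set")
}

#' Assemble the cube of a single patient
#'
#' Convenience wrapper around [assemble_cubes] for one patient; an empty
#' history yields all-zero tensors with the static vector still populated.
#'
#' @inheritParams assemble_cubes
#' @param patient_row one-row `claims_cohort`.
#' @return list of `d_s x T` matrices / length-`d_s` static vectors.
#' @export
assemble_cube <- function(feature_events, schema, patient_row, ...) {
  cs <- assemble_cubes(feature_events, schema, patient_row, ...)
  lapply(cs$sub, function(a) if (length(dim(a)) == 3) a[, , 1] else a[, 1])
}

#' @export
print.cube_set <- function(x, ...) {
  cat("cube_set:", length(x$patient_ids), "patients, T =", x$T_bins, "bins\n")
  for (nm in names(x$sub)) {
    d <- dim(x$sub[[nm]])
    cat(sprintf("  %-18s %s\n", nm, paste(d, collapse = " x ")))
  }
  invisible(x)
}

#' Subset a cube set by patient index
#'
#' @param cubes a `cube_set`.
#' @param idx integer patient indices.
#' @return A `cube_set` restricted to those patients.
#' @export
subset_cubes <- function(cubes, idx) {
  sub <- lapply(cubes$sub, function(a)
    if (length(dim(a)) == 3) a[, , idx, drop = FALSE]
    else a[, idx, drop = FALSE])
  structure(list(sub = sub, patient_ids = cubes$patient_ids[idx],
                 T_bins = cubes$T_bins, schema = cubes$schema,
                 scaling = cubes$scaling),
            class = "cube_set")
}

#' Number of patients in a cube set
#'
#' @param cubes a `cube_set`.
#' @return Integer count.
#' @export
n_patients <- function(cubes) length(cubes$patient_ids)
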