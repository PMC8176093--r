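#' Survival labels
#'
#' Light container for right-censored survival outcomes on the monthly time
#' scale used throughout the package: `time` is months from the index date to
#' the first comorbidity diagnosis (if `status == 1`) or to the end of
#' observation (if `status == 0`).
#'
#' @param time positive numeric vector of observed times (months).
#' @param status 0/1 event indicator (1 = comorbidity diagnosed, 0 = censored).
#' @param patient_id optional identifiers carried along.
#' @return An object of class `survival_labels`: a data.frame with columns
#'   `time`, `status` (and `patient_id` when given).
#' @export
survival_labels <- function(time, status, patient_id = NULL) {
  time <- as.numeric(time)
  status <- as.integer(status)
  if (length(time) != length(status))
    stop("'time' and 'status' must have equal length")
  if (any(!is.finite(time)) || any(time <= 0))
    stop("survival times must be finite and > 0")
  if (!all(status %in% c(0L, 1L)))
    stop("'status' must be 0 (censored) or 1 (event)")
  out <- data.frame(time = time, status = status)
  if (!is.null(patient_id)) out$patient_id <- patient_id
  class(out) <- c("survival_labels", "data.frame")
  out
}

## risk-set bookkeeping shared by the partial likelihood, its gradient and the
## Breslow estimator: sort descending in time so that the risk set
## {j : y_j >= y_i} is a prefix; ties share one prefix end (Breslow convention)
cox_prepare <- function(scores, time, status) {
  stopifnot(length(scores) == length(time), length(time) == length(status))
  ord <- order(time, decreasing = TRUE)
  t_s <- time[ord]
  n <- length(t_s)
  ## last index of each tie block == size of the risk set for that time
  block_end <- which(rev(!duplicated(rev(t_s))))
  r <- rep(block_end, times = diff(c(0L, block_end)))
  list(ord = ord, s = scores[ord], t = t_s, d = as.numeric(status)[ord], r = r, n = n)
}

#' Cox partial log-likelihood
#'
#' The (unpenalized) partial log-likelihood
#' \deqn{l = \sum_i \delta_i \big[ s_i - \log \sum_{j: y_j \ge y_i} e^{s_j} \big]}
#' of risk scores under a proportional-hazards model, with tied event times
#' handled in the Breslow convention (all tied events share one risk-set
#' denominator). This is the *log-likelihood*; trainers minimize its negative.
#'
#' @param scores numeric vector of model risk scores (one per subject).
#' @param labels a [survival_labels] object (or data.frame with `time`,
#'   `status`).
#' @return The scalar partial log-likelihood. If there are no events the
#'   result is 0, with a warning.
#' @examples
#' lab <- survival_labels(c(1, 2, 3), c(1, 1, 1))
#' cox_partial_loglik(c(0, 0, 0), lab)  # -log 3 - log 2
#' @export
cox_partial_loglik <- function(scores, labels) {
  if (sum(labels$status) == 0) {
    warning("no events (all observations censored); partial log-likelihood is 0")
    return(0)
  }
  p <- cox_prepare(scores, labels$time, labels$status)
  m <- max(p$s)
  lse <- log(cumsum(exp(p$s - m))) + m   # lse[k] = logsumexp(s[1..k])
  sum(p$d * (p$s - lse[p$r]))
}

## gradient of the partial log-likelihood w.r.t. each score, original order;
## dl/ds_k = delta_k - exp(s_k) * sum_{i: y_i <= y_k, delta_i = 1} 1 / S_i
cox_loglik_grad <- function(scores, time, status) {
  if (sum(status) == 0) return(numeric(length(scores)))
  p <- cox_prepare(scores, time, status)
  m <- max(p$s)
  S <- cumsum(exp(p$s - m))              # risk-set sums, scaled by exp(-m)
  w <- p$d / S[p$r]                      # per-event 1/S_i (scaled)
  cw <- cumsum(w)
  ## subject k belongs to risk set R_i iff k <= r_i; r is nondecreasing, so the
  ## events with r_i >= k form a suffix: total - cumsum up to the last i with r_i < k
  n_less <- findInterval(seq_len(p$n) - 0.5, p$r)
  suffix <- cw[p$n] - c(0, cw)[n_less + 1L]
  g_sorted <- p$d - exp(p$s - m) * suffix
  g <- numeric(p$n)
  g[p$ord] <- g_sorted
  g
}

#' Penalized training objective
#'
#' The minimized quantity: negative Cox partial log-likelihood plus groupwise
#' elastic-net penalties
#' \deqn{-l + \sum_s (\lambda_s^{\ell 1} \|W_s\|_1 + \lambda_s^{\ell 2} \|W_s\|_2^2)
#'       + \lambda_D^{\ell 1} \|W_D\|_1 + \lambda_D^{\ell 2} \|W_D\|_2^2}
#' where \eqn{W_s} are the input-to-first-hidden-layer weights of subdomain
#' \eqn{s} and \eqn{W_D} the weights feeding the output unit. The \eqn{\ell_2}
#' term is the squared norm (classical elastic net); set
#' `squared_l2 = FALSE` for the unsquared group-lasso variant.
#'
#' @param model a fitted or freshly built [build_network] model.
#' @param scores risk scores for the batch (as produced by [risk_score]).
#' @param labels [survival_labels] for the batch.
#' @param squared_l2 use the squared \eqn{\ell_2} norm (default `TRUE`).
#' @return The scalar objective, with attribute `"penalties"`: a named vector
#'   of per-group penalty contributions.
#' @export
penalized_loss <- function(model, scores, labels, squared_l2 = TRUE) {
  nl <- -cox_partial_loglik(scores, labels)
  pen <- penalty_terms(model, squared_l2 = squared_l2)
  structure(nl + sum(pen), penalties = pen)
}

## per-group elastic-net penalty values for a risk_model
penalty_terms <- function(model, squared_l2 = TRUE) {
  hp <- model$hp
  l2f <- if (squared_l2) function(w) sum(w^2) else function(w) sqrt(sum(w^2))
  pen <- c()
  for (s in names(model$groups$subdomain)) {
    W <- model$par[[model$groups$subdomain[[s]]]]
    pen[paste0(s, ".l1")] <- group_lambda(hp$lambda$l1, s) * sum(abs(W))
    pen[paste0(s, ".l2")] <- group_lambda(hp$lambda$l2, s) * l2f(W)
  }
  WD <- model$par[[model$groups$output]]
  pen["output.l1"] <- hp$lambda$l1_out * sum(abs(WD))
  pen["output.l2"] <- hp$lambda$l2_out * l2f(WD)
  pen
}

group_lambda <- function(lam, s) {
  if (length(lam) == 1L && is.null(names(lam))) return(as.numeric(lam))
  if (!s %in% names(lam)) stop("no penalty weight for group '", s, "'")
  as.numeric(lam[[s]])
}

#' Breslow estimator of the cumulative baseline hazard
#'
#' Nonparametric step-function estimate
#' \deqn{H_0(t) = \sum_{i: y_i \le t} \delta_i / \sum_{j: y_j \ge y_i} e^{s_j}}
#' given fitted risk scores. Tied event times share one risk-set denominator.
#'
#' @inheritParams cox_partial_loglik
#' @return Object of class `baseline_hazard` with fields `time` (unique event
#'   times, increasing) and `hazard` (cumulative hazard, nondecreasing).
#'   `H0(t) = 0` before the first event. With no events the function is
#'   identically zero (with a warning).
#' @export
breslow_cumulative_hazard <- function(scores, labels) {
  if (sum(labels$status) == 0) {
    warning("no events; baseline hazard is identically zero")
    return(structure(list(time = numeric(0), hazard = numeric(0)),
                     class = "baseline_hazard"))
  }
  p <- cox_prepare(scores, labels$time, labels$status)
  m <- max(p$s)
  S <- cumsum(exp(p$s - m)) * exp(m)     # prefix risk-set sums
  ev <- p$d > 0
  ## one increment per unique event time: (#events at t) / riskset sum at t
  inc <- tapply(1 / S[p$r][ev], p$t[ev], sum)
  tt <- as.numeric(names(inc))
  o <- order(tt)
  structure(list(time = tt[o], hazard = cumsum(as.numeric(inc)[o])),
            class = "baseline_hazard")
}

## right-continuous evaluation of a baseline_hazard at arbitrary times
eval_hazard <- function(h0, times) {
  if (length(h0$time) == 0) return(rep(0, length(times)))
  idx <- findInterval(times, h0$time)
  c(0, h0$hazard)[idx + 1L]
}

#' Patient-specific survival curve
#'
#' Converts a risk score and a baseline cumulative hazard into the
#' conditional event-free probability
#' \deqn{S(t \mid x) = \exp\{-e^{s} H_0(t)\}.}
#' The relative hazard of two patients is `exp(score1 - score2)` (see
#' [hazard_ratio]).
#'
#' @param score scalar risk score.
#' @param h0 a `baseline_hazard` from [breslow_cumulative_hazard].
#' @param times optional evaluation grid; defaults to `c(0, h0$time)`.
#' @return Object of class `survival_curve` with fields `time` and `surv`
#'   (values in `[0,1]`, nonincreasing, `S(0) = 1`).
#' @export
survival_curve <- function(score, h0, times = NULL) {
  stopifnot(length(score) == 1L, is.finite(score))
  if (is.null(times)) times <- c(0, h0$time)
  surv <- exp(-exp(score) * eval_hazard(h0, times))
  structure(list(time = times, surv = surv, score = score),
            class = "survival_curve")
}

#' Relative hazard of two risk scores
#'
#' Under the proportional-hazards model the hazard ratio of patient 1 versus
#' patient 2 is `exp(score1 - score2)`, independent of time.
#'
#' @param score1,score2 scalar risk scores.
#' @return The hazard ratio `exp(score1 - score2)`.
#' @examples
#' hazard_ratio(-17.29, -16.71)  # ~0.56: roughly half the reference hazard
#' @export
hazard_ratio <- function(score1, score2) exp(score1 - score2)

#' Kaplan-Meier product-limit estimator
#'
#' Product-limit estimate of the survival function of either the event
#' distribution (`mode = "event"`) or the censoring distribution
#' (`mode = "censoring"`, indicator flipped to `1 - status`); the latter is
#' the \eqn{\hat G} used for inverse-probability-of-censoring weights.
#'
#' @inheritParams cox_partial_loglik
#' @param mode which distribution to estimate.
#' @return Object of class `km_curve` with fields `time` (distinct times with
#'   at least one indicated event), `surv` (the step values after each such
#'   time), `n_risk`, `n_event`, and `mode`. Evaluate with [km_eval].
#' @export
kaplan_meier <- function(labels, mode = c("event", "censoring")) {
  mode <- match.arg(mode)
  if (nrow(labels) == 0) stop("empty labels")
  d <- if (mode == "event") labels$status else 1L - labels$status
  tt <- labels$time
  ut <- sort(unique(tt))
  n_risk <- vapply(ut, function(u) sum(tt >= u), numeric(1))
  n_event <- vapply(ut, function(u) sum(tt == u & d == 1L), numeric(1))
  keep <- n_event > 0
  surv <- cumprod(1 - n_event[keep] / n_risk[keep])
  structure(list(time = ut[keep], surv = surv,
                 n_risk = n_risk[keep], n_event = n_event[keep], mode = mode),
            class = "km_curve")
}

#' Evaluate a Kaplan-Meier curve
#'
#' Right-continuous evaluation: `km_eval(km, t)` is the estimated probability
#' of remaining event-free *through* time `t` (so the curve has already
#' dropped at an event time).
#'
#' @param km a `km_curve` from [kaplan_meier].
#' @param times numeric vector of evaluation times.
#' @return Numeric vector of survival probabilities.
#' @export
km_eval <- function(km, times) {
  if (length(km$time) == 0) return(rep(1, length(times)))
  idx <- findInterval(times, km$time)
  c(1, km$surv)[idx + 1L]
}

#' @export
print.baseline_hazard <- function(x, ...) {
  cat("Breslow cumulative baseline hazard:", length(x$time), "event times\n")
  if (length(x$time)) cat("  H0 range: [0, ", format(max(x$hazard)), "]\n", sep = "")
  invisible(x)
}

#' @export
print.survival_curve <- function(x, ...) {
  cat("Survival curve for risk score", format(x$score), "over",
      length(x$time), "time points\n")
  invisible(x)
}

#' Export a step function as a two-column table
#'
#' @param x a `baseline_hazard`, `survival_curve` or `km_curve`.
#' @param path file to write (tab-separated, columns `time`, `value`).
#' @return The written data.frame, invisibly.
#' @export
write_step_function <- function(x, path) {
  value <- if (inherits(x, "baseline_hazard")) x$hazard else x$surv
  df <- data.frame(time = x$time, value = value)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(df)
}
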