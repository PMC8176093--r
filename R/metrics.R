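#' Harrell's concordance index
#'
#' Fraction of comparable patient pairs whose predicted risk ordering matches
#' the observed event ordering. A pair (i, j) is comparable when subject i has
#' an event and either `time_i < time_j`, or `time_i == time_j` with j
#' censored. Concordance means the earlier event carries the higher risk
#' score; tied scores count 1/2.
#'
#' @param scores numeric risk scores (higher = riskier).
#' @param labels a [survival_labels] object.
#' @return Scalar in `[0, 1]`, with attribute `n_comparable`. If no pair is
#'   comparable the result is `NA` with a warning.
#' @export
harrell_c <- function(scores, labels) {
  t <- labels$time; d <- labels$status; s <- scores
  n <- length(t)
  Ti <- matrix(t, n, n); Tj <- t(Ti)
  Si <- matrix(s, n, n); Sj <- t(Si)
  Di <- matrix(d, n, n); Dj <- t(Di)
  comp <- (Di == 1) & (Ti < Tj | (Ti == Tj & Dj == 0))
  diag(comp) <- FALSE
  nc <- sum(comp)
  if (nc == 0) {
    warning("no comparable pairs; concordance undefined")
    return(structure(NA_real_, n_comparable = 0L))
  }
  conc <- sum(comp & Si > Sj) + 0.5 * sum(comp & Si == Sj)
  structure(conc / nc, n_comparable = nc)
}

#' Uno's IPCW concordance index
#'
#' Censoring-robust concordance: comparable pairs are reweighted by the
#' inverse squared Kaplan-Meier estimate of the censoring distribution,
#' \deqn{\hat C_\tau = \frac{\sum_i \sum_j \Delta_i \hat G(X_i)^{-2}
#'   I(X_i < X_j,\, X_i < \tau)\, c_{ij}}
#'   {\sum_i \sum_j \Delta_i \hat G(X_i)^{-2} I(X_i < X_j,\, X_i < \tau)}}
#' with \eqn{c_{ij} = I(\mathrm{risk}_i > \mathrm{risk}_j)} and tied risk
#' scores counting 1/2. Without censoring (\eqn{\hat G \equiv 1}) and with
#' `tau` beyond the last observed time this reduces to Harrell's C restricted
#' to strictly ordered times.
#'
#' @inheritParams harrell_c
#' @param tau truncation time; pairs with `time_i >= tau` are ignored.
#'   Default: the largest event time with positive censoring-survival
#'   estimate, which avoids the unstable tail.
#' @param G optional pre-computed censoring `km_curve` (e.g. from a training
#'   split); defaults to [kaplan_meier] in censoring mode on `labels`.
#' @return Object of class `concordance_result`: list with `estimate`, `tau`,
#'   `n_comparable` (pair count), `numerator`, `denominator`, and `G` (the
#'   censoring curve used).
#' @export
uno_c <- function(scores, labels, tau = NULL, G = NULL) {
  t <- labels$time; d <- labels$status; s <- scores
  if (is.null(G)) G <- kaplan_meier(labels, mode = "censoring")
  if (is.null(tau)) tau <- default_tau(labels, G)
  Gt <- km_eval(G, t)
  n <- length(t)
  Ti <- matrix(t, n, n); Tj <- t(Ti)
  Si <- matrix(s, n, n); Sj <- t(Si)
  comp <- (matrix(d, n, n) == 1) & (Ti < Tj) & (Ti < tau)
  if (any(comp & matrix(Gt, n, n) <= 0))
    stop("censoring survival G(X_i) = 0 for a contributing pair; lower 'tau'")
  W <- matrix(Gt^-2, n, n)
  W[!comp] <- 0
  den <- sum(W)
  if (den == 0) {
    warning("no comparable pairs below tau; Uno's C undefined")
    return(structure(list(estimate = NA_real_, tau = tau, n_comparable = 0L,
                          numerator = 0, denominator = 0, G = G),
                     class = "concordance_result"))
  }
  num <- sum(W * ((Si > Sj) + 0.5 * (Si == Sj)))
  structure(list(estimate = num / den, tau = tau, n_comparable = sum(comp),
                 numerator = num, denominator = den, G = G),
            class = "concordance_result")
}

## largest event time whose censoring-survival estimate is still positive
default_tau <- function(labels, G = NULL) {
  if (is.null(G)) G <- kaplan_meier(labels, mode = "censoring")
  ev <- labels$time[labels$status == 1]
  if (length(ev) == 0) return(max(labels$time))
  ok <- ev[km_eval(G, ev) > 0]
  if (length(ok) == 0) min(ev) else max(ok) + 1e-9
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("Uno's C = %.4f (tau = %.3g, %d comparable pairs)\n",
              x$estimate, x$tau, x$n_comparable))
  invisible(x)
}

#' Time-dependent IPCW AUC
#'
#' Cumulative/dynamic discrimination over time: at each grid time `t`, cases
#' are subjects with an observed event at or before `t` and controls are
#' subjects still event-free beyond `t`; case/control pairs are weighted by
#' \eqn{\hat G(X_i)^{-2}} as in [uno_c], tied scores counting 1/2.
#'
#' @inheritParams uno_c
#' @param times evaluation grid (within the observed time range).
#' @return data.frame with columns `time`, `auc`, `n_cases`, `n_controls`;
#'   `auc` is `NA` (flagged, not dropped) where no case or no control exists.
#' @export
auc_t <- function(scores, labels, times, G = NULL) {
  t <- labels$time; d <- labels$status; s <- scores
  if (is.null(G)) G <- kaplan_meier(labels, mode = "censoring")
  Gt <- km_eval(G, t)
  out <- data.frame(time = times, auc = NA_real_,
                    n_cases = 0L, n_controls = 0L)
  for (k in seq_along(times)) {
    tk <- times[k]
    case <- which(t <= tk & d == 1)
    ctrl <- which(t > tk)
    out$n_cases[k] <- length(case)
    out$n_controls[k] <- length(ctrl)
    if (length(case) == 0 || length(ctrl) == 0) next
    w <- Gt[case]^-2
    num <- 0; den <- 0
    for (ii in seq_along(case)) {
      i <- case[ii]
      num <- num + w[ii] * sum((s[i] > s[ctrl]) + 0.5 * (s[i] == s[ctrl]))
      den <- den + w[ii] * length(ctrl)
    }
    out$auc[k] <- num / den
  }
  out
}
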