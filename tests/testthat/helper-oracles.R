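## Independent brute-force oracles, deliberately written as plain double
## loops / enumerations so they share no code path with the implementation.

oracle_cox_loglik <- function(scores, time, status) {
  l <- 0
  for (i in seq_along(time)) {
    if (status[i] == 1) {
      rs <- 0
      for (j in seq_along(time)) if (time[j] >= time[i]) rs <- rs + exp(scores[j])
      l <- l + scores[i] - log(rs)
    }
  }
  l
}

oracle_breslow <- function(scores, time, status, at) {
  H <- 0
  for (i in seq_along(time)) {
    if (status[i] == 1 && time[i] <= at) {
      rs <- 0
      for (j in seq_along(time)) if (time[j] >= time[i]) rs <- rs + exp(scores[j])
      H <- H + 1 / rs
    }
  }
  H
}

oracle_harrell <- function(scores, time, status) {
  num <- 0; den <- 0
  for (i in seq_along(time)) for (j in seq_along(time)) {
    if (i == j) next
    comparable <- status[i] == 1 &&
      (time[i] < time[j] || (time[i] == time[j] && status[j] == 0))
    if (!comparable) next
    den <- den + 1
    if (scores[i] > scores[j]) num <- num + 1
    else if (scores[i] == scores[j]) num <- num + 0.5
  }
  if (den == 0) return(NA_real_)
  num / den
}

## product-limit estimate of the censoring distribution, evaluated at t
## (right-continuous), written as an explicit loop
oracle_G <- function(time, status, t) {
  ut <- sort(unique(time))
  S <- 1
  for (u in ut) {
    if (u > t) break
    n_risk <- sum(time >= u)
    n_cens <- sum(time == u & status == 0)
    if (n_cens > 0) S <- S * (1 - n_cens / n_risk)
  }
  S
}

oracle_uno <- function(scores, time, status, tau) {
  num <- 0; den <- 0
  for (i in seq_along(time)) for (j in seq_along(time)) {
    if (i == j) next
    if (status[i] != 1 || !(time[i] < time[j]) || !(time[i] < tau)) next
    w <- oracle_G(time, status, time[i])^-2
    den <- den + w
    if (scores[i] > scores[j]) num <- num + w
    else if (scores[i] == scores[j]) num <- num + 0.5 * w
  }
  if (den == 0) return(NA_real_)
  num / den
}

oracle_auc_t <- function(scores, time, status, t) {
  num <- 0; den <- 0
  for (i in seq_along(time)) for (j in seq_along(time)) {
    if (status[i] != 1 || time[i] > t || time[j] <= t) next
    w <- oracle_G(time, status, time[i])^-2
    den <- den + w
    if (scores[i] > scores[j]) num <- num + w
    else if (scores[i] == scores[j]) num <- num + 0.5 * w
  }
  if (den == 0) return(NA_real_)
  num / den
}

## Shapley values by averaging marginal contributions over all orderings
## (the permutation definition, distinct from the subset-weight formula)
oracle_shapley_perm <- function(f, x, reference) {
  M <- length(x)
  perms <- combinat_perms(M)
  phi <- numeric(M)
  for (p in seq_len(nrow(perms))) {
    z <- reference
    prev <- f(z)
    for (i in perms[p, ]) {
      z[i] <- x[i]
      cur <- f(z)
      phi[i] <- phi[i] + (cur - prev)
      prev <- cur
    }
  }
  phi / nrow(perms)
}

combinat_perms <- function(M) {
  if (M == 1) return(matrix(1))
  sub <- combinat_perms(M - 1)
  out <- NULL
  for (pos in seq_len(M)) {
    blk <- cbind(sub[, seq_len(pos - 1), drop = FALSE], M,
                 if (pos <= M - 1) sub[, pos:(M - 1), drop = FALSE])
    out <- rbind(out, blk)
  }
  out
}

## Independent evaluation of the five epilepsy inclusion criteria for one
## patient; returns NA (excluded) or the index day.
oracle_inclusion <- function(dx_days_ep, dx_days_status, dx_days_conv,
                             aed_days) {
  ep <- sort(unique(dx_days_ep)); st <- sort(unique(dx_days_status))
  cv <- sort(unique(dx_days_conv)); aed <- sort(unique(aed_days))
  idx <- c()
  if (length(ep) >= 2) idx <- c(idx, min(ep))
  if (length(ep) >= 1 && length(cv) >= 1) {
    sep <- FALSE
    for (e in ep) for (cc in cv) if (e != cc) sep <- TRUE
    if (sep) idx <- c(idx, min(ep))
  }
  if (length(ep) >= 1) {
    for (a in aed) if (a >= min(ep) + 1) { idx <- c(idx, min(ep)); break }
  }
  if (length(cv) >= 2) {
    second <- cv[2]
    for (a in aed) if (a >= second + 1) { idx <- c(idx, min(cv)); break }
  }
  if (length(st) >= 1) {
    for (s1 in st) for (s2 in st)
      if (abs(s1 - s2) >= 30) idx <- c(idx, min(st))
    for (s in st) for (cc in cv)
      if (abs(s - cc) >= 30) idx <- c(idx, min(s, cc))
    for (s in st) for (e in ep)
      if (s != e) idx <- c(idx, min(min(st), min(ep)))
  }
  if (length(idx) == 0) NA_real_ else min(idx)
}
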