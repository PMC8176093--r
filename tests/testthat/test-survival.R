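test_that("Cox partial log-likelihood matches hand-computed and degenerate cases", {
  # single censored patient: no event terms
  expect_warning(l0 <- cox_partial_loglik(0.3, survival_labels(5, 0)),
                 "no events")
  expect_identical(l0, 0)
  # single event: self-only risk set, any score cancels
  expect_equal(cox_partial_loglik(2.7, survival_labels(4, 1)), 0)
  # three events at distinct times, zero scores: -log3 - log2
  lab <- survival_labels(c(1, 2, 3), c(1, 1, 1))
  expect_equal(cox_partial_loglik(c(0, 0, 0), lab), -(log(3) + log(2)),
               tolerance = 1e-12)
})

test_that("partial likelihood and its gradient agree with brute force on random data", {
  set.seed(11)
  for (r in 1:30) {
    n <- sample(3:12, 1)
    lab <- random_labels(n)
    if (sum(lab$status) == 0) next
    s <- rnorm(n)
    expect_equal(cox_partial_loglik(s, lab),
                 oracle_cox_loglik(s, lab$time, lab$status),
                 tolerance = 1e-10)
    # analytic gradient vs central finite differences, 1e-5 relative
    g <- claimrisk:::cox_loglik_grad(s, lab$time, lab$status)
    eps <- 1e-6
    for (k in seq_len(n)) {
      sp <- s; sp[k] <- s[k] + eps
      sm <- s; sm[k] <- s[k] - eps
      fd <- (oracle_cox_loglik(sp, lab$time, lab$status) -
               oracle_cox_loglik(sm, lab$time, lab$status)) / (2 * eps)
      expect_equal(g[k], fd, tolerance = 1e-5)
    }
  }
})

test_that("negative partial likelihood is convex in a single coefficient", {
  set.seed(4)
  x <- rnorm(20)
  lab <- random_labels(20)
  grid <- seq(-2, 2, by = 0.1)
  nl <- vapply(grid, function(b)
    -cox_partial_loglik(b * x, lab), numeric(1))
  d2 <- diff(diff(nl))
  expect_true(all(d2 >= -1e-8))
})

test_that("penalized loss reduces to -loglik at zero penalty and matches hand arithmetic", {
  dat <- small_data()
  hp0 <- hyperparams(enc_units = 4, dom_units = 4, fin_units = 4)
  m <- build_network(dat$schema, hp0, T_bins = dat$cubes$T_bins, seed = 1)
  idx <- 1:30
  sc <- risk_score(m, dat$cubes, idx = idx)
  lab <- dat$labels[idx, ]
  pl <- penalized_loss(m, sc, lab)
  expect_equal(as.numeric(pl), -cox_partial_loglik(sc, lab))
  expect_true(all(attr(pl, "penalties") == 0))

  # hand-set weights and lambdas: per-group l1/l2 sums
  hp1 <- hyperparams(enc_units = 4, dom_units = 4, fin_units = 4,
                     lambda = list(l1 = 0.5, l2 = 0.25,
                                   l1_out = 2, l2_out = 3))
  m2 <- build_network(dat$schema, hp1, T_bins = dat$cubes$T_bins, seed = 1)
  for (nm in names(m2$par)) m2$par[[nm]] <- m2$par[[nm]] * 0
  m2$par[["enc.phewas.L1.W"]][1, 1:2] <- c(2, -3)
  m2$par[["out.W"]][1, 1] <- -1.5
  sc2 <- risk_score(m2, dat$cubes, idx = idx)
  pl2 <- penalized_loss(m2, sc2, lab)
  pen <- attr(pl2, "penalties")
  expect_equal(unname(pen["phewas.l1"]), 0.5 * (2 + 3))
  expect_equal(unname(pen["phewas.l2"]), 0.25 * (4 + 9))
  expect_equal(unname(pen["output.l1"]), 2 * 1.5)
  expect_equal(unname(pen["output.l2"]), 3 * 1.5^2)
  expect_equal(as.numeric(pl2), -cox_partial_loglik(sc2, lab) + sum(pen))
  # unknown group in the lambda map is rejected
  m3 <- m2
  m3$hp$lambda$l1 <- c(nonexistent = 1)
  expect_error(penalized_loss(m3, sc2, lab), "no penalty weight")
})

test_that("Breslow cumulative hazard matches direct summation and edge cases", {
  # no events: identically zero with a warning
  expect_warning(h <- breslow_cumulative_hazard(c(0, 0),
                                                survival_labels(c(1, 2), c(0, 0))),
                 "no events")
  expect_equal(claimrisk:::eval_hazard(h, c(0, 5)), c(0, 0))
  # times 1,2,3 all events, zero scores: H0(3) = 1/3 + 1/2 + 1
  lab <- survival_labels(c(1, 2, 3), c(1, 1, 1))
  h <- breslow_cumulative_hazard(c(0, 0, 0), lab)
  expect_equal(claimrisk:::eval_hazard(h, 3), 11 / 6, tolerance = 1e-12)
  # zero before the first event
  expect_equal(claimrisk:::eval_hazard(h, 0.5), 0)
  # random instances vs brute force (with ties and nonzero scores)
  set.seed(21)
  for (r in 1:25) {
    n <- sample(3:12, 1)
    lab <- random_labels(n)
    if (sum(lab$status) == 0) next
    s <- rnorm(n)
    h <- breslow_cumulative_hazard(s, lab)
    for (at in c(0.3, stats::median(lab$time), max(lab$time)))
      expect_equal(claimrisk:::eval_hazard(h, at),
                   oracle_breslow(s, lab$time, lab$status, at),
                   tolerance = 1e-10)
  }
})

test_that("survival curves follow S(t|x) = exp(-exp(s) H0(t))", {
  lab <- survival_labels(c(2, 4, 7), c(1, 1, 1))
  h <- breslow_cumulative_hazard(c(0, 0, 0), lab)
  sc <- survival_curve(0.7, h)
  expect_equal(sc$surv[1], 1)              # S(0) = 1
  expect_true(all(diff(sc$surv) <= 1e-12)) # nonincreasing
  expect_true(all(sc$surv >= 0 & sc$surv <= 1))
  # closed form: score 0, H0(t) = 1 gives exp(-1)
  h1 <- structure(list(time = 1, hazard = 1), class = "baseline_hazard")
  expect_equal(survival_curve(0, h1, times = 1)$surv, exp(-1),
               tolerance = 1e-12)
})

test_that("relative hazards reproduce the reference score arithmetic", {
  expect_equal(round(hazard_ratio(-17.29, -16.71), 2), 0.56)
  expect_equal(round(hazard_ratio(-15.63, -16.71), 2), 2.94)
  # the survival-curve contract implies S_1 = S_2 ^ HR
  h <- structure(list(time = c(1, 2), hazard = c(0.2, 0.5)),
                 class = "baseline_hazard")
  s1 <- survival_curve(-17.29, h)$surv
  s2 <- survival_curve(-16.71, h)$surv
  expect_equal(s1, s2^hazard_ratio(-17.29, -16.71), tolerance = 1e-12)
})

test_that("Kaplan-Meier estimator matches hand computation, survfit, and censoring symmetry", {
  # times 1(event), 2(censored), 3(event): S(1)=2/3, S(3)=0
  lab <- survival_labels(c(1, 2, 3), c(1, 0, 1))
  km <- kaplan_meier(lab)
  expect_equal(km_eval(km, c(1, 2.5, 3)), c(2 / 3, 2 / 3, 0))
  # all censored in event mode: S = 1 everywhere
  kmc <- kaplan_meier(survival_labels(c(1, 2), c(0, 0)))
  expect_equal(km_eval(kmc, c(0.5, 1, 5)), c(1, 1, 1))
  # event mode on delta-complemented data equals censoring mode
  set.seed(3)
  lab <- random_labels(40)
  k1 <- kaplan_meier(lab, mode = "censoring")
  k2 <- kaplan_meier(survival_labels(lab$time, 1L - lab$status),
                     mode = "event")
  expect_equal(k1$time, k2$time)
  expect_equal(k1$surv, k2$surv)
  # cross-check against the survival package
  sf <- survival::survfit(survival::Surv(lab$time, lab$status) ~ 1)
  km <- kaplan_meier(lab)
  expect_equal(km_eval(km, sf$time), sf$surv, tolerance = 1e-12)
})

test_that("Breslow at zero scores is consistent with Kaplan-Meier (no-tie limit)", {
  set.seed(8)
  n <- 100
  lab <- survival_labels(sample(seq(1, 4000) / 10, n), rbinom(n, 1, 0.7))
  h <- breslow_cumulative_hazard(rep(0, n), lab)
  km <- kaplan_meier(lab)
  at <- stats::quantile(lab$time, c(0.2, 0.5, 0.8))
  expect_equal(exp(-claimrisk:::eval_hazard(h, at)), km_eval(km, at),
               tolerance = 0.01)
})
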