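aeds <- c("AED001")

test_that("epilepsy inclusion criteria and index dates follow the five rules", {
  ev <- rbind(
    # A: two 345.xx on separate days -> criterion 1, index 100
    ev_row("A", 100, code = "345.40"), ev_row("A", 130, code = "345.41"),
    # B: single 345.40, nothing else -> excluded
    ev_row("B", 50, code = "345.40"),
    # C: two 780.39 plus AED one day after the second -> criterion 4, index 10
    ev_row("C", 10, code = "780.39"), ev_row("C", 40, code = "780.39"),
    ev_row("C", 41, "prescription", "AED001", 30, 30),
    # D: 345.xx then AED after it -> criterion 3, index 70
    ev_row("D", 70, code = "345.40"),
    ev_row("D", 100, "prescription", "AED001", 30, 30),
    # E: 345.3 twice 30+ days apart -> criterion 5, index 5
    ev_row("E", 5, code = "345.3"), ev_row("E", 40, code = "345.3"),
    # F: 345.xx + 780.39 same day only -> not separate encounters
    ev_row("F", 12, code = "345.40"), ev_row("F", 12, code = "780.39"))
  res <- identify_epilepsy_patients(ev, aeds)
  expect_setequal(res$patient_id, c("A", "C", "D", "E"))
  idx <- setNames(res$index_day, res$patient_id)
  expect_equal(unname(idx[c("A", "C", "D", "E")]), c(100, 10, 70, 5))
  expect_equal(res$criterion[res$patient_id == "C"], 4L)
  # empty input: empty map
  expect_equal(nrow(identify_epilepsy_patients(ev[0, ], aeds)), 0)
})

test_that("malformed records are rejected with a diagnostic, not silently dropped", {
  ev <- rbind(ev_row("A", 100, code = "345.40"),
              ev_row("A", 130, code = "345.41"),
              ev_row("Z", 10, code = ""),        # empty code
              ev_row("Z", 20, code = "345.40"))
  expect_message(res <- identify_epilepsy_patients(ev, aeds), "rejecting")
  expect_equal(res$patient_id, "A")
  expect_true("Z" %in% attr(res, "rejected")$patient_id)
})

test_that("rule engine equals an independently coded brute-force evaluation", {
  set.seed(19)
  codes <- c("345.40", "345.41", "345.3", "780.39", "599.0")
  for (rep in 1:20) {
    n_pat <- 25
    ev <- do.call(rbind, lapply(seq_len(n_pat), function(i) {
      k <- sample(1:7, 1)
      dx <- ev_row(sprintf("p%02d", i), sample(1:200, k, replace = TRUE),
                   code = sample(codes, k, replace = TRUE))
      if (runif(1) < 0.6)
        dx <- rbind(dx, ev_row(sprintf("p%02d", i), sample(1:220, 1),
                               "prescription", "AED001", 30, 30))
      dx
    }))
    res <- identify_epilepsy_patients(ev, aeds)
    for (p in unique(ev$patient_id)) {
      sub <- ev[ev$patient_id == p & ev$kind == "diagnosis", ]
      exp_idx <- oracle_inclusion(
        sub$day[startsWith(sub$code, "345") & !startsWith(sub$code, "345.3")],
        sub$day[startsWith(sub$code, "345.3")],
        sub$day[sub$code == "780.39"],
        ev$day[ev$patient_id == p & ev$kind == "prescription"])
      got <- res$index_day[res$patient_id == p]
      if (is.na(exp_idx)) {
        expect_length(got, 0)
      } else {
        expect_equal(got, exp_idx, label = paste("patient", p))
      }
    }
  }
})

test_that("cohort filters enforce history, follow-up, age and AED treatment", {
  cfg <- cohort_config()
  pats <- data.frame(
    patient_id = c("A", "B", "C", "D", "E"),
    age = c(30, 30, 17, 30, 30),
    sex = "F", region = "R1", plan = "p1",
    first_day = 0, last_day = c(1200, 1200, 1200, 450, 1200))
  cand <- data.frame(patient_id = c("A", "B", "C", "D", "E"),
                     index_day = c(400, 200, 400, 400, 400),
                     criterion = 1L)
  ev <- rbind(ev_row("A", 500, "prescription", "AED001", 30, 30),
              ev_row("B", 500, "prescription", "AED001", 30, 30),
              ev_row("C", 500, "prescription", "AED001", 30, 30),
              ev_row("D", 420, "prescription", "AED001", 30, 30))
  coh <- apply_cohort_filters(cand, pats, ev, cfg, aeds)
  expect_equal(coh$patient_id, "A")                   # all filters pass
  excl <- attr(coh, "exclusions")
  reason <- setNames(excl$reason, excl$patient_id)
  expect_equal(unname(reason["B"]), "insufficient history")   # only 200 days
  expect_equal(unname(reason["C"]), "age outside range")      # age 17
  expect_equal(unname(reason["D"]), "insufficient follow-up")
  expect_equal(unname(reason["E"]), "no AED treatment")
  # window annotations
  expect_equal(coh$history_start, 400 - 365)
  expect_equal(coh$history_end, 400 + 91)
})

test_that("boundary ages 18 and 65 are inclusive and missing age excludes", {
  cfg <- cohort_config()
  pats <- data.frame(patient_id = c("A", "B", "C"),
                     age = c(18, 65, NA),
                     sex = "F", region = "R1", plan = "p1",
                     first_day = 0, last_day = 1200)
  cand <- data.frame(patient_id = c("A", "B", "C"), index_day = 400,
                     criterion = 1L)
  ev <- do.call(rbind, lapply(c("A", "B", "C"), function(p)
    ev_row(p, 500, "prescription", "AED001", 30, 30)))
  coh <- apply_cohort_filters(cand, pats, ev, cfg, aeds)
  expect_setequal(coh$patient_id, c("A", "B"))
  excl <- attr(coh, "exclusions")
  expect_equal(excl$reason[excl$patient_id == "C"], "missing age")
})

test_that("code pre-filter removes rare codes under the either-condition rule", {
  cfg <- cohort_config()
  n <- 1000
  coh <- data.frame(patient_id = sprintf("p%04d", 1:n))
  class(coh) <- c("claims_cohort", "data.frame")
  ev <- rbind(
    do.call(rbind, lapply(1:10, function(i)
      ev_row(coh$patient_id[i], 10, code = "RARE"))),     # exactly 10 patients
    do.call(rbind, lapply(1:n, function(i)
      ev_row(coh$patient_id[i], 10, code = "COMMON"))),   # every patient
    do.call(rbind, lapply(1:11, function(i)
      ev_row(coh$patient_id[i], 10, code = "ELEVEN"))))   # 11 = 1.1% > both
  pf <- prefilter_codes(ev, coh, cfg)
  expect_false("RARE" %in% pf$vocabulary)     # <= 10 patients
  expect_true("COMMON" %in% pf$vocabulary)
  expect_true("ELEVEN" %in% pf$vocabulary)
  # 50-patient toy cohort: survivors match an exhaustive check
  set.seed(33)
  coh50 <- data.frame(patient_id = sprintf("q%02d", 1:50))
  class(coh50) <- c("claims_cohort", "data.frame")
  ev50 <- do.call(rbind, lapply(sprintf("c%02d", 1:12), function(cd) {
    carriers <- sample(coh50$patient_id, sample(1:50, 1))
    do.call(rbind, lapply(carriers, function(p) ev_row(p, 5, code = cd)))
  }))
  cfg50 <- cohort_config(min_patients_per_code = 5, min_code_freq = 0.2)
  pf50 <- prefilter_codes(ev50, coh50, cfg50)
  survivors <- character(0)
  for (cd in unique(ev50$code)) {
    np <- length(unique(ev50$patient_id[ev50$code == cd]))
    if (np > 5 && np / 50 > 0.2) survivors <- c(survivors, cd)
  }
  expect_setequal(pf50$vocabulary, survivors)
})

test_that("comorbidity labels partition the cohort and match hand enumeration", {
  cfg <- cohort_config()
  defn <- comorbidity_definition("toy", "CM")
  # 20-patient toy cohort, index day 400, coverage to day 1600
  n <- 20
  coh <- data.frame(patient_id = sprintf("p%02d", 1:n), index_day = 400,
                    criterion = 1L, age = 30, history_start = 35,
                    history_end = 491, followup_start = 491,
                    coverage_end = 1600)
  class(coh) <- c("claims_cohort", "data.frame")
  # planted first-diagnosis days (NA = never); lag window is [491, 671)
  first_cm <- c(300, 450, 490, NA, NA, 500, 600, 670, 671, 700,
                900, 1200, 1600, NA, NA, NA, 250, 495, 800, 1000)
  ev <- do.call(rbind, lapply(which(!is.na(first_cm)), function(i)
    ev_row(coh$patient_id[i], first_cm[i], code = "CM")))
  out <- build_comorbidity_labels(coh, ev, defn, cfg)
  # hand enumeration: excluded prior = days < 491; lag = [491, 671)
  expect_setequal(out$excluded$patient_id[out$excluded$reason == "prior_comorbidity"],
                  coh$patient_id[c(1, 2, 3, 17)])
  expect_setequal(out$excluded$patient_id[out$excluded$reason == "lag_window"],
                  coh$patient_id[c(6, 7, 8, 18)])
  inc <- out$labels$patient_id[out$labels$status == 1]
  expect_setequal(inc, coh$patient_id[c(9, 10, 11, 12, 13, 19, 20)])
  # partition: every patient exactly once
  expect_setequal(c(out$labels$patient_id, out$excluded$patient_id),
                  coh$patient_id)
  expect_equal(nrow(out$labels) + nrow(out$excluded), n)
  # censoring arithmetic: no CM code, coverage to index+1200: 40 months
  cens <- out$labels[out$labels$patient_id == "p04", ]
  expect_equal(cens$status, 0L)
  expect_equal(cens$time, 40)
  # incident time: first CM at 671 is exactly the 6-month boundary (ceil(271/30)=10)
  p09 <- out$labels[out$labels$patient_id == "p09", ]
  expect_equal(p09$status, 1L)
  expect_equal(p09$time, ceiling((671 - 400) / 30))
  # empty definition rejected
  expect_error(comorbidity_definition("bad", character(0)), "non-empty")
})

test_that("censoring arithmetic: coverage end at index+600 days gives 20 months", {
  cfg <- cohort_config()
  coh <- data.frame(patient_id = "x", index_day = 400, criterion = 1L,
                    age = 30, history_start = 35, history_end = 491,
                    followup_start = 491, coverage_end = 1000)
  class(coh) <- c("claims_cohort", "data.frame")
  out <- build_comorbidity_labels(coh, ev_row("x", 10, code = "OTHER"),
                                  comorbidity_definition("toy", "CM"), cfg)
  expect_equal(out$labels$time, 20)
  expect_equal(out$labels$status, 0L)
})

test_that("labelled patients always satisfy the cohort filters (re-run property)", {
  dat <- small_data()
  cfg <- cohort_config()
  coh <- dat$cohort
  expect_true(all(coh$index_day - (coh$history_start) == cfg$lookback_days))
  expect_true(all(coh$age >= 18 & coh$age <= 65))
  expect_true(all(coh$coverage_end - coh$index_day >= cfg$min_followup_days))
  expect_true(all(dat$labels$time > 0))
  expect_true(all(dat$labels$status %in% c(0L, 1L)))
})
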