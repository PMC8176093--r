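test_that("diagnosis mapping collapses same-day synonyms and reports unmapped codes", {
  mp <- mapping_table("icd2phe",
                      data.frame(source = c("250.00", "250.01", "401.1"),
                                 target = c("PHE250", "PHE250", "PHE401")),
                      target_subdomain = "phewas")
  ev <- rbind(ev_row("A", 10, code = "250.00"),
              ev_row("A", 10, code = "250.01"),   # same concept, same day
              ev_row("A", 40, code = "250.01"),
              ev_row("A", 10, code = "999.9"))    # unmapped
  out <- map_diagnoses(ev, mp)
  expect_equal(nrow(out), 2)  # one concept-day for day 10, one for day 40
  expect_equal(out$code, c("PHE250", "PHE250"))
  expect_equal(attr(out, "unmapped")$code, "999.9")
  # identity mapping: output vocabulary equals input vocabulary
  idmp <- mapping_table("id", data.frame(source = c("a", "b"),
                                         target = c("a", "b")), "phewas")
  ev2 <- rbind(ev_row("A", 1, code = "a"), ev_row("B", 2, code = "b"))
  expect_setequal(map_diagnoses(ev2, idmp)$code, c("a", "b"))
})

test_that("ICD-10 crosswalk chains are applied once; cyclic/chained tables are rejected", {
  xw <- mapping_table("xw", data.frame(source = "G40.9", target = "345.90"),
                      "phewas")
  mp <- mapping_table("mp", data.frame(source = "345.90", target = "PHE345"),
                      "phewas")
  ev <- ev_row("A", 5, code = "G40.9")
  out <- map_diagnoses(ev, mp, icd10_to_icd9 = xw)
  expect_equal(out$code, "PHE345")
  bad <- mapping_table("bad", data.frame(source = c("a", "b"),
                                         target = c("b", "c")), "phewas")
  expect_error(map_diagnoses(ev_row("A", 1, code = "a"), bad),
               "cyclic")
  expect_error(mapping_table("empty", data.frame(source = character(0),
                                                 target = character(0)),
                             "phewas"),
               "empty")
})

test_that("mapped concept counts equal an independent join on a random synthetic table", {
  set.seed(14)
  src <- sprintf("c%03d", 1:100)
  mp_df <- data.frame(source = sample(src, 160, replace = TRUE),
                      target = sprintf("t%02d", sample(1:40, 160, replace = TRUE)))
  mp_df <- unique(mp_df)
  mp <- mapping_table("rand", mp_df, "phewas")
  ev <- data.frame(patient_id = sample(sprintf("p%02d", 1:12), 300, TRUE),
                   day = sample(1:50, 300, TRUE), kind = "diagnosis",
                   code = sample(src, 300, TRUE))
  out <- map_diagnoses(ev, mp)
  ## brute-force join + dedup
  expected <- 0
  for (r in seq_len(nrow(ev))) {
    tg <- mp_df$target[mp_df$source == ev$code[r]]
    for (t in tg) expected <- c(expected, paste(ev$patient_id[r], ev$day[r], t))
  }
  expect_equal(nrow(out), length(unique(expected)) - 1)
})

test_that("knowledge expansion fans out, inherits time, and respects declarations", {
  tt <- mapping_table("targets",
                      data.frame(source = "S1", target = c("T1", "T2", "T3")),
                      target_subdomain = "target_tissue")
  ev <- data.frame(patient_id = "A", day = 37, code = "S1",
                   subdomain = "substance", duration_days = 60)
  out <- expand_knowledge(ev, list(tt))
  expect_equal(sum(out$subdomain == "target_tissue"), 3)  # fan-out 3
  expect_true(all(out$day == 37))                          # time inherited
  expect_true(all(out$duration_days == 60))
  # empty table set: claims-origin features only
  out0 <- expand_knowledge(ev)
  expect_equal(nrow(out0), 1)
  expect_equal(out0$subdomain, "substance")
  # undeclared target subdomain is an error
  expect_error(expand_knowledge(ev, list(tt), subdomains = "substance"),
               "undeclared subdomain")
  # counting oracle: fan-out f per code implies f x events expanded rows
  f <- 4
  tbl <- mapping_table("f4", data.frame(
    source = rep(c("S1", "S2"), each = f),
    target = sprintf("x%d", 1:(2 * f))), "target_tissue")
  ev2 <- data.frame(patient_id = rep("A", 10), day = 1:10,
                    code = sample(c("S1", "S2"), 10, TRUE),
                    subdomain = "substance")
  out2 <- expand_knowledge(ev2, list(tbl))
  expect_equal(sum(out2$subdomain == "target_tissue"), f * 10)
})

test_that("expansion is monotone in the table set", {
  ev <- data.frame(patient_id = "A", day = 1, code = "S1",
                   subdomain = "substance")
  t1 <- mapping_table("t1", data.frame(source = "S1", target = "T1"),
                      "target_tissue")
  t2 <- mapping_table("t2", data.frame(source = "S1", target = "C9"),
                      "therapeutic_class")
  rows1 <- nrow(expand_knowledge(ev, list(t1)))
  rows2 <- nrow(expand_knowledge(ev, list(t1, t2)))
  expect_gte(rows2, rows1)
})

test_that("schema layout, determinism, serialization round-trip, and errors", {
  vocab <- list(phewas = c("b", "a"), substance = c("s2", "s1"))
  stat <- list(demographics = c("age", "sex:F"), region = "region:R1")
  sch <- build_schema(vocab, static = stat)
  # claims-only inputs: exactly the claims-origin subdomains
  expect_setequal(names(sch$subdomains),
                  c("phewas", "substance", "demographics", "region"))
  expect_true(all(vapply(sch$subdomains, `[[`, "", "origin") == "claims"))
  # deterministic lexicographic feature order
  expect_equal(sch$subdomains$phewas$features, c("a", "b"))
  # static flags per domain
  expect_false(sch$subdomains$demographics$time_dependent)
  expect_true(sch$subdomains$phewas$time_dependent)
  # adding a weighted table adds an augmented subdomain
  se <- mapping_table("sidefx",
                      data.frame(source = "s1", target = c("e1", "e2"),
                                 weight = c(0.5, 0.1)), "side_effects")
  sch2 <- build_schema(vocab, tables = list(se), static = stat)
  expect_equal(sch2$subdomains$side_effects$origin, "augmented")
  expect_true(sch2$subdomains$side_effects$weighted)
  # dimension totals equal the config sums
  d <- schema_dims(sch2)
  expect_equal(sum(d$n_features), 2 + 2 + 2 + 2 + 1)
  # empty vocabulary errors
  expect_error(build_schema(list()), "empty vocabulary")
  expect_error(build_schema(list(phewas = character(0))), "empty")
  # serialization round-trips bit-exactly
  tf <- tempfile(fileext = ".json")
  write_schema(sch2, tf)
  sch3 <- read_schema(tf)
  expect_equal(sch3$subdomains, sch2$subdomains)
  expect_identical(claimrisk:::schema_hash(sch3),
                   claimrisk:::schema_hash(sch2))
})

test_that("duplicated feature events collapse to presence (idempotent expansion)", {
  dat <- small_data()
  ev <- dat$sim$events
  concepts <- map_diagnoses(ev, dat$sim$mappings$icd9_to_phewas)
  fe <- data.frame(patient_id = concepts$patient_id, day = concepts$day,
                   code = concepts$code, subdomain = "phewas")
  feats1 <- expand_knowledge(fe)
  feats2 <- expand_knowledge(rbind(fe, fe))  # doubled input
  coh <- dat$cohort[1:20, ]
  class(coh) <- c("claims_cohort", "data.frame")
  sch <- build_schema(list(phewas = sort(unique(fe$code))))
  c1 <- assemble_cubes(feats1, sch, coh, on_unknown = "drop")
  c2 <- assemble_cubes(feats2, sch, coh, on_unknown = "drop")
  expect_identical(c1$sub, c2$sub)
})
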