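test_that("exclusion windows follow the policy arithmetic and merge", {
  events <- data.frame(
    event_id = c("E1", "E2", "E3", "E4"),
    patient_id = c("P1", "P1", "P1", "P2"),
    code_system = c("CPT4", "CPT4", "ICD9CM", "ICD9CM"),
    code = c("00790", "00840", "2821", "5790"),
    event_date = c(100, 150, 200, 50), stringsAsFactors = FALSE)
  w <- build_exclusion_windows(events)
  surg <- w[w$category == "surgery_blood_loss", ]
  # [100,190] and [150,240] merge into [100,240] with both event ids
  expect_equal(nrow(surg), 1L)
  expect_equal(surg$start, 100)
  expect_equal(surg$end, 240)
  expect_setequal(strsplit(surg$event_ids, ";")[[1]], c("E1", "E2"))
  # hereditary anemia is chronic: lookback 30, right-unbounded
  chronic <- w[w$category == "condition" & w$patient_id == "P1", ]
  expect_equal(chronic$start, 170)
  expect_equal(chronic$end, Inf)
  # unknown code system skipped with warning, counted
  bad <- rbind(events, data.frame(event_id = "E5", patient_id = "P1",
                                  code_system = "ICD10", code = "C91",
                                  event_date = 1))
  expect_warning(w2 <- build_exclusion_windows(bad), "ICD10")
  expect_equal(attr(w2, "n_skipped"), 1L)
})

test_that("medication mentions match whole words case-insensitively", {
  notes <- data.frame(
    note_id = paste0("N", 1:5), patient_id = "P1", note_date = 1:5,
    text = c("started on methotrexate today",
             "Methotrexate 10 mg weekly",
             "methotrexatelike compound discussed",
             "on mycophenolate mofetil since March",
             "no relevant medications"),
    stringsAsFactors = FALSE)
  ev <- detect_medication_mentions(notes)
  expect_equal(sort(ev$event_id),
               sort(c("N1:methotrexate", "N2:methotrexate",
                      "N4:mycophenolate mofetil")))
  expect_true(all(ev$category == "medication_nlp"))
  expect_error(detect_medication_mentions(notes,
    default_medication_lexicon()[0, ]), "empty")
})

test_that("value exclusion is interval membership with closed finite ends", {
  labs <- data.frame(value_id = paste0("V", 1:4), patient_id = "P1",
                     trait = "HGB", value = 14,
                     sample_date = c(150, 190, 191, 99),
                     accession = paste0("A", 1:4), source = "x",
                     stringsAsFactors = FALSE)
  w <- data.frame(patient_id = "P1", category = "surgery_blood_loss",
                  start = 100, end = 190, event_ids = "E1",
                  stringsAsFactors = FALSE)
  dec <- exclude_values(labs, w)
  expect_identical(dec$decision, c("exclude", "exclude", "keep", "keep"))
  expect_identical(dec$reasons[1], "surgery_blood_loss")
  expect_identical(dec$event_ids[1], "E1")
  # every excluded value carries at least one reason and event id
  expect_true(all(nzchar(dec$reasons[dec$decision == "exclude"])))
  expect_true(all(nzchar(dec$event_ids[dec$decision == "exclude"])))
  expect_true(all(dec$reasons[dec$decision == "keep"] == ""))
})

test_that("filter decisions reproduce the independent truth labels", {
  for (seed in c(101, 202, 303)) {
    co <- small_cohort(seed = seed)
    pd <- pipeline_decisions(co)
    expect_identical(unname(pd$excluded),
                     co$truth$should_be_excluded[
                       match(pd$value_id, co$truth$value_id)])
  }
})

test_that("enlarging a window policy only grows the excluded set", {
  co <- small_cohort(seed = 404)
  nlp <- detect_medication_mentions(co$notes)
  ev <- rbind(co$events, nlp[names(co$events)])
  pol_small <- default_window_policies()
  pol_big <- pol_small
  pol_big$medication$duration_days <- 365
  pol_big$surgery$lookback_days <- 30
  d1 <- exclude_values(co$labs, build_exclusion_windows(ev, policies = pol_small))
  d2 <- exclude_values(co$labs, build_exclusion_windows(ev, policies = pol_big))
  ex1 <- d1$value_id[d1$decision == "exclude"]
  ex2 <- d2$value_id[d2$decision == "exclude"]
  expect_true(all(ex1 %in% ex2))
})

test_that("patients are dropped only when nothing remains", {
  labs <- data.frame(value_id = paste0("V", 1:3),
                     patient_id = c("P1", "P1", "P2"),
                     trait = c("HGB", "HCT", "HGB"), value = 1,
                     sample_date = 1:3, accession = paste0("A", 1:3),
                     source = "x", stringsAsFactors = FALSE)
  w <- data.frame(patient_id = "P2", category = "condition", start = 0,
                  end = Inf, event_ids = "E9", stringsAsFactors = FALSE)
  dec <- exclude_values(labs, w)
  drops <- drop_empty_patients(dec, labs)
  expect_identical(drops$dropped, "P2")
  expect_identical(drops$cohort, "P1")
  # empty exclusion set drops nobody
  dec0 <- exclude_values(labs, w[0, ])
  expect_length(drop_empty_patients(dec0, labs)$dropped, 0)
})
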