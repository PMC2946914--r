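raw_record <- function(pid, code, date, result, acc) {
  data.frame(patient_id = pid, test_code = code, sample_date = date,
             result = result, accession = acc, stringsAsFactors = FALSE)
}
code_map <- setNames(c("HGB", "HCT"), c("C_HGB", "C_HCT"))

test_that("multi-source loading dedups, drops junk, and accounts for it", {
  s1 <- rbind(raw_record("P1", "C_HGB", 100, "14.2", "A1"),
              raw_record("P1", "C_HGB", 101, "QNS", "A2"),
              raw_record("P1", "C_WBC", 102, "7.0", "A3"),
              raw_record("P2", "C_HCT", 103, "41.5", "A4"))
  s2 <- raw_record("P1", "C_HGB", 100, "14.2", "A1")  # duplicate of s1 row 1
  out <- load_lab_results(list(a = s1, b = s2), code_map)
  expect_equal(nrow(out$labs), 2L)
  expect_equal(unname(out$report["input"]), 5L)
  expect_equal(unname(out$report["duplicate"]), 1L)
  expect_equal(unname(out$report["non_numeric"]), 1L)
  expect_equal(unname(out$report["unmapped_code"]), 1L)
  expect_equal(unname(out$report["kept"] + out$report["duplicate"] +
                        out$report["non_numeric"] + out$report["unmapped_code"]),
               unname(out$report["input"]))
  expect_error(load_lab_results(list(s1[-1]), code_map), "patient_id")
})

test_that("synthetic raw sources reload to the canonical lab table", {
  cfg <- sim_config(n_patients = 25, seed = 12, dup_rate = 0.1)
  labs <- simulate_lab_series(simulate_patients(cfg), cfg)
  src <- emr_source_tables(labs, cfg)
  out <- load_lab_results(src$sources, src$code_map)
  # every kept record is one of the canonical values (QNS rows were lost)
  expect_true(all(out$labs$value_id %in% labs$value_id))
  expect_equal(unname(out$report["unmapped_code"]), max(1, round(0.01 * nrow(labs))))
  # conservation: every raw record is kept or accounted for under one reason
  expect_equal(unname(out$report["kept"] + out$report["duplicate"] +
                        out$report["non_numeric"] +
                        out$report["unmapped_code"] + out$report["bad_unit"]),
               unname(out$report["input"]))
})

test_that("inpatient flagging uses inclusive date boundaries", {
  labs <- data.frame(value_id = paste0("V", 1:4), patient_id = "P1",
                     trait = "HGB", value = 14,
                     sample_date = c(100, 105, 106, 99),
                     accession = paste0("A", 1:4), source = "x",
                     stringsAsFactors = FALSE)
  eps <- data.frame(patient_id = "P1", admit_date = 100, discharge_date = 105)
  fl <- flag_inpatient(labs, eps)
  expect_identical(fl$inpatient, c(TRUE, TRUE, FALSE, FALSE))
  # two overlapping episodes still flag each value once
  eps2 <- rbind(eps, data.frame(patient_id = "P1", admit_date = 99,
                                discharge_date = 103))
  fl2 <- flag_inpatient(labs, eps2)
  expect_identical(fl2$inpatient, c(TRUE, TRUE, FALSE, TRUE))
  expect_error(flag_inpatient(labs, data.frame(patient_id = "P1",
    admit_date = 10, discharge_date = 5)), "admit")
})

test_that("inpatient exclusion rescues patients with only inpatient values", {
  labs <- data.frame(
    value_id = paste0("V", 1:7),
    patient_id = c(rep("P1", 5), "P2", "P2"),
    trait = c(rep("HGB", 5), "HGB", "HGB"),
    value = 14, sample_date = c(1, 2, 50, 60, 70, 10, 11),
    accession = paste0("A", 1:7), source = "x", stringsAsFactors = FALSE)
  eps <- data.frame(patient_id = c("P1", "P2"), admit_date = c(1, 9),
                    discharge_date = c(2, 12))
  out <- apply_inpatient_exclusion(flag_inpatient(labs, eps))
  # P1 has outpatient values: its 2 inpatient values go
  expect_setequal(out$excluded$value_id, c("V1", "V2"))
  # P2's only HGB values are inpatient: rescued
  expect_true(all(c("V6", "V7") %in% out$kept$value_id))
  expect_equal(nrow(out$kept) + nrow(out$excluded), nrow(labs))
  # idempotent
  again <- apply_inpatient_exclusion(out$kept)
  expect_identical(again$kept$value_id, out$kept$value_id)
  # no episodes: output equals input
  none <- apply_inpatient_exclusion(flag_inpatient(labs, eps[0, ]))
  expect_equal(nrow(none$excluded), 0L)
})

test_that("extraction results are invariant to record order", {
  co <- small_cohort(seed = 55)
  perm <- sample(nrow(co$labs))
  a <- apply_inpatient_exclusion(flag_inpatient(co$labs, co$episodes))
  b <- apply_inpatient_exclusion(flag_inpatient(co$labs[perm, ], co$episodes))
  expect_setequal(a$kept$value_id, b$kept$value_id)
})
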