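reg <- code_registry()
cfg <- outcome_config()

mk_idx <- function(id = "P1", day = 0) {
  list(patient_id = id, index_date = fx_base + day, qualifying_code = "ICD10:R56.9",
       age_at_index_days = 1825L)
}

test_that("status epilepticus requires the primary/admitting positional rule", {
  # SE code primary at index+30: true
  p <- fx_patient("P1", encs = list(
    fx_enc(0, "ICD10:R56.9"),
    fx_enc(30, c("ICD10:G40.901", "ICD10:J06.9"), primary = 1)))
  expect_true(criterion_status_epilepticus(p, mk_idx(), reg, cfg))

  # SE code in third position, primary a non-epilepsy filler: false
  p <- fx_patient("P1", encs = list(
    fx_enc(0, "ICD10:R56.9"),
    fx_enc(30, c("ICD10:J06.9", "ICD10:H66.90", "ICD10:G40.901"), primary = 1)))
  expect_false(criterion_status_epilepticus(p, mk_idx(), reg, cfg))

  # SE code third, admitting code epilepsy-specific: true via second clause
  p <- fx_patient("P1", encs = list(
    fx_enc(0, "ICD10:R56.9"),
    fx_enc(30, c("ICD10:J06.9", "ICD10:G40.9", "ICD10:G40.901"),
           primary = 1, admitting = 2, setting = "inpatient")))
  expect_true(criterion_status_epilepticus(p, mk_idx(), reg, cfg))
})

test_that("procedure criterion needs an epilepsy-coded host encounter and a later dx", {
  host <- fx_enc(100, "ICD10:G40.909", setting = "inpatient", primary = 1,
                 id = "P1-host")
  later <- fx_enc(110, "ICD10:G40.909")
  p <- fx_patient("P1", encs = list(fx_enc(0, "ICD10:R56.9"), host, later),
                  procs = data.frame(day = 100, code = "CPT:95951",
                                     encounter_id = "P1-host"))
  expect_true(criterion_procedure(p, mk_idx(), reg, cfg))

  # later dx only 3 days after the procedure: false
  p3 <- fx_patient("P1", encs = list(fx_enc(0, "ICD10:R56.9"), host,
                                     fx_enc(103, "ICD10:G40.909")),
                   procs = data.frame(day = 100, code = "CPT:95951",
                                      encounter_id = "P1-host"))
  expect_false(criterion_procedure(p3, mk_idx(), reg, cfg))

  # host encounter primary dx is a convulsion code: false
  conv_host <- fx_enc(100, "ICD10:R56.9", setting = "inpatient", id = "P1-host")
  p4 <- fx_patient("P1", encs = list(fx_enc(0, "ICD10:R56.9"), conv_host, later),
                   procs = data.frame(day = 100, code = "CPT:95951",
                                      encounter_id = "P1-host"))
  expect_false(criterion_procedure(p4, mk_idx(), reg, cfg))
})

test_that("ASM criterion requires same-day epilepsy diagnosis and respects blanking", {
  p <- fx_patient("P1", encs = list(
    fx_enc(0, "ICD10:R56.9"), fx_enc(60, "ICD10:G40.9")),
    meds = data.frame(day = 60, drug = "levetiracetam"))
  expect_true(criterion_asm(p, mk_idx(), reg, cfg))

  # gabapentin on a neuropathic-pain day: false
  p2 <- fx_patient("P1", encs = list(
    fx_enc(0, "ICD10:R56.9"), fx_enc(60, "ICD10:G89.29")),
    meds = data.frame(day = 60, drug = "gabapentin"))
  expect_false(criterion_asm(p2, mk_idx(), reg, cfg))

  # ASM at index+3 sits inside the blanking window: false
  p3 <- fx_patient("P1", encs = list(
    fx_enc(0, "ICD10:R56.9"), fx_enc(3, "ICD10:G40.9")),
    meds = data.frame(day = 3, drug = "levetiracetam"))
  expect_false(criterion_asm(p3, mk_idx(), reg, cfg))

  # unknown drug name: warning, record ignored
  p4 <- fx_patient("P1", encs = list(
    fx_enc(0, "ICD10:R56.9"), fx_enc(60, "ICD10:G40.9")),
    meds = data.frame(day = 60, drug = "amoxicillin"))
  expect_warning(res <- criterion_asm(p4, mk_idx(), reg, cfg), "lexicon")
  expect_false(res)

  # adjunctive-only mode counts clobazam but not levetiracetam
  cfg_adj <- outcome_config(require_adjunctive_only = TRUE)
  expect_false(criterion_asm(p, mk_idx(), reg, cfg_adj))
  p5 <- fx_patient("P1", encs = list(
    fx_enc(0, "ICD10:R56.9"), fx_enc(60, "ICD10:G40.9")),
    meds = data.frame(day = 60, drug = "clobazam"))
  expect_true(criterion_asm(p5, mk_idx(), reg, cfg_adj))
})

test_that("utilisation counts distinct days, not encounters", {
  # two seizure-coded encounters on the same day count once
  p <- fx_patient("P1", encs = list(
    fx_enc(0, "ICD10:R56.9"),
    fx_enc(50, "ICD10:G40.9"), fx_enc(50, "ICD10:R56.9")))
  expect_false(criterion_utilisation(p, mk_idx(), reg, cfg, "seizure_related"))

  p2 <- fx_patient("P1", encs = list(
    fx_enc(0, "ICD10:R56.9"),
    fx_enc(50, "ICD10:G40.9"), fx_enc(90, "ICD10:R56.9"),
    fx_enc(130, "ICD10:G40.9")))
  expect_true(criterion_utilisation(p2, mk_idx(), reg, cfg, "seizure_related"))
})

test_that("inpatient and diagnostics criteria follow their thresholds", {
  p <- fx_patient("P1", encs = list(
    fx_enc(0, "ICD10:R56.9"),
    fx_enc(200, "ICD10:G40.909", setting = "inpatient", admitting = 1)))
  expect_true(criterion_inpatient(p, mk_idx(), reg, cfg))

  # outpatient-only seizure encounters: false
  p2 <- fx_patient("P1", encs = list(
    fx_enc(0, "ICD10:R56.9"), fx_enc(200, "ICD10:G40.909")))
  expect_false(criterion_inpatient(p2, mk_idx(), reg, cfg))

  # EEG order on a day with a G40 code: diagnostics true at threshold 1
  p3 <- fx_patient("P1", encs = list(
    fx_enc(0, "ICD10:R56.9"), fx_enc(30, "ICD10:G40.9")),
    procs = data.frame(day = 30, code = "CPT:95819"))
  expect_true(criterion_diagnostics(p3, mk_idx(), reg, cfg))
  # same order without a co-occurring seizure-related dx: false
  p4 <- fx_patient("P1", encs = list(
    fx_enc(0, "ICD10:R56.9"), fx_enc(35, "ICD10:G40.9")),
    procs = data.frame(day = 30, code = "CPT:95819"))
  expect_false(criterion_diagnostics(p4, mk_idx(), reg, cfg))
})

test_that("composite is the OR of the seven criteria", {
  # zero post-index events: everything false
  p0 <- fx_patient("P1", encs = list(fx_enc(0, "ICD10:R56.9")))
  lab <- composite_label(p0, mk_idx(), reg, cfg)
  expect_false(any(unlist(lab[-1])))

  # only the SE criterion fires: composite true
  p <- fx_patient("P1", encs = list(
    fx_enc(0, "ICD10:R56.9"),
    fx_enc(30, "ICD10:G40.901", primary = 1)))
  lab <- composite_label(p, mk_idx(), reg, cfg)
  expect_true(lab$status_epilepticus)
  expect_true(lab$composite)
  crit <- unlist(lab[c("asm", "status_epilepticus", "inpatient_seizure",
                       "seizure_utilisation", "all_utilisation",
                       "diagnostics", "procedure")])
  expect_equal(lab$composite, any(crit))
})

test_that("events at or before index + blanking never contribute", {
  # all events on day 7 (= blanking boundary): nothing fires
  p <- fx_patient("P1", encs = list(
    fx_enc(0, "ICD10:R56.9"),
    fx_enc(7, "ICD10:G40.901", primary = 1, setting = "inpatient",
           admitting = 1),
    fx_enc(7, "ICD10:G40.9")),
    meds = data.frame(day = 7, drug = "levetiracetam"),
    procs = data.frame(day = 7, code = "CPT:95819"))
  lab <- composite_label(p, mk_idx(), reg, cfg)
  expect_false(any(unlist(lab[-1])))
  # one day later the same events do count
  p8 <- fx_patient("P1", encs = list(
    fx_enc(0, "ICD10:R56.9"),
    fx_enc(8, "ICD10:G40.901", primary = 1, setting = "inpatient",
           admitting = 1)))
  expect_true(composite_label(p8, mk_idx(), reg, cfg)$status_epilepticus)
  # events beyond the two-year window are ignored
  p731 <- fx_patient("P1", encs = list(
    fx_enc(0, "ICD10:R56.9"),
    fx_enc(731, "ICD10:G40.901", primary = 1)))
  expect_false(composite_label(p731, mk_idx(), reg, cfg)$status_epilepticus)
})

test_that("criteria are monotone in the event set", {
  withr::with_seed(31, {
    co <- simulate_cohort(sim_config(n_patients = 60, seed = 31))
    records <- as_patient_records(co)
    ct <- build_cohort(records, reg, "emr")
    inc <- ct[ct$included, ]
    for (i in seq_len(min(20, nrow(inc)))) {
      p <- records[[inc$patient_id[i]]]
      idx <- list(patient_id = inc$patient_id[i],
                  index_date = inc$index_date[i])
      before <- composite_label(p, idx, reg, cfg)
      # add a post-index inpatient SE admission: no criterion may flip off
      extra <- p$encounters[1, ]
      extra$date <- inc$index_date[i] + 100
      extra$setting <- "inpatient"
      extra$codes <- list("ICD10:G40.901")
      extra$primary_pos <- 1L
      extra$admitting_pos <- 1L
      p2 <- p
      p2$encounters <- rbind(p$encounters, extra)
      p2$encounters <- p2$encounters[order(p2$encounters$date), ]
      after <- composite_label(p2, idx, reg, cfg)
      for (f in names(before)[-1]) {
        expect_true(!before[[f]] || after[[f]], info = f)
      }
    }
  })
})

test_that("composite labels match the brute-force oracle on random patients", {
  co <- simulate_cohort(sim_config(n_patients = 150, seed = 77))
  records <- as_patient_records(co)
  ct <- build_cohort(records, reg, "emr")
  lab <- label_cohort(records, ct, reg, cfg)
  inc <- ct[ct$included, ]
  for (i in seq_len(nrow(inc))) {
    idx <- list(index_date = inc$index_date[i])
    o <- orc_label(records[[inc$patient_id[i]]], idx, reg, cfg)
    got <- lab[lab$patient_id == inc$patient_id[i], ]
    for (f in names(o)) {
      expect_equal(got[[f]], o[[f]],
                   info = paste(inc$patient_id[i], f))
    }
  }
})
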