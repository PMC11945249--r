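mk_reading <- function(assay = 900, quench = 800, ref = 1000,
                       sub = 125, homog = NULL, abiotic = NULL,
                       params = assay_params()) {
  if (length(assay) == 1) assay <- rep(assay, 3)
  plate_reading("s1", "bg", assay = assay, quench_standard = quench,
                substrate_control = sub, reference_standard = ref,
                homogenate_control = homog, abiotic_control = abiotic,
                params = params)
}

test_that("quench, emission and net fluorescence follow the plate algebra", {
  expect_equal(quench_coefficient(mk_reading(quench = 800, ref = 1000)), 0.8)
  expect_equal(quench_coefficient(mk_reading(quench = 1000, ref = 1000)), 1.0)
  expect_equal(quench_coefficient(mk_reading(quench = 900, ref = 1000,
                                             homog = 100)), 0.8)
  expect_ev_error(quench_coefficient(mk_reading(quench = 0)), "ev_assay_error")

  p <- assay_params(standard_amount = 10)
  expect_equal(emission_coefficient(mk_reading(ref = 1000, params = p)), 100)
  expect_equal(emission_coefficient(mk_reading(ref = 250,
                                               params = assay_params(standard_amount = 2.5))),
               100)
  expect_ev_error(emission_coefficient(mk_reading(ref = 0)), "ev_assay_error")

  expect_equal(net_fluorescence(mk_reading(assay = 900, quench = 800,
                                           ref = 1000, sub = 125)), 1000)
  expect_equal(net_fluorescence(mk_reading(assay = 100, quench = 1000,
                                           ref = 1000, sub = 100)), 0)
  expect_equal(net_fluorescence(mk_reading(assay = 900, quench = 800,
                                           ref = 1000, sub = 125,
                                           abiotic = 325)), 800)
})

test_that("activity applies the unit-conversion chain and QC flags", {
  # net 1000 RFU at e = 100 RFU/nmol -> 10 nmol; x50 dilution; /(1 g * 0.5 h)
  p <- assay_params(standard_amount = 10, well_aliquot_volume = 0.2,
                    suspension_volume = 10, sediment_dry_mass = 1,
                    incubation_time = 0.5)
  r <- mk_reading(assay = 900, quench = 800, ref = 1000, sub = 125, params = p)
  out <- plate_activity(r)
  expect_equal(out$activity, 1000)
  expect_identical(out$qc_flags, "")

  neg <- plate_activity(mk_reading(assay = 80, quench = 1000, ref = 1000,
                                   sub = 120, params = p))
  expect_equal(neg$activity, 0)
  expect_match(neg$qc_flags, "NEGATIVE_CLAMPED")

  lowq <- plate_activity(mk_reading(assay = 900, quench = 50, ref = 1000,
                                    sub = 0, params = p))
  expect_match(lowq$qc_flags, "LOW_QUENCH")
  expect_equal(lowq$quench_coefficient, 0.05)

  noisy <- plate_activity(mk_reading(assay = c(100, 900, 1700), quench = 900,
                                     ref = 1000, sub = 0, params = p))
  expect_match(noisy$qc_flags, "HIGH_CV")
  expect_ev_error(plate_reading("s", "bg", assay = c(1, 2), quench_standard = 1,
                                substrate_control = 1, reference_standard = 1),
                  "ev_data_error")
})

test_that("noise-free simulated plates round-trip to the generating activities", {
  acts <- data.frame(sample_id = c("a", "b"), bg = c(120, 3), cbh = c(40, 1),
                     nag = c(55, 2), lap = c(70, 4), ap = c(200, 0.5))
  for (q in c(0.5, 0.8, 1.0)) {
    plate <- simulate_plate(acts, quench_q = q, noise_sd = 0)
    red <- reduce_plate_set(plate)
    m <- merge(acts, red$activities, by = "sample_id", suffixes = c("", ".r"))
    for (e in c("bg", "cbh", "nag", "lap", "ap"))
      expect_equal(m[[paste0(e, ".r")]], m[[e]], tolerance = 1e-9)
  }
})

test_that("quench linearity: scaling sample-matrix and standard wells cancels", {
  p <- assay_params(standard_amount = 10)
  base <- plate_activity(mk_reading(assay = 900, quench = 800, ref = 1000,
                                    sub = 125, params = p))
  # doubling quench-affected wells (assay + quench standard) leaves activity
  # unchanged because q doubles too
  scaled <- plate_activity(mk_reading(assay = 1800, quench = 1600, ref = 1000,
                                      sub = 125, params = p))
  expect_equal(scaled$activity, base$activity)
})

test_that("with q = 1 and zero blanks, activity is proportional to assay RFU", {
  p <- assay_params(standard_amount = 10)
  a1 <- plate_activity(mk_reading(assay = 300, quench = 1000, ref = 1000,
                                  sub = 0, params = p))$activity
  a2 <- plate_activity(mk_reading(assay = 600, quench = 1000, ref = 1000,
                                  sub = 0, params = p))$activity
  expect_equal(a2, 2 * a1)
})

test_that("noisy plates recover activities without material bias", {
  acts <- data.frame(sample_id = "a", bg = 100, cbh = 40, nag = 60, lap = 80,
                     ap = 150)
  set.seed(99)
  rel_err <- replicate(200, {
    plate <- simulate_plate(acts, quench_q = 0.7, noise_sd = 15)
    red <- reduce_plate_set(plate)
    mean(unlist(red$activities[c("bg", "cbh", "nag", "lap", "ap")]) /
           unlist(acts[c("bg", "cbh", "nag", "lap", "ap")]) - 1)
  })
  expect_lt(abs(mean(rel_err)), 0.01)
})

test_that("reduce_plate_set enforces completeness and uniqueness", {
  acts <- balanced_activities()
  plate <- simulate_plate(acts, noise_sd = 0)
  red <- reduce_plate_set(plate)
  expect_equal(nrow(red$activities), 1)
  expect_named(red$activities, c("sample_id", "bg", "cbh", "nag", "lap", "ap"))

  missing_ap <- plate[plate$enzyme != "ap", ]
  expect_warning(red2 <- reduce_plate_set(missing_ap), "missing")
  expect_equal(nrow(red2$activities), 0)
  expect_equal(red2$excluded, "bal")

  r <- mk_reading()
  expect_ev_error(reduce_plate_set(list(r, r)), "ev_data_error")
  empty <- reduce_plate_set(plate[0, ])
  expect_equal(nrow(empty$activities), 0)
  expect_equal(empty$excluded, character())
})

test_that("plate table IO validates the schema", {
  plate <- simulate_plate(balanced_activities(), noise_sd = 0)
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(plate, path, row.names = FALSE)
  expect_equal(nrow(read_plate_table(path)), nrow(plate))
  plate$well_role[1] <- "mystery"
  utils::write.csv(plate, path, row.names = FALSE)
  expect_ev_error(read_plate_table(path), "ev_data_error")
})
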