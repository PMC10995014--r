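test_that("degenerate SDs reproduce the group means exactly", {
  spec <- flat_spec(hr_mesor = 80, hr_amplitude = 10, hr_acrophase = 1.2,
                    rmssd_mesor = 40, rmssd_amplitude = 5,
                    rmssd_acrophase = 5.0)
  tr <- sample_subject_truth(spec, seed = 1)
  expect_identical(tr$hr_mesor, 80)
  expect_identical(tr$hr_amplitude, 10)
  expect_identical(tr$hr_acrophase, 1.2)
  expect_identical(tr$rmssd_mesor, 40)
})

test_that("identical seeds reproduce identical subjects and recordings", {
  spec <- rhythm_preset("nssi")
  t1 <- sample_subject_truth(spec, seed = 99)
  t2 <- sample_subject_truth(spec, seed = 99)
  expect_identical(t1, t2)
  s1 <- simulate_ibi(t1, duration_hours = 0.5, seed = 5)
  s2 <- simulate_ibi(t2, duration_hours = 0.5, seed = 5)
  expect_identical(s1$beats, s2$beats)
})

test_that("sampled HR MESOR is centred on the NSSI preset mean", {
  spec <- rhythm_preset("nssi")
  draws <- vapply(seq_len(10000),
                  function(i) sample_subject_truth(spec, seed = i)$hr_mesor,
                  numeric(1))
  se <- spec$hr_mesor_sd / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 85.98), 3 * se)
})

test_that("amplitudes are truncated at zero and acrophases wrapped", {
  spec <- group_rhythm_spec("W", 1, hr_mesor = 80, hr_amplitude = 1,
                            hr_acrophase = 0.05, rmssd_mesor = 40,
                            rmssd_amplitude = 1, rmssd_acrophase = 6.2,
                            hr_amplitude_sd = 10, hr_acrophase_sd = 3,
                            rmssd_amplitude_sd = 10, rmssd_acrophase_sd = 3)
  trs <- lapply(1:200, function(i) sample_subject_truth(spec, seed = i))
  amps <- vapply(trs, `[[`, numeric(1), "hr_amplitude")
  acro <- vapply(trs, `[[`, numeric(1), "hr_acrophase")
  expect_true(all(amps >= 0))
  expect_true(all(acro >= 0 & acro < 2 * pi))
})

test_that("beat noise is calibrated so empirical RMSSD matches the target", {
  spec <- flat_spec(hr_mesor = 70, rmssd_mesor = 50)
  tr <- sample_subject_truth(spec, seed = 2)
  ser <- simulate_ibi(tr, duration_hours = 1, seed = 3)
  expect_gt(nrow(ser$beats), 3000)
  emp <- rmssd(ser$beats$ibi)
  expect_lt(abs(emp - 50) / 50, 0.05)
})

test_that("noise-free constant-rate simulation gives exactly periodic beats", {
  spec <- flat_spec(hr_mesor = 75, rmssd_mesor = 0)
  tr <- sample_subject_truth(spec, seed = 1)
  ser <- simulate_ibi(tr, duration_hours = 0.5,
                      artifacts = artifact_spec(iid_noise_floor = 0), seed = 1)
  expect_equal(ser$beats$ibi, rep(60000 / 75, nrow(ser$beats)),
               tolerance = 1e-6)
})

test_that("non-wear windows delete all beats inside them", {
  spec <- flat_spec()
  tr <- sample_subject_truth(spec, seed = 4)
  art <- artifact_spec(nonwear_windows = list(c(2, 0.5)))
  ser <- simulate_ibi(tr, duration_hours = 4, artifacts = art, seed = 4)
  t_h <- ser$beats$t / 3600
  expect_false(any(t_h > 2 & t_h < 2.5))
  # the first beat after the window absorbs the gap
  after <- which(t_h >= 2.5)[1]
  expect_gt(ser$beats$ibi[after], 0.45 * 3600 * 1000)
})

test_that("ectopic events keep cumulative time and show the 0.6/compensatory shape", {
  spec <- flat_spec(hr_mesor = 60, rmssd_mesor = 0)
  tr <- sample_subject_truth(spec, seed = 5)
  clean <- simulate_ibi(tr, duration_hours = 0.5,
                        artifacts = artifact_spec(iid_noise_floor = 0), seed = 6)
  ect <- simulate_ibi(tr, duration_hours = 0.5,
                      artifacts = artifact_spec(ectopic_rate = 0.02,
                                                iid_noise_floor = 0), seed = 6)
  expect_equal(max(ect$beats$t), max(clean$beats$t), tolerance = 1e-6)
  short <- ect$beats$ibi[ect$beats$ibi < 900]
  expect_true(length(short) > 0)
  expect_equal(unique(round(short)), round(0.6 * 1000))
})

test_that("cohorts have the right composition and are seed-deterministic", {
  specs <- list(flat_spec(n = 3, label = "A"), flat_spec(n = 2, label = "B"))
  out_dir <- withr::local_tempdir()
  c1 <- simulate_cohort(specs, seed = 10, duration_hours = 0.2,
                        out_dir = out_dir)
  expect_equal(nrow(c1$metadata), 5)
  expect_equal(length(c1$series), 5)
  expect_equal(sum(grepl("^A_", c1$metadata$subject_id)), 3)
  expect_length(list.files(out_dir, pattern = "ibi\\.txt$"), 5)

  # an empty group contributes nothing
  c2 <- simulate_cohort(list(flat_spec(n = 0, label = "A"),
                             flat_spec(n = 2, label = "B")),
                        seed = 10, duration_hours = 0.2)
  expect_equal(nrow(c2$metadata), 2)
  expect_true(all(grepl("^B_", c2$metadata$subject_id)))

  # byte-identical metadata under the same seed
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_cohort(specs, seed = 77, duration_hours = 0.2, out_dir = d1)
  simulate_cohort(specs, seed = 77, duration_hours = 0.2, out_dir = d2)
  expect_identical(readLines(file.path(d1, "metadata.csv")),
                   readLines(file.path(d2, "metadata.csv")))

  expect_error(simulate_cohort(list(flat_spec(n = 2, label = "A"),
                                    flat_spec(n = 2, label = "A")),
                               seed = 1, duration_hours = 0.2),
               "duplicate subject ids")
})

test_that("spec validation names the offending field", {
  expect_error(rhythm_preset("nssi", n_subjects = -1), "n_subjects")
  expect_error(group_rhythm_spec("G", 2, hr_mesor = 10, hr_amplitude = 12,
                                 hr_acrophase = 1, rmssd_mesor = 40,
                                 rmssd_amplitude = 5, rmssd_acrophase = 5),
               "hr_mesor")
  expect_error(artifact_spec(ectopic_rate = 0.5), "ectopic_rate")
  expect_error(artifact_spec(nonwear_windows = list(c(1, 2), c(2, 1))),
               "overlap")
})
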