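# Montage resolution, EDF round-tripping and cohort metadata.

test_that("full 10-20 set resolves to 8 homologous pairs plus 3 midline", {
  m <- build_montage_map(ten_twenty_labels())
  expect_s3_class(m, "montage_map")
  expect_equal(nrow(m$pairs), 8)
  expect_equal(m$midline, c("Fz", "Cz", "Pz"))
  expect_equal(m$pairs$pair[1], "Fp1_Fp2")   # frontal first
  expect_equal(m$pairs$pair[8], "O1_O2")     # occipital last
  # partition: every label exactly once across pairs + midline
  all_labs <- c(m$pairs$left, m$pairs$right, m$midline)
  expect_setequal(all_labs, ten_twenty_labels())
  expect_equal(anyDuplicated(all_labs), 0L)
})

test_that("montage handles subsets, aliases and unpaired electrodes", {
  m <- build_montage_map(c("Fp1", "Fp2"))
  expect_equal(nrow(m$pairs), 1)
  expect_length(m$midline, 0)
  expect_error(build_montage_map("Fp1"), "homolog")
  expect_error(build_montage_map(c("Fp1", "Fp2", "Fp1")), "duplicate")
  # modern temporal-chain names map onto legacy ones
  expect_equal(canonical_labels(c("T7", "T8", "P7", "p8", "fp1")),
               c("T3", "T4", "T5", "T6", "Fp1"))
  m2 <- build_montage_map(c("T7", "T8"))
  expect_equal(m2$pairs$pair, "T3_T4")
  expect_error(canonical_labels("XX"), "unrecognized")
})

test_that("EDF round-trip preserves labels, fs and samples to 16-bit quantization", {
  rec <- small_recording()
  dir <- withr::local_tempdir()
  path <- file.path(dir, "pat.edf")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_equal(back$channels, rec$channels)
  expect_equal(back$fs, rec$fs)
  expect_equal(back$pathological_side, rec$pathological_side)
  expect_length(back$segments, 2)
  expect_equal(back$segments[[1]]$state, "wake")
  expect_equal(back$segments[[2]]$start, 60)
  # quantization bound: physical range / (2^16 - 2) per channel
  qstep <- apply(abs(rec$data), 1, max) * 1.002 * 2 / 65534
  err <- apply(abs(back$data - rec$data), 1, max)
  expect_true(all(err <= qstep + 1e-12))
})

test_that("EDF reader agrees with an independent python EDF implementation", {
  skip_if(Sys.which("python") == "", "python not on PATH")
  rec <- small_recording()
  dir <- withr::local_tempdir()
  path <- file.path(dir, "pat.edf")
  write_edf(rec, path)
  out <- tryCatch(
    system2("python", c("-c", shQuote(paste0(
      "import mne, numpy as np; ",
      "r = mne.io.read_raw_edf('", path, "', verbose='ERROR'); ",
      "d = r.get_data() * 1e6; ",  # volts -> microvolts
      "print(len(r.ch_names), int(r.info['sfreq']), ",
      "round(float(np.max(np.abs(d))), 3), round(float(d[0, :5].sum()), 3))"
    ))), stdout = TRUE, stderr = FALSE),
    warning = function(w) NA, error = function(e) NA)
  skip_if(length(out) == 0 || is.na(out[1]), "python EDF reader unavailable")
  parts <- as.numeric(strsplit(out[length(out)], " ")[[1]])
  expect_equal(parts[1], length(rec$channels))
  expect_equal(parts[2], rec$fs)
  back <- read_recording(path)
  expect_equal(parts[3], round(max(abs(back$data)), 3), tolerance = 1e-3)
  expect_equal(parts[4], round(sum(back$data[1, 1:5]), 3), tolerance = 1e-2)
})

test_that("a recording missing a required lateral channel is rejected by name", {
  rec <- small_recording()
  drop <- setdiff(rec$channels, "O2")
  rec2 <- new_recording(rec$patient_id, rec$fs, drop,
                        rec$data[drop, , drop = FALSE],
                        pathological_side = rec$pathological_side,
                        segments = rec$segments)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "short.edf")
  write_recording(rec2, path)
  expect_error(read_recording(path), "O2 absent")
  expect_error(patient_feature_tensor(rec2), "O2 absent")
})

test_that("bundled cohort loads with 21 records and the SF/NSF dichotomy", {
  cohort <- study_cohort()
  expect_equal(nrow(cohort), 21)
  expect_equal(sum(cohort$label == "SF"), 15)
  # SF exactly for Engel IA; everything else (ID, II, III, IV) is NSF
  expect_true(all(cohort$label[cohort$engel_outcome == "IA"] == "SF"))
  expect_true(all(cohort$label[cohort$engel_outcome != "IA"] == "NSF"))
  bad <- cohort
  bad$engel_outcome[3] <- "V"
  tf <- withr::local_tempfile(fileext = ".csv")
  write.csv(bad[, names(bad) != "label"], tf, row.names = FALSE)
  expect_error(load_cohort(tf), "Engel")
})

test_that("cohort summary matches the published headline values", {
  cohort <- study_cohort()
  s <- cohort_summary(cohort)
  expect_equal(s$pct_sf, 71)
  expect_equal(s$median_followup, 5.1)
  expect_equal(s$range_followup, c(2.3, 12.6))
  expect_equal(s$median_age, 7)
})

test_that("cohort summary is invariant under row permutation; single row is its own median", {
  cohort <- study_cohort()
  set.seed(4)
  perm <- cohort[sample(nrow(cohort)), ]
  expect_equal(cohort_summary(perm)[c("pct_sf", "median_age", "median_followup")],
               cohort_summary(cohort)[c("pct_sf", "median_age", "median_followup")])
  one <- cohort[7, ]
  s1 <- cohort_summary(one)
  expect_equal(s1$median_age, one$age_at_surgery)
  expect_equal(s1$median_followup, one$followup_years)
})
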