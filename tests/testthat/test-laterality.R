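# Electrode means, pathological-minus-healthy differencing and the four
# feature datasets.

# A synthetic feature tensor built directly (no signal processing): one
# value per (patient, state, electrode, feature).
toy_tensor <- function(patients = c("A", "B"), value_fn) {
  grid <- expand.grid(patient_id = patients, state = c("wake", "sleep"),
                      electrode = ten_twenty_labels(lateral_only = TRUE),
                      feature = feature_names(), stringsAsFactors = FALSE)
  grid$value <- value_fn(grid)
  grid
}

lat_montage <- build_montage_map(ten_twenty_labels())

test_that("window means aggregate correctly and incomplete patients drop out", {
  wt <- expand.grid(patient_id = "A", state = c("wake", "sleep"),
                    window_idx = 1:12, electrode = c("C3", "C4"),
                    feature = "activity", stringsAsFactors = FALSE)
  wt$value <- ifelse(wt$state == "wake", wt$window_idx, 7)
  agg <- aggregate_electrode_means(wt)
  expect_equal(agg$value[agg$state == "wake"], c(6.5, 6.5))  # mean of 1..12
  expect_equal(agg$value[agg$state == "sleep"], c(7, 7))
  # patient with only one state is excluded with a message
  wt2 <- rbind(wt, within(wt[wt$state == "wake", ], patient_id <- "B"))
  expect_message(agg2 <- aggregate_electrode_means(wt2), "excluding.*B")
  expect_setequal(unique(agg2$patient_id), "A")
})

test_that("a hemispherically symmetric brain has all-zero differences", {
  tens <- toy_tensor(value_fn = function(g)
    as.numeric(factor(g$feature)) + as.numeric(factor(g$state)))
  lat <- interhemispheric_difference(tens, lat_montage,
                                     c(A = "left", B = "right"))
  expect_equal(nrow(lat), 2 * 2 * 8 * 9)   # patients x states x pairs x features
  expect_true(all(lat$value == 0))
})

test_that("a uniform pathological alpha suppression appears as -2 on every pair", {
  left_set <- lat_montage$pairs$left
  tens <- toy_tensor(patients = "A", value_fn = function(g) {
    v <- rep(5, nrow(g))
    v[g$feature == "psd_alpha" & g$electrode %in% left_set] <- 3
    v
  })
  lat <- interhemispheric_difference(tens, lat_montage, c(A = "left"))
  expect_true(all(lat$value[lat$feature == "psd_alpha"] == -2))
  expect_true(all(lat$value[lat$feature != "psd_alpha"] == 0))
})

test_that("swapping the declared pathological side negates every difference", {
  set.seed(31)
  tens <- toy_tensor(value_fn = function(g) rnorm(nrow(g)))
  l1 <- interhemispheric_difference(tens, lat_montage, c(A = "left", B = "left"))
  l2 <- interhemispheric_difference(tens, lat_montage, c(A = "right", B = "right"))
  expect_equal(l2$value, -l1$value)
})

test_that("mirrored patients produce identical lateralized features", {
  set.seed(32)
  tens <- toy_tensor(patients = "A", value_fn = function(g) rnorm(nrow(g)))
  # mirror: swap homologous electrode values, flip the declared side
  swap <- c(stats::setNames(lat_montage$pairs$right, lat_montage$pairs$left),
            stats::setNames(lat_montage$pairs$left, lat_montage$pairs$right))
  mirrored <- tens
  mirrored$electrode <- unname(swap[tens$electrode])
  l1 <- interhemispheric_difference(tens, lat_montage, c(A = "left"))
  l2 <- interhemispheric_difference(mirrored, lat_montage, c(A = "right"))
  key <- function(d) d[order(d$state, d$pair, d$feature), "value"]
  expect_equal(key(l2), key(l1))
})

test_that("the four datasets have the prescribed column structure", {
  gen <- cached_fixture("tiny_full",
    synth_study(synth_params(n_patients = 3, seed = 77), ids = 1:4))
  dims <- vapply(gen$datasets, function(d) ncol(d$x), 0)
  expect_equal(unname(dims), c(144, 64, 96, 288))
  expect_equal(nrow(gen$datasets[["1"]]$x), 3)
  cols <- lapply(gen$datasets, function(d) colnames(d$x))
  # dataset 1 and 3 intersect exactly in the PSD columns; 1 and 2 in
  # total-band PSD + broadband Hjorth; 2 and 3 in total-band PSD only
  expect_setequal(intersect(cols[["2"]], cols[["3"]]),
                  grep("psd_total$", cols[["2"]], value = TRUE))
  expect_true(all(cols[["2"]] %in% cols[["1"]]))
  expect_true(all(cols[["3"]] %in% cols[["1"]]))
  # per-patient core tensor: 288 values (9 x 16 x 2) before pairing
  tens <- patient_feature_tensor(small_recording(), band_hjorth = FALSE)
  expect_equal(nrow(tens), 288)
  expect_error(build_dataset(gen$lateralized, 5), "unknown dataset")
})

test_that("dataset 4 requires band-filtered Hjorth features", {
  st <- synth_study(synth_params(n_patients = 2, seed = 78), ids = 1,
                    band_hjorth = FALSE)
  expect_error(build_dataset(st$lateralized, 4), "band_hjorth")
})

test_that("alternative input modes have the right shape and sign behaviour", {
  set.seed(33)
  tens <- rbind(toy_tensor(value_fn = function(g) rnorm(nrow(g))))
  sides <- c(A = "left", B = "right")
  x_pair <- build_input_matrix(tens, lat_montage, sides, "pair_difference")
  x_hemi <- build_input_matrix(tens, lat_montage, sides, "hemisphere_mean")
  x_raw <- build_input_matrix(tens, lat_montage, sides, "raw")
  expect_equal(dim(x_pair), c(2, 144))
  expect_equal(dim(x_hemi), c(2, 18))     # 9 features x 2 states
  expect_equal(dim(x_raw), c(2, 288))     # 9 x 16 x 2
  expect_false(anyNA(x_raw))
  # hemisphere mean of the per-pair differences equals the hemisphere-mean
  # difference (both are linear in the same values)
  a_alpha_wake <- x_pair["A", grep("^wake\\..*\\.psd_alpha$", colnames(x_pair))]
  expect_equal(unname(x_hemi["A", "wake.hemisphere.psd_alpha"]),
               mean(a_alpha_wake))
  # flipping the declared side negates the hemisphere-mean inputs too
  x_flip <- build_input_matrix(tens, lat_montage,
                               c(A = "right", B = "left"), "hemisphere_mean")
  expect_equal(unname(x_flip), -unname(x_hemi))
})

test_that("common-average re-referencing zeroes the channel mean", {
  rec <- small_recording()
  car <- rereference_car(rec)
  expect_equal(max(abs(colMeans(car$data))), 0, tolerance = 1e-12)
  expect_equal(car$reference_label, "CAR")
  # differences between homologous channels are reference-invariant
  expect_equal(car$data["O1", ] - car$data["O2", ],
               rec$data["O1", ] - rec$data["O2", ])
})

test_that("standardization uses training-fold statistics only", {
  x <- cbind(a = c(1, 9, 5, 100), b = rep(2, 4))
  z <- standardize(x, train_idx = 1:3)
  # train column a: mean 5, sd 4 -> value 9 maps to 1, held-out 100 to 23.75
  expect_equal(unname(z[2, "a"]), 1)
  expect_equal(unname(z[4, "a"]), (100 - 5) / 4)
  expect_equal(unname(z[, "b"]), rep(0, 4))  # constant column centered
  expect_equal(mean(z[1:3, "a"]), 0)
  expect_equal(sd(z[1:3, "a"]), 1)
})
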