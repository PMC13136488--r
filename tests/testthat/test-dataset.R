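toy_records <- function() {
  E <- rbind(c(-1, -2, -3, -4, -5, -6),
             c(-7, -8, -9, -10, -11, -12),
             c(-1, -2, -3, -4, -5, -6),    # duplicate of row 1
             c(-13, -14, -15, -16, -17, -18),
             c(-19, -20, -21, -22, -23, -24))
  colnames(E) <- c("k11", "k12", "k13", "k22", "k23", "k33")
  data.frame(circuit_id = paste0("c", 1:5), E,
             S = c(10, NaN, 10, 5, 2), P = c(5, 5, 5, 5, 5),
             adaptation = c(800, NaN, 800, 700, 600),
             overshoot_ratio = c(0.1, 0.2, 0.1, 0.3, 0.4),
             settled = TRUE, settling_time = c(100, 100, 100, 100, 100))
}

test_that("filtering removes NaN, slow and duplicate records with counts", {
  flt <- filter_records(toy_records())
  expect_equal(nrow(flt$records), 3L)
  expect_equal(unname(flt$removed), c(1, 0, 1))
  expect_named(flt$removed, c("nan", "slow", "duplicate"))
  # slow responders: settling beyond the horizon fraction
  rec <- toy_records(); rec$settling_time[4] <- 9e4
  flt2 <- filter_records(rec, slow_frac = 0.8, horizon = 1e5)
  expect_equal(unname(flt2$removed[["slow"]]), 1)
  # everything removed is an error with accounting
  rec3 <- toy_records()[2, ]
  expect_error(filter_records(rec3), "no records survive")
})

test_that("feature normalisation maps strong binding high and inverts", {
  set.seed(5)
  E <- matrix(runif(50 * 6, -30, 0), 50, 6)
  st <- fit_feature_norm(E)
  x <- apply_feature_norm(E, st)
  expect_true(all(x >= 0 & x <= 1))
  # most negative training energy in each feature maps to 1
  for (j in 1:6) expect_equal(x[which.min(E[, j]), j], 1)
  # training median sits at the robust-scale origin before min-max
  med_norm <- apply_feature_norm(matrix(apply(E, 2, median), 1), st)
  expect_equal(unname(med_norm[1, ]),
               unname((0 - st$min) / (st$max - st$min)))
  # roundtrip
  expect_equal(invert_feature_norm(x, st), E, tolerance = 1e-9,
               ignore_attr = TRUE)
  # zero-IQR feature falls back to min-max only
  E2 <- E; E2[, 3] <- -7
  E2[1:25, 3] <- -7; E2[26:50, 3] <- c(-9, rep(-7, 24))
  st2 <- fit_feature_norm(E2)
  expect_false(st2$robust_ok[3])
  x2 <- apply_feature_norm(E2, st2)
  expect_true(all(x2[, 3] >= 0 & x2[, 3] <= 1))
})

test_that("label objectives produce the right dimensions and thresholds", {
  rec <- toy_records()[c(1, 4, 5), ]
  rec$S <- c(10, 100, 1); rec$P <- c(100, 10, 1)
  lab_bin <- build_labels(rec, "binary")
  expect_equal(unname(lab_bin$c[1, ]), c(1, 1))  # S = 10, P = 100
  expect_equal(unname(lab_bin$c[3, ]), c(0, 0))
  expect_equal(ncol(build_labels(rec, "adaptation")$c), 1L)
  expect_equal(ncol(build_labels(rec, "sp")$c), 2L)
  expect_equal(ncol(build_labels(rec, "three_metric")$c), 3L)
  rec$ruggedness <- c(1, 10, 100)
  joint <- build_labels(rec, "adaptation_ruggedness")
  expect_equal(ncol(joint$c), 2L)
  # applying the fitted state to out-of-range ruggedness excludes samples
  rec2 <- rec; rec2$ruggedness <- c(1e-6, 10, 1e6)
  out <- build_labels(rec2, "adaptation_ruggedness", state = joint$state)
  expect_equal(out$keep, c(FALSE, TRUE, FALSE))
  # all retained labels are inside [0, 1]
  expect_true(all(out$c >= 0 & out$c <= 1))
})

test_that("dataset assembly is leakage-free, reproducible and NaN-free", {
  ds <- demo_dataset()
  expect_s3_class(ds, "conditioned_dataset")
  expect_length(intersect(ds$train_idx, ds$test_idx), 0L)
  expect_false(anyNA(ds$x)); expect_false(anyNA(ds$c))
  expect_true(all(ds$x >= 0 & ds$x <= 1))
  expect_true(all(ds$c >= 0 & ds$c <= 1))
  # normalisation statistics derive from the training split only
  st <- fit_feature_norm(ds$raw_energies[ds$train_idx, ])
  expect_equal(st$median, ds$feature_state$median)
  # split reproducibility
  circuits <- sample_energy_circuits(sampling_config(n_circuits = 50,
                                                     seed = 9))
  met <- simulate_circuit_metrics(circuits)
  d1 <- build_dataset(met, seed = 4)
  d2 <- build_dataset(met, seed = 4)
  expect_identical(d1$circuit_id, d2$circuit_id)
  expect_identical(d1$train_idx, d2$train_idx)
  expect_identical(d1$x, d2$x)
})

test_that("normalisation state serialises losslessly through the bundle", {
  ds <- demo_dataset()
  dir <- tempfile("bundle_")
  write_dataset_bundle(ds, dir)
  expect_true(all(file.exists(file.path(dir,
    c("features.csv", "labels.csv", "norm_state.json",
      "provenance.json")))))
  st <- read_norm_state(dir)
  x2 <- apply_feature_norm(ds$raw_energies, st)
  x2 <- pmin(pmax(x2, 0), 1)
  expect_identical(unname(x2), unname(ds$x))
})
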