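test_that("sensitivity and precision follow the relative-change definitions", {
  r <- make_response(I1 = 1, I2 = 2, I_peak = 2, O1 = 10, O2 = 11,
                     O_peak = 15)
  sp <- sensitivity_precision(r)
  expect_equal(sp[["S"]], 0.5)
  expect_equal(sp[["P"]], 10)

  # flat peak: zero sensitivity
  r0 <- make_response(1, 2, 2, 10, 11, 10)
  expect_equal(sensitivity_precision(r0)[["S"]], 0)

  # perfect return of the output is a division by zero: NaN precision
  rp <- make_response(1, 2, 2, 10, 10, 15)
  expect_true(is.nan(sensitivity_precision(rp)[["P"]]))

  # S is invariant under rescaling the output trajectory
  r2 <- make_response(1, 2, 2, 10 * 7, 11 * 7, 15 * 7)
  expect_equal(sensitivity_precision(r2)[["S"]], sp[["S"]])
})

test_that("adaptation score is a bounded concentric gradient", {
  # value C at the concentric centre
  expect_equal(adaptation_score(1e7, 10^7.5), 1000)
  # hand-evaluated point
  expect_equal(adaptation_score(10, 10), 849.75)
  # worst operational corner stays positive
  expect_equal(adaptation_score(1e-7, 1e-2), 321.75)
  # bounded above by C, equality only at the centre
  set.seed(1)
  S <- 10^runif(200, -7, 2); P <- 10^runif(200, -2, 7)
  a <- adaptation_score(S, P)
  expect_true(all(a <= 1000))
  expect_true(all(a > 0))  # positive on the whole operational box
  # NaN contract for degenerate metrics
  expect_true(is.nan(adaptation_score(0, 10)))
  expect_true(is.nan(adaptation_score(NaN, 10)))
})

test_that("adaptability threshold conventions both classify correctly", {
  expect_true(classify_adaptable(20, 5))
  expect_false(classify_adaptable(5, 5))
  # alternative convention (S > 1, P > 10)
  expect_true(classify_adaptable(5, 20, S_min = 1, P_min = 10))
  expect_false(classify_adaptable(NaN, 20))
})

test_that("response features capture overshoot and timing", {
  tt <- seq(0, 100, by = 0.5)
  # overshoot then partial return
  out <- 10 + 5 * (exp(-tt / 20) - exp(-tt / 2))
  traj <- cbind(x1 = 0, x2 = 0, x3 = out)
  op <- which.max(abs(out - out[1]))
  resp <- structure(list(I1 = 1, I2 = 2, I_peak = 2, O1 = 10,
                         O2 = out[length(out)], O_peak = out[op],
                         trajectory = traj, time = tt,
                         settled1 = TRUE, settled2 = TRUE, failed = FALSE),
                    class = "signal_response")
  f <- response_features(resp)
  expect_equal(f[["overshoot"]], abs(resp$O_peak - resp$O2))
  expect_equal(f[["overshoot_ratio"]], f[["overshoot"]] / 10)
  expect_gt(f[["settling_time"]], f[["response_time"]])
  # constant output: everything zero
  respc <- structure(list(I1 = 1, I2 = 2, I_peak = 2, O1 = 10, O2 = 10,
                          O_peak = 10,
                          trajectory = cbind(0, 0, rep(10, 20)),
                          time = seq_len(20),
                          settled1 = TRUE, settled2 = TRUE, failed = FALSE),
                     class = "signal_response")
  fc <- response_features(respc)
  expect_equal(fc[["overshoot"]], 0)
  expect_equal(fc[["settling_time"]], 0)
})

test_that("ruggedness equals a brute-force perturbation oracle", {
  # analytic arithmetic: one interaction moving adaptation by 0.5 at eps=1
  # contributes dk = 0.5 and r = 0.25 (checked through the oracle loop below)
  set.seed(21)
  for (rep in 1:2) {
    e <- runif(6, -25, -5)
    rg <- ruggedness(e, epsilon = 1)
    # independent loop rebuilding and re-simulating each perturbed circuit
    a0 <- simulate_adaptation(e)
    dk_oracle <- vapply(1:6, function(i) {
      ep <- e; ep[i] <- ep[i] + 1
      (simulate_adaptation(ep) - a0) / 1
    }, numeric(1))
    expect_identical(unname(rg$dk), dk_oracle)
    expect_identical(rg$r, sum(dk_oracle^2))
    expect_gte(rg$r, 0)
  }
})

test_that("ruggedness is order-invariant and propagates NaN", {
  e <- c(-18, -9, -22, -12, -6, -27)
  r1 <- ruggedness(e)
  r2 <- ruggedness(e)  # identical rebuild, any internal ordering
  expect_identical(r1$r, r2$r)
  # a NaN baseline poisons the statistic
  rg <- ruggedness(e, a0 = NaN)
  expect_true(is.nan(rg$r))
})

test_that("batch metrics carry flags and match single-circuit runs", {
  circ <- sample_energy_circuits(sampling_config(4, seed = 77))
  met <- simulate_circuit_metrics(circ)
  expect_equal(nrow(met), 4L)
  one <- run_signal_protocol(unlist(circ[2, -1]))
  sp <- sensitivity_precision(one)
  expect_equal(met$S[2], sp[["S"]])
  expect_equal(met$adaptation[2], adaptation_score(sp[["S"]], sp[["P"]]))
  expect_true(all(met$settled))
})
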