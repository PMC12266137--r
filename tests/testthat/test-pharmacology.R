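test_that("ddCt fold changes follow the closed form", {
  mk <- function(sample, cond, ct_t, ct_h) {
    data.frame(sample_id = sample, condition = cond, ct_target = ct_t,
               ct_housekeeping = ct_h, stringsAsFactors = FALSE)
  }
  meas <- rbind(mk("m1", "mock", 25, 20),     # calibrator: dCt = 5
                mk("s1", "treated", 24, 20),  # ddCt = -1 -> fold 2
                mk("s2", "treated", 25, 20),  # ddCt =  0 -> fold 1
                mk("s3", "knockdown", 29.644, 20))  # ddCt = 4.644
  out <- ddct_fold_change(meas, "mock")
  get <- function(id) out$fold_change[out$sample_id == id]
  expect_equal(get("m1"), 1)
  expect_equal(get("s2"), 1)
  expect_equal(get("s1"), 2)
  ## a ddCt of +4.644 is the ~96% knockdown magnitude
  expect_equal(get("s3"), 2^-4.644, tolerance = 1e-12)
  expect_equal(out$percent_of_calibrator[out$sample_id == "s3"], 4,
               tolerance = 0.01)
  ## technical replicates are averaged before calibration
  dup <- rbind(meas, mk("s1", "treated", 26, 20))
  out2 <- ddct_fold_change(dup, "mock")
  expect_equal(out2$fold_change[out2$sample_id == "s1"], 1)
  expect_error(ddct_fold_change(meas, "nope"), "calibrator")
  bad <- mk("x", "mock", 41, 20)
  expect_error(ddct_fold_change(rbind(meas, bad), "mock"), "40")
})

test_that("serial dilutions are geometric and descending", {
  d <- serial_dilution(20, 4, 5)
  expect_equal(d, c(20, 5, 1.25, 0.3125, 0.078125))
  expect_equal(round(min(d), 3), 0.078)
  expect_equal(min(serial_dilution(50, 2, 6)), 1.5625)
  expect_equal(serial_dilution(7, 3, 1), 7)
})

test_that("hit calling is strict and monotone in the threshold", {
  v <- c(a = 120, b = 125, c = 126)
  expect_identical(call_hits(v, 125), "c")  # strictly greater only
  expect_identical(length(call_hits(c(a = 100, b = 100), 125)), 0L)
  h140 <- call_hits(c(a = 150, b = 141, c = 139), 140)
  h120 <- call_hits(c(a = 150, b = 141, c = 139), 120)
  expect_true(all(h140 %in% h120))
  ## controls are excluded, with a warning when they exceed threshold
  expect_warning(
    h <- call_hits(c(a = 150, NTC = 160), 125, controls = "NTC"),
    "NTC")
  expect_identical(h, "a")
  ## dose-response input selects the stated dose
  tab <- data.frame(aso_id = rep(c("a", "b"), each = 2),
                    dose = c(20, 5, 20, 5),
                    response = c(150, 120, 130, 110))
  expect_identical(call_hits(tab, 140, at_dose = 20), "a")
  expect_error(call_hits(tab, 140, at_dose = 10), "dose level")
  expect_error(call_hits(tab, 140), "at_dose")
})

test_that("planted screen effects are all recovered at threshold 140", {
  set.seed(88)
  truth <- c(rep(160, 5), rep(100, 20))
  names(truth) <- c(sprintf("hit_%d", 1:5), sprintf("null_%d", 1:20))
  observed <- truth + rnorm(length(truth), 0, 5)
  hits <- call_hits(observed, 140)
  expect_true(all(sprintf("hit_%d", 1:5) %in% hits))
  expect_false(any(grepl("null", hits)))
})

test_that("noiseless 4PL curves are recovered exactly", {
  doses <- serial_dilution(20, 4, 5)
  for (mode in c("stimulation", "inhibition")) {
    tab <- simulate_dose_response(2, 1.5, doses, noise_sd = 0, seed = 1,
                                  mode = mode)
    fit <- fit_dose_response(tab)
    expect_true(fit$converged)
    expect_equal(fit$ec50_or_ic50, 2, tolerance = 1e-6)
    expect_equal(fit$hill, 1.5, tolerance = 1e-6)
    expect_false(fit$extrapolated)
    expect_equal(fit$r_squared, 1, tolerance = 1e-9)
    ## the curve crosses 50 on the normalized span at the absolute EC50
    expect_equal(
      predict_dose_response(fit, fit$ec50_or_ic50, normalized = TRUE),
      50, tolerance = 1e-6)
  }
})

test_that("EC50 scales exactly with a dose rescaling", {
  tab <- simulate_dose_response(2, 1.2, serial_dilution(20, 4, 5),
                                noise_sd = 8, seed = 6,
                                mode = "stimulation")
  f1 <- fit_dose_response(tab)
  tab_scaled <- tab
  tab_scaled$dose <- tab$dose * 1000
  f2 <- fit_dose_response(tab_scaled)
  expect_equal(f2$ec50_or_ic50 / f1$ec50_or_ic50, 1000,
               tolerance = 1e-6)
  expect_equal(f2$hill, f1$hill, tolerance = 1e-6)
})

test_that("noisy Monte-Carlo refits stay within 20% median error", {
  doses <- serial_dilution(20, 4, 5)
  errs <- vapply(1:60, function(i) {
    tab <- simulate_dose_response(2, 1, doses, noise_sd = 5,
                                  seed = 4000L + i, mode = "stimulation")
    fit <- fit_dose_response(tab)
    abs(fit$ec50_or_ic50 - 2) / 2
  }, numeric(1))
  expect_lt(stats::median(errs), 0.2)
})

test_that("degenerate dose tables are rejected or flagged", {
  tab <- data.frame(aso_id = "x", dose = c(1, 1), response = c(10, 20),
                    replicate = 1:2)
  expect_error(fit_dose_response(tab, mode = "stimulation"),
               "2 distinct doses")
  tab3 <- data.frame(aso_id = "x", dose = c(1, 4, 16),
                     response = c(110, 150, 190), replicate = 1L)
  expect_warning(fit_dose_response(tab3, mode = "stimulation"),
                 "fewer than 4")
  ## negative adjusted responses are retained, not clipped: a free-span
  ## fit places the bottom asymptote below zero
  tabn <- simulate_dose_response(2, 1.5, serial_dilution(20, 4, 5),
                                 noise_sd = 0, seed = 1,
                                 mode = "stimulation")
  tabn$response[tabn$dose == min(tabn$dose)] <- 95  # below mock
  fit <- fit_dose_response(tabn, span = "free")
  expect_true(fit$converged)
  expect_lt(fit$bottom, 0)
  ## the normalized-span fit still converges on the same data
  expect_true(fit_dose_response(tabn)$converged)
})
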