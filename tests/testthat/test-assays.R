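coupling_summary <- function(means) {
  data.frame(phase = c("baseline", "ADP", "oligomycin", "FCCP", "antimycin"),
             mean = means, sd = 0, n = 6, stringsAsFactors = FALSE)
}

eflow_summary <- function(means) {
  data.frame(phase = c("baseline", "rotenone", "succinate", "antimycinA",
                       "ascTMPD"),
             mean = means, sd = 0, n = 6, stringsAsFactors = FALSE)
}

test_that("segment_phases assigns samples to the latest injection", {
  sim <- simulate_ocr_trace(trace_sim_config(noise_sd = 0))
  ps <- segment_phases(sim$trace, sim$schedule)
  expect_equal(ps$phase, names(sim$truth$phase_means))
  expect_equal(ps$mean, unname(sim$truth$phase_means))
  expect_equal(ps$n, c(6L, rep(5L, 4))) # one post-injection cycle dropped
  ps0 <- segment_phases(sim$trace, sim$schedule, discard_first = 0)
  expect_equal(ps0$n, rep(6L, 5))
  # noiseless: discarding changes nothing but the counts
  expect_equal(ps$mean, ps0$mean)

  # a deviating post-injection cycle only shows when retained
  tr <- sim$trace
  first_adp <- which(tr$time_s >= sim$schedule$time_s[2])[1]
  tr$signal[first_adp] <- tr$signal[first_adp] + 30
  expect_equal(segment_phases(tr, sim$schedule)$mean, ps$mean)
  expect_false(isTRUE(all.equal(
    segment_phases(tr, sim$schedule, discard_first = 0)$mean, ps$mean)))

  # discarding every sample of a phase is an error
  expect_error(segment_phases(sim$trace, sim$schedule, discard_first = 6),
               "no retained samples")
  expect_error(segment_phases(sim$trace,
                              data.frame(label = "late", time_s = 1e6)),
               "beyond the end|postdate")
})

test_that("respiratory states subtract the antimycin residual", {
  st <- derive_resp_states(coupling_summary(c(50, 120, 40, 130, 10)))
  expect_equal(st$state_II, 40)
  expect_equal(st$state_III, 110)
  expect_equal(st$state_IVo, 30)
  expect_equal(st$state_IIIu, 120)
  expect_equal(st$rcr, 110 / 30)

  # residual above a phase mean floors at 0 with a warning
  expect_warning(st2 <- derive_resp_states(
    coupling_summary(c(50, 120, 40, 130, 45))), "floored")
  expect_equal(st2$state_IVo, 0)
  expect_true(is.na(st2$rcr))

  expect_error(derive_resp_states(coupling_summary(1:5)[-2, ]),
               "missing")
})

test_that("states and activities are invariant to trace offsets", {
  base <- c(50, 120, 40, 130, 10)
  st <- derive_resp_states(coupling_summary(base))
  st_shift <- derive_resp_states(coupling_summary(base + 17))
  for (f in c("state_II", "state_III", "state_IVo", "state_IIIu", "rcr")) {
    expect_equal(st[[f]], st_shift[[f]])
  }
  act <- derive_complex_activities(eflow_summary(c(100, 20, 90, 10, 150)))
  act_shift <- derive_complex_activities(
    eflow_summary(c(100, 20, 90, 10, 150) + 31))
  for (f in c("CxI", "CxII", "CxIII", "CxIV")) {
    expect_equal(act[[f]], act_shift[[f]])
  }
})

test_that("complex activities are the designated phase differences", {
  act <- derive_complex_activities(eflow_summary(c(100, 20, 90, 10, 150)))
  expect_equal(act$CxI, 80)
  expect_equal(act$CxII, 70)
  expect_equal(act$CxIII, 80)
  expect_equal(act$CxIV, 140)
  expect_false(any(act$flagged))

  # rotenone no-op -> CxI = 0
  act0 <- derive_complex_activities(eflow_summary(c(100, 100, 110, 10, 150)))
  expect_equal(act0$CxI, 0)

  # negative difference reported but flagged
  expect_warning(actn <- derive_complex_activities(
    eflow_summary(c(100, 20, 90, 95, 150))), "flagged")
  expect_equal(actn$CxIII, -5)
  expect_true(actn$flagged[["CxIII"]])
  expect_error(derive_complex_activities(eflow_summary(1:5)[-3, ]),
               "missing")
})

test_that("crc_retention handles flat, linear and exponential decays", {
  # constant after each pulse: no uptake
  t <- seq(0, 600, by = 5)
  flat <- data.frame(well = "A1", time_s = t,
                     signal = 10 + 10 * findInterval(t, c(120, 300)))
  expect_equal(crc_retention(flat, c(120, 300))$retention, 0)

  # linear decay from 10 to 0 over 60 s: triangle area 300
  t2 <- seq(0, 60, by = 1)
  lin <- data.frame(well = "A1", time_s = t2,
                    signal = pmax(10 - 10 * t2 / 60, 0))
  r_lin <- crc_retention(lin, 0)
  expect_equal(r_lin$retention, 300, tolerance = 1e-9)

  # exponential decay, long window: area above baseline -> A/k
  a <- 10
  k <- 0.05
  t3 <- seq(0, 600, by = 1)
  expo <- data.frame(well = "A1", time_s = t3,
                     signal = 2 + a * exp(-k * pmax(t3 - 30, 0)) *
                       (t3 >= 30))
  r_exp <- crc_retention(expo, 30, mode = "trace_auc")
  expect_equal(r_exp$retention, a / k, tolerance = 0.01)

  # baseline shift leaves retention unchanged; pulses are additive
  shifted <- lin
  shifted$signal <- shifted$signal + 100
  expect_equal(crc_retention(shifted, 0)$retention, r_lin$retention)

  expect_error(crc_retention(lin, 1e5), "outside the trace")
  expect_error(crc_retention(lin, numeric(0)), "at least one pulse")
})

test_that("crc_retention is additive over pulses", {
  sim <- simulate_crc_trace(crc_sim_config(rate = 0.05, seed = 6))
  all5 <- crc_retention(sim$trace, sim$pulse_times)
  expect_equal(all5$retention, sum(all5$per_pulse$area))
  expect_equal(nrow(all5$per_pulse), 5L)
})

test_that("h2o2_slope fits an OLS line in per-minute units", {
  tr <- data.frame(well = "A1", time_s = c(0, 60, 120), signal = c(0, 2, 4))
  fit <- h2o2_slope(tr)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)

  # nonlinear noiseless input: slope is the OLS value, R^2 reported
  t <- seq(0, 600, by = 30)
  quad <- data.frame(well = "A1", time_s = t, signal = (t / 60)^2)
  fitq <- h2o2_slope(quad)
  ols <- lm(signal ~ I(time_s / 60), data = quad)
  expect_equal(fitq$slope, unname(coef(ols)[2]))
  expect_lt(fitq$r_squared, 1)

  # noisy recovery within 3 SE
  sim <- simulate_h2o2_trace(slope = 5, noise_sd = 1, seed = 23)
  fitn <- h2o2_slope(sim$trace)
  expect_lt(abs(fitn$slope - 5), 3 * fitn$se)

  # window restriction
  fitw <- h2o2_slope(quad, window = c(0, 120))
  expect_equal(fitw$n, 5L)
  expect_error(h2o2_slope(quad, window = c(0, 10)), "at least 2")
})

test_that("ATP standard-curve inversion works on a ten-fold dilution", {
  std <- data.frame(conc = c(1, 0.1, 0.01), luminescence = c(1000, 100, 10))
  expect_equal(atp_from_standard_curve(std, 100), 0.1, tolerance = 1e-9)
  expect_equal(atp_from_standard_curve(std, 316.2), 0.3162,
               tolerance = 1e-3)
  expect_equal(atp_from_standard_curve(std, c(10, 1000)), c(0.01, 1),
               tolerance = 1e-9)
  expect_error(atp_from_standard_curve(std, 1e6), "extrapolation|range")
  expect_error(atp_from_standard_curve(std[1, , drop = FALSE], 100),
               "at least 2")
  expect_error(atp_from_standard_curve(
    data.frame(conc = c(1, -1), luminescence = c(10, 100)), 10),
    "positive")
})

test_that("er_aspect_ratio divides major by minor axis", {
  expect_equal(er_aspect_ratio(2, 1), 2)
  expect_equal(er_aspect_ratio(1, 1), 1)
  expect_equal(er_aspect_ratio(c(4, 6), c(2, 2)), c(2, 3))
  expect_error(er_aspect_ratio(1, 2), ">=")
  expect_error(er_aspect_ratio(1, 0), "> 0")
})

test_that("exact Mann-Whitney matches hand results and handles ties", {
  t1 <- mann_whitney_exact(c(1, 2, 3), c(4, 5, 6))
  expect_equal(t1$u, 0)
  expect_equal(t1$p, 0.1) # 2 of the 20 labelings are as extreme
  expect_true(t1$exact)

  same <- mann_whitney_exact(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p, 1)

  # exact and approximate agree for n = 10 vs 10 without ties
  set.seed(31)
  a <- rnorm(10)
  b <- rnorm(10, 1)
  ex <- mann_whitney_exact(a, b) # C(20,10) = 184756 labelings
  ap <- mann_whitney_exact(a, b, max_enumerate = 1)
  expect_true(ex$exact)
  expect_false(ap$exact)
  expect_lt(abs(ex$p - ap$p), 0.01)

  expect_error(mann_whitney_exact(numeric(0), 1:3), "non-empty")
})

test_that("exact Mann-Whitney matches the enumeration oracle up to n = 4", {
  set.seed(19)
  for (na in 2:4) {
    for (nb in 2:4) {
      a <- round(rnorm(na), 1) # rounding induces occasional ties
      b <- round(rnorm(nb), 1)
      got <- mann_whitney_exact(a, b)
      want <- oracle_mwu(a, b)
      expect_equal(got$u, want$u, label = sprintf("U na=%d nb=%d", na, nb))
      expect_equal(got$p, want$p, label = sprintf("p na=%d nb=%d", na, nb))
    }
  }
})

test_that("effect_size reports mean difference with quadrature SEM", {
  es <- effect_size(c(1, 2, 3), c(4, 5, 6))
  expect_equal(es$effect, 3.0)
  expect_equal(es$sem, sqrt(1 / 3 + 1 / 3), tolerance = 1e-12)
  es0 <- effect_size(c(2, 4, 6), c(2, 4, 6))
  expect_equal(es0$effect, 0)
  expect_gt(es0$sem, 0)
  expect_error(effect_size(1, c(1, 2)), ">= 2")
})
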