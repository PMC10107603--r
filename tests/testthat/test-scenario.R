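test_that("profile interpolation is exact at and between breakpoints", {
  p <- tk_profile(c(0, 1), c(10, 20), kind = "exposure")
  expect_equal(interpolate_profile(p, 0.5), 15)
  expect_equal(interpolate_profile(p, c(0, 1)), c(10, 20))
  expect_error(interpolate_profile(p, 1.5), "outside profile support")
  pe <- tk_profile(c(0, 1), c(10, 20), kind = "exposure", extrapolate = TRUE)
  expect_equal(interpolate_profile(pe, 2), 20)
  # previous-value hold
  ph <- tk_profile(c(0, 1, 2), c(5, 9, 1), kind = "exposure",
                   interp = "constant")
  expect_equal(interpolate_profile(ph, c(0.5, 1, 1.99)), c(5, 9, 9))
  expect_error(tk_profile(c(0, 0, 1), c(1, 2, 3), kind = "exposure"),
               "strictly increasing")
})

test_that("interpolated values stay within neighbouring breakpoints", {
  set.seed(3)
  for (i in 1:10) {
    tt <- sort(runif(8, 0, 5))
    vv <- cumsum(abs(rnorm(8)))
    p <- tk_profile(tt, vv, kind = "exposure")
    tq <- runif(40, min(tt), max(tt))
    got <- interpolate_profile(p, tq)
    idx <- findInterval(tq, tt)
    lo <- pmin(vv[idx], vv[pmin(idx + 1, 8)])
    hi <- pmax(vv[idx], vv[pmin(idx + 1, 8)])
    expect_true(all(got >= lo - 1e-9 & got <= hi + 1e-9))
  }
})

test_that("a single Heun step reproduces the hand-computed update", {
  # dC/dt = -C from C0 = 1, h = 0.1: 1 - h + h^2/2 = 0.905
  Tp <- tk_profile(c(0, 1), c(16, 16), kind = "temperature")
  Ep <- tk_profile(c(0, 1), c(0, 0), kind = "exposure")
  sp <- scenario_spec(c(0, -Inf), c(0, 0), Tp, Ep,
                      t_span = c(0, 0.1), step = 0.1, c0 = 1)
  expect_equal(simulate_scenario(sp)$conc[2], 0.905, tolerance = 1e-12)
})

test_that("constant conditions converge to the kinetic steady state", {
  arr_ku <- c(T_A = 8000, ln_A = log(10) + 8000 / 289.15)
  arr_ke <- c(T_A = 8000, ln_A = log(1) + 8000 / 289.15)
  Tp <- tk_profile(c(0, 30), c(16, 16), kind = "temperature")
  Ep <- tk_profile(c(0, 30), c(1, 1), kind = "exposure")
  sp <- scenario_spec(arr_ku, arr_ke, Tp, Ep, t_span = c(0, 30), step = 0.01)
  res <- simulate_scenario(sp)
  expect_equal(res$conc[length(res$conc)], 10, tolerance = 1e-4)
  expect_true(all(res$conc >= 0))
  expect_equal(nrow(res$trace), length(res$times))
})

test_that("simulation matches the closed form under constant temperature", {
  arr_ku <- c(T_A = 8000, ln_A = log(10) + 8000 / 289.15)
  arr_ke <- c(T_A = 8000, ln_A = log(1) + 8000 / 289.15)
  d <- exposure_design(1, 1, 4)
  p <- parent_params(10, 1)
  Tp <- tk_profile(c(0, 4), c(16, 16), kind = "temperature")
  # uptake phase (smooth): constant exposure
  Ep_up <- tk_profile(c(0, 4), c(1, 1), kind = "exposure")
  sp_up <- scenario_spec(arr_ku, arr_ke, Tp, Ep_up,
                         t_span = c(0, 1), step = 0.01)
  r_up <- simulate_scenario(sp_up)
  cf_up <- parent_conc(r_up$times, p, d)
  i <- r_up$times >= 0.1
  expect_lt(max(abs(r_up$conc[i] - cf_up[i]) / cf_up[i]), 1e-3)
  # elimination phase (smooth): zero exposure from the switch concentration
  Ep_el <- tk_profile(c(0, 4), c(0, 0), kind = "exposure")
  sp_el <- scenario_spec(arr_ku, arr_ke, Tp, Ep_el,
                         t_span = c(0, 3), step = 0.01, c0 = parent_conc(1, p, d))
  r_el <- simulate_scenario(sp_el)
  cf_el <- parent_conc(r_el$times + 1, p, d)
  expect_lt(max(abs(r_el$conc - cf_el) / cf_el), 1e-3)
})

test_that("the integrator is second order on smooth profiles", {
  arr_ku <- c(T_A = 8000, ln_A = log(10) + 8000 / 289.15)
  arr_ke <- c(T_A = 8000, ln_A = log(1) + 8000 / 289.15)
  Tp <- dtf_profile(289.15, 10, t_span = c(0, 2))
  Ep <- tk_profile(c(0, 2), c(1, 1), kind = "exposure")
  final_at <- function(h) {
    sp <- scenario_spec(arr_ku, arr_ke, Tp, Ep, t_span = c(0, 2), step = h)
    r <- simulate_scenario(sp)
    r$conc[length(r$conc)]
  }
  ref <- final_at(1 / 3840)
  e1 <- abs(final_at(1 / 240) - ref)
  e2 <- abs(final_at(1 / 480) - ref)
  expect_gt(e1 / e2, 3)   # ~4 for a second-order scheme
  expect_lt(e1 / e2, 5)
})

test_that("too-coarse steps and bad states are reported", {
  Tp <- tk_profile(c(0, 0.05, 4), c(16, 18, 16), kind = "temperature")
  Ep <- tk_profile(c(0, 4), c(1, 1), kind = "exposure")
  sp <- scenario_spec(c(8000, 30), c(8000, 2), Tp, Ep,
                      t_span = c(0, 1), step = 0.1)
  expect_warning(simulate_scenario(sp), "smallest temperature profile segment")
})

test_that("DTF profile has the requested mean, range and phase", {
  # zero range collapses to a constant profile
  p0 <- dtf_profile(289.15, 0, t_span = c(0, 2))
  expect_equal(unique(p0$value), 289.15)
  p <- dtf_profile(289.15, 10, t_span = c(0, 4))
  expect_equal(max(p$value), 294.15)
  expect_equal(min(p$value), 284.15)
  # time-average over one period equals the mean to < 0.01 K (quadrature)
  tq <- seq(0, 1, length.out = 20001)
  avg <- mean(interpolate_profile(p, tq))
  expect_lt(abs(avg - 289.15), 0.01)
  # phase selects the initial trend
  expect_gt(interpolate_profile(p, 0.05), 289.15)
  pc <- dtf_profile(289.15, 10, phase = "cooling-first", t_span = c(0, 4))
  expect_lt(interpolate_profile(pc, 0.05), 289.15)
})

test_that("identical scenarios compare as equal; zero exposure stays zero", {
  arr <- c(T_A = 8000, ln_A = 30)
  Tp <- tk_profile(c(0, 2), c(16, 16), kind = "temperature")
  Ep <- tk_profile(c(0, 2), c(1, 1), kind = "exposure")
  sp <- scenario_spec(arr, c(8000, 2), Tp, Ep, t_span = c(0, 2), step = 0.01)
  cmp <- compare_scenarios(list(sp, sp))
  expect_equal(unname(cmp$peak_ratio), matrix(1, 2, 2))
  expect_true(all(is.na(cmp$crossings$time)))
  E0 <- tk_profile(c(0, 2), c(0, 0), kind = "exposure")
  sp0 <- scenario_spec(arr, c(8000, 2), Tp, E0, t_span = c(0, 2), step = 0.01)
  expect_equal(max(simulate_scenario(sp0)$conc), 0)
  # mismatched spans refuse to compare
  sp2 <- scenario_spec(arr, c(8000, 2), Tp, Ep, t_span = c(0, 1), step = 0.01)
  expect_error(compare_scenarios(list(sp, sp2)), "share t_span")
})

test_that("warmer scenarios peak higher and cross below cooler ones", {
  arr_ku <- c(T_A = 8000, ln_A = log(10) + 8000 / 289.15)
  arr_ke <- c(T_A = 8000, ln_A = log(1) + 8000 / 289.15)
  Ep <- tk_profile(c(0, 0.2, 0.5, 1, 6), c(0, 5, 0.5, 0, 0), kind = "exposure")
  temps <- c(6.1, 11, 15.4, 21.2)
  specs <- lapply(temps, function(Tc)
    scenario_spec(arr_ku, arr_ke,
                  tk_profile(c(0, 6), rep(Tc, 2), kind = "temperature"),
                  Ep, t_span = c(0, 6), step = 0.002))
  cmp <- compare_scenarios(specs, labels = paste0("T", temps))
  expect_true(all(diff(cmp$summary$peak) > 0))
  crossing <- cmp$crossings$time[cmp$crossings$first == "T21.2" &
                                   cmp$crossings$second == "T6.1"]
  expect_true(is.finite(crossing))
  expect_gt(crossing, cmp$summary$t_peak[cmp$summary$label == "T21.2"])
})

test_that("daily fluctuation boosts pre-equilibrium uptake over constant mean", {
  arr_ku <- c(T_A = 8000, ln_A = log(10) + 8000 / 289.15)
  arr_ke <- c(T_A = 8000, ln_A = log(1) + 8000 / 289.15)
  Ep <- tk_profile(c(0, 4), c(1, 1), kind = "exposure")
  Tc <- tk_profile(c(0, 4), c(289.15, 289.15), kind = "temperature", unit = "K")
  r_const <- simulate_scenario(scenario_spec(arr_ku, arr_ke, Tc, Ep,
                                             t_span = c(0, 4), step = 0.002))
  for (ph in c("warming-first", "cooling-first")) {
    dtf <- dtf_profile(289.15, 10, phase = ph, t_span = c(0, 4))
    r_dtf <- simulate_scenario(scenario_spec(arr_ku, arr_ke, dtf, Ep,
                                             t_span = c(0, 4), step = 0.002))
    i1 <- which.min(abs(r_dtf$times - 1))
    expect_gt(r_dtf$conc[i1], r_const$conc[i1])
  }
})
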