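test_that("noise-free parent data are recovered essentially exactly", {
  out <- generate_experiment(truth_config(cv = 0, cv_medium = 0, seed = 1))
  for (i in c(1, 4)) {
    fit <- fit_parent(out$datasets[[i]], ci = FALSE)
    tru <- out$truth[i, ]
    expect_lt(abs(coef(fit)[["k_u"]] - tru$k_u) / tru$k_u, 1e-4)
    expect_lt(abs(coef(fit)[["k_e"]] - tru$k_e) / tru$k_e, 1e-4)
    expect_true(fit$converged)
  }
})

test_that("all-zero tissue data give a zero uptake estimate", {
  ds <- make_parent_dataset(std_times(), rep(0, 16))
  fit <- fit_parent(ds, ci = FALSE)
  expect_equal(coef(fit)[["k_u"]], 0)
})

test_that("the objective ignores observation order and weight scaling", {
  out <- generate_experiment(truth_config(seed = 5))
  ds <- out$datasets[[2]]
  f1 <- fit_parent(ds, ci = FALSE)
  # shuffle rows
  ds2 <- ds
  set.seed(1)
  ds2$observations <- ds2$observations[sample(nrow(ds2$observations)), ]
  f2 <- fit_parent(ds2, ci = FALSE)
  expect_equal(coef(f2), coef(f1), tolerance = 1e-6)
  # multiply all animal counts by a constant
  ds3 <- ds
  ds3$observations$n_animals <- ds3$observations$n_animals * 5
  f3 <- fit_parent(ds3, ci = FALSE)
  expect_equal(coef(f3), coef(f1), tolerance = 1e-6)
  expect_equal(f3$weighted_ssq, 5 * f1$weighted_ssq, tolerance = 1e-6)
})

test_that("insufficient phase coverage is refused with a diagnostic", {
  # only one elimination time point
  ds <- make_parent_dataset(c(0.25, 0.5, 1, 2), c(1, 2, 3, 1))
  expect_error(fit_parent(ds), "insufficient data")
})

test_that("noise-free cascade data recover all six rates", {
  tc <- truth_config(cv = 0, cv_medium = 0, seed = 2, conc_unit = "umol/L")
  out <- generate_btp_cascade(tc, preset = "minor")
  fit <- fit_biotrans(out$datasets[[3]], ci = FALSE)
  tru <- unlist(out$truth[["T15.4"]])
  est <- coef(fit)[names(tru)]
  expect_lt(max(abs(est - tru) / tru), 1e-3)
})

test_that("biotrans fit is consistent with the parent fit when k_m_1st = 0", {
  # data generated without biotransformation, but btp observations present
  # (all zero); the cascade fit must find k_m_1st ~ 0 and reproduce the
  # parent-model elimination rate
  d <- exposure_design(1, 1, 4)
  p_true <- parent_params(20, 1.5)
  tt <- std_times()
  conc <- parent_conc(tt, p_true, d)
  obs <- rbind(
    data.frame(time_day = tt, state = "parent", concentration = conc,
               replicate_id = "a", n_animals = 4, below_loq = FALSE,
               loq = NA_real_),
    data.frame(time_day = tt, state = "btp1", concentration = 0,
               replicate_id = "a", n_animals = 4, below_loq = FALSE,
               loq = NA_real_))
  ds <- tk_dataset("sp", "cmp", 15.4, d, obs)
  bf <- fit_biotrans(ds, ci = FALSE)
  pf <- fit_parent(ds, ci = FALSE)
  expect_lt(coef(bf)[["k_m_1st"]], 1e-4)
  expect_equal(coef(bf)[["k_u"]], coef(pf)[["k_u"]], tolerance = 1e-3)
  expect_equal(coef(bf)[["k_e_p"]] + coef(bf)[["k_m_1st"]],
               coef(pf)[["k_e"]], tolerance = 1e-3)
  # profile CI for k_m_1st reaches zero
  pr <- profile_ci(bf, param = "k_m_1st")
  expect_equal(pr$lo, 0)
})

test_that("biotransformation share is recovered under noise", {
  hits <- 0L
  n_rep <- 8L
  for (s in seq_len(n_rep)) {
    tc <- truth_config(seed = 400 + s, conc_unit = "umol/L")
    out <- generate_btp_cascade(tc, preset = "minor")
    fit <- fit_biotrans(out$datasets[[3]], ci = FALSE, n_starts = 2)
    est <- coef(fit)
    share <- est[["k_m_1st"]] / (est[["k_e_p"]] + est[["k_m_1st"]])
    if (abs(share - out$share) <= 0.1) hits <- hits + 1L
  }
  expect_gte(hits, n_rep - 1L)
})

test_that("profile interval matches the quadratic-objective oracle", {
  # large-n additive-noise dataset: the SSQ surface is near-quadratic, so
  # the chi-square profile bound must agree with the Wald interval computed
  # from the numerical Hessian at the optimum
  d <- exposure_design(1, 1, 4)
  p_true <- parent_params(20, 1.5)
  tt <- rep(c(0.125, 0.25, 0.5, 1, 1.25, 1.75, 2.5, 4), each = 60)
  mu <- parent_conc(tt, p_true, d)
  set.seed(11)
  conc <- pmax(mu + rnorm(length(mu), 0, 0.05 * mean(mu)), 0)
  ds <- make_parent_dataset(tt, conc, n_animals = 1)
  fit <- fit_parent(ds, ci = FALSE)
  pr <- profile_ci(fit, param = "k_u")
  # Wald oracle on the natural scale
  est <- coef(fit)
  obj <- function(k) {
    pred <- parent_conc(tt, parent_params(k[1], k[2]), d)
    sum((conc - pred)^2)
  }
  h <- est * 1e-4
  H <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2) {
    ei <- ej <- c(0, 0); ei[i] <- h[i]; ej[j] <- h[j]
    H[i, j] <- (obj(est + ei + ej) - obj(est + ei - ej) -
                  obj(est - ei + ej) + obj(est - ei - ej)) / (4 * h[i] * h[j])
  }
  sigma2 <- fit$weighted_ssq / fit$n_obs
  se_ku <- sqrt(2 * sigma2 * solve(H)[1, 1])
  expect_equal(pr$hi - pr$lo, 2 * 1.96 * se_ku, tolerance = 0.01)
  expect_equal((pr$hi + pr$lo) / 2, est[["k_u"]], tolerance = 0.005)
})

test_that("profile interval width shrinks to zero on noise-free data", {
  out <- generate_experiment(truth_config(cv = 0, cv_medium = 0, seed = 9))
  fit <- fit_parent(out$datasets[[2]], ci = FALSE)
  pr <- profile_ci(fit, param = "k_e")
  expect_lt((pr$hi - pr$lo) / coef(fit)[["k_e"]], 1e-3)
})

test_that("excretion dominated by biotransformation profiles to zero", {
  tc <- truth_config(seed = 21, conc_unit = "umol/L")
  out <- generate_btp_cascade(tc, preset = "dominant")
  fit <- fit_biotrans(out$datasets[[3]], ci = FALSE, n_starts = 3)
  pr <- profile_ci(fit, param = "k_e_p")
  expect_equal(pr$lo, 0)
  expect_equal(pr$lo_flag, "at_zero")
})

test_that("goodness of fit matches an independent R2 computation", {
  out <- generate_experiment(truth_config(seed = 13))
  ds <- out$datasets[[1]]
  fit <- fit_parent(ds, ci = FALSE)
  r2 <- goodness_of_fit(fit)
  # direct recomputation from the raw observations
  obs <- ds$observations[ds$observations$state == "parent", ]
  obs <- obs[!obs$below_loq, ]
  med <- ds$observations[ds$observations$state == "medium" &
                           ds$observations$time_day <= 1 + 1e-9, ]
  dd <- ds$design
  dd$c_water <- mean(med$concentration)
  pred <- parent_conc(obs$time_day, fit$params, dd)
  w <- obs$n_animals
  sres <- sum(w * (obs$concentration - pred)^2)
  mbar <- sum(w * obs$concentration) / sum(w)
  stot <- sum(w * (obs$concentration - mbar)^2)
  expect_equal(unname(r2[["parent"]]), 1 - sres / stot, tolerance = 1e-9)
  # a perfect fit has R2 = 1
  out0 <- generate_experiment(truth_config(cv = 0, cv_medium = 0, seed = 1))
  f0 <- fit_parent(out0$datasets[[1]], ci = FALSE)
  expect_equal(unname(goodness_of_fit(f0)[["parent"]]), 1, tolerance = 1e-9)
})

test_that("model selection applies the AIC window and R2 tie-break", {
  out <- generate_experiment(truth_config(seed = 17))
  fit <- fit_parent(out$datasets[[2]], ci = FALSE)
  # single candidate is returned unchanged
  sel <- select_model(fit)
  expect_identical(sel$estimates, fit$estimates)
  # clear AIC difference: lower AIC wins regardless of R2
  f_good <- fit
  f_bad <- fit
  f_bad$aic <- fit$aic + 5
  f_bad$r2 <- c(parent = 0.999)
  sel <- select_model(list(f_good, f_bad))
  expect_equal(sel$aic, f_good$aic)
  # within the 2-unit window the higher parent+btp1 R2 wins
  f1 <- fit; f1$aic <- 100; f1$r2 <- c(parent = 0.90, btp1 = 0.80)
  f2 <- fit; f2$aic <- 101; f2$r2 <- c(parent = 0.95, btp1 = 0.85)
  sel <- select_model(list(f1, f2))
  expect_equal(sel$r2[["parent"]], 0.95)
  trace <- attr(sel, "selection")
  expect_true(is.data.frame(trace) && sum(trace$selected) == 1)
  # the secondary-product R2 does not enter the tie-break
  f3 <- fit; f3$aic <- 100; f3$r2 <- c(parent = 0.95, btp1 = 0.85, btp2 = 0.1)
  f4 <- fit; f4$aic <- 100; f4$r2 <- c(parent = 0.90, btp1 = 0.80, btp2 = 0.99)
  sel <- select_model(list(f3, f4))
  expect_equal(sel$r2[["parent"]], 0.95)
  expect_error(select_model(list()), "no candidate")
})

test_that("below-LOQ observations follow the chosen policy", {
  tc <- truth_config(seed = 31, loq = 300)
  out <- generate_experiment(tc)
  ds <- out$datasets[[1]]  # coldest: lowest concentrations, most censoring
  expect_gt(sum(ds$observations$below_loq), 0)
  f_drop <- fit_parent(ds, loq_policy = "drop", ci = FALSE)
  expect_equal(f_drop$n_loq_dropped, sum(ds$observations$below_loq))
  f_half <- fit_parent(ds, loq_policy = "half", ci = FALSE)
  expect_gt(f_half$n_obs, f_drop$n_obs)
})

test_that("fit_report flattens estimates, CIs and derived quantities", {
  out <- generate_experiment(truth_config(seed = 3))
  fit <- fit_parent(out$datasets[[2]], ci = TRUE)
  rep <- fit_report(fit)
  expect_true(all(c("k_u", "k_e", "k_u_lo", "k_u_hi", "bcf_kin",
                    "half_life_day", "t_ss95_day", "aic", "r2_parent")
                  %in% names(rep)))
  expect_equal(rep$bcf_kin, coef(fit)[["k_u"]] / coef(fit)[["k_e"]])
  expect_true(rep$k_u_lo <= rep$k_u & rep$k_u <= rep$k_u_hi)
})
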