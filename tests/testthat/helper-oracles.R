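# Independent numerical oracles and dataset builders shared across tests.

# Adaptive-step ODE oracle for the parent model (independent of the
# package's closed form).
ode_oracle_parent <- function(t, k_u, k_e, c_water, t_dep) {
  # integrate the two phases separately so the solver never steps across
  # the exposure discontinuity
  solve_leg <- function(times, y0, cw) {
    rhs <- function(tt, y, p) list(cw * k_u - y * k_e)
    deSolve::lsoda(y0, times, rhs, NULL, rtol = 1e-11, atol = 1e-13)
  }
  tt_up <- sort(unique(c(0, t[t <= t_dep], t_dep)))
  up <- solve_leg(tt_up, 0, c_water)
  out <- numeric(length(t))
  out[t <= t_dep] <- up[match(t[t <= t_dep], tt_up), 2]
  if (any(t > t_dep)) {
    tt_el <- sort(unique(c(t_dep, t[t > t_dep])))
    el <- solve_leg(tt_el, up[nrow(up), 2], 0)
    out[t > t_dep] <- el[match(t[t > t_dep], tt_el), 2]
  }
  out
}

# Adaptive-step ODE oracle for the three-state cascade.
ode_oracle_cascade <- function(t, p, c_water, t_dep) {
  lam <- c(p$k_e_p + p$k_m_1st, p$k_e_1st + p$k_m_2nd, p$k_e_2nd)
  solve_leg <- function(times, y0, cw) {
    rhs <- function(tt, y, parms)
      list(c(cw * p$k_u - y[1] * lam[1],
             y[1] * p$k_m_1st - y[2] * lam[2],
             y[2] * p$k_m_2nd - y[3] * lam[3]))
    deSolve::lsoda(y0, times, rhs, NULL, rtol = 1e-11, atol = 1e-13)
  }
  m <- matrix(0, length(t), 3, dimnames = list(NULL, c("parent", "btp1", "btp2")))
  tt_up <- sort(unique(c(0, t[t <= t_dep], t_dep)))
  up <- solve_leg(tt_up, c(0, 0, 0), c_water)
  m[t <= t_dep, ] <- up[match(t[t <= t_dep], tt_up), -1]
  if (any(t > t_dep)) {
    tt_el <- sort(unique(c(t_dep, t[t > t_dep])))
    el <- solve_leg(tt_el, up[nrow(up), -1], 0)
    m[t > t_dep, ] <- el[match(t[t > t_dep], tt_el), -1]
  }
  m
}

# Build a parent-model dataset from explicit tissue concentrations.
make_parent_dataset <- function(times, conc, n_animals = 4, c_water = 1,
                                t_dep = 1, t_end = 4, temperature_C = 15.4,
                                below_loq = FALSE, loq = NA_real_) {
  obs <- data.frame(time_day = times, state = "parent", concentration = conc,
                    replicate_id = "r1", n_animals = n_animals,
                    below_loq = below_loq, loq = loq,
                    stringsAsFactors = FALSE)
  tk_dataset("test sp", "test cmp", temperature_C,
             exposure_design(c_water, t_dep, t_end), obs)
}

# Noise-free design times used in several fitting tests (duplicates at the
# standard 1 d uptake + 3 d elimination schedule).
std_times <- function() rep(c(0.125, 0.25, 0.5, 1, 1.25, 1.75, 2.5, 4), 2)
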