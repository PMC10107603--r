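# One-compartment toxicokinetic models: parent compound and the first-order
# biotransformation cascade (parent -> total primary BTPs -> total secondary
# BTPs), closed-form solutions and derived quantities.

#' Exposure design of an uptake--elimination experiment
#'
#' Describes the water-exposure regime of a standard bioconcentration test:
#' a constant (averaged) medium concentration during the uptake phase,
#' followed by clean medium during elimination. The medium concentration is
#' identically zero after `t_depuration_start`.
#'
#' @param c_water Average medium concentration during the uptake phase
#'   (amount per litre; the unit tag is carried through unchanged).
#' @param t_depuration_start Time at which uptake ends and elimination
#'   begins (day).
#' @param t_end End of the experiment (day).
#' @param unit Concentration unit tag, e.g. `"umol/L"` or `"ug/L"`.
#' @return An object of class `exposure_design`.
#' @examples
#' exposure_design(c_water = 50, t_depuration_start = 1, t_end = 4, unit = "ug/L")
#' @export
exposure_design <- function(c_water, t_depuration_start = 1, t_end = 4,
                            unit = "umol/L") {
  stopifnot(is.numeric(c_water), length(c_water) == 1L)
  if (!is.finite(c_water) || c_water < 0)
    stop("'c_water' must be a finite non-negative concentration")
  if (!is.finite(t_depuration_start) || t_depuration_start <= 0)
    stop("'t_depuration_start' must be > 0")
  if (t_end < t_depuration_start)
    stop("'t_end' must be >= 't_depuration_start'")
  structure(list(c_water = c_water,
                 t_depuration_start = t_depuration_start,
                 t_end = t_end, unit = unit),
            class = "exposure_design")
}

#' Parent-model rate constants
#'
#' Rate constants of the one-compartment parent model
#' \eqn{dC/dt = C_w(t) k_u - C k_e}: uptake across dermal and respiratory
#' surfaces, and total elimination (excretion plus biotransformation lumped).
#'
#' @param k_u Uptake rate constant (L/kg wet weight/day).
#' @param k_e Total elimination rate constant (1/day).
#' @return An object of class `parent_params`.
#' @examples
#' parent_params(k_u = 20, k_e = 2)
#' @export
parent_params <- function(k_u, k_e) {
  check_rates(c(k_u = k_u, k_e = k_e))
  structure(list(k_u = k_u, k_e = k_e), class = "parent_params")
}

#' Biotransformation-model rate constants
#'
#' Rate constants of the three-state cascade in which the parent compound is
#' excreted (`k_e_p`) or biotransformed into total primary biotransformation
#' products (`k_m_1st`), which in turn are eliminated (`k_e_1st`) or further
#' transformed into total secondary products (`k_m_2nd`), themselves
#' eliminated at `k_e_2nd`. Concentrations are molar so that one parent
#' molecule yields one product molecule.
#'
#' @param k_u Uptake rate constant of the parent (L/kg wet weight/day).
#' @param k_e_p Parent excretion rate (1/day).
#' @param k_m_1st Primary biotransformation rate (1/day).
#' @param k_e_1st Elimination rate of primary products (1/day).
#' @param k_m_2nd Secondary biotransformation rate (1/day).
#' @param k_e_2nd Elimination rate of secondary products (1/day).
#' @return An object of class `biotrans_params`.
#' @examples
#' biotrans_params(k_u = 10, k_e_p = 0.5, k_m_1st = 0.5,
#'                 k_e_1st = 0.3, k_m_2nd = 0.2, k_e_2nd = 0.4)
#' @export
biotrans_params <- function(k_u, k_e_p, k_m_1st, k_e_1st = 0,
                            k_m_2nd = 0, k_e_2nd = 0) {
  check_rates(c(k_u = k_u, k_e_p = k_e_p, k_m_1st = k_m_1st,
                k_e_1st = k_e_1st, k_m_2nd = k_m_2nd, k_e_2nd = k_e_2nd))
  structure(list(k_u = k_u, k_e_p = k_e_p, k_m_1st = k_m_1st,
                 k_e_1st = k_e_1st, k_m_2nd = k_m_2nd, k_e_2nd = k_e_2nd),
            class = "biotrans_params")
}

check_rates <- function(x) {
  bad <- !is.finite(x) | x < 0
  if (any(bad))
    stop("rate constants must be finite and non-negative; offending: ",
         paste(names(x)[bad], collapse = ", "))
  invisible(x)
}

# rate below which the k -> 0 linear-uptake limit replaces 1/k expressions
.K_ZERO_TOL <- 1e-12
# relative eigenvalue separation below which the closed form is abandoned
.EIG_DEGENERATE_RTOL <- 1e-8

#' Parent tissue concentration, closed form
#'
#' Piecewise closed-form solution of the one-compartment parent model under
#' the standard exposure design: constant water concentration `c_water`
#' until `t_depuration_start`, zero afterwards, clean animals at time zero.
#' During uptake \eqn{C(t) = C_w (k_u/k_e)(1 - e^{-k_e t})} (linear limit
#' \eqn{C_w k_u t} as \eqn{k_e \to 0}); during elimination the value at the
#' phase switch decays as \eqn{e^{-k_e (t - t_{dep})}}.
#'
#' @param t Time(s) since exposure start (day); vectorised.
#' @param params A [parent_params()] object.
#' @param design An [exposure_design()] object.
#' @return Numeric vector of tissue concentrations (same unit family as
#'   `design$c_water` times L/kg).
#' @examples
#' d <- exposure_design(c_water = 1, t_depuration_start = 1, t_end = 4)
#' parent_conc(c(0.5, 1, 2), parent_params(10, 1), d)
#' @export
parent_conc <- function(t, params, design) {
  stopifnot(inherits(params, "parent_params"), inherits(design, "exposure_design"))
  if (any(!is.finite(t)) || any(t < 0)) stop("'t' must be finite and >= 0")
  ku <- params$k_u; ke <- params$k_e
  td <- design$t_depuration_start; cw <- design$c_water
  up <- pmin(t, td)
  c_up <- if (ke < .K_ZERO_TOL) cw * ku * up
          else cw * ku / ke * (1 - exp(-ke * up))
  ifelse(t <= td, c_up, c_up * exp(-ke * (t - td)))
}

# Rate matrix of the cascade; states (parent, btp1, btp2)
cascade_matrix <- function(p) {
  lam_p <- p$k_e_p + p$k_m_1st
  lam_1 <- p$k_e_1st + p$k_m_2nd
  lam_2 <- p$k_e_2nd
  matrix(c(-lam_p, 0, 0,
           p$k_m_1st, -lam_1, 0,
           0, p$k_m_2nd, -lam_2),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("parent", "btp1", "btp2"), NULL))
}

# TRUE when the loss rates are pairwise distinct and all positive, i.e. the
# eigen closed form is well conditioned.
cascade_closed_form_ok <- function(A) {
  lam <- -diag(A)
  if (any(lam < .K_ZERO_TOL)) return(FALSE)
  d <- abs(outer(lam, lam, "-"))
  scale <- pmax(outer(lam, lam, pmax), .K_ZERO_TOL)
  all((d / scale)[upper.tri(d)] > .EIG_DEGENERATE_RTOL)
}

# x(t) for the triangular chain x' = A x + b (constant b), x(0) = x0.
# Analytic sum-of-exponentials (Bateman) solution: the eigenvalues are the
# negated loss rates on the diagonal and the eigenvectors have closed
# forms, so no numerical decomposition is needed. Requires pairwise
# distinct positive loss rates (checked by the caller).
lin_ode_closed <- function(t, A, b, x0) {
  lam <- -diag(A)
  k <- length(lam)
  V <- diag(k)
  if (k >= 2) V[2, 1] <- A[2, 1] / (lam[2] - lam[1])
  if (k >= 3) {
    V[3, 1] <- A[2, 1] * A[3, 2] / ((lam[2] - lam[1]) * (lam[3] - lam[1]))
    V[3, 2] <- A[3, 2] / (lam[3] - lam[2])
  }
  xss <- numeric(k)
  xss[1] <- b[1] / lam[1]
  for (i in seq_len(k)[-1]) xss[i] <- (A[i, i - 1L] * xss[i - 1L] + b[i]) / lam[i]
  r <- x0 - xss
  c0 <- numeric(k)
  c0[1] <- r[1]
  for (i in seq_len(k)[-1])
    c0[i] <- r[i] - sum(c0[seq_len(i - 1L)] * V[i, seq_len(i - 1L)])
  E <- exp(-outer(t, lam))
  matrix(xss, length(t), k, byrow = TRUE) +
    (E * matrix(c0, length(t), k, byrow = TRUE)) %*% t(V)
}

# numerical fallback used when loss rates are degenerate or ~0
cascade_numeric <- function(t, A, ku_cw, td) {
  rhs <- function(tt, y, parms) {
    inp <- if (tt <= td) c(ku_cw, 0, 0) else c(0, 0, 0)
    list(as.vector(A %*% y) + inp)
  }
  tt <- sort(unique(c(0, td, t)))
  sol <- deSolve::lsoda(c(0, 0, 0), tt, rhs, NULL,
                        rtol = 1e-10, atol = 1e-12)
  m <- sol[match(t, tt), -1, drop = FALSE]
  colnames(m) <- rownames(A)
  m
}

#' Cascade tissue concentrations, closed form
#'
#' Solves the three-state linear biotransformation chain under the standard
#' exposure design. When the three loss rates (parent: `k_e_p + k_m_1st`;
#' primary products: `k_e_1st + k_m_2nd`; secondary products: `k_e_2nd`) are
#' pairwise distinct and positive, the solution is the analytic
#' sum-of-exponentials form (evaluated through the eigen decomposition of
#' the rate matrix); otherwise the degenerate system is integrated
#' numerically with a stiff solver, since the closed form loses precision
#' as eigenvalues coalesce.
#'
#' @param t Time(s) since exposure start (day); vectorised.
#' @param params A [biotrans_params()] object.
#' @param design An [exposure_design()] object; molar water concentration
#'   assumed so that product stoichiometry holds.
#' @return A matrix with one row per time and columns
#'   `parent`, `btp1`, `btp2`.
#' @examples
#' d <- exposure_design(c_water = 1, t_depuration_start = 1, t_end = 4)
#' p <- biotrans_params(10, 0.5, 0.5, 0.3, 0.2, 0.4)
#' cascade_conc(c(0.5, 1, 2), p, d)
#' @export
cascade_conc <- function(t, params, design) {
  stopifnot(inherits(params, "biotrans_params"),
            inherits(design, "exposure_design"))
  if (any(!is.finite(t)) || any(t < 0)) stop("'t' must be finite and >= 0")
  A <- cascade_matrix(params)
  td <- design$t_depuration_start
  ku_cw <- params$k_u * design$c_water
  out <- matrix(0, length(t), 3, dimnames = list(NULL, rownames(A)))

  # states that never receive mass stay identically zero; solving only the
  # live head of the chain keeps the closed form available (and fast) for
  # the common reduced models
  n_active <- if (params$k_m_1st < .K_ZERO_TOL) 1L
              else if (params$k_m_2nd < .K_ZERO_TOL) 2L else 3L
  if (n_active == 1L) {
    pp <- parent_params(params$k_u, params$k_e_p + params$k_m_1st)
    out[, "parent"] <- parent_conc(t, pp, design)
    return(out)
  }
  Asub <- A[seq_len(n_active), seq_len(n_active), drop = FALSE]
  if (!cascade_closed_form_ok(Asub))
    return(cascade_numeric(t, A, ku_cw, td))
  b <- c(ku_cw, rep(0, n_active - 1L))
  x0 <- rep(0, n_active)
  sub <- matrix(0, length(t), n_active)
  in_up <- t <= td
  if (any(in_up))
    sub[in_up, ] <- lin_ode_closed(t[in_up], Asub, b, x0)
  if (any(!in_up)) {
    x_td <- drop(lin_ode_closed(td, Asub, b, x0))
    sub[!in_up, ] <- lin_ode_closed(t[!in_up] - td, Asub, b * 0, x_td)
  }
  out[, seq_len(n_active)] <- sub
  pmax(out, 0)
}

#' Kinetic bioconcentration factor
#'
#' Ratio of the uptake rate constant to the total elimination rate constant:
#' `k_u / k_e` for the parent model, `k_u / (k_e_p + k_m_1st)` for the
#' biotransformation model. This is the steady-state tissue/water partition
#' the kinetics imply, whether or not the experiment reached steady state.
#'
#' @param params A [parent_params()] or [biotrans_params()] object.
#' @return BCF in L/kg wet weight, or `NA` with attribute
#'   `reason = "elimination rate ~ 0; BCF_kin not computable"` when the
#'   total elimination rate is (numerically) zero.
#' @examples
#' bcf_kin(parent_params(10, 2))  # 5
#' bcf_kin(biotrans_params(10, 1, 1))  # 5
#' @export
bcf_kin <- function(params) {
  ke_tot <- if (inherits(params, "parent_params")) params$k_e
            else if (inherits(params, "biotrans_params"))
              params$k_e_p + params$k_m_1st
            else stop("'params' must be parent_params or biotrans_params")
  if (ke_tot < .K_ZERO_TOL)
    return(structure(NA_real_,
                     reason = "elimination rate ~ 0; BCF_kin not computable"))
  params$k_u / ke_tot
}

#' Apparent bioconcentration factor after 24 h of exposure
#'
#' Ratio of the mean measured parent tissue concentration at the end of a
#' 24-h uptake phase to the average water concentration. Unlike
#' [bcf_kin()] this is a direct measurement ratio and underestimates the
#' equilibrium partition for slow compounds that have not reached steady
#' state within a day.
#'
#' @param tissue_conc_24h Mean parent tissue concentration at t = 24 h
#'   (amount/kg wet weight).
#' @param c_water_avg Average water concentration during uptake (amount/L),
#'   must be positive; the two arguments must share the amount unit.
#' @return BCF in L/kg wet weight.
#' @examples
#' bcf_24h(50, 10)  # 5
#' @export
bcf_24h <- function(tissue_conc_24h, c_water_avg) {
  if (!is.finite(c_water_avg) || c_water_avg <= 0)
    stop("'c_water_avg' must be a positive water concentration")
  if (any(!is.finite(tissue_conc_24h)) || any(tissue_conc_24h < 0))
    stop("'tissue_conc_24h' must be finite and >= 0")
  tissue_conc_24h / c_water_avg
}

#' Elimination half-life and time to 95 % of steady state
#'
#' First-order summary times: `half_life()` returns \eqn{\ln 2 / k}, the
#' time for the internal concentration to halve once exposure stops;
#' `time_to_ss95()` returns \eqn{\ln 20 / k}, the time for
#' \eqn{1 - e^{-kt}} to reach 0.95, i.e. for the tissue to come within 5 %
#' of its steady-state concentration under constant exposure.
#'
#' @param k_total Total first-order elimination rate constant (1/day),
#'   vectorised.
#' @return Time in days; `Inf` with attribute
#'   `reason = "no steady state reachable (k <= 0)"` where `k_total <= 0`.
#' @examples
#' half_life(log(2))   # 1 day
#' time_to_ss95(1)     # log(20) ~ 3 days
#' @export
half_life <- function(k_total) first_order_time(k_total, log(2))

#' @rdname half_life
#' @export
time_to_ss95 <- function(k_total) first_order_time(k_total, log(20))

first_order_time <- function(k, num) {
  out <- ifelse(k > 0, num / k, Inf)
  if (any(k <= 0))
    attr(out, "reason") <- "no steady state reachable (k <= 0)"
  out
}

#' Export a solved trajectory as a tidy table
#'
#' Evaluates a parent or cascade model on a time grid and returns a long
#' data frame suitable for CSV export or plotting.
#'
#' @param params A [parent_params()] or [biotrans_params()] object.
#' @param design An [exposure_design()] object.
#' @param times Evaluation times (day); defaults to 200 points over the
#'   experiment.
#' @return A data frame with columns `time_day`, `state`, `concentration`,
#'   `unit`.
#' @export
tk_trajectory <- function(params, design,
                          times = seq(0, design$t_end, length.out = 200)) {
  unit_out <- paste0(sub("/L$", "", design$unit), "/kg")
  if (inherits(params, "parent_params")) {
    data.frame(time_day = times, state = "parent",
               concentration = parent_conc(times, params, design),
               unit = unit_out, stringsAsFactors = FALSE)
  } else {
    m <- cascade_conc(times, params, design)
    data.frame(time_day = rep(times, 3L),
               state = rep(colnames(m), each = length(times)),
               concentration = as.vector(m),
               unit = unit_out, stringsAsFactors = FALSE)
  }
}
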