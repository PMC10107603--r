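# Simultaneous weighted least-squares estimation of toxicokinetic rate
# constants, profile-likelihood confidence intervals, AIC and the
# model-selection tie-break on R2 of parent + primary products.

#' Toxicokinetic dataset for one compound x species x temperature experiment
#'
#' Bundles the observations of a single uptake--elimination experiment with
#' its exposure design. Observations live in a long data frame with one row
#' per measured sample.
#'
#' @param species Species label, e.g. `"G. pulex"`.
#' @param compound Compound label.
#' @param temperature_C Experiment water temperature in degrees Celsius
#'   (stored alongside its Kelvin equivalent).
#' @param design An [exposure_design()] object.
#' @param observations Data frame with columns `time_day`, `state` (one of
#'   `"parent"`, `"btp1"`, `"btp2"`, `"medium"`), `concentration`,
#'   `replicate_id`, `n_animals` (>= 1 for tissue rows), `below_loq`
#'   (logical) and `loq` (the quantification limit where `below_loq` is
#'   set, else `NA`).
#' @return An object of class `tk_dataset`.
#' @export
tk_dataset <- function(species, compound, temperature_C, design, observations) {
  stopifnot(inherits(design, "exposure_design"), is.data.frame(observations))
  need <- c("time_day", "state", "concentration", "replicate_id",
            "n_animals", "below_loq", "loq")
  miss <- setdiff(need, names(observations))
  if (length(miss))
    stop("observations lack required columns: ", paste(miss, collapse = ", "))
  obs <- observations
  if (any(!obs$state %in% c("parent", "btp1", "btp2", "medium")))
    stop("unknown state label in observations")
  if (any(obs$time_day < 0) || any(obs$time_day > design$t_end + 1e-9))
    stop("observation times must lie in [0, design$t_end]")
  bad_conc <- !obs$below_loq & (!is.finite(obs$concentration) | obs$concentration < 0)
  if (any(bad_conc))
    stop("negative or non-finite concentration in rows: ",
         paste(which(bad_conc), collapse = ", "))
  tissue <- obs$state != "medium"
  if (any(tissue & (is.na(obs$n_animals) | obs$n_animals < 1)))
    stop("tissue rows require n_animals >= 1")
  structure(list(species = species, compound = compound,
                 temperature_C = temperature_C,
                 temperature_K = temperature_C + 273.15,
                 design = design, observations = obs),
            class = "tk_dataset")
}

#' @export
print.tk_dataset <- function(x, ...) {
  cat(sprintf("<tk_dataset> %s / %s @ %.1f degC: %d observations (%s)\n",
              x$species, x$compound, x$temperature_C, nrow(x$observations),
              paste(sprintf("%s: %d", names(table(x$observations$state)),
                            as.integer(table(x$observations$state))),
                    collapse = ", ")))
  invisible(x)
}

# Replicate weighting: datasets are weighted by the number of animals pooled
# into each sample. Isolated here so the weighting convention has a single
# home.
obs_weights <- function(n_animals) as.numeric(n_animals)

# Tissue rows ready for fitting: LOQ policy applied, uptake-phase water
# concentration averaged from medium rows (elimination-phase medium is zero
# by design).
prepare_fit_data <- function(ds, states, loq_policy = c("drop", "half")) {
  loq_policy <- match.arg(loq_policy)
  obs <- ds$observations
  med <- obs[obs$state == "medium" &
               obs$time_day <= ds$design$t_depuration_start + 1e-9, ]
  cw <- if (nrow(med)) mean(med$concentration[!med$below_loq])
        else ds$design$c_water
  design <- ds$design
  design$c_water <- cw

  dat <- obs[obs$state %in% states, ]
  n_loq <- sum(dat$below_loq)
  if (loq_policy == "drop") {
    dat <- dat[!dat$below_loq, ]
  } else {
    dat$concentration[dat$below_loq] <- dat$loq[dat$below_loq] / 2
  }
  for (st in states) {
    tt <- dat$time_day[dat$state == st]
    n_up <- length(unique(tt[tt <= design$t_depuration_start + 1e-9]))
    n_el <- length(unique(tt[tt > design$t_depuration_start + 1e-9]))
    if (st == "parent" && (n_up < 2 || n_el < 2))
      stop(sprintf(paste0("insufficient data for fitting: need >= 2 distinct",
                          " uptake and elimination time points for state '%s'",
                          " (have %d and %d)"), st, n_up, n_el))
  }
  list(time = dat$time_day, state = dat$state, conc = dat$concentration,
       w = obs_weights(dat$n_animals), design = design, n_loq_dropped = n_loq)
}

wssq <- function(pred, obs, w) sum(w * (obs - pred)^2)

# AIC for weighted least squares with the error variance counted as a
# parameter: n log(SSQ_w / n) + 2 (K + 1). Only differences are meaningful.
ls_aic <- function(ssq, n, K) n * log(max(ssq, 1e-300) / n) + 2 * (K + 1)

# Deterministic multi-start: a data-driven start plus a fixed-seed Latin
# hypercube over log10-rates in [-3, 3]. RNG state of the session is left
# untouched.
lhs_starts <- function(n_starts, n_par, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  log(10^(lhs::randomLHS(n_starts, n_par) * 6 - 3))
}

# log-parameter box for the local optimizer
.LOG_LB <- log(1e-8)
.LOG_UB <- log(1e4)

run_multistart <- function(objfun, starts) {
  best <- NULL
  n_conv <- 0L
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      stats::nlminb(starts[i, ], objfun, lower = .LOG_LB, upper = .LOG_UB,
                    control = list(iter.max = 300, eval.max = 600)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (res$convergence == 0) n_conv <- n_conv + 1L
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  if (is.null(best)) stop("optimization failed from every start")
  # high-precision polish from the best basin
  pol <- tryCatch(
    stats::nlminb(best$par, objfun, lower = .LOG_LB, upper = .LOG_UB,
                  control = list(iter.max = 2000, eval.max = 4000,
                                 rel.tol = 1e-12)),
    error = function(e) NULL)
  if (!is.null(pol) && pol$objective <= best$objective) {
    pol$n_converged <- n_conv + as.integer(pol$convergence == 0)
    return(pol)
  }
  best$n_converged <- n_conv
  best
}

# Heuristic initial values: elimination slope from the log-linear tail,
# uptake rate from the concentration reached at the phase switch.
heuristic_start_parent <- function(fd) {
  td <- fd$design$t_depuration_start
  el <- fd$state == "parent" & fd$time > td + 1e-9 & fd$conc > 0
  ke <- if (sum(el) >= 2 && length(unique(fd$time[el])) >= 2) {
    sl <- stats::coef(stats::lm(log(fd$conc[el]) ~ fd$time[el]))[2]
    max(min(-sl, 1e3), 1e-3)
  } else 1
  up <- fd$state == "parent" & fd$time <= td + 1e-9
  c_td <- if (any(up)) max(mean(fd$conc[up][fd$time[up] == max(fd$time[up])]), 1e-6)
          else 1e-6
  cw <- max(fd$design$c_water, 1e-12)
  ku <- max(c_td * ke / (cw * (1 - exp(-ke * td))), 1e-3)
  log(c(ku, ke))
}

#' Fit the one-compartment parent model
#'
#' Estimates `k_u` and `k_e` by minimizing the replicate-weighted sum of
#' squares \eqn{\sum_i w_i (C_{obs,i} - C_{model}(t_i))^2} with
#' \eqn{w_i} the number of animals pooled per sample, using the closed-form
#' model solution. All parameters are fitted simultaneously; during the
#' uptake phase the arithmetic mean of measured medium concentrations is
#' used as the water concentration and the elimination-phase water
#' concentration is fixed at zero. Optimization is a deterministic
#' multi-start (heuristic start plus a fixed-seed Latin hypercube over
#' log-rates) followed by bounded local refinement in log-parameter space.
#'
#' @param ds A [tk_dataset()].
#' @param loq_policy How to treat below-LOQ observations: `"drop"` (default,
#'   the dropped count is recorded on the result) or `"half"` (substitute
#'   LOQ/2).
#' @param ci Compute 95 % profile-likelihood intervals for both parameters
#'   (default `TRUE`).
#' @param n_starts Number of Latin-hypercube starts in addition to the
#'   data-driven start.
#' @return A `tk_fit` object; see [profile_ci()], [goodness_of_fit()],
#'   [select_model()].
#' @examples
#' tc <- truth_config(cv = 0)
#' ds <- generate_experiment(tc)$datasets[[2]]
#' fit <- fit_parent(ds, ci = FALSE)
#' coef(fit)
#' @export
fit_parent <- function(ds, loq_policy = c("drop", "half"), ci = TRUE,
                       n_starts = 7) {
  stopifnot(inherits(ds, "tk_dataset"))
  loq_policy <- match.arg(loq_policy)
  fd <- prepare_fit_data(ds, "parent", loq_policy)
  objfun <- function(lp) {
    p <- parent_params(exp(lp[1]), exp(lp[2]))
    wssq(parent_conc(fd$time, p, fd$design), fd$conc, fd$w)
  }
  if (all(fd$conc == 0)) {
    # degenerate but well-defined: nothing was taken up
    est <- c(k_u = 0, k_e = 1)
    return(new_tk_fit("parent", est, fd, ds, objfun, converged = TRUE,
                      K = 2L, ci = FALSE, loq_policy = loq_policy))
  }
  starts <- rbind(heuristic_start_parent(fd), lhs_starts(n_starts, 2, seed = 20260101))
  best <- run_multistart(objfun, starts)
  est <- stats::setNames(exp(best$par), c("k_u", "k_e"))
  new_tk_fit("parent", est, fd, ds, objfun, converged = best$n_converged > 0,
             K = 2L, ci = ci, loq_policy = loq_policy)
}

#' Fit the biotransformation-cascade model
#'
#' Simultaneous weighted fit of the parent + biotransformation-product
#' cascade to all tissue states present in the dataset. If no secondary
#' product (`btp2`) observations exist, `k_m_2nd` and `k_e_2nd` are fixed at
#' zero and excluded from the parameter count. Objective, weighting,
#' optimizer and AIC conventions are those of [fit_parent()].
#'
#' @inheritParams fit_parent
#' @return A `tk_fit` object with estimates
#'   `k_u`, `k_e_p`, `k_m_1st`, `k_e_1st` (+ `k_m_2nd`, `k_e_2nd` when btp2
#'   data are present).
#' @export
fit_biotrans <- function(ds, loq_policy = c("drop", "half"), ci = TRUE,
                         n_starts = 7) {
  stopifnot(inherits(ds, "tk_dataset"))
  loq_policy <- match.arg(loq_policy)
  has_btp1 <- any(ds$observations$state == "btp1" & !ds$observations$below_loq)
  if (!has_btp1)
    stop("biotransformation model requires btp1 observations above LOQ")
  has_btp2 <- any(ds$observations$state == "btp2" & !ds$observations$below_loq)
  states <- c("parent", "btp1", if (has_btp2) "btp2")
  fd <- prepare_fit_data(ds, states, loq_policy)
  par_names <- c("k_u", "k_e_p", "k_m_1st", "k_e_1st",
                 if (has_btp2) c("k_m_2nd", "k_e_2nd"))
  K <- length(par_names)
  to_params <- function(k) biotrans_params(k[1], k[2], k[3], k[4],
                                           if (has_btp2) k[5] else 0,
                                           if (has_btp2) k[6] else 0)
  objfun <- function(lp) {
    p <- to_params(exp(lp))
    m <- cascade_conc(fd$time, p, fd$design)
    pred <- m[cbind(seq_along(fd$time), match(fd$state, colnames(m)))]
    wssq(pred, fd$conc, fd$w)
  }
  hs <- heuristic_start_parent(fd)
  start0 <- c(hs[1], hs[2] - log(2), hs[2] - log(2), hs[2],
              if (has_btp2) rep(hs[2] - log(2), 2))
  starts <- rbind(start0, lhs_starts(n_starts, K, seed = 20260102))
  best <- run_multistart(objfun, starts)
  est <- stats::setNames(exp(best$par), par_names)
  new_tk_fit("biotrans", est, fd, ds, objfun, converged = best$n_converged > 0,
             K = K, ci = ci, loq_policy = loq_policy)
}

as_tk_params <- function(model, est) {
  if (model == "parent") parent_params(est[["k_u"]], est[["k_e"]])
  else biotrans_params(est[["k_u"]], est[["k_e_p"]], est[["k_m_1st"]],
                       est[["k_e_1st"]],
                       if ("k_m_2nd" %in% names(est)) est[["k_m_2nd"]] else 0,
                       if ("k_e_2nd" %in% names(est)) est[["k_e_2nd"]] else 0)
}

new_tk_fit <- function(model, est, fd, ds, objfun, converged, K, ci,
                       loq_policy) {
  params <- as_tk_params(model, est)
  pred <- predict_states(params, fd)
  ssq <- wssq(pred, fd$conc, fd$w)
  n <- length(fd$conc)
  fit <- structure(list(
    model = model, estimates = est, params = params,
    weighted_ssq = ssq, n_obs = n, n_params = K,
    aic = ls_aic(ssq, n, K), converged = converged,
    fd = fd, objfun = objfun, dataset = ds,
    loq_policy = loq_policy, n_loq_dropped = fd$n_loq_dropped,
    ci95 = NULL, profiles = NULL), class = "tk_fit")
  fit$r2 <- goodness_of_fit(fit)
  if (ci) {
    prof <- lapply(names(est), function(pn) profile_ci(fit, param = pn))
    fit$ci95 <- do.call(rbind, lapply(prof, function(p)
      data.frame(param = p$param, lo = p$lo, hi = p$hi,
                 lo_flag = p$lo_flag, hi_flag = p$hi_flag,
                 stringsAsFactors = FALSE)))
    fit$profiles <- stats::setNames(lapply(prof, `[[`, "curve"), names(est))
  }
  fit
}

predict_states <- function(params, fd) {
  if (inherits(params, "parent_params")) {
    parent_conc(fd$time, params, fd$design)
  } else {
    m <- cascade_conc(fd$time, params, fd$design)
    m[cbind(seq_along(fd$time), match(fd$state, colnames(m)))]
  }
}

#' @export
coef.tk_fit <- function(object, ...) object$estimates

#' @export
print.tk_fit <- function(x, ...) {
  cat(sprintf("<tk_fit> %s model, %d obs, weighted SSQ %.4g, AIC %.2f%s\n",
              x$model, x$n_obs, x$weighted_ssq, x$aic,
              if (x$converged) "" else " [NOT CONVERGED]"))
  est <- data.frame(estimate = x$estimates)
  if (!is.null(x$ci95)) {
    est$ci_lo <- x$ci95$lo[match(rownames(est), x$ci95$param)]
    est$ci_hi <- x$ci95$hi[match(rownames(est), x$ci95$param)]
  }
  print(est)
  cat("R2:", paste(sprintf("%s %.3f", names(x$r2), x$r2), collapse = ", "), "\n")
  if (x$n_loq_dropped > 0)
    cat(sprintf("note: %d below-LOQ observation(s) %s\n", x$n_loq_dropped,
                if (x$loq_policy == "drop") "dropped" else "set to LOQ/2"))
  invisible(x)
}

#' Profile-likelihood 95 % confidence interval
#'
#' Profiles one rate constant on a multiplicative grid while re-optimizing
#' all remaining parameters, and reports the interval where the profiled
#' weighted sum of squares crosses
#' \eqn{SSQ_{best} \exp(\chi^2_{1,0.95} / n)} — the 3.84 threshold on the
#' -2 log-likelihood scale implied by the normal error model with estimated
#' variance. Bounds that never cross within the searchable range are
#' returned as `0` / `Inf` with a flag, which is the expected outcome for
#' practically non-identifiable rates (e.g. an excretion rate swamped by
#' biotransformation).
#'
#' @param fit A converged `tk_fit`.
#' @param ds Unused; the fit retains its data (kept for call symmetry).
#' @param param Name of the parameter to profile, e.g. `"k_e"`.
#' @param level Confidence level (default 0.95).
#' @return A list with `param`, `lo`, `hi`, `lo_flag`, `hi_flag`
#'   (`"crossed"`, `"at_zero"` or `"unbounded"`) and `curve`, a data frame
#'   of profiled (value, objective) pairs.
#' @export
profile_ci <- function(fit, ds = NULL, param, level = 0.95) {
  stopifnot(inherits(fit, "tk_fit"), param %in% names(fit$estimates))
  idx <- match(param, names(fit$estimates))
  lp_best <- log(pmax(fit$estimates, exp(.LOG_LB)))
  n <- fit$n_obs
  thresh <- max(fit$weighted_ssq, 1e-300) *
    exp(stats::qchisq(level, 1) / n)

  free <- setdiff(seq_along(lp_best), idx)
  prof_obj <- function(lv) {
    if (!length(free)) return(fit$objfun(replace(lp_best, idx, lv)))
    inner <- function(lp_free)
      fit$objfun(replace(`[<-`(lp_best, free, lp_free), idx, lv))
    res <- stats::nlminb(lp_best[free], inner, lower = .LOG_LB, upper = .LOG_UB)
    res$objective
  }

  curve <- data.frame(value = exp(lp_best[idx]),
                      objective = fit$weighted_ssq)
  walk <- function(dir) {
    step <- log(1.4)
    lv_prev <- lp_best[idx]; f_prev <- fit$weighted_ssq
    for (i in 1:80) {
      lv <- lv_prev + dir * step
      if (lv < .LOG_LB - 18 || lv > .LOG_UB + 9)
        return(list(bound = if (dir < 0) 0 else Inf,
                    flag = if (dir < 0) "at_zero" else "unbounded"))
      f <- prof_obj(lv)
      curve <<- rbind(curve, data.frame(value = exp(lv), objective = f))
      if (f >= thresh) {
        lo_lv <- min(lv_prev, lv); hi_lv <- max(lv_prev, lv)
        f_lo <- if (dir > 0) f_prev else f
        f_hi <- if (dir > 0) f else f_prev
        root <- stats::uniroot(function(z) prof_obj(z) - thresh,
                               lower = lo_lv, upper = hi_lv,
                               f.lower = f_lo - thresh,
                               f.upper = f_hi - thresh,
                               tol = 1e-5)$root
        return(list(bound = exp(root), flag = "crossed"))
      }
      lv_prev <- lv; f_prev <- f
    }
    list(bound = if (dir < 0) 0 else Inf,
         flag = if (dir < 0) "at_zero" else "unbounded")
  }
  lo <- walk(-1); hi <- walk(+1)
  list(param = param, lo = lo$bound, hi = hi$bound,
       lo_flag = lo$flag, hi_flag = hi$flag,
       curve = curve[order(curve$value), ])
}

#' Weighted coefficient of determination per fitted state
#'
#' Computes \eqn{R^2 = 1 - SSQ_{res} / SSQ_{tot}} for every tissue state
#' used in the fit, with the same replicate weights as the objective;
#' \eqn{SSQ_{tot}} is taken about the weighted state mean.
#'
#' @param fit A `tk_fit`.
#' @param ds Unused; the fit retains its data.
#' @return Named numeric vector of per-state R2; `NA` for a state with
#'   fewer than two observations.
#' @export
goodness_of_fit <- function(fit, ds = NULL) {
  stopifnot(inherits(fit, "tk_fit"))
  fd <- fit$fd
  pred <- predict_states(fit$params, fd)
  states <- unique(fd$state)
  out <- stats::setNames(numeric(length(states)), states)
  for (st in states) {
    i <- fd$state == st
    if (sum(i) < 2) { out[st] <- NA_real_; next }
    sres <- sum(fd$w[i] * (fd$conc[i] - pred[i])^2)
    mbar <- sum(fd$w[i] * fd$conc[i]) / sum(fd$w[i])
    stot <- sum(fd$w[i] * (fd$conc[i] - mbar)^2)
    out[st] <- if (stot <= 0) as.numeric(sres <= 1e-12) else 1 - sres / stot
  }
  out
}

#' Select among candidate fits by AIC with an R2 tie-break
#'
#' The fit with the lowest AIC wins; among all candidates within 2 AIC
#' units of the best, the one with the highest mean R2 over the parent and
#' primary-product states is preferred (secondary-product concentrations
#' carry more uncertainty and do not enter the tie-break). The decision
#' trace is attached to the returned fit.
#'
#' @param parent_fit A `tk_fit`, or a list of candidate `tk_fit`s.
#' @param biotrans_fits Optional further candidates (single fit or list).
#' @return The selected `tk_fit`, with attribute `selection` holding the
#'   decision table.
#' @export
select_model <- function(parent_fit, biotrans_fits = NULL) {
  cands <- c(if (inherits(parent_fit, "tk_fit")) list(parent_fit) else parent_fit,
             if (inherits(biotrans_fits, "tk_fit")) list(biotrans_fits)
             else biotrans_fits)
  if (!length(cands)) stop("no candidate fits supplied")
  stopifnot(all(vapply(cands, inherits, TRUE, "tk_fit")))
  aic <- vapply(cands, `[[`, 0, "aic")
  tiebreak_r2 <- vapply(cands, function(f)
    mean(f$r2[intersect(names(f$r2), c("parent", "btp1"))], na.rm = TRUE), 0)
  in_window <- aic - min(aic) < 2
  pick <- which(in_window)[which.max(tiebreak_r2[in_window])]
  trace <- data.frame(model = vapply(cands, `[[`, "", "model"),
                      n_params = vapply(cands, `[[`, 0L, "n_params"),
                      aic = aic, delta_aic = aic - min(aic),
                      tiebreak_r2 = tiebreak_r2,
                      in_window = in_window,
                      selected = seq_along(cands) == pick)
  out <- cands[[pick]]
  attr(out, "selection") <- trace
  out
}

#' Summarise a fit as a one-row report
#'
#' Flattens estimates, profile CI bounds, fit statistics and derived
#' quantities (kinetic BCF, elimination half-life, time to 95 % steady
#' state) into a single data-frame row for CSV/JSON export.
#'
#' @param fit A `tk_fit`.
#' @return A one-row data frame.
#' @export
fit_report <- function(fit) {
  stopifnot(inherits(fit, "tk_fit"))
  ds <- fit$dataset
  ke_tot <- if (fit$model == "parent") fit$estimates[["k_e"]]
            else fit$estimates[["k_e_p"]] + fit$estimates[["k_m_1st"]]
  row <- data.frame(species = ds$species, compound = ds$compound,
                    temperature_C = ds$temperature_C, model = fit$model,
                    n_obs = fit$n_obs, weighted_ssq = fit$weighted_ssq,
                    aic = fit$aic, converged = fit$converged,
                    bcf_kin = as.numeric(bcf_kin(fit$params)),
                    half_life_day = as.numeric(half_life(ke_tot)),
                    t_ss95_day = as.numeric(time_to_ss95(ke_tot)),
                    stringsAsFactors = FALSE)
  for (pn in names(fit$estimates)) row[[pn]] <- fit$estimates[[pn]]
  if (!is.null(fit$ci95)) {
    for (i in seq_len(nrow(fit$ci95))) {
      row[[paste0(fit$ci95$param[i], "_lo")]] <- fit$ci95$lo[i]
      row[[paste0(fit$ci95$param[i], "_hi")]] <- fit$ci95$hi[i]
    }
  }
  for (st in names(fit$r2)) row[[paste0("r2_", st)]] <- fit$r2[[st]]
  row
}
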