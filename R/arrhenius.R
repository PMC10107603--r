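# Temperature analysis of rate tables: Arrhenius regression of ln(k) on
# 1/T, rate prediction at temperature, and the BCF-temperature trend test.

#' Rate table for temperature analysis
#'
#' A small table of a rate constant measured or modelled at several
#' temperatures, the input of [arrhenius_fit()]. Temperatures may be given
#' in degrees Celsius (converted internally) or Kelvin.
#'
#' @param temperature Temperatures; Kelvin if `unit = "K"`, Celsius if
#'   `unit = "C"` (default).
#' @param rate Rate values, all strictly positive (their log is taken).
#' @param se Optional standard errors of the rates (same length), used only
#'   for inverse-variance weighting when requested in [arrhenius_fit()].
#' @param label What the rate is, e.g. `"k_u"`, `"k_e"`, `"SMR"`.
#' @param unit Temperature unit of the input, `"C"` or `"K"`.
#' @return An object of class `rate_table` (a data frame with columns
#'   `temperature_K`, `rate`, `se` and a `label` attribute).
#' @examples
#' rate_table(c(6.1, 11, 15.4, 21.2), c(2.1, 3.4, 5.2, 8.9), label = "k_u")
#' @export
rate_table <- function(temperature, rate, se = NULL, label = "rate",
                       unit = c("C", "K")) {
  unit <- match.arg(unit)
  stopifnot(length(temperature) == length(rate))
  tk <- if (unit == "C") temperature + 273.15 else temperature
  if (any(!is.finite(tk)) || any(tk <= 0))
    stop("temperatures must be finite and positive (Kelvin)")
  bad <- !is.finite(rate) | rate <= 0
  if (any(bad))
    stop("rates must be positive for log-scale regression; offending entries: ",
         paste(which(bad), collapse = ", "))
  if (!is.null(se)) stopifnot(length(se) == length(rate))
  out <- data.frame(temperature_K = tk, rate = rate,
                    se = if (is.null(se)) NA_real_ else se)
  attr(out, "label") <- label
  class(out) <- c("rate_table", "data.frame")
  out
}

#' Arrhenius regression of a rate table
#'
#' Ordinary least squares of \eqn{\ln k} on inverse absolute temperature,
#' \eqn{\ln k = -T_A (1/T) + \ln A}. The Arrhenius temperature
#' \eqn{T_A} (K) is minus the slope and quantifies how strongly the rate
#' accelerates with warming; \eqn{\ln A} is the intercept (log frequency
#' factor). The slope standard error is reported as `se_T_A` when three or
#' more distinct temperatures are available.
#'
#' @param rt A [rate_table()] (at least two distinct temperatures; all
#'   rates positive).
#' @param weighted If `TRUE` and the table carries standard errors, weight
#'   the regression by `1/se^2`. Off by default: the plain fit is the
#'   reference analysis.
#' @return An object of class `arrhenius_fit` with elements `T_A`,
#'   `se_T_A`, `ln_A`, `r2`, `n`, `residuals`, `label`.
#' @examples
#' rt <- rate_table(c(279.25, 284.15, 288.55, 294.35),
#'                  exp(10 - 8000 / c(279.25, 284.15, 288.55, 294.35)),
#'                  label = "k_u", unit = "K")
#' arrhenius_fit(rt)$T_A  # 8000
#' @export
arrhenius_fit <- function(rt, weighted = FALSE) {
  stopifnot(inherits(rt, "rate_table"))
  if (length(unique(rt$temperature_K)) < 2)
    stop("Arrhenius regression needs >= 2 distinct temperatures")
  inv_T <- 1 / rt$temperature_K
  w <- if (weighted && all(is.finite(rt$se)) && all(rt$se > 0)) 1 / rt$se^2
  fit <- stats::lm(log(rt$rate) ~ inv_T, weights = w)
  # summary.lm warns on noise-free (perfect) fits; that case is legitimate here
  sm <- suppressWarnings(summary(fit))
  n <- nrow(rt)
  se_TA <- if (length(unique(rt$temperature_K)) >= 3)
    sm$coefficients["inv_T", "Std. Error"] else NA_real_
  structure(list(T_A = -unname(stats::coef(fit)["inv_T"]),
                 se_T_A = unname(se_TA),
                 ln_A = unname(stats::coef(fit)["(Intercept)"]),
                 r2 = sm$r.squared, n = n,
                 residuals = unname(stats::residuals(fit)),
                 label = attr(rt, "label"), lm = fit),
            class = "arrhenius_fit")
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf("<arrhenius_fit> %s: T_A = %.0f K%s, ln A = %.3f, R2 = %.3f (n = %d)\n",
              x$label, x$T_A,
              if (is.finite(x$se_T_A)) sprintf(" +/- %.0f", x$se_T_A) else "",
              x$ln_A, x$r2, x$n))
  invisible(x)
}

as_arrhenius_pair <- function(af) {
  if (inherits(af, "arrhenius_fit")) c(T_A = af$T_A, ln_A = af$ln_A)
  else if (is.numeric(af) && length(af) == 2)
    c(T_A = unname(af[1]), ln_A = unname(af[2]))
  else stop("expected an 'arrhenius_fit' or a (T_A, ln_A) pair")
}

#' Predict a rate at a given temperature
#'
#' Evaluates the Arrhenius relationship \eqn{k(T) = A e^{-T_A / T}} from a
#' fitted [arrhenius_fit()] or an explicit `(T_A, ln_A)` pair.
#'
#' @param af An `arrhenius_fit` or numeric `c(T_A, ln_A)`.
#' @param temperature_K Absolute temperature(s) in Kelvin, > 0; vectorised.
#' @return Predicted rate(s), same units as the fitted rates.
#' @examples
#' rate_at_temperature(c(8030, 30), 284.15)
#' @export
rate_at_temperature <- function(af, temperature_K) {
  p <- as_arrhenius_pair(af)
  if (any(!is.finite(temperature_K)) || any(temperature_K <= 0))
    stop("'temperature_K' must be positive (Kelvin)")
  exp(p[["ln_A"]] - p[["T_A"]] / temperature_K)
}

#' Fold change of a rate (or trend) across a temperature range
#'
#' Ratio of the predicted quantity at the upper temperature to that at the
#' lower temperature. For an Arrhenius object this is
#' \eqn{\exp(T_A (1/T_{lo} - 1/T_{hi}))}; for a fitted linear BCF trend
#' (see [bcf_trend()]) the trend line is evaluated at the two endpoint
#' temperatures.
#'
#' @param af An `arrhenius_fit`, a `(T_A, ln_A)` pair, or a
#'   `bcf_trend` result.
#' @param T_lo,T_hi Endpoint temperatures in Kelvin, > 0.
#' @return The dimensionless ratio (quantity at `T_hi`) / (quantity at
#'   `T_lo`).
#' @examples
#' fold_change(c(8000, 0), 279.25, 294.35)
#' @export
fold_change <- function(af, T_lo, T_hi) {
  if (any(!is.finite(c(T_lo, T_hi))) || T_lo <= 0 || T_hi <= 0)
    stop("temperatures must be positive (Kelvin)")
  if (inherits(af, "bcf_trend"))
    return(unname((af$intercept + af$slope * T_hi) /
                    (af$intercept + af$slope * T_lo)))
  rate_at_temperature(af, T_hi) / rate_at_temperature(af, T_lo)
}

#' Test the kinetic BCF for a temperature trend
#'
#' Regresses the kinetic bioconcentration factor on absolute temperature and
#' applies the two-sided t-test of zero slope. A temperature dependence is
#' concluded when p < 0.05; otherwise the uptake and elimination rates are
#' taken to respond to temperature proportionally, leaving their ratio
#' stable.
#'
#' @param temperature Temperatures at which the BCFs were determined;
#'   Celsius by default (`unit = "C"`), converted internally. The verdict is
#'   invariant to the offset.
#' @param bcf Kinetic BCF values (L/kg wet weight), one per temperature;
#'   at least three distinct temperatures required.
#' @param unit `"C"` or `"K"`.
#' @return An object of class `bcf_trend`: `slope` (L/kg/K), `se_slope`,
#'   `p_value`, `intercept`, `verdict` (`"temperature-dependent"` or
#'   `"not temperature-dependent"`), `n`.
#' @examples
#' bcf_trend(c(6.1, 11, 15.4, 21.2), c(12, 12.4, 11.8, 12.1))
#' @export
bcf_trend <- function(temperature, bcf, unit = c("C", "K")) {
  unit <- match.arg(unit)
  stopifnot(length(temperature) == length(bcf))
  tk <- if (unit == "C") temperature + 273.15 else temperature
  if (length(unique(tk)) < 3)
    stop("BCF trend test needs >= 3 distinct temperatures")
  fit <- stats::lm(bcf ~ tk)
  cf <- suppressWarnings(summary(fit))$coefficients
  p <- cf["tk", "Pr(>|t|)"]
  # an exactly-flat line yields slope 0 with p = NaN; that is "no trend"
  if (!is.finite(p)) p <- 1
  structure(list(slope = unname(cf["tk", "Estimate"]),
                 se_slope = unname(cf["tk", "Std. Error"]),
                 intercept = unname(cf["(Intercept)", "Estimate"]),
                 p_value = unname(p),
                 verdict = if (is.finite(p) && p < 0.05) "temperature-dependent"
                           else "not temperature-dependent",
                 n = length(bcf), lm = fit),
            class = "bcf_trend")
}

#' @export
print.bcf_trend <- function(x, ...) {
  cat(sprintf("<bcf_trend> slope = %.4g L/kg/K (p = %.3g): %s (n = %d)\n",
              x$slope, x$p_value, x$verdict, x$n))
  invisible(x)
}

#' Reference Arrhenius temperatures
#'
#' Physiological Arrhenius temperatures used as report overlays when judging
#' whether toxicokinetic rates track whole-animal metabolism: Add-my-Pet
#' database entries for the two amphipods, and a respirometry-derived value
#' for \emph{H. azteca}.
#'
#' @return Named numeric vector (K).
#' @export
reference_TA <- function() {
  c(amp_g_pulex = 10560,
    amp_h_azteca = 10830,
    smr_h_azteca = 8030)
}

#' Screen a set of fitted rates for Arrhenius analysis
#'
#' Rates whose estimates are numerically zero (or whose profile CI reaches
#' zero while the estimate sits below a floor) are practically
#' non-identifiable — typically an excretion rate dominated by
#' biotransformation — and are excluded from Arrhenius fitting, with the
#' reason recorded.
#'
#' @param rates Numeric vector of rate estimates (one per temperature).
#' @param ci_lo Optional vector of lower CI bounds (same length).
#' @param floor Estimates below this (1/day) are considered "close to
#'   zero" when their CI reaches zero.
#' @return Logical vector marking usable entries, with attribute
#'   `excluded_reasons` naming the dropped indices.
#' @export
screen_rates <- function(rates, ci_lo = NULL, floor = 1e-3) {
  keep <- rates >= 1e-6
  reason <- ifelse(keep, NA_character_, "estimate < 1e-6/day (close to zero)")
  if (!is.null(ci_lo)) {
    hit <- keep & ci_lo <= 0 & rates < floor
    reason[hit] <- "CI lower bound 0 with estimate below floor"
    keep <- keep & !hit
  }
  attr(keep, "excluded_reasons") <- reason
  keep
}

#' Plot an Arrhenius fit
#'
#' Base-graphics diagnostic: ln(rate) against 1000/T with the fitted
#' regression line and a pointwise 95 % confidence band.
#'
#' @param x An `arrhenius_fit`.
#' @param ... Passed to [plot()].
#' @export
plot.arrhenius_fit <- function(x, ...) {
  dat <- stats::model.frame(x$lm)
  inv_T <- dat$inv_T
  grid <- seq(min(inv_T), max(inv_T), length.out = 50)
  pr <- stats::predict(x$lm, newdata = data.frame(inv_T = grid),
                       interval = "confidence")
  plot(inv_T * 1000, dat[[1]], xlab = "1000 / T (1/K)",
       ylab = paste0("ln ", x$label),
       main = sprintf("%s: T_A = %.0f K", x$label, x$T_A), ...)
  graphics::lines(grid * 1000, pr[, "fit"])
  graphics::lines(grid * 1000, pr[, "lwr"], lty = 3)
  graphics::lines(grid * 1000, pr[, "upr"], lty = 3)
  invisible(x)
}
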