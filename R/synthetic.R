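# Synthetic bioconcentration experiments and respirometry tables with the
# statistical structure the analysis assumes: Arrhenius-structured true
# rates, a 1-day uptake / 3-day elimination design with duplicate pooled
# samples, multiplicative lognormal measurement noise and LOQ censoring.

# evaluate expr under a fixed seed, leaving the session RNG untouched
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(expr)
}

# mean-1 multiplicative lognormal noise at a given coefficient of variation
ln_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sigma <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sigma^2 / 2, sigma))
}

#' Configuration of a synthetic bioconcentration study
#'
#' Describes the "true" system and the sampling design from which synthetic
#' uptake--elimination experiments are drawn. Defaults emulate a standard
#' amphipod bioconcentration study: four experiment temperatures, a
#' 50 ug/L exposure for 1 day followed by 3 days of elimination, duplicate
#' pooled samples at eight regular time points, and Arrhenius-structured
#' true rates with a common Arrhenius temperature of 8000 K for uptake and
#' elimination (so the true kinetic BCF is temperature-stable).
#'
#' @param arr_ku,arr_ke True Arrhenius parameters `c(T_A, ln_A)` of the
#'   uptake and elimination rates. Defaults anchor k_u = 100 L/kg/day and
#'   k_e = 2/day at 15.4 degC with T_A = 8000 K.
#' @param temperatures_C Experiment temperatures (degC).
#' @param c_water Nominal exposure concentration during uptake (default 50).
#' @param conc_unit Unit tag for concentrations (default `"ug/L"`).
#' @param t_uptake Uptake-phase duration (day).
#' @param t_elim Elimination-phase duration (day).
#' @param sampling_times Tissue sampling times (day); default eight regular
#'   times spanning both phases.
#' @param medium_times Medium sampling times during uptake (day).
#' @param replicates Samples per time point (default 2, duplicates).
#' @param n_animals Animals pooled per tissue sample (4 for
#'   \emph{G. pulex}, 15 for \emph{H. azteca}).
#' @param cv Lognormal coefficient of variation of tissue measurements
#'   (default 0.2).
#' @param cv_medium CV of medium measurements (default 0.05).
#' @param loq Limit of quantification on the tissue scale; observations
#'   below it are censored. Default 0 (no censoring).
#' @param medium_drift Fractional linear decline of the medium
#'   concentration over the uptake phase (0--0.2; default 0).
#' @param mortality_rate Per-experiment fraction of samples lost by the end
#'   of the experiment; loss probability grows linearly with time
#'   (default 0, off).
#' @param species,compound Labels carried into the datasets.
#' @param seed Seed making every generated draw reproducible (mandatory).
#' @return An object of class `truth_config`.
#' @export
truth_config <- function(arr_ku = c(T_A = 8000, ln_A = log(100) + 8000 / 288.55),
                         arr_ke = c(T_A = 8000, ln_A = log(2) + 8000 / 288.55),
                         temperatures_C = c(6.1, 11.0, 15.4, 21.2),
                         c_water = 50, conc_unit = "ug/L",
                         t_uptake = 1, t_elim = 3,
                         sampling_times = c(0.125, 0.25, 0.5, 1,
                                            1.25, 1.75, 2.5, 4),
                         medium_times = c(0, 0.5, 1),
                         replicates = 2, n_animals = 4,
                         cv = 0.2, cv_medium = 0.05,
                         loq = 0, medium_drift = 0, mortality_rate = 0,
                         species = "G. pulex", compound = "demo",
                         seed = 1) {
  stopifnot(cv >= 0, cv_medium >= 0, loq >= 0,
            medium_drift >= 0, medium_drift <= 1,
            mortality_rate >= 0, mortality_rate < 1,
            t_uptake > 0, t_elim >= 0, replicates >= 1, n_animals >= 1)
  if (anyDuplicated(temperatures_C))
    stop("'temperatures_C' must be distinct")
  if (is.null(seed) || !is.finite(seed))
    stop("a numeric 'seed' is mandatory for reproducible generation")
  t_end <- t_uptake + t_elim
  if (any(sampling_times < 0) || any(sampling_times > t_end))
    stop("sampling times must lie within [0, t_uptake + t_elim]")
  if (any(medium_times > t_uptake + 1e-9))
    stop("medium sampling times must lie in the uptake phase")
  structure(list(arr_ku = as_arrhenius_pair(arr_ku),
                 arr_ke = as_arrhenius_pair(arr_ke),
                 temperatures_C = temperatures_C, c_water = c_water,
                 conc_unit = conc_unit, t_uptake = t_uptake, t_elim = t_elim,
                 sampling_times = sampling_times, medium_times = medium_times,
                 replicates = replicates, n_animals = n_animals,
                 cv = cv, cv_medium = cv_medium, loq = loq,
                 medium_drift = medium_drift, mortality_rate = mortality_rate,
                 species = species, compound = compound, seed = seed),
            class = "truth_config")
}

#' Demonstration truth presets
#'
#' Two single-temperature-family presets spanning the equilibrium-versus-
#' kinetic BCF regimes: `"fast"` reaches 95 % of steady state within a day
#' at the warmest temperature (t_ss95 at 21.2 degC < 1 day), `"slow"` is
#' far from steady state even after days in the cold (t_ss95 at 6.1 degC
#' > 4 day). Both share T_A = 8000 K for uptake and elimination.
#'
#' @param which `"fast"` or `"slow"`.
#' @param ... Overrides passed to [truth_config()].
#' @return A `truth_config`.
#' @export
demo_truth <- function(which = c("fast", "slow"), ...) {
  which <- match.arg(which)
  ke_ref <- if (which == "fast") 2 else 0.3
  truth_config(arr_ke = c(T_A = 8000, ln_A = log(ke_ref) + 8000 / 288.55),
               compound = paste0("demo_", which), ...)
}

# per-temperature true parent parameters implied by the config
truth_rates <- function(tc) {
  Tk <- tc$temperatures_C + 273.15
  data.frame(temperature_C = tc$temperatures_C, temperature_K = Tk,
             k_u = rate_at_temperature(tc$arr_ku, Tk),
             k_e = rate_at_temperature(tc$arr_ke, Tk))
}

sample_grid <- function(tc) {
  expand.grid(time_day = tc$sampling_times,
              replicate_id = seq_len(tc$replicates),
              KEEP.OUT.ATTRS = FALSE)
}

# apply noise / censoring / mortality to model-true tissue values
observe_tissue <- function(true_val, grid, tc, state) {
  n <- length(true_val)
  conc <- true_val * ln_noise(n, tc$cv)
  keep <- rep(TRUE, n)
  if (tc$mortality_rate > 0) {
    p_lost <- tc$mortality_rate * grid$time_day / (tc$t_uptake + tc$t_elim)
    keep <- stats::runif(n) >= p_lost
  }
  below <- conc < tc$loq
  data.frame(time_day = grid$time_day, state = state,
             concentration = ifelse(below, NA_real_, conc),
             replicate_id = paste0(state, "_", grid$replicate_id),
             n_animals = tc$n_animals,
             below_loq = below, loq = ifelse(below, tc$loq, NA_real_),
             stringsAsFactors = FALSE)[keep, ]
}

observe_medium <- function(tc) {
  tt <- tc$medium_times
  true_med <- tc$c_water * (1 - tc$medium_drift * tt / tc$t_uptake)
  conc <- true_med * ln_noise(length(tt), tc$cv_medium)
  data.frame(time_day = tt, state = "medium", concentration = conc,
             replicate_id = "medium_1", n_animals = NA_real_,
             below_loq = FALSE, loq = NA_real_, stringsAsFactors = FALSE)
}

#' Generate a synthetic bioconcentration experiment series
#'
#' Draws one [tk_dataset()] per configured temperature from the
#' one-compartment parent model with the config's Arrhenius-structured true
#' rates, multiplicative mean-1 lognormal noise on tissue and medium
#' measurements, optional LOQ censoring, medium drift and
#' mortality-driven sample loss. The generating truth is returned alongside
#' for recovery studies. Identical configs (including seed) give identical
#' output.
#'
#' @param tc A [truth_config()].
#' @return A list with `datasets` (named by temperature, e.g. `"T6.1"`),
#'   `truth` (data frame of true per-temperature rates and BCF) and
#'   `config`.
#' @examples
#' out <- generate_experiment(truth_config(cv = 0, seed = 42))
#' out$truth
#' @export
generate_experiment <- function(tc) {
  stopifnot(inherits(tc, "truth_config"))
  tr <- truth_rates(tc)
  tr$bcf_kin <- tr$k_u / tr$k_e
  grid <- sample_grid(tc)
  datasets <- with_seed(tc$seed, lapply(seq_len(nrow(tr)), function(i) {
    design <- exposure_design(tc$c_water, tc$t_uptake, tc$t_uptake + tc$t_elim,
                              unit = tc$conc_unit)
    p <- parent_params(tr$k_u[i], tr$k_e[i])
    true_val <- parent_conc(grid$time_day, p, design)
    obs <- rbind(observe_tissue(true_val, grid, tc, "parent"),
                 observe_medium(tc))
    tk_dataset(tc$species, tc$compound, tr$temperature_C[i], design, obs)
  }))
  names(datasets) <- paste0("T", tr$temperature_C)
  list(datasets = datasets, truth = tr, config = tc)
}

#' Generate a synthetic biotransformation-cascade experiment series
#'
#' Like [generate_experiment()] but drawing parent, primary- and
#' secondary-product observations from the three-state cascade. The true
#' rate constants at the reference temperature (15.4 degC) are either given
#' explicitly or taken from one of two regime presets: `"minor"`, where
#' biotransformation contributes < 7 % of total parent elimination, and
#' `"dominant"`, where it contributes > 90 % (the regime in which the
#' excretion rate is practically unidentifiable). All rates share the
#' config's uptake Arrhenius temperature across the experiment
#' temperatures.
#'
#' @param tc A [truth_config()]; molar units are implied for product
#'   stoichiometry.
#' @param preset `"minor"` or `"dominant"` (ignored when `params` given).
#' @param params Optional [biotrans_params()] at the 15.4 degC reference.
#' @return A list with `datasets`, `truth` (per-temperature
#'   `biotrans_params`), `share` (true biotransformation share of parent
#'   elimination) and `config`.
#' @export
generate_btp_cascade <- function(tc, preset = c("minor", "dominant"),
                                 params = NULL) {
  stopifnot(inherits(tc, "truth_config"))
  preset <- match.arg(preset)
  if (is.null(params)) {
    params <- if (preset == "minor")
      biotrans_params(k_u = 100, k_e_p = 2, k_m_1st = 0.1,
                      k_e_1st = 1, k_m_2nd = 0.3, k_e_2nd = 0.8)
    else
      biotrans_params(k_u = 100, k_e_p = 0.02, k_m_1st = 2,
                      k_e_1st = 1, k_m_2nd = 0.3, k_e_2nd = 0.8)
  }
  T_A <- tc$arr_ku[["T_A"]]
  T_ref <- 288.55
  Tk <- tc$temperatures_C + 273.15
  share <- params$k_m_1st / (params$k_e_p + params$k_m_1st)
  grid <- sample_grid(tc)
  scale <- exp(-T_A / Tk + T_A / T_ref)
  truth <- lapply(scale, function(s)
    biotrans_params(params$k_u * s, params$k_e_p * s, params$k_m_1st * s,
                    params$k_e_1st * s, params$k_m_2nd * s, params$k_e_2nd * s))
  names(truth) <- paste0("T", tc$temperatures_C)
  datasets <- with_seed(tc$seed, lapply(seq_along(Tk), function(i) {
    design <- exposure_design(tc$c_water, tc$t_uptake, tc$t_uptake + tc$t_elim,
                              unit = tc$conc_unit)
    m <- cascade_conc(grid$time_day, truth[[i]], design)
    obs <- rbind(observe_tissue(m[, "parent"], grid, tc, "parent"),
                 observe_tissue(m[, "btp1"], grid, tc, "btp1"),
                 observe_tissue(m[, "btp2"], grid, tc, "btp2"),
                 observe_medium(tc))
    tk_dataset(tc$species, tc$compound, tc$temperatures_C[i], design, obs)
  }))
  names(datasets) <- names(truth)
  list(datasets = datasets, truth = truth, share = share, config = tc)
}

#' Generate a synthetic respirometry rate table
#'
#' Draws per-chamber standard metabolic rates (SMR, ug O2/g/h dry weight)
#' at each temperature from an Arrhenius-true curve with multiplicative
#' lognormal noise. The default truth anchors 330 ug O2/g/h at 7.3 degC
#' with T_A = 8030 K, the scale of amphipod respirometry.
#'
#' @param T_A True Arrhenius temperature (K).
#' @param anchor_rate,anchor_T_C Rate and temperature fixing the curve.
#' @param temperatures_C Chamber temperatures (degC).
#' @param n_chambers Replicate chambers per temperature (default 8).
#' @param cv Lognormal CV of chamber measurements (default 0.2).
#' @param seed Mandatory seed.
#' @return A [rate_table()] with `n_chambers` entries per temperature,
#'   labelled `"SMR"`, consumable by [arrhenius_fit()].
#' @examples
#' rt <- generate_respiration(cv = 0, seed = 1)
#' arrhenius_fit(rt)$T_A  # 8030
#' @export
generate_respiration <- function(T_A = 8030, anchor_rate = 330,
                                 anchor_T_C = 7.3,
                                 temperatures_C = c(7.3, 11.6, 16.4, 21.2),
                                 n_chambers = 8, cv = 0.2, seed = 1) {
  stopifnot(T_A >= 0, anchor_rate > 0, n_chambers >= 1, cv >= 0)
  if (is.null(seed) || !is.finite(seed))
    stop("a numeric 'seed' is mandatory for reproducible generation")
  ln_A <- log(anchor_rate) + T_A / (anchor_T_C + 273.15)
  Tk <- rep(temperatures_C + 273.15, each = n_chambers)
  true_val <- rate_at_temperature(c(T_A = T_A, ln_A = ln_A), Tk)
  val <- with_seed(seed, true_val * ln_noise(length(Tk), cv))
  rate_table(Tk, val, label = "SMR", unit = "K")
}
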