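# CSV interchange for observation tables, rate tables and profiles, plus
# JSON run manifests. One tabular dialect: UTF-8 CSV, '.' decimal, header
# row mandatory; temperatures stored in degC in files, Kelvin internally.

OBS_COLUMNS <- c("species", "compound", "temperature_C", "time_day", "state",
                 "matrix", "concentration", "unit", "replicate_id",
                 "n_animals", "below_loq", "loq")

read_csv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("missing required column(s) in ", basename(path), ": ",
         paste(miss, collapse = ", "))
  df
}

check_numeric_col <- function(df, col, path, min = -Inf, allow_na = FALSE) {
  x <- df[[col]]
  if (!is.numeric(x)) {
    bad <- which(is.na(suppressWarnings(as.numeric(x))) & !is.na(x))
    if (length(bad))
      stop("malformed numeric in column '", col, "' of ", basename(path),
           " at data row(s): ", paste(utils::head(bad, 5), collapse = ", "))
    x <- as.numeric(x)
  }
  bad <- which((!allow_na & is.na(x)) | (!is.na(x) & x < min))
  if (length(bad))
    stop("invalid value in column '", col, "' of ", basename(path),
         " (must be >= ", min, ") at data row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  x
}

#' Write observation datasets to CSV
#'
#' Flattens one or more [tk_dataset()] objects into the canonical long
#' observation table (columns `species, compound, temperature_C, time_day,
#' state, matrix, concentration, unit, replicate_id, n_animals, below_loq,
#' loq`).
#'
#' @param datasets A `tk_dataset` or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(datasets, path) {
  if (inherits(datasets, "tk_dataset")) datasets <- list(datasets)
  rows <- lapply(datasets, function(ds) {
    obs <- ds$observations
    data.frame(species = ds$species, compound = ds$compound,
               temperature_C = ds$temperature_C, time_day = obs$time_day,
               state = obs$state,
               matrix = ifelse(obs$state == "medium", "medium", "tissue"),
               concentration = obs$concentration,
               unit = ifelse(obs$state == "medium", ds$design$unit,
                             paste0(sub("/L$", "", ds$design$unit), "/kg")),
               replicate_id = obs$replicate_id, n_animals = obs$n_animals,
               below_loq = obs$below_loq, loq = obs$loq,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read observation datasets from CSV
#'
#' Parses the canonical observation table and splits it into one
#' [tk_dataset()] per species x compound x temperature experiment. The
#' exposure design is reconstructed from the file: the uptake-phase water
#' concentration is the mean of uptake-phase medium rows and the experiment
#' end is the latest observation time; the uptake duration is not stored in
#' the table and must be supplied.
#'
#' @param path CSV path with the columns written by [write_observations()].
#' @param t_uptake Uptake-phase duration in days (default 1).
#' @return Named list of `tk_dataset` objects
#'   (`species|compound|T<temperature>`).
#' @export
read_observations <- function(path, t_uptake = 1) {
  df <- read_csv_checked(path, OBS_COLUMNS)
  df$time_day <- check_numeric_col(df, "time_day", path, min = 0)
  df$concentration <- check_numeric_col(df, "concentration", path, min = 0,
                                        allow_na = TRUE)
  df$below_loq <- as.logical(df$below_loq)
  bad <- which(is.na(df$concentration) & !df$below_loq)
  if (length(bad))
    stop("missing concentration without below_loq flag in ", basename(path),
         " at data row(s): ", paste(utils::head(bad, 5), collapse = ", "))
  key <- interaction(df$species, df$compound, df$temperature_C, drop = TRUE)
  out <- lapply(split(df, key), function(d) {
    med <- d[d$matrix == "medium" & d$time_day <= t_uptake + 1e-9, ]
    cw <- if (nrow(med)) mean(med$concentration[!med$below_loq]) else 0
    unit <- if (nrow(med)) med$unit[1] else "umol/L"
    design <- exposure_design(cw, t_uptake, max(d$time_day, t_uptake),
                              unit = unit)
    tk_dataset(d$species[1], d$compound[1], d$temperature_C[1], design,
               d[, c("time_day", "state", "concentration", "replicate_id",
                     "n_animals", "below_loq", "loq")])
  })
  names(out) <- vapply(out, function(ds)
    paste(ds$species, ds$compound, paste0("T", ds$temperature_C), sep = "|"), "")
  out
}

#' Write / read a rate table CSV
#'
#' The rate-table dialect has columns `label, species, compound,
#' temperature_C, rate, unit, se`.
#'
#' @param rt A [rate_table()].
#' @param path CSV path.
#' @param species,compound,unit Optional metadata written alongside.
#' @return `path` invisibly (write); a `rate_table` (read).
#' @export
write_rate_table <- function(rt, path, species = NA, compound = NA,
                             unit = "1/day") {
  stopifnot(inherits(rt, "rate_table"))
  utils::write.csv(data.frame(label = attr(rt, "label"), species = species,
                              compound = compound,
                              temperature_C = rt$temperature_K - 273.15,
                              rate = rt$rate, unit = unit, se = rt$se,
                              stringsAsFactors = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rate_table
#' @export
read_rate_table <- function(path) {
  df <- read_csv_checked(path, c("label", "temperature_C", "rate"))
  df$temperature_C <- check_numeric_col(df, "temperature_C", path)
  df$rate <- check_numeric_col(df, "rate", path)
  bad <- which(df$rate <= 0)
  if (length(bad))
    stop("non-positive rate in ", basename(path), " at data row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  rate_table(df$temperature_C, df$rate,
             se = if ("se" %in% names(df)) df$se,
             label = df$label[1], unit = "C")
}

#' Write / read a profile CSV
#'
#' Profile files have columns `time_day, value, kind` with `kind` constant
#' per file (`"temperature"`, in degC, or `"exposure"`).
#'
#' @param p A [tk_profile()].
#' @param path CSV path.
#' @param interp,extrapolate Interpolation options applied on read (see
#'   [tk_profile()]).
#' @return `path` invisibly (write); a `tk_profile` (read).
#' @export
write_profile <- function(p, path) {
  stopifnot(inherits(p, "tk_profile"))
  value <- if (p$kind == "temperature") p$value - 273.15 else p$value
  utils::write.csv(data.frame(time_day = p$time, value = value,
                              kind = p$kind, stringsAsFactors = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path, interp = "linear", extrapolate = FALSE) {
  df <- read_csv_checked(path, c("time_day", "value", "kind"))
  df$time_day <- check_numeric_col(df, "time_day", path)
  df$value <- check_numeric_col(df, "value", path)
  if (is.unsorted(df$time_day, strictly = TRUE)) {
    bad <- which(diff(df$time_day) <= 0)[1] + 1L
    stop("profile times must be strictly increasing in ", basename(path),
         "; violation at data row ", bad)
  }
  kind <- match.arg(df$kind[1], c("temperature", "exposure"))
  tk_profile(df$time_day, df$value, kind = kind,
             unit = if (kind == "temperature") "C" else "",
             interp = interp, extrapolate = extrapolate)
}

#' Write a reproducibility manifest
#'
#' Records the package version, seed, configuration and an MD5 digest of
#' the configuration next to every pipeline output, so any result can be
#' regenerated from its manifest alone.
#'
#' @param path Output JSON path.
#' @param config Named list of the run configuration.
#' @param seed The seed used (or `NA`).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config = list(), seed = NA) {
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                               null = "null", force = TRUE)
  tmp <- tempfile()
  writeLines(as.character(cfg_json), tmp)
  manifest <- list(package = "thermotk",
                   version = as.character(utils::packageVersion("thermotk")),
                   seed = seed, config = config,
                   config_md5 = unname(tools::md5sum(tmp)))
  unlink(tmp)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE, pretty = TRUE)
  invisible(path)
}
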