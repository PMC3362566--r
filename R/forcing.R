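#' Idealized summer upwelling-event scenario
#'
#' Builds the forcing bundle for a wind-driven coastal upwelling event of the
#' kind observed on the western Iberian shelf in mid July: a quiet spin-up,
#' a smooth (cosine) ramp to a plateau of sustained upwelling-favourable
#' forcing, and relaxation back to quiescence. Because the column carries no
#' momentum equation, the wind narrative is mapped directly onto schedules
#' of upwelling velocity \code{w_up(t)} and mixed-layer diffusivity
#' \code{kv_ml(t)}. Irradiance follows a clear-sky diurnal cycle; surface
#' temperature dips while upwelled water reaches the surface.
#'
#' @param onset_day day the event ramp begins (days from scenario start)
#' @param duration_days length of the event including ramps (default 14, as
#'   in a two-week observed event)
#' @param peak_w_up plateau upwelling velocity (m d^-1)
#' @param t_end_days total scenario span (days)
#' @param dt_hours sampling interval of the forcing series (hours)
#' @param deep_N deep nitrate reservoir concentration (mmol N m^-3)
#' @param I0_max clear-sky noon shortwave (W m^-2)
#' @param T_base,T_upwelled background and upwelled surface temperature (C)
#' @param kv_bg,kv_event background and event mixed-layer diffusivity
#'   (m^2 s^-1); \code{kv_bg} applies below the mixed layer at all times
#' @param mld_m mixed-layer depth over which event mixing acts (m)
#' @param noise_sd standard deviation of optional Gaussian perturbations of
#'   the irradiance series (W m^-2); 0 disables them
#' @param seed RNG seed used only when \code{noise_sd > 0}
#' @return an object of class \code{npzd_scenario}: list with the shared
#'   time axis \code{t} (days), series \code{I0}, \code{T}, \code{w_up},
#'   \code{kv_ml}, and scalars \code{kv_bg}, \code{mld_m}, \code{deep_N},
#'   \code{description}
#' @export
upwelling_event_scenario <- function(onset_day = 10, duration_days = 14,
                                     peak_w_up = 5, t_end_days = 40,
                                     dt_hours = 1, deep_N = 10,
                                     I0_max = 800, T_base = 16,
                                     T_upwelled = 13.5, kv_bg = 1e-5,
                                     kv_event = 1e-3, mld_m = 30,
                                     noise_sd = 0, seed = 1L) {
  if (duration_days <= 0) stop("duration_days must be > 0", call. = FALSE)
  t <- seq(0, t_end_days, by = dt_hours / 24)

  # cosine ramp up over the first fifth of the event, plateau, cosine
  # relaxation over the last fifth
  ramp <- duration_days / 5
  env <- numeric(length(t))
  rel <- (t - onset_day)
  up <- rel >= 0 & rel < ramp
  plateau <- rel >= ramp & rel <= duration_days - ramp
  down <- rel > duration_days - ramp & rel <= duration_days
  env[up] <- 0.5 * (1 - cos(pi * rel[up] / ramp))
  env[plateau] <- 1
  env[down] <- 0.5 * (1 - cos(pi * (duration_days - rel[down]) / ramp))

  I0 <- pmax(I0_max * sin(pi * (t %% 1)), 0)^1  # daylight half-sine
  if (noise_sd > 0) {
    old <- get_rng_state(); on.exit(restore_rng_state(old))
    set.seed(seed)
    I0 <- pmax(I0 + rnorm(length(t), sd = noise_sd), 0)
  }
  structure(list(
    t = t,
    I0 = I0,
    T = T_base - (T_base - T_upwelled) * env,
    w_up = peak_w_up * env,
    kv_ml = kv_bg + (kv_event - kv_bg) * env,
    kv_bg = kv_bg, mld_m = mld_m, deep_N = deep_N,
    description = sprintf(
      "idealized %g-day upwelling event, onset day %g, peak w_up %g m/d, deep N %g",
      duration_days, onset_day, peak_w_up, deep_N)),
    class = "npzd_scenario")
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
restore_rng_state <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.npzd_scenario <- function(x, ...) {
  cat("forcing scenario:", x$description, "\n")
  cat(sprintf("  span %g days at %g-h sampling; deep_N %g mmol N m^-3\n",
              max(x$t), diff(x$t[1:2]) * 24, x$deep_N))
  invisible(x)
}

#' Write / read a scenario as a delimited text table
#'
#' The time-dependent series go into a tab-separated table (columns t, I0,
#' T, w_up, kv_ml); the scalars travel in \code{#}-prefixed header lines.
#'
#' @param scenario an \code{npzd_scenario}
#' @param path file path
#' @return \code{read_scenario} returns an \code{npzd_scenario}
#' @export
write_scenario <- function(scenario, path) {
  hdr <- sprintf("# %s: %s",
                 c("kv_bg", "mld_m", "deep_N", "description"),
                 c(scenario$kv_bg, scenario$mld_m, scenario$deep_N,
                   scenario$description))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(
    data.frame(t = scenario$t, I0 = scenario$I0, T = scenario$T,
               w_up = scenario$w_up, kv_ml = scenario$kv_ml),
    con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  get_scalar <- function(key) {
    m <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (!length(m)) stop("scenario file lacks header '", key, "'", call. = FALSE)
    sub(paste0("^# ", key, ": *"), "", m[1])
  }
  tab <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                           sep = "\t")
  structure(list(t = tab$t, I0 = tab$I0, T = tab$T, w_up = tab$w_up,
                 kv_ml = tab$kv_ml,
                 kv_bg = as.numeric(get_scalar("kv_bg")),
                 mld_m = as.numeric(get_scalar("mld_m")),
                 deep_N = as.numeric(get_scalar("deep_N")),
                 description = get_scalar("description")),
            class = "npzd_scenario")
}

#' River nitrate and chlorophyll inputs
#'
#' The shipped table of year-round riverine nitrate and chlorophyll a
#' concentrations for the 15 rivers of the model domain, as used for the
#' operational river forcing.
#'
#' @return data.frame with columns \code{river}, \code{nitrate_ug_per_l},
#'   \code{chlorophyll_ug_per_l}
#' @export
river_table <- function() {
  read.csv(system.file("extdata", "rivers.csv", package = "npzdcolumn",
                       mustWork = TRUE), check.names = TRUE)
}

#' River concentrations in model units
#'
#' Converts a river's tabulated nitrate and chlorophyll from micrograms per
#' litre to model units. Chlorophyll converts by identity (1 ug l^-1 =
#' 1 mg m^-3). The nitrate column's mass basis is ambiguous, so it must be
#' chosen: \code{"nitrogen-mass"} (default) divides by the molar mass of N
#' (14.007 g mol^-1), \code{"nitrate-mass"} by that of NO3^- (62.004 g
#' mol^-1), giving mmol N m^-3 either way.
#'
#' @param name river name as in \code{\link{river_table}}
#' @param interpretation \code{"nitrogen-mass"} or \code{"nitrate-mass"}
#' @return list with \code{nitrate} (mmol N m^-3) and \code{chlorophyll}
#'   (mg m^-3)
#' @export
#' @examples
#' river_concentrations("Douro")  # 88.5/14.007 mmol N m^-3, 5.4 mg m^-3
river_concentrations <- function(name,
                                 interpretation = c("nitrogen-mass",
                                                    "nitrate-mass")) {
  interpretation <- match.arg(interpretation)
  tab <- river_table()
  i <- match(name, tab$river)
  if (is.na(i))
    stop("unknown river '", name, "'; known: ",
         paste(tab$river, collapse = ", "), call. = FALSE)
  molar <- if (interpretation == "nitrogen-mass") 14.007 else 62.004
  list(nitrate = tab$nitrate_ug_per_l[i] / molar,   # ug/l = mg/m^3; /g/mol -> mmol/m^3
       chlorophyll = tab$chlorophyll_ug_per_l[i])
}

#' Synthetic satellite-like observation series
#'
#' Test double for remotely sensed time series: truth plus Gaussian noise,
#' with a fraction of samples knocked out as missing (cloud gaps).
#' Deterministic for a given seed; the caller's RNG state is left untouched.
#'
#' @param truth numeric vector of true values
#' @param noise_sd standard deviation of the additive Gaussian noise
#' @param gap_fraction fraction of samples set to NA, in [0, 1)
#' @param seed RNG seed
#' @return numeric vector like \code{truth} with noise and NA gaps
#' @export
synth_obs <- function(truth, noise_sd = 0, gap_fraction = 0, seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (gap_fraction < 0 || gap_fraction >= 1)
    stop("gap_fraction must be in [0, 1)", call. = FALSE)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  obs <- truth + rnorm(length(truth), sd = noise_sd)
  if (gap_fraction > 0) {
    ngap <- floor(gap_fraction * length(truth))
    if (ngap > 0) obs[sample.int(length(truth), ngap)] <- NA_real_
  }
  obs
}
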