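#' Paired model/observation series
#'
#' Container for skill statistics: timestamps, modelled and observed values
#' in the same units, and a validity mask. Pairs where either value is
#' missing are masked out.
#'
#' @param t timestamps (any numeric or time type)
#' @param model modelled values
#' @param obs observed values
#' @return object of class \code{skill_series}
#' @export
skill_series <- function(t, model, obs) {
  if (length(model) != length(obs) || length(t) != length(model))
    stop("t, model and obs must have the same length", call. = FALSE)
  structure(list(t = t, M = as.numeric(model), D = as.numeric(obs),
                 mask = is.finite(model) & is.finite(obs)),
            class = "skill_series")
}

#' Model bias
#'
#' The time-mean model-minus-observation difference
#' \code{MB = mean(M_t - D_t)} over valid pairs. Positive means the model
#' overestimates the observations; the closer to zero, the better.
#'
#' @param series a \code{\link{skill_series}}
#' @return scalar bias in the units of the series
#' @export
#' @examples
#' model_bias(skill_series(1:3, c(1, 2, 4), c(0, 2, 1)))  # 4/3
model_bias <- function(series) {
  if (!inherits(series, "skill_series"))
    stop("model_bias expects a skill_series", call. = FALSE)
  if (!any(series$mask))
    stop("no valid model/observation pairs", call. = FALSE)
  mean(series$M[series$mask] - series$D[series$mask])
}

#' Gridded field
#'
#' A small lon/lat field (or a time stack of them) carried as plain arrays:
#' \code{values} is \code{length(lon) x length(lat)} or
#' \code{length(lon) x length(lat) x n_times}.
#'
#' @param lon,lat coordinate vectors (degrees)
#' @param values matrix or 3-d array of values
#' @param units units label
#' @return object of class \code{gridded_field}
#' @export
gridded_field <- function(lon, lat, values, units = "") {
  d <- dim(values)
  if (is.null(d) || length(d) < 2L || d[1] != length(lon) || d[2] != length(lat))
    stop("values must be lon x lat (x time) with matching coordinates",
         call. = FALSE)
  structure(list(lon = lon, lat = lat, values = values, units = units),
            class = "gridded_field")
}

#' Per-grid-point model bias map
#'
#' Applies \code{\link{model_bias}} at every grid point over the time axis
#' of two co-registered field stacks. Points with no valid pair are NA.
#'
#' @param model_fields,obs_fields \code{\link{gridded_field}} stacks with a
#'   third (time) dimension, on identical grids
#' @return a \code{gridded_field} holding the bias map
#' @export
bias_map <- function(model_fields, obs_fields) {
  if (!isTRUE(all.equal(model_fields$lon, obs_fields$lon)) ||
      !isTRUE(all.equal(model_fields$lat, obs_fields$lat)))
    stop("model and observation grids differ", call. = FALSE)
  M <- model_fields$values; D <- obs_fields$values
  if (!identical(dim(M), dim(D)))
    stop("model and observation stacks differ in shape", call. = FALSE)
  if (length(dim(M)) == 2L) { dim(M) <- c(dim(M), 1L); dim(D) <- dim(M) }
  diffs <- M - D
  bias <- apply(diffs, c(1L, 2L), function(v) {
    v <- v[is.finite(v)]
    if (length(v)) mean(v) else NA_real_
  })
  gridded_field(model_fields$lon, model_fields$lat, bias,
                units = model_fields$units)
}

#' Zero-phase low-pass filter for uniformly sampled series
#'
#' Removes sub-diurnal (tidal/inertial) variability: a Butterworth low-pass
#' filter applied forward and backward (zero phase distortion), default
#' 5th order with a 40-hour cutoff, the usual sub-inertial convention.
#' Interior gaps of at most \code{max_gap} samples are linearly
#' interpolated first; longer gaps split the series into segments that are
#' filtered independently (segments shorter than three filter lengths are
#' an error).
#'
#' @param x values, uniformly sampled
#' @param dt_hours sampling interval (hours)
#' @param cutoff_hours cutoff period (hours); must exceed 2 * dt_hours
#' @param order filter order
#' @param max_gap longest interior NA run to interpolate over (samples)
#' @return filtered series, same length as \code{x} (NA where gaps were too
#'   long to bridge)
#' @export
lowpass <- function(x, dt_hours, cutoff_hours = 40, order = 5, max_gap = 3) {
  if (cutoff_hours <= 2 * dt_hours)
    stop("cutoff must exceed twice the sampling interval", call. = FALSE)
  min_len <- 3L * 3L * (order + 1L)   # three filter lengths, filtfilt padding
  W <- 2 * dt_hours / cutoff_hours    # cutoff frequency / Nyquist
  bf <- signal::butter(order, W, type = "low")
  out <- rep(NA_real_, length(x))
  ok <- is.finite(x)
  # close short interior gaps, then split on the remaining ones
  runs <- rle(ok)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
  bridge <- !runs$values & runs$lengths <= max_gap &
    starts > 1L & ends < length(x)
  for (i in which(bridge)) ok[starts[i]:ends[i]] <- TRUE
  xi <- x
  if (any(ok & !is.finite(x)))
    xi[ok] <- approx(seq_along(x)[is.finite(x)], x[is.finite(x)],
                     xout = seq_along(x)[ok])$y
  runs <- rle(ok)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
  for (i in which(runs$values)) {
    seg <- starts[i]:ends[i]
    if (length(seg) < min_len)
      stop("series segment of ", length(seg),
           " samples is shorter than three filter lengths (", min_len, ")",
           call. = FALSE)
    out[seg] <- filtfilt_padded(bf, xi[seg], cutoff_hours / dt_hours)
  }
  out
}

# Zero-phase filtering with odd-reflection end padding (and demeaning) so
# that edges carry no start-up transient: constants pass through exactly.
filtfilt_padded <- function(bf, x, cutoff_samples) {
  n <- length(x)
  mu <- mean(x)
  xc <- x - mu
  L <- min(n - 1L, ceiling(3 * cutoff_samples))
  head_pad <- 2 * xc[1] - xc[(L + 1L):2L]
  tail_pad <- 2 * xc[n] - xc[(n - 1L):(n - L)]
  y <- signal::filtfilt(bf, c(head_pad, xc, tail_pad))
  y[(L + 1L):(L + n)] + mu
}

#' Disc average of a gridded field
#'
#' Mean, population standard deviation and count of the valid grid points
#' inside a great-circle disc, as used to collocate gridded satellite data
#' with a point: all points within \code{radius_km} (haversine distance on a
#' sphere of radius 6371 km) of the centre.
#'
#' @param field a \code{\link{gridded_field}} (single time slice)
#' @param center_lon,center_lat disc centre (degrees)
#' @param radius_km disc radius (km), default 7
#' @return list with \code{mean}, \code{sd} (population, divide-by-n) and
#'   \code{n}
#' @export
disc_average <- function(field, center_lon, center_lat, radius_km = 7) {
  v <- field$values
  if (length(dim(v)) != 2L)
    stop("disc_average expects a single time slice", call. = FALSE)
  pts <- cbind(lon = rep(field$lon, times = length(field$lat)),
               lat = rep(field$lat, each = length(field$lon)))
  dist_m <- geosphere::distHaversine(pts, c(center_lon, center_lat),
                                     r = 6371000)
  sel <- dist_m <= radius_km * 1000 & is.finite(as.vector(v))
  if (!any(sel)) stop("no valid grid points within the disc", call. = FALSE)
  vals <- as.vector(v)[sel]
  list(mean = mean(vals),
       sd = sqrt(mean((vals - mean(vals))^2)),
       n = length(vals))
}

#' Read a paired model/observation series from CSV
#'
#' Expects columns \code{time}, \code{model}, \code{obs}.
#'
#' @param path CSV path
#' @return a \code{\link{skill_series}}
#' @export
read_skill_csv <- function(path) {
  d <- read.csv(path, comment.char = "#")
  need <- c("time", "model", "obs")
  if (!all(need %in% names(d)))
    stop("skill CSV must have columns time, model, obs", call. = FALSE)
  skill_series(d$time, d$model, d$obs)
}
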