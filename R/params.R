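#' NPZD model parameters
#'
#' Construct the full biological parameter set of the ecosystem model. The
#' defaults are the operational parameter values for the western Iberian
#' shelf configuration, all rates per day.
#'
#' @param k_w light attenuation by seawater (m^-1)
#' @param k_chla light attenuation by chlorophyll (m^-1 (mg Chla m^-3)^-1)
#' @param alpha initial slope of the photosynthesis-irradiance curve
#'   (mg C (mg Chla W m^-2 d)^-1)
#' @param c2n molar carbon-to-nitrogen (Redfield) ratio (mol C (mol N)^-1)
#' @param theta_max maximum cellular chlorophyll:C ratio (mg Chla (mg C)^-1)
#' @param K_N half-saturation for phytoplankton nitrate uptake (mmol N m^-3)
#' @param K_P zooplankton ingestion half-saturation (mmol N m^-3)
#' @param g_max maximum zooplankton grazing rate (d^-1)
#' @param beta zooplankton assimilation coefficient (dimensionless, in (0, 1])
#' @param m_P phytoplankton mortality rate, routed to detritus (d^-1)
#' @param m_Z zooplankton mortality rate, routed to detritus (d^-1)
#' @param e_Z zooplankton excretion rate, routed to nitrate (d^-1)
#' @param r_D detrital mineralisation (nitrification) rate to nitrate (d^-1)
#' @param w_P phytoplankton sinking velocity (m d^-1)
#' @param w_D detritus sinking velocity (m d^-1)
#' @param par_fraction fraction of incident shortwave that is
#'   photosynthetically available at the surface (dimensionless, in (0, 1))
#' @param mu0 maximum phytoplankton growth rate at 0 degrees C (d^-1)
#' @param a_T base of the Eppley temperature dependence of maximum growth
#'   (dimensionless per degree C); \code{a_T = 1} switches the dependence off
#'
#' @return an object of class \code{bio_params}: a validated named list.
#' @export
#' @examples
#' p <- bio_params()
#' p$K_N              # 1.5 mmol N m^-3
#' bio_params(g_max = 0.5)$g_max
bio_params <- function(k_w = 0.04, k_chla = 0.024, alpha = 1.0, c2n = 6.625,
                       theta_max = 0.03, K_N = 1.5, K_P = 1.0, g_max = 0.9,
                       beta = 0.75, m_P = 0.03, m_Z = 0.1, e_Z = 0.1,
                       r_D = 0.05, w_P = 0.5, w_D = 5, par_fraction = 0.43,
                       mu0 = 0.59, a_T = 1.066) {
  p <- list(k_w = k_w, k_chla = k_chla, alpha = alpha, c2n = c2n,
            theta_max = theta_max, K_N = K_N, K_P = K_P, g_max = g_max,
            beta = beta, m_P = m_P, m_Z = m_Z, e_Z = e_Z, r_D = r_D,
            w_P = w_P, w_D = w_D, par_fraction = par_fraction,
            mu0 = mu0, a_T = a_T)
  validate_bio_params(p)
  structure(p, class = "bio_params")
}

validate_bio_params <- function(p) {
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1L && is.finite(x),
                logical(1))
  if (!all(num))
    stop("non-numeric or non-scalar parameter value: ",
         paste(names(p)[!num], collapse = ", "), call. = FALSE)
  nonneg <- c("k_w", "k_chla", "alpha", "c2n", "K_P", "g_max", "m_P", "m_Z",
              "e_Z", "r_D", "w_P", "w_D", "mu0", "a_T")
  bad <- nonneg[vapply(nonneg, function(k) p[[k]] < 0, logical(1))]
  if (length(bad))
    stop("negative rate or velocity: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (p$K_N <= 0) stop("K_N must be > 0", call. = FALSE)
  if (p$theta_max <= 0) stop("theta_max must be > 0", call. = FALSE)
  if (p$beta <= 0 || p$beta > 1) stop("beta must be in (0, 1]", call. = FALSE)
  if (p$par_fraction <= 0 || p$par_fraction >= 1)
    stop("par_fraction must be in (0, 1)", call. = FALSE)
  invisible(p)
}

#' @export
print.bio_params <- function(x, ...) {
  cat("NPZD biological parameters (rates per day):\n")
  for (k in names(x)) cat(sprintf("  %-12s %g\n", k, x[[k]]))
  invisible(x)
}

#' Load NPZD parameters from a key/value file
#'
#' Reads a flat key/value document (one \code{key = value} or
#' \code{key: value} pair per line; \code{#} comments and blank lines
#' ignored). Keys must be names of \code{\link{bio_params}} fields; missing
#' keys are filled from the defaults. Unknown keys and non-numeric values are
#' rejected.
#'
#' @param path path to the parameter file; an empty file yields the defaults
#' @return a \code{bio_params} object
#' @export
load_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  defaults <- bio_params()
  if (!length(lines)) return(defaults)
  parts <- strsplit(lines, "[=:]", fixed = FALSE)
  ok <- vapply(parts, length, integer(1)) == 2L
  if (!all(ok))
    stop("malformed parameter line(s): ", paste(lines[!ok], collapse = "; "),
         call. = FALSE)
  keys <- trimws(vapply(parts, `[`, character(1), 1L))
  vals <- trimws(vapply(parts, `[`, character(1), 2L))
  unknown <- setdiff(keys, names(defaults))
  if (length(unknown))
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(keys))
    stop("duplicate parameter key(s): ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "), call. = FALSE)
  numvals <- suppressWarnings(as.numeric(vals))
  if (anyNA(numvals))
    stop("non-numeric value for key(s): ",
         paste(keys[is.na(numvals)], collapse = ", "), call. = FALSE)
  p <- unclass(defaults)
  p[keys] <- as.list(numvals)
  validate_bio_params(p)
  structure(p, class = "bio_params")
}
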