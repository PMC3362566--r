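#' @useDynLib npzdcolumn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx rnorm
#' @importFrom utils read.csv write.csv
NULL

# mg C per mmol N at a given Redfield ratio (12.011 g C per mol C)
carbon_per_nitrogen <- function(params) params$c2n * 12.011

#' Ecosystem state of the four nitrogen compartments plus chlorophyll
#'
#' All compartments are in mmol N m^-3; chlorophyll a is in mg m^-3. Each
#' argument may be a scalar (box model) or a vector over column cells.
#' Chlorophyll defaults to a cellular chlorophyll:C ratio \code{theta0} times
#' the phytoplankton carbon biomass.
#'
#' @param N nitrate
#' @param P phytoplankton
#' @param Z zooplankton
#' @param D detritus (the operational initialisation uses 0.02 mmol N m^-3)
#' @param Chl chlorophyll a (mg m^-3); if \code{NULL}, derived from
#'   \code{theta0}
#' @param theta0 initial chlorophyll:C ratio used when \code{Chl} is absent
#' @param params a \code{\link{bio_params}} object (for the C:N ratio and the
#'   \code{theta <= theta_max} validity check)
#' @return an object of class \code{eco_state}: list of equal-length numeric
#'   vectors N, P, Z, D, Chl.
#' @export
eco_state <- function(N, P, Z, D = 0.02, Chl = NULL, theta0 = 0.02,
                      params = bio_params()) {
  n <- max(length(N), length(P), length(Z), length(D))
  N <- rep_len(as.numeric(N), n); P <- rep_len(as.numeric(P), n)
  Z <- rep_len(as.numeric(Z), n); D <- rep_len(as.numeric(D), n)
  if (is.null(Chl)) Chl <- theta0 * carbon_per_nitrogen(params) * P
  Chl <- rep_len(as.numeric(Chl), n)
  s <- structure(list(N = N, P = P, Z = Z, D = D, Chl = Chl),
                 class = "eco_state")
  validate_eco_state(s, params)
  s
}

validate_eco_state <- function(s, params = bio_params(), tol = 1e-9) {
  for (k in c("N", "P", "Z", "D", "Chl")) {
    if (anyNA(s[[k]]) || any(s[[k]] < 0))
      stop("negative or missing ", k, " in ecosystem state", call. = FALSE)
  }
  th <- theta_diag(s, params)
  bad <- !is.na(th) & (th <= 0 | th > params$theta_max * (1 + tol))
  if (any(bad))
    stop("chlorophyll:C ratio outside (0, theta_max] in ",
         sum(bad), " cell(s)", call. = FALSE)
  invisible(s)
}

#' @export
print.eco_state <- function(x, ...) {
  n <- length(x$N)
  cat(sprintf("ecosystem state over %d cell(s) (mmol N m^-3; Chl mg m^-3)\n", n))
  print(vapply(unclass(x), function(v) c(min = min(v), max = max(v)),
               numeric(2)))
  invisible(x)
}

#' Diagnostic chlorophyll:C ratio
#'
#' \code{theta = Chl / (P * c2n * 12.011)}, the ratio of chlorophyll a mass to
#' phytoplankton carbon biomass. \code{NA} where \code{P = 0}.
#'
#' @param state an \code{\link{eco_state}}
#' @param params a \code{\link{bio_params}}
#' @return numeric vector of theta (mg Chla (mg C)^-1)
#' @export
theta_diag <- function(state, params = bio_params()) {
  ifelse(state$P > 0, state$Chl / (state$P * carbon_per_nitrogen(params)), NA_real_)
}

#' Nitrate limitation factor of phytoplankton uptake
#'
#' Michaelis-Menten limitation \code{N / (K_N + N)}, in \code{[0, 1)}.
#'
#' @param N nitrate concentration (mmol N m^-3), vectorised
#' @param K_N half-saturation constant (mmol N m^-3)
#' @return dimensionless limitation factor
#' @export
#' @examples
#' nutrient_limitation(1.5, 1.5)  # 0.5 at half-saturation
nutrient_limitation <- function(N, K_N = bio_params()$K_N) {
  if (any(N < 0)) stop("negative nitrate concentration", call. = FALSE)
  if (K_N <= 0) stop("K_N must be > 0", call. = FALSE)
  N / (K_N + N)
}

#' Temperature-dependent maximum phytoplankton growth rate
#'
#' Eppley-type dependence \code{mu0 * a_T^T}. With \code{a_T = 1} growth is
#' temperature independent.
#'
#' @param T_C temperature (degrees C), vectorised
#' @param params a \code{\link{bio_params}}
#' @return maximum specific growth rate (d^-1)
#' @export
max_growth <- function(T_C, params = bio_params()) {
  params$mu0 * params$a_T^T_C
}

#' Realised phytoplankton specific growth rate
#'
#' Geider-type growth: the nutrient- and temperature-limited maximum
#' \code{mu_NT = max_growth(T) * nutrient_limitation(N)} modulated by the
#' light-limitation factor \code{1 - exp(-alpha * PAR * theta / mu_NT)},
#' where \code{theta} is the current cellular chlorophyll:C ratio. Linear in
#' PAR when light-limited (\code{mu -> alpha * PAR * theta}), saturating to
#' \code{mu_NT} at high light. Zero where \code{P = 0}.
#'
#' @param state an \code{\link{eco_state}}
#' @param env list with fields \code{T} (deg C) and \code{PAR} (W m^-2),
#'   scalars or per-cell vectors
#' @param params a \code{\link{bio_params}}
#' @return specific growth rate mu (d^-1), per cell
#' @export
phyto_growth <- function(state, env, params = bio_params()) {
  if (any(env$PAR < 0)) stop("negative PAR", call. = FALSE)
  mu_NT <- max_growth(env$T, params) * nutrient_limitation(state$N, params$K_N)
  th <- theta_diag(state, params)
  x <- params$alpha * env$PAR * ifelse(is.na(th), 0, th)
  mu <- ifelse(mu_NT > 0 & x > 0, mu_NT * (1 - exp(-x / pmax(mu_NT, .Machine$double.xmin))), 0)
  ifelse(state$P > 0, mu, 0)
}

#' Chlorophyll synthesis ratio
#'
#' The fraction of photosynthetically fixed carbon allocated to chlorophyll a
#' biosynthesis: \code{rho = theta_max * mu / (alpha * PAR * theta)}, clamped
#' to \code{[0, theta_max]}. In the light-limited limit
#' (\code{mu -> alpha * PAR * theta}) the ratio tends to \code{theta_max};
#' that limit is returned explicitly when the denominator vanishes, avoiding
#' 0/0.
#'
#' @param mu realised specific growth rate (d^-1)
#' @param theta current chlorophyll:C ratio (mg Chla (mg C)^-1)
#' @param PAR photosynthetically available radiation (W m^-2)
#' @param params a \code{\link{bio_params}}
#' @return rho_chl (mg Chla (mg C)^-1), per cell
#' @export
chl_synthesis_ratio <- function(mu, theta, PAR, params = bio_params()) {
  denom <- params$alpha * PAR * theta
  rho <- ifelse(denom > 0, params$theta_max * mu / pmax(denom, .Machine$double.xmin),
                params$theta_max)
  pmin(pmax(rho, 0), params$theta_max)
}

#' Zooplankton specific ingestion rate
#'
#' Holling type II (Michaelis-Menten) functional response
#' \code{g_max * P / (K_P + P)}, per unit zooplankton biomass.
#'
#' @param P phytoplankton concentration (mmol N m^-3), vectorised
#' @param params a \code{\link{bio_params}}
#' @return specific ingestion rate (d^-1)
#' @export
#' @examples
#' grazing(1)      # half of g_max at the half-saturation prey level
#' grazing(1e6)    # approaches g_max = 0.9
grazing <- function(P, params = bio_params()) {
  if (any(P < 0)) stop("negative phytoplankton concentration", call. = FALSE)
  params$g_max * P / (params$K_P + P)
}

# The six inter-compartment flux rates (per day, units of donor concentration
# per day), vectorised over cells. Used by both the instantaneous tendency
# (sms) and the positivity-preserving stepper.
npzd_fluxes <- function(state, env, params) {
  mu <- phyto_growth(state, env, params)
  U <- mu * state$P                      # N -> P (uptake)
  G <- grazing(state$P, params) * state$Z  # P -> Z/D (grazing)
  list(U = U, G = G,
       mortP = params$m_P * state$P,     # P -> D
       mortZ = params$m_Z * state$Z,     # Z -> D
       excrZ = params$e_Z * state$Z,     # Z -> N
       minD = params$r_D * state$D,      # D -> N
       mu = mu)
}

#' Sink-minus-source biological tendencies
#'
#' Instantaneous tendencies (per day) of the four nitrogen compartments and
#' chlorophyll. With uptake \code{U = mu * P} and grazing
#' \code{G = grazing(P) * Z}:
#' \deqn{dN/dt = -U + e_Z Z + r_D D}
#' \deqn{dP/dt = U - G - m_P P}
#' \deqn{dZ/dt = \beta G - m_Z Z - e_Z Z}
#' \deqn{dD/dt = (1-\beta) G + m_P P + m_Z Z - r_D D}
#' Chlorophyll gains with the synthesis ratio \code{rho_chl} per unit carbon
#' fixed and loses in proportion to phytoplankton nitrogen losses at the
#' current theta, so losses never alter theta. The four nitrogen tendencies
#' sum to zero exactly.
#'
#' @param state an \code{\link{eco_state}}
#' @param env list with \code{T} (deg C) and \code{PAR} (W m^-2)
#' @param params a \code{\link{bio_params}}
#' @return list of tendencies \code{N, P, Z, D, Chl} (units of the field per
#'   day)
#' @export
sms <- function(state, env, params = bio_params()) {
  f <- npzd_fluxes(state, env, params)
  cn <- carbon_per_nitrogen(params)
  th <- theta_diag(state, params)
  th0 <- ifelse(is.na(th), 0, th)
  rho <- chl_synthesis_ratio(f$mu, th0, rep_len(as.numeric(env$PAR), length(th0)),
                             params)
  list(
    N = -f$U + f$excrZ + f$minD,
    P = f$U - f$G - f$mortP,
    Z = params$beta * f$G - f$mortZ - f$excrZ,
    D = (1 - params$beta) * f$G + f$mortP + f$mortZ - f$minD,
    Chl = rho * f$U * cn - th0 * cn * (f$G + f$mortP)
  )
}

#' Advance the biology by one positivity-preserving step
#'
#' Conservative Patankar-type Euler step: each compartment's outgoing fluxes
#' are damped implicitly by the factor \code{1 / (1 + dt * out / X)} and the
#' realised (damped) flux is what recipients receive, so total nitrogen
#' \code{N + P + Z + D} is conserved to machine precision and no compartment
#' can be driven negative. Chlorophyll gains follow the realised uptake flux
#' and losses follow the realised phytoplankton losses at the current theta.
#'
#' @param state an \code{\link{eco_state}}
#' @param env list with \code{T} and \code{PAR}
#' @param params a \code{\link{bio_params}}
#' @param dt_days time step (days)
#' @return updated \code{eco_state}
#' @export
sms_step <- function(state, env, params, dt_days) {
  f <- npzd_fluxes(state, env, params)
  cn <- carbon_per_nitrogen(params)
  th <- theta_diag(state, params)
  th0 <- ifelse(is.na(th), 0, th)
  rho <- chl_synthesis_ratio(f$mu, th0, rep_len(as.numeric(env$PAR), length(th0)),
                             params)

  damp <- function(X, out) ifelse(out > 0, X / (X + dt_days * out), 1)
  sN <- damp(state$N, f$U)
  sP <- damp(state$P, f$G + f$mortP)
  sZ <- damp(state$Z, f$mortZ + f$excrZ)
  sD <- damp(state$D, f$minD)

  U <- f$U * sN
  G <- f$G * sP; mortP <- f$mortP * sP
  mortZ <- f$mortZ * sZ; excrZ <- f$excrZ * sZ
  minD <- f$minD * sD

  N <- state$N + dt_days * (-U + excrZ + minD)
  P <- state$P + dt_days * (U - G - mortP)
  Z <- state$Z + dt_days * (params$beta * G - mortZ - excrZ)
  D <- state$D + dt_days * ((1 - params$beta) * G + mortP + mortZ - minD)
  Chl <- state$Chl + dt_days * (rho * U * cn - th0 * cn * (G + mortP))

  structure(list(N = pmax(N, 0), P = pmax(P, 0), Z = pmax(Z, 0),
                 D = pmax(D, 0), Chl = pmax(Chl, 0)),
            class = "eco_state")
}
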