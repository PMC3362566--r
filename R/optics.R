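#' Surface photosynthetically available radiation
#'
#' PAR at the surface is a fixed fraction (default 43 percent) of the
#' incident shortwave radiation.
#'
#' @param I0 incident shortwave radiation (W m^-2), vectorised
#' @param params a \code{\link{bio_params}} (uses \code{par_fraction})
#' @return surface PAR (W m^-2)
#' @export
#' @examples
#' surface_par(100)  # 43
surface_par <- function(I0, params = bio_params()) {
  if (any(I0 < 0)) stop("negative incident radiation", call. = FALSE)
  params$par_fraction * I0
}

#' PAR profile down the column
#'
#' Downward cell-by-cell integration of exponential attenuation with local
#' coefficient \code{k(z) = k_w + k_chla * Chl(z)}: absorption by seawater
#' plus self-shading by chlorophyll. PAR at a cell center accounts for
#' attenuation over the half cell above the center, so with zero chlorophyll
#' the value at every cell edge matches the analytic exponential exactly.
#'
#' @param PAR0 surface PAR (W m^-2)
#' @param chl per-cell chlorophyll (mg m^-3)
#' @param grid a \code{\link{column_grid}}
#' @param params a \code{\link{bio_params}}
#' @return list with \code{PAR0}, \code{PAR_at_center} (per cell) and
#'   \code{PAR_at_edges} (per interface), all W m^-2
#' @export
par_profile <- function(PAR0, chl, grid, params = bio_params()) {
  if (PAR0 < 0) stop("negative surface PAR", call. = FALSE)
  if (any(chl < 0)) stop("negative chlorophyll", call. = FALSE)
  k <- params$k_w + params$k_chla * chl          # per cell, m^-1
  tau <- k * grid$dz                             # optical thickness per cell
  edge <- PAR0 * exp(-cumsum(c(0, tau)))         # at interfaces
  center <- edge[-length(edge)] * exp(-tau / 2)  # half-cell attenuation
  list(PAR0 = PAR0, PAR_at_center = center, PAR_at_edges = edge)
}
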