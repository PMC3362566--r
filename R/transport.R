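# Interface exchange coefficients Kv_j / (z_center_{j+1} - z_center_j) for
# the n-1 interior interfaces; Kv may be a scalar or a length n+1 vector at
# interfaces (surface and bottom entries unused: zero-flux boundaries).
interface_coeff <- function(Kv, grid) {
  n <- grid$n
  if (n == 1L) return(numeric(0))
  if (length(Kv) == 1L) Kv <- rep(Kv, n + 1L)
  if (length(Kv) != n + 1L)
    stop("Kv must be scalar or one value per interface (n+1)", call. = FALSE)
  if (any(Kv < 0)) stop("negative diffusivity", call. = FALSE)
  Kv[2:n] / diff(grid$z_centers)
}

#' Implicit vertical diffusion of a tracer
#'
#' One backward-Euler (unconditionally stable) step of vertical diffusion
#' with zero-flux boundaries at surface and bottom, solved with the Thomas
#' algorithm. The flux-form discretisation conserves the column inventory
#' \code{sum(conc * dz)} to solver round-off and satisfies a maximum
#' principle (no new extrema).
#'
#' @param conc per-cell tracer vector, or a matrix with one tracer per column
#' @param Kv vertical eddy diffusivity (m^2 s^-1): scalar or one value per
#'   cell interface (length \code{n + 1})
#' @param grid a \code{\link{column_grid}}
#' @param dt time step (s)
#' @return diffused tracer, same shape as \code{conc}
#' @export
diffuse_tracer <- function(conc, Kv, grid, dt) {
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  n <- grid$n
  vec <- is.null(dim(conc))
  m <- if (vec) matrix(conc, ncol = 1L) else as.matrix(conc)
  if (nrow(m) != n) stop("tracer length does not match grid", call. = FALSE)
  a <- interface_coeff(Kv, grid)
  if (n == 1L || all(a == 0)) return(conc)
  r <- dt / grid$dz
  lower <- c(0, -r[-1L] * a)
  upper <- c(-r[-n] * a, 0)
  diag <- 1 - lower - upper
  out <- .solve_tridiag(lower, diag, upper, m)
  if (vec) drop(out) else {dimnames(out) <- dimnames(m); out}
}

# One conservative upwind pass shared by sinking (downward) and upwelling
# (upward). Returns the updated field; sub-steps internally to respect the
# CFL limit w * dt_sub <= min(dz).
upwind_advect <- function(conc, w_ms, grid, dt, downward, boundary_in = 0,
                          open_outflow = FALSE) {
  n <- grid$n
  if (w_ms == 0 || dt <= 0) return(conc)
  nsub <- max(1L, ceiling(w_ms * dt / min(grid$dz)))
  h <- (dt / nsub) * w_ms
  for (s in seq_len(nsub)) {
    if (downward) {
      inflow <- c(0, conc[-n])                 # from the cell above
      outflow <- conc
      if (!open_outflow) outflow[n] <- 0       # retain: bottom keeps its load
    } else {
      inflow <- c(conc[-1L], boundary_in)      # from the cell below / deep BC
      outflow <- conc                          # surface cell exports upward
    }
    conc <- conc + (h / grid$dz) * (inflow - outflow)
  }
  conc
}

#' Downward sinking of a particulate tracer
#'
#' First-order upwind downward advection at a constant sinking velocity,
#' sub-stepped internally so the CFL condition holds. With
#' \code{bottom_flux_mode = "retain"} the flux through the lowest interface
#' is suppressed and sinking matter accumulates in the bottom cell (closed
#' budget); with \code{"export"} it leaves the column.
#'
#' @param conc per-cell tracer vector
#' @param w_sink sinking velocity (m d^-1, positive down)
#' @param grid a \code{\link{column_grid}}
#' @param dt time step (s)
#' @param bottom_flux_mode \code{"retain"} (default) or \code{"export"}
#' @return advected tracer vector
#' @export
sink_tracer <- function(conc, w_sink, grid, dt,
                        bottom_flux_mode = c("retain", "export")) {
  bottom_flux_mode <- match.arg(bottom_flux_mode)
  if (w_sink < 0) stop("sinking velocity must be >= 0", call. = FALSE)
  upwind_advect(conc, w_sink / 86400, grid, dt, downward = TRUE,
                open_outflow = bottom_flux_mode == "export")
}

#' Prescribed upwelling of a tracer
#'
#' First-order upwind upward advection at a prescribed vertical velocity.
#' The deep boundary supplies water at concentration \code{deep_conc}
#' (typically the deep nitrate reservoir; 0 for other tracers) and the
#' surface cell exports upward out of the column, so the column inventory
#' changes only by these boundary fluxes.
#'
#' @param conc per-cell tracer vector
#' @param w_up upwelling velocity (m d^-1, positive up)
#' @param grid a \code{\link{column_grid}}
#' @param dt time step (s)
#' @param deep_conc concentration entering through the bottom boundary
#' @return advected tracer vector
#' @export
upwell_tracer <- function(conc, w_up, grid, dt, deep_conc = 0) {
  if (w_up < 0) stop("upwelling velocity must be >= 0", call. = FALSE)
  upwind_advect(conc, w_up / 86400, grid, dt, downward = FALSE,
                boundary_in = deep_conc)
}
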