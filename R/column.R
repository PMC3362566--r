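#' One operator-split time step of the coupled column model
#'
#' Fixed splitting order: optics (PAR profile from the current chlorophyll),
#' biology (positivity-preserving SMS step per cell), sinking of
#' phytoplankton, chlorophyll and detritus, prescribed upwelling, implicit
#' vertical diffusion. Light sees the chlorophyll of the current step;
#' mixing comes last to smooth splitting artifacts.
#'
#' @param state an \code{\link{eco_state}} over the grid cells
#' @param grid a \code{\link{column_grid}}
#' @param params a \code{\link{bio_params}}
#' @param forcing list with fields \code{I0} (incident shortwave, W m^-2),
#'   \code{T} (deg C, scalar or per cell), \code{Kv} (m^2 s^-1, scalar or per
#'   interface), \code{w_up} (m d^-1, positive up), \code{deep_N} (mmol N
#'   m^-3 entering through the bottom under upwelling) and optionally
#'   \code{bottom_flux_mode}
#' @param dt time step (s)
#' @return list with the updated \code{state} and the light profile
#'   \code{par} used for the biology
#' @export
column_step <- function(state, grid, params, forcing, dt) {
  bfm <- if (is.null(forcing$bottom_flux_mode)) "retain" else forcing$bottom_flux_mode
  lp <- par_profile(surface_par(forcing$I0, params), state$Chl, grid, params)
  env <- list(T = forcing$T, PAR = lp$PAR_at_center)
  s <- sms_step(state, env, params, dt / 86400)

  if (grid$n > 1L || identical(bfm, "export")) {
    s$P <- sink_tracer(s$P, params$w_P, grid, dt, bfm)
    s$Chl <- sink_tracer(s$Chl, params$w_P, grid, dt, bfm)
    s$D <- sink_tracer(s$D, params$w_D, grid, dt, bfm)
  }
  w_up <- if (is.null(forcing$w_up)) 0 else forcing$w_up
  if (w_up > 0) {
    deep_N <- if (is.null(forcing$deep_N)) 0 else forcing$deep_N
    s$N <- upwell_tracer(s$N, w_up, grid, dt, deep_conc = deep_N)
    s$P <- upwell_tracer(s$P, w_up, grid, dt)
    s$Z <- upwell_tracer(s$Z, w_up, grid, dt)
    s$D <- upwell_tracer(s$D, w_up, grid, dt)
    s$Chl <- upwell_tracer(s$Chl, w_up, grid, dt)
  }
  Kv <- if (is.null(forcing$Kv)) 0 else forcing$Kv
  if (grid$n > 1L && any(Kv > 0)) {
    m <- diffuse_tracer(cbind(N = s$N, P = s$P, Z = s$Z, D = s$D, Chl = s$Chl),
                        Kv, grid, dt)
    s <- structure(list(N = pmax(m[, 1L], 0), P = pmax(m[, 2L], 0),
                        Z = pmax(m[, 3L], 0), D = pmax(m[, 4L], 0),
                        Chl = pmax(m[, 5L], 0)),
                   class = "eco_state")
  }
  check_state_sane(s)
  list(state = s, par = lp)
}

check_state_sane <- function(s) {
  for (k in c("N", "P", "Z", "D", "Chl")) {
    v <- s[[k]]
    if (anyNA(v) || any(!is.finite(v)))
      stop("non-finite ", k, " in cell(s) ",
           paste(which(!is.finite(v)), collapse = ","),
           " after a column step", call. = FALSE)
    if (any(v < -1e-12))
      stop("negative ", k, " in cell(s) ",
           paste(which(v < -1e-12), collapse = ","),
           " after a column step", call. = FALSE)
  }
  invisible(s)
}

#' Total nitrogen inventory of a column state
#'
#' \code{sum((N + P + Z + D) * dz)} in mmol N m^-2; the conserved quantity of
#' a closed (retain, no upwelling) configuration.
#'
#' @param state an \code{\link{eco_state}}
#' @param grid a \code{\link{column_grid}}
#' @return scalar inventory (mmol N m^-2)
#' @export
nitrogen_inventory <- function(state, grid) {
  sum((state$N + state$P + state$Z + state$D) * grid$dz)
}

#' Default initial profile for upwelling scenarios
#'
#' Oligotrophic summer stratification: nutrient-poor surface layer over a
#' nutricline ramping to the deep nitrate value between 20 and 60 m, a small
#' phytoplankton and zooplankton seed concentrated in the upper 50 m, and
#' detritus constant at 0.02 mmol N m^-3.
#'
#' @param grid a \code{\link{column_grid}}
#' @param params a \code{\link{bio_params}}
#' @param N_surf surface nitrate (mmol N m^-3)
#' @param N_deep deep nitrate (mmol N m^-3)
#' @param P0,Z0 upper-layer plankton seed (mmol N m^-3)
#' @param D0 detritus (mmol N m^-3)
#' @param theta0 initial chlorophyll:C ratio
#' @return an \code{\link{eco_state}}
#' @export
init_profile <- function(grid, params = bio_params(), N_surf = 0.5,
                         N_deep = 10, P0 = 0.05, Z0 = 0.02, D0 = 0.02,
                         theta0 = 0.02) {
  z <- grid$z_centers
  frac <- pmin(pmax((z - 20) / 40, 0), 1)       # 0 above 20 m, 1 below 60 m
  N <- N_surf + (N_deep - N_surf) * frac
  P <- ifelse(z <= 50, P0, P0 / 10)
  Z <- ifelse(z <= 50, Z0, Z0 / 10)
  eco_state(N = N, P = P, Z = Z, D = D0, theta0 = theta0, params = params)
}

#' Run the 1-D column model over a forcing scenario
#'
#' Integrates the coupled optics/biology/transport column with fixed step
#' \code{dt}, interpolating the scenario series linearly in time. Records a
#' surface time series (with the nitrogen inventory diagnostic) at
#' \code{output_every_days} and full-depth snapshots of all tracers, theta
#' and PAR at \code{fields_every_days}. Deterministic given its arguments.
#'
#' @param scenario an \code{\link{upwelling_event_scenario}} or compatible
#'   scenario object
#' @param grid a \code{\link{column_grid}}
#' @param params a \code{\link{bio_params}}
#' @param init initial \code{\link{eco_state}}; default
#'   \code{\link{init_profile}} with the scenario's deep nitrate
#' @param dt time step (s)
#' @param t_end_days end of the integration (days); must not exceed the
#'   scenario span
#' @param output_every_days cadence of the surface series (days)
#' @param fields_every_days cadence of full-depth snapshots (days)
#' @param bottom_flux_mode \code{"retain"} (closed budget) or \code{"export"}
#' @param river optional list \code{(nitrate, chlorophyll, tau_days)}: the
#'   surface cell is nudged toward the river concentrations on timescale
#'   \code{tau_days} (volume-flux-free source)
#' @return an object of class \code{npzd_run} with elements \code{surface}
#'   (data.frame), \code{fields} (list of depth-time matrices), \code{grid},
#'   \code{params}, \code{config}
#' @export
run_column <- function(scenario, grid = column_grid(), params = bio_params(),
                       init = NULL, dt = 300, t_end_days = NULL,
                       output_every_days = 0.25, fields_every_days = 1,
                       bottom_flux_mode = "retain", river = NULL) {
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  span <- max(scenario$t)
  if (is.null(t_end_days)) t_end_days <- span
  if (t_end_days > span + 1e-9)
    stop("scenario (", span, " d) shorter than t_end (", t_end_days, " d)",
         call. = FALSE)
  if (is.null(init))
    init <- init_profile(grid, params, N_deep = scenario$deep_N)

  nstep <- ceiling(t_end_days * 86400 / dt)
  tmid <- (seq_len(nstep) - 0.5) * dt / 86400
  interp <- function(y) approx(scenario$t, y, xout = pmin(tmid, span),
                               rule = 2)$y
  I0s <- interp(scenario$I0); Ts <- interp(scenario$T)
  w_ups <- interp(scenario$w_up); kv_mls <- interp(scenario$kv_ml)
  kv_mask <- as.numeric(grid$z_edges <= scenario$mld_m)

  out_stride <- max(1L, round(output_every_days * 86400 / dt))
  fld_stride <- max(1L, round(fields_every_days * 86400 / dt))

  state <- init
  lp <- par_profile(surface_par(I0s[1], params), state$Chl, grid, params)
  surf <- vector("list", nstep %/% out_stride + 2L); is <- 1L
  flds <- vector("list", nstep %/% fld_stride + 2L); ifl <- 1L
  snap_surface <- function(k) {
    th <- theta_diag(state, params)
    data.frame(time_days = k * dt / 86400, N = state$N[1], P = state$P[1],
               Z = state$Z[1], D = state$D[1], Chl = state$Chl[1],
               theta = th[1], PAR0 = lp$PAR0,
               total_N = nitrogen_inventory(state, grid))
  }
  snap_fields <- function(k) {
    list(time_days = k * dt / 86400, N = state$N, P = state$P, Z = state$Z,
         D = state$D, Chl = state$Chl, theta = theta_diag(state, params),
         PAR = lp$PAR_at_center)
  }
  surf[[is]] <- snap_surface(0L); is <- is + 1L
  flds[[ifl]] <- snap_fields(0L); ifl <- ifl + 1L

  for (k in seq_len(nstep)) {
    forcing <- list(I0 = I0s[k], T = Ts[k], w_up = w_ups[k],
                    Kv = scenario$kv_bg + (kv_mls[k] - scenario$kv_bg) * kv_mask,
                    deep_N = scenario$deep_N, bottom_flux_mode = bottom_flux_mode)
    res <- column_step(state, grid, params, forcing, dt)
    state <- res$state; lp <- res$par
    if (!is.null(river)) {
      relax <- dt / 86400 / river$tau_days
      rN <- river$nitrate; rC <- river$chlorophyll
      state$N[1] <- state$N[1] + relax * (rN - state$N[1])
      cn <- carbon_per_nitrogen(params)
      state$P[1] <- state$P[1] + relax * (rC / (0.02 * cn) - state$P[1])
      state$Chl[1] <- state$Chl[1] + relax * (rC - state$Chl[1])
    }
    if (k %% out_stride == 0L || k == nstep) {
      surf[[is]] <- snap_surface(k); is <- is + 1L
    }
    if (k %% fld_stride == 0L || k == nstep) {
      flds[[ifl]] <- snap_fields(k); ifl <- ifl + 1L
    }
  }

  surface <- do.call(rbind, surf[seq_len(is - 1L)])
  surface <- surface[!duplicated(surface$time_days), , drop = FALSE]
  flds <- flds[seq_len(ifl - 1L)]
  flds <- flds[!duplicated(vapply(flds, `[[`, numeric(1), "time_days"))]
  fields <- list(
    time_days = vapply(flds, `[[`, numeric(1), "time_days"),
    z_centers = grid$z_centers)
  for (k in c("N", "P", "Z", "D", "Chl", "theta", "PAR"))
    fields[[k]] <- vapply(flds, `[[`, numeric(grid$n), k)
  structure(list(surface = surface, fields = fields, grid = grid,
                 params = params, final_state = state,
                 config = list(dt = dt, t_end_days = t_end_days,
                               bottom_flux_mode = bottom_flux_mode,
                               scenario = scenario$description)),
            class = "npzd_run")
}

#' @export
print.npzd_run <- function(x, ...) {
  s <- x$surface
  cat(sprintf("NPZD column run: %g days, %d cells, dt = %g s\n",
              max(s$time_days), x$grid$n, x$config$dt))
  cat(sprintf("  surface Chl: start %.3f, max %.3f (day %.1f), end %.3f mg m^-3\n",
              s$Chl[1], max(s$Chl), s$time_days[which.max(s$Chl)],
              s$Chl[nrow(s)]))
  dN <- (s$total_N[nrow(s)] - s$total_N[1]) / s$total_N[1]
  cat(sprintf("  nitrogen inventory change: %.3g relative\n", dN))
  invisible(x)
}

#' Run the 0-D box model
#'
#' Pure biological kinetics in a well-mixed box with prescribed PAR and
#' temperature (constant scalars or functions of time in days). Equivalent
#' to a single-cell column with attenuation switched off.
#'
#' @param init initial \code{\link{eco_state}} (single cell)
#' @param PAR photosynthetically available radiation at the box (W m^-2):
#'   scalar or \code{function(t_days)}
#' @param T_C temperature (deg C): scalar or \code{function(t_days)}
#' @param params a \code{\link{bio_params}}
#' @param dt time step (s)
#' @param t_end_days integration length (days)
#' @param output_every_days output cadence (days)
#' @return data.frame with columns time_days, N, P, Z, D, Chl, theta
#' @export
#' @examples
#' s0 <- eco_state(N = 2, P = 0.1, Z = 0.05)
#' tail(run_box(s0, PAR = 50, T_C = 15, t_end_days = 5), 1)
run_box <- function(init, PAR, T_C, params = bio_params(), dt = 300,
                    t_end_days = 30, output_every_days = 0.5) {
  if (dt <= 0 || t_end_days < 0) stop("dt and t_end must be > 0", call. = FALSE)
  parf <- if (is.function(PAR)) PAR else function(t) PAR
  tf <- if (is.function(T_C)) T_C else function(t) T_C
  nstep <- ceiling(t_end_days * 86400 / dt)
  stride <- max(1L, round(output_every_days * 86400 / dt))
  state <- init
  rows <- vector("list", nstep %/% stride + 2L); ir <- 1L
  snap <- function(k) data.frame(
    time_days = k * dt / 86400, N = state$N[1], P = state$P[1], Z = state$Z[1],
    D = state$D[1], Chl = state$Chl[1], theta = theta_diag(state, params)[1])
  rows[[ir]] <- snap(0L); ir <- ir + 1L
  for (k in seq_len(nstep)) {
    tm <- (k - 0.5) * dt / 86400
    env <- list(T = tf(tm), PAR = max(parf(tm), 0))
    state <- sms_step(state, env, params, dt / 86400)
    check_state_sane(state)
    if (k %% stride == 0L || k == nstep) { rows[[ir]] <- snap(k); ir <- ir + 1L }
  }
  out <- do.call(rbind, rows[seq_len(ir - 1L)])
  out[!duplicated(out$time_days), , drop = FALSE]
}
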