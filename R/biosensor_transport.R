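# Finite-volume flow-cell simulator: 2-D advection-diffusion of the analyte
# in a shallow chamber under fully developed Poiseuille flow, coupled to
# Langmuir surface binding at the sensor (bottom) wall.
#
# Discretization: first-order upwind advection, second-order central
# diffusion, backward Euler in time with the constant transport operator
# factorized once (sparse LU). The wall reaction is advanced by operator
# splitting: per column, the implicit Langmuir step is a scalar quadratic in
# the new surface density and conserves (bulk + surface) mass exactly, so
# the global balance closes to solver precision.

#' Flow-cell geometry
#'
#' The cylindrical measurement chamber (disc of the stated diameter and
#' height, with small inlet/outlet ports) is reduced to a 2-D slice along
#' the flow direction. The effective width is chosen so that
#' `width * height` equals the mean cross-sectional area of the disc,
#' i.e. `width = pi/4 * diameter`, preserving mean residence time and wall
#' shear at a given volumetric flow.
#'
#' @param height chamber height (m).
#' @param length chamber length = disc diameter (m).
#' @param width effective width (m); default `pi/4 * length`.
#' @param inlet_span inlet/outlet port diameter (m), recorded for reference.
#' @return A list of class `chamber_geometry`.
#' @export
chamber_geometry <- function(height = 0.64e-3, length = 11.1e-3,
                             width = NULL, inlet_span = 1e-3) {
  if (is.null(width)) width <- pi / 4 * length
  stopifnot(height > 0, length > 0, width > 0, inlet_span > 0)
  structure(list(height = height, length = length, width = width,
                 inlet_span = inlet_span),
            class = "chamber_geometry")
}

#' Fully developed laminar velocity profile
#'
#' Plane Poiseuille flow between no-slip walls:
#' `u(y) = 6 U (y/H)(1 - y/H)` with `U = Q / (W H)` the mean velocity.
#'
#' @param geometry a [chamber_geometry()].
#' @param flow_ul_min volumetric flow rate (microliters per minute).
#' @return A list of class `flow_field`: `u_mean` (m/s), `u(y)` (function),
#'   `Q` (m^3/s), `shear_wall` (1/s).
#' @export
velocity_profile <- function(geometry, flow_ul_min) {
  stopifnot(flow_ul_min >= 0)
  Q <- flow_ul_min * 1e-9 / 60
  H <- geometry$height
  u_mean <- Q / (geometry$width * H)
  u <- function(y) 6 * u_mean * (y / H) * (1 - y / H)
  structure(list(u_mean = u_mean, u = u, Q = Q,
                 shear_wall = 6 * u_mean / H),
            class = "flow_field")
}

#' Transport-and-binding scenario
#'
#' All tunables of a flow-cell run, in the bench units of the field
#' (nM, microliters/min) converted internally to strict SI. The schedule is
#' two-phase: analyte at `c_in_nM` until `t_assoc`, then clean buffer until
#' `t_end`.
#'
#' @param geometry a [chamber_geometry()].
#' @param D analyte diffusion coefficient (m^2/s); default is the
#'   literature value for thrombin in water.
#' @param flow_ul_min flow rate (ul/min).
#' @param c_in_nM inlet analyte concentration (nM).
#' @param k_on,k_off surface reaction rate constants (1/M/s and 1/s).
#' @param gamma_max immobilized receptor (aptamer) surface density
#'   (mol/m^2).
#' @param t_assoc,t_end association-phase end and simulation end (s).
#' @param nx,ny grid cells along the flow and the height.
#' @param dt time step (s); reduced automatically if the advective CFL
#'   number would exceed 2 (keeps the splitting error controlled even
#'   though the implicit scheme is unconditionally stable).
#' @param wall_cell height of the first cell at the sensor wall (m); cells
#'   grow geometrically away from the wall.
#' @return A list of class `transport_scenario` (SI fields `c_in`,
#'   `k_on_si`, `Q` alongside the bench-unit inputs).
#' @export
transport_scenario <- function(geometry = chamber_geometry(),
                               D = 8.76e-11, flow_ul_min = 40,
                               c_in_nM = 10, k_on = 1e8, k_off = 1,
                               gamma_max = 2.3e-7,
                               t_assoc = 100, t_end = 300,
                               nx = 256, ny = 64, dt = 0.05,
                               wall_cell = 2e-6) {
  stopifnot(D > 0, flow_ul_min >= 0, c_in_nM >= 0, k_on >= 0, k_off >= 0,
            gamma_max > 0, t_assoc > 0, t_end >= t_assoc,
            nx >= 4, ny >= 4, dt > 0, wall_cell > 0)
  structure(list(
    geometry = geometry, D = D, flow_ul_min = flow_ul_min,
    Q = flow_ul_min * 1e-9 / 60,
    c_in_nM = c_in_nM, c_in = c_in_nM * 1e-6,      # nM -> mol/m^3
    k_on = k_on, k_on_si = k_on * 1e-3,            # 1/M/s -> m^3/mol/s
    k_off = k_off, gamma_max = gamma_max,
    t_assoc = t_assoc, t_end = t_end,
    nx = as.integer(nx), ny = as.integer(ny), dt = dt,
    wall_cell = wall_cell), class = "transport_scenario")
}

# geometric cell heights from the wall: h1 * r^(j-1), summing to H
grid_heights <- function(H, ny, h1) {
  if (h1 * ny >= H) return(rep(H / ny, ny))
  f <- function(r) h1 * (r^ny - 1) / (r - 1) - H
  r <- uniroot(f, c(1 + 1e-12, 10), tol = 1e-14)$root
  h1 * r^(seq_len(ny) - 1)
}

# implicit Langmuir wall step: backward Euler on
#   dB/dt = kon*cw*(G - B) - koff*B,  h*dcw/dt = -dB/dt
# is a quadratic in B_new (vectorized over columns); conserves h*cw + B.
langmuir_wall_step <- function(cw, B, h, dt, kon, koff, G) {
  if (kon == 0) {
    Bn <- B / (1 + dt * koff)
    return(list(cw = cw + (B - Bn) / h, B = Bn))
  }
  a <- dt * kon
  alpha <- -a / h
  beta <- 1 + a * cw + a * (B + G) / h + dt * koff
  gam <- -(B + a * cw * G + a * B * G / h)
  disc <- sqrt(pmax(beta^2 - 4 * alpha * gam, 0))
  # alpha < 0: the root continuous with the linear (alpha -> 0) limit
  Bn <- (-beta + disc) / (2 * alpha)
  bad <- Bn < -1e-12 | Bn > G * (1 + 1e-9)
  if (any(bad)) Bn[bad] <- ((-beta - disc) / (2 * alpha))[bad]
  Bn <- pmin(pmax(Bn, 0), G)
  list(cw = cw + (B - Bn) / h, B = Bn)
}

#' Run a flow-cell transport-and-binding scenario
#'
#' Solves `dc/dt + u(y) dc/dx = D lap(c)` on the 2-D slice with Dirichlet
#' inlet, convective outflow, no-flux top wall, and a reactive sensor wall
#' where `dB/dt = k_on c_wall (Gamma_max - B) - k_off B`. Returns the
#' sensor-averaged surface density B(t) together with a running mass
#' balance.
#'
#' @param scenario a [transport_scenario()].
#' @param snapshot_times optional times (s) at which the full concentration
#'   field is stored.
#' @param residual_tol abort when the relative mass-balance residual
#'   exceeds this.
#' @return A list of class `sensor_response`: `times`, `B` (mol/m^2,
#'   averaged over the sensor), `B_profile` (final B(x)), `residual`
#'   (relative mass-balance residual series), `scenario`, and optional
#'   `snapshots` (list of ny x nx matrices).
#' @export
run_scenario <- function(scenario, snapshot_times = NULL,
                         residual_tol = 1e-3) {
  sc <- scenario
  g <- sc$geometry
  nx <- sc$nx; ny <- sc$ny
  dx <- g$length / nx
  h <- grid_heights(g$height, ny, sc$wall_cell)
  yc <- cumsum(h) - h / 2
  flow <- velocity_profile(g, sc$flow_ul_min)
  u <- flow$u(yc)

  dt <- sc$dt
  if (flow$u_mean > 0) {
    cfl <- max(u) * dt / dx
    if (cfl > 2) dt <- dt * 2 / cfl
  }
  nsteps <- ceiling(sc$t_end / dt)
  dt <- sc$t_end / nsteps

  N <- nx * ny
  idx <- function(i, j) (j - 1L) * nx + i
  V <- rep(dx * h, each = nx)           # cell volumes per unit width

  # vectorized assembly of the transport operator A (V dc/dt = -A c + ...)
  ig <- rep(seq_len(nx), times = ny)    # x index of cell k = 1..N
  jg <- rep(seq_len(ny), each = nx)     # y index of cell k
  uh <- (u * h)[jg]                     # advective face conductance
  dife <- (sc$D * h / dx)[jg]           # x-diffusive face conductance
  dyd <- c(Inf, (h[-1] + h[-ny]) / 2)   # center distance to cell below
  dyu <- c((h[-1] + h[-ny]) / 2, Inf)   # and above
  difd <- (sc$D * dx / dyd)[jg]; difd[jg == 1] <- 0
  difu <- (sc$D * dx / dyu)[jg]; difu[jg == ny] <- 0

  west <- ig > 1; east <- ig < nx; inlet <- ig == 1
  down <- jg > 1; up <- jg < ny
  k_all <- seq_len(N)

  diag <- uh +                                  # upwind outflow, east face
    dife * (west + east) + 2 * dife * inlet +   # x-diffusion (+ Dirichlet)
    difd + difu                                 # y-diffusion
  ii <- c(k_all,
          k_all[west], k_all[west],             # advection + diffusion west
          k_all[east],
          k_all[down], k_all[up])
  jj <- c(k_all,
          k_all[west] - 1L, k_all[west] - 1L,
          k_all[east] + 1L,
          k_all[down] - nx, k_all[up] + nx)
  vv <- c(diag,
          -uh[west], -dife[west],
          -dife[east],
          -difd[down], -difu[up])
  rhs_in <- numeric(N)                  # multiplied by c_in(t)
  rhs_in[inlet] <- uh[inlet] + 2 * dife[inlet]
  A <- sparseMatrix(i = ii, j = jj, x = vv, dims = c(N, N))
  M <- Diagonal(x = V / dt) + A
  LU <- lu(M)

  conc <- numeric(N)
  B <- numeric(nx)
  times <- seq_len(nsteps) * dt
  Bmean <- numeric(nsteps)
  resid <- numeric(nsteps)
  mass_in <- 0; mass_out <- 0
  mass0 <- 0
  want_snap <- !is.null(snapshot_times)
  snaps <- list()
  snap_left <- if (want_snap) sort(snapshot_times) else numeric(0)

  jtop <- seq_len(ny)
  out_idx <- idx(rep(nx, ny), jtop)
  in_idx <- idx(rep(1L, ny), jtop)
  bot_idx <- idx(seq_len(nx), rep(1L, nx))

  for (s in seq_len(nsteps)) {
    t_new <- s * dt
    cin <- if (t_new <= sc$t_assoc) sc$c_in else 0
    b <- (V / dt) * conc + rhs_in * cin
    conc <- as.numeric(solve(LU, b))
    # boundary fluxes consistent with the implicit solve
    mass_in <- mass_in +
      dt * sum(u * h * cin + 2 * sc$D * h / dx * (cin - conc[in_idx]))
    mass_out <- mass_out + dt * sum(u * h * conc[out_idx])
    # wall reaction (operator splitting, locally conservative)
    st <- langmuir_wall_step(conc[bot_idx], B, h[1], dt,
                             sc$k_on_si, sc$k_off, sc$gamma_max)
    conc[bot_idx] <- st$cw
    B <- st$B
    Bmean[s] <- mean(B)
    bulk <- sum(V * conc)
    surf <- dx * sum(B)
    denom <- max(mass_in, sc$c_in * sum(V), .Machine$double.eps)
    resid[s] <- abs(mass_in - mass_out - (bulk - mass0) - surf) / denom
    if (!is.finite(resid[s]) || resid[s] > residual_tol)
      stop(sprintf("mass-balance residual %.3g at t = %.2f s exceeds %g",
                   resid[s], t_new, residual_tol))
    if (want_snap && length(snap_left) && t_new >= snap_left[1] - dt / 2) {
      snaps[[sprintf("t%.1f", snap_left[1])]] <-
        matrix(conc, nrow = ny, ncol = nx, byrow = TRUE)
      snap_left <- snap_left[-1]
    }
  }
  structure(list(times = c(0, times), B = c(0, Bmean), B_profile = B,
                 residual = resid, scenario = sc,
                 snapshots = if (want_snap) snaps else NULL),
            class = "sensor_response")
}

#' Closed-form well-mixed Langmuir binding curve
#'
#' Analytic solution of `dB/dt = k_on c (Gamma_max - B) - k_off B` at
#' constant analyte concentration:
#' `B(t) = B_eq (1 - exp(-(k_on c + k_off) t))` with
#' `B_eq = Gamma_max c / (c + K_d)`. This is the reference the transport
#' solver must approach when mixing is fast compared to the reaction.
#'
#' @param k_on association rate constant (1/M/s).
#' @param k_off dissociation rate constant (1/s).
#' @param c analyte concentration (M), constant.
#' @param gamma_max receptor surface density (mol/m^2).
#' @param t times (s).
#' @return B(t) in mol/m^2.
#' @export
well_mixed_reference <- function(k_on, k_off, c, gamma_max, t) {
  rate <- k_on * c + k_off
  if (rate == 0) return(rep(0, length(t)))
  K_d <- if (k_on > 0) k_off / k_on else Inf
  B_eq <- if (is.infinite(K_d)) 0 else gamma_max * c / (c + K_d)
  B_eq * (1 - exp(-rate * t))
}

#' Initial capture rate of a sensor response
#'
#' Least-squares slope of B(t) over `[onset, onset + window]` (clipped to
#' the available times).
#'
#' @param response a `sensor_response`.
#' @param window slope window length (s).
#' @param onset window start (s).
#' @return Slope in mol m^-2 s^-1.
#' @export
capture_rate <- function(response, window = 300, onset = 0) {
  sel <- response$times >= onset & response$times <= onset + window
  if (sum(sel) < 2) stop("capture window not covered by the response")
  t <- response$times[sel]; b <- response$B[sel]
  coef(lm(b ~ t))[[2]]
}

#' Time at which the response first reaches a level
#'
#' Linear interpolation of B(t) to the first crossing of `level`.
#'
#' @param response a `sensor_response`.
#' @param level target surface density (mol/m^2).
#' @return Onset time (s), or NA if never reached.
#' @export
onset_time <- function(response, level) {
  i <- which(response$B >= level)[1]
  if (is.na(i)) return(NA_real_)
  if (i == 1) return(response$times[1])
  t0 <- response$times[i - 1]; t1 <- response$times[i]
  b0 <- response$B[i - 1]; b1 <- response$B[i]
  t0 + (level - b0) / (b1 - b0) * (t1 - t0)
}

#' One-axis parameter sweep of a transport scenario
#'
#' Reruns `base` with one parameter replaced by each value and summarizes
#' every response: capture rate over the association phase, peak B, final
#' B, and release fraction (1 - final/peak).
#'
#' @param base a [transport_scenario()].
#' @param axis one of `"flow"`, `"concentration"`, `"k_on"`, `"k_off"`.
#' @param values numeric values for the swept axis (flow in ul/min,
#'   concentration in nM, rates in 1/M/s and 1/s).
#' @return A list of class `scenario_sweep`: `responses` (named list of
#'   `sensor_response`), `summary` (data.frame: value, capture_rate,
#'   peak_B, final_B, release_fraction).
#' @export
sweep_scenario <- function(base, axis = c("flow", "concentration",
                                          "k_on", "k_off"), values) {
  axis <- match.arg(axis)
  field <- switch(axis, flow = "flow_ul_min", concentration = "c_in_nM",
                  k_on = "k_on", k_off = "k_off")
  responses <- lapply(values, function(v) {
    args <- base[c("geometry", "D", "flow_ul_min", "c_in_nM", "k_on",
                   "k_off", "gamma_max", "t_assoc", "t_end", "nx", "ny",
                   "dt", "wall_cell")]
    args[[field]] <- v
    run_scenario(do.call(transport_scenario, args))
  })
  names(responses) <- as.character(values)
  summ <- do.call(rbind, lapply(seq_along(values), function(k) {
    r <- responses[[k]]
    peak <- max(r$B)
    final <- r$B[length(r$B)]
    data.frame(value = values[k],
               capture_rate = capture_rate(r, window = r$scenario$t_assoc),
               peak_B = peak, final_B = final,
               release_fraction = if (peak > 0) 1 - final / peak else 0)
  }))
  structure(list(responses = responses, summary = summ, axis = axis),
            class = "scenario_sweep")
}
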