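#' Blood fluid properties
#'
#' Newtonian, incompressible, homogeneous blood model.
#'
#' @param density Density (kg/m^3), default 1060.
#' @param dynamic_viscosity Dynamic viscosity (Pa s), default 3.71e-3.
#' @return An object of class `fluid_properties`.
#' @export
fluid_properties <- function(density = 1060, dynamic_viscosity = 3.71e-3) {
  if (!is.finite(density) || density <= 0 ||
      !is.finite(dynamic_viscosity) || dynamic_viscosity <= 0) {
    stop("density and dynamic viscosity must be strictly positive", call. = FALSE)
  }
  structure(list(density = density, dynamic_viscosity = dynamic_viscosity),
            class = "fluid_properties")
}

#' Flow-field snapshot
#'
#' Staggered velocity/pressure state at a time instant: `u` on vertical
#' faces (`(nx+1) x ny`), `v` on horizontal faces (`nx x (ny+1)`), cell
#' pressures `p` (`nx x ny`, Pa).
#'
#' @param time Time (s).
#' @param u,v,p Field arrays (see description).
#' @return An object of class `flow_field`.
#' @export
flow_field <- function(time, u, v, p) {
  structure(list(time = time, u = u, v = v, p = p), class = "flow_field")
}

#' Adaptive CFL time step
#'
#' `dt = safety * spacing / max(speed, floor)`, capped at `dt_max`; the floor
#' speed is chosen so a quiescent field yields exactly `dt_max`.
#'
#' @param max_speed Maximum velocity magnitude in the field (m/s).
#' @param spacing Grid spacing (mm).
#' @param safety CFL safety factor in (0, 1].
#' @param dt_max Time-step cap (s).
#' @return Time step (s).
#' @export
cfl_timestep <- function(max_speed, spacing, safety = 0.5, dt_max = 1e-3) {
  if (safety <= 0 || safety > 1) stop("safety must be in (0, 1]", call. = FALSE)
  h <- spacing / 1000
  floor_speed <- safety * h / dt_max
  min(dt_max, safety * h / max(max_speed, floor_speed))
}

#' Maximum Reynolds number of a snapshot
#'
#' `Re = rho * U_max * D_h / mu` with the hydraulic diameter of the
#' undissected proximal channel (2D channel: twice the width). When `Re`
#' exceeds `re_critical` a warning-level message is emitted (the laminar
#' model is retained regardless).
#'
#' @param field A `flow_field`.
#' @param geom The [dissection_geometry()] (used for the channel width).
#' @param fluid [fluid_properties()].
#' @param re_critical Critical Reynolds number for the log check.
#' @param quiet Suppress the log message.
#' @return Reynolds number (dimensionless).
#' @export
max_reynolds <- function(field, geom, fluid = fluid_properties(),
                         re_critical = 2300, quiet = FALSE) {
  d_h <- 2 * geom$true_lumen_width / 1000
  umax <- max(abs(field$u), abs(field$v))
  re <- fluid$density * umax * d_h / fluid$dynamic_viscosity
  if (!quiet && re > re_critical) {
    message(sprintf("Re_max = %.0f exceeds Re_c = %.0f (laminar model retained)",
                    re, re_critical))
  }
  re
}

#' Default boundary conditions for a dissection geometry
#'
#' Pulsatile flat velocity profile at the inlet, pulsatile pressure at the
#' descending outlet, and branch outflow slots each diverting their
#' configured fraction of the instantaneous inlet flow. With
#' `branches = FALSE` the slots are closed and the inlet is scaled by
#' (1 - sum of branch fractions) so the distal flow matches.
#'
#' @param geom A [dissection_geometry()].
#' @param inlet,outlet Optional [waveform()] overrides.
#' @param branches Logical; divert flow through the branch slots?
#' @return A boundary-condition list for [simulate()].
#' @export
boundary_conditions <- function(geom, inlet = inlet_velocity_waveform(),
                                outlet = outlet_pressure_waveform(),
                                branches = TRUE) {
  fr <- sum(vapply(geom$branch_slots, function(s) s$outflow_fraction, numeric(1)))
  list(
    inlet = inlet, outlet = outlet, branches = branches,
    inlet_scale = if (branches) 1 else 1 - fr,
    inlet_type = "velocity", inlet_pressure = NULL
  )
}

# one explicit fractional step with PISO-style double pressure correction;
# st = list(t, U, V, P, p_out_prev, p_in_prev)
ns_step <- function(st, plan, bcf, dt, picard_sweeps = 2) {
  dx <- plan$dx; nu <- plan$nu; rho <- plan$rho
  nx <- plan$nx; ny <- plan$ny
  t1 <- st$t + dt
  U <- st$U; V <- st$V; P <- st$P

  # prescribe Dirichlet velocities at the new time
  if (plan$inlet_type == "velocity") U[plan$inlet_idx] <- bcf$u_in(t1)
  if (any(plan$branch_v)) {
    vb <- bcf$v_branch(t1)
    for (k in seq_along(vb)) V[bcf$branch_faces[[k]]] <- vb[k]
  }

  ## ---- u momentum ---------------------------------------------------------
  UW <- sh(U, 1); UE <- sh(U, -1)
  US <- sh(U, 0, 1); UN <- sh(U, 0, -1)
  # advecting v averaged to u faces
  VL <- rbind(matrix(0, 1, ny + 1), V)   # (nx+1) x (ny+1): V of left cell
  VR <- rbind(V, matrix(0, 1, ny + 1))
  vbar <- 0.25 * (VL[, 1:ny] + VL[, 2:(ny + 1)] + VR[, 1:ny] + VR[, 2:(ny + 1)])

  d1 <- (U - UW) / dx
  d2 <- (3 * U - 4 * UW + sh(U, 2)) / (2 * dx)
  dpx <- d1 + plan$u_ok2w * (d2 - d1)
  d1 <- (UE - U) / dx
  d2 <- (-3 * U + 4 * UE - sh(U, -2)) / (2 * dx)
  dnx <- d1 + plan$u_ok2e * (d2 - d1)
  dwall <- 2 * U / dx
  d1 <- (U - US) / dx
  d2 <- (3 * U - 4 * US + sh(U, 0, 2)) / (2 * dx)
  dpy <- dwall + plan$u_ok1s * (d1 - dwall) + plan$u_ok2s * (d2 - d1)
  d1 <- (UN - U) / dx
  d2 <- (-3 * U + 4 * UN - sh(U, 0, -2)) / (2 * dx)
  dny <- -dwall + plan$u_ok1n * (d1 + dwall) + plan$u_ok2n * (d2 - d1)
  conv_u <- pmax(U, 0) * dpx + pmin(U, 0) * dnx +
    pmax(vbar, 0) * dpy + pmin(vbar, 0) * dny

  uN_eff <- plan$u_usN * (UN + U) - U
  uS_eff <- plan$u_usS * (US + U) - U
  lap_u <- (UE - 2 * U + UW + uN_eff - 2 * U + uS_eff) / dx^2

  PL <- rbind(matrix(0, 1, ny), P); PR <- rbind(P, matrix(0, 1, ny))
  gpx <- (PR - PL) / dx

  Ustar <- U
  upd <- plan$act_u
  Ustar[upd] <- U[upd] + dt * (-conv_u[upd] + nu * lap_u[upd] -
                                 gpx[upd] / rho + bcf$fx(t1))

  ## ---- v momentum ---------------------------------------------------------
  VW <- sh(V, 1); VE <- sh(V, -1)
  VS <- sh(V, 0, 1); VN <- sh(V, 0, -1)
  UB <- cbind(matrix(0, nx + 1, 1), U)   # (nx+1) x (ny+1): U of row below
  UT <- cbind(U, matrix(0, nx + 1, 1))
  ubar <- 0.25 * (UB[1:nx, ] + UB[2:(nx + 1), ] + UT[1:nx, ] + UT[2:(nx + 1), ])

  d1 <- (V - VS) / dx
  d2 <- (3 * V - 4 * VS + sh(V, 0, 2)) / (2 * dx)
  dpy <- d1 + plan$v_ok2s * (d2 - d1)
  d1 <- (VN - V) / dx
  d2 <- (-3 * V + 4 * VN - sh(V, 0, -2)) / (2 * dx)
  dny <- d1 + plan$v_ok2n * (d2 - d1)
  dwall <- 2 * V / dx
  d1 <- (V - VW) / dx
  d2 <- (3 * V - 4 * VW + sh(V, 2)) / (2 * dx)
  dpx <- dwall + plan$v_ok1w * (d1 - dwall) + plan$v_ok2w * (d2 - d1)
  d1 <- (VE - V) / dx
  d2 <- (-3 * V + 4 * VE - sh(V, -2)) / (2 * dx)
  dnx <- -dwall + plan$v_ok1e * (d1 + dwall) + plan$v_ok2e * (d2 - d1)
  conv_v <- pmax(ubar, 0) * dpx + pmin(ubar, 0) * dnx +
    pmax(V, 0) * dpy + pmin(V, 0) * dny

  vE_eff <- plan$v_usE * (VE + V) - V
  vW_eff <- plan$v_usW * (VW + V) - V
  lap_v <- (VN - 2 * V + VS + vE_eff - 2 * V + vW_eff) / dx^2

  PB <- cbind(matrix(0, nx, 1), P); PT <- cbind(P, matrix(0, nx, 1))
  gpy <- (PT - PB) / dx

  Vstar <- V
  upd <- plan$act_v
  Vstar[upd] <- V[upd] + dt * (-conv_v[upd] + nu * lap_v[upd] - gpy[upd] / rho)

  ## ---- open-boundary faces (zero-gradient predictor, corrected below) -----
  Ustar[plan$outlet_idx] <- Ustar[plan$outlet_idx - 1L]
  if (plan$inlet_type == "pressure") {
    Ustar[plan$inlet_idx] <- Ustar[plan$inlet_idx + 1L]
  }

  ## ---- PISO pressure-correction sweeps ------------------------------------
  p_out1 <- bcf$p_out(t1)
  phiD_out <- (p_out1 - st$p_out_prev) / rho
  p_in1 <- NA_real_
  phiD_in <- 0
  if (plan$inlet_type == "pressure") {
    p_in1 <- bcf$p_in(t1)
    phiD_in <- (p_in1 - st$p_in_prev) / rho
  }
  two_odx <- 2 / dx
  for (sweep in seq_len(max(1, picard_sweeps))) {
    div <- (Ustar[2:(nx + 1), , drop = FALSE] - Ustar[1:nx, , drop = FALSE] +
            Vstar[, 2:(ny + 1), drop = FALSE] - Vstar[, 1:ny, drop = FALSE]) / dx
    b <- -div[plan$fluid_idx] / dt
    if (length(plan$out_cells)) b[plan$out_cells] <- b[plan$out_cells] +
        2 * plan$c2 * phiD_out
    if (length(plan$in_cells)) b[plan$in_cells] <- b[plan$in_cells] +
        2 * plan$c2 * phiD_in
    phi <- as.numeric(Matrix::solve(plan$chol, b))
    phiM <- matrix(0, nx, ny)
    phiM[plan$fluid_idx] <- phi

    gx <- (rbind(phiM, matrix(0, 1, ny)) - rbind(matrix(0, 1, ny), phiM)) / dx
    Ustar[plan$act_u] <- Ustar[plan$act_u] - dt * gx[plan$act_u]
    Ustar[plan$outlet_idx] <- Ustar[plan$outlet_idx] -
      dt * two_odx * (phiD_out - phiM[cbind(nx, plan$outlet_rows_j)])
    if (plan$inlet_type == "pressure") {
      Ustar[plan$inlet_idx] <- Ustar[plan$inlet_idx] -
        dt * two_odx * (phiM[cbind(1L, plan$inlet_rows_j)] - phiD_in)
    }
    gy <- (cbind(phiM, matrix(0, nx, 1)) - cbind(matrix(0, nx, 1), phiM)) / dx
    Vstar[plan$act_v] <- Vstar[plan$act_v] - dt * gy[plan$act_v]

    P[plan$fluid_idx] <- P[plan$fluid_idx] + rho * phi
    phiD_out <- 0; phiD_in <- 0  # boundary increment applied in the first sweep
  }

  div <- (Ustar[2:(nx + 1), , drop = FALSE] - Ustar[1:nx, , drop = FALSE] +
          Vstar[, 2:(ny + 1), drop = FALSE] - Vstar[, 1:ny, drop = FALSE]) / dx
  maxdiv <- max(abs(div[plan$fluid_idx]))
  if (!is.finite(maxdiv) || maxdiv > 1e-6) {
    if (!is.finite(maxdiv)) {
      stop("solver instability: NaN detected; reduce the time step", call. = FALSE)
    }
    stop(sprintf("solver failure: divergence residual %.3e 1/s above tolerance",
                 maxdiv), call. = FALSE)
  }

  list(t = t1, U = Ustar, V = Vstar, P = P,
       p_out_prev = p_out1,
       p_in_prev = if (plan$inlet_type == "pressure") p_in1 else st$p_in_prev,
       maxdiv = maxdiv)
}

# boundary-value closures for a run; branch velocities are built from the
# rasterized widths so the discrete flow split is exact
make_bc_functions <- function(grid, plan, bc) {
  dxmm <- grid$spacing
  n_in <- length(grid$inlet_rows)
  scale <- if (is.null(bc$inlet_scale)) 1 else bc$inlet_scale
  branch_faces <- list(); fr <- numeric(0); nb <- numeric(0)
  if (isTRUE(bc$branches) && length(grid$branch_slots)) {
    branch_faces <- lapply(grid$branch_slots, function(s)
      cbind(s$cols, rep(grid$ny + 1L, length(s$cols))))
    # convert to linear indices into the V array (nx x (ny+1))
    branch_faces <- lapply(branch_faces, function(m)
      (m[, 2] - 1L) * grid$nx + m[, 1])
    fr <- vapply(grid$branch_slots, function(s) s$fraction, numeric(1))
    nb <- vapply(grid$branch_slots, function(s) length(s$cols), numeric(1))
  }
  u_in <- function(t) scale * wf_eval(bc$inlet, t)
  list(
    u_in = u_in,
    v_branch = function(t) if (length(fr)) fr * u_in(t) * n_in / nb else numeric(0),
    branch_faces = branch_faces,
    p_out = function(t) wf_eval(bc$outlet, t),
    p_in = if (!is.null(bc$inlet_pressure)) function(t) wf_eval(bc$inlet_pressure, t)
           else function(t) 0,
    fx = if (!is.null(bc$body_force)) bc$body_force else function(t) 0
  )
}

#' Simulate pulsatile flow through a dissection geometry
#'
#' Advances the unsteady incompressible Navier-Stokes equations from rest
#' over `n_cycles` cardiac cycles on the masked staggered grid, with
#' second-order upwind convection, explicit central viscous terms and a
#' PISO-style double pressure-correction projection solved by a
#' pre-factorized sparse Cholesky method (fully deterministic). Returns
#' snapshots at the requested phases of the final cycle plus run
#' diagnostics, including the cycle-to-cycle periodicity error.
#'
#' @param geom A [dissection_geometry()], or a prebuilt `masked_grid`.
#' @param spacing Grid spacing (mm); ignored when `geom` is already a grid.
#' @param bc Boundary conditions from [boundary_conditions()]; defaults to
#'   the physiological set for the geometry.
#' @param fluid [fluid_properties()].
#' @param n_cycles Number of cardiac cycles simulated from rest.
#' @param snapshot_phases Phases (s, within `[0, period)`) of the final cycle
#'   at which snapshots are returned; defaults mirror peak systole (0.25 s)
#'   and early diastole (0.47 s).
#' @param numerics List of numeric controls: `cfl_safety`, `dt_max` (s),
#'   `picard_sweeps`, `visc_safety`.
#' @param verbose Print one log line per cycle.
#' @return An object of class `ns_simulation`: list with `snapshots` (list of
#'   [flow_field()]), `diagnostics` (named list), `flux_table` (per-step
#'   boundary fluxes, m^2/s), `grid`, `geom`.
#' @export
simulate <- function(geom, spacing = 1, bc = NULL, fluid = fluid_properties(),
                     n_cycles = 4, snapshot_phases = c(0.25, 0.47),
                     numerics = list(), verbose = FALSE) {
  grid <- if (inherits(geom, "masked_grid")) geom else rasterize(geom, spacing)
  gm <- grid$geom
  if (is.null(bc)) {
    if (is.null(gm)) stop("bc must be supplied for channel grids", call. = FALSE)
    bc <- boundary_conditions(gm)
  }
  nm <- utils::modifyList(
    list(cfl_safety = 0.5, dt_max = 1e-3, picard_sweeps = 2, visc_safety = 0.2),
    numerics)
  inlet_type <- if (!is.null(bc$inlet_type)) bc$inlet_type else "velocity"
  plan <- build_plan(grid, fluid, inlet_type)
  plan$outlet_rows_j <- grid$outlet_rows
  plan$inlet_rows_j <- grid$inlet_rows
  bcf <- make_bc_functions(grid, plan, bc)

  period <- bc$outlet$period
  if (!is.null(bc$inlet) && inherits(bc$inlet, "waveform")) {
    period <- bc$inlet$period
  }
  t_end <- n_cycles * period
  stopifnot(all(snapshot_phases >= 0 & snapshot_phases < period))
  snap_times <- sort((n_cycles - 1) * period + snapshot_phases)
  per_times <- if (n_cycles >= 2) {
    (n_cycles - 2:1) * period + snapshot_phases[1]
  } else numeric(0)
  targets <- sort(unique(c(snap_times, per_times)))

  nx <- plan$nx; ny <- plan$ny
  st <- list(t = 0,
             U = matrix(0, nx + 1, ny), V = matrix(0, nx, ny + 1),
             P = matrix(0, nx, ny), p_out_prev = bcf$p_out(0),
             p_in_prev = if (inlet_type == "pressure") bcf$p_in(0) else NA_real_)
  st$P[plan$fluid_idx] <- st$p_out_prev
  if (inlet_type == "velocity") st$U[plan$inlet_idx] <- bcf$u_in(0)

  dt_visc <- nm$visc_safety * plan$dx^2 / plan$nu
  captured <- vector("list", length(targets))
  flux_rows <- list()
  maxdiv <- 0; cfl_max <- 0; umax_run <- 0; imbalance <- 0; gross <- 0
  step_count <- 0L
  next_cycle_log <- period

  dy <- plan$dx
  while (st$t < t_end - 1e-12) {
    speed <- max(max(abs(st$U)), max(abs(st$V)))
    dt <- min(cfl_timestep(speed, grid$spacing, nm$cfl_safety, nm$dt_max),
              dt_visc, t_end - st$t)
    prev <- st
    st <- ns_step(st, plan, bcf, dt, nm$picard_sweeps)
    step_count <- step_count + 1L

    # boundary-flux audit (m^2/s, per unit depth)
    q_in <- sum(st$U[plan$inlet_idx]) * dy
    q_out <- sum(st$U[plan$outlet_idx]) * dy
    q_b <- vapply(bcf$branch_faces, function(ii) sum(st$V[ii]) * dy, numeric(1))
    flux_rows[[step_count]] <- c(st$t, q_in, q_out, q_b)
    imbalance <- max(imbalance, abs(q_in - q_out - sum(q_b)))
    gross <- max(gross, abs(q_in))

    maxdiv <- max(maxdiv, st$maxdiv)
    sp <- max(max(abs(st$U)), max(abs(st$V)))
    umax_run <- max(umax_run, sp)
    cfl_max <- max(cfl_max, dt * sp / plan$dx)

    for (k in seq_along(targets)) {
      tau <- targets[k]
      if (prev$t < tau && st$t >= tau - 1e-12) {
        w <- (tau - prev$t) / (st$t - prev$t)
        captured[[k]] <- flow_field(
          tau,
          (1 - w) * prev$U + w * st$U,
          (1 - w) * prev$V + w * st$V,
          (1 - w) * prev$P + w * st$P)
      }
    }
    if (verbose && st$t >= next_cycle_log - 1e-12) {
      message(sprintf("cycle %d done: steps %d, max|div| %.2e 1/s, u_max %.3f m/s",
                      round(next_cycle_log / period), step_count, maxdiv, umax_run))
      next_cycle_log <- next_cycle_log + period
    }
  }

  per_err <- NA_real_
  if (length(per_times) == 2) {
    f3 <- captured[[match(per_times[1], targets)]]
    f4 <- captured[[match(per_times[2], targets)]]
    num <- sqrt(sum((f4$u - f3$u)^2) + sum((f4$v - f3$v)^2))
    den <- sqrt(sum(f4$u^2) + sum(f4$v^2))
    per_err <- if (den > 0) num / den else 0
  }

  snaps <- captured[match(snap_times, targets)]
  ft <- do.call(rbind, flux_rows)
  colnames(ft) <- c("time_s", "q_inlet", "q_outlet",
                    if (length(bcf$branch_faces))
                      paste0("q_branch_", seq_along(bcf$branch_faces)))
  diag <- list(
    re_max = if (!is.null(gm))
      fluid$density * umax_run * 2 * (gm$true_lumen_width / 1000) /
        fluid$dynamic_viscosity else NA_real_,
    re_critical = 2300,
    cfl_max = cfl_max,
    divergence_max = maxdiv,
    mass_imbalance_max = imbalance,
    mass_imbalance_rel = if (gross > 0) imbalance / gross else 0,
    cycle_periodicity_error = per_err,
    u_max = umax_run,
    n_steps = step_count
  )
  structure(list(snapshots = snaps, diagnostics = diag,
                 flux_table = tibble::as_tibble(as.data.frame(ft)),
                 grid = grid, geom = gm),
            class = "ns_simulation")
}

#' @export
print.ns_simulation <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf(paste0("<ns_simulation: %d snapshots, %d steps, max|div| %.2e 1/s,\n",
                     "  mass imbalance %.2e (rel), periodicity error %s, Re_max %s>\n"),
              length(x$snapshots), d$n_steps, d$divergence_max,
              d$mass_imbalance_rel,
              ifelse(is.na(d$cycle_periodicity_error), "NA",
                     sprintf("%.3f", d$cycle_periodicity_error)),
              ifelse(is.na(d$re_max), "NA", sprintf("%.0f", d$re_max))))
  invisible(x)
}
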