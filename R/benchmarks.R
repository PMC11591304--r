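# minimal boundary closure + plan for a pressure-driven plain channel
channel_setup <- function(width, length, spacing, fluid, p_in_fun, p_out_fun) {
  grid <- channel_grid(width, length, spacing)
  plan <- build_plan(grid, fluid, inlet_type = "pressure")
  plan$outlet_rows_j <- grid$outlet_rows
  plan$inlet_rows_j <- grid$inlet_rows
  bcf <- list(u_in = function(t) 0, v_branch = function(t) numeric(0),
              branch_faces = list(), p_out = p_out_fun, p_in = p_in_fun,
              fx = function(t) 0)
  st <- list(t = 0,
             U = matrix(0, grid$nx + 1, grid$ny),
             V = matrix(0, grid$nx, grid$ny + 1),
             P = matrix(0, grid$nx, grid$ny),
             p_out_prev = p_out_fun(0), p_in_prev = p_in_fun(0))
  xw <- (seq_len(grid$nx) - 0.5) / grid$nx
  st$P[] <- p_in_fun(0) + xw[row(st$P)] * (p_out_fun(0) - p_in_fun(0))
  list(grid = grid, plan = plan, bcf = bcf, st = st)
}

#' Plane-Poiseuille validation benchmark
#'
#' Steady pressure-driven flow in a plain channel, compared against the
#' closed form `u(y) = (dp / 2 mu L) y (w - y)`. The channel is driven by
#' pressure Dirichlet conditions at both ends and integrated to steady
#' state; returned errors measure the developed discrete profile.
#'
#' @param spacing Grid spacing (mm).
#' @param width,length Channel dimensions (mm).
#' @param dp Driving pressure drop (Pa) over the channel length; the default
#'   gives a 0.1 m/s centerline velocity in blood.
#' @param fluid [fluid_properties()].
#' @param t_end Integration horizon (s); the slowest transient decays with
#'   rate `nu (pi/w)^2`.
#' @return List: `max_rel_error`, `l2_rel_error`, `residual` (final relative
#'   per-step change), `profile` tibble (`y_mm`, `u`, `u_exact`).
#' @export
poiseuille_benchmark <- function(spacing = 0.5, width = 5, length = 10,
                                 dp = NULL, fluid = fluid_properties(),
                                 t_end = 8) {
  w <- width / 1000; L <- length / 1000
  mu <- fluid$dynamic_viscosity
  if (is.null(dp)) dp <- 0.1 * 8 * mu * L / w^2  # 0.1 m/s centerline
  cs <- channel_setup(width, length, spacing, fluid,
                      p_in_fun = function(t) dp, p_out_fun = function(t) 0)
  st <- cs$st; plan <- cs$plan; grid <- cs$grid
  dt <- min(1e-3, 0.2 * plan$dx^2 / plan$nu)
  delta <- Inf
  while (st$t < t_end) {
    prev_u <- st$U
    st <- ns_step(st, plan, cs$bcf, dt)
    delta <- max(abs(st$U - prev_u))
  }
  # developed profile at mid-length (u is x-uniform at steady state)
  i_mid <- as.integer(round((grid$nx + 1) / 2))
  u <- st$U[i_mid, ]
  y <- (seq_len(grid$ny) - 0.5) * plan$dx
  u_exact <- dp / (2 * mu * L) * y * (w - y)
  err <- u - u_exact
  list(
    max_rel_error = max(abs(err)) / max(u_exact),
    l2_rel_error = sqrt(sum(err^2) / sum(u_exact^2)),
    residual = delta / max(abs(u)),
    profile = tibble::tibble(y_mm = y * 1000, u = u, u_exact = u_exact)
  )
}

#' Analytic oscillatory-channel (Womersley-type) velocity profile
#'
#' Velocity of fully developed flow in a 2D channel of width `w` driven by
#' the oscillating axial pressure gradient `-dp/dx = G cos(omega t)`:
#' the real part of
#' `(G / (i omega rho)) (1 - cosh(lambda (y - h)) / cosh(lambda h)) e^(i omega t)`
#' with `h = w/2` and `lambda = sqrt(i omega / nu)`.
#'
#' @param y Transverse positions (m), in `[0, w]`.
#' @param t Time (s).
#' @param width Channel width (m).
#' @param G Pressure-gradient amplitude (Pa/m).
#' @param omega Angular frequency (rad/s).
#' @param fluid [fluid_properties()].
#' @return Velocity (m/s) at `y`.
#' @export
womersley_profile <- function(y, t, width, G, omega, fluid = fluid_properties()) {
  rho <- fluid$density
  nu <- fluid$dynamic_viscosity / rho
  h <- width / 2
  lam <- sqrt(1i * omega / nu)
  ch <- function(z) (exp(z) + exp(-z)) / 2
  uhat <- (G / (1i * omega * rho)) * (1 - ch(lam * (y - h)) / ch(lam * h))
  Re(uhat * exp(1i * omega * t))
}

#' Oscillatory-channel (Womersley) validation benchmark
#'
#' Pulsatile pressure-driven flow in a plain channel against the analytic
#' oscillatory profile ([womersley_profile()]). With the defaults (6 mm
#' channel, 1 Hz, blood) the Womersley number is about 4. The solver starts
#' from rest and runs `n_cycles` forcing periods; errors are accumulated
#' over the final cycle.
#'
#' @param spacing Grid spacing (mm).
#' @param frequency Forcing frequency (Hz).
#' @param width,length Channel dimensions (mm).
#' @param dp_amplitude Pressure-drop amplitude (Pa) over the channel.
#' @param fluid [fluid_properties()].
#' @param n_cycles Forcing periods to integrate (initial transients decay
#'   with rate `nu (pi/w)^2`).
#' @return List: `l2_rel_error` (cycle-averaged, final cycle),
#'   `per_cycle_error` (last two cycles), `alpha` (Womersley number).
#' @export
womersley_benchmark <- function(spacing = 0.5, frequency = 1,
                                width = 6, length = 10, dp_amplitude = 10,
                                fluid = fluid_properties(), n_cycles = 8) {
  w <- width / 1000; L <- length / 1000
  omega <- 2 * pi * frequency
  G <- dp_amplitude / L
  p0 <- 1e4
  cs <- channel_setup(width, length, spacing, fluid,
                      p_in_fun = function(t) p0 + dp_amplitude * cos(omega * t),
                      p_out_fun = function(t) p0)
  st <- cs$st; plan <- cs$plan; grid <- cs$grid
  period <- 1 / frequency
  t_end <- n_cycles * period
  i_mid <- as.integer(round((grid$nx + 1) / 2))
  y <- (seq_len(grid$ny) - 0.5) * plan$dx

  num_acc <- den_acc <- c(0, 0)  # cycles n-1, n
  while (st$t < t_end - 1e-12) {
    umax <- max(abs(st$U), abs(st$V), 0.05)
    dt <- min(1e-3, 0.5 * plan$dx / umax, 0.2 * plan$dx^2 / plan$nu,
              t_end - st$t)
    st <- ns_step(st, plan, cs$bcf, dt)
    cyc <- ceiling(st$t / period - 1e-12)
    if (cyc >= n_cycles - 1) {
      ua <- womersley_profile(y, st$t, w, G, omega, fluid)
      u <- st$U[i_mid, ]
      k <- if (cyc >= n_cycles) 2L else 1L
      num_acc[k] <- num_acc[k] + dt * sum((u - ua)^2)
      den_acc[k] <- den_acc[k] + dt * sum(ua^2)
    }
  }
  per_cycle <- sqrt(num_acc / den_acc)
  nu <- fluid$dynamic_viscosity / fluid$density
  list(
    l2_rel_error = per_cycle[2],
    per_cycle_error = per_cycle,
    alpha = (w / 2) * sqrt(omega / nu)
  )
}
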