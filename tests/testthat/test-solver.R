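test_that("CFL time step follows the safety rule and its cap", {
  expect_equal(cfl_timestep(1, 1, 0.5, 1e-3), 5e-4)
  expect_equal(cfl_timestep(0, 1), 1e-3)            # quiescent -> dt_max
  expect_equal(cfl_timestep(10, 2), 2 * cfl_timestep(10, 1))  # linear in h
  expect_error(cfl_timestep(1, 1, safety = 0), "safety")
})

test_that("Reynolds number uses the proximal hydraulic diameter", {
  geom <- dissection_geometry(true_lumen_width = 10)  # D_h = 2 x 10 mm
  grid <- rasterize(geom, 1)
  f0 <- make_field(grid)
  expect_equal(max_reynolds(f0, geom, quiet = TRUE), 0)
  f <- make_field(grid, ufun = function(x, y) 0.5)
  re <- max_reynolds(f, geom, quiet = TRUE)
  expect_equal(re, 1060 * 0.5 * 0.02 / 0.00371, tolerance = 1e-12)  # ~2857
  f2 <- make_field(grid, ufun = function(x, y) 1.0)
  expect_equal(max_reynolds(f2, geom, quiet = TRUE), 2 * re)
  expect_message(max_reynolds(f2, geom, re_critical = 100), "laminar")
})

test_that("rest state with zero inflow is a fixed point", {
  geom <- make_case(1)
  bc <- boundary_conditions(geom, inlet = constant_velocity_wf(0),
                            outlet = constant_pressure_wf(1e4))
  sim <- simulate(geom, spacing = 2, bc = bc, n_cycles = 1,
                  snapshot_phases = c(0.5))
  f <- sim$snapshots[[1]]
  expect_lt(max(abs(f$u)), 1e-12)   # machine zero
  expect_lt(max(abs(f$v)), 1e-12)
  expect_equal(max(abs(f$p[sim$grid$fluid] - 1e4)), 0)
})

test_that("steady flat inflow develops the plane-Poiseuille profile", {
  grid <- channel_grid(width = 6, length = 40, spacing = 0.5)
  bc <- list(inlet = constant_velocity_wf(0.02), outlet = constant_pressure_wf(),
             branches = FALSE, inlet_type = "velocity")
  sim <- simulate(grid, bc = bc, n_cycles = 4, snapshot_phases = c(0.5))
  f <- sim$snapshots[[1]]
  prof <- f$u[sim$grid$nx - 2, ]          # near-outlet developed profile
  expect_equal(max(prof), 1.5 * 0.02, tolerance = 0.02)  # centerline 1.5 x mean
  # mirror symmetry across the channel axis
  expect_equal(prof, rev(prof), tolerance = 1e-8)
  # mass conservation and incompressibility diagnostics
  expect_lt(sim$diagnostics$divergence_max, 1e-8)
  expect_lt(sim$diagnostics$mass_imbalance_rel, 1e-10)
  # no-slip is exact on the walls
  expect_true(all(f$v[, 1] == 0))
  expect_true(all(f$v[, sim$grid$ny + 1] == 0))
})

test_that("the projection annihilates divergence of a manufactured field", {
  grid <- channel_grid(width = 6, length = 20, spacing = 1)
  plan <- tbadflow:::build_plan(grid, fluid_properties(), "velocity")
  plan$outlet_rows_j <- grid$outlet_rows
  plan$inlet_rows_j <- grid$inlet_rows
  bcf <- list(u_in = function(t) 0.05, v_branch = function(t) numeric(0),
              branch_faces = list(), p_out = function(t) 1e4,
              p_in = function(t) 0, fx = function(t) 0)
  nx <- grid$nx; ny <- grid$ny
  # smooth but strongly divergent initial velocity
  st <- list(t = 0,
             U = outer(seq_len(nx + 1) / nx, seq_len(ny) / ny,
                       function(a, b) 0.1 * sin(2 * pi * a) * b),
             V = matrix(0, nx, ny + 1),
             P = matrix(1e4, nx, ny), p_out_prev = 1e4, p_in_prev = NA_real_)
  st$V[, c(1, ny + 1)] <- 0
  out <- tbadflow:::ns_step(st, plan, bcf, dt = 5e-4)
  expect_lt(out$maxdiv, 1e-8)
})

test_that("identical configurations reproduce bit-identical snapshots", {
  grid <- channel_grid(width = 6, length = 20, spacing = 1)
  bc <- list(inlet = inlet_velocity_waveform(peak = 0.05),
             outlet = constant_pressure_wf(), branches = FALSE,
             inlet_type = "velocity")
  s1 <- simulate(grid, bc = bc, n_cycles = 1, snapshot_phases = c(0.25, 0.6))
  s2 <- simulate(grid, bc = bc, n_cycles = 1, snapshot_phases = c(0.25, 0.6))
  expect_identical(s1$snapshots[[1]]$u, s2$snapshots[[1]]$u)
  expect_identical(s1$snapshots[[2]]$v, s2$snapshots[[2]]$v)
  expect_identical(s1$snapshots[[2]]$p, s2$snapshots[[2]]$p)
})

test_that("snapshots land at the requested final-cycle phases", {
  geom <- make_case(1)
  sim <- simulate(geom, spacing = 2, n_cycles = 1)
  expect_length(sim$snapshots, 2)
  expect_equal(sim$snapshots[[1]]$time, 0.25)
  expect_equal(sim$snapshots[[2]]$time, 0.47)
})

test_that("quasi-steady limit of the oscillatory profile is Poiseuille", {
  fl <- fluid_properties()
  w <- 0.006; G <- 50
  y <- seq(0.0005, w - 0.0005, by = 0.0005)
  u_slow <- womersley_profile(y, t = 0, width = w, G = G, omega = 2 * pi * 1e-3,
                              fluid = fl)
  u_pois <- G / (2 * fl$dynamic_viscosity) * y * (w - y)
  expect_equal(u_slow, u_pois, tolerance = 0.01)
})
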