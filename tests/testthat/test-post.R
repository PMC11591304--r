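test_that("wall shear stress recovers the plane-Poiseuille closed form", {
  grid <- channel_grid(width = 20, length = 10, spacing = 1)
  mu <- 0.00371; U <- 0.2; w <- 0.02
  f <- make_field(grid, ufun = function(x, y) {
    ym <- y / 1000
    6 * U / w^2 * ym * (w - ym)
  })
  ws <- wall_shear_stress(f, grid, fluid_properties())
  expect_true(all(ws$reliable))
  # quadratic fit is exact for the parabolic profile: 6 mu U / w = 0.2226 Pa
  expect_equal(ws$wss, rep(6 * mu * U / w, nrow(ws)), tolerance = 1e-10)

  f0 <- make_field(grid)
  ws0 <- wall_shear_stress(f0, grid)
  expect_true(all(ws0$wss == 0))
})

test_that("wall-gradient error drops ~4x when the spacing is halved", {
  w <- 0.02
  exact <- pi / w  # d/dy sin(pi y / w) at the wall
  err <- vapply(c(1, 0.5), function(sp) {
    grid <- channel_grid(width = 20, length = 6, spacing = sp)
    f <- make_field(grid, ufun = function(x, y) sin(pi * (y / 1000) / w))
    ws <- wall_shear_stress(f, grid, fluid_properties(dynamic_viscosity = 1))
    abs(ws$wss[1] - exact)
  }, numeric(1))
  expect_gt(err[1] / err[2], 4 * 0.8)
  expect_lt(err[1] / err[2], 4 * 1.2)
})

test_that("regional summary has 12 complete rows with correct medians", {
  geom <- make_case(5)
  grid <- rasterize(geom, 1)
  f <- make_field(grid, pfun = function(x, y) 1000)
  s <- regional_summary(f, grid, geom, "systole")
  expect_equal(nrow(s), 12)
  expect_setequal(s$region, 1:6)
  expect_setequal(s$lumen, c("true", "false"))
  expect_equal(s$pressure_median, rep(1.0, 12))  # 1000 Pa -> 1 kPa
  expect_true(all(s$n_cells > 0))
  expect_true(all(s$wss_max >= s$wss_median))

  # medians match a brute-force sort-based median on the same cell sets
  set.seed(42)
  p <- matrix(stats::runif(grid$nx * grid$ny, 9e3, 2e4), grid$nx, grid$ny)
  f2 <- f; f2$p <- p
  s2 <- regional_summary(f2, grid, geom, "systole")
  sort_median <- function(x) {
    x <- sort(x); n <- length(x)
    if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
  }
  for (r in 1:6) {
    for (lum in c(2L, 3L)) {
      cells <- grid$lumen == lum & grid$region == r
      got <- s2$pressure_median[s2$region == r &
                                  s2$lumen == c("true", "false")[lum - 1L]]
      expect_equal(got, sort_median(p[cells]) / 1000)
    }
  }
})

test_that("pressure differences subtract true minus false lumen", {
  s <- tibble::tibble(
    case_id = 1, region = rep(1:6, each = 2),
    lumen = rep(c("true", "false"), 6), phase = "systole",
    pressure_median = rep(c(16.3, 16.0), 6),
    wss_median = 1, wss_max = 2, peak_speed = 1, n_cells = 10)
  pd <- pressure_difference(s)
  expect_equal(pd$by_region$tl_minus_fl_kpa, rep(0.3, 6))
  expect_equal(pd$tl_inlet_outlet_gap_kpa, 0)
  s$pressure_median[s$lumen == "false"] <- s$pressure_median[s$lumen == "true"]
  pd2 <- pressure_difference(s)
  expect_equal(pd2$by_region$tl_minus_fl_kpa, rep(0, 6))
})

test_that("tear flux integrates the septum-normal velocity with FL->TL sign", {
  geom <- make_case(5)
  grid <- rasterize(geom, 0.8)   # 6.4 mm tears rasterize exactly
  f0 <- make_field(grid)
  expect_equal(tear_flux(f0, grid, geom, "entry"), 0)
  f <- make_field(grid, vfun = function(x, y) 0.1)
  expect_equal(tear_flux(f, grid, geom, "entry"), 0.1 * 6.4e-3,
               tolerance = 1e-12)
  expect_equal(tear_flux(f, grid, geom, "re_entry"), 0.1 * 6.4e-3,
               tolerance = 1e-12)
  # antisymmetry under field negation
  fneg <- f; fneg$v <- -f$v
  expect_equal(tear_flux(fneg, grid, geom, "entry"),
               -tear_flux(f, grid, geom, "entry"))
  # absent tear is an explicit error
  g1 <- make_case(1)
  grid1 <- rasterize(g1, 0.8)
  expect_error(tear_flux(make_field(grid1), grid1, g1, "re_entry"), "absent")
})

test_that("recirculation extent counts reversed-flow area below the tear", {
  geom <- make_case(5)
  grid <- rasterize(geom, 1)
  fwd <- make_field(grid, ufun = function(x, y) 0.05)
  expect_equal(recirculation_extent(fwd, grid, geom)$area_fraction_reversed, 0)
  rev <- make_field(grid, ufun = function(x, y) -0.05)
  expect_equal(recirculation_extent(rev, grid, geom)$area_fraction_reversed, 1)

  # solid-body vortex centered in the sub-tear zone vs direct enumeration
  lay <- tbadflow:::geom_layout(geom)
  xc0 <- (lay$re1 + lay$fl_floor) / 2; yc0 <- lay$fl_hi / 2
  om <- 2  # rad/s -> speeds up to ~0.1 m/s at 50 mm radius
  fv <- make_field(grid,
                   ufun = function(x, y) -om * (y - yc0) / 1000,
                   vfun = function(x, y) om * (x - xc0) / 1000)
  rc <- recirculation_extent(fv, grid, geom, threshold = 0.01,
                             reference_speed = 0.125)
  zone <- grid$lumen == 3L &
    matrix(grid$xc >= lay$re1, grid$nx, grid$ny)
  uc <- 0.5 * (fv$u[seq_len(grid$nx), ] + fv$u[seq_len(grid$nx) + 1, ])
  brute <- sum(uc[zone] < -0.01 * 0.125) / sum(zone)
  expect_equal(rc$area_fraction_reversed, brute)
  expect_gt(rc$area_fraction_reversed, 0.2)  # about the reversed half
  expect_lt(rc$area_fraction_reversed, 0.8)
  expect_equal(rc$reversed_area_mm2 + 0, brute * sum(zone) * 1)

  # case 1: the whole false lumen is the zone
  g1 <- make_case(1)
  grid1 <- rasterize(g1, 1)
  rc1 <- recirculation_extent(make_field(grid1, ufun = function(x, y) -1),
                              grid1, g1)
  expect_equal(rc1$zone, "false_lumen")
  expect_equal(rc1$area_fraction_reversed, 1)
})

test_that("peak velocity location reports labels and documented tie-breaks", {
  geom <- make_case(5)
  grid <- rasterize(geom, 1)
  # single nonzero cell in the false lumen, region 4
  cells <- which(grid$lumen == 3L & grid$region == 4L, arr.ind = TRUE)
  f <- make_field(grid)
  ij <- cells[5, ]
  f$u[ij[1], ij[2]] <- 0.7; f$u[ij[1] + 1L, ij[2]] <- 0.7
  pv <- peak_velocity_location(f, grid, geom)
  expect_equal(pv$label, "false_lumen")
  expect_equal(pv$region, 4L)
  expect_equal(pv$speed, 0.7)

  # exact tie in regions 3 (false) and 5 (true): lowest region wins
  tl5 <- which(grid$lumen == 2L & grid$region == 5L, arr.ind = TRUE)[1, ]
  fl3 <- which(grid$lumen == 3L & grid$region == 3L, arr.ind = TRUE)[1, ]
  f2 <- make_field(grid)
  for (ij in list(tl5, fl3)) {
    f2$u[ij[1], ij[2]] <- 0.5; f2$u[ij[1] + 1L, ij[2]] <- 0.5
  }
  pv2 <- peak_velocity_location(f2, grid, geom)
  expect_equal(pv2$region, 3L)
  expect_equal(pv2$label, "false_lumen")

  # same region: true lumen before false
  tl3 <- which(grid$lumen == 2L & grid$region == 3L, arr.ind = TRUE)[1, ]
  f3 <- make_field(grid)
  for (ij in list(tl3, fl3)) {
    f3$u[ij[1], ij[2]] <- 0.5; f3$u[ij[1] + 1L, ij[2]] <- 0.5
  }
  expect_equal(peak_velocity_location(f3, grid, geom)$label, "true_lumen")

  # agrees with a brute-force argmax over all cells
  set.seed(11)
  f4 <- make_field(grid)
  f4$u[] <- stats::runif(length(f4$u))
  pv4 <- peak_velocity_location(f4, grid, geom)
  uc <- 0.5 * (f4$u[seq_len(grid$nx), ] + f4$u[seq_len(grid$nx) + 1, ])
  vc <- 0.5 * (f4$v[, seq_len(grid$ny)] + f4$v[, seq_len(grid$ny) + 1])
  sp <- sqrt(uc^2 + vc^2); sp[!grid$fluid] <- -Inf
  expect_equal(pv4$speed, max(sp))
})
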