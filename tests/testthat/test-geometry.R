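test_that("tear sizing follows the 50% short-axis rule", {
  expect_identical(tear_width(12.8), 6.4)
  expect_identical(tear_width(10.0), 5.0)
  expect_error(tear_width(0), "invalid geometry")
  expect_error(tear_width(-3), "invalid geometry")
  # linear and scale-equivariant
  for (a in c(0.5, 3, 12.8, 40)) {
    expect_equal(tear_width(2.5 * a), 2.5 * tear_width(a))
  }
})

test_that("the case factory enumerates the eleven-case scenario set", {
  expect_null(make_case(1)$re_entry)
  d <- reentry_distances()
  expect_length(d, 10)
  expect_true(all(diff(d) > 0))
  for (k in 2:11) {
    g <- make_case(k)
    expect_equal(g$re_entry$distance_from_floor, d[k - 1])
    expect_equal(g$re_entry$width, tear_width(g$false_lumen_short_axis))
  }
  expect_equal(make_case(2)$re_entry$distance_from_floor, 22.5)
  expect_equal(make_case(11)$re_entry$distance_from_floor, 202.3)
  expect_error(make_case(0), "1..11")
  expect_error(make_case(12), "1..11")

  tab <- case_table()
  expect_equal(nrow(tab), 11)
  expect_true(is.na(tab$re_entry_distance_mm[1]))
  expect_equal(tab$tear_width_mm[-1], rep(6.4, 10))
})

test_that("geometry invariants are enforced", {
  # re-entry overlapping the entry tear
  expect_error(
    dissection_geometry(re_entry = list(distance_from_floor = 215, width = 6.4)),
    "distal to the entry tear")
  # re-entry tear running past the proximal cap or the floor
  expect_error(
    dissection_geometry(re_entry = list(distance_from_floor = 219, width = 6.4)),
    "inside the dissected segment")
  expect_error(
    dissection_geometry(re_entry = list(distance_from_floor = 2, width = 6.4)),
    "inside the dissected segment")
  # tear wider than the false lumen short axis
  expect_error(dissection_geometry(entry_tear_width = 15), "wider")
  expect_error(dissection_geometry(true_lumen_width = -1), "positive")
  # branch fractions must sum below 1
  bad <- list(list(axial_position = 30, width = 6, outflow_fraction = 0.6),
              list(axial_position = 45, width = 6, outflow_fraction = 0.6))
  expect_error(dissection_geometry(branch_slots = bad), "sum to < 1")
})

test_that("region partition is exhaustive, disjoint and equal-length", {
  b <- partition_regions(225, 6)
  expect_equal(b, c(0, 37.5, 75, 112.5, 150, 187.5, 225))
  expect_equal(partition_regions(100, 1), c(0, 100))
  for (n in c(2, 5, 6, 9)) {
    b <- partition_regions(137.5, n)
    expect_length(b, n + 1)
    expect_true(all(diff(b) > 0))
    expect_equal(diff(b), rep(137.5 / n, n))   # equal length
    expect_equal(b[1], 0)
    expect_equal(b[n + 1], 137.5)              # union covers the segment
  }
  expect_error(partition_regions(100, 0), "positive integer")
})

test_that("rasterization honors septum openings and connectivity", {
  for (k in c(1, 2, 5, 11)) {
    g <- make_case(k)
    grid <- rasterize(g, 1)
    expect_equal(septum_openings(grid), if (k == 1) 1L else 2L)
    expect_true(grid_connected(grid))
  }
  # refinement preserves connectivity
  g <- make_case(5)
  for (sp in c(2, 1, 0.5)) expect_true(grid_connected(rasterize(g, sp)))
})

test_that("fluid cell count scales like area / spacing^2", {
  g <- make_case(5)
  n1 <- sum(rasterize(g, 1)$fluid)
  n2 <- sum(rasterize(g, 0.5)$fluid)
  expect_gt(n2 / n1, 4 * 0.9)
  expect_lt(n2 / n1, 4 * 1.1)
})

test_that("too-coarse rasterization names the under-resolved feature", {
  g <- make_case(5)
  expect_error(rasterize(g, 3), "entry_tear|re_entry_tear|false_lumen")
  expect_error(rasterize(dissection_geometry(septum_thickness = 0.4), 1),
               "septum")
})

test_that("lumen labels partition the dissected fluid cells", {
  g <- make_case(5)
  grid <- rasterize(g, 1)
  lay <- grid$layout
  diss <- grid$xc >= lay$x_d0 & grid$xc < lay$x_d1
  # every fluid cell in the dissected segment carries a dissected label
  codes <- grid$lumen[grid$fluid & matrix(diss, grid$nx, grid$ny)]
  expect_true(all(codes %in% 2:5))
  # both tears present, false lumen sealed from the proximal channel
  expect_true(any(grid$lumen == 4))
  expect_true(any(grid$lumen == 5))
  # undissected cells only outside
  codes_out <- grid$lumen[grid$fluid & !matrix(diss, grid$nx, grid$ny)]
  expect_true(all(codes_out == 1))
})

test_that("case table and mask exports are well-formed text files", {
  td <- withr::local_tempdir()
  p <- write_case_table_csv(path = file.path(td, "cases.csv"))
  tab <- utils::read.csv(p)
  expect_equal(nrow(tab), 11)
  g <- rasterize(make_case(1), 2)
  v <- write_mask_vtk(g, file.path(td, "mask.vtk"))
  head <- readLines(v, n = 4)
  expect_match(head[1], "vtk DataFile")
  expect_match(head[4], "STRUCTURED_POINTS")
})
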