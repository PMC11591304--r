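#' Re-entry tear locations of the eleven-case scenario set
#'
#' Distances of the candidate re-entry (fenestration) tear centers from the
#' distal floor of the false lumen, measured proximally, in millimetres.
#' Case 1 carries no re-entry tear; cases 2-11 map to these distances in order.
#'
#' @return Numeric vector of 10 distances (mm).
#' @export
reentry_distances <- function() {
  c(22.5, 33.7, 67.4, 89.9, 112.4, 134.9, 157.4, 168.6, 179.8, 202.3)
}

#' Tear diameter from the false-lumen short axis
#'
#' The re-entry tear is sized at 50% of the short axis of the false lumen.
#'
#' @param false_lumen_short_axis Short axis of the false lumen (mm), > 0.
#' @return Tear width (mm), exactly half the short axis.
#' @examples
#' tear_width(12.8)  # 6.4
#' @export
tear_width <- function(false_lumen_short_axis) {
  if (!is.numeric(false_lumen_short_axis) || length(false_lumen_short_axis) < 1 ||
      any(!is.finite(false_lumen_short_axis)) || any(false_lumen_short_axis <= 0)) {
    stop("invalid geometry: false_lumen_short_axis must be a positive length (mm)",
         call. = FALSE)
  }
  0.5 * false_lumen_short_axis
}

default_branch_slots <- function() {
  list(
    list(axial_position = 10, width = 6, outflow_fraction = 0.05),
    list(axial_position = 25, width = 6, outflow_fraction = 0.05),
    list(axial_position = 40, width = 6, outflow_fraction = 0.05)
  )
}

#' Idealized dissected-aorta geometry
#'
#' Parametric two-dimensional idealization of a type B dissected aorta:
#' a straight vessel whose dissected segment is split by a septum (intimal
#' flap) into a true lumen and a false lumen that is sealed at both ends,
#' with a proximal entry tear in the septum and an optional re-entry tear.
#' The axial coordinate x increases distally (in the flow direction); the
#' false lumen occupies the low-y side of the channel, the true lumen the
#' high-y side. Branch outflow slots sit on the outer (true-lumen side)
#' wall of the undissected proximal segment.
#'
#' @param proximal_length Undissected proximal segment length (mm).
#' @param dissected_length Length of the dissected segment (mm).
#' @param distal_length Undissected distal segment length (mm).
#' @param true_lumen_width Transverse width of the true lumen (mm).
#' @param false_lumen_short_axis Transverse width (short axis) of the false
#'   lumen (mm). The 50% tear-sizing rule applies to this value.
#' @param septum_thickness Thickness of the septum / intimal flap (mm); also
#'   used for the false-lumen end caps.
#' @param entry_tear_width Axial width of the entry tear (mm).
#' @param entry_tear_offset Axial offset of the entry-tear proximal edge from
#'   the start of the open false lumen (mm).
#' @param re_entry `NULL` (no re-entry tear) or a list with elements
#'   `distance_from_floor` (mm, tear center measured proximally from the
#'   false-lumen distal floor) and `width` (mm).
#' @param branch_slots List of branch outflow slots, each a list with
#'   `axial_position` (slot center, mm from the inlet), `width` (mm) and
#'   `outflow_fraction` (fraction of instantaneous inlet flow).
#' @param n_regions Number of equal axial regions partitioning the dissected
#'   segment (default 6).
#' @return An object of class `dissection_geometry`.
#' @export
dissection_geometry <- function(proximal_length = 60,
                                dissected_length = 225,
                                distal_length = 20,
                                true_lumen_width = 20,
                                false_lumen_short_axis = 12.8,
                                septum_thickness = 2,
                                entry_tear_width = 6.4,
                                entry_tear_offset = 0,
                                re_entry = NULL,
                                branch_slots = default_branch_slots(),
                                n_regions = 6) {
  lens <- c(proximal_length, dissected_length, distal_length,
            true_lumen_width, false_lumen_short_axis, septum_thickness,
            entry_tear_width)
  if (any(!is.finite(lens)) || any(lens <= 0)) {
    stop("invalid geometry: all lengths must be positive", call. = FALSE)
  }
  if (entry_tear_offset < 0) {
    stop("invalid geometry: entry_tear_offset must be >= 0", call. = FALSE)
  }
  if (entry_tear_width > false_lumen_short_axis) {
    stop("invalid geometry: entry tear wider than the false-lumen short axis",
         call. = FALSE)
  }
  g <- structure(
    list(
      proximal_length = proximal_length,
      dissected_length = dissected_length,
      distal_length = distal_length,
      true_lumen_width = true_lumen_width,
      false_lumen_short_axis = false_lumen_short_axis,
      septum_thickness = septum_thickness,
      entry_tear_width = entry_tear_width,
      entry_tear_offset = entry_tear_offset,
      re_entry = re_entry,
      branch_slots = branch_slots,
      region_bounds = partition_regions(dissected_length, n_regions)
    ),
    class = "dissection_geometry"
  )
  validate_geometry(g)
  g
}

# Axial/transverse layout (all mm, x from inlet, y from false-lumen outer wall).
geom_layout <- function(geom) {
  w_t <- geom$septum_thickness
  x_d0 <- geom$proximal_length
  x_d1 <- x_d0 + geom$dissected_length
  fl_lo <- 0
  fl_hi <- geom$false_lumen_short_axis
  sep_hi <- fl_hi + geom$septum_thickness
  width <- sep_hi + geom$true_lumen_width
  # open false-lumen axial extent (between the end caps)
  fl_x0 <- x_d0 + w_t
  fl_floor <- x_d1 - w_t
  entry0 <- fl_x0 + geom$entry_tear_offset
  entry1 <- entry0 + geom$entry_tear_width
  re0 <- re1 <- re_center <- NA_real_
  if (!is.null(geom$re_entry)) {
    re_center <- fl_floor - geom$re_entry$distance_from_floor
    re0 <- re_center - geom$re_entry$width / 2
    re1 <- re_center + geom$re_entry$width / 2
  }
  list(
    x_d0 = x_d0, x_d1 = x_d1, fl_x0 = fl_x0, fl_floor = fl_floor,
    fl_lo = fl_lo, fl_hi = fl_hi, sep_hi = sep_hi, width = width,
    length = x_d1 + geom$distal_length,
    entry0 = entry0, entry1 = entry1,
    re0 = re0, re1 = re1, re_center = re_center
  )
}

validate_geometry <- function(geom) {
  lay <- geom_layout(geom)
  if (lay$entry1 > lay$fl_floor) {
    stop("invalid geometry: entry tear extends past the false-lumen floor",
         call. = FALSE)
  }
  fr <- vapply(geom$branch_slots, function(s) s$outflow_fraction, numeric(1))
  if (length(fr) && (any(fr <= 0) || sum(fr) >= 1)) {
    stop("invalid geometry: branch outflow fractions must be in (0,1) and sum to < 1",
         call. = FALSE)
  }
  for (s in geom$branch_slots) {
    if (s$axial_position - s$width / 2 < 0 ||
        s$axial_position + s$width / 2 > geom$proximal_length) {
      stop("invalid geometry: branch slot outside the proximal segment",
           call. = FALSE)
    }
  }
  if (!is.null(geom$re_entry)) {
    re <- geom$re_entry
    if (!is.finite(re$distance_from_floor) || re$distance_from_floor <= 0 ||
        !is.finite(re$width) || re$width <= 0) {
      stop("invalid geometry: re-entry tear requires positive distance and width",
           call. = FALSE)
    }
    if (re$width > geom$false_lumen_short_axis) {
      stop("invalid geometry: re-entry tear wider than the false-lumen short axis",
           call. = FALSE)
    }
    if (lay$re0 <= lay$fl_x0 || lay$re1 >= lay$fl_floor) {
      stop("invalid geometry: re-entry tear not strictly inside the dissected segment",
           call. = FALSE)
    }
    if (lay$re0 <= lay$entry1) {
      stop("invalid geometry: re-entry tear must lie distal to the entry tear",
           call. = FALSE)
    }
  }
  bounds <- geom$region_bounds
  if (any(diff(bounds) <= 0) || abs(bounds[1]) > 1e-12 ||
      abs(bounds[length(bounds)] - geom$dissected_length) > 1e-9) {
    stop("invalid geometry: region bounds must increase and span the dissected segment",
         call. = FALSE)
  }
  invisible(geom)
}

#' Build one case of the eleven-case re-entry-location scenario set
#'
#' Case 1 has an entry tear only; cases 2-11 add a re-entry tear at the k-th
#' listed distance from the false-lumen floor (see [reentry_distances()]),
#' sized by the 50% rule ([tear_width()]).
#'
#' @param case_id Integer in 1..11.
#' @param base Geometry defaults, a [dissection_geometry()].
#' @return A `dissection_geometry` for the requested case, with attribute
#'   `case_id`.
#' @export
make_case <- function(case_id, base = dissection_geometry()) {
  if (length(case_id) != 1 || !is.finite(case_id) || case_id != round(case_id) ||
      case_id < 1 || case_id > 11) {
    stop("case_id must be an integer in 1..11", call. = FALSE)
  }
  case_id <- as.integer(case_id)
  re <- NULL
  if (case_id >= 2L) {
    re <- list(
      distance_from_floor = reentry_distances()[case_id - 1L],
      width = tear_width(base$false_lumen_short_axis)
    )
  }
  g <- dissection_geometry(
    proximal_length = base$proximal_length,
    dissected_length = base$dissected_length,
    distal_length = base$distal_length,
    true_lumen_width = base$true_lumen_width,
    false_lumen_short_axis = base$false_lumen_short_axis,
    septum_thickness = base$septum_thickness,
    entry_tear_width = base$entry_tear_width,
    entry_tear_offset = base$entry_tear_offset,
    re_entry = re,
    branch_slots = base$branch_slots,
    n_regions = length(base$region_bounds) - 1L
  )
  attr(g, "case_id") <- case_id
  g
}

#' Scenario table for the eleven cases
#'
#' @param base Geometry defaults used for the tear-sizing rule.
#' @return A tibble with `case_id`, `re_entry_distance_mm` (NA for case 1) and
#'   `tear_width_mm`.
#' @export
case_table <- function(base = dissection_geometry()) {
  tibble::tibble(
    case_id = 1:11,
    re_entry_distance_mm = c(NA_real_, reentry_distances()),
    tear_width_mm = c(NA_real_, rep(tear_width(base$false_lumen_short_axis), 10))
  )
}

#' Partition the dissected segment into equal axial regions
#'
#' @param dissected_length The dissected-segment length (mm), or a
#'   `dissection_geometry` whose `dissected_length` is used.
#' @param n_regions Number of regions (>= 1).
#' @return Numeric vector of `n_regions + 1` strictly increasing bounds
#'   spanning `[0, dissected_length]` (local axial coordinates, mm).
#' @export
partition_regions <- function(dissected_length, n_regions = 6) {
  if (inherits(dissected_length, "dissection_geometry")) {
    dissected_length <- dissected_length$dissected_length
  }
  if (n_regions < 1 || n_regions != round(n_regions)) {
    stop("n_regions must be a positive integer", call. = FALSE)
  }
  seq(0, dissected_length, length.out = n_regions + 1)
}

# lumen label codes used in masked grids
LUMEN_CODES <- c(solid = 0L, undissected = 1L, true_lumen = 2L,
                 false_lumen = 3L, entry_tear = 4L, re_entry_tear = 5L)

lumen_name <- function(code) names(LUMEN_CODES)[match(code, LUMEN_CODES)]

#' Rasterize a dissection geometry to a masked Cartesian grid
#'
#' Cell-centered stair-step masking: a cell is fluid when its center lies in
#' the fluid region. Cells are square with side `spacing`. The returned grid
#' carries per-cell lumen labels (undissected / true lumen / false lumen /
#' entry tear / re-entry tear), per-cell region ids over the dissected
#' segment, and the boundary bookkeeping (inlet, outlet, branch slots, tear
#' column ranges) the solver and post-processing need.
#'
#' @param geom A [dissection_geometry()].
#' @param spacing Grid spacing (mm). Every tear and lumen must span at least
#'   3 cells across, otherwise a resolution error naming the offending
#'   feature is raised.
#' @return An object of class `masked_grid`.
#' @export
rasterize <- function(geom, spacing) {
  stopifnot(inherits(geom, "dissection_geometry"))
  if (!is.finite(spacing) || spacing <= 0) {
    stop("spacing must be a positive length (mm)", call. = FALSE)
  }
  lay <- geom_layout(geom)
  nx <- max(1L, as.integer(round(lay$length / spacing)))
  ny <- max(1L, as.integer(round(lay$width / spacing)))
  xc <- (seq_len(nx) - 0.5) * spacing
  yc <- (seq_len(ny) - 0.5) * spacing

  in_band <- function(v, lo, hi) v >= lo & v < hi
  # resolution preconditions: feature span in cells
  span <- function(lo, hi, cc) sum(in_band(cc, lo, hi))
  checks <- list(
    true_lumen = span(lay$sep_hi, lay$width, yc),
    false_lumen = span(lay$fl_lo, lay$fl_hi, yc),
    entry_tear = span(lay$entry0, lay$entry1, xc)
  )
  if (!is.null(geom$re_entry)) {
    checks$re_entry_tear <- span(lay$re0, lay$re1, xc)
  }
  bad <- names(checks)[vapply(checks, function(n) n < 3L, logical(1))]
  if (length(bad)) {
    stop(sprintf("spacing %.3g mm too coarse: feature '%s' spans fewer than 3 cells",
                 spacing, bad[1]), call. = FALSE)
  }
  if (span(lay$fl_hi, lay$sep_hi, yc) < 1L) {
    stop(sprintf("spacing %.3g mm too coarse: feature 'septum' spans no cell row",
                 spacing), call. = FALSE)
  }

  X <- matrix(xc, nx, ny)
  Y <- matrix(yc, nx, ny, byrow = TRUE)
  dissected_x <- in_band(X, lay$x_d0, lay$x_d1)
  sep_band <- in_band(Y, lay$fl_hi, lay$sep_hi)
  fl_band <- in_band(Y, lay$fl_lo, lay$fl_hi)
  tl_band <- Y >= lay$sep_hi

  entry_gap <- in_band(X, lay$entry0, lay$entry1)
  re_gap <- if (is.null(geom$re_entry)) {
    matrix(FALSE, nx, ny)
  } else {
    in_band(X, lay$re0, lay$re1)
  }
  cap <- in_band(X, lay$x_d0, lay$fl_x0) | in_band(X, lay$fl_floor, lay$x_d1)

  # The vessel proper is the true-lumen band for the whole length; the false
  # lumen is an outward pocket off it within the dissected segment, sealed by
  # end caps, reached only through the septal tear gaps. Everything below the
  # septum top is wall otherwise.
  pocket <- dissected_x & !cap &
    (fl_band | (sep_band & (entry_gap | re_gap)))
  solid <- (fl_band | sep_band) & !pocket
  fluid <- !solid

  lumen <- matrix(LUMEN_CODES[["undissected"]], nx, ny)
  lumen[dissected_x & tl_band] <- LUMEN_CODES[["true_lumen"]]
  lumen[dissected_x & fl_band & fluid] <- LUMEN_CODES[["false_lumen"]]
  lumen[dissected_x & sep_band & fluid & entry_gap] <- LUMEN_CODES[["entry_tear"]]
  lumen[dissected_x & sep_band & fluid & re_gap] <- LUMEN_CODES[["re_entry_tear"]]
  lumen[solid] <- LUMEN_CODES[["solid"]]

  region <- matrix(0L, nx, ny)
  rb <- geom$region_bounds + lay$x_d0
  idx <- findInterval(xc, rb, rightmost.closed = TRUE)
  idx[xc < lay$x_d0 | xc >= lay$x_d1] <- 0L
  region[] <- idx[row(region)]
  region[!dissected_x] <- 0L
  region[solid] <- 0L

  # branch slot faces on the top wall (proximal segment only)
  slots <- lapply(seq_along(geom$branch_slots), function(k) {
    s <- geom$branch_slots[[k]]
    cols <- which(in_band(xc, s$axial_position - s$width / 2,
                          s$axial_position + s$width / 2) &
                  fluid[, ny][seq_len(nx)])
    if (!length(cols)) {
      stop(sprintf("spacing %.3g mm too coarse: feature 'branch slot %d' spans no cell",
                   spacing, k), call. = FALSE)
    }
    list(id = k, cols = cols, fraction = s$outflow_fraction,
         width_mm = length(cols) * spacing)
  })

  tear_cols <- function(lo, hi) which(in_band(xc, lo, hi))
  # v-face row just above the false-lumen top cell row (the tear throat)
  j_fl_top <- max(which(in_band(yc, lay$fl_lo, lay$fl_hi)))

  grid <- structure(
    list(
      spacing = spacing, nx = nx, ny = ny, xc = xc, yc = yc,
      fluid = fluid, lumen = lumen, region = region,
      inlet_rows = which(fluid[1, ]), outlet_rows = which(fluid[nx, ]),
      branch_slots = slots,
      entry_cols = tear_cols(lay$entry0, lay$entry1),
      re_entry_cols = if (is.null(geom$re_entry)) integer(0) else
        tear_cols(lay$re0, lay$re1),
      j_flux = j_fl_top + 1L,  # v-face index between FL top row and septum band
      layout = lay, geom = geom,
      case_id = attr(geom, "case_id")
    ),
    class = "masked_grid"
  )
  grid
}

#' Count septum openings in a rasterized grid
#'
#' An opening is a maximal run of grid columns, within the dissected segment,
#' whose septum band is fully fluid (a through-gap between the lumens).
#'
#' @param grid A [rasterize()]d `masked_grid`.
#' @return Integer count (1 for an entry-only case, 2 with a re-entry tear).
#' @export
septum_openings <- function(grid) {
  lay <- grid$layout
  sep_rows <- which(grid$yc >= lay$fl_hi & grid$yc < lay$sep_hi)
  cols <- which(grid$xc >= lay$x_d0 & grid$xc < lay$x_d1)
  open <- vapply(cols, function(i) all(grid$fluid[i, sep_rows]), logical(1))
  sum(diff(c(FALSE, open)) == 1L)
}

#' Check that every fluid cell is reachable from the inlet
#'
#' Flood fill over fluid-cell 4-adjacency starting from the inlet column.
#'
#' @param grid A `masked_grid`.
#' @return `TRUE` if all fluid cells are connected to the inlet.
#' @export
grid_connected <- function(grid) {
  F <- grid$fluid
  nx <- grid$nx; ny <- grid$ny
  reach <- matrix(FALSE, nx, ny)
  reach[1, grid$inlet_rows] <- TRUE
  repeat {
    grown <- reach
    grown[-1, ] <- grown[-1, ] | reach[-nx, ]
    grown[-nx, ] <- grown[-nx, ] | reach[-1, ]
    grown[, -1] <- grown[, -1] | reach[, -ny]
    grown[, -ny] <- grown[, -ny] | reach[, -1]
    grown <- grown & F
    if (identical(grown, reach)) break
    reach <- grown
  }
  all(reach[F])
}

#' Export the case table as CSV
#' @param base Geometry defaults.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_case_table_csv <- function(base = dissection_geometry(), path) {
  utils::write.csv(case_table(base), path, row.names = FALSE)
  invisible(path)
}

#' Export a grid mask (and optionally a snapshot) as legacy VTK
#'
#' Writes an ASCII VTK structured-points file with the cell mask, lumen
#' labels and region ids, plus velocity/pressure fields when a snapshot is
#' supplied; readable by ParaView.
#'
#' @param grid A `masked_grid`.
#' @param path Output file path.
#' @param field Optional `flow_field` snapshot to include.
#' @return `path`, invisibly.
#' @export
write_mask_vtk <- function(grid, path, field = NULL) {
  nx <- grid$nx; ny <- grid$ny
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# vtk DataFile Version 3.0",
    "tbadflow masked grid", "ASCII", "DATASET STRUCTURED_POINTS",
    sprintf("DIMENSIONS %d %d 1", nx, ny),
    sprintf("ORIGIN %g %g 0", grid$spacing / 2, grid$spacing / 2),
    sprintf("SPACING %g %g 1", grid$spacing, grid$spacing),
    sprintf("POINT_DATA %d", nx * ny)
  ), con)
  wr <- function(name, M, type = "int") {
    writeLines(sprintf("SCALARS %s %s 1", name,
                       if (type == "int") "int" else "float"), con)
    writeLines("LOOKUP_TABLE default", con)
    writeLines(paste(as.vector(M), collapse = " "), con)
  }
  wr("fluid", matrix(as.integer(grid$fluid), nx, ny))
  wr("lumen", grid$lumen)
  wr("region", grid$region)
  if (!is.null(field)) {
    wr("p", signif(field$p, 8), "float")
    uc <- 0.5 * (field$u[seq_len(nx), ] + field$u[seq_len(nx) + 1L, ])
    vc <- 0.5 * (field$v[, seq_len(ny)] + field$v[, seq_len(ny) + 1L])
    wr("u", signif(uc, 8), "float")
    wr("v", signif(vc, 8), "float")
  }
  invisible(path)
}
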