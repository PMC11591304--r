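# cell-centered velocity components of a snapshot
cell_velocity <- function(field, grid) {
  nx <- grid$nx; ny <- grid$ny
  list(
    u = 0.5 * (field$u[seq_len(nx), , drop = FALSE] +
                 field$u[seq_len(nx) + 1L, , drop = FALSE]),
    v = 0.5 * (field$v[, seq_len(ny), drop = FALSE] +
                 field$v[, seq_len(ny) + 1L, drop = FALSE])
  )
}

#' Wall shear stress samples along the wetted walls
#'
#' For every wall-adjacent fluid cell the tangential velocity gradient at
#' the wall is estimated by a one-sided quadratic fit through the wall
#' (no-slip zero) and the two nearest cell-centered tangential velocities:
#' `du/dn = (9 u1 - u2) / (3 h)`, second-order accurate and exact for
#' parabolic profiles. Samples whose second interior cell is unavailable
#' (walls under-resolved to fewer than 2 fluid cells across) are flagged
#' `reliable = FALSE` and excluded from summaries. Branch outflow slots and
#' the inlet/outlet planes are open boundaries, not walls, and produce no
#' samples.
#'
#' @param field A [flow_field()].
#' @param grid The `masked_grid` the field lives on.
#' @param fluid [fluid_properties()] providing the dynamic viscosity.
#' @return Tibble with `x_mm`, `y_mm` (wall point), `normal` (wall normal
#'   direction), `lumen`, `region`, `wss` (Pa, magnitude), `reliable`.
#' @export
wall_shear_stress <- function(field, grid, fluid = fluid_properties()) {
  nx <- grid$nx; ny <- grid$ny
  h <- grid$spacing / 1000
  mu <- fluid$dynamic_viscosity
  F <- grid$fluid
  cv <- cell_velocity(field, grid)

  branch_top <- rep(FALSE, nx)
  for (s in grid$branch_slots) branch_top[s$cols] <- TRUE

  out <- list()
  emit <- function(idx, tang, off_i, off_j, wall_x, wall_y, normal) {
    if (!nrow(idx)) return()
    u1 <- tang[idx]
    i2 <- idx[, 1] + off_i; j2 <- idx[, 2] + off_j
    ok <- i2 >= 1 & i2 <= nx & j2 >= 1 & j2 <= ny
    ok[ok] <- F[cbind(i2[ok], j2[ok])]
    u2 <- rep(NA_real_, length(u1))
    u2[ok] <- tang[cbind(i2[ok], j2[ok])]
    grad <- ifelse(ok, (9 * u1 - u2) / (3 * h), 2 * u1 / h)
    out[[length(out) + 1L]] <<- tibble::tibble(
      x_mm = wall_x, y_mm = wall_y, normal = normal,
      lumen = lumen_name(grid$lumen[idx]),
      region = grid$region[idx],
      wss = mu * abs(grad), reliable = ok)
  }

  solid_or_edge_S <- cbind(rep(TRUE, nx), !F[, -ny, drop = FALSE])
  solid_or_edge_N <- cbind(!F[, -1, drop = FALSE], !branch_top)
  idx <- which(F & solid_or_edge_S, arr.ind = TRUE)
  emit(idx, cv$u, 0L, 1L, grid$xc[idx[, 1]], (idx[, 2] - 1) * grid$spacing, "y-")
  idx <- which(F & solid_or_edge_N, arr.ind = TRUE)
  emit(idx, cv$u, 0L, -1L, grid$xc[idx[, 1]], idx[, 2] * grid$spacing, "y+")

  solid_W <- rbind(rep(FALSE, ny), !F[-nx, , drop = FALSE])  # x-edges are open
  solid_E <- rbind(!F[-1, , drop = FALSE], rep(FALSE, ny))
  idx <- which(F & solid_W, arr.ind = TRUE)
  emit(idx, cv$v, 1L, 0L, (idx[, 1] - 1) * grid$spacing, grid$yc[idx[, 2]], "x-")
  idx <- which(F & solid_E, arr.ind = TRUE)
  emit(idx, cv$v, -1L, 0L, idx[, 1] * grid$spacing, grid$yc[idx[, 2]], "x+")

  do.call(rbind, out)
}

# (x, y) positions (mm) of the re-entrant wall corners of a grid: tear lip
# corners on both septum surfaces, branch slot edges, and the wall junctions
# of the inlet/outlet planes. Concave (flow-stagnant) corners are harmless
# for wall shear and are not listed.
wall_corner_points <- function(grid) {
  lay <- grid$layout
  pts <- list()
  add <- function(x, y) pts[[length(pts) + 1L]] <<- c(x, y)
  if (!is.null(grid$geom)) {
    for (xe in c(lay$entry0, lay$entry1)) {
      add(xe, lay$fl_hi); add(xe, lay$sep_hi)
    }
    if (!is.na(lay$re0)) {
      for (xe in c(lay$re0, lay$re1)) {
        add(xe, lay$fl_hi); add(xe, lay$sep_hi)
      }
    }
    for (s in grid$geom$branch_slots) {
      add(s$axial_position - s$width / 2, lay$width)
      add(s$axial_position + s$width / 2, lay$width)
    }
    add(0, lay$sep_hi); add(0, lay$width)
    L <- lay$length
    add(L, lay$sep_hi); add(L, lay$width)
  } else {
    L <- grid$nx * grid$spacing; W <- grid$ny * grid$spacing
    add(0, 0); add(0, W); add(L, 0); add(L, W)
  }
  do.call(rbind, pts)
}

#' Maximum wall shear stress away from geometric corners
#'
#' Largest reliable WSS sample at a fixed physical distance from every
#' re-entrant wall corner of the stair-step geometry. At such corners the
#' continuum wall shear stress is unbounded, so a pointwise maximum taken
#' there cannot converge under grid refinement; the interior maximum is the
#' grid-convergent analog used by the mesh-sensitivity study.
#'
#' @param wss A [wall_shear_stress()] table.
#' @param grid The `masked_grid` the samples came from.
#' @param exclusion_mm Exclusion radius around each corner (mm); default one
#'   septum thickness.
#' @param scope `"dissected"` restricts to samples inside the dissected
#'   segment (the six analysis regions), avoiding the flat-inlet leading-edge
#'   boundary layer of the proximal plumbing; `"all"` keeps every wall.
#' @return Maximum WSS (Pa) over the retained samples.
#' @export
wss_max_interior <- function(wss, grid, exclusion_mm = 2,
                             scope = c("dissected", "all")) {
  scope <- match.arg(scope)
  keep <- wss$reliable
  if (scope == "dissected" && !is.null(grid$geom)) keep <- keep & wss$region > 0
  corners <- wall_corner_points(grid)
  for (k in seq_len(nrow(corners))) {
    d2 <- (wss$x_mm - corners[k, 1])^2 + (wss$y_mm - corners[k, 2])^2
    keep <- keep & d2 > exclusion_mm^2
  }
  if (!any(keep)) return(NA_real_)
  max(wss$wss[keep])
}

#' Per-region, per-lumen summary of a snapshot
#'
#' Aggregates cell pressures (median, kPa), wall shear stress samples
#' (median and max of reliable samples, Pa) and peak cell speed (m/s) over
#' the regions of the dissected segment, separately for the true and false
#' lumen. Tear cells belong to neither lumen and are excluded. A
#' (region, lumen) pair without fluid cells yields a row of `NA` markers,
#' never a dropped row.
#'
#' @param field A [flow_field()].
#' @param grid The `masked_grid`.
#' @param geom Geometry; defaults to the grid's.
#' @param phase Phase label, e.g. `"systole"` or `"diastole"`.
#' @param fluid [fluid_properties()] (for the WSS samples).
#' @param wss Optional precomputed [wall_shear_stress()] table.
#' @return Tibble with `n_regions x 2` rows: `case_id`, `region`, `lumen`,
#'   `phase`, `pressure_median` (kPa), `wss_median`, `wss_max` (Pa),
#'   `peak_speed` (m/s), `n_cells`.
#' @export
regional_summary <- function(field, grid, geom = grid$geom, phase = "systole",
                             fluid = fluid_properties(), wss = NULL) {
  n_regions <- length(geom$region_bounds) - 1L
  if (is.null(wss)) wss <- wall_shear_stress(field, grid, fluid)
  wss <- wss[wss$reliable & wss$region > 0 &
               wss$lumen %in% c("true_lumen", "false_lumen"), ]
  cv <- cell_velocity(field, grid)
  speed <- sqrt(cv$u^2 + cv$v^2)
  case_id <- if (is.null(grid$case_id)) NA_integer_ else grid$case_id

  rows <- list()
  for (reg in seq_len(n_regions)) {
    for (lum in c("true_lumen", "false_lumen")) {
      code <- LUMEN_CODES[[lum]]
      cells <- grid$lumen == code & grid$region == reg
      n <- sum(cells)
      ws <- wss[wss$region == reg & wss$lumen == lum, "wss", drop = TRUE]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        case_id = case_id, region = reg,
        lumen = if (lum == "true_lumen") "true" else "false",
        phase = phase,
        pressure_median = if (n) stats::median(field$p[cells]) / 1000 else NA_real_,
        wss_median = if (length(ws)) stats::median(ws) else NA_real_,
        wss_max = if (length(ws)) max(ws) else NA_real_,
        peak_speed = if (n) max(speed[cells]) else NA_real_,
        n_cells = n)
    }
  }
  do.call(rbind, rows)
}

#' True-minus-false lumen pressure gaps
#'
#' Per-region gap `pressure_median(true) - pressure_median(false)` (kPa) for
#' one case/phase summary, plus the true-lumen inlet-outlet gap
#' (region 1 minus region `n`).
#'
#' @param summaries A [regional_summary()] table for a single case and phase.
#' @return List with `by_region` (tibble `region`, `tl_minus_fl_kpa`) and
#'   `tl_inlet_outlet_gap_kpa`.
#' @export
pressure_difference <- function(summaries) {
  tl <- summaries[summaries$lumen == "true", ]
  fl <- summaries[summaries$lumen == "false", ]
  tl <- tl[order(tl$region), ]; fl <- fl[order(fl$region), ]
  if (!nrow(tl) || nrow(tl) != nrow(fl)) {
    stop("need a complete per-region summary of both lumens", call. = FALSE)
  }
  list(
    by_region = tibble::tibble(
      region = tl$region,
      tl_minus_fl_kpa = tl$pressure_median - fl$pressure_median),
    tl_inlet_outlet_gap_kpa =
      tl$pressure_median[1] - tl$pressure_median[nrow(tl)]
  )
}

#' Volumetric flow through a septal tear
#'
#' Integral of the septum-normal velocity across the tear gap (2D flow per
#' unit depth, m^2/s). Positive flux is directed from the false lumen to the
#' true lumen.
#'
#' @param field A [flow_field()].
#' @param grid The `masked_grid`.
#' @param geom Geometry; defaults to the grid's.
#' @param tear `"entry"` or `"re_entry"`.
#' @return Signed flux (m^2/s).
#' @export
tear_flux <- function(field, grid, geom = grid$geom,
                      tear = c("entry", "re_entry")) {
  tear <- match.arg(tear)
  cols <- if (tear == "entry") grid$entry_cols else grid$re_entry_cols
  if (!length(cols)) {
    stop(sprintf("tear '%s' is absent from this geometry", tear), call. = FALSE)
  }
  sum(field$v[cols, grid$j_flux]) * grid$spacing / 1000
}

#' Reversed-flow extent in the false lumen below the re-entry tear
#'
#' Over the false-lumen cells distal to the re-entry tear (the whole false
#' lumen when no re-entry tear exists), the fraction of cell area whose
#' axial velocity is reversed below `-threshold * reference_speed`.
#'
#' @param field A [flow_field()].
#' @param grid The `masked_grid`.
#' @param geom Geometry; defaults to the grid's.
#' @param threshold Relative reversal threshold (default 0.01).
#' @param reference_speed Reference speed (m/s); default 0.125, the default
#'   peak inlet velocity.
#' @param phase Phase label carried into the output.
#' @return One-row tibble: `case_id`, `phase`, `area_fraction_reversed`,
#'   `reversed_area_mm2`, `zone_area_mm2`, `zone`.
#' @export
recirculation_extent <- function(field, grid, geom = grid$geom,
                                 threshold = 0.01, reference_speed = 0.125,
                                 phase = NA_character_) {
  lay <- geom_layout(geom)
  fl <- grid$lumen == LUMEN_CODES[["false_lumen"]]
  if (is.null(geom$re_entry)) {
    zone <- fl
    zone_name <- "false_lumen"
  } else {
    zone <- fl & matrix(grid$xc >= lay$re1, grid$nx, grid$ny)
    zone_name <- "sub_tear_false_lumen"
  }
  cv <- cell_velocity(field, grid)
  nz <- sum(zone)
  rev_cells <- if (nz) sum(cv$u[zone] < -threshold * reference_speed) else 0L
  cell_area <- grid$spacing^2
  tibble::tibble(
    case_id = if (is.null(grid$case_id)) NA_integer_ else grid$case_id,
    phase = phase,
    area_fraction_reversed = if (nz) rev_cells / nz else 0,
    reversed_area_mm2 = rev_cells * cell_area,
    zone_area_mm2 = nz * cell_area,
    zone = zone_name)
}

#' Location of the peak velocity in a snapshot
#'
#' Maximum cell-centered speed and its location label. Tear gaps are
#' reported as their own labels (`entry_tear`, `re_entry_tear`). Exact ties
#' are broken by lowest region id, with the true lumen before the false
#' lumen and lumen locations before tear and undissected locations.
#'
#' @param field A [flow_field()].
#' @param grid The `masked_grid`.
#' @param geom Geometry; defaults to the grid's.
#' @return List with `speed` (m/s), `region` (0 outside the dissected
#'   segment) and `label`.
#' @export
peak_velocity_location <- function(field, grid, geom = grid$geom) {
  cv <- cell_velocity(field, grid)
  speed <- sqrt(cv$u^2 + cv$v^2)
  speed[!grid$fluid] <- -Inf
  mx <- max(speed)
  cand <- which(speed == mx, arr.ind = TRUE)
  pri <- c(true_lumen = 1, false_lumen = 2, entry_tear = 3,
           re_entry_tear = 4, undissected = 5)
  labels <- lumen_name(grid$lumen[cand])
  regions <- grid$region[cand]
  reg_key <- ifelse(regions == 0L, .Machine$integer.max, regions)
  ord <- order(reg_key, pri[labels])
  best <- ord[1]
  list(speed = mx, region = regions[best], label = labels[best])
}
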