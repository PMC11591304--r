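# Internal staggered-grid machinery.
#
# Layout (dx = dy = spacing, SI units inside the solver):
#   P : nx x ny        cell-center pressure (Pa)
#   U : (nx+1) x ny    axial velocity on vertical faces; U[i,j] at x=(i-1)dx
#   V : nx x (ny+1)    transverse velocity on horizontal faces; V[i,j] at y=(j-1)dy
# Face i of U separates cells i-1 and i; face j of V separates rows j-1 and j.
# Solid faces carry exactly zero velocity (rigid no-slip wall) and are never
# updated; Dirichlet faces (velocity inlet, branch slots) are prescribed each
# step; all remaining faces between fluid cells are unknowns.

# Shift so that out[i,j] = M[i-di, j-dj], zero/FALSE fill outside.
sh <- function(M, di = 0, dj = 0) {
  nr <- nrow(M); nc <- ncol(M)
  fill <- if (is.logical(M)) FALSE else 0
  out <- matrix(fill, nr, nc)
  rdst <- max(1, 1 + di):min(nr, nr + di)
  cdst <- max(1, 1 + dj):min(nc, nc + dj)
  out[rdst, cdst] <- M[rdst - di, cdst - dj, drop = FALSE]
  out
}

#' Plain rectangular channel grid
#'
#' All-fluid masked grid for the analytic validation benchmarks; no branch
#' slots, no septum. The inlet may be a velocity or a pressure boundary.
#'
#' @param width Channel width (mm).
#' @param length Channel length (mm).
#' @param spacing Grid spacing (mm).
#' @return A `masked_grid`.
#' @export
channel_grid <- function(width, length, spacing) {
  nx <- max(3L, as.integer(round(length / spacing)))
  ny <- max(3L, as.integer(round(width / spacing)))
  fluid <- matrix(TRUE, nx, ny)
  structure(
    list(
      spacing = spacing, nx = nx, ny = ny,
      xc = (seq_len(nx) - 0.5) * spacing, yc = (seq_len(ny) - 0.5) * spacing,
      fluid = fluid,
      lumen = matrix(LUMEN_CODES[["undissected"]], nx, ny),
      region = matrix(0L, nx, ny),
      inlet_rows = seq_len(ny), outlet_rows = seq_len(ny),
      branch_slots = list(),
      entry_cols = integer(0), re_entry_cols = integer(0), j_flux = NA_integer_,
      layout = list(width = width, length = length),
      geom = NULL, case_id = NA_integer_
    ),
    class = "masked_grid"
  )
}

# Precompute masks, stencil-availability maps and the factorized pressure
# Poisson operator for a masked grid.
build_plan <- function(grid, fluid = fluid_properties(),
                       inlet_type = c("velocity", "pressure")) {
  inlet_type <- match.arg(inlet_type)
  nx <- grid$nx; ny <- grid$ny
  dx <- grid$spacing / 1000  # m
  F <- grid$fluid

  # ---- u faces -------------------------------------------------------------
  cellL <- rbind(matrix(FALSE, 1, ny), F)       # (nx+1) x ny
  cellR <- rbind(F, matrix(FALSE, 1, ny))
  act_u <- cellL & cellR
  inlet_u <- matrix(FALSE, nx + 1, ny); inlet_u[1, grid$inlet_rows] <- TRUE
  outlet_u <- matrix(FALSE, nx + 1, ny); outlet_u[nx + 1, grid$outlet_rows] <- TRUE
  usable_u <- cellL | cellR

  # ---- v faces -------------------------------------------------------------
  cellB <- cbind(matrix(FALSE, nx, 1), F)       # nx x (ny+1)
  cellT <- cbind(F, matrix(FALSE, nx, 1))
  act_v <- cellB & cellT
  branch_v <- matrix(FALSE, nx, ny + 1)
  for (s in grid$branch_slots) branch_v[s$cols, ny + 1] <- TRUE
  usable_v <- cellB | cellT

  num <- function(M) array(as.numeric(M), dim(M))
  plan <- list(
    nx = nx, ny = ny, dx = dx, rho = fluid$density,
    nu = fluid$dynamic_viscosity / fluid$density,
    inlet_type = inlet_type,
    F = F, act_u = act_u, act_v = act_v,
    inlet_u = inlet_u, outlet_u = outlet_u, branch_v = branch_v,
    inlet_idx = which(inlet_u), outlet_idx = which(outlet_u),
    # one-sided second-order availability (upwind extrapolation never crosses
    # a wall): face k-1 and k-2 must both carry meaningful values
    u_ok2w = num(sh(usable_u, 1) & sh(usable_u, 2)),
    u_ok2e = num(sh(usable_u, -1) & sh(usable_u, -2)),
    u_ok1s = num(sh(usable_u, 0, 1)),
    u_ok2s = num(sh(usable_u, 0, 1) & sh(usable_u, 0, 2)),
    u_ok1n = num(sh(usable_u, 0, -1)),
    u_ok2n = num(sh(usable_u, 0, -1) & sh(usable_u, 0, -2)),
    v_ok2s = num(sh(usable_v, 0, 1) & sh(usable_v, 0, 2)),
    v_ok2n = num(sh(usable_v, 0, -1) & sh(usable_v, 0, -2)),
    v_ok1w = num(sh(usable_v, 1)),
    v_ok2w = num(sh(usable_v, 1) & sh(usable_v, 2)),
    v_ok1e = num(sh(usable_v, -1)),
    v_ok2e = num(sh(usable_v, -1) & sh(usable_v, -2)),
    # mirrored-ghost selectors for the tangential viscous terms
    u_usN = num(sh(usable_u, 0, -1)), u_usS = num(sh(usable_u, 0, 1)),
    v_usE = num(sh(usable_v, -1)), v_usW = num(sh(usable_v, 1))
  )

  # ---- pressure Poisson operator ------------------------------------------
  K <- matrix(0L, nx, ny)
  ncell <- sum(F)
  K[F] <- seq_len(ncell)
  c2 <- 1 / dx^2

  iw <- which(act_u, arr.ind = TRUE)  # face (i,j): cells (i-1,j),(i,j)
  kl <- K[cbind(iw[, 1] - 1L, iw[, 2])]
  kr <- K[cbind(iw[, 1], iw[, 2])]
  jw <- which(act_v, arr.ind = TRUE)  # face (i,j): cells (i,j-1),(i,j)
  kb <- K[cbind(jw[, 1], jw[, 2] - 1L)]
  kt <- K[cbind(jw[, 1], jw[, 2])]

  # off-diagonal couplings across interior faces, then their diagonal lumps
  ti <- c(kl, kr, kb, kt, kl, kr, kb, kt)
  tj <- c(kr, kl, kt, kb, kl, kr, kb, kt)
  tx <- c(rep(-c2, 2 * length(kl)), rep(-c2, 2 * length(kb)),
          rep(c2, 2 * length(kl)), rep(c2, 2 * length(kb)))

  # pressure-Dirichlet boundary cells (outlet, optionally inlet)
  out_cells <- K[cbind(rep(nx, length(grid$outlet_rows)), grid$outlet_rows)]
  dir_cells <- out_cells
  in_cells <- integer(0)
  if (inlet_type == "pressure") {
    in_cells <- K[cbind(rep(1L, length(grid$inlet_rows)), grid$inlet_rows)]
    dir_cells <- c(dir_cells, in_cells)
  }
  ti <- c(ti, dir_cells); tj <- c(tj, dir_cells)
  tx <- c(tx, rep(2 * c2, length(dir_cells)))

  A <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(ncell, ncell))
  A <- Matrix::forceSymmetric(A)
  plan$K <- K
  plan$fluid_idx <- which(F)
  plan$ncell <- ncell
  plan$out_cells <- out_cells
  plan$in_cells <- in_cells
  plan$chol <- Matrix::Cholesky(A, LDL = FALSE)
  plan$c2 <- c2
  plan
}
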