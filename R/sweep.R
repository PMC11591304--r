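#' Default sweep configuration
#'
#' Nested list mirroring the YAML configuration blocks: `geometry`
#' (overrides for [dissection_geometry()]), `cases`, `waveforms`, `fluid`,
#' `numerics`, `post`, `output`.
#'
#' @return Named list of configuration blocks.
#' @export
default_config <- function() {
  list(
    geometry = list(),
    cases = 1:11,
    waveforms = list(
      inlet = list(peak = 0.125, period = 1.0, systole_start = 0.05,
                   systole_end = 0.45, baseline = 0.0),
      outlet = list(diastolic = 10.6e3, systolic = 16.0e3, peak_phase = 0.30),
      branches = TRUE),
    fluid = list(density = 1060, dynamic_viscosity = 3.71e-3),
    numerics = list(spacing_mm = 1.0, cfl_safety = 0.5, dt_max_ms = 1.0,
                    n_cycles = 4, snapshot_phases_s = c(0.25, 0.47),
                    picard_sweeps = 2),
    post = list(recirculation_threshold = 0.01, reference_speed = 0.125),
    output = list(dir = NULL)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read a YAML sweep configuration
#'
#' Unspecified entries fall back to [default_config()].
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return Configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) cfg <- merge_config(cfg, yaml::read_yaml(path))
  cfg
}

#' Deterministic hash of a configuration
#' @param config Configuration list.
#' @return Character hash.
#' @export
config_hash <- function(config) rlang::hash(config)

config_pieces <- function(config) {
  geom_base <- do.call(dissection_geometry, config$geometry)
  wf <- config$waveforms
  inlet <- do.call(inlet_velocity_waveform, wf$inlet)
  outlet <- do.call(outlet_pressure_waveform, wf$outlet)
  fluid <- do.call(fluid_properties, config$fluid)
  nmx <- config$numerics
  list(
    geom_base = geom_base, inlet = inlet, outlet = outlet, fluid = fluid,
    branches = isTRUE(wf$branches),
    spacing = nmx$spacing_mm,
    n_cycles = nmx$n_cycles,
    phases = nmx$snapshot_phases_s,
    numerics = list(cfl_safety = nmx$cfl_safety, dt_max = nmx$dt_max_ms / 1000,
                    picard_sweeps = nmx$picard_sweeps)
  )
}

run_one_case <- function(case_id, pc, config) {
  geom <- make_case(case_id, pc$geom_base)
  bc <- boundary_conditions(geom, pc$inlet, pc$outlet, pc$branches)
  sim <- simulate(geom, pc$spacing, bc, pc$fluid, pc$n_cycles, pc$phases,
                  pc$numerics)
  phase_names <- c("systole", "diastole")[seq_along(sim$snapshots)]
  summaries <- fluxes <- recirc <- peaks <- list()
  for (k in seq_along(sim$snapshots)) {
    f <- sim$snapshots[[k]]
    ph <- phase_names[k]
    summaries[[k]] <- regional_summary(f, sim$grid, geom, ph, pc$fluid)
    fl <- tibble::tibble(
      case_id = case_id, phase = ph, tear = "entry",
      flux_m2_s = tear_flux(f, sim$grid, geom, "entry"))
    if (!is.null(geom$re_entry)) {
      fl <- rbind(fl, tibble::tibble(
        case_id = case_id, phase = ph, tear = "re_entry",
        flux_m2_s = tear_flux(f, sim$grid, geom, "re_entry")))
    }
    fluxes[[k]] <- fl
    recirc[[k]] <- recirculation_extent(
      f, sim$grid, geom, config$post$recirculation_threshold,
      config$post$reference_speed, ph)
    pv <- peak_velocity_location(f, sim$grid, geom)
    peaks[[k]] <- tibble::tibble(case_id = case_id, phase = ph,
                                 speed = pv$speed, region = pv$region,
                                 label = pv$label)
  }
  d <- sim$diagnostics
  list(
    summaries = do.call(rbind, summaries),
    tear_fluxes = do.call(rbind, fluxes),
    recirculation = do.call(rbind, recirc),
    peaks = do.call(rbind, peaks),
    diagnostics = tibble::tibble(
      case_id = case_id, re_max = d$re_max, cfl_max = d$cfl_max,
      divergence_max = d$divergence_max,
      mass_imbalance_rel = d$mass_imbalance_rel,
      cycle_periodicity_error = d$cycle_periodicity_error,
      u_max = d$u_max, n_steps = d$n_steps),
    snapshots = sim$snapshots, grid = sim$grid, geom = geom
  )
}

#' Run the re-entry-location case sweep
#'
#' Simulates every configured case at the configured resolution, runs the
#' full post-processing, and collects per-case regional summaries, tear
#' fluxes, recirculation metrics, peak-velocity records and solver
#' diagnostics. Cases are independent; a failing case is recorded and
#' skipped, and the sweep fails only if all cases fail. The pipeline
#' contains no random number generation: identical configurations produce
#' identical results.
#'
#' @param config Configuration from [default_config()]/[read_config()].
#' @param out_dir Optional output directory for CSV tables and a JSON run
#'   manifest; with `resume = TRUE` previously completed cases found there
#'   are reloaded instead of re-simulated.
#' @param resume Reuse completed per-case results from `out_dir`.
#' @param keep_fields Keep full snapshot fields in the result (memory-heavy
#'   for long sweeps).
#' @param verbose Log per-case progress.
#' @return An object of class `sweep_result`.
#' @export
run_sweep <- function(config = default_config(), out_dir = config$output$dir,
                      resume = FALSE, keep_fields = FALSE, verbose = FALSE) {
  pc <- config_pieces(config)
  hash <- config_hash(config)
  cases <- config$cases
  results <- list(); failures <- list()
  for (cs in cases) {
    cache <- if (!is.null(out_dir))
      file.path(out_dir, sprintf("case_%02d_%s.rds", cs, hash)) else NULL
    res <- NULL
    if (resume && !is.null(cache) && file.exists(cache)) {
      res <- readRDS(cache)
      if (verbose) message(sprintf("case %d: reusing stored result", cs))
    } else {
      res <- tryCatch(run_one_case(cs, pc, config), error = function(e) e)
      if (inherits(res, "error")) {
        warning(sprintf("case %d failed: %s", cs, conditionMessage(res)),
                call. = FALSE)
        failures[[as.character(cs)]] <- conditionMessage(res)
        res <- NULL
      } else if (!is.null(cache)) {
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        saveRDS(res, cache)
      }
      if (verbose && !is.null(res)) {
        message(sprintf("case %d done (%d steps)", cs,
                        res$diagnostics$n_steps[1]))
      }
    }
    if (!is.null(res)) results[[as.character(cs)]] <- res
  }
  if (!length(results)) stop("all cases failed", call. = FALSE)

  bind <- function(part) do.call(rbind, lapply(results, `[[`, part))
  out <- structure(list(
    summaries = bind("summaries"),
    tear_fluxes = bind("tear_fluxes"),
    recirculation = bind("recirculation"),
    peaks = bind("peaks"),
    diagnostics = bind("diagnostics"),
    failures = failures,
    cases = as.integer(names(results)),
    snapshots = if (keep_fields) lapply(results, `[[`, "snapshots") else NULL,
    config = config, config_hash = hash,
    provenance = list(
      package_version = as.character(utils::packageVersion("tbadflow")),
      r_version = R.version.string,
      timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
  ), class = "sweep_result")

  if (!is.null(out_dir)) write_sweep_outputs(out, out_dir)
  out
}

write_sweep_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, nm) utils::write.csv(
    df, file.path(out_dir, paste0(nm, ".csv")), row.names = FALSE)
  wr(result$summaries, "regional_summaries")
  wr(result$tear_fluxes, "tear_fluxes")
  wr(result$recirculation, "recirculation")
  wr(result$peaks, "peak_velocities")
  wr(result$diagnostics, "diagnostics")
  manifest <- list(config_hash = result$config_hash,
                   cases = result$cases,
                   failures = result$failures,
                   provenance = result$provenance,
                   config = result$config)
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result: cases %s, %d summary rows, config %s>\n",
              paste(x$cases, collapse = ","), nrow(x$summaries),
              substr(x$config_hash, 1, 8)))
  invisible(x)
}

#' Label the monotonicity of a numeric series
#' @param x Numeric vector (NAs dropped).
#' @return One of `"increasing"`, `"decreasing"`, `"constant"`,
#'   `"non-monotone"`, `"insufficient"`.
#' @export
trend_label <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return("insufficient")
  d <- diff(x)
  if (all(d > 0)) "increasing"
  else if (all(d < 0)) "decreasing"
  else if (all(d == 0)) "constant"
  else "non-monotone"
}

#' Cross-case trend report
#'
#' Builds the comparison blocks of the sweep analysis: (a) true-lumen
#' region-1 minus region-n systolic pressure gap per case; (b) per-region
#' systolic false-lumen pressure and WSS of each re-entry case minus the
#' entry-only baseline; (c) recirculation extent versus re-entry distance;
#' (d) tear-flux signs per phase. Each block carries a descriptive
#' monotonicity/sign annotation; the annotations are reported, not asserted.
#'
#' @param result A [run_sweep()] result with at least 2 completed cases for
#'   the comparison blocks (block (a) and the baseline block are emitted for
#'   a single case as well).
#' @return List of class `trend_report`.
#' @export
compare_cases <- function(result) {
  stopifnot(inherits(result, "sweep_result"))
  s <- result$summaries
  cases <- sort(result$cases)
  dist <- c(NA_real_, reentry_distances())[cases + 0]  # case 1 -> NA

  # (a) TL inlet-outlet systolic gap per case
  gap <- vapply(cases, function(cs) {
    sub <- s[s$case_id == cs & s$phase == "systole", ]
    if (!nrow(sub)) return(NA_real_)
    pressure_difference(sub)$tl_inlet_outlet_gap_kpa
  }, numeric(1))
  block_a <- tibble::tibble(case_id = cases, re_entry_distance_mm = dist,
                            tl_gap_kpa = gap)

  # (b) per-region systolic FL pressure / WSS relative to case 1
  block_b <- NULL
  if (1 %in% cases && length(cases) > 1) {
    base <- s[s$case_id == 1 & s$phase == "systole" & s$lumen == "false", ]
    base <- base[order(base$region), ]
    rows <- lapply(setdiff(cases, 1), function(cs) {
      sub <- s[s$case_id == cs & s$phase == "systole" & s$lumen == "false", ]
      sub <- sub[order(sub$region), ]
      tibble::tibble(
        case_id = cs, region = sub$region,
        fl_pressure_minus_case1_kpa = sub$pressure_median - base$pressure_median,
        fl_wss_minus_case1_pa = sub$wss_median - base$wss_median)
    })
    block_b <- do.call(rbind, rows)
  } else {
    block_b <- tibble::tibble(case_id = integer(0), region = integer(0),
                              fl_pressure_minus_case1_kpa = numeric(0),
                              fl_wss_minus_case1_pa = numeric(0))
  }

  # (c) recirculation vs re-entry distance (systole)
  rc <- result$recirculation
  rc <- rc[rc$phase == "systole" & rc$case_id %in% cases, ]
  rc <- rc[order(rc$case_id), ]
  block_c <- tibble::tibble(
    case_id = rc$case_id,
    re_entry_distance_mm = c(NA_real_, reentry_distances())[rc$case_id],
    area_fraction_reversed = rc$area_fraction_reversed,
    reversed_area_mm2 = rc$reversed_area_mm2)

  # (d) tear-flux signs
  tf <- result$tear_fluxes
  block_d <- tibble::tibble(
    case_id = tf$case_id, phase = tf$phase, tear = tf$tear,
    flux_m2_s = tf$flux_m2_s,
    direction = ifelse(tf$flux_m2_s > 0, "FL->TL",
                       ifelse(tf$flux_m2_s < 0, "TL->FL", "none")))

  re_cases <- block_c$case_id != 1
  structure(list(
    tl_pressure_gap = block_a,
    fl_vs_baseline = block_b,
    recirculation = block_c,
    tear_flux_direction = block_d,
    annotations = list(
      tl_gap_trend = trend_label(block_a$tl_gap_kpa[block_a$case_id != 1]),
      recirculation_vs_distance = trend_label(
        block_c$reversed_area_mm2[re_cases]),
      fl_pressure_below_baseline = if (nrow(block_b))
        all(block_b$fl_pressure_minus_case1_kpa < 0, na.rm = TRUE) else NA,
      systolic_re_entry_flux = if (any(block_d$tear == "re_entry")) {
        sgn <- block_d$direction[block_d$tear == "re_entry" &
                                   block_d$phase == "systole"]
        if (all(sgn == "FL->TL")) "all FL->TL" else "mixed"
      } else "no re-entry cases")
  ), class = "trend_report")
}

#' @export
print.trend_report <- function(x, ...) {
  cat("Trend report\n============\n")
  cat("(a) TL region-1 minus region-n systolic pressure gap (kPa):\n")
  print(as.data.frame(x$tl_pressure_gap), digits = 4)
  cat(sprintf("    trend across re-entry cases: %s\n",
              x$annotations$tl_gap_trend))
  cat("(b) systolic FL pressure/WSS minus entry-only baseline:",
      sprintf("%d rows\n", nrow(x$fl_vs_baseline)))
  cat(sprintf("    all FL pressures below baseline: %s\n",
              format(x$annotations$fl_pressure_below_baseline)))
  cat("(c) recirculation below the re-entry tear (systole):\n")
  print(as.data.frame(x$recirculation), digits = 4)
  cat(sprintf("    reversed area vs distance-from-floor: %s\n",
              x$annotations$recirculation_vs_distance))
  cat("(d) systolic re-entry tear flux:",
      x$annotations$systolic_re_entry_flux, "\n")
  invisible(x)
}
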