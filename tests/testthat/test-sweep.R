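# coarse, short settings: orchestration tests exercise the plumbing, not the
# converged physics (those run in the acceptance suite)
coarse_config <- function(cases) {
  cfg <- default_config()
  cfg$cases <- cases
  cfg$numerics$spacing_mm <- 2
  cfg$numerics$n_cycles <- 1
  cfg
}

test_that("configuration defaults, YAML merge and hashing behave", {
  cfg <- default_config()
  expect_setequal(names(cfg), c("geometry", "cases", "waveforms", "fluid",
                                "numerics", "post", "output"))
  expect_equal(cfg$cases, 1:11)
  expect_equal(cfg$fluid$density, 1060)
  expect_equal(cfg$fluid$dynamic_viscosity, 3.71e-3)
  expect_equal(cfg$numerics$n_cycles, 4)
  expect_equal(cfg$numerics$snapshot_phases_s, c(0.25, 0.47))

  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("cases: [1, 5]", "numerics:", "  spacing_mm: 2.0"), yml)
  cfg2 <- read_config(yml)
  expect_equal(cfg2$cases, c(1, 5))
  expect_equal(cfg2$numerics$spacing_mm, 2)
  expect_equal(cfg2$numerics$n_cycles, 4)          # untouched default
  expect_identical(config_hash(cfg), config_hash(default_config()))
  expect_false(config_hash(cfg) == config_hash(cfg2))

  shipped <- system.file("extdata", "default_config.yaml", package = "tbadflow")
  expect_true(nzchar(shipped))
  expect_silent(read_config(shipped))
})

test_that("a subset sweep produces complete, deterministic outputs", {
  cfg <- coarse_config(c(1, 5))
  out1 <- withr::local_tempdir()
  sw <- run_sweep(cfg, out_dir = out1)
  expect_s3_class(sw, "sweep_result")
  expect_equal(sw$cases, c(1L, 5L))
  # 2 cases x 2 phases x 12 rows
  expect_equal(nrow(sw$summaries), 48)
  expect_equal(nrow(sw$recirculation), 4)
  # entry-only case contributes 2 flux rows, re-entry case 4
  expect_equal(nrow(sw$tear_fluxes), 6)
  expect_true(all(file.exists(file.path(out1, c(
    "regional_summaries.csv", "tear_fluxes.csv", "recirculation.csv",
    "peak_velocities.csv", "diagnostics.csv", "run_manifest.json")))))
  man <- jsonlite::read_json(file.path(out1, "run_manifest.json"))
  expect_equal(man$config_hash, sw$config_hash)

  # bit-identical rerun
  out2 <- withr::local_tempdir()
  sw2 <- run_sweep(cfg, out_dir = out2)
  expect_identical(sw$summaries, sw2$summaries)
  expect_identical(
    readLines(file.path(out1, "regional_summaries.csv")),
    readLines(file.path(out2, "regional_summaries.csv")))

  # resume reuses the stored case results
  t_resume <- system.time(
    sw3 <- run_sweep(cfg, out_dir = out1, resume = TRUE))["elapsed"]
  expect_identical(sw3$summaries, sw$summaries)
  expect_lt(t_resume, 5)
})

test_that("trend report blocks have the documented shape", {
  cfg <- coarse_config(c(1, 5))
  sw <- run_sweep(cfg)
  cc <- compare_cases(sw)
  expect_equal(nrow(cc$tl_pressure_gap), 2)
  expect_equal(nrow(cc$fl_vs_baseline), 6)   # (n_cases - 1) x 6 regions
  expect_equal(nrow(cc$recirculation), 2)
  expect_true(all(cc$tear_flux_direction$direction %in%
                    c("FL->TL", "TL->FL", "none")))
  expect_output(print(cc), "Trend report")

  # case-1-only input: baseline present, comparison block empty
  sw1 <- run_sweep(coarse_config(1))
  cc1 <- compare_cases(sw1)
  expect_equal(nrow(cc1$tl_pressure_gap), 1)
  expect_equal(nrow(cc1$fl_vs_baseline), 0)
})

test_that("monotonicity labels match their series", {
  expect_equal(trend_label(c(3, 2, 1)), "decreasing")
  expect_equal(trend_label(c(1, 2, 9)), "increasing")
  expect_equal(trend_label(c(2, 2, 2)), "constant")
  expect_equal(trend_label(c(1, 3, 2)), "non-monotone")
  expect_equal(trend_label(c(1, NA)), "insufficient")
})
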