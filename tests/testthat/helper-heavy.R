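# Memoized heavy simulation runs shared across acceptance test blocks.
# Everything here is deterministic (the pipeline contains no RNG).
.heavy <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .heavy)) assign(key, force(expr), envir = .heavy)
  get(key, envir = .heavy)
}

# three-case sweep (entry-only, most distal tear, most proximal tear) at the
# default study conditions: 1 mm spacing, four cardiac cycles
heavy_sweep <- function() memo("sweep", {
  cfg <- default_config()
  cfg$cases <- c(1, 2, 11)
  run_sweep(cfg, keep_fields = TRUE)
})

# desk-scale mesh-sensitivity study at its default four levels
heavy_mesh <- function() memo("mesh", convergence_study())

# coarse one-cycle branch flow-split audit
heavy_audit <- function() memo("audit", simulate(make_case(1), spacing = 2,
                                                 n_cycles = 1))

heavy_poiseuille <- function() memo("poiseuille", {
  lapply(c(1, 0.5, 0.25), function(sp)
    poiseuille_benchmark(spacing = sp, width = 5, length = 10, t_end = 6))
})

heavy_womersley <- function() memo("womersley", womersley_benchmark(0.5))
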