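# tbadflow sweep configuration (annotated defaults)
#
# Any entry may be omitted; missing values fall back to the package defaults
# shown here. Lengths are mm, times s, pressures Pa, velocities m/s.

geometry:
  proximal_length: 60          # undissected proximal segment (carries branches)
  dissected_length: 225        # dissected segment; partitioned into 6 regions
  distal_length: 20
  true_lumen_width: 20
  false_lumen_short_axis: 12.8 # the 50% tear-sizing rule yields 6.4 mm
  septum_thickness: 2          # intimal flap; also the false-lumen end caps
  entry_tear_width: 6.4
  entry_tear_offset: 0         # from the start of the open false lumen

cases: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11]

waveforms:
  inlet:
    peak: 0.125                # keeps Re_max below the critical ~2300
    period: 1.0
    systole_start: 0.05
    systole_end: 0.45
    baseline: 0.0
  outlet:
    diastolic: 10600           # ~80 mmHg
    systolic: 16000            # ~120 mmHg
    peak_phase: 0.30
  branches: true               # false: close slots, scale inlet by 0.85

fluid:
  density: 1060                # kg/m^3
  dynamic_viscosity: 0.00371   # Pa s

numerics:
  spacing_mm: 1.0              # default sweep resolution; 0.5 for fine runs
  cfl_safety: 0.5
  dt_max_ms: 1.0
  n_cycles: 4                  # analysis uses the fourth cycle
  snapshot_phases_s: [0.25, 0.47]  # peak systole / early diastole
  picard_sweeps: 2             # pressure-correction sweeps per step

post:
  recirculation_threshold: 0.01  # fraction of reference_speed
  reference_speed: 0.125         # m/s; the default peak inlet velocity

output:
  dir: null                    # set to write CSV tables + run manifest
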