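# build a flow_field on a grid from analytic functions of (x, y) in mm
make_field <- function(grid, ufun = function(x, y) 0, vfun = function(x, y) 0,
                       pfun = function(x, y) 0, time = 0) {
  h <- grid$spacing
  nx <- grid$nx; ny <- grid$ny
  ux <- (seq_len(nx + 1) - 1) * h
  uy <- (seq_len(ny) - 0.5) * h
  vx <- (seq_len(nx) - 0.5) * h
  vy <- (seq_len(ny + 1) - 1) * h
  mk <- function(xs, ys, fn) {
    X <- matrix(xs, length(xs), length(ys))
    Y <- matrix(ys, length(xs), length(ys), byrow = TRUE)
    matrix(fn(X, Y), length(xs), length(ys))
  }
  flow_field(time, mk(ux, uy, ufun), mk(vx, vy, vfun), mk(vx, uy, pfun))
}

# constant-in-time waveforms for quiescent / steady boundary conditions
constant_velocity_wf <- function(value = 0, period = 1) {
  waveform(c(0, period / 2), c(value, value), period, "velocity")
}
constant_pressure_wf <- function(value = 1e4, period = 1) {
  waveform(c(0, period / 2), c(value, value), period, "pressure")
}
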