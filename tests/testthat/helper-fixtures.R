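# shared fixtures built in code

# minimal trace with a clean -600 -> 0 ft/min touchdown step
step_trace <- function() {
  flight_trace(t = seq(0, 0.5, by = 0.1),
               lat = rep(34, 6), lon = rep(-118, 6),
               alt = c(5, 4, 3, 2, 1, 0),
               vspeed = c(-600, -600, -600, -600, -600, 0))
}

# straight-line trace with prescribed altitude/vspeed, fixed position
flat_trace <- function(vspeed, alt = NULL, lat0 = 34, lon0 = -118) {
  n <- length(vspeed)
  if (is.null(alt)) alt <- seq(n - 1, 0)
  flight_trace(t = seq(0, by = 0.1, length.out = n),
               lat = rep(lat0, n), lon = rep(lon0, n),
               alt = alt, vspeed = vspeed)
}

# layout whose channels are all mutual neighbours
tight_layout <- function(n = 4) {
  data.frame(label = paste0("c", seq_len(n)),
             x = seq_len(n) * 1e-3, y = 0)
}
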