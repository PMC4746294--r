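#' Construct a flight trace
#'
#' A flight trace is 10 Hz telemetry for one landing attempt: time (s),
#' geodetic position (degrees), altitude above ground level (ft), and signed
#' vertical speed (ft/min, negative = descent). The touchdown index is the
#' first sample with zero altitude; traces flagged `missed` have none.
#'
#' @param t Time stamps in seconds, strictly increasing, uniform 0.1 s.
#' @param lat,lon Geodetic coordinates in degrees.
#' @param alt Altitude AGL in feet (>= 0).
#' @param vspeed Vertical speed in ft/min.
#' @param missed Logical missed-landing flag.
#' @return An object of class `flight_trace`.
#' @export
flight_trace <- function(t, lat, lon, alt, vspeed, missed = FALSE) {
  n <- length(t)
  if (any(diff(t) <= 0)) stop("time stamps must be strictly increasing")
  if (length(lat) != n || length(lon) != n || length(alt) != n ||
      length(vspeed) != n) stop("all telemetry columns must share a length")
  if (any(alt < 0)) stop("altitude AGL must be >= 0")
  td <- which(alt == 0)[1]
  structure(list(t = t, lat = lat, lon = lon, alt = alt, vspeed = vspeed,
                 touchdown_index = if (missed) NA_integer_ else
                   (if (is.na(td)) NA_integer_ else as.integer(td)),
                 missed = isTRUE(missed)),
            class = "flight_trace")
}

#' @export
print.flight_trace <- function(x, ...) {
  cat("Flight trace:", length(x$t), "samples at",
      round(1 / median(diff(x$t))), "Hz;",
      if (x$missed) "missed landing" else
        paste0("touchdown at t = ", x$t[x$touchdown_index], " s"), "\n")
  invisible(x)
}

#' @export
length.flight_trace <- function(x) length(x$t)

#' Reference autopilot landing trace
#'
#' Builds the idealised autopilot approach used as the comparison standard
#' for the easy-landing metrics: constant vertical speed (default
#' -600 ft/min) for the whole approach, with the vertical speed changing only
#' in the final 5 s before touchdown (the flare), where it ramps up, crosses
#' zero once at the nose flare, and decays back to zero during a short
#' rollout. The trace therefore contains exactly one vertical-speed sign
#' change (one major control input). The aircraft tracks the runway heading
#' at constant ground speed and touches down at the runway threshold
#' (`origin`).
#'
#' @param alt0 Initial altitude AGL in feet (approach starts at ~800 ft).
#' @param vspeed_approach Approach vertical speed in ft/min (negative).
#' @param flare_s Flare duration in seconds.
#' @param rollout_s Post-touchdown rollout recorded in the trace, seconds.
#' @param fs Sampling rate, Hz.
#' @param origin Named vector `c(lat =, lon =)` of the runway threshold.
#' @param heading_deg Runway heading, degrees clockwise from north.
#' @param ground_speed Ground speed along track, m/s.
#' @return A [flight_trace()].
#' @export
autopilot_trace <- function(alt0 = 800, vspeed_approach = -600, flare_s = 5,
                            rollout_s = 1, fs = 10,
                            origin = c(lat = 34, lon = -118),
                            heading_deg = 20, ground_speed = 50) {
  dt <- 1 / fs
  # flare: linear ramp from approach speed to +30 ft/min (nose flare)
  vs_flare <- seq(vspeed_approach, 30, length.out = round(flare_s * fs))
  # altitude consumed by the flare up to the zero crossing of vspeed
  neg <- vs_flare[vs_flare < 0]
  drop_flare <- -sum(neg) / 60 * dt
  t_approach <- round((alt0 - drop_flare) / (-vspeed_approach / 60) * fs) / fs
  n_approach <- round(t_approach * fs)
  vs_roll <- seq(30, 0, length.out = round(rollout_s * fs))
  vspeed <- c(rep(vspeed_approach, n_approach), vs_flare, vs_roll)
  n <- length(vspeed)
  t <- seq(0, by = dt, length.out = n)
  alt_start <- -sum(pmin(vspeed, 0)) / 60 * dt
  alt <- alt_start + cumsum(pmin(vspeed, 0)) / 60 * dt
  alt <- pmax(alt, 0)
  td <- which(alt <= 1e-9)[1]
  alt[td:n] <- 0
  # along-track distance from threshold (negative on approach)
  s <- (seq_len(n) - td) * dt * ground_speed
  hd <- heading_deg * pi / 180
  lat <- origin[["lat"]] + (s * cos(hd)) / 111194.9
  lon <- origin[["lon"]] + (s * sin(hd)) /
    (111194.9 * cos(origin[["lat"]] * pi / 180))
  flight_trace(t, lat, lon, alt, vspeed)
}

#' Simulate a subject landing attempt from an autopilot reference
#'
#' Perturbs the reference trace with skill-scaled noise: AR(1) vertical-speed
#' noise, a smooth lateral (cross-track) drift, and Bernoulli missed
#' landings. Altitude is re-integrated from the noisy vertical speed, so the
#' touchdown time shifts with the subject's profile. As `skill` grows the
#' noise vanishes and the trace converges to the reference (at `skill = Inf`
#' they are identical and every deviation metric is zero).
#'
#' @param reference A [flight_trace()] from [autopilot_trace()].
#' @param skill Positive scalar; all noise scales divide by it.
#' @param vspeed_sd Innovation scale of the AR(1) vertical-speed noise, ft/min.
#' @param ar AR(1) coefficient of the vertical-speed noise.
#' @param lateral_sd Cross-track drift scale, metres.
#' @param p_missed Probability the attempt overshoots the runway.
#' @param seed Optional integer seed.
#' @return A [flight_trace()].
#' @export
generate_flight_trace <- function(reference, skill = 1, vspeed_sd = 60,
                                  ar = 0.95, lateral_sd = 10,
                                  p_missed = 0, seed = NULL) {
  stopifnot(inherits(reference, "flight_trace"))
  if (!is.null(seed)) set.seed(seed)
  n <- length(reference$t)
  dt <- reference$t[2] - reference$t[1]
  sdv <- vspeed_sd / skill
  sdl <- lateral_sd / skill
  missed <- p_missed > 0 && stats::runif(1) < p_missed
  if (sdv == 0 && sdl == 0 && !missed) return(reference)
  if (sdv == 0) {
    vspeed <- reference$vspeed
  } else {
    innov <- stats::rnorm(n, 0, sdv * sqrt(1 - ar^2))
    noise <- as.numeric(stats::filter(innov, ar, method = "recursive"))
    vspeed <- reference$vspeed + noise
  }
  if (missed) {
    # balloon over the runway: push vertical speed up near the threshold
    idx <- max(1L, n - round(10 / dt)):n
    vspeed[idx] <- vspeed[idx] + 700
  }
  # altitude immediately before the first sample, so re-integration of the
  # unperturbed vertical speed reproduces the reference altitude exactly
  alt0 <- reference$alt[1] - min(reference$vspeed[1], 0) / 60 * dt
  alt <- alt0 + cumsum(vspeed) / 60 * dt
  td <- which(alt <= 0)[1]
  t <- reference$t
  if (is.na(td) && !missed) {
    # aircraft still airborne at the end of the reference window: continue
    # a final descent at -300 ft/min until the wheels touch
    sink <- 300 / 60 * dt
    n_add <- ceiling(alt[n] / sink) + 1L
    vspeed <- c(vspeed, rep(-300, n_add))
    alt <- c(alt, alt[n] - sink * seq_len(n_add))
    t <- c(t, t[n] + dt * seq_len(n_add))
    n <- n + n_add
    td <- which(alt <= 0)[1]
  }
  if (!is.na(td)) {
    alt[td:n] <- 0
    alt <- pmax(alt, 0)
  } else {
    alt <- pmax(alt, 1)
    missed <- TRUE
  }
  # ground track: the reference track, linearly continued if extended
  n_ref <- length(reference$t)
  base_lat <- reference$lat; base_lon <- reference$lon
  if (n > n_ref) {
    add <- seq_len(n - n_ref)
    base_lat <- c(base_lat, base_lat[n_ref] +
                    add * (base_lat[n_ref] - base_lat[n_ref - 1L]))
    base_lon <- c(base_lon, base_lon[n_ref] +
                    add * (base_lon[n_ref] - base_lon[n_ref - 1L]))
  }
  # smooth cross-track drift, zero-mean random walk re-centred
  if (sdl == 0) {
    lat <- base_lat; lon <- base_lon
  } else {
    walk <- cumsum(stats::rnorm(n, 0, sdl / sqrt(n)))
    drift <- (walk - mean(walk))
    hd <- atan2(base_lon[n] - base_lon[1], base_lat[n] - base_lat[1])
    lat <- base_lat + drift * cos(hd + pi / 2) / 111194.9
    lon <- base_lon + drift * sin(hd + pi / 2) /
      (111194.9 * cos(base_lat[1] * pi / 180))
  }
  flight_trace(t, lat, lon, alt, vspeed, missed = missed)
}
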