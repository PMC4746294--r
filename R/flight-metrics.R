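FT_PER_M <- 1 / 0.3048
EARTH_RADIUS_M <- 6371000

#' Landing impact g-force
#'
#' The derivative of the vertical speed across the touchdown sample,
#' converted to m/s^2 and divided by 9.8, reported as a magnitude. A
#' backward finite difference anchored at the touchdown sample is used
#' (there is no meaningful sample "after" impact on the approach side).
#'
#' @param trace A [flight_trace()] with a touchdown.
#' @return Impact magnitude in g (dimensionless), or `NA` for a missed
#'   landing (flagged, excluded from aggregation).
#' @export
#' @examples
#' # -600 -> 0 ft/min over one 0.1 s sample: (600*0.3048/60)/0.1/9.8 = 3.11 g
landing_gforce <- function(trace) {
  if (trace$missed || is.na(trace$touchdown_index)) return(NA_real_)
  td <- trace$touchdown_index
  dt <- trace$t[2] - trace$t[1]
  v_ms <- trace$vspeed * 0.3048 / 60
  i0 <- if (td > 1) td - 1L else td + 1L
  abs(v_ms[td] - v_ms[i0]) / dt / 9.8
}

#' Geodetic coordinates to local Cartesian (ENU) metres
#'
#' Transforms latitude/longitude/altitude into a local tangent-plane
#' East-North-Up frame on a spherical Earth (R = 6,371,000 m) anchored at a
#' fixed origin (the runway threshold). Adequate to sub-metre accuracy at
#' landing scale.
#'
#' @param lat,lon Degrees (vectorised).
#' @param alt Altitude in feet above the origin's ground level.
#' @param origin Named vector `c(lat =, lon =)` in degrees.
#' @return Matrix with columns `x` (east), `y` (north), `z` (up), metres.
#' @export
geodetic_to_cartesian <- function(lat, lon, alt, origin) {
  if (any(abs(lat) > 90) || abs(origin[["lat"]]) > 90)
    stop("latitude must lie in [-90, 90] degrees")
  rad <- pi / 180
  x <- EARTH_RADIUS_M * cos(origin[["lat"]] * rad) * (lon - origin[["lon"]]) * rad
  y <- EARTH_RADIUS_M * (lat - origin[["lat"]]) * rad
  z <- alt * 0.3048
  cbind(x = x, y = y, z = z)
}

# mean over m consecutive, order-preserving chunks spanning all of x
.resample_mean <- function(x, m) {
  g <- ceiling(seq_along(x) * m / length(x))
  as.numeric(tapply(x, g, mean))
}

.check_window <- function(subject, autopilot, window) {
  if (length(subject) < window || length(autopilot) < window)
    stop("trace shorter than the alignment window")
  max(1L, floor(min(length(subject), length(autopilot)) / window))
}

#' Total flight-path deviation from the autopilot reference
#'
#' Transforms both traces into a common local Cartesian frame, resamples
#' each by moving-window averaging onto a common number of aligned points,
#' and sums the per-sample Euclidean distances (metres). With `window = 1`
#' and equal-length traces this equals the naive pointwise sum.
#'
#' @param subject,autopilot [flight_trace()] objects.
#' @param window Moving-average window in samples (default 10 = 1 s at
#'   10 Hz); the aligned length is `floor(min(n_subject, n_autopilot) /
#'   window)`.
#' @param origin Cartesian origin; defaults to the autopilot touchdown point
#'   (runway threshold).
#' @return Summed deviation in metres.
#' @export
path_deviation <- function(subject, autopilot, window = 10, origin = NULL) {
  m <- .check_window(subject, autopilot, window)
  if (is.null(origin)) {
    td <- autopilot$touchdown_index
    if (is.na(td)) td <- length(autopilot)
    origin <- c(lat = autopilot$lat[td], lon = autopilot$lon[td])
  }
  xs <- geodetic_to_cartesian(subject$lat, subject$lon, subject$alt, origin)
  xa <- geodetic_to_cartesian(autopilot$lat, autopilot$lon, autopilot$alt, origin)
  rs <- apply(xs, 2, .resample_mean, m = m)
  ra <- apply(xa, 2, .resample_mean, m = m)
  if (m == 1L) { rs <- matrix(rs, 1); ra <- matrix(ra, 1) }
  sum(sqrt(rowSums((rs - ra)^2)))
}

#' Summed vertical-speed deviation from the autopilot reference
#'
#' Aligns the two vertical-speed series exactly as [path_deviation()] aligns
#' positions and sums the absolute per-sample differences (ft/min). Signed
#' sums would cancel and contradict "lower deviation is better", hence the
#' absolute value. Set `window = 1` to sum over raw samples instead of
#' window means.
#'
#' @inheritParams path_deviation
#' @return Summed absolute deviation, ft/min-samples.
#' @export
vspeed_deviation <- function(subject, autopilot, window = 10) {
  m <- .check_window(subject, autopilot, window)
  sum(abs(.resample_mean(subject$vspeed, m) -
            .resample_mean(autopilot$vspeed, m)))
}

#' Vertical-speed variance over the landing approach
#'
#' Sample variance of the vertical speed from the start of the recording to
#' touchdown (whole trace when no touchdown exists), measuring how steadily
#' the descent was held.
#'
#' @param trace A [flight_trace()].
#' @return Variance in (ft/min)^2.
#' @export
vspeed_variance <- function(trace) {
  end <- if (!is.na(trace$touchdown_index)) trace$touchdown_index else
    length(trace)
  stats::var(trace$vspeed[seq_len(end)])
}

#' Control-input count from vertical-speed sign changes
#'
#' Number of sign changes in the vertical speed over the landing period.
#' Zero samples inherit the previous non-zero sign (hysteresis), so a
#' noise-free hold at 0 ft/min counts no input; the count is invariant to
#' positive rescaling of the vertical speed.
#'
#' @param trace A [flight_trace()].
#' @return Non-negative integer count.
#' @export
control_inputs <- function(trace) {
  s <- sign(trace$vspeed)
  s <- s[s != 0]
  if (length(s) < 2L) return(0L)
  sum(diff(s) != 0)
}

#' Classify a missed landing
#'
#' An attempt is missed when no touchdown occurs within the runway extent:
#' either the trace is flagged missed / has no touchdown, or the touchdown
#' point lies beyond `runway_extent_m` from the threshold (inclusive
#' boundary: touching down exactly at the terminal end still counts as
#' landed).
#'
#' @param trace A [flight_trace()].
#' @param runway_origin Named vector `c(lat =, lon =)` of the threshold.
#' @param runway_extent_m Usable runway length in metres.
#' @return Logical.
#' @export
classify_missed <- function(trace, runway_origin, runway_extent_m) {
  if (trace$missed || is.na(trace$touchdown_index)) return(TRUE)
  td <- trace$touchdown_index
  xyz <- geodetic_to_cartesian(trace$lat[td], trace$lon[td], 0, runway_origin)
  # small tolerance keeps the inclusive boundary robust to round-off
  sqrt(sum(xyz[1, c("x", "y")]^2)) > runway_extent_m * (1 + 1e-9) + 1e-9
}

#' All easy-landing metrics for one attempt
#'
#' Convenience wrapper computing the five landing-performance metrics and
#' the missed flag for a subject trace against its autopilot reference.
#' Metrics that are undefined for missed landings are `NA` and should be
#' excluded from aggregation (missed attempts are summarised separately as
#' percentages).
#'
#' @inheritParams path_deviation
#' @param runway_extent_m Usable runway length in metres.
#' @return One-row data frame: `gforce`, `path_deviation`,
#'   `vspeed_deviation`, `vspeed_variance`, `control_inputs`, `missed`.
#' @export
landing_metrics <- function(subject, autopilot, window = 10,
                            runway_extent_m = 1000) {
  td <- autopilot$touchdown_index
  origin <- c(lat = autopilot$lat[td], lon = autopilot$lon[td])
  missed <- classify_missed(subject, origin, runway_extent_m)
  data.frame(
    gforce = if (missed) NA_real_ else landing_gforce(subject),
    path_deviation = if (missed) NA_real_ else
      path_deviation(subject, autopilot, window, origin),
    vspeed_deviation = if (missed) NA_real_ else
      vspeed_deviation(subject, autopilot, window),
    vspeed_variance = vspeed_variance(subject),
    control_inputs = control_inputs(subject),
    missed = missed)
}
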