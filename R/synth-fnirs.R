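#' Default fNIRS channel map
#'
#' The 20-channel source-detector montage of the study: 10 channels over
#' left M1 and 10 over right DLPFC, with source-detector separations of at
#' most 3.5 cm (a uniform 3.0 cm is used as the synthetic default since the
#' exact cap distances are not published).
#'
#' @param distance_cm Source-detector separation assigned to every channel.
#' @return Data frame with `channel`, `source`, `detector`, `distance_cm`,
#'   `roi`.
#' @export
fnirs_channel_map <- function(distance_cm = 3.0) {
  m1 <- c("FC3-FCC5h", "FC3-FCC3h", "C5-FCC5h", "C3-FCC5h", "C3-FCC3h",
          "C1-FCC3h", "C5-CCP5h", "C3-CCP5h", "C3-CCP3h", "C1-CCP3h")
  dlpfc <- c("AFF6h-AFF2h", "AFF6h-F4", "F2-AFF2h", "F2-F4", "F2-FFC4h",
             "FFC6h-F4", "FFC6h-FFT8h", "FFC6h-FFC4h", "FC4-FFC4h", "FC4-F4")
  pairs <- c(m1, dlpfc)
  sd <- strsplit(pairs, "-")
  data.frame(channel = pairs,
             source = vapply(sd, `[`, "", 1),
             detector = vapply(sd, `[`, "", 2),
             distance_cm = distance_cm,
             roi = rep(c("M1", "DLPFC"), each = 10L),
             stringsAsFactors = FALSE)
}

#' Simulate a dual-wavelength fNIRS session
#'
#' Builds ground-truth chromophore responses (task boxcars convolved with
#' the canonical HRF, per-channel Hboxy amplitudes with Hbdeoxy at a fixed
#' negative fraction), passes them through the forward modified
#' Beer-Lambert model, and adds sensor noise plus the slow drift and
#' cardiac/respiratory sinusoids that the band-pass stage is meant to
#' remove.
#'
#' @param channel_map Data frame from [fnirs_channel_map()].
#' @param amp_hbo Per-channel task-evoked Hboxy amplitude, mM (recycled;
#'   magnitudes must stay physically small, |amp| <= 0.05 mM).
#' @param onsets,durations Task events, seconds.
#' @param duration_s Session length, seconds.
#' @param fs Sampling rate (8 Hz).
#' @param hbr_ratio Hbdeoxy amplitude as a (negative) fraction of Hboxy.
#' @param od_noise_sd White sensor noise on each optical-density channel.
#' @param drift Linear drift magnitude over the session, OD units (0
#'   disables).
#' @param cardiac_amp,cardiac_freq Cardiac oscillation in OD units / Hz
#'   (1.2 Hz default); a 0.3 Hz respiratory tone at half amplitude is added
#'   with it.
#' @param optics An [extinction_model()]; distances are taken from the
#'   channel map.
#' @param seed Optional integer seed.
#' @return List with `od` (list of `od760`, `od850`), `truth` (the noiseless
#'   `chromophore_series`), `onsets`, `durations`, `fs`, `channel_map`,
#'   `optics`.
#' @export
generate_fnirs <- function(channel_map = fnirs_channel_map(),
                           amp_hbo = 0.002,
                           onsets = seq(30, 270, by = 60), durations = 30,
                           duration_s = 330, fs = 8,
                           hbr_ratio = -0.3,
                           od_noise_sd = 5e-4, drift = 2e-3,
                           cardiac_amp = 5e-4, cardiac_freq = 1.2,
                           optics = extinction_model(), seed = NULL) {
  if (is.null(channel_map$distance_cm))
    stop("channel map must provide source-detector distances")
  if (any(abs(amp_hbo) > 0.05))
    stop("concentration changes must be physically small (|amp| <= 0.05 mM)")
  if (!is.null(seed)) set.seed(seed)
  nch <- nrow(channel_map)
  n <- round(duration_s * fs)
  t <- seq_len(n) / fs
  amp_hbo <- rep_len(amp_hbo, nch)
  box <- numeric(n)
  durations <- rep_len(durations, length(onsets))
  for (i in seq_along(onsets)) {
    i0 <- floor(onsets[i] * fs) + 1L
    i1 <- min(n, i0 + round(durations[i] * fs) - 1L)
    box[i0:i1] <- 1
  }
  hrf <- canonical_hrf(seq(0, 32, by = 1 / fs))
  resp <- stats::convolve(box, rev(hrf), type = "open")[seq_len(n)]
  hbo <- outer(amp_hbo, resp)
  hbr <- hbr_ratio * hbo
  optics$distances <- channel_map$distance_cm
  od <- fnirs_forward(hbo, hbr, optics)
  for (w in c("od760", "od850")) {
    for (ch in seq_len(nch)) {
      nuisance <- drift * (t / duration_s - 0.5) +
        cardiac_amp * sin(2 * pi * cardiac_freq * t + stats::runif(1, 0, 2 * pi)) +
        0.5 * cardiac_amp * sin(2 * pi * 0.3 * t + stats::runif(1, 0, 2 * pi))
      od[[w]][ch, ] <- od[[w]][ch, ] + nuisance +
        stats::rnorm(n, 0, od_noise_sd)
    }
  }
  list(od = od,
       truth = chromophore_series(hbo, hbr, fs = fs,
                                  channels = channel_map$channel),
       onsets = onsets, durations = durations, fs = fs,
       channel_map = channel_map, optics = optics)
}
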