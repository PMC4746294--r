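#' Electrode layout
#'
#' Reads a channel layout file (columns `label`, `x`, `y`; schematic 2-D
#' head coordinates, nose up). The packaged default is a neutral 31-channel
#' 10-10 arrangement including Fz and FC1; the study cap's exact custom
#' geometry is not published, so a standard layout stands in.
#'
#' @param path Layout CSV; defaults to the packaged 31-channel file.
#' @return Data frame with columns `label`, `x`, `y`.
#' @export
eeg_layout <- function(path = system.file("extdata", "layout_31ch.csv",
                                          package = "flightlearn")) {
  lay <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("label", "x", "y") %in% names(lay)))
  lay
}

#' Construct an EEG record
#'
#' @param samples Channels x time numeric matrix, microvolts.
#' @param fs Sampling rate in Hz (500 in the study).
#' @param labels Channel labels (row names of `samples`).
#' @param annotations Optional data frame of task segments with columns
#'   `task`, `day`, `block`, `start_s`, `end_s`.
#' @return An object of class `eeg_record`.
#' @export
eeg_record <- function(samples, fs, labels, annotations = NULL) {
  stopifnot(is.matrix(samples), length(labels) == nrow(samples))
  rownames(samples) <- labels
  structure(list(samples = samples, fs = fs, labels = labels,
                 annotations = annotations),
            class = "eeg_record")
}

#' @export
print.eeg_record <- function(x, ...) {
  cat("EEG record:", nrow(x$samples), "channels x",
      ncol(x$samples), "samples @", x$fs, "Hz\n")
  invisible(x)
}

# pink (1/f amplitude) noise via spectral shaping, unit variance
.pink_noise <- function(n) {
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  f <- c(1, seq_len(n - 1))              # avoid dividing DC by zero
  f <- pmin(f, n - f + 1)                # mirror for negative frequencies
  spec <- spec / sqrt(f)
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  as.numeric(scale(x))
}

# gaussian spatial weight centred at a 2-D focus
.topo_weight <- function(layout, centre, width = 0.45) {
  d2 <- (layout$x - centre[1])^2 + (layout$y - centre[2])^2
  exp(-d2 / (2 * width^2))
}

#' Simulate a multichannel EEG record
#'
#' Generates continuous EEG at 500 Hz as pink (1/f) background noise plus
#' band-limited oscillations: a theta oscillation (default 6 Hz) with a
#' midline-frontal topography peaking at Fz/FC1, and an alpha oscillation
#' (default 10 Hz) with a parietal topography peaking at Pz. Amplitudes are
#' in microvolts at the topography's focus. The signal is generated as a raw
#' time series (not band power directly) so the whole spectral pipeline is
#' genuinely exercised.
#'
#' @param layout Electrode layout from [eeg_layout()].
#' @param duration_s Record duration in seconds.
#' @param theta_amp,alpha_amp Oscillation amplitudes (uV) at the focus.
#' @param theta_freq,alpha_freq Oscillation frequencies (Hz).
#' @param noise_sd Pink-noise standard deviation per channel (uV).
#' @param fs Sampling rate (Hz).
#' @param annotations Optional task-segment annotations (see
#'   [eeg_record()]).
#' @param seed Optional integer seed.
#' @return An [eeg_record()].
#' @export
generate_eeg <- function(layout = eeg_layout(), duration_s = 10,
                         theta_amp = 3, alpha_amp = 2,
                         theta_freq = 6, alpha_freq = 10,
                         noise_sd = 1, fs = 500,
                         annotations = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration_s * fs)
  t <- seq_len(n) / fs
  nch <- nrow(layout)
  fz <- layout[layout$label %in% c("Fz", "FC1"), c("x", "y")]
  centre_theta <- if (nrow(fz)) colMeans(fz) else c(0, 0.35)
  pz <- layout[layout$label == "Pz", c("x", "y")]
  centre_alpha <- if (nrow(pz)) as.numeric(pz) else c(0, -0.45)
  w_theta <- .topo_weight(layout, centre_theta)
  w_alpha <- .topo_weight(layout, centre_alpha)
  osc_theta <- sin(2 * pi * theta_freq * t + stats::runif(1, 0, 2 * pi))
  osc_alpha <- sin(2 * pi * alpha_freq * t + stats::runif(1, 0, 2 * pi))
  samples <- matrix(0, nch, n)
  for (ch in seq_len(nch)) {
    noise <- if (noise_sd > 0) noise_sd * .pink_noise(n) else numeric(n)
    samples[ch, ] <- theta_amp * w_theta[ch] * osc_theta +
      alpha_amp * w_alpha[ch] * osc_alpha + noise
  }
  eeg_record(samples, fs, layout$label, annotations)
}
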