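#' High-pass filter an EEG record
#'
#' Second-order (12 dB/octave) Butterworth high-pass, applied forward and
#' backward (zero phase). Band-power analysis is phase-insensitive, and
#' zero-phase application avoids group delay across epoch boundaries; note
#' the two passes square the magnitude response, so the single-pass -3 dB
#' design point at `fc` becomes -6 dB end to end.
#'
#' @param record An [eeg_record()].
#' @param fc Cutoff frequency, Hz (default 0.5).
#' @param order Filter order (default 2 = 12 dB/octave).
#' @return The filtered [eeg_record()].
#' @export
eeg_highpass <- function(record, fc = 0.5, order = 2) {
  bf <- signal::butter(order, fc / (record$fs / 2), type = "high")
  out <- record
  for (ch in seq_len(nrow(record$samples)))
    out$samples[ch, ] <- signal::filtfilt(bf, record$samples[ch, ])
  out
}

#' One-sided Hann-windowed power spectrum of a single epoch
#'
#' Hann-tapered FFT power spectral density with window-power normalisation,
#' so that broadband power integrates correctly; for a sinusoid at an
#' integer bin frequency the power summed over its (leakage-spread) bins
#' equals A^2/2 times the window's coherent/incoherent gain ratio. Used by
#' [epoch_band_power()]; exposed for spectral diagnostics.
#'
#' @param x Numeric vector (one channel, one epoch).
#' @param fs Sampling rate, Hz.
#' @return Data frame with `freq` (Hz, 0..Nyquist) and `power`
#'   (uV^2/Hz).
#' @export
hann_power_spectrum <- function(x, fs) {
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / n)  # periodic Hann
  X <- stats::fft(w * x)
  nb <- floor(n / 2) + 1L
  p <- (abs(X[seq_len(nb)])^2) / (fs * sum(w^2))
  # one-sided: double everything except DC (and Nyquist for even n)
  dbl <- rep(2, nb); dbl[1] <- 1
  if (n %% 2 == 0) dbl[nb] <- 1
  data.frame(freq = (seq_len(nb) - 1L) * fs / n, power = p * dbl)
}

#' Per-epoch band power of an EEG record
#'
#' Segments each channel into sequential non-overlapping 1-s epochs,
#' Hann-windows each epoch, and assesses frequency content at 1 Hz
#' increments over the requested band by FFT; the band value is the mean
#' power over the band's integer-frequency bins.
#'
#' @param record An [eeg_record()].
#' @param band Numeric length-2, band edges in Hz inclusive (theta
#'   `c(4, 7)`, alpha `c(8, 12)`).
#' @param epoch_s Epoch length in seconds (default 1).
#' @return Matrix of band power, epochs x channels (columns named by
#'   channel label).
#' @export
epoch_band_power <- function(record, band = c(4, 7), epoch_s = 1) {
  fs <- record$fs
  if (band[2] >= fs / 2) stop("band extends beyond the Nyquist frequency")
  len <- round(epoch_s * fs)
  n_ep <- floor(ncol(record$samples) / len)
  if (n_ep < 1L) stop("record shorter than one epoch")
  freqs <- seq(ceiling(band[1]), floor(band[2]))
  bins <- freqs * epoch_s + 1L          # 1 Hz resolution for 1-s epochs
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, len - 1) / len)
  norm <- 2 / (fs * sum(w^2))
  out <- matrix(0, n_ep, nrow(record$samples),
                dimnames = list(NULL, record$labels))
  for (e in seq_len(n_ep)) {
    idx <- ((e - 1L) * len + 1L):(e * len)
    seg <- record$samples[, idx, drop = FALSE] *
      rep(w, each = nrow(record$samples))
    X <- stats::mvfft(t(seg))
    out[e, ] <- colMeans(abs(X[bins, , drop = FALSE])^2) * norm
  }
  out
}

#' Reject high-power epochs
#'
#' Flags epochs whose band-average power (averaged over channels) exceeds
#' the across-epoch mean by more than `k` standard deviations. The
#' threshold is one-sided high: artifacts inflate power.
#'
#' @param epoch_powers Epochs x channels matrix from [epoch_band_power()].
#' @param k Threshold in standard deviations (default 2).
#' @return Logical keep vector, one element per epoch.
#' @export
reject_epochs <- function(epoch_powers, k = 2) {
  avg <- rowMeans(epoch_powers)
  s <- stats::sd(avg)
  if (!is.finite(s) || s == 0) return(rep(TRUE, length(avg)))
  avg <= mean(avg) + k * s
}

#' Subject/day/task band-power summary of one record
#'
#' Runs the spectral pipeline on one record: epoch, band power, 2-SD epoch
#' rejection, and averaging of the surviving epochs, returning one row per
#' channel.
#'
#' @param record An [eeg_record()].
#' @param subject,group,day,task Identifiers attached to the rows.
#' @param band Band edges in Hz.
#' @param band_name Band label for the output (e.g. `"theta"`).
#' @return Data frame with columns `subject`, `group`, `day`, `task`,
#'   `channel`, `band`, `power`, `imputed` (FALSE).
#' @export
band_power_table <- function(record, subject, group, day, task,
                             band = c(4, 7), band_name = "theta") {
  ep <- epoch_band_power(record, band)
  keep <- reject_epochs(ep)
  pw <- colMeans(ep[keep, , drop = FALSE])
  data.frame(subject = subject, group = group, day = day, task = task,
             channel = names(pw), band = band_name, power = unname(pw),
             imputed = FALSE, row.names = NULL)
}

#' Impute missing band-power cells by the group-day mean
#'
#' Completes a band-power table over the study grid: each missing
#' (subject, day, task, channel, band) cell is replaced with the mean power
#' of the same group, day, task, channel, and band, and flagged imputed.
#' Rows with `NA` power count as missing. A group-day cell with no observed
#' data at all cannot be imputed and raises an error.
#'
#' @param table Data frame as returned by [band_power_table()] (rows may be
#'   absent or have `NA` power).
#' @param grid Data frame of all required (subject, group, day, task)
#'   combinations.
#' @return The completed table with the `imputed` flag set on filled rows.
#' @export
impute_missing <- function(table, grid) {
  channels <- unique(table$channel)
  bands <- unique(table$band)
  full <- merge(grid,
                expand.grid(channel = channels, band = bands,
                            stringsAsFactors = FALSE))
  out <- merge(full, table,
               by = c("subject", "group", "day", "task", "channel", "band"),
               all.x = TRUE)
  out$imputed[is.na(out$imputed)] <- TRUE
  miss <- is.na(out$power)
  out$imputed[miss] <- TRUE
  if (any(miss)) {
    key <- interaction(out$group, out$day, out$task, out$channel, out$band,
                       drop = FALSE)
    means <- tapply(out$power, key, mean, na.rm = TRUE)
    fill <- means[key[miss]]
    if (any(!is.finite(fill)))
      stop("a group-day cell has no observed data to impute from")
    out$power[miss] <- fill
  }
  out[order(out$subject, out$day, out$task, out$channel, out$band), ]
}

#' Midline-frontal theta (MFT)
#'
#' Mean theta-band power across electrodes Fz and FC1 (the electrodes
#' nearest medial prefrontal cortex), per subject/day/task.
#'
#' @param table Band-power table containing a `"theta"` band and the Fz and
#'   FC1 channels.
#' @return Data frame with `subject`, `group`, `day`, `task`, `mft`.
#' @export
midline_frontal_theta <- function(table) {
  sub <- table[table$band == "theta" & table$channel %in% c("Fz", "FC1"), ]
  if (nrow(sub) == 0L) stop("table has no theta rows for Fz/FC1")
  key <- interaction(sub$subject, sub$group, sub$day, sub$task, drop = TRUE)
  agg <- tapply(sub$power, key, mean)
  ids <- unique(sub[, c("subject", "group", "day", "task")])
  ids$mft <- as.numeric(agg[interaction(ids$subject, ids$group, ids$day,
                                        ids$task, drop = TRUE)])
  rownames(ids) <- NULL
  ids
}
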