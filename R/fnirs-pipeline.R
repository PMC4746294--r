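# least-squares linear-phase (Type I) FIR design: minimise the weighted
# integrated squared error between H(f) = a0 + 2*sum a_k cos(2 pi f k / fs)
# and a piecewise-constant desired response over continuous frequency bands.
# The normal equations have closed form through the band integrals
# S(m) = int cos(2 pi m f / fs) df, so no frequency grid is involved.
.fir_ls <- function(n_taps, bands, desired, weights, fs) {
  if (n_taps %% 2 == 0L) n_taps <- n_taps + 1L
  M <- (n_taps - 1L) / 2L
  band_S <- function(m, f1, f2) {
    out <- numeric(length(m))
    z <- m == 0
    out[z] <- f2 - f1
    a <- 2 * pi * m[!z] / fs
    out[!z] <- (sin(a * f2) - sin(a * f1)) / a
    out
  }
  mm <- 0:(2L * M)
  S <- numeric(2L * M + 1L)          # sum_b w_b S_b(m)
  R <- numeric(M + 1L)               # right-hand side
  for (i in seq_len(nrow(bands))) {
    s <- band_S(mm, bands[i, 1], bands[i, 2])
    S <- S + weights[i] * s
    R[1] <- R[1] + desired[i] * weights[i] * s[1]
    R[-1] <- R[-1] + desired[i] * weights[i] * 2 * s[2:(M + 1L)]
  }
  G <- matrix(0, M + 1L, M + 1L)
  G[1, 1] <- S[1]
  G[1, -1] <- G[-1, 1] <- 2 * S[2:(M + 1L)]
  k <- seq_len(M)
  G[-1, -1] <- 2 * (S[abs(outer(k, k, "-")) + 1L] + S[outer(k, k, "+") + 1L])
  a <- solve(G, R)
  c(rev(a[-1]), a[1], a[-1])
}

.fir_cache <- new.env(parent = emptyenv())

# zero-phase application of a symmetric FIR by reflection-padded convolution
.apply_fir <- function(x, h) {
  half <- (length(h) - 1L) / 2L
  n <- length(x)
  pad <- min(half, n - 1L)
  xp <- c(rev(x[2:(pad + 1L)]), x, rev(x[(n - pad):(n - 1L)]))
  if (pad < half) xp <- c(rep(xp[1], half - pad), xp,
                          rep(xp[length(xp)], half - pad))
  # FFT-based full convolution; with symmetric h the centred slice is the
  # zero-phase filter output
  y <- stats::convolve(xp, rev(h), type = "open")
  as.numeric(y[(2L * half + 1L):(2L * half + n)])
}

#' Band-pass filter chromophore series
#'
#' Linear-phase least-squares FIR band-pass (default 0.01-0.2 Hz) removing
#' slow drifts below the passband and respiratory/cardiac rhythms above it.
#' The filter is applied with zero phase, and its DC response is forced to
#' exactly zero so constant offsets are removed completely. The default
#' length is three periods of the low edge (2401 taps at 8 Hz); the design
#' is checkable against its analytic frequency response via
#' [fir_frequency_response()].
#'
#' @param x A `chromophore_series`, or a channels x time matrix.
#' @param lo,hi Passband edges, Hz.
#' @param fs Sampling rate, Hz (taken from the series when available).
#' @param n_taps Filter length (odd; default `3 * fs / lo + 1`).
#' @return Filtered object of the same type.
#' @export
fnirs_bandpass <- function(x, lo = 0.01, hi = 0.2, fs = NULL, n_taps = NULL) {
  if (inherits(x, "chromophore_series")) {
    fs <- x$fs
    out <- x
    out$hbo <- fnirs_bandpass(x$hbo, lo, hi, fs, n_taps)
    out$hbr <- fnirs_bandpass(x$hbr, lo, hi, fs, n_taps)
    out$hbt <- out$hbo + out$hbr
    return(out)
  }
  if (is.null(fs)) stop("fs required for matrix input")
  h <- fnirs_bandpass_taps(lo, hi, fs, n_taps)
  if (is.matrix(x)) {
    for (ch in seq_len(nrow(x))) x[ch, ] <- .apply_fir(x[ch, ], h)
    return(x)
  }
  .apply_fir(x, h)
}

#' Band-pass filter coefficients
#'
#' The FIR taps used by [fnirs_bandpass()], exposed so the frequency
#' response can be inspected directly.
#'
#' @inheritParams fnirs_bandpass
#' @return Numeric vector of (odd-length, symmetric) filter taps.
#' @export
fnirs_bandpass_taps <- function(lo = 0.01, hi = 0.2, fs = 8, n_taps = NULL) {
  if (is.null(n_taps)) n_taps <- round(3 * fs / lo) + 1L
  key <- paste(lo, hi, fs, n_taps, sep = "|")
  if (!is.null(.fir_cache[[key]])) return(.fir_cache[[key]])
  nyq <- fs / 2
  # lightly-weighted half-amplitude transition bands keep the normal
  # equations well conditioned at this filter length
  bands <- rbind(c(0, lo / 2), c(lo / 2, lo), c(lo, hi),
                 c(hi, hi * 1.2), c(hi * 1.2, nyq))
  h <- .fir_ls(n_taps, bands, desired = c(0, 0.5, 1, 0.5, 0),
               weights = c(20, 0.05, 1, 0.05, 20), fs = fs)
  h <- h - mean(h)                       # exact zero at DC
  .fir_cache[[key]] <- h
  h
}

#' Analytic frequency response of a symmetric FIR
#'
#' @param h Odd-length symmetric taps.
#' @param f Frequencies, Hz.
#' @param fs Sampling rate, Hz.
#' @return Real-valued amplitude response at `f`.
#' @export
fir_frequency_response <- function(h, f, fs) {
  M <- (length(h) - 1L) / 2L
  a <- h[(M + 1L):length(h)]
  vapply(f, function(fi)
    a[1] + 2 * sum(a[-1] * cos(2 * pi * fi * seq_len(M) / fs)), 0)
}

#' Exclude channels with unstable baselines
#'
#' Drops a channel when the peak-to-peak fluctuation (max minus min) of any
#' chromophore during the baseline window is strictly greater than the
#' threshold (default 0.001 mM; a fluctuation of exactly the threshold is
#' kept).
#'
#' @param series A `chromophore_series`.
#' @param baseline_idx Sample indices of the baseline window.
#' @param threshold Fluctuation threshold, mM.
#' @return Logical keep mask, one element per channel.
#' @export
exclude_channels <- function(series, baseline_idx, threshold = 0.001) {
  ptp <- function(m) apply(m[, baseline_idx, drop = FALSE], 1,
                           function(v) max(v) - min(v))
  !(ptp(series$hbo) > threshold | ptp(series$hbr) > threshold |
      ptp(series$hbt) > threshold)
}

#' Baseline-subtract a chromophore series
#'
#' Subtracts the per-channel mean over the baseline window from each
#' chromophore. Inter-trial samples can be excised from the series (and
#' from the baseline averaging) first via `exclude_idx`.
#'
#' @param series A `chromophore_series`.
#' @param baseline_idx Sample indices of the baseline window (relative to
#'   the series after any excision).
#' @param exclude_idx Optional inter-trial sample indices to remove.
#' @return The corrected `chromophore_series`.
#' @export
baseline_subtract <- function(series, baseline_idx, exclude_idx = NULL) {
  out <- series
  if (!is.null(exclude_idx) && length(exclude_idx)) {
    keep <- setdiff(seq_len(ncol(series$hbo)), exclude_idx)
    for (f in c("hbo", "hbr", "hbt")) out[[f]] <- out[[f]][, keep, drop = FALSE]
    baseline_idx <- match(setdiff(baseline_idx, exclude_idx), keep)
    baseline_idx <- baseline_idx[!is.na(baseline_idx)]
  }
  for (f in c("hbo", "hbr", "hbt")) {
    bl <- rowMeans(out[[f]][, baseline_idx, drop = FALSE])
    out[[f]] <- out[[f]] - bl
  }
  out
}

# DCT high-pass regressors (SPM-style): cosines with periods > cutoff
.dct_basis <- function(n, fs, period) {
  order <- floor(2 * (n / fs) / period)
  if (order < 1L) return(NULL)
  t <- seq_len(n) - 1L
  sapply(seq_len(order), function(k) cos(pi * k * (2 * t + 1) / (2 * n)))
}

#' GLM betas of task-evoked chromophore responses
#'
#' Fits, per channel and chromophore, an ordinary least-squares general
#' linear model whose task regressor is the boxcar of event onsets convolved
#' with the canonical double-gamma HRF, with discrete-cosine high-pass
#' regressors (default cutoff period 128 s) and an intercept for temporal
#' filtering. Returns the task beta and its t statistic.
#'
#' @param series A `chromophore_series`.
#' @param onsets Event onset times, seconds.
#' @param durations Event durations, seconds (scalar or per onset).
#' @param dct_period DCT high-pass cutoff period, seconds.
#' @param hrf Optional HRF sampled at the series' rate; defaults to
#'   [canonical_hrf()] over 32 s.
#' @param chromophores Chromophores to fit (default all three).
#' @return Data frame with `channel`, `chromophore`, `beta`, `se`, `t`.
#' @export
glm_betas <- function(series, onsets, durations, dct_period = 128,
                      hrf = NULL, chromophores = c("hbo", "hbr", "hbt")) {
  fs <- series$fs
  n <- ncol(series$hbo)
  if (any(onsets < 0 | onsets > n / fs)) stop("event onsets fall outside the series")
  box <- numeric(n)
  durations <- rep_len(durations, length(onsets))
  for (i in seq_along(onsets)) {
    i0 <- floor(onsets[i] * fs) + 1L
    i1 <- min(n, i0 + max(1L, round(durations[i] * fs)) - 1L)
    box[i0:i1] <- 1
  }
  if (is.null(hrf)) hrf <- canonical_hrf(seq(0, 32, by = 1 / fs))
  reg <- stats::convolve(box, rev(hrf), type = "open")[seq_len(n)]
  X <- cbind(task = reg, intercept = 1)
  dct <- .dct_basis(n, fs, dct_period)
  if (!is.null(dct)) X <- cbind(X, dct)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[-seq_len(qrX$rank)]
    stop("rank-deficient design matrix; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  fit_one <- function(y) {
    fit <- stats::lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    dfree <- n - ncol(X)
    XtXinv11 <- chol2inv(qr.R(qrX))[1, 1]
    se <- sqrt(rss / dfree * XtXinv11)
    beta <- fit$coefficients[["task"]]
    c(beta = beta, se = se, t = if (se > 0) beta / se else sign(beta) * Inf)
  }
  out <- list()
  for (chrom in chromophores) {
    m <- series[[chrom]]
    for (ch in seq_len(nrow(m))) {
      r <- fit_one(m[ch, ])
      out[[length(out) + 1L]] <- data.frame(
        channel = series$channels[ch], chromophore = chrom,
        beta = r[["beta"]], se = r[["se"]], t = r[["t"]])
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Day-4 minus day-1 contrast of GLM betas with ROI summaries
#'
#' Per-channel paired t-test of day-4 against day-1 betas across subjects,
#' thresholded at the Bonferroni-corrected per-channel alpha (family alpha
#' divided by the number of channels: 0.05 / 20 = 0.0025 in the study
#' montage), plus region-of-interest summaries: day-1 and day-4 means and
#' standard deviations over subjects and channels, their difference, and
#' the count of individually significant channels.
#'
#' @param betas_day1,betas_day4 Subjects x channels matrices of task betas
#'   for one chromophore, subjects in the same order.
#' @param roi Character vector assigning each channel (column) to a region
#'   (e.g. `"M1"`, `"DLPFC"`).
#' @param family_alpha Family-wise alpha before correction (default 0.05).
#' @return An object of class `roi_contrast`: `channels` (per-channel t,
#'   p, significance) and `rois` (per-region summary). The corrected
#'   per-channel threshold is in `attr(, "alpha_corrected")`.
#' @export
day_contrast <- function(betas_day1, betas_day4, roi, family_alpha = 0.05) {
  b1 <- as.matrix(betas_day1); b4 <- as.matrix(betas_day4)
  stopifnot(all(dim(b1) == dim(b4)), length(roi) == ncol(b1))
  alpha_c <- family_alpha / ncol(b1)
  d <- b4 - b1
  n <- nrow(d)
  tval <- colMeans(d) / sqrt(apply(d, 2, stats::var) / n)
  tval[!is.finite(tval)] <- 0
  p <- 2 * stats::pt(-abs(tval), n - 1)
  chans <- data.frame(channel = colnames(b1) %||% seq_len(ncol(b1)),
                      roi = roi, t = tval, p = p,
                      significant = p < alpha_c)
  rois <- do.call(rbind, lapply(unique(roi), function(r) {
    sel <- roi == r
    data.frame(roi = r,
               day1_mean = mean(b1[, sel]), day1_sd = stats::sd(b1[, sel]),
               day4_mean = mean(b4[, sel]), day4_sd = stats::sd(b4[, sel]),
               day4_minus_day1 = mean(b4[, sel]) - mean(b1[, sel]),
               n_significant = sum(chans$significant[sel]))
  }))
  structure(list(channels = chans, rois = rois),
            class = "roi_contrast", alpha_corrected = alpha_c)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.roi_contrast <- function(x, ...) {
  cat("Day 4 - day 1 contrast (per-channel alpha",
      attr(x, "alpha_corrected"), ")\n")
  print(x$rois, row.names = FALSE)
  invisible(x)
}

#' Channel-wise 3.5-standard-deviation significance test
#'
#' Flags a channel when the magnitude of its trial-wise average
#' concentration change exceeds `k` standard errors (trial standard
#' deviation over the square root of the trial count) under the null of no
#' concentration change.
#'
#' @param trial_changes Trials x channels matrix of concentration changes.
#' @param k Threshold in standard errors (default 3.5).
#' @return Data frame with `channel`, `mean`, `se`, `z`, `significant`.
#' @export
channelwise_sd_test <- function(trial_changes, k = 3.5) {
  m <- as.matrix(trial_changes)
  n <- nrow(m)
  mu <- colMeans(m)
  se <- apply(m, 2, stats::sd) / sqrt(n)
  z <- ifelse(se > 0, mu / se, 0)
  data.frame(channel = colnames(m) %||% seq_len(ncol(m)),
             mean = mu, se = se, z = z, significant = abs(z) > k,
             row.names = NULL)
}
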