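#' Optical model for dual-wavelength fNIRS
#'
#' Holds the quantities of the modified Beer-Lambert law (MBLL): molar
#' extinction coefficients of oxygenated and deoxygenated haemoglobin at the
#' two measurement wavelengths, differential pathlength factors (DPF), and
#' per-channel source-detector separations. Defaults are the published
#' values: wavelengths 760/850 nm, epsilon_Hboxy = (1097.0, 781.0) and
#' epsilon_Hbdeoxy = (645.5, 1669.0) cm^-1/M, DPF 5.98 and 7.15. The source
#' binds one DPF to each chromophore; physically DPF is a property of the
#' wavelength, so by default 5.98 is mapped to 760 nm and 7.15 to 850 nm —
#' the mapping is configurable via `dpf`.
#'
#' @param wavelengths Two wavelengths, nm.
#' @param epsilon 2 x 2 matrix of extinction coefficients, cm^-1/M; rows =
#'   wavelengths, columns = chromophores (Hboxy, Hbdeoxy). Must be
#'   invertible.
#' @param dpf Differential pathlength factors, one per wavelength.
#' @param distances Named numeric vector of per-channel source-detector
#'   separations, cm (<= 3.5 in the study montage).
#' @return An object of class `extinction_model`.
#' @export
extinction_model <- function(wavelengths = c(760, 850),
                             epsilon = matrix(c(1097.0, 645.5,
                                                781.0, 1669.0),
                                              2, 2, byrow = TRUE,
                                              dimnames = list(c("760", "850"),
                                                              c("hbo", "hbr"))),
                             dpf = c(5.98, 7.15),
                             distances = NULL) {
  if (abs(det(epsilon)) < .Machine$double.eps * max(abs(epsilon))^2)
    stop("extinction coefficient matrix is singular")
  if (!is.null(distances) && any(distances <= 0))
    stop("source-detector distances must be > 0")
  structure(list(wavelengths = wavelengths, epsilon = epsilon, dpf = dpf,
                 distances = distances),
            class = "extinction_model")
}

# per-channel MBLL system matrix A (2x2): dOD_lambda = A %*% dc_mM
.mbll_matrix <- function(optics, distance_cm) {
  optics$epsilon * optics$dpf * distance_cm / 1000  # mM -> M
}

#' Forward modified Beer-Lambert model
#'
#' Maps chromophore concentration changes (mM) to optical-density changes
#' at the two wavelengths: dOD_lambda = sum_c eps(lambda, c) * dc * d *
#' DPF(lambda).
#'
#' @param hbo,hbr Channels x time matrices of concentration changes, mM.
#' @param optics An [extinction_model()] with per-channel `distances` named
#'   (or ordered) as the rows of `hbo`.
#' @return List with `od760` and `od850`, channels x time matrices.
#' @export
fnirs_forward <- function(hbo, hbr, optics) {
  hbo <- as.matrix(hbo); hbr <- as.matrix(hbr)
  d <- .channel_distances(optics, nrow(hbo))
  od760 <- od850 <- hbo * 0
  for (ch in seq_len(nrow(hbo))) {
    A <- .mbll_matrix(optics, d[ch])
    od <- A %*% rbind(hbo[ch, ], hbr[ch, ])
    od760[ch, ] <- od[1, ]; od850[ch, ] <- od[2, ]
  }
  list(od760 = od760, od850 = od850)
}

.channel_distances <- function(optics, n_channels) {
  d <- optics$distances
  if (is.null(d)) stop("optics must carry per-channel source-detector distances")
  if (length(d) == 1L) d <- rep(d, n_channels)
  if (length(d) != n_channels)
    stop("channel map / distances do not match the data")
  d
}

#' Invert the modified Beer-Lambert law
#'
#' Solves the per-sample 2 x 2 MBLL system for the oxygenated and
#' deoxygenated haemoglobin concentration changes and derives total
#' haemoglobin as their sum. The exact inverse of [fnirs_forward()] in the
#' noise-free case.
#'
#' @param od List with `od760`, `od850` channels x time matrices of
#'   optical-density changes.
#' @param optics An [extinction_model()] with distances.
#' @param fs Sampling rate, Hz (8 in the study); carried on the result.
#' @param channels Optional channel labels.
#' @return An object of class `chromophore_series`: matrices `hbo`, `hbr`,
#'   `hbt` (mM, channels x time), `fs`, `channels`.
#' @export
mbll_convert <- function(od, optics, fs = 8, channels = NULL) {
  od760 <- as.matrix(od$od760); od850 <- as.matrix(od$od850)
  d <- .channel_distances(optics, nrow(od760))
  hbo <- hbr <- od760 * 0
  for (ch in seq_len(nrow(od760))) {
    Ainv <- solve(.mbll_matrix(optics, d[ch]))
    conc <- Ainv %*% rbind(od760[ch, ], od850[ch, ])
    hbo[ch, ] <- conc[1, ]; hbr[ch, ] <- conc[2, ]
  }
  chromophore_series(hbo, hbr, fs = fs, channels = channels)
}

#' Construct a chromophore concentration series
#'
#' @param hbo,hbr Channels x time matrices, mM.
#' @param fs Sampling rate, Hz.
#' @param channels Optional channel labels.
#' @return Object of class `chromophore_series` with `hbt = hbo + hbr`.
#' @export
chromophore_series <- function(hbo, hbr, fs = 8, channels = NULL) {
  hbo <- as.matrix(hbo); hbr <- as.matrix(hbr)
  stopifnot(all(dim(hbo) == dim(hbr)))
  if (is.null(channels)) channels <- rownames(hbo)
  if (is.null(channels)) channels <- sprintf("ch%02d", seq_len(nrow(hbo)))
  structure(list(hbo = hbo, hbr = hbr, hbt = hbo + hbr,
                 fs = fs, channels = channels),
            class = "chromophore_series")
}

#' @export
print.chromophore_series <- function(x, ...) {
  cat("Chromophore series:", nrow(x$hbo), "channels x", ncol(x$hbo),
      "samples @", x$fs, "Hz\n")
  invisible(x)
}

#' Canonical haemodynamic response function
#'
#' Double-gamma canonical HRF: a positive gamma density peaking ~5-6 s minus
#' a later undershoot gamma (peak ~16 s) scaled by the undershoot ratio,
#' normalised to unit peak.
#'
#' @param t Time points, seconds.
#' @param peak Shape of the response gamma (seconds to peak ~ shape - 1).
#' @param undershoot Shape of the undershoot gamma.
#' @param ratio Undershoot amplitude ratio (default 1/6).
#' @return Numeric vector of HRF values.
#' @export
canonical_hrf <- function(t, peak = 6, undershoot = 16, ratio = 1 / 6) {
  h <- stats::dgamma(t, shape = peak, rate = 1) -
    ratio * stats::dgamma(t, shape = undershoot, rate = 1)
  h / max(h)
}
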