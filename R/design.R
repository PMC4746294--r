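#' Study design for a four-group flight-training experiment
#'
#' Describes the group structure and daily task schedule of a four-arm
#' (anodal tDCS over DLPFC or M1, each with a sham control) flight-simulator
#' training study: the number of training days, adaptive n-back blocks per
#' day, and easy-landing attempts per day. The defaults reproduce the
#' published cohort: DLPFC stim n = 7, DLPFC sham n = 7, M1 stim n = 10,
#' M1 sham n = 8; four consecutive daily sessions with six n-back blocks and
#' five easy landings each.
#'
#' @param groups Named integer vector of subjects per group. Names must be
#'   drawn from `DLPFC_stim`, `DLPFC_sham`, `M1_stim`, `M1_sham`.
#' @param n_days Number of training days (>= 2).
#' @param n_nback_blocks_per_day Adaptive n-back blocks per daily session.
#' @param n_landings_per_day Easy-landing attempts per daily session.
#' @param seed Integer seed that makes a generated study reproducible.
#' @return An object of class `study_design`.
#' @export
#' @examples
#' d <- study_design()
#' sum(d$groups)  # 32 subjects
study_design <- function(groups = c(DLPFC_stim = 7L, DLPFC_sham = 7L,
                                    M1_stim = 10L, M1_sham = 8L),
                         n_days = 4L,
                         n_nback_blocks_per_day = 6L,
                         n_landings_per_day = 5L,
                         seed = 1L) {
  valid <- c("DLPFC_stim", "DLPFC_sham", "M1_stim", "M1_sham")
  if (is.null(names(groups)) || !all(names(groups) %in% valid))
    stop("invalid group label; must be one of: ", paste(valid, collapse = ", "))
  groups <- vapply(groups, as.integer, integer(1))
  if (any(groups < 1L)) stop("all group sizes must be >= 1")
  if (n_days < 2L) stop("n_days must be >= 2")
  if (n_nback_blocks_per_day < 1L || n_landings_per_day < 1L)
    stop("all counts must be >= 1")
  structure(list(groups = groups,
                 n_days = as.integer(n_days),
                 n_nback_blocks_per_day = as.integer(n_nback_blocks_per_day),
                 n_landings_per_day = as.integer(n_landings_per_day),
                 seed = as.integer(seed)),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("Study design:", sum(x$groups), "subjects,", x$n_days, "days\n")
  for (g in names(x$groups)) cat(sprintf("  %-11s n = %d\n", g, x$groups[[g]]))
  cat(sprintf("  %d n-back blocks/day, %d landings/day, seed %d\n",
              x$n_nback_blocks_per_day, x$n_landings_per_day, x$seed))
  invisible(x)
}

#' Effect configuration for the synthetic-data generator
#'
#' Encodes, per experimental group, the behavioural and neural effects the
#' generator injects and the noise scales of each modality. The defaults
#' encode the direction of the study's headline findings: reduced
#' between-subject learning-rate variance under DLPFC stimulation, a rising
#' midline-frontal theta amplitude across days for DLPFC stim, and a
#' day-4-minus-day-1 decrease in DLPFC oxygenated haemoglobin. Group mean
#' online learning rates are equal by default (group differences in mean
#' rates were not observed; the group effect is on their variance).
#'
#' Units: `online_rate_mean`/`online_rate_sd` are scaled-accuracy points per
#' block; `variance_shrink_factor` multiplies the between-subject rate
#' variance (1 = no shrink); `theta_day_slope` is a theta oscillation
#' amplitude increment in microvolts per day at the midline-frontal focus;
#' `dlpfc_hboxy_day4_minus_day1` is the injected change in task-evoked
#' DLPFC Hboxy response amplitude, in mM.
#'
#' @param online_rate_mean,online_rate_sd Named numeric vectors per group.
#' @param variance_shrink_factor Named numeric vector per group; must lie in
#'   (0, 1].
#' @param theta_day_slope Named numeric vector per group (uV/day).
#' @param dlpfc_hboxy_day4_minus_day1 Named numeric vector per group (mM);
#'   defaults follow the magnitudes of the published easy-landing day
#'   contrasts.
#' @param noise List of modality noise scales: `nback` (none; trial
#'   correctness is Bernoulli), `flight_vspeed_sd` (ft/min), `flight_ar`
#'   (AR(1) coefficient of the vertical-speed noise), `flight_lateral_sd`
#'   (m), `missed_rate` (per-trial missed-landing probability),
#'   `eeg_pink_sd` (uV), `fnirs_od_sd` (optical-density units).
#' @return An object of class `effect_config`.
#' @export
effect_config <- function(
    online_rate_mean = c(DLPFC_stim = 2, DLPFC_sham = 2, M1_stim = 2, M1_sham = 2),
    online_rate_sd   = c(DLPFC_stim = 2, DLPFC_sham = 2, M1_stim = 2, M1_sham = 2),
    variance_shrink_factor = c(DLPFC_stim = 0.25, DLPFC_sham = 1, M1_stim = 1, M1_sham = 1),
    theta_day_slope  = c(DLPFC_stim = 1, DLPFC_sham = 0, M1_stim = 0, M1_sham = 0),
    dlpfc_hboxy_day4_minus_day1 = c(DLPFC_stim = -0.0024, DLPFC_sham = -0.00043,
                                    M1_stim = -0.0011, M1_sham = -0.00013),
    noise = list(flight_vspeed_sd = 60, flight_ar = 0.95, flight_lateral_sd = 10,
                 missed_rate = 0.03, eeg_pink_sd = 1, fnirs_od_sd = 5e-4)) {
  if (any(online_rate_sd < 0)) stop("all sd values must be >= 0")
  if (any(variance_shrink_factor <= 0 | variance_shrink_factor > 1))
    stop("variance_shrink_factor must lie in (0, 1]")
  structure(list(online_rate_mean = online_rate_mean,
                 online_rate_sd = online_rate_sd,
                 variance_shrink_factor = variance_shrink_factor,
                 theta_day_slope = theta_day_slope,
                 dlpfc_hboxy_day4_minus_day1 = dlpfc_hboxy_day4_minus_day1,
                 noise = noise),
            class = "effect_config")
}

#' High-definition tDCS montage with signed electrode currents
#'
#' Returns the multi-electrode stimulation montage for a target region, with
#' signed per-electrode currents in microamps at standard 10-10 sites. The
#' current-conservation invariant (signed currents sum to exactly 0) is
#' enforced, and the anode total is checked to be ~2000 uA within rounding.
#' The nominal total current (2 mA) and the printed scalp current density
#' (0.04 A/m^2) are stored verbatim without reconciling them against the
#' electrode areas.
#'
#' @param target `"M1"` or `"DLPFC"`.
#' @param electrode_currents Optional data.frame with columns `site` and
#'   `current_uA` overriding the built-in montage.
#' @return An object of class `stim_montage`.
#' @export
#' @examples
#' m <- stim_montage("M1")
#' sum(m$electrode_currents$current_uA)  # 0
stim_montage <- function(target = c("M1", "DLPFC"), electrode_currents = NULL) {
  target <- match.arg(target)
  if (is.null(electrode_currents)) {
    electrode_currents <- switch(target,
      M1 = data.frame(site = c("CP1", "CP3", "FP1", "F8", "F9"),
                      current_uA = c(1244, 745, -417, -448, -1124)),
      DLPFC = data.frame(site = c("F6", "FC6", "AF8", "AF4", "FP2"),
                         current_uA = c(1511, 482, -271, -283, -1439)))
  }
  tot <- sum(electrode_currents$current_uA)
  if (tot != 0)
    stop("montage currents must sum to exactly 0 uA (got ", tot, ")")
  anode <- sum(electrode_currents$current_uA[electrode_currents$current_uA > 0])
  if (abs(anode - 2000) > 25)
    warning("anode total ", anode, " uA departs from the nominal 2000 uA by more than rounding")
  structure(list(target = target,
                 electrode_currents = electrode_currents,
                 total_current_mA = 2,
                 scalp_current_density_A_m2 = 0.04),
            class = "stim_montage")
}

#' @export
print.stim_montage <- function(x, ...) {
  cat("tDCS montage, target", x$target, "\n")
  print(x$electrode_currents, row.names = FALSE)
  invisible(x)
}
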