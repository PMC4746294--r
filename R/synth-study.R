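#' Generate a complete synthetic training study
#'
#' Simulates the full four-group, four-day experiment with the statistical
#' structure the analysis pipeline assumes: per-subject adaptive n-back logs,
#' easy-landing telemetry against a common autopilot reference, multichannel
#' EEG with group/day-dependent midline-frontal theta amplitude, and
#' dual-wavelength fNIRS optical densities with a group-dependent
#' day-4-minus-day-1 DLPFC Hboxy change. Ground-truth per-subject parameters
#' (true online learning rates, ability, flight skill, injected neural
#' effects) are returned alongside the data so every downstream stage can be
#' checked for parameter recovery. Output is deterministic for a fixed
#' `design$seed`.
#'
#' Subject ability and its growth follow the model of
#' [generate_nback_log()]; between-subject online-rate standard deviations
#' are multiplied by the square root of the group's `variance_shrink_factor`
#' (so a factor of 0.25 halves the between-subject SD).
#'
#' @param design A [study_design()].
#' @param effects An [effect_config()].
#' @param modalities Character subset of `c("nback", "flight", "eeg",
#'   "fnirs")`; generate only what an analysis needs (EEG dominates memory).
#'   An empty vector returns ground truth only.
#' @param eeg_duration_s Per-subject-day EEG segment length, seconds.
#' @param fnirs_duration_s Per-subject-day fNIRS session length, seconds.
#' @return An object of class `synthetic_study`: `design`, `effects`,
#'   `truth` (per-subject data frame), `reference` (autopilot trace), and
#'   one element per requested modality (`nback`, `flight`, `eeg`,
#'   `fnirs`), each a list keyed by subject id.
#' @export
generate_study <- function(design = study_design(),
                           effects = effect_config(),
                           modalities = c("nback", "flight", "eeg", "fnirs"),
                           eeg_duration_s = 10, fnirs_duration_s = 330) {
  bad <- setdiff(modalities, c("nback", "flight", "eeg", "fnirs"))
  if (length(bad)) stop("unknown modality: ", paste(bad, collapse = ", "))
  if (!all(names(design$groups) %in% names(effects$online_rate_mean)))
    stop("effects must cover every group in the design")
  set.seed(design$seed)
  reference <- autopilot_trace()
  layout <- eeg_layout()
  cmap <- fnirs_channel_map()
  noise <- effects$noise

  truth <- list(); nback <- list(); flight <- list(); eeg <- list()
  fnirs <- list()
  for (g in names(design$groups)) {
    sd_g <- effects$online_rate_sd[[g]] *
      sqrt(effects$variance_shrink_factor[[g]])
    for (s in seq_len(design$groups[[g]])) {
      id <- sprintf("%s_%02d", g, s)
      rate <- stats::rnorm(1, effects$online_rate_mean[[g]], sd_g)
      ability <- stats::rnorm(1, 45, 8)
      offgain <- stats::rnorm(1, 3, 1)
      skill <- stats::rlnorm(1, 0, 0.25)
      truth[[id]] <- data.frame(
        subject = id, group = g, online_rate = rate, ability = ability,
        offline_gain = offgain, skill = skill,
        theta_amp_day1 = 3,
        theta_amp_day_slope = effects$theta_day_slope[[g]],
        hbo_day4_minus_day1 = effects$dlpfc_hboxy_day4_minus_day1[[g]])

      if ("nback" %in% modalities)
        nback[[id]] <- generate_nback_log(
          ability, online_rate = rate, offline_gain = offgain,
          n_days = design$n_days, n_blocks = design$n_nback_blocks_per_day)

      if ("flight" %in% modalities)
        flight[[id]] <- lapply(seq_len(design$n_days), function(d) {
          day_skill <- skill * (1 + 0.15 * (d - 1))
          lapply(seq_len(design$n_landings_per_day), function(tr)
            generate_flight_trace(reference, skill = day_skill,
                                  vspeed_sd = noise$flight_vspeed_sd,
                                  ar = noise$flight_ar,
                                  lateral_sd = noise$flight_lateral_sd,
                                  p_missed = noise$missed_rate))
        })

      if ("eeg" %in% modalities)
        eeg[[id]] <- lapply(seq_len(design$n_days), function(d)
          generate_eeg(layout, duration_s = eeg_duration_s,
                       theta_amp = 3 + effects$theta_day_slope[[g]] * (d - 1),
                       alpha_amp = 2, noise_sd = noise$eeg_pink_sd))

      if ("fnirs" %in% modalities) {
        base <- rep(0.002, nrow(cmap))
        amp4 <- base
        amp4[cmap$roi == "DLPFC"] <- amp4[cmap$roi == "DLPFC"] +
          effects$dlpfc_hboxy_day4_minus_day1[[g]]
        fnirs[[id]] <- list(
          day1 = generate_fnirs(cmap, amp_hbo = base,
                                duration_s = fnirs_duration_s,
                                od_noise_sd = noise$fnirs_od_sd),
          day4 = generate_fnirs(cmap, amp_hbo = amp4,
                                duration_s = fnirs_duration_s,
                                od_noise_sd = noise$fnirs_od_sd))
      }
    }
  }
  structure(list(design = design, effects = effects,
                 truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
                 reference = reference,
                 nback = if ("nback" %in% modalities) nback,
                 flight = if ("flight" %in% modalities) flight,
                 eeg = if ("eeg" %in% modalities) eeg,
                 fnirs = if ("fnirs" %in% modalities) fnirs),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic study:", nrow(x$truth), "subjects,", x$design$n_days,
      "days; modalities:",
      paste(Filter(function(m) !is.null(x[[m]]),
                   c("nback", "flight", "eeg", "fnirs")), collapse = ", "),
      "\n")
  invisible(x)
}
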