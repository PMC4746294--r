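#' Family-wise error rate of the cluster permutation test under the null
#'
#' Simulates independent null studies (two groups sharing one band-power
#' distribution, no true effect) and reports the fraction in which the
#' cluster-based permutation test declares at least one significant cluster
#' at the given settings. Under a valid test this empirical family-wise rate
#' is controlled at the cluster-level alpha.
#'
#' @param n_studies Number of simulated studies (default 500).
#' @param n_subjects Subjects per group (default 7).
#' @param n_channels Channels; laid out on a near-square grid (default 30).
#' @param n_perm Permutations per test (default 500).
#' @param point_alpha,cluster_alpha,min_extent Test settings (defaults
#'   0.05, 0.05, 2).
#' @return List with `rate` (fraction of studies with any significant
#'   cluster), `hits`, `n_studies`.
#' @export
fwer_null_study <- function(n_studies = 500, n_subjects = 7,
                            n_channels = 30, n_perm = 500,
                            point_alpha = 0.05, cluster_alpha = 0.05,
                            min_extent = 2L) {
  nr <- floor(sqrt(n_channels))
  nc <- ceiling(n_channels / nr)
  lay <- grid_layout(nr, nc)[seq_len(n_channels), ]
  adj <- build_adjacency(lay, max_distance = 1.0001)
  hits <- 0L
  for (i in seq_len(n_studies)) {
    a <- matrix(stats::rnorm(n_subjects * n_channels), n_subjects)
    b <- matrix(stats::rnorm(n_subjects * n_channels), n_subjects)
    res <- permutation_test(a, b, adj, n_perm = n_perm,
                            point_alpha = point_alpha,
                            cluster_alpha = cluster_alpha,
                            min_extent = min_extent)
    if (any(res$clusters$significant)) hits <- hits + 1L
  }
  list(rate = hits / n_studies, hits = hits, n_studies = n_studies)
}

#' Online-learning-rate recovery over replicate synthetic cohorts
#'
#' Generates replicate cohorts, estimates each subject's online learning
#' rate from the scaled n-back accuracies (mean over the days after the
#' adaptive level has stabilised, default days 2-4), and summarises, per
#' cohort and group: the estimated group mean, the injected mean, the
#' standard error of the estimator (combining the injected between-subject
#' SD with the per-subject OLS slope SEs), and the measurement-error
#' corrected between-subject variance (method of moments:
#' `var(estimates) - mean(se^2)`), from which the variance-shrink factor can
#' be recovered by pooling cohorts.
#'
#' @param n_cohorts Number of replicate cohorts.
#' @param design Template [study_design()]; each cohort uses seed
#'   `design$seed + cohort - 1`.
#' @param effects An [effect_config()].
#' @param days Days used for estimation (default 2:4).
#' @return Data frame with one row per (cohort, group): `est`, `mu`,
#'   `se_check`, `var_between_corrected`, `var_between_true`.
#' @export
rate_recovery_study <- function(n_cohorts = 200, design = study_design(),
                                effects = effect_config(), days = 2:4) {
  out <- list()
  for (k in seq_len(n_cohorts)) {
    d <- design
    d$seed <- design$seed + k - 1L
    study <- generate_study(d, effects, modalities = "nback")
    est <- se2 <- numeric(nrow(study$truth))
    for (i in seq_len(nrow(study$truth))) {
      sc <- score_log(study$nback[[study$truth$subject[i]]])
      fits <- lapply(days, function(dd)
        online_rate(sc$combined_scaled[sc$day == dd],
                    sc$block[sc$day == dd]))
      est[i] <- mean(vapply(fits, `[[`, 0, "slope"))
      se2[i] <- mean(vapply(fits, `[[`, 0, "se")^2) / length(days)
    }
    for (g in names(d$groups)) {
      sel <- study$truth$group == g
      n <- sum(sel)
      sigma_r2 <- (effects$online_rate_sd[[g]]^2 *
                     effects$variance_shrink_factor[[g]])
      out[[length(out) + 1L]] <- data.frame(
        cohort = k, group = g,
        est = mean(est[sel]),
        mu = effects$online_rate_mean[[g]],
        se_check = sqrt(sigma_r2 / n + mean(se2[sel]) / n),
        var_between_corrected = stats::var(est[sel]) - mean(se2[sel]),
        var_between_true = stats::var(study$truth$online_rate[sel]))
    }
  }
  do.call(rbind, out)
}

#' Sign recovery of the injected DLPFC Hboxy day contrast
#'
#' Runs the full fNIRS pipeline (forward simulation, MBLL inversion,
#' 0.01-0.2 Hz band-pass, baseline subtraction, HRF GLM, day contrast) on
#' replicate stimulated cohorts and reports how often the sign of the
#' injected DLPFC Hboxy day-4-minus-day-1 change is recovered in the ROI
#' contrast.
#'
#' @param n_reps Number of replicate cohorts.
#' @param n_subjects Subjects per replicate (default 7).
#' @param delta Injected DLPFC Hboxy change, mM (default the DLPFC-stim
#'   value of [effect_config()]).
#' @param duration_s Session length per day, seconds.
#' @return List with `fraction` of replicates recovering the sign,
#'   `contrasts` (the per-replicate ROI day contrasts).
#' @export
hbo_sign_recovery_study <- function(n_reps = 30, n_subjects = 7,
                                    delta = effect_config()$dlpfc_hboxy_day4_minus_day1[["DLPFC_stim"]],
                                    duration_s = 330) {
  cmap <- fnirs_channel_map()
  base <- rep(0.002, nrow(cmap))
  amp4 <- base
  amp4[cmap$roi == "DLPFC"] <- amp4[cmap$roi == "DLPFC"] + delta
  betas_of <- function(amp) {
    sim <- generate_fnirs(cmap, amp_hbo = amp, duration_s = duration_s)
    cs <- mbll_convert(sim$od, sim$optics, fs = sim$fs,
                       channels = cmap$channel)
    filt <- fnirs_bandpass(cs)
    bs <- baseline_subtract(filt, seq_len(sim$onsets[1] * sim$fs))
    b <- glm_betas(bs, sim$onsets, sim$durations, chromophores = "hbo")
    b$beta
  }
  contrasts <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    b1 <- t(vapply(seq_len(n_subjects), function(s) betas_of(base),
                   numeric(nrow(cmap))))
    b4 <- t(vapply(seq_len(n_subjects), function(s) betas_of(amp4),
                   numeric(nrow(cmap))))
    rc <- day_contrast(b1, b4, cmap$roi)
    contrasts[r] <- rc$rois$day4_minus_day1[rc$rois$roi == "DLPFC"]
  }
  list(fraction = mean(sign(contrasts) == sign(delta)),
       contrasts = contrasts)
}
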