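test_that("the high-pass removes DC, preserves 10 Hz, and is -3 dB at fc by design", {
  fs <- 500
  t <- seq_len(10 * fs) / fs
  rec <- eeg_record(matrix(5 + sin(2 * pi * 10 * t), 1), fs, "Fz")
  hp <- eeg_highpass(rec)
  mid <- (2 * fs):(8 * fs)   # steady state, away from edge transients
  expect_lt(abs(mean(hp$samples[1, mid])) / 5, 0.01)      # DC < 1%
  amp_ratio <- sd(hp$samples[1, mid]) / sd(rec$samples[1, mid] - 5)
  expect_equal(amp_ratio, 1, tolerance = 0.01)            # 10 Hz within 1%
  # analytic single-pass Butterworth magnitude at fc is -3 dB
  bf <- signal::butter(2, 0.5 / (fs / 2), type = "high")
  z <- exp(-1i * 2 * pi * 0.5 / fs)
  H <- sum(bf$b * z^(0:2)) / sum(bf$a * z^(0:2))
  expect_equal(20 * log10(abs(H)), -3.01, tolerance = 0.05)
})

test_that("band power selects its band, is flat for white noise, and scales as amplitude^2", {
  fs <- 500
  t <- seq_len(20 * fs) / fs
  alpha_sig <- eeg_record(matrix(sin(2 * pi * 10 * t), 1), fs, "Fz")
  pa <- mean(epoch_band_power(alpha_sig, c(8, 12)))
  pt_ <- mean(epoch_band_power(alpha_sig, c(4, 7)))
  expect_gt(pa / pt_, 100)
  # doubling amplitude quadruples band power
  alpha2 <- eeg_record(2 * alpha_sig$samples, fs, "Fz")
  expect_equal(mean(epoch_band_power(alpha2, c(8, 12))) / pa, 4,
               tolerance = 1e-6)
  # flat-spectrum oracle: white noise has equal per-Hz power in both bands
  set.seed(61)
  wn <- eeg_record(matrix(rnorm(200 * fs), 1), fs, "Fz")
  p_theta <- mean(epoch_band_power(wn, c(4, 7)))
  p_alpha <- mean(epoch_band_power(wn, c(8, 12)))
  expect_equal(p_theta / p_alpha, 1, tolerance = 0.1)
  expect_error(epoch_band_power(wn, c(240, 260)), "Nyquist")
})

test_that("Parseval holds for the Hann-windowed spectrum to 1e-6 relative", {
  set.seed(62)
  for (i in 1:3) {
    x <- rnorm(500)
    ps <- hann_power_spectrum(x, 500)
    w <- 0.5 - 0.5 * cos(2 * pi * seq(0, 499) / 500)
    # integral of the one-sided PSD (df = 1 Hz) = windowing-corrected power
    expect_equal(sum(ps$power), sum((w * x)^2) / sum(w^2),
                 tolerance = 1e-6)
  }
})

test_that("epoch rejection drops only high-power epochs, one-sided", {
  set.seed(63)
  ep <- matrix(rexp(40 * 5, 1), 40, 5) + 5
  base_keep <- reject_epochs(ep)
  ep2 <- ep
  ep2[7, ] <- ep2[7, ] * 100   # z-score check: one artifact epoch
  keep <- reject_epochs(ep2)
  expect_false(keep[7])
  expect_true(sum(keep) <= nrow(ep2))
  # a very LOW power epoch is never rejected (one-sided rule)
  ep3 <- ep; ep3[3, ] <- 0
  expect_true(reject_epochs(ep3)[3])
  # no extremes -> identity
  flat <- matrix(1 + seq(0, 0.1, length.out = 10), 10, 4)
  expect_true(all(reject_epochs(flat)))
})

test_that("imputation fills missing cells with the group-day mean and flags them", {
  grid <- expand.grid(subject = c("s1", "s2", "s3"), group = "G",
                      day = 1:2, task = "nback",
                      stringsAsFactors = FALSE)
  tab <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i)
    data.frame(grid[i, ], channel = c("Fz", "FC1"), band = "theta",
               power = c(2, 4) + grid$day[i], imputed = FALSE,
               row.names = NULL)))
  full <- impute_missing(tab, grid)
  expect_equal(nrow(full), nrow(tab))
  expect_equal(sort(full$power), sort(tab$power))  # no missing -> identity
  # drop one subject-day entirely; cells come back as the group-day mean
  tab2 <- tab[!(tab$subject == "s2" & tab$day == 1), ]
  full2 <- impute_missing(tab2, grid)
  got <- full2[full2$subject == "s2" & full2$day == 1 &
                 full2$channel == "Fz", ]
  expect_true(got$imputed)
  expect_equal(got$power, 3)   # mean of s1, s3 day-1 Fz
  # an empty group-day cannot be imputed
  tab3 <- tab[tab$day != 1, ]
  expect_error(impute_missing(tab3, grid), "no observed data")
})

test_that("midline-frontal theta is the Fz/FC1 mean and ignores other channels", {
  tab <- data.frame(subject = "s1", group = "G", day = 1, task = "nback",
                    channel = c("Fz", "FC1", "Pz"), band = "theta",
                    power = c(2, 4, 99), imputed = FALSE)
  expect_equal(midline_frontal_theta(tab)$mft, 3)
  tab$power[3] <- 1e6
  expect_equal(midline_frontal_theta(tab)$mft, 3)   # locality
  tab_eq <- tab; tab_eq$power[1:2] <- 5
  expect_equal(midline_frontal_theta(tab_eq)$mft, 5)
})

test_that("the spectral pipeline recovers an injected day-4/day-1 theta power ratio", {
  lay <- eeg_layout()
  day1 <- generate_eeg(lay, duration_s = 10, theta_amp = 3, seed = 64)
  day4 <- generate_eeg(lay, duration_s = 10, theta_amp = 6, seed = 65)
  mft_of <- function(rec, day) {
    tab <- band_power_table(rec, "s1", "G", day, "nback")
    midline_frontal_theta(tab)$mft
  }
  ratio <- mft_of(day4, 4) / mft_of(day1, 1)
  expect_equal(ratio, 4, tolerance = 0.1 * 4)  # power ~ amplitude^2
  # determinism of the generator
  expect_identical(generate_eeg(lay, duration_s = 2, seed = 9)$samples,
                   generate_eeg(lay, duration_s = 2, seed = 9)$samples)
  # zero oscillation amplitude leaves bands statistically equal
  null_rec <- generate_eeg(lay, duration_s = 6, theta_amp = 0, alpha_amp = 0,
                           seed = 66)
  tp <- colMeans(epoch_band_power(null_rec, c(4, 7)))
  expect_lt(max(tp) / min(tp), 20)  # no channel stands out by orders of magnitude
})
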