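optics20 <- function() {
  o <- extinction_model()
  o$distances <- rep(3, 2)
  o
}

test_that("MBLL inversion is the exact inverse of the forward model", {
  set.seed(91)
  hbo <- matrix(rnorm(2 * 50, 0, 0.001), 2, 50)
  hbr <- matrix(rnorm(2 * 50, 0, 0.0005), 2, 50)
  od <- fnirs_forward(hbo, hbr, optics20())
  cs <- mbll_convert(od, optics20())
  expect_equal(cs$hbo, hbo, tolerance = 1e-12)
  expect_equal(cs$hbr, hbr, tolerance = 1e-12)
  expect_equal(cs$hbt, hbo + hbr, tolerance = 1e-12)
  # zero optical-density change -> zero concentration change
  z <- mbll_convert(list(od760 = hbo * 0, od850 = hbo * 0), optics20())
  expect_true(all(z$hbo == 0) && all(z$hbr == 0))
  # linearity: doubling OD doubles concentrations
  cs2 <- mbll_convert(list(od760 = 2 * od$od760, od850 = 2 * od$od850),
                      optics20())
  expect_equal(cs2$hbo, 2 * cs$hbo, tolerance = 1e-12)
  # singular extinction matrix is rejected
  expect_error(extinction_model(epsilon = matrix(c(1, 2, 2, 4), 2)),
               "singular")
  expect_error(mbll_convert(od, extinction_model()), "distances")
})

test_that("Hbtot equals Hboxy + Hbdeoxy through every pipeline stage", {
  sim <- generate_fnirs(seed = 92, duration_s = 120)
  cs <- mbll_convert(sim$od, sim$optics)
  expect_equal(cs$hbt, cs$hbo + cs$hbr, tolerance = 1e-12)
  filt <- fnirs_bandpass(cs)
  expect_equal(filt$hbt, filt$hbo + filt$hbr, tolerance = 1e-12)
  bs <- baseline_subtract(filt, 1:100)
  expect_equal(bs$hbt, bs$hbo + bs$hbr, tolerance = 1e-12)
})

test_that("the band-pass meets its frequency-response oracle", {
  h <- fnirs_bandpass_taps()
  # DC exactly removed by construction
  expect_equal(fir_frequency_response(h, 0, 8), 0, tolerance = 1e-12)
  # 0.05 Hz passes within 5 %
  expect_equal(fir_frequency_response(h, 0.05, 8), 1, tolerance = 0.05)
  # cardiac tone at 1.2 Hz attenuated >= 40 dB
  expect_lt(20 * log10(abs(fir_frequency_response(h, 1.2, 8))), -40)
  # high stopband beyond 1.5x the upper edge stays below -40 dB
  expect_lt(20 * log10(max(abs(
    fir_frequency_response(h, seq(0.3, 4, by = 0.01), 8)))), -40)
  # a constant input comes out (numerically) zero
  const <- matrix(0.5, 1, 2400)
  expect_lt(max(abs(fnirs_bandpass(const, fs = 8))), 1e-9)
  # a 0.05 Hz sinusoid passes within 5 % (steady-state amplitude)
  t <- seq_len(4800) / 8
  s <- sin(2 * pi * 0.05 * t)
  filt <- fnirs_bandpass(matrix(s, 1), fs = 8)[1, ]
  mid <- 1600:3200
  expect_equal(sd(filt[mid]) / sd(s[mid]), 1, tolerance = 0.05)
})

test_that("drift and cardiac contamination are removed to > 0.95 truth correlation", {
  sim <- generate_fnirs(seed = 93)   # defaults include drift + 1.2 Hz cardiac
  cs <- mbll_convert(sim$od, sim$optics)
  filt <- fnirs_bandpass(cs)
  cors <- vapply(seq_len(nrow(filt$hbo)), function(ch)
    cor(filt$hbo[ch, ], sim$truth$hbo[ch, ]), 0)
  expect_true(all(cors > 0.95))
})

test_that("channel exclusion uses a strict peak-to-peak threshold", {
  hbo <- matrix(0, 3, 100)
  hbo[2, ] <- seq(0, 0.002, length.out = 100)         # 0.002 mM swing
  hbo[3, ] <- seq(0, 0.001, length.out = 100)         # exactly the threshold
  cs <- chromophore_series(hbo, hbo * 0)
  keep <- exclude_channels(cs, 1:100)
  expect_equal(keep, c(TRUE, FALSE, TRUE))            # flat kept, exact kept
})

test_that("baseline subtraction matches a hand-computed toy and is shift-invariant", {
  hbo <- matrix(c(1, 2, 3, 4, 5), 1, 5)
  cs <- chromophore_series(hbo, hbo * 0)
  bs <- baseline_subtract(cs, 1:2)                    # baseline mean = 1.5
  expect_equal(as.numeric(bs$hbo), c(-0.5, 0.5, 1.5, 2.5, 3.5))
  # constant series -> all zeros
  cc <- chromophore_series(matrix(7, 1, 5), matrix(0, 1, 5))
  expect_true(all(baseline_subtract(cc, 1:3)$hbo == 0))
  # adding a constant shifts the output by nothing
  shifted <- chromophore_series(hbo + 10, hbo * 0)
  expect_equal(baseline_subtract(shifted, 1:2)$hbo, bs$hbo)
  # inter-trial excision removes samples before averaging
  ex <- baseline_subtract(cs, 1:3, exclude_idx = 2)
  expect_equal(ncol(ex$hbo), 4)
  expect_equal(as.numeric(ex$hbo), c(1, 3, 4, 5) - 2)  # baseline mean of 1,3
})

test_that("GLM betas recover regressor amplitude and reject rank deficiency", {
  fs <- 8; n <- 2400
  onsets <- seq(30, 250, by = 60); dur <- 30
  box <- numeric(n)
  for (o in onsets) box[(o * fs + 1):((o + dur) * fs)] <- 1
  hrf <- canonical_hrf(seq(0, 32, by = 1 / fs))
  reg <- convolve(box, rev(hrf), type = "open")[1:n]
  # response exactly the regressor -> beta 1, huge t
  cs <- chromophore_series(matrix(reg, 1), matrix(0, 1, n))
  b <- glm_betas(cs, onsets, dur)
  expect_equal(b$beta[b$chromophore == "hbo"], 1, tolerance = 1e-8)
  expect_gt(b$t[b$chromophore == "hbo"], 1e6)
  # pure noise -> beta ~ 0, modest |t|
  set.seed(94)
  noise <- chromophore_series(matrix(rnorm(n, 0, 0.001), 1),
                              matrix(0, 1, n))
  bn <- glm_betas(noise, onsets, dur)
  expect_lt(abs(bn$beta[bn$chromophore == "hbo"]), 3e-4)
  expect_lt(abs(bn$t[bn$chromophore == "hbo"]), 5)
  # amplitude a recovered within 5% under noise
  a <- 0.003
  y <- a * reg + rnorm(n, 0, 0.0005)
  cs_a <- chromophore_series(matrix(y, 1), matrix(0, 1, n))
  ba <- glm_betas(cs_a, onsets, dur)
  expect_equal(ba$beta[ba$chromophore == "hbo"], a, tolerance = 0.05)
  # an all-zero response regressor is collinear with nothing to estimate
  expect_error(glm_betas(cs, onsets, dur, hrf = rep(0, 100)),
               "collinear|rank")
})

test_that("day contrasts apply the Bonferroni threshold and summarise ROIs", {
  set.seed(95)
  n_sub <- 7; n_ch <- 20
  roi <- rep(c("M1", "DLPFC"), each = 10)
  b1 <- matrix(rnorm(n_sub * n_ch, 0, 1e-4), n_sub, n_ch)
  # identical days -> zero contrast, nothing significant
  r0 <- day_contrast(b1, b1, roi)
  expect_equal(attr(r0, "alpha_corrected"), 0.0025)
  expect_true(all(!r0$channels$significant))
  expect_true(all(r0$rois$day4_minus_day1 == 0))
  # injected DLPFC-wide decrease: sign recovered on >= 9/10 channels
  delta <- -0.0024
  b4 <- b1
  b4[, roi == "DLPFC"] <- b4[, roi == "DLPFC"] + delta +
    matrix(rnorm(n_sub * 10, 0, 2e-4), n_sub, 10)
  r <- day_contrast(b1, b4, roi)
  ch_means <- colMeans(b4 - b1)[roi == "DLPFC"]
  expect_gte(sum(ch_means < 0), 9)
  dl <- r$rois[r$rois$roi == "DLPFC", ]
  expect_equal(dl$day4_minus_day1, delta, tolerance = 0.2)
  expect_gt(dl$n_significant, 5)
  m1 <- r$rois[r$rois$roi == "M1", ]
  expect_equal(m1$n_significant, 0)
})

test_that("the 3.5-SD channel test flags means beyond k standard errors", {
  set.seed(96)
  trials <- matrix(rnorm(30 * 4), 30, 4)
  colnames(trials) <- paste0("ch", 1:4)
  r <- channelwise_sd_test(trials)
  expect_true(all(!r$significant))       # zero-mean trials not flagged
  trials[, 2] <- trials[, 2] + 5 * sd(trials[, 2]) / sqrt(30) + 1
  r2 <- channelwise_sd_test(trials)
  expect_true(r2$significant[2])
  # hand z on a toy table
  toy <- matrix(c(1, 2, 3, 4), 4, 1)
  rt <- channelwise_sd_test(toy)
  expect_equal(rt$z, mean(toy) / (sd(toy) / 2), tolerance = 1e-12)
})

test_that("the default channel map matches the study montage layout", {
  cm <- fnirs_channel_map()
  expect_equal(nrow(cm), 20)
  expect_equal(sum(cm$roi == "M1"), 10)
  expect_equal(sum(cm$roi == "DLPFC"), 10)
  expect_true(all(cm$distance_cm <= 3.5))
  sim <- generate_fnirs(seed = 97, duration_s = 60)
  expect_error(generate_fnirs(channel_map = within(cm, rm(distance_cm))),
               "distances")
  expect_error(generate_fnirs(amp_hbo = 0.2), "physically small")
})
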