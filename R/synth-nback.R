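#' Simulate an adaptive n-back session log
#'
#' Generates trial-level correctness for a multi-day adaptive n-back session
#' under a saturating-linear accuracy model: a subject's ability is expressed
#' in expected scaled-accuracy points (the scale the analysis measures), and
#' each decision is correct with probability
#' `clamp(ability, 0, 100) / (100 * w(N))`, clamped to \[0, 1\], where `w(N)`
#' is the information-content weight of the current level. The model is
#' monotone in ability and in N; when ability exceeds `100 * w(N)` the block
#' saturates at the level's ceiling. Ability grows linearly within a day
#' (`online_rate` scaled points per block) and between days (`offline_gain`
#' points per day). The N level starts at `n_min` and evolves between blocks
#' by [adaptive_update()] on the realised pooled raw accuracy; the level
#' carries over between days.
#'
#' @param ability Baseline ability in expected scaled-accuracy points
#'   (day 1, block 1). Values >= 100 make every trial correct; values <= 0
#'   make every trial incorrect so the level stays at the floor.
#' @param online_rate Within-day ability growth, scaled points per block.
#' @param offline_gain Between-day ability growth, scaled points per day.
#' @param n_days,n_blocks Session layout (defaults: 4 days, 6 blocks).
#' @param n_trials Trials per block (20).
#' @param config An [nback_config()].
#' @param seed Optional integer seed (uses the current RNG stream if NULL).
#' @return Data frame with columns `day`, `block`, `trial`, `n_level`,
#'   `position_correct`, `image_correct`, carrying the generating parameters
#'   in `attr(, "truth")`.
#' @export
generate_nback_log <- function(ability, online_rate = 0, offline_gain = 0,
                               n_days = 4L, n_blocks = 6L, n_trials = 20L,
                               config = nback_config(), seed = NULL) {
  if (!is.finite(ability)) stop("ability must be finite")
  if (!is.null(seed)) set.seed(seed)
  n_level <- config$n_min
  rows <- vector("list", n_days * n_blocks)
  k <- 0L
  for (d in seq_len(n_days)) {
    for (b in seq_len(n_blocks)) {
      theta <- ability + offline_gain * (d - 1) + online_rate * (b - 1)
      w <- unname(config$weights[as.character(n_level)])
      p <- min(1, max(0, min(theta, 100) / (100 * w)))
      if (theta <= 0) p <- 0
      pos <- stats::rbinom(n_trials, 1L, p) == 1L
      img <- stats::rbinom(n_trials, 1L, p) == 1L
      k <- k + 1L
      rows[[k]] <- data.frame(day = d, block = b, trial = seq_len(n_trials),
                              n_level = n_level,
                              position_correct = pos, image_correct = img)
      raw <- 100 * mean(c(pos, img))
      n_level <- adaptive_update(raw, n_level, config)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "truth") <- list(ability = ability, online_rate = online_rate,
                             offline_gain = offline_gain)
  out
}
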