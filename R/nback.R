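#' Adaptive n-back task configuration
#'
#' Holds the information-content scaling weights and the adaptive difficulty
#' rule of the n-back engine. The default weights (0.33, 0.66, 1.0 for the
#' 1-, 2-, and 3-back levels) scale raw percent accuracy by the working-memory
#' load of each level relative to 3-back; difficulty steps up when block
#' accuracy exceeds 80% and down when it falls below 20%. Alternative
#' normalisations (e.g. bit-wise or log scalings) can be supplied through
#' `weights` behind the same interface.
#'
#' @param weights Named numeric vector of scaling weights, one per level,
#'   strictly increasing in N.
#' @param up_threshold,down_threshold Block-accuracy thresholds in percent
#'   (up > down, both in (0, 100)).
#' @param n_min,n_max Level bounds.
#' @return An object of class `nback_config`.
#' @export
nback_config <- function(weights = c(`1` = 0.33, `2` = 0.66, `3` = 1.0),
                         up_threshold = 80, down_threshold = 20,
                         n_min = 1L, n_max = 3L) {
  if (is.unsorted(weights, strictly = TRUE))
    stop("weights must be strictly increasing in N")
  if (!(down_threshold > 0 && up_threshold < 100 && up_threshold > down_threshold))
    stop("thresholds must satisfy 0 < down < up < 100")
  structure(list(weights = weights,
                 up_threshold = up_threshold, down_threshold = down_threshold,
                 n_min = as.integer(n_min), n_max = as.integer(n_max)),
            class = "nback_config")
}

#' Scale raw n-back accuracy by information content
#'
#' Multiplies raw percent accuracy by the scaling weight of its N level, so
#' that a perfect 2-back block scores 66 and a perfect 3-back block 100.
#'
#' @param raw Raw percent accuracy in \[0, 100\] (vectorised).
#' @param n_level N level(s), one of the configured levels.
#' @param config An [nback_config()].
#' @return Scaled percent accuracy.
#' @export
#' @examples
#' scale_accuracy(100, 2)  # 66
scale_accuracy <- function(raw, n_level, config = nback_config()) {
  if (any(raw < 0 | raw > 100, na.rm = TRUE))
    stop("raw accuracy must lie in [0, 100]")
  idx <- match(as.character(n_level), names(config$weights))
  if (anyNA(idx)) stop("unknown n_level: ",
                       paste(unique(n_level[is.na(idx)]), collapse = ", "))
  raw * unname(config$weights[idx])
}

#' Adaptive difficulty update
#'
#' Applies the adaptive rule to a block's raw percent accuracy: N + 1 when
#' accuracy is strictly above the upper threshold (capped at `n_max`), N - 1
#' when strictly below the lower threshold (floored at `n_min`), otherwise
#' unchanged.
#'
#' @param block_accuracy Raw percent accuracy of the completed block.
#' @param n_level Current N level.
#' @inheritParams scale_accuracy
#' @return The next N level.
#' @export
adaptive_update <- function(block_accuracy, n_level, config = nback_config()) {
  if (any(block_accuracy < 0 | block_accuracy > 100))
    stop("accuracy must lie in [0, 100]")
  nxt <- n_level + (block_accuracy > config$up_threshold) -
    (block_accuracy < config$down_threshold)
  pmin(pmax(nxt, config$n_min), config$n_max)
}

#' Score an n-back trial log
#'
#' Computes, per block, the raw and information-scaled percent accuracies of
#' the position stream, the image stream, and the two streams pooled with
#' equal weight ("combined"). Each block must have exactly 20 trials; each
#' trial carries one position decision and one image decision.
#'
#' @param log Data frame with columns `day`, `block`, `trial`, `n_level`,
#'   `position_correct`, `image_correct` (as produced by
#'   [generate_nback_log()] or read with [read_nback_log()]).
#' @inheritParams scale_accuracy
#' @return Data frame with one row per (day, block): `n_level`,
#'   `position_raw`, `image_raw`, `combined_raw` and their `_scaled`
#'   counterparts.
#' @export
score_log <- function(log, config = nback_config()) {
  key <- interaction(log$day, log$block, drop = TRUE, lex.order = TRUE)
  sizes <- tabulate(key)
  if (any(sizes != 20L))
    stop("every block must have exactly 20 trials")
  agg <- function(v) as.numeric(tapply(v, key, mean)) * 100
  lev <- as.integer(tapply(log$n_level, key, function(n) {
    if (length(unique(n)) != 1L) stop("n_level must be constant within a block")
    n[1]
  }))
  out <- unique(log[, c("day", "block")])
  out <- out[order(out$day, out$block), ]
  rownames(out) <- NULL
  out$n_level <- lev
  out$position_raw <- agg(log$position_correct)
  out$image_raw <- agg(log$image_correct)
  out$combined_raw <- (out$position_raw + out$image_raw) / 2
  for (s in c("position", "image", "combined"))
    out[[paste0(s, "_scaled")]] <- scale_accuracy(out[[paste0(s, "_raw")]],
                                                  out$n_level, config)
  out
}

#' Level-attainment statistics of an adaptive n-back session
#'
#' Reports, from the block-wise N trajectory, the first block (1-based count
#' over the whole study, levels change only between blocks) at which levels
#' 2 and 3 were reached, and the mean streak length (consecutive blocks) at
#' levels 2 and 3.
#'
#' @inheritParams score_log
#' @return A list with `blocks_to_reach_2`, `blocks_to_reach_3` (NA when a
#'   level is never reached) and `mean_streak_2`, `mean_streak_3`.
#' @export
level_statistics <- function(log) {
  key <- interaction(log$day, log$block, drop = TRUE, lex.order = TRUE)
  lev <- as.integer(tapply(log$n_level, key, function(n) n[1]))
  reach <- function(k) {
    i <- which(lev >= k)[1]
    if (is.na(i)) NA_integer_ else as.integer(i)
  }
  streak <- function(k) {
    r <- rle(lev == k)
    runs <- r$lengths[r$values]
    if (length(runs) == 0L) NA_real_ else mean(runs)
  }
  list(blocks_to_reach_2 = reach(2L), blocks_to_reach_3 = reach(3L),
       mean_streak_2 = streak(2L), mean_streak_3 = streak(3L))
}
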