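# closed-form OLS slope with standard error; x defaults to the trial index
.ols_slope <- function(y, x = seq_along(y)) {
  keep <- is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(y)
  if (n < 2L) return(list(slope = NA_real_, se = NA_real_, n = n))
  sxx <- sum((x - mean(x))^2)
  b <- sum((x - mean(x)) * (y - mean(y))) / sxx
  a <- mean(y) - b * mean(x)
  se <- if (n > 2L) sqrt(sum((y - a - b * x)^2) / (n - 2L) / sxx) else 0
  list(slope = b, se = se, n = n)
}

#' Online (within-day) learning rate
#'
#' Ordinary least-squares slope of a performance metric over the trial/block
#' index within one day, with the standard error of the slope. Missing
#' (outlier-rejected) trials are dropped with their indices preserved.
#'
#' @param series Metric values in within-day temporal order (`NA` allowed).
#' @param index Optional explicit trial indices.
#' @return List with `slope`, `se` (standard error of the slope), `n`.
#' @export
#' @examples
#' online_rate(c(10, 20, 30))$slope  # 10
online_rate <- function(series, index = seq_along(series)) {
  r <- .ols_slope(series, index)
  if (r$n < 2L) warning("fewer than 2 non-missing trials; rate undefined")
  r
}

#' Offline (between-day) learning rate
#'
#' Change in performance between the last trial of day n-1 and the first
#' trial of day n, expressed as a slope over unit trial-index spacing.
#' Antisymmetric: swapping the arguments flips the sign.
#'
#' @param last_of_previous_day,first_of_next_day Metric values.
#' @return Numeric slope.
#' @export
offline_rate <- function(last_of_previous_day, first_of_next_day) {
  first_of_next_day - last_of_previous_day
}

#' Overall learning rate across all days
#'
#' OLS slope over the concatenated trial index spanning the whole study.
#'
#' @inheritParams online_rate
#' @return List with `slope`, `se`, `n`.
#' @export
overall_rate <- function(series, index = seq_along(series)) {
  online_rate(series, index)
}

#' Meta-learning rate
#'
#' OLS slope over the interleaved online/offline rate series in temporal
#' order: on(1), off(1-2), on(2), off(2-3), ..., on(n_days) — the rate of
#' change of the learning rates themselves.
#'
#' @param rate_series Interleaved rates in temporal order.
#' @return List with `slope`, `se`, `n`.
#' @export
meta_rate <- function(rate_series) .ols_slope(rate_series)

#' Full learning-rate decomposition of a day-by-trial series
#'
#' Computes the overall, per-day online, per-day-pair offline, and meta
#' learning rates of one metric series.
#'
#' @param df Data frame with columns `day`, `trial` (block or landing index
#'   within day), `value`.
#' @return An object of class `learning_rate_set`: `overall` (slope/se),
#'   `online` (one row per day), `offline` (one per day pair), `meta`.
#' @export
learning_rates <- function(df) {
  df <- df[order(df$day, df$trial), ]
  days <- sort(unique(df$day))
  online <- do.call(rbind, lapply(days, function(d) {
    r <- online_rate(df$value[df$day == d], df$trial[df$day == d])
    data.frame(day = d, slope = r$slope, se = r$se, n = r$n)
  }))
  offline <- if (length(days) > 1L) {
    do.call(rbind, lapply(seq_len(length(days) - 1L), function(i) {
      prev <- df$value[df$day == days[i]]
      nxt <- df$value[df$day == days[i + 1L]]
      prev <- prev[is.finite(prev)]; nxt <- nxt[is.finite(nxt)]
      data.frame(from_day = days[i], to_day = days[i + 1L],
                 slope = offline_rate(prev[length(prev)], nxt[1]))
    }))
  } else NULL
  global_index <- match(interaction(df$day, df$trial, lex.order = TRUE),
                        sort(unique(interaction(df$day, df$trial,
                                                lex.order = TRUE))))
  overall <- overall_rate(df$value, global_index)
  inter <- numeric(0)
  for (i in seq_along(days)) {
    inter <- c(inter, online$slope[i])
    if (i < length(days)) inter <- c(inter, offline$slope[i])
  }
  meta <- meta_rate(inter)
  structure(list(overall = overall, online = online, offline = offline,
                 meta = meta, interleaved = inter),
            class = "learning_rate_set")
}

#' @export
print.learning_rate_set <- function(x, ...) {
  cat(sprintf("Overall rate: %.4g +/- %.4g (n = %d)\n",
              x$overall$slope, x$overall$se, x$overall$n))
  cat("Online (per day):\n"); print(x$online, row.names = FALSE)
  if (!is.null(x$offline)) {
    cat("Offline (per day pair):\n"); print(x$offline, row.names = FALSE)
  }
  cat(sprintf("Meta rate: %.4g +/- %.4g\n", x$meta$slope, x$meta$se))
  invisible(x)
}

#' Per-subject online learning rates of a cohort table
#'
#' Convenience helper: per (subject, day) OLS slope and standard error of a
#' metric over the within-day trial index. Rates can equally be computed on
#' block-wise group-averaged series by first averaging `value` over subjects;
#' both modes are legitimate and answer slightly different questions (the
#' group-average regression estimates the cohort-mean trajectory, per-subject
#' fits support between-subject variance analysis).
#'
#' @param df Data frame with columns `subject`, `day`, `trial`, `value`.
#' @return Data frame with `subject`, `day`, `slope`, `se`, `n`.
#' @export
online_rate_table <- function(df) {
  keys <- unique(df[, c("subject", "day")])
  keys <- keys[order(keys$subject, keys$day), ]
  out <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    sub <- df[df$subject == keys$subject[i] & df$day == keys$day[i], ]
    r <- online_rate(sub$value, sub$trial)
    data.frame(subject = keys$subject[i], day = keys$day[i],
               slope = r$slope, se = r$se, n = r$n)
  }))
  rownames(out) <- NULL
  out
}

#' t-tests for learning rates
#'
#' One-sample (against zero) or paired two-tailed t-tests on subject-level
#' learning rates, with the exact Student reference distribution. Degenerate
#' zero-variance inputs are handled explicitly: a constant sample equal to
#' the null mean gives t = 0, p = 1.
#'
#' @param rates Numeric vector of per-subject rates.
#' @param paired_with Optional second sample for a paired comparison.
#' @param mu Null value for the one-sample test.
#' @return List with `t`, `df`, `p`, `mean`.
#' @export
rate_tests <- function(rates, paired_with = NULL, mu = 0) {
  x <- if (is.null(paired_with)) rates - mu else rates - paired_with
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2L) stop("need at least 2 finite rates")
  if (stats::sd(x) == 0) {
    t <- if (mean(x) == 0) 0 else Inf * sign(mean(x))
    return(list(t = t, df = n - 1L, p = if (t == 0) 1 else 0,
                mean = mean(x) + if (is.null(paired_with)) mu else 0))
  }
  ht <- stats::t.test(x, mu = 0)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value,
       mean = mean(x) + if (is.null(paired_with)) mu else 0)
}
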