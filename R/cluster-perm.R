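#' Build a channel adjacency structure from a 2-D layout
#'
#' Two channels are neighbours when their 2-D distance falls within the
#' given quantile of all pairwise distances. The relation is symmetric and
#' irreflexive by construction.
#'
#' @param layout Data frame with `label`, `x`, `y` (see [eeg_layout()]).
#' @param distance_quantile Quantile of the off-diagonal pairwise distances
#'   below which channels are neighbours (default 0.12).
#' @param max_distance Optional absolute distance cap. The quantile rule is
#'   scale-free, so for degenerate layouts (e.g. only two channels) an
#'   absolute cap is the meaningful criterion.
#' @return An object of class `adjacency`: `labels`, `neighbors` (list of
#'   integer vectors) and `matrix` (logical).
#' @export
build_adjacency <- function(layout, distance_quantile = 0.12,
                            max_distance = NULL) {
  d <- as.matrix(stats::dist(layout[, c("x", "y")]))
  thr <- stats::quantile(d[upper.tri(d)], distance_quantile)
  if (!is.null(max_distance)) thr <- min(thr, max_distance)
  adj <- d <= thr & upper.tri(d) | d <= thr & lower.tri(d)
  diag(adj) <- FALSE
  structure(list(labels = layout$label,
                 neighbors = lapply(seq_len(nrow(adj)),
                                    function(i) which(adj[i, ])),
                 matrix = adj),
            class = "adjacency")
}

#' Regular grid layout
#'
#' Synthetic channel layout on an nrow x ncol unit grid, convenient for
#' simulation studies where a head geometry is irrelevant.
#'
#' @param nrow,ncol Grid dimensions.
#' @return Layout data frame (`label`, `x`, `y`).
#' @export
grid_layout <- function(nrow, ncol) {
  g <- expand.grid(x = seq_len(ncol), y = seq_len(nrow))
  data.frame(label = sprintf("ch%02d", seq_len(nrow * ncol)),
             x = g$x, y = g$y, stringsAsFactors = FALSE)
}

#' Per-channel t-statistics between two band-power maps
#'
#' Student (pooled-variance) independent-samples t per channel, or a paired
#' t on the within-subject differences.
#'
#' @param power_a,power_b Subjects x channels matrices (paired tests need
#'   equal row counts in subject order).
#' @param paired Logical.
#' @return Numeric vector of t values with a `df` attribute.
#' @export
channel_tmap <- function(power_a, power_b, paired = FALSE) {
  power_a <- as.matrix(power_a); power_b <- as.matrix(power_b)
  if (paired) {
    if (nrow(power_a) != nrow(power_b))
      stop("paired tests need equal numbers of subjects")
    d <- power_a - power_b
    n <- nrow(d)
    t <- colMeans(d) / sqrt(apply(d, 2, stats::var) / n)
    t[!is.finite(t)] <- 0
    attr(t, "df") <- n - 1L
    return(t)
  }
  na <- nrow(power_a); nb <- nrow(power_b)
  va <- apply(power_a, 2, stats::var); vb <- apply(power_b, 2, stats::var)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  t <- (colMeans(power_a) - colMeans(power_b)) /
    sqrt(sp2 * (1 / na + 1 / nb))
  t[!is.finite(t)] <- 0
  attr(t, "df") <- na + nb - 2L
  t
}

# connected components of supra-threshold channels of one sign (BFS)
.components <- function(idx, neighbors) {
  if (length(idx) == 0L) return(list())
  inset <- logical(length(neighbors))
  inset[idx] <- TRUE
  seen <- logical(length(inset))
  comps <- list()
  for (s in idx) {
    if (seen[s]) next
    queue <- s; seen[s] <- TRUE; comp <- integer(0)
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      comp <- c(comp, v)
      nb <- neighbors[[v]]
      nb <- nb[inset[nb] & !seen[nb]]
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

#' Find supra-threshold channel clusters in a t-map
#'
#' Thresholds the per-channel t-map at the two-sided data-point alpha,
#' groups same-sign supra-threshold channels into adjacency-connected
#' components, and discards components smaller than the minimum spatial
#' extent. The cluster mass statistic is the summed |t| of its members; the
#' reported cluster-level t is the signed mean over member channels.
#'
#' @param tmap t values with a `df` attribute (from [channel_tmap()]).
#' @param adjacency An [build_adjacency()] object.
#' @param point_alpha Data-point alpha for the two-sided t threshold.
#' @param min_extent Minimum cluster size in channels (default 2).
#' @return Data frame, one row per cluster: `channels` (comma-separated
#'   labels), `n_channels`, `mass` (summed |t|), `mean_t` (signed), `sign`.
#' @export
find_clusters <- function(tmap, adjacency, point_alpha = 0.05,
                          min_extent = 2L) {
  df <- attr(tmap, "df")
  thr <- stats::qt(1 - point_alpha / 2, df)
  out <- list()
  for (sgn in c(1, -1)) {
    idx <- which(sgn * tmap > thr)
    for (comp in .components(idx, adjacency$neighbors)) {
      if (length(comp) < min_extent) next
      out[[length(out) + 1L]] <- data.frame(
        channels = paste(adjacency$labels[comp], collapse = ","),
        n_channels = length(comp),
        mass = sum(abs(tmap[comp])),
        mean_t = mean(tmap[comp]),
        sign = sgn)
    }
  }
  if (length(out) == 0L)
    return(data.frame(channels = character(0), n_channels = integer(0),
                      mass = numeric(0), mean_t = numeric(0),
                      sign = numeric(0)))
  do.call(rbind, out)
}

# all-permutation t maps for the independent design: one matrix product set
# gives the t map of every relabelling (columns of `assign1`, logical,
# TRUE = group 1)
.tmaps_independent <- function(X, assign1) {
  n <- nrow(X); ch <- ncol(X)
  n1 <- colSums(assign1); n2 <- n - n1
  G <- matrix(as.numeric(assign1), n)
  S1 <- crossprod(G, X)                  # perms x ch group-1 sums
  Q1 <- crossprod(G, X^2)
  St <- matrix(colSums(X), nrow(S1), ch, byrow = TRUE)
  Qt <- matrix(colSums(X^2), nrow(S1), ch, byrow = TRUE)
  S2 <- St - S1; Q2 <- Qt - Q1
  m1 <- S1 / n1; m2 <- S2 / n2
  ss1 <- Q1 - S1^2 / n1; ss2 <- Q2 - S2^2 / n2
  sp2 <- (ss1 + ss2) / (n - 2)
  t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  t[!is.finite(t)] <- 0
  t                                       # perms x channels
}

# all-sign-flip t maps for the paired design (columns of `signs` in {-1, 1})
.tmaps_paired <- function(D, signs) {
  n <- nrow(D)
  m <- crossprod(signs, D) / n            # perms x ch means of s_i * d_i
  q <- matrix(colSums(D^2), nrow(m), ncol(D), byrow = TRUE)
  v <- (q - n * m^2) / (n - 1)
  t <- m / sqrt(v / n)
  t[!is.finite(t)] <- 0
  t
}

#' Cluster-based permutation test of band-power maps
#'
#' Corrects channel-wise comparisons for multiple comparisons by comparing
#' each observed cluster's mass (summed |t|) against the permutation null
#' distribution of the maximum cluster mass: group labels are exchanged
#' (independent design) or condition signs flipped (paired design). The
#' observed labelling is included among the `n_perm` repetitions, so cluster
#' p-values lie in `[1/n_perm, 1]`; a cluster is significant when its p is
#' at or below the cluster-level alpha. When the number of distinct
#' relabellings does not exceed `n_perm` the test enumerates them
#' exhaustively instead of sampling.
#'
#' @inheritParams channel_tmap
#' @param adjacency An [build_adjacency()] object.
#' @param n_perm Number of permutations (default 500).
#' @param point_alpha Data-point alpha for cluster formation (default 0.05).
#' @param cluster_alpha Cluster-level alpha (default 0.05).
#' @param min_extent Minimum spatial extent in channels (default 2).
#' @param seed Optional integer seed for the permutation draw.
#' @return An object of class `cluster_result`: `clusters` (data frame with
#'   per-cluster channels, mass, signed mean t, corrected p, significance),
#'   `null_max` (the permutation null), `n_perm`, `exhaustive`.
#' @export
permutation_test <- function(power_a, power_b, adjacency, paired = FALSE,
                             n_perm = 500L, point_alpha = 0.05,
                             cluster_alpha = 0.05, min_extent = 2L,
                             seed = NULL) {
  power_a <- as.matrix(power_a); power_b <- as.matrix(power_b)
  if (nrow(power_a) < 2L || nrow(power_b) < 2L)
    stop("need >= 2 subjects per group (or >= 2 pairs)")
  if (!is.null(seed)) set.seed(seed)
  obs_t <- channel_tmap(power_a, power_b, paired = paired)
  obs <- find_clusters(obs_t, adjacency, point_alpha, min_extent)

  max_mass <- function(tvec, df) {
    attr(tvec, "df") <- df
    cl <- find_clusters(tvec, adjacency, point_alpha, min_extent)
    if (nrow(cl) == 0L) 0 else max(cl$mass)
  }

  if (paired) {
    n <- nrow(power_a)
    exhaustive <- 2^n <= n_perm
    if (exhaustive) {
      signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
      signs <- t(signs)
    } else {
      signs <- matrix(sample(c(-1, 1), n * (n_perm - 1L), replace = TRUE), n)
      signs <- cbind(rep(1, n), signs)   # observed labelling first
    }
    tmaps <- .tmaps_paired(power_a - power_b, signs)
    df <- n - 1L
  } else {
    na <- nrow(power_a); n <- na + nrow(power_b)
    X <- rbind(power_a, power_b)
    n_distinct <- choose(n, na)
    exhaustive <- n_distinct <= n_perm
    if (exhaustive) {
      combs <- utils::combn(n, na)
      assign1 <- matrix(FALSE, n, ncol(combs))
      assign1[cbind(as.vector(combs),
                    rep(seq_len(ncol(combs)), each = na))] <- TRUE
    } else {
      assign1 <- matrix(FALSE, n, n_perm)
      assign1[seq_len(na), 1] <- TRUE    # observed labelling first
      for (p in 2:n_perm) assign1[sample(n, na), p] <- TRUE
    }
    tmaps <- .tmaps_independent(X, assign1)
    df <- n - 2L
  }
  null_max <- vapply(seq_len(nrow(tmaps)),
                     function(i) max_mass(tmaps[i, ], df), 0)
  m <- length(null_max)
  if (nrow(obs) > 0L) {
    # tolerance guards the identity permutation against round-off
    obs$p <- vapply(obs$mass,
                    function(ms) sum(null_max >= ms * (1 - 1e-10) - 1e-10) / m,
                    0)
    obs$significant <- obs$p <= cluster_alpha
  } else {
    obs$p <- numeric(0); obs$significant <- logical(0)
  }
  structure(list(clusters = obs, null_max = null_max, n_perm = m,
                 exhaustive = exhaustive,
                 point_alpha = point_alpha, cluster_alpha = cluster_alpha,
                 min_extent = min_extent),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("Cluster permutation test (%s%d permutations)\n",
              if (x$exhaustive) "exhaustive, " else "", x$n_perm))
  if (nrow(x$clusters) == 0L) {
    cat("  no supra-threshold clusters\n")
  } else {
    cl <- x$clusters
    for (i in seq_len(nrow(cl)))
      cat(sprintf("  %s | mean t = %.2f | p = %.3f%s\n", cl$channels[i],
                  cl$mean_t[i], cl$p[i],
                  if (cl$significant[i]) " *" else ""))
  }
  invisible(x)
}
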