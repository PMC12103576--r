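#' Simulate stepwise photobleaching intensity traces
#'
#' Each particle carries `n` fluorophores drawn from `size_distribution`
#' (probabilities over 1..length(size_distribution) fluorophores). Every
#' fluorophore bleaches at an independent exponential time with rate
#' `bleach_rate_per_s`; the trace is `unit_intensity` times the number of
#' surviving fluorophores plus Gaussian read noise. The true fluorophore
#' count per particle is returned as ground truth for step-counting
#' validation.
#'
#' @param n_particles number of traces.
#' @param size_distribution probability vector over cluster sizes 1..K
#'   (K <= 15); must sum to 1.
#' @param unit_intensity intensity contributed by one fluorophore (counts).
#' @param bleach_rate_per_s exponential bleaching rate, 1/s.
#' @param noise_sigma Gaussian read-noise s.d. (counts).
#' @param n_frames,dt_s trace length and frame interval.
#' @param seed integer seed.
#' @return list: `traces` (n_frames x n_particles matrix),
#'   `true_fluor_count` (integer vector), `dt_s`.
#' @export
simulate_photobleaching_traces <- function(n_particles, size_distribution,
                                           unit_intensity = 1000,
                                           bleach_rate_per_s = 0.25,
                                           noise_sigma = 100,
                                           n_frames = 400L, dt_s = 0.033,
                                           seed = 1L) {
  if (abs(sum(size_distribution) - 1) > 1e-8) {
    stop("size_distribution must sum to 1", call. = FALSE)
  }
  if (length(size_distribution) > 15L) {
    stop("size_distribution supports at most 15 fluorophores", call. = FALSE)
  }
  set.seed(seed)
  sizes <- sample.int(length(size_distribution), n_particles, replace = TRUE,
                      prob = size_distribution)
  tgrid <- (seq_len(n_frames) - 1L) * dt_s
  traces <- matrix(0, n_frames, n_particles)
  for (i in seq_len(n_particles)) {
    bt <- if (bleach_rate_per_s > 0) {
      stats::rexp(sizes[i], bleach_rate_per_s)
    } else rep(Inf, sizes[i])
    surviving <- vapply(tgrid, function(t) sum(bt > t), numeric(1))
    traces[, i] <- unit_intensity * surviving +
      stats::rnorm(n_frames, 0, noise_sigma)
  }
  list(traces = traces, true_fluor_count = sizes, dt_s = dt_s)
}

#' Count photobleaching steps in an intensity trace
#'
#' Piecewise-constant change-point segmentation by iterative binary
#' splitting under a Bayesian information criterion (the Kalafut-Visscher
#' construction): starting from a single plateau, the split that most
#' reduces the residual sum of squares is accepted while it lowers
#' `BIC = (k + 2) log N + N log(RSS / N)` (k = number of change points),
#' up to `max_steps` downward steps. Downward transitions between
#' consecutive plateau means are bleaching steps; upward transitions
#' (blinking or aggregation) are not counted but are flagged.
#'
#' @param trace numeric intensity series (>= 10 frames).
#' @param max_steps maximum number of bleaching steps (default 15).
#' @param penalty multiplier on the BIC model-size term. The plain criterion
#'   (penalty 1) does not account for optimizing the change-point position
#'   within each segment, so for traces of several hundred frames it admits
#'   spurious steps (the best noise-only split improves the fit by
#'   ~2 log(n) sigma^2, which exceeds a single log(n) penalty). The default
#'   2.5 compensates; detected-step accuracy is flat between ~2 and 3 at
#'   signal-to-noise 5.
#' @return object of class `step_fit`: `n_steps`, `step_frames` (0-based
#'   frame of each downward transition), `level_means`, `n_up` (flagged
#'   upward transitions), `bic`.
#' @export
fit_steps <- function(trace, max_steps = 15L, penalty = 2.5) {
  if (max_steps < 1L) stop("max_steps must be >= 1", call. = FALSE)
  n <- length(trace)
  if (n < 10L) stop("trace must have at least 10 frames", call. = FALSE)
  cs <- cumsum(trace); cs2 <- cumsum(trace^2)
  seg_rss <- function(i, j) { # inclusive 1-based bounds
    s <- cs[j] - if (i > 1L) cs[i - 1L] else 0
    s2 <- cs2[j] - if (i > 1L) cs2[i - 1L] else 0
    m <- j - i + 1L
    max(s2 - s * s / m, 0)
  }
  best_split <- function(i, j) {
    # best single change point inside [i, j]; returns c(pos, rss_reduction)
    if (j - i < 1L) return(c(NA, 0))
    whole <- seg_rss(i, j)
    ks <- i:(j - 1L)
    red <- vapply(ks, function(k) whole - seg_rss(i, k) - seg_rss(k + 1L, j),
                  numeric(1))
    b <- which.max(red)
    c(ks[b], red[b])
  }

  bounds <- c(0L, n)  # change points as "last index of left segment"
  rss <- seg_rss(1L, n)
  bic <- function(k, rss) {
    penalty * (k + 2) * log(n) + n * log(max(rss, 1e-12) / n)
  }
  cur_bic <- bic(0L, rss)
  # allow up/down transitions; cap total change points generously
  max_cp <- min(n - 1L, 2L * max_steps + 5L)
  repeat {
    k <- length(bounds) - 2L
    if (k >= max_cp) break
    segs <- cbind(utils::head(bounds, -1) + 1L, bounds[-1])
    cands <- t(apply(segs, 1, function(s) best_split(s[1], s[2])))
    ok <- !is.na(cands[, 1])
    if (!any(ok)) break
    bi <- which(ok)[which.max(cands[ok, 2])]
    new_rss <- rss - cands[bi, 2]
    new_bic <- bic(k + 1L, new_rss)
    if (new_bic >= cur_bic) break
    bounds <- sort(c(bounds, as.integer(cands[bi, 1])))
    rss <- new_rss
    cur_bic <- new_bic
  }
  segs <- cbind(utils::head(bounds, -1) + 1L, bounds[-1])
  means <- apply(segs, 1, function(s) mean(trace[s[1]:s[2]]))
  d <- diff(means)
  down <- which(d < 0)
  up <- which(d > 0)
  # cap at max_steps by keeping the largest drops
  if (length(down) > max_steps) {
    down <- sort(down[order(d[down])][seq_len(max_steps)])
  }
  structure(list(n_steps = length(down),
                 step_frames = bounds[down + 1L],  # 0-based transition frame
                 level_means = means,
                 n_up = length(up),
                 n_segments = nrow(segs),
                 bic = cur_bic),
            class = "step_fit")
}

#' @export
print.step_fit <- function(x, ...) {
  cat(sprintf("<step_fit> %d bleaching steps (%d plateaus, %d upward flagged)\n",
              x$n_steps, x$n_segments, x$n_up))
  invisible(x)
}

#' Cluster-size distribution from step-fit results
#'
#' Histogram of photobleaching step counts over 1..`max_steps` (proxy for
#' the number of fluorophores, hence cluster size). Particles with zero
#' detected steps (no bleaching within the movie) are excluded from the
#' histogram and reported separately. Optionally restrict to a subset of
#' particle indices (e.g. only particles classified as co-confined).
#'
#' @param results list of `step_fit` objects (or an integer vector of step
#'   counts).
#' @param restrict_to particle indices to keep (default: all).
#' @param max_steps histogram cap (default 15).
#' @return object of class `cluster_size_distribution`: `counts` (index =
#'   step count 1..max_steps), `fraction_monomeric`, `n_particles`,
#'   `n_zero_step`.
#' @export
cluster_size_distribution <- function(results, restrict_to = NULL,
                                      max_steps = 15L) {
  steps <- if (is.numeric(results)) as.integer(results) else {
    vapply(results, function(r) r$n_steps, integer(1))
  }
  if (!is.null(restrict_to)) steps <- steps[restrict_to]
  if (length(steps) == 0L) {
    stop("no particles left after restriction", call. = FALSE)
  }
  nz <- sum(steps == 0L)
  steps <- pmin(steps[steps > 0L], max_steps)
  if (length(steps) == 0L) {
    stop("all particles have zero detected steps", call. = FALSE)
  }
  counts <- tabulate(steps, nbins = max_steps)
  structure(list(counts = counts,
                 fraction_monomeric = counts[1] / sum(counts),
                 n_particles = sum(counts),
                 n_zero_step = nz),
            class = "cluster_size_distribution")
}

#' @export
print.cluster_size_distribution <- function(x, ...) {
  cat(sprintf("<cluster_size_distribution> %d particles, %.1f%% monomeric (%d zero-step excluded)\n",
              x$n_particles, 100 * x$fraction_monomeric, x$n_zero_step))
  invisible(x)
}
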