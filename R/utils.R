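# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# wrap coordinates onto [0, L)
wrap_torus <- function(x, L) x - floor(x / L) * L

# minimal-image signed difference on a periodic axis of length L
torus_diff <- function(dx, L) dx - round(dx / L) * L

# squared planar distance, optionally under the minimal-image convention
dist2_xy <- function(dx, dy, width = NULL, height = NULL, periodic = FALSE) {
  if (periodic) {
    dx <- torus_diff(dx, width)
    dy <- torus_diff(dy, height)
  }
  dx * dx + dy * dy
}

# convert a logical vector indexed by `frames` into closed integer intervals
# covering maximal runs of TRUE
intervals_from_logical <- function(flags, frames = seq_along(flags) - 1L) {
  stopifnot(length(flags) == length(frames))
  if (!any(flags)) {
    return(data.frame(start_frame = integer(0), end_frame = integer(0)))
  }
  r <- rle(as.logical(flags))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(
    start_frame = frames[starts[keep]],
    end_frame = frames[ends[keep]]
  )
}

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  }
  if (strict_lower && x <= lower) {
    stop(sprintf("'%s' must be > %g", name, lower), call. = FALSE)
  }
  if (!strict_lower && x < lower) {
    stop(sprintf("'%s' must be >= %g", name, lower), call. = FALSE)
  }
  if (x > upper) {
    stop(sprintf("'%s' must be <= %g", name, upper), call. = FALSE)
  }
  invisible(x)
}

# percentile bootstrap CI of a statistic over exchangeable units (e.g. cells)
boot_ci <- function(values, stat = stats::median, n_boot = 1000L,
                    conf = 0.95, seed = NULL) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop("no finite values to bootstrap", call. = FALSE)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  est <- stat(values)
  if (length(values) == 1L) {
    return(list(estimate = est, lower = est, upper = est))
  }
  reps <- vapply(seq_len(n_boot), function(i) {
    stat(sample(values, replace = TRUE))
  }, numeric(1))
  a <- (1 - conf) / 2
  q <- stats::quantile(reps, c(a, 1 - a), names = FALSE, na.rm = TRUE)
  list(estimate = est, lower = min(q[1], est), upper = max(q[2], est))
}
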