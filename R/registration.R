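#' Fit an affine inter-channel registration from bead fiducials
#'
#' Least-squares affine map taking source-channel bead coordinates onto the
#' destination channel, from coordinate pairs of multi-color fluorescent
#' beads imaged in both channels. Requires at least three non-collinear
#' bead pairs; the root-mean-square residual is reported as the achieved
#' registration precision.
#'
#' @param beads_src,beads_dst n x 2 matrices (or data.frames) of matched
#'   bead coordinates, um.
#' @return object of class `registration_model`: `coef` (2 x 3 matrix of
#'   affine coefficients, rows = output x/y, columns = intercept, x, y),
#'   `rms_residual_um`, `n_beads`.
#' @export
fit_registration <- function(beads_src, beads_dst) {
  src <- as.matrix(beads_src); dst <- as.matrix(beads_dst)
  if (nrow(src) != nrow(dst)) stop("bead sets differ in size", call. = FALSE)
  if (nrow(src) < 3L) stop("need at least 3 bead pairs", call. = FALSE)
  X <- cbind(1, src[, 1], src[, 2])
  if (qr(X)$rank < 3L) {
    stop("bead positions are collinear; affine map is degenerate",
         call. = FALSE)
  }
  fit <- stats::lm.fit(X, dst)
  res <- dst - X %*% fit$coefficients
  rms <- sqrt(mean(rowSums(res^2)))
  cf <- t(fit$coefficients)
  dimnames(cf) <- NULL
  structure(list(coef = cf, rms_residual_um = rms,
                 n_beads = nrow(src)),
            class = "registration_model")
}

#' @export
print.registration_model <- function(x, ...) {
  cat(sprintf("<registration_model> %d beads, rms residual %.4g um\n",
              x$n_beads, x$rms_residual_um))
  print(round(x$coef, 6))
  invisible(x)
}

#' Apply (or invert) a registration model
#'
#' Transforms the coordinates of one channel of a track set with the fitted
#' affine map; everything else is unchanged.
#'
#' @param model a `registration_model`.
#' @param ts a [track_set()].
#' @param channel which channel's coordinates to transform (default "B").
#' @return a transformed [track_set()].
#' @export
apply_registration <- function(model, ts, channel = "B") {
  dt <- data.table::copy(ts$tracks)
  i <- dt$channel == channel
  cf <- model$coef
  x <- dt$x_um[i]; y <- dt$y_um[i]
  dt$x_um[i] <- cf[1, 1] + cf[1, 2] * x + cf[1, 3] * y
  dt$y_um[i] <- cf[2, 1] + cf[2, 2] * x + cf[2, 3] * y
  out <- ts
  out$tracks <- dt
  out
}

#' @rdname apply_registration
#' @export
invert_registration <- function(model) {
  A <- model$coef[, 2:3]
  b <- model$coef[, 1]
  Ai <- solve(A)
  structure(list(coef = cbind(-Ai %*% b, Ai),
                 rms_residual_um = model$rms_residual_um,
                 n_beads = model$n_beads),
            class = "registration_model")
}

#' Serialize a registration model to/from JSON
#' @param model a `registration_model`.
#' @param file path of the JSON file.
#' @export
write_registration <- function(model, file) {
  jsonlite::write_json(list(coef = model$coef,
                            rms_residual_um = model$rms_residual_um,
                            n_beads = model$n_beads),
                       file, digits = NA, auto_unbox = TRUE)
  invisible(file)
}

#' @rdname write_registration
#' @export
read_registration <- function(file) {
  j <- jsonlite::read_json(file, simplifyVector = TRUE)
  cf <- j$coef
  if (!is.matrix(cf)) cf <- matrix(unlist(cf), 2, 3, byrow = TRUE)
  structure(list(coef = cf,
                 rms_residual_um = j$rms_residual_um, n_beads = j$n_beads),
            class = "registration_model")
}
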