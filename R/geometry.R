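#' Estimate the camera-to-manipulator calibration transform
#'
#' Fits the linear map between three-axis manipulator displacements
#' (micrometres) and the corresponding pixel displacements of the pipette tip
#' in the microscope image, from a table of annotated calibration moves.
#' The fit is ordinary least squares on the stacked 2x3 system
#' `(du, dv) = M (dx, dy, dz)`, the minimal scheme consistent with the
#' annotate-move-annotate calibration procedure. The in-plane (x-y) block is
#' modelled as a scaled rotation `u = s(x cos(theta) - y sin(theta))`,
#' `v = s(x sin(theta) + y cos(theta))`; the z (focus) column is retained for
#' diagnostics and is near zero for a well-aligned optical axis.
#'
#' @param pairs A data frame with one calibration displacement per row and
#'   columns `dx_um`, `dy_um`, `dz_um` (manipulator move, micrometres) and
#'   `du_px`, `dv_px` (annotated tip displacement, pixels; u is the 0-based
#'   column increasing rightward, v the row increasing downward).
#' @return A `calibration_transform` object: a list with `matrix` (2x3, px per
#'   um), `theta` (radians in (-pi, pi], rotation from the image u axis to the
#'   projected manipulator x axis, positive toward +v), `scale` (px per um,
#'   mean of the two in-plane column norms), `residual_rms` (px) and
#'   `n_pairs`.
#' @details At least two pairs with linearly independent in-plane (x-y)
#'   displacement projections are required. Near-collinear inputs (condition
#'   number of the in-plane design above 1e8) raise a calibration-failure
#'   error rather than returning a silent, unstable fit. If no calibration
#'   move has support on the z axis the z column is set to zero.
#' @examples
#' pairs <- tibble::tibble(
#'   dx_um = c(10, 0), dy_um = c(0, 10), dz_um = 0,
#'   du_px = c(20, 0), dv_px = c(0, 20)
#' )
#' ct <- estimate_transform(pairs)
#' ct$scale # 2 px/um
#' @seealso [forward_project()], [pixel_to_stage()], [positioning_error()]
#' @export
estimate_transform <- function(pairs) {
  pairs <- as_pairs_df(pairs)
  X <- as.matrix(pairs[, c("dx_um", "dy_um", "dz_um")])
  U <- as.matrix(pairs[, c("du_px", "dv_px")])
  if (nrow(X) < 2) {
    stop("calibration failure: need at least 2 displacement pairs", call. = FALSE)
  }
  if (any(rowSums(X^2) == 0)) {
    stop("calibration failure: zero stage displacement in input", call. = FALSE)
  }
  sv <- svd(X[, 1:2, drop = FALSE], nu = 0, nv = 0)$d
  if (length(sv) < 2 || sv[2] <= 0 || sv[1] / sv[2] > 1e8) {
    stop(
      "calibration failure: in-plane stage displacements are collinear ",
      "(condition number > 1e8); move along two independent x-y directions",
      call. = FALSE
    )
  }
  has_z <- sum(abs(X[, 3])) > 1e-12 && qr(X)$rank == 3
  cols <- if (has_z) 1:3 else 1:2
  # B is 3x2 (or 2x2): least-squares coefficients, transposed into the 2x3 map
  B <- qr.solve(X[, cols, drop = FALSE], U)
  M <- matrix(0, nrow = 2, ncol = 3)
  M[, cols] <- t(B)
  theta <- atan2(M[2, 1], M[1, 1])
  scale <- mean(c(sqrt(sum(M[, 1]^2)), sqrt(sum(M[, 2]^2))))
  if (scale <= 0) {
    stop("calibration failure: fitted scale is not positive", call. = FALSE)
  }
  resid <- X %*% t(M) - U
  new_calibration_transform(
    matrix = M, theta = theta, scale = scale,
    residual_rms = sqrt(mean(resid^2)), n_pairs = nrow(X)
  )
}

new_calibration_transform <- function(matrix, theta, scale, residual_rms,
                                      n_pairs = NA_integer_) {
  structure(
    list(
      matrix = matrix, theta = theta, scale = scale,
      residual_rms = residual_rms, n_pairs = n_pairs
    ),
    class = "calibration_transform"
  )
}

as_pairs_df <- function(pairs) {
  need <- c("dx_um", "dy_um", "dz_um", "du_px", "dv_px")
  missing <- setdiff(need, names(pairs))
  if (length(missing)) {
    stop("calibration pairs lack columns: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  pairs <- tibble::as_tibble(pairs)[need]
  if (!all(vapply(pairs, is.numeric, logical(1))) ||
    !all(is.finite(as.matrix(pairs)))) {
    stop("calibration pairs must be finite numerics", call. = FALSE)
  }
  pairs
}

#' Construct a calibration transform from angle and scale
#'
#' Convenience constructor for a pure scaled-rotation transform, used to
#' synthesise ground-truth calibrations in simulations and tests.
#'
#' @param theta Rotation angle in radians from the image u axis to the
#'   projected manipulator x axis (positive toward +v, i.e. downward).
#' @param scale Pixels per micrometre.
#' @return A `calibration_transform`.
#' @export
make_transform <- function(theta = 0, scale = 1) {
  stopifnot(is.finite(theta), is.finite(scale), scale > 0)
  M <- scale * rbind(
    c(cos(theta), -sin(theta), 0),
    c(sin(theta), cos(theta), 0)
  )
  new_calibration_transform(M, theta, scale, residual_rms = 0)
}

#' @export
print.calibration_transform <- function(x, ...) {
  cat("<calibration_transform>\n")
  cat(sprintf(
    "  theta: %.4f rad (%.2f deg)   scale: %.4f px/um\n",
    x$theta, x$theta * 180 / pi, x$scale
  ))
  cat(sprintf("  residual RMS: %.4g px", x$residual_rms))
  if (!is.na(x$n_pairs)) cat(sprintf("  (fit to %d pairs)", x$n_pairs))
  cat("\n")
  invisible(x)
}

#' Tidy a calibration transform
#'
#' @param x A `calibration_transform`.
#' @param ... Unused.
#' @return One row per fitted quantity with columns `term` and `estimate`.
#' @method tidy calibration_transform
#' @export
tidy.calibration_transform <- function(x, ...) {
  tibble::tibble(
    term = c(
      "theta_rad", "theta_deg", "scale_px_per_um", "residual_rms_px",
      paste0("m", rep(1:2, each = 3), rep(1:3, 2))
    ),
    estimate = c(
      x$theta, x$theta * 180 / pi, x$scale, x$residual_rms,
      as.vector(t(x$matrix))
    )
  )
}

#' Glance at a calibration transform
#'
#' @param x A `calibration_transform`.
#' @param ... Unused.
#' @return A one-row tibble with theta, scale, residual RMS and n.
#' @method glance calibration_transform
#' @export
glance.calibration_transform <- function(x, ...) {
  tibble::tibble(
    theta_rad = x$theta, scale_px_per_um = x$scale,
    residual_rms_px = x$residual_rms, n_pairs = x$n_pairs
  )
}

#' Project a manipulator displacement into image pixels
#'
#' Applies the fitted 2x3 linear map to one or more stage displacements.
#'
#' @param delta A data frame with columns `dx_um`, `dy_um`, `dz_um` (one
#'   displacement per row), or a numeric length-3 vector.
#' @param transform A `calibration_transform`.
#' @return A tibble with columns `du_px`, `dv_px`, one row per displacement.
#' @export
forward_project <- function(delta, transform) {
  check_transform(transform)
  if (is.numeric(delta) && is.null(dim(delta))) {
    stopifnot(length(delta) == 3)
    delta <- tibble::tibble(
      dx_um = delta[1], dy_um = delta[2], dz_um = delta[3]
    )
  }
  D <- as.matrix(tibble::as_tibble(delta)[, c("dx_um", "dy_um", "dz_um")])
  P <- D %*% t(transform$matrix)
  tibble::tibble(du_px = P[, 1], dv_px = P[, 2])
}

#' Convert an image target into a stage move
#'
#' Solves the in-plane 2x2 block of the calibration transform for the
#' manipulator x-y move that places the pipette tip, currently imaged at
#' `current_pixel`, onto `target`. Motion is constrained to the manipulator
#' x-y plane; z is carried through unchanged.
#'
#' @param target,current_pixel Pixel points: data frames (or named vectors)
#'   with `u_px`, `v_px`.
#' @param current_stage Stage point: data frame (or named vector) with
#'   `x_um`, `y_um`, `z_um`.
#' @param transform A `calibration_transform`.
#' @return A one-row tibble `x_um`, `y_um`, `z_um`; forward-projecting the
#'   implied displacement reproduces the pixel target to numerical precision.
#' @export
pixel_to_stage <- function(target, current_pixel, current_stage, transform) {
  check_transform(transform)
  target <- as_pixel(target)
  current_pixel <- as_pixel(current_pixel)
  current_stage <- as_stage(current_stage)
  M2 <- transform$matrix[, 1:2]
  if (abs(det(M2)) < 1e-12 || kappa(M2, exact = TRUE) > 1e8) {
    stop("in-plane calibration block is singular; cannot target pixels",
      call. = FALSE
    )
  }
  dpix <- c(target$u_px - current_pixel$u_px, target$v_px - current_pixel$v_px)
  dxy <- solve(M2, dpix)
  tibble::tibble(
    x_um = current_stage$x_um + dxy[1],
    y_um = current_stage$y_um + dxy[2],
    z_um = current_stage$z_um
  )
}

as_pixel <- function(p) {
  if (is.numeric(p) && is.null(dim(p)) && is.null(names(p)) && length(p) == 2) {
    p <- c(u_px = p[1], v_px = p[2])
  }
  p <- tibble::as_tibble(as.list(p))
  stopifnot(all(c("u_px", "v_px") %in% names(p)))
  p[, c("u_px", "v_px")]
}

as_stage <- function(p) {
  if (is.numeric(p) && is.null(dim(p)) && is.null(names(p)) && length(p) == 3) {
    p <- c(x_um = p[1], y_um = p[2], z_um = p[3])
  }
  p <- tibble::as_tibble(as.list(p))
  stopifnot(all(c("x_um", "y_um", "z_um") %in% names(p)))
  p[, c("x_um", "y_um", "z_um")]
}

check_transform <- function(transform) {
  if (!inherits(transform, "calibration_transform")) {
    stop("`transform` must be a calibration_transform", call. = FALSE)
  }
  invisible(transform)
}

#' Quantify image-guided positioning error
#'
#' Converts the pixel discrepancy between commanded and achieved tip positions
#' into manipulator micrometres through the inverse in-plane calibration, and
#' summarises the per-axis absolute error, mirroring how positioning accuracy
#' is reported for the physical system (mean +/- sd per manipulator axis).
#'
#' @param commanded,achieved Data frames with columns `u_px`, `v_px` and equal
#'   row counts.
#' @param transform A `calibration_transform`.
#' @return A tibble with one row per manipulator axis (`x`, `y`) and columns
#'   `mean_abs_um`, `sd_abs_um`, `n`.
#' @export
positioning_error <- function(commanded, achieved, transform) {
  check_transform(transform)
  commanded <- tibble::as_tibble(commanded)
  achieved <- tibble::as_tibble(achieved)
  if (nrow(commanded) == 0 || nrow(achieved) == 0) {
    stop("positioning_error needs at least one commanded/achieved pair",
      call. = FALSE
    )
  }
  if (nrow(commanded) != nrow(achieved)) {
    stop("commanded and achieved must have equal length", call. = FALSE)
  }
  dpix <- cbind(
    achieved$u_px - commanded$u_px,
    achieved$v_px - commanded$v_px
  )
  M2 <- transform$matrix[, 1:2]
  dum <- t(solve(M2, t(dpix))) # n x 2, manipulator um
  tibble::tibble(
    axis = c("x", "y"),
    mean_abs_um = c(mean(abs(dum[, 1])), mean(abs(dum[, 2]))),
    sd_abs_um = c(stats::sd(abs(dum[, 1])), stats::sd(abs(dum[, 2]))),
    n = nrow(dpix)
  )
}

#' Serialize a calibration transform to JSON
#'
#' @param transform A `calibration_transform`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_transform <- function(transform, path) {
  check_transform(transform)
  jsonlite::write_json(
    list(
      matrix = as.vector(t(transform$matrix)),
      theta_rad = transform$theta,
      scale_px_per_um = transform$scale,
      residual_rms_px = transform$residual_rms
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a calibration transform from JSON
#'
#' @param path File written by [write_transform()].
#' @return A `calibration_transform`.
#' @export
read_transform <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_calibration_transform(
    matrix = matrix(x$matrix, nrow = 2, byrow = TRUE),
    theta = x$theta_rad, scale = x$scale_px_per_um,
    residual_rms = x$residual_rms_px
  )
}

#' Read calibration displacement pairs from CSV
#'
#' Expected columns: `dx_um`, `dy_um`, `dz_um`, `du_px`, `dv_px`.
#'
#' @param path CSV file path.
#' @return A tibble of displacement pairs.
#' @export
read_calibration_pairs <- function(path) {
  as_pairs_df(readr::read_csv(path, show_col_types = FALSE))
}
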