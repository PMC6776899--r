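#' Simulated pressure chain
#'
#' Models the pneumatic chain of the microinjection rig: house pressure
#' (~2,400 mbar) coarsely downregulated by a mechanical regulator to a fixed
#' 340 mbar, fine-tuned by an electronic regulator over 0-250 mbar, and gated
#' by a solenoid valve. The regulators and valve are modelled as
#' instantaneous (no pneumatic rise time). Pressure delivered at the pipette
#' equals the electronic setpoint while the valve is open and 0 otherwise.
#'
#' @param house_mbar House line pressure, mbar.
#' @param mechanical_setpoint_mbar Fixed mechanical regulator output, mbar.
#' @return A `pressure_state` list with fields `house_mbar`,
#'   `mechanical_setpoint_mbar`, `electronic_setpoint_mbar`, `valve_open`,
#'   `delivered_mbar`.
#' @export
pressure_chain <- function(house_mbar = 2400, mechanical_setpoint_mbar = 340) {
  state <- structure(
    list(
      house_mbar = house_mbar,
      mechanical_setpoint_mbar = mechanical_setpoint_mbar,
      electronic_setpoint_mbar = 0,
      valve_open = FALSE,
      delivered_mbar = 0
    ),
    class = "pressure_state"
  )
  state
}

update_delivered <- function(state) {
  state$delivered_mbar <- if (state$valve_open) state$electronic_setpoint_mbar else 0
  state
}

#' Set the electronic regulator pressure
#'
#' @param state A `pressure_state`.
#' @param p_mbar Requested setpoint; must lie within the electronic
#'   regulator's 0-250 mbar range.
#' @return The updated `pressure_state`.
#' @export
set_pressure <- function(state, p_mbar) {
  stopifnot(inherits(state, "pressure_state"))
  if (!is.finite(p_mbar) || p_mbar < 0 || p_mbar > 250) {
    stop(
      "pressure ", p_mbar, " mbar is outside the electronic regulator ",
      "range [0, 250] mbar",
      call. = FALSE
    )
  }
  state$electronic_setpoint_mbar <- p_mbar
  update_delivered(state)
}

#' Open or close the solenoid valve
#'
#' @param state A `pressure_state`.
#' @param open Logical.
#' @return The updated `pressure_state`.
#' @export
set_valve <- function(state, open) {
  stopifnot(inherits(state, "pressure_state"), is.logical(open), length(open) == 1)
  state$valve_open <- open
  update_delivered(state)
}

#' Simulated straight-line manipulator move
#'
#' Constant-speed straight-line kinematics with exact arrival: the final
#' state's position equals the commanded target bit-exactly (no drift model).
#'
#' @param position Current stage point (`x_um`, `y_um`, `z_um` data frame or
#'   length-3 numeric).
#' @param target Target stage point, same forms.
#' @param speed_um_s Travel speed (> 0).
#' @param limits Symmetric per-axis travel limits, micrometres.
#' @param t0_s Start time of the move, seconds.
#' @return A tibble of timed manipulator states (start and end rows) with
#'   columns `t_s`, `x_um`, `y_um`, `z_um`, `moving`; the move duration is
#'   attached as attribute `duration_s`.
#' @export
move_to <- function(position, target, speed_um_s = 1000,
                    limits = c(-10000, 10000), t0_s = 0) {
  stopifnot(speed_um_s > 0)
  p0 <- unlist(as_stage(position))
  p1 <- unlist(as_stage(target))
  if (any(p1 < limits[1]) || any(p1 > limits[2])) {
    stop(
      "target outside manipulator travel limits [", limits[1], ", ",
      limits[2], "] um",
      call. = FALSE
    )
  }
  d <- sqrt(sum((p1 - p0)^2))
  dur <- d / speed_um_s
  if (d == 0) {
    out <- tibble::tibble(
      t_s = t0_s, x_um = p0[1], y_um = p0[2], z_um = p0[3], moving = FALSE
    )
  } else {
    out <- tibble::tibble(
      t_s = c(t0_s, t0_s + dur),
      x_um = c(p0[1], p1[1]), y_um = c(p0[2], p1[2]), z_um = c(p0[3], p1[3]),
      moving = c(TRUE, FALSE)
    )
  }
  attr(out, "duration_s") <- dur
  out
}

#' Virtual tissue for the simulator
#'
#' A static organotypic-slice stand-in: an apical (or basal) surface polyline
#' in stage micrometres, a thickness, the side on which the tissue interior
#' lies, and a cell population table (see the synthetic-data generators).
#'
#' @param surface Data frame with columns `x_um`, `y_um` (z assumed 0).
#' @param interior_side `"left"` or `"right"` of the surface travel direction.
#' @param thickness_um Slice thickness, micrometres.
#' @param cells Optional cell table (tibble); see [generate_tissue()].
#' @return A `virtual_tissue` list.
#' @export
virtual_tissue <- function(surface, interior_side = c("left", "right"),
                           thickness_um = 300, cells = NULL) {
  interior_side <- match.arg(interior_side)
  surface <- tibble::as_tibble(surface)
  stopifnot(all(c("x_um", "y_um") %in% names(surface)), nrow(surface) >= 2)
  structure(
    list(
      surface = surface[, c("x_um", "y_um")],
      interior_side = interior_side,
      thickness_um = thickness_um,
      cells = cells
    ),
    class = "virtual_tissue"
  )
}

# signed perpendicular distance of points (n x 2) to a polyline (m x 2);
# positive on the interior side
signed_distance_polyline <- function(pts, poly, interior_side) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  P <- as.matrix(poly)
  nseg <- nrow(P) - 1
  n <- nrow(pts)
  best <- rep(Inf, n)
  best_side <- rep(0, n)
  for (k in seq_len(nseg)) {
    a <- P[k, ]
    d <- P[k + 1, ] - a
    len2 <- sum(d^2)
    wx <- pts[, 1] - a[1]
    wy <- pts[, 2] - a[2]
    t <- pmin(pmax((wx * d[1] + wy * d[2]) / len2, 0), 1)
    ex <- wx - t * d[1]
    ey <- wy - t * d[2]
    dist <- sqrt(ex^2 + ey^2)
    cross <- d[1] * wy - d[2] * wx # >0: point left of segment direction
    upd <- dist < best
    best[upd] <- dist[upd]
    best_side[upd] <- sign(cross[upd])
  }
  sgn <- if (interior_side == "left") 1 else -1
  best * best_side * sgn
}

#' Signed depth of a point in the tissue
#'
#' Perpendicular distance from the pipette tip to the tissue-surface
#' polyline, signed positive inside the tissue and negative outside.
#'
#' @param tip Stage point (`x_um`, `y_um`, `z_um` data frame or length-3
#'   numeric); only the x-y plane enters the distance.
#' @param tissue A [virtual_tissue()].
#' @return Signed depth in micrometres.
#' @export
depth_in_tissue <- function(tip, tissue) {
  stopifnot(inherits(tissue, "virtual_tissue"))
  p <- unlist(as_stage(tip))[1:2]
  signed_distance_polyline(
    matrix(p, ncol = 2), tissue$surface, tissue$interior_side
  )
}

#' Camera model
#'
#' @param magnification Objective magnification (e.g. 10, 20).
#' @param pixel_size_um Micrometres per pixel at this magnification.
#' @param width_px,height_px Sensor size in pixels.
#' @return A `camera_model` list.
#' @export
camera_model <- function(magnification = 20, pixel_size_um = 0.5,
                         width_px = 200, height_px = 200) {
  stopifnot(pixel_size_um > 0, width_px > 0, height_px > 0)
  structure(
    list(
      magnification = magnification, pixel_size_um = pixel_size_um,
      width_px = as.integer(width_px), height_px = as.integer(height_px)
    ),
    class = "camera_model"
  )
}

#' Render a synthetic microscope frame
#'
#' Draws an 8-bit grayscale frame of the virtual tissue and pipette tip as
#' seen by the camera: darker background (30), tissue interior (80), a bright
#' edge band along the surface (160), a Gaussian blob (amplitude 200,
#' sigma 2 px) at the projected tip, plus optional additive Gaussian noise.
#' The ground-truth tip pixel and projected surface polyline are embedded
#' losslessly alongside the pixel data, so image-loop code can be tested
#' without a microscope.
#'
#' @param tissue A [virtual_tissue()].
#' @param tip Stage point of the pipette tip.
#' @param camera A [camera_model()].
#' @param transform A `calibration_transform` mapping stage displacements to
#'   pixel displacements.
#' @param noise_sd Additive Gaussian noise standard deviation on the 8-bit
#'   scale (0 for a noiseless frame).
#' @param anchor_stage Stage point imaged at the frame centre.
#' @return A `synthetic_frame`: list with `image` (height x width numeric
#'   matrix, 0-255), `camera`, `tip_px` (ground-truth u/v), `surface_px`
#'   (projected polyline) and `tip_in_fov` flag.
#' @export
render_frame <- function(tissue, tip, camera, transform, noise_sd = 0,
                         anchor_stage = c(0, 0, 0)) {
  stopifnot(inherits(tissue, "virtual_tissue"), inherits(camera, "camera_model"))
  check_transform(transform)
  anchor <- unlist(as_stage(anchor_stage))
  centre <- c(camera$width_px / 2, camera$height_px / 2)
  project <- function(xy) {
    d <- cbind(xy[, 1] - anchor[1], xy[, 2] - anchor[2], 0)
    px <- d %*% t(transform$matrix)
    cbind(u_px = px[, 1] + centre[1], v_px = px[, 2] + centre[2])
  }
  surf_px <- project(as.matrix(tissue$surface))
  tipv <- unlist(as_stage(tip))
  tip_px <- project(matrix(tipv[1:2], ncol = 2))
  tip_in_fov <- tip_px[1] >= 0 && tip_px[1] < camera$width_px &&
    tip_px[2] >= 0 && tip_px[2] < camera$height_px

  # pixel-centre grid; image is a matrix indexed [row = v + 1, col = u + 1]
  u <- rep(seq_len(camera$width_px) - 1, each = camera$height_px)
  v <- rep(seq_len(camera$height_px) - 1, times = camera$width_px)
  # tissue side in pixel space: mirror the stage-space interior convention;
  # the determinant sign of the in-plane block flips orientation
  flip <- det(transform$matrix[, 1:2]) < 0
  side <- tissue$interior_side
  if (flip) side <- if (side == "left") "right" else "left"
  sd_px <- signed_distance_polyline(cbind(u, v), surf_px, side)
  img <- rep(30, length(u))
  img[sd_px > 0] <- 80
  img[abs(sd_px) <= 2] <- 160
  if (tip_in_fov) {
    r2 <- (u - tip_px[1])^2 + (v - tip_px[2])^2
    img <- img + 200 * exp(-r2 / (2 * 2^2))
  }
  if (noise_sd > 0) img <- img + rnorm(length(img), 0, noise_sd)
  img <- matrix(pmin(pmax(img, 0), 255), nrow = camera$height_px)
  structure(
    list(
      image = img, camera = camera,
      tip_px = c(u_px = unname(tip_px[1]), v_px = unname(tip_px[2])),
      surface_px = tibble::tibble(u_px = surf_px[, 1], v_px = surf_px[, 2]),
      tip_in_fov = tip_in_fov
    ),
    class = "synthetic_frame"
  )
}

#' Intensity-weighted centroid of the tip blob
#'
#' Locates the pipette-tip blob in a frame. The bright band along the
#' annotated tissue edge is masked out first (the surface polyline is drawn
#' by the user, so its location is known to the system), the image is
#' smoothed with a small box filter to suppress pixel noise, and the
#' intensity-weighted centroid is taken in a window around the remaining
#' intensity peak — the standard way to recover a fluorescent tip or bead
#' position from a noisy frame.
#'
#' @param frame A `synthetic_frame`.
#' @param window_px Half-width of the centroid window around the smoothed
#'   intensity peak, pixels.
#' @param smooth_px Box-filter half-width in pixels (0 disables smoothing).
#' @param edge_mask_px Pixels within this distance of the annotated surface
#'   are excluded from peak finding.
#' @return Named numeric `u_px`, `v_px` (0-based pixel coordinates).
#' @export
frame_centroid <- function(frame, window_px = 6, smooth_px = 1,
                           edge_mask_px = 4) {
  stopifnot(inherits(frame, "synthetic_frame"))
  img <- frame$image
  if (edge_mask_px > 0 && nrow(frame$surface_px) >= 2) {
    u <- rep(seq_len(ncol(img)) - 1, each = nrow(img))
    v <- rep(seq_len(nrow(img)) - 1, times = ncol(img))
    d <- abs(signed_distance_polyline(
      cbind(u, v), as.matrix(frame$surface_px), "left"
    ))
    img[matrix(d <= edge_mask_px + smooth_px, nrow = nrow(img))] <-
      stats::median(img)
  }
  if (smooth_px > 0) img <- box_blur(img, smooth_px)
  peak <- which(img == max(img), arr.ind = TRUE)[1, ]
  rows <- max(1, peak[1] - window_px):min(nrow(img), peak[1] + window_px)
  cols <- max(1, peak[2] - window_px):min(ncol(img), peak[2] + window_px)
  sub <- img[rows, cols, drop = FALSE]
  # local threshold halfway between the peak and the frame's typical level,
  # so the surrounding tissue/edge intensities carry no weight
  thr <- (max(sub) + stats::median(img)) / 2
  w <- pmax(sub - thr, 0)
  if (sum(w) == 0) {
    return(c(u_px = NA_real_, v_px = NA_real_))
  }
  wu <- colSums(w)
  wv <- rowSums(w)
  c(
    u_px = sum((cols - 1) * wu) / sum(wu),
    v_px = sum((rows - 1) * wv) / sum(wv)
  )
}

# separable box filter with edge replication
box_blur <- function(img, half) {
  k <- rep(1, 2 * half + 1) / (2 * half + 1)
  pad <- function(m, n) rbind(
    m[rep(1, n), , drop = FALSE], m, m[rep(nrow(m), n), , drop = FALSE]
  )
  smooth_rows <- function(m) {
    p <- pad(m, half)
    out <- matrix(0, nrow(m), ncol(m))
    for (o in -half:half) {
      out <- out + p[(1 + half + o):(nrow(m) + half + o), , drop = FALSE]
    }
    out / (2 * half + 1)
  }
  t(smooth_rows(t(smooth_rows(img))))
}

#' Write a synthetic frame as an 8-bit PNG with a ground-truth sidecar
#'
#' @param frame A `synthetic_frame`.
#' @param path Output PNG path; a `.json` sidecar with the ground-truth tip
#'   pixel and projected surface is written alongside.
#' @return `path`, invisibly.
#' @export
write_frame <- function(frame, path) {
  stopifnot(inherits(frame, "synthetic_frame"))
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("writing frames requires the 'png' package", call. = FALSE)
  }
  png::writePNG(frame$image / 255, path)
  jsonlite::write_json(
    list(
      tip_px = as.list(frame$tip_px),
      tip_in_fov = frame$tip_in_fov,
      surface_px = frame$surface_px
    ),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @method autoplot synthetic_frame
#' @export
autoplot.synthetic_frame <- function(object, ...) {
  img <- object$image
  df <- tibble::tibble(
    u_px = rep(seq_len(ncol(img)) - 1, each = nrow(img)),
    v_px = rep(seq_len(nrow(img)) - 1, times = ncol(img)),
    intensity = as.vector(img)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$u_px, .data$v_px)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 255)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "u (px)", y = "v (px)", fill = "I") +
    ggplot2::theme_minimal()
}
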