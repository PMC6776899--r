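#' Injection session parameters
#'
#' Bundles the user-tunable parameters of an automated microinjection sweep.
#' Defaults reflect the optimised apical-progenitor protocol: 75 mbar line
#' pressure, 10 um axial depth, 30 um inter-site spacing, 45 degree approach
#' relative to the tissue-surface normal.
#'
#' @param depth_um Axial penetration along the pipette axis from the annotated
#'   surface, micrometres (>= 0).
#' @param pullout_um Retraction distance back out of the tissue between sites,
#'   micrometres (>= 0).
#' @param spacing_um Arclength between consecutive injection sites,
#'   micrometres (> 0).
#' @param pressure_mbar Constant line pressure held throughout the sweep;
#'   must lie within the electronic regulator's 0-250 mbar range.
#' @param approach_angle_deg Angle between the pipette axis and the local
#'   tissue-surface normal, degrees in [0, 90).
#' @param speed_um_s Travel speed of the manipulator, micrometres per second.
#' @param dwell_s In-tissue pause at the injection point, seconds.
#' @param depth_range_um Optional length-2 numeric. When set, each site draws
#'   its axial depth uniformly from this range instead of `depth_um` (used
#'   when targeting neurons at variable depth from the basal surface).
#' @return An `injection_parameters` list.
#' @export
injection_parameters <- function(depth_um = 10, pullout_um = 20,
                                 spacing_um = 30, pressure_mbar = 75,
                                 approach_angle_deg = 45, speed_um_s = 1000,
                                 dwell_s = 0, depth_range_um = NULL) {
  stopifnot(
    is.finite(depth_um), depth_um >= 0,
    is.finite(pullout_um), pullout_um >= 0,
    is.finite(spacing_um), spacing_um > 0,
    is.finite(speed_um_s), speed_um_s > 0,
    is.finite(dwell_s), dwell_s >= 0
  )
  if (!is.finite(pressure_mbar) || pressure_mbar < 0 || pressure_mbar > 250) {
    stop("pressure_mbar must lie in the electronic regulator range [0, 250]",
      call. = FALSE
    )
  }
  if (!is.finite(approach_angle_deg) || approach_angle_deg < 0 ||
    approach_angle_deg >= 90) {
    stop("approach_angle_deg must lie in [0, 90)", call. = FALSE)
  }
  if (!is.null(depth_range_um)) {
    stopifnot(
      length(depth_range_um) == 2, all(is.finite(depth_range_um)),
      depth_range_um[1] >= 0, depth_range_um[1] <= depth_range_um[2]
    )
  }
  structure(
    list(
      depth_um = depth_um, pullout_um = pullout_um, spacing_um = spacing_um,
      pressure_mbar = pressure_mbar, approach_angle_deg = approach_angle_deg,
      speed_um_s = speed_um_s, dwell_s = dwell_s,
      depth_range_um = depth_range_um
    ),
    class = "injection_parameters"
  )
}

#' Annotated tissue-edge path
#'
#' Wraps an ordered pixel polyline drawn along the tissue surface, together
#' with the side (relative to the direction of travel) on which the tissue
#' interior lies.
#'
#' @param points Data frame with columns `u_px`, `v_px`, at least two rows,
#'   consecutive points distinct. Sub-pixel coordinates are allowed.
#' @param interior_side `"left"` or `"right"` of the direction of travel.
#' @return An `annotated_path` list.
#' @export
annotated_path <- function(points, interior_side = c("left", "right")) {
  interior_side <- match.arg(interior_side)
  points <- tibble::as_tibble(points)[, c("u_px", "v_px")]
  if (nrow(points) < 2) stop("path needs at least 2 points", call. = FALSE)
  seg <- diff(as.matrix(points))
  if (any(rowSums(seg^2) == 0)) {
    stop("consecutive path points must be distinct", call. = FALSE)
  }
  structure(
    list(points = points, interior_side = interior_side),
    class = "annotated_path"
  )
}

#' Read an annotated path from CSV
#'
#' @param path CSV with columns `u_px`, `v_px`.
#' @param interior_side Side of the travel direction where tissue lies.
#' @return An `annotated_path`.
#' @export
read_annotated_path <- function(path, interior_side = "left") {
  annotated_path(readr::read_csv(path, show_col_types = FALSE), interior_side)
}

# arclength-parameterised polyline utilities (stage um, x-y plane) ---------

polyline_cumlen <- function(P) {
  seg <- sqrt(rowSums(diff(P)^2))
  c(0, cumsum(seg))
}

interp_polyline <- function(P, s) {
  cl <- polyline_cumlen(P)
  s <- pmin(pmax(s, 0), cl[length(cl)])
  i <- findInterval(s, cl, rightmost.closed = TRUE)
  i <- pmin(i, nrow(P) - 1)
  w <- (s - cl[i]) / pmax(cl[i + 1] - cl[i], .Machine$double.eps)
  P[i, , drop = FALSE] + w * (P[i + 1, , drop = FALSE] - P[i, , drop = FALSE])
}

#' Resample an annotated path at constant arclength spacing
#'
#' Converts the annotated pixel polyline to manipulator coordinates through
#' the calibration transform and places surface points at arclengths
#' 0, s, 2s, ... up to the total path length; the first point coincides with
#' the path start. Local unit tangents (central difference) and interior-
#' pointing unit normals are attached to each site.
#'
#' @param path An [annotated_path()].
#' @param spacing_um Arclength between sites, micrometres (> 0).
#' @param transform A `calibration_transform`.
#' @param anchor_pixel,anchor_stage Reference pair tying pixel coordinates to
#'   stage coordinates (defaults: first path vertex maps to the stage origin).
#' @return A tibble with one row per site: `site`, `arclength_um`,
#'   `x_um`, `y_um`, `z_um`, tangent `tx`, `ty` and interior normal `nx`, `ny`.
#' @export
resample_path <- function(path, spacing_um, transform,
                          anchor_pixel = NULL, anchor_stage = c(0, 0, 0)) {
  stopifnot(inherits(path, "annotated_path"))
  if (!is.finite(spacing_um) || spacing_um <= 0) {
    stop("spacing_um must be > 0", call. = FALSE)
  }
  check_transform(transform)
  if (is.null(anchor_pixel)) {
    anchor_pixel <- c(
      u_px = path$points$u_px[1],
      v_px = path$points$v_px[1]
    )
  }
  anchor_stage <- as_stage(anchor_stage)
  # pixel vertices -> stage x-y via the inverse in-plane block
  Pstage <- t(vapply(
    seq_len(nrow(path$points)),
    function(i) {
      s <- pixel_to_stage(
        c(path$points$u_px[i], path$points$v_px[i]),
        anchor_pixel, anchor_stage, transform
      )
      c(s$x_um, s$y_um)
    },
    numeric(2)
  ))
  total <- polyline_cumlen(Pstage)
  L <- total[length(total)]
  s <- seq(0, L, by = spacing_um)
  S <- interp_polyline(Pstage, s)
  n <- nrow(S)
  # central-difference tangents, one-sided at the ends
  tg <- matrix(0, n, 2)
  if (n == 1) {
    tg[1, ] <- Pstage[nrow(Pstage), ] - Pstage[1, ]
  } else {
    tg[1, ] <- S[2, ] - S[1, ]
    tg[n, ] <- S[n, ] - S[n - 1, ]
    if (n > 2) tg[2:(n - 1), ] <- S[3:n, ] - S[1:(n - 2), ]
  }
  tg <- tg / sqrt(rowSums(tg^2))
  # interior normal: rotate tangent +90 deg for "left", -90 for "right".
  # Left of travel direction (tx, ty) is (-ty, tx) in a right-handed x-y frame.
  sgn <- if (path$interior_side == "left") 1 else -1
  nx <- -sgn * tg[, 2]
  ny <- sgn * tg[, 1]
  tibble::tibble(
    site = seq_len(n), arclength_um = s,
    x_um = S[, 1], y_um = S[, 2], z_um = anchor_stage$z_um,
    tx = tg[, 1], ty = tg[, 2], nx = nx, ny = ny
  )
}

#' Pipette axis for a given approach angle
#'
#' Returns the unit direction along which the pipette advances into the
#' tissue: tilted by the approach angle away from the local surface normal,
#' within the plane spanned by the normal and the travel direction, oriented
#' into the tissue.
#'
#' @param normal Unit vector (length 3) pointing into the tissue.
#' @param travel Direction of pipette travel along the path (length 3).
#' @param angle_deg Approach angle in degrees, [0, 90).
#' @return A unit numeric vector of length 3.
#' @export
injection_axis <- function(normal, travel, angle_deg) {
  stopifnot(length(normal) == 3, length(travel) == 3)
  nn <- sqrt(sum(normal^2))
  if (nn < 1e-12) stop("zero surface normal", call. = FALSE)
  if (!is.finite(angle_deg) || angle_deg < 0 || angle_deg >= 90) {
    stop("approach angle must lie in [0, 90)", call. = FALSE)
  }
  n <- normal / nn
  t_perp <- travel - sum(travel * n) * n
  tn <- sqrt(sum(t_perp^2))
  if (angle_deg > 0 && tn < 1e-12) {
    stop("travel direction is parallel to the normal; axis plane undefined",
      call. = FALSE
    )
  }
  a <- angle_deg * pi / 180
  if (tn < 1e-12) {
    return(n)
  }
  cos(a) * n + sin(a) * t_perp / tn
}

#' Convert axial depth to perpendicular depth
#'
#' A pipette advancing a distance `d` along its own axis, inclined at
#' `angle_deg` to the surface normal, ends up `d * cos(angle)` below the
#' surface. At the standard 45 degree approach, axial depths of 15 and 25 um
#' correspond to 10.6 and 17.7 um perpendicular to the ventricular surface.
#'
#' @param depth_axial_um Distance advanced along the pipette axis (um).
#' @param angle_deg Angle between pipette axis and surface normal, [0, 90).
#' @return Perpendicular depth below the surface, micrometres.
#' @export
axial_to_normal_depth <- function(depth_axial_um, angle_deg) {
  if (any(!is.finite(angle_deg)) || any(angle_deg < 0) || any(angle_deg >= 90)) {
    stop("angle must lie in [0, 90)", call. = FALSE)
  }
  depth_axial_um * cos(angle_deg * pi / 180)
}

#' Plan an injection trajectory along an annotated edge
#'
#' Resamples the annotated path at the configured spacing and builds, for each
#' site, the approach point (pulled back out of the tissue along the pipette
#' axis), the injection point (advanced axially into the tissue) and the
#' timed command sequence approach -> inject (+ dwell) -> retract, with the
#' line pressure held constant across the whole plan.
#'
#' @param path An [annotated_path()].
#' @param params An [injection_parameters()] object.
#' @param transform A `calibration_transform`.
#' @param anchor_pixel,anchor_stage Passed to [resample_path()].
#' @param seed Optional integer; required for reproducible per-site depth
#'   draws when `params$depth_range_um` is set.
#' @return A `trajectory_plan`: list with `sites` (tibble: surface, approach
#'   and injection points plus per-site axial depth), `commands` (tibble:
#'   `t_s`, `kind`, target coordinates or pressure state) and `params`.
#' @export
plan_trajectory <- function(path, params, transform,
                            anchor_pixel = NULL, anchor_stage = c(0, 0, 0),
                            seed = NULL) {
  stopifnot(inherits(params, "injection_parameters"))
  sites <- resample_path(path, params$spacing_um, transform,
    anchor_pixel = anchor_pixel, anchor_stage = anchor_stage
  )
  n <- nrow(sites)
  if (!is.null(params$depth_range_um)) {
    if (!is.null(seed)) set.seed(seed)
    depths <- runif(n, params$depth_range_um[1], params$depth_range_um[2])
  } else {
    depths <- rep(params$depth_um, n)
  }
  axes <- t(vapply(
    seq_len(n),
    function(i) {
      injection_axis(
        c(sites$nx[i], sites$ny[i], 0),
        c(sites$tx[i], sites$ty[i], 0),
        params$approach_angle_deg
      )
    },
    numeric(3)
  ))
  surface <- as.matrix(sites[, c("x_um", "y_um", "z_um")])
  approach <- surface - params$pullout_um * axes
  inject <- surface + depths * axes
  sites_out <- tibble::tibble(
    site = sites$site, arclength_um = sites$arclength_um,
    axial_depth_um = depths,
    surface_x = surface[, 1], surface_y = surface[, 2], surface_z = surface[, 3],
    approach_x = approach[, 1], approach_y = approach[, 2],
    approach_z = approach[, 3],
    inject_x = inject[, 1], inject_y = inject[, 2], inject_z = inject[, 3]
  )
  # timed command list: constant pressure on, then the per-site triplet
  cmds <- list(tibble::tibble(
    t_s = 0, site = NA_integer_, kind = "pressure",
    x_um = NA_real_, y_um = NA_real_, z_um = NA_real_,
    state = params$pressure_mbar
  ))
  t_now <- 0
  pos <- approach[1, ]
  for (i in seq_len(n)) {
    t_now <- t_now + dist3(pos, approach[i, ]) / params$speed_um_s
    cmds[[length(cmds) + 1]] <- motion_cmd(t_now, i, "approach", approach[i, ])
    t_now <- t_now + dist3(approach[i, ], inject[i, ]) / params$speed_um_s
    cmds[[length(cmds) + 1]] <- motion_cmd(t_now, i, "inject", inject[i, ])
    if (params$dwell_s > 0) {
      t_now <- t_now + params$dwell_s
      cmds[[length(cmds) + 1]] <- tibble::tibble(
        t_s = t_now, site = i, kind = "dwell",
        x_um = inject[i, 1], y_um = inject[i, 2], z_um = inject[i, 3],
        state = params$dwell_s
      )
    }
    t_now <- t_now + dist3(inject[i, ], approach[i, ]) / params$speed_um_s
    cmds[[length(cmds) + 1]] <- motion_cmd(t_now, i, "retract", approach[i, ])
    pos <- approach[i, ]
  }
  structure(
    list(
      sites = sites_out,
      commands = dplyr::bind_rows(cmds),
      params = params
    ),
    class = "trajectory_plan"
  )
}

dist3 <- function(a, b) sqrt(sum((a - b)^2))

motion_cmd <- function(t_s, site, kind, p) {
  tibble::tibble(
    t_s = t_s, site = site, kind = kind,
    x_um = p[1], y_um = p[2], z_um = p[3], state = NA_real_
  )
}

#' @export
print.trajectory_plan <- function(x, ...) {
  cat("<trajectory_plan>\n")
  cat(sprintf(
    "  %d sites, %d commands, %.0f mbar, spacing %.1f um, depth %s um\n",
    nrow(x$sites), nrow(x$commands), x$params$pressure_mbar,
    x$params$spacing_um,
    if (is.null(x$params$depth_range_um)) {
      sprintf("%.1f", x$params$depth_um)
    } else {
      sprintf("[%.0f-%.0f]", x$params$depth_range_um[1], x$params$depth_range_um[2])
    }
  ))
  invisible(x)
}

#' Tidy a trajectory plan
#'
#' @param x A `trajectory_plan`.
#' @param ... Unused.
#' @return The per-site tibble of surface/approach/injection points.
#' @method tidy trajectory_plan
#' @export
tidy.trajectory_plan <- function(x, ...) x$sites

#' Glance at a trajectory plan
#'
#' @param x A `trajectory_plan`.
#' @param ... Unused.
#' @return One-row tibble: site count, command count, total path time.
#' @method glance trajectory_plan
#' @export
glance.trajectory_plan <- function(x, ...) {
  tibble::tibble(
    n_sites = nrow(x$sites),
    n_commands = nrow(x$commands),
    n_motion_commands = sum(x$commands$kind %in% c("approach", "inject", "retract")),
    duration_s = max(x$commands$t_s),
    pressure_mbar = x$params$pressure_mbar
  )
}

#' @method autoplot trajectory_plan
#' @export
autoplot.trajectory_plan <- function(object, ...) {
  s <- object$sites
  seg <- tibble::tibble(
    x = s$approach_x, y = s$approach_y, xend = s$inject_x, yend = s$inject_y
  )
  ggplot2::ggplot(s) +
    ggplot2::geom_path(
      ggplot2::aes(.data$surface_x, .data$surface_y),
      colour = "grey40"
    ) +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(.data$x, .data$y, xend = .data$xend, yend = .data$yend),
      colour = "steelblue",
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))
    ) +
    ggplot2::geom_point(
      ggplot2::aes(.data$inject_x, .data$inject_y),
      colour = "firebrick", size = 1.5
    ) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
}

#' Serialize a trajectory plan to JSON
#'
#' @param plan A `trajectory_plan`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_plan <- function(plan, path) {
  stopifnot(inherits(plan, "trajectory_plan"))
  jsonlite::write_json(
    list(
      params = unclass(plan$params),
      sites = plan$sites,
      commands = plan$commands
    ),
    path,
    auto_unbox = TRUE, digits = NA, dataframe = "rows", null = "null"
  )
  invisible(path)
}
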