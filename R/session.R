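#' Stochastic injection-outcome model
#'
#' Maps the controllable parameters of an attempt (line pressure, axial
#' depth) to a success probability via a lookup table, with nearest-neighbour
#' lookup by default (bilinear interpolation available for full grids).
#'
#' @param table Data frame with columns `pressure_mbar`, `depth_um`, `p`
#'   (probabilities in [0, 1]), non-empty.
#' @param interpolation `"nearest"` or `"bilinear"`.
#' @return An `outcome_model` list.
#' @export
outcome_model <- function(table, interpolation = c("nearest", "bilinear")) {
  interpolation <- match.arg(interpolation)
  table <- tibble::as_tibble(table)
  stopifnot(all(c("pressure_mbar", "depth_um", "p") %in% names(table)))
  if (nrow(table) == 0) stop("outcome table must be non-empty", call. = FALSE)
  if (any(table$p < 0 | table$p > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(table = table, interpolation = interpolation),
    class = "outcome_model"
  )
}

#' Depth-sweep outcome preset
#'
#' Success probabilities measured at a constant 75 mbar across axial depths
#' of 10, 15 and 25 um (68%, 22% and 11%). This is the default model for
#' apical-progenitor sessions.
#'
#' @return An `outcome_model`.
#' @export
depth_yield_model <- function() {
  outcome_model(tibble::tibble(
    pressure_mbar = 75, depth_um = c(10, 15, 25), p = c(0.68, 0.22, 0.11)
  ))
}

#' Pressure-sweep outcome preset
#'
#' Success probabilities measured at a constant 10 um depth across line
#' pressures of 75, 100 and 125 mbar (35%, 35% and 8%). Note this sweep and
#' the depth sweep disagree at (75 mbar, 10 um) — they come from different
#' slices and batches — so the two tables are exposed as separate presets
#' rather than being averaged.
#'
#' @return An `outcome_model`.
#' @export
pressure_yield_model <- function() {
  outcome_model(tibble::tibble(
    pressure_mbar = c(75, 100, 125), depth_um = 10, p = c(0.35, 0.35, 0.08)
  ))
}

#' Look up the success probability of an outcome model
#'
#' @param model An [outcome_model()].
#' @param pressure_mbar,depth_um Attempt parameters.
#' @return Success probability in [0, 1].
#' @export
model_lookup <- function(model, pressure_mbar, depth_um) {
  stopifnot(inherits(model, "outcome_model"))
  tb <- model$table
  if (model$interpolation == "nearest") {
    d2 <- (tb$pressure_mbar - pressure_mbar)^2 + (tb$depth_um - depth_um)^2
    return(tb$p[which.min(d2)])
  }
  # bilinear over the full grid of unique pressures x depths
  ps <- sort(unique(tb$pressure_mbar))
  ds <- sort(unique(tb$depth_um))
  if (nrow(tb) != length(ps) * length(ds)) {
    stop("bilinear interpolation requires a complete pressure x depth grid",
      call. = FALSE
    )
  }
  grid <- matrix(NA_real_, length(ps), length(ds))
  for (i in seq_len(nrow(tb))) {
    grid[match(tb$pressure_mbar[i], ps), match(tb$depth_um[i], ds)] <- tb$p[i]
  }
  interp1 <- function(v, x) {
    if (length(v) == 1) {
      return(c(1L, 1L, 0))
    }
    x <- min(max(x, v[1]), v[length(v)])
    i <- max(findInterval(x, v, rightmost.closed = TRUE), 1)
    i <- min(i, length(v) - 1)
    c(i, i + 1L, (x - v[i]) / (v[i + 1] - v[i]))
  }
  a <- interp1(ps, pressure_mbar)
  b <- interp1(ds, depth_um)
  (1 - a[3]) * ((1 - b[3]) * grid[a[1], b[1]] + b[3] * grid[a[1], b[2]]) +
    a[3] * ((1 - b[3]) * grid[a[2], b[1]] + b[3] * grid[a[2], b[2]])
}

#' Simulate one injection attempt
#'
#' Draws a Bernoulli success with the probability the outcome model assigns
#' to the attempt's pressure and axial depth. When a virtual tissue with
#' cells is supplied, the targeted cell is the nearest apically attached cell
#' whose apical process passes close to the insertion segment.
#'
#' @param site One row of a trajectory plan's `sites` tibble.
#' @param params The plan's [injection_parameters()].
#' @param model An [outcome_model()].
#' @param tissue Optional [virtual_tissue()] with a `cells` table.
#' @param t_s Attempt timestamp in seconds.
#' @param capture_um Lateral capture radius for matching an apical process to
#'   the insertion segment, micrometres.
#' @return A one-row tibble: `site`, `t_s`, `pressure_mbar`,
#'   `axial_depth_um`, `success`, `cell_id`.
#' @export
attempt_injection <- function(site, params, model, tissue = NULL, t_s = 0,
                              capture_um = 5) {
  p <- model_lookup(model, params$pressure_mbar, site$axial_depth_um)
  success <- runif(1) < p
  cell_id <- NA_character_
  if (success && !is.null(tissue) && !is.null(tissue$cells) &&
    nrow(tissue$cells) > 0) {
    cell_id <- target_cell(site, tissue, capture_um)
  }
  site_index <- site$site
  depth <- site$axial_depth_um
  tibble::tibble(
    site = site_index, t_s = t_s,
    pressure_mbar = params$pressure_mbar,
    axial_depth_um = depth,
    success = success, cell_id = cell_id
  )
}

# nearest apically attached cell whose apical-process foot lies within the
# capture radius of the insertion segment (surface -> injection point)
target_cell <- function(site, tissue, capture_um) {
  cells <- tissue$cells
  cand <- cells[as.logical(cells$apical_contact), , drop = FALSE]
  if (nrow(cand) == 0) {
    return(NA_character_)
  }
  a <- c(site$surface_x, site$surface_y)
  b <- c(site$inject_x, site$inject_y)
  ab <- b - a
  len2 <- max(sum(ab^2), .Machine$double.eps)
  # distance of each cell's apical foot (its surface anchor) to the segment:
  # use the cell's surface-projected position as the anchor
  foot <- cbind(cand$apical_x_um, cand$apical_y_um)
  t <- pmin(pmax(((foot[, 1] - a[1]) * ab[1] + (foot[, 2] - a[2]) * ab[2]) / len2, 0), 1)
  dx <- foot[, 1] - (a[1] + t * ab[1])
  dy <- foot[, 2] - (a[2] + t * ab[2])
  d <- sqrt(dx^2 + dy^2)
  if (min(d) > capture_um) {
    return(NA_character_)
  }
  as.character(cand$id[which.min(d)])
}

#' Execute a trajectory plan against the simulated hardware
#'
#' Runs every site of the plan in order: sets the line pressure once, then
#' for each site moves approach -> inject -> retract through the simulated
#' manipulator, drawing a stochastic outcome per attempt. Deterministic under
#' a fixed seed.
#'
#' @param plan A `trajectory_plan`.
#' @param model An [outcome_model()].
#' @param tissue Optional [virtual_tissue()].
#' @param seed Integer RNG seed (required for reproducible sessions).
#' @return A `session_log`: list with `attempts` (tibble), `duration_min`,
#'   `n_attempts`, `n_success`, `success_pct`, `attempts_per_min`,
#'   `successes_per_min`, `seed`.
#' @export
run_session <- function(plan, model, tissue = NULL, seed = NULL) {
  stopifnot(inherits(plan, "trajectory_plan"), inherits(model, "outcome_model"))
  if (!is.null(seed)) set.seed(seed)
  # pressure chain: constant setpoint, valve open for the whole sweep
  pc <- set_valve(set_pressure(pressure_chain(), plan$params$pressure_mbar), TRUE)
  stopifnot(pc$delivered_mbar == plan$params$pressure_mbar)
  inj_times <- plan$commands$t_s[plan$commands$kind == "inject"]
  attempts <- purrr::map_dfr(seq_len(nrow(plan$sites)), function(i) {
    attempt_injection(
      plan$sites[i, ], plan$params, model, tissue,
      t_s = inj_times[i]
    )
  })
  new_session_log(attempts, duration_min = max(plan$commands$t_s) / 60, seed = seed)
}

new_session_log <- function(attempts, duration_min, seed = NULL) {
  n <- nrow(attempts)
  s <- sum(attempts$success)
  structure(
    list(
      attempts = attempts,
      duration_min = duration_min,
      n_attempts = n,
      n_success = s,
      success_pct = if (n > 0) 100 * s / n else 0,
      attempts_per_min = if (duration_min > 0) n / duration_min else 0,
      successes_per_min = if (duration_min > 0) s / duration_min else 0,
      seed = seed
    ),
    class = "session_log"
  )
}

#' Build a session log from a raw attempt table
#'
#' @param attempts Data frame with at least a `success` column (and
#'   optionally `t_s`).
#' @param duration_min Session duration in minutes; defaults to the span of
#'   `t_s` when present.
#' @return A `session_log`.
#' @export
session_log <- function(attempts, duration_min = NULL) {
  attempts <- tibble::as_tibble(attempts)
  if (is.null(duration_min)) {
    duration_min <- if ("t_s" %in% names(attempts) && nrow(attempts) > 0) {
      max(attempts$t_s) / 60
    } else {
      0
    }
  }
  new_session_log(attempts, duration_min)
}

#' @export
print.session_log <- function(x, ...) {
  cat("<session_log>\n")
  cat(sprintf(
    "  %d attempts, %d successful (%.1f%%) in %.2f min\n  %.2f attempts/min, %.2f successes/min\n",
    x$n_attempts, x$n_success, x$success_pct, x$duration_min,
    x$attempts_per_min, x$successes_per_min
  ))
  invisible(x)
}

#' Tidy a session log
#'
#' @param x A `session_log`.
#' @param ... Unused.
#' @return The per-attempt tibble.
#' @method tidy session_log
#' @export
tidy.session_log <- function(x, ...) x$attempts

#' Glance at a session log
#'
#' @param x A `session_log`.
#' @param ... Unused.
#' @return One-row tibble of the session-level yield metrics.
#' @method glance session_log
#' @export
glance.session_log <- function(x, ...) {
  tibble::tibble(
    n_attempts = x$n_attempts, n_success = x$n_success,
    success_pct = x$success_pct, duration_min = x$duration_min,
    attempts_per_min = x$attempts_per_min,
    successes_per_min = x$successes_per_min
  )
}

#' Summarise sessions grouped by slice or condition
#'
#' Computes per-session yield metrics and then, per group, their mean and
#' standard deviation with each session (slice) weighted equally — the
#' conventional per-slice mean +/- sd reporting.
#'
#' @param logs A list of `session_log` objects.
#' @param groups Character/factor vector, one group label per log (a single
#'   group is assumed when omitted).
#' @return A tibble with one row per group and mean/sd columns for
#'   `success_pct`, `attempts_per_min` and `successes_per_min`.
#' @export
summarize_sessions <- function(logs, groups = NULL) {
  if (length(logs) == 0) stop("no session logs", call. = FALSE)
  if (inherits(logs, "session_log")) logs <- list(logs)
  if (is.null(groups)) groups <- rep("all", length(logs))
  stopifnot(length(groups) == length(logs))
  per <- purrr::map_dfr(logs, glance)
  per$group <- as.character(groups)
  per |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n_sessions = dplyr::n(),
      n_attempts = sum(.data$n_attempts),
      success_pct_mean = mean(.data$success_pct),
      success_pct_sd = sd0(.data$success_pct),
      attempts_per_min_mean = mean(.data$attempts_per_min),
      attempts_per_min_sd = sd0(.data$attempts_per_min),
      successes_per_min_mean = mean(.data$successes_per_min),
      successes_per_min_sd = sd0(.data$successes_per_min),
      .groups = "drop"
    )
}

sd0 <- function(x) if (length(x) <= 1) 0 else stats::sd(x)

#' Write a session log to CSV plus a summary JSON
#'
#' @param log A `session_log`.
#' @param csv_path Attempt-level CSV output path.
#' @param json_path Optional summary JSON path.
#' @return `csv_path`, invisibly.
#' @export
write_session_log <- function(log, csv_path, json_path = NULL) {
  stopifnot(inherits(log, "session_log"))
  readr::write_csv(log$attempts, csv_path)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      as.list(glance(log)),
      json_path,
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(csv_path)
}

#' @method autoplot session_log
#' @export
autoplot.session_log <- function(object, ...) {
  df <- object$attempts |>
    dplyr::mutate(cum_success = cumsum(.data$success))
  ggplot2::ggplot(df, ggplot2::aes(.data$t_s / 60, .data$cum_success)) +
    ggplot2::geom_step(colour = "steelblue") +
    ggplot2::labs(x = "time (min)", y = "cumulative successful injections") +
    ggplot2::theme_minimal()
}
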