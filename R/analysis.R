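#' Bin nucleus distances from the ventricular surface
#'
#' Distances of nucleus centres from the ventricular surface (defined as
#' 0 um) are binned into the standard nine half-open bins:
#' 0 to <20, 20 to <40, ..., 140 to <160, and >=160 micrometres.
#'
#' @param cells Data frame with a `distance_um` column (all values >= 0).
#' @return A tibble with one row per bin: `bin` (ordered factor label), `n`
#'   and `pct` (percent of total; sums to 100).
#' @export
bin_distances <- function(cells) {
  d <- tibble::as_tibble(cells)$distance_um
  if (is.null(d)) stop("cells must have a `distance_um` column", call. = FALSE)
  if (any(!is.finite(d)) || any(d < 0)) {
    stop("distances must be finite and >= 0", call. = FALSE)
  }
  breaks <- c(seq(0, 160, by = 20), Inf)
  labels <- c(sprintf("%d to <%d", seq(0, 140, 20), seq(20, 160, 20)), ">=160")
  bins <- cut(d, breaks = breaks, labels = labels, right = FALSE)
  counts <- table(bins)
  tibble::tibble(
    bin = factor(labels, levels = labels),
    n = as.integer(counts),
    pct = 100 * as.integer(counts) / length(d)
  )
}

#' Zone distribution of cells
#'
#' Percentage of cells residing in the ventricular zone (VZ), subventricular
#' zone (SVZ) and cortical plate (CP). Cells with unknown zone are excluded
#' from the denominator.
#'
#' @param cells Data frame with a `zone` column taking values in
#'   `c("VZ", "SVZ", "CP")` (others treated as unknown).
#' @return A tibble with `zone`, `n`, `pct` (percent of known-zone cells,
#'   sums to 100) and `pct_int` (nearest-integer percentage, the conventional
#'   reporting form).
#' @export
zone_distribution <- function(cells) {
  z <- as.character(tibble::as_tibble(cells)$zone)
  z <- z[z %in% c("VZ", "SVZ", "CP")]
  if (length(z) == 0) stop("no cells with a known zone", call. = FALSE)
  counts <- table(factor(z, levels = c("VZ", "SVZ", "CP")))
  tibble::tibble(
    zone = factor(c("VZ", "SVZ", "CP"), levels = c("VZ", "SVZ", "CP")),
    n = as.integer(counts),
    pct = 100 * as.integer(counts) / length(z),
    pct_int = round(100 * as.integer(counts) / length(z))
  )
}

#' Assign zones from distance thresholds
#'
#' When a cell table lacks histological zone calls, zones are assigned from
#' the nucleus distance to the ventricular surface using configurable
#' thresholds (defaults: VZ below 100 um, SVZ from 100 to below 160 um, CP
#' from 160 um).
#'
#' @param cells Data frame with `distance_um`.
#' @param vz_max,svz_max Upper (exclusive) distance bounds of VZ and SVZ.
#' @return `cells` with a `zone` column added (existing `zone` overwritten).
#' @export
assign_zones <- function(cells, vz_max = 100, svz_max = 160) {
  cells <- tibble::as_tibble(cells)
  stopifnot(vz_max < svz_max)
  cells$zone <- dplyr::case_when(
    cells$distance_um < vz_max ~ "VZ",
    cells$distance_um < svz_max ~ "SVZ",
    TRUE ~ "CP"
  )
  cells
}

#' Fraction of marker-positive cells
#'
#' Percentage of cells scoring positive for a marker among those with a
#' known (positive or negative) status; unknowns are excluded from the
#' denominator, matching the per-panel n's of immunostaining counts.
#'
#' @param cells Data frame.
#' @param marker Column name (string) holding `"pos"` / `"neg"` /
#'   `"unknown"` calls.
#' @param subset Optional logical vector (recycled rules apply) restricting
#'   the cells considered.
#' @return A one-row tibble: `marker`, `n_pos`, `n_known`, `pct`
#'   and `pct_int`.
#' @export
marker_fraction <- function(cells, marker, subset = NULL) {
  cells <- tibble::as_tibble(cells)
  if (!marker %in% names(cells)) {
    stop("no column `", marker, "` in cell table", call. = FALSE)
  }
  if (!is.null(subset)) cells <- cells[subset, ]
  status <- as.character(cells[[marker]])
  known <- status %in% c("pos", "neg")
  if (!any(known)) {
    stop("all `", marker, "` calls are unknown", call. = FALSE)
  }
  n_pos <- sum(status[known] == "pos")
  n_known <- sum(known)
  tibble::tibble(
    marker = marker, n_pos = n_pos, n_known = n_known,
    pct = 100 * n_pos / n_known, pct_int = round(100 * n_pos / n_known)
  )
}

#' Identify gap-junction coupled clusters from dye labels
#'
#' Cells positive for the junction-permeable dye are grouped by
#' single-linkage clustering in 3-D position, cutting the dendrogram at
#' `max_link_um`: two permeable cells belong to the same cluster if they are
#' connected by a chain of neighbours each within `max_link_um`. Each cluster
#' is then assigned to its injected member, identified by the
#' junction-impermeable dye (which cannot spread and therefore labels only
#' the injected cell). Clusters containing more than one impermeable-dye
#' cell violate uniqueness and are flagged rather than silently merged;
#' clusters with none are reported as orphans.
#'
#' @param cells Data frame with columns `id`, `x_um`, `y_um`, `z_um`,
#'   `dye_permeable`, `dye_impermeable` (logical or 0/1) and, optionally,
#'   `tbr2` (`"pos"`/`"neg"`/`"unknown"`) and `apical_contact` (logical).
#' @param max_link_um Single-linkage distance cutoff in micrometres. Default
#'   15 um, half the 30 um injection spacing, so that neighbouring injections
#'   cannot be merged into one cluster.
#' @return A tibble with one row per cluster: `cluster`, `size`, `members`
#'   (list of ids), `injected_id`, `n_impermeable`, `uniqueness_violated`,
#'   `tbr2_pos`, `apical_contact`. The ids of orphan clusters (no injected
#'   member) are attached as attribute `"orphans"`, with a warning.
#' @export
find_coupled_clusters <- function(cells, max_link_um = 15) {
  cells <- tibble::as_tibble(cells)
  need <- c("id", "x_um", "y_um", "z_um", "dye_permeable", "dye_impermeable")
  missing <- setdiff(need, names(cells))
  if (length(missing)) {
    stop("cell table lacks columns: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  perm <- cells[as.logical(cells$dye_permeable), ]
  if (nrow(perm) == 0) {
    return(structure(empty_clusters(), orphans = character(0)))
  }
  grp <- single_linkage_components(
    as.matrix(perm[, c("x_um", "y_um", "z_um")]), max_link_um
  )
  out <- perm |>
    dplyr::mutate(.cluster = grp) |>
    dplyr::group_by(.data$.cluster) |>
    dplyr::summarise(
      size = dplyr::n(),
      members = list(.data$id),
      injected_ids = list(.data$id[as.logical(.data$dye_impermeable)]),
      n_impermeable = sum(as.logical(.data$dye_impermeable)),
      tbr2_pos = if ("tbr2" %in% names(perm)) {
        sum(.data$tbr2 == "pos", na.rm = TRUE)
      } else {
        NA_integer_
      },
      apical_contact = if ("apical_contact" %in% names(perm)) {
        sum(as.logical(.data$apical_contact), na.rm = TRUE)
      } else {
        NA_integer_
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(
      cluster = dplyr::row_number(),
      injected_id = purrr::map_chr(
        .data$injected_ids,
        \(ids) if (length(ids) == 1) as.character(ids) else NA_character_
      ),
      uniqueness_violated = .data$n_impermeable > 1
    ) |>
    dplyr::select(
      "cluster", "size", "members", "injected_id", "n_impermeable",
      "uniqueness_violated", "tbr2_pos", "apical_contact"
    )
  orphans <- unlist(out$members[out$n_impermeable == 0])
  orphans <- if (is.null(orphans)) character(0) else as.character(orphans)
  if (length(orphans)) {
    warning(
      length(orphans), " permeable-dye cell(s) have no injected ",
      "(impermeable-dye) cell within linkage range",
      call. = FALSE
    )
  }
  structure(out, orphans = orphans)
}

# connected components of the <= h neighbour graph (equivalently, the
# single-linkage dendrogram cut at height h), via an x-sorted sweep and
# union-find so large tables never materialise an n x n distance matrix
single_linkage_components <- function(P, h) {
  n <- nrow(P)
  if (n == 1) {
    return(1L)
  }
  parent <- seq_len(n)
  find_root <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ord <- order(P[, 1])
  xs <- P[ord, 1]
  h2 <- h^2
  j0 <- 1
  for (k in 2:n) {
    while (xs[k] - xs[j0] > h) j0 <- j0 + 1
    if (j0 > k - 1) next
    for (j in j0:(k - 1)) {
      a <- ord[k]
      b <- ord[j]
      if (sum((P[a, ] - P[b, ])^2) <= h2) {
        ra <- find_root(a)
        rb <- find_root(b)
        if (ra != rb) parent[ra] <- rb
      }
    }
  }
  roots <- vapply(seq_len(n), find_root, integer(1))
  match(roots, unique(roots))
}

empty_clusters <- function() {
  tibble::tibble(
    cluster = integer(0), size = integer(0), members = list(),
    injected_id = character(0), n_impermeable = integer(0),
    uniqueness_violated = logical(0), tbr2_pos = integer(0),
    apical_contact = integer(0)
  )
}

#' Summary statistics over coupled clusters
#'
#' @param clusters Output of [find_coupled_clusters()].
#' @return A list with `fraction_coupled_pct` (percent of injected cells
#'   belonging to a cluster of size >= 2), `size_histogram` (tibble over
#'   sizes 1, 2, ..., 8+ as percent of clusters), `tbr2_pct` (percent
#'   Tbr2-positive among coupled cells) and `apical_contact_pct` (percent of
#'   coupled cells with an apical process).
#' @export
cluster_stats <- function(clusters) {
  clusters <- tibble::as_tibble(clusters)
  if (nrow(clusters) == 0) stop("no clusters", call. = FALSE)
  inj <- clusters[clusters$n_impermeable >= 1, ]
  n_injected <- sum(inj$n_impermeable)
  n_coupled_injected <- sum(inj$n_impermeable[inj$size >= 2])
  sizes <- pmin(clusters$size, 8)
  size_lab <- ifelse(sizes >= 8, "8+", as.character(sizes))
  lev <- c(as.character(1:7), "8+")
  hist <- table(factor(size_lab, levels = lev))
  coupled <- clusters[clusters$size >= 2, ]
  n_coupled_cells <- sum(coupled$size)
  list(
    fraction_coupled_pct = 100 * n_coupled_injected / n_injected,
    n_injected = n_injected,
    size_histogram = tibble::tibble(
      size = factor(lev, levels = lev),
      n = as.integer(hist),
      pct = 100 * as.integer(hist) / nrow(clusters)
    ),
    tbr2_pct = if (all(is.na(coupled$tbr2_pos)) || n_coupled_cells == 0) {
      NA_real_
    } else {
      100 * sum(coupled$tbr2_pos, na.rm = TRUE) / n_coupled_cells
    },
    apical_contact_pct = if (all(is.na(coupled$apical_contact)) ||
      n_coupled_cells == 0) {
      NA_real_
    } else {
      100 * sum(coupled$apical_contact, na.rm = TRUE) / n_coupled_cells
    }
  )
}

#' Pyknotic-nucleus density per region
#'
#' Cell-death readout: the number of pyknotic (condensed) nuclei per unit
#' area, computed per group label (e.g. slice or treatment).
#'
#' @param cells Data frame with logical `pyknotic` and a grouping column.
#' @param area_mm2 Region area in square millimetres (> 0); either a single
#'   value or one per group.
#' @param group Grouping column name (default `"group"`; a constant group is
#'   assumed when absent).
#' @return A tibble with `group`, `n_pyknotic`, `area_mm2`,
#'   `density_per_mm2`.
#' @export
pyknotic_density <- function(cells, area_mm2, group = "group") {
  cells <- tibble::as_tibble(cells)
  if (any(!is.finite(area_mm2)) || any(area_mm2 <= 0)) {
    stop("area must be positive", call. = FALSE)
  }
  if (!group %in% names(cells)) cells[[group]] <- "all"
  out <- cells |>
    dplyr::group_by(group = .data[[group]]) |>
    dplyr::summarise(n_pyknotic = sum(as.logical(.data$pyknotic)), .groups = "drop")
  out$area_mm2 <- area_mm2
  out$density_per_mm2 <- out$n_pyknotic / out$area_mm2
  out
}

#' Score injection success by dye/nucleus co-localization
#'
#' A nucleus counts as successfully injected when the fraction of its pixels
#' overlapped by the dye mask reaches `min_overlap_fraction`, mirroring the
#' co-localization criterion between the injected dextran dye and the DAPI
#' nuclear stain.
#'
#' @param dye_mask Logical (or 0/1) matrix of dye-positive pixels.
#' @param nucleus_mask Integer matrix of the same shape labelling nuclei
#'   (0 = background, 1..k = nucleus id), or a logical matrix for a single
#'   nucleus.
#' @param min_overlap_fraction Overlap threshold in [0, 1]; default 0.5.
#' @return A tibble with `nucleus`, `n_px`, `overlap_fraction`, `success`.
#' @export
colocalization_success <- function(dye_mask, nucleus_mask,
                                   min_overlap_fraction = 0.5) {
  if (!all(dim(dye_mask) == dim(nucleus_mask))) {
    stop("dye and nucleus masks must have the same shape", call. = FALSE)
  }
  dye <- dye_mask != 0
  labels <- if (is.logical(nucleus_mask)) {
    matrix(as.integer(nucleus_mask), nrow = nrow(nucleus_mask))
  } else {
    nucleus_mask
  }
  ids <- sort(unique(labels[labels > 0]))
  purrr::map_dfr(ids, function(i) {
    px <- labels == i
    ov <- sum(dye & px) / sum(px)
    tibble::tibble(
      nucleus = i, n_px = sum(px), overlap_fraction = ov,
      success = ov >= min_overlap_fraction
    )
  })
}

#' Summarise an injection-attempt log into a yield
#'
#' @param attempts Data frame with a logical/0-1 `success` column (one row
#'   per microinjection attempt).
#' @return A one-row tibble: `n_attempts`, `n_success`, `pct`, `pct_int`.
#' @export
yield_summary <- function(attempts) {
  attempts <- tibble::as_tibble(attempts)
  if (nrow(attempts) == 0) stop("empty attempt log", call. = FALSE)
  s <- sum(as.logical(attempts$success))
  tibble::tibble(
    n_attempts = nrow(attempts), n_success = s,
    pct = 100 * s / nrow(attempts),
    pct_int = round(100 * s / nrow(attempts))
  )
}

#' Read a cell table from CSV
#'
#' Columns follow the standard quantification schema: `id`, positions
#' (`x_um`, `y_um`, `z_um`), `distance_um`, `zone`, marker calls (`sox2`,
#' `tbr2`, `tuj1`, `reelin`, `satb2`, `rfp`, `edu` as pos/neg/unknown), dye
#' flags (`dye_permeable`, `dye_impermeable`, `dye_ly`), `apical_contact`,
#' `pyknotic`. Only the columns present are returned.
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_cell_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Plot a binned distance distribution
#'
#' @param bins Output of [bin_distances()].
#' @return A ggplot.
#' @export
plot_distance_bins <- function(bins) {
  ggplot2::ggplot(bins, ggplot2::aes(.data$bin, .data$pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "distance from ventricular surface (µm)",
      y = "% of cells"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a zone distribution
#'
#' @param zones Output of [zone_distribution()], optionally with a
#'   `timepoint` column bound on for faceting.
#' @return A ggplot.
#' @export
plot_zone_distribution <- function(zones) {
  p <- ggplot2::ggplot(zones, ggplot2::aes(.data$zone, .data$pct)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = NULL, y = "% of cells") +
    ggplot2::theme_minimal()
  if ("timepoint" %in% names(zones)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$timepoint))
  }
  p
}
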