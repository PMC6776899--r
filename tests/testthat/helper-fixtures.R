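# shared helpers for building synthetic calibrations and cell tables in code

# displacement pairs synthesised from a known scaled rotation, with optional
# annotation noise on the pixel side
synth_pairs <- function(theta, scale, deltas = NULL, noise_sd = 0) {
  if (is.null(deltas)) {
    deltas <- rbind(c(10, 0, 0), c(0, 10, 0), c(0, 0, 10), c(7, -3, 2))
  }
  M <- scale * rbind(
    c(cos(theta), -sin(theta), 0),
    c(sin(theta), cos(theta), 0)
  )
  px <- deltas %*% t(M)
  if (noise_sd > 0) px <- px + matrix(rnorm(length(px), 0, noise_sd), ncol = 2)
  tibble::tibble(
    dx_um = deltas[, 1], dy_um = deltas[, 2], dz_um = deltas[, 3],
    du_px = px[, 1], dv_px = px[, 2]
  )
}

straight_path <- function(length_px = 300) {
  annotated_path(tibble::tibble(u_px = c(0, length_px), v_px = c(0, 0)))
}

# independent oracle: connected components of the permeable-dye graph by BFS
# over the O(n^2) adjacency at the linkage radius
brute_force_components <- function(cells, max_link_um) {
  perm <- cells[as.logical(cells$dye_permeable), ]
  n <- nrow(perm)
  if (n == 0) {
    return(integer(0))
  }
  P <- as.matrix(perm[, c("x_um", "y_um", "z_um")])
  adj <- as.matrix(stats::dist(P)) <= max_link_um
  comp <- rep(NA_integer_, n)
  next_id <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    next_id <- next_id + 1L
    queue <- i
    comp[i] <- next_id
    while (length(queue)) {
      j <- queue[1]
      queue <- queue[-1]
      nb <- which(adj[j, ] & is.na(comp))
      comp[nb] <- next_id
      queue <- c(queue, nb)
    }
  }
  stats::setNames(comp, perm$id)
}

# canonical form of a partition (for comparing two labelings)
partition_canonical <- function(labels) {
  unname(lapply(
    split(names(labels), labels),
    sort
  ))[order(vapply(split(names(labels), labels), min, character(1)))]
}

cluster_labels_from_result <- function(clusters) {
  ids <- unlist(clusters$members)
  lab <- rep(clusters$cluster, clusters$size)
  stats::setNames(lab, ids)
}
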