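test_that("distance binning uses nine half-open 20 um bins", {
  one <- bin_distances(tibble::tibble(distance_um = 0))
  expect_equal(nrow(one), 9)
  expect_equal(one$pct[1], 100)
  # a cell at exactly 20 um falls in the second bin
  b <- bin_distances(tibble::tibble(distance_um = 20))
  expect_equal(as.character(b$bin[b$n == 1]), "20 to <40")
  # >= 160 collects the open tail
  b2 <- bin_distances(tibble::tibble(distance_um = c(160, 500)))
  expect_equal(b2$n[9], 2L)
  expect_error(bin_distances(tibble::tibble(distance_um = -1)), ">= 0")
})

test_that("uniform distances fill the bins uniformly and sum to 100", {
  set.seed(5)
  cells <- tibble::tibble(distance_um = runif(10000, 0, 180))
  b <- bin_distances(cells)
  expect_equal(sum(b$pct), 100, tolerance = 1e-9)
  expect_true(all(abs(b$pct - 100 / 9) < 1))
})

test_that("zone distributions match the printed lineage percentages", {
  vz_only <- tibble::tibble(zone = rep("VZ", 147))
  z0 <- zone_distribution(vz_only)
  expect_equal(z0$pct[z0$zone == "VZ"], 100)
  one_each <- zone_distribution(tibble::tibble(zone = c("VZ", "SVZ", "CP")))
  expect_equal(one_each$pct, rep(100 / 3, 3), tolerance = 1e-9)
  # 24 h counts: 47/89/15 of 151 are the smallest integers consistent with
  # the printed 31/59/10 percent
  t24 <- tibble::tibble(zone = rep(c("VZ", "SVZ", "CP"), c(47, 89, 15)))
  z24 <- zone_distribution(t24)
  expect_equal(z24$pct_int, c(31, 59, 10))
  expect_equal(sum(z24$pct), 100, tolerance = 1e-9)
  expect_error(zone_distribution(tibble::tibble(zone = character(0))), "known zone")
})

test_that("marker fractions exclude unknown calls from the denominator", {
  rfp <- tibble::tibble(rfp = rep(c("pos", "neg"), c(8, 9)))
  mf <- marker_fraction(rfp, "rfp")
  expect_equal(mf$pct_int, 47)
  expect_equal(mf$n_known, 17)
  tuj <- tibble::tibble(tuj1 = c(rep("neg", 13), rep("unknown", 4)))
  mt <- marker_fraction(tuj, "tuj1")
  expect_equal(mt$pct, 0)
  expect_equal(mt$n_known, 13)
  expect_equal(marker_fraction(tibble::tibble(m = rep("pos", 5)), "m")$pct, 100)
  expect_error(
    marker_fraction(tibble::tibble(m = rep("unknown", 3)), "m"),
    "unknown"
  )
  # subset predicate restricts the denominator
  df <- tibble::tibble(
    tbr2 = rep(c("pos", "neg"), 5),
    zone = rep(c("VZ", "CP"), each = 5)
  )
  sub <- marker_fraction(df, "tbr2", subset = df$zone == "VZ")
  expect_equal(sub$n_known, 5)
})

test_that("assign_zones applies the distance thresholds", {
  cells <- assign_zones(tibble::tibble(distance_um = c(0, 99.9, 100, 159.9, 160)))
  expect_equal(cells$zone, c("VZ", "VZ", "SVZ", "SVZ", "CP"))
})

test_that("a lone injected cell forms a size-1 (non-coupled) cluster", {
  cells <- tibble::tibble(
    id = "a", x_um = 0, y_um = 0, z_um = 0,
    dye_permeable = TRUE, dye_impermeable = TRUE
  )
  cl <- find_coupled_clusters(cells)
  expect_equal(cl$size, 1L)
  expect_equal(cl$injected_id, "a")
  expect_false(cl$uniqueness_violated)
})

test_that("a two-cell cluster has one impermeable-dye member", {
  cells <- tibble::tibble(
    id = c("inj", "partner"),
    x_um = c(0, 8), y_um = 0, z_um = 0,
    dye_permeable = TRUE,
    dye_impermeable = c(TRUE, FALSE)
  )
  cl <- find_coupled_clusters(cells, max_link_um = 15)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$size, 2L)
  expect_equal(cl$n_impermeable, 1L)
  expect_equal(cl$injected_id, "inj")
})

test_that("uniqueness violations are flagged and orphans warned about", {
  cells <- tibble::tibble(
    id = c("i1", "i2", "lonely"),
    x_um = c(0, 5, 100), y_um = 0, z_um = 0,
    dye_permeable = TRUE,
    dye_impermeable = c(TRUE, TRUE, FALSE)
  )
  expect_warning(cl <- find_coupled_clusters(cells), "no injected")
  merged <- cl[cl$size == 2, ]
  expect_true(merged$uniqueness_violated)
  expect_true(is.na(merged$injected_id))
  expect_equal(attr(cl, "orphans"), "lonely")
})

test_that("single-linkage clusters equal brute-force graph components", {
  set.seed(9)
  for (rep in 1:20) {
    n <- 200
    cells <- tibble::tibble(
      id = sprintf("c%03d", 1:n),
      x_um = runif(n, 0, 400), y_um = runif(n, 0, 100), z_um = runif(n, 0, 30),
      dye_permeable = runif(n) < 0.8,
      dye_impermeable = runif(n) < 0.3
    )
    link <- runif(1, 5, 25)
    cl <- suppressWarnings(find_coupled_clusters(cells, max_link_um = link))
    mine <- cluster_labels_from_result(cl)
    oracle <- brute_force_components(cells, link)
    expect_setequal(names(mine), names(oracle))
    expect_identical(
      partition_canonical(mine[order(names(mine))]),
      partition_canonical(oracle[order(names(oracle))])
    )
    # a true partition: disjoint and exhaustive over permeable cells
    expect_equal(sum(cl$size), sum(cells$dye_permeable))
    expect_equal(anyDuplicated(unlist(cl$members)), 0)
  }
})

test_that("cluster statistics recover the coupling benchmarks", {
  # 71 injected cells, 24 of them coupled (one-third), built explicitly
  rows <- list()
  for (i in 1:71) {
    coupled <- i <= 24
    rows[[i]] <- tibble::tibble(
      id = c(sprintf("i%02d", i), if (coupled) sprintf("i%02d_p", i)),
      x_um = (i - 1) * 30 + c(0, if (coupled) 6),
      y_um = 0, z_um = 0,
      dye_permeable = TRUE,
      dye_impermeable = c(TRUE, if (coupled) FALSE),
      tbr2 = "neg",
      apical_contact = TRUE
    )
  }
  cl <- find_coupled_clusters(dplyr::bind_rows(rows))
  st <- cluster_stats(cl)
  expect_equal(st$n_injected, 71)
  expect_equal(st$fraction_coupled_pct, 100 * 24 / 71, tolerance = 1e-9)
  expect_gte(round(st$fraction_coupled_pct), 33)
  expect_lte(round(st$fraction_coupled_pct), 34)
  # coupled-cell Tbr2 benchmark: 4 of 46 coupled cells positive -> 8.7%
  expect_equal(round(100 * 4 / 46, 1), 8.7)
  expect_equal(round(100 * 4 / 46), 9)
})

test_that("all-singleton cluster sets have zero coupled fraction", {
  cells <- tibble::tibble(
    id = sprintf("c%d", 1:5),
    x_um = (0:4) * 100, y_um = 0, z_um = 0,
    dye_permeable = TRUE, dye_impermeable = TRUE
  )
  st <- cluster_stats(find_coupled_clusters(cells))
  expect_equal(st$fraction_coupled_pct, 0)
  expect_equal(sum(st$size_histogram$n), 5)
})

test_that("pyknotic densities divide counts by area per group", {
  cells <- tibble::tibble(
    pyknotic = c(rep(TRUE, 5), rep(FALSE, 10)),
    group = "slice1"
  )
  pd <- pyknotic_density(cells, area_mm2 = 0.01)
  expect_equal(pd$density_per_mm2, 500)
  none <- pyknotic_density(
    tibble::tibble(pyknotic = FALSE, group = "g"),
    area_mm2 = 1
  )
  expect_equal(none$density_per_mm2, 0)
  expect_error(pyknotic_density(cells, area_mm2 = 0), "positive")
})

test_that("separated pyknotic-density groups give the exact p of 0.004", {
  # slice culture vs in vivo: 5 vs 5 slices, complete separation
  d <- tibble::tibble(
    group = rep(c("in_vivo", "slice"), each = 5),
    density = c(100, 120, 130, 140, 150, 300, 320, 330, 340, 350)
  )
  r <- rank_sum_exact(
    d$density[d$group == "in_vivo"], d$density[d$group == "slice"],
    alternative = "less"
  )
  expect_equal(round(r$p_value, 3), 0.004)
})

test_that("co-localization scoring thresholds the nucleus overlap", {
  m <- matrix(0L, 20, 20)
  m[5:14, 5:14] <- 1L # one 100-px nucleus
  full <- colocalization_success(m == 1, m)
  expect_true(full$success)
  expect_equal(full$overlap_fraction, 1)
  none <- colocalization_success(matrix(FALSE, 20, 20), m)
  expect_false(none$success)
  # dye covering 60 of 100 nucleus pixels: success at 0.5, failure at 0.7
  dye <- matrix(FALSE, 20, 20)
  dye[5:14, 5:10] <- TRUE
  at5 <- colocalization_success(dye, m, min_overlap_fraction = 0.5)
  at7 <- colocalization_success(dye, m, min_overlap_fraction = 0.7)
  expect_equal(at5$overlap_fraction, 0.6)
  expect_true(at5$success)
  expect_false(at7$success)
  expect_error(
    colocalization_success(matrix(FALSE, 2, 2), m),
    "same shape"
  )
})

test_that("yield summaries reproduce the published sweep percentages", {
  fixdir <- withr::local_tempdir()
  make_benchmark_fixtures(fixdir)
  expected <- list(
    pressure_75 = c(314, 110, 35),
    pressure_100 = c(185, 65, 35),
    pressure_125 = c(287, 23, 8),
    depth_10 = c(163, 111, 68),
    depth_15 = c(170, 37, 22),
    depth_25 = c(169, 19, 11)
  )
  for (nm in names(expected)) {
    log <- readr::read_csv(
      file.path(fixdir, paste0(nm, ".csv")),
      show_col_types = FALSE
    )
    ys <- yield_summary(log)
    expect_equal(ys$n_attempts, expected[[nm]][1])
    expect_equal(ys$n_success, expected[[nm]][2])
    expect_equal(ys$pct_int, expected[[nm]][3])
  }
})
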