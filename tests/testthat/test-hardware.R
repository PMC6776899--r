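test_that("the pressure chain delivers the setpoint only with the valve open", {
  pc <- pressure_chain()
  expect_equal(pc$mechanical_setpoint_mbar, 340)
  pc <- set_pressure(pc, 75)
  expect_equal(pc$delivered_mbar, 0) # valve still closed
  pc <- set_valve(pc, TRUE)
  expect_equal(pc$delivered_mbar, 75)
  pc <- set_pressure(pc, 0)
  expect_equal(pc$delivered_mbar, 0)
  expect_error(set_pressure(pc, 300), "\\[0, 250\\]")
  expect_error(set_pressure(pc, -5), "\\[0, 250\\]")
})

test_that("delivered pressure never escapes {0, setpoint} or [0, 250]", {
  pc <- pressure_chain()
  set.seed(2)
  for (i in 1:50) {
    p <- runif(1, 0, 250)
    pc <- set_pressure(pc, p)
    pc <- set_valve(pc, runif(1) < 0.5)
    expect_true(pc$delivered_mbar %in% c(0, pc$electronic_setpoint_mbar))
    expect_gte(pc$delivered_mbar, 0)
    expect_lte(pc$delivered_mbar, 250)
    expect_lte(pc$electronic_setpoint_mbar, pc$mechanical_setpoint_mbar)
  }
})

test_that("manipulator moves take distance/speed and arrive exactly", {
  mv <- move_to(c(0, 0, 0), c(100, 0, 0), speed_um_s = 100)
  expect_equal(attr(mv, "duration_s"), 1.0)
  expect_identical(
    unname(unlist(mv[nrow(mv), c("x_um", "y_um", "z_um")])),
    c(100, 0, 0)
  )
  z <- move_to(c(5, 5, 5), c(5, 5, 5), speed_um_s = 100)
  expect_equal(attr(z, "duration_s"), 0)
  expect_equal(nrow(z), 1)
  expect_error(move_to(c(0, 0, 0), c(1e5, 0, 0)), "travel limits")
})

test_that("piecewise move durations are additive", {
  A <- c(0, 0, 0)
  B <- c(30, 40, 0)
  C <- c(30, 40, 120)
  v <- 250
  d1 <- attr(move_to(A, B, v), "duration_s")
  d2 <- attr(move_to(B, C, v), "duration_s")
  expect_equal(d1 + d2, (50 + 120) / v, tolerance = 1e-12)
})

test_that("signed tissue depth follows the perpendicular geometry", {
  tissue <- virtual_tissue(
    tibble::tibble(x_um = c(0, 100), y_um = c(0, 0)),
    interior_side = "left"
  )
  expect_equal(depth_in_tissue(c(50, 0, 0), tissue), 0)
  # 10 um advance along an axis 45 deg off the normal: 7.07 um deep
  adv <- 10 * injection_axis(c(0, 1, 0), c(1, 0, 0), 45)
  expect_equal(
    depth_in_tissue(c(50 + adv[1], adv[2], 0), tissue),
    10 * cos(pi / 4),
    tolerance = 1e-9
  )
  # a 20 um pullout along the same axis sits 14.14 um outside
  back <- -20 * injection_axis(c(0, 1, 0), c(1, 0, 0), 45)
  expect_equal(
    depth_in_tissue(c(50 + back[1], back[2], 0), tissue),
    -20 * cos(pi / 4),
    tolerance = 1e-9
  )
})

test_that("noiseless frames put the blob centroid on the ground-truth tip", {
  tissue <- virtual_tissue(
    tibble::tibble(x_um = c(-100, 100), y_um = c(10, 10)),
    interior_side = "left"
  )
  ct <- make_transform(0, 1)
  cam <- camera_model(width_px = 200, height_px = 200)
  fr <- render_frame(tissue, c(10, -20, 0), cam, ct, noise_sd = 0)
  expect_true(fr$tip_in_fov)
  cen <- frame_centroid(fr)
  expect_equal(unname(cen["u_px"]), unname(fr$tip_px["u_px"]), tolerance = 0.1)
  expect_equal(unname(cen["v_px"]), unname(fr$tip_px["v_px"]), tolerance = 0.1)
  # edge band lies along the projected surface polyline
  mid <- fr$image[, 100] # column at u = 99
  edge_rows <- which(mid >= 150) - 1
  surf_v <- fr$surface_px$v_px[1]
  expect_lte(min(abs(edge_rows - surf_v)), 0.5)
})

test_that("tissue interior renders brighter than background on the correct side", {
  tissue <- virtual_tissue(
    tibble::tibble(x_um = c(-100, 100), y_um = c(0, 0)),
    interior_side = "left"
  )
  fr <- render_frame(
    tissue, c(500, 500, 0), camera_model(), make_transform(0, 1)
  )
  expect_false(fr$tip_in_fov)
  # interior ("left" of +x travel) is +y, i.e. rows below the centre line
  expect_equal(unname(fr$image[150, 100]), 80) # inside tissue
  expect_equal(unname(fr$image[50, 100]), 30) # background
})

test_that("noisy frames keep the centroid within 2 px of the truth", {
  tissue <- virtual_tissue(
    tibble::tibble(x_um = c(-100, 100), y_um = c(30, 30)),
    interior_side = "left"
  )
  cam <- camera_model()
  ct <- make_transform(0, 1)
  set.seed(12)
  errs <- replicate(20, {
    fr <- render_frame(tissue, c(-5, -15, 0), cam, ct, noise_sd = 50)
    cen <- frame_centroid(fr)
    sqrt(sum((cen - fr$tip_px)^2))
  })
  expect_lt(max(errs), 2)
})

test_that("rendered depth agrees with stage-space depth through the transform", {
  tissue <- virtual_tissue(
    tibble::tibble(x_um = c(-100, 100), y_um = c(0, 0)),
    interior_side = "left"
  )
  ct <- make_transform(0.25, 1.4)
  cam <- camera_model(width_px = 300, height_px = 300)
  for (tip in list(c(0, 12, 0), c(20, -8, 0), c(-30, 25, 0))) {
    fr <- render_frame(tissue, tip, cam, ct)
    # depth implied by the rendered pixel position: signed pixel distance to
    # the projected surface divided by the scale
    d_px <- microinjectr:::signed_distance_polyline(
      matrix(fr$tip_px, ncol = 2),
      as.matrix(fr$surface_px),
      tissue$interior_side
    )
    expect_equal(
      abs(d_px) / ct$scale,
      abs(depth_in_tissue(tip, tissue)),
      tolerance = 0.5
    )
  }
})

test_that("frames round-trip to PNG with a lossless ground-truth sidecar", {
  skip_if_not_installed("png")
  tissue <- virtual_tissue(
    tibble::tibble(x_um = c(-100, 100), y_um = c(0, 0)),
    interior_side = "left"
  )
  fr <- render_frame(
    tissue, c(5, -10, 0), camera_model(), make_transform(0, 1)
  )
  f <- withr::local_tempfile(fileext = ".png")
  write_frame(fr, f)
  img <- png::readPNG(f)
  expect_equal(dim(img), c(200, 200))
  side <- jsonlite::read_json(paste0(f, ".json"), simplifyVector = TRUE)
  expect_equal(side$tip_px$u_px, unname(fr$tip_px["u_px"]), tolerance = 1e-12)
})
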