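test_that("axis-aligned calibration recovers scale 2 and theta 0", {
  pairs <- tibble::tibble(
    dx_um = c(10, 0, 0), dy_um = c(0, 10, 0), dz_um = c(0, 0, 10),
    du_px = c(20, 0, 0), dv_px = c(0, 20, 0)
  )
  ct <- estimate_transform(pairs)
  expect_equal(ct$scale, 2, tolerance = 1e-12)
  expect_equal(ct$theta, 0, tolerance = 1e-12)
  expect_lt(ct$residual_rms, 1e-10)
})

test_that("rotated calibration recovers the generating angle", {
  th <- 30 * pi / 180
  pairs <- synth_pairs(th, 1, deltas = rbind(c(10, 0, 0), c(0, 10, 0)))
  ct <- estimate_transform(pairs)
  expect_equal(ct$theta, th, tolerance = 1e-6)
  expect_equal(ct$scale, 1, tolerance = 1e-9)
  fp <- forward_project(c(10, 0, 0), ct)
  expect_equal(fp$du_px, 10 * cos(th), tolerance = 1e-9)
  expect_equal(fp$dv_px, 10 * sin(th), tolerance = 1e-9)
})

test_that("theta recovery is exact to 1e-9 rad across the full circle", {
  for (th in seq(-pi + 0.05, pi, length.out = 13)) {
    ct <- estimate_transform(synth_pairs(th, 1.7))
    expect_equal(ct$theta, th, tolerance = 1e-9)
  }
})

test_that("collinear or degenerate displacement sets fail loudly", {
  one <- tibble::tibble(
    dx_um = 10, dy_um = 0, dz_um = 0, du_px = 20, dv_px = 0
  )
  expect_error(estimate_transform(one), "at least 2")
  collinear <- tibble::tibble(
    dx_um = c(10, 20, 30), dy_um = 0, dz_um = 0,
    du_px = c(20, 40, 60), dv_px = 0
  )
  expect_error(estimate_transform(collinear), "collinear")
  zero <- tibble::tibble(
    dx_um = c(0, 10), dy_um = c(0, 0), dz_um = c(0, 0),
    du_px = c(0, 20), dv_px = c(0, 0)
  )
  expect_error(estimate_transform(zero), "zero stage displacement")
})

test_that("forward projection handles trivial and z-only displacements", {
  ct <- make_transform(0, 2)
  expect_equal(
    forward_project(c(0, 0, 0), ct),
    tibble::tibble(du_px = 0, dv_px = 0)
  )
  expect_equal(
    forward_project(c(10, 0, 0), ct),
    tibble::tibble(du_px = 20, dv_px = 0)
  )
  # z column of a pure scaled rotation is zero: focus moves do not shift pixels
  expect_equal(unlist(forward_project(c(0, 0, 50), ct)), c(du_px = 0, dv_px = 0))
})

test_that("pixel targeting round-trips through the forward map", {
  expect_equal(
    pixel_to_stage(
      c(50, 60), c(50, 60), c(1, 2, 3),
      make_transform(0.4, 1.3)
    ),
    tibble::tibble(x_um = 1, y_um = 2, z_um = 3)
  )
  st <- pixel_to_stage(c(120, 100), c(100, 100), c(0, 0, 5), make_transform(0, 2))
  expect_equal(unlist(st), c(x_um = 10, y_um = 0, z_um = 5))
  set.seed(11)
  for (i in 1:25) {
    ct <- make_transform(runif(1, -pi, pi), runif(1, 0.3, 4))
    cur_px <- runif(2, 0, 500)
    cur_st <- runif(3, -100, 100)
    target <- runif(2, 0, 500)
    st <- pixel_to_stage(target, cur_px, cur_st, ct)
    achieved <- forward_project(
      c(st$x_um - cur_st[1], st$y_um - cur_st[2], 0), ct
    )
    expect_equal(cur_px[1] + achieved$du_px, target[1], tolerance = 1e-6)
    expect_equal(cur_px[2] + achieved$dv_px, target[2], tolerance = 1e-6)
    expect_equal(st$z_um, cur_st[3])
  }
})

test_that("noise raises the residual monotonically and leaves theta unbiased", {
  th <- 0.6
  rms_at <- function(sd, seed) {
    set.seed(seed)
    mean(replicate(40, estimate_transform(synth_pairs(th, 1, noise_sd = sd))$residual_rms))
  }
  r0 <- rms_at(0, 1)
  r1 <- rms_at(0.2, 2)
  r2 <- rms_at(0.8, 3)
  expect_lt(r0, r1)
  expect_lt(r1, r2)
  set.seed(4)
  thetas <- replicate(
    200,
    estimate_transform(synth_pairs(th, 1, noise_sd = 0.3))$theta
  )
  se <- sd(thetas) / sqrt(length(thetas))
  expect_lt(abs(mean(thetas) - th), 3 * se)
})

test_that("independently perturbed annotators give indistinguishable thetas", {
  # three synthetic operators re-annotate the same moves with i.i.d. click
  # noise; pairwise exact rank-sum on their fitted angles should show no
  # location difference
  th <- 0.35
  fit_thetas <- function(seed) {
    set.seed(seed)
    replicate(8, estimate_transform(synth_pairs(th, 1.2, noise_sd = 0.25))$theta)
  }
  ops <- lapply(c(101, 202, 303), fit_thetas)
  ps <- c(
    rank_sum_exact(ops[[1]], ops[[2]])$p_value,
    rank_sum_exact(ops[[1]], ops[[3]])$p_value,
    rank_sum_exact(ops[[2]], ops[[3]])$p_value
  )
  expect_true(all(ps > 0.05))
})

test_that("positioning error is zero for perfect moves and tracks noise", {
  ct <- make_transform(0.2, 2)
  pts <- tibble::tibble(u_px = runif(8, 0, 500), v_px = runif(8, 0, 500))
  pe <- positioning_error(pts, pts, ct)
  expect_equal(pe$mean_abs_um, c(0, 0))
  expect_equal(pe$sd_abs_um, c(0, 0))

  # Gaussian annotation noise of sigma um per stage coordinate gives a
  # half-normal per-axis absolute error with mean sigma * sqrt(2 / pi)
  sigma <- 0.4
  set.seed(7)
  n <- 1000
  commanded <- tibble::tibble(u_px = runif(n, 0, 500), v_px = runif(n, 0, 500))
  err_um <- matrix(rnorm(2 * n, 0, sigma), ncol = 2)
  err_px <- err_um %*% t(ct$matrix[, 1:2])
  achieved <- tibble::tibble(
    u_px = commanded$u_px + err_px[, 1],
    v_px = commanded$v_px + err_px[, 2]
  )
  pe <- positioning_error(commanded, achieved, ct)
  expected <- sigma * sqrt(2 / pi)
  expect_equal(pe$mean_abs_um[1], expected, tolerance = 0.1)
  expect_equal(pe$mean_abs_um[2], expected, tolerance = 0.1)
  # realism bound: simulated positioning error stays well under a micron
  expect_true(all(pe$mean_abs_um <= 1))
  expect_error(
    positioning_error(pts[0, ], pts[0, ], ct),
    "at least one"
  )
})

test_that("transforms serialize to JSON and back losslessly", {
  ct <- estimate_transform(synth_pairs(0.8, 1.9))
  f <- withr::local_tempfile(fileext = ".json")
  write_transform(ct, f)
  ct2 <- read_transform(f)
  expect_equal(ct2$matrix, ct$matrix, tolerance = 1e-12)
  expect_equal(ct2$theta, ct$theta, tolerance = 1e-12)
  expect_equal(ct2$scale, ct$scale, tolerance = 1e-12)
})

test_that("tidy and glance expose the fitted calibration quantities", {
  ct <- estimate_transform(synth_pairs(0.5, 2))
  td <- tidy(ct)
  expect_true(all(c("theta_rad", "scale_px_per_um") %in% td$term))
  gl <- glance(ct)
  expect_equal(gl$scale_px_per_um, 2, tolerance = 1e-9)
  expect_equal(gl$n_pairs, 4L)
})
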