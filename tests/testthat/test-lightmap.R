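# Light-intensity recovery from photobleaching: dF/F0, bleach-constant fit,
# exponential inversion, spatial summaries.

test_that("ROI detection finds well-separated spots at their centers", {
  dims <- c(40, 40, 20)
  blank <- array(0, dims)
  expect_equal(nrow(extract_roi_intensities(blank, voxel_um = 5)), 0L)
  expect_error(extract_roi_intensities(blank, voxel_um = NULL),
               "voxel-size")

  centers <- rbind(c(8, 8, 5), c(30, 8, 10), c(8, 30, 15),
                   c(30, 30, 5), c(20, 20, 10))
  stack <- array(0.1, dims)  # flat background b = 0.1
  amp <- 1
  for (i in seq_len(nrow(centers))) {
    cc <- centers[i, ]
    for (dx in -2:2) for (dy in -2:2) for (dz in -2:2)
      stack[cc[1] + dx, cc[2] + dy, cc[3] + dz] <-
      stack[cc[1] + dx, cc[2] + dy, cc[3] + dz] +
      amp * exp(-(dx^2 + dy^2 + dz^2) / 2)
  }
  rois <- extract_roi_intensities(stack, voxel_um = 5, roi_radius_um = 6)
  expect_equal(nrow(rois), 5L)
  # detected positions within one voxel of the planted centers
  planted <- sweep(sweep(centers - 1, 2, c(5, 5, 5), "*"), 2,
                   c(-(dims[1] - 1) / 2 * 5, -(dims[2] - 1) / 2 * 5, 0), "+")
  found <- as.matrix(rois[, c("x_um", "y_um", "z_um")])
  for (i in seq_len(5))
    expect_lte(min(sqrt(rowSums(sweep(found, 2, planted[i, ], "-")^2))), 5)
  # ROI intensity bounded by background and peak amplitude
  expect_true(all(rois$F > 0.1 & rois$F < 0.1 + amp))
})

test_that("compute_dff uses far ROIs as baseline", {
  df <- data.frame(x_um = c(0, 800, 900), y_um = 0, z_um = c(0, 0, 0),
                   F = c(40, 100, 100))
  rois <- roi_table(df)
  out <- compute_dff(rois, 700)
  expect_equal(attr(out, "F0"), 100)
  expect_equal(out$f[1], -0.6)
  expect_equal(out$f[2:3], c(0, 0))

  # equal intensities -> f = 0 everywhere
  flat <- compute_dff(roi_table(transform(df, F = 70)), 700)
  expect_true(all(flat$f == 0))

  # no far ROIs -> actionable error
  near <- roi_table(data.frame(x_um = c(0, 100), y_um = 0, z_um = 0,
                               F = c(1, 2)))
  expect_error(compute_dff(near, 700), "field of view|f0")

  # lateral-distance mode agrees when far ROIs are far laterally
  out_lat <- compute_dff(rois, 700, mode = "lateral")
  expect_equal(attr(out_lat, "F0"), attr(out, "F0"))
  # ...and differs when the far set is deep but on-axis
  deep <- roi_table(data.frame(x_um = c(0, 0, 800), y_um = 0,
                               z_um = c(0, 900, 0), F = c(40, 90, 100)))
  expect_equal(attr(compute_dff(deep, 700), "F0"), 95)
  expect_equal(attr(compute_dff(deep, 700, mode = "lateral"), "F0"), 100)
})

test_that("fit_bleach_constant recovers k from the exponential dose model", {
  doses <- c(50, 100, 200)
  f_exact <- -1 + exp(-0.01 * doses)
  expect_equal(f_exact, c(-0.3935, -0.6321, -0.8647), tolerance = 1e-4)
  fit <- fit_bleach_constant(data.frame(dose = doses, f = f_exact))
  expect_equal(fit$k, 0.01, tolerance = 1e-6)
  # model passes through the origin: dose 0 -> f = 0 consistent
  fit0 <- fit_bleach_constant(data.frame(dose = c(0, doses),
                                         f = c(0, f_exact)))
  expect_equal(fit0$k, 0.01, tolerance = 1e-6)

  expect_error(fit_bleach_constant(data.frame(dose = 50, f = -0.4)),
               "2 distinct doses")
  expect_error(fit_bleach_constant(data.frame(dose = doses, f = c(0, 0.1, 0.2))),
               "no bleaching signal")

  # 5% multiplicative noise on f: k recovered within 10%
  set.seed(11)
  d <- rep(c(25, 50, 100, 200, 400), each = 8)
  f_noisy <- (-1 + exp(-0.01 * d)) * rnorm(length(d), 1, 0.05)
  fitn <- fit_bleach_constant(data.frame(dose = d, f = f_noisy))
  expect_equal(fitn$k, 0.01, tolerance = 0.1)
})

test_that("invert_intensity inverts the exponential pointwise", {
  # f = exp(-1) - 1 at known ROIs: unnormalized intensity k*I*T = 1
  set.seed(3)
  n <- 600
  pos <- cbind(runif(n, -200, 200), runif(n, -200, 200), runif(n, 0, 400))
  kIT <- 2 * exp(-pos[, 3] / 150)
  df <- data.frame(x_um = pos[, 1], y_um = pos[, 2], z_um = pos[, 3],
                   F = 100 * exp(-kIT))
  rois <- compute_dff(roi_table(df), f0 = 100)
  expect_equal(-log1p(rois$f), kIT, tolerance = 1e-10)

  lf <- invert_intensity(rois, voxel_um = 50)
  expect_s3_class(lf, "light_field")
  expect_equal(max(lf$grid), 1)
  expect_true(all(lf$grid >= 0))

  # f = 0 -> I = 0; f <= -0.99 excluded and counted
  mix <- compute_dff(roi_table(data.frame(
    x_um = c(0, 50, 100, 0), y_um = 0, z_um = c(0, 0, 0, 50),
    F = c(100 * exp(-1), 100, 0.5, 50))), f0 = 100)
  lf2 <- invert_intensity(mix, voxel_um = 50)
  expect_equal(attr(lf2, "n_excluded"), 1L)

  flat <- compute_dff(roi_table(data.frame(x_um = 1:5, y_um = 0, z_um = 0,
                                           F = rep(80, 5))), f0 = 100)
  expect_error(invert_intensity(flat), "flat")
})

test_that("inversion is monotone and invariant to fluorescence scale", {
  f <- seq(-0.95, 0, by = 0.05)
  intensity <- -log1p(f)
  expect_true(all(diff(intensity) < 0))  # larger |f| => larger I

  set.seed(4)
  df <- data.frame(x_um = runif(300, -200, 200), y_um = runif(300, -200, 200),
                   z_um = runif(300, 0, 300), F = runif(300, 10, 100))
  r1 <- compute_dff(roi_table(df), f0 = 60)
  r2 <- compute_dff(roi_table(transform(df, F = F * 7.3)), f0 = 60 * 7.3)
  expect_equal(r1$f, r2$f, tolerance = 1e-12)
  lf1 <- invert_intensity(r1, voxel_um = 50)
  lf2 <- invert_intensity(r2, voxel_um = 50)
  expect_equal(lf1$grid, lf2$grid, tolerance = 1e-9)
})

test_that("forward-inverse round trip recovers the field on a 20^3 grid", {
  field_fn <- gauss_exp_field(200, 150)
  vol <- make_nuclei_volume(100000, c(500, 500, 500), seed = 9,
                            baseline_cv = 0)
  rois <- bleach_forward(vol, field_fn, k_dose = 0.01, dose = 200,
                         noise_cv = 0)
  dff <- compute_dff(rois, f0 = 100)
  lf <- invert_intensity(dff, voxel_um = 25)
  expect_equal(dim(lf$grid), c(20, 20, 20))
  ax <- optospread:::light_field_axes(lf)
  truth <- outer(ax$x, ax$y, function(x, y) exp(-(x^2 + y^2) / (2 * 150^2)))
  truth <- outer(as.vector(truth), exp(-ax$z / 200))
  dim(truth) <- c(20, 20, 20)
  # recovery is defined up to a global scale: fit it, then bound the error
  sc <- sum(lf$grid * truth) / sum(truth^2)
  expect_lt(max(abs(lf$grid / sc - truth)), 0.05)
})

test_that("profile_summary matches closed-form half-max distances", {
  # analytic separable field laid onto a light_field grid
  nx <- 41; nz <- 61; vox <- 25
  xax <- (seq_len(nx) - (nx + 1) / 2) * vox
  zax <- (seq_len(nz) - 1) * vox
  g <- array(0, c(nx, nx, nz))
  for (iz in seq_len(nz))
    g[, , iz] <- outer(xax, xax, function(x, y)
      exp(-(x^2 + y^2) / (2 * 114.7^2))) * exp(-zax[iz] / 433)
  lf <- light_field(g, vox, c(xax[1], xax[1], 0))
  ps <- profile_summary(lf)
  expect_equal(ps$half_max_depth_um, 433 * log(2), tolerance = 0.01)
  expect_equal(ps$lateral_half_width_um, 114.7 * sqrt(2 * log(2)),
               tolerance = 0.03)

  uniform <- light_field(array(1, c(5, 5, 5)), 25, c(-50, -50, 0))
  expect_error(profile_summary(uniform), "uniform|never falls")
})

test_that("bootstrap s.e.m. of half-max depth shrinks roughly as 1/sqrt(n)", {
  field_fn <- gauss_exp_field(433, 114.7)
  boot_sem <- function(n_rois, seed) {
    vol <- make_nuclei_volume(n_rois, c(1200, 1200, 1000), seed = seed)
    rois <- bleach_forward(vol, field_fn, k_dose = 3 / 200, dose = 200,
                           noise_cv = 0.1, seed = seed + 1)
    dff <- compute_dff(rois, 700)
    stat <- function(sub) {
      lf <- invert_intensity(sub, voxel_um = 50)
      profile_summary(lf)$half_max_depth_um
    }
    reps <- vapply(1:40, function(b) {
      set.seed(seed * 100 + b)
      idx <- sample.int(nrow(dff), nrow(dff), replace = TRUE)
      sub <- dff[idx, ]
      class(sub) <- class(dff)
      tryCatch(stat(sub), error = function(e) NA_real_)
    }, numeric(1))
    stats::sd(reps, na.rm = TRUE)
  }
  s_small <- boot_sem(4000, 21)
  s_large <- boot_sem(16000, 22)
  expect_lt(s_large, s_small)
})
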