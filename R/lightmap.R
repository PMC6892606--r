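# Recovery of the 3-D relative light-intensity profile in tissue from
# photobleaching of nuclear fluorophores, and summaries of its spatial extent.
#
# Model: bleaching is exponential in light dose, f(r) = -1 + exp(-k I(r) T),
# where f = dF/F0, I the relative light intensity and T the dose; hence
# I(r) is proportional to -log(f(r) + 1). The proportionality constant is
# absorbed by normalizing the recovered field to 1 at its maximum.

#' ROI fluorescence table
#'
#' Per-nucleus fluorescence measurements positioned relative to the laser
#' center (x = y = 0 at the surface, z positive downward, um).
#'
#' @param df data frame with columns `x_um`, `y_um`, `z_um`, `F` (F >= 0).
#' @param dose_mw_min light dose metadata (mW min).
#' @param wavelength_nm wavelength metadata (nm).
#' @return The validated data frame with class `roi_table`.
#' @export
roi_table <- function(df, dose_mw_min = NA_real_, wavelength_nm = NA_real_) {
  need <- c("x_um", "y_um", "z_um", "F")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("roi_table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(as.matrix(df[need]))))
    stop("roi_table coordinates and F must be finite", call. = FALSE)
  if (any(df$F < 0)) stop("roi_table fluorescence must be >= 0", call. = FALSE)
  structure(df, class = c("roi_table", "data.frame"),
            dose_mw_min = dose_mw_min, wavelength_nm = wavelength_nm)
}

#' Detect nuclei and measure ROI intensities in an image stack
#'
#' Nuclei are detected as local intensity maxima above a background-relative
#' threshold; the ROI intensity is the mean over a fixed-radius sphere around
#' each detected center. Intended for confocal-style stacks of
#' nuclear-targeted fluorophores.
#'
#' @param image_stack 3-D numeric array (x, y, z).
#' @param voxel_um voxel size in um: scalar or length-3 `(dx, dy, dz)`.
#'   Required; stacks carry no physical scale of their own.
#' @param origin_um position of the `[1, 1, 1]` voxel center relative to the
#'   laser center (um). Default places the laser center mid-stack laterally
#'   and the first plane at the surface.
#' @param threshold detection threshold as a fraction above background
#'   (median intensity); a voxel is a candidate when its value exceeds
#'   `background + threshold * (max - background)`.
#' @param roi_radius_um averaging-sphere radius (um), default 5.
#' @param min_separation_um minimum distance between detected centers.
#' @return An `roi_table` of detected nuclei.
#' @export
extract_roi_intensities <- function(image_stack, voxel_um,
                                    origin_um = NULL,
                                    threshold = 0.25,
                                    roi_radius_um = 5,
                                    min_separation_um = 10) {
  if (!is.array(image_stack) || length(dim(image_stack)) != 3L)
    stop("`image_stack` must be a 3-D array", call. = FALSE)
  if (missing(voxel_um) || is.null(voxel_um))
    stop("voxel-size metadata (`voxel_um`) is required", call. = FALSE)
  if (length(voxel_um) == 1L) voxel_um <- rep(voxel_um, 3L)
  stopifnot(is.numeric(voxel_um), length(voxel_um) == 3L, all(voxel_um > 0))
  d <- dim(image_stack)
  if (is.null(origin_um))
    origin_um <- c(-(d[1] - 1) / 2 * voxel_um[1],
                   -(d[2] - 1) / 2 * voxel_um[2], 0)

  bg <- stats::median(image_stack)
  hi <- max(image_stack)
  cut <- bg + threshold * (hi - bg)
  cand <- which(image_stack > cut, arr.ind = TRUE)
  empty <- roi_table(data.frame(x_um = numeric(0), y_um = numeric(0),
                                z_um = numeric(0), F = numeric(0)))
  if (nrow(cand) == 0L || hi <= bg) return(empty)

  # local maximum within the 26-neighborhood
  is_max <- vapply(seq_len(nrow(cand)), function(i) {
    ix <- cand[i, 1L]; iy <- cand[i, 2L]; iz <- cand[i, 3L]
    nb <- image_stack[max(1, ix - 1):min(d[1], ix + 1),
                      max(1, iy - 1):min(d[2], iy + 1),
                      max(1, iz - 1):min(d[3], iz + 1)]
    image_stack[ix, iy, iz] >= max(nb)
  }, logical(1))
  pk <- cand[is_max, , drop = FALSE]
  if (nrow(pk) == 0L) return(empty)

  # greedy non-maximum suppression by brightness
  pos <- sweep(sweep(pk - 1, 2L, voxel_um, "*"), 2L, origin_um, "+")
  val <- image_stack[pk]
  ord <- order(val, decreasing = TRUE)
  keep <- integer(0)
  for (i in ord) {
    if (length(keep) == 0L ||
        min(sqrt(rowSums(sweep(pos[keep, , drop = FALSE], 2L, pos[i, ],
                               "-")^2))) >= min_separation_um)
      keep <- c(keep, i)
  }
  pk <- pk[keep, , drop = FALSE]
  pos <- pos[keep, , drop = FALSE]

  # mean over a sphere of roi_radius_um around each center
  rad_vox <- ceiling(roi_radius_um / voxel_um)
  f_mean <- vapply(seq_len(nrow(pk)), function(i) {
    ctr <- pk[i, ]
    xr <- max(1, ctr[1] - rad_vox[1]):min(d[1], ctr[1] + rad_vox[1])
    yr <- max(1, ctr[2] - rad_vox[2]):min(d[2], ctr[2] + rad_vox[2])
    zr <- max(1, ctr[3] - rad_vox[3]):min(d[3], ctr[3] + rad_vox[3])
    gg <- expand.grid(x = xr, y = yr, z = zr)
    dist2 <- ((gg$x - ctr[1]) * voxel_um[1])^2 +
      ((gg$y - ctr[2]) * voxel_um[2])^2 +
      ((gg$z - ctr[3]) * voxel_um[3])^2
    inside <- dist2 <= roi_radius_um^2
    mean(image_stack[as.matrix(gg[inside, , drop = FALSE])])
  }, numeric(1))

  roi_table(data.frame(x_um = pos[, 1L], y_um = pos[, 2L], z_um = pos[, 3L],
                       F = f_mean))
}

#' Compute per-ROI fractional fluorescence change (dF/F0)
#'
#' The unbleached baseline `F0` is the mean fluorescence of all ROIs farther
#' than `far_threshold_um` from the laser center; each ROI then gets
#' `f = (F - F0) / F0`. Bleached ROIs have negative `f`. Distance is 3-D
#' Euclidean by default; `mode = "lateral"` uses lateral distance only, the
#' convention used when bleaching near the center is close to complete and
#' deep on-axis ROIs cannot be trusted as baseline.
#'
#' @param rois an `roi_table`.
#' @param far_threshold_um baseline distance cutoff (um), default 700.
#' @param mode `"3d"` or `"lateral"` far-ROI distance convention.
#' @param f0 explicit baseline fluorescence, bypassing the far-ROI average.
#' @return The input table with columns `distance_um`, `lateral_um` and `f`
#'   added; `F0` and the baseline ROI count are attached as attributes.
#' @export
compute_dff <- function(rois, far_threshold_um = 700,
                        mode = c("3d", "lateral"), f0 = NULL) {
  stopifnot(inherits(rois, "roi_table"))
  mode <- match.arg(mode)
  lateral <- sqrt(rois$x_um^2 + rois$y_um^2)
  dist3 <- sqrt(lateral^2 + rois$z_um^2)
  dref <- if (mode == "lateral") lateral else dist3
  if (is.null(f0)) {
    far <- dref > far_threshold_um
    if (!any(far))
      stop("no ROIs beyond ", far_threshold_um,
           " um: enlarge the field of view or supply `f0` explicitly",
           call. = FALSE)
    f0 <- mean(rois$F[far])
    n_far <- sum(far)
  } else {
    check_scalar(f0, "f0", lower = 0, strict_lower = TRUE)
    n_far <- 0L
  }
  out <- rois
  out$distance_um <- dist3
  out$lateral_um <- lateral
  out$f <- (rois$F - f0) / f0
  attr(out, "F0") <- f0
  attr(out, "n_far_rois") <- n_far
  out
}

#' Fit the bleach constant from center dF/F0 versus light dose
#'
#' Least-squares fit of the exponential dose model `f = -1 + exp(-k * dose)`
#' to paired (dose, f) observations taken near the laser center, one pair per
#' light dose. Separate fits per fluorophore/wavelength are expected.
#'
#' @param center_dff_by_dose data frame or matrix with columns `dose` (mW min)
#'   and `f` (dF/F0, negative under bleaching).
#' @return A `bleach_fit`: list with `k` (per mW min), `residuals`,
#'   `n_points`, `dose_range`.
#' @examples
#' d <- c(50, 100, 200)
#' fit_bleach_constant(data.frame(dose = d, f = -1 + exp(-0.01 * d)))
#' @export
fit_bleach_constant <- function(center_dff_by_dose) {
  df <- as.data.frame(center_dff_by_dose)
  if (!all(c("dose", "f") %in% names(df)))
    stop("need columns `dose` and `f`", call. = FALSE)
  df <- df[is.finite(df$dose) & is.finite(df$f), ]
  if (length(unique(df$dose)) < 2L)
    stop("need at least 2 distinct doses to fit the bleach constant",
         call. = FALSE)
  if (all(df$f >= 0))
    stop("no bleaching signal: all dF/F0 values are >= 0", call. = FALSE)
  # linearized start: -log(f + 1) = k * dose
  usable <- df$f > -1 & df$dose > 0
  k0 <- stats::median(-log(df$f[usable] + 1) / df$dose[usable])
  if (!is.finite(k0) || k0 <= 0) k0 <- 1e-3
  fit <- stats::nls(f ~ -1 + exp(-k * dose), data = df,
                    start = list(k = k0), algorithm = "port",
                    lower = list(k = 1e-12))
  k <- unname(stats::coef(fit)["k"])
  structure(list(k = k, residuals = stats::resid(fit), n_points = nrow(df),
                 dose_range = range(df$dose), fit = fit),
            class = "bleach_fit")
}

#' @export
print.bleach_fit <- function(x, ...) {
  cat(sprintf("Bleach fit: k = %.4g per mW*min (%d points, dose %g-%g, RMS resid %.3g)\n",
              x$k, x$n_points, x$dose_range[1], x$dose_range[2],
              sqrt(mean(x$residuals^2))))
  invisible(x)
}

#' @export
coef.bleach_fit <- function(object, ...) c(k = object$k)

#' Light-field grid constructor
#'
#' 3-D grid of relative light intensity normalized to 1 at its maximum, with
#' the origin at the laser center (axes in um, z positive downward).
#'
#' @param grid 3-D numeric array.
#' @param voxel_um voxel edge length (um).
#' @param origin_um coordinates of the `[1, 1, 1]` voxel center (um).
#' @return A `light_field`.
#' @export
light_field <- function(grid, voxel_um, origin_um) {
  stopifnot(is.array(grid), length(dim(grid)) == 3L)
  check_scalar(voxel_um, "voxel_um", lower = 0, strict_lower = TRUE)
  stopifnot(length(origin_um) == 3L)
  m <- max(grid, na.rm = TRUE)
  if (!is.finite(m) || m <= 0)
    stop("light field must contain positive intensity", call. = FALSE)
  structure(list(grid = grid / m, voxel_um = voxel_um,
                 origin_um = as.numeric(origin_um)),
            class = "light_field")
}

#' @export
print.light_field <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("Light field: %d x %d x %d grid, %g um voxels (max-normalized)\n",
              d[1], d[2], d[3], x$voxel_um))
  invisible(x)
}

# axis coordinates of a light_field
light_field_axes <- function(lf) {
  d <- dim(lf$grid)
  list(x = lf$origin_um[1] + (seq_len(d[1]) - 1) * lf$voxel_um,
       y = lf$origin_um[2] + (seq_len(d[2]) - 1) * lf$voxel_um,
       z = lf$origin_um[3] + (seq_len(d[3]) - 1) * lf$voxel_um)
}

# nearest-voxel lookup (clamped at the edges); pos is an n x 3 matrix in um
light_field_lookup <- function(lf, pos) {
  d <- dim(lf$grid)
  idx <- sapply(1:3, function(k) {
    i <- round((pos[, k] - lf$origin_um[k]) / lf$voxel_um) + 1
    pmin(pmax(i, 1), d[k])
  })
  lf$grid[cbind(idx[, 1], idx[, 2], idx[, 3])]
}

#' Invert dF/F0 measurements to a relative light-intensity field
#'
#' Under the exponential dose model the relative light intensity at an ROI is
#' proportional to `-log(f + 1)`. ROI-wise intensities are averaged into
#' cubic voxels (default 25 um), empty voxels are filled by iterative
#' inverse-distance averaging over the six face-adjacent neighbors, and the
#' field is normalized to 1 at its maximum. ROIs with `f <= clip_f` (near
#' complete bleach, where the log diverges) are excluded and counted.
#' Negative recovered intensities (unbleached ROIs whose noise puts f > 0)
#' are clamped to zero.
#'
#' @param dff_map output of [compute_dff()] (an `roi_table` with column `f`).
#' @param fit optional [fit_bleach_constant()] result; only used for metadata
#'   (normalization removes the k*T scale).
#' @param voxel_um voxel size of the output grid (um), default 25.
#' @param clip_f exclusion threshold for near-complete bleach, default -0.99.
#' @return A `light_field`; the number of excluded ROIs is attached as
#'   attribute `n_excluded`.
#' @export
invert_intensity <- function(dff_map, fit = NULL, voxel_um = 25,
                             clip_f = -0.99) {
  stopifnot(inherits(dff_map, "roi_table"), "f" %in% names(dff_map))
  check_scalar(voxel_um, "voxel_um", lower = 0, strict_lower = TRUE)
  f <- dff_map$f
  if (max(f) - min(f) < 1e-12)
    stop("flat dF/F0 field: relative intensity is undefined", call. = FALSE)
  drop <- f <= clip_f
  n_excluded <- sum(drop)
  use <- !drop
  intensity <- pmax(-log1p(f[use]), 0)

  pos <- cbind(dff_map$x_um[use], dff_map$y_um[use], dff_map$z_um[use])
  lo <- apply(pos, 2L, min); hi <- apply(pos, 2L, max)
  # voxel k spans [corner + (k-1) vox, corner + k vox); centers at +vox/2
  corner <- floor(lo / voxel_um) * voxel_um
  dims <- pmax(ceiling((hi - corner) / voxel_um), 1)
  origin <- corner + voxel_um / 2
  idx <- sapply(1:3, function(k)
    pmin(pmax(floor((pos[, k] - corner[k]) / voxel_um) + 1, 1), dims[k]))

  lin <- (idx[, 3] - 1) * dims[1] * dims[2] + (idx[, 2] - 1) * dims[1] + idx[, 1]
  sums <- array(0, dims); cnts <- array(0, dims)
  tab_sum <- rowsum(intensity, lin)
  tab_cnt <- rowsum(rep(1, length(lin)), lin)
  cells <- as.integer(rownames(tab_sum))
  sums[cells] <- tab_sum; cnts[cells] <- tab_cnt
  grid <- ifelse(cnts > 0, sums / pmax(cnts, 1), NA_real_)
  grid <- fill_empty_voxels(grid)

  out <- light_field(grid, voxel_um, origin)
  attr(out, "n_excluded") <- n_excluded
  attr(out, "bleach_fit") <- fit
  out
}

# iterative fill of NA voxels by averaging nonempty face-adjacent neighbors
fill_empty_voxels <- function(grid, max_pass = 200L) {
  d <- dim(grid)
  shift <- function(a, axis, by) {
    out <- array(NA_real_, d)
    ix <- lapply(d, seq_len)
    src <- ix; dst <- ix
    if (by == 1L) { src[[axis]] <- 1:(d[axis] - 1); dst[[axis]] <- 2:d[axis] }
    else { src[[axis]] <- 2:d[axis]; dst[[axis]] <- 1:(d[axis] - 1) }
    if (d[axis] < 2L) return(out)
    out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
    out
  }
  for (pass in seq_len(max_pass)) {
    nas <- is.na(grid)
    if (!any(nas)) break
    acc <- array(0, d); cnt <- array(0, d)
    for (axis in 1:3) for (by in c(1L, -1L)) {
      nb <- shift(grid, axis, by)
      ok <- !is.na(nb)
      acc[ok] <- acc[ok] + nb[ok]
      cnt[ok] <- cnt[ok] + 1
    }
    fill <- nas & cnt > 0
    grid[fill] <- acc[fill] / cnt[fill]
    if (!any(is.na(grid))) break
  }
  if (any(is.na(grid))) grid[is.na(grid)] <- 0
  grid
}

#' Summarize the spatial extent of a light field
#'
#' Computes the axial and lateral 50% fall-off distances of a recovered
#' light field: `half_max_depth_um` is the depth at which the on-axis
#' intensity first falls to half its surface value, and
#' `lateral_half_width_um` is the lateral distance, at `reference_depth_um`,
#' at which intensity falls to half the on-axis value at that depth, both by
#' linear interpolation between grid planes.
#'
#' Numerical conventions, chosen for gridded fields estimated from sparse
#' noisy ROIs: the on-axis profile is the mean over voxels within
#' `axis_radius_um` of the beam axis (for a laterally separable field this
#' rescales all depths equally and cancels in the ratios), lightly smoothed
#' with a 3-plane running mean before crossing detection; the surface
#' reference value is a log-linear extrapolation of the near-surface profile
#' to z = 0, and the on-axis reference at the lateral comparison depth is a
#' log-linear-in-r^2 extrapolation of the inner radial profile to r = 0.
#' Both extrapolations are exact for exponential (axial) and Gaussian
#' (lateral) profiles and avoid the edge bias of reading a single voxel
#' plane. The lateral profile is a radial average in voxel-width annuli over
#' a 5-plane slab centered on the reference depth.
#'
#' The on-axis disc radius defaults to half the field's own lateral
#' half-width at the surface (bounded below by 60 um): for a laterally
#' separable field any disc radius leaves the axial ratios unchanged, and
#' scaling the disc to the beam width keeps the per-plane estimate
#' well-averaged for broad fields.
#'
#' @param field a `light_field`.
#' @param reference_depth_um depth of the lateral profile (um), default 200.
#' @param axis_radius_um lateral radius defining "on-axis" voxels (um);
#'   `NULL` (default) adapts it to the surface lateral half-width.
#' @return List with `half_max_depth_um`, `lateral_half_width_um`,
#'   `surface_intensity`, `axis_radius_um`, `axial_profile` and
#'   `lateral_profile` data frames.
#' @export
profile_summary <- function(field, reference_depth_um = 200,
                            axis_radius_um = NULL) {
  stopifnot(inherits(field, "light_field"))
  ax <- light_field_axes(field)
  d <- dim(field$grid)
  lat2 <- outer(ax$x^2, ax$y^2, "+")
  if (is.null(axis_radius_um)) {
    surf_lat <- radial_mean_profile(field, lat2,
                                    seq_len(min(3L, d[3])))
    ctr <- loglin_extrapolate(surf_lat$r_um^2, surf_lat$intensity, n_fit = 5L)
    w_surf <- first_downward_crossing(surf_lat$r_um, surf_lat$intensity,
                                      ctr / 2)
    axis_radius_um <- if (is.na(w_surf)) 60 else max(60, w_surf / 2)
  }
  on_axis <- sqrt(lat2) <= max(axis_radius_um, field$voxel_um * 0.75)
  if (!any(on_axis))
    stop("no voxels on or near the beam axis; check the field origin",
         call. = FALSE)
  axial_raw <- vapply(seq_len(d[3]), function(iz)
    mean(field$grid[, , iz][on_axis]), numeric(1))
  axial <- running_mean3(axial_raw)
  axial_df <- data.frame(z_um = ax$z, intensity = axial)

  # surface value: log-linear extrapolation of the near-surface decay to
  # z = 0, fitted on the raw profile (the running mean distorts the edge)
  surf <- loglin_extrapolate(ax$z, axial_raw, n_fit = 6L)
  if (max(axial) - min(axial) < 1e-12)
    stop("uniform light field: no half-max crossing", call. = FALSE)
  half_depth <- first_downward_crossing(ax$z, axial, surf / 2)
  if (is.na(half_depth))
    stop(sprintf(
      "on-axis intensity never falls below half its surface value; half-max depth exceeds %g um",
      max(ax$z)), call. = FALSE)
  # refine the crossing by local log-linear regression: attenuation with
  # depth is locally exponential, so regressing log intensity on depth over
  # the planes bracketing the crossing pools their information instead of
  # relying on two noisy neighboring planes
  sel <- which(axial_raw > 0.25 * surf & axial_raw < 0.75 * surf &
                 abs(ax$z - half_depth) <= max(4 * field$voxel_um,
                                               0.5 * half_depth))
  if (length(sel) >= 3L) {
    co <- stats::coef(stats::lm(log(axial_raw[sel]) ~ ax$z[sel]))
    refined <- (log(surf / 2) - co[[1L]]) / co[[2L]]
    if (is.finite(refined) && co[[2L]] < 0 &&
        refined > 0 && refined <= max(ax$z))
      half_depth <- refined
  }

  iz_ref <- which.min(abs(ax$z - reference_depth_um))
  slab <- max(1L, iz_ref - 2L):min(d[3], iz_ref + 2L)
  lateral_df <- radial_mean_profile(field, lat2, slab)
  # on-axis value at the reference depth: log-linear-in-r^2 extrapolation
  center_val <- loglin_extrapolate(lateral_df$r_um^2, lateral_df$intensity,
                                   n_fit = 5L)
  half_lat <- first_downward_crossing(lateral_df$r_um, lateral_df$intensity,
                                      center_val / 2)
  if (is.na(half_lat))
    stop(sprintf(
      "lateral intensity never falls below half the on-axis value; half width exceeds %g um",
      max(lateral_df$r_um)), call. = FALSE)

  list(half_max_depth_um = half_depth,
       lateral_half_width_um = half_lat,
       surface_intensity = surf,
       axis_radius_um = axis_radius_um,
       axial_profile = axial_df,
       lateral_profile = lateral_df)
}

# radially averaged intensity profile (voxel-width annuli) over a z-slab
radial_mean_profile <- function(field, lat2, slab) {
  plane <- apply(field$grid[, , slab, drop = FALSE], c(1L, 2L), mean)
  bins <- floor(sqrt(lat2) / field$voxel_um)
  prof <- tapply(as.vector(plane), as.vector(bins), mean)
  data.frame(r_um = (as.numeric(names(prof)) + 0.5) * field$voxel_um,
             intensity = as.numeric(prof))
}

# running mean of window 3 with shortened edge windows
running_mean3 <- function(y) {
  n <- length(y)
  if (n < 3L) return(y)
  out <- y
  out[2:(n - 1)] <- (y[1:(n - 2)] + y[2:(n - 1)] + y[3:n]) / 3
  out[1L] <- mean(y[1:2]); out[n] <- mean(y[(n - 1):n])
  out
}

# extrapolate y(x) to x = 0 by a least-squares line on log(y) over the first
# n_fit points; falls back to the first value for flat/degenerate profiles
loglin_extrapolate <- function(x, y, n_fit = 5L) {
  sel <- seq_len(min(n_fit, length(y)))
  sel <- sel[y[sel] > 0]
  if (length(sel) < 2L) return(y[1L])
  co <- stats::coef(stats::lm(log(y[sel]) ~ x[sel]))
  val <- exp(co[[1L]])
  if (!is.finite(val)) y[1L] else val
}

#' @export
plot.light_field <- function(x, z_um = 0, ...) {
  ax <- light_field_axes(x)
  iz <- which.min(abs(ax$z - z_um))
  graphics::image(ax$x, ax$y, x$grid[, , iz],
                  xlab = "x (um)", ylab = "y (um)",
                  main = sprintf("Relative light intensity, z = %g um",
                                 ax$z[iz]), ...)
  invisible(x)
}
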