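# Synthetic moving-sphere phantom: fillable spheres of known volume and
# activity concentration on a PET-like grid, imaged through a simple
# forward model (partial-volume rasterization -> Gaussian point-spread
# blurring -> signal-dependent additive noise), with optional sinusoidal
# cranio-caudal motion averaged over the acquisition.

#' Specification of the synthetic sphere phantom
#'
#' Defaults emulate a standard fillable-sphere motion phantom: spheres of
#' 3, 12 and 26 ccm filled at 1.2 MBq/ccm, imaged on a 128 x 128 matrix
#' with 5 mm slices, smoothed with a 5 mm Gaussian post-filter, and driven
#' sinusoidally in the cranio-caudal (z) direction with 15 mm maximal
#' amplitude at 12 cycles per minute.
#'
#' @param volumes_ccm sphere volumes in ccm (default `c(3, 12, 26)`).
#' @param centers_mm optional n x 3 matrix of sphere centers in mm
#'   (world coordinates; the grid corner is at 0). When `NULL`, spheres are
#'   laid out along y at mid-x/mid-z with generous separation.
#' @param activity activity concentration inside the spheres (MBq/ccm,
#'   default 1.2).
#' @param background background activity concentration (default 0:
#'   watery spheres against a cold background; set > 0 for lesion-in-tissue
#'   scenarios).
#' @param matrix_size in-plane matrix (default 128).
#' @param pixel_mm in-plane pixel size (default 4 mm; a 128 matrix with a
#'   typical ~51 cm field of view).
#' @param slice_mm slice thickness (default 5 mm).
#' @param n_slices number of slices (default 32).
#' @param fwhm_mm FWHM of the Gaussian post-reconstruction filter
#'   (default 5 mm; 0 disables blurring).
#' @param amplitude_mm maximal (peak-to-peak) motion amplitude in z
#'   (default 15 mm).
#' @param freq_cpm motion frequency in cycles per minute (default 12,
#'   i.e. a 5 s respiratory period).
#' @param noise_coef standard deviation of the additive Gaussian noise as a
#'   fraction of the local blurred intensity (default 0.04).
#' @param noise_floor absolute noise-SD floor in activity units
#'   (default 0.01), so cold regions are not noise-free.
#' @param n_phases number of motion phases averaged for the blurred
#'   acquisition (default 32).
#' @param seed RNG seed for the noise realization (default 1).
#' @return A validated `phantom_spec` object.
#' @export
phantom_spec <- function(volumes_ccm = c(3, 12, 26),
                         centers_mm = NULL,
                         activity = 1.2,
                         background = 0,
                         matrix_size = 128L,
                         pixel_mm = 4,
                         slice_mm = 5,
                         n_slices = 32L,
                         fwhm_mm = 5,
                         amplitude_mm = 15,
                         freq_cpm = 12,
                         noise_coef = 0.04,
                         noise_floor = 0.01,
                         n_phases = 32L,
                         seed = 1L) {
  volumes_ccm <- as.numeric(volumes_ccm)
  if (!length(volumes_ccm) || any(volumes_ccm <= 0))
    stop("sphere volumes must be positive", call. = FALSE)
  matrix_size <- as.integer(matrix_size); n_slices <- as.integer(n_slices)
  if (matrix_size < 8L || n_slices < 4L) stop("grid too small", call. = FALSE)
  if (pixel_mm <= 0 || slice_mm <= 0) stop("voxel sizes must be positive", call. = FALSE)
  if (fwhm_mm < 0 || amplitude_mm < 0 || freq_cpm <= 0)
    stop("fwhm_mm/amplitude_mm must be >= 0 and freq_cpm > 0", call. = FALSE)
  if (noise_coef < 0 || noise_floor < 0) stop("noise parameters must be >= 0", call. = FALSE)
  n_phases <- as.integer(n_phases)
  if (n_phases < 1L) stop("`n_phases` must be >= 1", call. = FALSE)
  r <- sphere_radius_mm(volumes_ccm)
  fov <- c(matrix_size * pixel_mm, matrix_size * pixel_mm, n_slices * slice_mm)
  if (is.null(centers_mm)) {
    n <- length(volumes_ccm)
    ys <- fov[2] * (seq_len(n)) / (n + 1)
    centers_mm <- cbind(fov[1] / 2, ys, fov[3] / 2)
  }
  centers_mm <- matrix(as.numeric(centers_mm), ncol = 3L)
  if (nrow(centers_mm) != length(volumes_ccm))
    stop("one center per sphere required", call. = FALSE)
  # spheres must not overlap, and must stay inside the grid over the full
  # motion excursion
  n <- nrow(centers_mm)
  if (n > 1L) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (sqrt(sum((centers_mm[i, ] - centers_mm[j, ])^2)) <= r[i] + r[j])
        stop("spheres overlap", call. = FALSE)
    }
  }
  exc <- amplitude_mm / 2
  for (i in seq_len(n)) {
    if (any(centers_mm[i, ] - r[i] - c(0, 0, exc) < 0) ||
        any(centers_mm[i, ] + r[i] + c(0, 0, exc) > fov))
      stop("sphere ", i, " (with motion excursion) exceeds the image grid", call. = FALSE)
  }
  structure(list(volumes_ccm = volumes_ccm, centers_mm = centers_mm,
                 activity = activity, background = background,
                 matrix_size = matrix_size, pixel_mm = pixel_mm,
                 slice_mm = slice_mm, n_slices = n_slices,
                 fwhm_mm = fwhm_mm, amplitude_mm = amplitude_mm,
                 freq_cpm = freq_cpm, noise_coef = noise_coef,
                 noise_floor = noise_floor, n_phases = n_phases,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> spheres %s ccm at %.2g MBq/ccm, grid %dx%dx%d (%gx%gx%g mm)\n",
              paste(x$volumes_ccm, collapse = "/"), x$activity,
              x$matrix_size, x$matrix_size, x$n_slices,
              x$pixel_mm, x$pixel_mm, x$slice_mm))
  cat(sprintf("  PSF %g mm FWHM, motion %g mm @ %g cpm, noise %g (floor %g), seed %d\n",
              x$fwhm_mm, x$amplitude_mm, x$freq_cpm,
              x$noise_coef, x$noise_floor, x$seed))
  invisible(x)
}

#' Sphere radius from volume
#'
#' @param volume_ccm volume(s) in ccm.
#' @return Radius in mm: `(3 V / (4 pi))^(1/3)` with V in mm^3.
#' @export
sphere_radius_mm <- function(volume_ccm) (3 * volume_ccm * 1000 / (4 * pi))^(1 / 3)

phantom_spacing <- function(spec) c(spec$pixel_mm, spec$pixel_mm, spec$slice_mm)
phantom_dim <- function(spec) c(spec$matrix_size, spec$matrix_size, spec$n_slices)
# voxel centers: world coordinate of voxel i along an axis is (i - 1/2)*step,
# i.e. origin = spacing / 2
phantom_origin <- function(spec) phantom_spacing(spec) / 2

#' Ground-truth mask of one phantom sphere
#'
#' Voxels whose centers lie within the analytic sphere.
#'
#' @param spec a [phantom_spec()].
#' @param index which sphere (1-based).
#' @return A logical mask on the phantom grid.
#' @export
truth_mask <- function(spec, index) {
  stopifnot(inherits(spec, "phantom_spec"))
  index <- as.integer(index)
  if (index < 1L || index > length(spec$volumes_ccm))
    stop("sphere index out of range", call. = FALSE)
  d <- phantom_dim(spec)
  sp <- phantom_spacing(spec)
  ctr <- spec$centers_mm[index, ]
  r <- sphere_radius_mm(spec$volumes_ccm[index])
  dx2 <- ((seq_len(d[1]) - 0.5) * sp[1] - ctr[1])^2
  dy2 <- ((seq_len(d[2]) - 0.5) * sp[2] - ctr[2])^2
  dz2 <- ((seq_len(d[3]) - 0.5) * sp[3] - ctr[3])^2
  D2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
  array(D2 <= r^2, d)
}

#' Voxel index of a sphere center
#'
#' Convenience accessor used to place segmentation seeds.
#'
#' @inheritParams truth_mask
#' @return Integer length-3 voxel index of the voxel containing the center.
#' @export
sphere_center_voxel <- function(spec, index) {
  stopifnot(inherits(spec, "phantom_spec"))
  sp <- phantom_spacing(spec)
  pmax(1L, pmin(phantom_dim(spec),
                as.integer(ceiling(spec$centers_mm[index, ] / sp))))
}

# Analytic activity map rasterized onto the grid with partial-volume
# fractions: voxels fully inside a sphere get the sphere activity, voxels
# crossing the surface get a sub-sampled (sub^3 points) inside fraction.
rasterize_activity <- function(spec, z_shift = 0, sub = 4L) {
  d <- phantom_dim(spec)
  sp <- phantom_spacing(spec)
  arr <- array(spec$background, d)
  xc <- (seq_len(d[1]) - 0.5) * sp[1]
  yc <- (seq_len(d[2]) - 0.5) * sp[2]
  zc <- (seq_len(d[3]) - 0.5) * sp[3]
  half_diag <- sqrt(sum((sp / 2)^2))
  # sub-voxel offsets (centers of sub^3 sub-cells)
  offs <- as.matrix(expand.grid(
    ( (seq_len(sub) - 0.5) / sub - 0.5) * sp[1],
    ( (seq_len(sub) - 0.5) / sub - 0.5) * sp[2],
    ( (seq_len(sub) - 0.5) / sub - 0.5) * sp[3]))
  for (s in seq_along(spec$volumes_ccm)) {
    r <- sphere_radius_mm(spec$volumes_ccm[s])
    ctr <- spec$centers_mm[s, ] + c(0, 0, z_shift)
    ix <- which(abs(xc - ctr[1]) <= r + half_diag)
    iy <- which(abs(yc - ctr[2]) <= r + half_diag)
    iz <- which(abs(zc - ctr[3]) <= r + half_diag)
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (xc[ix] - ctr[1])^2
    dy2 <- (yc[iy] - ctr[2])^2
    dz2 <- (zc[iz] - ctr[3])^2
    D <- sqrt(outer(outer(dx2, dy2, `+`), dz2, `+`))
    frac <- array(0, dim(D))
    frac[D <= r - half_diag] <- 1
    shell <- which(D > r - half_diag & D < r + half_diag)
    if (length(shell)) {
      si <- arrayInd(shell, dim(D))
      px <- xc[ix][si[, 1]]; py <- yc[iy][si[, 2]]; pz <- zc[iz][si[, 3]]
      cnt <- numeric(length(shell))
      for (o in seq_len(nrow(offs))) {
        cnt <- cnt + (( (px + offs[o, 1] - ctr[1])^2 +
                        (py + offs[o, 2] - ctr[2])^2 +
                        (pz + offs[o, 3] - ctr[3])^2 ) <= r^2)
      }
      frac[shell] <- cnt / nrow(offs)
    }
    arr[ix, iy, iz] <- arr[ix, iy, iz] + (spec$activity - spec$background) * frac
  }
  arr
}

# Separable Gaussian convolution with zero padding; kernels are integrated
# (pnorm differences) and normalized to sum 1, so mass is conserved away
# from the grid edges.
gaussian_blur <- function(arr, sigma_vox) {
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    r <- max(1L, as.integer(ceiling(4 * s)))
    k <- diff(stats::pnorm(seq(-r - 0.5, r + 0.5, by = 1), sd = s))
    k <- k / sum(k)
    out <- array(0, dim(arr))
    for (t in -r:r) {
      d <- integer(3); d[ax] <- t
      out <- out + k[t + r + 1L] * shift_mask(arr, d)
    }
    arr <- out
  }
  arr
}

# seed = NULL draws from the current RNG stream (caller manages the seed)
add_noise <- function(arr, noise_coef, noise_floor, seed) {
  if (noise_coef == 0 && noise_floor == 0) return(arr)
  if (!is.null(seed)) set.seed(seed)
  sd <- noise_coef * pmax(arr, 0) + noise_floor
  arr + array(stats::rnorm(length(arr), 0, sd), dim(arr))
}

# Noiseless forward model shared by the static and motion-blurred
# acquisitions: rasterize (time-averaged over phases if moving), then blur.
phantom_noiseless <- function(spec, moving = FALSE) {
  if (!moving || spec$amplitude_mm == 0) {
    act <- rasterize_activity(spec, 0)
  } else {
    # uniform phase sampling over one motion period (60 / freq_cpm seconds);
    # an acquisition of minutes averages many periods, i.e. a uniform phase
    shifts <- (spec$amplitude_mm / 2) *
      sin(2 * pi * (seq_len(spec$n_phases) - 0.5) / spec$n_phases)
    act <- array(0, phantom_dim(spec))
    for (z in shifts) act <- act + rasterize_activity(spec, z)
    act <- act / length(shifts)
  }
  if (spec$fwhm_mm > 0) {
    sigma <- spec$fwhm_mm / (2 * sqrt(2 * log(2)))
    act <- gaussian_blur(act, sigma / phantom_spacing(spec))
  }
  act
}

#' Simulate a static (motionless) phantom acquisition
#'
#' Forward model: analytic activity map with partial-volume rasterization,
#' Gaussian post-filter of the stated FWHM, then additive Gaussian noise
#' with SD = `noise_coef` x local blurred intensity + `noise_floor`,
#' generated from the spec's RNG seed. Iterative reconstruction itself is
#' not modelled; the blur + signal-dependent-noise chain is a surrogate
#' producing comparable image statistics for segmentation studies.
#'
#' @param spec a [phantom_spec()].
#' @param seed optional override of `spec$seed` for the noise realization.
#' @return A [vol_image] of the simulated acquisition.
#' @export
simulate_static <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  arr <- add_noise(phantom_noiseless(spec, moving = FALSE),
                   spec$noise_coef, spec$noise_floor, seed)
  vol_image(arr, phantom_spacing(spec), phantom_origin(spec))
}

#' Simulate a motion-blurred (uncorrected) phantom acquisition
#'
#' Time-average of phase-shifted activity maps with sinusoidal z
#' displacement `z(t) = (A/2) sin(2 pi f t)` (A = maximal amplitude),
#' sampled uniformly over one motion period, followed by the same blur and
#' noise chain as [simulate_static()]. With `amplitude_mm = 0` the result
#' is identical to the static acquisition at the same seed.
#'
#' @inheritParams simulate_static
#' @return A [vol_image].
#' @export
simulate_motion_blurred <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  arr <- add_noise(phantom_noiseless(spec, moving = TRUE),
                   spec$noise_coef, spec$noise_floor, seed)
  vol_image(arr, phantom_spacing(spec), phantom_origin(spec))
}

#' Two-texture calibration phantom
#'
#' A synthetic image built so that lesion and background differ as
#' *textures*, used to exercise [calibrate_threshold()] and the texture
#' region grow end-to-end: a homogeneous high-uptake sphere embedded in a
#' low-uptake background of fine-grained uniform noise, with a
#' partial-volume edge (the sphere indicator is blurred by `edge_blur_vox`
#' voxels before mixing, while the textures themselves stay sharp).
#'
#' The texture parameters are chosen to make all three stop criteria
#' discriminative: the lesion noise is a contaminated Gaussian (a 30%
#' wide-component admixture) whose population kurtosis (~5.6) is high
#' enough above the uniform background's 1.8 that mixed candidate regions
#' are rejected at modest contamination, yet is still estimated reliably
#' from a 27-voxel start region; the uniform background spreads over many
#' gray levels (high co-occurrence entropy, single-voxel size zones) while
#' the lesion occupies few levels (low entropy, one large zone).
#'
#' @param radius_mm lesion radius (default 12 mm).
#' @param dim_vox grid size (default `c(40, 40, 40)`).
#' @param spacing_mm isotropic voxel spacing (default 3 mm).
#' @param tumor_activity lesion intensity (default 2).
#' @param tumor_sd SDs of the narrow and wide lesion-noise components
#'   (default `c(0.03, 0.075)`).
#' @param tumor_wide_frac mixing weight of the wide component (default 0.3).
#' @param background_range background uniform-noise range
#'   (default `c(0.1, 1.0)`).
#' @param edge_blur_vox Gaussian sigma (voxels) applied to the sphere
#'   indicator to create a partial-volume edge (default 0.6).
#' @param seed RNG seed.
#' @return List with `image` (a [vol_image]), `truth` (logical lesion
#'   mask), `center_voxel`, `tumor_cube` (the 27-voxel start-scale
#'   calibration mask at the lesion center), and a disjoint
#'   `background_box` calibration mask.
#' @export
simulate_texture_phantom <- function(radius_mm = 12,
                                     dim_vox = c(40L, 40L, 40L),
                                     spacing_mm = 3,
                                     tumor_activity = 2,
                                     tumor_sd = c(0.03, 0.075),
                                     tumor_wide_frac = 0.3,
                                     background_range = c(0.1, 1.0),
                                     edge_blur_vox = 0.6,
                                     seed = 1L) {
  d <- as.integer(dim_vox)
  sp <- rep_len(as.numeric(spacing_mm), 3L)
  ctr <- d * sp / 2 + sp / 2  # sphere center on a voxel center
  dx2 <- ((seq_len(d[1]) - 0.5) * sp[1] - ctr[1])^2
  dy2 <- ((seq_len(d[2]) - 0.5) * sp[2] - ctr[2])^2
  dz2 <- ((seq_len(d[3]) - 0.5) * sp[3] - ctr[3])^2
  D2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
  truth <- array(D2 <= radius_mm^2, d)
  w <- array(as.numeric(truth), d)
  if (edge_blur_vox > 0) w <- gaussian_blur(w, rep(edge_blur_vox, 3))
  set.seed(seed)
  n <- prod(d)
  bg <- stats::runif(n, background_range[1], background_range[2])
  wide <- stats::runif(n) < tumor_wide_frac
  tum <- tumor_activity +
    stats::rnorm(n, 0, ifelse(wide, tumor_sd[2], tumor_sd[1]))
  vals <- array(w * tum + (1 - w) * bg, d)
  cv <- as.integer(round(ctr / sp + 0.5))
  tc <- array(FALSE, d)
  tc[(cv[1] - 1L):(cv[1] + 1L), (cv[2] - 1L):(cv[2] + 1L),
     (cv[3] - 1L):(cv[3] + 1L)] <- TRUE
  if (!all(truth[tc]))
    stop("start-scale calibration cube must lie inside the lesion; increase radius_mm",
         call. = FALSE)
  bgm <- array(FALSE, d)
  bgm[3:7, 3:7, 3:7] <- TRUE
  if (any(bgm & truth)) stop("background box overlaps the lesion", call. = FALSE)
  list(image = vol_image(vals, sp, sp / 2),
       truth = truth,
       center_voxel = cv,
       tumor_cube = tc,
       background_box = bgm)
}
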