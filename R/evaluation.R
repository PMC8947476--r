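# Repeated-measurement statistics and difference metrics for comparing
# segmentation methods: mean / range / absolute and relative standard
# deviation over consecutive segmentations, relative difference to the
# true volume, and the signed difference between uncorrected and
# motion-corrected volumes.

# Reported percentages are rounded to one decimal, half away from zero
# (base R's round() is half-to-even).
round_half_up <- function(x, digits = 1L) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Stability statistics over repeated segmentations
#'
#' @param volumes numeric vector of at least 2 positive volumes (ccm) from
#'   consecutive segmentation measurements.
#' @return A `repeat_stats` object: list with `n`, `mean`, `min`, `max`,
#'   `sd` (sample SD, N - 1 denominator) and `rel_sd`
#'   (= 100 * sd / mean, percent).
#' @export
repeat_stats <- function(volumes) {
  v <- as.numeric(volumes)
  if (any(is.na(v))) stop("volumes must not contain NA", call. = FALSE)
  if (length(v) < 2L) stop("need at least 2 volumes", call. = FALSE)
  if (any(v <= 0)) stop("volumes must be positive", call. = FALSE)
  m <- mean(v)
  s <- stats::sd(v)
  structure(list(n = length(v), mean = m, min = min(v), max = max(v),
                 sd = s, rel_sd = 100 * s / m),
            class = "repeat_stats")
}

#' @export
print.repeat_stats <- function(x, ...) {
  cat(sprintf("<repeat_stats> n = %d: mean %.2f ccm, range %.2f-%.2f, SD %.2f ccm (%.1f%%)\n",
              x$n, x$mean, x$min, x$max, x$sd, x$rel_sd))
  invisible(x)
}

#' Relative difference between measured and true volume
#'
#' @param mean_volume measured (mean) volume in ccm.
#' @param true_volume nominal true volume in ccm (> 0).
#' @return `100 * |mean - true| / true`, rounded to one decimal
#'   (half away from zero).
#' @export
relative_difference_to_truth <- function(mean_volume, true_volume) {
  if (any(true_volume <= 0)) stop("`true_volume` must be positive", call. = FALSE)
  round_half_up(100 * abs(mean_volume - true_volume) / true_volume, 1L)
}

#' Signed relative difference of uncorrected to motion-corrected volume
#'
#' @param v_uncorrected volume (ccm) segmented without motion correction.
#' @param v_corrected volume (ccm) segmented after motion correction.
#' @return `100 * (uncorrected - corrected) / uncorrected`, rounded to one
#'   decimal (half away from zero), signed.
#' @export
motion_difference <- function(v_uncorrected, v_corrected) {
  if (any(v_uncorrected <= 0)) stop("`v_uncorrected` must be positive", call. = FALSE)
  round_half_up(100 * (v_uncorrected - v_corrected) / v_uncorrected, 1L)
}

# k-fold 26-neighbourhood dilation (used to build calibration shells).
dilate_mask <- function(mask, k = 1L) {
  for (i in seq_len(k)) {
    out <- mask
    for (o in seq_len(nrow(neighbour_offsets_26)))
      out <- out | shift_mask(mask, neighbour_offsets_26[o, ])
    mask <- out
  }
  mask
}

method_labels <- c(threshold = "threshold",
                   kurtosis = "kurtosis",
                   local_entropy = "local_entropy",
                   long_zone_emphasis = "long_zone_emphasis")

#' Repeated-segmentation stability experiment on the synthetic phantom
#'
#' Emulates a consecutive-measurement study: the noiseless forward model of
#' the phantom is computed once, then for each repeat a fresh noise
#' realization is drawn and the seed point is jittered (mimicking manual
#' seed placement), and every sphere is segmented with every requested
#' method. Per (method, sphere) cell the stability statistics of
#' [repeat_stats()] and the relative difference to the nominal sphere
#' volume are reported.
#'
#' Textural stop thresholds, unless supplied via `feature_specs`, are
#' calibrated once per (feature, sphere) with [calibrate_boundary()] on a
#' dedicated calibration noise realization: the threshold is placed between
#' the feature value on the sphere's truth mask and on the truth mask grown
#' by two voxel shells — the phantom analogue of thresholds imported from
#' prior clinical material. Per-region binning is used so the features
#' react to the dynamic-range jump when a region spills into the cold
#' background.
#'
#' @param spec a [phantom_spec()].
#' @param methods subset of
#'   `c("threshold", "kurtosis", "local_entropy", "long_zone_emphasis")`.
#' @param repeats number of consecutive measurements (default 20).
#' @param jitter_vox seed jitter: each repeat displaces the seed uniformly
#'   by -jitter..+jitter voxels per axis (default 1; 0 disables).
#' @param fraction threshold fraction for the reference method (default 0.40).
#' @param feature_specs optional list of lists of calibrated
#'   [feature_spec()]s, indexed as `feature_specs[[method]][[sphere]]`,
#'   overriding auto-calibration.
#' @param n_levels gray levels for auto-calibrated texture criteria
#'   (default 64, per-region binning).
#' @param moving if `TRUE`, segment the motion-blurred acquisition instead
#'   of the static one.
#' @param master_seed seed controlling noise streams and jitter
#'   (default `spec$seed`).
#' @return A data.frame with one row per (method, sphere): columns
#'   `method`, `sphere_ccm`, `n`, `mean_ccm`, `diff_pct`, `min_ccm`,
#'   `max_ccm`, `sd_ccm`, `rel_sd_pct`, `failures`. The raw per-repeat
#'   volumes are attached as `attr(x, "volumes")` (long data.frame), the
#'   calibrated specs as `attr(x, "feature_specs")`.
#' @export
stability_experiment <- function(spec,
                                 methods = c("threshold", "kurtosis",
                                             "local_entropy", "long_zone_emphasis"),
                                 repeats = 20L,
                                 jitter_vox = 1L,
                                 fraction = 0.40,
                                 feature_specs = NULL,
                                 n_levels = 64L,
                                 moving = FALSE,
                                 master_seed = spec$seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  methods <- match.arg(methods, several.ok = TRUE)
  repeats <- as.integer(repeats)
  if (repeats < 2L) stop("`repeats` must be >= 2", call. = FALSE)
  sp <- phantom_spacing(spec)
  d <- phantom_dim(spec)
  base <- phantom_noiseless(spec, moving = moving)
  set.seed(master_seed)
  seed_pool <- sample.int(2^30, repeats + 1L)

  n_sph <- length(spec$volumes_ccm)
  texture_methods <- setdiff(methods, "threshold")
  specs <- list()
  if (length(texture_methods)) {
    # calibrate on the *static* forward model: the motion-uncorrected study
    # reuses the thresholds of the corrected one, as the clinical workflow
    # reuses thresholds across acquisitions
    calib_base <- if (moving) phantom_noiseless(spec, moving = FALSE) else base
    calib_img <- vol_image(add_noise(calib_base, spec$noise_coef,
                                     spec$noise_floor, seed_pool[1L]),
                           sp, phantom_origin(spec))
    for (fn in texture_methods) {
      specs[[fn]] <- vector("list", n_sph)
      for (si in seq_len(n_sph)) {
        if (!is.null(feature_specs[[fn]][[si]])) {
          specs[[fn]][[si]] <- feature_specs[[fn]][[si]]
        } else {
          fs <- feature_spec(fn, n_levels = n_levels, binning = "per-region")
          specs[[fn]][[si]] <-
            calibrate_boundary(calib_img, truth_mask(spec, si), fs)$spec
        }
      }
    }
  }
  centers <- t(vapply(seq_len(n_sph), function(i) sphere_center_voxel(spec, i),
                      integer(3)))
  vols <- array(NA_real_, c(length(methods), n_sph, repeats),
                dimnames = list(methods, NULL, NULL))
  failures <- matrix(0L, length(methods), n_sph, dimnames = list(methods, NULL))

  for (r in seq_len(repeats)) {
    set.seed(seed_pool[r + 1L])
    img <- vol_image(add_noise(base, spec$noise_coef, spec$noise_floor, NULL),
                     sp, phantom_origin(spec))
    for (si in seq_len(n_sph)) {
      seed_vox <- centers[si, ]
      if (jitter_vox > 0L) {
        jit <- sample(seq.int(-jitter_vox, jitter_vox), 3L, replace = TRUE)
        seed_vox <- pmax(2L, pmin(d - 1L, seed_vox + jit))
      }
      for (mi in seq_along(methods)) {
        m <- methods[mi]
        v <- tryCatch({
          if (m == "threshold") {
            mask_volume_ccm(threshold_segment(img, seed_vox, fraction), sp)
          } else {
            texture_region_grow(img, seed_vox, specs[[m]][[si]])$volume_ccm
          }
        }, error = function(e) {
          warning(sprintf("repeat %d, sphere %d, %s: %s",
                          r, si, m, conditionMessage(e)), call. = FALSE)
          NA_real_
        })
        vols[mi, si, r] <- v
        if (is.na(v)) failures[mi, si] <- failures[mi, si] + 1L
      }
    }
  }

  rows <- list()
  raw <- list()
  for (mi in seq_along(methods)) for (si in seq_len(n_sph)) {
    v <- vols[mi, si, ]
    vok <- v[!is.na(v)]
    st <- if (length(vok) >= 2L && all(vok > 0)) repeat_stats(vok) else NULL
    rows[[length(rows) + 1L]] <- data.frame(
      method = methods[mi],
      sphere_ccm = spec$volumes_ccm[si],
      n = length(vok),
      mean_ccm = if (is.null(st)) NA_real_ else st$mean,
      diff_pct = if (is.null(st)) NA_real_ else
        relative_difference_to_truth(st$mean, spec$volumes_ccm[si]),
      min_ccm = if (is.null(st)) NA_real_ else st$min,
      max_ccm = if (is.null(st)) NA_real_ else st$max,
      sd_ccm = if (is.null(st)) NA_real_ else st$sd,
      rel_sd_pct = if (is.null(st)) NA_real_ else st$rel_sd,
      failures = failures[mi, si])
    raw[[length(raw) + 1L]] <- data.frame(
      method = methods[mi], sphere_ccm = spec$volumes_ccm[si],
      repeat_idx = seq_len(repeats), volume_ccm = v)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "volumes") <- do.call(rbind, raw)
  attr(out, "feature_specs") <- specs
  out
}

#' Quartile summary for box-and-whisker export
#'
#' Five-number summaries (min, Q1, median, Q3, max) of the raw per-repeat
#' volumes attached to a [stability_experiment()] result, suitable for CSV
#' export and external box-plot drawing.
#'
#' @param stab result of [stability_experiment()].
#' @return data.frame with one row per (method, sphere).
#' @export
boxplot_summary <- function(stab) {
  raw <- attr(stab, "volumes")
  if (is.null(raw)) stop("no raw volumes attached", call. = FALSE)
  parts <- split(raw, list(raw$method, raw$sphere_ccm), drop = TRUE)
  out <- lapply(parts, function(p) {
    q <- stats::quantile(p$volume_ccm, c(0, 0.25, 0.5, 0.75, 1), na.rm = TRUE)
    data.frame(method = p$method[1], sphere_ccm = p$sphere_ccm[1],
               min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
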