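# File I/O and the run-configuration surface: NIfTI reading/writing and a
# single-call segmentation runner producing a mask file plus a JSON report.

#' Read a 3D volume from a NIfTI file
#'
#' Loads a `.nii` / `.nii.gz` image into a [vol_image], taking the voxel
#' spacing (mm) from the header and the origin from the stored transform.
#' Only axis-aligned orientations are supported; oblique or rotated images
#' are rejected rather than silently resampled. DICOM series are not read
#' directly -- convert them to NIfTI first (e.g. with dcm2niix).
#'
#' @param path path to a NIfTI file.
#' @return A [vol_image].
#' @export
read_volume <- function(path) {
  if (dir.exists(path))
    stop("directory input (DICOM series) is not supported; convert the series to NIfTI first",
         call. = FALSE)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  nii <- RNifti::readNifti(path)
  d <- dim(nii)
  if (length(d) < 3L || sum(d > 1L) < 3L)
    stop("3D volume required", call. = FALSE)
  if (length(d) > 3L) {
    if (any(d[-(1:3)] != 1L))
      stop("4D input not supported; extract a single 3D frame", call. = FALSE)
    nii <- array(as.numeric(nii), d[1:3])
    d <- d[1:3]
  }
  spacing <- RNifti::pixdim(nii)[1:3]
  xf <- try(RNifti::xform(nii), silent = TRUE)
  origin <- c(0, 0, 0)
  if (!inherits(xf, "try-error") && is.matrix(xf) && all(dim(xf) >= c(3, 4))) {
    rot <- abs(xf[1:3, 1:3])
    offdiag <- rot; diag(offdiag) <- 0
    if (any(offdiag > 1e-3 * max(rot)))
      stop("non-axis-aligned image orientation is not supported", call. = FALSE)
    origin <- xf[1:3, 4]
  }
  vol_image(array(as.numeric(nii), d), spacing, origin)
}

#' Write a volume to a NIfTI file
#'
#' @param image a [vol_image].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(image, path) {
  if (!inherits(image, "vol_image")) stop("`image` must be a vol_image", call. = FALSE)
  nii <- RNifti::asNifti(image$values)
  RNifti::pixdim(nii) <- image$spacing
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' Write a binary mask to a NIfTI file
#'
#' The mask is stored as 0/1 integers on the geometry of its reference
#' image.
#'
#' @param mask 3D logical array.
#' @param reference the [vol_image] the mask belongs to.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, reference, path) {
  check_mask(mask)
  if (!inherits(reference, "vol_image"))
    stop("`reference` must be a vol_image", call. = FALSE)
  if (!identical(dim(mask), dim(reference$values)))
    stop("mask geometry does not match the reference image", call. = FALSE)
  arr <- array(0L, dim(mask))
  arr[mask] <- 1L
  nii <- RNifti::asNifti(arr)
  RNifti::pixdim(nii) <- reference$spacing
  RNifti::writeNifti(nii, path)
  invisible(path)
}

method_aliases <- c(threshold = "threshold",
                    kurtosis = "kurtosis",
                    entropy = "local_entropy",
                    local_entropy = "local_entropy",
                    lze = "long_zone_emphasis",
                    long_zone_emphasis = "long_zone_emphasis")

# Convert a world-mm position to the voxel whose center is nearest
# (ties toward the lower index).
world_to_voxel <- function(image, mm) {
  x <- (as.numeric(mm) - image$origin) / image$spacing + 1
  idx <- as.integer(ceiling(x - 0.5))
  pmax(1L, pmin(dim(image$values), idx))
}

# Move a seed to the hottest voxel within a ball of the given radius.
hottest_seed <- function(image, seed, radius_mm) {
  d <- dim(image$values)
  r_vox <- pmax(0L, as.integer(floor(radius_mm / image$spacing)))
  lo <- pmax(1L, seed - r_vox); hi <- pmin(d, seed + r_vox)
  box <- image$values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  w <- which(box == max(box), arr.ind = TRUE)[1, ]
  as.integer(lo + w - 1L)
}

#' Run one segmentation from a configuration
#'
#' Thin orchestration layer over the segmentation functions: resolves the
#' input volume and seed, dispatches on the method, and (optionally) writes
#' the mask as NIfTI, a JSON report, and the region-growing trace as CSV.
#'
#' @param config a list, or path to a YAML file, with fields:
#'   \describe{
#'     \item{input}{path to a NIfTI volume (alternatively pass a
#'       [vol_image] via `image`).}
#'     \item{method}{one of `"threshold"`, `"kurtosis"`, `"entropy"`,
#'       `"lze"` (full feature names are also accepted).}
#'     \item{seed_vox / seed_mm}{the seed, as voxel indices or world mm
#'       (exactly one of the two).}
#'     \item{seed_mode, search_radius_mm}{optional; `seed_mode: "hottest"`
#'       relocates the seed to the hottest voxel within the search radius,
#'       standardizing the start point.}
#'     \item{fraction}{threshold fraction for the reference method
#'       (default 0.4).}
#'     \item{feature_threshold, accept, n_levels}{textural stop criterion
#'       parameters.}
#'     \item{max_iterations, sequential}{growth controls.}
#'     \item{output_dir}{if set, `mask.nii.gz`, `report.json` and (for
#'       texture methods) `trace.csv` are written there.}
#'   }
#' @return The report as a list (invisibly when files are written):
#'   method, seed, parameters, volume in ccm, maximal diameter in mm,
#'   iteration count and convergence flags, plus the resolved config.
#' @export
run_segment <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("`config` must be a list or a YAML path", call. = FALSE)
  if (is.null(config$method)) stop("config: `method` is required", call. = FALSE)
  mkey <- match.arg(tolower(config$method), names(method_aliases))
  method <- method_aliases[[mkey]]

  image <- config$image
  if (is.null(image)) {
    if (is.null(config$input)) stop("config: `input` (or `image`) is required", call. = FALSE)
    image <- read_volume(config$input)
  }
  if (!is.null(config$seed_vox) && !is.null(config$seed_mm))
    stop("config: give exactly one of `seed_vox` or `seed_mm`", call. = FALSE)
  if (!is.null(config$seed_vox)) {
    seed <- as.integer(config$seed_vox)
  } else if (!is.null(config$seed_mm)) {
    seed <- world_to_voxel(image, config$seed_mm)
  } else stop("config: a seed (`seed_vox` or `seed_mm`) is required", call. = FALSE)
  if (identical(config$seed_mode, "hottest")) {
    radius <- if (is.null(config$search_radius_mm)) 15 else config$search_radius_mm
    seed <- hottest_seed(image, seed, radius)
  }

  sp <- image$spacing
  if (method == "threshold") {
    fraction <- if (is.null(config$fraction)) 0.40 else config$fraction
    mask <- threshold_segment(image, seed, fraction)
    res <- NULL
    report <- list(method = "threshold", seed_vox = seed, fraction = fraction,
                   volume_ccm = mask_volume_ccm(mask, sp),
                   max_diameter_mm = max_diameter_mm(mask, sp),
                   n_voxels = sum(mask))
  } else {
    if (is.null(config$feature_threshold))
      stop("config: `feature_threshold` is required for texture methods", call. = FALSE)
    fs <- feature_spec(method,
                       threshold = config$feature_threshold,
                       accept = if (is.null(config$accept)) "below" else config$accept,
                       n_levels = if (is.null(config$n_levels)) 64L else config$n_levels)
    res <- texture_region_grow(image, seed, fs,
                               max_iterations = if (is.null(config$max_iterations)) 200L
                                                else config$max_iterations,
                               sequential = isTRUE(config$sequential))
    mask <- res$mask
    report <- list(method = method, seed_vox = seed,
                   feature_threshold = fs$threshold, accept = fs$accept,
                   n_levels = fs$n_levels,
                   volume_ccm = res$volume_ccm,
                   max_diameter_mm = res$max_diameter_mm,
                   iterations = res$iterations,
                   terminated_at_start = res$terminated_at_start,
                   converged = res$converged,
                   n_voxels = sum(mask))
  }
  cfg <- config
  cfg$image <- NULL
  report$config <- cfg

  out <- config$output_dir
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    write_mask(mask, image, file.path(out, "mask.nii.gz"))
    report$mask_path <- file.path(out, "mask.nii.gz")
    if (!is.null(res) && nrow(res$trace)) {
      utils::write.csv(res$trace, file.path(out, "trace.csv"), row.names = FALSE)
      report$trace_path <- file.path(out, "trace.csv")
    }
    jsonlite::write_json(report, file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(c(report, list(mask = mask))))
  }
  c(report, list(mask = mask))
}
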