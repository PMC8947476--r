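# Core grid data types and geometric utilities.
#
# Conventions used throughout the package:
#   * voxel indices (i, j, k) are 1-based, following R array indexing;
#   * world coordinates (mm) of a voxel center are origin + (index - 1) * spacing;
#   * all distances and volumes are computed in mm / ccm, never in voxels;
#   * anisotropic spacing is fully supported;
#   * masks are plain logical arrays congruent with the image grid.

#' Construct a volumetric image
#'
#' A minimal in-memory representation of a 3D scalar image (e.g. a PET
#' activity-concentration map): a numeric array plus the physical voxel
#' spacing and the world position of the first voxel center.
#'
#' @param values 3D numeric array of voxel intensities (arbitrary units,
#'   typically activity concentration).
#' @param spacing numeric length-3, voxel size in mm along (x, y, z);
#'   all components must be positive.
#' @param origin numeric length-3, world coordinates (mm) of the center of
#'   voxel (1, 1, 1).
#' @return An object of class `vol_image` with fields `values`, `spacing`
#'   and `origin`.
#' @export
vol_image <- function(values, spacing, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive finite numbers (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be three finite numbers (mm)", call. = FALSE)
  if (any(!is.finite(values)))
    stop("image values must all be finite", call. = FALSE)
  storage.mode(values) <- "double"
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "vol_image")
}

#' @export
print.vol_image <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<vol_image> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.vol_image <- function(x) dim(x$values)

check_spacing <- function(spacing) {
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive finite numbers (mm)", call. = FALSE)
  spacing
}

check_mask <- function(mask) {
  if (!is.array(mask) || length(dim(mask)) != 3L || !is.logical(mask))
    stop("a mask must be a 3D logical array", call. = FALSE)
  mask
}

#' Volume of a binary mask in ccm
#'
#' @param mask 3D logical array.
#' @param spacing voxel spacing in mm (length 3).
#' @return Volume in ccm (cm^3): member count times the voxel volume.
#'   An empty mask yields 0.
#' @export
mask_volume_ccm <- function(mask, spacing) {
  check_mask(mask)
  spacing <- check_spacing(spacing)
  sum(mask) * prod(spacing) / 1000
}

# Member voxels lying on the mask surface: at least one of the six
# face neighbours is absent (or outside the grid). The two extreme points
# of any point set lie on its surface, so the maximal diameter is preserved.
surface_voxels <- function(mask) {
  interior <- mask
  for (ax in 1:3) for (s in c(-1L, 1L)) {
    d <- integer(3); d[ax] <- s
    interior <- interior & shift_mask(mask, d)
  }
  mask & !interior
}

#' Maximal diameter of a mask in mm
#'
#' Maximum Euclidean center-to-center distance between any two member
#' voxels. Large masks are first reduced to their surface voxels, which
#' leaves the maximum unchanged.
#'
#' @inheritParams mask_volume_ccm
#' @return Length in mm; 0 for a single-voxel mask.
#' @export
max_diameter_mm <- function(mask, spacing) {
  check_mask(mask)
  spacing <- check_spacing(spacing)
  n <- sum(mask)
  if (n == 0L) stop("empty mask", call. = FALSE)
  if (n == 1L) return(0)
  if (n > 1500L) mask <- surface_voxels(mask)
  co <- arrayInd(which(mask), dim(mask))
  pts <- sweep(co - 1L, 2L, spacing, `*`)
  max(stats::dist(pts))
}

#' Initial 27-voxel region around a seed
#'
#' The region-growing algorithm starts from a 3 x 3 x 3 voxel cube centered
#' on the user-supplied seed point; smaller start regions do not allow a
#' stable estimate of the textural stop parameter.
#'
#' @param seed integer length-3 voxel index (i, j, k), 1-based.
#' @param image a [vol_image] (defines the grid the mask lives on).
#' @return A logical mask with exactly 27 members.
#' @export
start_cube <- function(seed, image) {
  d <- dim(image$values)
  seed <- as.integer(round(seed))
  if (length(seed) != 3L || any(is.na(seed)))
    stop("`seed` must be three integer voxel indices", call. = FALSE)
  if (any(seed < 1L) || any(seed > d))
    stop("seed outside image grid", call. = FALSE)
  if (any(seed < 2L) || any(seed > d - 1L))
    stop("seed too close to boundary", call. = FALSE)
  m <- array(FALSE, d)
  m[(seed[1] - 1L):(seed[1] + 1L),
    (seed[2] - 1L):(seed[2] + 1L),
    (seed[3] - 1L):(seed[3] + 1L)] <- TRUE
  m
}

# Translate a logical/numeric array by an integer offset, filling with
# FALSE/0. Workhorse for directional growth, surface extraction and blurring.
shift_mask <- function(mask, d) {
  dm <- dim(mask)
  out <- array(if (is.logical(mask)) FALSE else 0, dm)
  idx <- vector("list", 3L)
  src <- vector("list", 3L)
  for (ax in 1:3) {
    if (abs(d[ax]) >= dm[ax]) return(out)
    if (d[ax] >= 0) {
      idx[[ax]] <- (1L + d[ax]):dm[ax]
      src[[ax]] <- 1L:(dm[ax] - d[ax])
    } else {
      idx[[ax]] <- 1L:(dm[ax] + d[ax])
      src[[ax]] <- (1L - d[ax]):dm[ax]
    }
  }
  out[idx[[1]], idx[[2]], idx[[3]]] <-
    mask[src[[1]], src[[2]], src[[3]]]
  out
}

# Bounding box of a mask: list(lo = c(i,j,k), hi = c(i,j,k)).
mask_bbox <- function(mask) {
  w <- which(mask)
  if (!length(w)) stop("empty mask", call. = FALSE)
  co <- arrayInd(w, dim(mask))
  list(lo = apply(co, 2L, min), hi = apply(co, 2L, max))
}

# The 26 neighbour offsets (Chebyshev distance 1) and the 13 unique
# (lexicographically positive) half-set used for symmetric pair counting.
neighbour_offsets_26 <- local({
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  g[rowSums(g != 0) > 0, , drop = FALSE]
})

neighbour_offsets_13 <- local({
  o <- neighbour_offsets_26
  keep <- (o[, 3] > 0) |
    (o[, 3] == 0 & o[, 2] > 0) |
    (o[, 3] == 0 & o[, 2] == 0 & o[, 1] > 0)
  o[keep, , drop = FALSE]
})

# 26-connected component of `member` containing the voxel at linear
# index `start` (which must itself be a member). Breadth-first search with
# a vectorised frontier.
connected_component <- function(member, start) {
  d <- dim(member)
  if (!member[start]) stop("component start voxel is not a member", call. = FALSE)
  visited <- array(FALSE, d)
  visited[start] <- TRUE
  front <- start
  offs <- neighbour_offsets_26
  lin_step <- offs[, 1] + offs[, 2] * d[1] + offs[, 3] * d[1] * d[2]
  while (length(front)) {
    fi <- arrayInd(front, d)
    nxt <- integer(0)
    for (o in seq_len(nrow(offs))) {
      ok <- fi[, 1] + offs[o, 1] >= 1L & fi[, 1] + offs[o, 1] <= d[1] &
            fi[, 2] + offs[o, 2] >= 1L & fi[, 2] + offs[o, 2] <= d[2] &
            fi[, 3] + offs[o, 3] >= 1L & fi[, 3] + offs[o, 3] <= d[3]
      if (!any(ok)) next
      lin <- front[ok] + lin_step[o]
      lin <- lin[member[lin] & !visited[lin]]
      if (length(lin)) {
        visited[lin] <- TRUE
        nxt <- c(nxt, lin)
      }
    }
    front <- unique(nxt)
  }
  visited
}
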