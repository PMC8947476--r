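# The two segmentation algorithms: the 40%-of-maximum adaptive threshold
# reference and the texture-feature region grow.

#' Adaptive threshold segmentation (fraction of lesion maximum)
#'
#' Keeps the 26-connected component, reachable from the seed, of voxels
#' with intensity >= fraction * (lesion maximum). Because the lesion is
#' not delimited beforehand, the lesion maximum is found by fixed-point
#' iteration: start from the maximum in the 3x3x3 cube around the seed,
#' threshold, take the seed's connected component, recompute the maximum
#' inside it, and repeat until stable. The component maximum is
#' non-decreasing and bounded by the image maximum, so the iteration
#' converges (a safety cap of `max_rounds` rounds is applied).
#'
#' @param image a [vol_image].
#' @param seed integer length-3 voxel index inside the lesion.
#' @param fraction threshold as a fraction of the lesion maximum
#'   (default 0.40); must lie strictly between 0 and 1. The comparison is
#'   inclusive (>=).
#' @param max_rounds cap on fixed-point rounds (default 10).
#' @return A logical mask (the thresholded connected component).
#' @export
threshold_segment <- function(image, seed, fraction = 0.40, max_rounds = 10L) {
  if (!inherits(image, "vol_image")) stop("`image` must be a vol_image", call. = FALSE)
  if (!is.numeric(fraction) || length(fraction) != 1L || fraction <= 0 || fraction >= 1)
    stop("`fraction` must lie strictly between 0 and 1", call. = FALSE)
  vals <- image$values
  d <- dim(vals)
  seed <- as.integer(round(seed))
  if (length(seed) != 3L || any(seed < 1L) || any(seed > d))
    stop("seed outside image grid", call. = FALSE)
  seed_lin <- seed[1] + (seed[2] - 1L) * d[1] + (seed[3] - 1L) * d[1] * d[2]
  if (vals[seed_lin] <= 0) stop("seed outside uptake", call. = FALSE)
  # local maximum in the clipped 3x3x3 cube around the seed
  ci <- lapply(1:3, function(ax) max(1L, seed[ax] - 1L):min(d[ax], seed[ax] + 1L))
  cube <- vals[ci[[1]], ci[[2]], ci[[3]], drop = FALSE]
  cur_max <- max(cube)
  # linear index of the voxel attaining the current maximum: always
  # supra-threshold, so it can anchor the flood fill when the seed itself
  # falls below the threshold
  w <- which(cube == cur_max, arr.ind = TRUE)[1, ]
  a <- c(ci[[1]][w[1]], ci[[2]][w[2]], ci[[3]][w[3]])
  max_lin <- a[1] + (a[2] - 1L) * d[1] + (a[3] - 1L) * d[1] * d[2]
  comp <- NULL
  for (round in seq_len(max_rounds)) {
    thr <- fraction * cur_max
    supra <- vals >= thr
    anchor <- if (supra[seed_lin]) seed_lin else max_lin
    comp <- connected_component(supra, anchor)
    new_max <- max(vals[comp])
    if (new_max == cur_max) break
    cur_max <- new_max
    max_lin <- which(comp)[which.max(vals[comp])]
  }
  comp
}

# Direction vocabulary for the six axis-aligned one-voxel growth steps.
grow_directions <- list(
  `+x` = c(1L, 0L, 0L), `-x` = c(-1L, 0L, 0L),
  `+y` = c(0L, 1L, 0L), `-y` = c(0L, -1L, 0L),
  `+z` = c(0L, 0L, 1L), `-z` = c(0L, 0L, -1L))

resolve_direction <- function(direction) {
  if (is.character(direction)) {
    if (!direction %in% names(grow_directions))
      stop("`direction` must be one of ", paste(names(grow_directions), collapse = ", "),
           call. = FALSE)
    return(grow_directions[[direction]])
  }
  direction <- as.integer(direction)
  if (length(direction) != 3L || sum(abs(direction)) != 1L)
    stop("`direction` must be a unit axis vector or one of \"+x\"...\"-z\"", call. = FALSE)
  direction
}

#' Grow a mask by one voxel in a single direction
#'
#' Candidate mask = mask united with its one-voxel translate along the
#' given direction; growth beyond the image face is silently clipped and
#' voxels are never removed.
#'
#' @param mask 3D logical array.
#' @param direction one of `"+x", "-x", "+y", "-y", "+z", "-z"` or an
#'   integer unit vector.
#' @return The candidate logical mask.
#' @export
directional_grow <- function(mask, direction) {
  check_mask(mask)
  if (!any(mask)) stop("empty mask", call. = FALSE)
  d <- resolve_direction(direction)
  mask | shift_mask(mask, d)
}

#' Texture-criterion region growing
#'
#' Semi-automatic lesion segmentation by iterative region growth with a
#' textural stop criterion. The algorithm:
#'
#' 1. Start from the 27-voxel cube centered on the seed. If the feature of
#'    the start region already violates the acceptance criterion, the start
#'    cube is returned unchanged (`terminated_at_start = TRUE`).
#' 2. In each iteration, six candidate regions are formed independently
#'    from the current region V -- one single-voxel growth step in each of
#'    +x, -x, +y, -y, +z, -z. A candidate is accepted if its feature value
#'    satisfies the criterion (strictly below or strictly above the
#'    threshold, per `spec$accept`). The new region is the union of all
#'    accepted candidates (rejected directions contribute V unchanged).
#' 3. If no direction changed the region, growth has converged; otherwise
#'    the next iteration starts from the union.
#'
#' For the matrix features, discretization bin edges are fixed once, from
#' the intensity range inside the bounding box of the start cube dilated by
#' `edges_margin_mm`, so that feature values are comparable across growth
#' steps (if `spec$edges` is already set those edges are used as-is).
#'
#' @param image a [vol_image].
#' @param seed integer length-3 voxel index (lesion center).
#' @param spec a [feature_spec()] with a finite threshold.
#' @param max_iterations safety cap on growth iterations (default 200);
#'   reaching it flags the result as non-converged.
#' @param sequential if `TRUE`, the six direction candidates within one
#'   iteration are evaluated cumulatively (each accepted step feeding the
#'   next) instead of independently from the same parent region. Provided
#'   for sensitivity analysis; default `FALSE`.
#' @param edges_margin_mm dilation (mm) of the start-cube bounding box used
#'   to derive global discretization edges (default 30).
#' @return A `region_grow_result`: list with `mask`, `volume_ccm`,
#'   `max_diameter_mm`, `iterations`, `trace` (one row per direction
#'   evaluation: iteration, direction, feature, accepted, volume_ccm),
#'   `terminated_at_start`, `converged`, `feature_start`, and the resolved
#'   `spec`.
#' @export
texture_region_grow <- function(image, seed, spec, max_iterations = 200L,
                                sequential = FALSE, edges_margin_mm = 30) {
  if (!inherits(image, "vol_image")) stop("`image` must be a vol_image", call. = FALSE)
  if (!inherits(spec, "feature_spec")) stop("`spec` must be a feature_spec", call. = FALSE)
  if (is.na(spec$threshold))
    stop("`spec$threshold` is not set; calibrate or supply one", call. = FALSE)
  V <- start_cube(seed, image)
  sp <- image$spacing
  if (spec$name != "kurtosis" && is.null(spec$edges) &&
      identical(spec$binning, "fixed-global"))
    spec$edges <- local_bin_edges(image, V, spec$n_levels, edges_margin_mm)
  ok <- if (spec$accept == "below") {
    function(f) f < spec$threshold
  } else {
    function(f) f > spec$threshold
  }
  f0 <- compute_feature(image, V, spec)
  trace <- list()
  finish <- function(mask, it, at_start, conv) {
    tr <- if (length(trace)) do.call(rbind, trace) else
      data.frame(iteration = integer(0), direction = character(0),
                 feature = numeric(0), accepted = logical(0),
                 volume_ccm = numeric(0))
    rownames(tr) <- NULL
    structure(list(mask = mask,
                   volume_ccm = mask_volume_ccm(mask, sp),
                   max_diameter_mm = max_diameter_mm(mask, sp),
                   iterations = it,
                   trace = tr,
                   terminated_at_start = at_start,
                   converged = conv,
                   feature_start = f0,
                   spec = spec,
                   seed = as.integer(round(seed))),
              class = "region_grow_result")
  }
  if (!ok(f0)) return(finish(V, 0L, TRUE, TRUE))
  it <- 0L
  converged <- FALSE
  nV <- sum(V)
  while (it < max_iterations) {
    it <- it + 1L
    U <- V
    for (dn in names(grow_directions)) {
      base <- if (sequential) U else V
      C <- directional_grow(base, dn)
      if (sum(C) == sum(base)) next  # clipped at the image face: no candidate
      f <- compute_feature(image, C, spec)
      acc <- ok(f)
      trace[[length(trace) + 1L]] <-
        data.frame(iteration = it, direction = dn, feature = f,
                   accepted = acc, volume_ccm = mask_volume_ccm(C, sp))
      if (acc) U <- if (sequential) C else (U | C)
    }
    nU <- sum(U)
    if (nU == nV) { converged <- TRUE; break }
    V <- U
    nV <- nU
  }
  finish(V, it, FALSE, converged)
}

#' @export
print.region_grow_result <- function(x, ...) {
  cat(sprintf("<region_grow_result> %s: %.2f ccm, max diameter %.1f mm\n",
              x$spec$name, x$volume_ccm, x$max_diameter_mm))
  cat(sprintf("  %d iterations, %d voxels%s%s\n",
              x$iterations, sum(x$mask),
              if (x$terminated_at_start) ", criterion violated in start cube" else "",
              if (!x$converged) ", NOT converged (iteration cap reached)" else ""))
  invisible(x)
}

# Fixed global bin edges from the intensity range inside the bounding box
# of `mask` dilated by `margin_mm` (clipped to the grid).
local_bin_edges <- function(image, mask, n_levels, margin_mm) {
  d <- dim(image$values)
  bb <- mask_bbox(mask)
  mv <- pmax(1L, as.integer(ceiling(margin_mm / image$spacing)))
  lo <- pmax(bb$lo - mv, 1L)
  hi <- pmin(bb$hi + mv, d)
  box <- image$values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  rng <- range(box)
  if (rng[2] <= rng[1]) rng[2] <- rng[1] + 1
  seq(rng[1], rng[2], length.out = n_levels + 1L)
}

#' Calibrate a textural stop threshold from example regions
#'
#' The stop thresholds of the textural criteria are scanner- and
#' protocol-dependent and must be derived from data. Given disjoint example
#' masks of tumor and background tissue, the feature is evaluated in both;
#' the threshold is placed at the midpoint, and the acceptance direction is
#' the side of the midpoint on which the tumor value lies.
#'
#' For the matrix features, a single fixed discretization (bin edges from
#' the intensity range over the bounding hull of both masks) is used for
#' both evaluations and embedded in the returned spec, so that a subsequent
#' [texture_region_grow()] call measures the feature on the same scale.
#'
#' @param image a [vol_image].
#' @param tumor_mask,background_mask disjoint logical masks with at least
#'   27 voxels each.
#' @param spec a [feature_spec()]; its threshold/accept fields are ignored.
#' @return A list with `threshold`, `accept`, `feature_tumor`,
#'   `feature_background`, and `spec` (a ready-to-use calibrated
#'   [feature_spec()] with fixed edges).
#' @export
calibrate_threshold <- function(image, tumor_mask, background_mask, spec) {
  if (!inherits(image, "vol_image")) stop("`image` must be a vol_image", call. = FALSE)
  if (!inherits(spec, "feature_spec")) stop("`spec` must be a feature_spec", call. = FALSE)
  check_mask(tumor_mask); check_mask(background_mask)
  if (sum(tumor_mask) < 27L || sum(background_mask) < 27L)
    stop("both calibration masks need at least 27 voxels", call. = FALSE)
  if (any(tumor_mask & background_mask))
    stop("calibration masks must be disjoint", call. = FALSE)
  if (spec$name != "kurtosis" && is.null(spec$edges) &&
      identical(spec$binning, "fixed-global")) {
    both <- tumor_mask | background_mask
    bb <- mask_bbox(both)
    box <- image$values[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3]]
    rng <- range(box)
    if (rng[2] <= rng[1]) rng[2] <- rng[1] + 1
    spec$edges <- seq(rng[1], rng[2], length.out = spec$n_levels + 1L)
  }
  ft <- compute_feature(image, tumor_mask, spec)
  fb <- compute_feature(image, background_mask, spec)
  if (ft == fb) stop("feature not discriminative", call. = FALSE)
  theta <- (ft + fb) / 2
  accept <- if (ft < theta) "below" else "above"
  spec$threshold <- theta
  spec$accept <- accept
  list(threshold = theta, accept = accept,
       feature_tumor = ft, feature_background = fb, spec = spec)
}

#' Calibrate a stop threshold at the lesion boundary of a known object
#'
#' Phantom-style calibration for images where the lesion geometry is known
#' (e.g. the synthetic sphere phantom): the feature is evaluated on the
#' true lesion mask ("inside") and on the lesion grown by `layers`
#' one-voxel shells ("spilled"), and the threshold is placed between the
#' two — the decision the region grower actually faces at the object
#' boundary. This stands in for thresholds imported from prior clinical
#' material when no textured background exists to calibrate against.
#'
#' The geometric midpoint is the default for long-zone emphasis, which is
#' a ratio-scale statistic spanning orders of magnitude across the
#' boundary; the arithmetic midpoint is used otherwise.
#'
#' @param image a [vol_image].
#' @param truth logical mask of the known object (>= 27 voxels).
#' @param spec a [feature_spec()]; threshold/accept fields are ignored.
#' @param layers how many one-voxel dilation shells define the spilled
#'   region (default 2).
#' @param midpoint `"arithmetic"` or `"geometric"`; default geometric for
#'   `long_zone_emphasis`, arithmetic otherwise.
#' @return Same shape as [calibrate_threshold()]: list with `threshold`,
#'   `accept`, `feature_tumor` (inside), `feature_background` (spilled),
#'   and the calibrated `spec`.
#' @export
calibrate_boundary <- function(image, truth, spec, layers = 2L,
                               midpoint = NULL) {
  if (!inherits(image, "vol_image")) stop("`image` must be a vol_image", call. = FALSE)
  if (!inherits(spec, "feature_spec")) stop("`spec` must be a feature_spec", call. = FALSE)
  check_mask(truth)
  if (sum(truth) < 27L) stop("`truth` needs at least 27 voxels", call. = FALSE)
  if (is.null(midpoint))
    midpoint <- if (spec$name == "long_zone_emphasis") "geometric" else "arithmetic"
  midpoint <- match.arg(midpoint, c("arithmetic", "geometric"))
  spilled <- dilate_mask(truth, as.integer(layers))
  fi <- compute_feature(image, truth, spec)
  fo <- compute_feature(image, spilled, spec)
  if (fi == fo) stop("feature not discriminative", call. = FALSE)
  theta <- if (midpoint == "geometric") {
    if (fi <= 0 || fo <= 0)
      stop("geometric midpoint needs positive feature values", call. = FALSE)
    sqrt(fi * fo)
  } else (fi + fo) / 2
  accept <- if (fi < theta) "below" else "above"
  spec$threshold <- theta
  spec$accept <- accept
  list(threshold = theta, accept = accept,
       feature_tumor = fi, feature_background = fo, spec = spec)
}
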