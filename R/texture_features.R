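# Textural features used as region-growing stop criteria:
# intensity kurtosis (first order), local entropy of the gray-level
# co-occurrence matrix (GLCM, "M1"), and long-zone emphasis of the
# gray-level size-zone matrix (GLSZM, "M4").

#' Specification of a textural stop criterion
#'
#' Bundles the feature name, its stop threshold, the side of the threshold
#' on which a candidate region is accepted, and the discretization settings
#' used for the matrix-based features.
#'
#' @param name one of `"kurtosis"`, `"local_entropy"`, `"long_zone_emphasis"`.
#' @param threshold stop threshold for the feature. No universal default
#'   exists: thresholds depend on scanner, reconstruction and discretization,
#'   and should be supplied by the user or obtained with
#'   [calibrate_threshold()].
#' @param accept `"below"` (candidate accepted while feature < threshold) or
#'   `"above"` (accepted while feature > threshold). Comparison is strict;
#'   a candidate exactly at the threshold is rejected.
#' @param n_levels number of gray levels G used to discretize intensities
#'   for the GLCM/GLSZM features (default 64). Ignored for kurtosis, which
#'   operates on raw intensities.
#' @param binning `"fixed-global"` (default): [texture_region_grow()]
#'   derives bin edges once from the neighbourhood of the start region, so
#'   absolute feature values are comparable across growth steps; or
#'   `"per-region"`: bins are recomputed from the min/max inside each
#'   evaluated region, the common radiomics convention, which makes the
#'   features react sharply when the region spills into tissue of a
#'   different intensity range (the dynamic range jump redistributes every
#'   bin at once).
#' @param edges optional length `n_levels + 1` ascending vector of bin
#'   edges fixing the discretization globally (implies fixed-global
#'   binning).
#' @return A `feature_spec` object (a validated list).
#' @export
feature_spec <- function(name = c("kurtosis", "local_entropy", "long_zone_emphasis"),
                         threshold = NA_real_,
                         accept = c("below", "above"),
                         n_levels = 64L,
                         binning = c("fixed-global", "per-region"),
                         edges = NULL) {
  name <- match.arg(name)
  accept <- match.arg(accept)
  binning <- match.arg(binning)
  threshold <- as.numeric(threshold)
  if (length(threshold) != 1L || is.nan(threshold))
    stop("`threshold` must be a single number (may be NA until calibrated)", call. = FALSE)
  n_levels <- as.integer(n_levels)
  if (is.na(n_levels) || n_levels < 2L)
    stop("`n_levels` must be an integer >= 2", call. = FALSE)
  if (!is.null(edges)) {
    edges <- as.numeric(edges)
    if (length(edges) != n_levels + 1L || any(diff(edges) <= 0))
      stop("`edges` must be ", n_levels + 1L, " strictly ascending values", call. = FALSE)
  }
  if (!is.null(edges)) binning <- "fixed-global"
  structure(list(name = name, threshold = threshold, accept = accept,
                 n_levels = n_levels, binning = binning, edges = edges),
            class = "feature_spec")
}

#' @export
print.feature_spec <- function(x, ...) {
  cat(sprintf("<feature_spec> %s, accept %s threshold %s",
              x$name, x$accept,
              if (is.na(x$threshold)) "<uncalibrated>" else format(x$threshold)))
  if (x$name != "kurtosis")
    cat(sprintf(", %d gray levels%s", x$n_levels,
                if (is.null(x$edges)) "" else " (fixed edges)"))
  cat("\n")
  invisible(x)
}

#' Discretize intensities inside a mask into G gray levels
#'
#' Uniform binning: level = clamp(floor(G * (x - lo) / (hi - lo)) + 1, 1, G),
#' with `[lo, hi]` taken from `edges` if supplied, otherwise from the
#' intensity range inside the mask. A constant region maps every voxel to
#' level 1.
#'
#' @param image a [vol_image] (or bare 3D numeric array).
#' @param mask 3D logical array congruent with the image.
#' @param n_levels number of gray levels G (>= 2).
#' @param edges optional `n_levels + 1` ascending bin edges.
#' @return A `discretized_region`: list with `levels` (integer array, `NA`
#'   outside the mask), `n_levels`, and the `edges` used.
#' @export
discretize <- function(image, mask, n_levels = 64L, edges = NULL) {
  vals <- if (inherits(image, "vol_image")) image$values else image
  check_mask(mask)
  if (!identical(dim(vals), dim(mask)))
    stop("image and mask dimensions differ", call. = FALSE)
  if (!any(mask)) stop("empty mask", call. = FALSE)
  n_levels <- as.integer(n_levels)
  if (is.na(n_levels) || n_levels < 2L)
    stop("`n_levels` must be an integer >= 2", call. = FALSE)
  x <- vals[mask]
  if (is.null(edges)) {
    lo <- min(x); hi <- max(x)
  } else {
    edges <- as.numeric(edges)
    if (length(edges) != n_levels + 1L || any(diff(edges) <= 0))
      stop("`edges` must be ", n_levels + 1L, " strictly ascending values", call. = FALSE)
    lo <- edges[1L]; hi <- edges[n_levels + 1L]
  }
  if (hi <= lo) {
    lev <- rep.int(1L, length(x))
    edges <- lo + seq(0, 1, length.out = n_levels + 1L)
  } else {
    lev <- pmin.int(pmax.int(floor(n_levels * (x - lo) / (hi - lo)) + 1, 1), n_levels)
    lev <- as.integer(lev)
    if (is.null(edges)) edges <- seq(lo, hi, length.out = n_levels + 1L)
  }
  levels <- array(NA_integer_, dim(mask))
  levels[mask] <- lev
  structure(list(levels = levels, n_levels = n_levels, edges = edges),
            class = "discretized_region")
}

#' Gray-level co-occurrence matrix (M1) of a discretized region
#'
#' Counts of gray-level pairs over the 13 unique 3D neighbour offsets at
#' Chebyshev distance 1, symmetrized (each pair counted in both orders),
#' restricted to voxel pairs that both belong to the region, and normalized
#' to sum 1. All offsets are aggregated into a single matrix.
#'
#' @param region a `discretized_region` from [discretize()].
#' @return A `cooc_matrix`: G x G numeric matrix of pair probabilities.
#' @export
cooccurrence <- function(region) {
  if (!inherits(region, "discretized_region"))
    stop("`region` must come from discretize()", call. = FALSE)
  L <- region$levels
  G <- region$n_levels
  d <- dim(L)
  counts <- matrix(0, G, G)
  offs <- neighbour_offsets_13
  for (o in seq_len(nrow(offs))) {
    a <- offs[o, 1]; b <- offs[o, 2]; cc <- offs[o, 3]
    if (abs(a) >= d[1] || abs(b) >= d[2] || abs(cc) >= d[3]) next
    si <- if (a >= 0) 1L:(d[1] - a) else (1L - a):d[1]
    sj <- if (b >= 0) 1L:(d[2] - b) else (1L - b):d[2]
    sk <- if (cc >= 0) 1L:(d[3] - cc) else (1L - cc):d[3]
    A <- L[si, sj, sk, drop = FALSE]
    B <- L[si + a, sj + b, sk + cc, drop = FALSE]
    ok <- !is.na(A) & !is.na(B)
    if (!any(ok)) next
    idx <- A[ok] + (B[ok] - 1L) * G
    counts <- counts + matrix(tabulate(idx, nbins = G * G), G, G)
  }
  counts <- counts + t(counts)  # symmetrize: each pair in both orders
  total <- sum(counts)
  if (total == 0) stop("no voxel pairs", call. = FALSE)
  structure(counts / total, class = c("cooc_matrix", "matrix"))
}

#' Gray-level size-zone matrix (M4) of a discretized region
#'
#' Zones are maximal 26-connected components of voxels sharing the same
#' gray level within the region. Entry (i, j) counts the zones of gray
#' level i and size j voxels; hence `sum(M4[i, j] * j)` equals the number
#' of member voxels.
#'
#' @inheritParams cooccurrence
#' @return A `size_zone_matrix`: list with integer `counts` (G x Jmax) and
#'   `n_levels`.
#' @export
size_zone <- function(region) {
  if (!inherits(region, "discretized_region"))
    stop("`region` must come from discretize()", call. = FALSE)
  L <- region$levels
  G <- region$n_levels
  d <- dim(L)
  mem <- which(!is.na(L))
  if (!length(mem)) stop("empty region", call. = FALSE)
  serial <- array(NA_integer_, d)
  serial[mem] <- seq_along(mem)
  offs <- neighbour_offsets_13
  edges <- vector("list", nrow(offs))
  for (o in seq_len(nrow(offs))) {
    a <- offs[o, 1]; b <- offs[o, 2]; cc <- offs[o, 3]
    if (abs(a) >= d[1] || abs(b) >= d[2] || abs(cc) >= d[3]) next
    si <- if (a >= 0) 1L:(d[1] - a) else (1L - a):d[1]
    sj <- if (b >= 0) 1L:(d[2] - b) else (1L - b):d[2]
    sk <- if (cc >= 0) 1L:(d[3] - cc) else (1L - cc):d[3]
    A <- L[si, sj, sk, drop = FALSE]
    B <- L[si + a, sj + b, sk + cc, drop = FALSE]
    SA <- serial[si, sj, sk, drop = FALSE]
    SB <- serial[si + a, sj + b, sk + cc, drop = FALSE]
    sel <- !is.na(A) & !is.na(B) & A == B
    if (any(sel)) edges[[o]] <- cbind(SA[sel], SB[sel])
  }
  el <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(mem), directed = FALSE)
  if (!is.null(el) && nrow(el)) g <- igraph::add_edges(g, t(el))
  comp <- igraph::components(g)
  zone_size <- comp$csize
  zone_level <- L[mem][match(seq_len(comp$no), comp$membership)]
  jmax <- max(zone_size)
  idx <- zone_level + (zone_size - 1L) * G
  counts <- matrix(tabulate(idx, nbins = G * jmax), G, jmax)
  structure(list(counts = counts, n_levels = G), class = "size_zone_matrix")
}

#' Kurtosis of a set of intensities
#'
#' Fourth standardized moment, (1/N) * sum(((x - mean) / sd)^4), using the
#' population (1/N) standard deviation, in the non-excess convention
#' (Gaussian data give values near 3). The Pearson lower bound guarantees
#' a result >= 1 for any distribution.
#'
#' @param x numeric vector of at least 2 values with nonzero variance.
#' @return The kurtosis (dimensionless scalar).
#' @export
region_kurtosis <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2L) stop("kurtosis needs at least 2 values", call. = FALSE)
  m <- mean(x)
  v <- mean((x - m)^2)
  if (v <= 0 || !is.finite(v)) stop("degenerate region: zero variance", call. = FALSE)
  mean(((x - m) / sqrt(v))^4)
}

#' Local entropy of a co-occurrence matrix
#'
#' Shannon entropy -sum(p * log2(p)) over the nonzero entries of the
#' normalized GLCM; lies in `[0, 2 * log2(G)]`.
#'
#' @param m1 a `cooc_matrix` from [cooccurrence()] (or any matrix of
#'   non-negative probabilities summing to 1).
#' @return Entropy in bits.
#' @export
local_entropy <- function(m1) {
  p <- as.numeric(m1)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-6)
    stop("`m1` must be a normalized co-occurrence matrix", call. = FALSE)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Long-zone emphasis of a size-zone matrix
#'
#' sum(M4[i, j] * j^2) / sum(M4[i, j]): the zone-count-weighted mean of the
#' squared zone size. Large homogeneous zones dominate; the value is always
#' >= 1, with equality when every zone is a single voxel.
#'
#' @param m4 a `size_zone_matrix` from [size_zone()].
#' @return The long-zone emphasis (dimensionless scalar, >= 1).
#' @export
long_zone_emphasis <- function(m4) {
  cnt <- if (inherits(m4, "size_zone_matrix")) m4$counts else as.matrix(m4)
  total <- sum(cnt)
  if (total == 0) stop("size-zone matrix has no zones", call. = FALSE)
  j2 <- seq_len(ncol(cnt))^2
  sum(colSums(cnt) * j2) / total
}

#' Evaluate a textural feature on a masked region of an image
#'
#' Dispatches on the feature name: kurtosis is computed on raw intensities;
#' the matrix features go through [discretize()] and the GLCM or GLSZM.
#' Computation is restricted to the bounding box of the mask.
#'
#' @param image a [vol_image].
#' @param mask 3D logical array congruent with the image.
#' @param spec a [feature_spec()]. If `spec$edges` is set, discretization
#'   uses those fixed global bin edges.
#' @return The scalar feature value.
#' @export
compute_feature <- function(image, mask, spec) {
  if (!inherits(spec, "feature_spec"))
    stop("`spec` must be a feature_spec", call. = FALSE)
  vals <- if (inherits(image, "vol_image")) image$values else image
  if (!identical(dim(vals), dim(mask)))
    stop("image and mask dimensions differ", call. = FALSE)
  if (spec$name == "kurtosis") return(region_kurtosis(vals[mask]))
  bb <- mask_bbox(mask)
  sub_v <- vals[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3], drop = FALSE]
  sub_m <- mask[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3], drop = FALSE]
  reg <- discretize(sub_v, sub_m, spec$n_levels, spec$edges)
  switch(spec$name,
         local_entropy = local_entropy(cooccurrence(reg)),
         long_zone_emphasis = long_zone_emphasis(size_zone(reg)))
}
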