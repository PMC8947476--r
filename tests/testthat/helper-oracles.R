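# Independent brute-force oracles used to verify the texture matrices,
# features and the region-growing scheme. These deliberately use plain
# loops / index arithmetic rather than the vectorised implementation paths.

rand_image <- function(dim3, seed, spacing = c(1, 1, 1)) {
  set.seed(seed)
  vol_image(array(stats::runif(prod(dim3)), dim3), spacing)
}

rand_mask <- function(dim3, seed, p = 0.6) {
  set.seed(seed)
  m <- array(stats::runif(prod(dim3)) < p, dim3)
  if (!any(m)) m[1] <- TRUE
  m
}

all_offsets_26 <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
all_offsets_26 <- all_offsets_26[rowSums(all_offsets_26 != 0) > 0, ]

# GLCM by exhaustive enumeration: every ordered neighbour pair counted once
# (the 26 offsets cover both orders of each of the 13 unique directions).
brute_glcm <- function(levels, G) {
  d <- dim(levels)
  counts <- matrix(0, G, G)
  for (lin in which(!is.na(levels))) {
    co <- arrayInd(lin, d)
    for (o in seq_len(nrow(all_offsets_26))) {
      nb <- co + all_offsets_26[o, ]
      if (any(nb < 1) || any(nb > d)) next
      lv <- levels[nb[1], nb[2], nb[3]]
      if (is.na(lv)) next
      a <- levels[lin]
      counts[a, lv] <- counts[a, lv] + 1
    }
  }
  if (sum(counts) == 0) stop("no pairs")
  counts / sum(counts)
}

# GLSZM by stack-based flood fill over equal-level 26-neighbourhoods.
brute_szm <- function(levels, G) {
  d <- dim(levels)
  lab <- array(0L, d)
  zones <- list()
  nxt <- 0L
  for (lin in which(!is.na(levels))) {
    if (lab[lin] > 0L) next
    nxt <- nxt + 1L
    lev <- levels[lin]
    stack <- lin
    lab[lin] <- nxt
    size <- 0L
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      size <- size + 1L
      co <- arrayInd(cur, d)
      for (o in seq_len(nrow(all_offsets_26))) {
        nb <- co + all_offsets_26[o, ]
        if (any(nb < 1) || any(nb > d)) next
        nl <- nb[1] + (nb[2] - 1L) * d[1] + (nb[3] - 1L) * d[1] * d[2]
        if (!is.na(levels[nl]) && levels[nl] == lev && lab[nl] == 0L) {
          lab[nl] <- nxt
          stack <- c(stack, nl)
        }
      }
    }
    zones[[nxt]] <- c(lev, size)
  }
  zm <- do.call(rbind, zones)
  counts <- matrix(0L, G, max(zm[, 2]))
  for (i in seq_len(nrow(zm)))
    counts[zm[i, 1], zm[i, 2]] <- counts[zm[i, 1], zm[i, 2]] + 1L
  counts
}

brute_kurtosis <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  s2 <- sum((x - m)^2) / n
  sum(((x - m) / sqrt(s2))^4) / n
}

brute_entropy <- function(p) {
  tot <- 0
  for (v in as.numeric(p)) if (v > 0) tot <- tot - v * log2(v)
  tot
}

brute_lze <- function(counts) {
  num <- 0; den <- 0
  for (i in seq_len(nrow(counts))) for (j in seq_len(ncol(counts))) {
    num <- num + counts[i, j] * j^2
    den <- den + counts[i, j]
  }
  num / den
}

brute_diameter <- function(mask, spacing) {
  co <- which(mask, arr.ind = TRUE)
  best <- 0
  if (nrow(co) < 2) return(0)
  for (i in 1:(nrow(co) - 1)) for (j in (i + 1):nrow(co)) {
    dd <- sqrt(sum(((co[i, ] - co[j, ]) * spacing)^2))
    if (dd > best) best <- dd
  }
  best
}

# 40%-of-max reference oracle: fixed-point on the supra-threshold component
# of the seed, component found by label propagation over a full scan.
brute_threshold_segment <- function(image, seed, fraction = 0.4) {
  vals <- image$values
  d <- dim(vals)
  cube <- vals[max(1, seed[1] - 1):min(d[1], seed[1] + 1),
               max(1, seed[2] - 1):min(d[2], seed[2] + 1),
               max(1, seed[3] - 1):min(d[3], seed[3] + 1)]
  cur_max <- max(cube)
  comp <- NULL
  for (round in 1:10) {
    supra <- vals >= fraction * cur_max
    start <- if (supra[seed[1], seed[2], seed[3]]) seed else {
      w <- which(vals == cur_max & supra, arr.ind = TRUE)[1, ]
      as.integer(w)
    }
    comp <- array(FALSE, d)
    comp[start[1], start[2], start[3]] <- TRUE
    repeat {
      grew <- FALSE
      for (lin in which(comp)) {
        co <- arrayInd(lin, d)
        for (o in seq_len(nrow(all_offsets_26))) {
          nb <- co + all_offsets_26[o, ]
          if (any(nb < 1) || any(nb > d)) next
          if (supra[nb[1], nb[2], nb[3]] && !comp[nb[1], nb[2], nb[3]]) {
            comp[nb[1], nb[2], nb[3]] <- TRUE
            grew <- TRUE
          }
        }
      }
      if (!grew) break
    }
    nm <- max(vals[comp])
    if (nm == cur_max) break
    cur_max <- nm
  }
  comp
}

# Straight-line re-implementation of the region-grow scheme: six
# independent one-voxel growth candidates from the current region, accept
# by strict comparison, union the accepted candidates, repeat.
reference_region_grow <- function(image, seed, spec, max_iterations = 200L) {
  d <- dim(image$values)
  V <- array(FALSE, d)
  V[(seed[1] - 1):(seed[1] + 1), (seed[2] - 1):(seed[2] + 1),
    (seed[3] - 1):(seed[3] + 1)] <- TRUE
  if (spec$name != "kurtosis" && is.null(spec$edges) &&
      identical(spec$binning, "fixed-global"))
    spec$edges <- petseg:::local_bin_edges(image, V, spec$n_levels, 30)
  pass <- function(f) if (spec$accept == "below") f < spec$threshold else f > spec$threshold
  f0 <- compute_feature(image, V, spec)
  tr <- list()
  if (!pass(f0))
    return(list(mask = V, trace = data.frame(), iterations = 0L, at_start = TRUE))
  dirs <- list(`+x` = c(1, 0, 0), `-x` = c(-1, 0, 0), `+y` = c(0, 1, 0),
               `-y` = c(0, -1, 0), `+z` = c(0, 0, 1), `-z` = c(0, 0, -1))
  it <- 0L
  repeat {
    it <- it + 1L
    U <- V
    idx <- which(V, arr.ind = TRUE)
    for (dn in names(dirs)) {
      tgt <- sweep(idx, 2, dirs[[dn]], `+`)
      keep <- tgt[, 1] >= 1 & tgt[, 1] <= d[1] &
              tgt[, 2] >= 1 & tgt[, 2] <= d[2] &
              tgt[, 3] >= 1 & tgt[, 3] <= d[3]
      C <- V
      C[tgt[keep, , drop = FALSE]] <- TRUE
      if (sum(C) == sum(V)) next
      f <- compute_feature(image, C, spec)
      acc <- pass(f)
      tr[[length(tr) + 1L]] <- data.frame(
        iteration = it, direction = dn, feature = f, accepted = acc,
        volume_ccm = sum(C) * prod(image$spacing) / 1000)
      if (acc) U <- U | C
    }
    if (sum(U) == sum(V) || it >= max_iterations) break
    V <- U
  }
  list(mask = V, trace = do.call(rbind, tr), iterations = it, at_start = FALSE)
}
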