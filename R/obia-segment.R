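#' Multiresolution region-merging segmentation
#'
#' Object-based image analysis segmentation in the Baatz--Schaepe family:
#' starting from single-pixel regions, adjacent regions are merged
#' pairwise while the heterogeneity increase of the cheapest merge stays
#' below `scale^2`. The merge cost is
#' `f = (1 - w_shape) * dh_colour + w_shape * dh_shape`, where
#' `dh_colour = sum_layers weight * (n_m * sd_m - n1 * sd1 - n2 * sd2)`
#' (population standard deviations) and `dh_shape` mixes compactness
#' (`n * perimeter / sqrt(n)`) and smoothness (`n * perimeter /
#' bounding-box perimeter`) with weight `w_cmpct`. The merge order is the
#' global minimum cost (which is always a mutual best fit), with ties
#' broken by the lower cost then the lower smaller-region id, so the
#' result is deterministic.
#'
#' @param layers list of co-registered [scene_raster]s (or matrices of one
#'   shape): typically orthomosaic bands, the DEM and slope.
#' @param scale scale parameter; merging stops when the cheapest merge
#'   cost reaches `scale^2`. Tool-specific values from commercial software
#'   do not transfer; see [suggest_scale()].
#' @param w_shape shape weight in `[0, 1)` (default 0.1).
#' @param w_cmpct compactness weight in `[0, 1]` (default 0.5).
#' @param layer_weights per-layer weights (default all 1).
#' @return a `segment_map`: list with `labels` (a [scene_raster] of segment
#'   ids `1..n_segments`, each segment 4-connected), `n_segments`,
#'   `merge_costs` (costs of executed merges in order) and the parameters.
#' @export
segment_scene <- function(layers, scale, w_shape = 0.1, w_cmpct = 0.5,
                          layer_weights = NULL) {
  mats <- lapply(layers, function(l) if (is_scene_raster(l)) l$values else l)
  d <- dim(mats[[1]])
  for (m in mats) {
    if (!identical(dim(m), d)) stop("layer shapes differ (not co-registered)")
    if (anyNA(m)) stop("segmentation layers must not contain nodata cells")
  }
  if (scale <= 0) stop("`scale` must be positive")
  if (w_shape < 0 || w_shape >= 1) stop("`w_shape` must be in [0, 1)")
  if (w_cmpct < 0 || w_cmpct > 1) stop("`w_cmpct` must be in [0, 1]")
  L <- length(mats)
  if (is.null(layer_weights)) layer_weights <- rep(1, L)
  if (length(layer_weights) != L) stop("one weight per layer required")

  nr <- d[1]; nc <- d[2]; n <- nr * nc
  thr <- scale^2
  X <- vapply(mats, as.vector, numeric(n))      # n x L, column-major cells
  if (is.null(dim(X))) X <- matrix(X, ncol = L)
  w <- layer_weights

  # per-region state, indexed by region id (initially the pixel index)
  cnt <- rep(1, n)
  Sm <- X                       # sums per layer
  Sq <- X^2                     # sums of squares
  perim <- rep(4, n)
  row_i <- rep(seq_len(nr), nc)
  col_i <- rep(seq_len(nc), each = nr)
  bb <- cbind(row_i, row_i, col_i, col_i)   # rmin, rmax, cmin, cmax
  hcol <- rep(0, n)                         # sum_l w_l * n * sd_l
  hcmp <- rep(4, n)                         # sqrt(n) * perim
  hsm <- rep(1, n)                          # n * perim / bbox perim
  alive <- rep(TRUE, n)
  parent <- seq_len(n)

  # adjacency: neighbour ids and shared boundary edge counts
  nb <- vector("list", n)
  sbc <- vector("list", n)
  id <- matrix(seq_len(n), nr, nc)
  for (px in seq_len(n)) {
    r <- row_i[px]; cc <- col_i[px]
    ids <- integer(0)
    if (r > 1) ids <- c(ids, id[r - 1, cc])
    if (r < nr) ids <- c(ids, id[r + 1, cc])
    if (cc > 1) ids <- c(ids, id[r, cc - 1])
    if (cc < nc) ids <- c(ids, id[r, cc + 1])
    nb[[px]] <- ids
    sbc[[px]] <- rep(1, length(ids))
  }

  pair_cost <- function(r1, r2, shared) {
    n1 <- cnt[r1]; n2 <- cnt[r2]; nm <- n1 + n2
    sm <- Sm[r1, ] + Sm[r2, ]
    sq <- Sq[r1, ] + Sq[r2, ]
    sdm <- sqrt(pmax(sq / nm - (sm / nm)^2, 0))
    dcol <- sum(w * nm * sdm) - hcol[r1] - hcol[r2]
    if (w_shape > 0) {
      pm <- perim[r1] + perim[r2] - 2 * shared
      rmin <- min(bb[r1, 1], bb[r2, 1]); rmax <- max(bb[r1, 2], bb[r2, 2])
      cmin <- min(bb[r1, 3], bb[r2, 3]); cmax <- max(bb[r1, 4], bb[r2, 4])
      bper <- 2 * ((rmax - rmin + 1) + (cmax - cmin + 1))
      dcmp <- sqrt(nm) * pm - hcmp[r1] - hcmp[r2]
      dsm <- nm * pm / bper - hsm[r1] - hsm[r2]
      dshape <- w_cmpct * dcmp + (1 - w_cmpct) * dsm
    } else dshape <- 0
    (1 - w_shape) * dcol + w_shape * dshape
  }

  best_of <- function(r) {
    ids <- nb[[r]]
    if (!length(ids)) return(c(Inf, NA))
    costs <- vapply(seq_along(ids),
                    function(j) pair_cost(r, ids[j], sbc[[r]][j]),
                    numeric(1))
    j <- which.min(pmax(costs, 0) + 0)  # ties: first = lowest stored order
    # deterministic tie-break on neighbour id
    mn <- min(costs)
    cand <- ids[costs <= mn + 0]
    c(mn, min(cand))
  }

  bestc <- rep(Inf, n)
  bestp <- rep(NA_integer_, n)

  # vectorised initial neighbour costs (all regions are single pixels)
  init_shape <- w_cmpct * (sqrt(2) * 6 - 8)          # smoothness term is 0
  hpair <- function(a_idx, b_idx) {
    dcol <- abs(X[a_idx, , drop = FALSE] - X[b_idx, , drop = FALSE]) %*% w
    (1 - w_shape) * as.vector(dcol) + w_shape * init_shape
  }
  # horizontal neighbours (same row, adjacent columns) and vertical
  hz_a <- as.vector(id[, -nc]); hz_b <- as.vector(id[, -1])
  vt_a <- as.vector(id[-nr, ]); vt_b <- as.vector(id[-1, ])
  ecost <- c(hpair(hz_a, hz_b), hpair(vt_a, vt_b))
  ea <- c(hz_a, vt_a); eb <- c(hz_b, vt_b)
  for (k in seq_along(ea)) {
    a <- ea[k]; b <- eb[k]; ck <- ecost[k]
    if (ck < bestc[a] || (ck == bestc[a] && b < bestp[a])) {
      bestc[a] <- ck; bestp[a] <- b
    }
    if (ck < bestc[b] || (ck == bestc[b] && a < bestp[b])) {
      bestc[b] <- ck; bestp[b] <- a
    }
  }

  merge_costs <- numeric(0)
  repeat {
    m <- which.min(bestc)
    if (!is.finite(bestc[m]) || bestc[m] >= thr) break
    r2 <- max(m, bestp[m]); r1 <- min(m, bestp[m])
    merge_costs <- c(merge_costs, bestc[m])

    # combine stats into r1
    j2 <- match(r2, nb[[r1]])
    shared <- sbc[[r1]][j2]
    nm <- cnt[r1] + cnt[r2]
    Sm[r1, ] <- Sm[r1, ] + Sm[r2, ]
    Sq[r1, ] <- Sq[r1, ] + Sq[r2, ]
    perim[r1] <- perim[r1] + perim[r2] - 2 * shared
    bb[r1, ] <- c(min(bb[r1, 1], bb[r2, 1]), max(bb[r1, 2], bb[r2, 2]),
                  min(bb[r1, 3], bb[r2, 3]), max(bb[r1, 4], bb[r2, 4]))
    cnt[r1] <- nm
    sdm <- sqrt(pmax(Sq[r1, ] / nm - (Sm[r1, ] / nm)^2, 0))
    hcol[r1] <- sum(w * nm * sdm)
    hcmp[r1] <- sqrt(nm) * perim[r1]
    hsm[r1] <- nm * perim[r1] /
      (2 * ((bb[r1, 2] - bb[r1, 1] + 1) + (bb[r1, 4] - bb[r1, 3] + 1)))

    # merge adjacency lists
    u1 <- nb[[r1]]; s1 <- sbc[[r1]]
    u2 <- nb[[r2]]; s2 <- sbc[[r2]]
    keep1 <- u1 != r2; keep2 <- u2 != r1
    u1 <- u1[keep1]; s1 <- s1[keep1]
    u2 <- u2[keep2]; s2 <- s2[keep2]
    uni <- union(u1, u2)
    suni <- numeric(length(uni))
    suni[match(u1, uni)] <- s1
    dup <- match(u2, uni)
    suni[dup] <- suni[dup] + s2
    nb[[r1]] <- uni; sbc[[r1]] <- suni
    nb[[r2]] <- integer(0); sbc[[r2]] <- numeric(0)
    alive[r2] <- FALSE
    parent[r2] <- r1
    bestc[r2] <- Inf; bestp[r2] <- NA_integer_

    # rewire neighbours of the pair to point at r1
    for (u in uni) {
      ids <- nb[[u]]; sh <- sbc[[u]]
      i1 <- match(r1, ids); i2 <- match(r2, ids)
      if (!is.na(i1) && !is.na(i2)) {
        sh[i1] <- sh[i1] + sh[i2]
        ids <- ids[-i2]; sh <- sh[-i2]
      } else if (!is.na(i2)) {
        ids[i2] <- r1
      }
      nb[[u]] <- ids; sbc[[u]] <- sh
    }

    # refresh best pairs: r1 fully; neighbours incrementally
    bf <- best_of(r1)
    bestc[r1] <- bf[1]; bestp[r1] <- as.integer(bf[2])
    for (u in uni) {
      if (!alive[u]) next
      if (!is.na(bestp[u]) && (bestp[u] == r1 || bestp[u] == r2)) {
        bf <- best_of(u)
        bestc[u] <- bf[1]; bestp[u] <- as.integer(bf[2])
      } else {
        cu <- pair_cost(u, r1, sbc[[u]][match(r1, nb[[u]])])
        if (cu < bestc[u] || (cu == bestc[u] && r1 < bestp[u])) {
          bestc[u] <- cu; bestp[u] <- r1
        }
      }
    }
  }

  # resolve labels and renumber contiguously
  find_root <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  roots <- seq_len(n)
  for (i in seq_len(n)) {
    r <- i
    path <- integer(0)
    while (parent[r] != r) { path <- c(path, r); r <- parent[r] }
    parent[path] <- r
    roots[i] <- r
  }
  lab <- match(roots, sort(unique(roots[alive[roots]])))
  labels <- matrix(lab, nr, nc)

  cs <- if (is_scene_raster(layers[[1]])) layers[[1]]$cell_size else 1
  org <- if (is_scene_raster(layers[[1]])) layers[[1]]$origin else c(0, nr)
  structure(
    list(labels = scene_raster(labels, cs, origin = org, band = "segment"),
         n_segments = max(lab),
         merge_costs = merge_costs,
         scale = scale, w_shape = w_shape, w_cmpct = w_cmpct,
         layer_weights = w),
    class = "segment_map")
}

#' @export
print.segment_map <- function(x, ...) {
  cat(sprintf(
    "<segment_map> %d segments over %d x %d cells (scale %.4g, w_shape %.2f)\n",
    x$n_segments, nrow(x$labels$values), ncol(x$labels$values),
    x$scale, x$w_shape))
  invisible(x)
}

#' Suggest a scale parameter for a target segment count
#'
#' Scale parameters are tool- and data-specific and do not transfer
#' between implementations. This helper merges a scene to completion,
#' records the executed merge costs, and returns the scale whose
#' `scale^2` threshold would have stopped the sequence at approximately
#' `target_segments` regions. Heuristic: merge costs are only
#' near-monotone, so treat the value as a starting point.
#'
#' @inheritParams segment_scene
#' @param target_segments desired number of segments.
#' @return suggested scale (numeric).
#' @export
suggest_scale <- function(layers, target_segments, w_shape = 0.1,
                          w_cmpct = 0.5, layer_weights = NULL) {
  sm <- segment_scene(layers, scale = .Machine$double.xmax^0.25,
                      w_shape = w_shape, w_cmpct = w_cmpct,
                      layer_weights = layer_weights)
  costs <- sm$merge_costs
  n0 <- length(costs) + sm$n_segments   # initial region count
  stopmerge <- n0 - target_segments     # merges executed before stopping
  if (stopmerge <= 0) return(sqrt(max(min(costs), 0)) * 0.99)
  if (stopmerge >= length(costs)) return(sqrt(max(costs)) * 1.01)
  sqrt(max((costs[stopmerge] + costs[stopmerge + 1]) / 2, 0))
}
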