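# Independent brute-force oracles and small fixture builders. Everything
# here is deliberately written the slow, literal way so it never shares
# code with the implementation it checks.

# --- terrain: literal 3x3 Horn stencil evaluated cell by cell -----------
oracle_horn <- function(z, cs) {
  nr <- nrow(z); nc <- ncol(z)
  gx <- gy <- matrix(NA_real_, nr, nc)
  for (r in 2:(nr - 1)) for (cc in 2:(nc - 1)) {
    w <- z[(r - 1):(r + 1), (cc - 1):(cc + 1)]
    if (anyNA(w)) next
    gx[r, cc] <- ((w[1, 3] + 2 * w[2, 3] + w[3, 3]) -
                  (w[1, 1] + 2 * w[2, 1] + w[3, 1])) / (8 * cs)
    gy[r, cc] <- ((w[1, 1] + 2 * w[1, 2] + w[1, 3]) -
                  (w[3, 1] + 2 * w[3, 2] + w[3, 3])) / (8 * cs)
  }
  list(slope = atan(sqrt(gx^2 + gy^2)) * 180 / pi,
       aspect = (atan2(-gx, -gy) * 180 / pi) %% 360,
       gx = gx, gy = gy)
}

# --- obia: per-pixel accumulation of segment features -------------------
oracle_features <- function(labels, mats) {
  ids <- sort(unique(as.vector(labels)))
  out <- list()
  for (i in ids) {
    sel <- labels == i
    row <- list(id = i, area = sum(sel))
    for (j in seq_along(mats)) {
      v <- mats[[j]][sel]
      row[[paste0("m", j)]] <- sum(v) / length(v)
      row[[paste0("s", j)]] <- sqrt(sum((v - mean(v))^2) / length(v))
    }
    out[[length(out) + 1]] <- row
  }
  out
}

# exhaustive nearest-neighbour scan in an already-standardized space
oracle_nn1 <- function(Zq, Ztr, classes, ids) {
  res <- character(nrow(Zq))
  for (i in seq_len(nrow(Zq))) {
    best <- Inf; bi <- NA
    for (j in seq_len(nrow(Ztr))) {
      d <- sum((Zq[i, ] - Ztr[j, ])^2)
      if (d < best || (d == best && ids[j] < ids[bi])) { best <- d; bi <- j }
    }
    res[i] <- classes[bi]
  }
  res
}

# recompute the Baatz-Schaepe merge cost of two regions straight from the
# label map and raw layer data (no reuse of package internals)
oracle_pair_cost <- function(labels, mats, w, r1, r2, w_shape, w_cmpct) {
  sel1 <- labels == r1; sel2 <- labels == r2; selm <- sel1 | sel2
  psd <- function(v) sqrt(mean((v - mean(v))^2))
  dcol <- 0
  for (j in seq_along(mats)) {
    v <- mats[[j]]
    dcol <- dcol + w[j] * (sum(selm) * psd(v[selm]) -
                           sum(sel1) * psd(v[sel1]) -
                           sum(sel2) * psd(v[sel2]))
  }
  per <- function(sel) {
    nr <- nrow(sel); nc <- ncol(sel); p <- 0
    for (r in seq_len(nr)) for (cc in seq_len(nc)) if (sel[r, cc]) {
      p <- p + (r == 1 || !sel[r - 1, cc]) + (r == nr || !sel[r + 1, cc]) +
        (cc == 1 || !sel[r, cc - 1]) + (cc == nc || !sel[r, cc + 1])
    }
    p
  }
  bboxp <- function(sel) {
    rr <- range(which(rowSums(sel) > 0)); cc <- range(which(colSums(sel) > 0))
    2 * ((rr[2] - rr[1] + 1) + (cc[2] - cc[1] + 1))
  }
  h <- function(sel) {
    n <- sum(sel); p <- per(sel)
    c(cmp = sqrt(n) * p, sm = n * p / bboxp(sel))
  }
  hm <- h(selm); h1 <- h(sel1); h2 <- h(sel2)
  dshape <- w_cmpct * (hm["cmp"] - h1["cmp"] - h2["cmp"]) +
    (1 - w_cmpct) * (hm["sm"] - h1["sm"] - h2["sm"])
  unname((1 - w_shape) * dcol + w_shape * dshape)
}

# all adjacent region pairs of a label map
adjacent_pairs <- function(labels) {
  nr <- nrow(labels); nc <- ncol(labels)
  p <- rbind(cbind(as.vector(labels[-nr, ]), as.vector(labels[-1, ])),
             cbind(as.vector(labels[, -nc]), as.vector(labels[, -1])))
  p <- p[p[, 1] != p[, 2], , drop = FALSE]
  unique(t(apply(p, 1, sort)))
}

# every label forms one 4-connected component and ids are 1..n
is_partition_4connected <- function(labels) {
  n <- max(labels)
  if (!setequal(unique(as.vector(labels)), seq_len(n))) return(FALSE)
  nr <- nrow(labels); nc <- ncol(labels)
  for (i in seq_len(n)) {
    cells <- which(labels == i)
    seen <- logical(length(labels))
    stack <- cells[1]; seen[cells[1]] <- TRUE; cnt <- 0
    while (length(stack)) {
      px <- stack[length(stack)]; stack <- stack[-length(stack)]
      cnt <- cnt + 1
      r <- (px - 1) %% nr + 1; cc <- (px - 1) %/% nr + 1
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        r2 <- r + d[1]; c2 <- cc + d[2]
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        q <- (c2 - 1) * nr + r2
        if (!seen[q] && labels[q] == i) { seen[q] <- TRUE; stack <- c(stack, q) }
      }
    }
    if (cnt != length(cells)) return(FALSE)
  }
  TRUE
}

# --- currents / integration: literal record scans -----------------------
oracle_facing_mean <- function(speed, direction, coral_aspect, tol) {
  opp <- (coral_aspect + 180) %% 360
  keep <- c()
  for (i in seq_along(speed)) {
    d <- abs(direction[i] - opp) %% 360
    if (min(d, 360 - d) <= tol) keep <- c(keep, speed[i])
  }
  if (!length(keep)) NA_real_ else sum(keep) / length(keep)
}

oracle_feeding_pct <- function(speed, direction, coral_aspect, smax, tol) {
  opp <- (coral_aspect + 180) %% 360
  hit <- 0
  for (i in seq_along(speed)) {
    d <- abs(direction[i] - opp) %% 360
    if (min(d, 360 - d) <= tol && speed[i] <= smax) hit <- hit + 1
  }
  100 * hit / length(speed)
}

oracle_exceedance <- function(speed) {
  c(lt5 = 100 * sum(speed < 5) / length(speed),
    lt10 = 100 * sum(speed < 10) / length(speed),
    gt30 = 100 * sum(speed > 30) / length(speed))
}

# Spearman by explicit counting ranks (average ranks for ties) + Pearson
oracle_spearman <- function(x, y) {
  rk <- function(v) {
    sapply(seq_along(v), function(i)
      1 + sum(v < v[i]) + (sum(v == v[i]) - 1) / 2)
  }
  rx <- rk(x); ry <- rk(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# --- samplers and builders ---------------------------------------------
# von Mises sampler (Best & Fisher rejection scheme); mu in degrees
rvonmises_deg <- function(n, mu_deg, kappa) {
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  th <- numeric(n); i <- 1
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1]); f <- (1 + r * z) / (r + z); cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      th[i] <- sign(u[3] - 0.5) * acos(pmin(pmax(f, -1), 1))
      i <- i + 1
    }
  }
  (mu_deg + th * 180 / pi) %% 360
}

# hand-built ADCP series from raw vectors (10-min cadence)
make_series <- function(speed, direction, tilt = 2, temp = 9,
                        start = as.POSIXct("2019-05-15 00:00:00", tz = "UTC")) {
  n <- length(speed)
  new_adcp_series(data.frame(
    timestamp = start + (seq_len(n) - 1) * 600,
    speed_cms = speed, direction_deg = direction,
    temp_c = rep_len(temp, n), tilt_deg = rep_len(tilt, n),
    pitch_deg = 0, roll_deg = 0))
}

# a fake segment map over an arbitrary label matrix (for feature tests)
make_segment_map <- function(labels, cell_size = 1) {
  structure(list(
    labels = scene_raster(labels, cell_size, origin = c(0, nrow(labels)),
                          band = "segment"),
    n_segments = max(labels), merge_costs = numeric(0),
    scale = NA_real_, w_shape = 0, w_cmpct = 0.5,
    layer_weights = NULL), class = "segment_map")
}

# random contiguous-ish partition: k seed cells grown by nearest seed
random_partition <- function(nr, nc, k) {
  sr <- sample(nr, k, replace = TRUE); sc <- sample(nc, k, replace = TRUE)
  lab <- matrix(0L, nr, nc)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    lab[r, cc] <- which.min((sr - r)^2 + (sc - cc)^2)
  }
  matrix(match(lab, sort(unique(as.vector(lab)))), nr, nc)
}
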