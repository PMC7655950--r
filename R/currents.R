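#' ADCP series container
#'
#' A data frame subclass holding fixed-cadence current-meter records with a
#' per-record QC mask. Columns: `timestamp` (POSIXct UTC), `speed_cms`
#' (>= 0), `direction_deg` (flow-toward azimuth in `[0, 360)`), `temp_c`,
#' `tilt_deg`, `pitch_deg`, `roll_deg`, `keep` (logical) and `qc_reason`
#' (`""` for kept records). All summary statistics use kept records only.
#'
#' @param df data frame with at least `timestamp`, `speed_cms`,
#'   `direction_deg`; attitude and temperature columns are optional
#'   (filled with `NA` when absent).
#' @return an object of classes `adcp_series`, `data.frame`.
#' @export
new_adcp_series <- function(df) {
  need <- c("timestamp", "speed_cms", "direction_deg")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  for (cc in c("temp_c", "tilt_deg", "pitch_deg", "roll_deg"))
    if (is.null(df[[cc]])) df[[cc]] <- NA_real_
  if (is.null(df$keep)) df$keep <- TRUE
  if (is.null(df$qc_reason)) df$qc_reason <- ""
  dt <- diff(as.numeric(df$timestamp))
  if (length(dt) && any(dt <= 0))
    stop("timestamps not strictly increasing at row ",
         which(dt <= 0)[1] + 1)
  if (any(!is.finite(df$speed_cms)) || any(df$speed_cms < 0))
    stop("speed must be finite and non-negative (row ",
         which(!is.finite(df$speed_cms) | df$speed_cms < 0)[1], ")")
  df$direction_deg <- df$direction_deg %% 360
  cadence <- if (length(dt)) min(dt) else NA_real_
  gaps <- which(dt > cadence + 1e-6)
  structure(df, class = c("adcp_series", "data.frame"),
            cadence_sec = cadence, gap_rows = gaps)
}

#' @export
print.adcp_series <- function(x, ...) {
  kept <- sum(x$keep)
  cat(sprintf("<adcp_series> %d records (%d kept), cadence %.0f s\n",
              nrow(x), kept, attr(x, "cadence_sec")))
  if (nrow(x)) {
    cat(sprintf("  %s .. %s UTC\n",
                format(x$timestamp[1], "%Y-%m-%d %H:%M"),
                format(x$timestamp[nrow(x)], "%Y-%m-%d %H:%M")))
    g <- attr(x, "gap_rows")
    if (length(g)) cat(sprintf("  %d cadence gap(s) flagged\n", length(g)))
  }
  invisible(x)
}

kept_records <- function(series) {
  stopifnot(inherits(series, "adcp_series"))
  as.data.frame(series)[series$keep, , drop = FALSE]
}

#' Read an ADCP series from CSV
#'
#' Expects the header `timestamp,speed_cms,direction_deg,temp_c,tilt_deg,
#' pitch_deg,roll_deg` (attitude/temperature columns optional). Validates
#' timestamp order, cadence (gaps are flagged, not fatal) and speed sign,
#' reporting the first offending row on failure.
#'
#' @param path CSV path.
#' @return an `adcp_series`.
#' @export
read_adcp <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "speed_cms", "direction_deg")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("ADCP file missing column(s): ", paste(miss, collapse = ", "))
  ts <- as.POSIXct(df$timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%SZ", "%Y-%m-%dT%H:%M:%S",
                                  "%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M"))
  if (any(is.na(ts)))
    stop("unparseable timestamp at row ", which(is.na(ts))[1])
  df$timestamp <- ts
  new_adcp_series(df)
}

#' Trim deployment margins and despike
#'
#' Drops a head and tail margin (deployment and retrieval periods, default
#' 1 h each) and flags spikes: records where the speed deviates from a
#' centred running median by more than `k` times the rolling median
#' absolute deviation. Flagged records are excluded from all downstream
#' statistics but retained in the table with a reason code.
#'
#' @param series an `adcp_series`.
#' @param margin_hours head/tail trim, hours.
#' @param window running-median window length, records (odd; default 13).
#' @param k spike threshold in rolling-MAD units (default 6).
#' @return the series with its QC mask updated.
#' @export
trim_and_despike <- function(series, margin_hours = 1, window = 13, k = 6) {
  stopifnot(inherits(series, "adcp_series"))
  n <- nrow(series)
  if (window >= n) stop("`window` longer than the series")
  if (window %% 2 == 0) window <- window + 1
  cadence <- attr(series, "cadence_sec")
  margin_n <- ceiling(margin_hours * 3600 / cadence)
  if (2 * margin_n >= n)
    stop("series shorter than the head/tail margins")

  keep <- series$keep
  reason <- series$qc_reason
  if (margin_n > 0) {
    idx <- c(seq_len(margin_n), seq(n - margin_n + 1, n))
    keep[idx] <- FALSE
    reason[idx] <- "deployment_margin"
  }

  sp <- series$speed_cms
  med <- stats::runmed(sp, window, endrule = "median")
  rmad <- zoo::rollapply(sp, window, stats::mad, partial = TRUE,
                         align = "center")
  spike <- abs(sp - med) > k * rmad
  spike[is.na(spike)] <- FALSE
  flag <- spike & keep
  keep[flag] <- FALSE
  reason[flag] <- "spike"

  out <- as.data.frame(series)
  out$keep <- keep
  out$qc_reason <- reason
  new_adcp_series(out)
}

#' Detect a lander topple from attitude data
#'
#' A lander that falls over shows a sustained tilt step. The baseline is
#' the median tilt over the first six hours; the topple time is the first
#' timestamp where tilt exceeds `baseline + tilt_jump` for at least
#' `sustain` consecutive records. Records at and after the topple should
#' be excluded from statistics (see `apply`).
#'
#' @param series an `adcp_series` with tilt data.
#' @param tilt_jump degrees above baseline that counts as fallen
#'   (default 10).
#' @param sustain minimum consecutive exceeding records (default 3).
#' @param baseline_hours window used for the baseline median (default 6).
#' @param apply if `TRUE`, return the series with records at/after the
#'   topple dropped from the QC mask instead of the timestamp.
#' @return the topple `POSIXct` timestamp, `NULL` if none, or (with
#'   `apply = TRUE`) the masked series carrying a `topple_time` attribute.
#' @export
detect_topple <- function(series, tilt_jump = 10, sustain = 3,
                          baseline_hours = 6, apply = FALSE) {
  stopifnot(inherits(series, "adcp_series"))
  tilt <- series$tilt_deg
  if (all(is.na(tilt))) {
    warning("attitude data all missing; topple detection skipped")
    return(if (apply) series else NULL)
  }
  cadence <- attr(series, "cadence_sec")
  nb <- max(1L, min(nrow(series),
                    as.integer(round(baseline_hours * 3600 / cadence))))
  base <- stats::median(tilt[seq_len(nb)], na.rm = TRUE)
  above <- !is.na(tilt) & tilt > base + tilt_jump
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  hit <- which(r$values & r$lengths >= sustain)
  if (!length(hit)) return(if (apply) series else NULL)
  t0 <- series$timestamp[starts[hit[1]]]
  if (!apply) return(t0)
  out <- as.data.frame(series)
  fallen <- out$timestamp >= t0
  out$keep[fallen] <- FALSE
  out$qc_reason[fallen] <- ifelse(out$qc_reason[fallen] == "",
                                  "toppled", out$qc_reason[fallen])
  res <- new_adcp_series(out)
  attr(res, "topple_time") <- t0
  res
}

#' Site summary statistics
#'
#' Mean and maximum kept speed, strict-inequality exceedance percentages
#' (the fractions of time the current flows at < 5, < 10 and > 30
#' cm s^-1), the dominant direction (centre of the modal direction
#' sector, default 10 deg wide), and temperature statistics.
#'
#' @param series an `adcp_series`.
#' @param sector_width width of the direction sectors used for the modal
#'   (dominant) direction, degrees.
#' @return an object of class `site_summary` (a list).
#' @export
summarize_currents <- function(series, sector_width = 10) {
  k <- kept_records(series)
  if (nrow(k) == 0) stop("no kept records to summarize")
  sp <- k$speed_cms
  sec <- floor((k$direction_deg %% 360) / sector_width)
  tab <- table(sec)
  dom <- (as.numeric(names(tab)[which.max(tab)]) + 0.5) * sector_width
  dur <- as.numeric(difftime(k$timestamp[nrow(k)], k$timestamp[1],
                             units = "days"))
  structure(list(
    mean_speed = mean(sp),
    max_speed = max(sp),
    dominant_direction = dom,
    pct_lt5 = 100 * mean(sp < 5),
    pct_lt10 = 100 * mean(sp < 10),
    pct_gt30 = 100 * mean(sp > 30),
    temp_mean = mean(k$temp_c, na.rm = TRUE),
    temp_min = suppressWarnings(min(k$temp_c, na.rm = TRUE)),
    temp_max = suppressWarnings(max(k$temp_c, na.rm = TRUE)),
    n_records = nrow(k),
    deployment_days = dur), class = "site_summary")
}

#' @export
summary.adcp_series <- function(object, ...) summarize_currents(object, ...)

#' @export
print.site_summary <- function(x, ...) {
  cat("Site current summary\n")
  cat(sprintf("  mean speed  %.1f cm/s   max %.1f cm/s\n",
              x$mean_speed, x$max_speed))
  cat(sprintf("  dominant direction %s (%g deg)\n",
              compass_sector(x$dominant_direction), x$dominant_direction))
  cat(sprintf("  time <5: %.1f%%   <10: %.1f%%   >30: %.1f%%\n",
              x$pct_lt5, x$pct_lt10, x$pct_gt30))
  if (is.finite(x$temp_mean))
    cat(sprintf("  temperature %.1f C (%.1f - %.1f)\n",
                x$temp_mean, x$temp_min, x$temp_max))
  cat(sprintf("  %d records over %.1f days\n", x$n_records,
              x$deployment_days))
  invisible(x)
}

#' Current rose table
#'
#' Joint frequency table of flow-toward direction sectors by speed bins;
#' fractions over kept records sum to 1. Sectors are centred on north
#' (sector 1 spans `[-w/2, w/2)` around 0 deg).
#'
#' @param series an `adcp_series`.
#' @param n_sectors number of direction sectors (default 16).
#' @param speed_breaks upper edges of the speed bins, cm s^-1; `Inf`
#'   appended if absent. Defaults to `c(5, 10, 20, 30, Inf)`.
#' @return a `rose_table`: matrix `n_sectors` x bins of fractions, with
#'   sector centres as row attribute.
#' @export
current_rose <- function(series, n_sectors = 16,
                         speed_breaks = c(5, 10, 20, 30, Inf)) {
  if (n_sectors < 2) stop("`n_sectors` must be at least 2")
  k <- kept_records(series)
  if (nrow(k) == 0) stop("no kept records")
  if (!is.infinite(speed_breaks[length(speed_breaks)]))
    speed_breaks <- c(speed_breaks, Inf)
  w <- 360 / n_sectors
  sec <- (floor(((k$direction_deg + w / 2) %% 360) / w) %% n_sectors) + 1
  bin <- findInterval(k$speed_cms, c(0, speed_breaks), left.open = FALSE,
                      rightmost.closed = FALSE)
  bin <- pmin(bin, length(speed_breaks))
  m <- matrix(0, n_sectors, length(speed_breaks))
  for (i in seq_len(nrow(k))) m[sec[i], bin[i]] <- m[sec[i], bin[i]] + 1
  m <- m / nrow(k)
  lo <- c(0, utils::head(speed_breaks, -1))
  colnames(m) <- paste0("[", lo, ",", speed_breaks, ")")
  rownames(m) <- sprintf("%.1f", (seq_len(n_sectors) - 1) * w)
  structure(m, class = c("rose_table", "matrix"),
            sector_centres = (seq_len(n_sectors) - 1) * w)
}

#' @export
print.rose_table <- function(x, ...) {
  cat("Current rose (fractions; rows = sector centre deg, cols = speed bin)\n")
  print(round(unclass(x), 3))
  invisible(x)
}

#' @export
plot.rose_table <- function(x, main = "Current rose", ...) {
  centres <- attr(x, "sector_centres")
  tot <- rowSums(x)
  th <- (90 - centres) * pi / 180   # compass -> math angle
  r <- tot / max(tot)
  graphics::plot(NA, xlim = c(-1.1, 1.1), ylim = c(-1.1, 1.1), asp = 1,
                 axes = FALSE, xlab = "", ylab = "", main = main)
  graphics::symbols(0, 0, circles = 1, inches = FALSE, add = TRUE,
                    fg = "grey80")
  graphics::segments(0, 0, r * cos(th), r * sin(th), lwd = 4,
                     col = "steelblue")
  graphics::text(1.08 * cos(c(90, 0, -90, 180) * pi / 180),
                 1.08 * sin(c(90, 0, -90, 180) * pi / 180),
                 c("N", "E", "S", "W"))
  invisible(x)
}
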