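#' Parameters for a synthetic near-bed current record
#'
#' Emulates what a lander-mounted acoustic Doppler current profiler logs at
#' a fixed cadence: a steady background flow, a semidiurnal tidal
#' oscillation, isotropic noise, temperature, and instrument attitude
#' (tilt/pitch/roll) with an optional lander-topple event.
#'
#' @param duration_days record length in days.
#' @param interval_min sampling interval in minutes (default 10, the usual
#'   deployment cadence); must divide the duration evenly.
#' @param steady_speed steady flow speed, cm s^-1.
#' @param steady_heading flow-toward azimuth of the steady component,
#'   degrees clockwise from north in `[0, 360)`.
#' @param tidal_amplitude tidal current amplitude, cm s^-1.
#' @param tidal_period tidal period in hours (default 12.42, the M2
#'   semidiurnal constituent).
#' @param tidal_heading azimuth of the tidal axis; defaults to the steady
#'   heading. A distinct bearing produces bimodal roses.
#' @param noise_sd isotropic velocity noise sd per component, cm s^-1.
#' @param temp_mean,temp_sd temperature mean and sd, degrees C.
#' @param topple_time optional `POSIXct` (UTC): tilt steps from its ~2 deg
#'   baseline to ~45 deg at this time and stays there.
#' @param start UTC start time of the record.
#' @param seed integer RNG seed.
#' @return an object of class `current_params`.
#' @export
current_params <- function(duration_days = 27,
                           interval_min = 10,
                           steady_speed = 20,
                           steady_heading = 185,
                           tidal_amplitude = 10,
                           tidal_period = 12.42,
                           tidal_heading = NULL,
                           noise_sd = 2,
                           temp_mean = 9.4,
                           temp_sd = 0.15,
                           topple_time = NULL,
                           start = as.POSIXct("2019-05-15 00:00:00",
                                              tz = "UTC"),
                           seed = 1L) {
  if (duration_days <= 0 || interval_min <= 0)
    stop("duration and interval must be positive")
  n <- duration_days * 24 * 60 / interval_min
  if (abs(n - round(n)) > 1e-9)
    stop("`interval_min` must divide the duration evenly")
  if (steady_speed < 0 || tidal_amplitude < 0 || noise_sd < 0)
    stop("speeds and noise must be non-negative")
  steady_heading <- steady_heading %% 360
  if (is.null(tidal_heading)) tidal_heading <- steady_heading
  structure(
    list(duration_days = duration_days, interval_min = interval_min,
         steady_speed = steady_speed, steady_heading = steady_heading,
         tidal_amplitude = tidal_amplitude, tidal_period = tidal_period,
         tidal_heading = tidal_heading %% 360,
         noise_sd = noise_sd, temp_mean = temp_mean, temp_sd = temp_sd,
         topple_time = topple_time, start = start, seed = as.integer(seed)),
    class = "current_params")
}

# azimuth (deg, clockwise from north) -> unit vector (east, north)
az_to_vec <- function(deg) {
  th <- deg * pi / 180
  cbind(east = sin(th), north = cos(th))
}

#' Simulate an ADCP record
#'
#' The velocity vector at each timestamp is the sum of the steady vector,
#' a sinusoidal tidal vector along the tidal axis, and isotropic Gaussian
#' noise; speed and flow-toward direction are derived from the vector, so
#' speeds are naturally non-negative. Timestamps are UTC, interval-aligned
#' on the half-open window `[start, start + duration)`.
#'
#' @param params a [current_params].
#' @return an `adcp_series`: a data frame with columns `timestamp`,
#'   `speed_cms`, `direction_deg`, `temp_c`, `tilt_deg`, `pitch_deg`,
#'   `roll_deg`, plus a logical `keep` QC column (all `TRUE` on
#'   generation) carried in attribute form by downstream QC.
#' @export
gen_adcp <- function(params) {
  stopifnot(inherits(params, "current_params"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(child_seed(params$seed, 404L))

  n <- as.integer(round(params$duration_days * 24 * 60 / params$interval_min))
  tsec <- (seq_len(n) - 1) * params$interval_min * 60
  ts <- params$start + tsec

  sv <- params$steady_speed * az_to_vec(params$steady_heading)
  tv <- az_to_vec(params$tidal_heading)
  phase <- sin(2 * pi * tsec / (params$tidal_period * 3600))
  east  <- sv[1] + params$tidal_amplitude * phase * tv[1]
  north <- sv[2] + params$tidal_amplitude * phase * tv[2]
  if (params$noise_sd > 0) {
    east  <- east + stats::rnorm(n, 0, params$noise_sd)
    north <- north + stats::rnorm(n, 0, params$noise_sd)
  }
  speed <- sqrt(east^2 + north^2)
  direction <- (atan2(east, north) * 180 / pi) %% 360
  temp <- params$temp_mean + stats::rnorm(n, 0, params$temp_sd)

  tilt <- abs(2 + stats::rnorm(n, 0, 0.2))
  pitch <- stats::rnorm(n, 0, 0.3)
  roll <- stats::rnorm(n, 0, 0.3)
  if (!is.null(params$topple_time)) {
    fallen <- ts >= params$topple_time
    tilt[fallen] <- 45 + stats::rnorm(sum(fallen), 0, 0.5)
    pitch[fallen] <- 40 + stats::rnorm(sum(fallen), 0, 0.5)
  }

  new_adcp_series(data.frame(
    timestamp = ts, speed_cms = speed, direction_deg = direction,
    temp_c = temp, tilt_deg = tilt, pitch_deg = pitch, roll_deg = roll))
}

#' Write an ADCP series to CSV
#'
#' Column layout `timestamp,speed_cms,direction_deg,temp_c,tilt_deg,
#' pitch_deg,roll_deg`; timestamps ISO-8601 UTC.
#'
#' @param series an `adcp_series`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_adcp_csv <- function(series, path) {
  stopifnot(inherits(series, "adcp_series"))
  out <- as.data.frame(series)[, c("timestamp", "speed_cms", "direction_deg",
                                   "temp_c", "tilt_deg", "pitch_deg",
                                   "roll_deg")]
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
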