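# Integration of the spatial (facies, aspect) and temporal (current)
# products. Convention used throughout, and embedded in every report:
# azimuths are degrees clockwise from geographic north; current directions
# are FLOW-TOWARD; aspect is the downslope azimuth a surface faces. The
# coral-facing statistic conditions on currents travelling INTO the coral
# face, i.e. flow heading within a tolerance of (aspect + 180) mod 360.

AZIMUTH_CONVENTION <- paste(
  "degrees clockwise from geographic north;",
  "currents flow-toward; aspect = downslope facing direction")

#' Facies area proportions
#'
#' Percentage of the mapped (valid) area covered by each facies class;
#' cells are equal-area, so the proportion is a cell count ratio.
#'
#' @param facies categorical [scene_raster] (codes per [facies_legend()]).
#' @return named numeric vector (%) over the classes present, summing
#'   to 100.
#' @export
facies_proportions <- function(facies) {
  stopifnot(is_scene_raster(facies))
  v <- as.vector(facies$values)
  v <- v[!is.na(v)]
  if (!length(v)) stop("facies raster has no valid cells")
  tab <- table(factor(names(facies_legend())[v],
                      levels = names(facies_legend())))
  pct <- 100 * as.vector(tab) / length(v)
  stats::setNames(pct, names(facies_legend()))
}

#' Dominant live-coral aspect
#'
#' Circular (unit-vector) mean of terrain aspect over live-coral-framework
#' cells, with the 45-degree compass sector containing it. The modal
#' sector (largest LCF area per sector) is reported alongside, since
#' categorical summaries of coral orientation are conventionally sectoral.
#'
#' @param facies categorical [scene_raster].
#' @param aspect_r aspect [scene_raster], co-registered with `facies`.
#' @param class facies class to extract (default `"LCF"`).
#' @return list with `mean_deg`, `sector` (compass label of the circular
#'   mean), `modal_sector` and `n_cells`; all-`NA` with a warning when no
#'   qualifying cells exist.
#' @export
lcf_aspect <- function(facies, aspect_r, class = "LCF") {
  stopifnot(is_scene_raster(facies), is_scene_raster(aspect_r))
  check_same_geometry(facies, aspect_r)
  code <- facies_legend()[[class]]
  sel <- !is.na(facies$values) & facies$values == code &
    !is.na(aspect_r$values)
  if (!any(sel)) {
    warning("no ", class, " cells with valid aspect")
    return(list(mean_deg = NA_real_, sector = NA_character_,
                modal_sector = NA_character_, n_cells = 0L))
  }
  a <- aspect_r$values[sel]
  mu <- circular_mean(a)
  sect <- compass_sector(a, 8)
  modal <- names(which.max(table(factor(sect, COMPASS8))))
  list(mean_deg = mu,
       sector = if (is.na(mu)) NA_character_ else compass_sector(mu),
       modal_sector = modal, n_cells = sum(sel))
}

#' Coral-facing mean current speed
#'
#' Mean speed over kept records whose flow-toward direction lies within
#' `tol` of the direction opposing the live-coral aspect, i.e. the current
#' travels into the coral face: `ang_diff(direction, aspect + 180) <= tol`.
#'
#' @param series an `adcp_series`.
#' @param coral_aspect live-coral aspect azimuth, degrees.
#' @param tol half-width of the opposing window, degrees in `(0, 90]`
#'   (default 22.5, one 45-degree compass sector).
#' @return list with `mean` (cm s^-1, `NA` when no record qualifies) and
#'   `n` (qualifying records).
#' @export
coral_facing_mean <- function(series, coral_aspect, tol = 22.5) {
  if (!(tol > 0 && tol <= 90)) stop("`tol` must be in (0, 90] degrees")
  if (is.na(coral_aspect)) stop("`coral_aspect` is missing")
  k <- kept_records(series)
  if (!nrow(k)) stop("no kept records")
  opposing <- (coral_aspect + 180) %% 360
  sel <- ang_diff(k$direction_deg, opposing) <= tol
  if (!any(sel)) return(list(mean = NA_real_, n = 0L))
  list(mean = mean(k$speed_cms[sel]), n = sum(sel))
}

#' Reduction of the coral-facing mean relative to the overall mean
#'
#' `100 * (overall - facing) / overall` percent; the printed habitat
#' tables round it to the nearest integer percent.
#'
#' @param overall_mean overall mean speed (> 0), cm s^-1.
#' @param facing_mean coral-facing mean speed, cm s^-1.
#' @return reduction in percent (unrounded).
#' @export
reduction_pct <- function(overall_mean, facing_mean) {
  if (!is.finite(overall_mean) || overall_mean <= 0)
    stop("`overall_mean` must be positive")
  100 * (overall_mean - facing_mean) / overall_mean
}

#' Feeding-window time fraction
#'
#' Percentage of kept records during which the current both opposes the
#' coral aspect (within `tol`) and flows at or below `speed_max` — the
#' flume-derived speeds at which coral food capture is most effective
#' (2.5 cm s^-1 for zooplankton, 5 cm s^-1 for phytoplankton).
#'
#' @inheritParams coral_facing_mean
#' @param speed_max speed ceiling, cm s^-1 (conventionally 2.5 or 5).
#' @return percentage of kept records.
#' @export
feeding_window_pct <- function(series, coral_aspect, speed_max, tol = 22.5) {
  if (!(tol > 0 && tol <= 90)) stop("`tol` must be in (0, 90] degrees")
  k <- kept_records(series)
  if (!nrow(k)) stop("no kept records")
  opposing <- (coral_aspect + 180) %% 360
  sel <- ang_diff(k$direction_deg, opposing) <= tol & k$speed_cms <= speed_max
  100 * mean(sel)
}

#' Cross-site rank trend
#'
#' Spearman rank correlation (average ranks for ties) between two per-site
#' columns, e.g. coral-rubble proportion against maximum current speed, or
#' live-coral proportion against the coral-facing mean. With the handful
#' of sites such surveys yield, the statistic is descriptive; no p-value
#' is attached.
#'
#' @param sites data frame with one row per site.
#' @param x,y column names.
#' @return list with `rho` and `n`.
#' @export
cross_site_trend <- function(sites, x, y) {
  xv <- sites[[x]]; yv <- sites[[y]]
  ok <- is.finite(xv) & is.finite(yv)
  if (sum(ok) < 3) stop("need at least 3 sites with both variables")
  list(rho = stats::cor(xv[ok], yv[ok], method = "spearman"), n = sum(ok))
}

#' Mean current speed in coral versus non-coral habitats
#'
#' Arithmetic mean of the per-site mean speeds within each habitat group.
#'
#' @param sites data frame with columns `mean_speed` and logical `coral`.
#' @return list `coral`, `non_coral` (cm s^-1; `NA` for an empty group).
#' @export
coral_vs_noncoral_means <- function(sites) {
  grp <- function(sel) {
    v <- sites$mean_speed[sel & is.finite(sites$mean_speed)]
    if (!length(v)) NA_real_ else mean(v)
  }
  list(coral = grp(sites$coral), non_coral = grp(!sites$coral))
}

#' Per-site habitat summary
#'
#' Joins the spatial products (facies map, aspect) with the current record
#' of one site into the habitat-summary shape: facies percentages,
#' live-coral aspect, coral-facing mean, reduction and feeding windows.
#'
#' @param site_id site identifier.
#' @param facies categorical [scene_raster].
#' @param aspect_r aspect [scene_raster].
#' @param series an `adcp_series` (after QC).
#' @param coral logical habitat tag; defaults to `TRUE` when any LCF is
#'   mapped.
#' @param tol opposing-window half-width, degrees.
#' @return an object of class `habitat_summary` (a list).
#' @export
habitat_summary <- function(site_id, facies, aspect_r, series,
                            coral = NULL, tol = 22.5) {
  fp <- facies_proportions(facies)
  la <- lcf_aspect(facies, aspect_r)
  ss <- summarize_currents(series)
  if (is.null(coral)) coral <- fp[["LCF"]] > 0
  cf <- if (!is.na(la$mean_deg))
    coral_facing_mean(series, la$mean_deg, tol = tol)
  else list(mean = NA_real_, n = 0L)
  red <- if (is.finite(cf$mean)) reduction_pct(ss$mean_speed, cf$mean)
  else NA_real_
  fw <- if (!is.na(la$mean_deg)) {
    c(`2.5` = feeding_window_pct(series, la$mean_deg, 2.5, tol = tol),
      `5` = feeding_window_pct(series, la$mean_deg, 5, tol = tol))
  } else c(`2.5` = NA_real_, `5` = NA_real_)
  structure(list(
    site_id = site_id, coral = coral,
    facies_pct = fp,
    lcf_aspect = la$mean_deg, lcf_aspect_sector = la$sector,
    lcf_modal_sector = la$modal_sector,
    coral_facing_mean = cf$mean, coral_facing_n = cf$n,
    overall_mean = ss$mean_speed,
    reduction_pct = red,
    feeding_window_pct = fw,
    site_summary = ss,
    convention = AZIMUTH_CONVENTION), class = "habitat_summary")
}

#' @export
print.habitat_summary <- function(x, ...) {
  cat(sprintf("Habitat summary - site %s (%s habitat)\n", x$site_id,
              if (x$coral) "coral" else "non-coral"))
  fp <- x$facies_pct[x$facies_pct > 0]
  cat("  facies: ", paste(sprintf("%s %.1f%%", names(fp), fp),
                          collapse = ", "), "\n", sep = "")
  if (is.finite(x$lcf_aspect))
    cat(sprintf("  LCF aspect %.1f deg (%s; modal %s)\n", x$lcf_aspect,
                x$lcf_aspect_sector, x$lcf_modal_sector))
  cat(sprintf("  overall mean %.1f cm/s", x$overall_mean))
  if (is.finite(x$coral_facing_mean))
    cat(sprintf("; coral-facing mean %.1f cm/s (%.0f%% reduction, n=%d)",
                x$coral_facing_mean, round(x$reduction_pct),
                x$coral_facing_n))
  cat("\n")
  if (is.finite(x$feeding_window_pct[1]))
    cat(sprintf("  feeding windows: %.1f%% of time <= 2.5 cm/s, %.1f%% <= 5 cm/s (coral-facing)\n",
                x$feeding_window_pct[1], x$feeding_window_pct[2]))
  invisible(x)
}

#' Write the site and cross-site report files
#'
#' Produces `site_summary.csv` (one row per site, flow and temperature
#' statistics), `habitat_summary.csv` (facies percentages, aspect and
#' coral-facing statistics; speeds to 0.1 cm s^-1, percentages to 0.1%,
#' reduction to integer %), `trends.csv` (cross-site Spearman statistics)
#' and `report.json` with the full machine-readable bundle, including the
#' azimuth convention string.
#'
#' @param summaries list of `habitat_summary` objects (>= 1).
#' @param out_dir output directory (created if needed).
#' @return invisibly, the list of file paths written.
#' @export
habitat_report <- function(summaries, out_dir) {
  if (!length(summaries)) stop("no site bundles to report")
  for (s in summaries) if (!inherits(s, "habitat_summary"))
    stop("`summaries` must be habitat_summary objects")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  site_df <- do.call(rbind, lapply(summaries, function(s) {
    ss <- s$site_summary
    data.frame(site = s$site_id, coral = s$coral,
               mean_speed = round(ss$mean_speed, 1),
               max_speed = round(ss$max_speed, 1),
               dominant_direction = ss$dominant_direction,
               pct_lt5 = round(ss$pct_lt5, 1),
               pct_lt10 = round(ss$pct_lt10, 1),
               pct_gt30 = round(ss$pct_gt30, 1),
               temp_mean = round(ss$temp_mean, 1),
               temp_min = round(ss$temp_min, 1),
               temp_max = round(ss$temp_max, 1),
               n_records = ss$n_records,
               deployment_days = round(ss$deployment_days, 1))
  }))
  hab_df <- do.call(rbind, lapply(summaries, function(s) {
    fp <- round(s$facies_pct, 1)
    data.frame(site = s$site_id,
               lcf_pct = fp[["LCF"]], dcf_pct = fp[["DCF"]],
               sc_pct = fp[["SC"]], cr_pct = fp[["CR"]], s_pct = fp[["S"]],
               lcf_aspect = round(s$lcf_aspect, 1),
               lcf_aspect_sector = s$lcf_aspect_sector,
               coral_facing_mean = round(s$coral_facing_mean, 1),
               overall_mean = round(s$overall_mean, 1),
               reduction_pct = round(s$reduction_pct),
               feeding_pct_2.5 = round(s$feeding_window_pct[[1]], 1),
               feeding_pct_5 = round(s$feeding_window_pct[[2]], 1))
  }))

  trends <- NULL
  joined <- merge(site_df, hab_df, by = "site")
  if (nrow(joined) >= 3) {
    tr <- list(
      cr_vs_max = tryCatch(cross_site_trend(joined, "cr_pct", "max_speed"),
                           error = function(e) NULL),
      lcf_vs_facing = tryCatch(
        cross_site_trend(joined[is.finite(joined$coral_facing_mean), ],
                         "lcf_pct", "coral_facing_mean"),
        error = function(e) NULL))
    tr <- tr[!vapply(tr, is.null, logical(1))]
    if (length(tr))
      trends <- data.frame(trend = names(tr),
                           rho = vapply(tr, `[[`, numeric(1), "rho"),
                           n = vapply(tr, `[[`, numeric(1), "n"))
  }

  paths <- c(site_summary = file.path(out_dir, "site_summary.csv"),
             habitat_summary = file.path(out_dir, "habitat_summary.csv"),
             report = file.path(out_dir, "report.json"))
  utils::write.csv(site_df, paths[["site_summary"]], row.names = FALSE)
  utils::write.csv(hab_df, paths[["habitat_summary"]], row.names = FALSE)
  if (!is.null(trends)) {
    paths <- c(paths, trends = file.path(out_dir, "trends.csv"))
    utils::write.csv(trends, paths[["trends"]], row.names = FALSE)
  }
  payload <- list(convention = AZIMUTH_CONVENTION,
                  sites = site_df, habitat = hab_df, trends = trends)
  jsonlite::write_json(payload, paths[["report"]], auto_unbox = TRUE,
                       digits = NA, na = "null", dataframe = "rows")
  invisible(as.list(paths))
}

#' Published upper Porcupine Bank Canyon site statistics
#'
#' Per-site summary values (current speeds, coral-facing means, facies
#' percentages, exceedance fractions, temperatures) for seven cold-water
#' coral study sites in the upper Porcupine Bank Canyon, as printed in the
#' survey's habitat tables. These printed values are the inputs to the
#' cross-site statistics ([cross_site_trend()],
#' [coral_vs_noncoral_means()], [reduction_pct()]); facies percentages
#' not printed for a site are `NA`.
#'
#' @return data frame, one row per site `a`--`g`.
#' @export
upbc_site_stats <- function() {
  path <- system.file("extdata", "upbc_site_stats.csv",
                      package = "reefscape", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$coral <- as.logical(df$coral)
  df
}
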