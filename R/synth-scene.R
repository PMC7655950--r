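#' Parameters for a synthetic seabed scene
#'
#' Defines a mound/ridge micro-topography scene with five benthic facies —
#' live coral framework (LCF), dead coral framework (DCF), soft coral (SC),
#' coral rubble (CR) and sediment (S) — in controlled proportions, with
#' class-distinct colour and texture for the matching orthomosaic.
#'
#' @param grid_shape integer length-2, rows x cols in cells.
#' @param cell_size metres per cell (photogrammetric products are of the
#'   order of millimetres to centimetres; default 0.01 m).
#' @param n_mounds number of positive-relief Gaussian mounds.
#' @param mound_height_range metres, range heights are drawn from.
#' @param base_slope background plane gradient (m per m, dips south).
#' @param roughness standard deviation (m) of small-scale smoothed relief.
#' @param facies_proportions named fractions over `LCF, DCF, SC, CR, S`;
#'   must be non-negative and sum to 1 (within 1e-9). All five names must
#'   be present (zeros allowed).
#' @param facies_smooth autocorrelation length (cells) of the facies patch
#'   field; larger values give larger contiguous patches.
#' @param texture_spec named list, one entry per facies, each a list with
#'   `mean` (length-3 RGB, 0--255), `sd` (per-band noise sd) and
#'   `smooth` (texture autocorrelation length in cells).
#' @param lcf_aspect_bias optional azimuth (degrees): LCF patches are
#'   preferentially placed on cells whose terrain aspect falls near this
#'   direction, giving the aspect-extraction stage a recoverable ground
#'   truth. `NULL` (default) disables the bias.
#' @param seed integer RNG seed; every generated product is a pure function
#'   of `(params, seed)`.
#' @return an object of class `scene_params`.
#' @export
scene_params <- function(grid_shape = c(256, 256),
                         cell_size = 0.02,
                         n_mounds = 8,
                         mound_height_range = c(0.3, 1),
                         base_slope = 0.02,
                         roughness = 0.05,
                         facies_proportions = c(LCF = 0.25, DCF = 0.2,
                                                SC = 0.05, CR = 0.25,
                                                S = 0.25),
                         facies_smooth = 8,
                         texture_spec = default_texture_spec(),
                         lcf_aspect_bias = NULL,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2 || any(grid_shape <= 0))
    stop("`grid_shape` must be two positive integers")
  if (cell_size <= 0) stop("`cell_size` must be positive")
  if (n_mounds < 0) stop("`n_mounds` must be non-negative")
  p <- facies_proportions
  if (!all(FACIES %in% names(p)))
    stop("`facies_proportions` must name all of ", paste(FACIES, collapse = ", "))
  p <- p[FACIES]
  if (any(p < 0)) stop("facies proportions must be non-negative")
  if (abs(sum(p) - 1) > 1e-9) stop("facies proportions must sum to 1")
  if (!is.null(lcf_aspect_bias)) lcf_aspect_bias <- lcf_aspect_bias %% 360
  structure(
    list(grid_shape = grid_shape, cell_size = cell_size,
         n_mounds = as.integer(n_mounds),
         mound_height_range = mound_height_range,
         base_slope = base_slope, roughness = roughness,
         facies_proportions = p, facies_smooth = facies_smooth,
         texture_spec = texture_spec, lcf_aspect_bias = lcf_aspect_bias,
         seed = as.integer(seed)),
    class = "scene_params")
}

#' @rdname scene_params
#' @export
default_texture_spec <- function() {
  list(
    LCF = list(mean = c(235, 225, 210), sd = c(12, 12, 12), smooth = 2),
    DCF = list(mean = c(150, 140, 125), sd = c(15, 15, 15), smooth = 2),
    SC  = list(mean = c(40, 45, 60),    sd = c(10, 10, 10), smooth = 2),
    CR  = list(mean = c(190, 185, 175), sd = c(20, 20, 20), smooth = 1),
    S   = list(mean = c(120, 110, 90),  sd = c(8, 8, 8),    smooth = 3))
}

#' Generate a synthetic digital elevation model
#'
#' Builds an elevation raster as a south-dipping base plane, `n_mounds`
#' superposed two-dimensional Gaussian mounds with random centres, widths
#' and heights, plus spatially smoothed small-scale roughness. Bit
#' reproducible per `(params, seed)`.
#'
#' @param params a [scene_params].
#' @return a [scene_raster] with band `"elevation"` (metres).
#' @export
gen_dem <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  nr <- params$grid_shape[1]; nc <- params$grid_shape[2]
  cs <- params$cell_size
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(child_seed(params$seed, 101L))

  # cell-centre coordinates, metres; row 1 is north
  x <- (seq_len(nc) - 0.5) * cs
  y <- (nr - seq_len(nr) + 0.5) * cs
  z <- outer(y, rep(1, nc)) * params$base_slope  # dips to the south

  if (params$n_mounds > 0) {
    cx <- stats::runif(params$n_mounds, 0, nc * cs)
    cy <- stats::runif(params$n_mounds, 0, nr * cs)
    h  <- stats::runif(params$n_mounds, params$mound_height_range[1],
                       params$mound_height_range[2])
    w  <- stats::runif(params$n_mounds, 0.08, 0.25) * min(nr, nc) * cs
    X <- outer(rep(1, nr), x)
    Y <- outer(y, rep(1, nc))
    for (i in seq_len(params$n_mounds)) {
      z <- z + h[i] * exp(-((X - cx[i])^2 + (Y - cy[i])^2) / (2 * w[i]^2))
    }
  }
  if (params$roughness > 0) {
    eps <- matrix(stats::rnorm(nr * nc), nr, nc)
    eps <- smooth_gaussian(eps, 2)
    eps <- eps / stats::sd(eps) * params$roughness
    z <- z + eps
  }
  scene_raster(z, cs, origin = c(0, nr * cs), band = "elevation")
}

# Save/restore the global RNG state so generators are pure functions of
# their seed without clobbering the caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Generate a ground-truth facies map
#'
#' One spatially smoothed Gaussian random field per facies class; each cell
#' takes the class whose field (plus a per-class offset) is largest. The
#' offsets are calibrated iteratively so realized class fractions match the
#' requested `facies_proportions` within the module contract of +-2
#' percentage points per class; patches are contiguous, not
#' salt-and-pepper. When `lcf_aspect_bias` is set, the LCF field is
#' augmented with a bonus on cells whose terrain aspect is near the chosen
#' azimuth, so live coral preferentially occupies slopes facing that way.
#'
#' @param dem a [scene_raster] elevation grid matching `params` (used only
#'   when `lcf_aspect_bias` is set).
#' @param params a [scene_params].
#' @return a [scene_raster] with band `"class"`; integer codes follow
#'   [facies_legend()].
#' @export
gen_facies_map <- function(dem, params) {
  stopifnot(inherits(params, "scene_params"))
  nr <- params$grid_shape[1]; nc <- params$grid_shape[2]
  if (!is.null(dem)) {
    if (!identical(dim(dem$values), c(nr, nc)))
      stop("dem shape does not match params")
  }
  p <- params$facies_proportions
  if (abs(sum(p) - 1) > 1e-9) stop("facies proportions must sum to 1")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(child_seed(params$seed, 202L))

  active <- names(p)[p > 0]
  if (length(active) == 1) {
    v <- matrix(match(active, FACIES), nr, nc)
    return(scene_raster(v, params$cell_size, origin = c(0, nr * params$cell_size),
                        band = "class"))
  }

  # standardized smoothed fields, one per active class
  G <- lapply(active, function(cl) {
    g <- smooth_gaussian(matrix(stats::rnorm(nr * nc), nr, nc),
                         params$facies_smooth)
    (g - mean(g)) / stats::sd(g)
  })
  names(G) <- active

  # optional aspect-dependent bonus for LCF placement: a von-Mises-shaped
  # kernel of the angular distance to the chosen azimuth, smoothed to the
  # patch scale and standardized, dominates the LCF field so live coral
  # settles on slopes facing that way
  if (!is.null(params$lcf_aspect_bias) && "LCF" %in% active && !is.null(dem)) {
    asp <- aspect(dem)$values
    bonus <- exp(3 * (cos(ang_diff(asp, params$lcf_aspect_bias) *
                            pi / 180) - 1))
    bonus[is.na(bonus)] <- mean(bonus, na.rm = TRUE)
    bonus <- smooth_gaussian(bonus, 1)
    bonus <- (bonus - mean(bonus)) / stats::sd(bonus)
    G[["LCF"]] <- G[["LCF"]] + 6 * bonus
  }

  S <- vapply(G, as.vector, numeric(nr * nc))   # cells x classes
  tgt <- p[active]
  a <- stats::qnorm(pmin(pmax(tgt, 1e-6), 1 - 1e-6))  # rough start
  cls <- max.col(sweep(S, 2, a, "+"), ties.method = "first")
  # damped fixed point on the per-class offsets
  for (it in seq_len(400)) {
    f <- tabulate(cls, nbins = length(active)) / length(cls)
    err <- tgt - f
    if (max(abs(err)) < 0.004) break
    a <- a + 1.5 * err
    cls <- max.col(sweep(S, 2, a, "+"), ties.method = "first")
  }
  v <- matrix(match(active[cls], FACIES), nr, nc)
  scene_raster(v, params$cell_size, origin = c(0, nr * params$cell_size),
               band = "class")
}

#' Facies legend
#'
#' @return named integer vector mapping facies names to the class codes
#'   used in categorical rasters.
#' @export
facies_legend <- function() stats::setNames(seq_along(FACIES), FACIES)

#' Generate a synthetic orthomosaic
#'
#' Renders a 3-band colour image from a facies map: each class gets its
#' `texture_spec` mean colour plus spatially autocorrelated noise with the
#' requested per-band standard deviation, clipped to 0--255. Deterministic
#' per `(params, seed)`.
#'
#' @param facies categorical [scene_raster] from [gen_facies_map()].
#' @param params a [scene_params]; `texture_spec` must cover every class
#'   present in `facies`.
#' @return a [scene_ortho].
#' @export
gen_orthomosaic <- function(facies, params) {
  stopifnot(is_scene_raster(facies), inherits(params, "scene_params"))
  v <- facies$values
  present <- FACIES[sort(unique(as.vector(v[!is.na(v)])))]
  missing_spec <- setdiff(present, names(params$texture_spec))
  if (length(missing_spec))
    stop("texture_spec missing class(es): ", paste(missing_spec, collapse = ", "))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(child_seed(params$seed, 303L))

  nr <- nrow(v); nc <- ncol(v)
  bands <- lapply(1:3, function(b) matrix(0, nr, nc))
  for (cl in present) {
    spec <- params$texture_spec[[cl]]
    mask <- !is.na(v) & v == match(cl, FACIES)
    for (b in 1:3) {
      tex <- matrix(spec$mean[b], nr, nc)
      if (spec$sd[b] > 0) {
        eps <- smooth_gaussian(matrix(stats::rnorm(nr * nc), nr, nc),
                               spec$smooth)
        eps <- eps / stats::sd(eps) * spec$sd[b]
        tex <- tex + eps
      }
      bands[[b]][mask] <- tex[mask]
    }
  }
  bands <- lapply(bands, function(b) pmin(pmax(b, 0), 255))
  scene_ortho(bands, params$cell_size, origin = c(0, nr * params$cell_size))
}

#' Generate a complete synthetic site
#'
#' Convenience wrapper: DEM, ground-truth facies map and orthomosaic from
#' one parameter set.
#'
#' @param params a [scene_params].
#' @return list with elements `dem`, `facies`, `ortho`, `params`.
#' @export
gen_scene <- function(params) {
  dem <- gen_dem(params)
  facies <- gen_facies_map(dem, params)
  ortho <- gen_orthomosaic(facies, params)
  list(dem = dem, facies = facies, ortho = ortho, params = params)
}
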