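#' Per-segment feature table
#'
#' Computes, for every segment, its area (cells), centroid (map
#' coordinates) and the mean and population standard deviation of each
#' layer, exactly by per-cell accumulation.
#'
#' @param seg a `segment_map` from [segment_scene()].
#' @param layers list of co-registered [scene_raster]s or matrices, in the
#'   order features should be named; names of the list are used as
#'   feature prefixes (defaults `layer1`, `layer2`, ...).
#' @return a `segment_table`: data frame with one row per segment id,
#'   columns `id`, `area_px`, `cx`, `cy`, `<layer>_mean`, `<layer>_sd`
#'   and a `label` column (`NA` until classified).
#' @export
compute_features <- function(seg, layers) {
  stopifnot(inherits(seg, "segment_map"))
  lab <- seg$labels$values
  mats <- lapply(layers, function(l) if (is_scene_raster(l)) l$values else l)
  nms <- names(layers)
  if (is.null(nms) || any(nms == ""))
    nms <- paste0("layer", seq_along(layers))
  for (m in mats) if (!identical(dim(m), dim(lab)))
    stop("layer shape does not match the segment map")

  ids <- seq_len(seg$n_segments)
  f <- factor(as.vector(lab), levels = ids)
  area <- as.vector(table(f))

  nr <- nrow(lab); nc <- ncol(lab)
  cs <- seg$labels$cell_size
  xo <- seg$labels$origin[1]; yo <- seg$labels$origin[2]
  xc <- rep((seq_len(nc) - 0.5) * cs + xo, each = nr)
  yc <- rep(yo - (seq_len(nr) - 0.5) * cs, nc)
  out <- data.frame(id = ids, area_px = area,
                    cx = as.vector(tapply(xc, f, mean)),
                    cy = as.vector(tapply(yc, f, mean)))
  for (j in seq_along(mats)) {
    v <- as.vector(mats[[j]])
    s <- as.vector(tapply(v, f, sum))
    s2 <- as.vector(tapply(v^2, f, sum))
    mu <- s / area
    out[[paste0(nms[j], "_mean")]] <- mu
    out[[paste0(nms[j], "_sd")]] <- sqrt(pmax(s2 / area - mu^2, 0))
  }
  out$label <- NA_character_
  class(out) <- c("segment_table", "data.frame")
  out
}

feature_columns <- function(table) {
  setdiff(names(table), c("id", "cx", "cy", "label"))
}

#' Nearest-neighbour classification of segments
#'
#' Classifies every unlabeled segment by the class of its nearest training
#' segment in z-standardized feature space (Euclidean distance;
#' standardization statistics come from the training rows only, matching
#' supervised practice). Features are the per-layer mean and standard
#' deviation plus the segment area. With `k > 1` the majority class among
#' the k nearest training samples wins, ties resolved by the nearest
#' member of the tied classes.
#'
#' @param table a `segment_table` from [compute_features()].
#' @param training data frame with columns `id` (segment id) and `class`,
#'   or a named character vector `class` indexed by segment id.
#' @param k number of neighbours (default 1, the classic behaviour).
#' @param min_per_class minimum training samples required per class
#'   (default 50, standard operator protocol; lower it for toy scenes).
#' @param seg optional `segment_map`; when given, a classified facies
#'   raster is attached as attribute `"facies_raster"`.
#' @return the `segment_table` with `label` filled for every segment;
#'   training segments keep their assigned labels.
#' @export
classify_nn <- function(table, training, k = 1, min_per_class = 50,
                        seg = NULL) {
  stopifnot(inherits(table, "segment_table"))
  if (!is.data.frame(training))
    training <- data.frame(id = as.integer(names(training)),
                           class = as.character(training))
  if (!all(c("id", "class") %in% names(training)))
    stop("training needs columns `id` and `class`")
  tc <- table(training$class)
  if (any(tc < min_per_class))
    stop("class(es) below min_per_class (", min_per_class, "): ",
         paste(names(tc)[tc < min_per_class], collapse = ", "))
  if (!all(training$id %in% table$id))
    stop("training ids not present in the segment table")

  fc <- feature_columns(table)
  Fm <- as.matrix(table[, fc, drop = FALSE])
  tr_idx <- match(training$id, table$id)
  mu <- colMeans(Fm[tr_idx, , drop = FALSE])
  sdv <- apply(Fm[tr_idx, , drop = FALSE], 2, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  Z <- sweep(sweep(Fm, 2, mu), 2, sdv, "/")
  Ztr <- Z[tr_idx, , drop = FALSE]

  lab <- rep(NA_character_, nrow(table))
  lab[tr_idx] <- training$class
  query <- which(is.na(lab))
  if (length(query)) {
    # squared Euclidean distances query x training, fully vectorised
    qq <- rowSums(Z[query, , drop = FALSE]^2)
    tt <- rowSums(Ztr^2)
    D <- outer(qq, tt, "+") - 2 * Z[query, , drop = FALSE] %*% t(Ztr)
    for (i in seq_along(query)) {
      ord <- order(D[i, ], training$id)      # id as deterministic tie-break
      if (k == 1) {
        lab[query[i]] <- training$class[ord[1]]
      } else {
        kn <- training$class[ord[seq_len(min(k, length(ord)))]]
        votes <- table(kn)
        top <- names(votes)[votes == max(votes)]
        lab[query[i]] <- kn[kn %in% top][1]
      }
    }
  }
  table$label <- lab
  if (!is.null(seg)) {
    code <- facies_legend()[lab]
    fr <- matrix(code[seg$labels$values], nrow(seg$labels$values),
                 ncol(seg$labels$values))
    attr(table, "facies_raster") <- scene_raster(
      fr, seg$labels$cell_size, origin = seg$labels$origin, band = "class")
  }
  table
}

#' Rasterize segment labels to a facies map
#'
#' @param table labeled `segment_table`.
#' @param seg the `segment_map` the table was built from.
#' @return categorical [scene_raster] using [facies_legend()] codes.
#' @export
facies_raster <- function(table, seg) {
  code <- facies_legend()[table$label[match(seg$labels$values, table$id)]]
  scene_raster(matrix(code, nrow(seg$labels$values), ncol(seg$labels$values)),
               seg$labels$cell_size, origin = seg$labels$origin,
               band = "class")
}

#' Classification accuracy assessment
#'
#' Confusion matrix between predicted and reference facies with overall
#' accuracy (trace over total), per-class producer's and user's accuracy,
#' and Cohen's kappa. Accepts either two categorical rasters of one
#' geometry (cell-by-cell comparison) or two label vectors aligned by
#' segment id (e.g. a held-back subset of training samples).
#'
#' @param pred predicted facies: [scene_raster] or character/integer
#'   vector.
#' @param ref reference facies of matching type.
#' @return a `confusion_report`: list with `matrix` (reference in rows,
#'   prediction in columns), `overall_accuracy` (%), `producers`,
#'   `users` (%), `kappa` and `n`.
#' @export
accuracy_assessment <- function(pred, ref) {
  to_vec <- function(x) {
    if (is_scene_raster(x)) {
      v <- as.vector(x$values)
      names(facies_legend())[v]
    } else as.character(x)
  }
  if (is_scene_raster(pred) && is_scene_raster(ref))
    check_same_geometry(pred, ref)
  p <- to_vec(pred); r <- to_vec(ref)
  if (length(p) != length(r)) stop("prediction and reference lengths differ")
  ok <- !is.na(p) & !is.na(r)
  p <- p[ok]; r <- r[ok]
  if (!length(r)) stop("empty reference")
  lev <- sort(unique(c(p, r)))
  cm <- table(factor(r, lev), factor(p, lev))
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  kappa <- if (abs(1 - pe) < 1e-12) {
    warning("kappa undefined: expected agreement is 1 (degenerate reference)")
    NA_real_
  } else (po - pe) / (1 - pe)
  producers <- 100 * diag(cm) / rowSums(cm)
  users <- 100 * diag(cm) / colSums(cm)
  structure(list(matrix = unclass(cm), overall_accuracy = 100 * po,
                 producers = producers, users = users, kappa = kappa,
                 n = n),
            class = "confusion_report")
}

#' @export
print.confusion_report <- function(x, ...) {
  cat("Accuracy assessment (rows = reference, cols = prediction)\n")
  print(x$matrix)
  cat(sprintf("overall accuracy %.1f%%   kappa %s   n = %d\n",
              x$overall_accuracy,
              ifelse(is.na(x$kappa), "NA", sprintf("%.3f", x$kappa)), x$n))
  invisible(x)
}

#' Stratified holdout split of a training set
#'
#' Operator protocol for accuracy assessment against a subset of training
#' samples: per class, a fraction is held back (not used to fit) and
#' scored against the classifier's prediction.
#'
#' @param training data frame `id`, `class`.
#' @param holdout fraction per class to hold back (default 0.3).
#' @param seed RNG seed for the split.
#' @return list with data frames `fit` and `held`.
#' @export
holdout_split <- function(training, holdout = 0.3, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(child_seed(seed, 505L))
  held <- unlist(lapply(split(seq_len(nrow(training)), training$class),
                        function(ix) {
    nh <- max(1L, round(length(ix) * holdout))
    sample(ix, nh)
  }), use.names = FALSE)
  list(fit = training[-held, , drop = FALSE],
       held = training[held, , drop = FALSE])
}
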