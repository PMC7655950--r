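test_that("two constant half-planes merge to exactly two segments", {
  m <- cbind(matrix(0, 16, 8), matrix(10, 16, 8))
  sm <- segment_scene(list(m), scale = 5, w_shape = 0)
  expect_equal(sm$n_segments, 2)
  expect_true(is_partition_4connected(sm$labels$values))
  # within each half all merges were free; the cross merge would cost
  # n_m * sd_m = 256 * 5 >> scale^2
  expect_true(all(sm$merge_costs < 25))
})

test_that("a scale below every pair cost leaves every pixel its own segment", {
  set.seed(21)
  m <- matrix(sample(seq(0, 1000, by = 10), 64), 8, 8)
  # smallest possible colour cost between adjacent distinct pixels is
  # |a - b| >= 10; pick the threshold under it
  sm <- segment_scene(list(m), scale = sqrt(9), w_shape = 0)
  expect_equal(sm$n_segments, 64)
})

test_that("executed and remaining merge costs audit cleanly on a toy image", {
  set.seed(22)
  truth <- cbind(matrix(0, 16, 8), matrix(8, 16, 8))
  img <- truth + matrix(rnorm(256, sd = 1), 16, 16)
  scale <- 6; w_shape <- 0.3; w_cmpct <- 0.5
  sm <- segment_scene(list(img), scale, w_shape = w_shape,
                      w_cmpct = w_cmpct)
  lab <- sm$labels$values
  expect_true(is_partition_4connected(lab))
  expect_true(all(sm$merge_costs < scale^2))
  # exhaustive terminal audit: no remaining adjacent pair is mergeable
  prs <- adjacent_pairs(lab)
  for (i in seq_len(nrow(prs))) {
    cost <- oracle_pair_cost(lab, list(img), w = 1, prs[i, 1], prs[i, 2],
                             w_shape, w_cmpct)
    expect_gte(cost, scale^2)
  }
})

test_that("segment count is non-increasing in scale", {
  set.seed(23)
  p <- scene_params(grid_shape = c(24, 24), seed = 6)
  sc <- gen_scene(p)
  layers <- sc$ortho$bands
  ns <- sapply(c(2, 5, 10, 20, 40, 80), function(s)
    segment_scene(layers, scale = s)$n_segments)
  expect_true(all(diff(ns) <= 0))
  for (s in c(2, 20)) {
    lab <- segment_scene(layers, scale = s)$labels$values
    expect_true(is_partition_4connected(lab))
  }
})

test_that("suggest_scale lands near the requested segment count", {
  p <- scene_params(grid_shape = c(24, 24), seed = 7)
  sc <- gen_scene(p)
  s <- suggest_scale(sc$ortho$bands, 12)
  n <- segment_scene(sc$ortho$bands, scale = s)$n_segments
  expect_gt(n, 3)
  expect_lt(n, 40)
})

test_that("segment features equal a per-pixel accumulation oracle", {
  set.seed(24)
  for (rep in 1:5) {
    lab <- random_partition(20, 20, 12)
    mats <- list(matrix(rnorm(400), 20, 20), matrix(runif(400) * 50, 20, 20))
    ft <- compute_features(make_segment_map(lab), mats)
    orc <- oracle_features(lab, mats)
    for (row in orc) {
      i <- row$id
      expect_equal(ft$area_px[ft$id == i], row$area)
      expect_equal(ft$layer1_mean[ft$id == i], row$m1, tolerance = 1e-12)
      expect_equal(ft$layer1_sd[ft$id == i], row$s1, tolerance = 1e-12)
      expect_equal(ft$layer2_mean[ft$id == i], row$m2, tolerance = 1e-12)
      expect_equal(ft$layer2_sd[ft$id == i], row$s2, tolerance = 1e-12)
    }
  }
  # constant layer: every mean equals the constant, sd 0
  lab <- random_partition(10, 10, 5)
  ftc <- compute_features(make_segment_map(lab), list(matrix(7, 10, 10)))
  expect_true(all(ftc$layer1_mean == 7))
  expect_true(all(ftc$layer1_sd == 0))
})

test_that("1-NN classification matches an exhaustive scan oracle", {
  set.seed(25)
  for (rep in 1:10) {
    nseg <- sample(50:120, 1)
    tab <- data.frame(id = seq_len(nseg), area_px = sample(1:50, nseg, TRUE),
                      cx = runif(nseg), cy = runif(nseg),
                      f_mean = rnorm(nseg), f_sd = abs(rnorm(nseg)))
    tab$label <- NA_character_
    class(tab) <- c("segment_table", "data.frame")
    tr_id <- sample(nseg, 20)
    training <- data.frame(id = tr_id,
                           class = sample(c("LCF", "S"), 20, TRUE))
    out <- classify_nn(tab, training, min_per_class = 1)
    # oracle: standardize with training stats, scan every pair
    fc <- c("area_px", "f_mean", "f_sd")
    Fm <- as.matrix(tab[, fc])
    tri <- match(training$id, tab$id)
    mu <- colMeans(Fm[tri, ]); sdv <- apply(Fm[tri, ], 2, sd)
    sdv[sdv == 0] <- 1
    Z <- sweep(sweep(Fm, 2, mu), 2, sdv, "/")
    q <- setdiff(seq_len(nseg), tri)
    lab_o <- oracle_nn1(Z[q, , drop = FALSE], Z[tri, , drop = FALSE],
                        training$class, training$id)
    expect_identical(out$label[q], lab_o)
    expect_identical(out$label[tri], training$class)
  }
})

test_that("nearest-neighbour geometry and training validation behave", {
  tab <- data.frame(id = 1:3, area_px = c(1, 1, 1), cx = 0, cy = 0,
                    f_mean = c(0, 10, 2), f_sd = 0)
  tab$label <- NA_character_
  class(tab) <- c("segment_table", "data.frame")
  training <- data.frame(id = 1:2, class = c("S", "LCF"))
  out <- classify_nn(tab, training, min_per_class = 1)
  expect_identical(out$label[3], "S")      # query at 2 is nearer 0 than 10
  expect_error(classify_nn(tab, training, min_per_class = 5),
               "min_per_class")
})

test_that("accuracy assessment reproduces hand-computed matrices", {
  # identity gives 100% and kappa 1
  r <- scene_raster(matrix(rep(1:2, each = 8), 4, 4), 1, band = "class")
  acc <- accuracy_assessment(r, r)
  expect_equal(acc$overall_accuracy, 100)
  expect_equal(acc$kappa, 1)

  # literal 2x2 matrix [[40,10],[20,30]]
  ref <- c(rep("A", 50), rep("B", 50))
  pred <- c(rep("A", 40), rep("B", 10), rep("A", 20), rep("B", 30))
  acc2 <- accuracy_assessment(pred, ref)
  expect_equal(acc2$overall_accuracy, 70)
  expect_equal(acc2$kappa, 0.4)
  expect_equal(unname(acc2$producers), c(80, 60))
  expect_equal(unname(acc2$users), c(400 / 6, 75))

  # one-class reference with perfect prediction: kappa undefined
  expect_warning(acc3 <- accuracy_assessment(rep("A", 5), rep("A", 5)),
                 "kappa")
  expect_true(is.na(acc3$kappa))
  expect_equal(acc3$overall_accuracy, 100)

  # overall accuracy is invariant to class relabeling
  relab <- c(A = "Z", B = "Q")
  acc4 <- accuracy_assessment(unname(relab[pred]), unname(relab[ref]))
  expect_equal(acc4$overall_accuracy, acc2$overall_accuracy)
  expect_equal(acc4$kappa, acc2$kappa)
})

test_that("mismatched layers and empty references error", {
  expect_error(segment_scene(list(matrix(1, 4, 4), matrix(1, 5, 4)), 10),
               "co-registered")
  expect_error(accuracy_assessment(character(0), character(0)), "empty")
})
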