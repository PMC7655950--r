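facies_from_counts <- function(counts) {
  # counts: named vector over facies classes; builds a categorical raster
  codes <- rep(unname(facies_legend()[names(counts)]), counts)
  n <- length(codes)
  nc <- ceiling(sqrt(n))
  v <- matrix(c(codes, rep(NA, nc^2 - n)), nc, nc)
  scene_raster(v, 1, band = "class")
}

test_that("facies proportions are exhaustive cell-count percentages", {
  r <- facies_from_counts(c(S = 25))
  expect_equal(unname(facies_proportions(r)["S"]), 100)

  # a rubble-dominated composition like a ridge-crest site
  r2 <- facies_from_counts(c(CR = 82, LCF = 10, DCF = 8))
  fp <- facies_proportions(r2)
  expect_equal(unname(fp["CR"]), 82)
  expect_equal(sum(fp), 100)

  set.seed(41)
  v <- matrix(sample(1:5, 144, TRUE), 12, 12)
  fp3 <- facies_proportions(scene_raster(v, 1, band = "class"))
  expect_equal(sum(fp3), 100)
  expect_error(facies_proportions(
    scene_raster(matrix(NA_real_, 3, 3), 1, band = "class")), "valid cells")
})

test_that("live-coral aspect is the circular mean over LCF cells", {
  fac <- scene_raster(matrix(facies_legend()[["LCF"]], 2, 2), 1,
                      band = "class")
  asp <- scene_raster(matrix(45, 2, 2), 1, band = "aspect")
  la <- lcf_aspect(fac, asp)
  expect_equal(la$mean_deg, 45)
  expect_identical(la$sector, "NE")

  # symmetric pair across north averages to 0, sector N
  asp2 <- scene_raster(matrix(c(10, 350, 10, 350), 2, 2), 1,
                       band = "aspect")
  la2 <- lcf_aspect(fac, asp2)
  expect_equal(la2$mean_deg %% 360, 0)
  expect_identical(la2$sector, "N")

  # no LCF cells: NA with warning
  fac3 <- scene_raster(matrix(facies_legend()[["S"]], 2, 2), 1,
                       band = "class")
  expect_warning(la3 <- lcf_aspect(fac3, asp), "LCF")
  expect_true(is.na(la3$mean_deg))
})

test_that("a von Mises aspect field is recovered within 5 degrees", {
  set.seed(42)
  for (mu in c(135, 350)) {
    a <- rvonmises_deg(1000, mu, 4)
    n <- ceiling(sqrt(1000))
    av <- matrix(c(a, rep(NA, n^2 - 1000)), n, n)
    fac <- scene_raster(matrix(facies_legend()[["LCF"]], n, n), 1,
                        band = "class")
    la <- lcf_aspect(fac, scene_raster(av, 1, band = "aspect"))
    d <- abs(la$mean_deg - mu) %% 360
    expect_lt(min(d, 360 - d), 5)
    expect_equal(la$n_cells, 1000)
  }
})

test_that("coral-facing mean conditions on opposing flow directions", {
  # currents into a 45-deg-facing coral travel toward 225
  s <- make_series(c(rep(10, 50), rep(30, 50)),
                   c(rep(225, 50), rep(45, 50)))
  cf <- coral_facing_mean(s, 45)
  expect_equal(cf$mean, 10)
  expect_equal(cf$n, 50)

  # no opposing records at all
  s2 <- make_series(rep(20, 30), rep(90, 30))
  cf2 <- coral_facing_mean(s2, 90)
  expect_true(is.na(cf2$mean))
  expect_equal(cf2$n, 0)

  # tol = 180 covers all directions: unconditional mean
  set.seed(43)
  s3 <- make_series(runif(100) * 40, runif(100) * 360)
  expect_error(coral_facing_mean(s3, 10, tol = 180), "tol")
  cf3a <- coral_facing_mean(s3, 10, tol = 90)
  cf3b <- coral_facing_mean(s3, 190, tol = 90)
  both <- (cf3a$mean * cf3a$n + cf3b$mean * cf3b$n) / (cf3a$n + cf3b$n)
  expect_equal(both, mean(s3$speed_cms))
})

test_that("facing and feeding statistics match brute-force record scans", {
  set.seed(44)
  for (rep in 1:25) {
    n <- sample(50:200, 1)
    sp <- runif(n) * 50
    dr <- runif(n) * 360
    ca <- runif(1) * 360
    s <- make_series(sp, dr)
    cf <- coral_facing_mean(s, ca, tol = 22.5)
    o <- oracle_facing_mean(sp, dr, ca, 22.5)
    if (is.na(o)) expect_true(is.na(cf$mean)) else expect_equal(cf$mean, o)
    for (smax in c(2.5, 5)) {
      expect_equal(feeding_window_pct(s, ca, smax, tol = 22.5),
                   oracle_feeding_pct(sp, dr, ca, smax, 22.5))
    }
    # adding full turns to directions or aspect changes nothing
    s360 <- make_series(sp, dr + 360)
    cf2 <- coral_facing_mean(s360, ca + 360, tol = 22.5)
    expect_identical(cf2, cf)
  }
  # constructed feeding window: 10% of records oppose slowly
  sp <- c(rep(2, 10), rep(30, 90))
  dr <- c(rep(180, 10), rep(0, 90))
  s <- make_series(sp, dr)
  expect_equal(feeding_window_pct(s, 0, 2.5), 10)
  expect_equal(feeding_window_pct(s, 0, 0), 0)  # strictly positive speeds
})

test_that("reduction percentage reproduces the published arithmetic", {
  expect_equal(reduction_pct(25, 7), 72)
  expect_equal(reduction_pct(13, 13), 0)
  expect_equal(reduction_pct(25.4, 7.0), 72.44094, tolerance = 1e-6)
  expect_error(reduction_pct(0, 5), "positive")
})

test_that("cross-site rank trends match exhaustive rank arithmetic", {
  sites <- upbc_site_stats()
  coral <- sites[sites$coral, ]
  tr <- cross_site_trend(coral, "cr_pct", "max_speed")
  expect_equal(tr$rho, 0.7)
  expect_equal(tr$n, 5)
  expect_equal(tr$rho, oracle_spearman(coral$cr_pct, coral$max_speed))

  with_lcf <- coral[is.finite(coral$lcf_pct), ]
  tr2 <- cross_site_trend(with_lcf, "lcf_pct", "coral_facing_mean")
  expect_equal(tr2$rho, -1)
  expect_equal(tr2$n, 4)
  expect_equal(tr2$rho,
               oracle_spearman(with_lcf$lcf_pct, with_lcf$coral_facing_mean))

  # monotone relation gives rho 1; ties use average ranks
  d <- data.frame(x = c(1, 2, 3, 4), y = c(10, 20, 30, 40))
  expect_equal(cross_site_trend(d, "x", "y")$rho, 1)
  d2 <- data.frame(x = c(1, 1, 2, 3), y = c(5, 5, 7, 9))
  expect_equal(cross_site_trend(d2, "x", "y")$rho,
               oracle_spearman(d2$x, d2$y))
  expect_error(cross_site_trend(d[1:2, ], "x", "y"), "3 sites")
})

test_that("coral and non-coral group means reproduce the published contrast", {
  sites <- upbc_site_stats()
  g <- coral_vs_noncoral_means(sites)
  expect_equal(round(g$coral, 1), 21.5)
  expect_equal(g$coral, mean(c(31.3, 24.0, 17.3, 25.4, 9.4)))
  expect_equal(round(g$non_coral, 2), 13.95)
  # degenerate groups
  one <- data.frame(mean_speed = 12, coral = TRUE)
  g2 <- coral_vs_noncoral_means(one)
  expect_equal(g2$coral, 12)
  expect_true(is.na(g2$non_coral))
})

test_that("the site report writes a stable, schema-complete bundle", {
  set.seed(45)
  fac <- facies_from_counts(c(LCF = 40, DCF = 20, CR = 30, S = 10))
  asp <- scene_raster(matrix(runif(100) * 360, 10, 10), 1, band = "aspect")
  s <- make_series(runif(300) * 30, runif(300) * 360)
  hs <- habitat_summary("synthA", fac, asp, s)
  expect_equal(sum(hs$facies_pct), 100)
  expect_true(abs(hs$reduction_pct -
                  100 * (hs$overall_mean - hs$coral_facing_mean) /
                    hs$overall_mean) < 1e-12)

  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  expect_error(habitat_report(list(), out1), "no site")
  p1 <- habitat_report(list(hs), out1)
  p2 <- habitat_report(list(hs), out2)
  expect_true(all(file.exists(unlist(p1))))
  j <- jsonlite::read_json(p1$report)
  expect_setequal(names(j), c("convention", "sites", "habitat", "trends"))
  expect_match(j$convention, "flow-toward")
  # deterministic re-run: identical bytes
  expect_identical(readLines(p1$report), readLines(p2$report))
  expect_identical(readLines(p1$habitat_summary),
                   readLines(p2$habitat_summary))
})
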