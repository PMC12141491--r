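test_that("circularity formula hits its closed forms", {
  r <- 7.3
  expect_equal(circularity(pi * r^2, 2 * pi * r), 1, tolerance = 1e-12)
  s <- 11
  expect_equal(circularity(s^2, 4 * s), pi / 4, tolerance = 1e-12)
  expect_equal(circularity(pi * 2, ellipse_perimeter(2, 1)),
               ellipse_circularity(2, 1), tolerance = 1e-12)
  expect_error(circularity(0, 10), "positive")
})

test_that("rasterized disk and square are measured within the estimator
           tolerance of their analytic values", {
  disk <- raster_disk(50)
  mo <- measure_objects(disk)
  expect_equal(nrow(mo), 1)
  expect_lt(abs(mo$area_px2 - pi * 50^2) / (pi * 50^2), 0.01)
  expect_lt(abs(mo$circularity - 1), 0.03)

  sq <- measure_objects(raster_square(100))
  expect_lt(abs(sq$circularity - pi / 4), 0.03)

  ell <- measure_objects(raster_ellipse(40, 20))
  expect_lt(abs(ell$circularity - ellipse_circularity(40, 20)), 0.03)
})

test_that("measured circularity of disks converges toward 1 with radius:
           largest error at the coarsest scale, then a sub-0.02 plateau", {
  errs <- vapply(c(10, 25, 50, 100), function(r) {
    mean(vapply(list(c(0, 0), c(0.5, 0.5), c(0.25, 0.37)), function(o)
      abs(measure_objects(raster_disk(r, off = o))$circularity - 1),
      numeric(1)))
  }, numeric(1))
  expect_gt(errs[1], errs[2])
  expect_gt(errs[1], errs[3])
  expect_gt(errs[1], errs[4])
  expect_true(all(errs < 0.02))
})

test_that("circularity is scale invariant while area scales quadratically", {
  disk <- raster_disk(25)
  m1 <- measure_objects(disk, pixel_size_um = 1)
  m2 <- measure_objects(disk, pixel_size_um = 0.31)
  expect_equal(m1$circularity, m2$circularity, tolerance = 1e-12)
  expect_equal(m2$area_um2, m1$area_um2 * 0.31^2, tolerance = 1e-12)
  expect_equal(m2$perimeter_um, m1$perimeter_um * 0.31, tolerance = 1e-12)
})

test_that("segmentation finds separated disks and honours the splitting
           switch for overlapping ones", {
  img <- matrix(0, 200, 200)
  mk_disk <- function(img, cx, cy, r) {
    idx <- which(outer(1:200, 1:200, function(i, j)
      (i - cx)^2 + (j - cy)^2 <= r^2))
    img[idx] <- 0.8
    img
  }
  two <- mk_disk(mk_disk(img, 60, 60, 20), 140, 140, 20)
  expect_equal(attr(segment_objects(two), "n_objects"), 2)

  # centers 1.5 r apart: one fused blob
  over <- mk_disk(mk_disk(img, 90, 100, 20), 120, 100, 20)
  expect_equal(attr(segment_objects(over, split_touching = TRUE),
                    "n_objects"), 2)
  expect_equal(attr(segment_objects(over, split_touching = FALSE),
                    "n_objects"), 1)
})

test_that("an all-dark image segments to zero objects with a warning", {
  dark <- matrix(0, 64, 64)
  expect_warning(mk <- segment_objects(dark), "empty|minimum area")
  expect_equal(attr(mk, "n_objects"), 0)
  expect_equal(nrow(measure_objects(mk)), 0)
})

test_that("tiny objects fall below the minimum area filter", {
  img <- matrix(0, 64, 64)
  img[30, 30] <- 1                       # 1-pixel speck
  img[10:20, 10:20] <- 0.9               # real object
  mk <- segment_objects(img, min_area_px = 20)
  expect_equal(attr(mk, "n_objects"), 1)
})

test_that("segmentation recovers counts and circularity on generated
           scenes with separation >= 3 px", {
  cfg <- image_gen_config(image_shape_px = c(512, 512), n_objects = 25,
                          axis_ratio = function(n) 1.4 + runif(n, -0.2, 0.2),
                          mean_radius_um = 3, pixel_size_um = 0.2,
                          min_separation_px = 3, seed = 9, noise_sd = 0.02)
  sc <- gen_chloroplast_image(cfg)
  mk <- segment_objects(sc$image)
  expect_equal(attr(mk, "n_objects"), 25)
  mo <- measure_objects(mk, sc$pixel_size_um)
  # match measured objects to truth by centroid
  idx <- vapply(seq_len(nrow(mo)), function(i) {
    which.min((sc$truth$cx_px - mo$centroid_row[i])^2 +
                (sc$truth$cy_px - mo$centroid_col[i])^2)
  }, integer(1))
  expect_equal(sort(idx), 1:25)
  expect_lt(mean(abs(mo$circularity - sc$truth$circularity[idx])), 0.03)
})

test_that("the true label mask can be re-measured directly (mask import)", {
  sc <- gen_chloroplast_image(image_gen_config(n_objects = 10, seed = 14))
  mo <- measure_objects(sc)             # measures sc$mask with its pixel size
  expect_equal(nrow(mo), 10)
  expect_lt(mean(abs(mo$circularity - sc$truth$circularity)), 0.03)
})

test_that("replicate summaries use the median with midpoint convention", {
  obj <- function(circ) data.frame(circularity = circ,
                                   area_um2 = seq_along(circ),
                                   touches_border = FALSE)
  s <- summarize_replicate(obj(c(0.2, 0.5, 0.9)), "r1", min_n = 1)
  expect_equal(s$median_circularity, 0.5)
  s2 <- summarize_replicate(obj(c(0.4, 0.6)), "r2", min_n = 1)
  expect_equal(s2$median_circularity, 0.5)
  expect_error(summarize_replicate(data.frame(), "r3"), "at least one")
  expect_warning(summarize_replicate(obj(c(0.4, 0.6)), "r4", min_n = 50),
                 "only 2 objects")
})

test_that("a 200-object scene's measured median circularity lands within
           0.03 of the analytic median", {
  cfg <- image_gen_config(image_shape_px = c(1200, 1200), n_objects = 200,
                          axis_ratio = function(n) 1.5 + runif(n, -0.3, 0.3),
                          mean_radius_um = 2.6, pixel_size_um = 0.2,
                          min_separation_px = 3, seed = 27, noise_sd = 0.02)
  sc <- gen_chloroplast_image(cfg)
  mo <- measure_objects(segment_objects(sc$image), sc$pixel_size_um)
  expect_equal(nrow(mo), 200)
  expect_lt(abs(median(mo$circularity) - median(sc$truth$circularity)), 0.03)
})

test_that("ordering of group medians is preserved and gated comparison
           separates ovoid from near-spherical populations", {
  set.seed(81)
  med_of <- function(sampler, seed) {
    sc <- gen_chloroplast_image(image_gen_config(
      image_shape_px = c(640, 640), n_objects = 40, axis_ratio = sampler,
      mean_radius_um = 2.6, pixel_size_um = 0.2, seed = seed,
      noise_sd = 0.02))
    mo <- measure_objects(segment_objects(sc$image), 0.2)
    c(measured = median(mo$circularity), truth = median(sc$truth$circularity))
  }
  alga <- t(vapply(1:4, function(i) med_of(alga_ratio_sampler, 100 + i),
                   numeric(2)))
  slug <- t(vapply(1:4, function(i) med_of(slug_ratio_sampler, 200 + i),
                   numeric(2)))
  # analytic medians order slug > alga; measured medians must agree
  expect_true(all(slug[, "truth"] > max(alga[, "truth"])))
  expect_true(all(slug[, "measured"] > max(alga[, "measured"])))
  res <- compare_shape_groups(list(alga = alga[, "measured"],
                                   slug = slug[, "measured"]))
  expect_true(res$significant)
})

test_that("three-group shape comparison with a non-normal group takes the
           Kruskal-Wallis branch", {
  set.seed(4)
  g <- list(a = rnorm(8, 0.8, 0.02), b = rnorm(8, 0.82, 0.02),
            c = 0.7 + rlnorm(8, -3, 1.5))
  res <- compare_shape_groups(g)
  expect_equal(res$branch, "nonparametric")
  expect_equal(res$omnibus$test, "Kruskal-Wallis")
  expect_error(compare_shape_groups(list(a = 1, b = c(1, 2))),
               "at least 2 replicates")
})
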