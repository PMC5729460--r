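slice_volume <- function(m, px = 0.25) {
  ct_volume(array(m, dim = c(dim(m), 1)), spacing = c(px, px, 0.625))
}

test_that("a uniform blob segments into one lesion with pixel-count area and peak HU", {
  m <- matrix(40, 12, 12)
  m[4:8, 4:8] <- 300   # 25 pixels
  v <- slice_volume(m)
  les <- segment_calcium(v, array(TRUE, dim = dim(v$data)))
  expect_equal(nrow(les), 1L)
  expect_equal(les$area_mm2, 25 * 0.0625)   # 1.5625
  expect_equal(les$peak_hu, 300)
  expect_equal(les$weight, 3L)
})

test_that("the 130 HU lesion threshold is strict", {
  m <- matrix(130, 6, 6)
  v <- slice_volume(m)
  expect_equal(nrow(segment_calcium(v, array(TRUE, dim = dim(v$data)))), 0L)
  m[3, 3] <- 130.5
  v <- slice_volume(m)
  expect_equal(nrow(segment_calcium(v, array(TRUE, dim = dim(v$data)))), 1L)
})

test_that("diagonally touching blobs are one lesion under 8-connectivity", {
  m <- matrix(40, 8, 8)
  m[2:3, 2:3] <- 200
  m[4:5, 4:5] <- 250   # touches only at the (3,3)-(4,4) corner
  v <- slice_volume(m)
  les <- segment_calcium(v, array(TRUE, dim = dim(v$data)))
  expect_equal(nrow(les), 1L)
  expect_equal(les$peak_hu, 250)
})

test_that("per-slice labelling agrees with a brute-force 8-connected flood fill", {
  set.seed(101)
  for (rep in 1:25) {
    mask <- matrix(runif(100) < 0.35, 10, 10)
    m <- matrix(40, 10, 10)
    m[mask] <- 200
    v <- slice_volume(m)
    les <- segment_calcium(v, array(TRUE, dim = dim(v$data)))
    oracle <- flood_fill_8(mask)
    expect_equal(nrow(les), max(oracle))
    if (max(oracle) > 0)
      expect_setequal(les$pixels, as.integer(table(oracle[oracle > 0])))
  }
})

test_that("peak-HU weights follow the half-open Agatston bands over a full sweep", {
  peaks <- seq(131, 500, by = 1)
  expect_equal(weight_from_peak(peaks),
               vapply(peaks, brute_weight, integer(1)))
  expect_error(weight_from_peak(130), "exceed 130")
  expect_error(weight_from_peak(100), "exceed 130")
})

test_that("total CALS applies the area filter and slice-thickness adjustment", {
  les <- data.frame(lesion_id = 1:2, slice = 1L, pixels = c(64L, 32L),
                    area_mm2 = c(4, 2), peak_hu = c(350, 150),
                    weight = c(3L, 1L), score = c(12, 2))
  r <- total_cals(les, slice_thickness = 0.625)
  expect_equal(r$raw_sum, 14)
  expect_equal(r$total, 14 * 0.625 / 3)

  tiny <- data.frame(lesion_id = 1L, slice = 1L, pixels = 8L,
                     area_mm2 = 0.5, peak_hu = 500, weight = 4L, score = 2)
  r <- total_cals(tiny)
  expect_equal(r$total, 0)
  expect_equal(r$n_excluded, 1L)

  empty <- total_cals(tiny[0, , drop = FALSE])
  expect_equal(empty$total, 0)
  expect_error(total_cals(les, slice_thickness = 0), "positive")
})

test_that("missing spacing metadata is rejected before any area is computed", {
  broken <- structure(list(data = array(200, dim = c(4, 4, 1)), spacing = NULL),
                      class = "ct_volume")
  expect_error(segment_calcium(broken, array(TRUE, dim = c(4, 4, 1))),
               "spacing")
})

test_that("pipeline CALS equals the analytic oracle on noise-free phantoms", {
  for (seed in 1:10) {
    ph <- random_lesion_phantom(seed)
    got <- compute_cals(ph$volume, ph$truth$roi)$total
    expect_equal(got, ph$truth$analytic_cals,
                 info = sprintf("seed %d", seed))
  }
})

test_that("CALS is additive over well-separated lesion sets and monotone in added lesions", {
  mk <- function(lesions, seed = 1) {
    sp <- phantom_spec(shape = c(40, 40, 3), lesions = lesions, seed = seed)
    ph <- generate_plaque_volume(sp)
    compute_cals(ph$volume, ph$truth$roi)$total
  }
  a <- list(center = c(10, 10), radius_mm = 1.2, peak_hu = 350, slices = 1:2)
  b <- list(center = c(30, 30), radius_mm = 0.9, peak_hu = 220, slices = 2:3)
  expect_equal(mk(list(a, b)), mk(list(a)) + mk(list(b)))
  expect_gte(mk(list(a, b)), mk(list(a)))
})

test_that("halving the in-plane pixel size changes CALS only within the discretisation bound", {
  mk <- function(px) {
    sp <- phantom_spec(shape = c(round(10 / px), round(10 / px), 2),
                       spacing = c(px, px, 0.625),
                       lesions = list(list(center = round(c(5 / px, 5 / px)),
                                           radius_mm = 1.4, peak_hu = 350,
                                           slices = 1:2)),
                       seed = 6)
    ph <- generate_plaque_volume(sp)
    compute_cals(ph$volume, ph$truth$roi)$total
  }
  coarse <- mk(0.25); fine <- mk(0.125)
  # per lesion-slice bound: one pixel ring of area ~ perimeter x pixel size,
  # times the max weight, times the thickness adjustment
  bound <- 2 * (2 * pi * 1.4 * 0.25) * 4 * (0.625 / 3) * 2
  expect_lt(abs(coarse - fine), bound)
})
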