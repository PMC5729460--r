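vol_of <- function(hu_matrix) {
  ct_volume(array(hu_matrix, dim = c(dim(hu_matrix), 1)),
            spacing = c(0.25, 0.25, 0.625))
}

test_that("voxels map to the five HU bands with half-open boundaries", {
  v <- vol_of(matrix(30, 4, 4))
  roi <- array(TRUE, dim = dim(v$data))
  expect_true(all(classify_voxels(v, roi) == 1L))   # all lipid

  hu <- c(10, 19.9, 20, 39.9, 40, 59.9, 60, 79.9, 80, 250, 250.1, 600)
  v <- vol_of(matrix(hu, 3, 4))
  lab <- classify_voxels(v, array(TRUE, dim = dim(v$data)))
  expect_equal(as.vector(lab)[1:12],
               c(0L, 0L, 1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L, 5L, 5L))
})

test_that("classification is pointwise: voxels outside the ROI stay NA and an empty ROI errors", {
  v <- vol_of(matrix(c(30, 70, 100, 300), 2, 2))
  roi <- array(c(TRUE, FALSE, TRUE, FALSE), dim = dim(v$data))
  lab <- classify_voxels(v, roi)
  expect_true(all(is.na(lab[!roi])))
  expect_false(anyNA(lab[roi]))
  expect_error(classify_voxels(v, array(FALSE, dim = dim(v$data))),
               "empty plaque region")
})

test_that("component quantification computes volumes and normalised fractions", {
  # counts 3/2/1/0/0 across the bands plus one unclassified voxel
  hu <- c(25, 30, 35, 45, 55, 65, 5)
  v <- ct_volume(array(c(hu, 5), dim = c(2, 2, 2)), c(0.25, 0.25, 0.625))
  lab <- classify_voxels(v, array(TRUE, dim = dim(v$data)))
  pr <- quantify_components(lab)
  expect_equal(pr$fraction, c(0.5, 1 / 3, 1 / 6, 0, 0))
  expect_equal(pr$voxels, c(3L, 2L, 1L, 0L, 0L))
  expect_equal(pr$volume_mm3, pr$voxels * prod(v$spacing))
  expect_equal(attr(pr, "unclassified_mm3"), 2 * prod(v$spacing))
  expect_false(attr(pr, "degenerate"))

  # all voxels below 20 HU: degenerate profile, fractions undefined
  v2 <- vol_of(matrix(5, 2, 2))
  pr2 <- quantify_components(classify_voxels(v2, array(TRUE, dim = dim(v2$data))))
  expect_true(attr(pr2, "degenerate"))
  expect_true(all(is.na(pr2$fraction)))
})

make_profile <- function(fracs) {
  data.frame(band = c("lipid", "fibrolipid", "fibrotic", "fibrocalcified",
                      "calcification"),
             fraction = fracs)
}

test_that("vulnerability decision matches the rules on the worked examples", {
  r <- call_vulnerability(make_profile(c(0.6, 0, 0, 0.4, 0)))
  expect_equal(r$verdict, "vulnerable"); expect_equal(r$reason, "dominant_lipidic")

  r <- call_vulnerability(make_profile(c(0, 0, 0.7, 0.3, 0)))
  expect_equal(r$verdict, "stable"); expect_equal(r$reason, "dominant_stable")

  r <- call_vulnerability(make_profile(c(0.1, 0, 0.6, 0.3, 0)))
  expect_equal(r$verdict, "vulnerable")
  expect_equal(r$reason, "fibrotic_with_lipid_override")

  r <- call_vulnerability(make_profile(c(0.1, 0, 0, 0, 0.9)), ulcerated = TRUE)
  expect_equal(r$verdict, "vulnerable"); expect_equal(r$reason, "ulceration_override")

  # the lipid-presence override is literal to the fibrotic band only
  r <- call_vulnerability(make_profile(c(0.1, 0, 0, 0.9, 0)))
  expect_equal(r$verdict, "stable")

  expect_error(call_vulnerability(make_profile(rep(NA_real_, 5))),
               "cannot call vulnerability")
})

test_that("all 20 dominant-band x lipid-presence x ulceration combinations follow the rules", {
  bands <- c("lipid", "fibrolipid", "fibrotic", "fibrocalcified", "calcification")
  for (d in seq_along(bands)) for (lip in c(TRUE, FALSE)) for (ulc in c(TRUE, FALSE)) {
    fr <- rep(0, 5)
    fr[d] <- 0.6
    extra <- if (lip && d > 2) 0.1 else 0
    if (extra > 0) fr[1] <- extra
    rest <- 1 - sum(fr)
    sink_band <- if (d == 5) 4 else 5
    fr[sink_band] <- fr[sink_band] + rest
    res <- call_vulnerability(make_profile(fr), ulcerated = ulc)
    lipid_present <- fr[1] > 0 || fr[2] > 0
    expected <- if (ulc) "vulnerable"
      else if (d <= 2) "vulnerable"
      else if (d == 3 && lipid_present) "vulnerable"
      else "stable"
    expect_equal(res$verdict, expected,
                 info = sprintf("dominant=%s lipid=%s ulcerated=%s",
                                bands[d], lip, ulc))
  }
})

test_that("dominance ties resolve toward the more vulnerable band and are flagged", {
  r <- call_vulnerability(make_profile(c(0, 0, 0.5, 0.5, 0)))
  expect_equal(r$dominant, "fibrotic")
  expect_true(r$tie)
  r <- call_vulnerability(make_profile(c(0.5, 0, 0, 0.5, 0)))
  expect_equal(r$verdict, "vulnerable")
})

test_that("quantified volumes equal ground truth exactly on noise-free phantoms", {
  comps <- list(
    list(name = "lipid", mean = 30, sd = 0, center = c(10, 10), radius_mm = 1.5, slices = 1:3),
    list(name = "fibrotic", mean = 70, sd = 0, center = c(30, 30), radius_mm = 2, slices = 1:3)
  )
  ph <- generate_plaque_volume(phantom_spec(shape = c(40, 40, 3),
                                            components = comps, seed = 4))
  pr <- quantify_components(classify_voxels(ph$volume, ph$truth$roi))
  expect_equal(pr$volume_mm3[pr$band == "lipid"],
               unname(ph$truth$component_volumes["lipid"]))
  expect_equal(pr$volume_mm3[pr$band == "fibrotic"],
               unname(ph$truth$component_volumes["fibrotic"]))
})
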