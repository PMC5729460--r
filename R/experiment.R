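#' Build one paired CTA/NCCT phantom at a given calcification burden
#'
#' The phantom holds a contrast-filled lumen cylinder with one or two
#' calcified lesions abutting it; `burden` in `[0, 1]` scales lesion radius,
#' peak HU, lesion count and slice extent from a single small low-attenuation
#' lesion to multiple large, dense ones.
#'
#' @param burden scalar in `[0, 1]`.
#' @param seed integer seed for the phantom noise.
#' @param shape,spacing phantom grid (defaults 48 x 48 x 6 voxels at
#'   0.25 x 0.25 x 0.625 mm).
#' @param background_sd background noise SD in HU.
#' @return a phantom list `(volume, truth)` as from
#'   [generate_plaque_volume()], with the phantom spec attached as attribute
#'   `spec`.
#' @export
burden_phantom <- function(burden, seed, shape = c(48, 48, 6),
                           spacing = c(0.25, 0.25, 0.625),
                           background_sd = 3) {
  stopifnot(burden >= 0, burden <= 1)
  lumen_c <- c(shape[1] %/% 2, 14)
  lumen_r <- 2.0
  les_r <- 0.7 + 1.5 * burden
  peak <- 220 + 480 * burden
  n_slices <- 2L + as.integer(round(2 * burden))
  slices <- seq(2L, length.out = n_slices)
  gap <- 0.3
  d_px <- (lumen_r + les_r + gap) / spacing[2]
  lesions <- list(list(center = c(lumen_c[1], round(lumen_c[2] + d_px)),
                       radius_mm = les_r, peak_hu = peak, slices = slices))
  if (burden > 0.5) {
    d_px1 <- (lumen_r + les_r + gap) / spacing[1]
    lesions[[2]] <- list(center = c(round(lumen_c[1] - d_px1), lumen_c[2]),
                         radius_mm = les_r * 0.8, peak_hu = peak * 0.9,
                         slices = slices)
  }
  sp <- phantom_spec(shape = shape, spacing = spacing,
                     background_hu = 40, background_sd = background_sd,
                     lumen = list(center = lumen_c, radius_mm = lumen_r),
                     lumen_hu = 400, lesions = lesions,
                     blooming_width_mm = 0.5, seed = seed)
  ph <- generate_plaque_volume(sp)
  attr(ph, "spec") <- sp
  ph
}

#' Score a contrast CTA volume with bloom-aware ROI
#'
#' CTA-mode measurement of a bloomed volume: the scoring ROI is the plaque
#' ROI minus the bloom-ambiguous zone around the lumen
#' ([bloom_exclusion_mask()]), reflecting that a reader cannot attribute the
#' blurred contrast-calcification border to calcification. NCCT-mode scoring
#' of the same phantom uses the full plaque ROI (ex vivo, no contrast, no
#' blooming).
#'
#' @param v the (bloomed) CTA volume.
#' @param truth the phantom ground truth.
#' @param kernel_width_mm blooming kernel width used.
#' @inheritParams total_cals
#' @return a `cals_result`.
#' @export
score_cta <- function(v, truth, kernel_width_mm, min_area = 1) {
  roi <- truth$roi & !bloom_exclusion_mask(truth, kernel_width_mm, v$spacing)
  compute_cals(v, roi, min_area = min_area, mode = "CTA")
}

#' Paired CTA/NCCT calcification-score experiment
#'
#' Generates seeded phantom pairs spanning low to high calcification burden.
#' For each pair the same planted geometry is scored twice: NCCT mode (clean
#' volume, full plaque ROI) and CTA mode (volume with simulated contrast
#' blooming, bloom-exclusion ROI via [score_cta()]). The output feeds
#' [bland_altman()] and reproduces the systematic CTA underestimation that
#' grows with calcification burden.
#'
#' @param n_pairs number of phantom pairs (>= 2).
#' @param seed integer master seed; per-phantom seeds are derived from it.
#' @param kernel_width_mm blooming kernel width (mm, default 0.5).
#' @param ... passed to [burden_phantom()].
#' @return data frame with one row per pair: `pair`, `burden`, `cals_ncct`,
#'   `cals_cta`, `diff` (NCCT - CTA) and `mean`.
#' @export
paired_cals_experiment <- function(n_pairs = 50, seed = 1L,
                                   kernel_width_mm = 0.5, ...) {
  stopifnot(n_pairs >= 2)
  burdens <- seq(0.05, 1, length.out = n_pairs)
  rows <- lapply(seq_len(n_pairs), function(i) {
    ph <- burden_phantom(burdens[i], seed = seed + i, ...)
    ncct <- compute_cals(ph$volume, ph$truth$roi, mode = "NCCT")$total
    bloomed <- simulate_blooming(ph$volume, ph$truth, kernel_width_mm)
    cta <- score_cta(bloomed, ph$truth, kernel_width_mm)$total
    data.frame(pair = i, burden = burdens[i], cals_ncct = ncct,
               cals_cta = cta)
  })
  out <- do.call(rbind, rows)
  out$diff <- out$cals_ncct - out$cals_cta
  out$mean <- (out$cals_ncct + out$cals_cta) / 2
  out
}
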