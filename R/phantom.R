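# run expr with a private RNG state seeded at `seed`, restoring the caller's
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# in-plane elliptical disc mask on a (nr x nc) grid; radius in mm
disc_mask <- function(nr, nc, center, radius_mm, spacing) {
  dy <- (seq_len(nr) - center[1]) * spacing[1]
  dx <- (seq_len(nc) - center[2]) * spacing[2]
  outer(dy^2, dx^2, `+`) <= radius_mm^2
}

# truncated normal draws on (lo, hi) via the inverse-CDF trick; sd = 0 gives mu
rtruncnorm <- function(n, mu, sd, lo, hi) {
  if (sd == 0) return(rep(mu, n))
  plo <- stats::pnorm(lo, mu, sd); phi <- stats::pnorm(hi, mu, sd)
  stats::qnorm(stats::runif(n, plo, phi), mu, sd)
}

#' Specify a synthetic carotid plaque CT phantom
#'
#' Describes a phantom volume: a soft-tissue background, an optional
#' contrast-filled lumen cylinder, plaque tissue components drawn as
#' in-plane discs with HU sampled from a truncated Gaussian inside the
#' component's band, and discrete calcified lesions with a radially
#' decreasing HU profile (peak at the centre, 140 HU at the rim, so the
#' whole lesion sits above the 130 HU scoring threshold). Because component
#' noise is truncated to the band, ground-truth band membership is exact and
#' downstream classification oracles are exact rather than probabilistic.
#'
#' Geometry is given in voxel indices (centres) and millimetres (radii).
#' Component entries are lists
#' `list(name, mean, sd, center = c(row, col), radius_mm, slices)` where
#' `name` is one of the five bands and `mean` lies strictly inside it.
#' Lesions are lists `list(center = c(row, col), radius_mm, peak_hu, slices)`.
#'
#' @param shape integer length-3: rows, columns, slices.
#' @param spacing voxel spacing in mm; default in-plane 0.25 mm, slice
#'   thickness 0.625 mm.
#' @param background_hu,background_sd soft-tissue background (default 40 HU,
#'   SD 0).
#' @param lumen `NULL` or `list(center = c(row, col), radius_mm)`; spans all
#'   slices.
#' @param lumen_hu contrast attenuation of the lumen (default 400 HU).
#' @param components list of component entries (see above).
#' @param lesions list of lesion entries (see above).
#' @param blooming_width_mm default blooming kernel width carried by the
#'   spec (must be >= 0); blooming itself is applied by
#'   [simulate_blooming()].
#' @param seed integer seed; a fixed seed yields bit-identical phantoms.
#' @return A validated list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(48, 48, 8),
                         spacing = c(0.25, 0.25, 0.625),
                         background_hu = 40, background_sd = 0,
                         lumen = NULL, lumen_hu = 400,
                         components = list(), lesions = list(),
                         blooming_width_mm = 0, seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) stop("shape must be 3 positive integers")
  if (any(spacing <= 0)) stop("voxel spacing must be positive")
  if (blooming_width_mm < 0) stop("blooming kernel width must be >= 0")
  sch <- component_scheme()
  for (cm in components) {
    if (!cm$name %in% sch$band)
      stop("unknown component band: ", cm$name)
    row <- sch[sch$band == cm$name, ]
    if (!(cm$mean > row$lower && cm$mean < row$upper))
      stop(sprintf("component '%s' mean %.1f HU is not strictly inside its band [%g, %g)",
                   cm$name, cm$mean, row$lower, row$upper))
    if (cm$radius_mm <= 0) stop("component radius must be > 0")
  }
  for (le in lesions) {
    if (le$radius_mm <= 0) stop("lesion radius must be > 0")
    if (le$peak_hu <= 140) stop("lesion peak HU must exceed the 140 HU rim value")
  }
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 background_hu = background_hu, background_sd = background_sd,
                 lumen = lumen, lumen_hu = lumen_hu,
                 components = components, lesions = lesions,
                 blooming_width_mm = blooming_width_mm,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# mask (3-D logical) of one region entry over its slice extent
region_mask <- function(spec, entry) {
  m <- array(FALSE, dim = spec$shape)
  disc <- disc_mask(spec$shape[1], spec$shape[2], entry$center,
                    entry$radius_mm, spec$spacing)
  slices <- if (is.null(entry$slices)) seq_len(spec$shape[3]) else entry$slices
  for (k in slices) m[, , k] <- disc
  m
}

#' Generate a plaque phantom volume with analytic ground truth
#'
#' Renders the phantom described by a [phantom_spec()]: background voxels get
#' `Normal(background_hu, background_sd)` noise, component voxels a Gaussian
#' truncated to the component's HU band, lumen voxels the contrast HU, and
#' lesion voxels a deterministic radial profile from `peak_hu` at the centre
#' down to 140 HU at the rim. Regions that overlap with conflicting HU
#' (component-component, lesion-lesion, or anything overlapping the lumen)
#' raise an error naming the colliding regions; a lesion inside a component
#' simply overwrites it (calcification embedded in plaque tissue).
#'
#' The ground truth carries per-component volumes (planted voxel count times
#' voxel volume), the per-slice lesion areas and peaks, the plaque ROI and
#' lumen masks, and the analytic CALS computed from the planted geometry:
#' sum of `area x weight(peak)` over lesion-slices with area >= 1 mm^2,
#' multiplied by `slice_thickness / 3`.
#'
#' @param spec a [phantom_spec()].
#' @param iph,ulcerated optional ground-truth flags carried through.
#' @return A list with elements `volume` (a [ct_volume()]) and `truth` (class
#'   `ground_truth`: `component_volumes`, `lesion_table`, `analytic_cals`,
#'   `roi`, `lumen_mask`, `lesion_mask`, `iph`, `ulcerated`).
#' @examples
#' sp <- phantom_spec(shape = c(24, 24, 3),
#'                    lesions = list(list(center = c(12, 12), radius_mm = 1.2,
#'                                        peak_hu = 350, slices = 2)))
#' ph <- generate_plaque_volume(sp)
#' ph$truth$analytic_cals
#' @export
generate_plaque_volume <- function(spec, iph = NA, ulcerated = FALSE) {
  stopifnot(inherits(spec, "phantom_spec"))
  sch <- component_scheme()
  nr <- spec$shape[1]; nc <- spec$shape[2]; ns <- spec$shape[3]

  comp_masks <- lapply(spec$components, function(cm) region_mask(spec, cm))
  les_masks <- lapply(spec$lesions, function(le) region_mask(spec, le))
  lumen_mask <- if (!is.null(spec$lumen))
    region_mask(spec, spec$lumen) else array(FALSE, dim = spec$shape)

  name_of <- function(prefix, i, entries)
    sprintf("%s '%s'", prefix,
            if (!is.null(entries[[i]]$name)) entries[[i]]$name else as.character(i))
  check_overlap <- function(masks_a, masks_b, label_a, label_b, entries_a, entries_b, same = FALSE) {
    for (i in seq_along(masks_a)) {
      jj <- if (same) seq_len(i - 1L) else seq_along(masks_b)
      for (j in jj)
        if (any(masks_a[[i]] & masks_b[[j]]))
          stop(sprintf("overlapping regions with conflicting HU: %s and %s",
                       name_of(label_a, i, entries_a), name_of(label_b, j, entries_b)))
    }
  }
  check_overlap(comp_masks, comp_masks, "component", "component",
                spec$components, spec$components, same = TRUE)
  check_overlap(les_masks, les_masks, "lesion", "lesion",
                spec$lesions, spec$lesions, same = TRUE)
  if (any(lumen_mask)) {
    for (i in seq_along(comp_masks))
      if (any(comp_masks[[i]] & lumen_mask))
        stop(sprintf("overlapping regions with conflicting HU: %s and the lumen",
                     name_of("component", i, spec$components)))
    for (i in seq_along(les_masks))
      if (any(les_masks[[i]] & lumen_mask))
        stop(sprintf("overlapping regions with conflicting HU: %s and the lumen",
                     name_of("lesion", i, spec$lesions)))
  }

  vol <- with_seed(spec$seed, {
    dat <- array(stats::rnorm(prod(spec$shape), spec$background_hu,
                              spec$background_sd), dim = spec$shape)
    for (i in seq_along(spec$components)) {
      cm <- spec$components[[i]]
      row <- sch[sch$band == cm$name, ]
      m <- comp_masks[[i]]
      dat[m] <- rtruncnorm(sum(m), cm$mean, cm$sd, row$lower, row$upper)
    }
    dat[lumen_mask] <- spec$lumen_hu
    dat
  })

  # lesions: deterministic radial profile, peak at the (voxel-centre) centre
  px <- spec$spacing[1] * spec$spacing[2]
  lesion_rows <- list()
  lesion_mask <- array(FALSE, dim = spec$shape)
  for (i in seq_along(spec$lesions)) {
    le <- spec$lesions[[i]]
    dy <- (seq_len(nr) - le$center[1]) * spec$spacing[1]
    dx <- (seq_len(nc) - le$center[2]) * spec$spacing[2]
    r <- sqrt(outer(dy^2, dx^2, `+`))
    disc <- r <= le$radius_mm
    prof <- le$peak_hu - (le$peak_hu - 140) * (r / le$radius_mm)
    slices <- if (is.null(le$slices)) seq_len(ns) else le$slices
    for (k in slices) {
      sl <- vol[, , k]
      sl[disc] <- prof[disc]
      vol[, , k] <- sl
      lesion_mask[, , k] <- lesion_mask[, , k] | disc
      lesion_rows[[length(lesion_rows) + 1L]] <-
        data.frame(lesion = i, slice = k, area_mm2 = sum(disc) * px,
                   peak_hu = le$peak_hu)
    }
  }
  lesion_table <- if (length(lesion_rows)) do.call(rbind, lesion_rows)
                  else data.frame(lesion = integer(), slice = integer(),
                                  area_mm2 = numeric(), peak_hu = numeric())

  roi <- Reduce(`|`, comp_masks, init = lesion_mask)

  comp_vol <- vapply(comp_masks, sum, numeric(1)) * prod(spec$spacing)
  names(comp_vol) <- vapply(spec$components, `[[`, character(1), "name")

  truth <- structure(list(
    component_volumes = comp_vol,
    lesion_table = lesion_table,
    analytic_cals = analytic_cals(lesion_table, spec$spacing[3]),
    roi = roi, lumen_mask = lumen_mask, lesion_mask = lesion_mask,
    iph = iph, ulcerated = ulcerated
  ), class = "ground_truth")

  list(volume = ct_volume(vol, spec$spacing), truth = truth)
}

#' Analytic CALS from planted lesion geometry
#'
#' The ground-truth oracle: per lesion-slice with true area of at least
#' `min_area`, `area x weight(true peak)`, summed and adjusted by
#' `slice_thickness / 3`. No image processing is involved.
#'
#' @param lesion_table data frame with `area_mm2` and `peak_hu` per
#'   lesion-slice.
#' @param slice_thickness mm (default 0.625).
#' @param min_area mm^2 (default 1).
#' @return the analytic total CALS (numeric scalar).
#' @export
analytic_cals <- function(lesion_table, slice_thickness = 0.625, min_area = 1) {
  keep <- lesion_table$area_mm2 >= min_area
  if (!any(keep)) return(0)
  sum(lesion_table$area_mm2[keep] *
        weight_from_peak(lesion_table$peak_hu[keep])) * slice_thickness / 3
}

#' Simulate contrast blooming near the lumen
#'
#' Models the blooming artifact of contrast-enhanced CT: intensities in a
#' band around the contrast-filled lumen are smoothed with a normalised
#' in-plane Gaussian kernel of the stated width, spreading contrast-level HU
#' into neighbouring voxels and blurring the contrast-calcification border.
#' Voxels outside the band — in particular lesions far from the lumen — are
#' untouched. A kernel width of 0 returns the input volume unchanged.
#'
#' @param v a [ct_volume()].
#' @param truth the phantom's `ground_truth` (provides the lumen mask).
#' @param kernel_width_mm Gaussian sigma in mm, >= 0; the affected band
#'   extends about `2 x kernel_width_mm` beyond the lumen.
#' @return a `ct_volume` with blooming applied.
#' @export
simulate_blooming <- function(v, truth, kernel_width_mm) {
  stopifnot_ct_volume(v)
  if (!is.numeric(kernel_width_mm) || length(kernel_width_mm) != 1L ||
      is.na(kernel_width_mm) || kernel_width_mm < 0)
    stop("blooming kernel width must be a single non-negative length (mm)")
  if (kernel_width_mm == 0) return(v)
  lumen <- truth$lumen_mask
  if (!any(lumen)) return(v)
  sigma_px <- kernel_width_mm / v$spacing[1]
  band_px <- max(1L, ceiling(2 * sigma_px))
  brush <- EBImage::makeBrush(2L * band_px + 1L, shape = "disc")
  out <- v$data
  for (k in seq_len(dim(out)[3])) {
    lum <- lumen[, , k]
    if (!any(lum)) next
    band <- EBImage::dilate(matrix(as.numeric(lum), nrow = nrow(lum)), brush) > 0
    blurred <- EBImage::gblur(out[, , k], sigma = sigma_px)
    sl <- out[, , k]
    sl[band] <- blurred[band]
    out[, , k] <- sl
  }
  ct_volume(out, v$spacing)
}

#' Mask of the bloom-ambiguous zone around the lumen
#'
#' The region a reader cannot attribute confidently to either contrast or
#' calcification once blooming has blurred the border: the lumen dilated
#' in-plane by the blooming extent. CTA-mode scoring excludes this zone from
#' the plaque ROI; see [paired_cals_experiment()].
#'
#' @param truth a phantom `ground_truth`.
#' @param kernel_width_mm blooming kernel width in mm.
#' @param spacing voxel spacing of the phantom.
#' @return logical array: TRUE inside the exclusion zone.
#' @export
bloom_exclusion_mask <- function(truth, kernel_width_mm, spacing) {
  lumen <- truth$lumen_mask
  if (kernel_width_mm <= 0 || !any(lumen)) return(lumen)
  band_px <- max(1L, ceiling(2 * kernel_width_mm / spacing[1]))
  brush <- EBImage::makeBrush(2L * band_px + 1L, shape = "disc")
  out <- lumen
  for (k in seq_len(dim(lumen)[3])) {
    lum <- lumen[, , k]
    if (!any(lum)) next
    out[, , k] <- EBImage::dilate(matrix(as.numeric(lum), nrow = nrow(lum)),
                                  brush) > 0
  }
  out
}

#' Write a phantom with its ground-truth sidecar
#'
#' The volume goes to NIfTI (signed 16-bit HU, spacing in the header), the
#' ground truth to a JSON sidecar (`<stem>.truth.json`) holding component
#' volumes, the lesion table and the analytic CALS.
#'
#' @param phantom a list `(volume, truth)` from [generate_plaque_volume()].
#' @param stem output path without extension.
#' @return paths of the files written, invisibly.
#' @export
write_phantom <- function(phantom, stem) {
  nii <- paste0(stem, ".nii.gz")
  js <- paste0(stem, ".truth.json")
  write_nifti_volume(phantom$volume, nii)
  tr <- phantom$truth
  jsonlite::write_json(list(component_volumes = as.list(tr$component_volumes),
                            lesion_table = tr$lesion_table,
                            analytic_cals = tr$analytic_cals,
                            iph = tr$iph, ulcerated = tr$ulcerated),
                       js, auto_unbox = TRUE, digits = NA)
  invisible(c(nii, js))
}
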