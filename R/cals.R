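#' Peak-HU weight of a calcified lesion
#'
#' The Agatston-style weighting of a lesion by its peak attenuation:
#' weight 1 for peaks in `[130, 200)` HU, 2 in `[200, 300)`, 3 in `[300, 400)`
#' and 4 for 400 HU and above. The printed protocol ranges overlap at their
#' edges (130-200 / 200-300 / 300-400 / >400); the half-open reading is the
#' only self-consistent one and follows the original Agatston convention.
#'
#' @param peak numeric vector of peak HU values; every element must exceed
#'   130 HU (the lesion threshold).
#' @return integer weights in `{1, 2, 3, 4}`.
#' @examples
#' weight_from_peak(c(150, 200, 350, 450))   # 1 2 3 4
#' @export
weight_from_peak <- function(peak) {
  if (any(peak <= 130))
    stop("peak HU must exceed 130 (not a lesion pixel)")
  w <- integer(length(peak))
  w[peak < 200] <- 1L
  w[peak >= 200 & peak < 300] <- 2L
  w[peak >= 300 & peak < 400] <- 3L
  w[peak >= 400] <- 4L
  w
}

# 8-connected 2-D labelling: EBImage::bwlabel is 4-connected, so merge labels
# that touch diagonally with a union-find pass.
label_8conn <- function(mask) {
  mask <- matrix(as.numeric(mask), nrow = nrow(mask))
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow = nrow(mask))
  n <- max(lab)
  if (n <= 1L) return(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union_ <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj) }
  nr <- nrow(lab); nc <- ncol(lab)
  # diagonal neighbour pairs: (i,j)-(i+1,j+1) and (i+1,j)-(i,j+1)
  a <- lab[-nr, -nc]; b <- lab[-1, -1]
  idx <- which(a > 0L & b > 0L & a != b)
  for (k in idx) union_(a[k], b[k])
  a <- lab[-1, -nc]; b <- lab[-nr, -1]
  idx <- which(a > 0L & b > 0L & a != b)
  for (k in idx) union_(a[k], b[k])
  root <- vapply(seq_len(n), find, integer(1))
  dense <- match(root, sort(unique(root)))
  lab[lab > 0L] <- dense[lab[lab > 0L]]
  lab
}

#' Segment calcified lesions per axial slice
#'
#' Pixels with HU strictly above 130 inside the ROI are grouped, per axial
#' slice, into 8-connected components; each component is one lesion with an
#' area (pixel count times in-plane pixel area) and a peak HU. A physical
#' calcification spanning several slices contributes one lesion per slice,
#' matching the per-slice manual scoring protocol.
#'
#' @param v a [ct_volume()] in HU with spacing metadata.
#' @param roi logical array of the same shape (the plaque ROI).
#' @param threshold lesion threshold in HU, strict (default 130).
#' @return A data frame of lesions with columns `lesion_id`, `slice`,
#'   `pixels`, `area_mm2`, `peak_hu`, `weight`, `score` (= area x weight).
#'   Zero rows when nothing exceeds the threshold.
#' @export
segment_calcium <- function(v, roi, threshold = 130) {
  stopifnot_ct_volume(v)
  roi <- check_roi(v, roi)
  px <- pixel_area(v)
  out <- vector("list", dim(v$data)[3])
  for (k in seq_len(dim(v$data)[3])) {
    sl <- v$data[, , k]
    mask <- roi[, , k] & (sl > threshold)
    if (!any(mask)) next
    lab <- label_8conn(mask)
    ids <- seq_len(max(lab))
    npix <- tabulate(lab[lab > 0L], nbins = max(lab))
    peak <- vapply(ids, function(i) max(sl[lab == i]), numeric(1))
    out[[k]] <- data.frame(slice = k, pixels = npix,
                           area_mm2 = npix * px, peak_hu = peak)
  }
  les <- do.call(rbind, out)
  if (is.null(les))
    les <- data.frame(slice = integer(), pixels = integer(),
                      area_mm2 = numeric(), peak_hu = numeric())
  les$weight <- if (nrow(les)) weight_from_peak(les$peak_hu) else integer()
  les$score <- les$area_mm2 * les$weight
  les <- cbind(lesion_id = seq_len(nrow(les)), les)
  rownames(les) <- NULL
  les
}

#' Total carotid calcification score (CALS)
#'
#' Sums per-lesion scores (area x peak-HU weight) after dropping lesions
#' smaller than `min_area`, then adjusts the raw sum by
#' `slice_thickness / 3` to convert the thin-slice acquisition (default
#' 0.625 mm) to the 3 mm reference thickness of the Agatston score.
#' The identical aggregation is used for contrast CTA and non-contrast CT;
#' `mode` is recorded for provenance only.
#'
#' @param lesions a lesion table from [segment_calcium()].
#' @param slice_thickness acquisition slice thickness in mm (default 0.625).
#' @param min_area minimum lesion area in mm^2; smaller lesions are ignored
#'   (default 1).
#' @param mode `"CTA"` or `"NCCT"`.
#' @return A list of class `cals_result`: `lesions` (retained), `n_excluded`,
#'   `raw_sum`, `adjustment` (= slice_thickness/3), `total` (adjusted CALS)
#'   and `mode`.
#' @examples
#' les <- data.frame(lesion_id = 1:2, slice = 1L, pixels = c(64, 32),
#'                   area_mm2 = c(4, 2), peak_hu = c(350, 150),
#'                   weight = c(3L, 1L), score = c(12, 2))
#' total_cals(les)$total   # (4*3 + 2*1) * 0.625/3 = 2.9167
#' @export
total_cals <- function(lesions, slice_thickness = 0.625, min_area = 1, mode = c("CTA", "NCCT")) {
  mode <- match.arg(mode)
  if (!is.numeric(slice_thickness) || slice_thickness <= 0)
    stop("slice thickness must be positive (mm)")
  keep <- lesions$area_mm2 >= min_area
  retained <- lesions[keep, , drop = FALSE]
  raw <- sum(retained$score)
  adj <- slice_thickness / 3
  structure(list(lesions = retained, n_excluded = sum(!keep),
                 raw_sum = raw, adjustment = adj, total = raw * adj,
                 mode = mode),
            class = "cals_result")
}

#' @export
print.cals_result <- function(x, ...) {
  cat(sprintf("<cals_result> mode %s: %d lesions (%d excluded < min area), raw %.4g, adjusted CALS %.4g\n",
              x$mode, nrow(x$lesions), x$n_excluded, x$raw_sum, x$total))
  invisible(x)
}

#' One-call CALS from a volume and ROI
#'
#' Convenience wrapper: [segment_calcium()] then [total_cals()].
#'
#' @inheritParams segment_calcium
#' @inheritParams total_cals
#' @return A `cals_result`.
#' @export
compute_cals <- function(v, roi, slice_thickness = v$spacing[3], min_area = 1,
                         mode = c("CTA", "NCCT"), threshold = 130) {
  total_cals(segment_calcium(v, roi, threshold = threshold),
             slice_thickness = slice_thickness, min_area = min_area,
             mode = mode)
}
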