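#' The five-band Hounsfield-unit plaque component scheme
#'
#' Carotid plaque tissue is classified by CT attenuation into five bands:
#' lipid (20-39 HU), fibrolipid (40-59 HU), fibrotic (60-79 HU),
#' fibrocalcified (80-250 HU) and calcification (>250 HU). For real-valued HU
#' the printed integer ranges are mapped to half-open intervals
#' `[20,40) [40,60) [60,80)`, then `[80,250]` and `(250,Inf)`, which preserves
#' the integer semantics while covering the continuum. HU below 20
#' (water/fat) is "unclassified" and excluded from component fractions.
#'
#' @return A data frame with columns `band`, `lower`, `upper` (one row per
#'   band, in order of increasing HU).
#' @examples
#' component_scheme()
#' @export
component_scheme <- function() {
  data.frame(
    band  = c("lipid", "fibrolipid", "fibrotic", "fibrocalcified", "calcification"),
    lower = c(20, 40, 60, 80, 250),
    upper = c(40, 60, 80, 250, Inf),
    stringsAsFactors = FALSE
  )
}

# vulnerability ordering used for dominance tie-breaks (most vulnerable first)
.band_order <- c("lipid", "fibrolipid", "fibrotic", "fibrocalcified", "calcification")

# pointwise band code: 0 = unclassified (HU < 20), 1..5 per .band_order
band_code <- function(hu) {
  code <- integer(length(hu))
  code[hu >= 20 & hu < 40] <- 1L
  code[hu >= 40 & hu < 60] <- 2L
  code[hu >= 60 & hu < 80] <- 3L
  code[hu >= 80 & hu <= 250] <- 4L
  code[hu > 250] <- 5L
  code
}

#' Classify plaque voxels into HU component bands
#'
#' Labels every voxel inside the plaque region of interest with its component
#' band; voxels outside the ROI are `NA`. Classification is a pure pointwise
#' function of HU.
#'
#' @param v a [ct_volume()].
#' @param roi logical array of the same shape marking the plaque ROI.
#' @param scheme the band scheme; only the default [component_scheme()] is
#'   supported and the argument exists for provenance in outputs.
#' @return An integer array (same shape) of class `plaque_labels`: `NA`
#'   outside the ROI, `0` for unclassified (HU < 20), `1..5` for the bands in
#'   the order of `component_scheme()`. The spacing is carried in attribute
#'   `spacing`.
#' @examples
#' v <- ct_volume(array(30, dim = c(4, 4, 2)), c(0.25, 0.25, 0.625))
#' roi <- array(TRUE, dim = dim(v$data))
#' table(classify_voxels(v, roi))          # all lipid (code 1)
#' @export
classify_voxels <- function(v, roi, scheme = component_scheme()) {
  stopifnot_ct_volume(v)
  roi <- check_roi(v, roi)
  if (!any(roi)) stop("empty plaque region")
  lab <- array(NA_integer_, dim = dim(v$data))
  lab[roi] <- band_code(v$data[roi])
  structure(lab, spacing = v$spacing, bands = .band_order,
            class = c("plaque_labels", class(lab)))
}

#' Quantify plaque component volumes and fractions
#'
#' Aggregates a label map into per-band voxel counts, volumes (mm^3) and
#' fractions of the classified plaque volume. Unclassified voxels (HU < 20)
#' are reported but excluded from the fraction denominator.
#'
#' @param labels a label map from [classify_voxels()], or a plain integer
#'   array with codes `NA`/0/1..5 (then `spacing` must be given).
#' @param spacing voxel spacing in mm, taken from the label map's attribute
#'   when absent.
#' @return A `component_profile`: data frame with one row per band
#'   (`band`, `voxels`, `volume_mm3`, `fraction`) plus attributes
#'   `unclassified_mm3`, `classified_mm3` and `degenerate` (TRUE when no voxel
#'   fell in any band, in which case fractions are `NA`).
#' @export
quantify_components <- function(labels, spacing = attr(labels, "spacing")) {
  if (is.null(spacing)) stop("voxel spacing required to compute volumes")
  vv <- prod(spacing)
  counts <- vapply(seq_along(.band_order),
                   function(k) sum(labels == k, na.rm = TRUE), integer(1))
  n_uncl <- sum(labels == 0L, na.rm = TRUE)
  total <- sum(counts)
  frac <- if (total > 0) counts / total else rep(NA_real_, 5L)
  out <- data.frame(band = .band_order, voxels = counts,
                    volume_mm3 = counts * vv, fraction = frac,
                    stringsAsFactors = FALSE)
  structure(out, unclassified_mm3 = n_uncl * vv, classified_mm3 = total * vv,
            degenerate = total == 0L,
            class = c("component_profile", class(out)))
}

#' Call a plaque vulnerable or stable from its component profile
#'
#' Applies the decision rules: (1) an ulcerated vessel is vulnerable
#' regardless of composition; otherwise the dominant component (largest
#' fraction of classified plaque volume) decides: (2) lipid or fibrolipid
#' dominant is vulnerable; (3) fibrotic dominant is stable unless any lipid
#' or fibrolipid is present, which flips the call to vulnerable; (4)
#' fibrocalcified or calcification dominant is stable. Note the lipid-presence
#' override applies only to the fibrotic band: a fibrocalcified- or
#' calcification-dominated plaque with some lipid content is still called
#' stable. Dominance ties are resolved toward the more vulnerable band
#' (lipid > fibrolipid > fibrotic > fibrocalcified > calcification) and
#' flagged.
#'
#' @param profile a `component_profile` from [quantify_components()], or any
#'   data frame with columns `band` and `fraction` over the five bands.
#' @param ulcerated logical flag: is the carotid vessel ulcerated?
#' @return A list of class `plaque_call` with `verdict` ("vulnerable" or
#'   "stable"), `dominant` band name (NA under pure ulceration override with a
#'   degenerate profile), `reason` (one of `dominant_lipidic`,
#'   `fibrotic_with_lipid_override`, `ulceration_override`, `dominant_stable`)
#'   and `tie` flag.
#' @examples
#' pr <- data.frame(band = c("lipid","fibrolipid","fibrotic","fibrocalcified",
#'                           "calcification"),
#'                  fraction = c(0.6, 0, 0, 0.4, 0))
#' call_vulnerability(pr, ulcerated = FALSE)$verdict   # "vulnerable"
#' @export
call_vulnerability <- function(profile, ulcerated = FALSE) {
  frac <- profile$fraction[match(.band_order, profile$band)]
  degenerate <- all(is.na(frac)) || isTRUE(attr(profile, "degenerate"))
  if (degenerate && !isTRUE(ulcerated))
    stop("no classified plaque voxels and no ulceration flag: cannot call vulnerability")

  dominant <- NA_character_
  tie <- FALSE
  if (!degenerate) {
    mx <- max(frac, na.rm = TRUE)
    at_max <- which(abs(frac - mx) < .Machine$double.eps^0.5)
    tie <- length(at_max) > 1L
    dominant <- .band_order[min(at_max)]  # ties break toward vulnerability
  }

  if (isTRUE(ulcerated)) {
    verdict <- "vulnerable"; reason <- "ulceration_override"
  } else if (dominant %in% c("lipid", "fibrolipid")) {
    verdict <- "vulnerable"; reason <- "dominant_lipidic"
  } else if (dominant == "fibrotic" && (frac[1] > 0 || frac[2] > 0)) {
    verdict <- "vulnerable"; reason <- "fibrotic_with_lipid_override"
  } else {
    verdict <- "stable"; reason <- "dominant_stable"
  }
  structure(list(verdict = verdict, dominant = dominant,
                 reason = reason, tie = tie),
            class = "plaque_call")
}

#' @export
print.plaque_call <- function(x, ...) {
  cat(sprintf("<plaque_call> %s (dominant: %s, reason: %s%s)\n",
              x$verdict, x$dominant, x$reason, if (x$tie) ", tie" else ""))
  invisible(x)
}
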