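#' Ordinal calcification grade from a plaque-area fraction
#'
#' Histological micro- and macrocalcification burden is graded 0-3 by the
#' fraction of the plaque area covered: 0 for none, 1 (mild) up to one third,
#' 2 (moderate) up to two thirds, 3 (severe) above. The printed integer-percent
#' bands (1-33 / 34-66 / 67-100%) are mapped to the continuum at thirds with
#' left-open intervals, so 0.33 is grade 1 and 0.34 is grade 2.
#'
#' @param area_fraction numeric vector of fractions in `[0, 1]`.
#' @return integer grades in `{0, 1, 2, 3}`.
#' @examples
#' grade_fraction(c(0, 0.2, 0.5, 0.8))   # 0 1 2 3
#' @export
grade_fraction <- function(area_fraction) {
  if (any(!is.finite(area_fraction)) ||
      any(area_fraction < 0) || any(area_fraction > 1))
    stop("area fraction must lie in [0, 1]")
  g <- integer(length(area_fraction))
  g[area_fraction > 0] <- 1L
  g[area_fraction > 1 / 3] <- 2L
  g[area_fraction > 2 / 3] <- 3L
  g
}

#' Aggregate per-slice histology into a specimen record
#'
#' A specimen is scored intraplaque haemorrhage (IPH) positive when
#' erythrocytes are present in any slice; micro- and macrocalcification
#' grades are the maxima of the per-slice grades. The aggregation is
#' permutation-invariant and idempotent under slice duplication.
#'
#' @param slices data frame with one row per histology slice and columns
#'   `erythrocytes` (logical or 0/1), `micro_fraction`, `macro_fraction`
#'   (plaque-area fractions in `[0, 1]`). An optional `specimen_id` column
#'   (constant) is carried through.
#' @return A one-row data frame: `specimen_id` (if given), `iph` (0/1),
#'   `micro_grade`, `macro_grade`.
#' @examples
#' sl <- data.frame(erythrocytes = c(0, 1, 0),
#'                  micro_fraction = c(0.1, 0.7, 0.4),
#'                  macro_fraction = c(0, 0, 0.2))
#' aggregate_specimen(sl)   # iph 1, micro grade 3, macro grade 1
#' @export
aggregate_specimen <- function(slices) {
  if (!is.data.frame(slices) || nrow(slices) < 1L)
    stop("at least one histology slice is required")
  out <- data.frame(
    iph = as.integer(any(as.logical(slices$erythrocytes))),
    micro_grade = max(grade_fraction(slices$micro_fraction)),
    macro_grade = max(grade_fraction(slices$macro_fraction))
  )
  if (!is.null(slices$specimen_id)) {
    id <- unique(slices$specimen_id)
    if (length(id) != 1L) stop("slices belong to more than one specimen")
    out <- cbind(specimen_id = id, out)
  }
  out
}

#' Read / write histology tables
#'
#' Slice tables have columns
#' `specimen_id,slice_id,erythrocytes,micro_fraction,macro_fraction`; specimen
#' tables `specimen_id,iph,micro_grade,macro_grade`. `read_slice_histology`
#' validates the columns; `aggregate_cohort_histology` aggregates a slice
#' table into one specimen row per `specimen_id`.
#'
#' @param path CSV file path.
#' @param x a data frame to write.
#' @return data frames as described.
#' @export
read_slice_histology <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen_id", "slice_id", "erythrocytes",
            "micro_fraction", "macro_fraction")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("slice histology table lacks columns: ",
                         paste(miss, collapse = ", "))
  x
}

#' @rdname read_slice_histology
#' @param slices a slice table as from [read_slice_histology()].
#' @export
aggregate_cohort_histology <- function(slices) {
  parts <- split(slices, slices$specimen_id)
  out <- do.call(rbind, lapply(parts, aggregate_specimen))
  rownames(out) <- NULL
  out[order(out$specimen_id), , drop = FALSE]
}

#' @rdname read_slice_histology
#' @export
write_specimen_histology <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}
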