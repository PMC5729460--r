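#' Specify a synthetic validation cohort
#'
#' Describes a cohort of carotid endarterectomy patients with a known
#' intraplaque-haemorrhage (IPH) prevalence, a software call of configurable
#' sensitivity and specificity against the IPH gold standard, and ordinal
#' 0-3 micro-/macrocalcification grade distributions per IPH stratum.
#'
#' Default grade distributions give the non-IPH stratum the heavier
#' microcalcification burden (the direction observed histologically) and
#' near-equal macrocalcification burdens.
#'
#' @param n number of patients (> 0).
#' @param prevalence IPH prevalence in `[0, 1]`.
#' @param sensitivity,specificity operating characteristics of the simulated
#'   software call, in `[0, 1]`.
#' @param micro_probs,macro_probs 2 x 4 matrices of grade probabilities
#'   (rows: IPH-negative, IPH-positive strata; columns: grades 0-3), each row
#'   summing to 1.
#' @param exact_margins if TRUE, exactly `round(n * prevalence)` patients are
#'   IPH-positive (fixed margins, as in a retrospective case series) instead
#'   of Bernoulli draws.
#' @param seed integer seed.
#' @return A validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n, prevalence, sensitivity, specificity,
                        micro_probs = rbind(neg = c(0.10, 0.25, 0.35, 0.30),
                                            pos = c(0.35, 0.35, 0.20, 0.10)),
                        macro_probs = rbind(neg = c(0.15, 0.30, 0.30, 0.25),
                                            pos = c(0.25, 0.30, 0.25, 0.20)),
                        exact_margins = FALSE, seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L || n <= 0 || n != round(n))
    stop("number of patients must be a positive integer")
  for (p in list(prevalence = prevalence, sensitivity = sensitivity,
                 specificity = specificity))
    if (p < 0 || p > 1) stop("prevalence, sensitivity and specificity must lie in [0, 1]")
  for (m in list(micro_probs, macro_probs)) {
    if (!is.matrix(m) || any(dim(m) != c(2L, 4L)) || any(m < 0) ||
        any(abs(rowSums(m) - 1) > 1e-8))
      stop("grade probabilities must be a 2 x 4 matrix with rows summing to 1")
  }
  structure(list(n = as.integer(n), prevalence = prevalence,
                 sensitivity = sensitivity, specificity = specificity,
                 micro_probs = micro_probs, macro_probs = macro_probs,
                 exact_margins = isTRUE(exact_margins), seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a cohort of specimen records
#'
#' Per patient: IPH drawn Bernoulli at the spec prevalence (or fixed margins),
#' the software call drawn with the stated sensitivity (IPH-positive) or
#' specificity (IPH-negative), grades drawn from the stratum distributions,
#' and paired CTA/NCCT calcification scores from a grade-linked burden model
#' in which CTA underestimates NCCT increasingly with burden (the blooming
#' phenomenology at table level). Deterministic under a fixed seed.
#'
#' @param spec a [cohort_spec()].
#' @return data frame with columns `patient_id`, `iph`, `software_call`,
#'   `micro_grade`, `macro_grade`, `cals_cta`, `cals_ncct`.
#' @examples
#' head(generate_cohort(cohort_spec(20, 0.7, 0.9, 0.3, seed = 7)))
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n
    if (spec$exact_margins) {
      npos <- round(n * spec$prevalence)
      iph <- sample(rep(c(1L, 0L), c(npos, n - npos)))
    } else {
      iph <- stats::rbinom(n, 1L, spec$prevalence)
    }
    call <- integer(n)
    pos <- iph == 1L
    call[pos] <- stats::rbinom(sum(pos), 1L, spec$sensitivity)
    call[!pos] <- stats::rbinom(sum(!pos), 1L, 1 - spec$specificity)
    draw_grade <- function(probs) {
      g <- integer(n)
      g[!pos] <- sample(0:3, sum(!pos), replace = TRUE, prob = probs[1, ])
      g[pos] <- sample(0:3, sum(pos), replace = TRUE, prob = probs[2, ])
      g
    }
    micro <- draw_grade(spec$micro_probs)
    macro <- draw_grade(spec$macro_probs)
    # grade-linked burden: NCCT score ~ gamma scaled by macro grade; CTA
    # underestimates proportionally more as burden grows
    burden <- stats::rgamma(n, shape = 2, scale = 2 + 10 * macro)
    cta <- pmax(0, burden * (1 - 0.35 * burden / (burden + 40)) +
                  stats::rnorm(n, 0, 0.5))
    data.frame(patient_id = seq_len(n), iph = iph, software_call = call,
               micro_grade = micro, macro_grade = macro,
               cals_cta = round(cta, 2), cals_ncct = round(burden, 2))
  })
}

#' @rdname generate_cohort
#' @param cohort a cohort data frame.
#' @param path CSV path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname generate_cohort
#' @export
read_cohort <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "iph", "software_call", "micro_grade",
            "macro_grade", "cals_cta", "cals_ncct")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("cohort table lacks columns: ",
                         paste(miss, collapse = ", "))
  x
}
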