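#' Tally a 2x2 confusion table
#'
#' Counts true/false positives and negatives of a binary software call against
#' the histological gold standard, with the vulnerable (IPH-containing) state
#' as the positive condition.
#'
#' @param predicted binary vector of calls (logical, 0/1, or the character
#'   labels `"vulnerable"`/`"stable"`).
#' @param truth binary vector of gold-standard labels, same encoding and
#'   length.
#' @return A list of class `confusion_table` with integer fields `tp`, `fn`,
#'   `fp`, `tn`.
#' @examples
#' confusion(c(1, 1, 0, 1), c(1, 0, 0, 1))
#' @export
confusion <- function(predicted, truth) {
  p <- as_binary(predicted); t <- as_binary(truth)
  if (length(p) != length(t)) stop("predicted and truth have different lengths")
  structure(list(tp = sum(p & t), fn = sum(!p & t),
                 fp = sum(p & !t), tn = sum(!p & !t)),
            class = "confusion_table")
}

as_binary <- function(x) {
  if (is.character(x) || is.factor(x)) {
    x <- as.character(x)
    if (!all(x %in% c("vulnerable", "stable")))
      stop("character labels must be 'vulnerable' or 'stable'")
    return(x == "vulnerable")
  }
  if (anyNA(x) || !all(x %in% c(0, 1))) stop("labels must be binary (0/1)")
  as.logical(x)
}

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf("<confusion_table> TP=%d FN=%d FP=%d TN=%d\n",
              x$tp, x$fn, x$fp, x$tn))
  invisible(x)
}

# Wilson score interval for a binomial proportion
wilson_ci <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = max(0, ctr - hw), upper = min(1, ctr + hw))
}

# Clopper-Pearson exact interval (beta quantile form)
clopper_pearson_ci <- function(x, n, conf = 0.95) {
  a <- (1 - conf) / 2
  lo <- if (x == 0) 0 else stats::qbeta(a, x, n - x + 1)
  hi <- if (x == n) 1 else stats::qbeta(1 - a, x + 1, n - x)
  c(lower = lo, upper = hi)
}

#' Diagnostic accuracy metrics with confidence intervals
#'
#' Sensitivity, specificity, positive and negative predictive value from a
#' 2x2 confusion table, each with a two-sided 95% interval. A metric whose
#' denominator is zero is returned as `NA` with `defined = FALSE`, never as a
#' silent 0.
#'
#' @param table a [confusion()] table (or a list with `tp`, `fn`, `fp`, `tn`).
#' @param ci_method `"clopper_pearson"` (default) or `"wilson"`; recorded in
#'   the output.
#' @param conf confidence level (default 0.95).
#' @return A data frame of class `diagnostic_metrics` with one row per metric:
#'   `metric`, `numerator`, `denominator`, `estimate`, `lower`, `upper`,
#'   `defined`, `ci_method`.
#' @examples
#' dm <- diagnostic_metrics(list(tp = 33, fn = 4, fp = 11, tn = 5))
#' as_pct(dm$estimate[dm$metric == "ppv"])   # 75.0
#' @export
diagnostic_metrics <- function(table, ci_method = c("clopper_pearson", "wilson"),
                               conf = 0.95) {
  ci_method <- match.arg(ci_method)
  ci_fun <- switch(ci_method, wilson = wilson_ci,
                   clopper_pearson = clopper_pearson_ci)
  with(table, {
    num <- c(sensitivity = tp, specificity = tn, ppv = tp, npv = tn)
    den <- c(sensitivity = tp + fn, specificity = tn + fp,
             ppv = tp + fp, npv = tn + fn)
    rows <- lapply(names(num), function(m) {
      if (den[[m]] == 0)
        return(data.frame(metric = m, numerator = num[[m]], denominator = 0L,
                          estimate = NA_real_, lower = NA_real_,
                          upper = NA_real_, defined = FALSE,
                          ci_method = ci_method))
      ci <- ci_fun(num[[m]], den[[m]], conf)
      data.frame(metric = m, numerator = num[[m]], denominator = den[[m]],
                 estimate = num[[m]] / den[[m]],
                 lower = ci[["lower"]], upper = ci[["upper"]],
                 defined = TRUE, ci_method = ci_method)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    class(out) <- c("diagnostic_metrics", class(out))
    out
  })
}

#' Mann-Whitney U test with mean ranks
#'
#' Rank-sum comparison of two independent samples using midranks over the
#' pooled data, reporting the U statistic and the per-group mean ranks (as
#' SPSS prints them) and a two-sided p-value from the tie-corrected normal
#' approximation. When every pooled value is identical the test is degenerate
#' and p is 1.
#'
#' @param a,b numeric (or ordinal) samples, both non-empty.
#' @return A list of class `rank_test` with `u_a`, `u_b`, `mean_rank_a`,
#'   `mean_rank_b`, `n_a`, `n_b`, `z`, `p`, `degenerate`.
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))   # U_a = 0, mean ranks 1.5 / 3.5
#' @export
mann_whitney <- function(a, b) {
  if (length(a) < 1L || length(b) < 1L) stop("both samples must be non-empty")
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))  # midranks
  ra <- sum(r[seq_len(na)]); rb <- sum(r) - ra
  ua <- ra - na * (na + 1) / 2
  ub <- na * nb - ua
  ties <- table(c(a, b))
  degenerate <- length(ties) == 1L
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  v <- na * nb / 12 * ((n + 1) - tie_term)
  if (degenerate || v <= 0) {
    z <- 0; p <- 1
  } else {
    z <- (ua - na * nb / 2) / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(u_a = ua, u_b = ub,
                 mean_rank_a = ra / na, mean_rank_b = rb / nb,
                 n_a = na, n_b = nb, z = z, p = p,
                 degenerate = degenerate),
            class = "rank_test")
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks, with a two-sided p-value from the t
#' approximation on `n - 2` degrees of freedom. Constant input yields an
#' undefined (`NA`) correlation with `defined = FALSE`.
#'
#' @param x,y numeric vectors of equal length, at least 3.
#' @return A list with `rho`, `p`, `n`, `defined`.
#' @export
spearman_rank <- function(x, y) {
  if (length(x) != length(y)) stop("x and y have different lengths")
  n <- length(x)
  if (n < 3L) stop("need at least 3 pairs")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    return(list(rho = NA_real_, p = NA_real_, n = n, defined = FALSE))
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p = p, n = n, defined = TRUE)
}

#' Bland-Altman agreement between two measurement methods
#'
#' Differences `d = m1 - m2` are summarised by their mean (bias), SD and the
#' 95% limits of agreement `mean +/- 1.96 SD`. The drift statistic — the
#' Spearman correlation between the difference and the pair mean — quantifies
#' whether disagreement grows with the measured quantity (as contrast blooming
#' makes CTA underestimate high calcification burdens relative to NCCT).
#'
#' @param m1,m2 paired numeric vectors, equal length >= 2.
#' @return A list of class `bland_altman` with `mean_diff`, `sd_diff`,
#'   `loa_lower`, `loa_upper`, `drift_rho`, `drift_p`, `n`, and the vectors
#'   `differences` and `means`.
#' @export
bland_altman <- function(m1, m2) {
  if (length(m1) != length(m2)) stop("paired samples have different lengths")
  if (length(m1) < 2L) stop("need at least 2 pairs")
  d <- m1 - m2
  m <- (m1 + m2) / 2
  sdd <- stats::sd(d)
  drift <- if (length(d) >= 3L) spearman_rank(d, m)
           else list(rho = NA_real_, p = NA_real_, defined = FALSE)
  structure(list(mean_diff = mean(d), sd_diff = sdd,
                 loa_lower = mean(d) - 1.96 * sdd,
                 loa_upper = mean(d) + 1.96 * sdd,
                 drift_rho = drift$rho, drift_p = drift$p,
                 n = length(d), differences = d, means = m),
            class = "bland_altman")
}

#' Cohen's kappa with Fleiss interpretation band
#'
#' Chance-corrected agreement between two raters over the same items:
#' `kappa = (po - pe) / (1 - pe)` with expected agreement from the product of
#' the marginal rating distributions. The Fleiss interpretation attaches
#' "excellent" above 0.75, "fair-to-good" from 0.40 to 0.75 and "poor" below
#' 0.40. When both raters give the same single rating throughout, chance
#' agreement is 1 and kappa is undefined.
#'
#' @param r1,r2 categorical rating vectors of equal length.
#' @return A list of class `kappa_result` with `po`, `pe`, `kappa`, `band`,
#'   `n`, `defined`.
#' @examples
#' cohen_kappa(c(0, 1, 1, 0), c(0, 1, 1, 0))$kappa   # 1
#' @export
cohen_kappa <- function(r1, r2) {
  if (length(r1) != length(r2)) stop("rating vectors have different lengths")
  n <- length(r1)
  if (n < 1L) stop("no ratings")
  lev <- sort(unique(c(r1, r2)))
  f1 <- factor(r1, levels = lev); f2 <- factor(r2, levels = lev)
  po <- mean(f1 == f2)
  pe <- sum((table(f1) / n) * (table(f2) / n))
  if (pe >= 1 - .Machine$double.eps^0.5)
    return(structure(list(po = po, pe = pe, kappa = NA_real_,
                          band = NA_character_, n = n, defined = FALSE),
                     class = "kappa_result"))
  k <- (po - pe) / (1 - pe)
  structure(list(po = po, pe = pe, kappa = k, band = fleiss_band(k),
                 n = n, defined = TRUE),
            class = "kappa_result")
}

#' @rdname cohen_kappa
#' @param kappa a kappa value.
#' @export
fleiss_band <- function(kappa) {
  ifelse(kappa > 0.75, "excellent",
         ifelse(kappa >= 0.40, "fair-to-good", "poor"))
}
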