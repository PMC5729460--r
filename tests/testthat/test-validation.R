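test_that("confusion tallies binary calls with vulnerable as the positive condition", {
  ct <- confusion(rep(1, 10), rep(1, 10))
  expect_equal(unclass(ct)[c("tp", "fn", "fp", "tn")],
               list(tp = 10L, fn = 0L, fp = 0L, tn = 0L), ignore_attr = TRUE)

  ct <- confusion(rep(1, 5), c(1, 1, 1, 0, 0))
  expect_equal(ct$tp, 3L); expect_equal(ct$fp, 2L)
  expect_equal(ct$fn, 0L); expect_equal(ct$tn, 0L)

  ct <- confusion(c("vulnerable", "stable"), c("vulnerable", "vulnerable"))
  expect_equal(ct$tp, 1L); expect_equal(ct$fn, 1L)

  expect_error(confusion(1, c(1, 0)), "lengths")
  expect_error(confusion(2, 1), "binary")

  # a cohort generated with sensitivity 1 and specificity 0 has no FN and no TN
  co <- generate_cohort(cohort_spec(300, 0.5, 1, 0, seed = 4))
  ct <- confusion(co$software_call, co$iph)
  expect_equal(ct$fn, 0L); expect_equal(ct$tn, 0L)
})

test_that("diagnostic metrics compute the four proportions with CIs and flag zero denominators", {
  dm <- diagnostic_metrics(list(tp = 33, fn = 4, fp = 11, tn = 5))
  est <- setNames(dm$estimate, dm$metric)
  expect_equal(unname(est["ppv"]), 0.75)
  expect_equal(unname(est["npv"]), 5 / 9)
  expect_equal(unname(est["sensitivity"]), 33 / 37)
  expect_equal(unname(est["specificity"]), 5 / 16)
  expect_true(all(dm$lower <= dm$estimate & dm$estimate <= dm$upper))

  perfect <- diagnostic_metrics(list(tp = 10, fn = 0, fp = 0, tn = 10))
  expect_equal(perfect$estimate, rep(1, 4))

  degen <- diagnostic_metrics(list(tp = 0, fn = 0, fp = 3, tn = 7))
  expect_false(degen$defined[degen$metric == "sensitivity"])
  expect_true(is.na(degen$estimate[degen$metric == "sensitivity"]))
})

test_that("Wilson and Clopper-Pearson intervals behave at the boundaries and contain p-hat", {
  dm0 <- diagnostic_metrics(list(tp = 0, fn = 12, fp = 0, tn = 8),
                            ci_method = "wilson")
  sens <- dm0[dm0$metric == "sensitivity", ]
  expect_equal(sens$lower, 0)
  expect_gt(sens$upper, 0)

  set.seed(9)
  for (i in 1:30) {
    n <- sample(5:40, 1); x <- sample(0:n, 1)
    w <- plaqueCT:::wilson_ci(x, n)
    cp <- plaqueCT:::clopper_pearson_ci(x, n)
    p <- x / n
    expect_true(w[1] <= p + 1e-12 && p <= w[2] + 1e-12)
    expect_true(cp[1] <= p + 1e-12 && p <= cp[2] + 1e-12)
    # cross-check the exact interval against binom.test
    bt <- stats::binom.test(x, n)$conf.int
    expect_equal(unname(cp), as.numeric(bt), tolerance = 1e-8)
  }
})

test_that("Mann-Whitney reports U, mean ranks and a tie-corrected p", {
  r <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(r$u_a, 0)
  expect_equal(r$mean_rank_a, 1.5)
  expect_equal(r$mean_rank_b, 3.5)
  expect_equal(r$u_a + r$u_b, r$n_a * r$n_b)

  same <- mann_whitney(c(2, 5, 7), c(2, 5, 7))
  expect_equal(same$mean_rank_a, same$mean_rank_b)

  tied <- mann_whitney(c(1, 1), c(1, 1))
  expect_equal(tied$mean_rank_a, 2.5)
  expect_equal(tied$mean_rank_b, 2.5)
  expect_true(tied$degenerate)
  expect_equal(tied$p, 1)
})

test_that("Mann-Whitney matches brute force and wilcox.test on random tied samples", {
  set.seed(33)
  for (i in 1:60) {
    a <- sample(0:4, sample(2:8, 1), replace = TRUE)
    b <- sample(0:4, sample(2:8, 1), replace = TRUE)
    r <- mann_whitney(a, b)
    expect_equal(r$u_a, brute_u(a, b))
    pooled <- c(a, b)
    mr <- brute_midranks(pooled)
    expect_equal(r$mean_rank_a, mean(mr[seq_along(a)]))
    expect_equal(r$mean_rank_b, mean(mr[-seq_along(a)]))
    # weighted mean ranks average to (N+1)/2
    N <- length(pooled)
    expect_equal((r$mean_rank_a * r$n_a + r$mean_rank_b * r$n_b) / N,
                 (N + 1) / 2)
    if (!r$degenerate) {
      w <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                               correct = FALSE))
      expect_equal(r$p, w$p.value, tolerance = 1e-10)
    }
  }
})

test_that("Spearman correlation handles identity, reversal, ties and constants", {
  x <- c(3, 1, 4, 1.5, 9)
  expect_equal(spearman_rank(x, x)$rho, 1)
  expect_equal(spearman_rank(x, -x)$rho, -1)

  y <- c(2, 2, 5, 1, 7)
  got <- spearman_rank(x, y)
  expect_equal(got$rho, brute_spearman(x, y))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  expect_equal(got$rho, unname(ct$estimate), tolerance = 1e-10)

  const <- spearman_rank(rep(1, 5), y)
  expect_false(const$defined)
  expect_true(is.na(const$rho))
  expect_error(spearman_rank(1:2, 1:2), "at least 3")
})

test_that("Bland-Altman summarises bias, limits and drift", {
  m <- c(1, 4, 2, 8, 5)
  same <- bland_altman(m, m)
  expect_equal(same$mean_diff, 0)
  expect_equal(same$sd_diff, 0)
  expect_equal(same$loa_lower, 0)
  expect_equal(same$loa_upper, 0)

  off <- bland_altman(m, m + 3)
  expect_equal(off$mean_diff, -3)
  expect_equal(off$sd_diff, 0)

  expect_error(bland_altman(1, 1), "at least 2")
  expect_error(bland_altman(1:3, 1:4), "lengths")
})

test_that("Cohen's kappa matches brute force, attaches Fleiss bands and flags degeneracy", {
  r <- cohen_kappa(c(0, 1, 1, 0, 2), c(0, 1, 1, 0, 2))
  expect_equal(r$kappa, 1)
  expect_equal(r$band, "excellent")

  set.seed(55)
  for (i in 1:40) {
    n <- sample(4:8, 1)
    r1 <- sample(0:2, n, replace = TRUE)
    r2 <- sample(0:2, n, replace = TRUE)
    got <- cohen_kappa(r1, r2)
    if (got$defined)
      expect_equal(got$kappa, brute_kappa(r1, r2))
  }

  expect_equal(fleiss_band(c(0.41, 0.39, 0.76, 0.75, 0.40)),
               c("fair-to-good", "poor", "excellent", "fair-to-good",
                 "fair-to-good"))

  degen <- cohen_kappa(rep(1, 5), rep(1, 5))
  expect_false(degen$defined)
  expect_true(is.na(degen$kappa))
})

test_that("kappa is near zero for independent raters and invariant to relabeling", {
  set.seed(70)
  n <- 20000
  r1 <- rbinom(n, 1, 0.6)
  r2 <- rbinom(n, 1, 0.3)
  k <- cohen_kappa(r1, r2)$kappa
  expect_lt(abs(k), 3 / sqrt(n) * 2)   # ~3 SE of kappa at independence

  set.seed(71)
  a <- sample(0:2, 50, replace = TRUE)
  b <- sample(0:2, 50, replace = TRUE)
  relab <- c(10, 20, 30)
  expect_equal(cohen_kappa(a, b)$kappa,
               cohen_kappa(relab[a + 1], relab[b + 1])$kappa)
})
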