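# Brute-force oracles, kept deliberately independent of the package internals.

# 8-connected labelling by breadth-first flood fill
flood_fill_8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(i, j)); lab[i, j] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        ii <- p[1] + di; jj <- p[2] + dj
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
            mask[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- nxt
          queue[[length(queue) + 1L]] <- c(ii, jj)
        }
      }
    }
  }
  lab
}

# midrank of each element of x within the pooled vector, by pair counting
brute_midranks <- function(pooled) {
  vapply(pooled, function(v)
    sum(pooled < v) + (sum(pooled == v) + 1) / 2, numeric(1))
}

# Mann-Whitney U of group a (wins + half-ties over all pairs)
brute_u <- function(a, b) {
  sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
}

brute_spearman <- function(x, y) {
  rx <- brute_midranks(x); ry <- brute_midranks(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

brute_kappa <- function(r1, r2) {
  n <- length(r1)
  po <- sum(r1 == r2) / n
  lev <- unique(c(r1, r2))
  pe <- sum(vapply(lev, function(l)
    (sum(r1 == l) / n) * (sum(r2 == l) / n), numeric(1)))
  (po - pe) / (1 - pe)
}

# Agatston-convention weight bands
brute_weight <- function(p) {
  if (p < 200) 1L else if (p < 300) 2L else if (p < 400) 3L else 4L
}

# random multi-lesion phantom with lesions confined to grid quadrants so they
# can never touch; returns the phantom list
random_lesion_phantom <- function(seed, background_sd = 0) {
  set.seed(seed)
  centers <- list(c(11, 11), c(11, 31), c(31, 11), c(31, 31))
  n_les <- sample(0:4, 1)
  lesions <- lapply(seq_len(n_les), function(i) {
    list(center = centers[[i]] + sample(-2:2, 2, replace = TRUE),
         radius_mm = runif(1, 0.35, 1.5),
         peak_hu = runif(1, 150, 650),
         slices = sort(sample(1:4, sample(1:3, 1))))
  })
  sp <- phantom_spec(shape = c(42, 42, 4), background_sd = background_sd,
                     lesions = lesions, seed = seed)
  generate_plaque_volume(sp)
}
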