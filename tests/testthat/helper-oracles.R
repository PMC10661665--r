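# Independent oracles and fixture builders shared across the test files.
# Fixtures are generated in code; no data files are read.

# Dense-grid cumulative-area oracle for the repolarization-offset point:
# samples the *continuous* test function at fs_dense, takes the analytic-limit
# derivative by finite differences on that dense grid, squares it, integrates
# by the trapezoidal rule, and interpolates the crossing of `frac` of the
# total area. Deliberately a different quadrature (trapezoid vs sample-sum)
# and a ~100x denser grid than the implementation under test.
auc_offset_oracle <- function(f, t0, t1, frac, fs_dense = 1e5) {
  tt <- seq(t0, t1, by = 1000 / fs_dense)
  x <- f(tt)
  g2 <- (diff(x) * fs_dense)^2
  tm <- (tt[-1] + tt[-length(tt)]) / 2
  inc <- (g2[-1] + g2[-length(g2)]) / 2 * diff(tm)
  cum <- c(0, cumsum(inc))
  total <- cum[length(cum)]
  target <- frac * total
  k <- which(cum >= target)[1]
  if (k == 1L) return(tm[1])
  tm[k - 1] + (tm[k] - tm[k - 1]) * (target - cum[k - 1]) / (cum[k] - cum[k - 1])
}

# Random smooth T-wave-like window: one dominant Gaussian component plus an
# optional overlapping secondary component (biphasic or notched morphology),
# random widths, amplitudes and polarity. The components overlap — as the
# limbs of a real T-wave do — so the squared-derivative density has no
# signal-free gap in which an area quantile would be ill-conditioned.
random_smooth_window <- function(t0, t1, seed) {
  set.seed(seed)
  mid <- (t0 + t1) / 2
  span <- t1 - t0
  c1 <- runif(1, mid - 0.2 * span, mid + 0.2 * span)
  w1 <- runif(1, 15, 32)
  a1 <- runif(1, 0.5, 1.5) * sample(c(-1, 1), 1)
  biphasic <- runif(1) < 0.6
  c2 <- c1 + runif(1, -1.2, 1.2) * w1
  w2 <- runif(1, 12, 28)
  a2 <- runif(1, 0.3, 1) * a1 * sample(c(-1, 1), 1)
  function(t) {
    y <- a1 * exp(-(t - c1)^2 / (2 * w1^2))
    if (biphasic) y <- y + a2 * exp(-(t - c2)^2 / (2 * w2^2))
    y
  }
}

# Brute-force reference for the ectopy exclusion rule: the excluded set is
# the union over ectopic positions e of {e-1, e, e+1, e+2}, clipped.
exclusion_bruteforce <- function(labels, exclude_paced = TRUE) {
  n <- length(labels)
  excluded <- integer(0)
  for (e in which(labels == "ectopic")) {
    excluded <- union(excluded, intersect(c(e - 1, e, e + 1, e + 2), 1:n))
  }
  keep <- !(seq_len(n) %in% excluded)
  if (exclude_paced) keep[labels == "paced"] <- FALSE
  keep
}

# Small clean EGM-style fixture used by several files.
make_clean_egm <- function(n_beats = 20, seed = 3, ...) {
  synthesize_record(synth_config(n_beats = n_beats, seed = seed,
                                 rr_jitter_sd = 0, repol_jitter_sd = 0,
                                 noise_sd = 0, ...))
}
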