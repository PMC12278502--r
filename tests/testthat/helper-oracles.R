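# Shared fixtures and independent oracles used across the suite.

the_space <- build_default_space()

# Printed hypervolume-contribution columns of the two campaign tables,
# transcribed for fixture-integrity and reproduction checks. `beta` is the
# main printed column; `alpha` the parenthesized column of campaign 2.
printed_hv <- list(
  c1_beta = c(60, 12, 8, 5, 50, 38, 28, 35, 51, 0, 18, 40, 24, 62, 64, 66,
              75, 37, 34, 44, 66, 40, 49, 66, 45, 0, 40, 0, 67, 69, 45, 10,
              75, 0, 45, 63, 76, 0, 59, 23, 42, 50, 22, 11, 42, 41, 43, 66,
              36, 36, 40, 51, 41, 59, 58),
  c2_beta = c(24, 0, 56, 11, 80, 44, 21, 0, 53, 22, 63, 65, 6, 8, 58, 78,
              60, 52, 18, 62),
  c2_alpha = c(50, 0, 43, 64, 21, 8, 32, 0, 27, 26, 23, 32, 71, 4, 16, 17,
               17, 40, 10, 36)
)

# Brute-force O(n^2) weak-dominance scan (maximize both axes); among exact
# duplicates every copy is flagged, so comparisons use the unique pairs.
brute_force_front <- function(yield, selectivity) {
  n <- length(yield)
  vapply(seq_len(n), function(i) {
    !any(yield >= yield[i] & selectivity >= selectivity[i] &
           (yield > yield[i] | selectivity > selectivity[i]))
  }, logical(1))
}

# Monte-Carlo estimate of the dominated area with standard error, by uniform
# sampling of the bounding box [0, xmax] x [0, ymax].
mc_hypervolume <- function(yield, selectivity, n_mc = 1e6, seed = 1,
                           xmax = 100, ymax = 100) {
  withr::with_seed(seed, {
    px <- stats::runif(n_mc, 0, xmax)
    py <- stats::runif(n_mc, 0, ymax)
    dominated <- rep(FALSE, n_mc)
    for (i in seq_along(yield)) {
      dominated <- dominated | (px <= yield[i] & py <= selectivity[i])
    }
    p <- mean(dominated)
    area <- xmax * ymax / 100  # as % of the 100 x 100 square
    list(hv = p * area, se = sqrt(p * (1 - p) / n_mc) * area)
  })
}

# Small deterministic campaign for surrogate/acquisition tests: virtual-lab
# responses on a random design.
small_campaign <- function(n = 12, seed = 42, noise_sd = 0) {
  cond <- sample_random(the_space, n, seed = seed)
  out <- simulate_reaction(lab_scenario(noise_sd = noise_sd), cond,
                           space = the_space, seed = seed + 1)
  out$Batch <- 1L
  out
}
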