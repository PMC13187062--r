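# Shared fixture builders for the test suite. Everything is generated in
# code; no binary fixtures.

# Regular polygon approximating a circle (vertices in pixel units).
circle_poly <- function(cx, cy, r, n = 256) {
  theta <- 2 * pi * (seq_len(n) - 1) / n
  cbind(cx + r * cos(theta), cy + r * sin(theta))
}

# Random star-shaped polygon about a centre: simple by construction.
random_star_polygon <- function(n = 12, r_min = 2, r_max = 10) {
  theta <- sort(stats::runif(n, 0, 2 * pi))
  r <- stats::runif(n, r_min, r_max)
  cbind(r * cos(theta), r * sin(theta))
}

# Monte-Carlo sample of the studentized range statistic for (k, df):
# range of k standard normals over sqrt(chi^2_df / df), an estimator
# independent of the numerator. Used as the simulation oracle for the
# studentized range CDF.
sample_studentized_range <- function(n_rep, k, df, chunk = 100000L) {
  out <- numeric(n_rep)
  done <- 0L
  while (done < n_rep) {
    m <- min(chunk, n_rep - done)
    z <- matrix(stats::rnorm(m * k), nrow = m)
    rng <- matrixStats_rowRange(z)
    s <- sqrt(stats::rchisq(m, df) / df)
    out[(done + 1):(done + m)] <- rng / s
    done <- done + m
  }
  out
}

# fast row range (max.col is C-level; avoids slow apply over 1e6 rows)
matrixStats_rowRange <- function(z) {
  idx <- seq_len(nrow(z))
  z[cbind(idx, max.col(z))] - z[cbind(idx, max.col(-z))]
}

# Lower-bound (as measured) summaries of the three osteon-bearing
# fragments, from the packaged fixture.
fragment_intervals <- function(upper_factor = 0.75) {
  sums <- load_fragment_summaries()
  lapply(sums, apply_shrinkage_bounds,
         model = shrinkage_model(upper_factor = upper_factor))
}
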