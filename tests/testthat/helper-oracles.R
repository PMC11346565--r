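# Independent oracles used across the suite.

# brute-force segmented-regression scan: per candidate breakpoint, fit the
# two-parameter model by QR (.lm.fit) and keep the global SSE minimiser.
# Deliberately independent of the analytic normal-equation path in
# fit_sweat_onset.
seg_oracle <- function(t, y, min_tail = 3) {
  n <- length(t)
  cand <- t[min_tail:(n - min_tail)]
  best <- NULL
  bsse <- Inf
  for (t0 in cand) {
    X <- cbind(1, pmax(t - t0, 0))
    f <- .lm.fit(X, y)
    sse <- sum(f$residuals^2)
    if (sse < bsse - 1e-12) {
      bsse <- sse
      best <- list(t0 = t0, a = f$coefficients[1], b = f$coefficients[2],
                   sse = sse)
    }
  }
  best
}

# brute-force grid posterior for the 2-observation-per-participant toy model
# (no covariate), with the participant intercepts marginalised analytically:
# (y_pre, y_post) ~ N((b0, b0+b1), [[s^2+t^2, t^2], [t^2, s^2+t^2]]).
# Priors match fit_hier_linear's defaults. Returns the posterior mean of b1.
grid_posterior_b1 <- function(yp, yq, n_b = 60, n_v = 36) {
  y <- c(yp, yq)
  sdy <- stats::sd(y)
  my <- mean(y)
  b0g <- seq(my - 4 * sdy, my + 4 * sdy, length.out = n_b)
  b1g <- seq(-6 * sdy, 6 * sdy, length.out = n_b)
  taug <- seq(0.01, 5 * sdy, length.out = n_v)
  sigg <- seq(0.05, 5 * sdy, length.out = n_v)
  lp_b <- outer(stats::dnorm(b0g, my, 10 * sdy, log = TRUE),
                stats::dnorm(b1g, 0, 5 * sdy, log = TRUE), "+")
  acc <- matrix(-Inf, n_b, n_b)
  lse <- function(a, b) pmax(a, b) + log1p(exp(-abs(a - b)))
  for (tau in taug) {
    for (sig in sigg) {
      v <- sig^2 + tau^2
      cv <- tau^2
      det2 <- v^2 - cv^2
      lp_ts <- stats::dnorm(tau, 0, 2.5 * sdy, log = TRUE) +
        stats::dnorm(sig, 0, 2.5 * sdy, log = TRUE)
      ll <- outer(b0g, b1g, function(a, b) {
        s <- 0
        for (i in seq_along(yp)) {
          r1 <- yp[i] - a
          r2 <- yq[i] - a - b
          s <- s - 0.5 * log(det2) -
            0.5 * (v * (r1^2 + r2^2) - 2 * cv * r1 * r2) / det2
        }
        s
      })
      acc <- lse(acc, ll + lp_b + lp_ts)
    }
  }
  w <- exp(acc - max(acc))
  w <- w / sum(w)
  sum(w * matrix(b1g, n_b, n_b, byrow = TRUE))
}

# noiseless LSR template matching the synthetic generator's construction
lsr_template_oracle <- function(t, baseline = 0.1, onset = 10, slope = 0.05,
                                plateau = 2.0) {
  pmin(baseline + slope * pmax(t - onset, 0), plateau)
}
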