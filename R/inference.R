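# Bayesian hierarchical pre/post inference. The workhorse is a Gibbs sampler
# for the Gaussian random-intercept model
#   y_ij = b0 + b1 * [period == post] + b2 * (vo2peak_i - mean) + u_i + e_ij
#   u_i ~ N(0, tau^2),  e_ij ~ N(0, sigma^2)
# with normal priors on the coefficients and half-normal priors on tau and
# sigma. tau's half-normal prior is implemented exactly through parameter
# expansion (u_i = xi * eta_i with eta_i ~ N(0,1), xi ~ N(0, scale^2), so
# tau = |xi| ~ half-N(scale) and every conditional stays normal); sigma's
# half-normal prior has no conjugate update and is drawn by slice sampling
# within the sweep.

# univariate slice sampler (Neal 2003: stepping out + shrinkage)
slice1 <- function(x0, logf, w = 1, max_steps = 50) {
  f0 <- logf(x0)
  if (!is.finite(f0)) stop("slice sampler started at zero density", call. = FALSE)
  z <- f0 - stats::rexp(1)
  u <- stats::runif(1)
  lo <- x0 - w * u
  hi <- lo + w
  for (i in seq_len(max_steps)) {
    if (logf(lo) < z) break
    lo <- lo - w
  }
  for (i in seq_len(max_steps)) {
    if (logf(hi) < z) break
    hi <- hi + w
  }
  repeat {
    x1 <- stats::runif(1, lo, hi)
    if (logf(x1) >= z) return(x1)
    if (x1 < x0) lo <- x1 else hi <- x1
  }
}

# split-Rhat (Gelman et al.): draws is iterations x chains
split_rhat <- function(draws) {
  n <- nrow(draws)
  half <- floor(n / 2)
  sub <- cbind(draws[seq_len(half), , drop = FALSE],
               draws[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sub); nn <- nrow(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, stats::var)
  b <- nn * stats::var(means)
  w <- mean(vars)
  if (w == 0) return(1)
  sqrt(((nn - 1) / nn * w + b / nn) / w)
}

# effective sample size from the pooled autocorrelation (initial positive
# sequence truncation)
ess_basic <- function(draws) {
  n <- nrow(draws); m <- ncol(draws)
  rho <- rowMeans(sapply(seq_len(m), function(j) {
    a <- stats::acf(draws[, j], lag.max = min(n - 2, 200), plot = FALSE)$acf[-1]
    a
  }))
  s <- 0
  for (t in seq_along(rho)) {
    if (rho[t] < 0) break
    s <- s + rho[t]
  }
  max(1, n * m / (1 + 2 * s))
}

#' Fit the hierarchical pre/post model by Gibbs sampling
#'
#' Fits the Gaussian random-intercept model described above to a tidy
#' outcome table. Default priors are weakly informative and scale with the
#' data: intercept `N(mean(y), (10 SD(y))^2)`, period effect
#' `N(0, (5 SD(y))^2)`, centered-covariate slope
#' `N(0, (2.5 SD(y)/SD(x))^2)`, and half-normal(2.5 SD(y)) on both the
#' participant-intercept SD tau and the residual SD sigma. The data are
#' sorted internally by participant and period, so row order never affects
#' the result.
#'
#' @param data Data frame with columns `participant`, `period` (`"pre"` /
#'   `"post"`), `y`, and optionally `vo2peak` (used as a centered covariate
#'   when present).
#' @param priors Optional named overrides: `b0_mean`, `b0_sd`, `b1_sd`,
#'   `b2_sd`, `tau_scale`, `sigma_scale`.
#' @param chains Number of chains (default 4).
#' @param iter Post-warmup draws per chain (default 2500).
#' @param warmup Warmup iterations discarded per chain (default 500).
#' @param seed Integer seed.
#' @return Object of class `hier_fit`: `draws` (matrix of pooled post-warmup
#'   draws with columns `b0`, `b1`, `b2` (if a covariate), `tau`, `sigma`),
#'   `chain` (chain index per draw), `diagnostics` (split-Rhat and ESS per
#'   parameter), `priors`, `data_info`, `call`.
#' @examples
#' coh <- generate_cohort(cohort_config(seed = 7))
#' tab <- simulate_outcome_table(coh, "resting_hr")
#' fit <- fit_hier_linear(tab, chains = 2, iter = 500, warmup = 200, seed = 1)
#' summary(fit)
#' @export
fit_hier_linear <- function(data, priors = list(), chains = 4, iter = 2500,
                            warmup = 500, seed = 1) {
  need <- c("participant", "period", "y")
  if (!all(need %in% names(data))) {
    stop("data must have columns participant, period, y", call. = FALSE)
  }
  if (!all(data$period %in% c("pre", "post"))) {
    stop("period must be 'pre' or 'post'", call. = FALSE)
  }
  if (length(unique(data$period)) < 2) {
    stop("both periods are required for a pre/post contrast", call. = FALSE)
  }
  both <- tapply(data$period, data$participant,
                 function(p) all(c("pre", "post") %in% p))
  if (sum(both, na.rm = TRUE) < 2) {
    stop("need at least 2 participants observed in both periods", call. = FALSE)
  }
  data <- data[order(data$participant, data$period), , drop = FALSE]

  y <- data$y
  n <- length(y)
  g <- as.integer(factor(data$participant))
  G <- max(g)
  ng <- tabulate(g, G)
  has_cov <- "vo2peak" %in% names(data)
  X <- cbind(b0 = 1, b1 = as.numeric(data$period == "post"))
  if (has_cov) X <- cbind(X, b2 = data$vo2peak - mean(data$vo2peak))
  p <- ncol(X)

  # floor keeps priors proper for (near-)constant outcomes
  sd_y <- max(stats::sd(y), 1e-6, 1e-6 * abs(mean(y)))
  pr <- list(b0_mean = mean(y), b0_sd = 10 * sd_y, b1_sd = 5 * sd_y,
             b2_sd = if (has_cov) 2.5 * sd_y / stats::sd(X[, "b2"]) else NA,
             tau_scale = 2.5 * sd_y, sigma_scale = 2.5 * sd_y)
  pr[names(priors)] <- priors
  m0 <- c(pr$b0_mean, 0, if (has_cov) 0)
  prior_prec <- diag(1 / c(pr$b0_sd, pr$b1_sd, if (has_cov) pr$b2_sd)^2,
                     nrow = p)

  XtX <- crossprod(X)
  run_chain <- function(ch) {
    set.seed(derive_seed(seed, 1000 + ch))
    b <- m0 + stats::rnorm(p, 0, 0.1 * sd_y)
    xi <- 0.5 * sd_y * stats::runif(1, 0.5, 1.5)
    eta <- stats::rnorm(G)
    sigma <- sd_y * stats::runif(1, 0.5, 1.5)
    keep <- matrix(NA_real_, iter, p + 2)
    total <- warmup + iter
    for (it in seq_len(total)) {
      u <- xi * eta
      # coefficients
      r <- y - u[g]
      V <- chol2inv(chol(XtX / sigma^2 + prior_prec))
      mn <- V %*% (crossprod(X, r) / sigma^2 + prior_prec %*% m0)
      b <- drop(mn + t(chol(V)) %*% stats::rnorm(p))
      r2 <- y - drop(X %*% b)
      # latent standardized intercepts
      S <- rowsum(r2, g)[, 1]
      prec_eta <- 1 + xi^2 * ng / sigma^2
      mean_eta <- (xi * S / sigma^2) / prec_eta
      eta <- stats::rnorm(G, mean_eta, sqrt(1 / prec_eta))
      # expansion scale (tau = |xi|, half-normal prior via xi ~ N(0, scale^2))
      prec_xi <- sum(ng * eta^2) / sigma^2 + 1 / pr$tau_scale^2
      mean_xi <- (sum(eta * S) / sigma^2) / prec_xi
      xi <- stats::rnorm(1, mean_xi, sqrt(1 / prec_xi))
      # residual SD: half-normal prior, slice step on log sigma
      ssr <- sum((r2 - xi * eta[g])^2)
      lp <- function(x) {
        s2 <- exp(2 * x)
        -n * x - ssr / (2 * s2) - s2 / (2 * pr$sigma_scale^2) + x
      }
      sigma <- exp(slice1(log(sigma), lp, w = 0.5))
      if (it > warmup) keep[it - warmup, ] <- c(b, abs(xi), sigma)
    }
    keep
  }

  per_chain <- lapply(seq_len(chains), run_chain)
  draws <- do.call(rbind, per_chain)
  cn <- c(colnames(X), "tau", "sigma")
  colnames(draws) <- cn
  chain_id <- rep(seq_len(chains), each = iter)

  diag_tab <- t(sapply(cn, function(par) {
    m <- matrix(draws[, par], nrow = iter, ncol = chains)
    c(rhat = split_rhat(m), ess = ess_basic(m))
  }))
  if (any(diag_tab[, "rhat"] > 1.01, na.rm = TRUE)) {
    warning("split-Rhat > 1.01 for: ",
            paste(cn[diag_tab[, "rhat"] > 1.01], collapse = ", "),
            "; consider more iterations", call. = FALSE)
  }

  structure(list(draws = draws, chain = chain_id,
                 diagnostics = as.data.frame(diag_tab),
                 priors = pr, has_covariate = has_cov,
                 data_info = list(n_obs = n, n_participants = G,
                                  outcome_sd = sd_y),
                 chains = chains, iter = iter, warmup = warmup,
                 call = match.call()),
            class = "hier_fit")
}

#' @export
print.hier_fit <- function(x, ...) {
  cat("Hierarchical pre/post model (Gibbs sampler)\n")
  cat(sprintf("  %d observations, %d participants; %d chains x %d draws\n",
              x$data_info$n_obs, x$data_info$n_participants, x$chains, x$iter))
  s <- summary(x)
  print(s, ...)
  invisible(x)
}

#' @export
summary.hier_fit <- function(object, level = 0.90, ...) {
  tab <- do.call(rbind, lapply(colnames(object$draws), function(par) {
    s <- summarize_posterior(object$draws[, par], level = level)
    data.frame(parameter = par, mean = s$mean, ci_low = s$ci_low,
               ci_high = s$ci_high, pd = s$pd,
               rhat = object$diagnostics[par, "rhat"],
               ess = object$diagnostics[par, "ess"])
  }))
  rownames(tab) <- NULL
  tab
}

#' @export
coef.hier_fit <- function(object, ...) {
  colMeans(object$draws)
}

#' @export
plot.hier_fit <- function(x, pars = colnames(x$draws), ...) {
  op <- graphics::par(mfrow = c(length(pars), 1), mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(op))
  for (par in pars) {
    graphics::plot(x$draws[, par], type = "l", col = x$chain,
                   ylab = par, xlab = "", ...)
  }
  invisible(x)
}

#' Summarize posterior draws
#'
#' Posterior mean, equal-tailed credible interval, and probability of
#' direction (the posterior probability that the quantity is strictly
#' positive or strictly negative, whichever is larger, in percent).
#'
#' @param draws Numeric vector of at least 1000 posterior draws.
#' @param level Credible level (default 0.90).
#' @return Object of class `posterior_summary`: list with `mean`, `ci_low`,
#'   `ci_high`, `pd` (percent, 50-100), `level`, `n_draws`.
#' @export
summarize_posterior <- function(draws, level = 0.90) {
  if (length(draws) < 1000) {
    stop("need at least 1000 draws for stable tail quantiles", call. = FALSE)
  }
  a <- (1 - level) / 2
  q <- unname(stats::quantile(draws, c(a, 1 - a)))
  pd <- 100 * max(mean(draws > 0), mean(draws < 0))
  structure(list(mean = mean(draws), ci_low = q[1], ci_high = q[2],
                 pd = pd, level = level, n_draws = length(draws)),
            class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("posterior mean %.3g [%.0f%% CrI %.3g, %.3g]; Pd = %.1f%% (n = %d)\n",
              x$mean, 100 * x$level, x$ci_low, x$ci_high, x$pd, x$n_draws))
  invisible(x)
}

#' Probability of direction from a printed posterior summary
#'
#' Normal-approximation consistency check for published posterior summaries:
#' given a posterior mean and an equal-tailed credible interval, recover the
#' implied posterior SD `(ci_high - ci_low) / (2 z)` (z the standard-normal
#' quantile at `1 - (1-level)/2`) and report
#' `Pd = 100 * Phi(|mean| / SD)` percent.
#'
#' @param mean Posterior mean.
#' @param ci_low,ci_high Equal-tailed interval bounds (`ci_low < ci_high`).
#' @param level Credible level of the interval (default 0.90).
#' @return Probability of direction, percent in (50, 100\]; vectorised.
#' @examples
#' pd_from_interval(-0.22, -0.48, 0.04)  # ~92
#' @export
pd_from_interval <- function(mean, ci_low, ci_high, level = 0.90) {
  if (any(ci_low >= ci_high)) stop("degenerate interval", call. = FALSE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  sd_hat <- (ci_high - ci_low) / (2 * z)
  100 * stats::pnorm(abs(mean) / sd_hat)
}

#' Fit penalized-spline time courses with a pre/post contrast
#'
#' Hierarchical penalized B-spline model for signals measured repeatedly
#' over exercise time in both periods:
#' `y = B(time) theta_period + u_participant + e`, with a second-difference
#' (random-walk) penalty on each period's basis coefficients acting as a
#' normal prior whose smoothing precision gets a conjugate gamma update,
#' participant intercepts via the same parameter expansion as
#' [fit_hier_linear()], and a half-normal prior on the residual SD.
#'
#' @param data Data frame with `participant`, `period` (`"pre"`/`"post"`),
#'   `time` (min) and `y`.
#' @param k Basis size per period (default 8); must not exceed the number
#'   of distinct time points.
#' @param chains,iter,warmup,seed MCMC settings as in [fit_hier_linear()].
#' @param grid Evaluation grid for the fitted curves (default 46 points
#'   across the observed time range).
#' @return Object of class `timecourse_fit`: `curves` data frame (period,
#'   time, mean, ci_low, ci_high), `contrast` data frame (time, mean,
#'   ci_low, ci_high of post minus pre), diagnostics, and settings.
#' @export
fit_timecourse <- function(data, k = 8, chains = 2, iter = 1000, warmup = 300,
                           seed = 1, grid = NULL) {
  need <- c("participant", "period", "time", "y")
  if (!all(need %in% names(data))) {
    stop("data must have columns participant, period, time, y", call. = FALSE)
  }
  tt <- sort(unique(data$time))
  if (length(tt) < 5) stop("need at least 5 distinct time points", call. = FALSE)
  if (k > length(tt)) {
    stop("basis size k exceeds the number of distinct time points", call. = FALSE)
  }
  data <- data[order(data$participant, data$period, data$time), , drop = FALSE]
  y <- data$y
  n <- length(y)
  g <- as.integer(factor(data$participant))
  G <- max(g); ng <- tabulate(g, G)
  is_post <- data$period == "post"
  basis <- splines::bs(data$time, df = k, intercept = TRUE,
                       Boundary.knots = range(tt))
  if (is.null(grid)) grid <- seq(min(tt), max(tt), length.out = 46)
  Bg <- stats::predict(basis, grid)

  D <- diff(diag(k), differences = 2)
  K <- crossprod(D) + 1e-8 * diag(k)
  sd_y <- max(stats::sd(y), 1e-6, 1e-6 * abs(mean(y)))
  sigma_scale <- 2.5 * sd_y
  tau_scale <- 2.5 * sd_y
  a_lam <- 1; b_lam <- 1e-4

  idx <- list(pre = which(!is_post), post = which(is_post))
  BtB <- lapply(idx, function(i) crossprod(basis[i, , drop = FALSE]))

  run_chain <- function(ch) {
    set.seed(derive_seed(seed, 2000 + ch))
    theta <- list(pre = rep(mean(y), k) * stats::runif(k, 0.9, 1.1),
                  post = rep(mean(y), k) * stats::runif(k, 0.9, 1.1))
    lambda <- c(pre = 1, post = 1)
    xi <- 0.1 * sd_y; eta <- stats::rnorm(G); sigma <- sd_y
    keep_pre <- matrix(NA_real_, iter, length(grid))
    keep_post <- matrix(NA_real_, iter, length(grid))
    keep_sig <- numeric(iter)
    for (it in seq_len(warmup + iter)) {
      u <- xi * eta
      fit_vec <- numeric(n)
      for (perd in c("pre", "post")) {
        i <- idx[[perd]]
        other <- if (perd == "pre") "post" else "pre"
        r <- y[i] - u[g[i]]
        V <- chol2inv(chol(BtB[[perd]] / sigma^2 + lambda[[perd]] * K))
        mn <- V %*% (crossprod(basis[i, , drop = FALSE], r) / sigma^2)
        theta[[perd]] <- drop(mn + t(chol(V)) %*% stats::rnorm(k))
        lambda[[perd]] <- stats::rgamma(1, a_lam + k / 2,
                                        b_lam + drop(crossprod(theta[[perd]],
                                                   K %*% theta[[perd]])) / 2)
      }
      fit_vec[idx$pre] <- basis[idx$pre, , drop = FALSE] %*% theta$pre
      fit_vec[idx$post] <- basis[idx$post, , drop = FALSE] %*% theta$post
      r2 <- y - fit_vec
      S <- rowsum(r2, g)[, 1]
      prec_eta <- 1 + xi^2 * ng / sigma^2
      eta <- stats::rnorm(G, (xi * S / sigma^2) / prec_eta, sqrt(1 / prec_eta))
      prec_xi <- sum(ng * eta^2) / sigma^2 + 1 / tau_scale^2
      xi <- stats::rnorm(1, (sum(eta * S) / sigma^2) / prec_xi,
                         sqrt(1 / prec_xi))
      ssr <- sum((r2 - xi * eta[g])^2)
      lp <- function(x) {
        s2 <- exp(2 * x)
        -n * x - ssr / (2 * s2) - s2 / (2 * sigma_scale^2) + x
      }
      sigma <- exp(slice1(log(sigma), lp, w = 0.5))
      if (it > warmup) {
        keep_pre[it - warmup, ] <- drop(Bg %*% theta$pre)
        keep_post[it - warmup, ] <- drop(Bg %*% theta$post)
        keep_sig[it - warmup] <- sigma
      }
    }
    list(pre = keep_pre, post = keep_post, sigma = keep_sig)
  }

  res <- lapply(seq_len(chains), run_chain)
  pre <- do.call(rbind, lapply(res, `[[`, "pre"))
  post <- do.call(rbind, lapply(res, `[[`, "post"))
  sig <- unlist(lapply(res, `[[`, "sigma"))

  band <- function(m) {
    data.frame(time = grid, mean = colMeans(m),
               ci_low = apply(m, 2, stats::quantile, 0.05),
               ci_high = apply(m, 2, stats::quantile, 0.95))
  }
  curves <- rbind(cbind(period = "pre", band(pre)),
                  cbind(period = "post", band(post)))
  contrast <- band(post - pre)
  sig_m <- matrix(sig, ncol = chains)

  structure(list(curves = curves, contrast = contrast,
                 sigma_mean = mean(sig),
                 diagnostics = data.frame(rhat_sigma = split_rhat(sig_m)),
                 k = k, grid = grid, chains = chains, iter = iter,
                 call = match.call()),
            class = "timecourse_fit")
}

#' @export
print.timecourse_fit <- function(x, ...) {
  cat(sprintf("Penalized-spline time course (k = %d, %d chains x %d draws)\n",
              x$k, x$chains, x$iter))
  excl <- x$contrast$ci_low > 0 | x$contrast$ci_high < 0
  cat(sprintf("  post-pre contrast excludes 0 at %d of %d grid times\n",
              sum(excl), nrow(x$contrast)))
  cat(sprintf("  residual SD (posterior mean) %.3g; split-Rhat(sigma) %.3f\n",
              x$sigma_mean, x$diagnostics$rhat_sigma))
  invisible(x)
}

#' @export
plot.timecourse_fit <- function(x, ...) {
  cr <- x$curves
  ylim <- range(cr$ci_low, cr$ci_high)
  pre <- cr[cr$period == "pre", ]
  post <- cr[cr$period == "post", ]
  graphics::plot(pre$time, pre$mean, type = "l", col = "steelblue", lwd = 2,
                 ylim = ylim, xlab = "time (min)", ylab = "fitted", ...)
  graphics::lines(pre$time, pre$ci_low, col = "steelblue", lty = 3)
  graphics::lines(pre$time, pre$ci_high, col = "steelblue", lty = 3)
  graphics::lines(post$time, post$mean, col = "firebrick", lwd = 2)
  graphics::lines(post$time, post$ci_low, col = "firebrick", lty = 3)
  graphics::lines(post$time, post$ci_high, col = "firebrick", lty = 3)
  graphics::legend("topleft", c("pre", "post"), lwd = 2,
                   col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}
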