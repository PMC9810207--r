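#' Raftery-Lewis run-length diagnostic
#'
#' Implements the Raftery-Lewis (1992) run-length control for estimating a
#' posterior quantile `q` to within +/- `r` with probability `s`. The chain
#' is dichotomized at its empirical q-quantile, a thinning interval `k` is
#' chosen as the smallest spacing at which a first-order Markov chain is
#' preferred over a second-order one (BIC on the triple contingency
#' table), and the fitted two-state transition probabilities give the
#' burn-in `M`, the required run length `N` and the dependence factor
#' I = (M + N) / Nmin, where Nmin is the run length needed under
#' independence.
#'
#' @param chain numeric vector of MCMC draws.
#' @param q quantile of interest (default 0.025).
#' @param r tolerated error on the quantile's cumulative probability
#'   (default 0.005).
#' @param s coverage probability (default 0.95).
#' @param converge_eps accuracy for the burn-in bound (default 0.001).
#' @return A list with `M` (burn-in), `N` (required iterations), `k`
#'   (thinning), `I` (dependence factor) and `Nmin`.
#' @export
raftery_lewis <- function(chain, q = 0.025, r = 0.005, s = 0.95,
                          converge_eps = 0.001) {
  chain <- as.numeric(chain)
  phi <- stats::qnorm(0.5 * (1 + s))
  nmin <- ceiling(q * (1 - q) * phi^2 / r^2)
  if (length(chain) < nmin)
    stop("chain too short: need at least ", nmin, " draws", call. = FALSE)
  cutoff <- stats::quantile(chain, probs = q, names = FALSE)
  dich <- chain <= cutoff
  # smallest thinning at which first-order Markov dependence suffices
  k <- 0L
  repeat {
    k <- k + 1L
    z <- dich[seq(1, length(dich), by = k)]
    if (length(z) < 3) { k <- k - 1L; break }
    if (markov_order_bic(z) >= 0) break
    if (k > max(1, length(dich) %/% 100)) break
  }
  z <- dich[seq(1, length(dich), by = k)]
  from <- z[-length(z)]; to <- z[-1]
  alpha <- sum(!from & to) / max(1, sum(!from))  # P(0 -> 1)
  beta <- sum(from & !to) / max(1, sum(from))    # P(1 -> 0)
  ab <- alpha + beta
  if (ab <= 0 || alpha <= 0 || beta <= 0) {
    # (near-)constant dichotomized chain: independence limit
    return(list(M = 0, N = nmin, k = k, I = 1, Nmin = nmin))
  }
  m <- log(converge_eps * ab / max(alpha, beta)) / log(abs(1 - ab))
  M <- ceiling(m) * k
  n <- ((2 - ab) * alpha * beta / ab^3) * phi^2 / r^2
  N <- ceiling(n) * k
  list(M = M, N = N, k = k, I = (M + N) / nmin, Nmin = nmin)
}

# BIC difference between second- and first-order Markov models for a
# binary sequence; >= 0 means first-order dependence is adequate.
markov_order_bic <- function(z) {
  n <- length(z) - 2
  tab <- table(factor(z[1:n], c(FALSE, TRUE)),
               factor(z[2:(n + 1)], c(FALSE, TRUE)),
               factor(z[3:(n + 2)], c(FALSE, TRUE)))
  g2 <- 0
  for (j in 1:2) {
    slice <- tab[, j, ]
    rs <- rowSums(slice); cs <- colSums(slice); tot <- sum(slice)
    if (tot == 0) next
    expct <- outer(rs, cs) / tot
    obs <- slice[slice > 0]
    g2 <- g2 + 2 * sum(slice[slice > 0] * log(slice[slice > 0] / expct[slice > 0]))
  }
  # df = 2 for conditional independence in a 2x2x2 table
  2 * log(n) - g2
}

# P(CvM statistic <= q): asymptotic Cramer-von Mises distribution
# (Csorgo & Faraway series with Bessel-K terms).
pcramer <- function(q, eps = 1e-5) {
  vapply(q, function(x) {
    if (x <= 0) return(0)
    total <- 0
    for (kk in 0:3) {
      z <- gamma(kk + 0.5) * sqrt(4 * kk + 1) / (gamma(kk + 1) * pi^1.5 * sqrt(x))
      u <- (4 * kk + 1)^2 / (16 * x)
      if (u <= -log(eps))
        total <- total + z * exp(-u) * besselK(u, nu = 0.25)
    }
    min(max(total, 0), 1)
  }, numeric(1))
}

# Spectral density of a chain at frequency zero, via an AIC-selected AR fit.
spectrum0_ar <- function(x) {
  x <- as.numeric(x)
  if (stats::var(x) == 0) return(0)
  fit <- stats::ar(x, aic = TRUE, order.max = min(30, length(x) %/% 5))
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Heidelberger-Welch stationarity and halfwidth diagnostics
#'
#' The stationarity test applies the Cramer-von Mises statistic to the
#' standardized cumulative-sum (Brownian bridge) of the chain, iteratively
#' discarding the first 10% until the test passes or less than half the
#' chain remains. The halfwidth test compares the asymptotic 95% CI
#' halfwidth of the retained-segment mean (spectral variance at frequency
#' zero) with `eps` times the mean.
#'
#' @param chain numeric vector of MCMC draws (length >= 100).
#' @param alpha significance level of the stationarity test (default 0.05).
#' @param eps relative halfwidth tolerance (default 0.1).
#' @return A list with `stationarity` (pass flag), `kept_frac`, `start`,
#'   `cvm_pvalue`, `mean`, `halfwidth`, `halfwidth_pass`.
#' @export
heidelberger_welch <- function(chain, alpha = 0.05, eps = 0.1) {
  chain <- as.numeric(chain)
  n <- length(chain)
  if (n < 100) stop("need a chain of length >= 100", call. = FALSE)
  if (stats::var(chain) == 0) {
    return(list(stationarity = TRUE, kept_frac = 1, start = 1, cvm_pvalue = 1,
                mean = chain[1], halfwidth = 0, halfwidth_pass = TRUE))
  }
  # spectral variance from the final half, which a non-stationary start
  # must not contaminate
  s0 <- spectrum0_ar(chain[(n %/% 2):n])
  passed <- FALSE; start <- 1; pval <- NA_real_
  if (s0 > 0) {
    for (frac in seq(0, 0.4, by = 0.1)) {
      start <- floor(frac * n) + 1
      y <- chain[start:n]; m <- length(y)
      ybar <- mean(y)
      csum <- cumsum(y) - seq_len(m) * ybar
      b <- csum / sqrt(s0 * m)
      cvm <- sum(b^2) / m
      pval <- 1 - pcramer(cvm)
      if (pval > alpha) { passed <- TRUE; break }
    }
  }
  y <- chain[start:n]
  s0 <- spectrum0_ar(y)
  hw <- stats::qnorm(0.975) * sqrt(s0 / length(y))
  list(stationarity = passed, kept_frac = (n - start + 1) / n, start = start,
       cvm_pvalue = pval, mean = mean(y), halfwidth = hw,
       halfwidth_pass = is.finite(hw) && abs(mean(y)) > 0 &&
         hw / abs(mean(y)) < eps)
}

#' Chain diagnostics for a fitted model
#'
#' Runs [raftery_lewis] and [heidelberger_welch] on the monitored scalar
#' traces of a fit: both variance components, the Poisson mean mu, the
#' log-likelihood, each singular value (conditional on its axis being
#' present), the first coordinate of each sign-aligned singular vector,
#' and the first genotype and block coordinates as estimable contrasts
#' (genotype effect minus the genotype mean; block effect minus its
#' environment's mean). The contrasts are monitored because the levels of
#' `g` and `beta` are only weakly identified against each other (the
#' additive level can move between them, constrained only by the priors),
#' so raw coordinates share one slowly mixing direction that carries no
#' information about any estimable quantity.
#'
#' @param draws a `bammi_draws` object.
#' @param q,r,s Raftery-Lewis settings.
#' @return A data frame, one row per monitored parameter, with the
#'   Raftery-Lewis burn-in, run length, thinning and dependence factor and
#'   the Heidelberger-Welch verdicts.
#' @export
diagnostic_report <- function(draws, q = 0.025, r = 0.005, s = 0.95) {
  stopifnot(inherits(draws, "bammi_draws"))
  draws <- align_signs(draws)
  bce <- draws$labels$block_cell_env
  beta_env1 <- rowMeans(draws$beta[, bce == bce[1], drop = FALSE])
  traces <- list(sigma2_g = draws$sigma2_g, sigma2_e = draws$sigma2_e,
                 mu = draws$mu, loglik = draws$loglik,
                 g1_contrast = draws$g[, 1] - rowMeans(draws$g),
                 beta1_contrast = draws$beta[, 1] - beta_env1)
  t_common <- if (draws$method == "gibbs") draws$t_fixed else
    as.integer(stats::quantile(draws$t, 0.5, type = 1))
  for (k in seq_len(max(t_common, 0))) {
    have <- draws$t >= k
    traces[[paste0("lambda", k)]] <- draws$lambda[have, k]
    traces[[paste0("alpha1_", k)]] <- draws$alpha[have, 1, k]
    traces[[paste0("gamma1_", k)]] <- draws$gamma[have, 1, k]
  }
  rows <- lapply(names(traces), function(nm) {
    x <- traces[[nm]]
    rl <- try(raftery_lewis(x, q, r, s), silent = TRUE)
    hw <- try(heidelberger_welch(x), silent = TRUE)
    data.frame(parameter = nm,
               rl_M = if (inherits(rl, "try-error")) NA else rl$M,
               rl_N = if (inherits(rl, "try-error")) NA else rl$N,
               rl_k = if (inherits(rl, "try-error")) NA else rl$k,
               rl_I = if (inherits(rl, "try-error")) NA else rl$I,
               hw_stationary = if (inherits(hw, "try-error")) NA else hw$stationarity,
               hw_kept_frac = if (inherits(hw, "try-error")) NA else hw$kept_frac,
               hw_pass = if (inherits(hw, "try-error")) NA else hw$halfwidth_pass,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
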