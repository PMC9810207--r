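# Posterior-mean plug-in state from a fixed-dimension fit (signs aligned,
# singular-vector means renormalized to unit length).
posterior_mean_state <- function(draws, t = draws$t_fixed) {
  draws <- align_signs(draws, t_star = max(t, 1L))
  g <- dim(draws$alpha)[2]; e <- dim(draws$gamma)[2]
  lam <- if (t > 0) colMeans(draws$lambda[, seq_len(t), drop = FALSE]) else numeric(0)
  alpha <- matrix(0, g, t); gamma <- matrix(0, e, t)
  for (k in seq_len(t)) {
    a <- colMeans(draws$alpha[, , k]); a <- a / sqrt(sum(a^2))
    c_ <- colMeans(draws$gamma[, , k]); c_ <- c_ / sqrt(sum(c_^2))
    alpha[, k] <- a; gamma[, k] <- c_
  }
  list(beta = colMeans(draws$beta), g_eff = colMeans(draws$g), t = t,
       lambda = lam, alpha = alpha, gamma = gamma,
       sigma2_g = mean(draws$sigma2_g), sigma2_e = mean(draws$sigma2_e),
       mu = mean(draws$mu))
}

#' AIC and BIC of a fixed-dimension fit
#'
#' Deviance is evaluated at the posterior means of all parameters
#' (sign-aligned singular vectors, renormalized). The parameter count uses
#' Gollob degrees of freedom per bilinear axis, g + e - 1 - 2k, plus the
#' block cells, the genotype effects and the two variance components.
#'
#' @param draws a `bammi_draws` object from a fixed-t [bammi_gibbs] fit.
#' @param data the [trial_data] the fit used.
#' @param t the fit's dimension (defaults to the fit's `t_fixed`).
#' @return A list with `AIC`, `BIC`, `p` (parameter count), `loglik`
#'   (at posterior means).
#' @export
aic_bic <- function(draws, data, t = draws$t_fixed) {
  stopifnot(inherits(draws, "bammi_draws"))
  state <- posterior_mean_state(draws, t)
  ll <- ammi_loglik(state, data)
  g <- dim(draws$alpha)[2]; e <- dim(draws$gamma)[2]
  p <- ncol(draws$beta) + g + 2 +
    if (t > 0) sum(g + e - 1 - 2 * seq_len(t)) else 0
  n <- data$n
  list(AIC = -2 * ll + 2 * p, BIC = -2 * ll + p * log(n), p = p, loglik = ll)
}

#' AICM from posterior log-likelihood draws
#'
#' A posterior-simulation analogue of AIC: AICM = -2 (mean - variance) of
#' the log-likelihood draws; smaller is better.
#'
#' @param loglik_draws numeric vector of post-burn-in log-likelihood values.
#' @return The AICM value.
#' @export
aicm <- function(loglik_draws) {
  loglik_draws <- loglik_draws[is.finite(loglik_draws)]
  if (length(loglik_draws) < 2)
    stop("need at least 2 log-likelihood draws", call. = FALSE)
  -2 * (mean(loglik_draws) - stats::var(loglik_draws))
}

#' Information-criterion table across model dimensions
#'
#' Builds the model-comparison ("Ockham") table from a set of fixed-t fits:
#' one row per dimension with AIC, BIC, AICM, mean log-likelihood,
#' posterior-mean residual variance, the per-axis singular-value posterior
#' means and the cumulative interaction sum of squares SS = sum(lambda_k^2).
#'
#' @param fits a named list of `bammi_draws`, names being the dimensions
#'   ("0", "1", ...).
#' @param data the [trial_data] all fits used.
#' @return A data frame, one row per dimension.
#' @export
ockham_table <- function(fits, data) {
  t_all <- sort(as.integer(names(fits)))
  rows <- lapply(t_all, function(t) {
    f <- fits[[as.character(t)]]
    ab <- aic_bic(f, data, t)
    lam <- if (t > 0) colMeans(f$lambda[, seq_len(t), drop = FALSE]) else numeric(0)
    row <- data.frame(hypothesis = f$prior$hypothesis, t = t,
                      AIC = ab$AIC, BIC = ab$BIC, AICM = aicm(f$loglik),
                      loglik_mean = mean(f$loglik),
                      sigma2_e_mean = mean(f$sigma2_e),
                      ss_gei = sum(lam^2))
    for (k in seq_len(t)) row[[paste0("lambda", k)]] <- lam[k]
    row
  })
  out <- Reduce(function(a, b) merge(a, b, all = TRUE, sort = FALSE), rows)
  out[order(out$t), ]
}
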