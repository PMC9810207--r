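# Internal fit context: index vectors and counts derived once per data set.
fit_context <- function(data) {
  nb <- tabulate(data$bi, nbins = length(data$block_cells))
  ngc <- tabulate(data$gi, nbins = data$g)
  if (any(nb == 0L)) stop("block cell with no records", call. = FALSE)
  if (any(ngc == 0L)) stop("genotype with no records", call. = FALSE)
  list(y = data$records$response, gi = data$gi, ei = data$ei, bi = data$bi,
       g = data$g, e = data$e, n = data$n, nc = length(data$block_cells),
       nb = nb, ngc = ngc, block_cell_env = data$block_cell_env,
       genotypes = data$genotypes, environments = data$environments,
       block_cells = data$block_cells)
}

# n-vector of the bilinear part sum_k lambda_k alpha[gi,k] gamma[ei,k]
bilinear_vector <- function(lambda, alpha, gamma, gi, ei) {
  t <- length(lambda)
  if (t == 0L) return(numeric(length(gi)))
  drop((alpha[gi, , drop = FALSE] * gamma[ei, , drop = FALSE]) %*% lambda)
}

grouped_sum <- function(x, idx, nbins) {
  drop(rowsum(x, idx, reorder = TRUE))
}

#' Gaussian log-likelihood of an AMMI model state
#'
#' Evaluates the log density of the observations under
#' y ~ N(X1 beta + Z g + sum_k lambda_k diag(Z alpha_k) X2 gamma_k,
#' I sigma_e^2).
#'
#' @param state a model state as stored in a fit (list with `beta`, `g_eff`,
#'   `lambda`, `alpha`, `gamma`, `sigma2_e`).
#' @param data a [trial_data] object.
#' @return The log-likelihood (scalar).
#' @export
ammi_loglik <- function(state, data) {
  ctx <- if (is.list(data) && !is.null(data$y) && !is.null(data$nb)) data
         else fit_context(data)
  if (state$sigma2_e <= 0) stop("sigma2_e must be positive", call. = FALSE)
  mu_vec <- state$beta[ctx$bi] + state$g_eff[ctx$gi] +
    bilinear_vector(state$lambda, state$alpha, state$gamma, ctx$gi, ctx$ei)
  r <- ctx$y - mu_vec
  -ctx$n / 2 * log(2 * pi * state$sigma2_e) - sum(r^2) / (2 * state$sigma2_e)
}

loglik_ctx <- function(state, ctx) ammi_loglik(state, ctx)

# Least-squares / SVD initialization of a state with t axes.
init_state <- function(ctx, t, spec) {
  y <- ctx$y
  beta <- grouped_sum(y, ctx$bi, ctx$nc) / ctx$nb
  g_eff <- grouped_sum(y - beta[ctx$bi], ctx$gi, ctx$g) / ctx$ngc
  g_eff <- g_eff - mean(g_eff)
  resid <- y - beta[ctx$bi] - g_eff[ctx$gi]
  lambda <- numeric(0); sigma2_lambda <- numeric(0)
  alpha <- matrix(0, ctx$g, 0); gamma <- matrix(0, ctx$e, 0)
  if (t > 0) {
    cellsum <- matrix(0, ctx$g, ctx$e); cellcnt <- matrix(0, ctx$g, ctx$e)
    ij <- cbind(ctx$gi, ctx$ei)
    for (r_ in seq_along(y)) {
      cellsum[ij[r_, 1], ij[r_, 2]] <- cellsum[ij[r_, 1], ij[r_, 2]] + resid[r_]
      cellcnt[ij[r_, 1], ij[r_, 2]] <- cellcnt[ij[r_, 1], ij[r_, 2]] + 1
    }
    cm <- cellsum / pmax(cellcnt, 1)
    sv <- svd(double_center(cm))
    lambda <- pmax(sv$d[seq_len(t)], 1e-3)
    alpha <- sv$u[, seq_len(t), drop = FALSE]
    gamma <- sv$v[, seq_len(t), drop = FALSE]
    sigma2_lambda <- vapply(lambda, function(l) {
      if (spec$hypothesis == "bammi") spec$bammi_sigma2_lambda else l^2 + 1
    }, numeric(1))
  }
  s2e <- stats::var(resid - bilinear_vector(lambda, alpha, gamma, ctx$gi, ctx$ei))
  list(beta = beta, g_eff = g_eff, t = t, lambda = lambda,
       alpha = alpha, gamma = gamma, sigma2_lambda = sigma2_lambda,
       sigma2_g = max(stats::var(g_eff), 1e-3),
       sigma2_e = max(s2e, 1e-3), mu = 1)
}

# One full Gibbs sweep (steps B through J) at fixed dimension state$t.
gibbs_sweep <- function(state, ctx, spec) {
  y <- ctx$y; gi <- ctx$gi; ei <- ctx$ei; bi <- ctx$bi
  t <- state$t
  bil <- bilinear_vector(state$lambda, state$alpha, state$gamma, gi, ei)

  # B: block-within-environment effects (flat prior)
  a1 <- y - state$g_eff[gi] - bil
  mb <- grouped_sum(a1, bi, ctx$nc) / ctx$nb
  state$beta <- stats::rnorm(ctx$nc, mb, sqrt(state$sigma2_e / ctx$nb))

  # C: genotype effects (ridge from sigma2_g)
  a2 <- y - state$beta[bi] - bil
  dg <- ctx$ngc + state$sigma2_e / state$sigma2_g
  mg <- grouped_sum(a2, gi, ctx$g) / dg
  state$g_eff <- stats::rnorm(ctx$g, mg, sqrt(state$sigma2_e / dg))

  # D-G: bilinear axes
  if (t > 0) {
    base <- y - state$beta[bi] - state$g_eff[gi]
    ones_g <- rep(1, ctx$g) / sqrt(ctx$g)
    ones_e <- rep(1, ctx$e) / sqrt(ctx$e)
    for (k in seq_len(t)) {
      ak <- state$alpha[, k]; ck <- state$gamma[, k]
      contrib_k <- state$lambda[k] * ak[gi] * ck[ei]
      resid_k <- base - (bil - contrib_k)   # y - X1b - Zg - other axes
      # D (lambda): truncated normal on (0, lambda_{k-1})
      phi <- ak[gi] * ck[ei]
      prec <- sum(phi^2) + state$sigma2_e / state$sigma2_lambda[k]
      lmean <- sum(phi * resid_k) / prec
      lsd <- sqrt(state$sigma2_e / prec)
      upper <- if (k == 1) Inf else max(state$lambda[k - 1], 1e-300)
      state$lambda[k] <- max(rtnorm(1, lmean, lsd, 0, upper), 1e-300)
      # sigma2_lambda_k per prior family
      state$sigma2_lambda[k] <- update_sigma2_lambda(spec, state$lambda[k])
      # E (alpha_k): vMF orthogonal to {1, other alphas}
      ca <- grouped_sum(ck[ei] * resid_k, gi, ctx$g)
      state$alpha[, k] <- rvmf_subspace(ca, state$lambda[k] / state$sigma2_e,
        basis = cbind(ones_g, state$alpha[, -k, drop = FALSE]))
      ak <- state$alpha[, k]
      # F (gamma_k): vMF orthogonal to {1, other gammas}
      cg <- grouped_sum(ak[gi] * resid_k, ei, ctx$e)
      state$gamma[, k] <- rvmf_subspace(cg, state$lambda[k] / state$sigma2_e,
        basis = cbind(ones_e, state$gamma[, -k, drop = FALSE]))
      ck <- state$gamma[, k]
      bil <- (bil - contrib_k) + state$lambda[k] * ak[gi] * ck[ei]
    }
  }

  # H: genotypic variance
  state$sigma2_g <- 1 / stats::rgamma(1, shape = ctx$g / 2,
                                      rate = sum(state$g_eff^2) / 2 + 1e-12)
  # I: residual variance
  rss <- sum((y - state$beta[bi] - state$g_eff[gi] - bil)^2)
  state$sigma2_e <- 1 / stats::rgamma(1, shape = ctx$n / 2, rate = rss / 2)
  # J: Poisson mean of t (conjugate Gamma update)
  state$mu <- stats::rgamma(1, shape = spec$tau + t, rate = spec$upsilon + 1)
  state
}

#' Fit a Bayesian AMMI model with a fixed number of bilinear axes
#'
#' Runs the Gibbs sampler at a fixed dimension `t`: block and genotype
#' effects have Gaussian conditionals, each singular value a truncated
#' normal on (0, lambda_(k-1)), its scale the family-specific conditional,
#' and each singular vector a von Mises-Fisher draw constrained to the
#' subspace orthogonal to the ones vector and the other vectors of its
#' side. Variances follow scaled-inverse-chi-square conditionals.
#'
#' @param data a [trial_data] object.
#' @param prior a [prior_spec].
#' @param t number of bilinear axes (0 to min(g, e) - 1).
#' @param iterations total sweeps.
#' @param burn_in sweeps discarded from the start.
#' @param thin keep every `thin`-th sweep after burn-in.
#' @param seed integer seed.
#' @param pilot if TRUE, a 500-sweep pilot chain is run first and
#'   Raftery-Lewis control ([raftery_lewis]) of the residual-variance trace
#'   sets the burn-in and thinning (never below the supplied values).
#' @return An object of class `bammi_draws` holding thinned post-burn-in
#'   draws of all parameters, the per-iteration dimension `t` and the
#'   log-likelihood trace.
#' @export
bammi_gibbs <- function(data, prior = prior_spec("bammi"), t = 2L,
                        iterations = 3000L, burn_in = 500L, thin = 1L,
                        seed = 1L, pilot = FALSE) {
  stopifnot(inherits(data, "trial_data"), inherits(prior, "prior_spec"),
            iterations > burn_in, burn_in >= 0, thin >= 1)
  ctx <- fit_context(data)
  t_max <- prior$t_max
  if (is.null(t_max)) t_max <- min(ctx$g, ctx$e) - 1L
  if (t > t_max) stop("t exceeds t_max = ", t_max, call. = FALSE)
  set.seed(as.integer(seed))
  if (pilot) {
    # the pilot needs at least the Raftery-Lewis minimum run length
    pf <- bammi_gibbs(data, prior, t = t, iterations = 4000L, burn_in = 0L,
                      thin = 1L, seed = seed + 1L, pilot = FALSE)
    rl <- try(raftery_lewis(pf$sigma2_e), silent = TRUE)
    if (!inherits(rl, "try-error")) {
      burn_in <- max(burn_in, ceiling(rl$M))
      thin <- max(thin, rl$k)
      # retain at least the Raftery-Lewis minimum run length
      iterations <- max(iterations, burn_in + 3800L * thin)
    }
    set.seed(as.integer(seed))
  }
  state <- init_state(ctx, t, prior)
  S <- (iterations - burn_in) %/% thin
  # storage kept in local arrays so subassignment is in place
  st_beta <- matrix(NA_real_, S, ctx$nc, dimnames = list(NULL, ctx$block_cells))
  st_g <- matrix(NA_real_, S, ctx$g, dimnames = list(NULL, ctx$genotypes))
  st_lambda <- matrix(NA_real_, S, t_max)
  st_s2l <- matrix(NA_real_, S, t_max)
  st_alpha <- array(NA_real_, c(S, ctx$g, t_max))
  st_gamma <- array(NA_real_, c(S, ctx$e, t_max))
  st_s2g <- numeric(S); st_s2e <- numeric(S); st_mu <- numeric(S)
  st_t <- integer(S); st_ll <- numeric(S)
  s <- 0L
  for (it in seq_len(iterations)) {
    state <- gibbs_sweep(state, ctx, prior)
    if (!all(is.finite(state$sigma2_e)) || !is.finite(state$sigma2_g))
      stop("non-finite state at iteration ", it, call. = FALSE)
    if (it > burn_in && (it - burn_in) %% thin == 0L && s < S) {
      s <- s + 1L
      tk <- state$t
      st_beta[s, ] <- state$beta; st_g[s, ] <- state$g_eff
      if (tk > 0) {
        st_lambda[s, seq_len(tk)] <- state$lambda
        st_s2l[s, seq_len(tk)] <- state$sigma2_lambda
        st_alpha[s, , seq_len(tk)] <- state$alpha
        st_gamma[s, , seq_len(tk)] <- state$gamma
      }
      st_s2g[s] <- state$sigma2_g; st_s2e[s] <- state$sigma2_e
      st_mu[s] <- state$mu; st_t[s] <- tk
      st_ll[s] <- loglik_ctx(state, ctx)
    }
  }
  st <- list(beta = st_beta, g = st_g, lambda = st_lambda,
             sigma2_lambda = st_s2l, alpha = st_alpha, gamma = st_gamma,
             sigma2_g = st_s2g, sigma2_e = st_s2e, mu = st_mu, t = st_t,
             loglik = st_ll)
  st$t_max <- t_max; st$t_fixed <- t; st$method <- "gibbs"
  st$prior <- prior; st$labels <- list(genotypes = ctx$genotypes,
                                       environments = ctx$environments,
                                       block_cells = ctx$block_cells,
                                       block_cell_env = ctx$block_cell_env)
  st$burn_in <- burn_in; st$thin <- thin; st$iterations <- iterations
  class(st) <- "bammi_draws"
  st
}

#' @export
print.bammi_draws <- function(x, ...) {
  cat("Bayesian AMMI", toupper(x$prior$hypothesis), "fit (", x$method, "):",
      length(x$t), "retained draws\n")
  if (x$method == "gibbs") cat("fixed dimension t =", x$t_fixed, "\n")
  else {
    tb <- table(x$t)
    cat("visited dimensions:",
        paste(names(tb), "(", as.integer(tb), ")", collapse = ", "), "\n")
  }
  cat("posterior mean sigma2_e =", round(mean(x$sigma2_e), 3),
      " sigma2_g =", round(mean(x$sigma2_g), 3), "\n")
  invisible(x)
}

# Extract a full model state (for likelihood evaluation) from stored draw s.
draw_state <- function(draws, s) {
  t <- draws$t[s]
  g <- dim(draws$alpha)[2]; e <- dim(draws$gamma)[2]
  list(beta = draws$beta[s, ], g_eff = draws$g[s, ], t = t,
       lambda = if (t > 0) draws$lambda[s, seq_len(t)] else numeric(0),
       alpha = matrix(draws$alpha[s, , seq_len2(t)], g, t),
       gamma = matrix(draws$gamma[s, , seq_len2(t)], e, t),
       sigma2_g = draws$sigma2_g[s], sigma2_e = draws$sigma2_e[s],
       mu = draws$mu[s])
}

seq_len2 <- function(t) if (t > 0) seq_len(t) else integer(0)
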