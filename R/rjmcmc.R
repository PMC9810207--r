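# Propose the parameters of a new axis t+1 from their conditionals given
# the current-state residuals (dimension-matching Jacobian = 1):
# alpha, gamma are drawn uniformly in the constraint complement (their
# conditional at lambda = 0), lambda from its truncated-normal conditional
# (diffuse proposal scale), then sigma2_lambda from its conditional.
propose_add <- function(state, ctx, spec) {
  t <- state$t
  ones_g <- rep(1, ctx$g) / sqrt(ctx$g)
  ones_e <- rep(1, ctx$e) / sqrt(ctx$e)
  alpha_c <- rvmf_subspace(stats::rnorm(ctx$g), 0,
                           basis = cbind(ones_g, state$alpha))
  gamma_c <- rvmf_subspace(stats::rnorm(ctx$e), 0,
                           basis = cbind(ones_e, state$gamma))
  resid <- ctx$y - state$beta[ctx$bi] - state$g_eff[ctx$gi] -
    bilinear_vector(state$lambda, state$alpha, state$gamma, ctx$gi, ctx$ei)
  phi <- alpha_c[ctx$gi] * gamma_c[ctx$ei]
  prec <- sum(phi^2) + state$sigma2_e / spec$bammi_sigma2_lambda
  lmean <- sum(phi * resid) / prec
  lsd <- sqrt(state$sigma2_e / prec)
  upper <- if (t == 0) Inf else state$lambda[t]
  lambda_c <- rtnorm(1, lmean, lsd, 0, upper)
  list(lambda = lambda_c, alpha = alpha_c, gamma = gamma_c,
       sigma2_lambda = update_sigma2_lambda(spec, lambda_c))
}

add_axis <- function(state, cand) {
  state$t <- state$t + 1L
  state$lambda <- c(state$lambda, cand$lambda)
  state$alpha <- cbind(state$alpha, cand$alpha)
  state$gamma <- cbind(state$gamma, cand$gamma)
  state$sigma2_lambda <- c(state$sigma2_lambda, cand$sigma2_lambda)
  state
}

drop_axis <- function(state, j) {
  state$t <- state$t - 1L
  state$lambda <- state$lambda[-j]
  state$alpha <- state$alpha[, -j, drop = FALSE]
  state$gamma <- state$gamma[, -j, drop = FALSE]
  state$sigma2_lambda <- state$sigma2_lambda[-j]
  state
}

#' Log acceptance ratio for adding a bilinear axis
#'
#' log a(t, t+1) = log L(y | t+1) - log L(y | t) + log(mu / (t+1)) +
#' log(pd / pa): the birth decision rule (likelihood ratio, truncated-Poisson
#' prior ratio, and the Hastings correction for proposing a birth with
#' probability pa whose reverse death is proposed with probability pd), with
#' unit Jacobian. With nested ordered axes the candidate is appended as the
#' last (smallest) axis and the reverse move deletes it, so no axis-count
#' factor enters the correction; this is what makes the sampler recover the
#' prior on t exactly when the likelihood ratio is switched off.
#'
#' @param state current model state (dimension t).
#' @param cand candidate axis from the conditional proposal.
#' @param data a [trial_data] or internal fit context.
#' @param prior a [prior_spec].
#' @param flat_likelihood if TRUE the likelihood ratio is forced to 1
#'   (prior-recovery test mode).
#' @return The log acceptance ratio.
#' @export
log_accept_add <- function(state, cand, data, prior, flat_likelihood = FALSE) {
  t <- state$t
  llr <- if (flat_likelihood) 0 else {
    ammi_loglik(add_axis(state, cand), data) - ammi_loglik(state, data)
  }
  llr + log(state$mu / (t + 1)) + log(prior$pd / prior$pa)
}

#' Log acceptance ratio for deleting a bilinear axis
#'
#' log a(t, t-1) = log L(y | t-1) - log L(y | t) + log(t / mu) +
#' log(pa / pd), the death decision rule symmetric to
#' [log_accept_add] so the pair satisfies detailed balance.
#'
#' @param state current model state (dimension t >= 1).
#' @param j index of the axis proposed for removal.
#' @inheritParams log_accept_add
#' @return The log acceptance ratio.
#' @export
log_accept_delete <- function(state, j, data, prior, flat_likelihood = FALSE) {
  t <- state$t
  stopifnot(t >= 1, j >= 1, j <= t)
  llr <- if (flat_likelihood) 0 else {
    ammi_loglik(drop_axis(state, j), data) - ammi_loglik(state, data)
  }
  llr + log(t / state$mu) + log(prior$pa / prior$pd)
}

# One reversible-jump sweep: a within-model Gibbs sweep, then one
# dimension move drawn from {add, delete, stay} with probabilities
# (pa, pd, p0); the delete move removes the last (smallest) axis.
rj_sweep <- function(state, ctx, spec, t_max, flat_likelihood = FALSE,
                     fix_mu = NULL) {
  state <- gibbs_sweep(state, ctx, spec)
  if (!is.null(fix_mu)) state$mu <- fix_mu
  u_move <- stats::runif(1)
  move <- if (u_move < spec$pa) "add" else if (u_move < spec$pa + spec$pd) "delete" else "stay"
  outcome <- list(move = move, accepted = FALSE, t_before = state$t)
  if (move == "add" && state$t < t_max) {
    cand <- propose_add(state, ctx, spec)
    lr <- log_accept_add(state, cand, ctx, spec, flat_likelihood)
    outcome$log_ratio <- lr
    if (log(stats::runif(1)) < lr) {
      state <- add_axis(state, cand)
      outcome$accepted <- TRUE
    }
  } else if (move == "delete" && state$t >= 1) {
    lr <- log_accept_delete(state, state$t, ctx, spec, flat_likelihood)
    outcome$log_ratio <- lr
    if (log(stats::runif(1)) < lr) {
      state <- drop_axis(state, state$t)
      outcome$accepted <- TRUE
    }
  }
  outcome$t_after <- state$t
  list(state = state, outcome = outcome)
}

#' Fit a Bayesian AMMI model with reversible-jump dimension selection
#'
#' Interleaves within-model Gibbs sweeps with transdimensional birth/death
#' moves on the number of bilinear axes. Each sweep proposes one move -
#' addition, deletion or no change - with prior probabilities (pa, pd, p0);
#' a birth draws the new axis's parameters from their conditionals given
#' the current residuals (unit Jacobian), a death removes the last
#' (smallest) axis. Acceptance follows the birth/death decision rules (see
#' [log_accept_add], [log_accept_delete]).
#'
#' @inheritParams bammi_gibbs
#' @param t_start initial dimension (default 0).
#' @param flat_likelihood if TRUE the likelihood ratio in the dimension
#'   moves is forced to 1, so the chain targets the prior on t - the
#'   canonical correctness check for the Hastings corrections.
#' @param fix_mu optional fixed value for the Poisson mean mu (disables its
#'   Gamma update; used with `flat_likelihood` so the reference prior on t
#'   is exactly the truncated Poisson).
#' @return A `bammi_draws` object with per-iteration dimension `t`.
#' @export
bammi_rj <- function(data, prior = prior_spec("bammie"),
                     iterations = 5000L, burn_in = 1000L, thin = 1L,
                     seed = 1L, t_start = 0L, flat_likelihood = FALSE,
                     fix_mu = NULL, pilot = FALSE) {
  stopifnot(inherits(data, "trial_data"), inherits(prior, "prior_spec"),
            iterations > burn_in, burn_in >= 0, thin >= 1)
  ctx <- fit_context(data)
  t_max <- prior$t_max
  if (is.null(t_max)) t_max <- min(ctx$g, ctx$e) - 1L
  set.seed(as.integer(seed))
  if (pilot) {
    # the pilot needs at least the Raftery-Lewis minimum run length
    pf <- bammi_gibbs(data, prior, t = min(2L, t_max), iterations = 4000L,
                      burn_in = 0L, thin = 1L, seed = seed + 1L)
    rl <- try(raftery_lewis(pf$sigma2_e), silent = TRUE)
    if (!inherits(rl, "try-error")) {
      burn_in <- max(burn_in, ceiling(rl$M))
      thin <- max(thin, rl$k)
      # retain at least the Raftery-Lewis minimum run length
      iterations <- max(iterations, burn_in + 3800L * thin)
    }
    set.seed(as.integer(seed))
  }
  state <- init_state(ctx, t_start, prior)
  if (!is.null(fix_mu)) state$mu <- fix_mu
  S <- (iterations - burn_in) %/% thin
  st_beta <- matrix(NA_real_, S, ctx$nc, dimnames = list(NULL, ctx$block_cells))
  st_g <- matrix(NA_real_, S, ctx$g, dimnames = list(NULL, ctx$genotypes))
  st_lambda <- matrix(NA_real_, S, t_max)
  st_s2l <- matrix(NA_real_, S, t_max)
  st_alpha <- array(NA_real_, c(S, ctx$g, t_max))
  st_gamma <- array(NA_real_, c(S, ctx$e, t_max))
  st_s2g <- numeric(S); st_s2e <- numeric(S); st_mu <- numeric(S)
  st_t <- integer(S); st_ll <- numeric(S)
  acc <- c(add = 0L, delete = 0L); prop <- c(add = 0L, delete = 0L)
  s <- 0L
  for (it in seq_len(iterations)) {
    sw <- rj_sweep(state, ctx, spec = prior, t_max = t_max,
                   flat_likelihood = flat_likelihood, fix_mu = fix_mu)
    state <- sw$state
    mv <- sw$outcome$move
    if (mv %in% c("add", "delete")) {
      prop[mv] <- prop[mv] + 1L
      if (sw$outcome$accepted) acc[mv] <- acc[mv] + 1L
    }
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
      st_ll[s] <- if (flat_likelihood) NA_real_ else loglik_ctx(state, ctx)
    }
  }
  st <- list(beta = st_beta, g = st_g, lambda = st_lambda,
             sigma2_lambda = st_s2l, alpha = st_alpha, gamma = st_gamma,
             sigma2_g = st_s2g, sigma2_e = st_s2e, mu = st_mu, t = st_t,
             loglik = st_ll)
  st$t_max <- t_max; st$t_fixed <- NA_integer_; st$method <- "rjmcmc"
  st$prior <- prior; st$labels <- list(genotypes = ctx$genotypes,
                                       environments = ctx$environments,
                                       block_cells = ctx$block_cells,
                                       block_cell_env = ctx$block_cell_env)
  st$burn_in <- burn_in; st$thin <- thin; st$iterations <- iterations
  st$acceptance <- list(proposed = prop, accepted = acc)
  class(st) <- "bammi_draws"
  st
}

#' Visit-frequency table and modal dimension of a reversible-jump fit
#'
#' Counts the retained iterations spent at each dimension t; the selected
#' model is the dimension with the highest visit frequency (ties broken
#' toward the smaller dimension).
#'
#' @param draws a `bammi_draws` object from [bammi_rj].
#' @return A list with `table` (named counts over 0..t_max) and `modal_t`.
#' @export
visit_table <- function(draws) {
  stopifnot(inherits(draws, "bammi_draws"), length(draws$t) > 0)
  counts <- tabulate(draws$t + 1L, nbins = draws$t_max + 1L)
  names(counts) <- 0:draws$t_max
  list(table = counts, modal_t = as.integer(names(counts)[which.max(counts)]))
}
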