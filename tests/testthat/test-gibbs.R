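test_that("log-likelihood matches the zero-residual closed form and a loop oracle", {
  td <- tiny_trial()
  ctx <- bammi:::fit_context(td)
  state <- fixed_state(2, 2, 2, t = 0)
  y_fit <- state$beta[ctx$bi] + state$g_eff[ctx$gi]
  td0 <- trial_data(td$records$genotype, td$records$environment,
                    td$records$block, y_fit)
  expect_equal(ammi_loglik(state, td0), -2 * log(2 * pi))

  sim <- simulate_met_trial(seed = 8, g = 4, e = 3, r = 2, unstable1 = 1,
                            unstable2 = 2, stable = 3:4, pos_envs = 1)
  st2 <- fixed_state(4, 3, 6, t = 2, sigma2_e = 1.7)
  ll <- ammi_loglik(st2, sim$data)
  ctx2 <- bammi:::fit_context(sim$data)
  mu_r <- st2$beta[ctx2$bi] + st2$g_eff[ctx2$gi] +
    bammi:::bilinear_vector(st2$lambda, st2$alpha, st2$gamma, ctx2$gi, ctx2$ei)
  ll_loop <- sum(stats::dnorm(ctx2$y, mu_r, sqrt(st2$sigma2_e), log = TRUE))
  expect_equal(ll, ll_loop, tolerance = 1e-10)

  st3 <- st2; st3$sigma2_e <- 2 * st2$sigma2_e
  rss <- sum((ctx2$y - mu_r)^2)
  expect_equal(ammi_loglik(st3, sim$data) - ll,
               -ctx2$n / 2 * log(2) + rss / (2 * st2$sigma2_e) / 2,
               tolerance = 1e-10)
  st_bad <- st2; st_bad$sigma2_e <- -1
  expect_error(ammi_loglik(st_bad, sim$data), "positive")
})

test_that("every Gibbs conditional matches its conjugate closed form (PIT)", {
  # draw each conditional many times from a fixed conditioning state and
  # check probability-integral-transform uniformity against closed forms
  # computed independently through the design matrices
  sim <- simulate_met_trial(seed = 10, g = 4, e = 3, r = 2, unstable1 = 1,
                            unstable2 = 2, stable = 3:4, pos_envs = 1)
  td <- sim$data
  ctx <- bammi:::fit_context(td)
  dm <- build_designs(td)
  spec <- prior_spec("bammie")
  s0 <- fixed_state(td$g, td$e, length(td$block_cells), t = 1,
                    sigma2_e = 1.3, seed = 11)
  s0$sigma2_lambda <- 2.5
  s0$sigma2_g <- 1.8
  set.seed(12)
  N <- 1200
  u_beta <- u_g <- u_lam <- u_s2l <- u_s2g <- u_s2e <- u_mu <- numeric(N)
  y <- ctx$y
  bil0 <- drop(diag(drop(dm$Z %*% s0$alpha[, 1])) %*% dm$X2 %*% s0$gamma[, 1]) *
    s0$lambda[1]
  for (i in seq_len(N)) {
    out <- bammi:::gibbs_sweep(s0, ctx, spec)
    # beta | g, axes, sigma2_e  (flat prior, block-cell means)
    A1 <- y - drop(dm$Z %*% s0$g_eff) - bil0
    mb <- solve(crossprod(dm$X1), crossprod(dm$X1, A1))
    sb <- sqrt(s0$sigma2_e / diag(crossprod(dm$X1)))
    u_beta[i] <- stats::pnorm(out$beta[1], mb[1], sb[1])
    # g | new beta, axes, sigma2_e, sigma2_g (ridge form)
    A2 <- y - drop(dm$X1 %*% out$beta) - bil0
    K <- crossprod(dm$Z) + diag(s0$sigma2_e / s0$sigma2_g, td$g)
    mg <- solve(K, crossprod(dm$Z, A2))
    sg <- sqrt(s0$sigma2_e * diag(solve(K)))
    u_g[i] <- stats::pnorm(out$g_eff[2], mg[2], sg[2])
    # lambda_1 | ... truncated normal on (0, Inf)
    resid <- y - drop(dm$X1 %*% out$beta) - drop(dm$Z %*% out$g_eff)
    phi <- drop(diag(drop(dm$Z %*% s0$alpha[, 1])) %*% dm$X2 %*% s0$gamma[, 1])
    prec <- sum(phi^2) + s0$sigma2_e / s0$sigma2_lambda[1]
    ml <- sum(phi * resid) / prec
    sl <- sqrt(s0$sigma2_e / prec)
    u_lam[i] <- (stats::pnorm(out$lambda[1], ml, sl) - stats::pnorm(0, ml, sl)) /
      (1 - stats::pnorm(0, ml, sl))
    # sigma2_lambda | lambda: inverse-gamma(a + 1/2, lambda^2/2)
    u_s2l[i] <- 1 - stats::pgamma(1 / out$sigma2_lambda[1],
                                  spec$bammie_a + 0.5,
                                  rate = out$lambda[1]^2 / 2)
    # sigma2_g | g: inverse-gamma(g/2, g'g/2)
    u_s2g[i] <- 1 - stats::pgamma(1 / out$sigma2_g, td$g / 2,
                                  rate = sum(out$g_eff^2) / 2)
    # sigma2_e | all: inverse-gamma(n/2, RSS/2)
    bil_out <- drop(diag(drop(dm$Z %*% out$alpha[, 1])) %*% dm$X2 %*%
                      out$gamma[, 1]) * out$lambda[1]
    rss <- sum((y - drop(dm$X1 %*% out$beta) - drop(dm$Z %*% out$g_eff) -
                  bil_out)^2)
    u_s2e[i] <- 1 - stats::pgamma(1 / out$sigma2_e, ctx$n / 2, rate = rss / 2)
    # mu | t: Gamma(tau + t, upsilon + 1)
    u_mu[i] <- stats::pgamma(out$mu, spec$tau + s0$t, rate = spec$upsilon + 1)
  }
  for (u in list(u_beta, u_g, u_lam, u_s2l, u_s2g, u_s2e, u_mu)) {
    expect_lt(abs(mean(u) - 0.5), 3 / sqrt(12 * N))
    expect_gt(suppressWarnings(stats::ks.test(u, "punif"))$p.value, 1e-3)
  }
})

test_that("an additive fit recovers genotype effects and a planted axis is found", {
  sim <- simulate_planted_trial(c(10), seed = 13, g = 10, e = 6, r = 2,
                                sigma2_e = 0.1)
  fit <- bammi_gibbs(sim$data, prior_spec("bammi"), t = 1,
                     iterations = 800, burn_in = 300, seed = 14)
  expect_gt(cor(colMeans(fit$g), sim$truth$g_eff), 0.95)
  # planted direction recovered up to sign
  a_hat <- colMeans(align_signs(fit, 1)$alpha[, , 1])
  expect_gt(abs(sum(a_hat * sim$truth$U[, 1])), 0.99)
  expect_lt(abs(mean(fit$lambda[, 1]) - 10) / 10, 0.15)
})

test_that("a dimension-zero fit runs and mu follows its conjugate law", {
  ad <- additive_trial(sd = 0.5, seed = 15)
  fit <- bammi_gibbs(ad$data, prior_spec("bammi"), t = 0,
                     iterations = 2500, burn_in = 500, seed = 16)
  expect_true(all(is.na(fit$lambda)))
  expect_gt(cor(colMeans(fit$g), ad$g_eff), 0.95)
  # t = 0: mu ~ Gamma(1, 2), mean 1/2, independent across sweeps
  expect_lt(abs(mean(fit$mu) - 0.5), 3 * 0.5 / sqrt(length(fit$mu)))
  expect_true(all(fit$sigma2_e > 0 & fit$sigma2_g > 0))
})

test_that("singular-value ordering is never violated within a fit", {
  sim <- simulate_met_trial(seed = 17, g = 8, e = 6, r = 2,
                            unstable1 = 1:2, unstable2 = 3:4, stable = 5:8,
                            pos_envs = 1:3)
  fit <- bammi_gibbs(sim$data, prior_spec("bammis"), t = 3,
                     iterations = 600, burn_in = 100, seed = 18)
  lam <- fit$lambda[, 1:3]
  expect_true(all(lam[, 1] >= lam[, 2] & lam[, 2] >= lam[, 3]))
  expect_true(all(lam > 0))
})

test_that("stored states keep orthonormality and centering constraints", {
  sim <- simulate_met_trial(seed = 19, g = 8, e = 6, r = 2,
                            unstable1 = 1:2, unstable2 = 3:4, stable = 5:8,
                            pos_envs = 1:3)
  fit <- bammi_gibbs(sim$data, prior_spec("bammi"), t = 2,
                     iterations = 400, burn_in = 100, seed = 20)
  worst <- 0
  for (s in seq(1, length(fit$t), by = 7)) {
    A <- fit$alpha[s, , 1:2]; G <- fit$gamma[s, , 1:2]
    worst <- max(worst,
                 abs(crossprod(A) - diag(2)), abs(crossprod(G) - diag(2)),
                 abs(colSums(A)), abs(colSums(G)))
  }
  expect_lt(worst, 1e-8)
})

test_that("the pilot option tightens burn-in and thinning when needed", {
  sim <- simulate_met_trial(seed = 21, g = 6, e = 5, r = 2,
                            unstable1 = 1:2, unstable2 = 3:4, stable = 5:6,
                            pos_envs = 1:2)
  fit <- bammi_gibbs(sim$data, prior_spec("bammi"), t = 1,
                     iterations = 1500, burn_in = 100, thin = 1, seed = 22,
                     pilot = TRUE)
  expect_gte(fit$burn_in, 100)
  expect_gte(fit$thin, 1)
  expect_gt(length(fit$t), 100)
})
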