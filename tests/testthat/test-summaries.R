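# build a synthetic draws object with known structure
fake_draws <- function(S = 400, g = 6, e = 5, t_max = 4, t_vec = NULL,
                       seed = 1) {
  set.seed(seed)
  if (is.null(t_vec)) t_vec <- rep(2L, S)
  U <- bammi:::centered_orthonormal(g, t_max)
  V <- bammi:::centered_orthonormal(e, t_max)
  alpha <- array(NA_real_, c(S, g, t_max))
  gamma <- array(NA_real_, c(S, e, t_max))
  lambda <- matrix(NA_real_, S, t_max)
  for (s in seq_len(S)) {
    t <- t_vec[s]
    if (t > 0) for (k in seq_len(t)) {
      sgn <- sample(c(-1, 1), 1)
      noise <- rnorm(g, 0, 0.05)
      a <- U[, k] + noise; a <- a - mean(a); a <- a / sqrt(sum(a^2))
      alpha[s, , k] <- sgn * a
      b <- V[, k] + rnorm(e, 0, 0.05); b <- b - mean(b); b <- b / sqrt(sum(b^2))
      gamma[s, , k] <- sgn * b
      lambda[s, k] <- max(0.1, 5 - k + rnorm(1, 0, 0.2))
    }
  }
  structure(list(
    beta = matrix(rnorm(S * e), S, e,
                  dimnames = list(NULL, paste0("E", 1:e, ":B1"))),
    g = matrix(rnorm(S * g), S, g, dimnames = list(NULL, paste0("G", 1:g))),
    lambda = lambda, sigma2_lambda = lambda,
    alpha = alpha, gamma = gamma,
    sigma2_g = rexp(S) + 0.5, sigma2_e = rexp(S) + 0.5,
    mu = rexp(S), t = as.integer(t_vec), loglik = rnorm(S),
    t_max = t_max, t_fixed = NA_integer_, method = "rjmcmc",
    prior = prior_spec("bammi"),
    labels = list(genotypes = paste0("G", 1:g),
                  environments = paste0("E", 1:e),
                  block_cells = paste0("E", 1:e, ":B1"),
                  block_cell_env = 1:e),
    burn_in = 0, thin = 1, iterations = S), class = "bammi_draws")
}

test_that("split_draws separates conditional and marginal sets", {
  d <- fake_draws(t_vec = rep(c(1L, 2L, 3L), length.out = 300), S = 300)
  sp <- split_draws(d, 2)
  expect_true(all(sp$conditional$t == 2))
  expect_true(all(sp$marginal$t == 2))  # truncated to the first 2 axes
  expect_lte(length(sp$conditional$t), length(sp$marginal$t))
  expect_true(all(is.na(sp$marginal$lambda[, 3])))
  expect_error(split_draws(d, 4), "no retained iteration")

  d3 <- fake_draws(t_vec = rep(3L, 100), S = 100)
  sp3 <- split_draws(d3, 3)
  expect_equal(length(sp3$conditional$t), length(sp3$marginal$t))
})

test_that("sign alignment is idempotent, flip-invariant and tightens means", {
  d <- fake_draws(S = 300)
  al <- align_signs(d, 2)
  al2 <- align_signs(al, 2)
  expect_equal(al$alpha, al2$alpha)
  # flipping every iteration's signs gives the same aligned draws
  fl <- d
  fl$alpha <- -fl$alpha; fl$gamma <- -fl$gamma
  alf <- align_signs(fl, 2)
  expect_equal(abs(alf$alpha), abs(al$alpha), tolerance = 1e-12)
  # aligned per-coordinate means dominate the unaligned ones in norm
  m_raw <- sqrt(sum(colMeans(d$alpha[, , 1])^2))
  m_al <- sqrt(sum(colMeans(al$alpha[, , 1])^2))
  expect_gt(m_al, m_raw)
  expect_gt(m_al, 0.9)
})

test_that("orthonormalization returns exact orthonormal, stable results", {
  set.seed(2)
  U <- bammi:::centered_orthonormal(8, 2)
  V <- bammi:::centered_orthonormal(6, 2)
  o <- orthonormalize_uv(U, V)
  expect_equal(o$U, U, tolerance = 1e-10)
  pert <- matrix(rnorm(16, 0, 1e-3), 8, 2)
  pert <- sweep(pert, 2, colMeans(pert))   # centered perturbation
  Up <- U + pert
  o2 <- orthonormalize_uv(Up, V)
  expect_equal(crossprod(o2$U), diag(2), tolerance = 1e-12)
  expect_lt(max(abs(o2$U - U)), 1e-2)
  expect_lt(max(abs(colSums(o2$U))), 1e-6)
  expect_error(orthonormalize_uv(cbind(U[, 1], U[, 1]), V), "rank")
})

test_that("hpd matches the normal closed form and beats equal tails", {
  set.seed(3)
  x <- rnorm(2e4)
  h <- hpd(x, 0.95)
  expect_equal(h$lower, -1.96, tolerance = 0.06)
  expect_equal(h$upper, 1.96, tolerance = 0.06)
  y <- rexp(2e4)
  he <- hpd(y, 0.9)
  eq <- unname(diff(quantile(y, c(0.05, 0.95))))
  expect_lt(he$upper - he$lower, eq)
  expect_gte(mean(y >= he$lower & y <= he$upper), 0.9 - 0.01)
  hc <- hpd(rep(3, 100), 0.95)
  expect_equal(c(hc$lower, hc$upper), c(3, 3))
  expect_error(hpd(x, 1.2), "prob")
})

test_that("biplot regions include or exclude the origin as constructed", {
  d <- fake_draws(S = 400, seed = 4)
  al <- align_signs(d, 2)
  bp <- biplot_regions(al, 0.95)
  expect_equal(crossprod(bp$U), diag(2), tolerance = 1e-8)
  # scores concentrated away from zero exclude the origin
  far <- which(abs(bp$centers[, 1]) > 0.3)
  expect_true(all(!bp$origin_in[far]))
  # ellipse coverage of fresh draws from the same law ~ prob
  ctr <- c(0.3, 0.3); cv <- matrix(c(0.01, 0.002, 0.002, 0.02), 2)
  ch <- chol(cv)
  set.seed(5)
  pts <- sweep(matrix(rnorm(4000), ncol = 2) %*% ch, 2, ctr, "+")
  d2 <- mahalanobis(pts, ctr, cv)
  expect_lt(abs(mean(d2 <= qchisq(0.95, 2)) - 0.95), 0.02)
  expect_error(biplot_regions(fake_draws(t_vec = rep(1L, 100), S = 100)),
               "t >= 2")
})

test_that("stability labels follow origin inclusion and are sign-invariant", {
  d <- fake_draws(S = 300, seed = 6)
  al <- align_signs(d, 2)
  bp <- biplot_regions(al, 0.95)
  lab <- classify_stability(bp)
  expect_equal(lab$label == "stable", unname(bp$origin_in))
  fl <- d; fl$alpha <- -fl$alpha; fl$gamma <- -fl$gamma
  bp2 <- biplot_regions(align_signs(fl, 2), 0.95)
  expect_equal(classify_stability(bp2)$label, lab$label)
})

test_that("simulated unstable genotypes are flagged by the biplot regions", {
  sim <- simulate_met_trial(seed = 30)
  fit <- bammi_gibbs(sim$data, prior_spec("bammi"), t = 2,
                     iterations = 900, burn_in = 300, seed = 31)
  bp <- biplot_regions(align_signs(fit, 2), 0.95)
  lab <- classify_stability(bp)
  glab <- lab[lab$kind == "genotype", ]
  truth <- sim$truth$stability[glab$entity]
  agree <- mean((glab$label == "stable") == (truth == "stable"))
  expect_gte(agree, 0.8)
})
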