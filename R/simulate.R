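#' Simulate a structured multi-environment trial
#'
#' Generates a randomized-complete-block multi-environment trial with the
#' default study design used throughout the package's tests: 20 genotypes,
#' 9 environments, 3 replicates. Genotype effects are N(0, 12), environment
#' effects N(0, 1), and the genotype-by-environment interaction has three
#' subgroups: genotypes 1-5 receive +|N(0, 16)| effects in environments 1-4
#' and -|N(0, 16)| in environments 5-9; genotypes 6-10 have the mirrored
#' sign pattern; genotypes 11-20 ("stable") receive N(0, 1) effects. The
#' interaction matrix is double-centered before use, block effects are
#' exactly zero, and plot errors are N(0, 2.5). All N(a, b) are
#' mean/variance.
#'
#' @param seed integer seed for the simulation.
#' @param g,e,r numbers of genotypes, environments and replicates.
#' @param sigma2_g,sigma2_env,sigma2_e variances of genotype effects,
#'   environment effects and plot errors.
#' @param unstable1,unstable2,stable genotype index vectors for the two
#'   opposite-signed interaction subgroups and the stable subgroup.
#' @param pos_envs environments in which subgroup 1 has positive effects
#'   (subgroup 2 is mirrored); the remaining environments get the opposite
#'   sign.
#' @param sigma2_gei,sigma2_stable interaction variances of the signed
#'   subgroups and the stable subgroup.
#' @param ge a g x e matrix of interaction effects to use instead of the
#'   subgroup mechanism (it is double-centered); used for planted-rank
#'   studies.
#' @return A list with `data` (a [trial_data]) and `truth` (genotype and
#'   environment effects, the centered interaction matrix `ge`, the error
#'   variance, and per-genotype `stability` labels).
#' @export
simulate_met_trial <- function(seed = 1L, g = 20L, e = 9L, r = 3L,
                               sigma2_g = 12, sigma2_env = 1, sigma2_e = 2.5,
                               unstable1 = 1:5, unstable2 = 6:10,
                               stable = 11:20, pos_envs = 1:4,
                               sigma2_gei = 16, sigma2_stable = 1,
                               ge = NULL) {
  if (is.null(ge) && max(c(unstable1, unstable2, stable, 0)) > g)
    stop("subgroup indices exceed the number of genotypes", call. = FALSE)
  set.seed(as.integer(seed))
  g_eff <- stats::rnorm(g, 0, sqrt(sigma2_g))
  e_eff <- stats::rnorm(e, 0, sqrt(sigma2_env))
  if (is.null(ge)) {
    ge <- matrix(0, g, e)
    neg_envs <- setdiff(seq_len(e), pos_envs)
    if (sigma2_gei > 0 && length(unstable1)) {
      for (i in unstable1) {
        v <- abs(stats::rnorm(e, 0, sqrt(sigma2_gei)))
        v[neg_envs] <- -v[neg_envs]
        ge[i, ] <- v
      }
      for (i in unstable2) {
        v <- abs(stats::rnorm(e, 0, sqrt(sigma2_gei)))
        v[pos_envs] <- -v[pos_envs]
        ge[i, ] <- v
      }
    }
    if (sigma2_stable > 0 && length(stable))
      ge[stable, ] <- stats::rnorm(length(stable) * e, 0, sqrt(sigma2_stable))
    stability <- rep("stable", g)
    stability[c(unstable1, unstable2)] <- "unstable"
  } else {
    stopifnot(nrow(ge) == g, ncol(ge) == e)
    stability <- rep(NA_character_, g)
  }
  ge <- double_center(ge)
  glab <- sprintf("G%02d", seq_len(g))
  elab <- sprintf("E%d", seq_len(e))
  gi <- rep(rep(seq_len(g), times = e), times = r)
  ei <- rep(rep(seq_len(e), each = g), times = r)
  bl <- rep(seq_len(r), each = g * e)
  y <- g_eff[gi] + e_eff[ei] + ge[cbind(gi, ei)] +
    stats::rnorm(g * e * r, 0, sqrt(sigma2_e))
  list(data = trial_data(glab[gi], elab[ei], paste0("B", bl), y),
       truth = list(g_eff = stats::setNames(g_eff, glab),
                    e_eff = stats::setNames(e_eff, elab),
                    ge = `dimnames<-`(ge, list(glab, elab)),
                    sigma2_e = sigma2_e,
                    stability = stats::setNames(stability, glab)))
}

#' Simulate a trial with an exactly low-rank interaction
#'
#' Builds a planted-rank interaction matrix lambda_1 u1 v1' + ... with
#' centered orthonormal singular vectors, then simulates a balanced trial
#' around it via [simulate_met_trial]. Useful for recovery studies where
#' the true singular values must be known exactly.
#'
#' @param lambdas true singular values, decreasing.
#' @param seed integer seed.
#' @param g,e,r trial dimensions.
#' @param sigma2_e error variance.
#' @inherit simulate_met_trial return
#' @export
simulate_planted_trial <- function(lambdas, seed = 1L, g = 20L, e = 9L, r = 3L,
                                   sigma2_e = 2.5) {
  t <- length(lambdas)
  stopifnot(t >= 1, t <= min(g, e) - 1, !is.unsorted(rev(lambdas)))
  set.seed(as.integer(seed) + 777L)
  # centered orthonormal score matrices via QR against the ones vector
  U <- centered_orthonormal(g, t)
  V <- centered_orthonormal(e, t)
  ge <- U %*% diag(lambdas, t) %*% t(V)
  sim <- simulate_met_trial(seed = seed, g = g, e = e, r = r,
                            sigma2_e = sigma2_e, ge = ge)
  sim$truth$lambdas <- lambdas
  sim$truth$U <- U
  sim$truth$V <- V
  sim
}

# random d x t matrix with orthonormal columns orthogonal to the ones vector
centered_orthonormal <- function(d, t) {
  m <- cbind(rep(1, d) / sqrt(d), matrix(stats::rnorm(d * t), d, t))
  q <- qr.Q(qr(m))[, -1, drop = FALSE]
  q
}

#' Singular-value truth summary of a simulated interaction
#'
#' Decomposes the true (double-centered) interaction matrix by SVD and
#' reports the ordered singular values, the cumulative interaction sum of
#' squares by dimension and the total. The sum-of-squares convention is
#' SS = sum(lambda_k^2) on the cell-mean scale: the replicate count is not
#' folded in, matching the convention used for model estimates.
#'
#' @param ge the true g x e double-centered interaction matrix (or a
#'   `truth` list from the simulators).
#' @return A list with `lambdas`, `ss_per_dim` (cumulative), `ss_total`.
#' @export
svd_truth <- function(ge) {
  if (is.list(ge)) ge <- ge$ge
  sv <- svd(ge)$d
  tmax <- min(nrow(ge), ncol(ge)) - 1L
  sv <- sv[seq_len(tmax)]
  list(lambdas = sv, ss_per_dim = cumsum(sv^2), ss_total = sum(sv^2))
}
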