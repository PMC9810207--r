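#' Prior specification for a Bayesian AMMI model
#'
#' The three model families differ only in the prior on the scale
#' sigma2_lambda_k of the truncated-normal N+(0, sigma2_lambda_k) prior on
#' each singular value:
#' \describe{
#'   \item{`"bammi"`}{sigma2_lambda fixed at a large constant (flat,
#'     non-informative).}
#'   \item{`"bammis"`}{Jeffreys-type shrinkage: p(s2) proportional to
#'     s2^(delta - 1) with 0 < delta < 1/2 (scaled inverse chi-square with
#'     zero scale), giving a posterior that shrinks small singular values.}
#'   \item{`"bammie"`}{maximum-entropy inverse-gamma prior with shape `a`
#'     (default 1) and scale `b` (default 0).}
#' }
#' The number of bilinear axes `t` has a truncated Poisson(mu) prior on
#' 0..t_max, and mu has a Gamma(tau, upsilon) hyperprior. `pa`, `pd`, `p0`
#' are the probabilities of proposing an axis addition, an axis deletion,
#' or no dimension change in each reversible-jump sweep.
#'
#' @param hypothesis one of "bammi", "bammis", "bammie".
#' @param sigma2_beta flat-prior variance for block effects (unused by the
#'   sampler, which integrates the flat limit; kept for completeness).
#' @param bammi_sigma2_lambda the fixed sigma2_lambda under "bammi".
#' @param bammis_delta exponent delta in (0, 1/2) for "bammis".
#' @param bammie_a,bammie_b inverse-gamma shape and scale for "bammie".
#' @param tau,upsilon Gamma hyperprior on mu (shape, rate), both default 1.
#' @param pa,pd,p0 reversible-jump move probabilities, summing to 1.
#' @param t_max maximum number of bilinear axes (default min(g, e) - 1 is
#'   filled in at fit time when NULL).
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(hypothesis = c("bammi", "bammis", "bammie"),
                       sigma2_beta = 1e8, bammi_sigma2_lambda = 1e8,
                       bammis_delta = 1 / 4, bammie_a = 1, bammie_b = 0,
                       tau = 1, upsilon = 1,
                       pa = 1 / 3, pd = 1 / 3, p0 = 1 / 3, t_max = NULL) {
  hypothesis <- match.arg(hypothesis)
  if (hypothesis == "bammis" && (bammis_delta <= 0 || bammis_delta >= 1 / 2))
    stop("bammis_delta must lie in (0, 1/2)", call. = FALSE)
  if (abs(pa + pd + p0 - 1) > 1e-10)
    stop("pa + pd + p0 must equal 1", call. = FALSE)
  stopifnot(sigma2_beta > 0, bammi_sigma2_lambda > 0, bammie_a > 0,
            bammie_b >= 0, tau > 0, upsilon > 0, pa > 0, pd > 0, p0 > 0)
  structure(list(hypothesis = hypothesis, sigma2_beta = sigma2_beta,
                 bammi_sigma2_lambda = bammi_sigma2_lambda,
                 bammis_delta = bammis_delta,
                 bammie_a = bammie_a, bammie_b = bammie_b,
                 tau = tau, upsilon = upsilon,
                 pa = pa, pd = pd, p0 = p0, t_max = t_max),
            class = "prior_spec")
}

#' Conditional update of the singular-value scale sigma2_lambda_k
#'
#' Draws sigma2_lambda_k from its full conditional given the current
#' singular value lambda_k, under the family's prior:
#' "bammi" returns the fixed constant; "bammis" draws from
#' inverse-gamma(1/2 - delta, lambda_k^2 / 2) (the conjugate update of the
#' s2^(delta - 1) prior against the zero-mean truncated-normal likelihood);
#' "bammie" draws from the conjugate inverse-gamma(a + 1/2, b + lambda_k^2 / 2).
#'
#' @param spec a [prior_spec].
#' @param lambda_k current singular value (> 0).
#' @return A positive scalar draw.
#' @export
update_sigma2_lambda <- function(spec, lambda_k) {
  stopifnot(inherits(spec, "prior_spec"), lambda_k >= 0)
  out <- switch(spec$hypothesis,
    bammi = spec$bammi_sigma2_lambda,
    bammis = 1 / stats::rgamma(1, shape = 1 / 2 - spec$bammis_delta,
                               rate = max(lambda_k^2 / 2, 1e-300)),
    bammie = 1 / stats::rgamma(1, shape = spec$bammie_a + 1 / 2,
                               rate = max(spec$bammie_b + lambda_k^2 / 2,
                                          1e-300)),
    stop("unknown hypothesis: ", spec$hypothesis, call. = FALSE))
  # keep the scale representable under extreme shrinkage or heavy tails
  min(max(out, 1e-300), 1e12)
}

#' Log prior mass of the number of bilinear axes
#'
#' Log pmf of a Poisson(mu) distribution truncated and renormalized to
#' {0, ..., t_max}.
#'
#' @param t number of axes (integer in 0..t_max).
#' @param mu Poisson mean (> 0).
#' @param t_max upper truncation point.
#' @return The log probability.
#' @export
log_prior_t <- function(t, mu, t_max) {
  if (t < 0 || t > t_max) stop("t outside 0..t_max", call. = FALSE)
  lp <- stats::dpois(0:t_max, mu, log = TRUE)
  lp[t + 1] - log(sum(exp(lp - max(lp)))) - max(lp)
}
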