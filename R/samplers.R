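#' Draw from a truncated normal distribution
#'
#' Samples from N(mean, sd^2) restricted to (lower, upper). Uses the
#' inverse-CDF method in the central region and Robert's exponential
#' rejection sampler when the interval lies far in a tail, so draws remain
#' correct at standardized bounds beyond ~8 sd where pnorm underflows.
#'
#' @param n number of draws.
#' @param mean,sd location and scale of the untruncated normal.
#' @param lower,upper truncation bounds (may be infinite).
#' @return A numeric vector of `n` draws in (lower, upper).
#' @export
rtnorm <- function(n, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  if (any(sd <= 0)) stop("sd must be positive", call. = FALSE)
  if (any(lower >= upper)) stop("lower must be < upper", call. = FALSE)
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  z <- vapply(seq_len(n), function(i) {
    ai <- a[min(i, length(a))]; bi <- b[min(i, length(b))]
    rtnorm_std1(ai, bi)
  }, numeric(1))
  # clamp against floating-point cancellation at the bounds
  pmin(pmax(mean + sd * z, lower), upper)
}

# one standard-normal draw truncated to (a, b)
rtnorm_std1 <- function(a, b) {
  # interval so narrow the density is locally constant: uniform is exact
  # to first order (also catches intervals far beyond double precision)
  if (is.finite(a) && is.finite(b) &&
      (b - a) * (abs(a) + 1) < 1e-10)
    return(a + (b - a) * stats::runif(1))
  if (a > 0) return(rtnorm_lower(a, b))     # right tail
  if (b < 0) return(-rtnorm_lower(-b, -a))  # left tail, reflect
  # interval straddles 0: inverse CDF is safe
  pa <- stats::pnorm(a); pb <- stats::pnorm(b)
  stats::qnorm(stats::runif(1, pa, pb))
}

# standard normal truncated to (a, b), 0 <= a < b
rtnorm_lower <- function(a, b) {
  if (a < 4) {
    pa <- stats::pnorm(a); pb <- stats::pnorm(b)
    if (pb - pa > 1e-12) return(stats::qnorm(stats::runif(1, pa, pb)))
  }
  # Robert (1995) shifted-exponential rejection for the far tail
  alpha <- (a + sqrt(a^2 + 4)) / 2
  for (i in 1:10000) {
    x <- a + stats::rexp(1, alpha)
    if (x > b) next
    if (stats::runif(1) <= exp(-(x - alpha)^2 / 2)) return(x)
  }
  # acceptance numerically zero: the mass is squeezed against a
  a + (b - a) * stats::runif(1) * .Machine$double.eps
}

#' Draw from the von Mises-Fisher distribution
#'
#' Samples unit vectors with density proportional to exp(kappa * m'x) on
#' the (d-1)-sphere, via the tangent-normal decomposition with Wood's
#' (1994) beta-envelope rejection for the cosine component. `kappa = 0`
#' returns a uniform draw on the sphere.
#'
#' @param direction mean direction (unit vector, any dimension >= 1).
#' @param kappa concentration parameter, >= 0.
#' @return A unit vector of the same dimension as `direction`.
#' @export
rvmf <- function(direction, kappa) {
  d <- length(direction)
  if (kappa < 0) stop("kappa must be >= 0", call. = FALSE)
  if (kappa == 0) {
    x <- stats::rnorm(d)
    return(x / sqrt(sum(x^2)))
  }
  nrm <- sqrt(sum(direction^2))
  if (nrm < 1e-12) stop("zero-length direction with kappa > 0", call. = FALSE)
  m <- direction / nrm
  if (d == 1) {
    # sphere in 1 dimension is {-1, 1}; P(x = +1) under exp(kappa * m * x)
    p <- 1 / (1 + exp(-2 * kappa * m))
    return(if (stats::runif(1) < p) 1 else -1)
  }
  w <- rvmf_cosine(d, kappa)
  # uniform tangent on the (d-2)-sphere orthogonal to m
  v <- stats::rnorm(d)
  v <- v - sum(v * m) * m
  vn <- sqrt(sum(v^2))
  if (vn < 1e-12) { v <- rvmf_tangent_fallback(m); vn <- 1 }
  x <- w * m + sqrt(max(0, 1 - w^2)) * v / vn
  x / sqrt(sum(x^2))
}

rvmf_tangent_fallback <- function(m) {
  d <- length(m)
  repeat {
    v <- stats::rnorm(d)
    v <- v - sum(v * m) * m
    vn <- sqrt(sum(v^2))
    if (vn > 1e-12) return(v / vn)
  }
}

# Wood (1994) rejection sampler for w = cos(angle) in dimension d >= 2
rvmf_cosine <- function(d, kappa) {
  p1 <- d - 1
  # stable form of (-2k + sqrt(4k^2 + p1^2))/p1 for large kappa
  b <- p1 / (2 * kappa + sqrt(4 * kappa^2 + p1^2))
  x0 <- (1 - b) / (1 + b)
  c0 <- kappa * x0 + p1 * log(1 - x0^2)
  repeat {
    z <- stats::rbeta(1, p1 / 2, p1 / 2)
    w <- (1 - (1 + b) * z) / (1 - (1 - b) * z)
    u <- stats::runif(1)
    if (kappa * w + p1 * log(1 - x0 * w) - c0 >= log(u)) return(w)
  }
}

#' Orthogonal complement of a set of orthonormal constraint vectors
#'
#' @param basis a d x m matrix with orthonormal columns (the forbidden
#'   directions), or NULL for no constraint.
#' @param d the ambient dimension (required when `basis` is NULL).
#' @return A d x (d - m) matrix whose columns are an orthonormal basis of
#'   the orthogonal complement of span(basis).
#' @export
null_complement <- function(basis, d = nrow(basis)) {
  if (is.null(basis) || ncol(basis) == 0L) return(diag(d))
  qr_ <- qr(basis)
  qr.Q(qr_, complete = TRUE)[, -seq_len(ncol(basis)), drop = FALSE]
}

#' Draw a von Mises-Fisher vector inside a constraint subspace
#'
#' Projects the (unnormalized) natural-parameter vector onto the orthogonal
#' complement of the constraint basis, draws a von Mises-Fisher vector in
#' complement coordinates with concentration `kappa_scale` times the norm
#' of the projected vector, and maps it back. The result has unit norm and
#' is orthogonal to every constraint vector. If the projection is
#' numerically zero the draw is uniform in the complement.
#'
#' @param raw_direction the unnormalized linear coefficient vector (length d).
#' @param kappa_scale nonnegative multiplier (e.g. lambda_k / sigma_e^2).
#' @param basis d x m matrix of orthonormal forbidden directions (the ones
#'   vector and the other singular vectors of the same side), or NULL.
#' @return A unit d-vector orthogonal to `basis`.
#' @export
rvmf_subspace <- function(raw_direction, kappa_scale, basis = NULL) {
  d <- length(raw_direction)
  N <- null_complement(basis, d)
  ctil <- drop(crossprod(N, raw_direction))
  nrm <- sqrt(sum(ctil^2))
  kappa <- kappa_scale * nrm
  z <- if (nrm < 1e-12 || kappa == 0) {
    zz <- stats::rnorm(ncol(N)); zz / sqrt(sum(zz^2))
  } else {
    rvmf(ctil / nrm, kappa)
  }
  drop(N %*% z)
}
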