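# Subset a draws object to iterations idx, optionally truncating the
# stored axes to the first t_keep.
subset_draws <- function(draws, idx, t_keep = NULL) {
  out <- draws
  out$beta <- draws$beta[idx, , drop = FALSE]
  out$g <- draws$g[idx, , drop = FALSE]
  out$lambda <- draws$lambda[idx, , drop = FALSE]
  out$sigma2_lambda <- draws$sigma2_lambda[idx, , drop = FALSE]
  out$alpha <- draws$alpha[idx, , , drop = FALSE]
  out$gamma <- draws$gamma[idx, , , drop = FALSE]
  out$sigma2_g <- draws$sigma2_g[idx]
  out$sigma2_e <- draws$sigma2_e[idx]
  out$mu <- draws$mu[idx]
  out$t <- draws$t[idx]
  out$loglik <- draws$loglik[idx]
  if (!is.null(t_keep)) {
    out$lambda[, seq_len(ncol(out$lambda)) > t_keep] <- NA_real_
    out$alpha[, , seq_len(dim(out$alpha)[3]) > t_keep] <- NA_real_
    out$gamma[, , seq_len(dim(out$gamma)[3]) > t_keep] <- NA_real_
    out$t <- pmin(out$t, t_keep)
  }
  out
}

#' Conditional and marginal draws at a selected dimension
#'
#' Splits a reversible-jump fit at the selected dimension `t_star`: the
#' conditional set keeps only iterations with t == t_star; the marginal set
#' keeps all iterations with t >= t_star, restricted to their first
#' `t_star` axes.
#'
#' @param draws a `bammi_draws` object.
#' @param t_star the selected number of axes (e.g. the modal dimension).
#' @return A list with `conditional` and `marginal` `bammi_draws`.
#' @export
split_draws <- function(draws, t_star) {
  stopifnot(inherits(draws, "bammi_draws"))
  if (!any(draws$t == t_star))
    stop("no retained iteration at t = ", t_star, call. = FALSE)
  list(conditional = subset_draws(draws, which(draws$t == t_star)),
       marginal = subset_draws(draws, which(draws$t >= t_star),
                               t_keep = t_star))
}

#' Align the signs of singular-vector draws
#'
#' Singular vectors are sign-indeterminate: (lambda, alpha, gamma) and
#' (lambda, -alpha, -gamma) give the same model. Before averaging, each
#' iteration's pair (alpha_k, gamma_k) is jointly negated when alpha_k has
#' negative inner product with a fixed reference (the first retained
#' iteration with axis k present). Idempotent; lambda is unchanged.
#'
#' @param draws a `bammi_draws` object.
#' @param t_star number of leading axes to align (default: all stored).
#' @return The draws object with aligned `alpha` and `gamma`.
#' @export
align_signs <- function(draws, t_star = draws$t_max) {
  stopifnot(inherits(draws, "bammi_draws"))
  for (k in seq_len(t_star)) {
    have <- which(draws$t >= k)
    if (!length(have)) next
    ref <- draws$alpha[have[1], , k]
    for (s in have) {
      if (sum(draws$alpha[s, , k] * ref) < 0) {
        draws$alpha[s, , k] <- -draws$alpha[s, , k]
        draws$gamma[s, , k] <- -draws$gamma[s, , k]
      }
    }
  }
  draws
}

#' Orthonormalize posterior-mean score matrices
#'
#' Posterior means of singular vectors are only approximately orthonormal;
#' this applies a QR-based correction with a positive-diagonal convention,
#' returning matrices U and V with exactly orthonormal columns that remain
#' centered (orthogonal to the ones vector up to the input's centering).
#'
#' @param mean_alphas g x t matrix of posterior-mean genotypic vectors.
#' @param mean_gammas e x t matrix of posterior-mean environmental vectors.
#' @return A list with orthonormalized `U` (g x t) and `V` (e x t).
#' @export
orthonormalize_uv <- function(mean_alphas, mean_gammas) {
  ortho <- function(m) {
    if (qr(m)$rank < ncol(m)) stop("rank-deficient score matrix", call. = FALSE)
    qr_ <- qr(m)
    q <- qr.Q(qr_); r <- qr.R(qr_)
    sgn <- sign(diag(r)); sgn[sgn == 0] <- 1
    sweep(q, 2, sgn, "*")
  }
  list(U = ortho(mean_alphas), V = ortho(mean_gammas))
}

#' Highest posterior density interval
#'
#' Shortest interval containing a given posterior mass, by the sorted
#' sliding-window (Chen-Shao) method.
#'
#' @param samples numeric vector of posterior draws (>= 50 for a stable
#'   interval; fewer raises an error).
#' @param prob credibility level in (0, 1), default 0.95.
#' @return A list with `lower`, `upper`, `prob`.
#' @export
hpd <- function(samples, prob = 0.95) {
  if (prob <= 0 || prob >= 1) stop("prob must be in (0,1)", call. = FALSE)
  samples <- sort(samples[is.finite(samples)])
  n <- length(samples)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  m <- max(1L, ceiling(prob * n))
  if (m >= n) return(list(lower = samples[1], upper = samples[n], prob = prob))
  widths <- samples[(m + 1):n] - samples[1:(n - m)]
  i <- which.min(widths)
  list(lower = samples[i], upper = samples[i + m], prob = prob)
}

#' Bivariate credibility regions for biplot scores
#'
#' For each genotype and each environment, the per-iteration pair of
#' first-two-axis scores yields a posterior mean and covariance; the
#' credibility region is the bivariate-normal ellipse whose squared
#' Mahalanobis radius is the chi-square(2) quantile at `prob` (Hu-Yang
#' construction from posterior score moments). An entity is flagged as
#' containing the origin when the origin's squared Mahalanobis distance
#' from the score mean is within that radius.
#'
#' @param draws a `bammi_draws` object, sign-aligned (see [align_signs]),
#'   typically the marginal or conditional set from [split_draws].
#' @param prob credibility level (default 0.95).
#' @param scale_lambda if TRUE, scores are scaled by sqrt(lambda_k) per
#'   iteration before summarizing (default FALSE: raw singular-vector
#'   coordinates).
#' @return An object of class `biplot_summary`: orthonormalized score
#'   means `U`, `V` (first two axes), per-entity `centers`, covariance
#'   list `covs`, `mahalanobis0` (squared distance of the origin),
#'   `origin_in` flags, `prob`, and an `entity` table.
#' @export
biplot_regions <- function(draws, prob = 0.95, scale_lambda = FALSE) {
  stopifnot(inherits(draws, "bammi_draws"))
  keep <- which(draws$t >= 2)
  if (length(keep) < 10)
    stop("need iterations with t >= 2 for bivariate regions; ",
         "use univariate HPD intervals instead", call. = FALSE)
  g <- dim(draws$alpha)[2]; e <- dim(draws$gamma)[2]
  sc1 <- if (scale_lambda) sqrt(draws$lambda[keep, 1]) else 1
  sc2 <- if (scale_lambda) sqrt(draws$lambda[keep, 2]) else 1
  entity_stats <- function(score1, score2) {
    ctr <- c(mean(score1), mean(score2))
    cv <- stats::cov(cbind(score1, score2))
    # guard against numerically singular covariances
    if (det(cv) <= 1e-300) cv <- cv + diag(1e-12, 2)
    d0 <- drop(t(ctr) %*% solve(cv, ctr))
    list(center = ctr, cov = cv, d0 = d0)
  }
  q2 <- stats::qchisq(prob, df = 2)
  res <- list()
  labs <- c(draws$labels$genotypes, draws$labels$environments)
  kind <- rep(c("genotype", "environment"), c(g, e))
  for (i in seq_len(g))
    res[[i]] <- entity_stats(sc1 * draws$alpha[keep, i, 1],
                             sc2 * draws$alpha[keep, i, 2])
  for (j in seq_len(e))
    res[[g + j]] <- entity_stats(sc1 * draws$gamma[keep, j, 1],
                                 sc2 * draws$gamma[keep, j, 2])
  centers <- do.call(rbind, lapply(res, `[[`, "center"))
  rownames(centers) <- labs
  d0 <- vapply(res, `[[`, numeric(1), "d0")
  uv <- orthonormalize_uv(
    cbind(colMeans(draws$alpha[keep, , 1]), colMeans(draws$alpha[keep, , 2])),
    cbind(colMeans(draws$gamma[keep, , 1]), colMeans(draws$gamma[keep, , 2])))
  structure(list(U = uv$U, V = uv$V, centers = centers,
                 covs = lapply(res, `[[`, "cov"),
                 mahalanobis0 = stats::setNames(d0, labs),
                 origin_in = stats::setNames(d0 <= q2, labs),
                 kind = stats::setNames(kind, labs), prob = prob),
            class = "biplot_summary")
}

#' Stability classification from biplot credibility regions
#'
#' A genotype (or environment) is classified stable when its bivariate
#' score credibility region contains the origin, i.e. it has no
#' significant contribution to the genotype-by-environment interaction.
#'
#' @param summary a `biplot_summary` from [biplot_regions].
#' @return A data frame with entity, kind, squared Mahalanobis distance of
#'   the origin and the stable/unstable label.
#' @export
classify_stability <- function(summary) {
  stopifnot(inherits(summary, "biplot_summary"))
  data.frame(entity = names(summary$origin_in),
             kind = unname(summary$kind),
             mahalanobis0 = unname(summary$mahalanobis0),
             label = ifelse(summary$origin_in, "stable", "unstable"),
             row.names = NULL, stringsAsFactors = FALSE)
}
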