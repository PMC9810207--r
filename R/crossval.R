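#' Fold plan for whole-cell cross-validation
#'
#' Randomly partitions the observed genotype-by-environment cells into `k`
#' folds; in each fold all records of the withheld cells (total loss of the
#' genotype within those environments) are removed from the training set.
#' The partition is rejection-resampled until every fold's training data
#' retains at least one record for every genotype and every environment.
#'
#' @param data a [trial_data] object.
#' @param fraction target fraction of cells withheld per fold (default 0.10).
#' @param k number of folds (default 10).
#' @param seed integer seed.
#' @return An object of class `fold_plan`: a list of k data frames of
#'   withheld (genotype, environment) label pairs, disjoint across folds.
#' @export
make_folds <- function(data, fraction = 0.10, k = 10L, seed = 1L) {
  stopifnot(inherits(data, "trial_data"))
  if (fraction <= 0 || fraction >= 1)
    stop("fraction must be in (0, 1)", call. = FALSE)
  cells <- unique(data.frame(gi = data$gi, ei = data$ei))
  ncell <- nrow(cells)
  per <- round(fraction * ncell)
  if (per < 1 || per * k > ncell)
    stop("cannot withhold ", per, " cells in each of ", k,
         " disjoint folds from ", ncell,
         " cells; use a smaller fraction or fewer folds", call. = FALSE)
  set.seed(as.integer(seed))
  ok <- FALSE
  for (try_ in 1:1000) {
    ord <- sample.int(ncell)
    folds <- lapply(seq_len(k), function(f)
      cells[ord[((f - 1) * per + 1):(f * per)], , drop = FALSE])
    ok <- all(vapply(folds, function(fd) {
      wkeep <- !(paste(data$gi, data$ei) %in% paste(fd$gi, fd$ei))
      length(unique(data$gi[wkeep])) == data$g &&
        length(unique(data$ei[wkeep])) == data$e
    }, logical(1)))
    if (ok) break
  }
  if (!ok) stop("could not satisfy the retention constraint; ",
                "use a smaller fraction", call. = FALSE)
  folds <- lapply(folds, function(fd)
    data.frame(genotype = data$genotypes[fd$gi],
               environment = data$environments[fd$ei],
               stringsAsFactors = FALSE))
  structure(list(folds = folds, fraction = fraction, k = k), class = "fold_plan")
}

#' Posterior-mean predictions for withheld cells
#'
#' Predicts the response of withheld genotype-by-environment cells from a
#' fit on the training data: for each retained iteration the prediction is
#' (environment-mean block effect) + genotype effect + bilinear
#' interaction, then averaged over iterations. For reversible-jump fits
#' every iteration uses its own dimension (marginal response).
#'
#' @param draws a `bammi_draws` from a fit on the training split.
#' @param cells data frame with `genotype` and `environment` label columns.
#' @return Numeric vector of predicted cell means, one per row of `cells`.
#' @export
predict_cells <- function(draws, cells) {
  stopifnot(inherits(draws, "bammi_draws"))
  gi <- match(cells$genotype, draws$labels$genotypes)
  ei <- match(cells$environment, draws$labels$environments)
  if (anyNA(gi) || anyNA(ei))
    stop("unseen genotype or environment in prediction cells", call. = FALSE)
  S <- length(draws$t)
  bce <- draws$labels$block_cell_env
  # S x e matrix of per-iteration environment-average block effects
  W <- 1 * outer(bce, seq_along(draws$labels$environments), "==")
  W <- sweep(W, 2, colSums(W), "/")
  env_beta <- draws$beta %*% W
  lam0 <- draws$lambda; lam0[is.na(lam0)] <- 0
  al0 <- draws$alpha; al0[is.na(al0)] <- 0
  ga0 <- draws$gamma; ga0[is.na(ga0)] <- 0
  vapply(seq_along(gi), function(c_) {
    bil <- rowSums(lam0 * al0[, gi[c_], ] * ga0[, ei[c_], ])
    mean(env_beta[, ei[c_]] + draws$g[, gi[c_]] + bil)
  }, numeric(1))
}

#' Predictive correlation and PRESS
#'
#' Cor is the Pearson correlation between observed and predicted values;
#' PRESS is the mean squared prediction error (the predicted residual sum
#' of squares divided by the number of validation records).
#'
#' @param observed,predicted numeric vectors of equal length >= 2.
#' @return A list with `cor` (NA if either vector has zero variance) and
#'   `press`.
#' @export
cv_metrics <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2)
  cr <- if (stats::sd(observed) == 0 || stats::sd(predicted) == 0) NA_real_
        else stats::cor(observed, predicted)
  list(cor = cr, press = mean((observed - predicted)^2))
}

#' K-fold predictive cross-validation under whole-cell loss
#'
#' Withholds whole genotype-by-environment cells per [make_folds], refits
#' the model on each training split and evaluates Cor and PRESS on the
#' withheld records.
#'
#' @param data a [trial_data].
#' @param prior a [prior_spec].
#' @param method "gibbs" (fixed dimension `t`) or "rj".
#' @param t the fixed dimension for `method = "gibbs"`.
#' @param fraction,k,seed fold-plan parameters (see [make_folds]).
#' @param iterations,burn_in,thin chain settings per fold (defaults are
#'   short: 800 sweeps with 200 burn-in).
#' @return A list of class `cv_result` with the per-fold metric table,
#'   `mean_cor`, `mean_press`, and pooled metrics over all folds.
#' @export
run_cv <- function(data, prior = prior_spec("bammi"),
                   method = c("gibbs", "rj"), t = 2L,
                   fraction = 0.10, k = 10L, seed = 1L,
                   iterations = 800L, burn_in = 200L, thin = 1L) {
  method <- match.arg(method)
  plan <- make_folds(data, fraction, k, seed)
  obs_all <- numeric(0); pred_all <- numeric(0)
  rows <- vector("list", plan$k)
  for (f in seq_len(plan$k)) {
    fd <- plan$folds[[f]]
    withheld <- paste(data$records$genotype, data$records$environment) %in%
      paste(fd$genotype, fd$environment)
    tr <- data$records[!withheld, ]
    te <- data$records[withheld, ]
    train <- trial_data(tr$genotype, tr$environment, tr$block, tr$response)
    fit <- try(switch(method,
      gibbs = bammi_gibbs(train, prior, t = t, iterations = iterations,
                          burn_in = burn_in, thin = thin, seed = seed + f),
      rj = bammi_rj(train, prior, iterations = iterations,
                    burn_in = burn_in, thin = thin, seed = seed + f,
                    t_start = min(2L, min(train$g, train$e) - 1L))),
      silent = TRUE)
    if (inherits(fit, "try-error")) {
      warning("fold ", f, " failed: ", attr(fit, "condition")$message)
      next
    }
    pred <- predict_cells(fit, te)
    m <- cv_metrics(te$response, pred)
    rows[[f]] <- data.frame(fold = f, n_validation = nrow(te),
                            cor = m$cor, press = m$press)
    obs_all <- c(obs_all, te$response); pred_all <- c(pred_all, pred)
  }
  per_fold <- do.call(rbind, rows)
  pooled <- cv_metrics(obs_all, pred_all)
  structure(list(per_fold = per_fold,
                 mean_cor = mean(per_fold$cor, na.rm = TRUE),
                 mean_press = mean(per_fold$press, na.rm = TRUE),
                 pooled_cor = pooled$cor, pooled_press = pooled$press,
                 method = method, t = if (method == "gibbs") t else NA_integer_,
                 hypothesis = prior$hypothesis),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("Cross-validation (", x$method,
      if (!is.na(x$t)) paste0(", t = ", x$t), ", ",
      toupper(x$hypothesis), "): mean Cor = ", round(x$mean_cor, 4),
      ", mean PRESS = ", round(x$mean_press, 4), "\n", sep = "")
  invisible(x)
}
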