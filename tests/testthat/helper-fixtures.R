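# Small deterministic trials used across tests.

tiny_trial <- function() {
  # 2 genotypes x 2 environments x 1 block, additive responses
  trial_data(genotype = c("g1", "g2", "g1", "g2"),
             environment = c("e1", "e1", "e2", "e2"),
             block = rep("b1", 4),
             response = c(1, 2, 3, 4))
}

# balanced g x e x r trial with known additive effects and zero interaction
additive_trial <- function(g = 4, e = 3, r = 2, g_eff = NULL, e_eff = NULL,
                           sd = 0, seed = 1) {
  set.seed(seed)
  if (is.null(g_eff)) g_eff <- seq_len(g) - mean(seq_len(g))
  if (is.null(e_eff)) e_eff <- (seq_len(e) - mean(seq_len(e))) / 2
  gi <- rep(rep(seq_len(g), times = e), times = r)
  ei <- rep(rep(seq_len(e), each = g), times = r)
  bl <- rep(seq_len(r), each = g * e)
  y <- g_eff[gi] + e_eff[ei] + rnorm(length(gi), 0, sd)
  list(data = trial_data(paste0("g", gi), paste0("e", ei), paste0("b", bl), y),
       g_eff = g_eff, e_eff = e_eff)
}

# a valid model state for the given trial dimensions
fixed_state <- function(ctx_g, ctx_e, nc, t = 1, sigma2_e = 1, seed = 42) {
  set.seed(seed)
  U <- bammi:::centered_orthonormal(ctx_g, max(t, 1))
  V <- bammi:::centered_orthonormal(ctx_e, max(t, 1))
  list(beta = rnorm(nc), g_eff = rnorm(ctx_g), t = t,
       lambda = if (t > 0) sort(runif(t, 1, 3), decreasing = TRUE) else numeric(0),
       alpha = U[, seq_len(t), drop = FALSE],
       gamma = V[, seq_len(t), drop = FALSE],
       sigma2_lambda = rep(1e8, t), sigma2_g = 1, sigma2_e = sigma2_e, mu = 1)
}
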