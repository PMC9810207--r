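test_that("a minimal table builds the expected trial structure", {
  td <- tiny_trial()
  expect_equal(td$g, 2)
  expect_equal(td$e, 2)
  expect_equal(td$n, 4)
  expect_equal(length(td$block_cells), 2)  # one block per environment
})

test_that("unparseable and missing responses are dropped and counted", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("genotype,environment,block,response",
               "g1,e1,b1,1.5", "g2,e1,b1,oops", "g1,e2,b1,2.5",
               "g2,e2,b1,3.5"), f)
  td <- read_trial_table(f)
  expect_equal(td$n, 3)
  expect_equal(td$dropped, 1)
})

test_that("reading validates columns and non-empty content", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("geno,environment,block,response", "g1,e1,b1,1"), f)
  expect_error(read_trial_table(f), "genotype")
  expect_error(read_trial_table(file.path(tempdir(), "nope.csv")), "not found")
})

test_that("write/read round-trips a simulated trial", {
  sim <- simulate_met_trial(seed = 4, g = 5, e = 4, r = 2,
                            unstable1 = 1:2, unstable2 = 3:4, stable = 5,
                            pos_envs = 1:2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trial_table(sim$data, f)
  back <- read_trial_table(f)
  ord1 <- with(sim$data$records, order(genotype, environment, block, response))
  ord2 <- with(back$records, order(genotype, environment, block, response))
  expect_equal(back$records[ord2, ], sim$data$records[ord1, ],
               ignore_attr = TRUE)
  expect_equal(back$g, sim$data$g)
})

test_that("design matrices are 0/1 incidence with correct counts", {
  td <- tiny_trial()
  d <- build_designs(td)
  for (m in d) {
    expect_true(all(m %in% c(0, 1)))
    expect_equal(rowSums(m), rep(1, td$n), ignore_attr = TRUE)
  }
  expect_equal(dim(d$Z), c(4, 2))
  expect_equal(dim(d$X2), c(4, 2))
  expect_equal(dim(d$X1), c(4, 2))

  sim <- simulate_met_trial(seed = 1)
  db <- build_designs(sim$data)
  expect_equal(ncol(db$X1), 27)   # 9 environments x 3 blocks
  expect_equal(unname(colSums(db$Z)), rep(27, 20))
  expect_equal(unname(colSums(db$X2)), rep(60, 9))
})

test_that("unbalanced data is reflected in design column sums", {
  sim <- simulate_met_trial(seed = 2, g = 4, e = 3, r = 2,
                            unstable1 = 1, unstable2 = 2, stable = 3:4,
                            pos_envs = 1)
  rec <- sim$data$records
  drop_cell <- rec$genotype == "G01" & rec$environment == "E1"
  td <- trial_data(rec$genotype[!drop_cell], rec$environment[!drop_cell],
                   rec$block[!drop_cell], rec$response[!drop_cell])
  d <- build_designs(td)
  expect_equal(unname(colSums(d$Z)[1]), 2 * 3 - 2)
  expect_equal(unname(colSums(d$X2)[1]), 4 * 2 - 2)
})

test_that("blocks with the same label are distinct across environments", {
  td <- tiny_trial()  # block "b1" appears in both environments
  expect_equal(length(td$block_cells), 2)
  expect_equal(td$block_cell_env, 1:2)
})

test_that("cell-mean interaction double-centers and detects pure additivity", {
  ad <- additive_trial()
  ge <- cell_mean_interaction(ad$data)
  expect_lt(max(abs(ge$values)), 1e-10)

  sim <- simulate_met_trial(seed = 5)
  ge2 <- cell_mean_interaction(sim$data)
  expect_lt(max(abs(rowSums(ge2$values))), 1e-8)
  expect_lt(max(abs(colSums(ge2$values))), 1e-8)
})

test_that("double-centering preserves a planted centered rank-1 term and is idempotent", {
  set.seed(9)
  g <- 6; e <- 5
  u <- bammi:::centered_orthonormal(g, 1)[, 1]
  v <- bammi:::centered_orthonormal(e, 1)[, 1]
  m <- 5 * outer(u, v)
  expect_equal(double_center(m), m, tolerance = 1e-12)
  noise <- matrix(rnorm(g * e), g, e)
  cc <- double_center(noise)
  expect_equal(double_center(cc), cc, tolerance = 1e-12)
})

test_that("model mean vector matches a record-by-record loop oracle", {
  sim <- simulate_met_trial(seed = 6, g = 5, e = 4, r = 2,
                            unstable1 = 1:2, unstable2 = 3:4, stable = 5,
                            pos_envs = 1:2)
  td <- sim$data
  ctx <- bammi:::fit_context(td)
  state <- fixed_state(td$g, td$e, length(td$block_cells), t = 2)
  mu_fast <- state$beta[ctx$bi] + state$g_eff[ctx$gi] +
    bammi:::bilinear_vector(state$lambda, state$alpha, state$gamma,
                            ctx$gi, ctx$ei)
  mu_loop <- vapply(seq_len(td$n), function(r) {
    i <- ctx$gi[r]; j <- ctx$ei[r]; b <- ctx$bi[r]
    state$beta[b] + state$g_eff[i] +
      sum(vapply(seq_len(state$t), function(k)
        state$lambda[k] * state$alpha[i, k] * state$gamma[j, k], numeric(1)))
  }, numeric(1))
  expect_equal(mu_fast, mu_loop, tolerance = 1e-12)
})
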