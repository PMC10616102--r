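test_that("model variants fix the prescribed parameters and counts", {
  expect_equal(model_spec("M1")$p, 7L)
  m2 <- model_spec("M2")
  expect_equal(m2$p, 5L)
  expect_equal(m2$fixed, list(zeta = 0, q = 0L))
  m3 <- model_spec("M3")
  expect_equal(m3$p, 3L)
  expect_equal(m3$fixed$omega, 1)
  expect_equal(m3$fixed$beta, 1 / 3)
  m4 <- model_spec("M4")
  expect_equal(m4$p, 2L)
  expect_equal(m4$fixed$k, 0L)
  expect_true(model_spec("M5")$random)
  expect_equal(model_spec("M5")$p, 0L)
})

test_that("the full grid is the 24,000-point product of the parameter ranges", {
  g <- parameter_grid()
  expect_equal(nrow(g), 3 * 8 * 5 * 4 * 5 * 5 * 4)
  expect_equal(nrow(unique(g)), nrow(g))
  # ascending lexicographic order over (alpha, omega, k, plan, zeta, q, beta)
  o <- order(g$alpha, g$omega, g$k, g$plan, g$zeta, g$q, g$beta)
  expect_identical(o, seq_len(nrow(g)))
  expect_equal(nrow(parameter_grid(reduced = TRUE)), 3 * 8 * 2 * 2 * 5 * 5 * 4)
  expect_error(parameter_grid(omega = 0.5), "off-grid")
  small <- parameter_grid(alpha = 0, omega = c(0.4, 1), k = 0L, plan = 1L,
                          zeta = 0, q = 2L, beta = 1)
  expect_equal(nrow(small), 2)
})

test_that("the uniform-random likelihood counts both players' free actions", {
  tr <- game_trajectory(rep(10, 10), rep(15, 10))
  expect_equal(trajectory_nll(NULL, tr), 20 * log(5))
  expect_equal(trajectory_nll(NULL, tr, scope = "investor_only"), 10 * log(5))
  # forced trustee responses to zero investments contribute log 1 = 0
  tr0 <- game_trajectory(c(rep(0, 4), rep(10, 6)), c(rep(0, 4), rep(15, 6)))
  expect_equal(trajectory_nll(NULL, tr0), 10 * log(5) + 6 * log(5))
})

test_that("the Draper BIC penalty is linear in p with the printed slope", {
  expect_equal(draper_bic(5, 0), 5)
  slope <- (log(10) - log(2 * pi)) / 2
  expect_equal(draper_bic(0, 7), 7 * slope)
  expect_equal(draper_bic(0, 7), 1.62648, tolerance = 1e-5)
  ps <- 0:7
  pen <- draper_bic(0, ps)
  expect_equal(diff(pen), rep(slope, 7))
  expect_equal(draper_bic(20 * log(5), 0), 32.19, tolerance = 0.005)
  expect_error(draper_bic(5, -1), "non-negative")
})

test_that("model-based trajectory likelihood matches stepwise enumeration", {
  # 2-round toy game: NLL equals -log of the product of hand-enumerated
  # step probabilities from the oracle
  tr <- game_trajectory(c(15, 10), c(7.5, 15), n_rounds = 2)
  for (k in 0:1) {
    pars <- agent_params("investor", alpha = 0.4, omega = 1.2, k = k,
                         plan = 2, zeta = 0.5, q = 2, beta = 1 / 2)
    expect_equal(trajectory_nll(pars, tr, ctx = agent_context(2)),
                 or_nll(pars, tr), tolerance = 1e-9)
    expect_equal(trajectory_nll(pars, tr, scope = "investor_only",
                                ctx = agent_context(2)),
                 or_nll(pars, tr, scope = "investor_only"), tolerance = 1e-9)
  }
})

test_that("likelihood is additive over rounds: truncation decreases NLL", {
  pars <- agent_params("investor", alpha = 0, omega = 1, k = 0, plan = 1,
                       zeta = 0, q = 2, beta = 1)
  full <- game_trajectory(rep(c(10, 15), 3), rep(c(15, 22.5), 3), n_rounds = 6)
  part <- game_trajectory(rep(c(10, 15), 2), rep(c(15, 22.5), 2), n_rounds = 4)
  # the first four rounds of both games coincide and policies depend only on
  # the past, except the horizon-dependent planning depth near the end; use
  # plan = 1 so only the final round's depth differs
  nll_full <- trajectory_nll(pars, full, ctx = agent_context(6))
  nll_part <- trajectory_nll(pars, part, ctx = agent_context(4))
  expect_gt(nll_full, nll_part)
})

test_that("grid search returns the lexicographic argmin with tie count", {
  tr <- game_trajectory(rep(c(10, 15), 5), rep(c(15, 22.5), 5))
  grid <- parameter_grid(alpha = c(0, 0.4), omega = c(0.6, 1, 1.4), k = 0L,
                         plan = 1L, zeta = c(0, 0.5), q = 2L, beta = c(1 / 3, 1))
  ctx <- agent_context(10)
  fit <- fit_subject(tr, model_spec("M1"), grid = grid, ctx = ctx)
  expect_s3_class(fit, "fit_result")
  expect_equal(fit$grid_size, nrow(grid))
  expect_gte(fit$n_ties, 1L)
  # argmin property: no grid point does better
  nlls <- apply(grid, 1L, function(gp) {
    pars <- agent_params("investor", alpha = gp["alpha"], omega = gp["omega"],
                         k = gp["k"], plan = gp["plan"], zeta = gp["zeta"],
                         q = gp["q"], beta = gp["beta"])
    trajectory_nll(pars, tr, ctx = ctx)
  })
  expect_equal(fit$nll, min(nlls), tolerance = 1e-12)
  # determinism
  fit2 <- fit_subject(tr, model_spec("M1"), grid = grid,
                      ctx = agent_context(10))
  expect_identical(fit_result_row(fit), fit_result_row(fit2))
  # M5 ignores the grid
  fit5 <- fit_subject(tr, model_spec("M5"), grid = grid)
  expect_equal(fit5$p, 0L)
  expect_equal(fit5$grid_size, 1L)
  expect_equal(fit5$nll, 20 * log(5))
})

test_that("nested model variants have monotone minimum NLL", {
  tr <- game_trajectory(c(10, 15, 5, 10, 20, 10, 15, 10, 5, 10),
                        c(5, 7.5, 2.5, 15, 30, 10, 15, 15, 5, 15))
  grid <- parameter_grid(alpha = c(0, 0.4, 1), omega = c(0.6, 1, 1.4),
                         k = 0L, plan = 1L, zeta = c(0, 0.5), q = c(0L, 2L),
                         beta = c(1 / 3, 1))
  ctx <- agent_context(10)
  nlls <- sapply(paste0("M", 1:4), function(m) {
    fit_subject(tr, model_spec(m), grid = grid, ctx = ctx)$nll
  })
  expect_true(all(diff(nlls) >= -1e-9))  # M1 <= M2 <= M3 <= M4
})

test_that("model comparison averages BIC and ranks ascending", {
  trs <- list(
    game_trajectory(rep(c(10, 15), 5), rep(c(15, 22.5), 5), subject_id = "a"),
    game_trajectory(rep(c(20, 5), 5), rep(c(30, 5), 5), subject_id = "b")
  )
  grid <- parameter_grid(alpha = 0, omega = c(0.6, 1), k = 0L, plan = 1L,
                         zeta = 0, q = 2L, beta = c(1 / 3, 1))
  cmp <- compare_models(trs, specs = lapply(c("M3", "M5"), model_spec),
                        grid = grid)
  expect_equal(nrow(cmp$summary), 2)
  expect_true(all(diff(cmp$summary$mean_bic) >= 0))
  expect_equal(cmp$summary$n_subjects, c(2L, 2L))
  m5 <- cmp$fits[cmp$fits$model == "M5", ]
  expect_equal(m5$bic, rep(20 * log(5), 2))
})
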