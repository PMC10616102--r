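# Cohort-generation problem sizes are kept small here (a handful of level-0
# subjects) so the suite stays fast; the generator's statistical structure is
# what is under test, not simulation scale.

fast_cohort <- function(n, seed, ...) {
  cohort_config(n_subjects = n, seed = seed, k_levels = 0L,
                beta_levels = 1, trustee = rep(c(1 / 2, 1 / 6), 5), ...)
}

test_that("simulated games follow the sampling contract", {
  inv <- agent_params("investor", alpha = 0.4, omega = 1, k = 0, plan = 1,
                      zeta = 0, q = 2, beta = 1)
  # replay trustee of all-zero fractions: every repayment 0
  tr <- simulate_game(inv, rep(0, 10), seed = 3)
  expect_true(all(tr$rounds$a_t == 0))
  # reproducibility
  tr2 <- simulate_game(inv, rep(0, 10), seed = 3)
  expect_identical(tr$rounds, tr2$rounds)
  tr3 <- simulate_game(inv, rep(0, 10), seed = 4)
  expect_false(identical(tr$rounds, tr3$rounds))
  # replay schedules must be legal fractions
  expect_error(simulate_game(inv, rep(0.4, 10), seed = 1), "fraction")
  # a zeta = 0 investor's trajectory is untouched by the irritation mixture:
  # regenerating with the mixture weight clamped (zeta = 0 implies w = 0)
  # yields the same game as an explicit w = 0 policy at every step
  set.seed(11)
  tr4 <- simulate_game(inv, rep(c(1 / 6, 0), 5), seed = 11)
  ctx <- agent_context(10)
  h_i <- h_t <- numeric(0)
  ok <- TRUE
  for (r in 1:10) {
    p_mix <- choice_probabilities(inv, h_i, h_t, ctx = ctx)$prob
    p_w0 <- choice_probabilities(inv, h_i, h_t, w = 0, ctx = ctx)$prob
    ok <- ok && isTRUE(all.equal(p_mix, p_w0, tolerance = 1e-12))
    h_i <- c(h_i, tr4$rounds$a_i[r])
    h_t <- c(h_t, tr4$rounds$a_t[r])
  }
  expect_true(ok)
})

test_that("alpha = 1 trustee facing a generous investor repays the equal split modally", {
  tru <- agent_params("trustee", alpha = 1, k = 1, plan = 1, zeta = 0, q = 2,
                      beta = 1)
  reps <- sapply(1:40, function(s) {
    .f <- simulate_game(agent_params("investor", alpha = 0, omega = 0.4,
                                     k = 0, plan = 1, zeta = 0, q = 2,
                                     beta = 1),
                        tru, seed = s, n_rounds = 2)
    idx <- which(.f$rounds$a_i == 20)
    if (length(idx)) .f$rounds$a_t[idx[1]] / (3 * 20) else NA
  })
  reps <- reps[!is.na(reps)]
  expect_gt(length(reps), 10)
  tab <- table(reps)
  expect_equal(as.numeric(names(tab)[which.max(tab)]), 1 / 2)
})

test_that("cohort generation is seed-reproducible with the declared schema", {
  c1 <- generate_cohort(fast_cohort(4, seed = 21))
  c2 <- generate_cohort(fast_cohort(4, seed = 21))
  expect_identical(c1$cohort, c2$cohort)
  expect_identical(c1$cfq, c2$cfq)
  expect_identical(lapply(c1$trajectories, `[[`, "rounds"),
                   lapply(c2$trajectories, `[[`, "rounds"))
  c3 <- generate_cohort(fast_cohort(4, seed = 22))
  expect_false(identical(c1$cohort$adversity, c3$cohort$adversity))
  expect_equal(nrow(c1$cohort), 8)            # 2 visits per subject
  expect_equal(length(c1$trajectories), 8)
  expect_equal(nrow(c1$cfq), 12)              # 3 waves per subject
  expect_true(all(c1$cohort$age >= 14 & c1$cohort$age <= 28))
  expect_true(all(diff(matrix(c1$cohort$age, nrow = 2)) > 0) ||
                all(matrix(c1$cohort$age, 2)[2, ] > matrix(c1$cohort$age, 2)[1, ]))
})

test_that("an empty cohort is schema-valid", {
  c0 <- generate_cohort(fast_cohort(0, seed = 1))
  expect_equal(nrow(c0$cohort), 0)
  expect_equal(nrow(c0$cfq), 0)
  expect_length(c0$trajectories, 0)
  expect_true(all(c("subject_id", "age", "adversity", "true_omega",
                    "true_zeta") %in% names(c0$cohort)))
})

test_that("config validation rejects inconsistent settings", {
  expect_error(cohort_config(n_subjects = 5), "seed")
  expect_error(cohort_config(n_subjects = -1, seed = 1), "n_subjects")
  expect_error(cohort_config(interval_sd = -1, seed = 1), "non-negative")
  expect_error(cohort_config(age_range = c(25, 14), seed = 1), "increasing")
})

test_that("the adversity-irritability link orders zeta by adversity", {
  # large-n check on the sampling rule alone (no game simulation): empirical
  # mean zeta is non-decreasing across adversity quartiles
  cfg <- fast_cohort(2, seed = 5, adversity_zeta_link = 2)
  g <- param_grid_levels()
  set.seed(99)
  adv <- rnorm(4000)
  zeta <- sapply(adv, function(a) {
    logits <- cfg$zeta_base_logits + cfg$adversity_zeta_link * a *
      seq(0, 1, length.out = 5)
    p <- exp(logits - max(logits))
    sample(g$zeta, 1, prob = p / sum(p))
  })
  qt <- cut(adv, breaks = quantile(adv, 0:4 / 4), include.lowest = TRUE)
  mz <- tapply(zeta, qt, mean)
  expect_true(all(diff(mz) > 0))
})

test_that("recovery experiments report rates on a tiny configuration", {
  grid <- parameter_grid(alpha = 0, omega = c(0.4, 1, 1.8), k = 0L,
                         plan = 1L, zeta = c(0, 0.5), q = 2L, beta = 1)
  rep_ <- recovery_experiment(n_agents = 6, truth_grid = grid,
                              trustee = rep(c(1 / 2, 1 / 6), 5), seed = 2)
  expect_s3_class(rep_, "recovery_report")
  expect_equal(nrow(rep_$table), 6)
  expect_equal(sort(rep_$rates$parameter),
               sort(c("alpha", "omega", "k", "plan", "zeta", "q", "beta")))
  expect_true(all(rep_$rates$exact >= 0 & rep_$rates$exact <= 1))
  expect_true(all(rep_$rates$exact_or_adjacent >= rep_$rates$exact - 1e-12))
  # fixed-parameter columns recover trivially
  expect_equal(rep_$rates$exact[rep_$rates$parameter == "beta"], 1)
})
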