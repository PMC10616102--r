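inv0 <- function(...) agent_params("investor", ...)

test_that("utilities evaluate the inequality-averse payoff rules", {
  expect_equal(investor_utility(inv0(alpha = 0, omega = 1), 10, 15), 25)
  expect_equal(investor_utility(inv0(alpha = 0, omega = 1.8), 0, 0), 36)
  expect_equal(investor_utility(inv0(alpha = 1, omega = 0.4), 20, 40), 20)
  tru <- agent_params("trustee", alpha = 1)
  expect_equal(trustee_utility(tru, 20, 30), 30)
  expect_equal(trustee_utility(tru, 20, 0), 0)
  # alpha = 1 trustee's myopic argmax is the equal-split repayment
  u <- trustee_utility(tru, 20, trustee_actions(20))
  expect_equal(trustee_actions(20)[which.max(u)], 30)
})

test_that("alpha = 1 trustee's myopic argmax equalizes payoffs for every a_i > 0", {
  tru <- agent_params("trustee", alpha = 1)
  for (a_i in c(5, 10, 15, 20)) {
    at <- trustee_actions(a_i)
    u <- trustee_utility(tru, a_i, at)
    gap <- abs((3 * a_i - at) - ((20 - a_i) + at))
    expect_equal(which.max(u), which.min(gap))
  }
})

test_that("agent parameters are validated against the discrete grids", {
  expect_error(agent_params("investor", omega = 0.5), "omega")
  expect_error(agent_params("investor", zeta = 0.3), "zeta")
  expect_error(agent_params("investor", beta = 0.4), "beta")
  expect_error(agent_params("investor", k = 5), "k = 5")
  expect_silent(agent_params("trustee", b_omega = 1.8))
})

test_that("inequality-aversion belief updates add likelihoods with gating", {
  b <- belief_state(q = 2)
  b2 <- update_inequality_belief(b, c(0.2, 0.5, 0.9), a_i = 10)
  expect_equal(b2$A_alpha, c(1.2, 1.5, 1.9))
  # equal likelihoods leave the (uniform) normalized belief unchanged
  b3 <- update_inequality_belief(b, c(0.4, 0.4, 0.4), a_i = 10)
  expect_equal(belief_probs(b3)$alpha, rep(1 / 3, 3))
  # responses to investments <= 5 carry no inequality information
  b4 <- update_inequality_belief(b, c(0.2, 0.5, 0.9), a_i = 5)
  expect_identical(b4$A_alpha, b$A_alpha)
  expect_error(update_inequality_belief(b, c(0.2, 1.5, 0.9), a_i = 10), "0, 1")
  # counts never decrease; added mass equals the likelihood sum
  expect_true(all(b2$A_alpha >= b$A_alpha))
  expect_equal(sum(b2$A_alpha) - sum(b$A_alpha), sum(c(0.2, 0.5, 0.9)))
})

test_that("irritability beliefs use the same additive rule, disabled at q = 0", {
  b <- belief_state(q = 2)
  b2 <- update_irritability_belief(b, c(0.1, 0.2, 0.3, 0.4, 0.5))
  expect_equal(b2$Z, c(1.1, 1.2, 1.3, 1.4, 1.5))
  b0 <- belief_state(q = 0)
  expect_identical(update_irritability_belief(b0, rep(0.5, 5))$Z, b0$Z)
  expect_equal(belief_probs(b0)$zeta, c(1, 0, 0, 0, 0))
})

test_that("expected partner value is the belief-weighted mean of type values", {
  b <- belief_state(q = 2)
  # point mass via overwhelming counts
  b$A_alpha <- c(1e9, 1e-9, 1e-9)
  expect_equal(expected_partner_value(b, c(12, 0, 0)), 12, tolerance = 1e-6)
  b$A_alpha <- c(1, 1, 1e-12)
  expect_equal(expected_partner_value(b, c(10, 20, 0)), 15, tolerance = 1e-6)
  b$A_alpha <- c(0.2, 0.3, 0.5)
  expect_equal(expected_partner_value(b, c(0, 10, 20)), 13)
  m <- matrix(rep(c(0, 10, 20), 5), nrow = 3)
  expect_equal(expected_partner_value(b, m), 13)
})

test_that("irritation weight shifts additively and clamps to [0, 1]", {
  w <- update_irritation(0, 0.25, "below")
  expect_equal(w, 0.25)
  for (i in 1:4) w <- update_irritation(w, 0.25, "below")
  expect_equal(w, 1)  # clamped after five shifts
  expect_equal(update_irritation(1, 0.5, "above"), 0.5)
  expect_equal(update_irritation(0, 0, "below"), 0)
  expect_equal(update_irritation(0.4, 0.5, "above"), 0)
})

test_that("softmax choice rule matches its closed form and degenerates correctly", {
  expect_equal(softmax_policy(rep(3, 5), 2), rep(0.2, 5))
  p <- softmax_policy(c(1, 0, 0, 0, 0), 1)
  expect_equal(p[1], exp(1) / (exp(1) + 4))
  expect_error(softmax_policy(c(1, Inf), 1), "finite")
  # beta concentrates probability on the argmax monotonically
  q <- c(2, 1.5, 1, 0.5, 0)
  pmax_seq <- sapply(c(1 / 4, 1 / 3, 1 / 2, 1, 2), function(b) softmax_policy(q, b)[1])
  expect_true(all(diff(pmax_seq) > 0))
})

test_that("choice probabilities are a proper irritation mixture", {
  ag <- inv0(alpha = 0.4, omega = 1.2, k = 0, plan = 1, zeta = 0.5, q = 2,
             beta = 1 / 2)
  # after two stingy repayments the agent carries irritation weight
  hist_i <- c(10, 10)
  hist_t <- c(0, 0)
  st <- agent_state(ag, hist_i, hist_t)
  expect_equal(st$w, 1)  # two below-expectation shifts of 0.5
  cp <- choice_probabilities(ag, hist_i, hist_t)
  expect_equal(sum(cp$prob), 1, tolerance = 1e-12)
  expect_true(all(cp$prob > 0 & cp$prob < 1))
  # w = 1 reproduces the irritated policy: static softmax with alpha = 0,
  # omega raised to at least 1 (here already 1.2)
  p_irr <- choice_probabilities(ag, hist_i, hist_t, w = 1)$prob
  static_trustee <- function(alpha, a_i) {
    at <- trustee_actions(a_i)
    u <- (3 * a_i - at) - alpha * pmax((3 * a_i - at) - ((20 - a_i) + at), 0)
    softmax_policy(u, 1 / 2)
  }
  u_static <- sapply(1:5, function(i) {
    a <- c(0, 5, 10, 15, 20)[i]
    if (a == 0) return(1.2 * 20)
    at <- trustee_actions(a)
    presp <- (static_trustee(0, a) + static_trustee(0.4, a) +
                static_trustee(1, a)) / 3
    sum(presp * (1.2 * (20 - a) + at))
  })
  expect_equal(p_irr, softmax_policy(u_static, 1 / 2), tolerance = 1e-12)
  # w = 0 reproduces the nonirritated softmax over the Q values
  av <- action_values(ag, hist_i, hist_t)
  expect_equal(choice_probabilities(ag, hist_i, hist_t, w = 0)$prob,
               softmax_policy(av$q, 1 / 2), tolerance = 1e-12)
  # zeta = 0 agents never mix: full policy equals the nonirritated softmax
  ag0 <- inv0(alpha = 0.4, omega = 1.2, k = 0, plan = 1, zeta = 0, q = 2,
              beta = 1 / 2)
  av0 <- action_values(ag0, hist_i, hist_t)
  expect_equal(choice_probabilities(ag0, hist_i, hist_t)$prob,
               softmax_policy(av0$q, 1 / 2), tolerance = 1e-12)
})

test_that("round-10 action values equal expected immediate utility", {
  ag <- inv0(alpha = 0, omega = 1.8, k = 0, plan = 4, zeta = 0, q = 2,
             beta = 1)
  hist_i <- rep(10, 9)
  hist_t <- rep(15, 9)
  av <- action_values(ag, hist_i, hist_t)
  # no future term: Q(a) = 1.8 * (20 - a) + E[a_t | a]
  for (i in 1:5) {
    a <- av$actions[i]
    pp <- partner_prediction(ag, hist_i, hist_t, pending_investment = a)
    e_rep <- sum(pp$prob * pp$actions)
    expect_equal(av$q[i], 1.8 * (20 - a) + e_rep, tolerance = 1e-9)
  }
  expect_equal(av$q[1], 36)  # zero investment keeps 20 coins at omega = 1.8
})

test_that("expected round-1 investment is non-increasing in risk aversion", {
  omegas <- param_grid_levels()$omega
  einv <- sapply(omegas, function(om) {
    ag <- inv0(alpha = 0, omega = om, k = 0, plan = 1, zeta = 0, q = 2,
               beta = 1)
    cp <- choice_probabilities(ag)
    sum(cp$prob * cp$actions)
  })
  expect_true(all(diff(einv) <= 1e-9))
})

test_that("recursive action values match brute-force enumeration on short games", {
  # 2-round games, several parameter corners, round-1 (planning engaged) and
  # round-2 (horizon boundary) decisions
  cases <- rbind(
    expand.grid(alpha = c(0, 1), omega = c(0.4, 1.8), k = 0, plan = 1:2,
                zeta = c(0, 0.5)),
    data.frame(alpha = c(0, 1, 0, 1), omega = c(0.4, 1.8, 1.8, 0.4),
               k = 1, plan = c(1, 1, 2, 2), zeta = c(0, 0.5, 0.5, 0))
  )
  h <- c(4L, 2L)  # round 1: investment 15, repayment fraction 1/6 (2.5 * 3)
  hist_i <- 15
  hist_t <- or_tset(4)[2]
  for (r in seq_len(nrow(cases))) {
    cs <- cases[r, ]
    ag <- inv0(alpha = cs$alpha, omega = cs$omega, k = cs$k, plan = cs$plan,
               zeta = cs$zeta, q = 2, beta = 1 / 2)
    ctx <- agent_context(2)
    oag <- or_agent("investor", cs$k, cs$alpha, cs$omega, cs$zeta, 2, 1 / 2,
                    cs$plan)
    # round 1, empty history
    av1 <- action_values(ag, ctx = ctx, game_length = 2)
    expect_equal(av1$q, or_q(oag, integer(0), min(cs$plan, 1), 2),
                 tolerance = 1e-9)
    p1 <- choice_probabilities(ag, ctx = ctx, game_length = 2)$prob
    expect_equal(p1, or_policy(oag, integer(0), 2), tolerance = 1e-9)
    # round 2, after one completed round
    av2 <- action_values(ag, hist_i, hist_t, ctx = ctx, game_length = 2)
    expect_equal(av2$q, or_q(oag, h, 0, 2), tolerance = 1e-9)
    p2 <- choice_probabilities(ag, hist_i, hist_t, ctx = ctx,
                               game_length = 2)$prob
    expect_equal(p2, or_policy(oag, h, 2), tolerance = 1e-9)
  }
})

test_that("belief and irritation states match the oracle on short histories", {
  ag <- inv0(alpha = 0.4, omega = 1, k = 1, plan = 1, zeta = 0.5, q = 3,
             beta = 1 / 3)
  hist_i <- c(10, 20, 5)
  hist_t <- c(5, 40, 0)
  st <- agent_state(ag, hist_i, hist_t, game_length = 3)
  oag <- or_agent("investor", 1, 0.4, 1, 0.5, 3, 1 / 3, 1)
  h <- integer(0)
  for (r in 1:3) {
    i_idx <- match(hist_i[r], OR_ACTS)
    h <- c(h, i_idx, which(abs(or_tset(i_idx) - hist_t[r]) < 1e-9))
  }
  ob <- or_beliefs(oag, h, 3)
  expect_equal(st$A, ob$A, tolerance = 1e-9)
  expect_equal(st$Z, ob$Z, tolerance = 1e-9)
  expect_equal(st$w, or_w(oag, h, 3), tolerance = 1e-9)
  # counts are monotone in history length
  st2 <- agent_state(ag, hist_i[1:2], hist_t[1:2], game_length = 3)
  expect_true(all(st$A >= st2$A - 1e-12) && all(st$Z >= st2$Z - 1e-12))
})
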