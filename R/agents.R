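# Agent model: utilities, beliefs, irritability, level-k recursion, planning,
# choice probabilities.
#
# The engine represents a game as a sequence of half-moves (investor move,
# trustee move, investor move, ...) encoded as action indices.  Every agent
# quantity -- Dirichlet beliefs about the partner's inequality-aversion type
# and irritability, the agent's own irritation mixture weight, action values,
# policies -- is a deterministic function of (agent specification, half-move
# history), which makes belief transitions inside planning rollouts automatic
# and permits aggressive memoization across grid points.

# -- Parameter grid (discrete parameter space) -------------------------------

#' Discrete parameter space of the trust-game model
#'
#' The seven model parameters live on fixed grids: inequality aversion
#' `alpha` in \{0, 0.4, 1\}, social risk aversion `omega` in \{0.4, 0.6, ...,
#' 1.8\}, theory-of-mind level `k` in 0..4, planning horizon `plan` in 1..4,
#' irritability `zeta` in \{0, 0.25, 0.5, 0.75, 1\}, irritation awareness `q`
#' in 0..4 and inverse temperature `beta` in \{1/4, 1/3, 1/2, 1\}.
#'
#' @return Named list of grid vectors.
#' @export
param_grid_levels <- function() {
  list(
    alpha = c(0, 0.4, 1),
    omega = seq(0.4, 1.8, by = 0.2),
    k = 0:4,
    plan = 1:4,
    zeta = c(0, 0.25, 0.5, 0.75, 1),
    q = 0:4,
    beta = c(1 / 4, 1 / 3, 1 / 2, 1)
  )
}

.on_grid <- function(value, grid) any(abs(grid - value) < 1e-9)

#' Agent parameter vector
#'
#' Bundles the seven-parameter vector Theta = (alpha, omega, k, P, zeta,
#' q(zeta), beta) together with the agent's role.  A trustee carries
#' `b_omega`, its static assumption about the investor's risk aversion, on the
#' same grid as `omega`; a trustee's own utility does not involve `omega`.
#'
#' @param role `"investor"` or `"trustee"`.
#' @param alpha Inequality aversion.
#' @param omega Social risk aversion (investor only; ignored for trustees).
#' @param k Theory-of-mind level (0..4).
#' @param plan Planning horizon P (1..4).
#' @param zeta Irritability.
#' @param q Irritation awareness (0..4).
#' @param beta Inverse temperature.
#' @param b_omega Trustee's assumption about the investor's risk aversion.
#' @return An object of class `agent_params`.
#' @export
#' @examples
#' agent_params("investor", alpha = 0, omega = 1, k = 0, plan = 1,
#'              zeta = 0, q = 2, beta = 1)
agent_params <- function(role = c("investor", "trustee"), alpha = 0, omega = 1,
                         k = 0, plan = 1, zeta = 0, q = 2, beta = 1 / 3,
                         b_omega = 1) {
  role <- match.arg(role)
  g <- param_grid_levels()
  chk <- function(nm, val, grid) {
    if (length(val) != 1L || is.na(val) || !.on_grid(val, grid)) {
      stop(nm, " = ", val, " is not on its grid {",
           paste(signif(grid, 4), collapse = ", "), "}")
    }
  }
  chk("alpha", alpha, g$alpha)
  chk("omega", omega, g$omega)
  chk("k", k, g$k)
  chk("plan", plan, g$plan)
  chk("zeta", zeta, g$zeta)
  chk("q", q, g$q)
  chk("beta", beta, g$beta)
  chk("b_omega", b_omega, g$omega)
  structure(
    list(role = role, alpha = alpha, omega = omega, k = as.integer(k),
         plan = as.integer(plan), zeta = zeta, q = as.integer(q), beta = beta,
         b_omega = b_omega),
    class = "agent_params"
  )
}

#' @export
#' @method print agent_params
print.agent_params <- function(x, ...) {
  cat("<agent_params>", x$role,
      sprintf("alpha=%g omega=%g k=%d P=%d zeta=%g q=%d beta=%g",
              x$alpha, if (x$role == "investor") x$omega else x$b_omega,
              x$k, x$plan, x$zeta, x$q, x$beta), "\n")
  invisible(x)
}

# -- Utilities ---------------------------------------------------------------

#' Investor round utility
#'
#' `u = omega * (20 - a_i) + a_t - alpha * max(chi_i - chi_t, 0)`: risk-scaled
#' value of coins kept, plus the repayment, minus a Fehr-Schmidt penalty on
#' advantageous inequality.
#'
#' @param params An `agent_params` with role `"investor"` (or any list with
#'   `alpha` and `omega`).
#' @param a_i Investment in coins.
#' @param a_t Repayment in coins (vectorized).
#' @return Numeric utility vector.
#' @export
investor_utility <- function(params, a_i, a_t) {
  chi_i <- (ENDOWMENT - a_i) + a_t
  chi_t <- 3 * a_i - a_t
  params$omega * (ENDOWMENT - a_i) + a_t - params$alpha * pmax(chi_i - chi_t, 0)
}

#' Trustee round utility
#'
#' `u = chi_t - alpha * max(chi_t - chi_i, 0)`: the kept share of the tripled
#' investment, penalized for advantageous inequality.  An `alpha = 1` trustee
#' maximizes utility at the payoff-equalizing repayment.
#'
#' @inheritParams investor_utility
#' @export
trustee_utility <- function(params, a_i, a_t) {
  chi_i <- (ENDOWMENT - a_i) + a_t
  chi_t <- 3 * a_i - a_t
  chi_t - params$alpha * pmax(chi_t - chi_i, 0)
}

.u_inv <- function(alpha, omega, a_i, a_t) {
  chi_i <- (ENDOWMENT - a_i) + a_t
  chi_t <- 3 * a_i - a_t
  omega * (ENDOWMENT - a_i) + a_t - alpha * pmax(chi_i - chi_t, 0)
}

.u_tru <- function(alpha, a_i, a_t) {
  chi_i <- (ENDOWMENT - a_i) + a_t
  chi_t <- 3 * a_i - a_t
  chi_t - alpha * pmax(chi_t - chi_i, 0)
}

# -- Beliefs and irritation --------------------------------------------------

#' Default Dirichlet priors over partner irritability
#'
#' Irritation awareness `q` selects the prior pseudo-counts over the five
#' partner-irritability levels.  `q = 0` ("irritation ignorant") is a point
#' mass on zeta = 0 with updating disabled; `q = 1`..`4` shift prior mass
#' progressively toward high irritability ("unlikely", "possible", "likely",
#' "certain"); `q = 4` places no mass on zeta = 0.  Override via
#' `options(trustmrt.irritation_priors = <list of 5 count vectors>)`.
#'
#' @return List of five numeric count vectors (one per `q`), each length 5.
#' @export
irritation_priors <- function() {
  opt <- getOption("trustmrt.irritation_priors", NULL)
  if (!is.null(opt)) return(opt)
  list(
    q0 = c(1, 0, 0, 0, 0),
    q1 = c(3, 0.5, 0.5, 0.5, 0.5),
    q2 = c(1, 1, 1, 1, 1),
    q3 = c(0.5, 0.5, 0.5, 0.5, 3),
    q4 = c(0, 1.25, 1.25, 1.25, 1.25)
  )
}

#' Belief state over partner types
#'
#' Dirichlet pseudo-counts over the partner's inequality-aversion type
#' (uniform prior `(1, 1, 1)` over alpha in \{0, 0.4, 1\}) and over the
#' partner's irritability level (prior chosen by irritation awareness `q`).
#'
#' @param q Irritation awareness (0..4) setting the zeta prior.
#' @return Object of class `belief_state` with count vectors `A_alpha`, `Z`
#'   and the supports.
#' @export
belief_state <- function(q = 2) {
  stopifnot(q %in% 0:4)
  structure(
    list(
      A_alpha = c(1, 1, 1),
      Z = irritation_priors()[[q + 1L]],
      alpha_support = c(0, 0.4, 1),
      zeta_support = c(0, 0.25, 0.5, 0.75, 1),
      q = as.integer(q)
    ),
    class = "belief_state"
  )
}

#' @export
#' @method print belief_state
print.belief_state <- function(x, ...) {
  cat("<belief_state>\n alpha counts:", paste(signif(x$A_alpha, 4), collapse = " "),
      "\n zeta counts: ", paste(signif(x$Z, 4), collapse = " "), "\n")
  invisible(x)
}

#' Normalized belief probabilities
#' @param belief A `belief_state`.
#' @return List with probability vectors `alpha` and `zeta`.
#' @export
belief_probs <- function(belief) {
  list(alpha = belief$A_alpha / sum(belief$A_alpha),
       zeta = belief$Z / sum(belief$Z))
}

#' Approximate Dirichlet update of the inequality-aversion belief
#'
#' Adds the likelihood of the observed partner action under each
#' inequality-aversion type to the corresponding pseudo-count:
#' `A_alpha <- A_alpha + p(o | alpha)`.  An investor's belief is not updated
#' from trustee responses to investments of 5 or less (an investment of 5
#' equalizes payoffs, so the response carries no inequality information).
#'
#' @param belief A `belief_state`.
#' @param likelihoods `p(o | alpha)`, numeric length 3, each in [0, 1].
#' @param a_i The investment preceding the observed response; updates are
#'   applied only when `a_i > 5`.  Use the default `Inf` for observations
#'   that are not gated (e.g. a trustee observing investments).
#' @return Updated `belief_state`.
#' @export
update_inequality_belief <- function(belief, likelihoods, a_i = Inf) {
  if (length(likelihoods) != length(belief$A_alpha)) {
    stop("need one likelihood per inequality-aversion type")
  }
  if (anyNA(likelihoods) || any(likelihoods < 0) || any(likelihoods > 1)) {
    stop("likelihoods must lie in [0, 1]")
  }
  if (a_i <= 5) return(belief)
  belief$A_alpha <- belief$A_alpha + likelihoods
  belief
}

#' Approximate Dirichlet update of the irritability belief
#'
#' Same additive pseudo-count rule as [update_inequality_belief()], applied to
#' the five partner-irritability levels.  No update is performed when the
#' prior is the `q = 0` point mass (irritation-ignorant agents do not learn
#' about irritability).
#'
#' @param belief A `belief_state`.
#' @param likelihoods `p(o | zeta)`, numeric length 5, each in [0, 1].
#' @return Updated `belief_state`.
#' @export
update_irritability_belief <- function(belief, likelihoods) {
  if (length(likelihoods) != length(belief$Z)) {
    stop("need one likelihood per irritability level")
  }
  if (anyNA(likelihoods) || any(likelihoods < 0) || any(likelihoods > 1)) {
    stop("likelihoods must lie in [0, 1]")
  }
  if (belief$q == 0L) return(belief)
  belief$Z <- belief$Z + likelihoods
  belief
}

#' Expected monetary value of the partner's next action
#'
#' Probability-weighted mean of per-type expected action values under the
#' current belief mixture: the quantity an agent compares against the
#' partner's observed action to decide whether it was below expectation
#' (the irritation trigger).
#'
#' @param belief A `belief_state`.
#' @param type_values Matrix (3 x 5, alpha types by zeta levels) or vector of
#'   expected monetary action values under each partner-type policy.  A
#'   vector is interpreted as alpha-type values shared across zeta levels.
#' @return Scalar expected value.
#' @export
expected_partner_value <- function(belief, type_values) {
  pb <- belief_probs(belief)
  if (is.matrix(type_values)) {
    if (!all(dim(type_values) == c(3L, 5L))) {
      stop("type_values matrix must be 3 x 5 (alpha types x zeta levels)")
    }
    return(as.numeric(pb$alpha %*% type_values %*% pb$zeta))
  }
  if (length(type_values) == 0L || sum(belief$A_alpha) <= 0) {
    stop("empty belief support")
  }
  sum(pb$alpha * type_values)
}

#' Additive irritation-weight update
#'
#' A below-expectation partner action shifts the policy mixture weight toward
#' the irritated policy by the agent's irritability, `w <- min(w + zeta, 1)`;
#' an above-expectation action shifts it back at the same rate,
#' `w <- max(w - zeta, 0)`.  Ties leave `w` unchanged, as does `zeta = 0`.
#'
#' @param w Current mixture weight in [0, 1].
#' @param zeta Irritability.
#' @param event `"below"` or `"above"` (observed vs expected partner value).
#' @return Updated weight.
#' @export
update_irritation <- function(w, zeta, event = c("below", "above")) {
  event <- match.arg(event)
  stopifnot(w >= 0, w <= 1)
  if (zeta <= 0) return(w)
  if (event == "below") min(w + zeta, 1) else max(w - zeta, 0)
}

#' Softmax choice rule
#'
#' `P[a] = exp(beta * q_a) / sum_c exp(beta * q_c)`, computed stably.
#'
#' @param q Numeric vector of action values.
#' @param beta Inverse temperature.
#' @return Probability vector.
#' @export
softmax_policy <- function(q, beta) {
  if (anyNA(q) || any(!is.finite(q))) stop("action values must be finite")
  z <- beta * (q - max(q))
  e <- exp(z)
  e / sum(e)
}

# -- Engine: history encoding ------------------------------------------------

# Half-move history: integer vector of action indices, odd positions are
# investor moves (index into INVESTOR_ACTIONS), even positions trustee moves
# (index into the legal repayment set for the preceding investment; a zero
# investment leaves the single forced index 1).  Cache keys use the digit
# string `hk` (one digit 1..5 per half-move), threaded through the recursion
# and extended by concatenation.

TRUSTEE_SETS <- lapply(c(0L, 5L, 10L, 15L, 20L), function(a) {
  if (a == 0L) 0 else TRUSTEE_FRACTIONS * 3 * a
})

.hkey <- function(h) if (length(h) == 0L) "" else paste(h, collapse = "")

.current_round <- function(h) length(h) %/% 2L + 1L

.mover_at <- function(h) if (length(h) %% 2L == 0L) "investor" else "trustee"

.mover_of_position <- function(n) if (n %% 2L == 1L) "investor" else "trustee"

#' Create an agent evaluation context
#'
#' Holds the memoization cache shared by policy, belief and likelihood
#' computations.  Reusing one context across grid points and model variants
#' for the same trajectory lets nested partner models be computed once;
#' caching never changes any probability (identical keys map to identical
#' deterministic computations).
#'
#' @param game_length Number of rounds (10 for the task; smaller only for
#'   truncated-horizon analyses).
#' @return Environment of class `agent_context`.
#' @export
agent_context <- function(game_length = N_ROUNDS) {
  ctx <- new.env(parent = emptyenv())
  ctx$memo <- new.env(hash = TRUE, parent = emptyenv())
  ctx$L <- as.integer(game_length)
  ctx$hits <- 0L
  ctx$misses <- 0L
  class(ctx) <- "agent_context"
  ctx
}

.memo_get <- function(ctx, key) {
  v <- get0(key, envir = ctx$memo, inherits = FALSE)
  if (!is.null(v)) ctx$hits <- ctx$hits + 1L
  v
}

.memo_set <- function(ctx, key, value) {
  ctx$misses <- ctx$misses + 1L
  assign(key, value, envir = ctx$memo)
  value
}

# Internal engine agent spec: plain list with precomputed cache-key parts.
# `omega` means the investor's own risk aversion when role == "investor" and
# the (assumed) investor risk aversion b^T(omega) when role == "trustee".
# `famp` keys the partner-model policy components, which depend only on the
# modelled level, the inherited risk-aversion assumption, beta and planning;
# `famb` adds the agent's irritation awareness q for belief-dependent
# quantities; `qsig` adds alpha and omega for action-value keys.
.eng_agent <- function(role, level, alpha, omega, zeta, q, beta, plan) {
  famp <- paste(substr(role, 1, 1), level,
                if (role == "trustee") omega else "", beta, plan, sep = "|")
  famb <- paste(famp, q, sep = "|")
  list(role = role, level = as.integer(level), alpha = alpha, omega = omega,
       zeta = zeta, q = as.integer(q), beta = beta, plan = as.integer(plan),
       famp = famp, famb = famb, qsig = paste(famb, alpha, omega, sep = "|"))
}

.eng_from_params <- function(params) {
  .eng_agent(params$role, params$k, params$alpha,
             if (params$role == "investor") params$omega else params$b_omega,
             params$zeta, params$q, params$beta, params$plan)
}

GRID_ALPHA <- c(0, 0.4, 1)
GRID_ZETA <- c(0, 0.25, 0.5, 0.75, 1)

# Nested model of the partner at one theory-of-mind level down.  Nested
# models share the modelling agent's beta, hold a uniform irritability
# prior (q = 2), and plan one round ahead (deep planning inside partner
# models multiplies the rollout tree at every level; one-step planning
# keeps them forward looking at tractable cost).  Risk aversion passes one
# level down the modelling chain: a trustee equips its direct investor
# models with its assumed b^T(omega); nested trustee models assume a
# risk-neutral investor (omega = 1), which keeps an investor's
# partner-model computations independent of the investor's own risk
# aversion.
.eng_nested <- function(ag, alpha, zeta) {
  .eng_agent(if (ag$role == "investor") "trustee" else "investor",
             ag$level - 1L, alpha,
             if (ag$role == "trustee") ag$omega else 1,
             zeta, 2L, ag$beta, 1L)
}

# -- Engine: static (level -1) policies --------------------------------------

# A static model neither learns nor plans.  A static trustee values
# repayments by immediate utility; a static investor values each investment
# by its expected immediate utility against the uniform-prior mixture of the
# three static trustee type policies (so its expected repayment fraction is
# the prior-weighted softmax response, below 1/3 -- which is what makes the
# irritated investor policy, alpha = 0 and omega >= 1, withhold investment).
# Both choose by softmax.
.eng_static_policy <- function(ctx, role, alpha, omega, beta, a_i_idx = NA) {
  key <- paste("ST", role, alpha, omega, beta, a_i_idx, sep = "|")
  v <- .memo_get(ctx, key)
  if (!is.null(v)) return(v)
  if (role == "investor") {
    u <- vapply(seq_along(INVESTOR_ACTIONS), function(i) {
      a <- INVESTOR_ACTIONS[i]
      if (a == 0L) return(.u_inv(alpha, omega, 0, 0))
      presp <- (.eng_static_policy(ctx, "trustee", GRID_ALPHA[1], 1, beta, i) +
                .eng_static_policy(ctx, "trustee", GRID_ALPHA[2], 1, beta, i) +
                .eng_static_policy(ctx, "trustee", GRID_ALPHA[3], 1, beta, i)) / 3
      sum(presp * .u_inv(alpha, omega, a, TRUSTEE_SETS[[i]]))
    }, numeric(1))
    p <- softmax_policy(u, beta)
  } else {
    a_i <- INVESTOR_ACTIONS[a_i_idx]
    if (a_i == 0L) {
      p <- 1
    } else {
      p <- softmax_policy(.u_tru(alpha, a_i, TRUSTEE_SETS[[a_i_idx]]), beta)
    }
  }
  .memo_set(ctx, key, p)
}

# Irritation weight of a static partner model with irritability `zeta` after
# history `h`.  A static model's expectation of the other side's move is the
# uniform-policy expectation: 10 coins for an incoming investment, `a_i`
# coins for a repayment to investment `a_i` (mean repayment fraction 1/3).
.eng_static_w <- function(ctx, role, zeta, h, hk) {
  if (zeta <= 0 || length(h) == 0L) return(0)
  key <- paste0("SW|", substr(role, 1, 1), zeta, "|", hk)
  v <- .memo_get(ctx, key)
  if (!is.null(v)) return(v)
  n <- length(h)
  w <- .eng_static_w(ctx, role, zeta, h[-n], substr(hk, 1L, n - 1L))
  observer_sees <- if (role == "investor") "trustee" else "investor"
  if (.mover_of_position(n) == observer_sees) {
    if (observer_sees == "investor") {
      obs <- INVESTOR_ACTIONS[h[n]]
      expd <- mean(INVESTOR_ACTIONS)
    } else {
      a_i_idx <- h[n - 1L]
      obs <- TRUSTEE_SETS[[a_i_idx]][h[n]]
      expd <- INVESTOR_ACTIONS[a_i_idx]
    }
    if (obs < expd - 1e-9) w <- min(w + zeta, 1)
    else if (obs > expd + 1e-9) w <- max(w - zeta, 0)
  }
  .memo_set(ctx, key, w)
}

# -- Engine: partner-type policies -------------------------------------------

# Components of the 15 partner-type policies (3 alpha x 5 zeta) for the move
# to be made at history `h`, each modeled at level ag$level - 1.  Every
# type's policy is its own irritation mixture
# (1 - w'(zeta')) * nonirritated(alpha') + w'(zeta') * irritated, where the
# irritated component has alpha = 0, no planning, no partner model, and risk
# aversion raised to at least 1.  Because planning rollouts evaluate future
# behaviour under the nonirritated policy, the nonirritated component is
# shared across the five zeta levels and the mixture is separable: only the
# three alpha-type policies, the irritated policy and the five irritation
# weights are stored.
.eng_partner_parts <- function(ctx, ag, h, hk) {
  key <- paste0("M|", ag$famp, "|", hk)
  v <- .memo_get(ctx, key)
  if (!is.null(v)) return(v)
  partner_role <- .mover_at(h)
  a_i_idx <- if (partner_role == "trustee") h[length(h)] else NA
  if (partner_role == "trustee" && INVESTOR_ACTIONS[a_i_idx] == 0L) {
    return(.memo_set(ctx, key, list(forced = TRUE)))
  }
  omega_p <- if (partner_role == "investor") ag$omega else 1
  p_irr <- .eng_static_policy(ctx, partner_role, 0, max(omega_p, 1), ag$beta,
                              a_i_idx)
  wzs <- numeric(5L)
  pols <- vector("list", 3L)
  if (ag$level == 0L) {
    for (ai in 1:3) {
      pols[[ai]] <- .eng_static_policy(ctx, partner_role, GRID_ALPHA[ai],
                                       omega_p, ag$beta, a_i_idx)
    }
    for (zi in 2:5) {
      wzs[zi] <- .eng_static_w(ctx, partner_role, GRID_ZETA[zi], h, hk)
    }
  } else {
    depth <- min(1L, ctx$L - .current_round(h))
    for (ai in 1:3) {
      nested <- .eng_nested(ag, GRID_ALPHA[ai], 0)
      pols[[ai]] <- softmax_policy(.eng_q(ctx, nested, h, hk, depth), ag$beta)
    }
    for (zi in 2:5) {
      wzs[zi] <- .eng_w(ctx, .eng_nested(ag, 0, GRID_ZETA[zi]), h, hk)
    }
  }
  .memo_set(ctx, key, list(forced = FALSE, pols = pols, p_irr = p_irr,
                           wzs = wzs))
}

# Belief-weighted mixture over the partner-type policies: the agent's
# predictive distribution for the partner's next move at `h`.
.eng_predict_partner <- function(ctx, ag, h, hk) {
  key <- paste0("PP|", ag$famb, "|", hk)
  v <- .memo_get(ctx, key)
  if (!is.null(v)) return(v)
  parts <- .eng_partner_parts(ctx, ag, h, hk)
  if (isTRUE(parts$forced)) return(.memo_set(ctx, key, 1))
  st <- .eng_beliefs(ctx, ag, h, hk)
  bA <- st$A / sum(st$A)
  bZ <- st$Z / sum(st$Z)
  wbar <- sum(bZ * parts$wzs)
  base <- bA[1L] * parts$pols[[1L]] + bA[2L] * parts$pols[[2L]] +
    bA[3L] * parts$pols[[3L]]
  .memo_set(ctx, key, (1 - wbar) * base + wbar * parts$p_irr)
}

# -- Engine: beliefs and irritation ------------------------------------------

# Dirichlet counts of agent `ag` after history `h`.  Own moves change
# nothing; each informative partner move adds the type likelihoods of the
# observed action: the investor's alpha update is gated to investments > 5,
# forced moves (trustee response to a zero investment) are skipped, and the
# zeta counts update only when irritation awareness q > 0.
.eng_beliefs <- function(ctx, ag, h, hk) {
  if (length(h) == 0L) {
    return(list(A = c(1, 1, 1), Z = irritation_priors()[[ag$q + 1L]]))
  }
  key <- paste0("B|", ag$famb, "|", hk)
  v <- .memo_get(ctx, key)
  if (!is.null(v)) return(v)
  n <- length(h)
  st <- .eng_beliefs(ctx, ag, h[-n], substr(hk, 1L, n - 1L))
  if (.mover_of_position(n) == ag$role) return(.memo_set(ctx, key, st))
  a_i <- NA
  if (ag$role == "investor") {
    a_i <- INVESTOR_ACTIONS[h[n - 1L]]
    if (a_i == 0L) return(.memo_set(ctx, key, st))  # forced: no information
  }
  parts <- .eng_partner_parts(ctx, ag, h[-n], substr(hk, 1L, n - 1L))
  o <- h[n]
  pol_o <- c(parts$pols[[1L]][o], parts$pols[[2L]][o], parts$pols[[3L]][o])
  irr_o <- parts$p_irr[o]
  bA <- st$A / sum(st$A)
  bZ <- st$Z / sum(st$Z)
  wbar <- sum(bZ * parts$wzs)
  if (ag$role == "trustee" || a_i > 5) {
    st$A <- st$A + (1 - wbar) * pol_o + wbar * irr_o     # p(o | alpha)
  }
  if (ag$q > 0L) {
    st$Z <- st$Z + (1 - parts$wzs) * sum(bA * pol_o) +
      parts$wzs * irr_o                                  # p(o | zeta)
  }
  .memo_set(ctx, key, st)
}

# Expected monetary value of the partner's move at `h` under the agent's
# current beliefs: the irritation-trigger reference point.
.eng_expectation <- function(ctx, ag, h, hk) {
  key <- paste0("E|", ag$famb, "|", hk)
  v <- .memo_get(ctx, key)
  if (!is.null(v)) return(v)
  vals <- if (.mover_at(h) == "investor") INVESTOR_ACTIONS else
    TRUSTEE_SETS[[h[length(h)]]]
  p <- .eng_predict_partner(ctx, ag, h, hk)
  .memo_set(ctx, key, sum(p * vals))
}

# Irritation mixture weight of agent `ag` after `h`: shifts toward the
# irritated policy by zeta after each below-expectation partner move and
# back after each above-expectation one, clamped to [0, 1].
.eng_w <- function(ctx, ag, h, hk) {
  if (ag$zeta <= 0 || length(h) == 0L) return(0)
  key <- paste0("W|", ag$famb, "|", ag$zeta, "|", hk)
  v <- .memo_get(ctx, key)
  if (!is.null(v)) return(v)
  n <- length(h)
  hk0 <- substr(hk, 1L, n - 1L)
  w <- .eng_w(ctx, ag, h[-n], hk0)
  if (.mover_of_position(n) != ag$role) {
    obs <- NA
    if (ag$role == "investor") {
      a_i_idx <- h[n - 1L]
      if (INVESTOR_ACTIONS[a_i_idx] > 0L) obs <- TRUSTEE_SETS[[a_i_idx]][h[n]]
    } else {
      obs <- INVESTOR_ACTIONS[h[n]]
    }
    if (!is.na(obs)) {
      expd <- .eng_expectation(ctx, ag, h[-n], hk0)
      if (obs < expd - 1e-9) w <- min(w + ag$zeta, 1)
      else if (obs > expd + 1e-9) w <- max(w - ag$zeta, 0)
    }
  }
  .memo_set(ctx, key, w)
}

# Composite state (beliefs + irritation weight), used by the exported
# surface.
.eng_state <- function(ctx, ag, h) {
  hk <- .hkey(h)
  st <- .eng_beliefs(ctx, ag, h, hk)
  list(A = st$A, Z = st$Z, w = .eng_w(ctx, ag, h, hk))
}

# -- Engine: planning recursion ----------------------------------------------

# Action values at history `h` for agent `ag` (whose turn it must be), with
# `depth` further rounds of lookahead.  Partner responses are predicted by
# the belief-weighted level-(k-1) partner mixture; future own behaviour is
# evaluated under the nonirritated softmax policy; values are backed up by
# expectation under that policy (soft Bellman backup, undiscounted).
.eng_q <- function(ctx, ag, h, hk, depth) {
  key <- paste0("Q|", ag$qsig, "|", depth, "|", hk)
  v <- .memo_get(ctx, key)
  if (!is.null(v)) return(v)
  t <- .current_round(h)
  future <- depth > 0L && t < ctx$L
  if (ag$role == "investor") {
    q <- numeric(5L)
    for (i in 1:5) {
      h1 <- c(h, i)
      hk1 <- paste0(hk, i)
      resp <- TRUSTEE_SETS[[i]]
      u <- .u_inv(ag$alpha, ag$omega, INVESTOR_ACTIONS[i], resp)
      presp <- if (i == 1L) 1 else .eng_predict_partner(ctx, ag, h1, hk1)
      if (future) {
        for (j in seq_along(resp)) {
          u[j] <- u[j] + .eng_value(ctx, ag, c(h1, j), paste0(hk1, j),
                                    depth - 1L)
        }
      }
      q[i] <- sum(presp * u)
    }
  } else {
    a_i_idx <- h[length(h)]
    resp <- TRUSTEE_SETS[[a_i_idx]]
    q <- .u_tru(ag$alpha, INVESTOR_ACTIONS[a_i_idx], resp)
    if (future) {
      for (j in seq_along(resp)) {
        h1 <- c(h, j)
        hk1 <- paste0(hk, j)
        pinv <- .eng_predict_partner(ctx, ag, h1, hk1)
        fut <- 0
        for (m in 1:5) {
          fut <- fut + pinv[m] * .eng_value(ctx, ag, c(h1, m),
                                            paste0(hk1, m), depth - 1L)
        }
        q[j] <- q[j] + fut
      }
    }
  }
  .memo_set(ctx, key, q)
}

# Expected value of standing at `h` (agent's own turn) with `depth`
# lookahead, under the nonirritated softmax policy.  Not memoized: each
# (history, depth) pair has a unique parent in the rollout tree and the
# underlying Q values are cached.
.eng_value <- function(ctx, ag, h, hk, depth) {
  q <- .eng_q(ctx, ag, h, hk, depth)
  if (length(q) == 1L) return(q)
  sum(softmax_policy(q, ag$beta) * q)
}

# Full policy of agent `ag` at its decision point `h`: planning horizon
# min(P, rounds remaining), irritation mixture applied at choice time.
.eng_policy <- function(ctx, ag, h, hk = .hkey(h)) {
  if (ag$level < 0L) stop("theory-of-mind level must be >= 0 for a planning policy")
  if (ag$plan < 1L) stop("planning horizon must be >= 1")
  key <- paste0("P|", ag$qsig, "|", ag$zeta, "|", hk)
  v <- .memo_get(ctx, key)
  if (!is.null(v)) return(v)
  t <- .current_round(h)
  if (t > ctx$L) stop("no decision remains after round ", ctx$L)
  if (ag$role == "trustee" && INVESTOR_ACTIONS[h[length(h)]] == 0L) {
    return(.memo_set(ctx, key, 1))
  }
  depth <- min(ag$plan, ctx$L - t)
  q <- .eng_q(ctx, ag, h, hk, depth)
  p <- softmax_policy(q, ag$beta)
  w <- .eng_w(ctx, ag, h, hk)
  if (w > 0) {
    a_i_idx <- if (ag$role == "trustee") h[length(h)] else NA
    p_irr <- .eng_static_policy(ctx, ag$role, 0, max(ag$omega, 1), ag$beta,
                                a_i_idx)
    p <- (1 - w) * p + w * p_irr
  }
  .memo_set(ctx, key, p)
}

# -- Exported decision surface ----------------------------------------------

# Build a half-move history vector from completed-round actions (+ optionally
# the pending investment of the current round, for a trustee decision).
.build_history <- function(investments, repayments, pending_investment = NULL) {
  ni <- length(investments)
  if (length(repayments) != ni) {
    stop("investments and repayments must describe the same completed rounds")
  }
  h <- integer(0)
  for (r in seq_len(ni)) {
    i_idx <- match(investments[r], INVESTOR_ACTIONS)
    if (is.na(i_idx)) stop("invalid investor action: ", investments[r])
    legal <- TRUSTEE_SETS[[i_idx]]
    t_idx <- which(abs(legal - repayments[r]) < 1e-9)
    if (length(t_idx) != 1L) {
      stop("invalid trustee repayment ", repayments[r], " for investment ",
           investments[r], "; legal repayments: ", paste(legal, collapse = ", "))
    }
    h <- c(h, i_idx, t_idx)
  }
  if (!is.null(pending_investment)) {
    i_idx <- match(pending_investment, INVESTOR_ACTIONS)
    if (is.na(i_idx)) stop("invalid investor action: ", pending_investment)
    h <- c(h, i_idx)
  }
  h
}

#' Expected action values under the generative agent model
#'
#' Computes Q values for the agent's decision at the current point of a game:
#' expected immediate utility plus the expected value of the next
#' `min(P, 10 - round)` rounds, with partner responses predicted by the
#' belief-weighted level-(k-1) partner model mixture and belief/irritation
#' states evolved along every considered continuation.
#'
#' @param agent An [agent_params()].
#' @param investments,repayments Actions of the completed rounds (possibly
#'   empty), in coins on the action grid.
#' @param pending_investment For a trustee decision: the current round's
#'   investment, already observed.
#' @param ctx An [agent_context()]; pass one to share cached computations
#'   across calls.  Defaults to a fresh context.
#' @param game_length Number of rounds in the game.
#' @return List with `actions` (legal actions in coins) and `q` (their
#'   values).
#' @export
#' @examples
#' ag <- agent_params("investor", alpha = 0, omega = 1, k = 0, plan = 1,
#'                    zeta = 0, q = 2, beta = 1)
#' action_values(ag)
action_values <- function(agent, investments = numeric(0),
                          repayments = numeric(0), pending_investment = NULL,
                          ctx = NULL, game_length = N_ROUNDS) {
  stopifnot(inherits(agent, "agent_params"))
  if (is.null(ctx)) ctx <- agent_context(game_length)
  ag <- .eng_from_params(agent)
  h <- .build_history(investments, repayments, pending_investment)
  if (.mover_at(h) != agent$role) {
    stop("it is not the ", agent$role, "'s turn at this history")
  }
  t <- .current_round(h)
  if (t > ctx$L) stop("the game is over after round ", ctx$L)
  depth <- min(ag$plan, ctx$L - t)
  q <- .eng_q(ctx, ag, h, .hkey(h), depth)
  acts <- if (agent$role == "investor") INVESTOR_ACTIONS else
    TRUSTEE_SETS[[h[length(h)]]]
  list(actions = acts, q = q)
}

#' Choice probabilities under the irritation-mixture policy
#'
#' `P[a] = (1 - w) * softmax_beta(Q_nonirritated)(a) +
#'  w * softmax_beta(Q_irritated)(a)`, where the irritated policy plans zero
#' steps ahead, has inequality aversion 0, models the partner at level -1,
#' and raises risk aversion to at least 1; `beta` and the remaining
#' parameters are unchanged.  The mixture weight `w` is the agent's
#' irritation state implied by the history (override with `w`).
#'
#' @inheritParams action_values
#' @param w Optional mixture-weight override in [0, 1].
#' @return List with `actions` and probability vector `prob`.
#' @export
choice_probabilities <- function(agent, investments = numeric(0),
                                 repayments = numeric(0),
                                 pending_investment = NULL, w = NULL,
                                 ctx = NULL, game_length = N_ROUNDS) {
  stopifnot(inherits(agent, "agent_params"))
  if (is.null(ctx)) ctx <- agent_context(game_length)
  ag <- .eng_from_params(agent)
  h <- .build_history(investments, repayments, pending_investment)
  if (.mover_at(h) != agent$role) {
    stop("it is not the ", agent$role, "'s turn at this history")
  }
  acts <- if (agent$role == "investor") INVESTOR_ACTIONS else
    TRUSTEE_SETS[[h[length(h)]]]
  if (is.null(w)) {
    p <- .eng_policy(ctx, ag, h)
  } else {
    stopifnot(w >= 0, w <= 1)
    t <- .current_round(h)
    depth <- min(ag$plan, ctx$L - t)
    q <- .eng_q(ctx, ag, h, .hkey(h), depth)
    if (length(acts) == 1L) {
      p <- 1
    } else {
      a_i_idx <- if (agent$role == "trustee") h[length(h)] else NA
      p_irr <- .eng_static_policy(ctx, ag$role, 0, max(ag$omega, 1), ag$beta,
                                  a_i_idx)
      p <- (1 - w) * softmax_policy(q, ag$beta) + w * p_irr
    }
  }
  list(actions = acts, prob = p)
}

#' Predictive distribution for the partner's next action
#'
#' The agent's belief-weighted mixture of level-(k-1) partner-type policies:
#' used for the irritation trigger, the approximate belief updates, and for
#' scoring trustee actions in the trajectory likelihood.
#'
#' @inheritParams action_values
#' @return List with `actions` (the partner's legal actions) and `prob`.
#' @export
partner_prediction <- function(agent, investments = numeric(0),
                               repayments = numeric(0),
                               pending_investment = NULL, ctx = NULL,
                               game_length = N_ROUNDS) {
  stopifnot(inherits(agent, "agent_params"))
  if (is.null(ctx)) ctx <- agent_context(game_length)
  ag <- .eng_from_params(agent)
  h <- .build_history(investments, repayments, pending_investment)
  if (.mover_at(h) == agent$role) {
    stop("it is the ", agent$role, "'s own turn at this history")
  }
  acts <- if (.mover_at(h) == "investor") INVESTOR_ACTIONS else
    TRUSTEE_SETS[[h[length(h)]]]
  if (length(acts) == 1L) return(list(actions = acts, prob = 1))
  list(actions = acts, prob = .eng_predict_partner(ctx, ag, h, .hkey(h)))
}

#' Belief and irritation state implied by a history
#'
#' @inheritParams action_values
#' @return List with Dirichlet counts `A_alpha` (partner inequality-aversion
#'   types), `Z` (partner irritability levels) and irritation weight `w`.
#' @export
agent_state <- function(agent, investments = numeric(0),
                        repayments = numeric(0), pending_investment = NULL,
                        ctx = NULL, game_length = N_ROUNDS) {
  stopifnot(inherits(agent, "agent_params"))
  if (is.null(ctx)) ctx <- agent_context(game_length)
  ag <- .eng_from_params(agent)
  h <- .build_history(investments, repayments, pending_investment)
  .eng_state(ctx, ag, h)
}
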