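# Synthetic-data generator: simulated games, longitudinal cohorts with the
# statistical structure the analysis stages assume, and parameter-recovery
# experiments.

# Run code with a temporary RNG state derived from `seed`, restoring the
# caller's RNG afterwards.
.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv())) {
          rm(".Random.seed", envir = globalenv())
        }
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Simulate one multi-round trust game
#'
#' Samples investments from the investor's irritation-mixture policy and
#' repayments from either a trustee agent's policy or a replay schedule of
#' canned repayment fractions, with belief and irritation states evolving
#' round by round on both sides.
#'
#' @param investor An [agent_params()] with role `"investor"`.
#' @param trustee An [agent_params()] with role `"trustee"`, or a numeric
#'   vector of repayment fractions (values in \{0, 1/6, 1/3, 1/2, 2/3\}, one
#'   per round) replayed regardless of history.
#' @param seed Integer seed; the trajectory is reproducible given the seed.
#' @param subject_id,timepoint Labels for the trajectory.
#' @param n_rounds Number of rounds (10 for the task).
#' @param ctx Optional shared [agent_context()]; passing one across many
#'   simulated games reuses the planning subtrees the agents revisit.
#' @return A [game_trajectory()].
#' @export
#' @examples
#' inv <- agent_params("investor", alpha = 0.4, omega = 1, k = 0, plan = 1,
#'                     zeta = 0, q = 2, beta = 1)
#' simulate_game(inv, rep(1/3, 10), seed = 1)
simulate_game <- function(investor, trustee, seed = NULL, subject_id = "s1",
                          timepoint = "T1", n_rounds = N_ROUNDS, ctx = NULL) {
  stopifnot(inherits(investor, "agent_params"), investor$role == "investor")
  replay <- NULL
  if (inherits(trustee, "agent_params")) {
    stopifnot(trustee$role == "trustee")
  } else {
    replay <- as.numeric(trustee)
    if (length(replay) != n_rounds ||
        !all(vapply(replay, .on_grid, logical(1), grid = TRUSTEE_FRACTIONS))) {
      stop("replay schedule must give one legal repayment fraction per round")
    }
  }
  if (is.null(ctx)) ctx <- agent_context(n_rounds)
  if (ctx$L != n_rounds) stop("context game_length does not match n_rounds")
  ag_i <- .eng_from_params(investor)
  ag_t <- if (is.null(replay)) .eng_from_params(trustee) else NULL
  .with_seed(seed, {
    h <- integer(0)
    inv <- numeric(n_rounds)
    rep_ <- numeric(n_rounds)
    for (r in seq_len(n_rounds)) {
      p_i <- .eng_policy(ctx, ag_i, h)
      i_idx <- sample.int(5L, 1L, prob = p_i)
      inv[r] <- INVESTOR_ACTIONS[i_idx]
      h <- c(h, i_idx)
      legal <- TRUSTEE_SETS[[i_idx]]
      if (length(legal) == 1L) {
        t_idx <- 1L
      } else if (!is.null(replay)) {
        t_idx <- which(abs(TRUSTEE_FRACTIONS - replay[r]) < 1e-9)
      } else {
        p_t <- .eng_policy(ctx, ag_t, h)
        t_idx <- sample.int(length(legal), 1L, prob = p_t)
      }
      rep_[r] <- legal[t_idx]
      h <- c(h, t_idx)
    }
    game_trajectory(inv, rep_, subject_id = subject_id, timepoint = timepoint,
                    n_rounds = n_rounds)
  })
}

#' Default algorithmic trustee
#'
#' A moderately trustworthy, mildly irritable trustee agent used as the
#' partner in synthetic cohorts: alpha = 0.4, theory of mind 1, planning 1,
#' irritability 0.25, uniform irritability prior, beta = 1/3, and an assumed
#' investor risk aversion of 1.  The trustee is fully configurable; a replay
#' mode (canned repayment fractions) is available wherever a trustee is
#' accepted.
#'
#' @return An [agent_params()] with role `"trustee"`.
#' @export
default_trustee <- function() {
  agent_params("trustee", alpha = 0.4, omega = 1, k = 1, plan = 1,
               zeta = 0.25, q = 2, beta = 1 / 3, b_omega = 1)
}

#' Configuration for synthetic cohort generation
#'
#' Defaults mirror the longitudinal study design the generator emulates:
#' baseline ages uniform on 14--25 years, a follow-up visit after an
#' interval of mean 1.48 (sd 0.29) years, social risk aversion declining
#' with both cross-sectional age and longitudinal development, irritability
#' probability increasing with a standard-normal family-adversity factor,
#' and three waves of friendship-questionnaire scores driven by wave,
#' baseline round-1 investment, adversity and their interaction.
#'
#' @param n_subjects Number of subjects.
#' @param age_range Baseline age range in years.
#' @param interval_mean,interval_sd Inter-visit interval distribution
#'   (years); intervals are truncated below at 0.5.
#' @param omega_base Latent mean risk aversion at the mean baseline age.
#' @param omega_age_slope Cross-sectional slope of latent omega on age
#'   (per year; negative = older subjects less risk averse).
#' @param omega_long_slope Longitudinal slope of latent omega on the
#'   inter-visit interval (per year; negative = risk aversion declines
#'   within person).
#' @param omega_noise_sd Subject-level noise on latent omega.
#' @param adversity_zeta_link Strength of the ordered-categorical link from
#'   the adversity factor to irritability (positive = more adversity, more
#'   irritable).
#' @param zeta_base_logits Baseline logits over the five irritability
#'   levels (most mass on zeta = 0).
#' @param alpha_probs,k_levels,plan_levels,beta_levels Sampling settings for
#'   the remaining investor parameters.
#' @param cfq_intercept,cfq_wave_slope,cfq_trust_slope,cfq_adversity_slope,cfq_interaction,cfq_noise_sd
#'   Friendship-score generator coefficients (interaction = adversity x
#'   baseline trust).
#' @param trustee Trustee for the simulated games: an [agent_params()] or a
#'   replay fraction schedule.
#' @param n_rounds Rounds per game.
#' @param seed Mandatory integer seed.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 30L,
                          age_range = c(14, 25),
                          interval_mean = 1.48, interval_sd = 0.29,
                          omega_base = 1.1,
                          omega_age_slope = -0.05,
                          omega_long_slope = -0.1,
                          omega_noise_sd = 0.2,
                          adversity_zeta_link = 1,
                          zeta_base_logits = c(2, 0, -0.5, -1, -1.5),
                          alpha_probs = c(0.3, 0.4, 0.3),
                          k_levels = 0:1,
                          plan_levels = 1L,
                          beta_levels = c(1 / 3, 1 / 2, 1),
                          cfq_intercept = 50,
                          cfq_wave_slope = 1,
                          cfq_trust_slope = 0.3,
                          cfq_adversity_slope = -2,
                          cfq_interaction = 0.15,
                          cfq_noise_sd = 5,
                          trustee = default_trustee(),
                          n_rounds = N_ROUNDS,
                          seed = NULL) {
  if (is.null(seed)) stop("a seed is mandatory for reproducible cohorts")
  if (interval_sd < 0 || omega_noise_sd < 0 || cfq_noise_sd < 0) {
    stop("standard deviations must be non-negative")
  }
  if (n_subjects < 0) stop("n_subjects must be >= 0")
  if (diff(age_range) < 0) stop("age_range must be increasing")
  if (length(alpha_probs) != 3L || any(alpha_probs < 0)) {
    stop("alpha_probs must be 3 non-negative weights")
  }
  if (length(zeta_base_logits) != 5L) {
    stop("zeta_base_logits must have length 5")
  }
  cfg <- as.list(environment())
  class(cfg) <- "cohort_config"
  cfg
}

#' Generate a synthetic longitudinal cohort
#'
#' Per subject: a baseline age, a follow-up visit after a sampled interval,
#' a standard-normal adversity factor, investor parameters with irritability
#' linked to adversity (softmax over the zeta grid with a linear shift) and
#' risk aversion declining in age and longitudinally, one simulated game per
#' visit, and three waves of friendship (CFQ-like) scores generated as a
#' linear function of wave, baseline round-1 investment, adversity and the
#' adversity-by-trust interaction plus noise.
#'
#' @param config A [cohort_config()].
#' @return List of class `synthetic_cohort` with `cohort` (long-format
#'   subject-by-visit data frame including true parameters), `cfq`
#'   (subject-by-wave data frame) and `trajectories` (list of
#'   [game_trajectory()], one per subject-visit).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cf <- config
  g <- param_grid_levels()
  sim_ctx <- agent_context(cf$n_rounds)
  .with_seed(cf$seed, {
    n <- cf$n_subjects
    subjects <- sprintf("s%03d", seq_len(n))
    rows <- list()
    cfq_rows <- list()
    trajs <- list()
    for (s in seq_len(n)) {
      age1 <- stats::runif(1, cf$age_range[1], cf$age_range[2])
      interval <- max(0.5, stats::rnorm(1, cf$interval_mean, cf$interval_sd))
      ages <- c(age1, age1 + interval)
      sex <- sample(c("female", "male"), 1L)
      adversity <- stats::rnorm(1)
      # irritability: ordered-categorical link, shift increasing in adversity
      logits <- cf$zeta_base_logits + cf$adversity_zeta_link * adversity *
        seq(0, 1, length.out = 5L)
      pz <- exp(logits - max(logits)); pz <- pz / sum(pz)
      zeta <- sample(g$zeta, 1L, prob = pz)
      alpha <- sample(g$alpha, 1L, prob = cf$alpha_probs)
      k <- sample(cf$k_levels, 1L)
      plan <- sample(cf$plan_levels, 1L)
      beta <- sample(cf$beta_levels, 1L)
      q <- if (zeta > 0) 2L else sample(0:2, 1L)
      mean_age_ref <- mean(cf$age_range)
      for (v in 1:2) {
        long_term <- if (v == 1) 0 else interval
        om_lat <- cf$omega_base +
          cf$omega_age_slope * (age1 - mean_age_ref) +
          cf$omega_long_slope * long_term +
          stats::rnorm(1, 0, cf$omega_noise_sd)
        omega <- g$omega[which.min(abs(g$omega - om_lat))]
        inv_params <- agent_params("investor", alpha = alpha, omega = omega,
                                   k = k, plan = plan, zeta = zeta, q = q,
                                   beta = beta)
        tp <- paste0("T", v)
        traj <- simulate_game(inv_params, cf$trustee,
                              seed = sample.int(.Machine$integer.max, 1L),
                              subject_id = subjects[s], timepoint = tp,
                              n_rounds = cf$n_rounds, ctx = sim_ctx)
        trajs[[length(trajs) + 1L]] <- traj
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = subjects[s], timepoint = tp, age = ages[v], sex = sex,
          adversity = adversity, true_alpha = alpha, true_omega = omega,
          true_k = k, true_plan = plan, true_zeta = zeta, true_q = q,
          true_beta = beta, stringsAsFactors = FALSE
        )
      }
      # three waves of friendship scores driven by baseline a-priori trust
      trust1 <- a_priori_trust(trajs[[length(trajs) - 1L]])
      for (wv in 1:3) {
        score <- cf$cfq_intercept + cf$cfq_wave_slope * (wv - 1) +
          cf$cfq_trust_slope * trust1 +
          cf$cfq_adversity_slope * adversity +
          cf$cfq_interaction * adversity * trust1 +
          stats::rnorm(1, 0, cf$cfq_noise_sd)
        cfq_rows[[length(cfq_rows) + 1L]] <- data.frame(
          subject_id = subjects[s], wave = wv, cfq = score,
          adversity = adversity, trust_t1 = trust1,
          age_at_wave = age1 + (wv - 1) * 1.13, sex = sex,
          stringsAsFactors = FALSE
        )
      }
    }
    empty_cohort <- data.frame(
      subject_id = character(0), timepoint = character(0), age = numeric(0),
      sex = character(0), adversity = numeric(0), true_alpha = numeric(0),
      true_omega = numeric(0), true_k = integer(0), true_plan = integer(0),
      true_zeta = numeric(0), true_q = integer(0), true_beta = numeric(0),
      stringsAsFactors = FALSE
    )
    empty_cfq <- data.frame(
      subject_id = character(0), wave = integer(0), cfq = numeric(0),
      adversity = numeric(0), trust_t1 = numeric(0), age_at_wave = numeric(0),
      sex = character(0), stringsAsFactors = FALSE
    )
    structure(
      list(
        cohort = if (length(rows)) do.call(rbind, rows) else empty_cohort,
        cfq = if (length(cfq_rows)) do.call(rbind, cfq_rows) else empty_cfq,
        trajectories = trajs,
        config = cf
      ),
      class = "synthetic_cohort"
    )
  })
}

#' @export
#' @method print synthetic_cohort
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>", length(unique(x$cohort$subject_id)), "subjects,",
      length(x$trajectories), "games,", nrow(x$cfq), "friendship-score rows\n")
  invisible(x)
}

#' Parameter-recovery experiment
#'
#' Simulates agents at known grid points, refits them by exhaustive grid
#' search, and reports per-parameter recovery: the truth/estimate table,
#' per-parameter confusion matrices, and exact and exact-or-adjacent (one
#' grid step) recovery rates.
#'
#' @param n_agents Number of simulated agents.
#' @param truth_grid Data frame of candidate true parameter points (columns
#'   alpha, omega, k, plan, zeta, q, beta); agents are sampled from its rows
#'   with replacement.
#' @param fit_grid Grid searched during refitting.
#' @param trustee Trustee for the simulated games.
#' @param scope Likelihood scope.
#' @param seed Integer seed.
#' @param n_rounds Rounds per game.
#' @return List of class `recovery_report` with `table` (truth and
#'   estimates per agent), `rates` (per-parameter exact and adjacent
#'   recovery), and `confusion` (named list of confusion matrices).
#' @export
recovery_experiment <- function(n_agents = 50L,
                                truth_grid = parameter_grid(
                                  reduced = TRUE, alpha = c(0, 1),
                                  plan = 1L, q = 2L, beta = 1,
                                  zeta = c(0, 0.5)),
                                fit_grid = truth_grid,
                                trustee = default_trustee(),
                                scope = "both_players",
                                seed = 1L, n_rounds = N_ROUNDS) {
  par_names <- c("alpha", "omega", "k", "plan", "zeta", "q", "beta")
  .with_seed(seed, {
    pick <- sample.int(nrow(truth_grid), n_agents, replace = TRUE)
    game_seeds <- sample.int(.Machine$integer.max, n_agents)
    sim_ctx <- agent_context(n_rounds)
    fit_ctx <- agent_context(n_rounds)
    fit_cache <- new.env(parent = emptyenv())
    rows <- list()
    for (i in seq_len(n_agents)) {
      tru <- truth_grid[pick[i], ]
      inv <- agent_params("investor", alpha = tru$alpha, omega = tru$omega,
                          k = tru$k, plan = tru$plan, zeta = tru$zeta,
                          q = tru$q, beta = tru$beta)
      traj <- simulate_game(inv, trustee, seed = game_seeds[i],
                            subject_id = sprintf("a%03d", i),
                            n_rounds = n_rounds, ctx = sim_ctx)
      # identical trajectories yield identical (deterministic) fits: fit each
      # distinct game once, sharing one cache across the grid evaluations
      tkey <- paste(traj$rounds$a_i, traj$rounds$a_t, collapse = "|")
      fit <- get0(tkey, envir = fit_cache, inherits = FALSE)
      if (is.null(fit)) {
        fit <- fit_subject(traj, model_spec("M1"), grid = fit_grid,
                           scope = scope, ctx = fit_ctx)
        assign(tkey, fit, envir = fit_cache)
      }
      est <- fit$params
      row <- data.frame(agent = i)
      for (nm in par_names) {
        row[[paste0("true_", nm)]] <- tru[[nm]]
        row[[paste0("est_", nm)]] <- if (nm == "plan") est$plan else est[[nm]]
      }
      row$nll <- fit$nll
      row$n_ties <- fit$n_ties
      rows[[i]] <- row
    }
    tab <- do.call(rbind, rows)
    rates <- list()
    confusion <- list()
    for (nm in par_names) {
      lv <- sort(unique(c(tab[[paste0("true_", nm)]], tab[[paste0("est_", nm)]])))
      tr <- tab[[paste0("true_", nm)]]
      es <- tab[[paste0("est_", nm)]]
      ti <- match(tr, lv)
      ei <- match(es, lv)
      confusion[[nm]] <- table(true = factor(tr, levels = lv),
                               est = factor(es, levels = lv))
      rates[[nm]] <- data.frame(
        parameter = nm,
        exact = mean(ti == ei),
        exact_or_adjacent = mean(abs(ti - ei) <= 1L)
      )
    }
    structure(
      list(table = tab, rates = do.call(rbind, rates), confusion = confusion,
           seed = seed),
      class = "recovery_report"
    )
  })
}

#' @export
#' @method print recovery_report
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>", nrow(x$table), "agents\n")
  print(x$rates, row.names = FALSE)
  invisible(x)
}
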