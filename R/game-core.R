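# -- Action space ------------------------------------------------------------

#' Discrete action space of the multi-round trust game
#'
#' The investor's 0--20 coin choice is discretized into five bins with
#' representatives 0, 5, 10, 15, 20.  The trustee repays one of five fractions
#' of the tripled investment: 0, 1/6, 1/3, 1/2 or 2/3.  When the investor
#' invests 0 the trustee has no choice: the only legal repayment is 0.
#'
#' @return A list with components `investor_breaks` (bin upper bounds),
#'   `investor_representatives`, and `trustee_fractions`.
#' @export
#' @examples
#' action_grid()$investor_representatives
action_grid <- function() {
  list(
    investor_breaks = c(2L, 7L, 12L, 17L, 20L),
    investor_representatives = c(0L, 5L, 10L, 15L, 20L),
    trustee_fractions = c(0, 1 / 6, 1 / 3, 1 / 2, 2 / 3)
  )
}

INVESTOR_ACTIONS <- c(0L, 5L, 10L, 15L, 20L)
TRUSTEE_FRACTIONS <- c(0, 1 / 6, 1 / 3, 1 / 2, 2 / 3)
N_ROUNDS <- 10L
ENDOWMENT <- 20L

#' Map a raw 0--20 investment to its bin representative
#'
#' Bins are \{[0,2], [3,7], [8,12], [13,17], [18,20]\} with representatives
#' 0, 5, 10, 15, 20.
#'
#' @param raw Integer vector of raw investments in coins, each in 0..20.
#' @return Integer vector of representatives.
#' @export
#' @examples
#' discretize_investment(c(2, 12, 18))
discretize_investment <- function(raw) {
  if (length(raw) == 0L) return(integer(0))
  if (anyNA(raw) || any(raw != as.integer(raw)) || any(raw < 0) || any(raw > 20)) {
    bad <- raw[is.na(raw) | raw != suppressWarnings(as.integer(raw)) | raw < 0 | raw > 20]
    stop("investment must be an integer in 0..20; offending value(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  idx <- findInterval(raw, c(0, 3, 8, 13, 18))
  INVESTOR_ACTIONS[idx]
}

#' Legal trustee repayments for a given investment
#'
#' For `a_i > 0` the five repayments are the trustee fractions applied to the
#' tripled investment, kept as exact doubles (e.g. 2.5 coins for `a_i = 5`,
#' fraction 1/6).  For `a_i = 0` the action set collapses to `0`.
#'
#' @param a_i Investor action in coins, one of 0, 5, 10, 15, 20.
#' @return Numeric vector of legal repayments, ascending.
#' @export
#' @examples
#' trustee_actions(5)
#' trustee_actions(0)
trustee_actions <- function(a_i) {
  check_investor_action(a_i)
  if (a_i == 0) return(0)
  TRUSTEE_FRACTIONS * 3 * a_i
}

check_investor_action <- function(a_i) {
  if (length(a_i) != 1L || is.na(a_i) || !(a_i %in% INVESTOR_ACTIONS)) {
    stop("invalid investor action: ", a_i,
         " (must be one of ", paste(INVESTOR_ACTIONS, collapse = ", "), ")")
  }
  invisible(a_i)
}

check_action_pair <- function(a_i, a_t) {
  check_investor_action(a_i)
  legal <- trustee_actions(a_i)
  if (length(a_t) != 1L || is.na(a_t) || !any(abs(legal - a_t) < 1e-9)) {
    stop("invalid trustee repayment ", a_t, " for investment ", a_i,
         "; legal repayments: ", paste(legal, collapse = ", "))
  }
  invisible(a_t)
}

#' Round payoffs for an investor/trustee action pair
#'
#' The investor keeps the uninvested endowment and receives the repayment; the
#' trustee keeps the tripled investment minus the repayment:
#' `chi_i = (20 - a_i) + a_t`, `chi_t = 3 a_i - a_t`.
#'
#' @param a_i Investment in coins (a grid representative).
#' @param a_t Repayment in coins, legal for `a_i`.
#' @return Named numeric vector `c(chi_i = , chi_t = )`.
#' @export
#' @examples
#' compute_payoffs(10, 15)
compute_payoffs <- function(a_i, a_t) {
  check_action_pair(a_i, a_t)
  c(chi_i = (ENDOWMENT - a_i) + a_t, chi_t = 3 * a_i - a_t)
}

# -- Trajectory container ----------------------------------------------------

#' Construct a game trajectory
#'
#' A trajectory is the ordered record of one 10-round game for one
#' subject-session: per round the (binned) investment and the repayment.
#'
#' @param investments Numeric vector of investments (grid representatives).
#' @param repayments Numeric vector of repayments, each legal for its round's
#'   investment.
#' @param subject_id Subject identifier.
#' @param timepoint Session / visit label (e.g. `"T1"`).
#' @param n_rounds Number of rounds; the task has 10, shorter games are
#'   permitted only for truncated-horizon analyses.
#' @return An object of class `game_trajectory`: a list with `subject_id`,
#'   `timepoint`, and a `rounds` data frame (`round`, `a_i`, `a_t`).
#' @export
#' @examples
#' tr <- game_trajectory(rep(10, 10), rep(15, 10))
#' tr
game_trajectory <- function(investments, repayments, subject_id = "s1",
                            timepoint = "T1", n_rounds = length(investments)) {
  if (length(investments) != n_rounds || length(repayments) != n_rounds) {
    stop("investments and repayments must each have length ", n_rounds)
  }
  if (n_rounds < 1L) stop("a trajectory needs at least one round")
  for (r in seq_len(n_rounds)) check_action_pair(investments[r], repayments[r])
  structure(
    list(
      subject_id = as.character(subject_id),
      timepoint = as.character(timepoint),
      rounds = data.frame(
        round = seq_len(n_rounds),
        a_i = as.numeric(investments),
        a_t = as.numeric(repayments)
      )
    ),
    class = "game_trajectory"
  )
}

#' @export
#' @method print game_trajectory
print.game_trajectory <- function(x, ...) {
  cat("<game_trajectory> subject", x$subject_id, "timepoint", x$timepoint,
      "-", nrow(x$rounds), "rounds\n")
  cat(" investments:", paste(x$rounds$a_i, collapse = " "), "\n")
  cat(" repayments: ", paste(x$rounds$a_t, collapse = " "), "\n")
  invisible(x)
}

#' @export
#' @method length game_trajectory
length.game_trajectory <- function(x) nrow(x$rounds)

is_full_game <- function(traj) nrow(traj$rounds) == N_ROUNDS
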