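# Model-free behavioural trust indices computed per trajectory.

#' A-priori (unconditional) trust
#'
#' The round-1 investment, made before any feedback from the partner.
#'
#' @param traj A [game_trajectory()].
#' @return Coins invested in round 1.
#' @export
a_priori_trust <- function(traj) {
  stopifnot(inherits(traj, "game_trajectory"))
  if (nrow(traj$rounds) < 1L) stop("empty trajectory")
  traj$rounds$a_i[1L]
}

#' Mean trust
#'
#' Arithmetic mean investment across the rounds of a game.
#'
#' @param traj A [game_trajectory()].
#' @return Mean investment in coins.
#' @export
mean_trust <- function(traj) {
  stopifnot(inherits(traj, "game_trajectory"))
  mean(traj$rounds$a_i)
}

# Repayment fraction per round: a_t / (3 a_i), NA when nothing was invested.
.repayment_fraction <- function(traj) {
  with(traj$rounds, ifelse(a_i > 0, a_t / (3 * a_i), NA_real_))
}

#' Reciprocity index
#'
#' Tit-for-tat-like adjustment of investment to the partner's previous
#' change in repayment.  The default operationalization is the ordinary
#' least-squares slope of the round-to-round investment change
#' `a_i[t] - a_i[t-1]` on the preceding change in repayment fraction
#' `f[t-1] - f[t-2]`; rounds with an undefined fraction (zero investment)
#' are dropped.  Returns `NA` when fewer than two usable pairs remain or the
#' predictor has zero variance.
#'
#' @param traj A [game_trajectory()].
#' @param method Operationalization; currently `"ols_slope"`.
#' @return Slope (coins per unit change in repayment fraction), or `NA`.
#' @export
reciprocity <- function(traj, method = c("ols_slope")) {
  method <- match.arg(method)
  stopifnot(inherits(traj, "game_trajectory"))
  inv <- traj$rounds$a_i
  f <- .repayment_fraction(traj)
  n <- length(inv)
  if (n < 3L) return(NA_real_)
  t_idx <- 3:n
  x <- f[t_idx - 1L] - f[t_idx - 2L]
  y <- inv[t_idx] - inv[t_idx - 1L]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L) return(NA_real_)
  vx <- stats::var(x)
  if (!is.finite(vx) || vx < 1e-12) {
    # no variation in the partner's behaviour; the slope is undefined unless
    # the response is constant too (then tit-for-tat adjustment is absent)
    if (stats::var(y) < 1e-12 && all(abs(y) < 1e-12)) return(0)
    return(NA_real_)
  }
  stats::cov(x, y) / vx
}

#' Retaliation index
#'
#' Mean change of investment following an unfair trustee action, defined by
#' default as a repayment fraction strictly below 1/3 of the tripled
#' investment (the trustee returned less than was invested).  Negative
#' values indicate retaliation (investment reductions after unfairness).
#' Returns `NA` when no qualifying event occurred.
#'
#' @param traj A [game_trajectory()].
#' @param fairness_threshold Repayment fraction below which a trustee action
#'   counts as unfair.
#' @return Mean next-round investment change in coins, or `NA`.
#' @export
retaliation_index <- function(traj, fairness_threshold = 1 / 3) {
  stopifnot(inherits(traj, "game_trajectory"))
  inv <- traj$rounds$a_i
  f <- .repayment_fraction(traj)
  n <- length(inv)
  if (n < 2L) return(NA_real_)
  t_idx <- 1:(n - 1L)
  unfair <- is.finite(f[t_idx]) & f[t_idx] < fairness_threshold - 1e-9
  if (!any(unfair)) return(NA_real_)
  mean(inv[t_idx + 1L][unfair] - inv[t_idx][unfair])
}

#' Total winnings of the investor
#'
#' Sum over rounds of the investor payoff `(20 - a_i) + a_t`.  Each round
#' starts from a fresh 20-coin endowment; coins are not carried over.
#'
#' @param traj A [game_trajectory()].
#' @return Total coins won.
#' @export
total_winnings <- function(traj) {
  stopifnot(inherits(traj, "game_trajectory"))
  sum((ENDOWMENT - traj$rounds$a_i) + traj$rounds$a_t)
}

#' All behavioural trust indices for one trajectory
#'
#' @param traj A [game_trajectory()].
#' @param fairness_threshold Passed to [retaliation_index()].
#' @return One-row data frame: subject_id, timepoint, a_priori_trust,
#'   mean_trust, reciprocity, retaliation_index, total_winnings.
#' @export
trust_indices <- function(traj, fairness_threshold = 1 / 3) {
  data.frame(
    subject_id = traj$subject_id,
    timepoint = traj$timepoint,
    a_priori_trust = a_priori_trust(traj),
    mean_trust = mean_trust(traj),
    reciprocity = reciprocity(traj),
    retaliation_index = retaliation_index(traj, fairness_threshold),
    total_winnings = total_winnings(traj),
    stringsAsFactors = FALSE
  )
}
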