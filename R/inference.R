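# Likelihood, exhaustive grid-search estimation and M1-M5 model comparison.

# -- Model variants ----------------------------------------------------------

#' Model-variant specification (M1--M5)
#'
#' The comparison set consists of nested restrictions of the full model:
#' \describe{
#'   \item{M1}{all seven parameters free (p = 7).}
#'   \item{M2}{irritability and irritation awareness fixed to 0 (p = 5).}
#'   \item{M3}{additionally risk aversion fixed to 1 and inverse temperature
#'     to 1/3 (p = 3).}
#'   \item{M4}{additionally theory of mind fixed to 0 (p = 2).}
#'   \item{M5}{uniform-random policy: every action in a five-option set has
#'     probability 1/5 (p = 0).}
#' }
#'
#' @param name One of `"M1"`..`"M5"`.
#' @return Object of class `model_spec` with the fixed-parameter map and the
#'   free-parameter count `p`.
#' @export
#' @examples
#' model_spec("M3")
model_spec <- function(name = c("M1", "M2", "M3", "M4", "M5")) {
  name <- match.arg(name)
  fixed <- switch(name,
    M1 = list(),
    M2 = list(zeta = 0, q = 0L),
    M3 = list(zeta = 0, q = 0L, omega = 1, beta = 1 / 3),
    M4 = list(zeta = 0, q = 0L, omega = 1, beta = 1 / 3, k = 0L),
    M5 = list()
  )
  p <- switch(name, M1 = 7L, M2 = 5L, M3 = 3L, M4 = 2L, M5 = 0L)
  structure(list(name = name, fixed = fixed, p = p, random = name == "M5"),
            class = "model_spec")
}

#' @export
#' @method print model_spec
print.model_spec <- function(x, ...) {
  cat("<model_spec>", x$name, "p =", x$p)
  if (length(x$fixed)) {
    cat("; fixed:", paste(names(x$fixed), unlist(x$fixed), sep = "=",
                          collapse = ", "))
  }
  if (x$random) cat(" (uniform-random policy)")
  cat("\n")
  invisible(x)
}

# -- Parameter grids ---------------------------------------------------------

#' Parameter grid for the exhaustive search
#'
#' The full grid is the Cartesian product of the seven parameter ranges
#' (24,000 points).  `reduced = TRUE` gives a desk-scale grid with theory of
#' mind restricted to \{0, 1\} and planning to \{1, 2\} (4,800 points);
#' individual levels can be overridden to shrink further.  All grids keep the
#' values 1 (omega), 1/3 (beta) and 0 (k, zeta, q) needed for the nested
#' model variants.
#'
#' @param reduced Use the reduced theory-of-mind/planning ranges.
#' @param ... Named level overrides, e.g. `omega = c(0.4, 1, 1.8)`.
#' @return Data frame with columns alpha, omega, k, plan, zeta, q, beta, in
#'   ascending lexicographic order over (alpha, omega, k, plan, zeta, q,
#'   beta).
#' @export
#' @examples
#' nrow(parameter_grid())          # 24000
#' nrow(parameter_grid(reduced = TRUE))
parameter_grid <- function(reduced = FALSE, ...) {
  lv <- param_grid_levels()
  if (reduced) {
    lv$k <- 0:1
    lv$plan <- 1:2
  }
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(lv)) stop("unknown parameter: ", nm)
    bad <- over[[nm]][!vapply(over[[nm]], .on_grid, logical(1),
                              grid = param_grid_levels()[[nm]])]
    if (length(bad)) stop("off-grid ", nm, " value(s): ", paste(bad, collapse = ", "))
    lv[[nm]] <- over[[nm]]
  }
  g <- expand.grid(beta = lv$beta, q = lv$q, zeta = lv$zeta, plan = lv$plan,
                   k = lv$k, omega = lv$omega, alpha = lv$alpha,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("alpha", "omega", "k", "plan", "zeta", "q", "beta")]
  rownames(g) <- NULL
  g
}

# Apply a model spec's fixed-parameter map to a grid and deduplicate.
.fix_grid <- function(grid, spec) {
  for (nm in names(spec$fixed)) grid[[nm]] <- spec$fixed[[nm]]
  grid <- unique(grid)
  grid <- grid[order(grid$alpha, grid$omega, grid$k, grid$plan, grid$zeta,
                     grid$q, grid$beta), , drop = FALSE]
  rownames(grid) <- NULL
  grid
}

# -- Trajectory likelihood ---------------------------------------------------

#' Negative log likelihood of a game trajectory
#'
#' Sums, over rounds, the negative natural-log probabilities of the observed
#' actions.  With `scope = "both_players"` (the default) investor actions are
#' scored under the subject model and trustee actions under the subject's
#' belief-weighted partner-model mixture, giving 20 modeled actions per full
#' game; `"investor_only"` scores the 10 investments alone.  Under the
#' uniform-random variant (M5) every action in a five-option set has
#' probability 1/5; a trustee's forced response to a zero investment
#' contributes log 1 = 0.
#'
#' @param params An [agent_params()] for the subject (investor role), or
#'   `NULL` for the uniform-random variant.
#' @param traj A [game_trajectory()].
#' @param scope `"both_players"` or `"investor_only"`.
#' @param ctx Optional [agent_context()] to share cached computations across
#'   grid points; its `game_length` must match the trajectory.
#' @return Negative log likelihood in nats (`Inf` if any observed action has
#'   zero probability).
#' @export
#' @examples
#' tr <- game_trajectory(rep(10, 10), rep(15, 10))
#' trajectory_nll(NULL, tr)   # uniform-random: 20 * log(5)
trajectory_nll <- function(params, traj,
                           scope = c("both_players", "investor_only"),
                           ctx = NULL) {
  scope <- match.arg(scope)
  stopifnot(inherits(traj, "game_trajectory"))
  nr <- nrow(traj$rounds)
  if (is.null(params)) {  # uniform-random policy
    nll <- nr * log(5)
    if (scope == "both_players") {
      nll <- nll + sum(traj$rounds$a_i > 0) * log(5)
    }
    return(nll)
  }
  stopifnot(inherits(params, "agent_params"))
  if (params$role != "investor") {
    stop("the subject model takes the investor role")
  }
  if (is.null(ctx)) ctx <- agent_context(nr)
  if (ctx$L != nr) stop("context game_length (", ctx$L,
                        ") does not match the trajectory (", nr, " rounds)")
  ag <- .eng_from_params(params)
  h <- integer(0)
  hk <- ""
  nll <- 0
  for (r in seq_len(nr)) {
    i_idx <- match(traj$rounds$a_i[r], INVESTOR_ACTIONS)
    p_inv <- .eng_policy(ctx, ag, h, hk)
    pr <- p_inv[i_idx]
    nll <- nll - if (pr > 0) log(pr) else Inf
    h <- c(h, i_idx)
    hk <- paste0(hk, i_idx)
    legal <- TRUSTEE_SETS[[i_idx]]
    t_idx <- which(abs(legal - traj$rounds$a_t[r]) < 1e-9)
    if (length(t_idx) != 1L) stop("repayment ", traj$rounds$a_t[r],
                                  " is not legal for investment ",
                                  traj$rounds$a_i[r])
    if (scope == "both_players" && length(legal) > 1L) {
      p_tr <- .eng_predict_partner(ctx, ag, h, hk)
      pr <- p_tr[t_idx]
      nll <- nll - if (pr > 0) log(pr) else Inf
    }
    h <- c(h, t_idx)
    hk <- paste0(hk, t_idx)
  }
  if (is.nan(nll)) nll <- Inf
  nll
}

# -- Draper BIC --------------------------------------------------------------

#' Draper Bayesian information criterion
#'
#' `BIC = NLL + (p / 2) * (log(10) - log(2 * pi))` in natural logs, where 10
#' is the number of modeled actions per player role and `p` the
#' free-parameter count.  Lower is better.
#'
#' @param nll Negative log likelihood in nats.
#' @param p Free-parameter count (>= 0).
#' @return BIC value.
#' @export
#' @examples
#' draper_bic(20 * log(5), 0)
draper_bic <- function(nll, p) {
  if (any(p < 0)) stop("parameter count p must be non-negative")
  nll + (p / 2) * (log(10) - log(2 * pi))
}

# -- Grid search -------------------------------------------------------------

#' Fit one subject-session by exhaustive grid search
#'
#' Evaluates the trajectory likelihood at every grid point (after applying
#' the model variant's fixed-parameter map) and returns the argmin.  Ties
#' within `1e-9` nats are broken by ascending lexicographic order over
#' (alpha, omega, k, plan, zeta, q, beta) and counted.
#'
#' @param traj A [game_trajectory()].
#' @param spec A [model_spec()] (default the full model M1).
#' @param grid Parameter grid data frame (see [parameter_grid()]); ignored
#'   for M5.
#' @param scope Likelihood scope, see [trajectory_nll()].
#' @param b_omega Trustee-assumption parameter used when scoring trustee
#'   actions is irrelevant for the investor-role subject model; retained for
#'   completeness (default 1).
#' @param ctx Optional shared [agent_context()].
#' @return Object of class `fit_result`: best parameters, `nll`, `p`, `bic`,
#'   `n_ties`, `grid_size`, and `unfittable` flag.
#' @export
fit_subject <- function(traj, spec = model_spec("M1"),
                        grid = parameter_grid(reduced = TRUE),
                        scope = c("both_players", "investor_only"),
                        b_omega = 1, ctx = NULL) {
  scope <- match.arg(scope)
  stopifnot(inherits(spec, "model_spec"))
  nr <- nrow(traj$rounds)
  if (is.null(ctx)) ctx <- agent_context(nr)
  if (spec$random) {
    nll <- trajectory_nll(NULL, traj, scope = scope)
    res <- list(model = spec$name, params = NULL, nll = nll, p = 0L,
                bic = draper_bic(nll, 0L), n_ties = 1L, grid_size = 1L,
                unfittable = FALSE)
    class(res) <- "fit_result"
    return(res)
  }
  grid <- .fix_grid(grid, spec)
  if (nrow(grid) == 0L) stop("empty parameter grid")
  nlls <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    pars <- agent_params("investor", alpha = grid$alpha[i],
                         omega = grid$omega[i], k = grid$k[i],
                         plan = grid$plan[i], zeta = grid$zeta[i],
                         q = grid$q[i], beta = grid$beta[i],
                         b_omega = b_omega)
    nlls[i] <- trajectory_nll(pars, traj, scope = scope, ctx = ctx)
  }
  if (all(!is.finite(nlls))) {
    res <- list(model = spec$name, params = NULL, nll = Inf, p = spec$p,
                bic = Inf, n_ties = 0L, grid_size = nrow(grid),
                unfittable = TRUE)
    class(res) <- "fit_result"
    return(res)
  }
  best <- which.min(nlls)  # grid is in lexicographic order: first min wins
  ties <- sum(nlls <= nlls[best] + 1e-9)
  pars <- agent_params("investor", alpha = grid$alpha[best],
                       omega = grid$omega[best], k = grid$k[best],
                       plan = grid$plan[best], zeta = grid$zeta[best],
                       q = grid$q[best], beta = grid$beta[best],
                       b_omega = b_omega)
  res <- list(model = spec$name, params = pars, nll = nlls[best], p = spec$p,
              bic = draper_bic(nlls[best], spec$p), n_ties = as.integer(ties),
              grid_size = nrow(grid), unfittable = FALSE)
  class(res) <- "fit_result"
  res
}

#' @export
#' @method print fit_result
print.fit_result <- function(x, ...) {
  cat("<fit_result>", x$model, "NLL =", round(x$nll, 3), "BIC =",
      round(x$bic, 3), "p =", x$p, "(", x$n_ties, "tie(s) over",
      x$grid_size, "grid points )\n")
  if (!is.null(x$params)) print(x$params)
  invisible(x)
}

#' Flatten a fit result to a one-row data frame
#'
#' @param fit A `fit_result`.
#' @param subject_id,timepoint Identifiers for the output row.
#' @return Data frame matching the fit-results CSV schema.
#' @export
fit_result_row <- function(fit, subject_id = NA, timepoint = NA) {
  p <- fit$params
  data.frame(
    subject_id = subject_id, timepoint = timepoint, model = fit$model,
    alpha = if (is.null(p)) NA_real_ else p$alpha,
    omega = if (is.null(p)) NA_real_ else p$omega,
    tom = if (is.null(p)) NA_integer_ else p$k,
    plan = if (is.null(p)) NA_integer_ else p$plan,
    zeta = if (is.null(p)) NA_real_ else p$zeta,
    q_zeta = if (is.null(p)) NA_integer_ else p$q,
    beta = if (is.null(p)) NA_real_ else p$beta,
    nll = fit$nll, p = fit$p, bic = fit$bic, n_ties = fit$n_ties,
    stringsAsFactors = FALSE
  )
}

#' Compare model variants across a cohort of trajectories
#'
#' Fits every model variant to every trajectory and averages the Draper BIC
#' per variant; variants are ranked ascending (lower mean BIC wins).
#' Subjects whose likelihood is infinite under a variant are excluded from
#' that variant's average with a warning.
#'
#' @param trajs List of [game_trajectory()] objects.
#' @param specs List of [model_spec()] objects.
#' @param grid Parameter grid used for the non-random variants.
#' @param scope Likelihood scope.
#' @return List with `summary` (data frame: model, mean_bic, mean_nll,
#'   n_subjects) sorted by mean BIC, and `fits` (data frame of per-subject
#'   fits).
#' @export
compare_models <- function(trajs, specs = lapply(paste0("M", 1:5), model_spec),
                           grid = parameter_grid(reduced = TRUE),
                           scope = c("both_players", "investor_only")) {
  scope <- match.arg(scope)
  if (length(trajs) < 1L) stop("need at least one trajectory")
  rows <- list()
  for (ti in seq_along(trajs)) {
    traj <- trajs[[ti]]
    ctx <- agent_context(nrow(traj$rounds))
    for (spec in specs) {
      fit <- fit_subject(traj, spec, grid = grid, scope = scope, ctx = ctx)
      if (fit$unfittable) {
        warning("subject ", traj$subject_id, " (", traj$timepoint,
                ") is unfittable under ", spec$name, "; excluded")
        next
      }
      rows[[length(rows) + 1L]] <-
        fit_result_row(fit, traj$subject_id, traj$timepoint)
    }
  }
  fits <- do.call(rbind, rows)
  agg <- aggregate(cbind(bic, nll) ~ model, data = fits, FUN = mean)
  n <- aggregate(subject_id ~ model, data = fits, FUN = length)
  out <- data.frame(model = agg$model, mean_bic = agg$bic,
                    mean_nll = agg$nll, n_subjects = n$subject_id)
  out <- out[order(out$mean_bic), ]
  rownames(out) <- NULL
  list(summary = out, fits = fits)
}
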