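# Brute-force oracle for the agent model: a plain enumerative implementation
# of the same generative semantics, independent of the package's engine.
# States are recomputed by walking the history (not evolved incrementally)
# and partner-type mixtures are formed over the full 15-type table (the
# engine instead uses a separable factorization).  Results are cached by a
# simple argument-keyed table so that repeated subcomputations do not repeat
# work; every path is still enumerated explicitly.  Tractable only on short
# games; used to validate the package's recursive engine on truncated
# histories.

.or_cache <- new.env(parent = emptyenv())
or_memo <- function(key, expr) {
  v <- get0(key, envir = .or_cache, inherits = FALSE)
  if (!is.null(v)) return(v)
  v <- force(expr)
  assign(key, v, envir = .or_cache)
  v
}
or_key <- function(tag, ag, h, extra = "") {
  paste(tag, ag$role, ag$level, ag$alpha, ag$omega, ag$zeta, ag$q, ag$beta,
        ag$plan, paste(h, collapse = "."), extra, sep = "|")
}

OR_ACTS <- c(0, 5, 10, 15, 20)
OR_FRC <- c(0, 1 / 6, 1 / 3, 1 / 2, 2 / 3)
OR_ALPHA <- c(0, 0.4, 1)
OR_ZETA <- c(0, 0.25, 0.5, 0.75, 1)
OR_PRIORS <- list(
  c(1, 0, 0, 0, 0),
  c(3, 0.5, 0.5, 0.5, 0.5),
  c(1, 1, 1, 1, 1),
  c(0.5, 0.5, 0.5, 0.5, 3),
  c(0, 1.25, 1.25, 1.25, 1.25)
)

or_tset <- function(i) if (i == 1) 0 else OR_FRC * 3 * OR_ACTS[i]

or_softmax <- function(u, b) {
  e <- exp(b * (u - max(u)))
  e / sum(e)
}

or_uinv <- function(al, om, a, at) {
  om * (20 - a) + at - al * pmax((20 - a + at) - (3 * a - at), 0)
}

or_utru <- function(al, a, at) {
  (3 * a - at) - al * pmax((3 * a - at) - (20 - a + at), 0)
}

or_agent <- function(role, level, alpha, omega, zeta, q, beta, plan) {
  list(role = role, level = level, alpha = alpha, omega = omega, zeta = zeta,
       q = q, beta = beta, plan = plan)
}

or_mover <- function(n) if (n %% 2 == 1) "investor" else "trustee"
or_turn <- function(h) if (length(h) %% 2 == 0) "investor" else "trustee"
or_round <- function(h) length(h) %/% 2 + 1

or_static_pol <- function(role, alpha, omega, beta, i_idx = NA) {
  if (role == "investor") {
    u <- sapply(1:5, function(i) {
      if (i == 1) return(or_uinv(alpha, omega, 0, 0))
      presp <- (or_static_pol("trustee", OR_ALPHA[1], 1, beta, i) +
                or_static_pol("trustee", OR_ALPHA[2], 1, beta, i) +
                or_static_pol("trustee", OR_ALPHA[3], 1, beta, i)) / 3
      sum(presp * or_uinv(alpha, omega, OR_ACTS[i], or_tset(i)))
    })
    or_softmax(u, beta)
  } else {
    if (i_idx == 1) return(1)
    or_softmax(or_utru(alpha, OR_ACTS[i_idx], or_tset(i_idx)), beta)
  }
}

or_static_w <- function(role, zeta, h) {
  if (zeta <= 0) return(0)
  w <- 0
  sees <- if (role == "investor") "trustee" else "investor"
  for (n in seq_along(h)) {
    if (or_mover(n) != sees) next
    if (sees == "investor") {
      obs <- OR_ACTS[h[n]]
      expd <- mean(OR_ACTS)
    } else {
      obs <- or_tset(h[n - 1])[h[n]]
      expd <- OR_ACTS[h[n - 1]]
    }
    if (obs < expd - 1e-9) w <- min(w + zeta, 1)
    else if (obs > expd + 1e-9) w <- max(w - zeta, 0)
  }
  w
}

# full 15-type partner-policy table for the move at `h` (partner of `ag`)
or_type_policies <- function(ag, h, L) {
  or_memo(or_key("tp", ag, h, L), or_type_policies_(ag, h, L))
}

or_type_policies_ <- function(ag, h, L) {
  partner_role <- or_turn(h)
  i_idx <- if (partner_role == "trustee") h[length(h)] else NA
  if (partner_role == "trustee" && OR_ACTS[i_idx] == 0) return("forced")
  omega_p <- if (partner_role == "investor") ag$omega else 1
  p_irr <- or_static_pol(partner_role, 0, max(omega_p, 1), ag$beta, i_idx)
  out <- vector("list", 15)
  for (ai in 1:3) {
    for (zi in 1:5) {
      al <- OR_ALPHA[ai]
      zt <- OR_ZETA[zi]
      if (ag$level == 0) {
        pn <- or_static_pol(partner_role, al, omega_p, ag$beta, i_idx)
        wz <- or_static_w(partner_role, zt, h)
      } else {
        sub <- or_agent(partner_role, ag$level - 1, al, omega_p, 0, 2,
                        ag$beta, 1)
        qn <- or_q(sub, h, min(1, L - or_round(h)), L)
        pn <- if (length(qn) == 1) 1 else or_softmax(qn, ag$beta)
        subz <- or_agent(partner_role, ag$level - 1, al, omega_p, zt, 2,
                         ag$beta, 1)
        wz <- or_w(subz, h, L)
      }
      out[[(ai - 1) * 5 + zi]] <-
        if (wz > 0) (1 - wz) * pn + wz * p_irr else pn
    }
  }
  out
}

or_beliefs <- function(ag, h, L) {
  or_memo(or_key("be", ag, h, L), or_beliefs_(ag, h, L))
}

or_beliefs_ <- function(ag, h, L) {
  A <- c(1, 1, 1)
  Z <- OR_PRIORS[[ag$q + 1]]
  for (n in seq_along(h)) {
    if (or_mover(n) == ag$role) next
    a_i <- NA
    if (ag$role == "investor") {
      a_i <- OR_ACTS[h[n - 1]]
      if (a_i == 0) next
    }
    tp <- or_type_policies(ag, h[seq_len(n - 1)], L)
    o <- h[n]
    bA <- A / sum(A)
    bZ <- Z / sum(Z)
    lik <- matrix(0, 3, 5)
    for (ai in 1:3) for (zi in 1:5) lik[ai, zi] <- tp[[(ai - 1) * 5 + zi]][o]
    if (ag$role == "trustee" || a_i > 5) A <- A + as.numeric(lik %*% bZ)
    if (ag$q > 0) Z <- Z + as.numeric(bA %*% lik)
  }
  list(A = A, Z = Z)
}

or_predict <- function(ag, h, L) {
  or_memo(or_key("pr", ag, h, L), or_predict_(ag, h, L))
}

or_predict_ <- function(ag, h, L) {
  tp <- or_type_policies(ag, h, L)
  if (identical(tp, "forced")) return(1)
  st <- or_beliefs(ag, h, L)
  bA <- st$A / sum(st$A)
  bZ <- st$Z / sum(st$Z)
  p <- 0
  for (ai in 1:3) {
    for (zi in 1:5) {
      p <- p + bA[ai] * bZ[zi] * tp[[(ai - 1) * 5 + zi]]
    }
  }
  p
}

or_w <- function(ag, h, L) {
  or_memo(or_key("w", ag, h, L), or_w_(ag, h, L))
}

or_w_ <- function(ag, h, L) {
  if (ag$zeta <= 0) return(0)
  w <- 0
  for (n in seq_along(h)) {
    if (or_mover(n) == ag$role) next
    if (ag$role == "investor") {
      if (OR_ACTS[h[n - 1]] == 0) next
      obs <- or_tset(h[n - 1])[h[n]]
    } else {
      obs <- OR_ACTS[h[n]]
    }
    hprev <- h[seq_len(n - 1)]
    vals <- if (or_turn(hprev) == "investor") OR_ACTS else or_tset(hprev[length(hprev)])
    expd <- sum(or_predict(ag, hprev, L) * vals)
    if (obs < expd - 1e-9) w <- min(w + ag$zeta, 1)
    else if (obs > expd + 1e-9) w <- max(w - ag$zeta, 0)
  }
  w
}

or_q <- function(ag, h, depth, L) {
  or_memo(or_key("q", ag, h, paste(depth, L)), or_q_(ag, h, depth, L))
}

or_q_ <- function(ag, h, depth, L) {
  t <- or_round(h)
  future <- depth > 0 && t < L
  if (ag$role == "investor") {
    q <- numeric(5)
    for (i in 1:5) {
      h1 <- c(h, i)
      resp <- or_tset(i)
      u <- or_uinv(ag$alpha, ag$omega, OR_ACTS[i], resp)
      presp <- if (i == 1) 1 else or_predict(ag, h1, L)
      if (future) {
        for (j in seq_along(resp)) {
          u[j] <- u[j] + or_v(ag, c(h1, j), depth - 1, L)
        }
      }
      q[i] <- sum(presp * u)
    }
    q
  } else {
    i_idx <- h[length(h)]
    resp <- or_tset(i_idx)
    q <- or_utru(ag$alpha, OR_ACTS[i_idx], resp)
    if (future) {
      for (j in seq_along(resp)) {
        h1 <- c(h, j)
        pinv <- or_predict(ag, h1, L)
        for (m in 1:5) {
          q[j] <- q[j] + pinv[m] * or_v(ag, c(h1, m), depth - 1, L)
        }
      }
    }
    q
  }
}

or_v <- function(ag, h, depth, L) {
  q <- or_q(ag, h, depth, L)
  if (length(q) == 1) return(q)
  sum(or_softmax(q, ag$beta) * q)
}

or_policy <- function(ag, h, L) {
  if (ag$role == "trustee" && OR_ACTS[h[length(h)]] == 0) return(1)
  depth <- min(ag$plan, L - or_round(h))
  q <- or_q(ag, h, depth, L)
  p <- or_softmax(q, ag$beta)
  w <- or_w(ag, h, L)
  if (w > 0) {
    i_idx <- if (ag$role == "trustee") h[length(h)] else NA
    p_irr <- or_static_pol(ag$role, 0, max(ag$omega, 1), ag$beta, i_idx)
    p <- (1 - w) * p + w * p_irr
  }
  p
}

# negative log likelihood of a trajectory by stepwise enumeration
or_nll <- function(params, traj, scope = "both_players") {
  L <- nrow(traj$rounds)
  ag <- or_agent("investor", params$k, params$alpha, params$omega,
                 params$zeta, params$q, params$beta, params$plan)
  h <- integer(0)
  nll <- 0
  for (r in seq_len(L)) {
    i_idx <- match(traj$rounds$a_i[r], OR_ACTS)
    nll <- nll - log(or_policy(ag, h, L)[i_idx])
    h <- c(h, i_idx)
    legal <- or_tset(i_idx)
    t_idx <- which(abs(legal - traj$rounds$a_t[r]) < 1e-9)
    if (scope == "both_players" && length(legal) > 1) {
      nll <- nll - log(or_predict(ag, h, L)[t_idx])
    }
    h <- c(h, t_idx)
  }
  nll
}
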