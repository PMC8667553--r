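#' Penalty configuration
#'
#' Collects the regularization hyperparameters shared by the loss functions:
#' the sparsity strength `lambda`, the multi-task coupling strength `mu`, the
#' group-weight exponent `w` (groups are weighted `|g|^w`; the default 0.5
#' gives the customary `sqrt(|g|)` group lasso weighting), the tolerance
#' below which a group block counts as inactive inside the coupling
#' indicator, and which coupling variant to use.
#'
#' @param lambda Non-negative sparsity strength.
#' @param mu Non-negative coupling strength.
#' @param weight_exponent Exponent `w` in the per-group weight `|g|^w`.
#' @param indicator_tolerance Block-norm threshold for the coupling
#'   indicator function.
#' @param variant One of `"main"`, `"abs_difference"`, `"cosine"`,
#'   `"normalized_difference"`.
#' @return A `penalty_config` list.
#' @export
penalty_config <- function(lambda = 0, mu = 0, weight_exponent = 0.5,
                           indicator_tolerance = 1e-8,
                           variant = c("main", "abs_difference", "cosine",
                                       "normalized_difference")) {
  variant <- match.arg(variant)
  stopifnot(lambda >= 0, mu >= 0, indicator_tolerance >= 0)
  structure(list(lambda = lambda, mu = mu,
                 weight_exponent = weight_exponent,
                 indicator_tolerance = indicator_tolerance,
                 variant = variant),
            class = "penalty_config")
}

# Risk-set bookkeeping shared by the value and gradient of the partial
# likelihood.  Ties use the Breslow convention: the risk set at an event
# time Y_i is every subject with Y_j >= Y_i, tied events included.
cox_risk_sets <- function(time) {
  ord <- order(time)
  t_sorted <- time[ord]
  n <- length(time)
  # first/last index of each tie block, per sorted position
  first_new <- !duplicated(t_sorted)
  block_id <- cumsum(first_new)
  block_first <- match(block_id, block_id)              # first pos of my block
  block_last <- n + 1L - match(block_id, rev(block_id)) # last pos of my block
  list(ord = ord, block_first = block_first, block_last = block_last)
}

#' Cox negative log-partial likelihood
#'
#' Evaluates `l(beta) = -sum over events i of (x_i . beta - log sum over
#' j in the risk set of exp(x_j . beta))`, where the risk set of event `i`
#' is every subject with `Y_j >= Y_i` (Breslow convention for ties).  The
#' log-sum-exp is computed with a max shift, so the value is finite for any
#' finite inputs.
#'
#' @param beta Coefficient vector, one entry per column of `x`.
#' @param x Covariate matrix, samples in rows.
#' @param time Observed times.
#' @param event 0/1 status indicators; at least one event is required.
#' @return The negative log-partial likelihood (a scalar).
#' @export
cox_nll <- function(beta, x, time, event) {
  stopifnot(length(beta) == ncol(x), nrow(x) == length(time),
            length(time) == length(event))
  if (sum(event) == 0) {
    rlang::abort("partial likelihood undefined without any event")
  }
  eta <- drop(x %*% beta)
  mx <- max(eta)
  e <- exp(eta - mx)
  rs <- cox_risk_sets(time)
  e_sorted <- e[rs$ord]
  s_tail <- rev(cumsum(rev(e_sorted)))       # sum over Y_j >= (sorted pos)
  log_s <- mx + log(s_tail[rs$block_first])  # risk-set log-sum-exp per subject
  ev_sorted <- event[rs$ord] == 1
  -sum(eta[rs$ord][ev_sorted] - log_s[ev_sorted])
}

# Gradient of cox_nll with respect to beta: X' (w - d), where d is the event
# indicator and w_j = exp(eta_j) * sum over events i with Y_i <= Y_j of
# 1 / S_i (Breslow risk-set sums S_i).
cox_nll_grad <- function(beta, x, time, event) {
  eta <- drop(x %*% beta)
  mx <- max(eta)
  e <- exp(eta - mx)
  rs <- cox_risk_sets(time)
  e_sorted <- e[rs$ord]
  s_tail <- rev(cumsum(rev(e_sorted)))
  s_i <- s_tail[rs$block_first]
  ev_sorted <- as.double(event[rs$ord] == 1)
  a <- ev_sorted / s_i
  cum_a <- cumsum(a)[rs$block_last]  # events with Y_i <= Y_j, ties included
  w_sorted <- e_sorted * cum_a
  resid <- numeric(length(eta))
  resid[rs$ord] <- w_sorted - ev_sorted
  drop(crossprod(x, resid))
}

#' Lasso penalty
#'
#' `lambda * sum(|beta_k|)`, the standard L1 penalty inducing gene-level
#' sparsity.
#'
#' @param beta Coefficient vector.
#' @param lambda Non-negative strength.
#' @return Scalar penalty value.
#' @export
lasso_penalty <- function(beta, lambda) {
  stopifnot(lambda >= 0)
  lambda * sum(abs(beta))
}

#' Latent group lasso penalty
#'
#' `lambda * sum over groups g of |g|^w * ||beta_g||_2` on the disjoint
#' block partition of a latent design.  The L2 norm within a block and L1
#' across blocks zeroes whole pathways at once.
#'
#' @param beta Coefficient vector in latent space.
#' @param design A [build_latent_design()] result.
#' @param lambda Non-negative strength.
#' @param weight_exponent Exponent `w` of the group weight `|g|^w`.
#' @return Scalar penalty value.
#' @export
group_lasso_penalty <- function(beta, design, lambda, weight_exponent = 0.5) {
  stopifnot(lambda >= 0, length(beta) == ncol(design$x))
  w <- design$group_sizes^weight_exponent
  lambda * sum(w * group_norms(beta, design))
}

# Subgradient of the group lasso penalty; zero on blocks at the origin.
group_lasso_subgrad <- function(beta, design, lambda, weight_exponent = 0.5) {
  g <- numeric(length(beta))
  norms <- group_norms(beta, design)
  w <- design$group_sizes^weight_exponent
  for (k in seq_along(design$groups)) {
    if (norms[k] > 0) {
      idx <- design$groups[[k]]
      g[idx] <- lambda * w[k] * beta[idx] / norms[k]
    }
  }
  g
}

coupling_terms <- function(b1, b2, design, cfg) {
  eps <- cfg$indicator_tolerance
  lapply(design$groups, function(idx) {
    u <- b1[idx]; v <- b2[idx]
    ru <- sqrt(sum(u^2)); rv <- sqrt(sum(v^2))
    list(u = u, v = v, ru = ru, rv = rv,
         active = ru > eps && rv > eps)
  })
}

#' Multi-task coupling penalty
#'
#' The pairwise penalty `C_mu = mu * sum over groups g of |g|^w *
#' sqrt(A_g^{12}^2 + A_g^{21}^2)` with `A_g^{ij} = || beta_g^i - beta_g^j *
#' (||beta_g^i|| / ||beta_g^j||) || * I(||beta_g^i|| > eps) *
#' I(||beta_g^j|| > eps)`.  It matches the two cohorts' active blocks up to
#' a positive per-group scale (so a pathway may be differentially predictive
#' without cost), exempts any group inactive in either cohort via the
#' indicators, and is symmetric in its two arguments.
#'
#' @param beta1,beta2 Latent coefficient vectors on the same design.
#' @param design The shared `latent_design`.
#' @param mu Non-negative coupling strength.
#' @param cfg A [penalty_config()] supplying `weight_exponent`,
#'   `indicator_tolerance` and `variant`.
#' @return Scalar penalty value.
#' @export
coupling_penalty <- function(beta1, beta2, design, mu,
                             cfg = penalty_config()) {
  stopifnot(mu >= 0)
  if (length(beta1) != ncol(design$x) || length(beta2) != ncol(design$x)) {
    rlang::abort("coefficient vectors must live on the supplied latent design")
  }
  if (cfg$variant != "main") {
    return(coupling_penalty_variant(beta1, beta2, design, mu, cfg$variant,
                                    weight_exponent = cfg$weight_exponent,
                                    indicator_tolerance = cfg$indicator_tolerance))
  }
  w <- design$group_sizes^cfg$weight_exponent
  terms <- coupling_terms(beta1, beta2, design, cfg)
  per_group <- vapply(terms, function(tt) {
    if (!tt$active) return(0)
    a12 <- sqrt(sum((tt$u - tt$v * (tt$ru / tt$rv))^2))
    a21 <- sqrt(sum((tt$v - tt$u * (tt$rv / tt$ru))^2))
    sqrt(a12^2 + a21^2)
  }, numeric(1))
  mu * sum(w * per_group)
}

#' Alternative coupling penalties
#'
#' Three simpler coupling terms kept for comparison with the main penalty:
#' `abs_difference` penalizes `||beta_g^1 - beta_g^2||` directly (no
#' rescaling, so differentially scaled cohorts are penalized);
#' `cosine` penalizes `1 - cos(beta_g^1, beta_g^2)`; and
#' `normalized_difference` penalizes the distance between the two unit
#' block vectors.  For the latter two, groups inactive in either cohort are
#' skipped.
#'
#' @inheritParams coupling_penalty
#' @param variant Which alternative to evaluate.
#' @param weight_exponent,indicator_tolerance See [penalty_config()].
#' @return Scalar penalty value.
#' @export
coupling_penalty_variant <- function(beta1, beta2, design, mu,
                                     variant = c("abs_difference", "cosine",
                                                 "normalized_difference"),
                                     weight_exponent = 0.5,
                                     indicator_tolerance = 1e-8) {
  variant <- match.arg(variant)
  stopifnot(mu >= 0)
  w <- design$group_sizes^weight_exponent
  cfg <- penalty_config(indicator_tolerance = indicator_tolerance)
  terms <- coupling_terms(beta1, beta2, design, cfg)
  per_group <- vapply(terms, function(tt) {
    switch(variant,
      abs_difference = sqrt(sum((tt$u - tt$v)^2)),
      cosine = {
        if (!tt$active) 0
        else 1 - sum(tt$u * tt$v) / (tt$ru * tt$rv)
      },
      normalized_difference = {
        if (!tt$active) 0
        else sqrt(sum((tt$u / tt$ru - tt$v / tt$rv)^2))
      }
    )
  }, numeric(1))
  mu * sum(w * per_group)
}

# Gradient of the main coupling penalty with respect to (beta1, beta2).
# Indicator gating and block norms crossing zero make the term
# non-differentiable there; gated groups and zero blocks get gradient 0.
coupling_grad <- function(beta1, beta2, design, mu, cfg = penalty_config()) {
  g1 <- numeric(length(beta1))
  g2 <- numeric(length(beta2))
  if (mu == 0) return(list(g1 = g1, g2 = g2))
  w <- design$group_sizes^cfg$weight_exponent
  terms <- coupling_terms(beta1, beta2, design, cfg)
  for (k in seq_along(design$groups)) {
    tt <- terms[[k]]
    if (!tt$active) next
    idx <- design$groups[[k]]
    u <- tt$u; v <- tt$v; ru <- tt$ru; rv <- tt$rv
    d12 <- u - v * (ru / rv)
    d21 <- v - u * (rv / ru)
    tg <- sqrt(sum(d12^2) + sum(d21^2))
    if (tg <= cfg$indicator_tolerance) next  # proportional blocks: subgradient 0
    # d/du of |d12|^2 and |d21|^2 (and symmetrically for v)
    du <- (d12 - (sum(v * d12) / (rv * ru)) * u) +
      (-(rv / ru) * d21 + (rv / ru^3) * sum(u * d21) * u)
    dv <- (d21 - (sum(u * d21) / (ru * rv)) * v) +
      (-(ru / rv) * d12 + (ru / rv^3) * sum(v * d12) * v)
    g1[idx] <- mu * w[k] * du / tg
    g2[idx] <- mu * w[k] * dv / tg
  }
  list(g1 = g1, g2 = g2)
}

#' Single-cohort penalized Cox loss
#'
#' `cox_nll(beta) + lambda * sum_g |g|^w ||beta_g||` on a latent design, or
#' `cox_nll(beta) + lambda * ||beta||_1` on a plain matrix.
#'
#' @param beta Coefficient vector.
#' @param design A `latent_design` (group lasso) or a plain numeric matrix
#'   (gene-level lasso).
#' @param time,event Survival outcome vectors.
#' @param cfg A [penalty_config()].
#' @return Scalar loss.
#' @export
total_loss_single <- function(beta, design, time, event,
                              cfg = penalty_config()) {
  if (inherits(design, "latent_design")) {
    cox_nll(beta, design$x, time, event) +
      group_lasso_penalty(beta, design, cfg$lambda, cfg$weight_exponent)
  } else {
    cox_nll(beta, design, time, event) + lasso_penalty(beta, cfg$lambda)
  }
}

#' Joint two-cohort loss with coupling
#'
#' The sum of the two cohorts' penalized Cox losses plus the coupling
#' penalty `C_mu(beta1, beta2)`.  At `mu = 0` it equals the sum of the two
#' single-cohort losses exactly.
#'
#' @param beta1,beta2 Latent coefficient vectors.
#' @param design1,design2 The two cohorts' latent designs (built from the
#'   same pathway collection, so the group partitions align).
#' @param time1,event1,time2,event2 Per-cohort outcomes.
#' @param cfg1,cfg2 Per-cohort [penalty_config()]s (their `lambda`s may
#'   differ); `cfg1` also supplies `mu` and the coupling settings.
#' @return Scalar loss.
#' @export
total_loss_pair <- function(beta1, beta2, design1, design2,
                            time1, event1, time2, event2,
                            cfg1 = penalty_config(), cfg2 = cfg1) {
  if (!identical(names(design1$groups), names(design2$groups)) ||
      !identical(design1$group_sizes, design2$group_sizes)) {
    rlang::abort("the two cohorts must share one latent group structure")
  }
  total_loss_single(beta1, design1, time1, event1, cfg1) +
    total_loss_single(beta2, design2, time2, event2, cfg2) +
    coupling_penalty(beta1, beta2, design1, cfg1$mu, cfg1)
}
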