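#' Optimizer configuration
#'
#' Settings for the first-order adaptive-moment (Adam) minimization of the
#' penalized Cox losses.  The truncation threshold follows the convention of
#' zeroing a whole group when every coefficient in it is below 0.001 in
#' absolute value after optimization.  Setting `convergence_tolerance = 0`
#' disables early stopping and runs exactly `max_iterations` steps, which
#' makes paired and single fits bit-comparable.
#'
#' @param max_iterations Maximum Adam steps.
#' @param learning_rate Adam step size.
#' @param truncation_threshold Post-hoc group truncation level.
#' @param convergence_tolerance Relative loss-change threshold over a
#'   10-iteration window; 0 disables early stopping.
#' @param seed Seed for the random initialization.
#' @param init_scale Standard deviation of the `N(0, init_scale^2)`
#'   initialization around zero.
#' @param polyak_window Width of the exponential tail average of the
#'   iterates returned as the solution.  Coefficients whose optimum is zero
#'   oscillate around it at the scale of the Adam step under the
#'   non-smooth penalties; averaging cancels the oscillation so post-hoc
#'   truncation can zero them, while converged coordinates are unaffected.
#'   0 returns the raw final iterate.
#' @return A `fit_config` list.
#' @export
fit_config <- function(max_iterations = 5000, learning_rate = 0.01,
                       truncation_threshold = 0.001,
                       convergence_tolerance = 1e-6,
                       seed = 1, init_scale = 0.01,
                       polyak_window = 100) {
  stopifnot(max_iterations >= 1, learning_rate > 0,
            truncation_threshold >= 0, convergence_tolerance >= 0,
            init_scale >= 0, polyak_window >= 0)
  structure(list(max_iterations = as.integer(max_iterations),
                 learning_rate = learning_rate,
                 truncation_threshold = truncation_threshold,
                 convergence_tolerance = convergence_tolerance,
                 seed = as.integer(seed), init_scale = init_scale,
                 polyak_window = polyak_window),
            class = "fit_config")
}

# Adam minimization of loss_fn with gradient grad_fn from beta0.
# Returns beta, per-iteration loss trace and convergence status.
adam_minimize <- function(beta0, loss_fn, grad_fn, cfg) {
  beta <- beta0
  beta_avg <- beta0
  alpha <- if (cfg$polyak_window > 0) 1 / cfg$polyak_window else 1
  m <- numeric(length(beta))
  v <- numeric(length(beta))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  trace <- numeric(cfg$max_iterations)
  converged <- FALSE
  it <- 0L
  for (t in seq_len(cfg$max_iterations)) {
    g <- grad_fn(beta)
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    m_hat <- m / (1 - b1^t)
    v_hat <- v / (1 - b2^t)
    beta <- beta - cfg$learning_rate * m_hat / (sqrt(v_hat) + eps)
    beta_avg <- (1 - alpha) * beta_avg + alpha * beta
    l <- loss_fn(beta)
    if (!is.finite(l)) {
      rlang::abort(sprintf("loss diverged (non-finite) at iteration %d", t))
    }
    trace[t] <- l
    it <- t
    if (cfg$convergence_tolerance > 0 && t > 10) {
      rel <- abs(trace[t] - trace[t - 10]) / (abs(trace[t - 10]) + 1e-12)
      if (rel < cfg$convergence_tolerance) {
        converged <- TRUE
        break
      }
    }
  }
  list(beta = if (cfg$polyak_window > 0) beta_avg else beta,
       loss_trace = trace[seq_len(it)],
       converged = converged, n_iterations = it)
}

# Zero out every group whose coefficients are all below the threshold in
# absolute value.  For a plain (lasso) fit each coefficient is its own group.
truncate_groups <- function(beta, groups, threshold) {
  if (threshold <= 0) return(beta)
  if (is.null(groups)) {
    beta[abs(beta) < threshold] <- 0
    return(beta)
  }
  for (idx in groups) {
    if (all(abs(beta[idx]) < threshold)) beta[idx] <- 0
  }
  beta
}

new_pathcox_fit <- function(beta, design, penalty, cfg, opt, mode) {
  groups <- if (mode == "group") design$groups else NULL
  beta <- truncate_groups(beta, groups, cfg$truncation_threshold)
  selected <- if (mode == "group") {
    names(design$groups)[group_norms(beta, design) > 0]
  } else {
    character(0)
  }
  structure(
    list(beta = beta,
         mode = mode,
         selected_groups = selected,
         loss_trace = opt$loss_trace,
         converged = opt$converged,
         n_iterations = opt$n_iterations,
         penalty = penalty,
         config = cfg,
         origin = if (mode == "group") design$origin else
           tibble::tibble(column = seq_along(beta), pathway = NA_character_,
                          gene = colnames(design)),
         group_sizes = if (mode == "group") design$group_sizes else NULL),
    class = "pathcox_fit"
  )
}

#' @export
print.pathcox_fit <- function(x, ...) {
  cat(sprintf(
    "<pathcox_fit> %s model, %d coefficients (%d non-zero)%s; %s after %d iterations\n",
    if (x$mode == "group") "latent group lasso" else "lasso",
    length(x$beta), sum(x$beta != 0),
    if (x$mode == "group")
      sprintf(", %d selected pathway group(s)", length(x$selected_groups))
    else "",
    if (x$converged) "converged" else "stopped", x$n_iterations))
  invisible(x)
}

#' Fit a penalized Cox model on one cohort
#'
#' Minimizes the penalized negative log-partial likelihood by Adam from a
#' seeded near-zero random initialization, then truncates to exact zero any
#' group whose coefficients are all below `truncation_threshold` in absolute
#' value.  With a `latent_design` the penalty is the latent group lasso;
#' with a plain matrix it is the gene-level lasso (each coefficient its own
#' truncation group).  Deterministic given data, seed and configuration.
#'
#' @param design A `latent_design` or a plain numeric covariate matrix.
#' @param time,event Survival outcome vectors; at least one event required.
#' @param penalty A [penalty_config()] (its `mu` is ignored here).
#' @param cfg A [fit_config()].
#' @return A `pathcox_fit` object.
#' @export
fit_single <- function(design, time, event, penalty = penalty_config(),
                       cfg = fit_config()) {
  if (sum(event) == 0) rlang::abort("cannot fit without any event")
  mode <- if (inherits(design, "latent_design")) "group" else "lasso"
  x <- if (mode == "group") design$x else design
  p <- ncol(x)
  if (penalty$lambda == 0) cfg$polyak_window <- 0  # smooth problem: no oscillation
  set.seed(cfg$seed)
  beta0 <- stats::rnorm(p, 0, cfg$init_scale)
  if (mode == "group") {
    loss_fn <- function(b) total_loss_single(b, design, time, event, penalty)
    grad_fn <- function(b) {
      cox_nll_grad(b, x, time, event) +
        group_lasso_subgrad(b, design, penalty$lambda, penalty$weight_exponent)
    }
  } else {
    loss_fn <- function(b) total_loss_single(b, x, time, event, penalty)
    grad_fn <- function(b) {
      cox_nll_grad(b, x, time, event) + penalty$lambda * sign(b)
    }
  }
  opt <- adam_minimize(beta0, loss_fn, grad_fn, cfg)
  new_pathcox_fit(opt$beta, design, penalty, cfg, opt, mode)
}

#' Jointly fit two cohorts with the multi-task coupling penalty
#'
#' Minimizes the joint loss — the sum of the two cohorts' penalized Cox
#' losses plus the coupling term `C_mu(beta1, beta2)` — over both
#' coefficient vectors at once.  The two cohorts must be built on the same
#' pathway collection so their latent group partitions align.  Cohort `j`'s
#' initialization uses seed `cfg$seed + j`, so at `mu = 0` (where the loss
#' separates) each cohort reproduces `fit_single` run with that seed.
#' Truncation is applied per cohort.
#'
#' @param design1,design2 Latent designs for the two cohorts.
#' @param time1,event1,time2,event2 Per-cohort outcomes.
#' @param penalty1,penalty2 Per-cohort [penalty_config()]s; `penalty1$mu`
#'   sets the coupling strength and coupling options.
#' @param cfg A [fit_config()].
#' @return List with elements `fit1` and `fit2`, both `pathcox_fit`s.
#' @export
fit_pair <- function(design1, design2, time1, event1, time2, event2,
                     penalty1 = penalty_config(), penalty2 = penalty1,
                     cfg = fit_config()) {
  if (!identical(names(design1$groups), names(design2$groups)) ||
      !identical(design1$group_sizes, design2$group_sizes)) {
    rlang::abort("the two cohorts must share one latent group structure")
  }
  if (sum(event1) == 0 || sum(event2) == 0) {
    rlang::abort("cannot fit without any event in each cohort")
  }
  if (penalty1$lambda == 0 && penalty2$lambda == 0 && penalty1$mu == 0) {
    cfg$polyak_window <- 0  # fully smooth problem: no oscillation
  }
  p1 <- ncol(design1$x); p2 <- ncol(design2$x)
  set.seed(cfg$seed + 1L)
  b1 <- stats::rnorm(p1, 0, cfg$init_scale)
  set.seed(cfg$seed + 2L)
  b2 <- stats::rnorm(p2, 0, cfg$init_scale)
  i1 <- seq_len(p1); i2 <- p1 + seq_len(p2)
  loss_fn <- function(b) {
    total_loss_pair(b[i1], b[i2], design1, design2,
                    time1, event1, time2, event2, penalty1, penalty2)
  }
  grad_fn <- function(b) {
    cg <- coupling_grad(b[i1], b[i2], design1, penalty1$mu, penalty1)
    g1 <- cox_nll_grad(b[i1], design1$x, time1, event1) +
      group_lasso_subgrad(b[i1], design1, penalty1$lambda,
                          penalty1$weight_exponent) + cg$g1
    g2 <- cox_nll_grad(b[i2], design2$x, time2, event2) +
      group_lasso_subgrad(b[i2], design2, penalty2$lambda,
                          penalty2$weight_exponent) + cg$g2
    c(g1, g2)
  }
  opt <- adam_minimize(c(b1, b2), loss_fn, grad_fn, cfg)
  split1 <- list(beta = opt$beta[i1], loss_trace = opt$loss_trace,
                 converged = opt$converged, n_iterations = opt$n_iterations)
  split2 <- list(beta = opt$beta[i2], loss_trace = opt$loss_trace,
                 converged = opt$converged, n_iterations = opt$n_iterations)
  list(fit1 = new_pathcox_fit(opt$beta[i1], design1, penalty1, cfg, split1,
                              "group"),
       fit2 = new_pathcox_fit(opt$beta[i2], design2, penalty2, cfg, split2,
                              "group"))
}

#' Smallest penalty strength that zeroes every group
#'
#' For the group lasso, `beta = 0` minimizes the penalized loss exactly when
#' `||grad_g l(0)||_2 <= lambda * |g|^w` for every group, so the critical
#' strength is `max_g ||grad_g l(0)|| / |g|^w`.  For the plain lasso it is
#' `max_k |grad_k l(0)|`.  Used as the upper end of default lambda grids.
#'
#' @param design A `latent_design` or plain matrix.
#' @param time,event Outcomes.
#' @param weight_exponent Group-weight exponent `w`.
#' @return The critical `lambda` (scalar).
#' @export
lambda_max <- function(design, time, event, weight_exponent = 0.5) {
  if (inherits(design, "latent_design")) {
    g0 <- cox_nll_grad(numeric(ncol(design$x)), design$x, time, event)
    norms <- vapply(design$groups, function(idx) sqrt(sum(g0[idx]^2)),
                    numeric(1))
    max(norms / design$group_sizes^weight_exponent)
  } else {
    g0 <- cox_nll_grad(numeric(ncol(design)), design, time, event)
    max(abs(g0))
  }
}

#' Default log-spaced lambda grid
#'
#' @param lmax Upper grid end, typically [lambda_max()].
#' @param n_points Grid size.
#' @param ratio Lower end as a fraction of `lmax`.
#' @return Increasing numeric vector of length `n_points`.
#' @export
lambda_grid <- function(lmax, n_points = 10, ratio = 1e-3) {
  exp(seq(log(lmax * ratio), log(lmax), length.out = n_points))
}

#' Write a fitted model to delimited text plus a JSON sidecar
#'
#' One row per latent column (pathway, gene, coefficient), with the penalty
#' and optimizer configuration and convergence metadata in `<path>.json`.
#'
#' @param fit A `pathcox_fit`.
#' @param path Output path for the coefficient table.
#' @return `path`, invisibly.
#' @export
write_fit_result <- function(fit, path) {
  tab <- tidy(fit)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(
    penalty = unclass(fit$penalty),
    config = unclass(fit$config),
    converged = fit$converged,
    n_iterations = fit$n_iterations,
    final_loss = fit$loss_trace[length(fit$loss_trace)],
    selected_groups = fit$selected_groups
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
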