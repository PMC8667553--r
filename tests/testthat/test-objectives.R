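test_that("partial likelihood matches hand evaluation and null formula", {
  # beta = 0: every exp term is 1, so the value is the sum over events of
  # log(risk set size)
  set.seed(2)
  time <- c(3, 1, 4, 2, 5)
  event <- c(1, 0, 1, 1, 0)
  x <- matrix(rnorm(10), 5, 2)
  sizes <- vapply(which(event == 1),
                  function(i) sum(time >= time[i]), numeric(1))
  expect_equal(cox_nll(c(0, 0), x, time, event), sum(log(sizes)))

  # two subjects, both events, one covariate: direct evaluation
  x2 <- matrix(c(1, 0), 2, 1)
  expect_equal(cox_nll(1, x2, time = c(1, 2), event = c(1, 1)),
               -(1 - log(exp(1) + exp(0))) - (0 - log(exp(0))))

  # no events is an error
  expect_error(cox_nll(c(0, 0), x, time, rep(0, 5)), "without any event")
})

test_that("partial likelihood is invariant to column shifts", {
  set.seed(4)
  x <- matrix(rnorm(60), 20, 3)
  time <- rexp(20); event <- rbinom(20, 1, 0.7); event[1] <- 1
  beta <- rnorm(3)
  for (cc in c(0, 5)) {
    xs <- x
    xs[, 2] <- xs[, 2] + cc
    expect_equal(cox_nll(beta, xs, time, event),
                 cox_nll(beta, x, time, event), tolerance = 1e-9)
  }
})

test_that("partial likelihood agrees with an independent reference", {
  # survival::coxph evaluates the same Breslow partial likelihood
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(20:50, 1)
    x <- matrix(rnorm(n * 3), n, 3)
    time <- rexp(n)  # continuous: no ties
    event <- rbinom(n, 1, 0.7); event[1] <- 1
    beta <- rnorm(3, 0, 0.5)
    ref <- survival::coxph(survival::Surv(time, event) ~ x,
                           ties = "breslow", init = beta,
                           control = survival::coxph.control(iter.max = 0))
    expect_equal(cox_nll(beta, x, time, event), -ref$loglik[1],
                 tolerance = 1e-8)
  }
})

test_that("gradients match central differences", {
  toy <- make_toy(seed = 6)
  des <- toy$design
  set.seed(6)
  beta <- rnorm(ncol(des$x), 0, 0.4)
  g <- pathcox:::cox_nll_grad(beta, des$x, toy$data$time, toy$data$event)
  ng <- num_grad(function(b) cox_nll(b, des$x, toy$data$time,
                                     toy$data$event), beta, h = 1e-5)
  expect_equal(unname(g), ng, tolerance = 1e-5)

  gp <- pathcox:::group_lasso_subgrad(beta, des, lambda = 0.7)
  ngp <- num_grad(function(b) group_lasso_penalty(b, des, 0.7), beta)
  expect_equal(gp, ngp, tolerance = 1e-5)

  b2 <- rnorm(ncol(des$x), 0, 0.4)
  cfg <- penalty_config(mu = 0.9)
  cg <- pathcox:::coupling_grad(beta, b2, des, 0.9, cfg)
  f <- function(u, v) coupling_penalty(u, v, des, 0.9, cfg)
  expect_equal(cg$g1, num_grad(function(b) f(b, b2), beta),
               tolerance = 1e-5)
  expect_equal(cg$g2, num_grad(function(b) f(beta, b), b2),
               tolerance = 1e-5)
})

test_that("lasso and group penalties follow their formulas", {
  toy <- make_toy()
  des <- toy$design
  expect_equal(lasso_penalty(c(1, -2), 0.5), 1.5)
  expect_equal(lasso_penalty(c(1, -2), 0), 0)
  expect_equal(lasso_penalty(numeric(3), 2), 0)

  # single group of size 4 with unit block norm: sqrt(4) * 1 = 2
  d <- survival_dataset(
    matrix(rnorm(20), 5, dimnames = list(NULL, paste0("g", 1:4))),
    time = 1:5, event = rep(1, 5))
  des1 <- build_latent_design(d, pathway_collection(list(P = paste0("g", 1:4))))
  expect_equal(group_lasso_penalty(c(1, 0, 0, 0), des1, 1), 2)

  # additive over groups; permuting group contents leaves the value fixed
  beta <- rnorm(ncol(des$x))
  per_group <- vapply(seq_along(des$groups), function(k) {
    idx <- des$groups[[k]]
    des$group_sizes[k]^0.5 * sqrt(sum(beta[idx]^2))
  }, numeric(1))
  expect_equal(group_lasso_penalty(beta, des, 1.3), 1.3 * sum(per_group))

  # positive homogeneity of degree 1
  expect_equal(group_lasso_penalty(3 * beta, des, 1),
               3 * group_lasso_penalty(beta, des, 1))
  expect_equal(lasso_penalty(3 * beta, 1), 3 * lasso_penalty(beta, 1))
})

test_that("coupling penalty has the four design properties", {
  toy <- make_toy(seed = 8)
  des <- toy$design
  M <- ncol(des$x)
  cfg <- penalty_config(mu = 1)
  set.seed(8)
  for (rep in 1:20) {
    b1 <- rnorm(M)
    b2 <- rnorm(M)
    # symmetry, exactly
    expect_identical(coupling_penalty(b1, b2, des, 1, cfg),
                     coupling_penalty(b2, b1, des, 1, cfg))
    # per-group positive proportionality gives exactly zero
    scales <- runif(length(des$groups), 0.1, 5)
    b_prop <- b1
    for (k in seq_along(des$groups)) {
      b_prop[des$groups[[k]]] <- scales[k] * b1[des$groups[[k]]]
    }
    expect_equal(coupling_penalty(b1, b_prop, des, 1, cfg), 0,
                 tolerance = 1e-10)
    # indicator gating: zeroing a block never increases the penalty
    base <- coupling_penalty(b1, b2, des, 1, cfg)
    k <- sample(length(des$groups), 1)
    bz <- b1; bz[des$groups[[k]]] <- 0
    expect_lte(coupling_penalty(bz, b2, des, 1, cfg), base + 1e-12)
  }
  # all-zero first cohort gates every term
  expect_equal(coupling_penalty(numeric(M), rnorm(M), des, 1, cfg), 0)
  # numeric value matches the straight-line oracle
  set.seed(9)
  b1 <- rnorm(M); b2 <- rnorm(M)
  expect_equal(coupling_penalty(b1, b2, des, 0.8, penalty_config(mu = 0.8)),
               coupling_oracle(b1, b2, des, 0.8), tolerance = 1e-12)
})

test_that("coupling variants follow their formulas", {
  toy <- make_toy(seed = 10)
  des <- toy$design
  M <- ncol(des$x)
  set.seed(10)
  b1 <- rnorm(M)

  expect_equal(coupling_penalty_variant(b1, b1, des, 1, "abs_difference"), 0)
  expect_equal(coupling_penalty_variant(b1, 3 * b1, des, 1, "cosine"), 0,
               tolerance = 1e-12)
  # antiparallel unit vectors differ by a vector of norm 2 per group
  expect_equal(coupling_penalty_variant(b1, -b1, des, 1,
                                        "normalized_difference"),
               sum(des$group_sizes^0.5 * 2), tolerance = 1e-12)
  # cosine/normalized variants are invariant to per-cohort rescaling
  b2 <- rnorm(M)
  for (v in c("cosine", "normalized_difference")) {
    expect_equal(coupling_penalty_variant(2.5 * b1, 0.3 * b2, des, 1, v),
                 coupling_penalty_variant(b1, b2, des, 1, v),
                 tolerance = 1e-10)
  }
  # the main penalty is jointly 1-homogeneous instead
  cfg <- penalty_config(mu = 1)
  expect_equal(coupling_penalty(2 * b1, 2 * b2, des, 1, cfg),
               2 * coupling_penalty(b1, b2, des, 1, cfg), tolerance = 1e-10)
  expect_error(coupling_penalty_variant(b1, b2, des, 1, "nope"))
})

test_that("pair loss separates at mu = 0 and dominates the raw likelihoods", {
  toy1 <- make_toy(seed = 12)
  toy2 <- make_toy(seed = 13)
  des1 <- toy1$design; des2 <- toy2$design
  set.seed(12)
  for (rep in 1:10) {
    b1 <- rnorm(ncol(des1$x), 0, 0.5)
    b2 <- rnorm(ncol(des2$x), 0, 0.5)
    cfg0 <- penalty_config(lambda = runif(1, 0, 2), mu = 0)
    pair <- total_loss_pair(b1, b2, des1, des2,
                            toy1$data$time, toy1$data$event,
                            toy2$data$time, toy2$data$event, cfg0)
    singles <- total_loss_single(b1, des1, toy1$data$time,
                                 toy1$data$event, cfg0) +
      total_loss_single(b2, des2, toy2$data$time, toy2$data$event, cfg0)
    expect_equal(pair, singles, tolerance = 1e-12)

    cfg1 <- penalty_config(lambda = runif(1, 0, 2), mu = runif(1, 0, 2))
    pair1 <- total_loss_pair(b1, b2, des1, des2,
                             toy1$data$time, toy1$data$event,
                             toy2$data$time, toy2$data$event, cfg1)
    nlls <- cox_nll(b1, des1$x, toy1$data$time, toy1$data$event) +
      cox_nll(b2, des2$x, toy2$data$time, toy2$data$event)
    expect_gte(pair1, nlls - 1e-10)
  }
  # lambda = 0 reduces the single loss to the bare likelihood
  b1 <- rnorm(ncol(des1$x))
  expect_equal(total_loss_single(b1, des1, toy1$data$time, toy1$data$event,
                                 penalty_config(lambda = 0)),
               cox_nll(b1, des1$x, toy1$data$time, toy1$data$event))
})
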