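test_that("overwhelming penalty truncates every group to exact zero", {
  toy <- make_toy(seed = 20)
  ft <- fit_single(toy$design, toy$data$time, toy$data$event,
                   penalty_config(lambda = 1e6), fast_cfg(iters = 400))
  expect_identical(unname(ft$beta), rep(0, ncol(toy$design$x)))
  expect_length(ft$selected_groups, 0)
  expect_equal(stats::sd(hazard_scores(ft$beta, toy$design$x)), 0)
})

test_that("unpenalized fit matches the reference maximum partial likelihood", {
  set.seed(21)
  for (rep in 1:3) {
    n <- 100
    x <- matrix(rnorm(n * 3), n, 3)
    time <- rexp(n)
    event <- rbinom(n, 1, 0.8); event[1] <- 1
    ft <- fit_single(x, time, event, penalty_config(lambda = 0),
                     fit_config(max_iterations = 12000,
                                learning_rate = 0.02,
                                convergence_tolerance = 1e-11,
                                truncation_threshold = 0, seed = rep))
    ref <- survival::coxph(survival::Surv(time, event) ~ x,
                           ties = "breslow")
    expect_lt(max(abs(ft$beta - coef(ref))), 1e-3)  # per-coefficient
  }
})

test_that("fits are deterministic and decrease the loss", {
  toy <- make_toy(seed = 22)
  pen <- penalty_config(lambda = 2)
  f1 <- fit_single(toy$design, toy$data$time, toy$data$event, pen,
                   fast_cfg(seed = 5))
  f2 <- fit_single(toy$design, toy$data$time, toy$data$event, pen,
                   fast_cfg(seed = 5))
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$loss_trace, f2$loss_trace)
  expect_lte(f1$loss_trace[length(f1$loss_trace)], f1$loss_trace[1])
  expect_true(all(is.finite(f1$loss_trace)))
  # truncated groups are exactly zero
  for (k in seq_along(toy$design$groups)) {
    blk <- f1$beta[toy$design$groups[[k]]]
    if (!(names(toy$design$groups)[k] %in% f1$selected_groups)) {
      expect_identical(unname(blk), rep(0, length(blk)))
    }
  }
})

test_that("uncoupled pair fit reproduces the single fits", {
  toy1 <- make_toy(seed = 23)
  toy2 <- make_toy(seed = 24)
  pen <- penalty_config(lambda = 1.5, mu = 0)
  cfg <- fit_config(max_iterations = 300, learning_rate = 0.02,
                    convergence_tolerance = 0, seed = 40)
  pair <- fit_pair(toy1$design, toy2$design,
                   toy1$data$time, toy1$data$event,
                   toy2$data$time, toy2$data$event, pen, pen, cfg)
  cfg1 <- cfg; cfg1$seed <- cfg$seed + 1L
  cfg2 <- cfg; cfg2$seed <- cfg$seed + 2L
  s1 <- fit_single(toy1$design, toy1$data$time, toy1$data$event, pen, cfg1)
  s2 <- fit_single(toy2$design, toy2$data$time, toy2$data$event, pen, cfg2)
  expect_equal(pair$fit1$beta, s1$beta, tolerance = 1e-10)
  expect_equal(pair$fit2$beta, s2$beta, tolerance = 1e-10)
})

test_that("strong coupling drives shared-group proportionality", {
  # both cohorts share one predictive pathway; under a large mu the two
  # fitted blocks should align up to scale (property 2 of the penalty)
  set.seed(25)
  genes <- paste0("g", 1:10)
  pw <- pathway_collection(list(S = genes[1:5], N = genes[6:10]))
  gen <- function(n, seed) {
    set.seed(seed)
    x <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, genes))
    score <- x[, 1:5] %*% c(1, 0.8, -0.6, 0.4, 0.2)
    d <- survival_dataset(x, time = exp(-score / sd(score)),
                          event = rbinom(n, 1, 0.85))
    suppressMessages(standardize(d))
  }
  d1 <- gen(120, 26); d2 <- gen(120, 27)
  des1 <- build_latent_design(d1, pw)
  des2 <- build_latent_design(d2, pw)
  pen_hi <- penalty_config(lambda = 1, mu = 50)
  fits <- fit_pair(des1, des2, d1$time, d1$event, d2$time, d2$event,
                   pen_hi, pen_hi, fast_cfg(seed = 3, iters = 1200))
  u <- fits$fit1$beta[des1$groups$S]
  v <- fits$fit2$beta[des2$groups$S]
  expect_gt(sum(u * v) / sqrt(sum(u^2) * sum(v^2)), 0.99)
})

test_that("indicator gating preserves cohort-private signal groups", {
  # disjoint true pathways: coupling must not erase either cohort's own
  set.seed(28)
  genes <- paste0("g", 1:10)
  pw <- pathway_collection(list(A = genes[1:5], B = genes[6:10]))
  gen <- function(n, seed, cols) {
    set.seed(seed)
    x <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, genes))
    score <- rowSums(x[, cols])
    d <- survival_dataset(x, time = exp(-score / sd(score)),
                          event = rbinom(n, 1, 0.85))
    suppressMessages(standardize(d))
  }
  d1 <- gen(120, 29, 1:5)    # cohort 1 driven by pathway A
  d2 <- gen(120, 30, 6:10)   # cohort 2 driven by pathway B
  des1 <- build_latent_design(d1, pw)
  des2 <- build_latent_design(d2, pw)
  lam1 <- 0.2 * lambda_max(des1, d1$time, d1$event)
  lam2 <- 0.2 * lambda_max(des2, d2$time, d2$event)
  fits <- fit_pair(des1, des2, d1$time, d1$event, d2$time, d2$event,
                   penalty_config(lambda = lam1, mu = 1),
                   penalty_config(lambda = lam2, mu = 1),
                   fast_cfg(seed = 4, iters = 1200))
  expect_true("A" %in% fits$fit1$selected_groups)
  expect_true("B" %in% fits$fit2$selected_groups)
})

test_that("selection is sparser at the top of the lambda path", {
  toy <- make_toy(n = 80, seed = 31)
  lmax <- lambda_max(toy$design, toy$data$time, toy$data$event)
  grid <- lambda_grid(lmax, n_points = 5, ratio = 1e-2)
  nsel <- vapply(grid, function(lam) {
    ft <- fit_single(toy$design, toy$data$time, toy$data$event,
                     penalty_config(lambda = lam), fast_cfg(iters = 1000))
    length(ft$selected_groups)
  }, numeric(1))
  expect_lte(nsel[length(nsel)], nsel[1])
})

test_that("a pure-noise group is truncated at moderate lambda", {
  # one predictive pathway, one noise pathway
  genes <- paste0("g", 1:10)
  pw <- pathway_collection(list(SIG = genes[1:5], NOISE = genes[6:10]))
  hits <- 0
  for (s in 1:20) {
    set.seed(100 + s)
    n <- 150
    x <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, genes))
    score <- rowSums(x[, 1:5])
    d <- suppressMessages(standardize(survival_dataset(
      x, time = exp(-score / sd(score)), event = rbinom(n, 1, 0.85))))
    des <- build_latent_design(d, pw)
    lam <- 0.6 * lambda_max(des, d$time, d$event)
    ft <- fit_single(des, d$time, d$event, penalty_config(lambda = lam),
                     fast_cfg(seed = s, iters = 1500))
    if (!("NOISE" %in% ft$selected_groups)) hits <- hits + 1
  }
  expect_gte(hits, 18)  # >= 90% of runs
})

test_that("divergent losses and event-free data raise errors", {
  toy <- make_toy(seed = 33)
  no_event <- toy$data
  expect_error(fit_single(toy$design, no_event$time,
                          rep(0, n_samples(no_event))),
               "without any event")
  # a non-finite loss is reported with the iteration it occurred at
  expect_error(
    pathcox:::adam_minimize(
      c(1, 1), function(b) if (max(abs(b)) > 1.5) NaN else sum(b^2),
      function(b) -2 * b, fit_config(max_iterations = 200,
                                    learning_rate = 0.5)),
    "iteration")
})

test_that("fit results serialize to text with a JSON sidecar", {
  toy <- make_toy(seed = 34)
  ft <- fit_single(toy$design, toy$data$time, toy$data$event,
                   penalty_config(lambda = 2), fast_cfg(iters = 300))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fit_result(ft, path)
  tab <- read.delim(path)
  expect_equal(nrow(tab), ncol(toy$design$x))
  expect_named(tab, c("column", "pathway", "gene", "coefficient",
                      "selected"))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$penalty$lambda, 2)
  expect_true(is.numeric(meta$final_loss))
})
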