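#' Per-sample hazard scores
#'
#' The linear predictor `x_i . beta`; higher scores predict earlier events.
#'
#' @param beta Coefficient vector.
#' @param x Covariate matrix with matching columns.
#' @return Numeric vector of length `nrow(x)`.
#' @export
hazard_scores <- function(beta, x) {
  stopifnot(length(beta) == ncol(x))
  drop(x %*% beta)
}

#' Concordance index (c-value)
#'
#' The proportion of comparable observation pairs in which the individual
#' with the higher predicted hazard score experienced the event first.
#' A pair is comparable when the earlier observed time is an event
#' (`Y_i < Y_j` with `C_i = 1`), or the times are tied with exactly one
#' event (the event subject's death occurred at or before the other's
#' censoring).  Pairs of tied event times, censored-before-event pairs and
#' doubly censored pairs are not comparable.  Tied scores on a comparable
#' pair count 0.5.  This is the usual Harrell convention.
#'
#' @param scores Predicted hazard scores.
#' @param time Observed times.
#' @param event 0/1 status indicators.
#' @return The c-value, in `[0, 1]`.
#' @export
concordance_index <- function(scores, time, event) {
  n <- length(scores)
  stopifnot(length(time) == n, length(event) == n)
  lt <- outer(time, time, "<")
  eq <- outer(time, time, "==")
  ev_i <- matrix(event == 1, n, n)
  cens_j <- matrix(event == 0, n, n, byrow = TRUE)
  comparable <- (lt & ev_i) | (eq & ev_i & cens_j)
  n_comp <- sum(comparable)
  if (n_comp == 0) rlang::abort("no comparable pairs for the c-value")
  sgt <- outer(scores, scores, ">")
  seq_ <- outer(scores, scores, "==")
  (sum(sgt & comparable) + 0.5 * sum(seq_ & comparable)) / n_comp
}

#' Tucker's congruence coefficient, averaged over pairs
#'
#' For each unordered pair of coefficient vectors `(u, v)` computes
#' `phi = sum(u_k v_k) / sqrt(sum(u_k^2) * sum(v_k^2))` and returns the
#' mean over all pairs; a pair involving an all-zero vector contributes
#' `phi = 0` and is flagged with a message.  Measures how consistently
#' resampled fits select and weight the same coefficients (1 = identical
#' direction, 0 = orthogonal).
#'
#' @param beta_set List of at least two equal-length numeric vectors.
#' @return Mean pairwise congruence, in `[-1, 1]`.
#' @export
tucker_congruence <- function(beta_set) {
  if (length(beta_set) < 2) {
    rlang::abort("congruence needs at least two coefficient vectors")
  }
  lens <- lengths(beta_set)
  if (length(unique(lens)) != 1) {
    rlang::abort("coefficient vectors must have equal length")
  }
  pairs <- utils::combn(length(beta_set), 2)
  zero_flagged <- FALSE
  phis <- apply(pairs, 2, function(ij) {
    u <- beta_set[[ij[1]]]; v <- beta_set[[ij[2]]]
    su <- sum(u^2); sv <- sum(v^2)
    if (su == 0 || sv == 0) {
      zero_flagged <<- TRUE
      return(0)
    }
    sum(u * v) / sqrt(su * sv)
  })
  if (zero_flagged) {
    rlang::inform("congruence of a pair with an all-zero vector set to 0")
  }
  mean(phis)
}

#' Paired t-test on per-split differences
#'
#' Two-sided one-sample t-test of the paired differences against zero mean,
#' used to compare two methods' per-split c-values (or congruences).
#'
#' @param diffs Numeric vector of paired differences (method A - method B).
#' @return A one-row tibble with `estimate` (mean difference),
#'   `t_statistic`, `df` and `p_value`.
#' @export
paired_t_test <- function(diffs) {
  if (length(diffs) < 2) {
    rlang::abort("need at least two paired differences")
  }
  if (stats::sd(diffs) == 0) {
    rlang::abort("paired differences have zero variance; t-test undefined")
  }
  tt <- stats::t.test(diffs)
  tibble::tibble(estimate = unname(tt$estimate),
                 t_statistic = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p_value = tt$p.value)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values controlling the false discovery rate across a
#' family of tests (e.g. all pairings tested for one cancer).
#'
#' @param p_values Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
fdr_correct <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    rlang::abort("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Hyperparameter-search and resampling protocol settings
#'
#' Defaults follow the study protocol: 10-fold cross-validated grid search
#' for `lambda`; 100 random 80-20 train-test splits for single-task
#' comparisons (30 for multi-task runs); for the multi-task random search,
#' 30 draws of each `lambda_j` from `N(lambda_j, (0.1 lambda_j)^2)` around
#' the single-task optimum and 30 draws of `mu` from a half-normal with
#' standard deviation 0.5.
#'
#' @param lambda_grid Candidate `lambda`s; `NULL` means a log-spaced
#'   `n_lambda`-point grid up to [lambda_max()] is built from the data.
#' @param n_lambda,grid_ratio Size and lower-end ratio of the default grid.
#' @param n_folds Cross-validation folds.
#' @param n_splits Repeated train-test splits.
#' @param split_fraction Training fraction per split.
#' @param n_random_draws Random-search draws for the multi-task model.
#' @param lambda_prior_sd_fraction Proposal sd as a fraction of the
#'   single-task `lambda`.
#' @param mu_half_normal_sd Half-normal sd of the `mu` proposal.
#' @param seed Master seed; all sub-experiment seeds derive from it.
#' @return A `search_spec` list.
#' @export
search_spec <- function(lambda_grid = NULL, n_lambda = 10, grid_ratio = 1e-3,
                        n_folds = 10, n_splits = 100, split_fraction = 0.8,
                        n_random_draws = 30,
                        lambda_prior_sd_fraction = 0.1,
                        mu_half_normal_sd = 0.5, seed = 1) {
  stopifnot(n_folds >= 2, n_splits >= 1,
            split_fraction > 0, split_fraction < 1, n_random_draws >= 1)
  structure(list(lambda_grid = lambda_grid, n_lambda = n_lambda,
                 grid_ratio = grid_ratio, n_folds = n_folds,
                 n_splits = n_splits, split_fraction = split_fraction,
                 n_random_draws = n_random_draws,
                 lambda_prior_sd_fraction = lambda_prior_sd_fraction,
                 mu_half_normal_sd = mu_half_normal_sd,
                 seed = as.integer(seed)),
            class = "search_spec")
}

#' Subset a survival dataset by sample index
#' @param data A `survival_dataset`.
#' @param idx Integer or logical sample index.
#' @return A `survival_dataset` over the selected samples.
#' @export
subset_samples <- function(data, idx) {
  survival_dataset(data$expression[idx, , drop = FALSE],
                   data$time[idx], data$event[idx])
}

# Standardize train/test on training statistics and build the design for
# the requested method.  Lasso mode may restrict the gene universe to the
# pathway genes (restrict_to_pathways) or use all genes.
prepare_split <- function(train, test, pathways, method,
                          restrict_to_pathways = FALSE) {
  tr_std <- suppressMessages(standardize(train))
  te_std <- suppressMessages(standardize(test, reference = tr_std))
  te_std$standardization <- tr_std$standardization
  if (method == "group_lasso") {
    list(train_design = suppressMessages(build_latent_design(tr_std, pathways)),
         test_design = suppressMessages(build_latent_design(te_std, pathways)),
         train = tr_std, test = te_std)
  } else {
    genes <- if (restrict_to_pathways) {
      intersect(train$gene_ids, unique(unlist(pathways)))
    } else {
      train$gene_ids
    }
    list(train_design = tr_std$expression[, genes, drop = FALSE],
         test_design = te_std$expression[, genes, drop = FALSE],
         train = tr_std, test = te_std)
  }
}

test_design_matrix <- function(prep) {
  if (inherits(prep$test_design, "latent_design")) prep$test_design$x
  else prep$test_design
}

#' Repeated random-split evaluation of one method
#'
#' Runs `n_splits` random train-test splits: standardize on the training
#' samples, fit, score the held-out samples, record the test c-value, and
#' collect the fitted coefficient vectors for congruence.  Per-split seeds
#' derive deterministically from `spec$seed` plus the split index.  Splits
#' whose test portion holds no event are skipped with a message.
#'
#' @param data A `survival_dataset` (unstandardized; each split
#'   standardizes on its own training set).
#' @param pathways A `pathway_collection`.
#' @param spec A [search_spec()]; `n_splits` and `split_fraction` are used.
#' @param method `"group_lasso"` or `"lasso"`.
#' @param penalty A [penalty_config()] with the `lambda` to use.
#' @param fit_cfg A [fit_config()].
#' @param restrict_to_pathways For `"lasso"`, restrict the gene universe to
#'   pathway genes (default uses all genes).
#' @return An `eval_report`: list with `splits` (tibble: `split`, `c_value`,
#'   `n_selected_groups`), `betas` (list of latent/gene coefficient
#'   vectors), `congruence_mean`, and the settings used.
#' @export
repeated_split_eval <- function(data, pathways, spec = search_spec(),
                                method = c("group_lasso", "lasso"),
                                penalty = penalty_config(),
                                fit_cfg = fit_config(),
                                restrict_to_pathways = FALSE) {
  method <- match.arg(method)
  n <- n_samples(data)
  rows <- list()
  betas <- list()
  for (s in seq_len(spec$n_splits)) {
    set.seed(spec$seed + s)
    train_idx <- sort(sample.int(n, round(spec$split_fraction * n)))
    test_idx <- setdiff(seq_len(n), train_idx)
    train <- subset_samples(data, train_idx)
    test <- subset_samples(data, test_idx)
    if (sum(test$event) == 0 || sum(train$event) == 0) {
      rlang::inform(sprintf("split %d skipped: no events in one portion", s))
      next
    }
    prep <- prepare_split(train, test, pathways, method, restrict_to_pathways)
    cfg_s <- fit_cfg
    cfg_s$seed <- fit_cfg$seed + s
    fit <- fit_single(prep$train_design, train$time, train$event,
                      penalty, cfg_s)
    scores <- hazard_scores(fit$beta, test_design_matrix(prep))
    rows[[length(rows) + 1]] <- tibble::tibble(
      split = s,
      c_value = concordance_index(scores, test$time, test$event),
      n_selected_groups = if (method == "group_lasso")
        length(fit$selected_groups) else sum(fit$beta != 0)
    )
    betas[[length(betas) + 1]] <- fit$beta
  }
  if (length(rows) == 0) rlang::abort("every split was skipped")
  splits <- dplyr::bind_rows(rows)
  structure(
    list(splits = splits, betas = betas,
         congruence_mean = if (length(betas) >= 2)
           suppressMessages(tucker_congruence(betas)) else NA_real_,
         method = method, penalty = penalty, spec = spec),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> %s: %d splits, mean c-value %.3f (sd %.3f), congruence %.3f\n",
    x$method, nrow(x$splits), mean(x$splits$c_value),
    stats::sd(x$splits$c_value), x$congruence_mean))
  invisible(x)
}

# Fold assignment used by both searches: deterministic given seed.
make_folds <- function(n, k, seed) {
  set.seed(seed)
  sample(rep(seq_len(k), length.out = n))
}

cv_c_values <- function(data, pathways, lambda, spec, fit_cfg, method,
                        restrict_to_pathways = FALSE, fold_seed_offset = 0L) {
  folds <- make_folds(n_samples(data), spec$n_folds,
                      spec$seed + fold_seed_offset)
  cs <- c()
  for (f in seq_len(spec$n_folds)) {
    train <- subset_samples(data, folds != f)
    val <- subset_samples(data, folds == f)
    if (sum(val$event) == 0 || sum(train$event) == 0) next
    prep <- prepare_split(train, val, pathways, method, restrict_to_pathways)
    cfg_f <- fit_cfg
    cfg_f$seed <- fit_cfg$seed + f
    fit <- fit_single(prep$train_design, train$time, train$event,
                      penalty_config(lambda = lambda), cfg_f)
    scores <- hazard_scores(fit$beta, test_design_matrix(prep))
    cs <- c(cs, concordance_index(scores, val$time, val$event))
  }
  if (length(cs) == 0) rlang::abort("no usable cross-validation fold")
  cs
}

#' Cross-validated grid search for the sparsity strength
#'
#' For each candidate `lambda`, computes the mean validation c-value over
#' `n_folds` folds (standardizing within each fold's training portion).
#' Under `rule = "max"` the maximizer is returned, ties breaking toward the
#' larger (sparser) `lambda`.  Under `rule = "1se"` the largest `lambda`
#' whose mean c-value lies within one standard error of the best is
#' returned — the usual remedy when the CV curve is flat (as on strongly
#' predictive data, where a near-zero penalty scores as well as a sparse
#' one and the argmax is decided by fold noise).
#' The default grid is log-spaced over `[lambda_max * grid_ratio,
#' lambda_max]` with `lambda_max` the smallest strength that zeroes every
#' group at the optimum (closed form from the null gradient).
#'
#' @inheritParams repeated_split_eval
#' @param rule Selection rule, `"max"` (default) or `"1se"`.
#' @return A list of class `lambda_search`: `lambda` (the selected value)
#'   and `cv` (tibble: `lambda`, `mean_c_value`, `se_c_value`).
#' @export
grid_search_lambda <- function(data, pathways, spec = search_spec(),
                               method = c("group_lasso", "lasso"),
                               fit_cfg = fit_config(),
                               restrict_to_pathways = FALSE,
                               rule = c("max", "1se")) {
  method <- match.arg(method)
  rule <- match.arg(rule)
  grid <- spec$lambda_grid
  if (is.null(grid)) {
    std <- suppressMessages(standardize(data))
    des <- if (method == "group_lasso") {
      suppressMessages(build_latent_design(std, pathways))
    } else {
      genes <- if (restrict_to_pathways)
        intersect(data$gene_ids, unique(unlist(pathways)))
      else data$gene_ids
      std$expression[, genes, drop = FALSE]
    }
    grid <- lambda_grid(lambda_max(des, data$time, data$event),
                        spec$n_lambda, spec$grid_ratio)
  }
  if (length(grid) == 0) rlang::abort("empty lambda grid")
  fold_cs <- lapply(grid, function(lam) {
    cv_c_values(data, pathways, lam, spec, fit_cfg, method,
                restrict_to_pathways)
  })
  mean_c <- vapply(fold_cs, mean, numeric(1))
  se_c <- vapply(fold_cs, function(cs) {
    if (length(cs) > 1) stats::sd(cs) / sqrt(length(cs)) else 0
  }, numeric(1))
  best <- if (rule == "max") {
    max(grid[mean_c == max(mean_c)])  # ties toward the sparser lambda
  } else {
    max(grid[mean_c >= max(mean_c) - se_c[which.max(mean_c)]])
  }
  structure(list(lambda = best, rule = rule,
                 cv = tibble::tibble(lambda = grid, mean_c_value = mean_c,
                                     se_c_value = se_c)),
            class = "lambda_search")
}

cv_c_value_pair <- function(data1, data2, pathways, lambda1, lambda2, mu,
                            spec, fit_cfg, coupling_cfg = penalty_config()) {
  folds1 <- make_folds(n_samples(data1), spec$n_folds, spec$seed + 101L)
  folds2 <- make_folds(n_samples(data2), spec$n_folds, spec$seed + 202L)
  cs1 <- c(); cs2 <- c()
  for (f in seq_len(spec$n_folds)) {
    tr1 <- subset_samples(data1, folds1 != f)
    va1 <- subset_samples(data1, folds1 == f)
    tr2 <- subset_samples(data2, folds2 != f)
    va2 <- subset_samples(data2, folds2 == f)
    if (sum(va1$event) == 0 || sum(va2$event) == 0 ||
        sum(tr1$event) == 0 || sum(tr2$event) == 0) next
    p1 <- prepare_split(tr1, va1, pathways, "group_lasso")
    p2 <- prepare_split(tr2, va2, pathways, "group_lasso")
    pen1 <- coupling_cfg; pen1$lambda <- lambda1; pen1$mu <- mu
    pen2 <- coupling_cfg; pen2$lambda <- lambda2; pen2$mu <- mu
    cfg_f <- fit_cfg
    cfg_f$seed <- fit_cfg$seed + f
    fits <- fit_pair(p1$train_design, p2$train_design,
                     tr1$time, tr1$event, tr2$time, tr2$event,
                     pen1, pen2, cfg_f)
    cs1 <- c(cs1, concordance_index(
      hazard_scores(fits$fit1$beta, test_design_matrix(p1)),
      va1$time, va1$event))
    cs2 <- c(cs2, concordance_index(
      hazard_scores(fits$fit2$beta, test_design_matrix(p2)),
      va2$time, va2$event))
  }
  if (length(cs1) == 0) rlang::abort("no usable cross-validation fold")
  c(mean(cs1), mean(cs2))
}

#' Random search for the multi-task hyperparameters
#'
#' Draws `n_random_draws` triples `(lambda1, lambda2, mu)`: each `lambda_j`
#' from a normal centered on the single-task optimum with sd
#' `lambda_prior_sd_fraction * lambda_j` (clipped to a small positive
#' floor), and `mu` from a half-normal with sd `mu_half_normal_sd`.  Each
#' triple is scored by the cross-validated mean c-value of the jointly
#' fitted pair, separately per cohort, and the best draw per cohort is
#' returned.
#'
#' @param data1,data2 The two cohorts.
#' @param pathways Shared `pathway_collection`.
#' @param spec A [search_spec()].
#' @param base_lambda1,base_lambda2 Single-task optima from
#'   [grid_search_lambda()].
#' @param fit_cfg A [fit_config()].
#' @return A list of class `mt_search`: `draws` (tibble with the triples
#'   and per-cohort CV c-values), `best1` and `best2` (one-row tibbles with
#'   each cohort's selected triple).
#' @export
random_search_multitask <- function(data1, data2, pathways,
                                    spec = search_spec(),
                                    base_lambda1, base_lambda2,
                                    fit_cfg = fit_config()) {
  set.seed(spec$seed + 7L)
  nd <- spec$n_random_draws
  l1 <- pmax(stats::rnorm(nd, base_lambda1,
                          spec$lambda_prior_sd_fraction * base_lambda1), 1e-6)
  l2 <- pmax(stats::rnorm(nd, base_lambda2,
                          spec$lambda_prior_sd_fraction * base_lambda2), 1e-6)
  mu <- abs(stats::rnorm(nd, 0, spec$mu_half_normal_sd))
  cv <- vapply(seq_len(nd), function(d) {
    cv_c_value_pair(data1, data2, pathways, l1[d], l2[d], mu[d],
                    spec, fit_cfg)
  }, numeric(2))
  draws <- tibble::tibble(draw = seq_len(nd), lambda1 = l1, lambda2 = l2,
                          mu = mu, cv_c1 = cv[1, ], cv_c2 = cv[2, ])
  structure(list(draws = draws,
                 best1 = draws[which.max(draws$cv_c1), ],
                 best2 = draws[which.max(draws$cv_c2), ]),
            class = "mt_search")
}
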