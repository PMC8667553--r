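#' @keywords internal
"_PACKAGE"

# Serialize the fully resolved settings of a run next to its outputs so the
# run is reproducible from the emitted files alone.
write_run_config <- function(out_dir, command, ...) {
  cfg <- list(command = command, ...)
  strip <- function(x) {
    if (inherits(x, "pathway_collection")) {
      list(n_pathways = length(x), pathways = names(x))
    } else if (is.list(x)) {
      lapply(unclass(x), strip)
    } else x
  }
  jsonlite::write_json(strip(cfg), file.path(out_dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA)
}

#' Simulate a paired synthetic study and write it to disk
#'
#' Thin driver over [generate_pair()] / [write_synthetic_pair()]: writes the
#' two cohorts' expression and clinical tables, the ground-truth JSON, and a
#' resolved-configuration JSON.
#'
#' @param out_dir Output directory.
#' @param spec A [synthetic_spec()].
#' @return The generated `synthetic_pair`, invisibly.
#' @export
run_simulate <- function(out_dir, spec = synthetic_spec()) {
  pair <- generate_pair(spec)
  write_synthetic_pair(pair, out_dir)
  write_run_config(out_dir, "simulate",
                   spec = spec[setdiff(names(spec), "pathways")],
                   n_pathways = length(spec$pathways))
  invisible(pair)
}

#' Compare gene-level lasso with pathway group lasso on one cohort
#'
#' The single-cohort comparison protocol: select each method's `lambda` by
#' cross-validated grid search, run the repeated random-split evaluation for
#' both, then report the per-split c-values, the paired t-test of their
#' differences, mean congruences with a paired t-test over non-overlapping
#' split pairs, and the pathway selection frequency of the group lasso
#' across splits.
#'
#' @param data A `survival_dataset`.
#' @param pathways A `pathway_collection`.
#' @param spec A [search_spec()].
#' @param fit_cfg A [fit_config()].
#' @param restrict_to_pathways Restrict the lasso gene universe to pathway
#'   genes (default: all genes).
#' @param out_dir Optional directory; when given, per-split tables, the
#'   selection-frequency table, a JSON summary and the resolved
#'   configuration are written there.
#' @param lambda_rule Selection rule passed to [grid_search_lambda()].
#' @return A `compare_report` list: `splits` (tibble: split, per-method
#'   c-values and difference), `c_test` and `congruence_test` (tibbles from
#'   [paired_t_test()]), `congruence` (per-method means),
#'   `selection_frequency` (tibble: pathway, frequency), `lambdas`.
#' @export
run_compare <- function(data, pathways, spec = search_spec(),
                        fit_cfg = fit_config(),
                        restrict_to_pathways = FALSE, out_dir = NULL,
                        lambda_rule = "max") {
  gl_lambda <- grid_search_lambda(data, pathways, spec, "group_lasso",
                                  fit_cfg, rule = lambda_rule)
  la_lambda <- grid_search_lambda(data, pathways, spec, "lasso", fit_cfg,
                                  restrict_to_pathways, rule = lambda_rule)
  rep_gl <- repeated_split_eval(data, pathways, spec, "group_lasso",
                                penalty_config(lambda = gl_lambda$lambda),
                                fit_cfg)
  rep_la <- repeated_split_eval(data, pathways, spec, "lasso",
                                penalty_config(lambda = la_lambda$lambda),
                                fit_cfg, restrict_to_pathways)
  splits <- dplyr::inner_join(
    dplyr::rename(rep_gl$splits, c_group_lasso = "c_value",
                  n_groups = "n_selected_groups"),
    dplyr::select(dplyr::rename(rep_la$splits, c_lasso = "c_value"),
                  "split", "c_lasso"),
    by = "split")
  splits <- dplyr::mutate(splits,
                          c_difference = .data$c_group_lasso - .data$c_lasso)
  c_test <- paired_t_test(splits$c_difference)

  # congruence over non-overlapping split pairs: (1,2), (3,4), ...
  pair_phis <- function(betas) {
    k <- length(betas) %/% 2
    vapply(seq_len(k), function(i) {
      suppressMessages(tucker_congruence(betas[(2 * i - 1):(2 * i)]))
    }, numeric(1))
  }
  phi_gl <- pair_phis(rep_gl$betas)
  phi_la <- pair_phis(rep_la$betas)
  congruence_test <- if (length(phi_gl) >= 2 &&
                         stats::sd(phi_gl - phi_la) > 0) {
    paired_t_test(phi_gl - phi_la)
  } else NULL

  # selection frequency from the latent betas on the canonical partition
  sizes <- pathways_retained_sizes(data, pathways)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  sel <- purrr::map2_dfr(rep_gl$betas, rep_gl$splits$split, function(b, s) {
    on <- vapply(seq_along(sizes),
                 function(k) any(b[starts[k]:ends[k]] != 0), logical(1))
    tibble::tibble(split = s, pathway = names(sizes)[on])
  })
  selection_frequency <- dplyr::arrange(
    dplyr::summarise(dplyr::group_by(sel, .data$pathway),
                     n_selected = dplyr::n(),
                     frequency = dplyr::n() / nrow(rep_gl$splits),
                     .groups = "drop"),
    dplyr::desc(.data$frequency))

  report <- structure(
    list(splits = splits, c_test = c_test,
         congruence = tibble::tibble(
           method = c("group_lasso", "lasso"),
           congruence_mean = c(rep_gl$congruence_mean,
                               rep_la$congruence_mean)),
         congruence_test = congruence_test,
         selection_frequency = selection_frequency,
         lambdas = tibble::tibble(method = c("group_lasso", "lasso"),
                                  lambda = c(gl_lambda$lambda,
                                             la_lambda$lambda)),
         reports = list(group_lasso = rep_gl, lasso = rep_la)),
    class = "compare_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(splits, file.path(out_dir, "per_split.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(selection_frequency,
                       file.path(out_dir, "selection_frequency.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(mean_c_group_lasso = mean(splits$c_group_lasso),
           mean_c_lasso = mean(splits$c_lasso),
           c_t_statistic = c_test$t_statistic, c_p_value = c_test$p_value,
           congruence_group_lasso = rep_gl$congruence_mean,
           congruence_lasso = rep_la$congruence_mean,
           lambda_group_lasso = gl_lambda$lambda,
           lambda_lasso = la_lambda$lambda),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
    write_run_config(out_dir, "compare", search = spec, fit = fit_cfg,
                     restrict_to_pathways = restrict_to_pathways)
  }
  report
}

# Names/sizes of the pathway groups a latent design over `data` would
# retain, without building the matrix (used for bookkeeping on betas).
pathways_retained <- function(data, pathways) {
  kept <- lapply(pathways, function(g) g[g %in% data$gene_ids])
  kept[lengths(kept) > 0]
}

pathways_retained_sizes <- function(data, pathways) {
  lengths(pathways_retained(data, pathways))
}

#' @export
print.compare_report <- function(x, ...) {
  cat(sprintf(
    "<compare_report> %d splits: mean c %.3f (group lasso) vs %.3f (lasso), paired t p = %.3g\n",
    nrow(x$splits), mean(x$splits$c_group_lasso), mean(x$splits$c_lasso),
    x$c_test$p_value))
  invisible(x)
}

#' Multi-task evaluation of two cohorts against their single-task fits
#'
#' The paired-cohort protocol: per-cohort `lambda` by cross-validated grid
#' search, then a cross-validated random search for `(lambda1, lambda2,
#' mu)`, then repeated 80-20 splits in which each cohort is scored under
#' its single-task fit and under the jointly fitted multi-task model (each
#' cohort using its own best triple), finishing with a paired t-test of the
#' per-split c-value differences and FDR adjustment over the pairings
#' tested per cohort (a single pairing here, so the adjusted value equals
#' the raw one).
#'
#' @param data1,data2 The two cohorts.
#' @param pathways Shared `pathway_collection`.
#' @param spec A [search_spec()] (use `n_splits = 30` for the multi-task
#'   protocol).
#' @param fit_cfg A [fit_config()].
#' @param base_lambdas Optional pair of pre-selected single-task lambdas
#'   (skips the grid searches).
#' @param mt_best Optional list with `best1`/`best2` one-row tibbles
#'   (`lambda1`, `lambda2`, `mu`) to skip the random search.
#' @param out_dir Optional output directory for tables, summary JSON and
#'   resolved configuration.
#' @param lambda_rule Selection rule passed to [grid_search_lambda()].
#' @return A `multitask_report` list: `splits` (tibble: split, cohort,
#'   c_single, c_multi, difference), `tests` (per-cohort paired t-test with
#'   `fdr_adjusted_p`), `congruence` (per cohort and method),
#'   `hyperparameters`.
#' @export
run_multitask <- function(data1, data2, pathways, spec = search_spec(),
                          fit_cfg = fit_config(), base_lambdas = NULL,
                          mt_best = NULL, out_dir = NULL,
                          lambda_rule = "max") {
  if (is.null(base_lambdas)) {
    base_lambdas <- c(
      grid_search_lambda(data1, pathways, spec, "group_lasso",
                         fit_cfg, rule = lambda_rule)$lambda,
      grid_search_lambda(data2, pathways, spec, "group_lasso",
                         fit_cfg, rule = lambda_rule)$lambda)
  }
  if (is.null(mt_best)) {
    mt <- random_search_multitask(data1, data2, pathways, spec,
                                  base_lambdas[1], base_lambdas[2], fit_cfg)
    mt_best <- list(best1 = mt$best1, best2 = mt$best2)
  }
  datasets <- list(data1, data2)
  rows <- list()
  betas <- list(single = list(list(), list()),
                multi = list(list(), list()))
  same_triple <- isTRUE(all.equal(
    unlist(mt_best$best1[c("lambda1", "lambda2", "mu")]),
    unlist(mt_best$best2[c("lambda1", "lambda2", "mu")])))
  for (s in seq_len(spec$n_splits)) {
    prep <- vector("list", 2)
    trains <- vector("list", 2)
    tests <- vector("list", 2)
    ok <- TRUE
    for (j in 1:2) {
      n <- n_samples(datasets[[j]])
      set.seed(spec$seed + 500L + 31L * s + j)
      tr_idx <- sort(sample.int(n, round(spec$split_fraction * n)))
      trains[[j]] <- subset_samples(datasets[[j]], tr_idx)
      tests[[j]] <- subset_samples(datasets[[j]],
                                   setdiff(seq_len(n), tr_idx))
      if (sum(tests[[j]]$event) == 0 || sum(trains[[j]]$event) == 0) {
        ok <- FALSE
      }
    }
    if (!ok) {
      rlang::inform(sprintf("split %d skipped: no events in one portion", s))
      next
    }
    for (j in 1:2) {
      prep[[j]] <- prepare_split(trains[[j]], tests[[j]], pathways,
                                 "group_lasso")
    }
    cfg_s <- fit_cfg
    cfg_s$seed <- fit_cfg$seed + 1000L + s
    single_fits <- lapply(1:2, function(j) {
      fit_single(prep[[j]]$train_design, trains[[j]]$time,
                 trains[[j]]$event,
                 penalty_config(lambda = base_lambdas[j]), cfg_s)
    })
    pair_for <- function(best) {
      pen1 <- penalty_config(lambda = best$lambda1, mu = best$mu)
      pen2 <- penalty_config(lambda = best$lambda2, mu = best$mu)
      fit_pair(prep[[1]]$train_design, prep[[2]]$train_design,
               trains[[1]]$time, trains[[1]]$event,
               trains[[2]]$time, trains[[2]]$event, pen1, pen2, cfg_s)
    }
    mf1 <- pair_for(mt_best$best1)
    mf2 <- if (same_triple) mf1 else pair_for(mt_best$best2)
    multi_fits <- list(mf1$fit1, mf2$fit2)
    for (j in 1:2) {
      xte <- test_design_matrix(prep[[j]])
      c_single <- concordance_index(
        hazard_scores(single_fits[[j]]$beta, xte),
        tests[[j]]$time, tests[[j]]$event)
      c_multi <- concordance_index(
        hazard_scores(multi_fits[[j]]$beta, xte),
        tests[[j]]$time, tests[[j]]$event)
      rows[[length(rows) + 1]] <- tibble::tibble(
        split = s, cohort = j, c_single = c_single, c_multi = c_multi,
        difference = c_multi - c_single)
      betas$single[[j]][[length(betas$single[[j]]) + 1]] <-
        single_fits[[j]]$beta
      betas$multi[[j]][[length(betas$multi[[j]]) + 1]] <-
        multi_fits[[j]]$beta
    }
  }
  if (length(rows) == 0) rlang::abort("every split was skipped")
  splits <- dplyr::bind_rows(rows)
  tests_tbl <- dplyr::bind_rows(lapply(1:2, function(j) {
    d <- splits$difference[splits$cohort == j]
    tt <- tryCatch(paired_t_test(d), error = function(e) {
      # degenerate (e.g. identical per-split c-values): report the mean only
      tibble::tibble(estimate = mean(d), t_statistic = NA_real_,
                     df = NA_real_, p_value = NA_real_)
    })
    dplyr::mutate(tt, cohort = j, .before = 1)
  }))
  tests_tbl$fdr_adjusted_p <- vapply(tests_tbl$p_value, function(p) {
    if (is.na(p)) NA_real_ else fdr_correct(p)
  }, numeric(1))
  congruence <- tidyr::expand_grid(cohort = 1:2,
                                   method = c("single", "multi"))
  congruence$congruence_mean <- purrr::pmap_dbl(congruence, function(cohort,
                                                                     method) {
    b <- betas[[method]][[cohort]]
    if (length(b) >= 2) suppressMessages(tucker_congruence(b)) else NA_real_
  })
  hyper <- tibble::tibble(
    cohort = 1:2,
    base_lambda = base_lambdas,
    lambda1 = c(mt_best$best1$lambda1, mt_best$best2$lambda1),
    lambda2 = c(mt_best$best1$lambda2, mt_best$best2$lambda2),
    mu = c(mt_best$best1$mu, mt_best$best2$mu))
  report <- structure(
    list(splits = splits, tests = tests_tbl, congruence = congruence,
         hyperparameters = hyper),
    class = "multitask_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(splits, file.path(out_dir, "per_split.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(tests_tbl, file.path(out_dir, "tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(mean_difference = stats::setNames(
             as.list(tapply(splits$difference, splits$cohort, mean)),
             c("cohort1", "cohort2")),
           tests = tests_tbl, congruence = congruence,
           hyperparameters = hyper),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
    write_run_config(out_dir, "multitask", search = spec, fit = fit_cfg)
  }
  report
}

#' @export
print.multitask_report <- function(x, ...) {
  md <- tapply(x$splits$difference, x$splits$cohort, mean)
  cat(sprintf(
    "<multitask_report> mean c-value change (multi - single): cohort 1 %+.4f, cohort 2 %+.4f\n",
    md[1], md[2]))
  invisible(x)
}
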