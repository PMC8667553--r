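#' Synthetic paired-cohort specification
#'
#' Describes two "toy cancer" cohorts whose survival is fully determined by
#' a small number of true pathways.  Defaults mirror the validation design:
#' cohorts of 300 and 200 patients, ~70% events / 30% right-censoring, two
#' true pathways per cohort with one shared (cohort 1: P1 and P2; cohort 2:
#' P1 and P3), and within-pathway gene correlation mimicking the strong
#' collinearity of tumor expression data.  The gene count defaults to a
#' desk-scale 2,000 (the original design used nearly 10,000; set `n_genes`
#' higher to match).
#'
#' @param n_samples Integer pair: cohort sizes.
#' @param n_genes Total genes (pathway members plus background noise genes).
#' @param pathways A [pathway_collection()]; `NULL` builds
#'   [synthetic_pathways()] over the gene universe.
#' @param true_pathways List of two character vectors naming each cohort's
#'   predictive pathways.
#' @param event_probability Bernoulli probability of an event (vs
#'   censoring).
#' @param correlation_model `"block"` (within-pathway equicorrelation via a
#'   shared factor) or `"independent"`.
#' @param rho Within-pathway correlation under the block model.
#' @param time_scale Scale of the rank-preserving `exp(-score / scale)`
#'   time transform; `NULL` uses the score's standard deviation.
#' @param seed Generator seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_samples = c(300L, 200L), n_genes = 2000L,
                           pathways = NULL,
                           true_pathways = list(c("P1", "P2"),
                                                c("P1", "P3")),
                           event_probability = 0.7,
                           correlation_model = c("block", "independent"),
                           rho = 0.5, time_scale = NULL, seed = 1L) {
  correlation_model <- match.arg(correlation_model)
  stopifnot(length(n_samples) == 2, all(n_samples >= 2),
            event_probability > 0, event_probability <= 1,
            rho >= 0, rho < 1)
  if (is.null(pathways)) pathways <- synthetic_pathways(n_genes)
  missing_tp <- setdiff(unlist(true_pathways), names(pathways))
  if (length(missing_tp) > 0) {
    rlang::abort(paste0("true pathway(s) not in the collection: ",
                        paste(missing_tp, collapse = ", ")))
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes),
                 pathways = pathways, true_pathways = true_pathways,
                 event_probability = event_probability,
                 correlation_model = correlation_model, rho = rho,
                 time_scale = time_scale, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Synthetic overlapping pathway collection
#'
#' Consecutive windows of the gene universe: pathway `k` holds
#' `pathway_size` genes and shares `overlap` of them with pathway `k + 1`,
#' so adjacent pathways overlap — the situation the latent group lasso
#' exists for.  Genes beyond the last window belong to no pathway
#' (background genes).
#'
#' @param n_genes Gene universe size.
#' @param n_pathways Number of pathways.
#' @param pathway_size Genes per pathway.
#' @param overlap Shared genes between adjacent pathways.
#' @return A [pathway_collection()] named `P1 ... Pn`.
#' @export
synthetic_pathways <- function(n_genes, n_pathways = 20L,
                               pathway_size = 50L, overlap = 10L) {
  stride <- pathway_size - overlap
  needed <- (n_pathways - 1L) * stride + pathway_size
  if (needed > n_genes) {
    rlang::abort(sprintf(
      "pathway layout needs %d genes but the universe has %d", needed, n_genes))
  }
  gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  groups <- lapply(seq_len(n_pathways), function(k) {
    start <- (k - 1L) * stride + 1L
    gene_ids[start:(start + pathway_size - 1L)]
  })
  names(groups) <- paste0("P", seq_len(n_pathways))
  pathway_collection(groups)
}

# One cohort's expression matrix under the chosen correlation model.
# Block model: gene i with pathway memberships S gets
#   sqrt(rho) * mean-factor(S) + sqrt(1 - rho) * noise,
# giving correlation rho between genes exclusive to the same pathway.
sample_expression <- function(n, gene_ids, pathways, model, rho, prefix) {
  m <- length(gene_ids)
  x <- matrix(stats::rnorm(n * m), n, m,
              dimnames = list(sprintf("%s_s%04d", prefix, seq_len(n)),
                              gene_ids))
  if (model == "block" && rho > 0) {
    membership <- lapply(gene_ids, function(g) {
      which(vapply(pathways, function(p) g %in% p, logical(1)))
    })
    factors <- matrix(stats::rnorm(n * length(pathways)), n,
                      length(pathways))
    in_pw <- lengths(membership) > 0
    shared <- vapply(which(in_pw), function(i) {
      idx <- membership[[i]]
      rowSums(factors[, idx, drop = FALSE]) / sqrt(length(idx))
    }, numeric(n))
    x[, in_pw] <- sqrt(rho) * shared +
      sqrt(1 - rho) * x[, in_pw, drop = FALSE]
  }
  x
}

#' Generate the two cohorts' expression matrices
#'
#' Draws multivariate-normal expression per cohort under the spec's
#' correlation model.  Consumes the current RNG state; seed via
#' `set.seed()` or use [generate_pair()] which seeds from the spec.
#'
#' @param spec A [synthetic_spec()].
#' @return List of two samples-by-genes matrices.
#' @export
generate_expression <- function(spec) {
  gene_ids <- sprintf("gene%04d", seq_len(spec$n_genes))
  list(
    sample_expression(spec$n_samples[1], gene_ids, spec$pathways,
                      spec$correlation_model, spec$rho, "T1"),
    sample_expression(spec$n_samples[2], gene_ids, spec$pathways,
                      spec$correlation_model, spec$rho, "T2")
  )
}

#' Ground-truth coefficient vectors from first principal components
#'
#' For each true pathway, the loadings are the first principal component of
#' that pathway's gene columns over the two cohorts pooled (so a pathway
#' shared between cohorts gets identical loadings in both).  The component
#' sign is fixed so the largest-magnitude loading is positive.  All other
#' genes get exactly zero.
#'
#' @param spec A [synthetic_spec()].
#' @param expression List of the two cohorts' matrices (as from
#'   [generate_expression()]).
#' @return List of two named gene-space coefficient vectors.
#' @export
true_beta <- function(spec, expression) {
  pooled <- rbind(expression[[1]], expression[[2]])
  gene_ids <- colnames(pooled)
  loadings_for <- function(pw) {
    genes <- intersect(spec$pathways[[pw]], gene_ids)
    if (length(genes) < 2) {
      rlang::abort(sprintf(
        "pathway %s has fewer than 2 measured genes; PC undefined", pw))
    }
    pc <- stats::prcomp(pooled[, genes, drop = FALSE], center = TRUE,
                        scale. = FALSE)
    load <- pc$rotation[, 1]
    if (load[which.max(abs(load))] < 0) load <- -load
    load
  }
  all_true <- unique(unlist(spec$true_pathways))
  loads <- lapply(stats::setNames(all_true, all_true), loadings_for)
  lapply(spec$true_pathways, function(tps) {
    beta <- stats::setNames(numeric(length(gene_ids)), gene_ids)
    for (pw in tps) {
      beta[names(loads[[pw]])] <- beta[names(loads[[pw]])] + loads[[pw]]
    }
    beta
  })
}

#' Generate survival outcomes from hazard scores
#'
#' Event status is i.i.d. Bernoulli(`event_probability`).  The base time is
#' the rank-preserving transform `exp(-score / scale)` of the hazard score
#' (higher score, earlier death; only the ordering matters to the partial
#' likelihood).  Censored patients' recorded times are then stochastically
#' reduced below the latent death time: multiplied by `U^q_i` with
#' `U ~ Uniform(0, 1)` and `q_i` the fraction of patients with a strictly
#' higher score, so low-risk patients (whose death would be late) are
#' shrunk more.
#'
#' @param expression Cohort expression matrix.
#' @param beta Named gene-space coefficient vector.
#' @param spec A [synthetic_spec()].
#' @return List with `time`, `event` and the latent `score`.
#' @export
generate_survival <- function(expression, beta, spec) {
  score <- drop(expression %*% beta[colnames(expression)])
  n <- length(score)
  scale_ <- spec$time_scale
  if (is.null(scale_)) scale_ <- max(stats::sd(score), 1e-12)
  base_time <- exp(-score / scale_)
  event <- stats::rbinom(n, 1, spec$event_probability)
  q <- vapply(score, function(s) mean(score > s), numeric(1))
  u <- stats::runif(n)
  time <- base_time
  cens <- event == 0
  time[cens] <- base_time[cens] * u[cens]^q[cens]
  list(time = time, event = event, score = score)
}

#' Generate a complete paired synthetic study
#'
#' Seeds the RNG from the spec and composes expression, ground-truth
#' coefficients and survival outcomes into two ready-to-model cohorts plus
#' the ground truth needed for support-recovery scoring.
#'
#' @param spec A [synthetic_spec()].
#' @return A `synthetic_pair` list: `data1`, `data2` (`survival_dataset`s),
#'   `true_beta1`, `true_beta2` (gene-space vectors), `true_pathways`,
#'   `pathways`, `spec`.
#' @export
generate_pair <- function(spec = synthetic_spec()) {
  set.seed(spec$seed)
  expr <- generate_expression(spec)
  betas <- true_beta(spec, expr)
  surv1 <- generate_survival(expr[[1]], betas[[1]], spec)
  surv2 <- generate_survival(expr[[2]], betas[[2]], spec)
  structure(
    list(data1 = survival_dataset(expr[[1]], surv1$time, surv1$event),
         data2 = survival_dataset(expr[[2]], surv2$time, surv2$event),
         true_beta1 = betas[[1]], true_beta2 = betas[[2]],
         true_score1 = surv1$score, true_score2 = surv2$score,
         true_pathways = spec$true_pathways,
         pathways = spec$pathways, spec = spec),
    class = "synthetic_pair"
  )
}

#' @export
print.synthetic_pair <- function(x, ...) {
  cat(sprintf(
    "<synthetic_pair> cohorts %d and %d samples x %d genes; true pathways %s | %s\n",
    n_samples(x$data1), n_samples(x$data2), n_genes(x$data1),
    paste(x$true_pathways[[1]], collapse = ","),
    paste(x$true_pathways[[2]], collapse = ",")))
  invisible(x)
}

#' Write a synthetic pair to disk
#'
#' Emits, per cohort, the expression and clinical tables in the delimited
#' formats [load_survival_dataset()] reads, plus a ground-truth JSON sidecar
#' (true pathways, non-zero true coefficients, seed and spec scalars).
#'
#' @param pair A [generate_pair()] result.
#' @param dir Output directory (created if needed).
#' @return Character vector of the five file paths, invisibly.
#' @export
write_synthetic_pair <- function(pair, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (j in 1:2) {
    d <- pair[[paste0("data", j)]]
    ep <- file.path(dir, sprintf("cohort%d_expression.tsv", j))
    cp <- file.path(dir, sprintf("cohort%d_clinical.tsv", j))
    expr_df <- data.frame(sample = d$sample_ids, d$expression,
                          check.names = FALSE)
    utils::write.table(expr_df, ep, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(
      data.frame(sample = d$sample_ids, time = d$time, event = d$event),
      cp, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, ep, cp)
  }
  tp <- file.path(dir, "truth.json")
  nz1 <- pair$true_beta1[pair$true_beta1 != 0]
  nz2 <- pair$true_beta2[pair$true_beta2 != 0]
  jsonlite::write_json(
    list(true_pathways = pair$true_pathways,
         true_beta1 = as.list(nz1), true_beta2 = as.list(nz2),
         seed = pair$spec$seed,
         n_samples = pair$spec$n_samples, n_genes = pair$spec$n_genes,
         event_probability = pair$spec$event_probability,
         correlation_model = pair$spec$correlation_model,
         rho = pair$spec$rho),
    tp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, tp))
}
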