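#' Construct a survival dataset
#'
#' Bundles a samples-by-genes expression matrix with right-censored survival
#' outcomes.  `time` holds the observed time (event or censoring) per sample
#' and `event` the status indicator (1 = deceased, 0 = right-censored).
#'
#' @param expression Numeric matrix, samples in rows and genes in columns,
#'   with unique row (sample) and column (gene) names.
#' @param time Non-negative, finite numeric vector, one entry per sample.
#' @param event Integer/numeric vector of 0/1 indicators, one per sample.
#' @return An object of class `survival_dataset`: a list with elements
#'   `expression`, `time`, `event`, `sample_ids`, `gene_ids`, and
#'   `standardization` (`NULL` until [standardize()] is applied).
#' @export
survival_dataset <- function(expression, time, event) {
  expression <- as.matrix(expression)
  storage.mode(expression) <- "double"
  n <- nrow(expression)
  if (is.null(rownames(expression))) {
    rownames(expression) <- paste0("sample", seq_len(n))
  }
  if (is.null(colnames(expression))) {
    colnames(expression) <- paste0("gene", seq_len(ncol(expression)))
  }
  if (anyDuplicated(colnames(expression))) {
    rlang::abort("gene identifiers must be unique")
  }
  if (anyDuplicated(rownames(expression))) {
    rlang::abort("sample identifiers must be unique")
  }
  if (anyNA(expression)) {
    rlang::abort("expression matrix contains missing values")
  }
  if (length(time) != n || length(event) != n) {
    rlang::abort("time and event must each have one entry per sample")
  }
  time <- as.double(time)
  event <- as.double(event)
  if (anyNA(time) || any(!is.finite(time)) || any(time < 0)) {
    rlang::abort("time values must be non-negative and finite")
  }
  if (!all(event %in% c(0, 1))) {
    rlang::abort("event indicators must be 0 (censored) or 1 (deceased)")
  }
  structure(
    list(
      expression = expression,
      time = unname(time),
      event = unname(event),
      sample_ids = rownames(expression),
      gene_ids = colnames(expression),
      standardization = NULL
    ),
    class = "survival_dataset"
  )
}

#' @export
print.survival_dataset <- function(x, ...) {
  cat(sprintf(
    "<survival_dataset> %d samples x %d genes; %d events (%.0f%%), %d censored%s\n",
    length(x$time), length(x$gene_ids), sum(x$event),
    100 * mean(x$event), sum(x$event == 0),
    if (is.null(x$standardization)) "" else "; standardized"
  ))
  invisible(x)
}

#' Number of samples / genes in a survival dataset
#' @param x A `survival_dataset`.
#' @return Integer count.
#' @export
n_samples <- function(x) length(x$time)

#' @rdname n_samples
#' @export
n_genes <- function(x) length(x$gene_ids)

# Sniff the field separator of a delimited text file (tab or comma).
detect_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

read_delim_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = detect_delim(path),
                    check.names = FALSE, stringsAsFactors = FALSE)
}

#' Load expression and clinical files into a survival dataset
#'
#' Reads a delimited (tab or comma, auto-detected) expression table and a
#' clinical table, aligns them on sample identifier, and returns a validated
#' [survival_dataset()].  Samples present in only one of the files are
#' dropped with a message reporting the count.
#'
#' @param expression_path Path to the expression table.  The first column
#'   must hold row identifiers; remaining columns are numeric.
#' @param clinical_path Path to the clinical table.
#' @param sample_col,time_col,event_col Column names in the clinical file.
#' @param orientation `"samples_by_genes"` (rows are samples) or
#'   `"genes_by_samples"` (rows are genes; the matrix is transposed).
#' @return A `survival_dataset`.
#' @export
load_survival_dataset <- function(expression_path, clinical_path,
                                  sample_col = "sample",
                                  time_col = "time",
                                  event_col = "event",
                                  orientation = c("samples_by_genes",
                                                  "genes_by_samples")) {
  orientation <- match.arg(orientation)
  expr_df <- read_delim_table(expression_path)
  mat <- as.matrix(expr_df[, -1, drop = FALSE])
  rownames(mat) <- as.character(expr_df[[1]])
  storage.mode(mat) <- "double"
  if (orientation == "genes_by_samples") mat <- t(mat)

  clin <- read_delim_table(clinical_path)
  missing_cols <- setdiff(c(sample_col, time_col, event_col), names(clin))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("clinical file lacks column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  clin_ids <- as.character(clin[[sample_col]])
  shared <- intersect(rownames(mat), clin_ids)
  if (length(shared) == 0) {
    rlang::abort("no samples shared between expression and clinical files")
  }
  n_dropped <- (nrow(mat) - length(shared)) + (length(clin_ids) - length(shared))
  if (n_dropped > 0) {
    rlang::inform(sprintf(
      "dropped %d sample(s) absent from one of the two files", n_dropped))
  }
  clin <- clin[match(shared, clin_ids), , drop = FALSE]
  survival_dataset(mat[shared, , drop = FALSE],
                   time = clin[[time_col]], event = clin[[event_col]])
}

#' Standardize gene expression columns
#'
#' Centers and scales every gene column to mean 0, standard deviation 1
#' (sample convention, divisor `n - 1`).  When `reference` is supplied its
#' per-gene statistics are applied instead, so a held-out set can be placed
#' on the training set's scale.  Zero-variance genes become all-zero columns
#' and are flagged rather than dropped, keeping column indexing stable.
#'
#' @param data A `survival_dataset`.
#' @param reference Optional `survival_dataset` whose gene set equals
#'   `data`'s; its means/sds define the transformation.
#' @return A standardized `survival_dataset` whose `standardization` element
#'   is a tibble with columns `gene`, `center`, `scale`, `zero_variance`.
#' @export
standardize <- function(data, reference = NULL) {
  stopifnot(inherits(data, "survival_dataset"))
  src <- if (is.null(reference)) data else reference
  if (!identical(src$gene_ids, data$gene_ids)) {
    rlang::abort("reference gene set must equal the dataset's gene set")
  }
  center <- colMeans(src$expression)
  scale_ <- apply(src$expression, 2, stats::sd)
  zero_var <- !is.finite(scale_) | scale_ <= 0
  safe_scale <- ifelse(zero_var, 1, scale_)
  out <- sweep(sweep(data$expression, 2, center, "-"), 2, safe_scale, "/")
  out[, zero_var] <- 0
  res <- survival_dataset(out, data$time, data$event)
  res$standardization <- tibble::tibble(
    gene = data$gene_ids, center = unname(center),
    scale = unname(scale_), zero_variance = unname(zero_var)
  )
  if (any(zero_var) && is.null(reference)) {
    rlang::inform(sprintf("%d zero-variance gene(s) set to all-zero columns",
                          sum(zero_var)))
  }
  res
}

#' Construct a pathway collection
#'
#' A named, ordered set of gene groups.  Groups may overlap: a gene appearing
#' in several pathways is the motivating case for the latent group lasso.
#'
#' @param groups Named list of character vectors of gene identifiers.
#' @return An object of class `pathway_collection`.
#' @export
pathway_collection <- function(groups) {
  if (is.null(names(groups)) || any(names(groups) == "") ||
      anyDuplicated(names(groups))) {
    rlang::abort("pathway names must be present and unique")
  }
  groups <- lapply(groups, function(g) unique(as.character(g)))
  if (any(lengths(groups) == 0)) {
    rlang::abort("every pathway must contain at least one gene")
  }
  structure(groups, class = "pathway_collection")
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat(sprintf("<pathway_collection> %d pathways, %d distinct genes\n",
              length(x), length(unique(unlist(x)))))
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' One record per line: pathway name, description, then gene identifiers.
#' Duplicate genes within a record are deduplicated; duplicate pathway names
#' or records without genes are errors.
#'
#' @param path Path to a GMT file.
#' @return A [pathway_collection()].
#' @export
read_gene_sets <- function(path) {
  sets <- fgsea::gmtPathways(path)
  if (anyDuplicated(names(sets))) {
    rlang::abort("duplicate pathway names in gene-set file")
  }
  if (any(lengths(sets) == 0)) {
    rlang::abort("gene-set file contains a record with no genes")
  }
  pathway_collection(sets)
}

#' Write a pathway collection as a GMT file
#' @param pathways A `pathway_collection`.
#' @param path Output path.
#' @param description Description field written for every record.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(pathways, path, description = "na") {
  lines <- vapply(names(pathways), function(nm) {
    paste(c(nm, description, pathways[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Expand overlapping pathways into a latent (duplicated-column) design
#'
#' The latent group lasso handles overlapping groups by giving each pathway
#' its own copy of every member gene's column.  The resulting latent matrix
#' has `M = sum over retained pathways of measured-member count` columns and
#' its columns partition into disjoint per-pathway blocks.  Genes absent
#' from the expression matrix are excluded from their groups; pathways left
#' empty by that intersection are dropped (both reported via a message).
#'
#' @param data A (standardized) `survival_dataset`.
#' @param pathways A `pathway_collection`.
#' @return An object of class `latent_design`: list with `x` (n-by-M latent
#'   matrix), `groups` (named list of column-index blocks), `group_sizes`,
#'   `origin` (tibble: `column`, `pathway`, `gene`), `gene_ids` (the full
#'   gene universe of `data`), and `dropped_pathways`.
#' @export
build_latent_design <- function(data, pathways) {
  stopifnot(inherits(data, "survival_dataset"),
            inherits(pathways, "pathway_collection"))
  measured <- lapply(pathways, function(g) g[g %in% data$gene_ids])
  dropped <- names(measured)[lengths(measured) == 0]
  kept <- measured[lengths(measured) > 0]
  if (length(kept) == 0) {
    rlang::abort("no pathway retains any measured gene")
  }
  n_lost <- sum(lengths(pathways)) - sum(lengths(kept))
  if (n_lost > 0) {
    rlang::inform(sprintf(
      "excluded %d unmeasured gene membership(s); dropped %d empty pathway(s)",
      n_lost, length(dropped)))
  }
  genes_flat <- unlist(kept, use.names = FALSE)
  x <- data$expression[, genes_flat, drop = FALSE]
  colnames(x) <- paste(rep(names(kept), lengths(kept)), genes_flat, sep = "|")
  sizes <- lengths(kept)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  groups <- stats::setNames(
    purrr::map2(starts, ends, ~ seq.int(.x, .y)), names(kept))
  structure(
    list(
      x = x,
      groups = groups,
      group_sizes = sizes,
      origin = tibble::tibble(
        column = seq_along(genes_flat),
        pathway = rep(names(kept), sizes),
        gene = genes_flat
      ),
      gene_ids = data$gene_ids,
      dropped_pathways = dropped
    ),
    class = "latent_design"
  )
}

#' @export
print.latent_design <- function(x, ...) {
  cat(sprintf("<latent_design> %d samples x %d latent columns, %d groups\n",
              nrow(x$x), ncol(x$x), length(x$groups)))
  invisible(x)
}

#' Collapse a latent coefficient vector to gene space
#'
#' Sums the latent copies of each gene, returning one coefficient per gene of
#' the originating dataset (zero for genes outside every retained pathway).
#' By linearity, hazard scores computed from the latent matrix and a latent
#' beta equal scores from the original expression matrix and the collapsed
#' beta.
#'
#' @param beta Numeric vector over the latent columns of `design`.
#' @param design A `latent_design`.
#' @return Named numeric vector over `design$gene_ids`.
#' @export
collapse_beta <- function(beta, design) {
  stopifnot(inherits(design, "latent_design"),
            length(beta) == ncol(design$x))
  out <- stats::setNames(numeric(length(design$gene_ids)), design$gene_ids)
  sums <- tapply(beta, design$origin$gene, sum)
  out[names(sums)] <- sums
  out
}

#' Per-group Euclidean norms of a latent coefficient vector
#' @param beta Numeric vector over latent columns.
#' @param design A `latent_design`.
#' @return Named numeric vector, one norm per pathway block.
#' @export
group_norms <- function(beta, design) {
  vapply(design$groups, function(idx) sqrt(sum(beta[idx]^2)), numeric(1))
}
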