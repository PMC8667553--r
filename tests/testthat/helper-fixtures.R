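# Shared fixtures and independent oracles.  Oracles are deliberately
# written as naive straight-line code so they stay independent of the
# package's vectorized implementations.

# Small dataset with overlapping pathways for unit tests.
make_toy <- function(n = 40, seed = 1, standardized = TRUE) {
  set.seed(seed)
  genes <- paste0("g", 1:12)
  pw <- pathway_collection(list(A = genes[1:5], B = genes[4:8],
                                C = genes[9:12]))
  x <- matrix(rnorm(n * 12), n, 12, dimnames = list(NULL, genes))
  d <- survival_dataset(x, time = rexp(n), event = rbinom(n, 1, 0.7))
  if (sum(d$event) == 0) d$event[1] <- 1
  ds <- if (standardized) suppressMessages(standardize(d)) else d
  list(data = ds, pathways = pw,
       design = suppressMessages(build_latent_design(ds, pw)))
}

# Exhaustive O(n^2) concordance oracle: double loop over ordered pairs.
cindex_oracle <- function(scores, time, event) {
  num <- 0; den <- 0
  n <- length(scores)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    comparable <- (time[i] < time[j] && event[i] == 1) ||
      (time[i] == time[j] && event[i] == 1 && event[j] == 0)
    if (!comparable) next
    den <- den + 1
    if (scores[i] > scores[j]) num <- num + 1
    else if (scores[i] == scores[j]) num <- num + 0.5
  }
  if (den == 0) stop("no comparable pairs")
  num / den
}

# Straight-line evaluation of the coupling penalty from its formula.
coupling_oracle <- function(b1, b2, design, mu, w = 0.5, eps = 1e-8) {
  total <- 0
  for (k in seq_along(design$groups)) {
    idx <- design$groups[[k]]
    u <- b1[idx]; v <- b2[idx]
    ru <- sqrt(sum(u^2)); rv <- sqrt(sum(v^2))
    if (ru <= eps || rv <= eps) next
    a12 <- sqrt(sum((u - v * ru / rv)^2))
    a21 <- sqrt(sum((v - u * rv / ru)^2))
    total <- total + unname(design$group_sizes[k])^w * sqrt(a12^2 + a21^2)
  }
  mu * total
}

# Naive Benjamini-Hochberg step-up oracle.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (k in m:1) {
    val <- min(prev, p[o[k]] * m / k)
    adj[o[k]] <- val
    prev <- val
  }
  adj
}

# Central-difference gradient.
num_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(k) {
    xp <- x; xp[k] <- xp[k] + h
    xm <- x; xm[k] <- xm[k] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

# Write a small expression + clinical file pair; returns the two paths.
write_toy_files <- function(dir, n = 3, m = 4, sep = "\t",
                            extra_clinical = 0, event_codes = NULL) {
  set.seed(99)
  samples <- paste0("s", seq_len(n))
  genes <- paste0("g", seq_len(m))
  expr <- matrix(round(rnorm(n * m), 3), n, m,
                 dimnames = list(samples, genes))
  ep <- file.path(dir, "expr.txt")
  cp <- file.path(dir, "clin.txt")
  write.table(data.frame(sample = samples, expr, check.names = FALSE),
              ep, sep = sep, quote = FALSE, row.names = FALSE)
  all_samples <- c(samples, if (extra_clinical > 0)
    paste0("x", seq_len(extra_clinical)))
  ev <- if (is.null(event_codes)) rep(c(1, 0), length.out = length(all_samples))
        else event_codes
  write.table(data.frame(sample = all_samples,
                         time = seq_along(all_samples),
                         event = ev),
              cp, sep = sep, quote = FALSE, row.names = FALSE)
  c(expression = ep, clinical = cp)
}

# Compact synthetic spec for fast end-to-end tests.
tiny_spec <- function(seed = 1, n1 = 90, n2 = 70, n_genes = 240,
                      n_pathways = 6, size = 25, overlap = 5) {
  tp <- if (n_pathways >= 3) list(c("P1", "P2"), c("P1", "P3"))
        else list("P1", "P2")
  synthetic_spec(
    n_samples = c(n1, n2), n_genes = n_genes,
    pathways = synthetic_pathways(n_genes, n_pathways, size, overlap),
    true_pathways = tp, seed = seed)
}

# Fast optimizer settings for tests.
fast_cfg <- function(seed = 1, iters = 800) {
  fit_config(max_iterations = iters, learning_rate = 0.02,
             convergence_tolerance = 1e-8, seed = seed)
}
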