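# Brute-force reference implementations, kept deliberately naive and
# independent of the package's code paths. Used to cross-check the
# statistic operations on random small instances.

oracle_cv_percent <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  s <- sqrt(sum((x - m)^2) / (n - 1))
  100 * s / m
}

oracle_mfc <- function(x) {
  x <- unname(x)
  mn <- x[1]; mx <- x[1]
  for (v in x) {
    if (v < mn) mn <- v
    if (v > mx) mx <- v
  }
  if (mn == 0) Inf else mx / mn
}

# sort-based median: middle value (odd n) or mean of the two central ones
oracle_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

# exhaustive pair enumeration for GeNorm M
oracle_m_values <- function(q) {
  genes <- rownames(q)
  vapply(genes, function(j) {
    others <- setdiff(genes, j)
    mean(vapply(others, function(k) {
      stats::sd(log2(q[j, ] / q[k, ]))
    }, numeric(1)))
  }, numeric(1))
}

# rolling-window CV quantiles straight from an expression matrix
oracle_quantile_curves <- function(x, window, levels, step = 1) {
  cvs <- apply(x, 1, oracle_cv_percent)
  means <- rowMeans(x)
  ord <- order(means, rownames(x))
  cvs <- cvs[ord]; means <- means[ord]
  starts <- seq(1, nrow(x) - window + 1, by = step)
  t(vapply(starts, function(i) {
    idx <- i:(i + window - 1)
    c(mean(means[idx]),
      stats::quantile(cvs[idx], probs = levels / 100, names = FALSE))
  }, numeric(1 + length(levels))))
}

# random strictly positive gene-by-sample matrix
random_expr <- function(n_genes, n_samples, label = "rnd") {
  vals <- matrix(exp(stats::rnorm(n_genes * n_samples, 3, 1)),
                 nrow = n_genes,
                 dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                 sprintf("s%03d", seq_len(n_samples))))
  expression_matrix(vals, dataset_label = label)
}
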