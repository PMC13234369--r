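# small in-code fixtures shared across test files

toy_expr <- function(values = NULL, is_log2 = TRUE) {
  if (is.null(values)) {
    values <- matrix(c(1, 2, 3, 4,
                       2, 4, 6, 8,
                       4, 3, 2, 1), nrow = 3, byrow = TRUE)
  }
  dimnames(values) <- list(sprintf("g%d", seq_len(nrow(values))),
                           sprintf("s%d", seq_len(ncol(values))))
  expression_matrix(values, is_log2 = is_log2)
}

random_expr <- function(n_genes, n_samples, seed) {
  set.seed(seed)
  toy_expr(matrix(rnorm(n_genes * n_samples, 8, 2), n_genes, n_samples))
}

# brute-force PC1 oracle: eigendecomposition of the gene covariance of the
# z-scored submatrix, samples projected by hand (independent of prcomp)
pc1_oracle <- function(z) {
  # z: genes x samples, each row mean 0 sd 1
  cv <- stats::cov(t(z))
  eg <- eigen(cv, symmetric = TRUE)
  v <- eg$vectors[, 1L]
  scores <- drop(t(z) %*% v)
  list(scores = scores - mean(scores),
       evf = eg$values[1L] / sum(eg$values))
}

# equality up to a global sign flip
expect_equal_up_to_sign <- function(x, y, tolerance = 1e-8) {
  d1 <- max(abs(x - y))
  d2 <- max(abs(x + y))
  expect_lt(min(d1, d2), tolerance)
}

simple_clinical <- function(n, seed = 1, tissue = "tumor") {
  set.seed(seed)
  clinical_table(data.frame(
    sample_id = sprintf("s%d", seq_len(n)),
    os_time = round(rexp(n, 0.1), 3),
    os_event = rbinom(n, 1, 0.7),
    tissue = tissue,
    stringsAsFactors = FALSE))
}
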