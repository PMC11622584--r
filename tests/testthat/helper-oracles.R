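# Independent oracles used across the suite. These stay deliberately naive
# (enumeration, brute force) so they never share code with the implementation.

# Benjamini-Hochberg step-up by direct definition: sort ascending, scale by
# m/i, enforce monotonicity from the largest rank down, cap at 1.
bh_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  scaled <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# All points of the K-simplex with coordinates on a grid of the given step
# (step must divide 1). Rows sum to exactly 1.
simplex_grid <- function(K, step) {
  n <- round(1 / step)
  comp_int <- function(n, k) {
    if (k == 1) return(matrix(n, 1, 1))
    do.call(rbind, lapply(0:n, function(i) cbind(i, comp_int(n - i, k - 1))))
  }
  comp_int(n, K) / n
}

# Best sum-of-squares objective ||R w - m||^2 over a precomputed simplex
# grid of candidate weight vectors (grid: K x G).
grid_search_best <- function(R, m, grid_t) {
  V <- R %*% grid_t                      # sites x G
  obj <- colSums(V^2) - 2 * drop(crossprod(V, m)) + sum(m^2)
  g <- which.min(obj)
  list(objective = obj[g], w = grid_t[, g])
}

# Per-site ordinary least squares via the normal equations, one site at a
# time — the slow-but-obvious counterpart of the pseudoinverse fit.
ols_per_site <- function(X, M) {
  XtX_inv <- solve(t(X) %*% X)
  vapply(seq_len(ncol(M)), function(j) {
    drop(XtX_inv %*% t(X) %*% M[, j])
  }, numeric(ncol(X)))
}

# Small dense methylation matrix with the given values (samples x sites).
toy_matrix <- function(values, sample_ids = NULL, site_ids = NULL) {
  if (is.null(sample_ids)) sample_ids <- sprintf("S%02d", seq_len(nrow(values)))
  if (is.null(site_ids)) site_ids <- paste0("chr1:", 100 + 50 * seq_len(ncol(values)))
  dimnames(values) <- list(sample_ids, site_ids)
  methylation_matrix(values)
}

# Tiny reference with well-separated synthetic columns.
toy_reference <- function(n_sites = 120, types = c("a", "b", "c"),
                          seed = 42) {
  withr::with_seed(seed, {
    K <- length(types)
    values <- matrix(runif(n_sites * K, 0.05, 0.95), n_sites, K)
    block <- floor(n_sites / K)
    for (k in seq_len(K)) {
      idx <- ((k - 1) * block + 1):(k * block)
      values[idx, ] <- 0.05
      values[idx, k] <- 0.95
    }
    rownames(values) <- paste0("chr1:", 100 + 50 * seq_len(n_sites))
    colnames(values) <- types
    reference_methylome(values)
  })
}

write_cgmap_lines <- function(lines) {
  f <- tempfile(fileext = ".cgmap")
  writeLines(lines, f)
  f
}
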