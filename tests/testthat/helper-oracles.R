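# Shared fixtures and independent oracle implementations. Everything here is
# deliberately naive (dense enumeration over all pairs) so it cannot share a
# defect with the closed-form / sparse routes it cross-checks.

# tiny binning: n_chroms equal chromosomes, acrocentric r
tiny_binning <- function(n_chroms = 2, chrom_length = 300, bin_size = 100) {
  b <- genome_binning(paste0("chr", seq_len(n_chroms)),
                      rep(chrom_length, n_chroms), bin_size)
  compute_relative_positions(b)
}

# dense count matrix from a contact table
dense_counts <- function(tab) {
  n <- tab$binning$n_bins
  N <- matrix(0, n, n)
  N[cbind(tab$i, tab$j)] <- tab$count
  N + t(N)
}

rabl_factor_matrix <- function(binning, alpha, beta) {
  r <- binning$r
  outer(r, r, function(x, y) 1 + alpha * x * y + beta * (x + y) * x * y)
}

# naive log-likelihood: explicit loop over every eligible trans pair
naive_loglik <- function(tab, C, alpha = 0, beta = 0, exclusions = NULL) {
  b <- tab$binning
  C <- as.matrix(C)
  if (!is.null(exclusions)) C[exclusions$blacklist, ] <- 0
  N <- dense_counts(tab)
  R <- rabl_factor_matrix(b, alpha, beta)
  ep <- hicsubcomp:::eligible_pairs(b, exclusions)
  L <- 0
  for (q in seq_len(nrow(ep))) {
    i <- ep[q, 1]; j <- ep[q, 2]
    f <- R[i, j] * sum(C[i, ] * C[j, ])
    if (N[i, j] > 0) {
      if (f <= 0) return(-Inf)
      L <- L + N[i, j] * log(f)
    }
    L <- L - f
  }
  L
}

# central finite differences of a scalar function
fd_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(k) {
    e <- numeric(length(x)); e[k] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

# central-difference Jacobian of a vector-valued function
fd_jac <- function(g, x, h = 1e-6) {
  cols <- lapply(seq_along(x), function(k) {
    e <- numeric(length(x)); e[k] <- h
    (g(x + e) - g(x - e)) / (2 * h)
  })
  do.call(cbind, cols)
}

fd_hess <- function(f, x, h = 1e-4) {
  m <- length(x)
  H <- matrix(0, m, m)
  for (k in seq_len(m)) for (l in seq_len(m)) {
    ek <- numeric(m); ek[k] <- h
    el <- numeric(m); el[l] <- h
    H[k, l] <- (f(x + ek + el) - f(x + ek - el) -
                  f(x - ek + el) + f(x - ek - el)) / (4 * h^2)
  }
  (H + t(H)) / 2
}

# random small contact table with every count drawn positive
random_instance <- function(n_chroms = 3, bins_per_chrom = 3, M = 2,
                            seed = 1, alpha = 0.4, beta = 0.2,
                            rate_scale = 5) {
  b <- tiny_binning(n_chroms, bins_per_chrom * 100, 100)
  set.seed(seed)
  C <- matrix(stats::rgamma(b$n_bins * M, 2, 1), b$n_bins, M)
  tab <- simulate_contacts(b, C * sqrt(rate_scale), alpha, beta,
                           depth_scale = 1, seed = seed + 1000)
  list(binning = b, C = C, tab = tab, alpha = alpha, beta = beta)
}

# depth calibration: expected trans read-ends per bin -> depth_scale
depth_for_coverage <- function(binning, C, alpha, beta, ends_per_bin) {
  target <- ends_per_bin * binning$n_bins / 2
  target / expected_total_contacts(binning, C, alpha, beta)
}

expect_monotone_trace <- function(trace, rel = 1e-8) {
  drops <- diff(trace) < -rel * (abs(trace[-length(trace)]) + 1)
  expect_false(any(drops),
               info = paste("likelihood decreased at outer iteration(s)",
                            paste(which(drops), collapse = ", ")))
}
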