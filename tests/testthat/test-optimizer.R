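# Derivative and solver checks use the dense naive likelihood as the oracle.

test_that("locus gradient and Hessian match finite differences of the likelihood", {
  for (seed in c(2, 7, 21)) {
    inst <- random_instance(3, 3, M = 2, seed = seed)
    b <- inst$binning
    m <- compartment_model(inst$C, inst$alpha, inst$beta, b)
    for (i in c(1L, 5L)) {
      gh <- locus_gradient_hessian(i, inst$tab, m)
      f <- function(ci) {
        C2 <- inst$C; C2[i, ] <- ci
        naive_loglik(inst$tab, C2, inst$alpha, inst$beta)
      }
      x0 <- inst$C[i, ]
      expect_equal(gh$G, fd_grad(f, x0), tolerance = 1e-6)
      g_of_c <- function(ci) {
        C2 <- inst$C; C2[i, ] <- ci
        locus_gradient_hessian(i, inst$tab,
          compartment_model(C2, inst$alpha, inst$beta, b))$G
      }
      expect_equal(gh$H, fd_jac(g_of_c, x0), tolerance = 1e-6)
      # -H is positive semidefinite (convex subproblem)
      expect_true(all(eigen(-gh$H, symmetric = TRUE,
                            only.values = TRUE)$values > -1e-9))
    }
  }
})

test_that("the no-reads locus gradient is minus the Rabl-weighted column sum", {
  inst <- random_instance(2, 3, M = 2, seed = 4)
  b <- inst$binning
  # locus with all counts removed
  keep <- inst$tab$i != 1L & inst$tab$j != 1L
  tab <- contact_table(inst$tab$i[keep], inst$tab$j[keep],
                       inst$tab$count[keep], b)
  m <- compartment_model(inst$C, inst$alpha, inst$beta, b)
  gh <- locus_gradient_hessian(1L, tab, m)
  other <- which(b$bin_chrom != b$bin_chrom[1])
  R <- rabl_term(b$r[1], b$r[other], inst$alpha, inst$beta)
  expect_equal(gh$G, -colSums(R * inst$C[other, ]))
  expect_equal(gh$H, matrix(0, 2, 2))
})

test_that("solve_locus finds the closed-form M = 1 stationary point", {
  # two bins, single compartment, one neighbor with N = 4 and C_j = 2:
  # G = 4/C_i - 2, zero at C_i = 2
  b <- tiny_binning(2, 100, 100)
  tab <- contact_table(1L, 2L, 4, b)
  m <- compartment_model(matrix(c(5, 2), 2, 1), 0, 0, b)
  res <- solve_locus(1L, tab, m, inner_tol = 1e-10)
  expect_equal(res$row, 2, tolerance = 1e-8)
  expect_lt(res$kkt, 1e-9)
})

test_that("a locus with no trans reads solves to the zero row", {
  inst <- random_instance(2, 3, M = 2, seed = 8)
  keep <- inst$tab$i != 1L & inst$tab$j != 1L
  tab <- contact_table(inst$tab$i[keep], inst$tab$j[keep],
                       inst$tab$count[keep], inst$binning)
  m <- compartment_model(inst$C, inst$alpha, inst$beta, inst$binning)
  res <- solve_locus(1L, tab, m)
  expect_equal(res$row, c(0, 0))
})

test_that("solve_locus matches a dense grid search and never decreases the objective", {
  inst <- random_instance(3, 1, M = 2, seed = 15)  # 3 loci, one per chromosome
  m <- compartment_model(inst$C, 0, 0, inst$binning)
  res <- solve_locus(1L, inst$tab, m, inner_tol = 1e-10)
  # locus-1 objective, vectorized over candidate rows (other loci fixed)
  N <- dense_counts(inst$tab)
  f1 <- function(rows) {
    L <- 0
    for (j in 2:3) {
      dots <- rows %*% inst$C[j, ]
      L <- L + ifelse(N[1, j] > 0,
                      N[1, j] * log(pmax(dots, .Machine$double.xmin)), 0) - dots
    }
    drop(L)
  }
  hi <- max(res$row) * 1.5 + 0.5
  grid <- as.matrix(expand.grid(seq(0, hi, by = 0.01), seq(0, hi, by = 0.01)))
  best_grid <- max(f1(grid))
  f_hat <- f1(matrix(res$row, 1))
  expect_gte(f_hat - best_grid, -1e-6 * (abs(best_grid) + 1))
  expect_gte(f_hat, f1(matrix(inst$C[1, ], 1)))
})

test_that("Rabl gradient and Hessian match finite differences; -H is PSD", {
  for (seed in c(3, 11)) {
    inst <- random_instance(3, 3, M = 2, seed = seed)
    m <- compartment_model(inst$C, inst$alpha, inst$beta, inst$binning)
    gh <- rabl_gradient_hessian(inst$tab, m)
    f <- function(ab) naive_loglik(inst$tab, inst$C, ab[1], ab[2])
    x0 <- c(inst$alpha, inst$beta)
    expect_equal(unname(gh$G), fd_grad(f, x0, h = 1e-6), tolerance = 1e-6)
    g_of_ab <- function(ab) rabl_gradient_hessian(
      inst$tab, compartment_model(inst$C, ab[1], ab[2], inst$binning))$G
    expect_equal(gh$H, unname(fd_jac(g_of_ab, x0, h = 1e-6)), tolerance = 1e-6)
    expect_true(all(eigen(-gh$H, only.values = TRUE)$values > -1e-9))
  }
})

test_that("one Rabl Newton step never decreases the likelihood and keeps R positive", {
  inst <- random_instance(3, 4, M = 2, seed = 23)
  m <- compartment_model(inst$C, 0, 0, inst$binning)
  L0 <- log_likelihood(inst$tab, m)
  st <- rabl_step(inst$tab, m)
  m2 <- compartment_model(inst$C, st$alpha, st$beta, inst$binning)
  expect_gte(log_likelihood(inst$tab, m2), L0)
  expect_gt(hicsubcomp:::cpp_min_rabl(st$alpha, st$beta), 0)
})

test_that("null Rabl simulations recover coefficients near zero", {
  g <- make_synthetic_genome(4, 5e6, 1e5, 2, seed = 31)
  ds <- depth_for_coverage(g$binning, g$C, 0, 0, 2000)
  tab <- simulate_contacts(g$binning, g$C, 0, 0, ds, seed = 32)
  fit <- fit_compartments(tab, fit_config(M = 2, seed = 33, n_restarts = 2))
  # standard errors from the observed information at the fit
  gh <- rabl_gradient_hessian(tab, fit)
  se <- sqrt(diag(solve(-gh$H)))
  expect_lt(abs(fit$alpha), 3 * se[1] + 1e-3)
  expect_lt(abs(fit$beta), 3 * se[2] + 1e-3)
})

test_that("the score in (alpha, beta) vanishes at the generating values on deep data", {
  g <- make_synthetic_genome(4, 10e6, 1e5, 2, seed = 41)
  ds <- depth_for_coverage(g$binning, g$C, 0.3, 0.1, 5000)
  tab <- simulate_contacts(g$binning, g$C, 0.3, 0.1, ds, seed = 42)
  m <- compartment_model(sqrt(ds) * g$C, 0.3, 0.1, g$binning)
  gh <- rabl_gradient_hessian(tab, m)
  # score ~ N(0, -H): standardized components within sampling error
  z <- gh$G / sqrt(diag(-gh$H))
  expect_true(all(abs(z) < 4))
})

test_that("fits recover a 2-compartment simulation and the trace ascends", {
  g <- make_synthetic_genome(4, 5e6, 1e5, 2, seed = 51)  # 200 bins
  ds <- 1e5 / expected_total_contacts(g$binning, g$C, 0.3, 0.1)
  tab <- simulate_contacts(g$binning, g$C, 0.3, 0.1, ds, seed = 52)
  fit <- fit_compartments(tab, fit_config(M = 2, seed = 53, n_restarts = 3))
  expect_monotone_trace(fit$trace)
  mc <- matched_correlation(decompose(fit)$P, g$P)
  expect_gt(min(mc$r), 0.95)
  # joint stationarity at termination: small relative KKT residual, and
  # re-solving a locus at the fit does not move it
  expect_lt(fit$kkt_max, 0.05)
  rs <- solve_locus(7L, tab, fit, inner_tol = 1e-8)
  expect_equal(rs$row, unname(fit$C[7, ]), tolerance = 1e-3)
  expect_lt(rs$kkt, 1e-8)
})

test_that("M = 1 reduces to bias estimation", {
  g <- make_synthetic_genome(4, 5e6, 1e5, 1, seed = 61)
  ds <- depth_for_coverage(g$binning, g$C, 0, 0, 1000)
  tab <- simulate_contacts(g$binning, g$C, 0, 0, ds, seed = 62)
  fit <- fit_compartments(tab, fit_config(M = 1, seed = 63, n_restarts = 2,
                                          rabl_enabled = FALSE))
  expect_gt(cor(fit$C[, 1], g$B), 0.99)
})

test_that("different seeds reach the same likelihood within restart tolerance", {
  g <- make_synthetic_genome(3, 4e6, 1e5, 2, seed = 71)
  ds <- depth_for_coverage(g$binning, g$C, 0.2, 0, 1500)
  tab <- simulate_contacts(g$binning, g$C, 0.2, 0, ds, seed = 72)
  f1 <- fit_compartments(tab, fit_config(M = 2, seed = 73, n_restarts = 2))
  f2 <- fit_compartments(tab, fit_config(M = 2, seed = 74, n_restarts = 2))
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-4)
  # and relabeling the fitted columns leaves the likelihood unchanged
  mp <- compartment_model(f1$C[, 2:1], f1$alpha, f1$beta, g$binning)
  expect_equal(log_likelihood(tab, mp), f1$loglik, tolerance = 1e-10)
})

test_that("blacklisted bins stay at zero and grouped pairs do not drive scores", {
  g <- make_synthetic_genome(3, 3e6, 1e5, 2, seed = 81)  # 90 bins
  ds <- depth_for_coverage(g$binning, g$C, 0, 0, 1000)
  tab <- simulate_contacts(g$binning, g$C, 0, 0, ds, seed = 82)
  ex <- exclusion_set(blacklist = c(3L, 40L), groups = list(c(10L, 45L, 75L)))
  fit <- fit_compartments(tab, fit_config(M = 2, seed = 83, n_restarts = 2),
                          exclusions = ex)
  expect_true(all(fit$C[c(3, 40), ] == 0))
  expect_monotone_trace(fit$trace)
})

test_that("fit requires contacts and a positive configuration", {
  b <- tiny_binning()
  empty <- contact_table(integer(0), integer(0), numeric(0), b)
  expect_error(fit_compartments(empty, fit_config(M = 2, seed = 1)), "empty")
  expect_error(fit_config(M = 2), "seed")
  expect_error(fit_config(M = 0, seed = 1))
})
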