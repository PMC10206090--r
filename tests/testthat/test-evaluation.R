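test_that("AIC follows 2(nM + 2) - 2L, with the nM variant available", {
  expect_equal(aic(loglik = -1000, n_nonempty = 100, M = 5), 3004)
  expect_equal(aic(loglik = -1000, n_nonempty = 100, M = 5,
                   k_formula = "nM"), 3000)
  # comparative property: AIC drops iff L gains more than n per extra compartment
  n <- 100
  a1 <- aic(loglik = 0, n_nonempty = n, M = 3)
  expect_lt(aic(loglik = n + 1, n_nonempty = n, M = 4), a1)
  expect_gt(aic(loglik = n - 1, n_nonempty = n, M = 4), a1)
})

test_that("a single-M sweep degenerates to one aic call", {
  g <- make_synthetic_genome(3, 3e6, 1e5, 2, seed = 1)
  ds <- depth_for_coverage(g$binning, g$C, 0, 0, 800)
  tab <- simulate_contacts(g$binning, g$C, 0, 0, ds, seed = 2)
  cfg <- fit_config(M = 2, seed = 3, n_restarts = 2)
  sw <- aic_sweep(tab, 2L, cfg)
  expect_equal(nrow(sw), 1L)
  expect_equal(attr(sw, "selected_M"), 2L)
  fit <- attr(sw, "models")[["2"]]
  expect_equal(sw$aic, aic(fit))
  # nested models: likelihood cannot drop when M grows (up to restart noise)
  sw2 <- aic_sweep(tab, c(1L, 2L, 3L), cfg)
  expect_true(all(diff(sw2$loglik) > -1e-4 * abs(sw2$loglik[-3])))
})

test_that("information content has its closed-form extremes", {
  expect_equal(information_content(rep(0.2, 5)), 0)
  expect_equal(information_content(c(1, 0, 0, 0, 0)), log2(5))
  expect_equal(information_content(c(0.5, 0.5, 0, 0, 0)), log2(5 / 2))
  # permutation invariance and missing-row handling
  p <- c(0.6, 0.25, 0.1, 0.05, 0)
  expect_equal(information_content(p), information_content(sample(p)))
  expect_true(is.na(information_content(rep(0, 5))))
  expect_error(information_content(c(-0.1, 1.1)), "negative")
  expect_error(information_content(c(0.7, 0.7)), "sum to 1")
})

test_that("information content decreases along any mixing path to uniform", {
  set.seed(4)
  p <- as.numeric(randomize_from_annotation("K1", 0.3, seed = 5,
                                            levels = paste0("K", 1:5)))
  u <- rep(0.2, 5)
  lam <- seq(0, 1, by = 0.25)
  ics <- vapply(lam, function(l) information_content((1 - l) * p + l * u),
                numeric(1))
  expect_true(all(diff(ics) < 0))
})

test_that("argmax assignment breaks ties low and flags missing bins", {
  P <- rbind(c(0.1, 0.7, 0.2), c(0.5, 0.5, 0), c(0, 0, 0))
  expect_equal(assign_compartments(P), c(2L, 1L, NA_integer_))
})

test_that("matched correlation recovers column shuffles exactly", {
  set.seed(6)
  P <- matrix(rgamma(500 * 4, 1), 500, 4)
  self <- matched_correlation(P, P)
  expect_equal(self$permutation, 1:4)
  expect_equal(self$r, rep(1, 4))
  perm <- c(3, 1, 4, 2)
  sh <- matched_correlation(P[, perm], P)
  expect_equal(sh$r, rep(1, 4))
  expect_equal(P[, perm][, sh$permutation], P, ignore_attr = TRUE)
})

test_that("independent matrices correlate near zero; few common bins error", {
  set.seed(7)
  A <- matrix(runif(1000 * 3), 1000, 3)
  B <- matrix(runif(1000 * 3), 1000, 3)
  mc <- matched_correlation(A, B)
  expect_true(all(abs(mc$r) < 0.15))
  expect_error(matched_correlation(A[1:2, ], B[1:2, ]), "fewer than 3")
})

test_that("the Hungarian matcher agrees with exhaustive search", {
  set.seed(8)
  for (q in 1:20) {
    cors <- matrix(runif(25, -1, 1), 5, 5)
    perms <- hicsubcomp:::all_permutations(5L)
    sums <- vapply(seq_len(nrow(perms)), function(t)
      sum(cors[cbind(1:5, perms[t, ])]), numeric(1))
    best <- max(sums)
    hung <- hicsubcomp:::solve_assignment(-cors)
    expect_equal(sum(cors[cbind(1:5, hung)]), best, tolerance = 1e-12)
  }
})

test_that("rectangular matching picks the best inferred subset", {
  set.seed(9)
  Tm <- matrix(rgamma(300 * 3, 1), 300, 3)
  noise <- matrix(rgamma(300 * 4, 1), 300, 4)
  inferred <- cbind(noise[, 1:2], Tm[, 3], noise[, 3:4], Tm[, 1:2])
  mc <- matched_correlation(inferred, Tm)
  expect_equal(mc$permutation, c(6L, 7L, 3L))
  expect_true(all(mc$r > 0.99))
})
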