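test_that("an all-zero truth simulates an empty table; determinism holds", {
  b <- tiny_binning(2, 300, 100)
  empty <- simulate_contacts(b, matrix(0, 6, 2), 0.3, 0.1, 1, seed = 1)
  expect_equal(length(empty$i), 0L)
  g <- make_synthetic_genome(3, 2e6, 1e5, 3, seed = 2)
  t1 <- simulate_contacts(g$binning, g$C, 0.3, 0.1, 5, seed = 3)
  t2 <- simulate_contacts(g$binning, g$C, 0.3, 0.1, 5, seed = 3)
  expect_identical(t1[c("i", "j", "count")], t2[c("i", "j", "count")])
})

test_that("simulated totals match the analytic expectation", {
  g <- make_synthetic_genome(4, 5e6, 1e5, 3, seed = 11)
  mu <- expected_total_contacts(g$binning, g$C, 0.3, 0.1, depth_scale = 8)
  tab <- simulate_contacts(g$binning, g$C, 0.3, 0.1, 8, seed = 12)
  # Poisson total: within 4 standard deviations
  expect_lt(abs(tab$total_trans - mu), 4 * sqrt(mu))
})

test_that("orthogonal pure-compartment bins never interact", {
  b <- tiny_binning(2, 100, 100)
  C <- rbind(c(50, 0), c(0, 50))
  tab <- simulate_contacts(b, C, 0, 0, 1, seed = 21)
  expect_equal(length(tab$i), 0L)
})

test_that("downsampling is binomial thinning and fraction 1 is the identity", {
  g <- make_synthetic_genome(3, 3e6, 1e5, 2, seed = 31)
  ds <- depth_for_coverage(g$binning, g$C, 0, 0, 2000)
  tab <- simulate_contacts(g$binning, g$C, 0, 0, ds, seed = 32)
  expect_identical(downsample_contacts(tab, 1, seed = 33), tab)
  thin <- downsample_contacts(tab, 0.01, seed = 34)
  mu <- 0.01 * tab$total_trans
  expect_lt(abs(thin$total_trans - mu), 4 * sqrt(mu))
  # thinning a Poisson(F) table is Poisson(f*F): per-pair empirical means
  # across seeds match the thinned rates
  picks <- order(tab$count, decreasing = TRUE)[1:50]
  key <- paste(tab$i[picks], tab$j[picks])
  sums <- numeric(50)
  for (s in 1:40) {
    th <- downsample_contacts(tab, 0.3, seed = 100 + s)
    m <- match(key, paste(th$i, th$j))
    sums <- sums + ifelse(is.na(m), 0, th$count[m])
  }
  emp <- sums / 40
  expected <- 0.3 * tab$count[picks]
  se <- sqrt(expected * 0.7 / 40)  # binomial se of the mean
  expect_true(all(abs(emp - expected) < 5 * se))
})

test_that("mixing depth-matches then sums; totals are conserved", {
  g <- make_synthetic_genome(3, 3e6, 1e5, 2, seed = 41)
  ds <- depth_for_coverage(g$binning, g$C, 0, 0, 1000)
  ta <- simulate_contacts(g$binning, g$C, 0, 0, ds, seed = 42)
  tb <- simulate_contacts(g$binning, g$C, 0, 0, 2 * ds, seed = 43)
  mixed <- mix_contacts(ta, tb, seed = 44)
  # deeper table thinned to ta's depth, then summed: total ~ 2x ta
  expect_lt(abs(mixed$total_trans - 2 * ta$total_trans),
            4 * sqrt(ta$total_trans))
  # equal-depth mix is exactly additive
  same <- mix_contacts(ta, ta, seed = 45)
  expect_equal(same$total_trans, 2 * ta$total_trans)
  # mixing with an empty table gives an empty table
  b0 <- contact_table(integer(0), integer(0), numeric(0), g$binning)
  expect_equal(mix_contacts(ta, b0, seed = 46)$total_trans, 0)
})

test_that("annotation randomization brackets scores by noise level", {
  labels <- rep(c("A1", "A2", "B1", "B2", "B3"), each = 40)
  P <- randomize_from_annotation(labels, NL = 0.2, seed = 51)
  expect_equal(rowSums(P), rep(1, 200), tolerance = 1e-12)
  expect_equal(colnames(P), c("A1", "A2", "B1", "B2", "B3"))
  # near-zero noise tends to the one-hot indicator
  P0 <- randomize_from_annotation(labels, NL = 0.001, seed = 52)
  expect_true(all(P0[cbind(1:200, match(labels, colnames(P0)))] > 0.99))
  # even at NL = 0.5 the annotated entry has the largest mean
  P5 <- randomize_from_annotation(labels, NL = 0.5, seed = 53)
  ann <- P5[cbind(1:200, match(labels, colnames(P5)))]
  expect_gt(mean(ann), mean((1 - ann) / 4))
  expect_error(randomize_from_annotation(c("A1", "Zz"), 0.2, seed = 1,
                                         levels = c("A1", "A2")), "unknown")
})

test_that("synthetic genomes honor requested dimensions and are reproducible", {
  g <- make_synthetic_genome(3, 1.05e6, 1e5, 4, seed = 61)
  expect_equal(g$binning$n_bins, 3L * ceiling(1.05e6 / 1e5))
  expect_true(all(g$C >= 0))
  expect_equal(rowSums(g$P), rep(1, g$binning$n_bins), tolerance = 1e-12)
  g2 <- make_synthetic_genome(3, 1.05e6, 1e5, 4, seed = 61)
  expect_identical(g$C, g2$C)
  # dominant compartments form contiguous blocks, not bin-level noise
  expect_lt(mean(diff(g$dominant) != 0), 0.5)
})

test_that("recovery improves with sequencing depth", {
  g <- make_synthetic_genome(4, 5e6, 1e5, 2, seed = 71)
  cors <- vapply(c(100, 3000), function(ends) {
    ds <- depth_for_coverage(g$binning, g$C, 0, 0, ends)
    tab <- simulate_contacts(g$binning, g$C, 0, 0, ds, seed = 72)
    fit <- fit_compartments(tab, fit_config(M = 2, seed = 73, n_restarts = 2,
                                            rabl_enabled = FALSE))
    mean(matched_correlation(decompose(fit)$P, g$P)$r)
  }, numeric(1))
  expect_gt(cors[2], cors[1])
})
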