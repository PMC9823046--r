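# Data generation: exact-moment mode, stochastic mode, error injection.

test_that("exact moments reproduce the generator and reject empty designs", {
  th <- theta_generic()
  data <- exact_moments(th, 800, 1200)
  expect_equal(data$mz$n, 800)
  expect_equal(data$dz$cov, implied_moments(th, "DZ")$covariance)
  fit <- mrdoc_fit(data, restarts = 0, start = th)
  expect_lt(fit$discrepancy, 1e-8)
  expect_error(exact_moments(th, 0, 0), "degenerate")
})

test_that("sampling is seed-reproducible and respects the MZ score rule", {
  th <- theta_generic()
  t1 <- simulate_twins(th, 300, 300, seed = 42)
  t2 <- simulate_twins(th, 300, 300, seed = 42)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 600)
  mz <- dplyr::filter(t1, zygosity == "MZ")
  expect_equal(mz$ps1_t1, mz$ps1_t2)
  expect_equal(mz$ps2_t1, mz$ps2_t2)
  dz <- dplyr::filter(t1, zygosity == "DZ")
  expect_gt(stats::sd(dz$ps1_t1 - dz$ps1_t2), 0)
})

test_that("sample covariance converges to the implied covariance", {
  # Monte-Carlo oracle: 200k pairs per zygosity, entrywise within 4 SE
  th <- theta_generic()
  n <- 200000
  tbl <- simulate_twins(th, n, n, seed = 7)
  mom <- moments_from_table(tbl)
  for (z in c("MZ", "DZ")) {
    S_hat <- if (z == "MZ") mom$mz$cov else mom$dz$cov
    S_exp <- implied_moments(th, z)$covariance
    se <- sqrt((outer(diag(S_exp), diag(S_exp)) + S_exp^2) / n)
    keep <- se > 1e-12  # identical-by-construction MZ score entries
    expect_lt(max(abs(S_hat - S_exp)[keep] / se[keep]), 4)
  }
})

test_that("sampling error shrinks as O(n^-1/2)", {
  th <- theta_strong()
  S_exp <- implied_moments(th, "DZ")$covariance
  errs <- vapply(c(1e3, 1e4, 1e5), function(n) {
    tbl <- simulate_twins(th, 0, n, seed = 13)
    mom <- suppressWarnings(moments_from_table(tbl))  # DZ-only by design
    max(abs(mom$dz$cov - S_exp))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], errs[1] / 3)
})

test_that("perfect reliability leaves the table untouched, imperfect does
           not move covariances with the scores", {
  th <- theta_generic()
  tbl <- simulate_twins(th, 2000, 2000, seed = 5)
  expect_identical(inject_measurement_error(tbl, 1, 1), tbl)

  noisy <- inject_measurement_error(tbl, 0.8, 0.8, seed = 6)
  # reliability calibration: observed variance inflates by 1/rel
  expect_equal(stats::var(noisy$ph1_t1), stats::var(tbl$ph1_t1) / 0.8,
               tolerance = 0.1)
  # additive error: instrument-phenotype covariance unchanged in expectation
  expect_equal(stats::cov(noisy$ph1_t1, noisy$ps1_t1),
               stats::cov(tbl$ph1_t1, tbl$ps1_t1), tolerance = 0.05)
  expect_identical(noisy$ps1_t1, tbl$ps1_t1)
})

test_that("unmodeled error inflates the unique-environment loading", {
  th <- theta_generic()
  tbl <- simulate_twins(th, 4000, 4000, seed = 21)
  noisy <- inject_measurement_error(tbl, 0.8, 0.8, seed = 22)
  fit <- mrdoc_fit(moments_from_table(noisy), restarts = 0, start = th)
  expect_gt(fit$estimates[["e1"]], th[["e1"]] + 0.05)
  expect_gt(fit$estimates[["e2"]], th[["e2"]] + 0.05)
})

test_that("measurement error reduces power to detect causation", {
  th <- theta_strong()
  n <- 4000
  tbl <- simulate_twins(th, n, n, seed = 31)
  noisy <- inject_measurement_error(tbl, 0.7, 0.7, seed = 32)
  lr_of <- function(t) {
    mom <- moments_from_table(t)
    full <- mrdoc_fit(mom, restarts = 0, start = th)
    st0 <- unclass(th); st0["g1"] <- 0
    null <- mrdoc_fit(mom, pattern_fix(mrdoc_pattern(), g1 = 0),
                      restarts = 0, start = st0)
    null$discrepancy - full$discrepancy
  }
  expect_lt(lr_of(noisy), lr_of(tbl))
})
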