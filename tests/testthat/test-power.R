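# Factorial power engine: design enumeration, per-cell NCP behaviour, the
# beta^2 variance decomposition, and required-N curves.

test_that("the three named designs enumerate their documented cell counts", {
  expect_equal(factorial_design("design1")$n_cells, 4096)
  expect_equal(factorial_design("design2")$n_cells, 8748)
  expect_equal(factorial_design("design3")$n_cells, 256)
  expect_equal(nrow(design_cells(factorial_design("design3"))), 256)
  # every cell respects a^2 + c^2 <= 1
  d1 <- design_cells(factorial_design("design1"))
  expect_true(all(d1$a1^2 + d1$c1^2 <= 1))
})

test_that("swapping the trait-1 and trait-2 roles swaps the two 1-df NCPs", {
  th <- mrdoc_params(ra = 0.2, re = 0.3, rf = 0.25,
                     a1 = 0.5, a2 = 0.4, g1 = 0.25, g2 = 0.1,
                     b1 = 0.3, b3 = 0.15)
  th_sw <- mrdoc_params(ra = 0.2, re = 0.3, rf = 0.25,
                        a1 = 0.4, a2 = 0.5, g1 = 0.1, g2 = 0.25,
                        b1 = 0.15, b3 = 0.3)
  expect_equal(mrdoc2:::ncp_exact(th, "g1"), mrdoc2:::ncp_exact(th_sw, "g2"),
               tolerance = 1e-6)
  expect_equal(mrdoc2:::ncp_exact(th, "g2"), mrdoc2:::ncp_exact(th_sw, "g1"),
               tolerance = 1e-6)
})

test_that("the g1 NCP is insensitive to the other trait's instrument and
           causal path", {
  base <- list(a1 = sqrt(0.1), a2 = sqrt(0.1), b1 = sqrt(0.075),
               g1 = sqrt(0.06))
  ncps <- vapply(list(c(0.075, 0.06), c(0.025, 0.02), c(0.05, 0.04)),
                 function(lv) {
    th <- do.call(mrdoc_params,
                  c(base, list(b3 = sqrt(lv[1]), g2 = sqrt(lv[2]))))
    mrdoc2:::ncp_exact(th, "g1")
  }, numeric(1))
  expect_lt(diff(range(ncps)) / mean(ncps), 0.005)
})

test_that("run_design reports joint NCPs dominating the 1-df NCPs", {
  d3 <- factorial_design("design3")
  cells <- run_design(d3, cells = c(1, 50, 120, 200, 256))
  expect_true(all(is.na(cells$error)))
  expect_true(all(cells$ncp_joint >= pmax(cells$ncp_g1, cells$ncp_g2) - 1e-4))
  expect_true(all(cells$pow_g1 >= 0.05 - 1e-8 & cells$pow_g1 <= 1))
})

test_that("beta^2 shares equal ANOVA sum-of-squares shares on an orthogonal
           two-level grid", {
  d <- factorial_design("custom",
                        factors = list(b1 = c(0.15, 0.3), g1 = c(0.1, 0.25),
                                       re = c(0.1, 0.4)),
                        fixed = list(a1 = 0.5, a2 = 0.5, b3 = 0.2, g2 = 0.1))
  cells <- run_design(d, tests = "g1")
  reg <- regress_ncp(cells, "ncp_g1")
  # independent oracle: per-factor share of total sum of squares via aov
  fit <- stats::aov(ncp_g1 ~ b1 + g1 + re, data = cells)
  ss <- summary(fit)[[1]][["Sum Sq"]]
  shares <- stats::setNames(ss[1:3] / sum((cells$ncp_g1 -
                                             mean(cells$ncp_g1))^2),
                            c("b1", "g1", "re"))
  b2 <- tibble::deframe(reg$terms[, c("term", "beta_squared")])
  expect_equal(b2[names(shares)], shares, tolerance = 1e-10)
  expect_equal(reg$total_r2, sum(shares), tolerance = 1e-10)
})

test_that("a constant NCP column yields an all-zero decomposition", {
  cells <- tibble::tibble(b1 = c(0.1, 0.2, 0.1, 0.2),
                          g1 = c(0.1, 0.1, 0.3, 0.3),
                          ncp_g1 = 2, error = NA_character_)
  reg <- regress_ncp(cells, "ncp_g1")
  expect_equal(reg$terms$beta_squared, c(0, 0))
  expect_equal(reg$total_r2, 0)
})

test_that("collinear factors are reported by name", {
  cells <- tibble::tibble(b1 = c(0.1, 0.2, 0.3, 0.4),
                          g1 = c(0.2, 0.4, 0.6, 0.8),
                          ncp_g1 = c(1, 2, 3, 4), error = NA_character_)
  expect_error(regress_ncp(cells, "ncp_g1"), "collinear")
})

test_that("a 128-cell smoke subsample of the ACE factorial shows the
           instrument and causal paths dominating the NCP variance", {
  set.seed(77)
  smoke <- sample(4096, 128)
  cells <- run_design(factorial_design("design1"), tests = "g1",
                      cells = smoke)
  expect_true(all(is.na(cells$error)))
  reg <- regress_ncp(cells, "ncp_g1")
  b2 <- tibble::deframe(reg$terms[, c("term", "beta_squared")])
  expect_gt(b2[["b1"]] + b2[["g1"]], 0.6)
  expect_gt(reg$total_r2, 0.8)
  expect_lt(b2[["rc"]], 0.05)
  expect_lt(b2[["ra"]], 0.05)
})

test_that("required sample size decreases with instrument strength and
           scales inversely with per-pair NCP", {
  th <- mrdoc_params(ra = 0.3, rc = 0.25, re = 0.3, rf = 0.25,
                     a1 = sqrt(0.49), c1 = sqrt(0.10),
                     a2 = sqrt(0.22), c2 = 0,
                     b3 = sqrt(0.05), g1 = sqrt(0.05), g2 = sqrt(0.05))
  curve <- required_n_curve(th, c(0.01, 0.03, 0.06))
  expect_true(all(!curve$flagged))
  expect_true(all(diff(curve$n_pairs_80) <= 0))
  # power at the reported n crosses the target, one step below does not
  for (i in seq_len(nrow(curve))) {
    expect_gte(power_from_ncp(curve$ncp_per_pair[i] * curve$n_pairs_80[i], 1),
               0.80)
    expect_lt(power_from_ncp(
      curve$ncp_per_pair[i] * (curve$n_pairs_80[i] - 2), 1), 0.80)
  }
  # doubling the per-pair NCP halves the required count (integer rounding)
  n_half <- 2 * ceiling(stats::uniroot(
    function(x) power_from_ncp(x, 1) - 0.8, c(1e-9, 100),
    tol = 1e-10)$root / (2 * curve$ncp_per_pair[1]) / 2)
  expect_equal(curve$n_pairs_80[1], n_half * 2, tolerance = 4)
})

test_that("plot helpers return ggplot objects", {
  th <- mrdoc_params(ra = 0.3, rc = 0.25, re = 0.3, rf = 0.25,
                     a1 = sqrt(0.49), c1 = sqrt(0.10), a2 = sqrt(0.22),
                     b3 = sqrt(0.05), g1 = sqrt(0.05), g2 = sqrt(0.05))
  curve <- required_n_curve(th, c(0.02, 0.05))
  expect_s3_class(plot_power_curve(curve), "ggplot")
  cells <- run_design(factorial_design("design3"), cells = 1:4, tests = "g1")
  expect_s3_class(plot_design_power(cells, "g1"), "ggplot")
  bias <- pleiotropy_violation_study(
    mrdoc_params(ra = 0.3, a1 = 0.5, a2 = 0.5, b1 = 0.3, b3 = 0.3,
                 g1 = 0.2, b2 = 0.1))
  expect_s3_class(plot_bias(bias), "ggplot")
})

test_that("the required-N value at a reference grid point is stable", {
  # frozen from an independent bisection over n at the same parameters
  th <- mrdoc_params(ra = 0.3, rc = 0.25, re = 0.3, rf = 0.25,
                     a1 = sqrt(0.49), c1 = sqrt(0.10),
                     a2 = sqrt(0.22), c2 = 0,
                     b3 = sqrt(0.05), g1 = sqrt(0.05), g2 = sqrt(0.05))
  curve <- required_n_curve(th, 0.05)
  lo <- 2; hi <- 20000
  while (hi - lo > 2) {
    mid <- 2 * round((lo + hi) / 4)
    ncp <- mrdoc2:::ncp_exact(
      as_mrdoc_params(replace(unclass(th), "b1", curve$b1[1])), "g1",
      n_mz = mid / 2, n_dz = mid / 2)
    if (power_from_ncp(ncp, 1) >= 0.80) hi <- mid else lo <- mid
  }
  expect_equal(curve$n_pairs_80[1], hi, tolerance = 2)
})
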