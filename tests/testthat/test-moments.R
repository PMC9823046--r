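# Reference implied-covariance checks: closed forms worked out from the
# reduced form by hand, cross-twin assembly rules, and a Monte-Carlo oracle.

test_that("reduced form is identity without causation, closed form with", {
  rf0 <- reduced_form(mrdoc_params(b1 = 0.3, b3 = 0.2))
  expect_equal(rf0$mixing, diag(2), ignore_attr = TRUE)
  expect_equal(rf0$instrument, diag(c(0.3, 0.2)), ignore_attr = TRUE)

  g <- sqrt(0.06); b <- sqrt(0.075)
  rf1 <- reduced_form(mrdoc_params(g1 = g, g2 = g, b1 = b, b3 = b,
                                   e1 = 1, e2 = 1))
  # Ph1's instrument column of (I-B)^-1 G with 1 - g1*g2 = 0.94
  expect_equal(unname(rf1$instrument[, 1]), c(b / 0.94, g * b / 0.94))

  expect_error(reduced_form(c(g1 = 1, g2 = 1)), "reduced form")
})

test_that("null model yields identity phenotype blocks and PS share rules", {
  th <- mrdoc_params(e1 = 1, e2 = 1)
  mz <- implied_moments(th, "MZ")$covariance
  dz <- implied_moments(th, "DZ")$covariance
  expect_equal(mz[1:2, 1:2], diag(2), ignore_attr = TRUE)
  expect_equal(mz[1:2, 5:6], matrix(0, 2, 2), ignore_attr = TRUE)
  expect_equal(mz["ps1_t1", "ps1_t2"], 1)
  expect_equal(dz["ps1_t1", "ps1_t2"], 0.5)
})

test_that("implied variance and cross-trait covariance match hand algebra", {
  # a^2 = 0.25, c = 0, e^2 = 0.75, b^2 = 0.075, g^2 = 0.06:
  # Var(Ph) = 1.075 * (1 + g^2) / 0.94^2, cov = 1.075 * 2g / 0.94^2
  th <- mrdoc_params(a1 = 0.5, a2 = 0.5, b1 = sqrt(0.075), b3 = sqrt(0.075),
                     g1 = sqrt(0.06), g2 = sqrt(0.06))
  S <- implied_moments(th, "DZ")$covariance
  g <- sqrt(0.06)
  expect_equal(S["ph1_t1", "ph1_t1"], 1.075 * (1 + g^2) / 0.94^2,
               tolerance = 1e-12)
  expect_equal(S["ph1_t1", "ph2_t1"], 1.075 * 2 * g / 0.94^2,
               tolerance = 1e-12)
  expect_equal(round(S["ph1_t1", "ph1_t1"], 4), 1.2896)
  expect_equal(round(S["ph1_t1", "ph2_t1"], 3), 0.596)
})

test_that("instrument-outcome covariance follows g1*b1/(1 - g1 g2)", {
  th <- mrdoc_params(a1 = 0.5, a2 = 0.4, g1 = 0.25, g2 = 0.1,
                     b1 = 0.3, b3 = 0.2, sigma_x = 1.2)
  S <- implied_moments(th, "DZ")$covariance
  expect_equal(S["ph2_t1", "ps1_t1"],
               0.25 * 0.3 * 1.2^2 / (1 - 0.25 * 0.1), tolerance = 1e-12)

  th0 <- mrdoc_params(a1 = 0.5, a2 = 0.4, b1 = 0.3, b3 = 0.2)
  expect_equal(implied_moments(th0, "DZ")$covariance["ph2_t1", "ps1_t1"], 0)
})

test_that("implied covariances are symmetric, PSD, and zygosity-consistent", {
  set.seed(11)
  for (i in 1:25) {
    th <- random_theta()
    mz <- implied_moments(th, "MZ")$covariance
    dz <- implied_moments(th, "DZ")$covariance
    expect_lt(max(abs(mz - t(mz))), 1e-12)
    expect_lt(max(abs(dz - t(dz))), 1e-12)
    expect_gt(min(eigen(dz, symmetric = TRUE, only.values = TRUE)$values),
              -1e-10)
    expect_gt(min(eigen(mz, symmetric = TRUE, only.values = TRUE)$values),
              -1e-10)
    # the within-twin 4x4 blocks are the same for both twins and zygosities
    expect_equal(unname(mz[1:4, 1:4]), unname(mz[5:8, 5:8]))
    expect_equal(unname(mz[1:4, 1:4]), unname(dz[1:4, 1:4]))
  }
})

test_that("compiled covariance equals the R reference implementation", {
  set.seed(12)
  for (i in 1:10) {
    th <- random_theta()
    v <- as.numeric(unclass(th))
    expect_lt(max(abs(mrdoc2:::cpp_implied_cov(v, 1.0) -
                        implied_moments(th, "MZ")$covariance)), 1e-12)
    expect_lt(max(abs(mrdoc2:::cpp_implied_cov(v, 0.5) -
                        implied_moments(th, "DZ")$covariance)), 1e-12)
  }
})

test_that("dropping the scores recovers the classic two-trait DoC structure", {
  th <- mrdoc_params(ra = 0.3, rc = 0.2, re = 0.25,
                     a1 = 0.5, c1 = 0.4, a2 = 0.6, c2 = 0.3,
                     g1 = 0.2, g2 = 0.1)
  # independent assembly of the 4x4 phenotype-only DoC covariance
  W <- solve(diag(2) - matrix(c(0, 0.2, 0.1, 0), 2, 2))
  Lam <- rbind(c(0.5, 0.4, th[["e1"]], 0, 0, 0),
               c(0, 0, 0, 0.6, 0.3, th[["e2"]]))
  doc_cov <- function(share) {
    Pw <- diag(6); Pw[1, 4] <- Pw[4, 1] <- 0.3
    Pw[2, 5] <- Pw[5, 2] <- 0.2; Pw[3, 6] <- Pw[6, 3] <- 0.25
    Px <- matrix(0, 6, 6)
    Px[1, 1] <- Px[4, 4] <- share; Px[1, 4] <- Px[4, 1] <- share * 0.3
    Px[2, 2] <- Px[5, 5] <- 1; Px[2, 5] <- Px[5, 2] <- 0.2
    w <- W %*% Lam %*% Pw %*% t(Lam) %*% t(W)
    x <- W %*% Lam %*% Px %*% t(Lam) %*% t(W)
    rbind(cbind(w, x), cbind(t(x), w))
  }
  for (z in c("MZ", "DZ")) {
    S <- implied_moments(th, z)$covariance
    ph <- c("ph1_t1", "ph2_t1", "ph1_t2", "ph2_t2")
    expect_equal(unname(S[ph, ph]), doc_cov(genetic_share(z)),
                 tolerance = 1e-12)
  }
})

test_that("phenotype summaries match the implied regressions", {
  th <- theta_strong()
  s <- phenotype_summary(th)
  S <- implied_moments(th, "DZ")$covariance
  expect_equal(s$r2_ph1_on_ps1,
               S["ph1_t1", "ps1_t1"]^2 / S["ph1_t1", "ph1_t1"])
  expect_equal(s$r2_ph2_ph1,
               S["ph1_t1", "ph2_t1"]^2 /
                 (S["ph1_t1", "ph1_t1"] * S["ph2_t1", "ph2_t1"]))
  # no instrument path, uncorrelated scores: zero explained variance
  s0 <- phenotype_summary(mrdoc_params(a1 = 0.5, a2 = 0.5, b3 = 0.2))
  expect_equal(s0$r2_ph1_on_ps1, 0)
})
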