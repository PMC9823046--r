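# Shared fixtures: named parameter configurations and a random-theta draw.

# the high-power configuration (strong instruments, strong reciprocal
# causation, independent backgrounds, a^2 = 0.10 for both traits)
theta_strong <- function() {
  mrdoc_params(a1 = sqrt(0.10), a2 = sqrt(0.10),
               b1 = sqrt(0.075), b3 = sqrt(0.075),
               g1 = sqrt(0.06), g2 = sqrt(0.06))
}

# weak instrument for trait 1, correlated scores and backgrounds
theta_weak <- function() {
  mrdoc_params(ra = 0.5, re = 0.5, rf = 0.5,
               a1 = sqrt(0.25), a2 = sqrt(0.25),
               b1 = sqrt(0.025), b3 = sqrt(0.05),
               g1 = sqrt(0.02), g2 = sqrt(0.02))
}

# generic mid-range configuration with all pieces nonzero
theta_generic <- function() {
  mrdoc_params(ra = 0.3, rc = 0.2, re = 0.25, rf = 0.25,
               a1 = 0.5, c1 = 0.4, a2 = 0.6, c2 = 0.3,
               g1 = 0.2, g2 = 0.15, b1 = 0.25, b3 = 0.2)
}

# random admissible parameter vector; loadings positive (the fitter's
# convention), e derived from the unit-variance rule
random_theta <- function() {
  repeat {
    a1 <- stats::runif(1, 0.2, 0.7); c1 <- stats::runif(1, 0.1, 0.5)
    a2 <- stats::runif(1, 0.2, 0.7); c2 <- stats::runif(1, 0.1, 0.5)
    if (a1^2 + c1^2 < 0.85 && a2^2 + c2^2 < 0.85) break
  }
  mrdoc_params(
    ra = stats::runif(1, -0.5, 0.5), rc = stats::runif(1, -0.5, 0.5),
    re = stats::runif(1, -0.5, 0.5), rf = stats::runif(1, -0.5, 0.5),
    a1 = a1, c1 = c1, a2 = a2, c2 = c2,
    g1 = stats::runif(1, -0.3, 0.3), g2 = stats::runif(1, -0.3, 0.3),
    b1 = stats::runif(1, 0.1, 0.4) * sample(c(-1, 1), 1),
    b3 = stats::runif(1, 0.1, 0.4) * sample(c(-1, 1), 1),
    sigma_x = stats::runif(1, 0.8, 1.25),
    sigma_y = stats::runif(1, 0.8, 1.25)
  )
}
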