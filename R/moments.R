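# Model-implied moment structure (pure-R reference; the fitter's objective
# uses the equivalent compiled version in src/implied.cpp).

mrdoc_var_names <- function() {
  c("ph1_t1", "ph2_t1", "ps1_t1", "ps2_t1",
    "ph1_t2", "ph2_t2", "ps1_t2", "ps2_t2")
}

#' Genetic share of a zygosity group
#'
#' MZ co-twins share all additive-genetic effects (share 1), DZ co-twins on
#' average half (share 0.5). The share scales the cross-twin covariances of
#' the A factors and of the polygenic scores, which are themselves additive
#' genotype aggregates.
#'
#' @param zygosity `"MZ"` or `"DZ"`.
#' @return 1 for MZ, 0.5 for DZ.
#' @export
genetic_share <- function(zygosity) {
  zygosity <- match.arg(toupper(zygosity), c("MZ", "DZ"))
  if (zygosity == "MZ") 1 else 0.5
}

#' Reduced form of the reciprocal-causation system
#'
#' With phenotype vector P, instrument loadings G and latent loadings, the
#' structural system P = B P + G s + Lambda f (B the 2x2 causal matrix with
#' off-diagonals g2 and g1) has reduced form P = (I-B)^-1 (G s + Lambda f).
#' This returns the instrument mixing (I-B)^-1 G and the mixing matrix
#' (I-B)^-1 itself; the closed form of the latter is
#' 1/(1 - g1 g2) * [[1, g2], [g1, 1]].
#'
#' @param theta An [mrdoc_params()] vector.
#' @return List with 2x2 matrices `instrument` ((I-B)^-1 G) and `mixing`
#'   ((I-B)^-1).
#' @examples
#' reduced_form(mrdoc_params(g1 = 0.2, b1 = 0.3))
#' @export
reduced_form <- function(theta) {
  theta <- as_mrdoc_params(theta)
  g1 <- theta[["g1"]]; g2 <- theta[["g2"]]
  d <- 1 - g1 * g2
  if (abs(d) < 1e-12) {
    stop("g1 * g2 = 1: (I - B) is singular, the reciprocal-causation ",
         "reduced form does not exist", call. = FALSE)
  }
  W <- matrix(c(1, g1, g2, 1), 2, 2) / d
  G <- matrix(c(theta[["b1"]], theta[["b2"]], theta[["b4"]], theta[["b3"]]),
              2, 2)
  dimnames(W) <- list(c("ph1", "ph2"), c("ph1", "ph2"))
  ins <- W %*% G
  dimnames(ins) <- list(c("ph1", "ph2"), c("ps1", "ps2"))
  list(instrument = ins, mixing = W)
}

#' Model-implied moments of a twin pair
#'
#' Assembles the 8x8 covariance matrix of
#' (Ph1, Ph2, PS1, PS2) for both members of a twin pair, under the MR-DoC2
#' structural model. Within a person, the A, C, E cross-trait correlations
#' are `ra`, `rc`, `re` and the score correlation is `rf`. Across co-twins,
#' A-A and PS-PS covariances (including the cross-trait/-score terms) are
#' scaled by the zygosity's genetic share, C factors are shared fully, and E
#' factors are uncorrelated. Means are structurally zero.
#'
#' For MZ pairs the co-twin polygenic scores are perfectly correlated, so the
#' 8x8 matrix is positive semidefinite but singular; likelihood computations
#' in [mrdoc_fit()] therefore use the 6 non-degenerate coordinates for the MZ
#' group.
#'
#' @param theta An [mrdoc_params()] vector.
#' @param zygosity `"MZ"` or `"DZ"`.
#' @return An object of class `mrdoc_moments`: list with `covariance` (8x8,
#'   dimnames `ph1_t1 ... ps2_t2`), `mean` (zeros), `zygosity`, and
#'   `genetic_share`.
#' @examples
#' implied_moments(mrdoc_params(a1 = 0.5, a2 = 0.5, b1 = 0.3), "DZ")
#' @export
implied_moments <- function(theta, zygosity) {
  theta <- as_mrdoc_params(theta)
  zygosity <- match.arg(toupper(zygosity), c("MZ", "DZ"))
  share <- genetic_share(zygosity)

  W <- reduced_form(theta)$mixing
  Lam <- matrix(0, 2, 6)
  Lam[1, 1:3] <- c(theta[["a1"]], theta[["c1"]], theta[["e1"]])
  Lam[2, 4:6] <- c(theta[["a2"]], theta[["c2"]], theta[["e2"]])
  G <- matrix(c(theta[["b1"]], theta[["b2"]], theta[["b4"]], theta[["b3"]]),
              2, 2)
  sx <- theta[["sigma_x"]]; sy <- theta[["sigma_y"]]
  Sps <- matrix(c(sx^2, theta[["rf"]] * sx * sy,
                  theta[["rf"]] * sx * sy, sy^2), 2, 2)

  Pw <- diag(6)
  Pw[1, 4] <- Pw[4, 1] <- theta[["ra"]]
  Pw[2, 5] <- Pw[5, 2] <- theta[["rc"]]
  Pw[3, 6] <- Pw[6, 3] <- theta[["re"]]
  Px <- matrix(0, 6, 6)
  Px[1, 1] <- Px[4, 4] <- share
  Px[1, 4] <- Px[4, 1] <- share * theta[["ra"]]
  Px[2, 2] <- Px[5, 5] <- 1
  Px[2, 5] <- Px[5, 2] <- theta[["rc"]]

  Cpp_w <- W %*% (Lam %*% Pw %*% t(Lam) + G %*% Sps %*% t(G)) %*% t(W)
  Cps_w <- W %*% G %*% Sps
  Cpp_x <- W %*% (Lam %*% Px %*% t(Lam) + share * G %*% Sps %*% t(G)) %*% t(W)
  Cps_x <- share * W %*% G %*% Sps

  within <- rbind(cbind(Cpp_w, Cps_w), cbind(t(Cps_w), Sps))
  cross <- rbind(cbind(Cpp_x, Cps_x), cbind(t(Cps_x), share * Sps))
  S <- rbind(cbind(within, cross), cbind(t(cross), within))
  S <- (S + t(S)) / 2
  dimnames(S) <- list(mrdoc_var_names(), mrdoc_var_names())

  ev_min <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-8) {
    stop("implied pair covariance is not positive semidefinite ",
         "(min eigenvalue ", signif(ev_min, 3),
         "): inadmissible correlation combination", call. = FALSE)
  }

  structure(
    list(covariance = S,
         mean = stats::setNames(rep(0, 8), mrdoc_var_names()),
         zygosity = zygosity,
         genetic_share = share),
    class = "mrdoc_moments"
  )
}

#' @export
print.mrdoc_moments <- function(x, ...) {
  cat("<mrdoc_moments> ", x$zygosity,
      " twin pair (genetic share ", x$genetic_share, ")\n", sep = "")
  print(round(x$covariance, 4))
  invisible(x)
}

#' Implied phenotype and instrument summary statistics
#'
#' Computes, from the within-twin implied moments, the proportion of variance
#' in each phenotype explained by its own polygenic score and the squared
#' phenotypic correlation between the two traits — the auxiliary columns
#' reported alongside power results.
#'
#' @param theta An [mrdoc_params()] vector (or a data frame of them, one row
#'   per configuration).
#' @return A tibble with columns `r2_ph1_on_ps1`, `r2_ph2_on_ps2`,
#'   `r2_ph2_ph1`.
#' @examples
#' phenotype_summary(mrdoc_params(
#'   a1 = 0.5, a2 = 0.5, b1 = sqrt(0.075), b3 = sqrt(0.075),
#'   g1 = sqrt(0.06), g2 = sqrt(0.06)
#' ))
#' @export
phenotype_summary <- function(theta) {
  if (is.data.frame(theta) && nrow(theta) > 1) {
    return(purrr::map_dfr(seq_len(nrow(theta)), function(i) {
      phenotype_summary(as_mrdoc_params(theta[i, , drop = FALSE]))
    }))
  }
  theta <- as_mrdoc_params(theta)
  S <- implied_moments(theta, "DZ")$covariance
  v1 <- S["ph1_t1", "ph1_t1"]; v2 <- S["ph2_t1", "ph2_t1"]
  if (v1 <= 0 || v2 <= 0) stop("zero phenotype variance", call. = FALSE)
  vx <- S["ps1_t1", "ps1_t1"]; vy <- S["ps2_t1", "ps2_t1"]
  tibble::tibble(
    r2_ph1_on_ps1 = S["ph1_t1", "ps1_t1"]^2 / (vx * v1),
    r2_ph2_on_ps2 = S["ph2_t1", "ps2_t1"]^2 / (vy * v2),
    r2_ph2_ph1 = S["ph1_t1", "ph2_t1"]^2 / (v1 * v2)
  )
}
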