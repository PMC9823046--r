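# Factorial power designs, NCP variance decomposition, required-N curves.

design_specs <- function() {
  list(
    design1 = list(
      label = "ACE, 2 levels per factor",
      factors = list(
        b1 = sqrt(c(0.025, 0.05)), b3 = sqrt(c(0.025, 0.05)),
        g1 = sqrt(c(0.020, 0.05)), g2 = sqrt(c(0.020, 0.05)),
        ra = c(0.25, 0.50), rc = c(0.25, 0.50),
        re = c(0.25, 0.50), rf = c(0.25, 0.50),
        a1 = sqrt(c(0.10, 0.25)), a2 = sqrt(c(0.10, 0.25)),
        c1 = sqrt(c(0.10, 0.25)), c2 = sqrt(c(0.10, 0.25))
      ),
      fixed = list()
    ),
    design2 = list(
      label = "AE, 2-3 levels per factor",
      factors = list(
        b1 = sqrt(c(0.025, 0.05, 0.075)), b3 = sqrt(c(0.025, 0.05, 0.075)),
        g1 = sqrt(c(0.020, 0.04, 0.06)), g2 = sqrt(c(0.020, 0.04, 0.06)),
        ra = c(0, 0.25, 0.50), re = c(0, 0.25, 0.50), rf = c(0, 0.25, 0.50),
        a1 = sqrt(c(0.10, 0.25)), a2 = sqrt(c(0.10, 0.25))
      ),
      fixed = list(rc = 0, c1 = 0, c2 = 0)
    ),
    design3 = list(
      label = "AE, signed causal and instrument paths",
      factors = list(
        b1 = c(-sqrt(0.075), -sqrt(0.03), sqrt(0.03), sqrt(0.075)),
        b3 = c(-sqrt(0.075), -sqrt(0.03), sqrt(0.03), sqrt(0.075)),
        g1 = c(-sqrt(0.050), -sqrt(0.020), sqrt(0.050), sqrt(0.020)),
        g2 = c(-sqrt(0.050), -sqrt(0.020), sqrt(0.050), sqrt(0.020))
      ),
      fixed = list(ra = 0.3, rc = 0, re = 0.3, rf = 0.3,
                   a1 = sqrt(0.5), a2 = sqrt(0.3), c1 = 0, c2 = 0)
    )
  )
}

#' Define a factorial power-study design
#'
#' The three named designs cross instrument paths, causal paths, background
#' correlations and loadings (levels on the path-coefficient scale, i.e.
#' signed square roots of the variance-scale levels): `design1` is the full
#' ACE grid with two levels per factor (4096 cells), `design2` the AE grid
#' with two or three levels (8748 cells), `design3` the AE grid with signed
#' instrument and causal paths (256 cells). `e1`/`e2` are always derived as
#' `sqrt(1 - a^2 - c^2)`, and both score standard deviations stay at 1.
#'
#' @param name `"design1"`, `"design2"`, `"design3"`, or `"custom"`.
#' @param factors For a custom design, a named list of level vectors (path
#'   scale).
#' @param fixed For a custom design, a named list of non-varying parameters.
#' @return Object of class `mrdoc_design` with `factors`, `fixed`, `id`,
#'   `n_cells`.
#' @examples
#' factorial_design("design3")
#' @export
factorial_design <- function(name = c("design1", "design2", "design3",
                                      "custom"),
                             factors = NULL, fixed = list()) {
  name <- match.arg(name)
  if (name == "custom") {
    stopifnot(is.list(factors), length(factors) > 0,
              !is.null(names(factors)))
    spec <- list(factors = factors, fixed = fixed)
  } else {
    spec <- design_specs()[[name]]
  }
  bad <- setdiff(c(names(spec$factors), names(spec$fixed)),
                 mrdoc_param_names())
  if (length(bad)) {
    stop("unknown parameter(s) in design: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(factors = spec$factors, fixed = spec$fixed, id = name,
         n_cells = prod(lengths(spec$factors))),
    class = "mrdoc_design"
  )
}

#' @export
print.mrdoc_design <- function(x, ...) {
  cat("<mrdoc_design> ", x$id, ": ", x$n_cells, " cells, factors ",
      paste(names(x$factors), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Enumerate the parameter cells of a design
#'
#' @param design An [factorial_design()].
#' @return Tibble with `cell` and one column per parameter (varying factors
#'   plus fixed values), on the path-coefficient scale.
#' @export
design_cells <- function(design) {
  stopifnot(inherits(design, "mrdoc_design"))
  grid <- tidyr::expand_grid(!!!design$factors)
  for (nm in names(design$fixed)) grid[[nm]] <- design$fixed[[nm]]
  dplyr::mutate(grid, cell = dplyr::row_number(), .before = 1)
}

cell_theta <- function(row) {
  keep <- intersect(names(row), setdiff(mrdoc_param_names(), c("e1", "e2")))
  do.call(mrdoc_params, as.list(row[keep]))
}

#' Run a factorial power design on exact moments
#'
#' For every cell: build the parameter vector (`e` derived), form the exact
#' population moments at the given group sizes, fit each constrained null
#' model (`g1 = 0`, `g2 = 0`, and the joint `g1 = g2 = 0`) starting from the
#' generating values, and record the resulting exact NCP and power. The
#' full-model discrepancy is identically zero on exact data, so each test's
#' NCP is its constrained fit's discrepancy. A cell whose fit fails is
#' recorded with `NA` results and the run continues.
#'
#' @param design An [factorial_design()].
#' @param n_mz,n_dz Pair counts (default 1000 each).
#' @param alpha Type-I error rate.
#' @param tests Which tests to run (subset of `"g1"`, `"g2"`, `"joint"`).
#' @param cells Optional integer vector of cell indices to run (e.g. a smoke
#'   subsample of a large design).
#' @param polish Passed to [mrdoc_fit()]; bulk runs default to the faster
#'   non-polished fits (NCPs accurate well beyond the 3 printed digits).
#' @return Tibble: `cell`, parameter columns, implied `r2_*` summaries,
#'   `ncp_*` and `pow_*` per test, and `error` (`NA` or the failure message).
#' @examples
#' d3 <- factorial_design("design3")
#' run_design(d3, cells = 1:2, tests = "g1")
#' @export
run_design <- function(design, n_mz = 1000, n_dz = 1000, alpha = 0.05,
                       tests = c("g1", "g2", "joint"), cells = NULL,
                       polish = FALSE) {
  tests <- match.arg(tests, several.ok = TRUE)
  grid <- design_cells(design)
  if (!is.null(cells)) grid <- grid[grid$cell %in% cells, , drop = FALSE]

  # the fitted model is the design's own generating model: structural zeros
  # of the design (e.g. the C paths of the AE designs) stay fixed in fitting
  zero_fixed <- names(design$fixed)[vapply(design$fixed, function(v) {
    identical(v, 0) || isTRUE(v == 0)
  }, logical(1))]
  base_fix <- c(b2 = 0, b4 = 0,
                stats::setNames(rep(0, length(zero_fixed)), zero_fixed))
  base_pat <- mrdoc_pattern(fix = base_fix)

  fix_sets <- list(g1 = "g1", g2 = "g2", joint = c("g1", "g2"))[tests]

  res <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    row <- unlist(grid[i, setdiff(names(grid), "cell")])
    out <- tibble::tibble(cell = grid$cell[i])
    tryCatch({
      theta <- cell_theta(row)
      data <- exact_moments(theta, n_mz, n_dz)
      out <- dplyr::bind_cols(out, phenotype_summary(theta))
      start <- stats::setNames(theta_numeric(theta), mrdoc_param_names())
      for (ts in names(fix_sets)) {
        fz <- fix_sets[[ts]]
        pat <- do.call(pattern_fix,
                       c(list(base_pat),
                         stats::setNames(as.list(rep(0, length(fz))), fz)))
        st <- start; st[fz] <- 0
        fit <- mrdoc_fit(data, pat, start = st, restarts = 0,
                         polish = polish)
        ncp <- fit$discrepancy
        out[[paste0("ncp_", ts)]] <- ncp
        out[[paste0("pow_", ts)]] <-
          power_from_ncp(ncp, df = length(fz), alpha = alpha)
      }
      out$error <- NA_character_
      out
    }, error = function(e) {
      for (ts in names(fix_sets)) {
        out[[paste0("ncp_", ts)]] <- NA_real_
        out[[paste0("pow_", ts)]] <- NA_real_
      }
      out$error <- conditionMessage(e)
      out
    })
  })
  dplyr::left_join(grid, res, by = "cell")
}

#' Regress NCP on design parameters (variance decomposition)
#'
#' Standardises the chosen NCP column and every varying parameter (on the
#' path-coefficient scale) across cells and fits ordinary least squares; the
#' squared standardised coefficients report each parameter's share of NCP
#' variance, which on an orthogonal factorial equals its ANOVA
#' sum-of-squares share. With `order = 2`, centred squared terms of factors
#' with three or more levels are added and the R-squared gain is reported.
#'
#' @param cells Output of [run_design()].
#' @param response Which NCP column to decompose (`"ncp_g1"`, `"ncp_g2"`,
#'   `"ncp_joint"`).
#' @param order 1 for linear only, 2 to add quadratic terms.
#' @return Object of class `ncp_regression`; `tidy()` gives the per-term
#'   `beta_squared` table, `glance()` the `total_r2` (and
#'   `quadratic_r2_gain` when `order = 2`).
#' @export
regress_ncp <- function(cells, response = c("ncp_g1", "ncp_g2", "ncp_joint"),
                        order = 1) {
  response <- match.arg(response)
  stopifnot(order %in% c(1, 2), response %in% names(cells))
  cells <- cells[is.na(cells$error) | !nzchar(cells$error), , drop = FALSE]

  params <- intersect(mrdoc_param_names(), names(cells))
  varying <- params[vapply(params, function(p) {
    length(unique(cells[[p]])) > 1
  }, logical(1))]
  if (!length(varying)) stop("no varying parameters in cells", call. = FALSE)

  y <- cells[[response]]
  if (stats::sd(y) == 0) {
    terms <- tibble::tibble(term = varying, beta = 0, beta_squared = 0)
    return(structure(list(terms = terms, total_r2 = 0, response = response,
                          order = order, quadratic_r2_gain = NA_real_),
                     class = "ncp_regression"))
  }

  Z <- as.data.frame(lapply(cells[varying], function(x) as.numeric(scale(x))))
  qrX <- qr(as.matrix(Z))
  if (qrX$rank < length(varying)) {
    dropped <- varying[-qrX$pivot[seq_len(qrX$rank)]]
    stop("collinear design: factor(s) ", paste(dropped, collapse = ", "),
         " are linearly dependent on the others", call. = FALSE)
  }
  Z$.y <- as.numeric(scale(y))
  fit1 <- stats::lm(.y ~ ., data = Z)
  r2_1 <- summary(fit1)$r.squared
  beta <- stats::coef(fit1)[varying]
  terms <- tibble::tibble(term = varying, beta = as.numeric(beta),
                          beta_squared = as.numeric(beta)^2)

  gain <- NA_real_
  if (order == 2) {
    quad <- varying[vapply(varying, function(p) {
      length(unique(cells[[p]])) > 2
    }, logical(1))]
    if (length(quad)) {
      for (p in quad) {
        Z[[paste0(p, "_sq")]] <-
          as.numeric(scale(as.numeric(scale(cells[[p]]))^2))
      }
      fit2 <- stats::lm(.y ~ ., data = Z)
      gain <- summary(fit2)$r.squared - r2_1
    } else {
      gain <- 0
    }
  }

  structure(list(terms = terms, total_r2 = r2_1, response = response,
                 order = order, quadratic_r2_gain = gain),
            class = "ncp_regression")
}

#' @export
print.ncp_regression <- function(x, ...) {
  cat("<ncp_regression> response ", x$response,
      ", total R^2 = ", round(x$total_r2, 3), "\n", sep = "")
  print(dplyr::arrange(x$terms, dplyr::desc(.data$beta_squared)), n = Inf)
  if (!is.na(x$quadratic_r2_gain)) {
    cat("quadratic R^2 gain: ", round(x$quadratic_r2_gain, 4), "\n", sep = "")
  }
  invisible(x)
}

#' @param x An `ncp_regression`.
#' @param ... Unused.
#' @rdname regress_ncp
#' @export
tidy.ncp_regression <- function(x, ...) x$terms

#' @rdname regress_ncp
#' @export
glance.ncp_regression <- function(x, ...) {
  tibble::tibble(response = x$response, total_r2 = x$total_r2,
                 order = x$order, quadratic_r2_gain = x$quadratic_r2_gain)
}

# Implied R^2 of Ph1 on PS1 as a function of b1, all else from theta_base.
r2_of_b1 <- function(theta_base, b1) {
  th <- stats::setNames(theta_numeric(theta_base), mrdoc_param_names())
  th["b1"] <- b1
  phenotype_summary(as_mrdoc_params(th))$r2_ph1_on_ps1
}

#' Required sample size across instrument strength
#'
#' For each target instrument R-squared (variance in Ph1 explained by PS1),
#' solves for the `b1` achieving it, evaluates the exact per-pair NCP of the
#' `g1 = 0` test once, and uses the exact proportionality of the NCP in the
#' total pair count (equal MZ/DZ split) to jump to the smallest even total
#' achieving the target power; the crossing is then verified directly and
#' adjusted by steps of 2 if needed. A grid point whose per-pair NCP is zero
#' is flagged (`n_pairs_80 = NA`).
#'
#' @param theta_base Base parameters; `b1` is overwritten per grid point.
#' @param r2_grid Instrument R-squared values (each in (0, 1)).
#' @param target_power Power to reach (default 0.80).
#' @param alpha Type-I error rate.
#' @return Tibble: `r2_instrument`, `b1`, `ncp_per_pair`, `n_pairs_80`,
#'   `flagged`.
#' @export
required_n_curve <- function(theta_base, r2_grid, target_power = 0.80,
                             alpha = 0.05) {
  theta_base <- as_mrdoc_params(theta_base)
  stopifnot(all(r2_grid > 0), all(r2_grid < 1),
            target_power > alpha, target_power < 1)
  n_ref <- 2000
  ncp_needed <- stats::uniroot(
    function(x) power_from_ncp(x, 1, alpha) - target_power,
    c(1e-9, 1000), tol = 1e-10
  )$root

  purrr::map_dfr(r2_grid, function(r2) {
    b1 <- tryCatch(
      stats::uniroot(function(b) r2_of_b1(theta_base, b) - r2,
                     c(1e-9, 4.9), tol = 1e-12)$root,
      error = function(e) NA_real_
    )
    if (is.na(b1)) {
      return(tibble::tibble(r2_instrument = r2, b1 = NA_real_,
                            ncp_per_pair = NA_real_, n_pairs_80 = NA_real_,
                            flagged = TRUE))
    }
    th <- stats::setNames(theta_numeric(theta_base), mrdoc_param_names())
    th["b1"] <- b1
    ncp_ref <- ncp_exact(as_mrdoc_params(th), "g1",
                         n_mz = n_ref / 2, n_dz = n_ref / 2)
    ncp_pp <- ncp_ref / n_ref
    if (ncp_pp <= 1e-12) {
      return(tibble::tibble(r2_instrument = r2, b1 = b1, ncp_per_pair = ncp_pp,
                            n_pairs_80 = NA_real_, flagged = TRUE))
    }
    n_tot <- 2 * ceiling(ncp_needed / ncp_pp / 2)
    while (n_tot > 2 &&
           power_from_ncp(ncp_pp * (n_tot - 2), 1, alpha) >= target_power) {
      n_tot <- n_tot - 2
    }
    while (power_from_ncp(ncp_pp * n_tot, 1, alpha) < target_power) {
      n_tot <- n_tot + 2
    }
    tibble::tibble(r2_instrument = r2, b1 = b1, ncp_per_pair = ncp_pp,
                   n_pairs_80 = n_tot, flagged = FALSE)
  })
}
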