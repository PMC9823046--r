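# Assumption-violation experiments: direct pleiotropy and unmodeled
# measurement error.

#' Bias from fitting the no-pleiotropy model to pleiotropic truth
#'
#' Generates exact population moments under a truth with nonzero direct
#' pleiotropic paths (`b2`, `b4`) and fits the standard identified pattern
#' that fixes both to zero. Because the moments are exact, the reported
#' biases are deterministic consequences of the misspecification, with no
#' Monte-Carlo noise. Under positive `b2`/`b4`, the causal paths `g1`, `g2`
#' are overestimated and the background correlations `ra`, `rc`, `re`
#' underestimated; when the true causal paths are zero the inflated
#' estimates also inflate the false-positive rate of the `g1 = 0` test,
#' reported here via its NCP under the misspecified fit.
#'
#' @param theta_true Generating parameters (typically with `b2 > 0` and/or
#'   `b4 > 0`).
#' @param n_mz,n_dz Pair counts.
#' @param alpha Type-I error rate for the false-positive-rate summary.
#' @return Object of class `mrdoc_bias`: `estimates` tibble (`term`, `true`,
#'   `estimate`, `bias`), `fp_ncp_g1` / `fp_rate_g1` (NCP and rejection rate
#'   of the `g1 = 0` test under the misspecified model), metadata.
#' @examples
#' th <- mrdoc_params(a1 = 0.5, a2 = 0.5, ra = 0.3, re = 0.3,
#'                    b1 = 0.3, b3 = 0.3, b2 = 0.1, b4 = 0.1)
#' pleiotropy_violation_study(th)
#' @export
pleiotropy_violation_study <- function(theta_true, n_mz = 1000, n_dz = 1000,
                                       alpha = 0.05) {
  theta_true <- as_mrdoc_params(theta_true)
  data <- exact_moments(theta_true, n_mz, n_dz)

  start <- stats::setNames(theta_numeric(theta_true), mrdoc_param_names())
  start[c("b2", "b4")] <- 0
  fit <- mrdoc_fit(data, mrdoc_pattern(), start = start, restarts = 2)

  terms <- mrdoc_param_names()
  est <- tibble::tibble(
    term = terms,
    true = as.numeric(unclass(theta_true)[terms]),
    estimate = as.numeric(unclass(fit$estimates)[terms])
  ) |>
    dplyr::mutate(bias = .data$estimate - .data$true)

  # rejection rate of g1 = 0 when fitting the misspecified pattern: the LR
  # statistic is noncentral chi-square with this NCP
  st0 <- start; st0["g1"] <- 0
  fit0 <- mrdoc_fit(data, pattern_fix(mrdoc_pattern(), g1 = 0),
                    start = st0, restarts = 2)
  ncp_g1 <- max(fit0$discrepancy - fit$discrepancy, 0)

  structure(
    list(estimates = est,
         fp_ncp_g1 = ncp_g1,
         fp_rate_g1 = power_from_ncp(ncp_g1, 1, alpha),
         misfit = fit$discrepancy,
         n_mz = n_mz, n_dz = n_dz, alpha = alpha,
         experiment = "pleiotropy_violation"),
    class = "mrdoc_bias"
  )
}

#' Bias and power loss from unmodeled measurement error
#'
#' Repeatedly samples twin pairs under `theta_true`, degrades the phenotypes
#' to the given reliabilities, and fits the standard model to the noisy
#' sample moments. Reports per-parameter mean bias with Monte-Carlo standard
#' errors, and the empirical power of the `g1 = 0` LR test with and without
#' the error. Unmodeled error is absorbed by the unique-environment part of
#' the model: `e1`, `e2`, `re` are biased while `g1`, `g2`, `b1`, `b3` are
#' not, and power drops.
#'
#' @param theta_true Generating parameters.
#' @param rel_ph1,rel_ph2 Phenotype reliabilities in (0, 1].
#' @param n_mz,n_dz Pair counts per replicate.
#' @param n_reps Number of Monte-Carlo replicates.
#' @param seed Master seed; replicate seeds derive from it.
#' @param alpha Type-I error rate.
#' @return Object of class `mrdoc_bias`: `estimates` tibble (`term`, `true`,
#'   `estimate` = mean estimate, `bias`, `mc_se`), `power_g1` (empirical,
#'   with error), `power_g1_clean` (without), metadata.
#' @export
measurement_error_study <- function(theta_true, rel_ph1 = 0.8, rel_ph2 = 0.8,
                                    n_mz = 1000, n_dz = 1000, n_reps = 100,
                                    seed = 1, alpha = 0.05) {
  theta_true <- as_mrdoc_params(theta_true)
  stopifnot(n_reps >= 2)
  start <- stats::setNames(theta_numeric(theta_true), mrdoc_param_names())
  pat_full <- mrdoc_pattern()
  pat_null <- pattern_fix(pat_full, g1 = 0)
  crit <- stats::qchisq(1 - alpha, 1)

  one_rep <- function(r, with_error) {
    tbl <- simulate_twins(theta_true, n_mz, n_dz, seed = seed + 7L * r)
    if (with_error) {
      tbl <- inject_measurement_error(tbl, rel_ph1, rel_ph2,
                                      seed = seed + 7L * r + 3L)
    }
    mom <- moments_from_table(tbl)
    fit <- mrdoc_fit(mom, pat_full, start = start, restarts = 0)
    st0 <- start; st0["g1"] <- 0
    fit0 <- mrdoc_fit(mom, pat_null, start = st0, restarts = 0)
    lr <- max(fit0$discrepancy - fit$discrepancy, 0)
    list(est = as.numeric(unclass(fit$estimates)[mrdoc_param_names()]),
         reject = lr > crit)
  }

  noisy <- lapply(seq_len(n_reps), one_rep, with_error = TRUE)
  clean_reject <- vapply(seq_len(n_reps), function(r) {
    one_rep(r, with_error = FALSE)$reject
  }, logical(1))

  E <- do.call(rbind, lapply(noisy, `[[`, "est"))
  colnames(E) <- mrdoc_param_names()
  est <- tibble::tibble(
    term = mrdoc_param_names(),
    true = as.numeric(unclass(theta_true)[mrdoc_param_names()]),
    estimate = colMeans(E),
    mc_se = apply(E, 2, stats::sd) / sqrt(n_reps)
  ) |>
    dplyr::mutate(bias = .data$estimate - .data$true, .before = "mc_se")

  structure(
    list(estimates = est,
         power_g1 = mean(vapply(noisy, `[[`, logical(1), "reject")),
         power_g1_clean = mean(clean_reject),
         rel_ph1 = rel_ph1, rel_ph2 = rel_ph2,
         n_mz = n_mz, n_dz = n_dz, n_reps = n_reps, seed = seed,
         alpha = alpha,
         experiment = "measurement_error"),
    class = "mrdoc_bias"
  )
}

#' @export
print.mrdoc_bias <- function(x, ...) {
  cat("<mrdoc_bias> ", x$experiment, " (", x$n_mz, " MZ + ", x$n_dz,
      " DZ pairs)\n", sep = "")
  print(x$estimates, n = Inf)
  if (x$experiment == "pleiotropy_violation") {
    cat("false-positive NCP for g1 = 0: ", round(x$fp_ncp_g1, 3),
        " (rejection rate ", round(x$fp_rate_g1, 3), " at alpha ", x$alpha,
        ")\n", sep = "")
  } else {
    cat("empirical power for g1 = 0: ", x$power_g1, " with error, ",
        x$power_g1_clean, " without\n", sep = "")
  }
  invisible(x)
}

#' @param x An `mrdoc_bias`.
#' @param ... Unused.
#' @return The per-parameter bias tibble.
#' @rdname pleiotropy_violation_study
#' @export
tidy.mrdoc_bias <- function(x, ...) x$estimates
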