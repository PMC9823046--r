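# Twin-pair data generation: exact (population) moments and stochastic
# sampling, plus measurement-error injection.

#' Exact-data moments for a twin study design
#'
#' Exact data simulation hands the population moments implied by `theta`
#' directly to the fitter, with the design's pair counts attached. Fitting
#' the generating model to this object yields a discrepancy of zero and
#' estimates equal to the generating values, and the discrepancy of any
#' nested constrained fit is the exact noncentrality parameter of the
#' corresponding LR test — no Monte-Carlo noise.
#'
#' @param theta An [mrdoc_params()] vector.
#' @param n_mz,n_dz Numbers of MZ and DZ pairs (default 1000 each).
#' @return An `mrdoc_data` object (per-group covariance, zero means, counts).
#' @examples
#' exact_moments(mrdoc_params(a1 = 0.5, b1 = 0.3), 1000, 1000)
#' @export
exact_moments <- function(theta, n_mz = 1000, n_dz = 1000) {
  theta <- as_mrdoc_params(theta)
  stopifnot(n_mz >= 0, n_dz >= 0)
  if (n_mz + n_dz == 0) {
    stop("degenerate design: n_mz = n_dz = 0 carries no information",
         call. = FALSE)
  }
  new_mrdoc_data(
    mz_cov = implied_moments(theta, "MZ")$covariance,
    n_mz = n_mz,
    dz_cov = implied_moments(theta, "DZ")$covariance,
    n_dz = n_dz,
    theta = theta
  )
}

#' Simulate twin-pair records from the MR-DoC2 model
#'
#' Draws each pair's 8-vector (both twins' phenotypes and polygenic scores)
#' from the zygosity-specific multivariate normal implied by `theta`. MZ
#' co-twins receive literally identical score values (their correlation is 1
#' under the model): the six non-degenerate coordinates are sampled and the
#' twin-1 scores are copied to twin 2.
#'
#' @param theta An [mrdoc_params()] vector.
#' @param n_mz,n_dz Numbers of MZ and DZ pairs.
#' @param seed Integer seed; every run with the same seed yields the same
#'   table.
#' @return A tibble with columns `pair_id`, `zygosity`, `ph1_t1`, `ph2_t1`,
#'   `ps1_t1`, `ps2_t1`, `ph1_t2`, `ph2_t2`, `ps1_t2`, `ps2_t2`.
#' @examples
#' simulate_twins(mrdoc_params(a1 = 0.5, b1 = 0.3), 5, 5, seed = 1)
#' @export
simulate_twins <- function(theta, n_mz = 1000, n_dz = 1000, seed = 1) {
  theta <- as_mrdoc_params(theta)
  stopifnot(n_mz >= 0, n_dz >= 0)
  set.seed(seed)
  vn <- mrdoc_var_names()
  out <- list()
  if (n_mz > 0) {
    S6 <- implied_moments(theta, "MZ")$covariance[1:6, 1:6]
    X <- MASS::mvrnorm(n_mz, mu = rep(0, 6), Sigma = S6)
    X <- cbind(X, X[, 3], X[, 4])  # co-twin scores are identical
    colnames(X) <- vn
    out$mz <- tibble::as_tibble(as.data.frame(X)) |>
      dplyr::mutate(zygosity = "MZ", .before = 1)
  }
  if (n_dz > 0) {
    S8 <- implied_moments(theta, "DZ")$covariance
    X <- MASS::mvrnorm(n_dz, mu = rep(0, 8), Sigma = S8)
    colnames(X) <- vn
    out$dz <- tibble::as_tibble(as.data.frame(X)) |>
      dplyr::mutate(zygosity = "DZ", .before = 1)
  }
  dplyr::bind_rows(out) |>
    dplyr::mutate(pair_id = dplyr::row_number(), .before = 1)
}

#' Inject unmodeled measurement error into phenotypes
#'
#' Adds independent normal noise to each phenotype column, with the noise
#' variance set to `var(x) * (1 - rel) / rel` so that the reliability of the
#' noisy column — the proportion of its variance that is true score — equals
#' `rel`. Additive noise leaves every covariance with other variables intact
#' (it is absorbed by the unique-environment part of a subsequent model fit),
#' which is what makes the instrument and causal paths immune to this kind
#' of error while `e1`, `e2` and `re` are not. Polygenic-score columns are
#' untouched. With `rel = 1` the table is returned unchanged.
#'
#' @param table A twin table from [simulate_twins()] (or with the same
#'   columns).
#' @param rel_ph1,rel_ph2 Reliabilities of the two phenotypes, in (0, 1].
#' @param seed Integer seed for the noise draws.
#' @return The table with noisy phenotype columns.
#' @export
inject_measurement_error <- function(table, rel_ph1 = 1, rel_ph2 = 1,
                                     seed = 1) {
  stopifnot(rel_ph1 > 0, rel_ph1 <= 1, rel_ph2 > 0, rel_ph2 <= 1)
  if (rel_ph1 == 1 && rel_ph2 == 1) return(table)
  set.seed(seed)
  n <- nrow(table)
  noisy <- function(x, rel) {
    x + sqrt(stats::var(x) * (1 - rel) / rel) * stats::rnorm(n)
  }
  table |>
    dplyr::mutate(
      ph1_t1 = noisy(.data$ph1_t1, rel_ph1),
      ph1_t2 = noisy(.data$ph1_t2, rel_ph1),
      ph2_t1 = noisy(.data$ph2_t1, rel_ph2),
      ph2_t2 = noisy(.data$ph2_t2, rel_ph2)
    )
}

#' Per-zygosity sample moments of a twin table
#'
#' @param table A twin table (columns as in [simulate_twins()]).
#' @return An `mrdoc_data` object with each group's sample covariance, mean
#'   and pair count. A group with no rows gets count 0 and a warning.
#' @export
moments_from_table <- function(table) {
  vn <- mrdoc_var_names()
  missing_cols <- setdiff(c("zygosity", vn), names(table))
  if (length(missing_cols)) {
    stop("twin table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_zyg <- setdiff(unique(table$zygosity), c("MZ", "DZ"))
  if (length(bad_zyg)) {
    stop("unknown zygosity value(s): ", paste(bad_zyg, collapse = ", "),
         call. = FALSE)
  }
  grab <- function(z) {
    X <- as.matrix(table[table$zygosity == z, vn])
    n <- nrow(X)
    if (n == 0) {
      warning("no ", z, " pairs in table", call. = FALSE)
      return(list(cov = NULL, n = 0))
    }
    list(cov = stats::cov(X), n = n)
  }
  mz <- grab("MZ")
  dz <- grab("DZ")
  new_mrdoc_data(mz_cov = mz$cov, n_mz = mz$n,
                 dz_cov = dz$cov, n_dz = dz$n)
}

#' Read / write twin tables as CSV
#'
#' The on-disk format is one header line with the exact column names of
#' [simulate_twins()] and one row per pair; zygosity values must be `MZ` or
#' `DZ`. Writing uses full double precision so that a write-read round trip
#' is lossless.
#'
#' @param path File path.
#' @return `read_twin_csv()` returns the validated tibble.
#' @export
read_twin_csv <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  vn <- mrdoc_var_names()
  missing_cols <- setdiff(c("pair_id", "zygosity", vn), names(tbl))
  if (length(missing_cols)) {
    stop("twin CSV ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (v in vn) {
    if (!is.numeric(tbl[[v]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(tbl[[v]]))))
      stop("non-numeric values in column ", v, " (e.g. line ",
           bad[1] + 1, ")", call. = FALSE)
    }
  }
  bad <- which(!tbl$zygosity %in% c("MZ", "DZ"))
  if (length(bad)) {
    stop("unknown zygosity at line ", bad[1] + 1, ": '",
         tbl$zygosity[bad[1]], "'", call. = FALSE)
  }
  tbl
}

#' @param table Twin table to write.
#' @rdname read_twin_csv
#' @export
write_twin_csv <- function(table, path) {
  readr::write_csv(table, path)
  invisible(path)
}
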