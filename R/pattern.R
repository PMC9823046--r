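# Free/fixed parameter patterns used by the fitter and identification checks.

#' Define which MR-DoC2 parameters are free
#'
#' A pattern assigns every parameter a status: free, or fixed at a value.
#' The default fixes the two direct pleiotropic paths at zero
#' (`b2 = b4 = 0`), the configuration under which the model is locally
#' identified; everything else, including `e1`/`e2`, is freely estimated.
#' Optionally the latent genetic correlation can be tied to the score
#' correlation through `ra = m * rf` with a fixed constant `m`, the
#' device used in sensitivity analyses that treat the score as a noisy
#' measure of the additive-genetic liability.
#'
#' @param fix Named numeric vector of parameters fixed at the given values.
#' @param ra_equals_m_rf `NULL`, or the constant `m` in the equality
#'   constraint `ra = m * rf` (then `ra` is no longer a free parameter).
#' @return Object of class `mrdoc_pattern` with elements `fixed`, `ra_m`,
#'   `free` (parameter names, canonical order) and `n_free`.
#' @examples
#' mrdoc_pattern()                                   # identified default
#' mrdoc_pattern(fix = c(b2 = 0, b4 = 0, g1 = 0))    # null model for g1
#' mrdoc_pattern(fix = c(b4 = 0), ra_equals_m_rf = 1)
#' @export
mrdoc_pattern <- function(fix = c(b2 = 0, b4 = 0), ra_equals_m_rf = NULL) {
  nm <- mrdoc_param_names()
  fix <- unlist(fix)
  if (length(fix)) {
    bad <- setdiff(names(fix), nm)
    if (length(bad)) {
      stop("unknown parameter name(s) in fix: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    if (anyDuplicated(names(fix))) stop("duplicated names in fix", call. = FALSE)
  }
  if (!is.null(ra_equals_m_rf)) {
    stopifnot(is.finite(ra_equals_m_rf), length(ra_equals_m_rf) == 1)
    if ("ra" %in% names(fix)) {
      stop("ra cannot be both fixed and constrained to m * rf", call. = FALSE)
    }
    if ("rf" %in% names(fix)) {
      stop("rf must stay free under the ra = m * rf constraint", call. = FALSE)
    }
  }
  free <- setdiff(nm, names(fix))
  if (!is.null(ra_equals_m_rf)) free <- setdiff(free, "ra")
  structure(
    list(fixed = fix, ra_m = ra_equals_m_rf, free = free,
         n_free = length(free)),
    class = "mrdoc_pattern"
  )
}

#' Add fixed values to an existing pattern
#'
#' Convenience for building a nested null model, e.g. fixing `g1 = 0` on top
#' of the identified default.
#'
#' @param pattern An [mrdoc_pattern()].
#' @param ... Name-value pairs of additional fixed parameters.
#' @return A new `mrdoc_pattern`.
#' @examples
#' pattern_fix(mrdoc_pattern(), g1 = 0)
#' @export
pattern_fix <- function(pattern, ...) {
  extra <- unlist(list(...))
  overlap <- intersect(names(extra), names(pattern$fixed))
  fix <- c(pattern$fixed[setdiff(names(pattern$fixed), overlap)], extra)
  mrdoc_pattern(fix = fix, ra_equals_m_rf = pattern$ra_m)
}

#' @export
print.mrdoc_pattern <- function(x, ...) {
  cat("<mrdoc_pattern> ", x$n_free, " free parameters\n", sep = "")
  if (length(x$fixed)) {
    cat("  fixed: ",
        paste(names(x$fixed), "=", x$fixed, collapse = ", "), "\n", sep = "")
  }
  if (!is.null(x$ra_m)) cat("  constraint: ra = ", x$ra_m, " * rf\n", sep = "")
  invisible(x)
}

# Resolve a full parameter vector from the pattern and free values.
pattern_theta <- function(pattern, x_free, base = NULL) {
  th <- if (is.null(base)) {
    stats::setNames(rep(0, 18), mrdoc_param_names())
  } else {
    stats::setNames(theta_numeric(base), mrdoc_param_names())
  }
  th[names(pattern$fixed)] <- pattern$fixed
  th[pattern$free] <- x_free
  if (!is.null(pattern$ra_m)) th["ra"] <- pattern$ra_m * th["rf"]
  th
}

# Box bounds for each free parameter, used by the bounded quasi-Newton
# optimizer. Loadings are kept nonnegative to remove the sign indeterminacy
# of latent factors; correlations and causal paths stay inside (-1, 1).
pattern_bounds <- function(pattern) {
  lower <- c(ra = -0.999, rc = -0.999, re = -0.999, rf = -0.999,
             a1 = 0, c1 = 0, e1 = 0, a2 = 0, c2 = 0, e2 = 0,
             g1 = -0.99, g2 = -0.99, b1 = -5, b3 = -5, b2 = -5, b4 = -5,
             sigma_x = 1e-6, sigma_y = 1e-6)
  upper <- c(ra = 0.999, rc = 0.999, re = 0.999, rf = 0.999,
             a1 = 3, c1 = 3, e1 = 3, a2 = 3, c2 = 3, e2 = 3,
             g1 = 0.99, g2 = 0.99, b1 = 5, b3 = 5, b2 = 5, b4 = 5,
             sigma_x = 10, sigma_y = 10)
  list(lower = lower[pattern$free], upper = upper[pattern$free])
}
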