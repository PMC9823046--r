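#' @keywords internal
"_PACKAGE"

#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
#' @useDynLib mrdoc2, .registration = TRUE
NULL

# Canonical parameter order; the C++ layer (src/implied.cpp) indexes into this
# order, keep in sync.
mrdoc_param_names <- function() {
  c("ra", "rc", "re", "rf", "a1", "c1", "e1", "a2", "c2", "e2",
    "g1", "g2", "b1", "b3", "b2", "b4", "sigma_x", "sigma_y")
}

#' Construct an MR-DoC2 parameter vector
#'
#' The MR-DoC2 model describes two phenotypes (`Ph1`, `Ph2`) measured on both
#' members of MZ and DZ twin pairs, each phenotype instrumented by its own
#' polygenic score (`PS1`, `PS2`). Each phenotype loads on additive-genetic
#' (A), shared-environmental (C) and unique-environmental (E) latent factors
#' with unit variances; the factors of the two traits correlate within a
#' person (`ra`, `rc`, `re`), and the two scores correlate (`rf`). The
#' reciprocal causal paths are `g1` (Ph1 to Ph2) and `g2` (Ph2 to Ph1);
#' `b1`/`b3` are the instrument paths PS1 to Ph1 and PS2 to Ph2. The direct
#' (horizontally pleiotropic) paths `b2` (PS1 to Ph2) and `b4` (PS2 to Ph1)
#' default to zero, the assumption under which the model is identified.
#'
#' When `e1` (or `e2`) is `NULL` it is derived as `sqrt(1 - a1^2 - c1^2)`
#' (analogously for trait 2), so that each phenotype's residual latent
#' variance is standardised to one before causal and instrument effects.
#'
#' @param ra,rc,re Cross-trait correlations of the A, C and E factors, each in
#'   `[-1, 1]`.
#' @param rf Correlation between the two polygenic scores, in `[-1, 1]`.
#' @param a1,c1,e1 Loadings of Ph1 on its A, C, E factors; `e1 = NULL` derives
#'   it from the unit-variance rule.
#' @param a2,c2,e2 Loadings of Ph2, analogously.
#' @param g1,g2 Reciprocal causal paths Ph1->Ph2 and Ph2->Ph1; `|g1*g2| < 1`
#'   is required for the reduced form to exist.
#' @param b1,b3 Instrument paths PS1->Ph1 and PS2->Ph2.
#' @param b2,b4 Direct pleiotropic paths PS1->Ph2 and PS2->Ph1 (default 0).
#' @param sigma_x,sigma_y Standard deviations of PS1 and PS2 (default 1).
#'
#' @return A named numeric vector of class `mrdoc_params`.
#' @examples
#' theta <- mrdoc_params(
#'   a1 = 0.5, a2 = 0.5, g1 = sqrt(0.06), g2 = sqrt(0.06),
#'   b1 = sqrt(0.075), b3 = sqrt(0.075)
#' )
#' theta
#' @export
mrdoc_params <- function(ra = 0, rc = 0, re = 0, rf = 0,
                         a1 = 0, c1 = 0, e1 = NULL,
                         a2 = 0, c2 = 0, e2 = NULL,
                         g1 = 0, g2 = 0,
                         b1 = 0, b3 = 0, b2 = 0, b4 = 0,
                         sigma_x = 1, sigma_y = 1) {
  if (is.null(e1)) {
    if (a1^2 + c1^2 > 1 + 1e-12) {
      stop("cannot derive e1: a1^2 + c1^2 = ", a1^2 + c1^2, " exceeds 1",
           call. = FALSE)
    }
    e1 <- sqrt(max(0, 1 - a1^2 - c1^2))
  }
  if (is.null(e2)) {
    if (a2^2 + c2^2 > 1 + 1e-12) {
      stop("cannot derive e2: a2^2 + c2^2 = ", a2^2 + c2^2, " exceeds 1",
           call. = FALSE)
    }
    e2 <- sqrt(max(0, 1 - a2^2 - c2^2))
  }
  theta <- c(ra = ra, rc = rc, re = re, rf = rf,
             a1 = a1, c1 = c1, e1 = e1, a2 = a2, c2 = c2, e2 = e2,
             g1 = g1, g2 = g2, b1 = b1, b3 = b3, b2 = b2, b4 = b4,
             sigma_x = sigma_x, sigma_y = sigma_y)
  validate_mrdoc_params(theta)
  structure(theta, class = c("mrdoc_params", "numeric"))
}

#' Coerce a named vector or one-row data frame to `mrdoc_params`
#'
#' Unnamed parameters take the [mrdoc_params()] defaults; unknown names are an
#' error.
#'
#' @param x Named numeric vector, list, or one-row data frame.
#' @return An `mrdoc_params` vector.
#' @export
as_mrdoc_params <- function(x) {
  if (inherits(x, "mrdoc_params")) return(x)
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1)
    x <- unlist(x[intersect(names(x), mrdoc_param_names())])
  }
  x <- unlist(x)
  bad <- setdiff(names(x), mrdoc_param_names())
  if (length(bad)) {
    stop("unknown parameter name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(mrdoc_params, as.list(x))
}

validate_mrdoc_params <- function(theta) {
  nm <- mrdoc_param_names()
  if (!all(nm %in% names(theta))) {
    stop("parameter vector is missing: ",
         paste(setdiff(nm, names(theta)), collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(theta))) stop("non-finite parameter value", call. = FALSE)
  for (r in c("ra", "rc", "re", "rf")) {
    if (abs(theta[[r]]) > 1) {
      stop("correlation ", r, " = ", theta[[r]], " outside [-1, 1]",
           call. = FALSE)
    }
  }
  if (theta[["sigma_x"]] <= 0 || theta[["sigma_y"]] <= 0) {
    stop("sigma_x and sigma_y must be positive", call. = FALSE)
  }
  if (abs(theta[["g1"]] * theta[["g2"]]) >= 1) {
    stop("|g1 * g2| = ", abs(theta[["g1"]] * theta[["g2"]]),
         " >= 1: the reciprocal-causation reduced form (I - B)^-1 ",
         "does not exist", call. = FALSE)
  }
  invisible(theta)
}

#' @export
print.mrdoc_params <- function(x, ...) {
  cat("<mrdoc_params>\n")
  print(round(unclass(x), 6))
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.mrdoc_params <- function(x, ...) {
  tibble::as_tibble(as.list(unclass(x)))
}

# Internal: bare numeric vector in canonical order for the C++ layer.
theta_numeric <- function(theta) {
  as.numeric(unclass(theta)[mrdoc_param_names()])
}
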