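# Shared primitives: Fisher transform, p-values, single-correlation CIs,
# correlation-matrix validity.

#' Fisher r-to-Z transformation
#'
#' Variance-stabilising transform of a Pearson correlation,
#' \eqn{Z = \tfrac12 \log\{(1+r)/(1-r)\} = \mathrm{atanh}(r)}.  The sampling
#' variance of \eqn{Z} is approximately \eqn{1/(n-3)}.
#'
#' @param r Numeric vector of correlations, each strictly inside (-1, 1).
#' @return Numeric vector of Fisher Z values.
#' @seealso [fisher_z_to_r()] for the inverse.
#' @examples
#' fisher_r_to_z(0.3213)
#' fisher_z_to_r(fisher_r_to_z(0.5))
#' @export
fisher_r_to_z <- function(r) {
  if (!is.numeric(r) || anyNA(r)) {
    stop("'r' must be a numeric correlation without missing values")
  }
  if (any(abs(r) >= 1)) {
    stop("Fisher's Z transform requires -1 < r < 1; got r = ",
         paste(r[abs(r) >= 1], collapse = ", "))
  }
  0.5 * log((1 + r) / (1 - r))
}

#' Inverse Fisher transformation
#'
#' Back-transforms a Fisher Z value to the correlation scale,
#' \eqn{r = \tanh(Z)}.
#'
#' @param z Numeric vector of finite Fisher Z values.
#' @return Numeric vector of correlations in (-1, 1).
#' @export
fisher_z_to_r <- function(z) {
  if (!is.numeric(z) || anyNA(z) || any(!is.finite(z))) {
    stop("'z' must be finite numeric")
  }
  tanh(z)
}

#' P-value from a z or t statistic
#'
#' Converts a test statistic to a p-value under the standard normal (`"z"`)
#' or central t (`"t"`) reference distribution, for a two-sided or one-sided
#' alternative.  The sign convention for one-sided alternatives is that the
#' statistic is positive when the first correlation exceeds the second, so
#' `"greater"` means \eqn{\rho_1 > \rho_2}.
#'
#' @param statistic Numeric scalar test statistic.
#' @param kind `"z"` or `"t"`.
#' @param df Degrees of freedom; required when `kind = "t"`.
#' @param alternative One of `"two.sided"`, `"greater"`, `"less"`.
#' @return The p-value in \[0, 1\].
#' @examples
#' p_from_statistic(1.5869, "z")
#' p_from_statistic(-2.8066, "t", df = 288)
#' @export
p_from_statistic <- function(statistic, kind = c("z", "t"), df = NULL,
                             alternative = c("two.sided", "greater", "less")) {
  kind <- match.arg(kind)
  alternative <- match.arg(alternative)
  if (!is.numeric(statistic) || length(statistic) != 1L || !is.finite(statistic)) {
    stop("'statistic' must be a single finite number")
  }
  if (kind == "t") {
    if (is.null(df)) stop("degrees of freedom 'df' are required for a t statistic")
    if (df < 1) stop("'df' must be >= 1")
    cdf <- function(q) stats::pt(q, df = df)
  } else {
    cdf <- function(q) stats::pnorm(q)
  }
  switch(alternative,
         two.sided = 2 * (1 - cdf(abs(statistic))),
         greater   = 1 - cdf(statistic),
         less      = cdf(statistic))
}

#' Confidence interval for a single correlation
#'
#' The usual Fisher-transform interval: transform `r` to the Z scale, add
#' normal-quantile margins with standard error \eqn{1/\sqrt{n-3}}, and
#' back-transform.  These per-correlation limits are the building blocks of
#' Zou's intervals for correlation differences.
#'
#' @param r Correlation, strictly inside (-1, 1).
#' @param n Sample size; must exceed 3.
#' @param conf.level Confidence level in (0, 1); default 0.95.
#' @return Numeric vector `c(lower, upper)`, strictly inside (-1, 1).
#'   The interval is not symmetric about `r` unless `r = 0`.
#' @examples
#' single_corr_ci(0.3213, n = 291)
#' @export
single_corr_ci <- function(r, n, conf.level = 0.95) {
  .check_corr(r, "r")
  .check_n(n, "n")
  .check_prob(conf.level, "conf.level")
  q <- stats::qnorm((1 + conf.level) / 2)
  z <- fisher_r_to_z(r)
  se <- 1 / sqrt(n - 3)
  fisher_z_to_r(c(z - q * se, z + q * se))
}

#' Check that a correlation matrix is positive semi-definite
#'
#' Validates the structure of a correlation matrix (symmetric, unit diagonal,
#' entries in \[-1, 1\]) and tests positive semi-definiteness via its
#' eigenvalues.  User-supplied related correlations in the dependent
#' comparisons can be jointly impossible even when each coefficient is
#' individually admissible; this check flags such inputs.
#'
#' @param R Square numeric correlation matrix.
#' @param tol Eigenvalue tolerance; the matrix passes when the smallest
#'   eigenvalue is at least `-tol`.  Default `1e-9`.
#' @return `TRUE` or `FALSE`, with the eigenvalues attached as attribute
#'   `"eigenvalues"` and the smallest as `"min.eigenvalue"`.
#' @examples
#' check_psd(diag(3))
#' R <- matrix(c(1, .1038, .3213, .1038, 1, .0257, .3213, .0257, 1), 3)
#' check_psd(R)
#' @export
check_psd <- function(R, tol = 1e-9) {
  if (!is.matrix(R) || !is.numeric(R) || nrow(R) != ncol(R)) {
    stop("'R' must be a square numeric matrix")
  }
  if (anyNA(R)) stop("'R' must not contain missing values")
  if (any(abs(R - t(R)) > 1e-8)) stop("'R' must be symmetric")
  if (any(abs(diag(R) - 1) > 1e-8)) stop("'R' must have a unit diagonal")
  if (any(abs(R) > 1 + 1e-8)) stop("all entries of 'R' must lie in [-1, 1]")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  structure(min(ev) >= -tol, eigenvalues = ev, min.eigenvalue = min(ev))
}

# --- input validators shared by every comparison ---------------------------

.check_corr <- function(r, name) {
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r)) {
    stop("'", name, "' must be a single finite correlation", call. = FALSE)
  }
  # |r| = 1 is rejected uniformly: every procedure transforms r or divides
  # by (1 - r^2)
  if (abs(r) >= 1) {
    stop("'", name, "' must lie strictly between -1 and 1 (got ", r, ")",
         call. = FALSE)
  }
  invisible(r)
}

.check_n <- function(n, name) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n != round(n)) {
    stop("'", name, "' must be a single whole number", call. = FALSE)
  }
  if (n <= 3) {
    stop("sample size must exceed 3 (got ", name, " = ", n, ")", call. = FALSE)
  }
  invisible(as.integer(n))
}

.check_prob <- function(p, name) {
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p <= 0 || p >= 1) {
    stop("'", name, "' must lie strictly between 0 and 1", call. = FALSE)
  }
  invisible(p)
}

.check_null_value <- function(nv) {
  if (!is.numeric(nv) || length(nv) != 1L || !is.finite(nv) || nv < 0 || nv >= 2) {
    stop("'null.value' must be a number in [0, 2)", call. = FALSE)
  }
  invisible(nv)
}
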