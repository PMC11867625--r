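#' Standardize a timeseries to mean 0, sd 1
#'
#' Standardization throughout the package uses the population standard
#' deviation (divide by `n`, not `n - 1`), so that a standardized series `x`
#' satisfies `sum(x^2) == length(x)` exactly. All summary and semi-simulated
#' timeseries pass through this function.
#'
#' @param x Numeric vector.
#' @return Numeric vector with mean 0 and population sd 1.
#' @export
#' @examples
#' z <- zscore(rnorm(100, mean = 5, sd = 3))
#' c(mean(z), sqrt(mean(z^2)))
zscore <- function(x) {
  if (!is.numeric(x)) stop("`x` must be numeric", call. = FALSE)
  s <- pop_sd(x)
  if (s == 0) stop("cannot standardize a zero-variance series", call. = FALSE)
  (x - mean(x)) / s
}

# population sd (divide by n)
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

is_zero_var <- function(x, tol = 1e-12) pop_sd(x) < tol

#' Fisher z-transform with clipping
#'
#' `atanh()` of a correlation, with `|r|` clipped to `1 - 1e-12` so that
#' correlations of exactly +/- 1 stay finite and can be averaged.
#'
#' @param r Numeric vector of correlations in `[-1, 1]`.
#' @return `atanh()` of the clipped correlations.
#' @seealso [fisher_z_inv()]
#' @export
fisher_z <- function(r) {
  clip <- 1 - 1e-12
  atanh(pmin(pmax(r, -clip), clip))
}

#' @rdname fisher_z
#' @param z Numeric vector of Fisher-z values.
#' @export
fisher_z_inv <- function(z) tanh(z)

# correlation that maps zero-variance input to 0 with a warning, so
# correlation matrices stay finite for the assignment solver
safe_cor <- function(x, y) {
  if (is_zero_var(x) || is_zero_var(y)) {
    warning("zero-variance map encountered; correlation set to 0", call. = FALSE)
    return(0)
  }
  stats::cor(x, y)
}

stopifnot_scalar <- function(x, name, positive = TRUE, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be positive", name), call. = FALSE)
  if (integerish && x != round(x))
    stop(sprintf("`%s` must be a whole number", name), call. = FALSE)
  invisible(x)
}
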