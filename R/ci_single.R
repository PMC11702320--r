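.make_ci <- function(method, estimate, lower, upper, level,
                     na = FALSE, na_reason = "") {
  structure(list(method = method,
                 estimate = if (na) NA_real_ else estimate,
                 lower = if (na) NA_real_ else lower,
                 upper = if (na) NA_real_ else upper,
                 level = level, na = na, na_reason = na_reason),
            class = "mcc_ci")
}

#' @export
print.mcc_ci <- function(x, ...) {
  cat(sprintf("%s %g%% confidence interval\n", x$method, 100 * x$level))
  if (x$na) {
    cat("  NA (", x$na_reason, ")\n", sep = "")
  } else {
    cat(sprintf("  estimate %.6g, interval [%.6g, %.6g]\n",
                x$estimate, x$lower, x$upper))
  }
  invisible(x)
}

.check_level <- function(level) {
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1)
    stop("level must be a probability in (0, 1)", call. = FALSE)
  stats::qnorm(1 - (1 - level) / 2)
}

.phat <- function(counts) as.numeric(counts) / attr(counts, "n")

#' Confidence intervals for a single MCC
#'
#' Three asymptotic interval constructions for the MCC of one binary
#' classifier, all based on the multinomial central limit theorem for the
#' 2x2 cell proportions:
#' \describe{
#'   \item{`simple_ci()`}{the direct delta-method (Wald) interval
#'     \eqn{\widehat{\mathrm{MCC}} \pm z_{\alpha/2}
#'     \sqrt{\nabla\varphi^T \Sigma \nabla\varphi / n}}. Symmetric; its limits
#'     are not truncated to \eqn{[-1,1]}, since the unconstrained normal
#'     interval is the method being characterized.}
#'   \item{`fisher_ci()`}{Fisher's z transformation with a delta-method
#'     variance: the interval is built on the artanh scale and mapped back
#'     through tanh, so it is asymmetric around the estimate and always lies
#'     inside \eqn{(-1, 1)}.}
#'   \item{`naive_fisher_ci()`}{Fisher's z transformation with the
#'     normal-theory variance \eqn{1/(n-3)}. That variance presumes bivariate
#'     normal data and is unreliable for binary data; the method is included
#'     as the comparison baseline.}
#' }
#'
#' The interval is `NA` (with a reason) when the MCC itself is undefined
#' (a zero margin), when the plug-in variance degenerates to zero, or — for
#' the two transformed methods — when \eqn{|\widehat{\mathrm{MCC}}| = 1},
#' where artanh diverges.
#'
#' @param counts A [confusion_counts()] object.
#' @param level Confidence level in (0, 1); default 0.95.
#' @return An object of class `mcc_ci` with fields `method`, `estimate`,
#'   `lower`, `upper`, `level`, `na`, `na_reason`.
#' @examples
#' x <- confusion_counts(35, 15, 15, 35)
#' simple_ci(x)
#' fisher_ci(x)
#' naive_fisher_ci(x)
#' @export
simple_ci <- function(counts, level = 0.95) {
  z <- .check_level(level)
  n <- attr(counts, "n")
  if (n < 2) stop("need n >= 2", call. = FALSE)
  p <- .phat(counts)
  est <- .mcc_of_cells(p)
  if (is.na(est))
    return(.make_ci("simple", NA, NA, NA, level, TRUE, "zero margin"))
  v <- delta_variance(grad_phi(p), multinomial_cov(p))
  if (!is.finite(v) || v == 0)
    return(.make_ci("simple", est, NA, NA, level, TRUE, "zero variance"))
  hw <- z * sqrt(v / n)
  .make_ci("simple", est, est - hw, est + hw, level)
}

#' @rdname simple_ci
#' @export
fisher_ci <- function(counts, level = 0.95) {
  z <- .check_level(level)
  n <- attr(counts, "n")
  if (n < 2) stop("need n >= 2", call. = FALSE)
  p <- .phat(counts)
  est <- .mcc_of_cells(p)
  if (is.na(est))
    return(.make_ci("fisher", NA, NA, NA, level, TRUE, "zero margin"))
  if (abs(est) >= 1)
    return(.make_ci("fisher", est, NA, NA, level, TRUE, "MCC equals 1 in absolute value"))
  v <- delta_variance(grad_fisher_phi(p), multinomial_cov(p))
  if (!is.finite(v) || v == 0)
    return(.make_ci("fisher", est, NA, NA, level, TRUE, "zero variance"))
  hw <- z * sqrt(v / n)
  .make_ci("fisher", est, tanh(atanh(est) - hw), tanh(atanh(est) + hw), level)
}

#' @rdname simple_ci
#' @export
naive_fisher_ci <- function(counts, level = 0.95) {
  z <- .check_level(level)
  n <- attr(counts, "n")
  if (n < 4) stop("the 1/(n-3) variance needs n >= 4", call. = FALSE)
  p <- .phat(counts)
  est <- .mcc_of_cells(p)
  if (is.na(est))
    return(.make_ci("naive", NA, NA, NA, level, TRUE, "zero margin"))
  if (abs(est) >= 1)
    return(.make_ci("naive", est, NA, NA, level, TRUE, "MCC equals 1 in absolute value"))
  hw <- z * sqrt(1 / (n - 3))
  .make_ci("naive", est, tanh(atanh(est) - hw), tanh(atanh(est) + hw), level)
}

#' @rdname simple_ci
#' @param method One of `"fisher"`, `"simple"`, `"naive"`.
#' @export
mcc_ci <- function(counts, method = c("fisher", "simple", "naive"),
                   level = 0.95) {
  method <- match.arg(method)
  switch(method,
         fisher = fisher_ci(counts, level),
         simple = simple_ci(counts, level),
         naive  = naive_fisher_ci(counts, level))
}

.mcc_of_cells <- function(p) {
  m <- .margins(p)
  if (any(m == 0)) return(NA_real_)
  if (p[2] == 0 && p[3] == 0) return(1)
  if (p[1] == 0 && p[4] == 0) return(-1)
  min(1, max(-1, (p[1] * p[4] - p[2] * p[3]) / sqrt(prod(m))))
}
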