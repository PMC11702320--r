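#' Joint estimate for two MCCs in a paired design
#'
#' From a 2x2x2 table of two classifiers evaluated on the same subjects,
#' computes each classifier's MCC, the difference, the delta-method
#' variance-covariance of the pair (via the 8x2 Jacobian of
#' \eqn{(\varphi(m_1), \varphi(m_2))} against the 8-cell multinomial
#' covariance, divided by n), and the implied correlation of the two
#' estimates, clamped to \eqn{[-1, 1]}.
#'
#' @param counts A [paired_counts()] object.
#' @return An object of class `paired_mcc_estimate`: a list with `r1`, `r2`,
#'   `diff`, `var1`, `var2`, `cov12`, `corr`, `n`, `na`, `na_reason`.
#' @examples
#' pc <- paired_counts(c(p111 = 40, p110 = 5, p101 = 5, p100 = 3,
#'                       p011 = 2, p010 = 4, p001 = 1, p000 = 40))
#' paired_estimate(pc)
#' @export
paired_estimate <- function(counts) {
  n <- attr(counts, "n")
  p <- as.numeric(counts) / n
  m <- .paired_marginals(p)
  out <- list(r1 = NA_real_, r2 = NA_real_, diff = NA_real_,
              var1 = NA_real_, var2 = NA_real_, cov12 = NA_real_,
              corr = NA_real_, n = n, na = FALSE, na_reason = "")
  if (any(.margins(m$m1) == 0) || any(.margins(m$m2) == 0)) {
    out$na <- TRUE; out$na_reason <- "zero margin in a marginal table"
    return(structure(out, class = "paired_mcc_estimate"))
  }
  out$r1 <- .mcc_of_cells(m$m1)
  out$r2 <- .mcc_of_cells(m$m2)
  out$diff <- out$r1 - out$r2
  V <- delta_variance(grad_psi_tilde(p), multinomial_cov(p)) / n
  out$var1 <- max(0, V[1, 1]); out$var2 <- max(0, V[2, 2]); out$cov12 <- V[1, 2]
  out$corr <- if (out$var1 > 0 && out$var2 > 0)
    min(1, max(-1, out$cov12 / sqrt(out$var1 * out$var2))) else NA_real_
  structure(out, class = "paired_mcc_estimate")
}

#' @export
print.paired_mcc_estimate <- function(x, ...) {
  cat("Paired MCC estimate (n =", x$n, ")\n")
  if (x$na) {
    cat("  NA (", x$na_reason, ")\n", sep = "")
  } else {
    cat(sprintf("  MCC1 %.6g (var %.3g), MCC2 %.6g (var %.3g)\n",
                x$r1, x$var1, x$r2, x$var2))
    cat(sprintf("  difference %.6g, estimated correlation %.4g\n",
                x$diff, x$corr))
  }
  invisible(x)
}

#' Confidence intervals for the difference of two paired MCCs
#'
#' Three asymptotic intervals for \eqn{\mathrm{MCC}_1 - \mathrm{MCC}_2} when
#' both classifiers are evaluated on the same subjects (so the two estimates
#' are correlated through the shared 8-cell multinomial):
#' \describe{
#'   \item{`simple_diff_ci()`}{delta method applied directly to the
#'     difference functional \eqn{\psi}; a symmetric Wald interval.}
#'   \item{`zou_ci()`}{a MOVER-style interval: Fisher's z marginal intervals
#'     \eqn{(\ell_l, u_l)} for each MCC (at the same level) are recombined as
#'     \deqn{L = \hat r_1 - \hat r_2 - \sqrt{(\hat r_1-\ell_1)^2 +
#'       (u_2-\hat r_2)^2 - 2\hat\rho(\hat r_1-\ell_1)(u_2-\hat r_2)}}
#'     and symmetrically for \eqn{U}, with \eqn{\hat\rho} the delta-method
#'     correlation of the two estimates (not the bivariate-normal
#'     approximation, which binary data violate). Negative radicands arising
#'     from floating error are clipped at 0.}
#'   \item{`mt_ci()`}{the difference, which lives in \eqn{(-2,2)}, is mapped
#'     through \eqn{g(x) = \tfrac12\log\{(2+x)/(2-x)\}}, given a Wald interval
#'     on that scale with the delta variance of \eqn{g\circ\psi}, and mapped
#'     back through \eqn{2\tanh}; limits stay inside \eqn{(-2, 2)}.}
#' }
#'
#' Intervals are `NA` when either marginal table has a zero margin, when the
#' relevant variance degenerates to zero (e.g. two identical prediction
#' columns, where the normal approximation is vacuous), for `zou_ci()`
#' additionally when a marginal \eqn{|\widehat{\mathrm{MCC}}| = 1}, and for
#' `mt_ci()` when the difference sits at the boundary \eqn{\pm 2}.
#'
#' @param counts A [paired_counts()] object.
#' @param level Confidence level in (0, 1); default 0.95.
#' @return An object of class `mcc_ci`.
#' @examples
#' pc <- paired_counts(c(p111 = 40, p110 = 5, p101 = 5, p100 = 3,
#'                       p011 = 2, p010 = 4, p001 = 1, p000 = 40))
#' mt_ci(pc)
#' zou_ci(pc)
#' @export
simple_diff_ci <- function(counts, level = 0.95) {
  z <- .check_level(level)
  est <- paired_estimate(counts)
  if (est$na)
    return(.make_ci("simple", NA, NA, NA, level, TRUE, est$na_reason))
  p <- as.numeric(counts) / est$n
  v <- delta_variance(grad_psi(p), multinomial_cov(p))
  if (!is.finite(v) || v == 0)
    return(.make_ci("simple", est$diff, NA, NA, level, TRUE, "zero variance"))
  hw <- z * sqrt(v / est$n)
  .make_ci("simple", est$diff, est$diff - hw, est$diff + hw, level)
}

#' @rdname simple_diff_ci
#' @export
zou_ci <- function(counts, level = 0.95) {
  .check_level(level)
  est <- paired_estimate(counts)
  if (est$na)
    return(.make_ci("zou", NA, NA, NA, level, TRUE, est$na_reason))
  ci1 <- fisher_ci(marginalize(counts, 1), level)
  ci2 <- fisher_ci(marginalize(counts, 2), level)
  if (ci1$na || ci2$na) {
    reason <- paste0("marginal Fisher interval undefined (",
                     if (ci1$na) ci1$na_reason else ci2$na_reason, ")")
    return(.make_ci("zou", est$diff, NA, NA, level, TRUE, reason))
  }
  rho <- est$corr
  if (is.na(rho))
    return(.make_ci("zou", est$diff, NA, NA, level, TRUE, "degenerate variance"))
  dl <- est$r1 - ci1$lower; du2 <- ci2$upper - est$r2
  ul <- ci1$upper - est$r1; dl2 <- est$r2 - ci2$lower
  radL <- max(0, dl^2 + du2^2 - 2 * rho * dl * du2)
  radU <- max(0, ul^2 + dl2^2 - 2 * rho * ul * dl2)
  .make_ci("zou", est$diff, est$diff - sqrt(radL), est$diff + sqrt(radU), level)
}

#' @rdname simple_diff_ci
#' @export
mt_ci <- function(counts, level = 0.95) {
  z <- .check_level(level)
  est <- paired_estimate(counts)
  if (est$na)
    return(.make_ci("mt", NA, NA, NA, level, TRUE, est$na_reason))
  if (abs(est$diff) >= 2)
    return(.make_ci("mt", est$diff, NA, NA, level, TRUE, "difference at boundary"))
  p <- as.numeric(counts) / est$n
  v <- delta_variance(grad_g_psi(p), multinomial_cov(p))
  if (!is.finite(v) || v == 0)
    return(.make_ci("mt", est$diff, NA, NA, level, TRUE, "zero variance"))
  hw <- z * sqrt(v / est$n)
  gd <- mt_transform(est$diff)
  .make_ci("mt", est$diff, mt_transform_inv(gd - hw), mt_transform_inv(gd + hw),
           level)
}

#' @rdname simple_diff_ci
#' @param method One of `"mt"`, `"zou"`, `"simple"`.
#' @export
mcc_diff_ci <- function(counts, method = c("mt", "zou", "simple"),
                        level = 0.95) {
  method <- match.arg(method)
  switch(method,
         mt = mt_ci(counts, level),
         zou = zou_ci(counts, level),
         simple = simple_diff_ci(counts, level))
}
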