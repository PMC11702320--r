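# Delta-method machinery. Gradients are of the formulas viewed as functions on
# an open box around the probability simplex (no tangent-space projection); the
# multinomial covariance already carries the sum-to-one degeneracy, so the
# quadratic form is the standard asymptotic variance.

#' Multinomial covariance matrix
#'
#' Covariance of the cell-proportion estimator \eqn{\hat p} scaled by
#' \eqn{\sqrt n}: diagonal \eqn{p_a(1-p_a)}, off-diagonal \eqn{-p_a p_b}.
#'
#' @param p A [cell_probs()] or [paired_cell_probs()] object (or bare
#'   probability vector summing to 1).
#' @return A symmetric positive semidefinite matrix whose rows sum to zero.
#' @examples
#' multinomial_cov(cell_probs(0.25, 0.25, 0.25, 0.25))
#' @export
multinomial_cov <- function(p) {
  p <- as.numeric(p)
  S <- -tcrossprod(p)
  diag(S) <- p * (1 - p)
  S
}

.margins <- function(p) c(p[1] + p[2], p[1] + p[3], p[4] + p[2], p[4] + p[3])

#' Gradient of the MCC as a function of the four cell probabilities
#'
#' Analytic gradient of
#' \eqn{\varphi(p) = (p_{11}p_{00} - p_{10}p_{01}) / \sqrt{m_1 m_2 m_3 m_4}}
#' with margins \eqn{m_1 = p_{11}+p_{10}} (predicted positive),
#' \eqn{m_2 = p_{11}+p_{01}} (actual positive), \eqn{m_3 = p_{00}+p_{10}},
#' \eqn{m_4 = p_{00}+p_{01}}, obtained by the quotient rule:
#' \deqn{\partial_{p_{11}}\varphi = p_{00}/D - \tfrac{\varphi}{2}(1/m_1 + 1/m_2)}
#' and symmetrically for the other cells, where \eqn{D = \sqrt{m_1m_2m_3m_4}}.
#'
#' @param p A [cell_probs()] object (or vector in `(p11, p10, p01, p00)` order).
#'   All four margins must be positive.
#' @return Numeric gradient of length 4, ordered as `p`.
#' @export
grad_phi <- function(p) {
  p <- as.numeric(p)
  m <- .margins(p)
  if (any(m <= 0)) stop("all four margins must be positive", call. = FALSE)
  D <- sqrt(prod(m))
  phi <- (p[1] * p[4] - p[2] * p[3]) / D
  c(p[4] / D - phi / 2 * (1 / m[1] + 1 / m[2]),
    -p[3] / D - phi / 2 * (1 / m[1] + 1 / m[3]),
    -p[2] / D - phi / 2 * (1 / m[2] + 1 / m[4]),
    p[1] / D - phi / 2 * (1 / m[3] + 1 / m[4]))
}

#' Gradient of the Fisher-transformed MCC
#'
#' Chain rule: \eqn{\nabla (f\circ\varphi)(p) = \nabla\varphi(p) /
#' (1 - \varphi(p)^2)} with \eqn{f = \mathrm{artanh}}.
#'
#' @inheritParams grad_phi
#' @return Numeric gradient of length 4.
#' @export
grad_fisher_phi <- function(p) {
  phi <- mcc(cell_probs(p[[1]], p[[2]], p[[3]], p[[4]]))
  if (is.na(phi) || abs(phi) >= 1)
    stop("|MCC| must be < 1 for the Fisher transform", call. = FALSE)
  grad_phi(p) / (1 - phi^2)
}

.paired_marginals <- function(p) {
  list(m1 = drop(.J1 %*% as.numeric(p)), m2 = drop(.J2 %*% as.numeric(p)))
}

#' Gradients for paired-design MCC functionals
#'
#' For the 8-cell joint probability vector \eqn{p} of two classifiers on the
#' same subjects, `grad_psi()` differentiates the MCC difference
#' \eqn{\psi(p) = \varphi(m_1(p)) - \varphi(m_2(p))},
#' `grad_psi_tilde()` returns the 8x2 Jacobian of the pair
#' \eqn{(\varphi(m_1), \varphi(m_2))} (one column per classifier), and
#' `grad_g_psi()` differentiates the transformed difference
#' \eqn{g(\psi(p))}, using \eqn{g'(x) = 2/(4 - x^2)}.
#' Here \eqn{m_l(p)} is the linear marginalization onto classifier `l`'s
#' 2x2 table, so each gradient is \eqn{J_l^T \nabla\varphi(m_l)} composed
#' by linearity.
#'
#' @param p A [paired_cell_probs()] object (or length-8 vector in canonical
#'   cell order); both marginal tables must have positive margins.
#' @return `grad_psi` and `grad_g_psi`: numeric length-8 gradients;
#'   `grad_psi_tilde`: an 8x2 matrix.
#' @export
grad_psi <- function(p) {
  G <- grad_psi_tilde(p)
  drop(G[, 1] - G[, 2])
}

#' @rdname grad_psi
#' @export
grad_psi_tilde <- function(p) {
  m <- .paired_marginals(p)
  cbind(drop(crossprod(.J1, grad_phi(m$m1))),
        drop(crossprod(.J2, grad_phi(m$m2))))
}

#' @rdname grad_psi
#' @export
grad_g_psi <- function(p) {
  m <- .paired_marginals(p)
  psi <- mcc(cell_probs(m$m1[1], m$m1[2], m$m1[3], m$m1[4])) -
    mcc(cell_probs(m$m2[1], m$m2[2], m$m2[3], m$m2[4]))
  if (is.na(psi) || abs(psi) >= 2)
    stop("|MCC difference| must be < 2 for the transform", call. = FALSE)
  grad_psi(p) * 2 / (4 - psi^2)
}

#' Delta-method variance (quadratic form against the multinomial covariance)
#'
#' @param grad A gradient vector, or a matrix with one gradient per column
#'   (as returned by [grad_psi_tilde()]).
#' @param cov A covariance matrix from [multinomial_cov()].
#' @return For a vector gradient, the scalar \eqn{\nabla^T \Sigma \nabla}
#'   (tiny negative values from floating-point cancellation are clipped to 0);
#'   for a matrix gradient, the corresponding covariance matrix.
#' @export
delta_variance <- function(grad, cov) {
  grad <- as.matrix(grad)
  if (nrow(grad) != nrow(cov)) stop("gradient/covariance shape mismatch", call. = FALSE)
  V <- crossprod(grad, cov %*% grad)
  if (length(V) == 1L) {
    v <- V[1, 1]
    if (v < 0) {
      if (v < -1e-12) stop("negative quadratic form beyond tolerance", call. = FALSE)
      v <- 0
    }
    return(v)
  }
  (V + t(V)) / 2
}

#' Central finite-difference gradient (test oracle)
#'
#' Differentiates a scalar function of a probability vector coordinate by
#' coordinate with central differences, without renormalizing onto the
#' simplex — matching the convention under which the analytic gradients are
#' derived.
#'
#' @param func A function taking a numeric vector and returning a scalar.
#' @param p Point of evaluation.
#' @param h Step size.
#' @return Numeric gradient of `length(p)`.
#' @export
fd_gradient <- function(func, p, h = 1e-6) {
  p <- as.numeric(p)
  vapply(seq_along(p), function(a) {
    up <- p; up[a] <- up[a] + h
    dn <- p; dn[a] <- dn[a] - h
    (func(up) - func(dn)) / (2 * h)
  }, numeric(1))
}

# Raw phi on an unnormalized/unconstrained 4-vector (used by the fd oracle and
# internal code paths where constructing a cell_probs object would reject
# points off the simplex).
.phi_raw <- function(p) {
  m <- .margins(p)
  (p[1] * p[4] - p[2] * p[3]) / sqrt(prod(m))
}

.psi_raw <- function(p) {
  .phi_raw(drop(.J1 %*% p)) - .phi_raw(drop(.J2 %*% p))
}
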