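# Partial identification of the 2x2x2 joint distribution of two paired
# classifiers when only marginal performance is reported. Sensitivities and
# specificities pin down the within-class margins; the two remaining degrees
# of freedom are p001 (both classifiers miss a positive) and p110 (both call
# a negative positive). Every completion of the joint table is a point in the
# feasibility box, and the MCC difference is the same at every point (the
# marginals are fixed) while the interval width is not.

#' Marginal performance summary of two paired classifiers
#'
#' @param n_pos,n_neg Numbers of truly positive and truly negative subjects.
#' @param sens1,spec1,sens2,spec2 Reported sensitivity and specificity of
#'   each classifier.
#' @return An object of class `marginal_summary`.
#' @examples
#' marginal_summary(200, 200, sens1 = 0.80, spec1 = 0.85,
#'                  sens2 = 0.76, spec2 = 0.79)
#' @export
marginal_summary <- function(n_pos, n_neg, sens1, spec1, sens2, spec2) {
  if (n_pos < 1 || n_neg < 1) stop("need at least one subject per class", call. = FALSE)
  pr <- c(sens1, spec1, sens2, spec2)
  if (any(pr < 0 | pr > 1)) stop("sensitivities/specificities must be in [0, 1]",
                                 call. = FALSE)
  structure(list(n_pos = n_pos, n_neg = n_neg,
                 sens1 = sens1, spec1 = spec1, sens2 = sens2, spec2 = spec2,
                 prevalence = n_pos / (n_pos + n_neg)),
            class = "marginal_summary")
}

#' Feasibility box for the two free joint-cell probabilities
#'
#' Given marginal sensitivities and specificities, the joint cells are linear
#' in the two free parameters and nonnegativity of all eight cells confines
#' them to a rectangle:
#' \deqn{p_{001} \in [\max(0, \pi(1 - s_1 - s_2)),\ \pi \min(1-s_1, 1-s_2)]}
#' \deqn{p_{110} \in [\max(0, (1-\pi)(1 - t_1 - t_2)),\ (1-\pi)\min(1-t_1, 1-t_2)]}
#' with \eqn{\pi} the prevalence, \eqn{s_l} sensitivities, \eqn{t_l}
#' specificities.
#'
#' @param marg A [marginal_summary()] object.
#' @return An object of class `feasible_box`: list with `p001_min`,
#'   `p001_max`, `p110_min`, `p110_max`.
#' @export
feasible_box <- function(marg) {
  pi <- marg$prevalence
  box <- list(
    p001_min = max(0, pi * (1 - marg$sens1 - marg$sens2)),
    p001_max = pi * min(1 - marg$sens1, 1 - marg$sens2),
    p110_min = max(0, (1 - pi) * (1 - marg$spec1 - marg$spec2)),
    p110_max = (1 - pi) * min(1 - marg$spec1, 1 - marg$spec2)
  )
  if (box$p001_min > box$p001_max + 1e-12 || box$p110_min > box$p110_max + 1e-12)
    stop("marginals admit no nonnegative joint distribution", call. = FALSE)
  structure(box, class = "feasible_box")
}

#' Reconstruct the 2x2x2 joint distribution from marginals and free cells
#'
#' Completes the joint table from the marginal summary plus chosen values of
#' the free cells: on the positive class,
#' \eqn{p_{111} = \pi(s_1 + s_2 - 1) + p_{001}},
#' \eqn{p_{101} = \pi(1 - s_2) - p_{001}},
#' \eqn{p_{011} = \pi(1 - s_1) - p_{001}}; on the negative class the
#' analogous identities with specificities and \eqn{p_{110}}.
#'
#' @param marg A [marginal_summary()] object.
#' @param p001 P(both classifiers predict 0, Y = 1).
#' @param p110 P(both classifiers predict 1, Y = 0).
#' @return A [paired_cell_probs()] object.
#' @export
reconstruct_joint <- function(marg, p001, p110) {
  pi <- marg$prevalence
  s1 <- marg$sens1; s2 <- marg$sens2; t1 <- marg$spec1; t2 <- marg$spec2
  cells <- c(
    p111 = pi * (s1 + s2 - 1) + p001,
    p110 = p110,
    p101 = pi * (1 - s2) - p001,
    p100 = (1 - pi) * (1 - t1) - p110,
    p011 = pi * (1 - s1) - p001,
    p010 = (1 - pi) * (1 - t2) - p110,
    p001 = p001,
    p000 = (1 - pi) * (t1 + t2 - 1) + p110
  )
  neg <- which(cells < -1e-12)
  if (length(neg))
    stop("(p001, p110) outside the feasibility box: cell ", names(cells)[neg[1]],
         " would be ", format(cells[neg[1]]), call. = FALSE)
  cells <- pmax(cells, 0)
  paired_cell_probs(cells / sum(cells))
}

#' Sweep the MT interval for the MCC difference over the feasibility box
#'
#' Evaluates the modified-transformation confidence interval for
#' \eqn{\mathrm{MCC}_1 - \mathrm{MCC}_2} at every grid point of the free
#' cells \eqn{(p_{001}, p_{110})}, treating the reconstructed cells as exact
#' plug-in probabilities with effective sample size `n_pos + n_neg`. The
#' point estimate of the difference is the same at every grid point (it is
#' identified by the marginals); the interval width is not, which is what the
#' sweep exposes.
#'
#' @param marg A [marginal_summary()] object.
#' @param p001_step,p110_step Grid increments; both range endpoints are
#'   always included.
#' @param level Confidence level; default 0.95.
#' @return A `data.frame` with columns `p001`, `p110`, `diff`, `lower`,
#'   `upper`, `excludes_zero`.
#' @export
mt_grid <- function(marg, p001_step = 0.025, p110_step = 0.001, level = 0.95) {
  if (p001_step <= 0 || p110_step <= 0) stop("steps must be positive", call. = FALSE)
  box <- feasible_box(marg)
  n <- marg$n_pos + marg$n_neg
  grid1 <- .closed_seq(box$p001_min, box$p001_max, p001_step)
  grid2 <- .closed_seq(box$p110_min, box$p110_max, p110_step)
  pts <- expand.grid(p001 = grid1, p110 = grid2, KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(pts)), function(i) {
    p <- reconstruct_joint(marg, pts$p001[i], pts$p110[i])
    ci <- .mt_ci_from_probs(as.numeric(p), n, level)
    data.frame(p001 = pts$p001[i], p110 = pts$p110[i], diff = ci$estimate,
               lower = ci$lower, upper = ci$upper,
               excludes_zero = !ci$na && (ci$lower > 0 || ci$upper < 0))
  })
  do.call(rbind, res)
}

.closed_seq <- function(from, to, by) {
  if (to - from < by) return(unique(c(from, to)))
  s <- seq(from, to, by = by)
  if (abs(s[length(s)] - to) > 1e-12) s <- c(s, to)
  s
}

# MT interval from plug-in joint probabilities and an effective sample size.
.mt_ci_from_probs <- function(p, n, level = 0.95) {
  z <- .check_level(level)
  m <- .paired_marginals(p)
  if (any(.margins(m$m1) == 0) || any(.margins(m$m2) == 0))
    return(.make_ci("mt", NA, NA, NA, level, TRUE, "zero margin in a marginal table"))
  diff <- .mcc_of_cells(m$m1) - .mcc_of_cells(m$m2)
  if (abs(diff) >= 2)
    return(.make_ci("mt", diff, NA, NA, level, TRUE, "difference at boundary"))
  v <- delta_variance(grad_g_psi(p), multinomial_cov(p))
  if (!is.finite(v) || v == 0)
    return(.make_ci("mt", diff, NA, NA, level, TRUE, "zero variance"))
  hw <- z * sqrt(v / n)
  gd <- mt_transform(diff)
  .make_ci("mt", diff, mt_transform_inv(gd - hw), mt_transform_inv(gd + hw),
           level)
}
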