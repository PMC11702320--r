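# Coverage simulation engine. Everything is vectorized over replicates:
# counts come out of rmultinom() as a cells-by-replicates matrix, and the MCC,
# gradients and delta variances are evaluated with closed-form columnwise
# arithmetic, so a million replicates cost a few seconds.
#
# For a k-cell multinomial, the quadratic form g' S(p) g collapses to
#   sum_a p_a g_a^2 - (sum_a p_a g_a)^2,
# which is what the columnwise code computes.

.CHUNK_SIZE <- 200000L  # fixed so results depend only on (seed, n, m)

#' Construct a single-classifier simulation scenario
#'
#' Builds the 2x2 cell probabilities for a classifier with prevalence
#' \eqn{\pi = P(Y=1)} and a target true MCC, under the balance constraint
#' TP/FN = TN/FP, which forces sensitivity = specificity = s. The cells are
#' then \eqn{(p_{11}, p_{10}, p_{01}, p_{00}) = (\pi s, (1-\pi)(1-s),
#' \pi(1-s), (1-\pi)s)} and s solves
#' \deqn{\frac{\pi(1-\pi)(2s-1)}{\sqrt{\pi(1-\pi)\,m_1 m_4}} = \rho}
#' by bisection on \eqn{s \in (1/2, 1)} (at \eqn{\pi = 1/2} the closed form
#' is \eqn{s = (1+\rho)/2}).
#'
#' @param prevalence \eqn{P(Y = 1)}, in (0, 1).
#' @param true_mcc Target population MCC, in (0, 1).
#' @return An object of class `mcc_scenario`: list with `prevalence`,
#'   `true_mcc`, `s` (the implied sensitivity = specificity) and `cells`
#'   (a [cell_probs()] vector).
#' @examples
#' single_scenario(0.5, 0.4)  # s = 0.7, cells (0.35, 0.15, 0.15, 0.35)
#' @export
single_scenario <- function(prevalence, true_mcc) {
  if (prevalence <= 0 || prevalence >= 1)
    stop("prevalence must be in (0, 1)", call. = FALSE)
  if (true_mcc <= 0 || true_mcc >= 1)
    stop("true_mcc must be in (0, 1)", call. = FALSE)
  pi <- prevalence
  phi_of_s <- function(s) {
    m1 <- pi * s + (1 - pi) * (1 - s)
    m4 <- (1 - pi) * s + pi * (1 - s)
    pi * (1 - pi) * (2 * s - 1) / sqrt(pi * (1 - pi) * m1 * m4)
  }
  lo <- 0.5; hi <- 1 - 1e-15
  if (phi_of_s(hi) < true_mcc)
    stop("no sensitivity in (0.5, 1) attains this MCC at this prevalence",
         call. = FALSE)
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    if (phi_of_s(mid) < true_mcc) lo <- mid else hi <- mid
    if (hi - lo < 1e-16) break
  }
  s <- (lo + hi) / 2
  cells <- cell_probs(pi * s, (1 - pi) * (1 - s), pi * (1 - s), (1 - pi) * s)
  stopifnot(abs(mcc(cells) - true_mcc) <= 1e-10)
  structure(list(prevalence = pi, true_mcc = true_mcc, s = s, cells = cells),
            class = "mcc_scenario")
}

#' Construct a paired-design simulation scenario
#'
#' Parametrizes the 2x2x2 joint distribution of two classifiers sharing the
#' same subjects by each classifier's sensitivity and specificity plus two
#' agreement probabilities: `agree_pos` = P(both predict 1 | Y = 1) and
#' `agree_neg` = P(both predict 0 | Y = 0). These must respect the Frechet
#' bounds, e.g. \eqn{\max(0, s_1 + s_2 - 1) \le} `agree_pos`
#' \eqn{\le \min(s_1, s_2)}. Independence within each class corresponds to
#' `agree_pos = sens1 * sens2`, `agree_neg = spec1 * spec2`.
#'
#' @param prevalence \eqn{P(Y = 1)}.
#' @param sens1,spec1,sens2,spec2 Marginal sensitivities and specificities.
#' @param agree_pos,agree_neg Within-class joint agreement probabilities.
#' @return An object of class `paired_mcc_scenario`: list with the inputs,
#'   `cells` (a [paired_cell_probs()] vector) and the implied `true_mcc1`,
#'   `true_mcc2`, `true_diff`.
#' @examples
#' sc <- single_scenario(0.5, 0.6)
#' paired_scenario(0.5, sc$s, sc$s, 0.7, 0.7,
#'                 agree_pos = sc$s * 0.7, agree_neg = sc$s * 0.7)
#' @export
paired_scenario <- function(prevalence, sens1, spec1, sens2, spec2,
                            agree_pos, agree_neg) {
  pi <- prevalence
  probs <- c(pi, sens1, spec1, sens2, spec2, agree_pos, agree_neg)
  if (any(probs < 0 | probs > 1) || pi <= 0 || pi >= 1)
    stop("all arguments must be probabilities; prevalence strictly inside (0,1)",
         call. = FALSE)
  tol <- 1e-12
  if (agree_pos < max(0, sens1 + sens2 - 1) - tol ||
      agree_pos > min(sens1, sens2) + tol)
    stop("agree_pos violates its Frechet bounds [",
         format(max(0, sens1 + sens2 - 1)), ", ", format(min(sens1, sens2)),
         "]", call. = FALSE)
  if (agree_neg < max(0, spec1 + spec2 - 1) - tol ||
      agree_neg > min(spec1, spec2) + tol)
    stop("agree_neg violates its Frechet bounds [",
         format(max(0, spec1 + spec2 - 1)), ", ", format(min(spec1, spec2)),
         "]", call. = FALSE)
  cl <- function(x) min(1, max(0, x))
  cells <- c(
    p111 = pi * cl(agree_pos),
    p110 = (1 - pi) * cl(1 - spec1 - spec2 + agree_neg),
    p101 = pi * cl(sens1 - agree_pos),
    p100 = (1 - pi) * cl(spec2 - agree_neg),
    p011 = pi * cl(sens2 - agree_pos),
    p010 = (1 - pi) * cl(spec1 - agree_neg),
    p001 = pi * cl(1 - sens1 - sens2 + agree_pos),
    p000 = (1 - pi) * cl(agree_neg)
  )
  cells <- paired_cell_probs(cells / sum(cells))
  r1 <- mcc(marginalize(cells, 1))
  r2 <- mcc(marginalize(cells, 2))
  structure(list(prevalence = pi, sens1 = sens1, spec1 = spec1,
                 sens2 = sens2, spec2 = spec2,
                 agree_pos = agree_pos, agree_neg = agree_neg,
                 cells = cells, true_mcc1 = r1, true_mcc2 = r2,
                 true_diff = r1 - r2),
            class = "paired_mcc_scenario")
}

# --- columnwise statistics ---------------------------------------------------

# P: 4 x m matrix of cell proportions (rows p11, p10, p01, p00).
# Returns columnwise mcc, delta variance of phi and of f.phi, and margin flag.
.col_phi_stats <- function(P) {
  p11 <- P[1, ]; p10 <- P[2, ]; p01 <- P[3, ]; p00 <- P[4, ]
  m1 <- p11 + p10; m2 <- p11 + p01; m3 <- p00 + p10; m4 <- p00 + p01
  ok <- m1 > 0 & m2 > 0 & m3 > 0 & m4 > 0
  D <- sqrt(m1 * m2 * m3 * m4)
  r <- ifelse(ok, (p11 * p00 - p10 * p01) / D, NA_real_)
  r <- pmin(1, pmax(-1, r))
  # |MCC| = 1 exactly iff both off-diagonal (or both diagonal) cells are
  # empty; detect structurally so the artanh omission rule is exact
  r[ok & p10 == 0 & p01 == 0] <- 1
  r[ok & p11 == 0 & p00 == 0] <- -1
  g11 <- p00 / D - r / 2 * (1 / m1 + 1 / m2)
  g10 <- -p01 / D - r / 2 * (1 / m1 + 1 / m3)
  g01 <- -p10 / D - r / 2 * (1 / m2 + 1 / m4)
  g00 <- p11 / D - r / 2 * (1 / m3 + 1 / m4)
  s1 <- p11 * g11 + p10 * g10 + p01 * g01 + p00 * g00
  s2 <- p11 * g11^2 + p10 * g10^2 + p01 * g01^2 + p00 * g00^2
  v <- pmax(0, s2 - s1^2)
  list(ok = ok, mcc = r, var_phi = v, var_fisher = v / (1 - r^2)^2,
       g = rbind(g11, g10, g01, g00))
}

.chunk_streams <- function(seed, n_chunks) {
  s0 <- local({
    set.seed(seed, kind = "L'Ecuyer-CMRG")
    get(".Random.seed", envir = globalenv())
  })
  streams <- vector("list", n_chunks)
  for (i in seq_len(n_chunks)) {
    streams[[i]] <- s0
    s0 <- parallel::nextRNGStream(s0)
  }
  streams
}

.with_stream <- function(stream, expr) {
  assign(".Random.seed", stream, envir = globalenv())
  expr
}

.coverage_row <- function(method, n, m, n_na, n_cover, sum_width, seed) {
  defined <- m - n_na
  cov <- if (defined > 0) n_cover / defined else NA_real_
  data.frame(method = method, n = n, m = m, n_na = n_na,
             coverage = cov,
             mc_se = if (defined > 0) sqrt(cov * (1 - cov) / defined) else NA_real_,
             mean_width = if (defined > 0) sum_width / defined else NA_real_,
             seed = seed, stringsAsFactors = FALSE)
}

#' Monte-Carlo coverage study for MCC confidence intervals
#'
#' Draws `m` multinomial samples of size `n` from a scenario's true cell
#' probabilities, builds the requested confidence intervals for every
#' replicate, and estimates each method's coverage of the true MCC (or true
#' MCC difference) conditional on the interval being defined. Replicates
#' where a method's interval is undefined are omitted from that method's
#' denominator and counted in `n_na`, mirroring the omission rule of the
#' simulation design: the Simple methods drop only replicates with a zero
#' margin (degenerate zero-variance tables stay in the denominator as
#' non-covering point intervals), while the transformed methods (Fisher,
#' naive, Zou's marginals) additionally drop replicates with
#' \eqn{|\widehat{\mathrm{MCC}}| = 1}, where artanh diverges.
#'
#' Replicates are generated in fixed-size chunks with per-chunk L'Ecuyer-CMRG
#' substreams derived from `seed`, so the result is reproducible given
#' `(seed, n, m)` and the work can be resumed or split without changing the
#' stream.
#'
#' @param scenario An [single_scenario()] or [paired_scenario()] object.
#' @param n Sample size per replicate.
#' @param m Number of replicates.
#' @param methods Character vector of methods: subset of
#'   `c("simple", "fisher", "naive")` for single scenarios,
#'   `c("simple", "zou", "mt")` for paired (defaults: all).
#' @param level Confidence level; default 0.95.
#' @param seed Integer seed controlling the whole stream.
#' @return A `data.frame` with one row per method and columns `method`, `n`,
#'   `m`, `n_na`, `coverage`, `mc_se` (binomial Monte-Carlo standard error of
#'   the coverage estimate), `mean_width`, `seed`.
#' @examples
#' sc <- single_scenario(0.5, 0.4)
#' run_coverage(sc, n = 50, m = 2000, seed = 1)
#' @export
run_coverage <- function(scenario, n, m, methods = NULL, level = 0.95,
                         seed = 1) {
  if (n < 2 || m < 1) stop("need n >= 2 and m >= 1", call. = FALSE)
  z <- .check_level(level)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  old_kind <- RNGkind()[1]
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    else RNGkind(old_kind)
  })
  if (inherits(scenario, "mcc_scenario"))
    .run_coverage_single(scenario, n, m, methods, z, level, seed)
  else if (inherits(scenario, "paired_mcc_scenario"))
    .run_coverage_paired(scenario, n, m, methods, z, level, seed)
  else stop("scenario must come from single_scenario() or paired_scenario()",
            call. = FALSE)
}

.run_coverage_single <- function(scenario, n, m, methods, z, level, seed) {
  if (is.null(methods)) methods <- c("simple", "fisher", "naive")
  methods <- match.arg(methods, c("simple", "fisher", "naive"),
                       several.ok = TRUE)
  p <- as.numeric(scenario$cells)
  rho <- scenario$true_mcc
  acc <- list()
  for (meth in methods) acc[[meth]] <- c(n_na = 0, n_cover = 0, sum_width = 0)
  n_chunks <- ceiling(m / .CHUNK_SIZE)
  streams <- .chunk_streams(seed, n_chunks)
  done <- 0L
  for (ci in seq_len(n_chunks)) {
    sz <- min(.CHUNK_SIZE, m - done); done <- done + sz
    C <- .with_stream(streams[[ci]], stats::rmultinom(sz, n, p))
    st <- .col_phi_stats(C / n)
    for (meth in methods) {
      if (meth == "simple") {
        def <- st$ok
        hw <- z * sqrt(st$var_phi / n)
        lo <- st$mcc - hw; hi <- st$mcc + hw
      } else {
        def <- st$ok & abs(st$mcc) < 1
        hw <- if (meth == "fisher") z * sqrt(st$var_fisher / n)
              else rep(z * sqrt(1 / (n - 3)), sz)
        fz <- atanh(pmin(1 - 1e-15, pmax(-1 + 1e-15, st$mcc)))
        lo <- tanh(fz - hw); hi <- tanh(fz + hw)
      }
      cov <- def & !is.na(lo) & lo <= rho & rho <= hi
      acc[[meth]] <- acc[[meth]] +
        c(sum(!def), sum(cov, na.rm = TRUE),
          sum((hi - lo)[def], na.rm = TRUE))
    }
  }
  do.call(rbind, lapply(methods, function(meth)
    .coverage_row(meth, n, m, acc[[meth]][["n_na"]], acc[[meth]][["n_cover"]],
                  acc[[meth]][["sum_width"]], seed)))
}

# row indices expanding a 4 x m marginal-gradient matrix to the 8 joint cells
.EXPAND1 <- c(1L, 2L, 1L, 2L, 3L, 4L, 3L, 4L)  # classifier 1 reads (i, k)
.EXPAND2 <- c(1L, 2L, 3L, 4L, 1L, 2L, 3L, 4L)  # classifier 2 reads (j, k)

.run_coverage_paired <- function(scenario, n, m, methods, z, level, seed) {
  if (is.null(methods)) methods <- c("simple", "zou", "mt")
  methods <- match.arg(methods, c("simple", "zou", "mt"), several.ok = TRUE)
  p <- as.numeric(scenario$cells)
  target <- scenario$true_diff
  acc <- list()
  for (meth in methods) acc[[meth]] <- c(n_na = 0, n_cover = 0, sum_width = 0)
  n_chunks <- ceiling(m / .CHUNK_SIZE)
  streams <- .chunk_streams(seed, n_chunks)
  done <- 0L
  for (ci in seq_len(n_chunks)) {
    sz <- min(.CHUNK_SIZE, m - done); done <- done + sz
    C <- .with_stream(streams[[ci]], stats::rmultinom(sz, n, p))
    P8 <- C / n
    st1 <- .col_phi_stats(.J1 %*% P8)
    st2 <- .col_phi_stats(.J2 %*% P8)
    ok <- st1$ok & st2$ok
    diff <- st1$mcc - st2$mcc
    a <- st1$g[.EXPAND1, , drop = FALSE]
    b <- st2$g[.EXPAND2, , drop = FALSE]
    Sa <- colSums(P8 * a); Sb <- colSums(P8 * b)
    V11 <- pmax(0, colSums(P8 * a^2) - Sa^2)
    V22 <- pmax(0, colSums(P8 * b^2) - Sb^2)
    C12 <- colSums(P8 * a * b) - Sa * Sb
    var_psi <- pmax(0, V11 + V22 - 2 * C12)
    for (meth in methods) {
      if (meth == "simple") {
        def <- ok
        hw <- z * sqrt(var_psi / n)
        lo <- diff - hw; hi <- diff + hw
      } else if (meth == "mt") {
        def <- ok
        inner <- abs(diff) < 2
        gd <- mt_transform(ifelse(inner, diff, 0))
        hw <- z * sqrt(var_psi / n) * 2 / (4 - diff^2)
        lo <- ifelse(inner, 2 * tanh(gd - hw), diff)
        hi <- ifelse(inner, 2 * tanh(gd + hw), diff)
      } else {  # zou
        def <- ok & abs(st1$mcc) < 1 & abs(st2$mcc) < 1
        rho12 <- ifelse(V11 > 0 & V22 > 0,
                        pmin(1, pmax(-1, C12 / sqrt(V11 * V22))), 0)
        hw1 <- z * sqrt(st1$var_fisher / n)
        hw2 <- z * sqrt(st2$var_fisher / n)
        f1 <- atanh(pmin(1 - 1e-15, pmax(-1 + 1e-15, st1$mcc)))
        f2 <- atanh(pmin(1 - 1e-15, pmax(-1 + 1e-15, st2$mcc)))
        l1 <- tanh(f1 - hw1); u1 <- tanh(f1 + hw1)
        l2 <- tanh(f2 - hw2); u2 <- tanh(f2 + hw2)
        d1 <- st1$mcc - l1; e2 <- u2 - st2$mcc
        e1 <- u1 - st1$mcc; d2 <- st2$mcc - l2
        lo <- diff - sqrt(pmax(0, d1^2 + e2^2 - 2 * rho12 * d1 * e2))
        hi <- diff + sqrt(pmax(0, e1^2 + d2^2 - 2 * rho12 * e1 * d2))
      }
      cov <- def & !is.na(lo) & lo <= target & target <= hi
      acc[[meth]] <- acc[[meth]] +
        c(sum(!def), sum(cov, na.rm = TRUE),
          sum((hi - lo)[def], na.rm = TRUE))
    }
  }
  do.call(rbind, lapply(methods, function(meth)
    .coverage_row(meth, n, m, acc[[meth]][["n_na"]], acc[[meth]][["n_cover"]],
                  acc[[meth]][["sum_width"]], seed)))
}
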