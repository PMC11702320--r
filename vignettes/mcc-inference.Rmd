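---
title: "Asymptotic inference for the Matthews correlation coefficient"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Asymptotic inference for the Matthews correlation coefficient}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mccinfer)
```

## The estimand and its sampling model

A binary classifier evaluated on $n$ i.i.d. subjects produces a $2\times 2$
confusion table $(TP, FP, FN, TN)$. Writing
$p_{ij} = P(\text{prediction} = i, \text{actual} = j)$ and
$p = (p_{11}, p_{10}, p_{01}, p_{00})^T$, the Matthews correlation
coefficient (phi coefficient) is

$$\varphi(p) = \frac{p_{11}p_{00} - p_{10}p_{01}}
{\sqrt{(p_{11}+p_{10})(p_{11}+p_{01})(p_{00}+p_{10})(p_{00}+p_{01})}},$$

which is exactly the Pearson correlation between the binary actual and
predicted labels. The observed table is a single draw from a 4-cell
multinomial, so $\sqrt n(\hat p - p) \rightsquigarrow N(0, \Sigma(p))$ with
$\Sigma(p) = \mathrm{diag}(p) - pp^T$, and smooth functionals of $\hat p$
inherit normal limits through the delta method. Everything in this package
is built on that chain: no distributional assumption beyond multinomial
sampling is used anywhere.

The MCC is undefined when any margin of the table is zero (the denominator
vanishes). We apply that rule uniformly — the estimate, every interval, and
the simulation bookkeeping all treat a zero-margin table as NA.

## Single-MCC intervals

Three constructions are implemented, differing in the scale on which the
normal approximation is applied and in the variance plugged in:

* **Simple** (`simple_ci()`): the Wald interval
  $\widehat{\mathrm{MCC}} \pm z_{\alpha/2}\sqrt{\hat v/n}$ with
  $\hat v = \nabla\varphi(\hat p)^T\Sigma(\hat p)\nabla\varphi(\hat p)$.
  The limits are deliberately *not* truncated to $[-1,1]$: the method under
  study is the unconstrained normal interval, and truncating would
  misrepresent its coverage behaviour without changing whether an interior
  true value is covered.
* **Fisher's z** (`fisher_ci()`): the same delta-method variance, but
  propagated to the artanh scale ($f = \mathrm{artanh}$,
  $f' (x) = 1/(1-x^2)$), where the sampling distribution is much closer to
  normal; the symmetric z-scale interval is mapped back through $\tanh$,
  yielding an asymmetric interval inside $(-1, 1)$. This requires
  $|\widehat{\mathrm{MCC}}| < 1$; tables with empty off-diagonal (or
  diagonal) cells are NA for this method.
* **Naive $1/(n-3)$** (`naive_fisher_ci()`): Fisher's transform with the
  classical normal-theory variance $1/(n-3)$. That variance presumes
  bivariate normal data; binary data violate it badly, and the method is
  included precisely to quantify how badly (its coverage stays far from
  nominal at every sample size).

The gradient $\nabla\varphi$ is implemented in closed form from the quotient
rule,
$\partial_{p_{11}}\varphi = p_{00}/D - \tfrac{\varphi}{2}(m_1^{-1}+m_2^{-1})$
and symmetrically for the other three cells ($D$ the denominator, $m_k$ the
margins). A central finite-difference oracle (`fd_gradient()`, step
$10^{-6}$, no simplex renormalization — the delta method differentiates the
unconstrained formula) is the correctness authority in the tests; analytic
and numeric gradients agree to $10^{-5}$ relative error at hundreds of
random interior points.

## Paired-design difference intervals

When two classifiers are applied to the same subjects the data are an
8-cell multinomial over $(h_1, h_2, Y)$, and the two MCC estimates are
correlated. With $\psi(p) = \varphi(m_1(p)) - \varphi(m_2(p))$ ($m_l$ the
linear marginalization onto classifier $l$'s table):

* **Simple** (`simple_diff_ci()`): Wald interval with
  $\hat v = \nabla\psi^T\Sigma\nabla\psi$.
* **Zou's method** (`zou_ci()`): each MCC first gets its own Fisher's z
  interval $(\ell_l, u_l)$ at the same level; the limits are recombined
  MOVER-style,
  $$L = \hat r_1 - \hat r_2 - \sqrt{(\hat r_1 - \ell_1)^2 +
  (u_2 - \hat r_2)^2 - 2\hat\rho\,(\hat r_1 - \ell_1)(u_2 - \hat r_2)},$$
  symmetrically for $U$. The correlation $\hat\rho$ comes from the
  delta-method covariance of $(\hat r_1, \hat r_2)$ — the two-column
  Jacobian $\nabla\tilde\psi$ against the 8-cell $\Sigma(\hat p)$ — rather
  than from bivariate-normal approximation formulas, which binary data do
  not satisfy.
* **Modified transformation** (`mt_ci()`): the difference lives in
  $(-2, 2)$, so the artanh-type map $g(x) = \tfrac12\log\{(2+x)/(2-x)\}$
  (equivalently $g(x) = f(x/2)$, $g'(x) = 2/(4-x^2)$) symmetrizes it; the
  Wald interval on the $g$ scale is mapped back through $2\tanh$.

Numerical safeguards, chosen once: $\hat\rho$ is clamped to $[-1, 1]$ and
Zou radicands are clipped at zero — both guard against floating-point
excursions of order machine epsilon, not against model failure. A pair of
identical prediction columns gives a degenerate zero variance for the
difference; we return NA rather than a width-0 interval, because the normal
approximation is vacuous there. Tiny negative quadratic forms (below
$10^{-12}$) from cancellation are clipped to zero; an exactly zero variance
propagates NA.

One detail worth making explicit: $|\widehat{\mathrm{MCC}}| = 1$ is detected
*structurally* (both off-diagonal cells empty, or both diagonal cells empty)
rather than by comparing the floating-point ratio to 1. The ratio computes
to $1 \pm$ a few ulps depending on how the denominator square root rounds,
and the artanh-based methods need the boundary case identified exactly.

## The coverage simulation

`run_coverage()` draws $m$ multinomial samples of size $n$ from a scenario's
true cells and reports, per method, the fraction of *defined* intervals
containing the truth, the NA count, the binomial Monte-Carlo standard error,
and the mean width.

**Scenarios.** `single_scenario(prevalence, true_mcc)` encodes the balance
constraint $TP/FN = TN/FP$, which forces sensitivity = specificity = $s$;
the cells are then determined uniquely by $(\pi, \rho)$ and $s$ is found by
bisection to $|\varphi - \rho| \le 10^{-12}$ (at $\pi = 0.5$,
$s = (1+\rho)/2$ in closed form). The study grid is
$\pi \in \{0.1, 0.5\}$, $\rho \in \{0.4, 0.6, 0.8\}$.
`paired_scenario()` parametrizes the joint law by marginal sensitivities /
specificities plus two within-class agreement probabilities (with their
Fréchet bounds checked); independence corresponds to
`agree_pos = sens1 * sens2`. We expose paired scenarios only through this
constructor: published coverage grids for the paired case depend on a
correlation structure that is not identified by the marginal descriptions,
so the paired claims we test are the reproducible, structural ones (nominal
coverage at large $n$ across the family, NA-set ordering) rather than
specific table cells.

**NA accounting.** The omission rule is method-specific: the Simple methods
drop only zero-margin replicates; Fisher-transformed methods additionally
drop $|\widehat{\mathrm{MCC}}| = 1$ (Zou's, through its marginals, inherits
both marginal rules and so never drops fewer than the others). Degenerate
zero-variance tables that are *not* boundary cases stay in the Simple
denominator as non-covering point intervals. Under the imbalanced
$\pi = 0.1$, $n = 50$ scenarios the dominant NA source is the
no-positive-subjects event with probability $(1-\pi)^n = 0.9^{50}$, about
$5.2 \times 10^{-3}$ — the analytic cross-check the tests use.

**Vectorization and RNG.** For a $k$-cell multinomial the quadratic form
collapses to $\sum_a p_a g_a^2 - (\sum_a p_a g_a)^2$, so all per-replicate
statistics are columnwise arithmetic on a cells-by-replicates matrix; one
million replicates take a couple of seconds. Replicates are generated in
fixed chunks of $2\times 10^5$ with per-chunk L'Ecuyer-CMRG substreams
derived from the single seed, so results are reproducible from
$(\mathrm{seed}, n, m)$ alone and independent of how the chunks are
processed.

**Problem sizes.** The package's own simulation checks use the full
$m = 10^6$ for the single-MCC coverage grid and the NA accounting (a few
seconds per scenario), and $m = 10^5$ with $n = 10^4$ per configuration for
the 24-configuration paired family; the unit-test smoke versions use
$m = 10^5$ with correspondingly wider ($\pm 0.006$) bands.

```{r coverage-example}
sc <- single_scenario(prevalence = 0.5, true_mcc = 0.4)
run_coverage(sc, n = 50, m = 20000, seed = 1)
```

## Reconstructing a partially identified paired table

When two classifiers are compared from published marginal summaries only
(class sizes, sensitivity, specificity of each), the 8-cell joint law is not
identified: two degrees of freedom remain, naturally taken as
$p_{001}$ (both miss a positive) and $p_{110}$ (both false-alarm a
negative). Nonnegativity of the remaining cells confines them to a
rectangle, computed by `feasible_box()`:
$p_{001} \in [\max(0, \pi(1-s_1-s_2)),\ \pi\min(1-s_1, 1-s_2)]$ and the
specificity analogue for $p_{110}$. `reconstruct_joint()` completes the
table at a chosen point, and `mt_grid()` sweeps the MT interval over the
whole box (default steps 0.025 for $p_{001}$ and 0.001 for $p_{110}$, both
endpoints included), treating the reconstructed cells as exact plug-in
probabilities with effective $n = n_{pos} + n_{neg}$.

Because the marginals fix both MCCs, the difference estimate is constant
across the box while the interval width varies — the sweep shows exactly
how much the unidentified dependence structure matters for significance.
The sensitivities/specificities are user inputs; the package ships a
synthetic worked example (two classifiers of similar accuracy on 200 + 200
subjects) rather than hard-coding any particular published pair.

```{r reconstruction-example}
m <- marginal_summary(n_pos = 200, n_neg = 200,
                      sens1 = 0.80, spec1 = 0.85,
                      sens2 = 0.795, spec2 = 0.845)
grid <- mt_grid(m, p001_step = 0.05, p110_step = 0.05)
head(grid)
range(grid$upper - grid$lower)
```

## What the simulations do and do not show

The generator draws exact multinomial samples from exactly specified cells:
it emulates the sampling noise of a confusion table under independent
subjects, which is the model all the interval methods assume. It does not
emulate covariate drift, clustered or dependent subjects, label noise, or
classifiers tuned on the evaluation data — coverage statements here say
nothing about those failure modes. Within the model, the known small-sample
behaviour is visible in the package's own output: the Simple interval
under-covers at $n = 50$ (more severely under imbalance), Fisher's z tracks
the nominal level much earlier, the naive $1/(n-3)$ variance never attains
it, and in the paired case Zou's method leans conservative at small $n$ and
high MCC while the MT method approaches 0.95 from below.

## Known limitations

* Binary classification only; multi-class MCC has no single accepted
  definition and is out of scope.
* All intervals are first-order asymptotic; none carries small-sample or
  continuity corrections, and no bootstrap alternative is provided.
* The unpaired two-sample comparison is not wrapped: it is a one-line
  composition of two single-MCC variances and did not seem worth an API
  surface.
* `mt_grid()` treats reconstructed cells as exact; uncertainty in the
  published sensitivities/specificities themselves is not propagated.
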