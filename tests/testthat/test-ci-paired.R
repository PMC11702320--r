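fixture_paired <- function() {
  paired_counts(c(p111 = 40, p110 = 5, p101 = 5, p100 = 3,
                  p011 = 2, p010 = 4, p001 = 1, p000 = 40))
}

test_that("paired_estimate: degenerate dependence patterns", {
  # identical prediction columns
  same <- paired_counts(c(p111 = 30, p110 = 10, p101 = 0, p100 = 0,
                          p011 = 0, p010 = 0, p001 = 8, p000 = 52))
  pe <- paired_estimate(same)
  expect_equal(pe$r1, pe$r2)
  expect_equal(pe$diff, 0)
  expect_equal(pe$corr, 1, tolerance = 1e-9)
  # second classifier is the complement of the first
  comp <- paired_counts(c(p111 = 0, p110 = 0, p101 = 30, p100 = 10,
                          p011 = 8, p010 = 52, p001 = 0, p000 = 0))
  pe2 <- paired_estimate(comp)
  expect_equal(pe2$r2, -pe2$r1, tolerance = 1e-12)
  expect_equal(pe2$corr, -1, tolerance = 1e-9)
})

test_that("paired_estimate marginal variances agree with the single-table machinery", {
  set.seed(51)
  for (i in 1:10) {
    pc <- rand_paired_counts(500)
    pe <- paired_estimate(pc)
    for (l in 1:2) {
      ml <- marginalize(pc, l)
      p <- as.numeric(ml) / attr(ml, "n")
      v <- delta_variance(grad_phi(p), multinomial_cov(p)) / attr(ml, "n")
      expect_equal(if (l == 1) pe$var1 else pe$var2, v, tolerance = 1e-12)
    }
  }
})

test_that("simple difference interval: variance identity and antisymmetry", {
  set.seed(52)
  for (i in 1:10) {
    pc <- rand_paired_counts(400)
    ci <- simple_diff_ci(pc)
    pe <- paired_estimate(pc)
    v_from_pair <- pe$var1 + pe$var2 -
      2 * pe$corr * sqrt(pe$var1 * pe$var2)
    expect_equal((half_width(ci) / qnorm(0.975))^2, v_from_pair,
                 tolerance = 1e-12)
    ci_swapped <- simple_diff_ci(swap_classifiers(pc))
    expect_equal(ci_swapped$lower, -ci$upper, tolerance = 1e-12)
    expect_equal(ci_swapped$upper, -ci$lower, tolerance = 1e-12)
  }
  # identical classifiers: zero variance, NA by design
  same <- paired_counts(c(p111 = 30, p110 = 10, p101 = 0, p100 = 0,
                          p011 = 0, p010 = 0, p001 = 8, p000 = 52))
  ci <- simple_diff_ci(same)
  expect_true(ci$na)
  expect_match(ci$na_reason, "zero variance")
  expect_true(mt_ci(same)$na)
})

test_that("zou interval recombines the marginal fisher limits", {
  set.seed(53)
  for (i in 1:10) {
    pc <- rand_paired_counts(400)
    ci <- zou_ci(pc)
    pe <- paired_estimate(pc)
    ci1 <- fisher_ci(marginalize(pc, 1))
    ci2 <- fisher_ci(marginalize(pc, 2))
    rho <- pe$corr
    L <- pe$diff - sqrt((pe$r1 - ci1$lower)^2 + (ci2$upper - pe$r2)^2 -
                          2 * rho * (pe$r1 - ci1$lower) * (ci2$upper - pe$r2))
    U <- pe$diff + sqrt((ci1$upper - pe$r1)^2 + (pe$r2 - ci2$lower)^2 -
                          2 * rho * (ci1$upper - pe$r1) * (pe$r2 - ci2$lower))
    expect_equal(ci$lower, L, tolerance = 1e-12)
    expect_equal(ci$upper, U, tolerance = 1e-12)
    expect_true(ci$lower <= pe$diff && pe$diff <= ci$upper)
  }
})

test_that("zou interval reduces to the Pythagorean form at zero correlation", {
  # product structure: classifier 2 independent of (classifier 1, truth),
  # so the estimated correlation is zero to machine precision
  q <- c(300, 100, 150, 450)  # (h1, y) counts: (1,1), (1,0), (0,1), (0,0)
  w <- c(0.6, 0.4)
  cnt <- c(p111 = q[1] * w[1], p110 = q[2] * w[1],
           p101 = q[1] * w[2], p100 = q[2] * w[2],
           p011 = q[3] * w[1], p010 = q[4] * w[1],
           p001 = q[3] * w[2], p000 = q[4] * w[2])
  pc <- paired_counts(cnt)
  pe <- paired_estimate(pc)
  expect_equal(pe$corr, 0, tolerance = 1e-12)
  ci <- zou_ci(pc)
  ci1 <- fisher_ci(marginalize(pc, 1)); ci2 <- fisher_ci(marginalize(pc, 2))
  expect_equal(pe$diff - ci$lower,
               sqrt((pe$r1 - ci1$lower)^2 + (ci2$upper - pe$r2)^2),
               tolerance = 1e-12)
  expect_equal(ci$upper - pe$diff,
               sqrt((ci1$upper - pe$r1)^2 + (pe$r2 - ci2$lower)^2),
               tolerance = 1e-12)
})

test_that("zou NA set includes marginal |MCC| = 1", {
  pc <- paired_counts(c(p111 = 30, p110 = 0, p101 = 10, p100 = 0,
                        p011 = 0, p010 = 5, p001 = 0, p000 = 50))
  # marginal 1 has fp = fn = 0 -> MCC1 = 1
  expect_identical(mcc(marginalize(pc, 1)), 1)
  expect_true(zou_ci(pc)$na)
  expect_false(mt_ci(pc)$na)
  expect_false(simple_diff_ci(pc)$na)
})

test_that("mt interval: transform geometry and antisymmetry", {
  pc <- fixture_paired()
  ci <- mt_ci(pc)
  pe <- paired_estimate(pc)
  # on the g scale the interval is symmetric, with half-width equal to the
  # simple half-width scaled by g'(diff) = 2/(4 - diff^2)
  sc <- simple_diff_ci(pc)
  g <- function(x) 0.5 * log((2 + x) / (2 - x))
  expect_equal(g(ci$upper) - g(pe$diff), g(pe$diff) - g(ci$lower),
               tolerance = 1e-10)
  expect_equal(g(ci$upper) - g(pe$diff),
               half_width(sc) * 2 / (4 - pe$diff^2), tolerance = 1e-12)
  expect_true(ci$lower > -2 && ci$upper < 2)
  ci_swapped <- mt_ci(swap_classifiers(pc))
  expect_equal(ci_swapped$lower, -ci$upper, tolerance = 1e-12)
  # table symmetric under classifier swap: identical marginals, diff = 0,
  # so the interval is symmetric about zero
  balanced <- paired_counts(c(p111 = 30, p110 = 5, p101 = 7, p100 = 4,
                              p011 = 7, p010 = 4, p001 = 2, p000 = 41))
  pe0 <- paired_estimate(balanced)
  expect_identical(pe0$diff, 0)
  ci0 <- mt_ci(balanced)
  expect_equal(ci0$lower, -ci0$upper, tolerance = 1e-10)
})

test_that("the three paired methods converge as counts scale up", {
  pc <- fixture_paired()
  gaps <- sapply(c(1, 10, 100, 1000), function(k) {
    pck <- paired_counts(as.numeric(fixture_paired()) * k)
    cis <- list(simple_diff_ci(pck), zou_ci(pck), mt_ci(pck))
    lo <- sapply(cis, `[[`, "lower"); hi <- sapply(cis, `[[`, "upper")
    max(diff(range(lo)), diff(range(hi)))
  })
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[4], 1e-4)
})

test_that("paired NA propagates from zero marginal margins", {
  # no actual positives at all
  pc <- paired_counts(c(p111 = 0, p110 = 10, p101 = 0, p100 = 5,
                        p011 = 0, p010 = 5, p001 = 0, p000 = 80))
  for (f in list(simple_diff_ci, zou_ci, mt_ci)) {
    ci <- f(pc)
    expect_true(ci$na)
    expect_match(ci$na_reason, "margin")
  }
})
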