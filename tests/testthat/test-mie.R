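test_that("Mie well depth and minimum hold for every tabulated parameter set", {
  for (r in seq_len(nrow(table2_rows))) {
    p <- mie_params(table2_rows$eps[r], table2_rows$n[r], table2_rows$m[r],
                    r0 = table2_rows$r0[r])
    expect_equal(mie_energy(p$r0, p), -p$epsilon, tolerance = 1e-14)
    expect_equal(mie_energy_force(p$r0, p)$force, 0, tolerance = 1e-12)
    # numerically at the minimum: U(r0 +/- h) > U(r0)
    expect_true(all(mie_energy(p$r0 * c(0.99, 1.01), p) > -p$epsilon))
  }
})

test_that("Mie energy matches the frozen high-precision value and decays from below", {
  p <- mie_params(0.375, 9, 6, r0 = 4.693)
  expect_equal(mie_energy(4.0, p), frozen$mie_I1_r4, tolerance = 1e-12)
  expect_gt(mie_energy(4.0, p), 0)
  # beyond r0 the potential is negative and rises monotonically to zero
  r <- seq(p$r0, 60, length.out = 200)
  u <- mie_energy(r, p)
  expect_true(all(u <= 0))
  expect_true(all(diff(u) > 0))
  expect_lt(abs(mie_energy(1e4, p)), 1e-18)
})

test_that("analytic radial force matches finite differences of the energy", {
  p <- mie_params(0.469, 9, 6, r0 = 5.249)
  for (r in c(3.5, 4.8, 5.249, 7.0, 12.0)) {
    fd <- -fd_gradient(function(x) mie_energy(x, p), r)
    expect_equal(mie_energy_force(r, p)$force, fd, tolerance = 1e-7)
  }
})

test_that("invalid Mie inputs are rejected", {
  expect_error(mie_energy(0, mie_params(1, 9, 6, r0 = 4)), "r must be > 0")
  expect_error(mie_params(-1, 9, 6, r0 = 4), "epsilon")
  expect_error(mie_params(1, 6, 9, r0 = 4), "n > m")
  expect_error(r0_from_sigma(1, 6, 6), "degenerate")
  expect_error(mie_params(1, 9, 6), "exactly one")
  expect_error(mie_params(1, 9, 6, r0 = 4, sigma = 4), "exactly one")
})

test_that("r0/sigma conversions reproduce closed forms and invert exactly", {
  expect_equal(r0_from_sigma(1, 9, 6), frozen$r0_sigma_9_6, tolerance = 1e-14)
  expect_equal(r0_from_sigma(1, 12, 6), frozen$r0_sigma_12_6, tolerance = 1e-14)
  set.seed(11)
  s <- runif(50, 1, 10)
  for (exps in list(c(9, 6), c(12, 6), c(10, 7))) {
    rt <- sigma_from_r0(r0_from_sigma(s, exps[1], exps[2]), exps[1], exps[2])
    expect_equal(rt, s, tolerance = 1e-12)
  }
})

test_that("Lorentz-Berthelot mixing is self-consistent, symmetric and matches arithmetic", {
  ff <- default_forcefield()
  i1 <- ff$sites$I1; ct <- ff$sites$CT
  # a = b returns a's own parameters
  self <- mix_params(i1, i1)
  expect_equal(self$epsilon, i1$self_params$epsilon, tolerance = 1e-14)
  expect_equal(self$r0, i1$self_params$r0, tolerance = 1e-12)
  # unlike pair: geometric epsilon, arithmetic sigma
  x <- mix_params(i1, ct)
  expect_equal(x$epsilon, frozen$eps_I1_CT, tolerance = 1e-14)
  expect_equal(x$sigma, (i1$self_params$sigma + ct$self_params$sigma) / 2,
               tolerance = 1e-14)
  expect_equal(x$r0, r0_from_sigma(x$sigma, x$n, x$m), tolerance = 1e-12)
  # symmetry over all registry pairs with Mie interactions
  nm <- names(ff$sites)
  for (a in nm) for (b in nm) {
    pa <- ff$sites[[a]]$self_params; pb <- ff$sites[[b]]$self_params
    if (is.null(pa) || is.null(pb)) next
    ab <- mix_params(ff$sites[[a]], ff$sites[[b]])
    ba <- mix_params(ff$sites[[b]], ff$sites[[a]])
    expect_equal(ab[c("epsilon", "n", "m", "r0")], ba[c("epsilon", "n", "m", "r0")])
  }
})

test_that("unlike-exponent mixing follows the declared exponent rule", {
  ff <- default_forcefield()
  i3 <- ff$sites$I3; ci <- ff$sites$CI   # 9-6 vs 12-6
  x <- mix_params(i3, ci, rule = "arithmetic")
  # brute-force re-derivation of the rule
  m_expect <- round((6 + 6) / 2)
  n_expect <- max(round((9 + 12) / 2), m_expect + 1)
  expect_identical(c(x$n, x$m), c(n_expect, m_expect))
  expect_equal(x$epsilon, sqrt(0.199 * 0.148), tolerance = 1e-14)
  # fixed rule override
  xf <- mix_params(i3, ci, rule = "fixed", fixed_exponents = c(9, 6))
  expect_identical(c(xf$n, xf$m), c(9, 6))
})
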