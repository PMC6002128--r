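test_that("receptor activity and CheR concentration follow their closed forms", {
  p <- signaling_params()
  expect_equal(receptor_activity(1, p), 0.5)
  expect_equal(receptor_activity(1.2, p), 1 / (1 + exp(-6 * 1.7 * 0.2)))
  expect_lt(receptor_activity(-30, p), 1e-20)
  expect_equal(receptor_activity(30, p), 1)
  m <- seq(0, 2, by = 0.05)
  expect_true(all(diff(receptor_activity(m, p)) > 0))
  # CheR: free concentration at m = m0 (A = 1/2) and the saturation limit
  expect_equal(cheR_concentration(1, p), 0.3 / (1 + 0.15 * (5 / 3) * 0.5))
  expect_equal(cheR_concentration(40, p), p$Rt, tolerance = 1e-12)
  expect_true(all(diff(cheR_concentration(m, p)) > 0))
  expect_true(all(cheR_concentration(m, p) <= p$Rt))
})

test_that("parameter bundles validate their inputs", {
  expect_error(signaling_params(h0 = 1.2), "h0")
  expect_error(signaling_params(Zww = 1), "unknown")
  expect_error(motility_params(w = 9), "w <= nf")
  expect_equal(field_params(doubling_time = 1800)$r, log(2) / 1800)
})

test_that("solve_phospho satisfies the balance equations and physical bounds", {
  p <- signaling_params()
  scale <- 1e-10 * p$kA * p$Tt
  for (mz in list(c(0.7, 1.23), c(1.0, 1.23), c(0.9, 0.5), c(1.2, 2.0),
                  c(0.5, 0.1), c(0.707, 1.11))) {
    st <- solve_phospho(mz[1], mz[2], p)
    expect_true(all(abs(phospho_residuals(st, mz[1], mz[2], p)) < scale))
    expect_true(st$Yp >= 0 && st$Yp <= p$Yt)
    expect_true(st$Bp >= 0 && st$Bp <= p$Bt)
    expect_lte(st$Tp, p$Tt * receptor_activity(mz[1], p) + 1e-12)
  }
})

test_that("CheYp from the solver is monotone decreasing in CheZ at fixed m", {
  z <- seq(0, 2, by = 0.1)
  Yp <- vapply(z, function(zi) solve_phospho(0.9, zi)$Yp, numeric(1))
  expect_true(all(diff(Yp) < 0))
  expect_lt(solve_phospho(0.9, 1e3)$Yp, solve_phospho(0.9, 1.23)$Yp)
})

test_that("solver agrees with the ODE-relaxation oracle on random states", {
  skip_if_not_installed("deSolve")
  set.seed(42)
  for (k in 1:12) {
    m <- runif(1, 0.5, 1.5); z <- runif(1, 0, 2)
    st <- solve_phospho(m, z)
    or <- oracle_phospho(m, z)
    expect_equal(st$Yp, or$Yp, tolerance = 1e-6)
    expect_equal(st$Tp, or$Tp, tolerance = 1e-6)
    expect_equal(st$Bp, or$Bp, tolerance = 1e-6)
  }
})

test_that("methylation balance has the expected sign structure", {
  p <- signaling_params()
  ms <- steady_methylation(1.23, p)
  expect_lt(abs(methylation_rhs(ms, 1.23, p)), 1e-12)
  expect_gt(methylation_rhs(ms - 0.2, 1.23, p), 0)
  expect_lt(methylation_rhs(ms + 0.2, 1.23, p), 0)
  # far below the transition the demethylation term vanishes
  expect_equal(methylation_rhs(-20, 1.23, p),
               p$kR * p$Rt / (1 + p$KR * p$Tt), tolerance = 1e-8)
})

test_that("steady methylation matches a plain bisection oracle", {
  for (z in c(0.9, 1.11, 1.23)) {
    expect_equal(steady_methylation(z), oracle_mstar(z), tolerance = 1e-8)
  }
  expect_lt(abs(methylation_rhs(steady_methylation(1.23), 1.23)), 1e-12)
})

test_that("steady methylation round-trips across a CheZ grid", {
  zg <- seq(0.02, 1.29, length.out = 50)
  res <- vapply(zg, function(z) abs(methylation_rhs(steady_methylation(z), z)),
                numeric(1))
  expect_true(all(res < 1e-12))
})

test_that("CheZ dynamics switch branches at the AHL threshold", {
  p <- signaling_params()
  expect_equal(chez_rhs(p$Zw, 0.1, 3.85e-4, p), 0)
  expect_equal(chez_rhs(1.0, 0.3, 3.85e-4, p), -3.85e-4)
  # the boundary h == h0 belongs to the suppressed branch
  expect_equal(chez_rhs(1.0, p$h0, 3.85e-4, p), -3.85e-4)
  expect_equal(chez_rhs(1.0, p$h0 - 1e-9, 3.85e-4, p), 3.85e-4 * (p$Zw - 1))
  # smooth variant blends the branches
  mid <- chez_rhs(1.0, p$h0, 3.85e-4, p, smooth = 50)
  expect_lt(mid, 3.85e-4 * (p$Zw - 1))
  expect_gt(mid, -3.85e-4)
})

test_that("forward CheZ integration stays inside [0, Zw]", {
  p <- signaling_params()
  z <- p$Zw
  kV <- 3.85e-4
  for (k in 1:2000) {
    h <- if (k < 1000) 0.5 else 0.0  # suppression then recovery
    z <- z + 10 * chez_rhs(z, h, kV, p)
    expect_true(z >= 0 && z <= p$Zw + 1e-12)
  }
})

test_that("steady CheYp decreases in CheZ and is continuous across the grid", {
  zg <- seq(0, 2, length.out = 60)
  Yp <- steady_Yp(zg)
  expect_true(all(Yp >= 0))
  expect_true(all(diff(Yp) < 0))
  # no root-branch jumps: the largest step shrinks proportionally under
  # grid refinement (a discontinuity would keep it constant)
  zf <- seq(0, 2, length.out = 120)
  Ypf <- steady_Yp(zf)
  expect_lt(max(abs(diff(Ypf))), 0.65 * max(abs(diff(Yp))))
  expect_gt(steady_Yp(1.11), steady_Yp(1.23))
})
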