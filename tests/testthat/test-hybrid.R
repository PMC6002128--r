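small_cfg <- function(...) {
  args <- list(geometry = "cartesian1d", L = 10, T_end = 600,
               n_init = 200, snap_dt = 300, seed = 5)
  over <- list(...)
  args[names(over)] <- over
  do.call(stripe_config, args)
}

test_that("the initial population matches the Gaussian inoculum", {
  cfg <- stripe_config(n_init = 4000, sigma0 = 2, L = 25)
  set.seed(123)
  pop <- init_population(cfg)
  expect_equal(nrow(pop$x), 4000)
  expect_lt(abs(mean(pop$x)), 0.3)
  expect_gt(sd(pop$x), 1.7); expect_lt(sd(pop$x), 2.3)
  expect_true(all(pop$z == cfg$signaling$Zw))
  expect_true(all(pop$m == 1))
  expect_true(all(abs(pop$heading) == 1))
  empty <- init_population(stripe_config(n_init = 0))
  expect_equal(nrow(empty$x), 0)
})

test_that("CheZ decays exponentially under quorum suppression", {
  cfg <- small_cfg()
  fg <- field_grid(cfg$L, cfg$dx_field)
  fg$h[] <- 0.5  # everywhere above threshold
  pop <- init_population(cfg)
  tab <- get_table()
  r <- cfg$fields$r
  for (k in 1:120) pop <- step_internal(pop, fg, 10, cfg, table = tab)
  expect_equal(pop$z, rep(cfg$signaling$Zw * exp(-r * 1200), nrow(pop$x)),
               tolerance = 1e-6)
  # below threshold at equilibrium: z untouched
  fg$h[] <- 0
  pop2 <- init_population(cfg)
  pop2 <- step_internal(pop2, fg, 10, cfg, table = tab)
  expect_equal(pop2$z, rep(cfg$signaling$Zw, nrow(pop2$x)))
})

test_that("explicit methylation relaxes monotonically to its steady state", {
  cfg <- small_cfg(n_init = 1)
  fg <- field_grid(cfg$L, cfg$dx_field)
  pop <- init_population(cfg)
  pop$z <- 1.11; pop$m <- 0.9   # away from m*(1.11)
  ms <- steady_methylation(1.11)
  fg$h[] <- 0
  dev <- abs(pop$m - ms)
  for (k in 1:20) {
    # hold z fixed by resetting it; step methylation explicitly
    pop <- step_internal(pop, fg, 0.1, cfg, m_mode = "explicit")
    pop$z <- 1.11
    dnew <- abs(pop$m - ms)
    expect_lte(dnew, dev + 1e-12)
    dev <- dnew
  }
  expect_lt(dev, abs(0.9 - ms))
})

test_that("motion is ballistic without tumbling and reflects at walls", {
  cfg <- small_cfg(n_init = 1)
  set.seed(1)
  pop <- init_population(cfg)
  pop$x[1, 1] <- 9.9; pop$heading[1, 1] <- 1; pop$moving[1] <- TRUE
  pop <- step_motion(pop, 10, lambda = 0, mu = 1, s0 = 0.02, L = 10)
  expect_equal(pop$x[1, 1], 2 * 10 - (9.9 + 0.2))  # reflected
  expect_equal(pop$heading[1, 1], -1)
  expect_true(pop$moving[1])
  # never tumbles at lambda = 0 over many steps
  for (k in 1:200) pop <- step_motion(pop, 1, 0, 1, 0.02, 10)
  expect_true(pop$moving[1])
})

test_that("long-run moving fraction matches mu/(lambda+mu)", {
  cfg <- small_cfg(n_init = 10000, L = 50)
  set.seed(9)
  pop <- init_population(cfg)
  lam <- 0.5; mu <- 1.5
  for (k in 1:400) pop <- step_motion(pop, 0.05, lam, mu, 0.02, 50)
  frac <- mean(pop$moving)
  p <- mu / (lam + mu)
  # 3 sigma with an effective sample size reduced by temporal correlation
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / 2000))
})

test_that("division reproduces exponential growth at full nutrient", {
  cfg <- small_cfg(n_init = 2000, L = 10)
  fg <- field_grid(cfg$L, cfg$dx_field)   # n = 1 everywhere
  set.seed(21)
  pop <- init_population(cfg)
  r <- cfg$fields$r
  t_end <- 3600
  for (k in 1:60) pop <- step_division(pop, fg, 60, r)
  Nt <- nrow(pop$x)
  mean_N <- 2000 * exp(r * t_end)
  sd_N <- sqrt(2000 * exp(r * t_end) * (exp(r * t_end) - 1))
  expect_lt(abs(Nt - mean_N), 3 * sd_N)
  # daughters inherit state
  expect_true(all(pop$z == cfg$signaling$Zw))
  # no nutrient, no divisions
  fg0 <- fg; fg0$n[] <- 0
  expect_equal(nrow(step_division(pop, fg0, 600, r)$x), Nt)
})

test_that("fields decay and conserve their closed-form limits", {
  fp <- field_params(beta = 0.01)
  fg <- field_grid(5, 0.1)
  fg$h[] <- 2
  for (k in 1:200) fg <- step_fields(fg, NULL, 1, fp)
  expect_equal(fg$h, rep(2 * exp(-0.01 * 200), length(fg$h)),
               tolerance = 1e-8)
  expect_equal(fg$n, rep(1, length(fg$n)))  # no cells: nutrient unchanged
  # one immobile cell: total AHL approaches alpha_d / beta
  cfg <- small_cfg(n_init = 1, L = 5)
  pop <- init_population(cfg)
  pop$x[1, 1] <- 0
  fg <- field_grid(5, 0.1)
  for (k in 1:1500) fg <- step_fields(fg, pop, 1, fp)
  expect_equal(sum(fg$h * fg$vol), fp$alpha_d / 0.01, tolerance = 1e-3)
})

test_that("density histograms conserve counts and flatten for uniform samples", {
  set.seed(4)
  snap <- list(x = runif(10000, -10, 10), z = runif(10000, 0, 1.2))
  hh <- density_histograms(snap, L = 10)
  expect_equal(sum(hh$rho) * 1000 * 0.1, 10000)
  expect_equal(sum(hh$rho_z) * 100, 10000)
  # multinomial 3 sigma bound per bin (uniform expectation)
  expect_lt(max(abs(hh$rho * 1000 * 0.1 - 50)), 3.5 * sqrt(50))
  one <- density_histograms(list(x = 0.03, z = 1.23), L = 10)
  expect_equal(sum(one$rho > 0), 1)
})

test_that("hybrid runs are bit-identical under the same seed", {
  cfg <- small_cfg()
  a <- run_hybrid(cfg)
  b <- run_hybrid(cfg)
  for (s in seq_along(a$snapshots)) {
    expect_identical(a$snapshots[[s]]$x, b$snapshots[[s]]$x)
    expect_identical(a$snapshots[[s]]$z, b$snapshots[[s]]$z)
    expect_identical(a$snapshots[[s]]$h, b$snapshots[[s]]$h)
  }
  c2 <- run_hybrid(cfg, seed = cfg$seed + 1)
  expect_false(identical(a$snapshots[[2]]$x, c2$snapshots[[2]]$x))
})

test_that("cell count changes only through division", {
  cfg <- small_cfg(T_end = 900)
  run <- run_hybrid(cfg, no_growth = TRUE)
  counts <- vapply(run$snapshots, function(s) length(s$x), integer(1))
  expect_true(all(counts == cfg$n_init))
})

test_that("agent dispersal matches the tabulated diffusivity", {
  # frozen internal state, no growth: MSD after T ~ 2 D T
  cfg <- stripe_config(geometry = "cartesian1d", L = 40, T_end = 500,
                       n_init = 8000, sigma0 = 1e-3, snap_dt = 500, seed = 8)
  tab <- get_table()
  run <- run_hybrid(cfg, table = tab, freeze_internal = TRUE,
                    no_growth = TRUE)
  last <- run$snapshots[[length(run$snapshots)]]
  D <- interp_z(tab, cfg$signaling$Zw, "D1")
  expect_equal(mean(last$x^2), 2 * D * 500, tolerance = 0.05)
})
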