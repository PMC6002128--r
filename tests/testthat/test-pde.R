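test_that("the initial density matches the inoculum in both geometries", {
  cfg1 <- stripe_config(geometry = "cartesian1d", L = 25, Nx = 500)
  f1 <- init_pde(cfg1)
  expect_equal(field_mass(f1), 0.5, tolerance = 1e-6)
  expect_true(all(f1$h == 0))
  expect_true(all(f1$n == 1))
  # all mass sits in the z-cell containing Zw
  jz <- which(colSums(f1$rho_z) > 0)
  expect_length(jz, 1)
  expect_true(abs(f1$zc[jz] - 1.23) <= f1$dz / 2)
  cfg2 <- stripe_config(geometry = "radial", L = 40, Nx = 800)
  f2 <- init_pde(cfg2)
  rho0 <- rowSums(f2$rho_z) * f2$dz
  expect_equal(rho0[1], 1 / (4 * sqrt(2 * pi)), tolerance = 1e-3)
  # radial mass of the Gaussian inoculum: integral of xi * rho d xi
  expect_equal(field_mass(f2), 1 / (4 * sqrt(2 * pi)) * 4, tolerance = 1e-3)
})

test_that("transport operators conserve mass to near machine precision", {
  for (geom in c("cartesian1d", "radial")) {
    cfg <- stripe_config(geometry = geom, L = 10, Nx = 80, Nz = 20,
                         fields = list(doubling_time = 1800))
    f <- init_pde(cfg)
    m0 <- field_mass(f)
    # r = 0 switches off both growth and the z-velocity (kV = r n = 0)
    cfg$fields$r <- 0
    f <- step_pde(f, cfg, dt = 2, nsteps = 10000)
    expect_equal(field_mass(f), m0, tolerance = 1e-10)
    expect_true(all(f$rho_z >= -1e-12))
  }
})

test_that("constant-diffusivity spreading matches the heat kernel", {
  cfg <- stripe_config(geometry = "cartesian1d", L = 25, Nx = 500,
                       Nz = 10, sigma0 = 0.5)
  f <- init_pde(cfg)
  cfg$fields$r <- 0
  D <- 6e-4
  t_end <- 3600
  f <- step_pde(f, cfg, dt = 2, nsteps = t_end / 2,
                Dz = rep(D, length(f$zc)))
  rho <- rowSums(f$rho_z) * f$dz
  s2 <- 0.5^2 + 2 * D * t_end
  exact <- cfg$rho0 * exp(-f$x^2 / (2 * s2)) / sqrt(2 * pi * s2)
  keep <- exact > 1e-3 * max(exact)
  expect_lt(max(abs(rho[keep] - exact[keep])) / max(exact), 0.01)
})

test_that("the z-marginal mean obeys the advection moment identity", {
  # h held above threshold, n constant: d<z>/dt = -kappa * r * <z>
  cfg <- stripe_config(geometry = "cartesian1d", L = 5, Nx = 40, Nz = 120,
                       kappa = 1.6,
                       fields = list(alpha_d = 0, beta = 0, gamma_d = 0))
  f <- init_pde(cfg)
  f$h[] <- 1  # above threshold everywhere, no decay keeps it there
  r <- cfg$fields$r
  t_end <- 1800
  dt <- stripesim:::resolve_dt(cfg, f$dz)
  f <- step_pde(f, cfg, dt = dt, nsteps = ceiling(t_end / dt))
  zbar <- sum(outer(rep(1, length(f$x)), f$zc) * f$rho_z) / sum(f$rho_z)
  expect_equal(zbar, 1.23 * exp(-cfg$kappa * r * ceiling(t_end / dt) * dt),
               tolerance = 0.02)
  expect_true(all(f$rho_z >= -1e-12))
})

test_that("front position is grid-converged at the default resolution", {
  coarse <- run_pde(scenario_preset("radial_baseline", Nx = 250, Nz = 30,
                                    T_end = 10 * 3600, snap_dt = 3600))
  fine <- run_pde(scenario_preset("radial_baseline", Nx = 500, Nz = 60,
                                  T_end = 10 * 3600, snap_dt = 3600))
  fc <- front_position(coarse$x, coarse$snapshots[[11]]$rho)
  ff <- front_position(fine$x, fine$snapshots[[11]]$rho)
  expect_lt(abs(fc - ff) / ff, 0.02)
})

test_that("the reduced model reproduces diffusion-growth when AHL stays low", {
  # alpha = 0 keeps h = 0 < h0 forever: constant diffusivity D(Zw);
  # gamma = 0 keeps n = 1 so growth is uniform
  cfg <- stripe_config(mode = "wildtype", geometry = "cartesian1d", L = 25,
                       Nx = 500, sigma0 = 1, T_end = 2 * 3600,
                       snap_dt = 2 * 3600, fields = list(gamma_d = 0))
  run <- run_reduced_model(cfg)
  last <- run$snapshots[[length(run$snapshots)]]
  D <- effective_diffusion(1.23, d = 1)
  s2 <- 1 + 2 * D * last$t
  exact <- exp(cfg$fields$r * last$t) * cfg$rho0 *
    exp(-run$x^2 / (2 * s2)) / sqrt(2 * pi * s2)
  keep <- exact > 1e-3 * max(exact)
  expect_lt(max(abs(last$rho[keep] - exact[keep])) / max(exact), 0.01)
})

test_that("the reduced model conserves mass without growth", {
  cfg <- stripe_config(geometry = "radial", L = 10, Nx = 100,
                       T_end = 3600, snap_dt = 3600)
  cfg$fields$r <- 0
  run <- run_reduced_model(cfg)
  m <- vapply(run$snapshots, function(s) sum(s$rho * run$x) * run$dx,
              numeric(1))
  expect_equal(m[length(m)], m[1], tolerance = 1e-10)
})

test_that("comparing a PDE run against itself gives zero discrepancy", {
  cfg <- stripe_config(geometry = "cartesian1d", L = 10, Nx = 100,
                       T_end = 1800, snap_dt = 900)
  pd <- run_pde(cfg)
  fake <- list(t = vapply(pd$snapshots, `[[`, numeric(1), "t"),
               x = pd$x,
               rho_mean = vapply(pd$snapshots, `[[`, numeric(length(pd$x)),
                                 "rho"))
  cmp <- compare_hybrid_pde(fake, pd, times = 1800)
  expect_equal(cmp$l1_rel, 0, tolerance = 1e-12)
  expect_equal(cmp$linf_rel, 0, tolerance = 1e-12)
})

test_that("PDE runs are deterministic", {
  cfg <- stripe_config(geometry = "radial", L = 10, Nx = 100,
                       T_end = 1800, snap_dt = 900)
  a <- run_pde(cfg); b <- run_pde(cfg)
  expect_identical(a$snapshots[[length(a$snapshots)]]$rho,
                   b$snapshots[[length(b$snapshots)]]$rho)
})
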