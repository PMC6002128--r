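# Shared fixtures and independent oracles for the test suite.

.fixture_cache <- new.env(parent = emptyenv())

# Memoized quasi-steady motility table at default parameters.
get_table <- function() {
  if (is.null(.fixture_cache$tab)) {
    sp <- signaling_params()
    .fixture_cache$tab <- motility_table(zmax = 1.05 * sp$Zw, dz = 0.005)
  }
  .fixture_cache$tab
}

# Independent oracle for the phospho-protein quasi-steady state: relax the
# three phosphorylation balance ODEs (written from scratch from the balance
# equations, with the conservation substitutions) to steady state with
# deSolve. Shares no code with solve_phospho().
oracle_phospho <- function(m, z, p = signaling_params(), t_end = 2e3) {
  A <- 1 / (1 + exp(p$Nr * p$alpha0 * (p$m0 - m)))
  rhs <- function(t, y, parms) {
    Tp <- y[1]; Yp <- y[2]; Bp <- y[3]
    Z <- z / (1 + p$KZ * Yp)
    Y <- (p$Yt - (1 + p$KZ * Z) * Yp) / (1 + p$KY * Tp)
    B <- (p$Bt - (1 + p$KBp * p$Tt * A) * Bp) / (1 + p$KB * Tp)
    list(c(p$kA * (p$Tt * A - Tp) - p$kY * Y * Tp - p$kB * B * Tp,
           p$kY * Y * Tp - p$muY * Yp - p$kZ * Z * Yp,
           p$kB * B * Tp - p$muB * Bp))
  }
  out <- deSolve::lsoda(c(Tp = 0, Yp = 0, Bp = 0), c(0, t_end), rhs, NULL,
                        rtol = 1e-12, atol = 1e-14)
  st <- out[nrow(out), -1]
  list(Tp = unname(st[1]), Yp = unname(st[2]), Bp = unname(st[3]))
}

# Residuals of the three balance equations, coded independently, for
# validating any candidate (Tp, Yp, Bp).
phospho_residuals <- function(st, m, z, p = signaling_params()) {
  A <- 1 / (1 + exp(p$Nr * p$alpha0 * (p$m0 - m)))
  Z <- z / (1 + p$KZ * st$Yp)
  Y <- (p$Yt - (1 + p$KZ * Z) * st$Yp) / (1 + p$KY * st$Tp)
  B <- (p$Bt - (1 + p$KBp * p$Tt * A) * st$Bp) / (1 + p$KB * st$Tp)
  c(p$kA * (p$Tt * A - st$Tp) - p$kY * Y * st$Tp - p$kB * B * st$Tp,
    p$kY * Y * st$Tp - p$muY * st$Yp - p$kZ * Z * st$Yp,
    p$kB * B * st$Tp - p$muB * st$Bp)
}

# Plain bisection on the methylation balance, independent of uniroot.
oracle_mstar <- function(z, p = signaling_params(), lo = 0, hi = 3,
                         tol = 1e-10) {
  f <- function(m) methylation_rhs(m, z, p)
  flo <- f(lo)
  for (k in 1:200) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (hi - lo < tol) break
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
  }
  (lo + hi) / 2
}

# Linear lookup in a motility table (test-local convenience).
interp_z <- function(tab, z, col) {
  stats::approx(tab$z, tab[[col]], xout = z, rule = 2)$y
}
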