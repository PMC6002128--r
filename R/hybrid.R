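#' Initialize an agent population
#'
#' Places `n_init` cells with positions drawn from a centred Gaussian of
#' standard deviation `sigma0` (truncated to the domain), all with internal
#' states at the wild-type equilibrium (`z = Zw`, `m = m0`), in the running
#' state with uniformly random headings.
#'
#' @param config a [stripe_config()].
#' @param d spatial dimension (1 or 2; 2 is square-domain test-grade).
#' @return an object of class `agent_population`: a list with matrix `x`
#'   (n x d positions, mm), matrix `heading` (n x d unit vectors), logical
#'   `moving`, numeric `z` (uM) and `m`.
#' @export
init_population <- function(config, d = 1) {
  n <- config$n_init
  L <- config$L
  x <- matrix(stats::rnorm(n * d, 0, config$sigma0), ncol = d)
  x[x > L] <- L; x[x < -L] <- -L
  heading <- random_headings(n, d)
  pop <- list(x = x, heading = heading,
              moving = rep(TRUE, n),
              z = rep(config$signaling$Zw, n),
              m = rep(config$signaling$m0, n),
              d = d)
  class(pop) <- "agent_population"
  pop
}

random_headings <- function(n, d) {
  if (d == 1) matrix(sample(c(-1, 1), n, replace = TRUE), ncol = 1)
  else {
    th <- stats::runif(n, 0, 2 * pi)
    cbind(cos(th), sin(th))
  }
}

#' @export
print.agent_population <- function(x, ...) {
  cat(sprintf("<agent_population> %d cells (%dD), %.1f%% running, mean z=%.3f uM\n",
              nrow(x$x), x$d, 100 * mean(x$moving), mean(x$z)))
  invisible(x)
}

#' Create a field grid
#'
#' Node-centred finite-volume grid for AHL and nutrient over `[-L, L]`
#' (1D). Boundary nodes carry half volumes; no-flux boundaries.
#'
#' @param L domain half-length (mm).
#' @param dx node spacing (mm).
#' @param n0 initial nutrient level.
#' @return a list of class `field_grid` with `x` (node coordinates), `h`,
#'   `n`, `dx`, `vol`.
#' @export
field_grid <- function(L, dx = 0.1, n0 = 1) {
  xg <- seq(-L, L, by = dx)
  M <- length(xg)
  vol <- rep(dx, M); vol[c(1, M)] <- dx / 2
  structure(list(x = xg, h = rep(0, M), n = rep(n0, M), dx = dx, L = L,
                 vol = vol),
            class = "field_grid")
}

nearest_node <- function(xpos, grid) {
  j <- round((xpos - grid$x[1]) / grid$dx) + 1L
  pmin(pmax(j, 1L), length(grid$x))
}

#' Advance internal states of all cells
#'
#' One step of the CheZ/methylation dynamics for every cell, using the AHL
#' and nutrient levels at the nearest field node. The CheZ branch equation is
#' linear with frozen coefficients over the step, so it is integrated with
#' its exact exponential factor. Methylation either tracks its quasi-steady
#' level `m*(z)` (default; the methylation time scale is much shorter than
#' the CheZ time scale) or is advanced explicitly with the full rhs.
#'
#' @param pop an `agent_population` (1D positions used for field lookup).
#' @param fields a `field_grid`.
#' @param dt step (s).
#' @param config a `stripe_config`.
#' @param table optional precomputed [motility_table()] for the quasi-steady
#'   methylation lookup.
#' @param m_mode `"quasi_steady"` or `"explicit"`.
#' @return the population with updated `z` and `m`.
#' @export
step_internal <- function(pop, fields, dt, config, table = NULL,
                          m_mode = c("quasi_steady", "explicit")) {
  m_mode <- match.arg(m_mode)
  sp <- config$signaling
  j <- nearest_node(pop$x[, 1], fields)
  kV <- config$fields$r * fields$n[j]
  e <- exp(-kV * dt)
  on <- fields$h[j] < sp$h0
  pop$z <- ifelse(on, sp$Zw + (pop$z - sp$Zw) * e, pop$z * e)
  if (m_mode == "quasi_steady") {
    if (is.null(table))
      table <- motility_table(zmax = config$zmax, dz = config$table_dz,
                              sig_params = sp, mot_params = config$motility)
    pop$m <- interp_table(table, pop$z, "mstar")
  } else {
    pop$m <- pop$m + dt * vapply(seq_along(pop$z), function(i)
      methylation_rhs(pop$m[i], pop$z[i], sp), numeric(1))
  }
  pop
}

#' Advance cell positions by one velocity-jump step
#'
#' Running cells displace ballistically by `s0 * heading * dt` and reflect
#' at the domain walls; each then tumbles with probability
#' `1 - exp(-lambda * dt)`. Tumbling cells resume running with probability
#' `1 - exp(-mu * dt)`, drawing a fresh uniform heading.
#'
#' @param pop an `agent_population`.
#' @param dt step (s).
#' @param lambda,mu per-cell switching rates (s^-1), recycled.
#' @param s0 run speed (mm/s).
#' @param L domain half-length (mm); reflection applies per coordinate
#'   (square domain in 2D).
#' @return the updated population.
#' @export
step_motion <- function(pop, dt, lambda, mu, s0, L) {
  n <- nrow(pop$x)
  lambda <- rep_len(lambda, n); mu <- rep_len(mu, n)
  mov <- pop$moving
  if (any(mov)) {
    pop$x[mov, ] <- pop$x[mov, , drop = FALSE] +
      s0 * pop$heading[mov, , drop = FALSE] * dt
    for (k in seq_len(pop$d)) {
      hi <- pop$x[, k] > L
      if (any(hi)) { pop$x[hi, k] <- 2 * L - pop$x[hi, k]
                     pop$heading[hi, k] <- -pop$heading[hi, k] }
      lo <- pop$x[, k] < -L
      if (any(lo)) { pop$x[lo, k] <- -2 * L - pop$x[lo, k]
                     pop$heading[lo, k] <- -pop$heading[lo, k] }
    }
  }
  u <- stats::runif(n)
  stopped <- mov & (u < 1 - exp(-lambda * dt))
  started <- !mov & (u < 1 - exp(-mu * dt))
  pop$moving[stopped] <- FALSE
  if (any(started)) {
    pop$moving[started] <- TRUE
    pop$heading[started, ] <- random_headings(sum(started), pop$d)
  }
  pop
}

#' Cell division step
#'
#' Each cell divides with probability `1 - exp(-kV * dt)` where
#' `kV = r * n(x)` is the local growth rate (exact for the Poisson division
#' process at any step size). Daughters appear at the mother's position,
#' inherit `(z, m)` and the mother's movement state, and get a fresh
#' uniform heading.
#'
#' @param pop an `agent_population`.
#' @param fields a `field_grid`.
#' @param dt step (s).
#' @param r maximum growth rate (s^-1).
#' @return the population, possibly enlarged.
#' @export
step_division <- function(pop, fields, dt, r) {
  j <- nearest_node(pop$x[, 1], fields)
  kV <- r * fields$n[j]
  divide <- stats::runif(nrow(pop$x)) < 1 - exp(-kV * dt)
  if (any(divide)) {
    nd <- sum(divide)
    pop$x <- rbind(pop$x, pop$x[divide, , drop = FALSE])
    pop$heading <- rbind(pop$heading, random_headings(nd, pop$d))
    pop$moving <- c(pop$moving, pop$moving[divide])
    pop$z <- c(pop$z, pop$z[divide])
    pop$m <- c(pop$m, pop$m[divide])
  }
  pop
}

#' Advance the AHL and nutrient fields
#'
#' Per-cell delta sources are deposited on the nearest node
#' (`alpha_d / vol` per unit time); nutrient is consumed multiplicatively at
#' rate `gamma_d` per co-located cell; diffusion (no-flux) and AHL decay are
#' integrated implicitly, unconditionally stably.
#'
#' @param fields a `field_grid`.
#' @param pop an `agent_population` (or `NULL` for cell-free evolution).
#' @param dt step (s).
#' @param params a [field_params()] bundle.
#' @return the updated `field_grid`.
#' @export
step_fields <- function(fields, pop, dt, params = field_params()) {
  M <- length(fields$x)
  counts <- numeric(M)
  if (!is.null(pop) && nrow(pop$x) > 0) {
    j <- nearest_node(pop$x[, 1], fields)
    tj <- tabulate(j, nbins = M)
    counts <- as.numeric(tj)
  }
  h <- (fields$h + dt * params$alpha_d * counts / fields$vol) *
    exp(-params$beta * dt)
  n <- fields$n * exp(-params$gamma_d * counts / fields$vol * dt)
  fields$h <- implicit_diffuse(h, params$Dh, dt, fields$dx, fields$vol)
  fields$n <- implicit_diffuse(n, params$Dn, dt, fields$dx, fields$vol)
  if (any(fields$h < -1e-12) || any(fields$n < -1e-12))
    stop("field step produced negative concentration")
  fields$h[fields$h < 0] <- 0
  fields$n[fields$n < 0] <- 0
  fields
}

# Backward-Euler no-flux finite-volume diffusion + linear decay (R-level
# reference used by the step functions; the run engines use the compiled
# equivalent).
implicit_diffuse <- function(u, D, dt, dx, vol, decay = 0) {
  M <- length(u)
  fa <- c(0, rep(1, M - 1), 0)
  aw <- D * fa[1:M] / dx
  ae <- D * fa[2:(M + 1)] / dx
  lo <- -dt * aw / vol
  up <- -dt * ae / vol
  di <- 1 + dt * (aw + ae) / vol + dt * decay
  # Thomas
  for (i in 2:M) {
    w <- lo[i] / di[i - 1]
    di[i] <- di[i] - w * up[i - 1]
    u[i] <- u[i] - w * u[i - 1]
  }
  u[M] <- u[M] / di[M]
  for (i in (M - 1):1) u[i] <- (u[i] - up[i] * u[i + 1]) / di[i]
  u
}

#' Run the hybrid agent-based model
#'
#' One realization of the coupled agent/field simulation in 1D: cells carry
#' `(x, heading, moving, z)` with methylation at quasi-steady state, move by
#' a velocity-jump process with rates looked up from the precomputed z-table,
#' divide as a Poisson process at rate `kV = r n(x)`, and source the AHL field
#' that in turn suppresses their CheZ. The loop advances fields and internal
#' states on `dt_field` and motion on `dt_motion`; snapshots are stored
#' every `snap_dt`. Deterministic given `config$seed`.
#'
#' @param config a [stripe_config()] (geometry `"cartesian1d"`).
#' @param table optional precomputed [motility_table()]; built from the
#'   config if missing.
#' @param seed RNG seed override (defaults to `config$seed`).
#' @param freeze_internal if `TRUE`, hold every cell's `z` fixed (used for
#'   diffusion cross-checks).
#' @param no_growth if `TRUE`, disable cell division.
#' @return an object of class `hybrid_run`: list of snapshots (each with
#'   `t`, `x`, `dir`, `moving`, `z`, `h`, `n`), the field node coordinates
#'   `x_nodes`, the `config` and a [run_manifest()].
#' @export
run_hybrid <- function(config, table = NULL, seed = config$seed,
                       freeze_internal = FALSE, no_growth = FALSE) {
  if (config$geometry != "cartesian1d")
    stop("run_hybrid supports cartesian1d geometry; use the step functions ",
         "to compose 2D test runs")
  if (is.null(table)) {
    m_fixed <- if (config$mode == "cherb") config$m_fixed else NULL
    table <- motility_table(zmax = config$zmax, dz = config$table_dz,
                            sig_params = config$signaling,
                            mot_params = config$motility, m_fixed = m_fixed)
  }
  fp <- config$fields; sp <- config$signaling
  t0 <- proc.time()[["elapsed"]]
  set.seed(seed)
  pop <- init_population(config, d = 1)
  nsteps <- round(config$T_end / config$dt_field)
  snap_steps <- unique(round(seq(0, config$T_end, by = config$snap_dt) /
                               config$dt_field))
  snap_steps <- snap_steps[snap_steps <= nsteps]
  snaps <- hybrid_run_cpp(
    x0 = pop$x[, 1], dir0 = pop$heading[, 1],
    moving0 = as.integer(pop$moving), z0 = pop$z,
    L = config$L, dx = config$dx_field,
    ztab = table$z, lamtab = table$lambda0, mutab = table$mu0,
    s0 = config$motility$s0, Zw = sp$Zw, h0_thresh = sp$h0,
    r = fp$r, Dh = fp$Dh, Dn = fp$Dn, alpha_d = fp$alpha_d,
    beta = fp$beta, gamma_d = fp$gamma_d,
    dt_motion = config$dt_motion, dt_field = config$dt_field,
    T_end = config$T_end, snap_steps = as.integer(snap_steps),
    freeze_internal = freeze_internal, no_growth = no_growth)
  out <- list(snapshots = snaps,
              x_nodes = seq(-config$L, config$L, by = config$dx_field),
              config = config, seed = seed,
              manifest = run_manifest(config,
                                      proc.time()[["elapsed"]] - t0))
  class(out) <- "hybrid_run"
  out
}

#' @export
print.hybrid_run <- function(x, ...) {
  last <- x$snapshots[[length(x$snapshots)]]
  cat(sprintf("<hybrid_run> %d snapshots, final t=%.2f h, %d cells\n",
              length(x$snapshots), last$t / 3600, length(last$x)))
  invisible(x)
}

#' Run an ensemble of hybrid realizations
#'
#' Repeats [run_hybrid()] with seeds `config$seed + 0:(n-1)` and returns the
#' individual runs plus the ensemble-mean density profile at each snapshot
#' time (histogram on `dx_bin` bins, normalized by `rho_s`).
#'
#' @param config a [stripe_config()].
#' @param n number of realizations (default `config$n_realizations`).
#' @param dx_bin histogram bin width (mm).
#' @return a list with `runs`, `t` (snapshot times), `x` (bin centres) and
#'   `rho_mean` (matrix: bins x times).
#' @export
run_hybrid_ensemble <- function(config, n = config$n_realizations,
                                dx_bin = 0.1) {
  m_fixed <- if (config$mode == "cherb") config$m_fixed else NULL
  table <- motility_table(zmax = config$zmax, dz = config$table_dz,
                          sig_params = config$signaling,
                          mot_params = config$motility, m_fixed = m_fixed)
  runs <- lapply(seq_len(n) - 1L, function(k)
    run_hybrid(config, table = table, seed = config$seed + k))
  breaks <- seq(-config$L, config$L, by = dx_bin)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  times <- vapply(runs[[1]]$snapshots, `[[`, numeric(1), "t")
  rho_mean <- matrix(0, length(mids), length(times))
  for (rn in runs) {
    for (s in seq_along(rn$snapshots)) {
      cnt <- graphics::hist(rn$snapshots[[s]]$x, breaks = breaks,
                            plot = FALSE)$counts
      rho_mean[, s] <- rho_mean[, s] +
        cnt / (config$fields$rho_s * dx_bin) / n
    }
  }
  list(runs = runs, t = times, x = mids, rho_mean = rho_mean)
}

#' Density histograms of an agent snapshot
#'
#' The spatial density is a histogram of positions on `dx_bin` bins,
#' normalized by the density scale (`counts / (rho_s * dx_bin)`); the joint
#' (x, z) density uses rectangular cells of `dx_bin` by `dz_bin` normalized
#' by `norm` cells per unit.
#'
#' @param snapshot one element of `hybrid_run$snapshots` (needs `x`, `z`).
#' @param L domain half-length (mm).
#' @param dx_bin,dz_bin bin sizes (mm, uM).
#' @param rho_s density scale (cells/mm).
#' @param norm normalization count for the joint histogram.
#' @param zmax top of the z-range (uM).
#' @return a list with `x` (bin centres), `rho`, `z` (z-bin centres) and
#'   matrix `rho_z` (x-bins by z-bins).
#' @export
density_histograms <- function(snapshot, L, dx_bin = 0.1, dz_bin = 0.03,
                               rho_s = 1000, norm = 100, zmax = 1.3) {
  if (length(snapshot$x) == 0) stop("empty snapshot")
  xb <- seq(-L, L, by = dx_bin)
  if (xb[length(xb)] < L) xb <- c(xb, L)
  zb <- seq(0, zmax, by = dz_bin)
  if (zb[length(zb)] < zmax) zb <- c(zb, zmax)
  xi <- findInterval(snapshot$x, xb, rightmost.closed = TRUE,
                     all.inside = TRUE)
  zi <- findInterval(pmin(snapshot$z, zmax), zb, rightmost.closed = TRUE,
                     all.inside = TRUE)
  counts <- table(factor(xi, levels = seq_len(length(xb) - 1)),
                  factor(zi, levels = seq_len(length(zb) - 1)))
  rho_z <- matrix(as.numeric(counts), length(xb) - 1, length(zb) - 1) / norm
  rho <- tabulate(xi, nbins = length(xb) - 1) / (rho_s * dx_bin)
  list(x = (xb[-1] + xb[-length(xb)]) / 2, rho = rho,
       z = (zb[-1] + zb[-length(zb)]) / 2, rho_z = rho_z)
}
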