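#' Initialize the mean-field density
#'
#' Builds the initial `(space x z)` density for the PDE model: a Gaussian
#' inoculum in space (`rho0 * P(x)` with `P` the N(0, sigma0^2) density in
#' 1D; `1/(4*sqrt(2*pi)) * exp(-xi^2/8)` in the radial geometry), with all
#' mass at the wild-type CheZ level — the delta in z is realized by placing
#' the whole z-integral in the single z-cell containing `Zw`, cell-averaged
#' so the spatial marginal is grid-exact. AHL starts at zero and nutrient at
#' `n0`.
#'
#' @param config a [stripe_config()].
#' @return a list of class `density_field` with `x` (cell centres), `zc`
#'   (z-cell centres), `dx`, `dz`, `rho_z` (Nx x Nz), `h`, `n`, `geometry`.
#' @export
init_pde <- function(config) {
  sp <- config$signaling
  Nx <- config$Nx; Nz <- config$Nz
  if (sp$Zw >= config$zmax)
    stop("Zw lies outside the z-grid; increase zmax_factor")
  # Align the z-grid so Zw falls exactly on a cell centre: the inoculum's
  # delta layer then carries D(Zw) at every resolution, which makes front
  # propagation grid-convergent (D varies steeply around Zw).
  jz <- round(sp$Zw * Nz / config$zmax + 0.5)
  jz <- min(max(jz, 1L), Nz - 2L)
  dz <- sp$Zw / (jz - 0.5)
  zc <- (seq_len(Nz) - 0.5) * dz
  if (config$geometry == "cartesian1d") {
    dx <- 2 * config$L / Nx
    x <- -config$L + (seq_len(Nx) - 0.5) * dx
  } else {
    dx <- config$L / Nx
    x <- (seq_len(Nx) - 0.5) * dx
  }
  # both geometries share the 1D Gaussian line profile of the inoculum
  marg <- config$rho0 * stats::dnorm(x, 0, config$sigma0)
  rho_z <- matrix(0, Nx, Nz)
  rho_z[, jz] <- marg / dz
  structure(list(x = x, zc = zc, dx = dx, dz = dz, rho_z = rho_z,
                 h = rep(0, Nx), n = rep(config$fields$n0, Nx),
                 geometry = config$geometry),
            class = "density_field")
}

#' @export
print.density_field <- function(x, ...) {
  cat(sprintf("<density_field> %s, Nx=%d Nz=%d, mass=%.4g\n",
              x$geometry, length(x$x), length(x$zc), field_mass(x)))
  invisible(x)
}

#' Total cell mass of a density field
#'
#' `sum rho_z dx dz` with the radial volume weight `xi` in the radial
#' geometry (the constant 2*pi factor is omitted throughout).
#'
#' @param field a `density_field`.
#' @return total nondimensional mass.
#' @export
field_mass <- function(field) {
  w <- if (field$geometry == "radial") field$x else rep(1, length(field$x))
  sum(w * rowSums(field$rho_z)) * field$dx * field$dz
}

# Resolve the tabulated diffusivity D(z) at the z-cell centres for the
# config's mode and geometry dimension.
resolve_Dz <- function(config, zc, table = NULL) {
  if (is.null(table)) {
    m_fixed <- if (config$mode == "cherb") config$m_fixed else NULL
    table <- motility_table(zmax = config$zmax, dz = config$table_dz,
                            sig_params = config$signaling,
                            mot_params = config$motility, m_fixed = m_fixed)
  }
  col <- if (config$geometry == "radial") "D2" else "D1"
  interp_table(table, zc, col)
}

# Split the macro step to satisfy the z-advection CFL with velocity
# kappa * max|g| <= kappa * r * n0 * max(Zw, zmax).
resolve_dt <- function(config, dz) {
  vmax <- config$kappa * config$fields$r * config$fields$n0 *
    max(config$signaling$Zw, config$zmax)
  dt_cfl <- 0.4 * dz / vmax
  min(config$dt, dt_cfl)
}

#' Advance the mean-field PDE by one (or more) steps
#'
#' One operator-split IMEX step of the density equation: implicit spatial
#' diffusion with z-dependent diffusivity `D(z)`, conservative first-order
#' upwind advection in z with velocity `kappa * g(z, h)`, exact exponential
#' growth `r n`, then the AHL/nutrient reaction-diffusion update.
#'
#' @param field a `density_field`.
#' @param config the `stripe_config`.
#' @param dt step size (s); defaults to the config step reduced to the
#'   z-advection CFL limit.
#' @param nsteps number of steps.
#' @param Dz optional precomputed diffusivities at the z-cell centres.
#' @param growth if `FALSE`, the growth term is switched off (growth rate set to zero).
#' @param advect if `FALSE`, the z-advection term is switched off.
#' @return the advanced `density_field`.
#' @export
step_pde <- function(field, config, dt = NULL, nsteps = 1, Dz = NULL,
                     growth = TRUE, advect = TRUE) {
  if (is.null(dt)) dt <- resolve_dt(config, field$dz)
  if (is.null(Dz)) Dz <- resolve_Dz(config, field$zc)
  fp <- config$fields
  snaps <- pde_run_cpp(field$rho_z, field$h, field$n,
                       geometry = if (field$geometry == "radial") 1L else 0L,
                       dx = field$dx, zc = field$zc, Dz = Dz,
                       kappa = if (advect) config$kappa else 0,
                       r = if (growth) fp$r else 0,
                       Zw = config$signaling$Zw,
                       h0_thresh = config$signaling$h0,
                       Dh = fp$Dh, Dn = fp$Dn, alpha = fp$alpha,
                       beta = fp$beta, gamma = fp$gamma,
                       dt = dt, nsteps = as.integer(nsteps),
                       snap_steps = as.integer(nsteps), store_rhoz = TRUE)
  last <- snaps[[length(snaps)]]
  field$rho_z <- last$rho_z
  field$h <- last$h
  field$n <- last$n
  field
}

#' Run the mean-field PDE model
#'
#' Integrates the density PDE coupled to the AHL and nutrient fields from
#' the standard Gaussian inoculum to `config$T_end`, storing snapshots every
#' `config$snap_dt`. Deterministic.
#'
#' @param config a [stripe_config()].
#' @param table optional precomputed [motility_table()].
#' @param store_rhoz keep the full `(x, z)` density in each snapshot (the
#'   spatial marginal `rho` is always kept).
#' @return an object of class `pde_run`: list of snapshots (`t`, `rho`,
#'   `h`, `n`, optionally `rho_z`), grid vectors `x`, `zc`, the `config`
#'   and a [run_manifest()].
#' @export
run_pde <- function(config, table = NULL, store_rhoz = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  field <- init_pde(config)
  Dz <- resolve_Dz(config, field$zc, table)
  dt <- resolve_dt(config, field$dz)
  nsteps <- ceiling(config$T_end / dt)
  dt <- config$T_end / nsteps
  snap_steps <- unique(round(seq(0, config$T_end, by = config$snap_dt) / dt))
  snap_steps <- snap_steps[snap_steps <= nsteps]
  fp <- config$fields
  snaps <- pde_run_cpp(field$rho_z, field$h, field$n,
                       geometry = if (field$geometry == "radial") 1L else 0L,
                       dx = field$dx, zc = field$zc, Dz = Dz,
                       kappa = config$kappa, r = fp$r,
                       Zw = config$signaling$Zw,
                       h0_thresh = config$signaling$h0,
                       Dh = fp$Dh, Dn = fp$Dn, alpha = fp$alpha,
                       beta = fp$beta, gamma = fp$gamma,
                       dt = dt, nsteps = as.integer(nsteps),
                       snap_steps = as.integer(snap_steps),
                       store_rhoz = store_rhoz)
  out <- list(snapshots = snaps, x = field$x, zc = field$zc,
              dx = field$dx, dz = field$dz, dt = dt, config = config,
              manifest = run_manifest(config, proc.time()[["elapsed"]] - t0))
  class(out) <- "pde_run"
  out
}

#' @export
print.pde_run <- function(x, ...) {
  last <- x$snapshots[[length(x$snapshots)]]
  cat(sprintf("<pde_run> %s, %d snapshots, final t=%.2f h, peak rho=%.3f\n",
              x$config$geometry, length(x$snapshots), last$t / 3600,
              max(last$rho)))
  invisible(x)
}

#' @export
plot.pde_run <- function(x, times = NULL, ...) {
  tt <- vapply(x$snapshots, `[[`, numeric(1), "t")
  if (is.null(times)) times <- tt[length(tt)]
  idx <- vapply(times, function(ti) which.min(abs(tt - ti)), integer(1))
  ylim <- c(0, max(vapply(x$snapshots[idx], function(s) max(s$rho),
                          numeric(1))))
  graphics::plot(x$x, x$snapshots[[idx[1]]]$rho, type = "l",
                 xlab = "position (mm)", ylab = "normalized density",
                 ylim = ylim, ...)
  if (length(idx) > 1)
    for (k in seq_along(idx)[-1])
      graphics::lines(x$x, x$snapshots[[idx[k]]]$rho, col = k)
  invisible(x)
}

#' Run the reduced switch-diffusivity model
#'
#' The scalar limit obtained by assuming CheZ is slaved to its steady state
#' (either `Zw` or 0 depending on whether AHL is below threshold):
#' `d rho/dt = Lap(Dbar(h) rho) + r n rho`, with the diffusivity a step
#' function of the AHL level and the flux in the form `grad(Dbar * rho)`.
#'
#' @param config a [stripe_config()].
#' @param table optional precomputed [motility_table()].
#' @return an object of class `pde_run` (scalar snapshots: `t`, `rho`, `h`,
#'   `n`).
#' @export
run_reduced_model <- function(config, table = NULL) {
  t0 <- proc.time()[["elapsed"]]
  field <- init_pde(config)
  rho0 <- rowSums(field$rho_z) * field$dz
  if (is.null(table))
    table <- motility_table(zmax = config$zmax, dz = config$table_dz,
                            sig_params = config$signaling,
                            mot_params = config$motility)
  col <- if (config$geometry == "radial") "D2" else "D1"
  D_on <- interp_table(table, config$signaling$Zw, col)
  D_off <- interp_table(table, 0, col)
  dt <- min(config$dt, 2)
  nsteps <- ceiling(config$T_end / dt)
  dt <- config$T_end / nsteps
  snap_steps <- unique(round(seq(0, config$T_end, by = config$snap_dt) / dt))
  snap_steps <- snap_steps[snap_steps <= nsteps]
  fp <- config$fields
  snaps <- reduced_run_cpp(rho0, field$h, field$n,
                           geometry = if (field$geometry == "radial") 1L else 0L,
                           dx = field$dx, D_on = D_on, D_off = D_off,
                           r = fp$r, h0_thresh = config$signaling$h0,
                           Dh = fp$Dh, Dn = fp$Dn, alpha = fp$alpha,
                           beta = fp$beta, gamma = fp$gamma, dt = dt,
                           nsteps = as.integer(nsteps),
                           snap_steps = as.integer(snap_steps))
  out <- list(snapshots = snaps, x = field$x, dx = field$dx, dt = dt,
              config = config, reduced = TRUE,
              manifest = run_manifest(config, proc.time()[["elapsed"]] - t0))
  class(out) <- "pde_run"
  out
}

#' Compare hybrid-ensemble and PDE density profiles
#'
#' Relative L1 and Linf distances between the ensemble-mean hybrid density
#' and the PDE marginal at matched times, on the hybrid histogram bins (the
#' PDE profile is interpolated to the bin centres). Also reports front
#' positions from both models.
#'
#' @param hybrid_out result of [run_hybrid_ensemble()].
#' @param pde_out result of [run_pde()] on the matching scenario.
#' @param times times (s) to compare; defaults to the last common snapshot.
#' @param threshold front-detection threshold for the front comparison.
#' @return a data.frame with columns `t`, `l1_rel`, `linf_rel`,
#'   `front_hybrid`, `front_pde`.
#' @export
compare_hybrid_pde <- function(hybrid_out, pde_out, times = NULL,
                               threshold = 0.1) {
  tp <- vapply(pde_out$snapshots, `[[`, numeric(1), "t")
  th <- hybrid_out$t
  if (is.null(times)) times <- max(intersect(th, tp))
  rows <- lapply(times, function(ti) {
    ih <- which.min(abs(th - ti)); ip <- which.min(abs(tp - ti))
    rh <- hybrid_out$rho_mean[, ih]
    rp <- stats::approx(pde_out$x, pde_out$snapshots[[ip]]$rho,
                        xout = hybrid_out$x, rule = 2)$y
    fh <- front_position(hybrid_out$x, rh, threshold)
    fp <- front_position(pde_out$x, pde_out$snapshots[[ip]]$rho, threshold)
    data.frame(t = ti,
               l1_rel = sum(abs(rh - rp)) / sum(rp),
               linf_rel = max(abs(rh - rp)) / max(rp),
               front_hybrid = fh, front_pde = fp)
  })
  do.call(rbind, rows)
}
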