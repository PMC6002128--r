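#' Single-flagellum switching rates
#'
#' Empirical dependence of the flagellar motor switching rates on CheYp:
#' `lambda_f = a1 * exp(b1 * Yp)` (CCW -> CW) and
#' `mu_f = a2 * exp(-(b2 - Yp)^4 / c)` (CW -> CCW). Since `b2 < 0`, `mu_f`
#' is evaluated literally with no clamping.
#'
#' @param Yp CheYp concentration (uM), vectorized.
#' @param params a [motility_params()] bundle.
#' @return a list with components `lambda_f` and `mu_f` (s^-1).
#' @export
flagellum_rates <- function(Yp, params = motility_params()) {
  list(lambda_f = params$a1 * exp(params$b1 * Yp),
       mu_f     = params$a2 * exp(-(params$b2 - Yp)^4 / params$c))
}

#' Probability of exactly i flagella rotating CCW
#'
#' With `nf` independent two-state flagella, each CCW with probability
#' `mu_f / (lambda_f + mu_f)`, the number of CCW flagella is binomial.
#'
#' @param i number of CCW flagella, integer in `0:nf` (vectorized).
#' @param lambda_f,mu_f single-flagellum switching rates (s^-1).
#' @param params a [motility_params()] bundle.
#' @return probabilities.
#' @export
p_ccw <- function(i, lambda_f, mu_f, params = motility_params()) {
  if (any(i < 0L) || any(i > params$nf)) stop("i must lie in 0:nf")
  stats::dbinom(i, params$nf, mu_f / (lambda_f + mu_f))
}

#' Run and tumble probabilities
#'
#' A cell runs when at least `w` of its `nf` flagella rotate CCW:
#' `P_run = sum_{i=w}^{nf} P_CCW(i)`, `P_tumble = 1 - P_run`.
#'
#' @inheritParams p_ccw
#' @return a list with components `p_run` and `p_tumble`.
#' @export
run_tumble_probs <- function(lambda_f, mu_f, params = motility_params()) {
  p_run <- stats::pbinom(params$w - 1L, params$nf,
                         mu_f / (lambda_f + mu_f), lower.tail = FALSE)
  list(p_run = p_run, p_tumble = 1 - p_run)
}

# Whole-cell rates from a CheYp value (the voting step shared by the
# wild-type and mutant pipelines). Switches between run and tumble are
# dominated by the marginal flagellum: a runner with exactly w CCW flagella
# tumbles when one of the w switches to CW, and a tumbler with w-1 CCW
# flagella starts running when one of the remaining nf-w+1 switches to CCW.
rates_from_Yp <- function(Yp, params = motility_params()) {
  fr <- flagellum_rates(Yp, params)
  nf <- params$nf; w <- params$w
  p  <- fr$mu_f / (fr$lambda_f + fr$mu_f)
  Pw   <- stats::dbinom(w, nf, p)
  Pwm1 <- stats::dbinom(w - 1L, nf, p)
  prun <- stats::pbinom(w - 1L, nf, p, lower.tail = FALSE)
  lam <- w * fr$lambda_f * Pw / prun
  mu  <- (nf - w + 1L) * fr$mu_f * Pwm1 / (1 - prun)
  list(lambda = lam, mu = mu, lambda_f = fr$lambda_f, mu_f = fr$mu_f,
       p_run = prun)
}

#' Whole-cell run/tumble switching rates
#'
#' Maps an intracellular state `(m, z)` to the run -> tumble rate `lambda`
#' and tumble -> run rate `mu` through the signaling quasi-steady state and
#' the flagellar voting rule:
#' `lambda = w * lambda_f * P_CCW(w) / P_run` and
#' `mu = (nf - w + 1) * mu_f * P_CCW(w - 1) / P_tumble`.
#'
#' @param m methylation level.
#' @param z total CheZ (uM).
#' @param sig_params a [signaling_params()] bundle.
#' @param mot_params a [motility_params()] bundle.
#' @return a list of class `turning_rates` with `lambda`, `mu` (s^-1) plus
#'   the underlying `lambda_f`, `mu_f`, `p_run` and `Yp`.
#' @examples
#' sp <- signaling_params()
#' cell_rates(steady_methylation(sp$Zw, sp), sp$Zw)
#' @export
cell_rates <- function(m, z, sig_params = signaling_params(),
                       mot_params = motility_params()) {
  Yp <- solve_phospho(m, z, sig_params)$Yp
  out <- rates_from_Yp(Yp, mot_params)
  out$Yp <- Yp
  class(out) <- "turning_rates"
  out
}

#' @export
print.turning_rates <- function(x, ...) {
  cat(sprintf("<turning_rates> lambda=%.5g mu=%.5g (s^-1), Yp=%.5g uM\n",
              x$lambda, x$mu, x$Yp))
  invisible(x)
}

#' Mean fraction of time spent running
#'
#' `mu / (lambda + mu)` evaluated at the quasi-steady methylation level
#' `m = m*(z)`.
#'
#' @param z total CheZ (uM), vectorized.
#' @param sig_params,mot_params parameter bundles.
#' @return run-time fraction(s) in (0, 1).
#' @examples
#' run_fraction(1.23)   # ~0.9: mostly running at wild-type CheZ
#' @export
run_fraction <- function(z, sig_params = signaling_params(),
                         mot_params = motility_params()) {
  vapply(z, function(zi) {
    ms <- steady_methylation(zi, sig_params)
    r <- cell_rates(ms, zi, sig_params, mot_params)
    r$mu / (r$lambda + r$mu)
  }, numeric(1))
}

#' Effective diffusion coefficient of a cell
#'
#' The long-time diffusivity of the velocity-jump process with frozen total
#' CheZ `z` and quasi-steady methylation:
#' `D(z) = s0^2 * mu0 / (d * lambda0 * (mu0 + lambda0))`, where `lambda0(z)`
#' and `mu0(z)` are the whole-cell switching rates at `m = m*(z)` and `d` is
#' the space dimension.
#'
#' @param z total CheZ (uM), vectorized.
#' @param d space dimension, 1, 2 or 3.
#' @param sig_params,mot_params parameter bundles.
#' @return diffusivity in mm^2/s.
#' @export
effective_diffusion <- function(z, d = 1,
                                sig_params = signaling_params(),
                                mot_params = motility_params()) {
  if (!(d %in% c(1, 2, 3))) stop("d must be 1, 2 or 3")
  vapply(z, function(zi) {
    ms <- steady_methylation(zi, sig_params)
    r <- cell_rates(ms, zi, sig_params, mot_params)
    mot_params$s0^2 * r$mu / (d * r$lambda * (r$mu + r$lambda))
  }, numeric(1))
}

#' Turning rates and diffusivity for the CheR-CheB- double mutant
#'
#' In the CheR-CheB- knockout the methylation machinery is absent: `R`, `Bt`
#' and `Bp` are all zero and the methylation level stays frozen at its value
#' `m_fixed` at the time of mutation. The phospho system is solved with the
#' CheB branch removed and the voting pipeline applied unchanged.
#'
#' @param m_fixed frozen methylation level.
#' @param z total CheZ (uM), vectorized.
#' @param d space dimension for the diffusivity.
#' @param sig_params,mot_params parameter bundles.
#' @return a data.frame with columns `z`, `Yp`, `lambda`, `mu`, `D`.
#' @export
cherb_mutant_rates <- function(m_fixed, z, d = 2,
                               sig_params = signaling_params(),
                               mot_params = motility_params()) {
  rows <- lapply(z, function(zi) {
    Yp <- solve_phospho(m_fixed, zi, sig_params, mutant_cherb = TRUE)$Yp
    r <- rates_from_Yp(Yp, mot_params)
    data.frame(z = zi, Yp = Yp, lambda = r$lambda, mu = r$mu,
               D = mot_params$s0^2 * r$mu / (d * r$lambda * (r$mu + r$lambda)))
  })
  do.call(rbind, rows)
}

#' Tabulate quasi-steady single-cell quantities over a CheZ grid
#'
#' Precomputes `m*(z)`, `Yp*(z)`, the whole-cell rates `lambda0(z)`,
#' `mu0(z)`, the run fraction and the effective diffusivities `D1`, `D2`
#' (1D and 2D) on a uniform z-grid. The simulators interpolate linearly in
#' this table instead of re-solving the signaling system per cell per step;
#' all tabulated quantities are smooth in `z` so linear interpolation at the
#' default spacing is accurate well below solver tolerances that matter.
#'
#' @param zmax upper end of the grid (uM); the grid is `[0, zmax]`.
#' @param dz grid spacing (uM).
#' @param sig_params,mot_params parameter bundles.
#' @param m_fixed if non-`NULL`, tabulate the CheR-CheB- mutant pipeline at
#'   this frozen methylation level instead of `m*(z)`.
#' @return a data.frame of class `motility_table` with columns `z`, `mstar`,
#'   `Yp`, `lambda0`, `mu0`, `run_frac`, `D1`, `D2`.
#' @examples
#' tab <- motility_table(zmax = 1.3, dz = 0.05)
#' head(tab)
#' @export
motility_table <- function(zmax = 1.05 * sig_params$Zw, dz = 0.005,
                           sig_params = signaling_params(),
                           mot_params = motility_params(),
                           m_fixed = NULL) {
  zg <- seq(0, zmax, by = dz)
  if (zg[length(zg)] < zmax) zg <- c(zg, zmax)
  rows <- lapply(zg, function(zi) {
    if (is.null(m_fixed)) {
      ms <- steady_methylation(zi, sig_params)
      Yp <- solve_phospho(ms, zi, sig_params)$Yp
    } else {
      ms <- m_fixed
      Yp <- solve_phospho(ms, zi, sig_params, mutant_cherb = TRUE)$Yp
    }
    r <- rates_from_Yp(Yp, mot_params)
    s0sq <- mot_params$s0^2
    data.frame(z = zi, mstar = ms, Yp = Yp, lambda0 = r$lambda, mu0 = r$mu,
               run_frac = r$mu / (r$lambda + r$mu),
               D1 = s0sq * r$mu / (1 * r$lambda * (r$mu + r$lambda)),
               D2 = s0sq * r$mu / (2 * r$lambda * (r$mu + r$lambda)))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("motility_table", "data.frame")
  out
}

# Linear interpolation into a motility_table column, constant beyond ends.
interp_table <- function(tab, z, col) {
  stats::approx(tab$z, tab[[col]], xout = z, rule = 2)$y
}
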