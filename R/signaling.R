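#' Mean receptor activity
#'
#' Probability that the receptor-kinase complex is active at mean methylation
#' level `m`: `A(m) = 1 / (1 + exp(Nr * alpha0 * (m0 - m)))`. A logistic in
#' `m` with a sharp transition near the reference level `m0`.
#'
#' @param m methylation level (dimensionless), vectorized.
#' @param params a [signaling_params()] bundle.
#' @return activity in (0, 1), strictly increasing in `m`.
#' @examples
#' receptor_activity(1, signaling_params())  # 0.5 at the reference level
#' @export
receptor_activity <- function(m, params = signaling_params()) {
  1 / (1 + exp(params$Nr * params$alpha0 * (params$m0 - m)))
}

#' Free CheR concentration
#'
#' `R(m) = Rt / (1 + KR * Tt * (1 - A(m)))`: CheR is sequestered by inactive
#' receptors, so the free concentration rises with activity.
#'
#' @inheritParams receptor_activity
#' @return CheR concentration in uM, in (0, Rt].
#' @export
cheR_concentration <- function(m, params = signaling_params()) {
  A <- receptor_activity(m, params)
  params$Rt / (1 + params$KR * params$Tt * (1 - A))
}

# Given a trial Yp, close the remaining quasi-steady-state relations in
# closed form. The phosphotransfer balance for CheYp fixes the product
# kY*Y*Tp, which combined with the CheY conservation relation yields Tp
# explicitly; the CheBp balance then gives Bp. Returns the residual of the
# CheA autophosphorylation balance, which the outer root search drives to 0.
# feasible = FALSE marks trial values beyond the physical branch (Tp would
# be negative or infinite).
phospho_closure <- function(Yp, m, z, p, mutant_cherb = FALSE) {
  A  <- receptor_activity(m, p)
  Z  <- z / (1 + p$KZ * Yp)
  S  <- p$muY * Yp + p$kZ * Z * Yp         # = kY * Y * Tp at QSS
  a  <- p$kY * (p$Yt - (1 + p$KZ * Z) * Yp)
  den <- a - S * p$KY
  if (!is.finite(den) || den <= 0)
    return(list(feasible = FALSE, residual = -Inf))
  Tp <- S / den
  if (mutant_cherb) {
    Bp <- 0; B <- 0
  } else {
    q  <- 1 + p$KBp * p$Tt * A
    Bp <- p$kB * Tp * p$Bt / (p$muB * (1 + p$KB * Tp) + p$kB * Tp * q)
    B  <- (p$Bt - q * Bp) / (1 + p$KB * Tp)
  }
  Y <- (p$Yt - (1 + p$KZ * Z) * Yp) / (1 + p$KY * Tp)
  residual <- p$kA * (p$Tt * A - Tp) - p$kY * Y * Tp - p$kB * B * Tp
  list(feasible = TRUE, residual = residual,
       Tp = Tp, Yp = Yp, Bp = Bp, Y = Y, Z = Z, B = B)
}

#' Solve the phospho-protein quasi-steady state
#'
#' Solves the algebraic system for the phosphorylated fractions (Tp, Yp, Bp)
#' at a given methylation level `m` and total CheZ `z`. The three balance
#' equations (CheA autophosphorylation, CheYp phosphotransfer, CheBp
#' phosphotransfer) together with the protein conservation relations are
#' reduced to a single scalar root problem in Yp on the physical branch and
#' solved by bracketed bisection/interpolation. This guarantees the unique
#' nonnegative root and is robust through the ultrasensitive transition where
#' Newton-type iterations diverge.
#'
#' @param m methylation level.
#' @param z total CheZ concentration (uM), `z >= 0`.
#' @param params a [signaling_params()] bundle.
#' @param mutant_cherb if `TRUE`, model the CheR-CheB- double knockout:
#'   `R = Bt = Bp = 0` in the algebraic system (methylation is then frozen
#'   externally).
#' @param tol absolute tolerance on Yp (uM).
#' @return a list of class `phospho_state` with components `Tp`, `Yp`, `Bp`
#'   (phosphorylated, uM), `Y`, `Z`, `B` (free unphosphorylated, uM), and
#'   `residual` (the CheA balance residual at the root).
#' @examples
#' ps <- solve_phospho(1, 1.23)
#' ps$Yp
#' @export
solve_phospho <- function(m, z, params = signaling_params(),
                          mutant_cherb = FALSE, tol = 1e-13) {
  stopifnot(is.finite(m), length(m) == 1L, length(z) == 1L, z >= 0)
  p <- params
  fres <- function(Yp) phospho_closure(Yp, m, z, p, mutant_cherb)$residual

  # Locate the upper end of the physical branch: the closure blows up
  # (Tp -> +Inf) where the CheY conservation margin vanishes; the residual
  # is +kA*Tt*A > 0 at Yp = 0 and -> -Inf at the branch end, so a sign
  # change is guaranteed inside.
  feas_margin <- function(Yp) {
    Z <- z / (1 + p$KZ * Yp)
    p$kY * (p$Yt - (1 + p$KZ * Z) * Yp) - (p$muY * Yp + p$kZ * Z * Yp) * p$KY
  }
  ub <- p$Yt
  if (feas_margin(ub) <= 0) {
    ub <- stats::uniroot(feas_margin, c(0, p$Yt), tol = 1e-13)$root
    ub <- ub * (1 - 1e-12)
  }
  if (!(fres(0) > 0))
    stop("solve_phospho: no physical root (residual at Yp=0 not positive)")
  f_ub <- fres(ub)
  while (!is.finite(f_ub) || f_ub > 0) {
    if (is.finite(f_ub) && f_ub > 0)
      stop("solve_phospho: failed to bracket the physical root")
    ub <- ub * (1 - 1e-9)
    f_ub <- fres(ub)
  }
  Yp <- stats::uniroot(fres, c(0, ub), tol = tol)$root
  out <- phospho_closure(Yp, m, z, p, mutant_cherb)
  out$feasible <- NULL
  if (out$Yp < 0 || out$Bp < 0 || out$Tp < 0 || out$Y < -1e-12 || out$B < -1e-12)
    stop("solve_phospho: nonphysical root")
  class(out) <- "phospho_state"
  out
}

#' @export
print.phospho_state <- function(x, ...) {
  cat(sprintf("<phospho_state> Tp=%.6g Yp=%.6g Bp=%.6g (uM), residual=%.3g\n",
              x$Tp, x$Yp, x$Bp, x$residual))
  invisible(x)
}

#' Methylation dynamics right-hand side
#'
#' `dm/dt = f(m, z) = kR * R(m) * (1 - A(m)) - kBp * Bp(m, z) * A(m)`:
#' methylation by free CheR acting on inactive receptors, demethylation by
#' CheBp acting on active ones. `Bp` comes from [solve_phospho()].
#'
#' @inheritParams solve_phospho
#' @return dm/dt in s^-1.
#' @export
methylation_rhs <- function(m, z, params = signaling_params()) {
  A  <- receptor_activity(m, params)
  R  <- cheR_concentration(m, params)
  Bp <- solve_phospho(m, z, params)$Bp
  params$kR * R * (1 - A) - params$kBp * Bp * A
}

#' CheZ dynamics right-hand side
#'
#' Total CheZ relaxes to the wild-type level `Zw` at the cell growth rate
#' `kV` while AHL is below the quorum threshold `h0`; above threshold cheZ
#' transcription is off and CheZ is diluted by growth:
#' `dz/dt = kV * (Zw - z)` if `h < h0`, `-kV * z` if `h >= h0`. The boundary
#' `h == h0` belongs to the suppressed branch.
#'
#' @param z total CheZ (uM), vectorized.
#' @param h local AHL level (nondimensional), vectorized (recycled).
#' @param kV local growth rate (s^-1), vectorized (recycled).
#' @param params a [signaling_params()] bundle.
#' @param smooth optional steepness of a logistic blend between the two
#'   branches (`NULL`, the default, keeps the sharp switch). The blended form
#'   is a convenience for sensitivity checks, not part of the baseline model.
#' @return dz/dt in uM/s.
#' @export
chez_rhs <- function(z, h, kV, params = signaling_params(), smooth = NULL) {
  on_branch  <- kV * (params$Zw - z)   # h < h0: production on
  off_branch <- -kV * z                # h >= h0: dilution only
  if (is.null(smooth)) {
    ifelse(h < params$h0, on_branch, off_branch)
  } else {
    s <- 1 / (1 + exp(-smooth * (h - params$h0)))
    (1 - s) * on_branch + s * off_branch
  }
}

#' Quasi-steady methylation level
#'
#' Solves `f(m, z) = 0` for the stationary methylation level `m*(z)` by a
#' bracketed root search on `m` in `bracket` (widened once by a factor 2 if
#' the sign change is not found).
#'
#' @param z total CheZ (uM), scalar.
#' @param params a [signaling_params()] bundle.
#' @param bracket search interval for `m`.
#' @param tol root tolerance on `m`.
#' @return the stationary methylation level `m*`.
#' @examples
#' msz <- steady_methylation(1.23)
#' abs(methylation_rhs(msz, 1.23)) < 1e-10
#' @export
steady_methylation <- function(z, params = signaling_params(),
                               bracket = c(0, 3), tol = 1e-12) {
  f <- function(m) methylation_rhs(m, z, params)
  lo <- bracket[1]; hi <- bracket[2]
  flo <- f(lo); fhi <- f(hi)
  if (sign(flo) == sign(fhi)) {
    mid <- (lo + hi) / 2; half <- (hi - lo)
    lo <- mid - half; hi <- mid + half
    flo <- f(lo); fhi <- f(hi)
    if (sign(flo) == sign(fhi))
      stop("steady_methylation: no sign change of f(m, z) in bracket ",
           "[", lo, ", ", hi, "]")
  }
  stats::uniroot(f, c(lo, hi), f.lower = flo, f.upper = fhi, tol = tol)$root
}

#' Quasi-steady CheYp concentration
#'
#' CheYp at the stationary methylation level: the `Yp` component of
#' [solve_phospho()] evaluated at `m = m*(z)`. Decreasing in `z` (more CheZ,
#' faster CheYp dephosphorylation).
#'
#' @param z total CheZ (uM); vectorized.
#' @param params a [signaling_params()] bundle.
#' @return CheYp concentration(s) in uM.
#' @export
steady_Yp <- function(z, params = signaling_params()) {
  vapply(z, function(zi) {
    ms <- steady_methylation(zi, params)
    solve_phospho(ms, zi, params)$Yp
  }, numeric(1))
}
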