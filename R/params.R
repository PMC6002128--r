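#' Intracellular signaling parameters
#'
#' Rate constants, association constants and total protein concentrations for
#' the chemotaxis signaling pathway (receptor activity, CheA/CheY/CheB
#' phosphorylation cycle, receptor methylation, CheZ turnover). Defaults are
#' the baseline values for the engineered stripe-forming strain.
#'
#' Units: first-order rates in s^-1, second-order rates in uM^-1 s^-1,
#' association constants in uM^-1, concentrations in uM. `h0` is the
#' nondimensional AHL threshold above which cheZ transcription is shut off;
#' `Zw` is the wild-type steady-state total CheZ. `m0`, `alpha0` and `Nr` set
#' the receptor free-energy dependence on the mean methylation level.
#'
#' @param ... named overrides of the defaults, e.g. `Zw = 0.81`.
#' @return an object of class `signaling_params` (a validated named list).
#' @examples
#' p <- signaling_params()
#' p$Zw
#' signaling_params(Zw = 0.81)$Zw
#' @export
signaling_params <- function(...) {
  p <- list(
    kR   = 3.82e-2,  # methylation rate via CheR
    kBp  = 3.25,     # demethylation rate via CheBp
    kA   = 100,      # receptor-CheA autophosphorylation
    kY   = 130,      # phosphotransfer to CheY
    kB   = 7.5,      # phosphotransfer to CheB
    kZ   = 8.45,     # CheYp dephosphorylation by CheZ
    muY  = 0.1,      # CheYp spontaneous dephosphorylation
    muB  = 1,        # CheBp spontaneous dephosphorylation
    KB   = 0.25,
    KBp  = 6.5,
    KR   = 0.15,
    KY   = 0.65,
    KZ   = 1,
    Bt   = 2,
    Rt   = 0.3,
    Tt   = 5 / 3,
    Yt   = 18,
    Zw   = 1.23,
    h0   = 0.25,
    m0   = 1,
    alpha0 = 1.7,
    Nr   = 6
  )
  p <- merge_params(p, list(...), "signaling_params")
  pos <- c("kR", "kBp", "kA", "kY", "kB", "kZ", "muB", "KB", "KBp", "KR",
           "KY", "KZ", "Bt", "Rt", "Tt", "Yt", "Zw")
  for (nm in pos) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || p[[nm]] <= 0)
      stop("signaling parameter '", nm, "' must be a positive scalar")
  }
  if (p$muY < 0) stop("muY must be nonnegative")
  if (p$h0 <= 0 || p$h0 >= 1) stop("h0 must lie in (0, 1)")
  structure(p, class = "signaling_params")
}

#' Cell movement parameters
#'
#' Flagellar switching-rate coefficients, the flagellar voting rule and the
#' run speed. `lambda_f = a1 * exp(b1 * Yp)` is the CCW->CW switching rate of
#' a single motor and `mu_f = a2 * exp(-(b2 - Yp)^4 / c)` the CW->CCW rate,
#' both functions of the CheYp concentration `Yp` (uM). A cell with `nf`
#' independent flagella runs when at least `w` of them rotate CCW.
#'
#' @param ... named overrides, e.g. `s0 = 0.03`.
#' @return an object of class `motility_params`.
#' @examples
#' motility_params()$s0
#' @export
motility_params <- function(...) {
  p <- list(
    s0 = 0.02,       # run speed, mm/s
    a1 = 0.0174001,  # s^-1
    b1 = 1.32887,    # uM^-1
    a2 = 12.0809,    # s^-1
    b2 = -5.83762,   # uM
    c  = 2892.12,    # uM^4
    nf = 8L,
    w  = 6L
  )
  p <- merge_params(p, list(...), "motility_params")
  p$nf <- as.integer(p$nf); p$w <- as.integer(p$w)
  stopifnot(p$s0 > 0, p$a1 > 0, p$a2 > 0, p$c > 0)
  if (p$w < 1L || p$w > p$nf) stop("need 1 <= w <= nf")
  structure(p, class = "motility_params")
}

#' Growth, AHL and nutrient parameters
#'
#' Reaction-diffusion parameters for the quorum-sensing signal AHL (h) and
#' the nutrient (n), plus cell growth. The per-cell growth rate is
#' `kV = r n` with the rate constant derived as `log(2)/doubling_time`; each cell secretes AHL at
#' rate `alpha_d` and consumes nutrient at rate `gamma_d * n`. For the
#' mean-field model the population-level coefficients are
#' `alpha = alpha_d * rho_s` and `gamma = gamma_d * rho_s`, where `rho_s` is
#' the cell density scale used to nondimensionalize the density.
#'
#' @param doubling_time cell doubling time at full nutrient, in seconds
#'   (default 30 minutes); the growth rate is derived as `log(2)/doubling_time`.
#' @param ... named overrides of `Dh`, `Dn`, `alpha_d`, `beta`, `gamma_d`,
#'   `n0`, `rho_s`.
#' @return an object of class `field_params` with derived entries `r`,
#'   `alpha` and `gamma`.
#' @examples
#' fp <- field_params()
#' fp$r                      # ~= 3.85e-4 / s
#' log(2) / fp$doubling_time # identical by construction
#' @export
field_params <- function(doubling_time = 30 * 60, ...) {
  p <- list(
    Dh      = 5e-4,      # AHL diffusivity, mm^2/s
    Dn      = 7.7e-4,    # nutrient diffusivity, mm^2/s
    alpha_d = 1e-6,      # AHL production per cell, 1/s
    beta    = 1e-3,      # AHL degradation, 1/s
    gamma_d = 1.155e-6,  # nutrient consumption per cell, 1/s
    n0      = 1,         # initial nondimensional nutrient
    rho_s   = 1000       # density scale, cells/mm
  )
  p <- merge_params(p, list(...), "field_params")
  stopifnot(doubling_time > 0, p$Dh > 0, p$Dn > 0, p$beta >= 0,
            p$alpha_d >= 0, p$gamma_d >= 0, p$rho_s > 0)
  p$doubling_time <- doubling_time
  p$r <- log(2) / doubling_time
  p$alpha <- p$alpha_d * p$rho_s
  p$gamma <- p$gamma_d * p$rho_s
  structure(p, class = "field_params")
}

# Apply named overrides, rejecting unknown keys (with the offending key named).
merge_params <- function(defaults, overrides, what) {
  if (length(overrides) == 0L) return(defaults)
  nms <- names(overrides)
  if (is.null(nms) || any(nms == ""))
    stop(what, ": overrides must be named")
  unknown <- setdiff(nms, names(defaults))
  if (length(unknown))
    stop(what, ": unknown parameter(s): ", paste(unknown, collapse = ", "))
  defaults[nms] <- overrides
  defaults
}

#' @export
print.signaling_params <- function(x, ...) {
  cat("<signaling_params>\n")
  print(unlist(x)); invisible(x)
}

#' @export
print.motility_params <- function(x, ...) {
  cat("<motility_params>\n")
  print(unlist(x)); invisible(x)
}

#' @export
print.field_params <- function(x, ...) {
  cat("<field_params>  (r, alpha, gamma derived)\n")
  print(unlist(x)); invisible(x)
}
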