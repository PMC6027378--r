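#' @include AllClasses.R
NULL

#' Kinetic parameter set
#'
#' Builds a [KineticParams-class] with the published defaults (SI units).
#' Two closures have no published value and are exposed explicitly:
#' \describe{
#'   \item{kc}{growth saturation coefficient of the proliferation law
#'     `rg = Kg(tau) * cgc / (kc * rhoCell * epsC + cgc)`. The default is
#'     chosen so that, for a fully packed monolayer (`epsC = 1`),
#'     half-saturation occurs at a fluid glucose concentration equal to half
#'     the default inlet concentration (4.5 kg/m^3), i.e.
#'     `kc * rhoCell ~ 2.25 kg/m^3` (kc = 0.01236). Not a published
#'     value; override to taste.}
#'   \item{rd}{death rate, default 0: cell loss arises only through the pH
#'     viability gate.}
#' }
#' Cell migration (`dcMig`) defaults to 0 (quantitatively negligible).
#'
#' @param vm,km,kg0,alphaC,betaC,keq,dgf,dgc,dlf,rhoCell,rhoCb,dc,kc,rd,dcMig,phThreshold
#'   see [KineticParams-class] for units.
#' @return a [KineticParams-class].
#' @export
kineticParams <- function(vm = 3.9e-5, km = 6.3e-3, kg0 = 5.8e-6,
                          alphaC = 0.8761, betaC = 104.5, keq = 0.1,
                          dgf = 1e-9, dgc = 1e-10, dlf = 1.4e-9,
                          rhoCell = 182, rhoCb = 182, dc = 13e-6,
                          kc = 0.01236, rd = 0, dcMig = 0,
                          phThreshold = 6.8) {
  new("KineticParams", vm = vm, km = km, kg0 = kg0, alphaC = alphaC,
      betaC = betaC, keq = keq, dgf = dgf, dgc = dgc, dlf = dlf,
      rhoCell = rhoCell, rhoCb = rhoCb, dc = dc, kc = kc, rd = rd,
      dcMig = dcMig, phThreshold = phThreshold)
}

#' Volume of one cell, used to convert cell counts to volume fractions
#'
#' Cells are taken as spheres of diameter `dc` (the monolayer thickness), so
#' `epsC = N * pi/6 * dc^3` for a number density N.
#'
#' @param p a [KineticParams-class].
#' @return cell volume in m^3.
#' @export
cellVolume <- function(p) pi / 6 * p@dc^3

#' Michaelis-Menten glucose uptake rate
#'
#' `Rg = Vm * eb * c / (Km + eb * c)` with `eb` the cell volume fraction and
#' `c` the cell-phase glucose concentration. Bounded above by `Vm`.
#'
#' @param cgc cell-phase glucose concentration (kg/m^3).
#' @param epsB cell volume fraction in `[0, 1]`.
#' @param p a [KineticParams-class].
#' @return uptake rate (kg/m^3/s), same shape as the inputs.
#' @export
glucoseUptakeRate <- function(cgc, epsB, p = kineticParams()) {
  if (any(cgc < 0)) stop("cgc must be nonnegative")
  if (any(epsB < 0 | epsB > 1)) stop("epsB must lie in [0, 1]")
  x <- epsB * cgc
  ifelse(x > 0, p@vm * x / (p@km + x), 0)
}

#' Lactate production rate
#'
#' Lactate is produced at twice the glucose consumption rate.
#'
#' @param rg glucose uptake rate (kg/m^3/s).
#' @return lactate production rate (kg/m^3/s).
#' @export
lactateRate <- function(rg) {
  if (any(rg < 0)) stop("rg must be nonnegative")
  2 * rg
}

#' Culture pH from the local lactate concentration
#'
#' Affine relation `pH = 7.4 - 0.0406 * cl` (cl in kg/m^3).
#'
#' @param cl lactate concentration (kg/m^3).
#' @return pH, same shape as `cl`.
#' @export
phFromLactate <- function(cl) {
  if (any(cl < 0)) stop("cl must be nonnegative")
  7.4 - 0.0406 * cl
}

#' Viability step function
#'
#' Chondrocytes are damaged below the acidity threshold: the gate is 1 at or
#' above the threshold (alive at exactly the boundary) and 0 below it.
#'
#' @param ph local pH.
#' @param threshold viability cutoff (default 6.8).
#' @return 0/1, same shape as `ph`.
#' @export
viabilityStep <- function(ph, threshold = 6.8) as.numeric(ph >= threshold)

#' Shear-stress-modulated growth rate coefficient
#'
#' Piecewise law for the growth coefficient `Kg(tau)`:
#' \itemize{
#'   \item stimulation, `tau` in [0, 0.1) Pa: `Kg0 * (alpha + beta * tau)`;
#'   \item plateau, [0.1, 0.6) Pa: `Kg0 * 11.326`;
#'   \item inhibition, [0.6, 1) Pa: `Kg0 * 2.5 * (1 - tau) * 11.326`;
#'   \item lethal, `tau >= 1` Pa: 0.
#' }
#' With the default `alpha = 0.8761`, `beta = 104.5` 1/Pa the factor is
#' continuous at 0.1 Pa (to ~1e-4) and exactly continuous at 0.6 Pa and 1 Pa.
#'
#' @param tau shear-stress magnitude (Pa), nonnegative.
#' @param p a [KineticParams-class].
#' @return growth coefficient `Kg` (1/s), same shape as `tau`.
#' @export
shearGrowthFactor <- function(tau, p = kineticParams()) {
  if (any(tau < 0)) stop("tau must be nonnegative")
  f <- ifelse(tau < 0.1, p@alphaC + p@betaC * tau,
       ifelse(tau < 0.6, 11.326,
       ifelse(tau < 1.0, 2.5 * (1 - tau) * 11.326, 0)))
  p@kg0 * f
}

#' Local cell proliferation rate
#'
#' `rg = Kg(tau) * cgc / (kc * rhoCell * epsC + cgc)`: growth saturates in
#' the cell-phase glucose concentration, is self-limited by the local cell
#' fraction, and is modulated by shear through [shearGrowthFactor()].
#' A vanishing denominator (no substrate and no cells) returns 0.
#'
#' @param cgc cell-phase glucose concentration (kg/m^3).
#' @param epsC cell volume fraction in `[0, 1]`.
#' @param tau shear-stress magnitude (Pa).
#' @param p a [KineticParams-class].
#' @return growth rate (1/s), same shape as the inputs.
#' @export
growthRate <- function(cgc, epsC, tau, p = kineticParams()) {
  if (any(cgc < 0) || any(tau < 0)) stop("inputs must be nonnegative")
  if (any(epsC < 0 | epsC > 1)) stop("epsC must lie in [0, 1]")
  kg <- shearGrowthFactor(tau, p)
  den <- p@kc * p@rhoCell * epsC + cgc
  ifelse(den > 0, kg * cgc / den, 0)
}
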