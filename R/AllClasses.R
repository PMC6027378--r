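#' @import methods
NULL

#' Parametric four-fiber scaffold unit
#'
#' A scaffold unit is the repeating junction volume of a fibrous scaffold,
#' bounded by an imaginary cube of edge \code{2r}. Each pair of opposite
#' fibers is encoded by one indicator-point displacement: \code{deltaY} sets
#' the primary pair (caps bulging from the top and bottom faces, fiber axes
#' along y) and \code{deltaZ} the secondary pair (front/back faces, axes
#' along z). A displacement \code{delta} is the sagitta of the circular
#' segment the fiber occupies inside the unit, so the fiber diameter follows
#' the sagitta relation \code{D = (r^2 + delta^2)/delta}; \code{delta = 0}
#' is the flat-wall sentinel (no fiber on that pair of faces).
#'
#' @slot r half-edge of the imaginary cube (micrometres).
#' @slot deltaY indicator-point displacement of the primary pair (um).
#' @slot deltaZ indicator-point displacement of the secondary pair (um).
#' @slot culturedSurfaces character subset of
#'   \code{c("bottom","top","front","back")}: faces whose fiber (or flat
#'   wall) carries the initial cell monolayer.
#' @seealso [unitDesign()], [diameterFromDelta()], [voxelize()]
#' @export
setClass("UnitDesign",
  representation(r = "numeric", deltaY = "numeric", deltaZ = "numeric",
                 culturedSurfaces = "character"),
  prototype(r = 100, deltaY = 100, deltaZ = 100,
            culturedSurfaces = "bottom"))

setValidity("UnitDesign", function(object) {
  msg <- character()
  if (length(object@r) != 1L || !is.finite(object@r) || object@r <= 0)
    msg <- c(msg, "r must be a single positive length (um)")
  for (nm in c("deltaY", "deltaZ")) {
    d <- slot(object, nm)
    if (length(d) != 1L || !is.finite(d))
      msg <- c(msg, sprintf("%s must be a single finite number", nm))
    else if (d < 0 || d > object@r)
      msg <- c(msg, sprintf("%s must lie in [0, r] = [0, %g] um", nm, object@r))
  }
  bad <- setdiff(object@culturedSurfaces,
                 c("bottom", "top", "front", "back"))
  if (length(bad))
    msg <- c(msg, paste("unknown cultured surface(s):",
                        paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Labeled voxel grid of one scaffold unit
#'
#' Uniform Cartesian voxelization of the unit (or of a benchmark duct).
#' Every voxel carries exactly one phase label: 0 fluid, 1 solid (inside a
#' fiber cap), 2 biomass (the monolayer shell of thickness `dc` over the
#' cultured surfaces). Perfusion is along the x axis (axis 1).
#'
#' @slot dims integer vector (nx, ny, nz) of voxel counts.
#' @slot spacing voxel edge length (metres).
#' @slot labels integer array dims (nx,ny,nz); 0 fluid / 1 solid / 2 biomass.
#' @slot shellFace integer array, same shape: 0 for non-biomass voxels,
#'   otherwise the id of the cultured face owning the voxel
#'   (1 bottom, 2 top, 3 front, 4 back). Used for per-column monolayer caps.
#' @slot flowAxis integer, axis of perfusion (always 1 = x).
#' @slot design the generating [UnitDesign-class] (or NULL for benchmark
#'   domains built directly).
#' @export
setClass("VoxelDomain",
  representation(dims = "integer", spacing = "numeric",
                 labels = "array", shellFace = "array",
                 flowAxis = "integer", design = "ANY"))

setValidity("VoxelDomain", function(object) {
  msg <- character()
  if (length(object@dims) != 3L || any(object@dims < 1L))
    msg <- c(msg, "dims must be three positive integers")
  if (!identical(dim(object@labels), object@dims))
    msg <- c(msg, "labels shape must match dims")
  if (!all(object@labels %in% 0:2))
    msg <- c(msg, "labels must be 0 (fluid), 1 (solid) or 2 (biomass)")
  if (!identical(dim(object@shellFace), object@dims))
    msg <- c(msg, "shellFace shape must match dims")
  if (any((object@shellFace > 0L) != (object@labels == 2L)))
    msg <- c(msg, "shellFace must mark exactly the biomass voxels")
  if (!identical(object@flowAxis, 1L))
    msg <- c(msg, "flowAxis must be 1 (perfusion along x)")
  if (length(object@spacing) != 1L || object@spacing <= 0)
    msg <- c(msg, "spacing must be a single positive length (m)")
  if (length(msg)) msg else TRUE
})

#' Steady flow solution on the voxel grid
#'
#' Staggered (marker-and-cell) velocity components, cell-centred pressure
#' and shear-stress magnitude. Velocities are zero on faces adjacent to
#' solid voxels (no-slip); the biomass phase is penalized through its
#' viscosity rather than excluded.
#'
#' @slot u,v,w staggered velocity arrays, dims (nx+1,ny,nz), (nx,ny+1,nz),
#'   (nx,ny,nz+1) (m/s).
#' @slot pressure cell-centred gauge pressure (Pa), 0 in solid voxels.
#' @slot shear cell-centred shear-stress magnitude (Pa).
#' @slot massImbalance relative divergence residual of the returned field.
#' @slot iterations outer (pressure) iterations used.
#' @slot converged logical.
#' @slot inletFlux volumetric influx (m^3/s).
#' @export
setClass("FlowField",
  representation(u = "array", v = "array", w = "array",
                 pressure = "array", shear = "array",
                 massImbalance = "numeric", iterations = "integer",
                 converged = "logical", inletFlux = "numeric"))

#' Kinetic and material parameters of the culture model
#'
#' All values in SI units. Defaults are the model's published parameter set
#' (uptake, diffusion and growth constants for a chondrocyte culture):
#' Vm = 3.9e-5 kg/m^3/s, Km = 6.3e-3 kg/m^3, Kg0 = 5.8e-6 1/s,
#' alpha = 0.8761, beta = 104.5 1/Pa, Keq = 0.1, Dgf = 1e-9 m^2/s,
#' Dgc = 1e-10 m^2/s, Dlf = 1.4e-9 m^2/s, rho_cell = 182 kg/m^3,
#' dc = 13e-6 m. See [kineticParams()] for the remaining closures.
#'
#' @slot vm maximal glucose consumption rate (kg/m^3/s).
#' @slot km glucose half-saturation constant (kg/m^3).
#' @slot kg0 maximal static growth rate (1/s).
#' @slot alphaC,betaC intercept (-) and slope (1/Pa) of the low-shear branch
#'   of the shear-growth law.
#' @slot keq interfacial linear equilibrium coefficient (-).
#' @slot dgf,dgc,dlf diffusivities of glucose in fluid/cell phase and of
#'   lactate in fluid (m^2/s).
#' @slot rhoCell cellular density (kg/m^3).
#' @slot rhoCb intrinsic average cell mass density (kg/m^3).
#' @slot dc monolayer (one cell) thickness (m).
#' @slot kc growth saturation coefficient (dimensionless; the product
#'   kc * rhoCell * epsC is a concentration in kg/m^3).
#' @slot rd cell death rate (1/s).
#' @slot dcMig cell migration diffusivity (m^2/s).
#' @slot phThreshold viability cutoff (pH units); cells below it are killed.
#' @export
setClass("KineticParams",
  representation(vm = "numeric", km = "numeric", kg0 = "numeric",
                 alphaC = "numeric", betaC = "numeric", keq = "numeric",
                 dgf = "numeric", dgc = "numeric", dlf = "numeric",
                 rhoCell = "numeric", rhoCb = "numeric", dc = "numeric",
                 kc = "numeric", rd = "numeric", dcMig = "numeric",
                 phThreshold = "numeric"))

setValidity("KineticParams", function(object) {
  msg <- character()
  for (nm in slotNames("KineticParams")) {
    x <- slot(object, nm)
    if (length(x) != 1L || !is.finite(x))
      msg <- c(msg, sprintf("%s must be a single finite number", nm))
    else if (nm != "phThreshold" && x < 0)
      msg <- c(msg, sprintf("%s must be nonnegative", nm))
  }
  if (length(msg)) msg else TRUE
})

#' State of the transient culture on the voxel grid
#'
#' @slot cgf glucose concentration in the fluid phase (kg/m^3), per voxel.
#' @slot cl lactate concentration (kg/m^3), per voxel.
#' @slot epsC cell volume fraction, nonzero only in biomass voxels.
#' @slot time elapsed culture time (s).
#' @slot budgets list with cumulative \code{glucoseConsumed} and
#'   \code{lactateProduced} (kg) and \code{clippedMass} (kg).
#' @export
setClass("CultureState",
  representation(cgf = "array", cl = "array", epsC = "array",
                 time = "numeric", budgets = "list"))

setValidity("CultureState", function(object) {
  msg <- character()
  if (any(object@epsC < -1e-12 | object@epsC > 1 + 1e-12))
    msg <- c(msg, "epsC must lie in [0, 1]")
  if (any(object@cgf < -1e-12) || any(object@cl < -1e-12))
    msg <- c(msg, "concentrations must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Bioreactor operating conditions
#'
#' Stored in SI; construct from the customary bioreactor units with
#' [operatingConditions()].
#'
#' @slot inletVelocity plug inflow velocity (m/s).
#' @slot glin inlet glucose concentration (kg/m^3).
#' @slot initialCellDensity seeded cell density (cells/m^3).
#' @slot duration culture duration (s).
#' @slot dt time step (s).
#' @export
setClass("OperatingConditions",
  representation(inletVelocity = "numeric", glin = "numeric",
                 initialCellDensity = "numeric", duration = "numeric",
                 dt = "numeric"))

setValidity("OperatingConditions", function(object) {
  msg <- character()
  if (object@inletVelocity <= 0) msg <- c(msg, "inletVelocity must be > 0")
  if (object@glin < 0) msg <- c(msg, "glin must be >= 0")
  if (object@initialCellDensity <= 0)
    msg <- c(msg, "initialCellDensity must be > 0")
  if (object@duration < 0) msg <- c(msg, "duration must be >= 0")
  if (object@dt <= 0) msg <- c(msg, "dt must be > 0")
  if (object@duration > 0 && object@dt > object@duration)
    msg <- c(msg, "dt must not exceed duration")
  if (length(msg)) msg else TRUE
})

#' Result of one culture simulation
#'
#' @slot ce culture efficiency, the relative change of the mean cell
#'   density over the biomass shell: (final - initial)/initial.
#' @slot finalMeanDensity mean cell density at the end (cells/cm^3).
#' @slot trajectory per-step diagnostics (data.frame).
#' @slot metrics list: geometry metrics plus mean/max shear in biomass.
#' @slot design the [UnitDesign-class] used.
#' @slot conditions the [OperatingConditions-class] used.
#' @export
setClass("CultureResult",
  representation(ce = "numeric", finalMeanDensity = "numeric",
                 trajectory = "data.frame", metrics = "list",
                 design = "ANY", conditions = "ANY"))

#' A generate-and-test design campaign
#'
#' @slot nCandidates number of sampled candidate designs.
#' @slot seed RNG seed of the campaign.
#' @slot deltaRange sampling interval for displacements (um).
#' @slot results per-candidate table (deltaY, deltaZ, D1, D2, ratio, ce,
#'   attachment area, mean shear, status).
#' @slot candidates list of [UnitDesign-class] objects.
#' @slot best index of the winning candidate (max CE; ties broken by larger
#'   attachment area, then lower index).
#' @export
setClass("DesignCampaign",
  representation(nCandidates = "integer", seed = "integer",
                 deltaRange = "numeric", results = "data.frame",
                 candidates = "list", best = "integer"))

setMethod("show", "UnitDesign", function(object) {
  d1 <- if (object@deltaY > 0) (object@r^2 + object@deltaY^2) / object@deltaY else Inf
  d2 <- if (object@deltaZ > 0) (object@r^2 + object@deltaZ^2) / object@deltaZ else Inf
  cat("UnitDesign: imaginary cube edge", 2 * object@r, "um\n")
  cat(sprintf("  primary pair   deltaY = %6.2f um  D1 = %s\n", object@deltaY,
              if (is.finite(d1)) sprintf("%.1f um", d1) else "flat wall"))
  cat(sprintf("  secondary pair deltaZ = %6.2f um  D2 = %s\n", object@deltaZ,
              if (is.finite(d2)) sprintf("%.1f um", d2) else "flat wall"))
  cat("  cultured surfaces:", paste(object@culturedSurfaces, collapse = ", "),
      "\n")
})

setMethod("show", "VoxelDomain", function(object) {
  n <- object@dims
  cat(sprintf("VoxelDomain: %d x %d x %d voxels, spacing %.3g um\n",
              n[1], n[2], n[3], object@spacing * 1e6))
  tab <- table(factor(object@labels, levels = 0:2,
                      labels = c("fluid", "solid", "biomass")))
  cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
})

setMethod("show", "FlowField", function(object) {
  cat(sprintf(
    "FlowField: inlet flux %.3g m^3/s, mass imbalance %.2g, %d iterations%s\n",
    object@inletFlux, object@massImbalance, object@iterations,
    if (object@converged) "" else " (NOT converged)"))
})

setMethod("show", "CultureResult", function(object) {
  cat(sprintf("CultureResult: CE = %.4f, final mean density %.3g cells/cm^3\n",
              object@ce, object@finalMeanDensity))
  cat(sprintf("  %d recorded steps, mean biomass shear %.4g Pa\n",
              nrow(object@trajectory),
              object@metrics$meanShearBiomass %||% NA_real_))
})

setMethod("show", "DesignCampaign", function(object) {
  cat(sprintf("DesignCampaign: %d candidates, seed %d\n",
              object@nCandidates, object@seed))
  ok <- object@results$status == "ok"
  cat(sprintf("  completed: %d, failed: %d\n", sum(ok), sum(!ok)))
  if (length(object@best) && !is.na(object@best)) {
    b <- object@results[object@best, ]
    cat(sprintf("  best: #%d deltaY = %.1f, deltaZ = %.1f um, CE = %.4f\n",
                object@best, b$deltaY, b$deltaZ, b$ce))
  }
})

`%||%` <- function(a, b) if (is.null(a)) b else a
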