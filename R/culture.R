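#' @include AllClasses.R AllGenerics.R transport.R geometry.R
NULL

#' Construct operating conditions from bioreactor units
#'
#' Inputs use the customary bioreactor units (mm/s, g/cm^3, cells/cm^3,
#' hours) and are converted to SI once here. Defaults are the published
#' operating point: 3 mm/s inlet velocity, 4.5e-3 g/cm^3 inlet glucose,
#' 5e7 cells/cm^3 seeding density, 1 h time step.
#'
#' @param inletVelocityMmS plug inflow velocity (mm/s).
#' @param glinGCm3 inlet glucose concentration (g/cm^3); 1e-3 g/cm^3 =
#'   1 kg/m^3.
#' @param initialCellDensityCm3 seeded density (cells/cm^3).
#' @param durationH culture duration (hours).
#' @param dtH time step (hours).
#' @return an [OperatingConditions-class].
#' @export
operatingConditions <- function(inletVelocityMmS = 3, glinGCm3 = 4.5e-3,
                                initialCellDensityCm3 = 5e7,
                                durationH = 120, dtH = 1) {
  new("OperatingConditions",
      inletVelocity = inletVelocityMmS * 1e-3,
      glin = glinGCm3 * 1e3,
      initialCellDensity = initialCellDensityCm3 * 1e6,
      duration = durationH * 3600,
      dt = dtH * 3600)
}

#' Run one culture simulation and compute its culture efficiency
#'
#' Voxelizes the design, runs the coupled transient simulation under the
#' given operating conditions and evaluates the culture efficiency
#' `CE = (mean final cell density - mean initial)/mean initial` over the
#' biomass shell. Deterministic for fixed inputs.
#'
#' @param design a [UnitDesign-class].
#' @param oc an [OperatingConditions-class].
#' @param p a [KineticParams-class].
#' @param resolution voxels per cube edge.
#' @param control solver settings, see [integrateCulture()].
#' @return a [CultureResult-class].
#' @export
runCulture <- function(design, oc, p = kineticParams(), resolution = 32L,
                       control = list()) {
  domain <- voxelize(design, resolution = resolution, dc = p@dc)
  state0 <- initCultureState(domain, oc@glin, oc@initialCellDensity, p)
  d0 <- meanCellDensity(state0, domain, p)
  sim <- integrateCulture(domain, oc, p, state = state0, control = control)
  d1 <- meanCellDensity(sim$state, domain, p)
  ceVal <- if (d0 > 0) (d1 - d0) / d0 else 0
  metrics <- geometryMetrics(domain)
  nr <- nrow(sim$trajectory)
  metrics$meanShearBiomass <- if (nr) sim$trajectory$meanShearBiomass[nr]
    else NA_real_
  metrics$maxShearBiomass <- if (nr) sim$trajectory$maxShearBiomass[nr]
    else NA_real_
  new("CultureResult", ce = ceVal, finalMeanDensity = d1 * 1e-6,
      trajectory = sim$trajectory, metrics = metrics, design = design,
      conditions = oc)
}

#' Sweep operating conditions for one design
#'
#' Runs [runCulture()] for every condition in the grid; failures are
#' recorded per row and do not stop the sweep. The table is sorted by
#' (inlet velocity, inlet glucose).
#'
#' @param ocList list of [OperatingConditions-class] objects.
#' @param design a [UnitDesign-class].
#' @param p a [KineticParams-class].
#' @param resolution voxels per edge.
#' @param control solver settings.
#' @return data.frame with one row per condition: velocity (mm/s), glin
#'   (g/cm^3), initial density (cells/cm^3), ce, final density, status.
#' @export
sweepConditions <- function(ocList, design, p = kineticParams(),
                            resolution = 16L, control = list()) {
  stopifnot(length(ocList) >= 1)
  rows <- lapply(seq_along(ocList), function(i) {
    oc <- ocList[[i]]
    out <- data.frame(
      velocity_mm_s = oc@inletVelocity * 1e3,
      glin_g_cm3 = oc@glin * 1e-3,
      initialDensity_cm3 = oc@initialCellDensity * 1e-6,
      ce = NA_real_, finalDensity_cm3 = NA_real_,
      status = "ok", stringsAsFactors = FALSE)
    res <- tryCatch(
      runCulture(design, oc, p, resolution = resolution, control = control),
      error = function(e) e)
    if (inherits(res, "error")) {
      out$status <- conditionMessage(res)
    } else {
      out$ce <- res@ce
      out$finalDensity_cm3 <- res@finalMeanDensity
    }
    out
  })
  tab <- do.call(rbind, rows)
  tab[order(tab$velocity_mm_s, tab$glin_g_cm3), , drop = FALSE]
}
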