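#' @include AllClasses.R AllGenerics.R culture.R design_search.R
NULL

.configSchema <- list(
  design = c("r_um", "delta_y_um", "delta_z_um", "cultured_surfaces",
             "resolution"),
  conditions = c("inlet_velocity_mm_s", "glin_g_cm3",
                 "initial_cell_density_cm3", "duration_h", "dt_h"),
  kinetics = c("vm_kg_m3s", "km_kg_m3", "kg0_per_s", "alpha", "beta_per_pa",
               "keq", "dgf_cm2_s", "dgc_cm2_s", "dlf_cm2_s",
               "rho_cell_g_cm3", "dc_um", "kc", "rd_per_s", "dc_mig_cm2_s",
               "ph_threshold"),
  solver = c("scheme", "flow_tol", "viability_mode", "flow_every",
             "max_cells_per_area", "transport_picard"),
  campaign = c("n", "seed", "range_um"))
.configTop <- c(names(.configSchema), "seed", "out_dir", "schema_version")

#' Default run configuration
#'
#' Full configuration with documented defaults: the 200 um unit at the
#' published operating point and parameter table, 32 voxels per edge, 1 h
#' time step. Config files use bioreactor units (um, mm/s, g/cm^3, cells/
#' cm^3, hours); conversion to SI happens once in the constructors.
#'
#' @return nested list (class `scafflowConfig`).
#' @export
defaultConfig <- function() {
  cfg <- list(
    schema_version = 1L,
    design = list(r_um = 100, delta_y_um = 100, delta_z_um = 100,
                  cultured_surfaces = "bottom", resolution = 32L),
    conditions = list(inlet_velocity_mm_s = 3, glin_g_cm3 = 4.5e-3,
                      initial_cell_density_cm3 = 5e7, duration_h = 120,
                      dt_h = 1),
    kinetics = list(vm_kg_m3s = 3.9e-5, km_kg_m3 = 6.3e-3,
                    kg0_per_s = 5.8e-6, alpha = 0.8761, beta_per_pa = 104.5,
                    keq = 0.1, dgf_cm2_s = 1e-5, dgc_cm2_s = 1e-6,
                    dlf_cm2_s = 1.4e-5, rho_cell_g_cm3 = 0.182, dc_um = 13,
                    kc = 0.01236, rd_per_s = 0, dc_mig_cm2_s = 0,
                    ph_threshold = 6.8),
    solver = list(scheme = "be", flow_tol = 1e-8, viability_mode = "remove",
                  flow_every = 1L, max_cells_per_area = NULL,
                  transport_picard = 6L),
    seed = 1L,
    out_dir = ".")
  class(cfg) <- "scafflowConfig"
  cfg
}

.validateConfig <- function(cfg) {
  unknownTop <- setdiff(names(cfg), .configTop)
  if (length(unknownTop))
    stop("unknown config key(s): ", paste(unknownTop, collapse = ", "))
  for (sec in names(.configSchema)) {
    if (is.null(cfg[[sec]])) next
    bad <- setdiff(names(cfg[[sec]]), .configSchema[[sec]])
    if (length(bad))
      stop(sprintf("unknown key(s) in '%s': %s", sec,
                   paste(bad, collapse = ", ")))
  }
  d <- cfg$design
  if (!is.null(d)) {
    r <- d$r_um %||% 100
    for (nm in c("delta_y_um", "delta_z_um")) {
      v <- d[[nm]]
      if (!is.null(v) && (v < 0 || v > r))
        stop(sprintf("design$%s = %g outside [0, r] = [0, %g]", nm, v, r))
    }
    if (!is.null(d$resolution) && d$resolution < 8)
      stop("design$resolution must be at least 8")
    bad <- setdiff(d$cultured_surfaces %||% character(),
                   c("bottom", "top", "front", "back"))
    if (length(bad))
      stop("unknown cultured surface(s): ", paste(bad, collapse = ", "))
  }
  cc <- cfg$conditions
  if (!is.null(cc)) {
    for (nm in c("inlet_velocity_mm_s", "glin_g_cm3",
                 "initial_cell_density_cm3", "dt_h"))
      if (!is.null(cc[[nm]]) && cc[[nm]] <= 0 && nm != "glin_g_cm3")
        stop(sprintf("conditions$%s must be positive", nm))
    if (!is.null(cc$duration_h) && cc$duration_h < 0)
      stop("conditions$duration_h must be nonnegative")
  }
  k <- cfg$kinetics
  if (!is.null(k))
    for (nm in setdiff(names(k), "ph_threshold"))
      if (!is.null(k[[nm]]) && k[[nm]] < 0)
        stop(sprintf("kinetics$%s must be nonnegative", nm))
  invisible(TRUE)
}

#' Load and validate a run configuration
#'
#' Reads a YAML config, rejects unknown keys, validates ranges and fills in
#' the documented defaults for everything omitted.
#'
#' @param path YAML file.
#' @return nested list (class `scafflowConfig`).
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  .validateConfig(raw)
  cfg <- defaultConfig()
  for (sec in names(.configSchema))
    if (!is.null(raw[[sec]]))
      cfg[[sec]] <- modifyList(cfg[[sec]] %||% list(), raw[[sec]])
  for (nm in c("seed", "out_dir", "schema_version"))
    if (!is.null(raw[[nm]])) cfg[[nm]] <- raw[[nm]]
  .validateConfig(cfg)
  class(cfg) <- "scafflowConfig"
  cfg
}

#' Save a configuration as YAML
#'
#' `saveConfig` followed by [loadConfig()] is an identity on validated
#' configurations.
#'
#' @param cfg config list.
#' @param path output YAML file.
#' @return the path, invisibly.
#' @export
saveConfig <- function(cfg, path) {
  .validateConfig(cfg)
  out <- unclass(cfg)
  out$solver <- out$solver[!vapply(out$solver, is.null, logical(1))]
  yaml::write_yaml(out, path, precision = 17L)
  invisible(path)
}

#' Stable hash of a configuration
#'
#' MD5 of the canonical (key-sorted) YAML serialization; embedded in every
#' artifact written by the package so outputs can be traced to their exact
#' configuration.
#'
#' @param cfg config list.
#' @return character MD5 hash.
#' @export
configHash <- function(cfg) {
  canon <- function(x) {
    if (is.list(x)) {
      x <- x[order(names(x))]
      lapply(x, canon)
    } else x
  }
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(canon(unclass(cfg)), tmp, precision = 17L)
  unname(tools::md5sum(tmp))
}

# objects from a config
.configDesign <- function(cfg) {
  d <- cfg$design
  unitDesign(d$delta_y_um, d$delta_z_um, r = d$r_um,
             culturedSurfaces = unlist(d$cultured_surfaces))
}
.configConditions <- function(cfg) {
  cc <- cfg$conditions
  operatingConditions(cc$inlet_velocity_mm_s, cc$glin_g_cm3,
                      cc$initial_cell_density_cm3, cc$duration_h, cc$dt_h)
}
.configParams <- function(cfg) {
  k <- cfg$kinetics
  kineticParams(vm = k$vm_kg_m3s, km = k$km_kg_m3, kg0 = k$kg0_per_s,
                alphaC = k$alpha, betaC = k$beta_per_pa, keq = k$keq,
                dgf = k$dgf_cm2_s * 1e-4, dgc = k$dgc_cm2_s * 1e-4,
                dlf = k$dlf_cm2_s * 1e-4,
                rhoCell = k$rho_cell_g_cm3 * 1e3,
                rhoCb = k$rho_cell_g_cm3 * 1e3, dc = k$dc_um * 1e-6,
                kc = k$kc, rd = k$rd_per_s, dcMig = k$dc_mig_cm2_s * 1e-4,
                phThreshold = k$ph_threshold)
}
.configControl <- function(cfg) {
  s <- cfg$solver
  list(flowTol = s$flow_tol, scheme = s$scheme,
       viabilityMode = s$viability_mode,
       flowEvery = s$flow_every %||% 1L,
       maxCellsPerArea = s$max_cells_per_area,
       transportPicard = s$transport_picard %||% 6L)
}

#' Run a simulation described by a configuration
#'
#' Executes [runCulture()] for a loaded configuration and, if `outDir` is
#' given, writes the trajectory CSV, a VTK field snapshot, a JSON result
#' summary, and archives the configuration verbatim with its hash.
#'
#' @param cfg config list (from [loadConfig()] or [defaultConfig()]).
#' @param outDir output directory (default: the config's `out_dir`; use
#'   `NA` to skip writing).
#' @return the [CultureResult-class], invisibly when writing.
#' @export
runFromConfig <- function(cfg, outDir = cfg$out_dir) {
  .validateConfig(cfg)
  design <- .configDesign(cfg)
  oc <- .configConditions(cfg)
  p <- .configParams(cfg)
  res <- runCulture(design, oc, p, resolution = cfg$design$resolution,
                    control = .configControl(cfg))
  if (is.na(outDir %||% NA)) return(res)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  hash <- configHash(cfg)
  write.csv(cbind(res@trajectory, config_hash = hash),
            file.path(outDir, "trajectory.csv"), row.names = FALSE)
  saveConfig(cfg, file.path(outDir, "config.yaml"))
  jsonlite::write_json(
    list(config_hash = hash, ce = res@ce,
         final_mean_density_cells_cm3 = res@finalMeanDensity,
         metrics = res@metrics),
    file.path(outDir, "result.json"), auto_unbox = TRUE, digits = NA)
  invisible(res)
}

#' Write ready-to-run fixture configurations
#'
#' Emits the study's standard configurations:
#' \describe{
#'   \item{reference_design}{D1 = D2 = 200 um (displacements 100/100).}
#'   \item{improved_design_1}{displacements 7/90 um (D1 ~ 1436 um),
#'     monolayer on the bottom fiber.}
#'   \item{improved_design_2}{displacements 17/40 um (D1 ~ 605 um),
#'     monolayer on all four fibers.}
#'   \item{poiseuille_duct}{empty duct (flat walls), for flow validation.}
#'   \item{campaign_smoke}{5-candidate seeded campaign at coarse settings.}
#' }
#'
#' @param kind one of the names above.
#' @param outDir directory to write into.
#' @return path of the written YAML, invisibly.
#' @export
makeFixtures <- function(kind = c("reference_design", "improved_design_1",
                                  "improved_design_2", "poiseuille_duct",
                                  "campaign_smoke"), outDir = ".") {
  kind <- match.arg(kind)
  cfg <- defaultConfig()
  if (kind == "reference_design") {
    cfg$design$delta_y_um <- 100
    cfg$design$delta_z_um <- 100
  } else if (kind == "improved_design_1") {
    cfg$design$delta_y_um <- 7
    cfg$design$delta_z_um <- 90
  } else if (kind == "improved_design_2") {
    cfg$design$delta_y_um <- 17
    cfg$design$delta_z_um <- 40
    cfg$design$cultured_surfaces <- c("bottom", "top", "front", "back")
  } else if (kind == "poiseuille_duct") {
    cfg$design$delta_y_um <- 0
    cfg$design$delta_z_um <- 0
    cfg$conditions$duration_h <- 0
  } else if (kind == "campaign_smoke") {
    cfg$campaign <- list(n = 5L, seed = 42L, range_um = c(0, 100))
    cfg$design$resolution <- 12L
    cfg$conditions$duration_h <- 4
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(outDir, paste0(kind, ".yaml"))
  saveConfig(cfg, path)
  invisible(path)
}

#' Export simulation fields
#'
#' Writes the phase labels and (if given) flow and culture fields either as
#' a legacy-ASCII VTK structured-points file readable by standard viewers,
#' or as a CSV voxel table with 0-based indices, voxel-center coordinates
#' in um and one column per field. Output is bit-stable for fixed input.
#'
#' @param domain a [VoxelDomain-class].
#' @param path output file.
#' @param format "vtk" or "csv".
#' @param flow optional [FlowField-class].
#' @param state optional [CultureState-class].
#' @return the path, invisibly.
#' @export
exportFields <- function(domain, path, format = c("vtk", "csv"),
                         flow = NULL, state = NULL) {
  format <- match.arg(format)
  n <- domain@dims
  h <- domain@spacing
  fields <- list(label = array(as.numeric(domain@labels), n))
  if (!is.null(flow)) {
    nx <- n[1]; ny <- n[2]; nz <- n[3]
    fields$pressure <- flow@pressure
    fields$shear <- flow@shear
    fields$velocity_x <- 0.5 * array(flow@u[1:nx, , ] + flow@u[2:(nx+1), , ], n)
    fields$velocity_y <- 0.5 * array(flow@v[, 1:ny, ] + flow@v[, 2:(ny+1), ], n)
    fields$velocity_z <- 0.5 * array(flow@w[, , 1:nz] + flow@w[, , 2:(nz+1)], n)
  }
  if (!is.null(state)) {
    fields$glucose <- state@cgf
    fields$lactate <- state@cl
    fields$epsC <- state@epsC
  }
  if (format == "vtk") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("# vtk DataFile Version 3.0",
                 "scafflow voxel fields", "ASCII",
                 "DATASET STRUCTURED_POINTS",
                 sprintf("DIMENSIONS %d %d %d", n[1], n[2], n[3]),
                 sprintf("ORIGIN %.9g %.9g %.9g", h / 2, h / 2, h / 2),
                 sprintf("SPACING %.9g %.9g %.9g", h, h, h),
                 sprintf("POINT_DATA %d", prod(n))), con)
    for (nm in setdiff(names(fields),
                       c("velocity_x", "velocity_y", "velocity_z"))) {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(format(as.numeric(fields[[nm]]), digits = 9,
                        scientific = TRUE, trim = TRUE), con)
    }
    if (!is.null(flow)) {
      writeLines("VECTORS velocity double", con)
      writeLines(paste(
        format(as.numeric(fields$velocity_x), digits = 9, trim = TRUE),
        format(as.numeric(fields$velocity_y), digits = 9, trim = TRUE),
        format(as.numeric(fields$velocity_z), digits = 9, trim = TRUE)), con)
    }
  } else {
    idx <- which(array(TRUE, n), arr.ind = TRUE) - 1L
    tab <- data.frame(x = idx[, 1], y = idx[, 2], z = idx[, 3],
                      x_um = (idx[, 1] + 0.5) * h * 1e6,
                      y_um = (idx[, 2] + 0.5) * h * 1e6,
                      z_um = (idx[, 3] + 0.5) * h * 1e6)
    for (nm in names(fields)) tab[[nm]] <- as.numeric(fields[[nm]])
    write.csv(tab, path, row.names = FALSE)
  }
  invisible(path)
}

#' Write a campaign report
#'
#' Ranked CSV of all candidates plus a machine-readable JSON summary.
#'
#' @param campaign a [DesignCampaign-class].
#' @param outDir output directory.
#' @return invisibly, the two paths.
#' @export
writeCampaignReport <- function(campaign, outDir = ".") {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  res <- campaign@results
  ord <- order(-ifelse(is.na(res$ce), -Inf, res$ce))
  csv <- file.path(outDir, "campaign_ranked.csv")
  write.csv(res[ord, ], csv, row.names = FALSE)
  b <- campaign@results[campaign@best, ]
  js <- file.path(outDir, "campaign_summary.json")
  jsonlite::write_json(
    list(n_candidates = campaign@nCandidates, seed = campaign@seed,
         delta_range_um = campaign@deltaRange,
         completed = sum(res$status == "ok"),
         best = as.list(b[c("candidate", "deltaY", "deltaZ", "D1", "D2",
                            "ratio", "ce", "attachmentArea")])),
    js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, js))
}
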