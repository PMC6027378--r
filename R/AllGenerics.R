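#' @include AllClasses.R
NULL

#' Voxelize a scaffold design into a simulation domain
#'
#' @param design a [UnitDesign-class].
#' @param resolution voxels per cube edge (>= 8).
#' @param dc biomass monolayer thickness (m); defaults to the parameter
#'   set's `dc`.
#' @param ... further arguments for methods.
#' @return a [VoxelDomain-class].
#' @export
setGeneric("voxelize", function(design, resolution = 32L, dc = 13e-6, ...)
  standardGeneric("voxelize"))

#' Minimum free cross-sectional area normal to the flow axis
#'
#' @param domain a [VoxelDomain-class].
#' @return area in m^2 (free = non-solid voxels).
#' @export
setGeneric("minCrossSection", function(domain)
  standardGeneric("minCrossSection"))

#' Geometric metrics of a cultured scaffold unit
#'
#' Attachment area, minimum free cross-section and effective curvature
#' (1/D of the cultured fiber).
#'
#' @param object a [UnitDesign-class] or [VoxelDomain-class].
#' @param ... further arguments for methods.
#' @return named list with `attachmentArea` (m^2), `minCrossSection` (m^2,
#'   needs a voxel domain), `effectiveCurvature` (1/um) and
#'   `attachmentAngle` (degrees).
#' @export
setGeneric("geometryMetrics", function(object, ...)
  standardGeneric("geometryMetrics"))

#' Culture efficiency of a result
#'
#' CE = (mean final cell density - mean initial)/mean initial over the
#' biomass shell.
#' @param object a [CultureResult-class] or [DesignCampaign-class].
#' @return numeric CE (vector for campaigns).
#' @export
setGeneric("ce", function(object) standardGeneric("ce"))

#' @describeIn ce CE of one culture run.
#' @export
setMethod("ce", "CultureResult", function(object) object@ce)

#' @describeIn ce CE values of all completed candidates.
#' @export
setMethod("ce", "DesignCampaign", function(object) object@results$ce)

#' Winning design of a campaign
#' @param object a [DesignCampaign-class].
#' @return the best [UnitDesign-class].
#' @export
setGeneric("bestDesign", function(object) standardGeneric("bestDesign"))

#' @describeIn bestDesign best candidate by CE (ties: larger attachment
#'   area, then lower index).
#' @export
setMethod("bestDesign", "DesignCampaign", function(object) {
  if (is.na(object@best)) stop("campaign has no completed candidate")
  object@candidates[[object@best]]
})

#' Per-step diagnostics of a culture run
#' @param object a [CultureResult-class].
#' @return data.frame of per-step diagnostics.
#' @export
setGeneric("trajectory", function(object) standardGeneric("trajectory"))

#' @describeIn trajectory diagnostics table.
#' @export
setMethod("trajectory", "CultureResult", function(object) object@trajectory)
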