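#' @include AllClasses.R AllGenerics.R
NULL

# face ids used throughout: 1 bottom (z-), 2 top (z+), 3 front (y+), 4 back (y-)
.faceIds <- c(bottom = 1L, top = 2L, front = 3L, back = 4L)

#' Fiber diameter from an indicator-point displacement
#'
#' The displacement `delta` is the sagitta of the circular segment a fiber
#' occupies inside the unit cube, with chord equal to the cube edge `2r`;
#' the fiber diameter is therefore `D = (r^2 + delta^2)/delta`. `D` is
#' minimal (= 2r) when `delta = r` and grows without bound as the cap
#' flattens; `delta = 0` encodes a flat wall and returns `Inf`.
#'
#' @param delta displacement in `[0, r]` (um).
#' @param r half-edge of the imaginary cube (um).
#' @return fiber diameter in um (`Inf` for the flat-wall sentinel).
#' @examples
#' diameterFromDelta(7, 100)    # ~1436 um
#' diameterFromDelta(100, 100)  # 200 um, the tangent minimum
#' @export
diameterFromDelta <- function(delta, r = 100) {
  stopifnot(is.numeric(delta), is.numeric(r), all(r > 0))
  if (any(delta < 0) || any(delta > r))
    stop("delta must lie in [0, r]")
  ifelse(delta == 0, Inf, (r^2 + delta^2) / delta)
}

#' Displacement from a fiber diameter (inverse sagitta relation)
#'
#' Returns the smaller root `delta = (D - sqrt(D^2 - 4 r^2))/2`, so that
#' [diameterFromDelta()] recovers `D`. Diameters below the tangent minimum
#' `2r` have no real solution.
#'
#' @param D fiber diameter (um), `D >= 2r`.
#' @param r half-edge of the imaginary cube (um).
#' @return displacement in um; `0` for `D = Inf` (flat wall).
#' @export
deltaFromDiameter <- function(D, r = 100) {
  stopifnot(is.numeric(D), is.numeric(r), all(r > 0))
  if (any(D < 2 * r))
    stop("D must be >= 2 r (no real sagitta below the tangent diameter)")
  ifelse(is.infinite(D), 0, (D - sqrt(D^2 - 4 * r^2)) / 2)
}

#' Cylindrical-cap attachment area
#'
#' Area of the fiber surface exposed inside the unit: the cap arc,
#' `D * asin(chord/D)`, times the axial span. `D = Inf` gives the flat-face
#' limit `chord * span`.
#'
#' @param D fiber diameter (um); may be `Inf`.
#' @param chord chord of the cap (um), normally the cube edge `2r`.
#' @param span axial extent of the fiber inside the unit (um).
#' @return area in m^2.
#' @examples
#' attachmentArea(1435, 200, 200)  # ~4.01e-8 m^2
#' @export
attachmentArea <- function(D, chord, span) {
  stopifnot(all(chord > 0), all(span > 0))
  if (any(D < chord)) stop("D must be >= chord")
  arc <- ifelse(is.infinite(D), chord, D * asin(chord / D))
  arc * span * 1e-12
}

#' Construct a scaffold unit design
#'
#' @param deltaY displacement of the primary (top/bottom) pair (um).
#' @param deltaZ displacement of the secondary (front/back) pair (um).
#' @param r half-edge of the imaginary cube (um); the published study uses
#'   a 200 um cube, r = 100 um.
#' @param culturedSurfaces faces carrying the initial monolayer.
#' @return a [UnitDesign-class].
#' @export
unitDesign <- function(deltaY, deltaZ, r = 100,
                       culturedSurfaces = "bottom") {
  new("UnitDesign", r = as.numeric(r), deltaY = as.numeric(deltaY),
      deltaZ = as.numeric(deltaZ),
      culturedSurfaces = as.character(culturedSurfaces))
}

#' Fiber diameters of a design
#' @param design a [UnitDesign-class].
#' @return diameter in um (`Inf` for a flat wall).
#' @export
primaryDiameter <- function(design) diameterFromDelta(design@deltaY, design@r)

#' @rdname primaryDiameter
#' @export
secondaryDiameter <- function(design) diameterFromDelta(design@deltaZ, design@r)

#' Attachment angle of the cultured fiber (descriptive)
#'
#' The inclination of the cultured cap surface against the cube face at its
#' contact line, `asin(2r/D)` in degrees. A flat, large-diameter fiber
#' approaches 0 degrees; the tangent minimum D = 2r gives 90 degrees. Only a
#' descriptive output; it is never used in any computation.
#'
#' @param design a [UnitDesign-class].
#' @return angle in degrees.
#' @export
attachmentAngle <- function(design) {
  D <- primaryDiameter(design)
  if (is.infinite(D)) return(0)
  asin(min(1, 2 * design@r / D)) * 180 / pi
}

# cap descriptors for the four faces of a design (um units).
# Each cap is a cylinder of radius R whose axis lies outside the face at
# distance R - delta, so the segment inside the cube has sagitta delta and
# chord exactly 2r (guaranteed by the sagitta relation).
.capList <- function(design) {
  r <- design@r
  caps <- list()
  if (design@deltaY > 0) {
    R <- diameterFromDelta(design@deltaY, r) / 2
    caps$bottom <- list(face = 1L, axis = "y", coord = "z",
                        center = -(r + R - design@deltaY), R = R)
    caps$top <- list(face = 2L, axis = "y", coord = "z",
                     center = +(r + R - design@deltaY), R = R)
  }
  if (design@deltaZ > 0) {
    R <- diameterFromDelta(design@deltaZ, r) / 2
    caps$front <- list(face = 3L, axis = "z", coord = "y",
                       center = +(r + R - design@deltaZ), R = R)
    caps$back <- list(face = 4L, axis = "z", coord = "y",
                      center = -(r + R - design@deltaZ), R = R)
  }
  caps
}

# squared distance from points to a cap axis; x, t are the flow coordinate
# and the cap's transverse coordinate (z for bottom/top, y for front/back)
.capDist2 <- function(cap, x, t) x^2 + (t - cap$center)^2

#' @describeIn voxelize Voxelize a parametric unit: solid voxels are those
#'   entirely inside a fiber cap (conservative labelling, which keeps the
#'   cusp channels of mutually tangent caps open and converges to the
#'   analytic solid volume under refinement); biomass voxels form the
#'   monolayer shell of thickness `dc` over the cultured surfaces; the
#'   remainder is fluid.
#' @export
setMethod("voxelize", "UnitDesign",
function(design, resolution = 32L, dc = 13e-6, ...) {
  n <- as.integer(resolution)
  if (n < 8L) stop("resolution must be at least 8 voxels per edge")
  validObject(design)
  r <- design@r                       # um
  L <- 2 * r
  h <- L / n                          # um
  dcUm <- dc * 1e6
  ctr <- -r + (seq_len(n) - 0.5) * h  # voxel centers, um
  caps <- .capList(design)

  # solid masks per cap: voxel entirely inside the cap cross-section circle.
  # The worst (farthest-from-axis is irrelevant; we need ALL corners inside,
  # i.e. the farthest corner from the axis center must be inside) corner in
  # the (x, t) cross-section plane decides; the cap is invariant along its
  # axis.
  cor0 <- ctr - h / 2
  cor1 <- ctr + h / 2
  labels <- array(0L, c(n, n, n))
  shellFace <- array(0L, c(n, n, n))
  capSolid <- list()
  for (nm in names(caps)) {
    cap <- caps[[nm]]
    # farthest corner: in each of x and t pick the corner coordinate with
    # the larger |coordinate - axis position| (axis at x = 0, t = center)
    xm <- pmax(abs(cor0), abs(cor1))                   # n-vector over x
    tm <- pmax(abs(cor0 - cap$center), abs(cor1 - cap$center))  # over t
    inside2d <- outer(xm^2, tm^2, "+") < cap$R^2       # strict: tangency open
    solid2d <- inside2d
    m <- array(FALSE, c(n, n, n))
    if (cap$coord == "z") {            # bottom/top: cross-section in (x, z)
      for (k in seq_len(n)) m[, , k] <- matrix(solid2d[, k], n, n)
    } else {                           # front/back: cross-section in (x, y)
      for (j in seq_len(n)) m[, j, ] <- matrix(solid2d[, j], n, n)
    }
    capSolid[[nm]] <- m
    labels[m] <- 1L
  }

  # biomass shell over cultured surfaces
  for (nm in design@culturedSurfaces) {
    fid <- .faceIds[[nm]]
    isY <- nm %in% c("front", "back")
    delta <- if (isY) design@deltaZ else design@deltaY
    if (delta > 0) {
      cap <- caps[[nm]]
      d2 <- array(0, c(n, n, n))
      dist2d <- sqrt(outer(ctr^2, (ctr - cap$center)^2, "+"))  # (x, t)
      near2d <- dist2d <= cap$R + dcUm
      m <- array(FALSE, c(n, n, n))
      if (cap$coord == "z") {
        for (k in seq_len(n)) m[, , k] <- matrix(near2d[, k], n, n)
      } else {
        for (j in seq_len(n)) m[, j, ] <- matrix(near2d[, j], n, n)
      }
      # guarantee at least one layer: voxels face-adjacent to this cap's solid
      m <- m | .adjacentTo(capSolid[[nm]])
    } else {
      # flat cultured wall: within dc of the face plane (or first layer)
      m <- array(FALSE, c(n, n, n))
      distFace <- switch(nm,
        bottom = ctr + r, top = r - ctr, front = r - ctr, back = ctr + r)
      lay <- which(distFace <= max(dcUm, h))
      if (!length(lay)) lay <- 1L
      if (nm == "bottom") m[, , lay] <- TRUE
      if (nm == "top") m[, , n + 1L - lay] <- TRUE
      if (nm == "front") m[, n + 1L - lay, ] <- TRUE
      if (nm == "back") m[, lay, ] <- TRUE
    }
    sel <- m & labels == 0L
    labels[sel] <- 2L
    shellFace[sel] <- fid
  }

  dom <- new("VoxelDomain", dims = rep(n, 3L), spacing = h * 1e-6,
             labels = labels, shellFace = shellFace, flowAxis = 1L,
             design = design)
  .checkOccluded(dom)
  dom
})

# voxels face-adjacent to a logical mask (6-neighbourhood), excluding the
# mask itself
.adjacentTo <- function(m) {
  n <- dim(m)
  a <- array(FALSE, n)
  a[-1, , ] <- a[-1, , ] | m[-n[1], , ]
  a[-n[1], , ] <- a[-n[1], , ] | m[-1, , ]
  a[, -1, ] <- a[, -1, ] | m[, -n[2], ]
  a[, -n[2], ] <- a[, -n[2], ] | m[, -1, ]
  a[, , -1] <- a[, , -1] | m[, , -n[3]]
  a[, , -n[3]] <- a[, , -n[3]] | m[, , -1]
  a & !m
}

.checkOccluded <- function(domain) {
  lab <- domain@labels
  freePerSlab <- apply(lab != 1L, 1, sum)
  if (any(freePerSlab == 0L))
    stop("occluded domain: a cross-section normal to the flow axis is ",
         "entirely solid")
  invisible(TRUE)
}

#' Build a benchmark voxel domain directly
#'
#' Constructs a rectangular duct (optionally with biomass layers) without a
#' parametric design, for solver validation.
#'
#' @param dims integer (nx, ny, nz).
#' @param spacing voxel edge (m).
#' @param labels optional integer array (default all fluid).
#' @param shellFace optional integer array matching biomass voxels.
#' @return a [VoxelDomain-class].
#' @export
ductDomain <- function(dims, spacing, labels = NULL, shellFace = NULL) {
  dims <- as.integer(dims)
  if (is.null(labels)) labels <- array(0L, dims)
  if (is.null(shellFace)) {
    shellFace <- array(0L, dims)
    shellFace[labels == 2L] <- 1L
  }
  dom <- new("VoxelDomain", dims = dims, spacing = spacing,
             labels = labels, shellFace = shellFace, flowAxis = 1L,
             design = NULL)
  .checkOccluded(dom)
  dom
}

#' @describeIn minCrossSection minimum over planes normal to the flow axis
#'   of free (non-solid) voxel count times the voxel face area.
#' @export
setMethod("minCrossSection", "VoxelDomain", function(domain) {
  free <- apply(domain@labels != 1L, 1, sum)
  min(free) * domain@spacing^2
})

#' Solid volume fraction of a voxelized unit
#' @param domain a [VoxelDomain-class].
#' @return fraction of voxels labelled solid.
#' @export
solidVolumeFraction <- function(domain) mean(domain@labels == 1L)

.designAttachmentArea <- function(design) {
  r <- design@r
  span <- 2 * r
  total <- 0
  for (nm in design@culturedSurfaces) {
    delta <- if (nm %in% c("front", "back")) design@deltaZ else design@deltaY
    D <- diameterFromDelta(delta, r)
    total <- total + attachmentArea(D, 2 * r, span)
  }
  total
}

#' @describeIn geometryMetrics metrics from the parametric design alone
#'   (minimum cross-section requires voxelization and is NA here).
#' @export
setMethod("geometryMetrics", "UnitDesign", function(object, ...) {
  cultD <- if (any(object@culturedSurfaces %in% c("bottom", "top")))
    primaryDiameter(object) else secondaryDiameter(object)
  list(attachmentArea = .designAttachmentArea(object),
       minCrossSection = NA_real_,
       effectiveCurvature = if (is.finite(cultD)) 1 / cultD else 0,
       attachmentAngle = attachmentAngle(object))
})

#' @describeIn geometryMetrics metrics of a voxelized unit, including the
#'   voxel-counted minimum cross-section.
#' @export
setMethod("geometryMetrics", "VoxelDomain", function(object, ...) {
  if (is.null(object@design))
    return(list(attachmentArea = NA_real_,
                minCrossSection = minCrossSection(object),
                effectiveCurvature = NA_real_,
                attachmentAngle = NA_real_))
  m <- geometryMetrics(object@design)
  m$minCrossSection <- minCrossSection(object)
  m
})
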