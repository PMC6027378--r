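# Independent closed-form oracles used across the suite.

# circular-segment area for sagitta `delta` and half-chord `r` (um^2);
# computed from the segment geometry directly, not via the package
segmentArea <- function(delta, r = 100) {
  if (delta == 0) return(0)
  R <- (r^2 + delta^2) / (2 * delta)
  R^2 * acos(1 - delta / R) - (R - delta) * sqrt(2 * R * delta - delta^2)
}

# series solution for fully developed laminar flow in a rectangular duct
# (0..a) x (0..b), no-slip walls; arbitrary scale
ductSeriesProfile <- function(y, z, a, b, nterms = 199) {
  s <- 0
  for (k in seq(1, nterms, by = 2))
    s <- s + (1 / k^3) *
      (1 - cosh(k * pi * (z - b / 2) / a) / cosh(k * pi * b / (2 * a))) *
      sin(k * pi * y / a)
  s
}

# small all-fluid duct domain with an optional flat biomass layer at the
# bottom (z low) face
makeDuct <- function(dims, spacing = 200e-6 / dims[2], biomassLayers = 0L) {
  labels <- array(0L, dims)
  if (biomassLayers > 0L) labels[, , seq_len(biomassLayers)] <- 2L
  ductDomain(dims, spacing, labels = labels)
}

# an empty culture state over a domain
blankState <- function(dom, cgf = 0, cl = 0) {
  n <- dom@dims
  new("CultureState", cgf = array(cgf, n), cl = array(cl, n),
      epsC = array(0, n), time = 0,
      budgets = list(glucoseConsumed = 0, lactateProduced = 0,
                     clippedMass = 0))
}

# total phase-weighted glucose content of a state (kg); epsC may be
# overridden with the cell-fraction field the concentrations were solved at
glucoseContent <- function(state, dom, p = kineticParams(),
                           epsC = state@epsC) {
  open <- dom@labels != 1L
  bio <- dom@labels == 2L
  phi <- array(1, dom@dims)
  phi[bio] <- 1 - epsC[bio] * (1 - p@keq)
  sum((phi * state@cgf)[open]) * dom@spacing^3
}

lactateContent <- function(state, dom) {
  sum(state@cl[dom@labels != 1L]) * dom@spacing^3
}
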