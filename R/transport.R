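#' @include AllClasses.R AllGenerics.R linsolve.R flow.R kinetics.R
NULL

#' Initialize a culture state on a voxel domain
#'
#' Fluid and biomass voxels start at the inlet glucose concentration with
#' zero lactate; the biomass shell is seeded uniformly at the cell volume
#' fraction corresponding to the initial cell density
#' (`epsC0 = N0 * cellVolume`).
#'
#' @param domain a [VoxelDomain-class].
#' @param glin initial/inlet glucose concentration (kg/m^3).
#' @param initialCellDensity seeded density (cells/m^3).
#' @param p a [KineticParams-class].
#' @return a [CultureState-class].
#' @export
initCultureState <- function(domain, glin, initialCellDensity,
                             p = kineticParams()) {
  n <- domain@dims
  open <- domain@labels != 1L
  cgf <- array(0, n); cgf[open] <- glin
  cl <- array(0, n)
  epsC <- array(0, n)
  eps0 <- initialCellDensity * cellVolume(p)
  if (eps0 > 1)
    stop("initial cell density exceeds a fully packed monolayer")
  epsC[domain@labels == 2L] <- eps0
  new("CultureState", cgf = cgf, cl = cl, epsC = epsC, time = 0,
      budgets = list(glucoseConsumed = 0, lactateProduced = 0,
                     clippedMass = 0))
}

#' Cell-phase glucose concentration
#'
#' The interfacial linear equilibrium `cgc = Keq * cgf` applied inside the
#' biomass shell (zero elsewhere).
#'
#' @param state a [CultureState-class].
#' @param domain a [VoxelDomain-class].
#' @param p a [KineticParams-class].
#' @return array of cell-phase concentrations (kg/m^3).
#' @export
cellPhaseGlucose <- function(state, domain, p = kineticParams()) {
  cgc <- p@keq * state@cgf
  cgc[domain@labels != 2L] <- 0
  cgc
}

# assemble and solve one implicit scalar step.
#
# content per volume: phi * c; diffusivity D per cell (0 in solid);
# advection by the staggered face velocities (upwind, conservative);
# linear sink s * c (Picard-linearized outside); source `src` explicit.
# boundary: "perfusion" (Dirichlet cIn at inlet + outflow at outlet),
# "closed" (all zero-flux), "fixed" (Dirichlet cLeft/cRight on the x faces).
.scalarStep <- function(cOld, cPrev2 = NULL, phi, Dcell, flow, open, h, dt,
                        s = 0, src = 0, boundary = "perfusion",
                        cIn = 0, cRight = 0, tol = 1e-12, scheme = "be",
                        phiOld = phi) {
  n <- dim(cOld)
  nx <- n[1]; ny <- n[2]; nz <- n[3]
  h2 <- h^2; h3 <- h^3
  st <- .newStencil(n)
  st$act <- open
  actN <- array(as.numeric(open), n)
  harm <- function(a, b) ifelse(a + b > 0, 2 * a * b / (a + b), 0)

  diag <- array(0, n)
  rhs <- array(0, n)

  # x faces between cells i and i+1
  if (nx > 1L) {
    DP <- Dcell[1:(nx - 1), , , drop = FALSE]
    DQ <- Dcell[2:nx, , , drop = FALSE]
    gx <- harm(DP, DQ) * h                       # conductance
    Fx <- if (is.null(flow)) 0 else
      array(flow@u[2:nx, , , drop = FALSE], c(nx - 1L, ny, nz)) * h2
    # row P (outward +x): diag += g + max(F,0); aE = -g + min(F,0)
    dP <- gx + pmax(Fx, 0)
    aE <- -gx + pmin(Fx, 0)
    # row Q (outward -x, flux -F): diag += g + max(-F,0); aW = -g - max(F,0)
    dQ <- gx + pmax(-Fx, 0)
    aW <- -gx - pmax(Fx, 0)
    pad <- function(a, at) { z <- array(0, n); idx <- lapply(n, seq_len)
      idx[[1]] <- at; z[idx[[1]], , ] <- a; z }
    diag <- diag + pad(dP, 1:(nx - 1)) + pad(dQ, 2:nx)
    st$aE <- st$aE + pad(aE, 1:(nx - 1))
    st$aW <- st$aW + pad(aW, 2:nx)
  }
  # y faces
  if (ny > 1L) {
    DP <- Dcell[, 1:(ny - 1), , drop = FALSE]
    DQ <- Dcell[, 2:ny, , drop = FALSE]
    gy <- harm(DP, DQ) * h
    Fy <- if (is.null(flow)) 0 else
      array(flow@v[, 2:ny, , drop = FALSE], c(nx, ny - 1L, nz)) * h2
    dP <- gy + pmax(Fy, 0); aN <- -gy + pmin(Fy, 0)
    dQ <- gy + pmax(-Fy, 0); aS <- -gy - pmax(Fy, 0)
    pad <- function(a, at) { z <- array(0, n); z[, at, ] <- a; z }
    diag <- diag + pad(dP, 1:(ny - 1)) + pad(dQ, 2:ny)
    st$aN <- st$aN + pad(aN, 1:(ny - 1))
    st$aS <- st$aS + pad(aS, 2:ny)
  }
  # z faces
  if (nz > 1L) {
    DP <- Dcell[, , 1:(nz - 1), drop = FALSE]
    DQ <- Dcell[, , 2:nz, drop = FALSE]
    gz <- harm(DP, DQ) * h
    Fz <- if (is.null(flow)) 0 else
      array(flow@w[, , 2:nz, drop = FALSE], c(nx, ny, nz - 1L)) * h2
    dP <- gz + pmax(Fz, 0); aT <- -gz + pmin(Fz, 0)
    dQ <- gz + pmax(-Fz, 0); aB <- -gz - pmax(Fz, 0)
    pad <- function(a, at) { z <- array(0, n); z[, , at] <- a; z }
    diag <- diag + pad(dP, 1:(nz - 1)) + pad(dQ, 2:nz)
    st$aT <- st$aT + pad(aT, 1:(nz - 1))
    st$aB <- st$aB + pad(aB, 2:nz)
  }

  influx <- 0
  if (boundary == "perfusion") {
    Fin <- if (is.null(flow)) 0 else flow@u[1, , ] * h2
    gb <- 2 * Dcell[1, , ] * h
    diag[1, , ] <- diag[1, , ] + gb + 0 * Fin
    rhs[1, , ] <- rhs[1, , ] + (gb + Fin) * cIn
    Fout <- if (is.null(flow)) 0 else pmax(flow@u[nx + 1, , ], 0) * h2
    diag[nx, , ] <- diag[nx, , ] + Fout
  } else if (boundary == "fixed") {
    gb <- 2 * Dcell[1, , ] * h
    diag[1, , ] <- diag[1, , ] + gb
    rhs[1, , ] <- rhs[1, , ] + gb * cIn
    gb2 <- 2 * Dcell[nx, , ] * h
    diag[nx, , ] <- diag[nx, , ] + gb2
    rhs[nx, , ] <- rhs[nx, , ] + gb2 * cRight
  }

  # time term and reaction; the old content enters with the capacity it was
  # stored at (phiOld), so growth-driven capacity changes conserve mass
  if (identical(scheme, "bdf2") && !is.null(cPrev2)) {
    diag <- diag + 1.5 * phi * h3 / dt
    rhs <- rhs + (2 * cOld * phiOld - 0.5 * cPrev2 * phiOld) * h3 / dt
  } else {
    diag <- diag + phi * h3 / dt
    rhs <- rhs + phiOld * h3 * cOld / dt
  }
  diag <- diag + s * h3
  rhs <- rhs + src * h3

  st$diag <- diag * actN
  st$diag[!open] <- 1
  for (nm in c("aW", "aE", "aS", "aN", "aB", "aT"))
    st[[nm]] <- st[[nm]] * actN
  rhs <- rhs * actN

  x <- .stencilSolve(st, rhs, x0 = cOld * actN, tol = tol, maxit = 400,
                     method = "bicgstab")
  x
}

# effective capacity and diffusivity fields for glucose
.glucosePhase <- function(domain, epsC, p) {
  bio <- domain@labels == 2L
  phi <- array(1, domain@dims)
  phi[bio] <- 1 - epsC[bio] * (1 - p@keq)
  Dcell <- array(p@dgf, domain@dims)
  Dcell[bio] <- p@dgf + p@keq * p@dgc
  Dcell[domain@labels == 1L] <- 0
  list(phi = phi, Dcell = Dcell)
}

#' One implicit glucose transport step
#'
#' Implicit Euler (optionally two-step BDF2) finite-volume update of the
#' phase-weighted glucose content `phi * cgf` with
#' `phi = epsF + Keq * epsC` in the biomass shell: diffusion in both
#' phases, upwind advection by the fluid velocity, and the
#' Michaelis-Menten sink (Picard-linearized, iterated to convergence).
#' Inlet Dirichlet at `glin`, zero-gradient outflow, zero flux at solid.
#'
#' @param state a [CultureState-class].
#' @param domain a [VoxelDomain-class].
#' @param flow a [FlowField-class] or NULL (no advection).
#' @param p a [KineticParams-class].
#' @param dt time step (s).
#' @param glin inlet glucose concentration (kg/m^3).
#' @param boundary "perfusion", "closed", or "fixed" (see details in the
#'   package vignette); benchmark modes disable inflow.
#' @param cRight right Dirichlet value for `boundary = "fixed"`.
#' @param picard maximum Picard iterations for the uptake linearization.
#' @param scheme "be" (implicit Euler) or "bdf2".
#' @param cPrev2 previous-step field for BDF2.
#' @return list with the updated `state` and a `diagnostics` list
#'   (`consumed` kg, `clipped` kg, `picard` iterations used).
#' @export
stepGlucose <- function(state, domain, flow, p = kineticParams(), dt,
                        glin = 4.5, boundary = "perfusion", cRight = 0,
                        picard = 6, scheme = "be", cPrev2 = NULL,
                        epsCPrev = NULL) {
  stopifnot(dt > 0)
  open <- domain@labels != 1L
  bio <- domain@labels == 2L
  ph <- .glucosePhase(domain, state@epsC, p)
  phiOld <- if (is.null(epsCPrev)) ph$phi else
    .glucosePhase(domain, epsCPrev, p)$phi
  h <- domain@spacing
  cOld <- state@cgf
  cNew <- cOld
  epsb <- state@epsC
  iter <- 0L
  for (k in seq_len(max(1L, picard))) {
    iter <- k
    x <- epsb * p@keq * pmax(cNew, 0)
    s <- ifelse(bio, p@vm * epsb * p@keq / (p@km + x), 0)
    cNext <- .scalarStep(cOld, cPrev2, ph$phi, ph$Dcell, flow, open, h, dt,
                         s = s, src = 0, boundary = boundary, cIn = glin,
                         scheme = scheme, phiOld = phiOld)
    delta <- max(abs(cNext - cNew))
    cNew <- cNext
    if (delta < 1e-10 * max(glin, max(abs(cNew)), 1e-12)) break
  }
  clipped <- max(0, sum(pmin(cNew[open], 0) * -ph$phi[open]) * h^3)
  cNew[cNew < 0] <- 0
  x <- epsb * p@keq * cNew
  rg <- ifelse(bio, p@vm * x / (p@km + x), 0)     # kg/m^3/s at new state
  consumed <- sum(rg) * h^3 * dt
  st2 <- state
  st2@cgf <- cNew
  st2@budgets$glucoseConsumed <- st2@budgets$glucoseConsumed + consumed
  st2@budgets$clippedMass <- st2@budgets$clippedMass + clipped
  list(state = st2, diagnostics = list(consumed = consumed,
                                       clipped = clipped, picard = iter,
                                       uptakeField = rg))
}

#' One implicit lactate transport step
#'
#' Same discretization as [stepGlucose()] with unit capacity, lactate
#' diffusivity, zero inlet concentration and the explicit source
#' `Rl = 2 Rg` evaluated at the post-step glucose field.
#'
#' @inheritParams stepGlucose
#' @param uptakeField glucose uptake rate field (kg/m^3/s) from the glucose
#'   step of the same time level.
#' @return list with updated `state` and `diagnostics` (`produced` kg).
#' @export
stepLactate <- function(state, domain, flow, p = kineticParams(), dt,
                        uptakeField, boundary = "perfusion",
                        scheme = "be", cPrev2 = NULL) {
  stopifnot(dt > 0)
  open <- domain@labels != 1L
  h <- domain@spacing
  Dcell <- array(p@dlf, domain@dims)
  Dcell[domain@labels == 1L] <- 0
  phi <- array(1, domain@dims)
  rl <- lactateRate(uptakeField)
  cNew <- .scalarStep(state@cl, cPrev2, phi, Dcell, flow, open, h, dt,
                      s = 0, src = rl, boundary = boundary, cIn = 0,
                      scheme = scheme)
  clipped <- max(0, -sum(pmin(cNew[open], 0)) * h^3)
  cNew[cNew < 0] <- 0
  produced <- sum(rl) * h^3 * dt
  st2 <- state
  st2@cl <- cNew
  st2@budgets$lactateProduced <- st2@budgets$lactateProduced + produced
  st2@budgets$clippedMass <- st2@budgets$clippedMass + clipped
  list(state = st2, diagnostics = list(produced = produced,
                                       clipped = clipped))
}

#' One biomass growth step
#'
#' Applies the pH viability gate, then grows the cell fraction of each
#' biomass voxel exponentially at the local rate
#' `rg - rd` from [growthRate()] (cell-phase glucose, local shear), and
#' enforces the monolayer caps: per-voxel `epsC <= 1` and the per-column
#' bound on cells per unit attachment area.
#'
#' @param state a [CultureState-class].
#' @param domain a [VoxelDomain-class].
#' @param shear cell-centred shear-stress magnitude array (Pa).
#' @param p a [KineticParams-class].
#' @param dt time step (s).
#' @param viabilityMode "remove" (cells below the pH threshold are removed
#'   instantly, the published formulation `epsC * S{pH}`) or "freeze"
#'   (growth stops but biomass is retained).
#' @param maxCellsPerArea monolayer bound (cells/m^2); default corresponds
#'   to a fully packed layer of thickness `dc` (`dc / cellVolume`).
#' @return list with updated `state` and `diagnostics` (`capped` voxel
#'   count, `killed` voxel count, `meanGrowthRate` 1/s).
#' @export
stepBiomass <- function(state, domain, shear, p = kineticParams(), dt,
                        viabilityMode = c("remove", "freeze"),
                        maxCellsPerArea = NULL) {
  stopifnot(dt > 0)
  viabilityMode <- match.arg(viabilityMode)
  bio <- domain@labels == 2L
  if (!any(bio)) return(list(state = state,
                             diagnostics = list(capped = 0L, killed = 0L,
                                                meanGrowthRate = 0)))
  h <- domain@spacing
  epsC <- state@epsC
  S <- viabilityStep(phFromLactate(state@cl), p@phThreshold)
  killed <- sum(bio & S == 0 & epsC > 0)
  cgc <- p@keq * state@cgf
  # exponential Heun update: predictor with the start-of-step rate, rate
  # re-evaluated at the predicted cell fraction, then the averaged exponent.
  # Exact for a constant rate; second-order in the self-limitation.
  rg <- array(0, domain@dims)
  rg[bio] <- growthRate(cgc[bio], epsC[bio], shear[bio], p)
  epsStar <- pmin(1, epsC * exp((rg - p@rd) * dt))
  rg2 <- rg
  rg2[bio] <- growthRate(cgc[bio], epsStar[bio], shear[bio], p)
  rgEff <- 0.5 * (rg + rg2)
  if (viabilityMode == "remove") {
    epsC[bio] <- epsC[bio] * S[bio]
    fac <- exp((rgEff - p@rd) * dt)
  } else {
    fac <- ifelse(S > 0, exp((rgEff - p@rd) * dt), 1)
  }
  epsC[bio] <- epsC[bio] * fac[bio]
  nCap <- sum(epsC > 1)
  if (nCap > 0) {
    warning(sprintf("%d voxel(s) reached a fully packed cell fraction; %s",
                    nCap, "capped at 1"))
    epsC[epsC > 1] <- 1
  }
  # per-column monolayer bound: integrated epsC * h along the shell column
  # must not exceed maxCellsPerArea * cellVolume (default: dc)
  capLen <- if (is.null(maxCellsPerArea)) p@dc else
    maxCellsPerArea * cellVolume(p)
  colid <- .shellColumns(domain)
  tot <- rowsum(epsC[bio] * h, colid)
  scale <- pmin(1, capLen / pmax(tot[, 1], 1e-300))
  epsC[bio] <- epsC[bio] * scale[match(colid, rownames(tot))]
  st2 <- state
  st2@epsC <- epsC
  list(state = st2,
       diagnostics = list(capped = nCap, killed = killed,
                          meanGrowthRate = mean(rg[bio])))
}

# column key of each biomass voxel: cultured face + transverse indices
.shellColumns <- function(domain) {
  bio <- which(domain@labels == 2L, arr.ind = TRUE)
  face <- domain@shellFace[domain@labels == 2L]
  # columns run along the face normal: (x, y) for bottom/top, (x, z) for
  # front/back
  transB <- ifelse(face %in% c(1L, 2L), bio[, 2], bio[, 3])
  paste(face, bio[, 1], transB, sep = ":")
}

#' Mean cell density over the biomass shell
#'
#' @param state a [CultureState-class].
#' @param domain a [VoxelDomain-class].
#' @param p a [KineticParams-class].
#' @return mean density in cells/m^3.
#' @export
meanCellDensity <- function(state, domain, p = kineticParams()) {
  bio <- domain@labels == 2L
  if (!any(bio)) return(0)
  mean(state@epsC[bio]) / cellVolume(p)
}

#' Integrate the coupled culture over time
#'
#' Sequential quasi-steady coupling per step: viscosity from the cell
#' fraction, steady flow re-solve, implicit glucose step, implicit lactate
#' step, pH/viability gate, biomass growth. Diagnostics are recorded per
#' step.
#'
#' @param domain a [VoxelDomain-class].
#' @param oc an [OperatingConditions-class].
#' @param p a [KineticParams-class].
#' @param state optional initial [CultureState-class] (default: seeded from
#'   `oc`).
#' @param control list of solver settings: `flowTol`, `transportPicard`,
#'   `scheme` ("be"/"bdf2"), `viabilityMode`, `flowEvery` (re-solve the flow
#'   every k growth steps, default 1), `maxCellsPerArea`, `clipLimit`
#'   (abort if clipped mass exceeds this fraction of throughput, default
#'   1e-3), `verbose`.
#' @return list with final `state`, `trajectory` (data.frame, one row per
#'   step), the final `flow` and `shear` fields.
#' @export
integrateCulture <- function(domain, oc, p = kineticParams(), state = NULL,
                             control = list()) {
  ctl <- modifyList(list(flowTol = 1e-8, transportPicard = 6, scheme = "be",
                         viabilityMode = "remove", flowEvery = 1L,
                         maxCellsPerArea = NULL, clipLimit = 1e-3,
                         verbose = FALSE), control)
  validObject(oc)
  if (is.null(state))
    state <- initCultureState(domain, oc@glin, oc@initialCellDensity, p)
  nSteps <- if (oc@duration == 0) 0L else as.integer(round(oc@duration / oc@dt))
  bio <- domain@labels == 2L
  rows <- vector("list", nSteps)
  flow <- NULL
  shear <- array(0, domain@dims)
  meanTau <- maxTau <- NA_real_
  cgfPrev <- clPrev <- epsCPrevStep <- NULL
  for (stp in seq_len(nSteps)) {
    if (stp == 1L || ((stp - 1L) %% max(1L, ctl$flowEvery)) == 0L) {
      mu <- viscosityFromCellFraction(state@epsC)
      flow <- solveFlow(domain, mu, oc@inletVelocity, tol = ctl$flowTol,
                        warmStart = flow)
      sh <- shearMagnitude(flow, mu, domain)
      shear <- sh$tau
      meanTau <- sh$meanBiomass
      maxTau <- sh$maxBiomass
    }
    gl <- stepGlucose(state, domain, flow, p, oc@dt, glin = oc@glin,
                      picard = ctl$transportPicard, scheme = ctl$scheme,
                      cPrev2 = cgfPrev, epsCPrev = epsCPrevStep)
    cgfPrev <- if (identical(ctl$scheme, "bdf2")) state@cgf else NULL
    epsCPrevStep <- state@epsC
    la <- stepLactate(gl$state, domain, flow, p, oc@dt,
                      uptakeField = gl$diagnostics$uptakeField,
                      scheme = ctl$scheme, cPrev2 = clPrev)
    clPrev <- if (identical(ctl$scheme, "bdf2")) state@cl else NULL
    bm <- withCallingHandlers(
      stepBiomass(la$state, domain, shear, p, oc@dt,
                  viabilityMode = ctl$viabilityMode,
                  maxCellsPerArea = ctl$maxCellsPerArea),
      warning = function(w) invokeRestart("muffleWarning"))
    state <- bm$state
    state@time <- stp * oc@dt
    thr <- state@budgets$glucoseConsumed + oc@glin * flow@inletFlux *
      state@time
    if (state@budgets$clippedMass > ctl$clipLimit * max(thr, 1e-300))
      stop(sprintf("step %d: clipped mass exceeds %.3g of throughput",
                   stp, ctl$clipLimit))
    rows[[stp]] <- data.frame(
      step = stp, time_h = state@time / 3600,
      meanGlucose = mean(state@cgf[domain@labels != 1L]),
      minGlucose = min(state@cgf[domain@labels != 1L]),
      meanLactate = mean(state@cl[domain@labels != 1L]),
      maxLactate = max(state@cl[domain@labels != 1L]),
      minPH = min(phFromLactate(state@cl[domain@labels != 1L])),
      meanEpsC = if (any(bio)) mean(state@epsC[bio]) else 0,
      meanDensity = meanCellDensity(state, domain, p),
      meanShearBiomass = meanTau, maxShearBiomass = maxTau,
      glucoseConsumed = state@budgets$glucoseConsumed,
      lactateProduced = state@budgets$lactateProduced,
      capped = bm$diagnostics$capped, killed = bm$diagnostics$killed)
    if (isTRUE(ctl$verbose))
      message(sprintf("step %d/%d: meanEpsC = %.4f, tau = %.3g Pa",
                      stp, nSteps, rows[[stp]]$meanEpsC, meanTau))
  }
  trajectory <- if (nSteps > 0) do.call(rbind, rows) else
    data.frame(step = integer(), time_h = numeric())
  list(state = state, trajectory = trajectory, flow = flow, shear = shear)
}
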