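#' @include AllClasses.R AllGenerics.R linsolve.R
NULL

#' Dynamic viscosity from the local cell volume fraction
#'
#' The biomass is treated as a single-field penalized medium: viscosity
#' rises linearly with the cell fraction from 0.001 Pa s (pure medium,
#' water-like) to 1 Pa s (fully packed cells), which throttles fluid
#' penetration into densely populated regions.
#'
#' @param epsC cell volume fraction in `[0, 1]` (any shape).
#' @param muMin viscosity of the cell-free medium (Pa s).
#' @param muMax viscosity of a fully packed cell bulk (Pa s).
#' @return viscosity, same shape as `epsC` (Pa s).
#' @export
viscosityFromCellFraction <- function(epsC, muMin = 1e-3, muMax = 1.0) {
  if (any(epsC < 0 | epsC > 1)) stop("epsC must lie in [0, 1]")
  muMin + epsC * (muMax - muMin)
}

# ---- staggered Stokes solver ------------------------------------------------

# shift an array by +1/-1 along a dimension, padding with `fill`
.shift <- function(a, dim, by, fill = 0) {
  n <- base::dim(a)
  out <- array(fill, n)
  idx <- lapply(n, seq_len)
  src <- idx
  if (by == 1L) {        # out[i] = a[i+1]
    idx[[dim]] <- seq_len(n[dim] - 1L)
    src[[dim]] <- seq_len(n[dim] - 1L) + 1L
  } else {               # out[i] = a[i-1]
    idx[[dim]] <- seq_len(n[dim] - 1L) + 1L
    src[[dim]] <- seq_len(n[dim] - 1L)
  }
  out[idx[[1]], idx[[2]], idx[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# Assemble the viscous operator for one velocity component.
#
# `normal` is the component axis (1 = u, 2 = v, 3 = w). For u the DOF box
# covers faces i = 2..nx+1 (inlet face Dirichlet-eliminated, outlet face an
# unknown with a natural zero-stress condition); for v/w the box covers the
# interior faces (domain-boundary faces are no-slip zeros). Tangential
# links get the half-cell wall factor 2 at solid or domain walls; at the
# inlet plane tangential components see a wall (plug inflow), at the outlet
# plane a zero-gradient condition (link dropped).
.momentumStencil <- function(open, mu, h, normal, uin = NULL) {
  n <- dim(open)
  nx <- n[1]; ny <- n[2]; nz <- n[3]
  openN <- array(as.numeric(open), n)

  if (normal == 1L) {
    dims <- c(nx, ny, nz)
    # cells W = box index, E = box index + 1 (absent on the outlet row)
    openW <- open
    openE <- .shift(open, 1L, 1L, fill = FALSE); openE[nx, , ] <- FALSE
    hasE <- array(TRUE, dims); hasE[nx, , ] <- FALSE
    act <- openW & (.shift(open, 1L, 1L, fill = TRUE))
    muW <- mu; muE <- .shift(mu, 1L, 1L)
    af <- array(h, dims); af[nx, , ] <- h / 2   # tangential CV area factor
  } else {
    d <- normal
    nd <- n[d] - 1L
    dims <- n; dims[d] <- nd
    sel0 <- lapply(n, seq_len); sel0[[d]] <- seq_len(nd)
    sel1 <- lapply(n, seq_len); sel1[[d]] <- seq_len(nd) + 1L
    openW <- open[sel0[[1]], sel0[[2]], sel0[[3]], drop = FALSE]
    openE <- open[sel1[[1]], sel1[[2]], sel1[[3]], drop = FALSE]
    dim(openW) <- dims; dim(openE) <- dims
    act <- openW & openE
    muW <- array(mu[sel0[[1]], sel0[[2]], sel0[[3]]], dims)
    muE <- array(mu[sel1[[1]], sel1[[2]], sel1[[3]]], dims)
    hasE <- array(TRUE, dims)
    af <- array(h, dims)
  }

  st <- .newStencil(dims)
  st$act <- act
  actN <- array(as.numeric(act), dims)
  diag <- array(0, dims)
  rhs <- array(0, dims)

  # normal-direction links: conductance mu(cell) * h to the neighbouring
  # face DOF across that cell
  cW <- muW * h
  cE <- ifelse(hasE, muE * h, 0)
  if (normal == 1L) {
    diag <- diag + cW + cE
    nbW <- .shift(actN, 1L, -1L)          # box neighbour iu-1 active?
    aW <- -cW * nbW
    aW[1, , ] <- 0                        # inlet Dirichlet: to rhs
    if (!is.null(uin)) {
      rhsIn <- array(0, dims)
      rhsIn[1, , ] <- cW[1, , ] * uin
      rhs <- rhs + rhsIn
    }
    st$aW <- aW * actN
    st$aE <- -cE * .shift(actN, 1L, 1L) * actN
  } else {
    diag <- diag + cW + cE
    # neighbours along the normal axis: box +-1; at box ends the neighbour
    # is the domain-boundary face (no-slip zero) at distance h: diag only
    aM <- -cW * .shift(actN, normal, -1L) * actN
    aP <- -cE * .shift(actN, normal, 1L) * actN
    if (normal == 2L) { st$aS <- aM; st$aN <- aP }
    else { st$aB <- aM; st$aT <- aP }
  }

  # tangential links: edge viscosities are harmonic means over the open
  # cells around the edge, which keeps the shear stress continuous across
  # viscosity jumps (biomass-fluid interfaces)
  sWE <- openW / muW + openE / ifelse(hasE, muE, 1)
  cnt <- openW + openE
  muF <- ifelse(cnt > 0, pmax(cnt, 1) / pmax(sWE, 1e-300), 0)
  for (d in setdiff(1:3, normal)) {
    for (s in c(-1L, 1L)) {
      sWEn <- .shift(sWE, d, s)
      cntn <- .shift(cnt, d, s)
      openWn <- .shift(openW, d, s, fill = FALSE)
      openEn <- .shift(openE, d, s, fill = FALSE)
      inDom <- array(TRUE, dims)
      if (s == 1L) {
        ed <- lapply(dims, seq_len); ed[[d]] <- dims[d]
        inDom[ed[[1]], ed[[2]], ed[[3]]] <- FALSE
      } else {
        ed <- lapply(dims, seq_len); ed[[d]] <- 1L
        inDom[ed[[1]], ed[[2]], ed[[3]]] <- FALSE
      }
      if (normal != 1L && d == 1L) {
        # tangential x: inlet side is a wall (plug), outlet side is
        # zero-gradient (dropped)
        if (s == 1L) {
          wall <- inDom & ((openWn + openEn) < cnt)  # a solid blocks
          cpl <- inDom & !wall
          cT <- ifelse(cpl, (cnt + cntn) / pmax(sWE + sWEn, 1e-300), 0) * af
          wT <- ifelse(wall, 2 * muF, 0) * af
          diag <- diag + (cT + wT) * actN
          st$aE <- st$aE - cT * .shift(actN, d, s) * actN
          next
        } else {
          wall <- !inDom | ((openWn + openEn) < cnt)
          cpl <- !wall
          cT <- ifelse(cpl, (cnt + cntn) / pmax(sWE + sWEn, 1e-300), 0) * af
          wT <- ifelse(wall, 2 * muF, 0) * af
          diag <- diag + (cT + wT) * actN
          st$aW <- st$aW - cT * .shift(actN, d, s) * actN
          next
        }
      }
      # generic tangential: domain boundary or solid neighbour cell => wall
      wall <- (!inDom) | ((openWn + openEn) < cnt)
      cpl <- !wall
      cT <- ifelse(cpl, (cnt + cntn) / pmax(sWE + sWEn, 1e-300), 0) * af
      wT <- ifelse(wall, 2 * muF, 0) * af
      diag <- diag + (cT + wT) * actN
      a <- -cT * .shift(actN, d, s) * actN
      nm <- if (d == 1L) (if (s == 1L) "aE" else "aW")
            else if (d == 2L) (if (s == 1L) "aN" else "aS")
            else (if (s == 1L) "aT" else "aB")
      st[[nm]] <- st[[nm]] + a
    }
  }

  st$diag <- diag * actN
  st$diag[!act] <- 1            # inert rows
  list(st = st, rhs = rhs * actN)
}

# divergence of full staggered fields over open cells, times h^2
.divergence <- function(uu, vv, ww, n, h2) {
  nx <- n[1]; ny <- n[2]; nz <- n[3]
  d <- uu[2:(nx + 1), , , drop = FALSE] - uu[1:nx, , , drop = FALSE] +
       vv[, 2:(ny + 1), , drop = FALSE] - vv[, 1:ny, , drop = FALSE]
  if (nz > 1L)
    d <- d + ww[, , 2:(nz + 1), drop = FALSE] - ww[, , 1:nz, drop = FALSE]
  array(d, n) * h2
}

# assemble full staggered arrays from box solutions (Dirichlet faces zero)
.fullU <- function(xu, act, n) {
  uu <- array(0, c(n[1] + 1L, n[2], n[3]))
  uu[2:(n[1] + 1L), , ] <- xu * act
  uu
}
.fullV <- function(xv, act, n) {
  vv <- array(0, c(n[1], n[2] + 1L, n[3]))
  if (n[2] > 1L) vv[, 2:n[2], ] <- xv * act
  vv
}
.fullW <- function(xw, act, n) {
  ww <- array(0, c(n[1], n[2], n[3] + 1L))
  if (n[3] > 1L) ww[, , 2:n[3]] <- xw * act
  ww
}

#' Solve steady creeping flow through a voxel domain
#'
#' Steady incompressible Stokes flow with spatially varying viscosity on a
#' staggered (MAC) grid: plug inflow on the open part of the x = 0 plane, a
#' natural zero-stress/zero-pressure outlet, no-slip on solid voxels and
#' domain walls. The biomass phase flows with its penalized viscosity.
#' Solved by conjugate gradients on the pressure Schur complement with
#' multigrid-preconditioned inner momentum solves.
#'
#' @param domain a [VoxelDomain-class].
#' @param mu cell viscosity array (Pa s) or a scalar; default 1e-3 (medium).
#' @param inletVelocity plug inflow velocity (m/s), > 0.
#' @param tol relative divergence residual target (default 1e-8; the
#'   resulting cross-plane flux imbalance is far below 1e-6 relative).
#' @param maxIter outer iteration cap.
#' @param innerTol relative tolerance of the inner momentum solves.
#' @param warmStart optional previous [FlowField-class] to start from.
#' @return a [FlowField-class].
#' @export
setGeneric("solveFlow", function(domain, mu = 1e-3, inletVelocity,
                                 tol = 1e-8, maxIter = 500,
                                 innerTol = 1e-11, warmStart = NULL)
  standardGeneric("solveFlow"))

#' @describeIn solveFlow staggered finite-volume solution on the voxel grid.
#' @export
setMethod("solveFlow", "VoxelDomain",
function(domain, mu = 1e-3, inletVelocity, tol = 1e-8, maxIter = 500,
         innerTol = 1e-11, warmStart = NULL) {
  stopifnot(inletVelocity > 0)
  .checkOccluded(domain)
  n <- domain@dims
  nx <- n[1]; ny <- n[2]; nz <- n[3]
  h <- domain@spacing
  h2 <- h^2
  open <- domain@labels != 1L
  if (length(mu) == 1L) mu <- array(mu, n)
  stopifnot(identical(dim(mu), n))

  # plug inflow feeds the open pore; biomass voxels on the inlet plane are
  # not force-fed (their upstream continuation is more cell layer, not
  # free stream)
  uin <- array(0, c(ny, nz))
  uin[domain@labels[1, , ] == 0L] <- inletVelocity

  asmU <- .momentumStencil(open, mu, h, 1L, uin = uin)
  asmV <- .momentumStencil(open, mu, h, 2L)
  hasW <- nz > 1L
  asmW <- if (hasW) .momentumStencil(open, mu, h, 3L) else NULL
  hU <- .stencilSetup(asmU$st)
  hV <- .stencilSetup(asmV$st)
  hW <- if (hasW) .stencilSetup(asmW$st) else NULL
  g <- array(0, n)
  g[1, , ] <- uin * h2
  g[!open] <- 0
  inletFlux <- sum(uin) * h2

  gradP <- function(p) {
    pE <- .shift(p, 1L, 1L)            # p[i+1]; outlet ghost 0
    gu <- (p - pE) * h2 * asmU$st$act
    gv <- (p[, 1:(ny - 1), , drop = FALSE] -
           p[, 2:ny, , drop = FALSE]) * h2
    gv <- array(gv, dim(asmV$st$act)) * asmV$st$act
    gw <- NULL
    if (hasW) {
      gw <- (p[, , 1:(nz - 1), drop = FALSE] -
             p[, , 2:nz, drop = FALSE]) * h2
      gw <- array(gw, dim(asmW$st$act)) * asmW$st$act
    }
    list(u = gu, v = gv, w = gw)
  }

  solveMom <- function(rhs, x0 = NULL) {
    xu <- .stencilSolve(asmU$st, rhs$u, x0 = x0$u, tol = innerTol,
                        maxit = 200, method = "cg", handle = hU)
    xv <- .stencilSolve(asmV$st, rhs$v, x0 = x0$v, tol = innerTol,
                        maxit = 200, method = "cg", handle = hV)
    xw <- if (hasW) .stencilSolve(asmW$st, rhs$w, x0 = x0$w, tol = innerTol,
                                  maxit = 200, method = "cg", handle = hW)
    list(u = xu, v = xv, w = xw)
  }

  divOf <- function(X) {
    .divergence(.fullU(X$u, asmU$st$act, n), .fullV(X$v, asmV$st$act, n),
                if (hasW) .fullW(X$w, asmW$st$act, n) else
                  array(0, c(nx, ny, nz + 1L)), n, h2) * (open * 1)
  }

  # Schur-complement approximation D diag(A)^-1 D': a pressure Poisson
  # operator whose multigrid V-cycle preconditions the outer CG
  stS <- .newStencil(n)
  cx <- array(0, c(nx, ny, nz))                     # faces i+1 <-> box iu = i
  du <- ifelse(asmU$st$act, asmU$st$diag, Inf)
  cx <- h2^2 / du                                   # includes outlet column
  cxInt <- cx; cxInt[nx, , ] <- 0                   # interior x faces only
  stS$aE <- -cxInt
  stS$aW <- -.shift(cxInt, 1L, -1L)
  dv <- ifelse(asmV$st$act, asmV$st$diag, Inf)
  cy <- array(0, n); cy[, 1:(ny - 1), ] <- h2^2 / dv
  stS$aN <- -cy
  stS$aS <- -.shift(cy, 2L, -1L)
  if (hasW) {
    dw <- ifelse(asmW$st$act, asmW$st$diag, Inf)
    cz <- array(0, n); cz[, , 1:(nz - 1)] <- h2^2 / dw
    stS$aT <- -cz
    stS$aB <- -.shift(cz, 3L, -1L)
  }
  stS$diag <- -(stS$aW + stS$aE + stS$aS + stS$aN + stS$aB + stS$aT)
  stS$diag[nx, , ] <- stS$diag[nx, , ] + cx[nx, , ]  # outlet Dirichlet p = 0
  stS$act <- open & (stS$diag > 0)
  stS$diag[!stS$act] <- 1
  actS <- array(as.numeric(stS$act), n)
  for (nm in c("aW", "aE", "aS", "aN", "aB", "aT"))
    stS[[nm]] <- stS[[nm]] * actS
  hS <- .stencilSetup(stS)
  precS <- function(r) {
    res <- mg_solve(hS, as.numeric(r), numeric(prod(n)), 0, 1L, "mg")
    array(res$x, n)
  }

  # Uzawa-CG on S p = g - D A^-1 b, maintaining U = A^-1 (b + D' p)
  p <- if (!is.null(warmStart)) warmStart@pressure else array(0, n)
  p[!open] <- 0
  gp <- gradP(p)
  U <- solveMom(list(u = asmU$rhs + gp$u, v = gp$v,
                     w = if (hasW) gp$w else NULL))
  r <- g - divOf(U)
  gnorm <- sqrt(sum(g^2))
  z <- precS(r)
  q <- z
  rz <- sum(r * z)
  it <- 0L
  conv <- FALSE
  relres <- sqrt(sum(r^2)) / gnorm
  while (it < maxIter) {
    if (relres < tol) { conv <- TRUE; break }
    it <- it + 1L
    gq <- gradP(q)
    Y <- solveMom(gq)
    s <- divOf(Y)
    qs <- sum(q * s)
    if (qs <= 0) break
    alpha <- rz / qs
    p <- p + alpha * q
    U <- list(u = U$u + alpha * Y$u, v = U$v + alpha * Y$v,
              w = if (hasW) U$w + alpha * Y$w else NULL)
    r <- r - alpha * s
    relres <- sqrt(sum(r^2)) / gnorm
    if (relres < tol) { conv <- TRUE; break }
    z <- precS(r)
    rzn <- sum(r * z)
    beta <- rzn / rz
    rz <- rzn
    q <- z + beta * q
  }
  if (!conv && relres >= tol * 10)
    stop(sprintf(
      "flow solver did not converge: %d iterations, divergence residual %.3g",
      it, relres))

  uu <- .fullU(U$u, asmU$st$act, n)
  uu[1, , ] <- uin                       # inlet Dirichlet values
  vv <- .fullV(U$v, asmV$st$act, n)
  ww <- if (hasW) .fullW(U$w, asmW$st$act, n) else
    array(0, c(nx, ny, nz + 1L))
  shear <- .shearField(uu, vv, ww, mu, open, h)
  new("FlowField", u = uu, v = vv, w = ww, pressure = p, shear = shear,
      massImbalance = relres, iterations = it, converged = conv,
      inletFlux = inletFlux)
})

# Shear-stress magnitude tau = sqrt(0.5 sigma':sigma') at cell centres
# (equals mu |du/dy| for simple shear).
#
# Off-diagonal stresses are evaluated at the staggered edge positions with
# harmonic-mean edge viscosities - the same coefficients as the momentum
# operator - so the stress stays continuous across viscosity jumps
# (evaluating mu_cell x a gradient that straddles a biomass-fluid interface
# would overestimate the interface-cell stress by about mu_b/mu_f).
.shearField <- function(uu, vv, ww, mu, open, h) {
  n <- dim(open)
  nx <- n[1]; ny <- n[2]; nz <- n[3]
  muInv <- ifelse(open, 1 / mu, 0)
  openN <- array(as.numeric(open), n)

  # harmonic-mean viscosity on the edge lattice along dims (da, db):
  # edge (ia, ib) touches cells {ia-1, ia} x {ib-1, ib} (clamped at walls)
  edgeMu <- function(da, db) {
    dims <- n; dims[da] <- n[da] + 1L; dims[db] <- n[db] + 1L
    s <- array(0, dims); cnt <- array(0, dims)
    for (oa in 0:1) for (ob in 0:1) {
      idx <- lapply(seq_len(3), function(d) seq_len(dims[d]))
      idx[[da]] <- idx[[da]] - oa; idx[[db]] <- idx[[db]] - ob
      ok <- lapply(seq_len(3), function(d)
        idx[[d]] >= 1L & idx[[d]] <= n[d])
      sel <- lapply(seq_len(3), function(d) pmin(pmax(idx[[d]], 1L), n[d]))
      m <- array(muInv[sel[[1]], sel[[2]], sel[[3]]], dims)
      o <- array(openN[sel[[1]], sel[[2]], sel[[3]]], dims)
      valid <- outer(outer(ok[[1]], ok[[2]]), ok[[3]])
      dim(valid) <- dims
      s <- s + m * o * valid
      cnt <- cnt + o * valid
    }
    ifelse(cnt > 0, cnt / pmax(s, 1e-300), 0)
  }

  # edge-difference of a staggered component along a transverse dim, with
  # mirror ghosts at the domain walls (wall at half spacing)
  edgeDiff <- function(f, d) {
    nf <- dim(f)
    dims <- nf; dims[d] <- nf[d] + 1L
    g <- array(0, dims)
    idx <- lapply(dims, seq_len)
    iIn <- idx; iIn[[d]] <- 2:nf[d]
    lo <- idx; lo[[d]] <- 1:(nf[d] - 1L)
    hi <- idx; hi[[d]] <- 2:nf[d]
    g[iIn[[1]], iIn[[2]], iIn[[3]]] <-
      (f[hi[[1]], hi[[2]], hi[[3]]] - f[lo[[1]], lo[[2]], lo[[3]]]) / h
    w0 <- idx; w0[[d]] <- 1L
    f0 <- idx; f0[[d]] <- 1L
    g[w0[[1]], w0[[2]], w0[[3]]] <- 2 * f[f0[[1]], f0[[2]], f0[[3]]] / h
    w1 <- idx; w1[[d]] <- dims[d]
    f1 <- idx; f1[[d]] <- nf[d]
    g[w1[[1]], w1[[2]], w1[[3]]] <- -2 * f[f1[[1]], f1[[2]], f1[[3]]] / h
    g
  }

  # average the 4 surrounding edges of dims (da, db) to cell centres
  toCentre <- function(E, da, db) {
    dims <- dim(E)
    i0 <- lapply(seq_len(3), function(d) seq_len(n[d]))
    i1 <- i0; i1[[da]] <- i0[[da]] + 1L
    i2 <- i0; i2[[db]] <- i0[[db]] + 1L
    i3 <- i1; i3[[db]] <- i0[[db]] + 1L
    0.25 * (array(E[i0[[1]], i0[[2]], i0[[3]]], n) +
            array(E[i1[[1]], i1[[2]], i1[[3]]], n) +
            array(E[i2[[1]], i2[[2]], i2[[3]]], n) +
            array(E[i3[[1]], i3[[2]], i3[[3]]], n))
  }

  dudx <- (uu[2:(nx + 1), , , drop = FALSE] - uu[1:nx, , , drop = FALSE]) / h
  dvdy <- (vv[, 2:(ny + 1), , drop = FALSE] - vv[, 1:ny, , drop = FALSE]) / h
  dwdz <- (ww[, , 2:(nz + 1), drop = FALSE] - ww[, , 1:nz, drop = FALSE]) / h
  dim(dudx) <- n; dim(dvdy) <- n; dim(dwdz) <- n
  sxx <- 2 * mu * dudx
  syy <- 2 * mu * dvdy
  szz <- 2 * mu * dwdz

  # tau_xy on (x, y) edges: u has y-edges along dim 2, v has x-edges (its
  # x-extent nx, one ghost column at the outlet where dv/dx = 0)
  muXY <- edgeMu(1L, 2L)                          # (nx+1, ny+1, nz)
  dudy <- edgeDiff(uu, 2L)                        # (nx+1, ny+1, nz)
  dvdxE <- edgeDiff(vv, 1L)                       # (nx+1, ny+1, nz)
  dvdxE[nx + 1L, , ] <- 0                         # outlet: zero-gradient
  sxyC <- toCentre(muXY * (dudy + dvdxE), 1L, 2L)

  muXZ <- edgeMu(1L, 3L)
  dudz <- edgeDiff(uu, 3L)
  dwdxE <- edgeDiff(ww, 1L)
  dwdxE[nx + 1L, , ] <- 0
  sxzC <- toCentre(muXZ * (dudz + dwdxE), 1L, 3L)

  muYZ <- edgeMu(2L, 3L)
  dvdz <- edgeDiff(vv, 3L)
  dwdy <- edgeDiff(ww, 2L)
  syzC <- toCentre(muYZ * (dvdz + dwdy), 2L, 3L)

  tau <- sqrt(0.5 * (sxx^2 + syy^2 + szz^2) + sxyC^2 + sxzC^2 + syzC^2)
  tau[!open] <- 0
  tau
}

#' Shear-stress magnitude of a flow field
#'
#' `tau = mu * sqrt(2 e:e)` per voxel with `e` the strain-rate tensor
#' (for simple shear `du/dy` this equals `mu |du/dy|`). Also reports the
#' mean and maximum over the biomass shell.
#'
#' @param flow a [FlowField-class].
#' @param mu viscosity array or scalar (Pa s).
#' @param domain the [VoxelDomain-class] the flow was solved on.
#' @return list with `tau` (array), `meanBiomass`, `maxBiomass` (Pa).
#' @export
shearMagnitude <- function(flow, mu, domain) {
  open <- domain@labels != 1L
  if (length(mu) == 1L) mu <- array(mu, domain@dims)
  tau <- .shearField(flow@u, flow@v, flow@w, mu, open, domain@spacing)
  bio <- domain@labels == 2L
  list(tau = tau,
       meanBiomass = if (any(bio)) mean(tau[bio]) else NA_real_,
       maxBiomass = if (any(bio)) max(tau[bio]) else NA_real_)
}

# ---- developed-flow reductions ---------------------------------------------

#' Fully developed plane-channel flow (1-D reduction)
#'
#' Solves `-mu u'' = G` across the gap with no-slip walls, scaled to the
#' requested mean velocity. The analytic wall shear is `6 mu U / H`
#' (equivalently `3 mu U / h` for half-gap h).
#'
#' @param n cells across the gap.
#' @param mu viscosity (Pa s).
#' @param meanVelocity mean velocity U (m/s).
#' @param gap channel gap H (m).
#' @return list with `y` (cell centres), `u` (velocity profile), and
#'   `wallShear` (Pa, second-order one-sided extraction).
#' @export
solveChannelFlow <- function(n, mu = 1e-3, meanVelocity, gap) {
  n <- as.integer(n)
  h <- gap / n
  st <- .newStencil(c(n, 1L, 1L))
  st$act[] <- TRUE
  a <- mu / h^2
  st$aW[2:n, 1, 1] <- -a
  st$aE[1:(n - 1), 1, 1] <- -a
  st$diag <- -(st$aW + st$aE)
  st$diag[1, 1, 1] <- st$diag[1, 1, 1] + 2 * a
  st$diag[n, 1, 1] <- st$diag[n, 1, 1] + 2 * a
  u <- as.numeric(.stencilSolve(st, rep(1, n), tol = 1e-12, maxit = 200))
  u <- u * meanVelocity / mean(u)
  wallShear <- mu * (9 * u[1] - u[2]) / (3 * h)
  list(y = (seq_len(n) - 0.5) * h, u = u, wallShear = wallShear)
}

#' Fully developed rectangular-duct flow (2-D reduction)
#'
#' Solves the developed-flow Poisson problem `-mu lap(u) = G` on the duct
#' cross-section with no-slip walls, scaled to the requested mean velocity.
#'
#' @param ny,nz cells across the section.
#' @param mu viscosity (Pa s).
#' @param meanVelocity mean velocity (m/s).
#' @param widthY,widthZ section dimensions (m).
#' @return list with `y`, `z` (cell centres) and matrix `u` (ny x nz).
#' @export
solveDuctFlow <- function(ny, nz, mu = 1e-3, meanVelocity, widthY, widthZ) {
  ny <- as.integer(ny); nz <- as.integer(nz)
  hy <- widthY / ny; hz <- widthZ / nz
  st <- .newStencil(c(ny, nz, 1L))
  st$act[] <- TRUE
  ay <- mu / hy^2; az <- mu / hz^2
  st$aW[2:ny, , 1] <- -ay
  st$aE[1:(ny - 1), , 1] <- -ay
  st$aS[, 2:nz, 1] <- -az
  st$aN[, 1:(nz - 1), 1] <- -az
  st$diag <- -(st$aW + st$aE + st$aS + st$aN)
  st$diag[1, , 1] <- st$diag[1, , 1] + 2 * ay
  st$diag[ny, , 1] <- st$diag[ny, , 1] + 2 * ay
  st$diag[, 1, 1] <- st$diag[, 1, 1] + 2 * az
  st$diag[, nz, 1] <- st$diag[, nz, 1] + 2 * az
  u <- .stencilSolve(st, rep(1, ny * nz), tol = 1e-12, maxit = 300)
  u <- u * meanVelocity / mean(u)
  list(y = (seq_len(ny) - 0.5) * hy, z = (seq_len(nz) - 0.5) * hz,
       u = matrix(u, ny, nz))
}
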