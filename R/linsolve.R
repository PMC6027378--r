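#' @include AllClasses.R
NULL

# Thin wrapper over the C++ multigrid-preconditioned Krylov core.
#
# A "stencil" is a list of arrays over a DOF box of dimensions `dims`:
#   diag, aW/aE (x couplings), aS/aN (y), aB/aT (z), act (logical).
# Off-diagonal entries must be zero wherever they would point at an
# inactive DOF or outside the box; inactive DOFs are Dirichlet-eliminated.

.newStencil <- function(dims) {
  z <- array(0, dims)
  list(dims = as.integer(dims), diag = z, aW = z, aE = z, aS = z, aN = z,
       aB = z, aT = z, act = array(FALSE, dims))
}

.stencilSetup <- function(st) {
  mg_setup(st$dims, as.numeric(st$diag),
           as.numeric(st$aW), as.numeric(st$aE),
           as.numeric(st$aS), as.numeric(st$aN),
           as.numeric(st$aB), as.numeric(st$aT),
           as.logical(st$act))
}

# solve A x = b for an assembled stencil; returns array-shaped solution
.stencilSolve <- function(st, b, x0 = NULL, tol = 1e-10, maxit = 400,
                          method = c("cg", "bicgstab"), handle = NULL) {
  method <- match.arg(method)
  if (is.null(handle)) handle <- .stencilSetup(st)
  if (is.null(x0)) x0 <- numeric(prod(st$dims))
  res <- mg_solve(handle, as.numeric(b), as.numeric(x0), tol, maxit, method)
  if (!res$converged)
    stop(sprintf(
      "linear solver did not converge: %d iterations, relative residual %.3g",
      res$iter, res$relres))
  array(res$x, st$dims)
}
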