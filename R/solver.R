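#' @importFrom Matrix sparseMatrix Cholesky solve
NULL

# Face conductances (per unit depth) with harmonic averaging across the
# conductivity jump; zero wherever either cell is non-conducting, which
# realizes the zero-flux condition on the outer boundary and around
# internal insulating holes (trachea, esophagus).
faceConductances <- function(sigma, dx, dy) {
  nx <- nrow(sigma); ny <- ncol(sigma)
  hm <- function(a, b) ifelse(a + b > 0, 2 * a * b / (a + b), 0)
  gx <- hm(sigma[-nx, , drop = FALSE], sigma[-1, , drop = FALSE]) * dy / dx
  gy <- hm(sigma[, -ny, drop = FALSE], sigma[, -1, drop = FALSE]) * dx / dy
  list(gx = gx, gy = gy)
}

# Connected conducting component containing the reference electrode,
# by iterative dilation. Floating conducting islands (if any) are left out
# of the linear system; their potential is reported as 0.
connectedComponent <- function(active, start) {
  nx <- nrow(active); ny <- ncol(active)
  comp <- matrix(FALSE, nx, ny)
  comp[start] <- TRUE
  repeat {
    grown <- comp
    grown[-1, ] <- grown[-1, ] | comp[-nx, ]
    grown[-nx, ] <- grown[-nx, ] | comp[-1, ]
    grown[, -1] <- grown[, -1] | comp[, -ny]
    grown[, -ny] <- grown[, -ny] | comp[, -1]
    grown <- grown & active
    if (identical(grown, comp)) break
    comp <- grown
  }
  comp
}

#' Prefactorized potential solver for a phantom
#'
#' Assembles the 5-point finite-difference operator for
#' `div(sigma grad u)` on the conducting cells (face-harmonic conductivity
#' averaging, zero-flux outer boundary), gauges the potential to 0 at the
#' reference electrode e0 by pinning its cell, and caches a sparse Cholesky
#' factorization so repeated solves (time samples, reciprocal fields) cost
#' one triangular solve each.
#'
#' @param phantom a [NeckPhantom-class].
#' @param sigma optional conductivity override matrix (same grid).
#' @return an object of class `PotentialSolver`.
#' @export
makeSolver <- function(phantom, sigma = NULL) {
  sigma <- sigma %||% phantom@sigma
  if (all(sigma == 0)) stopf("all-zero conductivity: system is unsolvable")
  nx <- phantom@nx; ny <- phantom@ny
  e0 <- phantom@electrodes[1]
  if (sigma[e0] <= 0) stopf("reference electrode sits on a non-conducting cell")
  active <- connectedComponent(sigma > 0, e0)
  g <- faceConductances(ifelse(active, sigma, 0), phantom@dx, phantom@dy)

  cells <- which(active)
  eqOf <- matrix(NA_integer_, nx, ny)
  eqOf[cells] <- seq_along(cells)

  # x-faces between (i,j) and (i+1,j)
  fi <- which(g$gx > 0, arr.ind = TRUE)
  pA <- eqOf[cbind(fi[, 1], fi[, 2])]
  pB <- eqOf[cbind(fi[, 1] + 1L, fi[, 2])]
  wX <- g$gx[g$gx > 0]
  fj <- which(g$gy > 0, arr.ind = TRUE)
  qA <- eqOf[cbind(fj[, 1], fj[, 2])]
  qB <- eqOf[cbind(fj[, 1], fj[, 2] + 1L)]
  wY <- g$gy[g$gy > 0]

  ii <- c(pA, pB, pA, pB, qA, qB, qA, qB)
  jj <- c(pA, pB, pB, pA, qA, qB, qB, qA)
  vv <- c(wX, wX, -wX, -wX, wY, wY, -wY, -wY)
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = vv,
                            dims = c(length(cells), length(cells)))

  pin <- eqOf[e0]
  keep <- setdiff(seq_along(cells), pin)
  Msub <- M[keep, keep, drop = FALSE]
  fac <- Matrix::Cholesky(methods::as(Matrix::forceSymmetric(Msub), "CsparseMatrix"),
                          LDL = FALSE, perm = TRUE)
  structure(list(nx = nx, ny = ny, dx = phantom@dx, dy = phantom@dy,
                 sigma = sigma, active = active, cells = cells, eqOf = eqOf,
                 keep = keep, pin = pin, fac = fac, g = g, e0 = e0),
            class = "PotentialSolver")
}

#' @export
print.PotentialSolver <- function(x, ...) {
  cat(sprintf("PotentialSolver: %d unknowns on %d x %d grid (e0 pinned)\n",
              length(x$keep), x$nx, x$ny))
  invisible(x)
}

# Solve M u = b for a full-grid right-hand side (vector or matrix of
# stacked columns); returns full-grid potentials with 0 on pinned and
# non-conducting cells.
solveGrid <- function(solver, b) {
  b <- as.matrix(b)
  bs <- b[solver$cells[solver$keep], , drop = FALSE]
  x <- as.matrix(Matrix::solve(solver$fac, bs, system = "A"))
  u <- matrix(0, solver$nx * solver$ny, ncol(b))
  u[solver$cells[solver$keep], ] <- x
  u
}

# Right-hand side div(sigma * F) for a y-directed impressed field Fy (v x B),
# in flux (per-unit-depth current) form matching the assembled operator.
fluxRHS <- function(solver, Fy) {
  nx <- solver$nx; ny <- solver$ny
  sig <- ifelse(solver$active, solver$sigma, 0)
  hm <- function(a, b) ifelse(a + b > 0, 2 * a * b / (a + b), 0)
  sf <- hm(sig[, -ny, drop = FALSE], sig[, -1, drop = FALSE])
  ff <- (Fy[, -ny, drop = FALSE] + Fy[, -1, drop = FALSE]) / 2
  s <- sf * ff * solver$dx
  b <- matrix(0, nx, ny)
  b[, -ny] <- b[, -ny] - s
  b[, -1] <- b[, -1] + s
  as.vector(b)
}

#' Solve the flow-induced potential equation
#'
#' Solves `div(sigma grad u) = div(sigma (v x B))` on the heterogeneous
#' phantom with a uniform magnetic field along +x and axial flow along +z,
#' so the impressed field `v x B` points along +y with magnitude `v * B`.
#' Zero-flux outer boundary; potential gauged to 0 at e0.
#'
#' @param phantom a [NeckPhantom-class].
#' @param vel a `VelocityField` from [velocityField()].
#' @param B magnetic field strength (T); a negative value flips the field
#'   and negates every potential (the PDE is linear in B).
#' @param solver optional prebuilt [makeSolver()] result.
#' @return potential matrix (V) over the grid (0 on non-conducting cells).
#' @export
solveFlowPotential <- function(phantom, vel, B, solver = NULL) {
  solver <- solver %||% makeSolver(phantom)
  Fy <- vel$vz * B
  u <- solveGrid(solver, fluxRHS(solver, Fy))
  matrix(u, phantom@nx, phantom@ny)
}

#' Extract electrode potential differences
#'
#' `U_k = u(e_k) - u(e0)` for the 11 measuring electrodes.
#'
#' @param u potential matrix from [solveFlowPotential()].
#' @param phantom a [NeckPhantom-class].
#' @return numeric vector of length 11 (V).
#' @export
electrodeVoltages <- function(u, phantom) {
  e <- phantom@electrodes
  as.numeric(u[e[2:12]] - u[e[1]])
}

#' Reciprocal current-density field of one measuring electrode
#'
#' Injects unit current (1 A per unit depth) at measuring electrode `k` and
#' withdraws it at the reference e0, solves `div(sigma grad uA) = 0`, and
#' evaluates `J_A = -sigma grad uA` at cell centres (central differences
#' where both neighbours conduct, one-sided at boundaries and holes).
#'
#' @param phantom a [NeckPhantom-class].
#' @param k measuring electrode index, 1..11 (0 — the reference — is rejected).
#' @param solver optional prebuilt solver.
#' @return object of class `ReciprocalField`: list with `Jx`, `Jy` (A/m^2
#'   matrices), `uA` and `electrode`.
#' @export
reciprocalField <- function(phantom, k, solver = NULL) {
  if (length(k) != 1L || k < 1 || k > 11)
    stopf("k must be a measuring electrode index 1..11 (the reference e0 cannot be driven)")
  solver <- solver %||% makeSolver(phantom)
  b <- numeric(solver$nx * solver$ny)
  b[phantom@electrodes[k + 1L]] <- 1
  uA <- matrix(solveGrid(solver, b), solver$nx, solver$ny)
  J <- currentDensity(uA, solver)
  structure(list(Jx = J$Jx, Jy = J$Jy, uA = uA, electrode = as.integer(k)),
            class = "ReciprocalField")
}

#' @export
print.ReciprocalField <- function(x, ...) {
  cat(sprintf("ReciprocalField e%d: max |J| = %.3g A/m^2\n", x$electrode,
              max(sqrt(x$Jx^2 + x$Jy^2))))
  invisible(x)
}

# J = -sigma grad u at cell centres, evaluated as the mean of the two
# face current densities per direction (harmonic face conductivity, same
# faces the operator uses). The normal current is continuous across
# conductivity jumps, so this form stays accurate at tissue boundaries and
# makes the assembled weight matrix the exact discrete adjoint of the flow
# solve. Faces into non-conducting cells carry zero current.
currentDensity <- function(u, solver) {
  nx <- solver$nx; ny <- solver$ny
  sig <- ifelse(solver$active, solver$sigma, 0)
  hm <- function(a, b) ifelse(a + b > 0, 2 * a * b / (a + b), 0)
  # x-direction: face current density between (i,j) and (i+1,j)
  sfx <- hm(sig[-nx, , drop = FALSE], sig[-1, , drop = FALSE])
  jxf <- -sfx * (u[-1, , drop = FALSE] - u[-nx, , drop = FALSE]) / solver$dx
  jxE <- rbind(jxf, 0)   # east face of each cell
  jxW <- rbind(0, jxf)   # west face
  sfy <- hm(sig[, -ny, drop = FALSE], sig[, -1, drop = FALSE])
  jyf <- -sfy * (u[, -1, drop = FALSE] - u[, -ny, drop = FALSE]) / solver$dy
  jyN <- cbind(jyf, 0)
  jyS <- cbind(0, jyf)
  act <- solver$active
  list(Jx = (jxE + jxW) / 2 * act, Jy = (jyN + jyS) / 2 * act)
}

#' Net outward current across a rectangular contour
#'
#' Sums the discrete face currents `g * (u_in - u_out)` across the boundary
#' of the cell rectangle `x0:x1, y0:y1`. For a solution of the reciprocal
#' problem, any contour separating the driven electrode from the reference
#' carries the full injected current (Kirchhoff's current law); a single
#' cell gives the discrete divergence.
#'
#' @param phantom a [NeckPhantom-class].
#' @param u potential matrix.
#' @param rect integer(4): `c(x0, x1, y0, y1)` cell bounds (inclusive).
#' @param solver optional prebuilt solver.
#' @return net outward current (A per unit depth).
#' @export
netCurrentThrough <- function(phantom, u, rect, solver = NULL) {
  solver <- solver %||% makeSolver(phantom)
  g <- solver$g
  x0 <- rect[1]; x1 <- rect[2]; y0 <- rect[3]; y1 <- rect[4]
  nx <- solver$nx; ny <- solver$ny
  tot <- 0
  ys <- y0:y1; xs <- x0:x1
  if (x1 < nx) tot <- tot + sum(g$gx[x1, ys] * (u[x1, ys] - u[x1 + 1, ys]))
  if (x0 > 1) tot <- tot + sum(g$gx[x0 - 1, ys] * (u[x0, ys] - u[x0 - 1, ys]))
  if (y1 < ny) tot <- tot + sum(g$gy[xs, y1] * (u[xs, y1] - u[xs, y1 + 1]))
  if (y0 > 1) tot <- tot + sum(g$gy[xs, y0 - 1] * (u[xs, y0] - u[xs, y0 - 1]))
  tot
}

#' Assemble the weight (sensitivity) matrix
#'
#' Drives the 11 measuring electrodes in turn, computes each reciprocal
#' field, and forms `W[k, i] = -J_Ay^(k)(cell i) * B * S_i` over the ROI
#' cells in x-fastest window order, so that `U = W v` reproduces the full
#' PDE electrode voltages for ROI-supported velocity fields (reciprocity).
#' The sensitivity map is meant to be computed from the stenosis-free
#' phantom; stenosed measurements are deliberately reconstructed with this
#' mismatched W.
#'
#' @param phantom a [NeckPhantom-class] (stenosis-free).
#' @param weightB field strength (T) for the sensitivity map.
#' @param solver optional prebuilt solver.
#' @return a [WeightMatrix-class] of shape 11 x n.
#' @export
assembleWeightMatrix <- function(phantom, weightB = 0.1, solver = NULL) {
  if (weightB < 0) stopf("weightB must be nonnegative")
  solver <- solver %||% makeSolver(phantom)
  idx <- roiCells(phantom)
  S <- cellArea(phantom)
  W <- matrix(0, 11L, length(idx))
  for (k in 1:11) {
    rf <- reciprocalField(phantom, k, solver)
    W[k, ] <- -rf$Jy[idx] * weightB * S
  }
  new("WeightMatrix", W, areas = rep(S, length(idx)), weightB = weightB,
      roiDim = phantom@roi[3:4])
}
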