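#' Small-grid linear-elastic voxel finite elements
#'
#' Every voxel becomes an 8-node hexahedral element with trilinear shape
#' functions and 2x2x2 Gauss quadrature; the material is isotropic with a
#' per-voxel Young's modulus and a shared Poisson's ratio. Two boundary
#' condition modes are supported: `"uniaxial"` fixes the bottom (z = 0) face in
#' all directions and displaces the top face axially by
#' `axial_strain x length` (lateral top components free), the uniaxial
#' compression protocol used for mouse vertebra models; `"affine"` imposes
#' the affine displacement field of uniform uniaxial strain with lateral
#' contraction `-poisson x strain` on all boundary nodes, for which a
#' homogeneous block has the exact solution SED `= E strain^2 / 2`
#' everywhere. The reduced system is solved by Jacobi-preconditioned
#' conjugate gradients to a relative residual of 1e-8.
#'
#' Units: moduli in MPa and lengths in um give SED in MPa and reaction
#' forces in N (1 MPa um^2 = 1e-6 N).
#'
#' @param E_field [scalar_volume()] of per-voxel Young's modulus (MPa), all
#'   values > 0.
#' @param poisson Poisson's ratio in `[0, 0.5)`.
#' @param axial_strain applied axial strain (unitless, e.g. 0.01 for 1%).
#' @param bc_mode `"uniaxial"` or `"affine"` (see above).
#' @param tol relative residual for the iterative solve.
#' @param maxit iteration cap for conjugate gradients.
#' @param size_cap refuse grids with any dimension above this (elements).
#' @return a list with `sed` (per-element [scalar_volume()], MPa),
#'   `reaction_force` (N, axial force on the displaced face), `iterations`
#'   and `residual`.
#' @export
microfe_solve <- function(E_field, poisson = 0.3, axial_strain = 0.01,
                          bc_mode = c("uniaxial", "affine"), tol = 1e-8,
                          maxit = 20000L, size_cap = 64L) {
  bc_mode <- match.arg(bc_mode)
  stopifnot(inherits(E_field, "voxel_volume"))
  if (any(E_field$data <= 0)) {
    stop("E_field must be strictly positive", call. = FALSE)
  }
  d <- dim(E_field$data)                      # elements per axis (z, y, x)
  if (any(d > size_cap)) {
    stop(sprintf("grid too large for the desk-scale solver (cap %d)",
                 size_cap), call. = FALSE)
  }
  h <- E_field$voxel_size
  nzn <- d[1] + 1L; nyn <- d[2] + 1L; nxn <- d[3] + 1L
  nn <- nzn * nyn * nxn
  ndof <- 3L * nn

  k_unit <- hex8_stiffness(1, poisson, h)

  # node ids laid out (z fastest, then y, then x) to match element order
  nid <- function(z, y, x) z + (y - 1L) * nzn + (x - 1L) * nzn * nyn
  el <- expand.grid(z = seq_len(d[1]), y = seq_len(d[2]), x = seq_len(d[3]))
  corners <- expand.grid(dx = 0:1, dy = 0:1, dz = 0:1)  # local node order
  enodes <- matrix(0L, nrow(el), 8L)
  for (i in 1:8) {
    enodes[, i] <- nid(el$z + corners$dz[i], el$y + corners$dy[i],
                       el$x + corners$dx[i])
  }
  edof <- matrix(0L, nrow(el), 24L)
  for (i in 1:8) {
    edof[, 3L * i - 2L] <- 3L * (enodes[, i] - 1L) + 1L
    edof[, 3L * i - 1L] <- 3L * (enodes[, i] - 1L) + 2L
    edof[, 3L * i]      <- 3L * (enodes[, i] - 1L) + 3L
  }
  Ee <- as.vector(E_field$data)

  K <- assemble_stiffness(edof, Ee, k_unit, ndof)

  # node coordinates (um), origin at the fixed face
  gz <- rep(seq_len(nzn) - 1L, times = nyn * nxn) * h
  gy <- rep(rep(seq_len(nyn) - 1L, each = nzn), times = nxn) * h
  gx <- rep(seq_len(nxn) - 1L, each = nzn * nyn) * h
  Lz <- d[1] * h

  prescribed <- logical(ndof)
  uval <- numeric(ndof)
  on_bottom <- gz == 0
  on_top <- gz == Lz
  if (bc_mode == "uniaxial") {
    bot_nodes <- which(on_bottom); top_nodes <- which(on_top)
    for (c in 1:3) prescribed[3L * (bot_nodes - 1L) + c] <- TRUE
    zdof_top <- 3L * (top_nodes - 1L) + 3L
    prescribed[zdof_top] <- TRUE
    uval[zdof_top] <- axial_strain * Lz
  } else {
    boundary <- on_bottom | on_top | gy == 0 | gy == max(gy) |
      gx == 0 | gx == max(gx)
    bn <- which(boundary)
    prescribed[3L * (bn - 1L) + 1L] <- TRUE
    prescribed[3L * (bn - 1L) + 2L] <- TRUE
    prescribed[3L * (bn - 1L) + 3L] <- TRUE
    uval[3L * (bn - 1L) + 1L] <- -poisson * axial_strain * gx[bn]
    uval[3L * (bn - 1L) + 2L] <- -poisson * axial_strain * gy[bn]
    uval[3L * (bn - 1L) + 3L] <- axial_strain * gz[bn]
  }

  free <- which(!prescribed)
  fixed <- which(prescribed)
  u <- uval
  if (length(free) > 0) {
    Kff <- K[free, free, drop = FALSE]
    rhs <- -as.vector(K[free, fixed, drop = FALSE] %*% uval[fixed])
    sol <- pcg_solve(Kff, rhs, tol = tol, maxit = maxit)
    u[free] <- sol$x
    iterations <- sol$iterations
    residual <- sol$residual
    if (!sol$converged) {
      stop(sprintf(
        "microfe_solve: CG did not reach tolerance %g in %d iterations (residual %g)",
        tol, maxit, residual), call. = FALSE)
    }
  } else {
    iterations <- 0L
    residual <- 0
  }

  # per-element SED = strain energy / element volume
  ue <- matrix(u[edof], nrow(edof), 24L)
  quad <- rowSums((ue %*% k_unit) * ue)
  sed_vals <- pmax(0.5 * Ee * quad / h^3, 0)
  sed <- scalar_volume(array(sed_vals, dim = d), h)

  # axial reaction on the displaced (top) face, MPa um^2 -> N
  f_all <- as.vector(K %*% u)
  top_nodes <- which(on_top)
  reaction <- sum(f_all[3L * (top_nodes - 1L) + 3L]) * 1e-6

  list(sed = sed, reaction_force = reaction,
       iterations = iterations, residual = residual)
}

# Block-wise triplet assembly of the global stiffness matrix.
assemble_stiffness <- function(edof, Ee, k_unit, ndof, block = 4096L) {
  kvec <- as.vector(k_unit)                 # column-major, 576 values
  pvec <- rep(1:24, times = 24)
  qvec <- rep(1:24, each = 24)
  nel <- nrow(edof)
  K <- NULL
  for (start in seq(1L, nel, by = block)) {
    idx <- start:min(start + block - 1L, nel)
    ii <- edof[idx, pvec, drop = FALSE]
    jj <- edof[idx, qvec, drop = FALSE]
    xx <- Ee[idx] %o% kvec
    Kb <- Matrix::sparseMatrix(i = as.vector(ii), j = as.vector(jj),
                               x = as.vector(xx), dims = c(ndof, ndof))
    K <- if (is.null(K)) Kb else K + Kb
  }
  K
}

#' Element stiffness of the 8-node voxel hexahedron
#'
#' Isoparametric trilinear element on a cube of edge `h`, isotropic material
#' `(E, nu)`, 2x2x2 Gauss quadrature. Local nodes are ordered x fastest,
#' then y, then z; each node carries `(ux, uy, uz)`.
#'
#' @param E Young's modulus (MPa).
#' @param nu Poisson's ratio.
#' @param h element edge length (um).
#' @return dense 24 x 24 stiffness matrix (MPa um).
#' @export
hex8_stiffness <- function(E, nu, h) {
  lambda <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lambda
  diag(D)[1:3] <- lambda + 2 * mu
  diag(D)[4:6] <- mu
  corners <- expand.grid(dx = 0:1, dy = 0:1, dz = 0:1)
  xi_n <- 2 * corners$dx - 1
  eta_n <- 2 * corners$dy - 1
  zeta_n <- 2 * corners$dz - 1
  gp <- c(-1, 1) / sqrt(3)
  K <- matrix(0, 24, 24)
  detJ <- (h / 2)^3
  dscale <- 2 / h
  for (a in gp) for (b in gp) for (c in gp) {
    dNdx <- 0.125 * xi_n * (1 + eta_n * b) * (1 + zeta_n * c) * dscale
    dNdy <- 0.125 * (1 + xi_n * a) * eta_n * (1 + zeta_n * c) * dscale
    dNdz <- 0.125 * (1 + xi_n * a) * (1 + eta_n * b) * zeta_n * dscale
    B <- matrix(0, 6, 24)
    for (i in 1:8) {
      col <- 3 * (i - 1)
      B[1, col + 1] <- dNdx[i]
      B[2, col + 2] <- dNdy[i]
      B[3, col + 3] <- dNdz[i]
      B[4, col + 1] <- dNdy[i]; B[4, col + 2] <- dNdx[i]
      B[5, col + 2] <- dNdz[i]; B[5, col + 3] <- dNdy[i]
      B[6, col + 1] <- dNdz[i]; B[6, col + 3] <- dNdx[i]
    }
    K <- K + t(B) %*% D %*% B * detJ
  }
  K
}

# Jacobi-preconditioned conjugate gradients for SPD sparse systems.
pcg_solve <- function(A, b, tol = 1e-8, maxit = 20000L) {
  n <- length(b)
  x <- numeric(n)
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0) {
    return(list(x = x, iterations = 0L, residual = 0, converged = TRUE))
  }
  dinv <- 1 / Matrix::diag(A)
  r <- b
  z <- dinv * r
  p <- z
  rz <- sum(r * z)
  it <- 0L
  repeat {
    it <- it + 1L
    Ap <- as.vector(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    res <- sqrt(sum(r^2)) / bnorm
    if (res <= tol || it >= maxit) {
      return(list(x = x, iterations = it, residual = res,
                  converged = res <= tol))
    }
    z <- dinv * r
    rz_new <- sum(r * z)
    beta <- rz_new / rz
    rz <- rz_new
    p <- z + beta * p
  }
}
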