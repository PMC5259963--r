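#' Linear elastic isotropic material
#'
#' The TM is modeled as a homogeneous, isotropic, linearly elastic solid.
#' The reference parameter set for rat trabecular meshwork is a Young's
#' modulus of 162 Pa and a Poisson ratio of 0.48.
#'
#' @param young_modulus Young's modulus E, Pa (> 0).
#' @param poisson_ratio Poisson ratio nu, in (-1, 0.5).
#' @return An object of class `material_model`.
#' @export
material_model <- function(young_modulus = 162, poisson_ratio = 0.48) {
  if (young_modulus <= 0)
    tb_stop("tb_invalid_input", "young_modulus must be > 0")
  if (poisson_ratio <= -1 || poisson_ratio > 0.5 - 1e-12)
    if (abs(poisson_ratio - 0.5) < 1e-12)
      tb_stop("tb_incompressible",
              "nu = 0.5 is the incompressible limit: Hooke matrix is singular")
    else tb_stop("tb_invalid_input", "poisson_ratio must lie in (-1, 0.5)")
  structure(list(young_modulus = young_modulus,
                 poisson_ratio = poisson_ratio), class = "material_model")
}

#' Isotropic Hooke matrix in Voigt form
#'
#' 6x6 constitutive matrix relating engineering strain
#' `(exx, eyy, ezz, gxy, gyz, gzx)` to stress, with Lame parameters
#' `lambda = E nu / ((1 + nu)(1 - 2 nu))` and `mu = E / (2 (1 + nu))`.
#'
#' @param material a [material_model()].
#' @return Symmetric positive-definite 6x6 matrix (Pa).
#' @export
elasticity_matrix <- function(material) {
  E <- material$young_modulus; nu <- material$poisson_ratio
  lambda <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- diag(c(rep(2 * mu + lambda, 3), rep(mu, 3)))
  D[1:3, 1:3][upper.tri(diag(3)) | lower.tri(diag(3))] <- lambda
  D
}

# Constant strain-displacement matrix (6 x 12) and volume of a linear tet.
tet_b_matrix <- function(coords) {
  M <- cbind(1, coords)
  V <- det(M) / 6
  if (V <= 0)
    tb_stop("tb_degenerate_element",
            sprintf("tetrahedron has non-positive volume %g", V))
  C <- solve(M)  # shape function i = C[1,i] + C[2,i] x + C[3,i] y + C[4,i] z
  B <- matrix(0, 6, 12)
  for (i in 1:4) {
    bx <- C[2, i]; by <- C[3, i]; bz <- C[4, i]
    cols <- 3 * (i - 1) + 1:3
    B[1, cols[1]] <- bx
    B[2, cols[2]] <- by
    B[3, cols[3]] <- bz
    B[4, cols[1]] <- by; B[4, cols[2]] <- bx
    B[5, cols[2]] <- bz; B[5, cols[3]] <- by
    B[6, cols[1]] <- bz; B[6, cols[3]] <- bx
  }
  list(B = B, V = V)
}

#' Element stiffness of a constant-strain tetrahedron
#'
#' `K_e = V B' D B` with `B` the constant strain-displacement matrix of the
#' 4-node linear tetrahedron. The result is symmetric with a 6-dimensional
#' null space (rigid translations and rotations).
#'
#' @param coords 4 x 3 matrix of node coordinates (consistent length unit;
#'   the assembled solver uses meters).
#' @param D 6x6 constitutive matrix from [elasticity_matrix()].
#' @return 12 x 12 symmetric stiffness matrix.
#' @export
element_stiffness <- function(coords, D) {
  bv <- tet_b_matrix(coords)
  K <- bv$V * crossprod(bv$B, D %*% bv$B)
  (K + t(K)) / 2
}

#' Assemble the global stiffness matrix
#'
#' Geometry is converted from um to m during assembly, so with pressures in
#' Pa the force unit is N and displacements come out in m. For a single
#' connected unconstrained mesh the matrix has exactly the 6 rigid-body
#' modes in its null space.
#'
#' @param mesh a `tet_mesh` (coordinates in um).
#' @param material a [material_model()].
#' @return Sparse symmetric `3N x 3N` stiffness matrix (N/m per dof).
#' @export
assemble_stiffness <- function(mesh, material) {
  vols <- tet_volumes(mesh)
  if (any(vols <= 0))
    tb_stop("tb_mesh_error", "mesh contains non-positively-oriented tets")
  D <- elasticity_matrix(material)
  nt <- nrow(mesh$tets)
  nn <- nrow(mesh$nodes)
  ii <- integer(nt * 144); jj <- integer(nt * 144); xx <- numeric(nt * 144)
  pos <- 0L
  for (e in seq_len(nt)) {
    en <- mesh$tets[e, ]
    Ke <- element_stiffness(mesh$nodes[en, , drop = FALSE] * 1e-6, D)
    dofs <- as.vector(t(outer(en, 1:3, function(n, c) 3 * (n - 1) + c)))
    idx <- pos + seq_len(144L)
    ii[idx] <- rep(dofs, times = 12)
    jj[idx] <- rep(dofs, each = 12)
    xx[idx] <- as.vector(Ke)
    pos <- pos + 144L
  }
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(3 * nn, 3 * nn))
  Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
}

#' Dof indices of node components
#'
#' Maps node ids and displacement components to global degree-of-freedom
#' indices (`x = 1`, `y = 2`, `z = 3`).
#'
#' @param nodes integer node ids.
#' @param components which components to constrain at those nodes.
#' @return Integer vector of dof indices.
#' @export
fixed_dofs <- function(nodes, components = 1:3) {
  sort(unique(as.vector(outer(3 * (nodes - 1), components, `+`))))
}

#' Define a FEM load case
#'
#' @param pressure applied pressure magnitude, Pa (>= 0); physically the
#'   IOP-EVP pressure drop across the TM.
#' @param pressure_normal length-3 direction (normalized internally); the
#'   load pushes into the tissue, i.e. along `-pressure_normal`.
#' @param fixed integer vector of constrained dof indices (see
#'   [fixed_dofs()]); must be non-empty.
#' @return An object of class `load_case`.
#' @export
load_case <- function(pressure, pressure_normal, fixed) {
  if (pressure < 0) tb_stop("tb_invalid_input", "pressure must be >= 0")
  if (length(fixed) == 0)
    tb_stop("tb_insufficient_constraint", "fixed dof set must be non-empty")
  n <- sqrt(sum(pressure_normal^2))
  if (n == 0) tb_stop("tb_invalid_input", "pressure_normal must be non-zero")
  structure(list(pressure = pressure, pressure_normal = pressure_normal / n,
                 fixed = sort(unique(as.integer(fixed)))),
            class = "load_case")
}

#' Consistent nodal forces of a uniform boundary pressure
#'
#' Each `pressure`-labeled boundary triangle of area `A` contributes a force
#' `p A / 3` to each of its vertices, directed along `-pressure_normal`
#' (pushing into the tissue); the total applied force is `p` times the total
#' pressure-face area. Geometry is converted um -> m, so forces are in N.
#'
#' @param mesh a labeled `tet_mesh` (see [label_boundaries()]).
#' @param p pressure, Pa.
#' @param pressure_normal load direction (defaults to the normal stored by
#'   [label_boundaries()]).
#' @return Numeric force vector of length `3N` (N).
#' @export
pressure_load <- function(mesh, p, pressure_normal = mesh$pressure_normal) {
  sel <- mesh$boundary_label == "pressure"
  if (!any(sel))
    tb_stop("tb_unloaded_model", "no boundary faces labeled 'pressure'")
  if (is.null(pressure_normal))
    tb_stop("tb_invalid_input", "pressure_normal not given nor stored in mesh")
  pn <- pressure_normal / sqrt(sum(pressure_normal^2))
  geo <- boundary_geometry(mesh)
  areas_m2 <- geo$areas[sel] * 1e-12  # um^2 -> m^2
  tris <- mesh$boundary_tris[sel, , drop = FALSE]
  f <- numeric(3 * nrow(mesh$nodes))
  dir <- -pn
  idx_all <- integer(0); val_all <- numeric(0)
  for (v in 1:3) {
    for (c in 1:3) {
      idx_all <- c(idx_all, 3 * (tris[, v] - 1) + c)
      val_all <- c(val_all, p * areas_m2 / 3 * dir[c])
    }
  }
  agg <- rowsum(val_all, idx_all)
  f[as.integer(rownames(agg))] <- agg[, 1]
  f
}
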