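#' Solve a linear-elastic FEM load case
#'
#' Solves `K u = f` with the fixed dofs eliminated (row/column removal), so
#' constrained displacements are exactly zero. The reduced symmetric
#' positive-definite system is solved by sparse Cholesky factorization, with
#' a Jacobi-preconditioned conjugate-gradient fallback (tolerance 1e-10)
#' should the factorization fail. Displacements are reported in um;
#' directional deformation is the displacement component along the pressure
#' normal.
#'
#' @param mesh a labeled `tet_mesh` (see [label_boundaries()]).
#' @param material a [material_model()].
#' @param load a [load_case()].
#' @return A `fem_result`: list with `pressure`, `displacement` (N x 3 um),
#'   `directional` (um, signed, per node), `max_directional` (um, absolute),
#'   `argmax_node`, `reactions` (N, at fixed dofs), `residual` (relative),
#'   and `solver` stats.
#' @export
solve_fem <- function(mesh, material, load) {
  K <- assemble_stiffness(mesh, material)
  f <- pressure_load(mesh, load$pressure, load$pressure_normal)
  sol <- solve_reduced(K, f, load$fixed)
  fem_result(mesh, load, sol$u, K, f, sol$stats)
}

solve_reduced <- function(K, f, fixed) {
  ndof <- nrow(K)
  if (any(fixed < 1 | fixed > ndof))
    tb_stop("tb_invalid_input", "fixed dof index out of range")
  free <- setdiff(seq_len(ndof), fixed)
  if (length(free) == 0)
    tb_stop("tb_insufficient_constraint", "no free dofs remain")
  Kff <- K[free, free, drop = FALSE]
  ff <- f[free]
  u <- numeric(ndof)
  stats <- list(method = "cholesky", iterations = 0L)
  uf <- tryCatch(
    as.vector(Matrix::solve(Kff, ff)),
    error = function(e) NULL
  )
  if (is.null(uf)) {
    cg <- cg_solve(Kff, ff, tol = 1e-10)
    uf <- cg$x
    stats <- list(method = "cg", iterations = cg$iterations)
  }
  rnorm_f <- sqrt(sum(ff^2))
  resid <- if (rnorm_f > 0)
    sqrt(sum((as.vector(Kff %*% uf) - ff)^2)) / rnorm_f else 0
  if (!is.finite(resid) || resid > 1e-8) {
    if (stats$method == "cholesky") {
      cg <- cg_solve(Kff, ff, tol = 1e-10)
      uf <- cg$x
      stats <- list(method = "cg", iterations = cg$iterations)
      resid <- if (rnorm_f > 0)
        sqrt(sum((as.vector(Kff %*% uf) - ff)^2)) / rnorm_f else 0
    }
    if (!is.finite(resid) || resid > 1e-8)
      tb_stop("tb_solver_error", sprintf(
        "solver did not reach the 1e-8 residual target (got %g); %s",
        resid, "check that the constraints remove all rigid-body modes"))
  }
  u[free] <- uf
  stats$residual <- resid
  list(u = u, stats = stats)
}

# Jacobi-preconditioned conjugate gradients on the reduced SPD system.
cg_solve <- function(A, b, tol = 1e-10, maxit = NULL) {
  n <- length(b)
  if (is.null(maxit)) maxit <- min(20L * n, 10000L)
  Minv <- 1 / Matrix::diag(A)
  x <- numeric(n)
  r <- b
  z <- Minv * r
  p <- z
  rz <- sum(r * z)
  bnorm <- sqrt(sum(b^2))
  it <- 0L
  while (sqrt(sum(r^2)) > tol * bnorm && it < maxit) {
    Ap <- as.vector(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    z <- Minv * r
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
    it <- it + 1L
  }
  list(x = x, iterations = it)
}

fem_result <- function(mesh, load, u_m, K, f, stats) {
  nn <- nrow(mesh$nodes)
  disp <- matrix(u_m, nn, 3, byrow = TRUE) * 1e6  # m -> um
  colnames(disp) <- c("ux", "uy", "uz")
  directional <- as.vector(disp %*% load$pressure_normal)
  amax <- which.max(abs(directional))
  reactions <- as.vector(K %*% u_m) - f
  reactions[-load$fixed] <- 0
  structure(list(
    pressure = load$pressure,
    pressure_normal = load$pressure_normal,
    displacement = disp,
    directional = directional,
    max_directional = abs(directional[amax]),
    argmax_node = amax,
    fixed = load$fixed,
    reactions = reactions,
    residual = stats$residual,
    solver = stats
  ), class = "fem_result")
}

#' @export
print.fem_result <- function(x, ...) {
  cat(sprintf("fem_result: p = %g Pa, max |directional deformation| = %g um (node %d)\n",
              x$pressure, x$max_directional, x$argmax_node))
  cat(sprintf("  solver %s, relative residual %g\n", x$solver$method,
              x$residual))
  invisible(x)
}

#' Sweep the applied pressure
#'
#' Solves one load case per pressure, reusing the single stiffness
#' factorization (the load scales linearly with pressure, so each solve is a
#' triangular back-substitution). The default sweep covers the physiological
#' IOP-EVP pressure-drop range 10 to 160 Pa in steps of 10 Pa.
#'
#' @param mesh a labeled `tet_mesh`.
#' @param material a [material_model()].
#' @param pressures pressures in Pa, each >= 0.
#' @param fixed constrained dof indices (see [fixed_dofs()]).
#' @return List of `fem_result`, sorted by pressure, class `fem_sweep`.
#' @export
pressure_sweep <- function(mesh, material, pressures = seq(10, 160, by = 10),
                           fixed) {
  if (length(pressures) == 0 || any(pressures < 0))
    tb_stop("tb_invalid_input", "pressures must be non-empty and >= 0")
  pressures <- sort(pressures)
  K <- assemble_stiffness(mesh, material)
  f1 <- pressure_load(mesh, 1, mesh$pressure_normal)
  base <- solve_reduced(K, f1, fixed)
  results <- lapply(pressures, function(p) {
    load <- load_case(p, mesh$pressure_normal, fixed)
    fem_result(mesh, load, base$u * p, K, f1 * p, base$stats)
  })
  structure(results, class = "fem_sweep")
}

#' Summarize directional deformation across a pressure sweep
#'
#' @param results a `fem_sweep` or list of `fem_result`.
#' @return data.frame with columns `pressure_pa`,
#'   `max_directional_deformation_um`, `node_id`.
#' @export
deformation_report <- function(results) {
  if (length(results) == 0)
    tb_stop("tb_invalid_input", "no results to report")
  do.call(rbind, lapply(results, function(r) data.frame(
    pressure_pa = r$pressure,
    max_directional_deformation_um = r$max_directional,
    node_id = r$argmax_node
  )))
}

#' Export a FEM displacement field to legacy VTK
#'
#' Writes the mesh together with point-data arrays `displacement` (um) and
#' `directional_deformation` (um) for visualization.
#'
#' @param mesh the `tet_mesh` that was solved.
#' @param result a `fem_result`.
#' @param path output `.vtk` file.
#' @return `path`, invisibly.
#' @export
write_vtk_result <- function(mesh, result, path) {
  write_vtk_mesh(mesh, path)
  con <- file(path, "a")
  on.exit(close(con))
  nn <- nrow(mesh$nodes)
  writeLines(c(sprintf("POINT_DATA %d", nn),
               "VECTORS displacement double"), con)
  utils::write.table(format(result$displacement, digits = 12, trim = TRUE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(c("SCALARS directional_deformation double 1",
               "LOOKUP_TABLE default"), con)
  writeLines(format(result$directional, digits = 12, trim = TRUE), con)
  invisible(path)
}
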