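#' Convert a segmented voxel volume into a conforming tetrahedral mesh
#'
#' Each tissue voxel is split into 6 tetrahedra by the Kuhn (Freudenthal)
#' subdivision along the cube's main diagonal. Because every cube uses the
#' same diagonal orientation, shared faces of neighboring voxels are split
#' identically, so the mesh is face-conforming by construction, and the total
#' tetrahedral volume equals the voxel volume exactly (up to floating point).
#' Nodes are placed at voxel corners in physical coordinates
#' `x = col * lateral_pitch`, `y = row * lateral_pitch`,
#' `z = slice * axial_step` (um, right-handed). Boundary triangles are the
#' faces belonging to exactly one tetrahedron, all initially labeled `free`.
#'
#' @param volume a `segmented_volume` with a non-empty mask.
#' @return A `tet_mesh`: list with `nodes` (N x 3, um), `tets` (M x 4 node
#'   ids, positively oriented), `boundary_tris` (B x 3 node ids),
#'   `boundary_label` (character), `boundary_opp` (opposite vertex per
#'   boundary face, used for outward orientation).
#' @export
voxel_to_tetmesh <- function(volume) {
  mask <- volume$mask
  if (!any(mask)) tb_stop("tb_empty_segmentation", "empty mask cannot be meshed")
  d <- dim(mask)
  nr <- d[1]; nc <- d[2]; ns <- d[3]
  pl <- volume$pitch[1]; al <- volume$pitch[2]

  vox <- which(mask, arr.ind = TRUE)  # (row, col, slice), 1-based
  i0 <- vox[, 1] - 1L; j0 <- vox[, 2] - 1L; k0 <- vox[, 3] - 1L
  gid <- function(i, j, k) 1 + i + (nr + 1) * (j + (nc + 1) * k)

  pats <- kuhn_patterns(pl, al)
  nvox <- nrow(vox)
  tets <- matrix(0, nvox * 6L, 4L)
  for (p in seq_len(6L)) {
    off <- pats[[p]]  # 4 x 3 corner offsets (di, dj, dk)
    for (v in seq_len(4L)) {
      tets[seq_len(nvox) + (p - 1L) * nvox, v] <-
        gid(i0 + off[v, 1], j0 + off[v, 2], k0 + off[v, 3])
    }
  }

  used <- sort(unique(as.vector(tets)))
  tets <- matrix(match(tets, used), nrow(tets), 4L)
  g <- used - 1
  i <- g %% (nr + 1)
  j <- (g %/% (nr + 1)) %% (nc + 1)
  k <- g %/% ((nr + 1) * (nc + 1))
  nodes <- cbind(x = j * pl, y = i * pl, z = k * al)

  bnd <- boundary_faces(tets, nrow(nodes))
  structure(list(
    nodes = nodes, tets = tets,
    boundary_tris = bnd$tris, boundary_opp = bnd$opp,
    boundary_label = rep("free", nrow(bnd$tris)),
    pitch = volume$pitch
  ), class = "tet_mesh")
}

# The 6 Kuhn tetrahedra of the unit cube, vertex order fixed so that the
# signed volume is positive under the physical mapping (x, y, z) =
# (j * pl, i * pl, k * al).
kuhn_patterns <- function(pl, al) {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  lapply(perms, function(s) {
    v <- matrix(0, 4, 3)
    v[2, ] <- v[1, ]; v[2, s[1]] <- 1
    v[3, ] <- v[2, ]; v[3, s[2]] <- 1
    v[4, ] <- c(1, 1, 1)
    xyz <- cbind(v[, 2] * pl, v[, 1] * pl, v[, 3] * al)
    if (tet_signed_volume(xyz) < 0) v <- v[c(1, 2, 4, 3), ]
    v
  })
}

tet_signed_volume <- function(xyz) {
  a <- xyz[2, ] - xyz[1, ]; b <- xyz[3, ] - xyz[1, ]; c <- xyz[4, ] - xyz[1, ]
  det(rbind(a, b, c)) / 6
}

#' Signed volumes of all tetrahedra of a mesh
#'
#' @param mesh a `tet_mesh`.
#' @return Numeric vector of signed volumes (um^3), positive for a
#'   consistently oriented mesh.
#' @export
tet_volumes <- function(mesh) {
  n <- mesh$nodes
  t <- mesh$tets
  a <- n[t[, 2], , drop = FALSE] - n[t[, 1], , drop = FALSE]
  b <- n[t[, 3], , drop = FALSE] - n[t[, 1], , drop = FALSE]
  cc <- n[t[, 4], , drop = FALSE] - n[t[, 1], , drop = FALSE]
  (a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
   a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
   a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

# Faces belonging to exactly one tet, with the opposite vertex of the owning
# tet (for outward orientation).
boundary_faces <- function(tets, nnodes) {
  m <- nrow(tets)
  faces <- rbind(tets[, c(2, 3, 4)], tets[, c(1, 3, 4)],
                 tets[, c(1, 2, 4)], tets[, c(1, 2, 3)])
  opp <- c(tets[, 1], tets[, 2], tets[, 3], tets[, 4])
  a <- pmin(faces[, 1], faces[, 2], faces[, 3])
  c_ <- pmax(faces[, 1], faces[, 2], faces[, 3])
  b <- faces[, 1] + faces[, 2] + faces[, 3] - a - c_
  key <- a + (nnodes + 1) * (b + (nnodes + 1) * c_)
  ord <- order(key)
  ks <- key[ord]
  first <- c(TRUE, ks[-1] != ks[-length(ks)])
  grp <- cumsum(first)
  cnt <- tabulate(grp)
  sel <- logical(length(key))
  sel[ord] <- cnt[grp] == 1L
  list(tris = faces[sel, , drop = FALSE], opp = opp[sel])
}

# Outward unit normals and areas of the boundary triangles.
boundary_geometry <- function(mesh) {
  n <- mesh$nodes; tr <- mesh$boundary_tris
  p1 <- n[tr[, 1], , drop = FALSE]
  e1 <- n[tr[, 2], , drop = FALSE] - p1
  e2 <- n[tr[, 3], , drop = FALSE] - p1
  nx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  ny <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  nz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  nrm <- cbind(nx, ny, nz)
  # orient away from the opposite vertex of the owning tet
  vopp <- mesh$nodes[mesh$boundary_opp, , drop = FALSE] - p1
  flip <- rowSums(nrm * vopp) > 0
  nrm[flip, ] <- -nrm[flip, ]
  len <- sqrt(rowSums(nrm^2))
  list(normals = nrm / len, areas = len / 2)
}

#' Label boundary faces for FEM loading and constraint
#'
#' Boundary triangles whose outward normal lies within `angle_tol` degrees of
#' `pressure_normal` are labeled `pressure`; triangles all of whose vertices
#' satisfy `fixed_region` are labeled `fixed` (a triangle matching both is
#' `fixed` - the constraint wins); all others stay `free`.
#'
#' @param mesh a `tet_mesh`.
#' @param pressure_normal length-3 direction of the applied pressure (will be
#'   normalized); for the TM model, perpendicular to the plane parallel to the
#'   SC inner wall.
#' @param angle_tol half-angle of the acceptance cone, degrees; default 30 to
#'   capture the non-planar TM inner surface.
#' @param fixed_region predicate `function(nodes) -> logical` over node
#'   coordinates (N x 3 um matrix) marking the constrained (scleral) region.
#' @return The mesh with `boundary_label` filled in.
#' @export
label_boundaries <- function(mesh, pressure_normal, angle_tol = 30,
                             fixed_region) {
  if (length(pressure_normal) != 3 || sum(pressure_normal^2) == 0)
    tb_stop("tb_invalid_input", "pressure_normal must be a non-zero 3-vector")
  if (nrow(mesh$boundary_tris) == 0)
    tb_stop("tb_boundary_labeling", "mesh has no boundary")
  pn <- pressure_normal / sqrt(sum(pressure_normal^2))
  geo <- boundary_geometry(mesh)
  cosang <- geo$normals %*% pn
  lab <- rep("free", nrow(mesh$boundary_tris))
  lab[cosang >= cos(angle_tol * pi / 180) - 1e-12] <- "pressure"
  fixed_nodes <- fixed_region(mesh$nodes)
  tr <- mesh$boundary_tris
  all_fixed <- fixed_nodes[tr[, 1]] & fixed_nodes[tr[, 2]] & fixed_nodes[tr[, 3]]
  lab[all_fixed] <- "fixed"
  if (!any(lab == "pressure"))
    tb_stop("tb_boundary_labeling", "no pressure faces found: model unloaded")
  if (!any(lab == "fixed"))
    tb_stop("tb_boundary_labeling", "no fixed faces found: model unconstrained")
  mesh$boundary_label <- lab
  mesh$pressure_normal <- pn
  mesh
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("tet_mesh: %d nodes, %d tets, %d boundary triangles\n",
              nrow(x$nodes), nrow(x$tets), nrow(x$boundary_tris)))
  cat(sprintf("  total volume %.6g um^3; labels: %s\n", sum(tet_volumes(x)),
              paste(sprintf("%s=%d", names(table(x$boundary_label)),
                            table(x$boundary_label)), collapse = ", ")))
  invisible(x)
}

label_codes <- c(free = 0L, pressure = 1L, fixed = 2L)

#' Write and read tetrahedral meshes
#'
#' `write_vtk_mesh()`/`read_vtk_mesh()` use the legacy ASCII VTK unstructured
#' grid format, storing tetrahedra plus boundary triangles with a
#' `boundary_label` cell-data array (-1 for tets; 0 free, 1 pressure,
#' 2 fixed). `write_msh_mesh()` writes Gmsh MSH v2.2 ASCII with the label code
#' as the physical tag of each boundary triangle.
#'
#' @param mesh a `tet_mesh`.
#' @param path output file.
#' @return Writers return `path` invisibly; `read_vtk_mesh()` returns a
#'   `tet_mesh` (with `boundary_opp` recomputed from the tets).
#' @export
write_vtk_mesh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nn <- nrow(mesh$nodes); nt <- nrow(mesh$tets); nb <- nrow(mesh$boundary_tris)
  writeLines(c("# vtk DataFile Version 3.0",
               "tetrahedral mesh with boundary labels", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nn)), con)
  utils::write.table(format(mesh$nodes, digits = 17, scientific = FALSE,
                            trim = TRUE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELLS %d %d", nt + nb, 5 * nt + 4 * nb), con)
  utils::write.table(cbind(4L, mesh$tets - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3L, mesh$boundary_tris - 1L), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELL_TYPES %d", nt + nb), con)
  writeLines(as.character(c(rep(10L, nt), rep(5L, nb))), con)
  writeLines(c(sprintf("CELL_DATA %d", nt + nb),
               "SCALARS boundary_label int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(c(rep(-1L, nt),
                            label_codes[mesh$boundary_label])), con)
  invisible(path)
}

#' @rdname write_vtk_mesh
#' @export
read_vtk_mesh <- function(path) {
  ln <- readLines(path)
  ip <- grep("^POINTS", ln)[1]
  nn <- as.integer(strsplit(ln[ip], " +")[[1]][2])
  nodes <- matrix(scan(text = ln[(ip + 1):(ip + nn)], quiet = TRUE),
                  nn, 3, byrow = TRUE)
  colnames(nodes) <- c("x", "y", "z")
  ic <- grep("^CELLS", ln)[1]
  ncell <- as.integer(strsplit(ln[ic], " +")[[1]][2])
  cells <- lapply((ic + 1):(ic + ncell), function(i)
    scan(text = ln[i], quiet = TRUE))
  sizes <- vapply(cells, function(x) x[1], numeric(1))
  tets <- do.call(rbind, lapply(cells[sizes == 4], function(x) x[-1] + 1))
  tris <- do.call(rbind, lapply(cells[sizes == 3], function(x) x[-1] + 1))
  id <- grep("^SCALARS boundary_label", ln)[1]
  vals <- scan(text = ln[(id + 2):(id + 1 + ncell)], quiet = TRUE)
  codes <- vals[sizes == 3]
  bnd <- boundary_faces(tets, nn)  # recover opposite vertices
  # match stored triangle order to recomputed boundary faces
  keyof <- function(m) apply(t(apply(m, 1, sort)), 1, paste, collapse = "_")
  opp <- bnd$opp[match(keyof(tris), keyof(bnd$tris))]
  structure(list(nodes = nodes, tets = tets, boundary_tris = tris,
                 boundary_opp = opp,
                 boundary_label = names(label_codes)[match(codes, label_codes)],
                 pitch = NULL), class = "tet_mesh")
}

#' @rdname write_vtk_mesh
#' @export
write_msh_mesh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nn <- nrow(mesh$nodes); nt <- nrow(mesh$tets); nb <- nrow(mesh$boundary_tris)
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat",
               "$Nodes", as.character(nn)), con)
  utils::write.table(cbind(seq_len(nn),
                           format(mesh$nodes, digits = 17, trim = TRUE)),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(c("$EndNodes", "$Elements", as.character(nt + nb)), con)
  codes <- label_codes[mesh$boundary_label]
  utils::write.table(cbind(seq_len(nb), 2L, 2L, codes, codes,
                           mesh$boundary_tris),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(nb + seq_len(nt), 4L, 2L, 0L, 0L, mesh$tets),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines("$EndElements", con)
  invisible(path)
}
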