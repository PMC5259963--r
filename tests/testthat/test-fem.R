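test_that("the Hooke matrix matches its closed form and is SPD", {
  # E = 1, nu = 0: lambda = 0, mu = 1/2
  D0 <- elasticity_matrix(material_model(1, 0))
  expect_equal(D0, diag(c(1, 1, 1, 0.5, 0.5, 0.5)))
  # reference TM material: plug in the Lame parameters directly
  E <- 162; nu <- 0.48
  lambda <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- elasticity_matrix(material_model(E, nu))
  expect_equal(D[1, 1], 2 * mu + lambda)
  expect_equal(D[1, 2], lambda)
  expect_equal(D[4, 4], mu)
  expect_equal(lambda, 162 * 0.48 / (1.48 * 0.04))
  expect_equal(mu, 162 / 2.96)
  for (m in list(material_model(1e3, 0.3), material_model(0.5, -0.5),
                 material_model(162, 0.48))) {
    Dm <- elasticity_matrix(m)
    expect_equal(Dm, t(Dm))
    expect_true(all(eigen(Dm, symmetric = TRUE, only.values = TRUE)$values > 0))
  }
  expect_error(material_model(162, 0.5), class = "tb_incompressible")
})

test_that("element stiffness has rigid-body null space and matches quadrature", {
  coords <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  D <- elasticity_matrix(material_model(1, 0))
  Ke <- element_stiffness(coords, D)
  expect_equal(Ke, t(Ke))
  # rigid translations map to zero force
  for (t in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(2, -1, 3))) {
    u <- rep(t, 4)
    expect_lt(max(abs(Ke %*% u)), 1e-12)
  }
  expect_equal(sum(abs(eigen(Ke, symmetric = TRUE,
                             only.values = TRUE)$values) < 1e-10), 6)
  # independent numerical-quadrature construction
  Kq <- quadrature_element_stiffness(coords, D)
  expect_equal(Ke, Kq, tolerance = 1e-6, ignore_attr = TRUE)
  set.seed(4)
  coords2 <- coords + matrix(runif(12, -0.1, 0.1), 4, 3)
  D2 <- elasticity_matrix(material_model(162, 0.48))
  expect_equal(element_stiffness(coords2, D2),
               quadrature_element_stiffness(coords2, D2),
               tolerance = 1e-5, ignore_attr = TRUE)
  # K scales linearly with uniform coordinate scaling (V ~ s^3, B ~ 1/s)
  expect_equal(element_stiffness(coords2 * 3, D2),
               3 * element_stiffness(coords2, D2))
  expect_error(element_stiffness(rbind(coords[1:3, ], coords[1, ]), D),
               class = "tb_degenerate_element")
})

test_that("assembly is symmetric with a six-dimensional rigid-body null space", {
  mesh <- voxel_to_tetmesh(box_volume(2, 3, 2, pitch = c(2, 4)))
  mat <- material_model(162, 0.48)
  K <- assemble_stiffness(mesh, mat)
  expect_equal(Matrix::norm(K - Matrix::t(K), "M"), 0)
  nodes_m <- mesh$nodes * 1e-6
  kscale <- max(abs(K))
  # 3 translations + 3 linearized rotations
  modes <- list(
    function(p) c(1, 0, 0), function(p) c(0, 1, 0), function(p) c(0, 0, 1),
    function(p) c(-p[2], p[1], 0), function(p) c(0, -p[3], p[2]),
    function(p) c(p[3], 0, -p[1]))
  U <- sapply(modes, function(f) as.vector(apply(nodes_m, 1, f)))
  for (j in 1:6)
    expect_lt(max(abs(K %*% U[, j])) / (kscale * max(abs(U[, j]))), 1e-8)
  # single-tet mesh: global equals element matrix
  one <- list(nodes = rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(0, 0, 2)),
              tets = matrix(1:4, 1), boundary_tris = matrix(0, 0, 3),
              boundary_opp = integer(0), boundary_label = character(0))
  class(one) <- "tet_mesh"
  K1 <- as.matrix(assemble_stiffness(one, mat))
  Ke <- element_stiffness(one$nodes * 1e-6, elasticity_matrix(mat))
  perm <- as.vector(t(outer(1:4, 1:3, function(n, c) 3 * (n - 1) + c)))
  expect_equal(K1, unname(Ke[order(perm), order(perm)]), tolerance = 1e-12)
})

test_that("consistent pressure loads sum to p times the loaded area", {
  mesh <- voxel_to_tetmesh(box_volume(3, 3, 2, pitch = c(2, 2)))
  mesh <- label_boundaries(mesh, c(0, 0, 1), 10,
                           function(n) n[, 3] < 1e-9)
  p <- 60
  f <- pressure_load(mesh, p)
  fz <- f[seq(3, length(f), by = 3)]
  area_m2 <- (6 * 6) * 1e-12
  expect_equal(sum(fz), -p * area_m2)              # pushes along -z
  expect_equal(sum(f[seq(1, length(f), by = 3)]), 0)
  expect_equal(sum(f[seq(2, length(f), by = 3)]), 0)
  expect_true(all(pressure_load(mesh, 0) == 0))
  # every vertex of one pressure triangle receives p * A / 3
  geo <- boundary_geometry(mesh)
  i <- which(mesh$boundary_label == "pressure")[1]
  tri <- mesh$boundary_tris[i, ]
  single <- mesh
  single$boundary_label[] <- "free"
  single$boundary_label[i] <- "pressure"
  f1 <- pressure_load(single, p)
  expect_equal(f1[3 * (tri - 1) + 3],
               rep(-p * geo$areas[i] * 1e-12 / 3, 3))
})

test_that("uniaxial compression of a bar reproduces p L / E exactly", {
  # rollers on three orthogonal planes leave a uniform uniaxial stress state
  vol <- box_volume(4, 4, 10, pitch = c(2, 10))   # 8 x 8 x 100 um bar
  mesh <- voxel_to_tetmesh(vol)
  mesh <- label_boundaries(mesh, c(0, 0, 1), 10,
                           function(n) n[, 3] < 1e-9)
  L <- max(mesh$nodes[, 3])
  fx <- c(fixed_dofs(which(mesh$nodes[, 3] < 1e-9), 3),
          fixed_dofs(which(mesh$nodes[, 1] < 1e-9), 1),
          fixed_dofs(which(mesh$nodes[, 2] < 1e-9), 2))
  for (nu in c(0, 0.3, 0.48)) {
    mat <- material_model(162, nu)
    res <- solve_fem(mesh, mat, load_case(16.2, c(0, 0, 1), fx))
    expect_equal(res$max_directional, 16.2 * L / 162, tolerance = 1e-6)
    tipz <- which(mesh$nodes[, 3] > L - 1e-9)
    expect_equal(res$directional[tipz], rep(-10, length(tipz)),
                 tolerance = 1e-6)
    expect_lt(res$residual, 1e-8)
    # fixed dofs are exactly zero
    u <- as.vector(t(res$displacement))
    expect_true(all(u[fx] == 0))
  }
})

test_that("reactions balance applied loads and solutions scale linearly", {
  mesh <- voxel_to_tetmesh(box_volume(3, 3, 4, pitch = c(2, 5)))
  mesh <- label_boundaries(mesh, c(0, 0, 1), 10,
                           function(n) n[, 3] < 1e-9)
  fx <- fixed_dofs(which(mesh$nodes[, 3] < 1e-9))
  mat <- material_model(162, 0.48)
  res <- solve_fem(mesh, mat, load_case(40, c(0, 0, 1), fx))
  f <- pressure_load(mesh, 40)
  expect_lt(abs(sum(res$reactions) + sum(f)) / sum(abs(f)), 1e-8)
  # zero pressure: zero displacement
  res0 <- solve_fem(mesh, mat, load_case(0, c(0, 0, 1), fx))
  expect_true(all(res0$displacement == 0))
  # doubling pressure doubles displacement; doubling E halves it
  res2 <- solve_fem(mesh, mat, load_case(80, c(0, 0, 1), fx))
  expect_equal(res2$displacement, 2 * res$displacement, tolerance = 1e-8)
  resE <- solve_fem(mesh, material_model(324, 0.48),
                    load_case(40, c(0, 0, 1), fx))
  expect_equal(resE$displacement, res$displacement / 2, tolerance = 1e-8)
})

test_that("the solution is invariant under node reordering", {
  mesh <- voxel_to_tetmesh(box_volume(2, 2, 3, pitch = c(2, 4)))
  mesh <- label_boundaries(mesh, c(0, 0, 1), 10, function(n) n[, 3] < 1e-9)
  fx <- fixed_dofs(which(mesh$nodes[, 3] < 1e-9))
  mat <- material_model(162, 0.48)
  res <- solve_fem(mesh, mat, load_case(30, c(0, 0, 1), fx))

  set.seed(2)
  perm <- sample(nrow(mesh$nodes))          # new id of old node i is perm[i]
  inv <- Matrix::invPerm(perm)
  mesh2 <- mesh
  mesh2$nodes <- mesh$nodes[inv, , drop = FALSE]
  mesh2$tets <- matrix(perm[mesh$tets], ncol = 4)
  mesh2$boundary_tris <- matrix(perm[mesh$boundary_tris], ncol = 3)
  mesh2$boundary_opp <- perm[mesh$boundary_opp]
  fx2 <- fixed_dofs(which(mesh2$nodes[, 3] < 1e-9))
  res2 <- solve_fem(mesh2, mat, load_case(30, c(0, 0, 1), fx2))
  expect_equal(res2$displacement[perm, ], res$displacement, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("the pressure sweep is linear through the origin with 16 default points", {
  mesh <- voxel_to_tetmesh(box_volume(3, 3, 4, pitch = c(2, 5)))
  mesh <- label_boundaries(mesh, c(0, 0, 1), 10, function(n) n[, 3] < 1e-9)
  fx <- fixed_dofs(which(mesh$nodes[, 3] < 1e-9))
  sweep <- pressure_sweep(mesh, material_model(162, 0.48), fixed = fx)
  expect_length(sweep, 16)
  rep_ <- deformation_report(sweep)
  expect_equal(rep_$pressure_pa, seq(10, 160, by = 10))
  expect_true(all(diff(rep_$max_directional_deformation_um) > 0))
  expect_equal(rep_$max_directional_deformation_um[16],
               16 * rep_$max_directional_deformation_um[1],
               tolerance = 1e-8)
  # deformation / pressure is constant across the sweep
  ratio <- rep_$max_directional_deformation_um / rep_$pressure_pa
  expect_equal(max(ratio) / min(ratio), 1, tolerance = 1e-8)
  expect_error(pressure_sweep(mesh, material_model(), numeric(0), fx),
               class = "tb_invalid_input")
})

test_that("an unconstrained or unloaded model raises a classed error", {
  mesh <- voxel_to_tetmesh(box_volume(2, 2, 2, pitch = c(2, 2)))
  expect_error(pressure_load(mesh, 10, c(0, 0, 1)),
               class = "tb_unloaded_model")
  mesh <- label_boundaries(mesh, c(0, 0, 1), 10, function(n) n[, 3] < 1e-9)
  expect_error(load_case(10, c(0, 0, 1), integer(0)),
               class = "tb_insufficient_constraint")
  # constraining a single node leaves rotational rigid modes: solver reports it
  expect_error(solve_fem(mesh, material_model(),
                         load_case(10, c(0, 0, 1), fixed_dofs(1L))),
               class = "trabecula_error")
})

test_that("TM deformation localizes on slender beams away from the constraint", {
  cfg <- small_scene_config(seed = 19L, psf_sigma = c(0, 0),
                            attenuation_length = Inf)
  lab <- build_labels(cfg)
  stk <- render_intensities(lab, cfg, noise = FALSE)
  vol <- threshold_segment(stk, cfg$noise$photon_scale / 2)
  # keep a small TM window so the FEM stays light
  sub <- mask_volume(vol$mask[33:64, 49:80, 2:6, drop = FALSE],
                     pitch = c(cfg$lateral_pitch, cfg$axial_step))
  # grow face-connected tissue from the scleral-side face (vertex-only
  # contacts would articulate as mechanisms), keep the largest candidate,
  # then consolidate with a closing - the morphological "edit" stage
  cand <- which(sub$mask, arr.ind = TRUE)
  cand <- cand[cand[, 2] == max(cand[, 2]), , drop = FALSE]
  grown <- NULL
  for (i in seq_len(min(10, nrow(cand)))) {
    g <- region_grow(sub, cand[i, ], connectivity = 6)
    if (is.null(grown) || sum(g$mask) > sum(grown$mask)) grown <- g
  }
  sub <- morphological_edit(grown, list(list(op = "close", radius_um = 4),
                                        list(op = "fill_holes")))
  seed0 <- which(grown$mask, arr.ind = TRUE)[1, ]
  sub <- region_grow(sub, seed0, connectivity = 6)
  mesh <- voxel_to_tetmesh(sub)
  xmax <- max(mesh$nodes[, 1])
  mesh <- label_boundaries(mesh, c(1, 0, 0), angle_tol = 30,
                           fixed_region = function(n) n[, 1] > xmax - 1e-9)
  fx <- fixed_dofs(which(mesh$nodes[, 1] > xmax - 1e-9))
  sweep <- pressure_sweep(mesh, material_model(162, 0.48),
                          pressures = c(20, 60, 120), fixed = fx)
  rep_ <- deformation_report(sweep)
  expect_equal(nrow(rep_), 3)
  expect_true(all(rep_$max_directional_deformation_um > 0))
  expect_true(all(diff(rep_$max_directional_deformation_um) > 0))
  # the most-deformed node is on the free TM surface, not the fixed sclera side
  argmax <- rep_$node_id[2]
  expect_lt(mesh$nodes[argmax, 1], xmax - 1e-9)
  expect_true(argmax %in% as.vector(mesh$boundary_tris))
})
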