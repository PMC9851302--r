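# Conservative rasterization and solid voxelization.

test_that("triangle/box overlap is conservative (touching counts)", {
  box <- aabb3(c(0, 0, 0), c(1, 1, 1))
  inside <- rbind(c(0.2, 0.2, 0.5), c(0.8, 0.2, 0.5), c(0.5, 0.8, 0.5))
  expect_true(triangle_box_overlap(inside, box))

  touching <- rbind(c(1, 0.5, 0.5), c(2, 0, 0.5), c(2, 1, 0.5))
  expect_true(triangle_box_overlap(touching, box))

  distant <- rbind(c(2.5, 0, 0), c(3.5, 0, 0), c(2.5, 1, 0))
  expect_false(triangle_box_overlap(distant, box))
})

test_that("surface voxelization equals the exhaustive oracle", {
  # axis-aligned unit square at z = 0 inside a padded grid
  sq <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
                     triangulate_ngons(list(c(1, 2, 3, 4))))
  opts <- voxelization_options(4, 2, solid_mode = "none")
  got <- surface_voxelize(sq, opts)
  want <- surface_voxelize_oracle(sq, got$spec)
  expect_identical(got$bits, want$bits)

  for (seed in 1:10) {
    m <- random_small_mesh(seed)
    spec <- grid_from_aabb(mesh_aabb(m), 3, 1)
    expect_lte(max(spec$dims), 32)
    g1 <- surface_voxelize(m, spec)
    g2 <- surface_voxelize_oracle(m, spec)
    expect_identical(g1$bits, g2$bits, info = paste("seed", seed))
  }
})

test_that("rasterization has set-union semantics", {
  m <- random_small_mesh(3)
  spec <- grid_from_aabb(mesh_aabb(m), 4, 1)
  base <- surface_voxelize(m, spec)
  doubled <- surface_mesh(m$vertices, rbind(m$triangles, m$triangles))
  expect_identical(surface_voxelize(doubled, spec)$bits, base$bits)

  t1 <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), rbind(c(1, 2, 3)))
  t2 <- surface_mesh(rbind(c(5, 5, 5), c(6, 5, 5), c(5, 6, 5)), rbind(c(1, 2, 3)))
  spec2 <- grid_from_aabb(aabb3(c(-1, -1, -1), c(7, 7, 7)), 2, 1)
  both <- surface_voxelize(merge_meshes(list(t1, t2)), spec2)
  expect_equal(count_set(both),
               count_set(surface_voxelize(t1, spec2)) +
               count_set(surface_voxelize(t2, spec2)))
  expect_error(surface_voxelize(surface_mesh(matrix(numeric(0), 0, 3),
                                             matrix(integer(0), 0, 3))),
               "empty")
})

test_that("slice flood fill closes enclosed regions only", {
  ring <- matrix(FALSE, 9, 9)
  ring[3:7, 3] <- TRUE; ring[3:7, 7] <- TRUE
  ring[3, 3:7] <- TRUE; ring[7, 3:7] <- TRUE
  filled <- flood_fill_slice(ring)
  expect_true(all(filled[3:7, 3:7]))
  expect_false(any(filled[1:2, ]))

  blank <- matrix(FALSE, 6, 6)
  expect_identical(flood_fill_slice(blank), blank)

  # nested rings: outer ring, gap, inner ring -> everything inside the
  # outer ring is enclosed, including the gap between the rings
  nest <- matrix(FALSE, 9, 9)
  nest[2:8, 2] <- TRUE; nest[2:8, 8] <- TRUE
  nest[2, 2:8] <- TRUE; nest[8, 2:8] <- TRUE
  nest[4:6, 4] <- TRUE; nest[4:6, 6] <- TRUE
  nest[4, 4:6] <- TRUE; nest[6, 4:6] <- TRUE
  fn <- flood_fill_slice(nest)
  expect_true(all(fn[2:8, 2:8]))
  expect_equal(sum(fn), 49)
})

test_that("solid voxelization brackets the ball volume from above", {
  ico <- make_icosphere(1, 3)
  ball_shell <- surface_voxelize(ico, voxelization_options(16, 2, solid_mode = "none"))
  solid <- solid_voxelize(ball_shell)
  R <- 16
  # conservative rasterization makes the solid a superset of the ball,
  # bounded by the ball dilated by the voxel half-diagonal
  expect_gte(count_set(solid) / R^3, enclosed_volume(ico))
  expect_lte(count_set(solid) / R^3, 4 / 3 * pi * (1 + sqrt(3) / 2 / R)^3)
  # idempotence and monotonicity
  expect_identical(solid_voxelize(solid)$bits, solid$bits)
  expect_true(all(solid$bits[ball_shell$bits]))
})

test_that("single-axis fills agree across axes on convex shapes", {
  shell <- surface_voxelize(make_icosphere(1, 2),
                            voxelization_options(8, 2, solid_mode = "none"))
  sx <- solid_voxelize(shell, "x")
  sy <- solid_voxelize(shell, "y")
  sz <- solid_voxelize(shell, "z")
  expect_identical(sx$bits, sy$bits)
  expect_identical(sy$bits, sz$bits)
  expect_identical(solid_voxelize_three_way(shell)$bits, sz$bits)
})

test_that("z-axis fill wrongly floods a torus hole; three-way fixes it", {
  # torus with symmetry axis z: every z-slice of the hole is an annulus
  # interior, so the single-axis fill closes the hole (documented failure)
  tor <- make_torus(2, 0.6, 32)
  shell <- surface_voxelize(tor, voxelization_options(5, 2, solid_mode = "none"))
  sz <- solid_voxelize(shell, "z")
  oracle <- flood3d_oracle(shell)
  expect_gt(count_set(sz), count_set(oracle))        # hole filled in error
  s3 <- solid_voxelize_three_way(shell)
  expect_identical(s3$bits, oracle$bits)             # three-way matches 3D flood
  g <- genus_of(marching_cubes(s3))
  expect_equal(g, 1)
})

test_that("three-way voxelization repairs punctured shells into closed solids", {
  punct <- punctured_icosphere(2, 3, cap_deg = 10)
  expect_gt(watertightness_report(punct, FALSE)$n_boundary_edges, 0)
  shell <- surface_voxelize(punct, voxelization_options(5, 2, solid_mode = "none"))
  s3 <- solid_voxelize_three_way(shell)
  mc <- marching_cubes(s3)
  expect_equal(watertightness_report(mc, FALSE)$n_boundary_edges, 0)
  expect_gt(count_set(s3), 2 * count_set(shell))     # interior actually filled

  # ball shell: three-way equals the 3D flood oracle too
  bsh <- surface_voxelize(make_icosphere(1, 2),
                          voxelization_options(8, 2, solid_mode = "none"))
  expect_identical(solid_voxelize_three_way(bsh)$bits, flood3d_oracle(bsh)$bits)
})

test_that("solid voxel counts converge to the ball volume as resolution doubles", {
  errs <- vapply(c(8, 16, 32), function(res) {
    shell <- surface_voxelize(make_icosphere(1, 3),
                              voxelization_options(res, 2, solid_mode = "none"))
    abs(count_set(solid_voxelize(shell)) / res^3 / (4 / 3 * pi) - 1)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})
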