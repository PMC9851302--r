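# Triangle meshes: triangulation, connectivity, defect detectors,
# partitions and geometric measures.

test_that("fan triangulation splits n-gons and passes triangles through", {
  expect_equal(triangulate_ngons(list(c(1, 2, 3, 4))),
               matrix(c(1L, 2L, 3L, 1L, 3L, 4L), 2, 3, byrow = TRUE))
  expect_equal(triangulate_ngons(list(c(5, 6, 7))),
               matrix(c(5L, 6L, 7L), 1, 3))
  expect_equal(nrow(triangulate_ngons(list(1:6))), 4L)
  expect_error(triangulate_ngons(list(c(1, 2))), "3 vertices")
})

test_that("edge incidence tables satisfy the 3F invariant", {
  tri <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                      rbind(c(1, 2, 3)))
  topo <- build_topology(tri)
  expect_length(topo$edges$count, 3)
  expect_true(all(topo$edges$count == 1L))

  tet <- extract_tet_boundary(rbind(c(1, 2, 3, 4)),
                              rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
  ttopo <- build_topology(tet)
  expect_length(ttopo$edges$count, 6)
  expect_true(all(ttopo$edges$count == 2L))

  two <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)),
                      rbind(c(1, 2, 3), c(2, 4, 3)))
  et <- build_topology(two)$edges
  expect_equal(sum(et$count), 3L * 2L)
  expect_equal(sum(et$count == 2L), 1L)
})

test_that("boundary, non-manifold and floating defects are detected exactly", {
  ico <- make_icosphere(1, 0)
  holed <- surface_mesh(ico$vertices, ico$triangles[-1, , drop = FALSE])
  topo <- build_topology(holed)
  expect_length(boundary_edges(topo), 3)

  fan3 <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                             c(0, -1, 0), c(0, 0, 1)),
                       rbind(c(1, 2, 3), c(1, 2, 4), c(1, 2, 5)))
  expect_length(non_manifold_edges(build_topology(fan3)), 1)

  # two tetrahedra glued at one shared vertex -> one non-manifold vertex
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
             c(-1, 0, 0), c(0, -1, 0), c(0, 0, -1))
  t1 <- extract_tet_boundary(rbind(c(1, 2, 3, 4)), v)$triangles
  glued <- surface_mesh(v, rbind(
    extract_tet_boundary(rbind(c(1, 2, 3, 4)), v)$triangles,
    matrix(c(1, 5, 6, 1, 6, 7, 1, 7, 5, 5, 7, 6), 4, 3, byrow = TRUE)))
  nmv <- non_manifold_vertices(glued, build_topology(glued))
  expect_equal(nmv, 1L)

  iso <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(9, 9, 9)),
                      rbind(c(1, 2, 3)))
  expect_equal(floating_vertices(iso, build_topology(iso)), 4L)
})

test_that("self-intersection search matches the brute-force oracle", {
  a <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                          c(10, 10, 10), c(11, 10, 10), c(10, 11, 10)),
                    rbind(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(nrow(self_intersections(a)), 0L)

  expect_equal(nrow(self_intersections(make_icosphere(1, 2))), 0L)

  s1 <- make_icosphere(1, 1)
  s2 <- make_icosphere(1, 1, center = c(1, 0.1, 0.05))
  soup <- merge_meshes(list(s1, s2))
  got <- self_intersections(soup)
  want <- self_intersections_oracle(soup)
  expect_gt(nrow(got), 0)
  expect_equal(got[order(got[, 1], got[, 2]), , drop = FALSE],
               want[order(want[, 1], want[, 2]), , drop = FALSE],
               ignore_attr = TRUE)
})

test_that("self-intersection search equals the oracle on random soups", {
  for (seed in 1:12) {
    m <- random_small_mesh(seed)
    got <- self_intersections(m)
    want <- self_intersections_oracle(m)
    expect_equal(nrow(got), nrow(want), info = paste("seed", seed))
    if (nrow(got)) {
      expect_equal(got[order(got[, 1], got[, 2]), , drop = FALSE],
                   want[order(want[, 1], want[, 2]), , drop = FALSE],
                   ignore_attr = TRUE, info = paste("seed", seed))
    }
  }
})

test_that("partition splitting conserves triangles and computes genus", {
  two <- merge_meshes(list(make_icosphere(1, 1),
                           make_icosphere(0.5, 1, center = c(5, 0, 0))))
  parts <- split_partitions(two)
  expect_length(parts, 2)
  expect_equal(sum(vapply(parts, function(p) nrow(p$triangles), integer(1))),
               nrow(two$triangles))
  expect_true(all(vapply(parts, euler_char, numeric(1)) == 2))

  expect_length(split_partitions(make_torus(2, 0.8, 24)), 1)
  expect_equal(euler_char(make_torus(2, 0.8, 24)), 0)

  k <- 5
  soup <- surface_mesh(matrix(runif(9 * k), ncol = 3),
                       matrix(seq_len(3 * k), ncol = 3, byrow = TRUE))
  expect_length(split_partitions(soup), k)
})

test_that("area and enclosed volume are exact on the cube and tight on spheres", {
  box <- make_box(1)
  expect_equal(surface_area(box), 6)
  expect_equal(enclosed_volume(box), 1)

  ico <- make_icosphere(1, 3)
  v <- enclosed_volume(ico)
  expect_lt(v, 4 * pi / 3)
  expect_gt(v, 0.98 * 4 * pi / 3)

  moved <- box
  moved$vertices <- sweep(moved$vertices, 2, c(17, -3, 2), "+")
  expect_equal(enclosed_volume(moved), 1)
  expect_equal(surface_area(moved), 6)

  ico0 <- make_icosphere(1, 0)
  holed <- surface_mesh(ico0$vertices, ico0$triangles[-1, , drop = FALSE])
  expect_error(enclosed_volume(holed), "boundary edges")
})

test_that("icosphere volume converges monotonically to the ball volume", {
  vols <- vapply(0:3, function(s) enclosed_volume(make_icosphere(1, s)), numeric(1))
  expect_true(all(diff(vols) > 0))
  expect_true(all(vols < 4 * pi / 3))
})

test_that("watertightness verdict follows the four-zero definition", {
  r <- watertightness_report(make_icosphere(1, 0))
  expect_true(r$is_watertight)
  expect_equal(r$n_partitions, 1L)

  ico <- make_icosphere(1, 0)
  holed <- surface_mesh(ico$vertices, ico$triangles[-1, , drop = FALSE])
  rh <- watertightness_report(holed)
  expect_false(rh$is_watertight)
  expect_equal(rh$n_boundary_edges, 3L)

  soup <- merge_meshes(list(make_icosphere(1, 1),
                            make_icosphere(1, 1, center = c(0.8, 0, 0))))
  rs <- watertightness_report(soup)
  expect_false(rs$is_watertight)
  expect_gt(rs$n_self_intersections, 0)
})

test_that("hausdorff distance behaves on identity, translation and concentric spheres", {
  ico <- make_icosphere(1, 2)
  expect_equal(hausdorff_distance(ico, ico, 500), 0)

  far <- ico
  far$vertices <- sweep(far$vertices, 2, c(50, 0, 0), "+")
  expect_equal(hausdorff_distance(ico, far, 500), 50, tolerance = 0.01)

  big <- make_icosphere(2, 3)
  small <- make_icosphere(1, 3)
  expect_equal(hausdorff_distance(small, big, 2000), 1, tolerance = 0.02)

  empty <- surface_mesh(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 3))
  expect_error(hausdorff_distance(empty, ico), "non-empty")
})

test_that("tet boundary extraction keeps single-owner faces, oriented outward", {
  v1 <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  one <- extract_tet_boundary(rbind(c(1, 2, 3, 4)), v1)
  expect_equal(nrow(one$triangles), 4)
  expect_equal(enclosed_volume(one), 1 / 6)

  v2 <- rbind(v1, c(1, 1, 1))
  two <- extract_tet_boundary(rbind(c(1, 2, 3, 4), c(2, 3, 4, 5)), v2)
  expect_equal(nrow(two$triangles), 6)

  # 5-tet decomposition of the unit cube -> closed 12-face cube boundary
  vc <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  tets <- rbind(c(1, 2, 3, 5), c(2, 3, 4, 8), c(2, 5, 6, 8),
                c(3, 5, 7, 8), c(2, 3, 5, 8))
  cube <- extract_tet_boundary(tets, vc)
  expect_equal(nrow(cube$triangles), 12)
  expect_true(watertightness_report(cube)$is_watertight)
  expect_equal(enclosed_volume(cube), 1)
})
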