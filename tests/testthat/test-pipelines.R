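# End-to-end pipelines. Heavier integration runs live in the acceptance
# suite; here each application is exercised once at modest sizes.

test_that("mesh2mesh turns a damaged two-sphere soup into one watertight union", {
  s1 <- make_icosphere(2, 2)
  s2 <- make_icosphere(2, 2, center = c(1, 0, 0))
  soup <- break_mesh(merge_meshes(list(s1, s2)), seed = 5,
                     del_frac = 0.05, dup_frac = 0.05)
  res <- mesh2mesh(soup, pipeline_options())
  expect_true(res$stats$watertight)
  expect_equal(res$report$n_partitions, 1L)
  # boolean-union volume oracle by dense point sampling of the two intact
  # input spheres
  g <- as.matrix(expand.grid(x = seq(-2.1, 3.1, by = 0.1),
                             y = seq(-2.1, 2.1, by = 0.1),
                             z = seq(-2.1, 2.1, by = 0.1)))
  in_union <- points_in_mesh(s1, g) | points_in_mesh(s2, g)
  union_vol <- mean(in_union) * prod(c(5.2, 4.2, 4.2))
  expect_lt(abs(res$stats$volume / union_vol - 1), 0.05)
})

test_that("an already-watertight icosphere stays close to itself", {
  ico <- make_icosphere(2, 3)
  res <- mesh2mesh(ico, pipeline_options())
  expect_true(res$stats$watertight)
  expect_lte(res$stats$hausdorff_voxels, 2)
})

test_that("meshes2mesh fuses overlapping inputs and keeps disjoint partitions", {
  a <- make_icosphere(1.5, 2)
  b <- make_icosphere(1.5, 2, center = c(6, 0, 0))
  res <- meshes2mesh(list(a, b), pipeline_options(partitions = "all"))
  expect_true(res$stats$watertight)
  expect_equal(res$report$n_partitions, 2L)

  soma <- make_icosphere(1.5, 2)
  tubes <- lapply(1:3, function(k) {
    dir <- diag(3)[k, ]
    sweep_tube(cbind(rbind(dir * 0.5, dir * 3.5), c(0.4, 0.4))[, c(1, 2, 3, 4)], 10)
  })
  res2 <- meshes2mesh(c(list(soma), tubes), pipeline_options(partitions = "all"))
  expect_equal(res2$report$n_partitions, 1L)

  one <- mesh2mesh(a, pipeline_options())
  same <- meshes2mesh(list(a), pipeline_options())
  expect_identical(same$mesh$vertices, one$mesh$vertices)
  expect_identical(same$mesh$triangles, one$mesh$triangles)
})

test_that("mesh2volume nests surface inside solid and survives 1/8-bit export", {
  ico <- make_icosphere(1, 2)
  opts16 <- pipeline_options(resolution = 16)
  solid <- mesh2volume(ico, opts16)
  # conservative rasterization yields a superset of the mesh, bounded by
  # the mesh dilated by the voxel half-diagonal
  vox_vol <- count_set(solid) * (1 / 16)^3
  expect_gte(vox_vol, enclosed_volume(ico))
  expect_lte(vox_vol, 4 * pi / 3 * (1 + sqrt(3) / 2 / 16)^3)
  shell <- mesh2volume(ico, pipeline_options(resolution = 16, solid = "none"))
  expect_true(all(solid$bits[shell$bits]))
  expect_lt(count_set(shell), count_set(solid))

  td <- withr::local_tempdir()
  mesh2volume(ico, opts16, path = file.path(td, "v1"), format = "bit")
  mesh2volume(ico, opts16, path = file.path(td, "v8"), format = "raw8")
  b1 <- read_volume(file.path(td, "v1.hdr"))
  b8 <- read_volume(file.path(td, "v8.hdr"))
  expect_identical(as.vector(b1$bits), as.vector(b8$labels > 0))
})

test_that("volume2mesh meshes an isovalue slab and rejects empty selections", {
  spec <- grid_spec(c(0, 0, 0), 1, c(20, 20, 12))
  vals <- array(0L, dim = c(20, 20, 12))
  for (z in 1:12) vals[, , z] <- z * 20L - 10L
  ramp <- annotated_grid(spec, vals)
  res <- volume2mesh(ramp, 90, 200, pipeline_options())
  expect_true(res$stats$watertight)
  slab_vol <- 20 * 20 * 6          # z-slices 5..10 selected (inclusive range)
  expect_lt(abs(res$stats$volume / slab_vol - 1), 0.05)
  expect_error(volume2mesh(ramp, 3000, 4000), "selects no voxel")
})

test_that("mask2mesh meshes a synthetic ball mask", {
  res <- mask2mesh(make_ball_mask(10), voxel_size = 1)
  expect_true(res$stats$watertight)
  expect_equal(euler_char(res$mesh), 2)
  expect_lt(abs(res$stats$volume / (4 / 3 * pi * 1000) - 1), 0.05)
})

test_that("neuron pipeline encloses every skeleton sample", {
  swc <- make_neuron_swc(seed = 11, depth = 1, n_stems = 2)
  f <- write_swc_tmp(swc)
  res <- neuromorpho2mesh(f, pipeline_options())
  expect_true(res$stats$watertight)
  expect_equal(res$report$n_partitions, 1L)
  tab <- do.call(rbind, lapply(strsplit(swc, " "), as.numeric))
  expect_true(all(points_in_mesh(res$mesh, tab[, 3:5])))
})

test_that("vessel pipeline keeps the loop as genus-1 output", {
  f <- write_swc_tmp(make_vessel_graph(seed = 2, n_loops = 1))
  res <- vessmorpho2mesh(f, pipeline_options())
  expect_true(res$stats$watertight)
  expect_equal(genus_of(res$mesh), 1)
  expect_gte(res$stats$n_samples_removed, 0)
})

test_that("astrocyte pipeline adds endfeet volume and stays one partition", {
  ast <- make_astrocyte(seed = 6, n_endfeet = 2)
  f <- write_swc_tmp(ast$swc)
  bare <- astromorpho2mesh(f, list(), pipeline_options())
  with_ef <- astromorpho2mesh(f, ast$endfeet, pipeline_options())
  expect_true(with_ef$stats$watertight)
  expect_equal(with_ef$report$n_partitions, 1L)
  expect_gt(with_ef$stats$volume, bare$stats$volume)
})

test_that("pipelines are deterministic and reports serialize", {
  ico <- make_icosphere(1.5, 2)
  r1 <- mesh2mesh(ico, pipeline_options())
  r2 <- mesh2mesh(ico, pipeline_options())
  expect_identical(r1$mesh, r2$mesh)
  f <- tempfile(fileext = ".json")
  write_run_report(r1, f)
  parsed <- jsonlite::fromJSON(f)
  expect_true(parsed$stats$watertight)
  expect_equal(parsed$stats$n_triangles, r1$stats$n_triangles)
})
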