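# Occupancy grids: world anchoring, bit accounting, serialization.

test_that("grid_from_aabb sizes and anchors the grid", {
  g <- grid_from_aabb(aabb3(c(0, 0, 0), c(1, 1, 1)), 10, 0)
  expect_equal(g$dims, c(10L, 10L, 10L))
  expect_equal(g$voxel_size, 0.1)
  expect_equal(g$origin, c(0, 0, 0))

  g2 <- grid_from_aabb(aabb3(c(0, 0, 0), c(1, 1, 1)), 10, 2)
  expect_equal(g2$dims, c(14L, 14L, 14L))
  expect_equal(g2$origin, c(-0.2, -0.2, -0.2))

  g3 <- grid_from_aabb(aabb3(c(0, 0, 0), c(1.05, 1, 1)), 10, 0)
  expect_equal(g3$dims, c(11L, 10L, 10L))

  expect_error(grid_from_aabb(aabb3(c(0, 0, 0), c(1, 1, 1)), 0),
               "resolution")
})

test_that("voxel boxes and world/index mapping are mutually inverse", {
  spec <- grid_spec(c(0, 0, 0), 1, c(4, 4, 4))
  b <- voxel_world_box(spec, c(0, 0, 0))
  expect_equal(b$min, c(0, 0, 0))
  expect_equal(b$max, c(1, 1, 1))

  spec2 <- grid_spec(c(-0.2, -0.2, -0.2), 0.1, c(14, 14, 14))
  b2 <- voxel_world_box(spec2, c(2, 0, 0))
  expect_equal(b2$min[1], 0.0)
  expect_equal(b2$max[1], 0.1)

  expect_error(voxel_world_box(spec, c(4, 0, 0)), "out of range")

  set.seed(7)
  for (i in 1:20) {
    spec3 <- grid_spec(runif(3, -5, 5), runif(1, 0.05, 2),
                       sample(2:9, 3, replace = TRUE))
    idx <- vapply(spec3$dims, function(d) sample.int(d, 1) - 1L, integer(1))
    box <- voxel_world_box(spec3, idx)
    expect_equal(box$max - box$min, rep(spec3$voxel_size, 3))
    ctr <- (box$min + box$max) / 2
    expect_equal(as.integer(world_to_index(spec3, ctr)), idx)
  }
})

test_that("count_set counts exactly and setting is idempotent", {
  spec <- grid_spec(c(0, 0, 0), 1, c(4, 4, 4))
  g <- bit_grid(spec)
  expect_equal(count_set(g), 0L)
  g$bits[] <- TRUE
  expect_equal(count_set(g), 64L)
  g2 <- bit_grid(spec)
  g2$bits[2, 2, 2] <- TRUE
  g2$bits[2, 2, 2] <- TRUE
  expect_equal(count_set(g2), 1L)
})

test_that("volume round trips are bit-exact and payload sizes match 1-bit packing", {
  set.seed(11)
  td <- withr::local_tempdir()
  spec <- grid_spec(c(-1, 0.5, 2), 0.25, c(8, 8, 8))
  g <- bit_grid(spec, runif(512) > 0.5)

  for (fmt in c("bit", "raw8", "nrrd")) {
    p <- write_volume(g, file.path(td, paste0("g_", fmt)), fmt)
    back <- read_volume(p)
    occ <- if (inherits(back, "bit_grid")) back$bits else back$labels > 0
    expect_identical(as.vector(occ), as.vector(g$bits))
    expect_equal(back$spec$origin, spec$origin)
    expect_equal(back$spec$voxel_size, spec$voxel_size)
    expect_equal(back$spec$dims, spec$dims)
  }

  g10 <- bit_grid(grid_spec(c(0, 0, 0), 1, c(10, 10, 10)))
  p <- write_volume(g10, file.path(td, "ten"), "bit")
  expect_equal(file.info(p)$size, 125)   # ceil(1000 / 8)

  for (d in list(c(3, 3, 3), c(5, 7, 2), c(16, 4, 4))) {
    gg <- bit_grid(grid_spec(c(0, 0, 0), 1, d), runif(prod(d)) > 0.3)
    pp <- write_volume(gg, file.path(td, paste(d, collapse = "x")), "bit")
    expect_equal(file.info(pp)$size, ceiling(prod(d) / 8))
  }
})

test_that("malformed volume files raise format errors naming the field", {
  td <- withr::local_tempdir()
  writeLines(c("dims 2 2 2", "type uint8", "voxel_size 1", "origin 0 0 0"),
             file.path(td, "bad.hdr"))
  writeBin(as.raw(1:7), file.path(td, "bad.raw"))
  expect_error(read_volume(file.path(td, "bad.hdr")), "size.*does not match")

  writeLines(c("dims 2 2 2", "voxel_size 1", "origin 0 0 0"),
             file.path(td, "nofield.hdr"))
  expect_error(read_volume(file.path(td, "nofield.hdr")), "missing field 'type'")

  con <- file(file.path(td, "bad.nrrd"), "wb")
  writeLines(c("NRRD0004", "type: uint8", "dimension: 3", "sizes: 2 2 2",
               "encoding: raw", ""), con)
  writeBin(as.raw(1:7), con)
  close(con)
  expect_error(read_volume(file.path(td, "bad.nrrd")), "sizes")
})

test_that("tag_occupancy paints labels in painter's order", {
  spec <- grid_spec(c(0, 0, 0), 1, c(4, 4, 4))
  s1 <- bit_grid(spec); s1$bits[1:2, 1, 1] <- TRUE
  s2 <- bit_grid(spec); s2$bits[2:3, 1, 1] <- TRUE
  a <- annotated_grid(spec)
  a <- tag_occupancy(a, s1, 1L)
  a <- tag_occupancy(a, s2, 2L)
  expect_equal(sum(a$labels == 1L), 1L)   # overlap voxel overwritten by 2
  expect_equal(sum(a$labels == 2L), 2L)
  expect_equal(a$labels[2, 1, 1], 2L)

  empty <- bit_grid(spec)
  a2 <- tag_occupancy(a, empty, 9L)
  expect_identical(a2$labels, a$labels)

  other <- bit_grid(grid_spec(c(0, 0, 0), 0.5, c(4, 4, 4)))
  expect_error(tag_occupancy(a, other, 1L), "specs differ")
})
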