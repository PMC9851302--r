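# Synthetic fixture generators: known topology, seeded damage, determinism.

test_that("analytic shapes have the documented counts and topology", {
  ih <- make_icosphere(1, 0)
  expect_equal(nrow(ih$vertices), 12)
  expect_equal(nrow(ih$triangles), 20)
  expect_true(watertightness_report(ih)$is_watertight)

  expect_equal(euler_char(make_torus(2, 0.5, 24)), 0)
  expect_equal(enclosed_volume(make_box(1)), 1)
  expect_equal(enclosed_volume(make_box(c(1, 2, 3))), 6)
})

test_that("break_mesh injects exactly the requested defect classes", {
  ico <- make_icosphere(1, 2)
  holey <- break_mesh(ico, seed = 1, del_frac = 0.05)
  expect_gt(watertightness_report(holey, FALSE)$n_boundary_edges, 0)

  dupey <- break_mesh(ico, seed = 2, del_frac = 0, dup_frac = 0.05)
  expect_gt(voxmesh:::clean_triangles(dupey)$n_duplicate, 0)

  shifted <- break_mesh(ico, seed = 3, del_frac = 0, n_shift_partitions = 1)
  expect_gt(watertightness_report(shifted)$n_self_intersections, 0)
})

test_that("fixture generators are seed-deterministic and RNG-hygienic", {
  set.seed(123)
  before <- runif(1)
  set.seed(123); runif(1)  # restore stream position
  a <- make_neuron_swc(seed = 7)
  b <- make_neuron_swc(seed = 7)
  expect_identical(a, b)
  after <- runif(1)
  set.seed(123); runif(1)
  expect_identical(after, runif(1))  # generator did not disturb the stream

  expect_identical(make_vessel_graph(seed = 5), make_vessel_graph(seed = 5))
  expect_false(identical(make_neuron_swc(seed = 7), make_neuron_swc(seed = 8)))
})

test_that("neuron generator produces parseable trees with the requested shape", {
  f <- write_swc_tmp(make_neuron_swc(seed = 1, depth = 1, branch_prob = 1,
                                     n_stems = 1))
  m <- read_swc(f, "neuron")
  leaves <- sum(vapply(m$sections, function(s) length(s$children) == 0, logical(1)))
  expect_equal(leaves, 2)
  radii <- unlist(lapply(m$sections, function(s) s$samples[, 4]))
  expect_true(all(radii > 0))
})

test_that("vessel generator hits the requested cycle rank", {
  for (nl in 1:2) {
    f <- write_swc_tmp(make_vessel_graph(seed = 3, n_loops = nl))
    m <- read_swc(f, "vasculature")
    # cycle rank = E - V + C on the merged section graph
    ends <- do.call(rbind, lapply(m$sections, function(s)
      rbind(s$samples[1, 1:3], s$samples[nrow(s$samples), 1:3])))
    nodes <- unique(voxmesh:::pos_key(ends))
    n_edges <- sum(vapply(m$sections, function(s) nrow(s$samples) - 1L, integer(1)))
    n_vertices <- length(unique(voxmesh:::pos_key(
      do.call(rbind, lapply(m$sections, function(s) s$samples[, 1:3])))))
    expect_equal(n_edges - n_vertices + 1L, nl)
  }
})

test_that("astrocyte fixture serializes endfeet through the JSON sidecar", {
  ast <- make_astrocyte(seed = 4, n_endfeet = 2)
  expect_length(ast$endfeet, 2)
  f <- tempfile(fileext = ".json")
  write_endfeet_json(ast$endfeet, f)
  back <- read_endfeet(f)
  expect_length(back, 2)
  expect_equal(back[[1]]$vertices, ast$endfeet[[1]]$vertices, ignore_attr = TRUE)
  expect_equal(back[[1]]$thickness, ast$endfeet[[1]]$thickness)
})

test_that("ball masks are exact at r = 0, near-analytic at r = 16, symmetric", {
  expect_equal(count_set(make_ball_mask(0, dims = c(5, 5, 5))), 1L)

  b16 <- make_ball_mask(16)
  expect_lt(abs(count_set(b16) / (4 / 3 * pi * 16^3) - 1), 0.05)

  b <- make_ball_mask(5, dims = c(13, 13, 13))
  expect_identical(b$bits, aperm(b$bits, c(2, 3, 1)))
  expect_identical(b$bits, aperm(b$bits, c(3, 1, 2)))
})
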