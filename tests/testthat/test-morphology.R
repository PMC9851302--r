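# Skeleton conditioning, spline interpolation, sweeps, soma and endfeet.

section_of <- function(samples) {
  voxmesh:::make_section(1L, as.matrix(samples))
}

morph_of <- function(sections, soma = NULL) {
  structure(list(kind = "neuron", sections = sections, soma = soma,
                 endfeet = list()), class = "morphology")
}

test_that("skeleton repair interpolates radii, merges duplicates, filters spikes", {
  sec <- section_of(cbind(c(0, 1, 2), 0, 0, c(1, 0, 1)))
  m <- morph_of(list(sec))
  r <- repair_skeleton(m)$sections[[1]]$samples[, 4]
  expect_equal(r, c(1, 1, 1), ignore_attr = TRUE)

  dup <- section_of(cbind(c(0, 1, 1, 2), 0, 0, 0.5))
  m2 <- repair_skeleton(morph_of(list(dup)))
  expect_equal(nrow(m2$sections[[1]]$samples), 3)

  spiky <- section_of(cbind(0:4, 0, 0, c(1, 1, 9, 1, 1)))
  m3 <- repair_skeleton(morph_of(list(spiky)))
  expect_equal(m3$sections[[1]]$samples[, 4], rep(1, 5), ignore_attr = TRUE)

  collapsed <- section_of(cbind(c(1, 1), 0, 0, 0.5))
  expect_error(repair_skeleton(morph_of(list(collapsed))), "< 2 samples")
})

test_that("adaptive resampling keeps radius-spaced samples and endpoints", {
  sec <- section_of(cbind(seq(0, 9.9, by = 0.1), 0, 0, 1))
  out <- resample_adaptive(sec)
  s <- out$samples
  expect_gte(attr(out, "n_removed") / 100, 0.6)
  kept_d <- diff(s[, 1])
  expect_true(all(kept_d[-length(kept_d)] > 1 - 1e-9))
  expect_equal(s[1, 1:3], c(0, 0, 0), ignore_attr = TRUE)
  expect_equal(s[nrow(s), 1:3], c(9.9, 0, 0), ignore_attr = TRUE)
  # kept samples are original samples, never moved
  orig_keys <- apply(sec$samples, 1, paste, collapse = ",")
  expect_true(all(apply(s, 1, paste, collapse = ",") %in% orig_keys))

  two <- section_of(cbind(c(0, 1), 0, 0, 1))
  expect_equal(resample_adaptive(two)$samples, two$samples)

  sparse <- section_of(cbind(c(0, 3, 6), 0, 0, 1))
  expect_equal(nrow(resample_adaptive(sparse)$samples), 3)
})

test_that("path interpolation hits knots and matches the Catmull-Rom closed form", {
  P <- rbind(c(0, 0, 0), c(1, 0.5, 0.2), c(2, -0.3, 0.5), c(3, 0.8, -0.2))
  dense <- interpolate_path(cbind(P, 1), step = 0.05)
  expect_equal(dense[1, 1:3], P[1, ], ignore_attr = TRUE)
  expect_equal(dense[nrow(dense), 1:3], P[4, ], ignore_attr = TRUE)
  for (k in 2:3) {
    d <- min(sqrt(rowSums(sweep(dense[, 1:3], 2, P[k, ])^2)))
    expect_lt(d, 1e-12)
  }
  # collinear knots stay collinear (affine invariance)
  L <- cbind(0:3, 0, 0)
  dl <- interpolate_path(cbind(L, 1), step = 0.1)
  expect_equal(max(abs(dl[, 2:3])), 0)

  # middle segment equals the Barry-Goldman pyramid to 1e-9
  t <- c(0, cumsum(rowSums(diff(P)^2)^0.25))
  seglen <- sqrt(rowSums(diff(P)^2))
  nsub <- pmax(1, ceiling(seglen / 0.05))
  mid_rows <- 1 + nsub[1] + seq_len(nsub[2])
  u <- t[2] + (t[3] - t[2]) * seq_len(nsub[2]) / nsub[2]
  expect_lt(max(abs(dense[mid_rows, 1:3] - bg_catmull_rom(P, u))), 1e-9)
})

test_that("tube sweeps have the stated vertex budget and cylinder area", {
  L <- 5; r <- 0.5; n_ring <- 16
  path <- cbind(seq(0, L, by = 0.25), 0, 0, r)
  tube <- sweep_tube(path, n_ring)
  k <- nrow(path)
  expect_equal(nrow(tube$vertices), n_ring * k + 2)
  expect_equal(nrow(tube$triangles), 2 * n_ring * (k - 1) + 2 * n_ring)
  expect_true(watertightness_report(tube, FALSE)$n_boundary_edges == 0)

  areas <- tri_areas_of(tube)
  lateral <- sum(areas[seq_len(2 * n_ring * (k - 1))])
  expect_lt(abs(lateral / (2 * pi * r * L) - 1), 0.02)
  expect_error(sweep_tube(path, 2), "n_ring")
})

test_that("a bent tube with radius-bounded spacing does not self-cross", {
  th <- seq(0, pi / 2, length.out = 20)
  P <- cbind(2 * cos(th), 2 * sin(th), 0)
  tube <- sweep_tube(interpolate_path(cbind(P, 0.15), 0.1), 16)
  expect_equal(nrow(self_intersections(tube)), 0)
})

test_that("path enumeration is exhaustive over root-to-leaf routes", {
  f <- write_swc_tmp(c("1 1 0 0 0 1 -1",
                       "2 3 2 0 0 0.5 1",
                       "3 3 4 0 0 0.5 2"))
  m <- read_swc(f, "neuron")
  expect_length(build_paths(m), 1)

  fy <- write_swc_tmp(c("1 1 0 0 0 1 -1",
                        "2 3 2 0 0 0.5 1",
                        "3 3 4 1 0 0.4 2",
                        "4 3 4 -1 0 0.4 2"))
  my <- read_swc(fy, "neuron")
  paths <- build_paths(my)
  expect_length(paths, 2)
  # paths start at the soma centroid
  for (p in paths) expect_equal(p[1, 1:3], my$soma$centroid, ignore_attr = TRUE)

  # full binary tree of depth 3 -> 8 root-to-leaf paths
  swc <- make_neuron_swc(seed = 4, depth = 3, branch_prob = 1, n_stems = 1)
  fb <- write_swc_tmp(swc)
  expect_length(build_paths(read_swc(fb, "neuron")), 8)
})

test_that("packing spheres take the largest terminal radius at a junction", {
  sec <- function(id, from, to, r_from, r_to) {
    voxmesh:::make_section(id, cbind(rbind(from, to)[, 1:3],
                                     c(r_from, r_to)))
  }
  y <- structure(list(kind = "vasculature", sections = list(
    sec(1L, c(-2, 0, 0), c(0, 0, 0), 1.0, 1.0),
    sec(2L, c(0, 0, 0), c(2, 1, 0), 2.0, 2.0),
    sec(3L, c(0, 0, 0), c(2, -1, 0), 1.5, 1.5)),
    soma = NULL, endfeet = list()), class = "morphology")
  pr <- per_section_proxies(y, 12)
  expect_length(pr$spheres, 1)
  sph <- pr$spheres[[1]]
  radius <- max(sqrt(rowSums(sweep(sph$vertices, 2, c(0, 0, 0))^2)))
  expect_equal(radius, 2.0, tolerance = 1e-6)

  chain <- structure(list(kind = "vasculature", sections = list(
    sec(1L, c(0, 0, 0), c(1, 0, 0), 0.5, 0.5),
    sec(2L, c(1, 0, 0), c(2, 0, 0), 0.5, 0.5)),
    soma = NULL, endfeet = list()), class = "morphology")
  expect_length(per_section_proxies(chain, 8)$spheres, 1)

  f <- write_swc_tmp(make_vessel_graph(seed = 2, n_loops = 1))
  loop <- read_swc(f, "vasculature")
  expect_length(per_section_proxies(loop, 8)$spheres,
                length(unique(voxmesh:::pos_key(do.call(rbind, lapply(loop$sections, function(s)
                  rbind(s$samples[1, 1:3], s$samples[nrow(s$samples), 1:3])))))))
})

test_that("soma reconstruction preserves volume and fixture symmetry", {
  f <- write_swc_tmp(c("1 1 0 0 0 1.5 -1",
                       "2 3 0 0 2 0.5 1",
                       "3 3 0 0 4 0.5 2",
                       "4 3 0 0 -2 0.5 1",
                       "5 3 0 0 -4 0.5 4"))
  m <- read_swc(f, "neuron")
  soma <- reconstruct_soma(m)
  r0 <- m$soma$radius
  v0 <- enclosed_volume(make_icosphere(r0, 3))
  expect_lt(abs(enclosed_volume(soma) / v0 - 1), 0.01)

  # pulled towards +z and -z: vertex set symmetric under 180-degree
  # rotation about x (z -> -z, y -> -y)
  rot <- soma$vertices %*% diag(c(1, -1, -1))
  d <- vapply(seq_len(nrow(rot)), function(i) {
    min(sqrt(rowSums(sweep(soma$vertices, 2, rot[i, ])^2)))
  }, numeric(1))
  expect_lt(max(d), 1e-6)
})

test_that("soma fall-backs cover missing neurites and missing soma samples", {
  f <- write_swc_tmp(c("1 1 0 0 0 1.2 -1"))
  m <- read_swc(f, "neuron")
  expect_warning(s <- reconstruct_soma(m), "no soma-connected neurites")
  expect_equal(enclosed_volume(s), enclosed_volume(make_icosphere(1.2, 3)),
               tolerance = 1e-9)
})

test_that("neurite connectivity classifies by distance threshold", {
  # three stems starting close to the soma plus one far outlier; the mean
  # soma radius is dominated by the near stems, so the outlier exceeds
  # k = 2 times the mean radius while the near stems stay connected
  f <- write_swc_tmp(c("1 1 0 0 0 1 -1",
                       "2 3 1.0 0 0 0.4 1", "3 3 3 0 0 0.4 2",
                       "4 3 0 1.1 0 0.4 1", "5 3 0 3 0 0.4 4",
                       "6 3 0 0 1.2 0.4 1", "7 3 0 0 3 0.4 6",
                       "8 3 -8 0 0 0.4 1", "9 3 -10 0 0 0.4 8"))
  m <- read_swc(f, "neuron")
  cc <- neurite_connectivity(m, k = 2)
  expect_length(cc$connected, 3)
  expect_length(cc$detached, 1)
  far_first <- m$sections[[cc$detached]]$samples[1, 1:3]
  expect_equal(far_first, c(-8, 0, 0), ignore_attr = TRUE)

  f0 <- write_swc_tmp(c("1 3 0 0 0 0.5 -1", "2 3 2 0 0 0.5 1"))
  m0 <- read_swc(f0, "neuron")
  expect_warning(r0 <- neurite_connectivity(m0), "no soma samples")
  expect_length(r0$detached, length(m0$soma$root_sections))
})

test_that("endfeet rasterize to one connected thickened sheet", {
  spec <- grid_spec(c(-2, -2, -2), 0.2, c(30, 30, 30))
  grid <- bit_grid(spec)
  patch <- structure(list(
    vertices = rbind(c(0, 0, 0), c(2, 0, 0), c(1, 1.5, 0)),
    thickness = rep(0.8, 3),
    triangles = matrix(c(1L, 2L, 3L), 1, 3)), class = "endfoot_patch")
  out <- endfeet_proxy(list(patch), grid)
  expect_gt(count_set(out), 0)
  comp <- voxel_components_26(out)
  expect_equal(comp, 1L)

  expect_identical(endfeet_proxy(list(), grid)$bits, grid$bits)

  bad <- patch; bad$thickness <- c(0.8, -1, 0.8)
  expect_error(endfeet_proxy(list(bad), grid), "thickness")
})

test_that("long endfoot edges are subdivided to the thickness scale", {
  spec <- grid_spec(c(-1, -6, -2), 0.2, c(70, 70, 25))
  patch <- structure(list(
    vertices = rbind(c(0, 0, 0), c(10, 0, 0), c(5, 0.9, 0)),
    thickness = rep(1, 3),
    triangles = matrix(c(1L, 2L, 3L), 1, 3)), class = "endfoot_patch")
  # the 10-thickness edge needs >= ceil(log2(10)) = 4 halving generations
  out <- endfeet_proxy(list(patch), bit_grid(spec))
  expect_gt(count_set(out), 0)
  # the rasterized sheet must span the long edge without fragmentation
  expect_equal(voxel_components_26(out), 1L)
})
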