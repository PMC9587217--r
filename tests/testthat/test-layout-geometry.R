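# Electrode lattices, planted modules, and module spatial geometry.

test_that("lattice construction matches the array geometry", {
  lay <- make_layout(8, 8, 0.4)
  expect_equal(lay$n, 64)
  expect_equal(max(lay$coords[, 1]) - min(lay$coords[, 1]), 2.8)
  expect_equal(max(lay$coords[, 2]) - min(lay$coords[, 2]), 2.8)
  expect_equal(nrow(unique(lay$coords)), 64)
  # nearest-neighbor distance equals the pitch
  d <- as.matrix(dist(lay$coords))
  diag(d) <- Inf
  expect_equal(min(d), 0.4)

  lay2 <- make_layout(2, 2, 1.0)
  expect_equal(sort(lay2$coords[, 1] + 10 * lay2$coords[, 2]),
               sort(c(0, 1, 10, 11)))

  lay3 <- drop_corners(make_layout(10, 10, 0.4))
  expect_equal(lay3$n, 96)
  expect_false(any(lay3$coords[, 1] == 0 & lay3$coords[, 2] == 0))

  expect_error(make_layout(1, 8, 0.4))
  expect_error(make_layout(8, 8, 0))
})

test_that("planted modules are contiguous blocks with the expected extent", {
  lay <- make_layout(8, 8, 0.4)
  map <- plant_modules(lay, 4, seed = 3)
  expect_equal(map$n_modules, 4)
  expect_equal(sort(unique(map$labels)), 1:4)
  expect_equal(as.vector(table(map$labels)), rep(16, 4))

  # oracle: 4x4 quadrant R_g from the coordinate formula directly
  m1 <- which(map$labels == map$labels[1])
  xy <- lay$coords[m1, ]
  rg <- sqrt(mean((xy[, 1] - mean(xy[, 1]))^2 + (xy[, 2] - mean(xy[, 2]))^2))
  expect_equal(unname(module_diameter(map$labels, lay)[as.character(map$labels[1])]),
               2 * rg)
  expect_equal(2 * rg, 1.2649111, tolerance = 1e-6)

  # contiguity: every module is 4-connected
  nb <- micromod:::mm_lattice_neighbors(lay)
  for (m in 1:4) {
    members <- which(map$labels == m)
    reach <- members[1]
    repeat {
      grow <- unique(c(reach, members[apply(
        nb[members, reach, drop = FALSE], 1, any)]))
      if (length(grow) == length(reach)) break
      reach <- grow
    }
    expect_setequal(reach, members)
  }

  expect_equal(plant_modules(lay, 1)$labels, rep(1L, 64))
  expect_identical(plant_modules(lay, 4, seed = 5)$labels,
                   plant_modules(lay, 4, seed = 5)$labels)
  expect_warning(plant_modules(make_layout(2, 4, 0.4), 2,
                               target_diameter = 5))
})

test_that("module diameter follows the radius-of-gyration formula", {
  lay <- make_layout(2, 2, 1.0)
  # two electrodes 1 mm apart: R_g = 0.5, diameter 1
  labels <- c(1, 1, 2, 2)
  expect_equal(unname(module_diameter(labels, lay)["1"]), 1.0)
  # 2x2 block at 0.4 pitch: each node 0.4/sqrt(2) from centroid
  lay4 <- make_layout(2, 2, 0.4)
  expect_equal(unname(module_diameter(rep(1, 4), lay4)["1"]),
               2 * 0.4 / sqrt(2), tolerance = 1e-12)
  # singleton
  expect_equal(unname(module_diameter(c(1, 2, 2, 2), lay)["1"]), 0)
})

test_that("compactness counts in-hull electrodes with boundary inclusion", {
  lay <- make_layout(8, 8, 0.4)
  # contiguous 3x3 block alone in its hull -> 1
  labels <- rep(2L, 64)
  block <- which(lay$coords[, 1] <= 0.8 & lay$coords[, 2] <= 0.8)
  labels[block] <- 1L
  expect_equal(unname(module_compactness(labels, lay)["1"]), 1)

  # 4 corners of a 3x3 patch whose interior belongs elsewhere -> 4/9
  labels2 <- rep(2L, 64)
  corners <- which(lay$coords[, 1] %in% c(0, 0.8) &
                     lay$coords[, 2] %in% c(0, 0.8))
  labels2[corners] <- 1L
  expect_equal(unname(module_compactness(labels2, lay)["1"]), 4 / 9)

  # singleton -> 1
  labels3 <- rep(2L, 64); labels3[10] <- 1L
  expect_equal(unname(module_compactness(labels3, lay)["1"]), 1)

  # rigid-transformation invariance (rotation + translation)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  lay_rot <- lay
  lay_rot$coords <- sweep(lay$coords %*% R, 2, c(-3, 5))
  expect_equal(module_compactness(labels, lay_rot),
               module_compactness(labels, lay))
  expect_equal(module_diameter(labels, lay_rot),
               module_diameter(labels, lay), tolerance = 1e-9)
})

test_that("boundary pairs are distance-matched at one pitch", {
  lay <- make_layout(8, 8, 0.4)
  xcol <- round(lay$coords[, 1] / 0.4)  # 0-based column index
  labels <- ifelse(xcol <= 3, 1L, 2L)   # two 8x4 halves
  bp <- boundary_pairs(labels, lay)
  b1 <- bp$pairs[["1"]]
  expect_gt(nrow(b1$inside), 0)
  expect_gt(nrow(b1$outside), 0)
  # facing column: boundary electrodes of module 1 are in lattice column 3
  expect_true(all(xcol[b1$outside[, "boundary"]] == 3))
  # all pair distances equal the pitch
  dists <- sqrt(rowSums((lay$coords[b1$inside[, 1], , drop = FALSE] -
                           lay$coords[b1$inside[, 2], , drop = FALSE])^2))
  expect_true(all(abs(dists - 0.4) < 1e-9))
  dists2 <- sqrt(rowSums((lay$coords[b1$outside[, 1], , drop = FALSE] -
                            lay$coords[b1$outside[, 2], , drop = FALSE])^2))
  expect_true(all(abs(dists2 - 0.4) < 1e-9))
  # outside neighbors belong to the other module
  expect_true(all(labels[b1$outside[, "neighbor"]] == 2L))
  expect_true(all(labels[b1$inside[, "neighbor"]] == 1L))

  expect_error(boundary_pairs(rep(1L, 64), lay))
})

test_that("boundary GC contrast separates constructed within/across weights", {
  lay <- make_layout(4, 4, 0.4)
  labels <- ifelse(lay$coords[, 1] <= 0.4, 1L, 2L)
  A <- matrix(0, 16, 16)
  same <- outer(labels, labels, "==")
  A[same] <- 2; A[!same] <- 1; diag(A) <- 0
  net <- structure(list(adjacency = A, layout = lay, session_id = "c"),
                   class = "mm_network")
  bp <- boundary_pairs(labels, lay)
  ct <- boundary_gc_contrast(net, bp)
  expect_true(all(ct$per_module$inside_mean > ct$per_module$outside_mean))
  expect_equal(ct$per_module$inside_mean, rep(2, 2))
  expect_equal(ct$per_module$outside_mean, rep(1, 2))

  # uniform weights: no contrast
  A1 <- matrix(1, 16, 16); diag(A1) <- 0
  net1 <- structure(list(adjacency = A1, layout = lay, session_id = "u"),
                    class = "mm_network")
  ct1 <- boundary_gc_contrast(net1, bp)
  expect_equal(ct1$pooled_inside, ct1$pooled_outside)
})
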