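test_that("thinning reduces tubes to one-voxel centerlines", {
  d <- c(60L, 15L, 15L)
  vol <- straight_tube(d, r = 2, z0 = 5, z1 = 55)
  sk <- skeletonize(vol)
  expect_true(all(vol[sk]))                       # skeleton inside the mask
  expect_equal(sum(sk), 51, tolerance = 0.05)     # ~tube length in voxels
  nb <- vasculometry:::neighbor_count_cpp(
    vasculometry:::.as_int_volume(sk), dim(sk))
  expect_true(all(nb[sk] <= 2))                   # a simple path
  expect_equal(sum(skeletonize(array(FALSE, c(8, 8, 8)))), 0)
})

test_that("thinning preserves the number of connected components", {
  set.seed(3)
  vol <- array(FALSE, c(40L, 60L, 60L))
  for (i in 1:10) {
    y <- 6 * i; x <- sample(10:50, 1)
    vol <- stamp_tube(vol, cbind(seq(5, 35, by = 0.5), y, x), 1.6)
  }
  ncomp <- function(b) max(vasculometry:::.label3(b))
  expect_equal(ncomp(vol), 10)
  expect_equal(ncomp(skeletonize(vol)), 10)
})

test_that("graphs capture nodes, edges and physical lengths", {
  # Y-shaped skeleton drawn directly as one-voxel paths
  sk <- array(FALSE, c(64L, 48L, 48L))
  for (z in 5:32) sk[z, 24, 24] <- TRUE
  for (i in 1:22) { sk[32 + i, 24 + i, 24] <- TRUE; sk[32 + i, 24 - i, 24] <- TRUE }
  g <- build_graph(sk, voxel_size_um = 4)
  expect_equal(nrow(g$nodes), 4)
  expect_equal(sum(g$nodes$kind == "bifurcation"), 1)
  expect_equal(sum(g$nodes$kind == "endpoint"), 3)
  expect_equal(nrow(g$edges), 3)
  # straight 50-voxel path: 49 steps of 4 um
  sk2 <- array(FALSE, c(60L, 9L, 9L))
  sk2[6:55, 5, 5] <- TRUE
  g2 <- build_graph(sk2, voxel_size_um = 4)
  expect_equal(g2$edges$path_length_um, 196, tolerance = 0.03)
  expect_equal(g2$edges$chord_length_um, g2$edges$path_length_um,
               tolerance = 1e-9)
})

test_that("phantom graphs reproduce the constructed node kinds", {
  ph <- generate_vessel_tree(tree_spec(rng_seed = 5))
  g <- build_graph(skeletonize(ph$volume), voxel_size_um = 4)
  truth_nodes <- ph$truth$graph$nodes
  expect_equal(sum(g$nodes$kind == "bifurcation"),
               sum(truth_nodes$kind == "bifurcation"))
  expect_equal(sum(g$nodes$kind == "endpoint"),
               sum(truth_nodes$kind == "endpoint"))
})

test_that("tortuosity is the arc-chord ratio", {
  # straight edge
  sk <- array(FALSE, c(40L, 9L, 9L)); sk[5:35, 5, 5] <- TRUE
  g <- build_graph(sk, voxel_size_um = 4)
  expect_equal(unname(tortuosity_index(g)), 1, tolerance = 1e-9)
  # semicircular arc: path/chord = pi/2
  th <- seq(0, pi, length.out = 400)
  pts <- cbind(8 + 20 * sin(th), 26 + 20 * cos(th), 8)
  ska <- array(FALSE, c(40L, 52L, 15L))
  ska[unique(round(pts))] <- TRUE
  ga <- build_graph(skeletonize(ska), voxel_size_um = 4)
  expect_equal(unname(tortuosity_index(ga)), pi / 2, tolerance = 0.02 * pi / 2)
  # sinusoidal phantom branch matches the analytic arc-length ratio
  ph <- generate_vessel_tree(tree_spec(rng_seed = 8,
                                       tortuosity_amplitude = 0.05))
  gm <- build_graph(skeletonize(ph$volume), voxel_size_um = 4)
  ti <- tortuosity_index(gm)
  # deep child branches: compare the measured median to the analytic truth
  truth_ti <- ph$truth$per_branch$tortuosity[ph$truth$per_branch$order == 3]
  deep <- gm$edges$edge_id[
    gm$nodes$z_um[match(gm$edges$node_b, gm$nodes$node_id)] > 400 |
      gm$nodes$z_um[match(gm$edges$node_a, gm$nodes$node_id)] > 400]
  expect_equal(median(ti[as.character(deep)]), median(truth_ti),
               tolerance = 0.03)
  expect_true(all(ti >= 1 - 1e-9, na.rm = TRUE))
})

test_that("layer metrics partition the volume and locate bifurcations", {
  d <- c(140L, 64L, 64L)
  vol <- straight_tube(d, r = 5, z0 = 1, z1 = 125)
  sk <- skeletonize(vol)
  g <- build_graph(sk, voxel_size_um = 4)
  m <- layer_metrics(vol, sk, g, voxel_size_um = 4)
  # uniform tube: identical vessel density in L1..L5
  expect_lt(diff(range(m$vessel_density)) / mean(m$vessel_density), 0.02)
  # densities match direct voxel counts
  expect_equal(m$vessel_density[1], sum(vol[1:25, , ]) / (64 * 64 * 25))
  # partition: per-layer voxels sum to the 0-500 um total
  expect_equal(sum(m$vessel_density) * 64 * 64 * 25, sum(vol[1:125, , ]))
  expect_error(layer_metrics(vol, sk, g, surface_aligned = FALSE),
               "align before layer analysis")
  # a bifurcation at 150 um lands in L2 and only L2 (half-open layers)
  gfake <- g
  gfake$nodes <- data.frame(node_id = 1, z_um = 150, y_um = 0, x_um = 0,
                            degree = 3, kind = "bifurcation")
  m2 <- layer_metrics(vol, sk, gfake, voxel_size_um = 4)
  expect_equal(m2$bifurcation_count, c(0, 1, 0, 0, 0))
})

test_that("morphometry is invariant under lateral translation", {
  ph <- generate_vessel_tree(tree_spec(rng_seed = 9))
  vol <- ph$volume
  shifted <- array(FALSE, dim(vol))
  shifted[, , 3:dim(vol)[3]] <- vol[, , 1:(dim(vol)[3] - 2)]
  m1 <- layer_metrics(vol, skeletonize(vol),
                      build_graph(skeletonize(vol), 4), voxel_size_um = 4)
  m2 <- layer_metrics(shifted, skeletonize(shifted),
                      build_graph(skeletonize(shifted), 4), voxel_size_um = 4)
  expect_equal(m2$bifurcation_count, m1$bifurcation_count)
  expect_equal(m2$vessel_density, m1$vessel_density, tolerance = 1e-3)
})
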