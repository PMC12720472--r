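test_that("straight single-tube phantom has unit tortuosity and no bifurcations", {
  spec <- tree_spec(n_pial_vessels = 1L, branching_depth = 1L,
                    tortuosity_amplitude = 0, rng_seed = 1)
  ph <- generate_vessel_tree(spec)
  expect_true(all(abs(ph$truth$per_branch$tortuosity - 1) < 1e-6))
  expect_true(all(ph$truth$per_layer$bifurcation_count == 0))
  expect_equal(sum(ph$truth$graph$nodes$degree >= 3), 0)
})

test_that("branching phantoms have the constructed topology", {
  # depth 2: each mainstem gains exactly one degree-3 junction (Y per tree)
  ph2 <- generate_vessel_tree(tree_spec(n_pial_vessels = 1L,
                                        branching_depth = 2L, rng_seed = 2))
  expect_equal(sum(ph2$truth$graph$nodes$degree >= 3), 1)
  # full depth: mainstem junction plus deep bifurcation per tree
  ph3 <- generate_vessel_tree(tree_spec(n_pial_vessels = 2L, rng_seed = 2))
  expect_equal(sum(ph3$truth$graph$nodes$degree >= 3), 4)
  expect_equal(sum(ph3$truth$per_layer$bifurcation_count), 4)
  # counts are invariant to volume padding (enlarging the grid)
  ph3b <- generate_vessel_tree(tree_spec(volume_shape = c(176L, 112L, 112L),
                                         n_pial_vessels = 2L, rng_seed = 2))
  expect_equal(sum(ph3b$truth$per_layer$bifurcation_count), 4)
  # endpoints have degree 1, bifurcations degree 3
  nd <- ph3$truth$graph$nodes
  expect_true(all(nd$degree[nd$kind == "endpoint"] == 1))
  expect_true(all(nd$degree[nd$kind == "bifurcation"] == 3))
})

test_that("phantom generation is deterministic and validates its inputs", {
  a <- generate_vessel_tree(tree_spec(rng_seed = 7))
  b <- generate_vessel_tree(tree_spec(rng_seed = 7))
  expect_identical(a$volume, b$volume)
  expect_identical(a$truth$per_branch, b$truth$per_branch)
  expect_error(generate_vessel_tree(tree_spec(voxel_size_um = 20)),
               "unresolvable vessel")
  expect_error(tree_spec(radius_by_order = c(8, 10, 6)), "strictly decrease")
  expect_error(tree_spec(volume_shape = c(40L, 96L, 96L)), "5 layers")
})

test_that("rendered vessel volume matches the per-layer density bookkeeping", {
  ph <- generate_vessel_tree(tree_spec(rng_seed = 3))
  lay_vox <- 100 / ph$truth$voxel_size_um
  d <- dim(ph$volume)
  counted <- sum(ph$truth$per_layer$vessel_density) * d[2] * d[3] * lay_vox
  in_range <- sum(ph$volume[seq_len(5 * lay_vox), , ])
  expect_equal(counted, in_range, tolerance = 1e-9)
})

test_that("phase rendering obeys the Doppler forward model", {
  ph <- generate_vessel_tree(tree_spec(rng_seed = 4))
  # zero-velocity truth gives an all-zero phase volume at zero noise
  ph0 <- ph
  ph0$truth$per_branch$velocity_mm_s[] <- 0
  expect_true(all(render_phase_volume(ph0$truth) == 0))
  # v = 1.42 mm/s along the beam gives ~pi radians with the default constants
  p <- doppler_params()
  dphi <- 4 * pi * p$n_refractive * p$T_s * 1.42 / (p$lambda0_um * 1e-3)
  expect_equal(dphi, pi, tolerance = 0.005)
  # velocities beyond the wrap limit are rejected
  phbad <- ph
  phbad$truth$per_branch$velocity_mm_s[] <- 2.0
  expect_error(render_phase_volume(phbad$truth), "phase wrap")
})

test_that("speckle stacks track the prescribed flow reproducibly", {
  prof <- data.frame(t_min = seq(-5, 5, by = 1 / 60), dcbf_pct = 0)
  st <- simulate_lsci_stack(prof, frame_shape = c(48L, 48L), seed = 0)
  sc <- spatial_contrast(st)
  rois <- data.frame(y0 = 5, x0 = 5, y1 = 44, x1 = 44)
  p <- apply(1 / sc$perfusion[, 5:44, 5:44], 1, mean)
  # constant flow: perfusion index time series flat within Monte-Carlo noise
  expect_lt(sd(1 / p) / mean(1 / p), 0.05)
  # doubled flow after onset raises the downstream trace
  prof2 <- data.frame(t_min = seq(-5, 5, by = 1 / 60),
                      dcbf_pct = ifelse(seq(-5, 5, by = 1 / 60) >= 0, 100, 0))
  st2 <- simulate_lsci_stack(prof2, frame_shape = c(48L, 48L), seed = 0)
  tr <- delta_cbf_trace(spatial_contrast(st2)$perfusion, st2$t_min, rois)
  expect_gt(mean(tr$dcbf_pct[tr$t_min > 1]), 50)
  # different seeds: different frames, matching ensemble contrast
  sa <- simulate_lsci_stack(prof, frame_shape = c(48L, 48L), seed = 1)
  sb <- simulate_lsci_stack(prof, frame_shape = c(48L, 48L), seed = 2)
  expect_false(identical(sa$frames, sb$frames))
  ka <- mean(spatial_contrast(sa)$contrast, na.rm = TRUE)
  kb <- mean(spatial_contrast(sb)$contrast, na.rm = TRUE)
  expect_lt(abs(ka - kb) / ka, 0.02)
  expect_error(simulate_lsci_stack(prof, fps = 0), "fps")
})

test_that("feature tables carry the prescribed group effects", {
  # null effect: group means agree within 3 SEM at large n
  big <- simulate_feature_table(group_effect_spec(n_per_group = 1000L,
                                                  n_parameters = 2L,
                                                  effect_size = 0,
                                                  rng_seed = 11))
  dmean <- abs(mean(big$p01[big$group == "E3"]) -
                 mean(big$p01[big$group == "E4"]))
  expect_lt(dmean, 3 * sqrt(2 / 1000))
  # a huge effect separates the groups completely at n = 6
  sep <- simulate_feature_table(group_effect_spec(n_per_group = 6L,
                                                  n_parameters = 1L,
                                                  effect_size = 10,
                                                  rng_seed = 12))
  expect_gt(min(sep$p01[sep$group == "E4"]), max(sep$p01[sep$group == "E3"]))
  # fixed seed reproduces the table
  expect_identical(
    simulate_feature_table(group_effect_spec(rng_seed = 5)),
    simulate_feature_table(group_effect_spec(rng_seed = 5)))
  expect_error(group_effect_spec(n_per_group = 1), "at least 2")
  expect_error(group_effect_spec(effect_size = Inf), "finite")
})
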