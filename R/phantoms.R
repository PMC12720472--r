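# Synthetic phantoms with exact ground truth: tubular vessel trees rendered
# into binary volumes, Doppler phase volumes obeying the velocimetry forward
# model, speckle frame stacks whose contrast tracks a prescribed flow
# time-course, and two-group Gaussian feature tables.

#' Specification of a synthetic vessel-tree phantom
#'
#' Defines the geometry of a pial-vessel tree: 1st-order mainstems running
#' near the surface, 2nd-order diving vessels descending into the cortex,
#' and 3rd-order children bifurcating from them at depth. Radii strictly
#' decrease with branch order; each branch can carry a sinusoidal bend whose
#' analytic arc length provides the tortuosity ground truth.
#'
#' @param volume_shape integer (z, y, x) volume size in voxels.
#' @param voxel_size_um voxel edge length, micrometers (isotropic).
#' @param n_pial_vessels number of 1st-order mainstem vessels. Odd-numbered
#'   mainstems are arterial trees (descending flow), even-numbered venous
#'   (ascending), so both Doppler flow signs are exercised.
#' @param branching_depth maximum branch order generated (1-3).
#' @param radius_by_order vessel radius per order, micrometers; must be
#'   strictly decreasing and resolve to at least one voxel.
#' @param tortuosity_amplitude sinusoidal bend amplitude as a fraction of
#'   branch length (0 = straight branches).
#' @param velocity_by_order flow speed per order, mm/s (magnitudes).
#' @param rng_seed integer seed; a fixed seed gives byte-identical output.
#' @return object of class `tree_spec`.
#' @export
tree_spec <- function(volume_shape = c(160L, 96L, 96L),
                      voxel_size_um = 4,
                      n_pial_vessels = 3L,
                      branching_depth = 3L,
                      radius_by_order = c(16, 10, 6),
                      tortuosity_amplitude = 0.03,
                      velocity_by_order = c(1.0, 0.8, 0.5),
                      rng_seed = 1L) {
  stopifnot(length(volume_shape) == 3L, voxel_size_um > 0,
            n_pial_vessels >= 1L, branching_depth %in% 1:3,
            length(radius_by_order) >= branching_depth,
            length(velocity_by_order) >= branching_depth)
  if (any(diff(radius_by_order) >= 0))
    stop("radius_by_order must strictly decrease with order", call. = FALSE)
  if (volume_shape[1] * voxel_size_um < 500)
    stop("volume too shallow: need at least 5 layers of 100 um", call. = FALSE)
  structure(list(volume_shape = as.integer(volume_shape),
                 voxel_size_um = voxel_size_um,
                 n_pial_vessels = as.integer(n_pial_vessels),
                 branching_depth = as.integer(branching_depth),
                 radius_by_order = radius_by_order,
                 tortuosity_amplitude = tortuosity_amplitude,
                 velocity_by_order = velocity_by_order,
                 rng_seed = as.integer(rng_seed)),
            class = "tree_spec")
}

# A branch is a straight chord P0 -> P1 (voxel coordinates, z,y,x) plus a
# sinusoidal lateral bend of one full period (zero displacement and zero
# junction offset at both ends). Sampled densely; the analytic polyline is
# the ground truth centerline.
.branch_curve <- function(p0, p1, amp_frac, u_lat, n_samp = NULL) {
  chord <- sqrt(sum((p1 - p0)^2))
  if (is.null(n_samp)) n_samp <- max(8L, ceiling(chord / 0.25))
  t <- seq(0, 1, length.out = n_samp)
  base <- outer(t, p1 - p0) + rep(p0, each = n_samp)
  lat <- amp_frac * chord * sin(2 * pi * t)
  base + outer(lat, u_lat)
}

.polyline_length <- function(pts) {
  if (nrow(pts) < 2L) return(0)
  sum(sqrt(rowSums(diff(pts)^2)))
}

# unit vector perpendicular to v, rotated by a random angle about v
.perp_unit <- function(v, angle) {
  v <- v / sqrt(sum(v^2))
  a <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u1 <- a - sum(a * v) * v
  u1 <- u1 / sqrt(sum(u1^2))
  u2 <- c(v[2] * u1[3] - v[3] * u1[2],
          v[3] * u1[1] - v[1] * u1[3],
          v[1] * u1[2] - v[2] * u1[1])
  cos(angle) * u1 + sin(angle) * u2
}

# Mark all voxels within radius r (voxels) of a sampled centerline.
.mark_tube <- function(marked, dims, pts, r) {
  base <- round(pts)
  offs <- as.matrix(.ball_offsets(ceiling(r)))
  for (k in seq_len(nrow(offs))) {
    vox <- sweep(base, 2, unlist(offs[k, ]), "+")
    d2 <- rowSums((vox - pts)^2)
    ok <- d2 <= r^2 &
      vox[, 1] >= 1 & vox[, 1] <= dims[1] &
      vox[, 2] >= 1 & vox[, 2] <= dims[2] &
      vox[, 3] >= 1 & vox[, 3] <= dims[3]
    if (any(ok)) {
      idx <- vox[ok, 1] + dims[1] * (vox[ok, 2] - 1) +
        dims[1] * dims[2] * (vox[ok, 3] - 1)
      marked[idx] <- TRUE
    }
  }
  marked
}

# Digital centerline: dedup consecutive rounded samples, then compress the
# staircase (drop voxels whose predecessor and successor are 26-adjacent) so
# the count matches a minimal 26-connected digital line.
.rasterize_centerline <- function(pts, dims) {
  vox <- round(pts)
  keep <- c(TRUE, rowSums(abs(diff(vox))) > 0)
  vox <- vox[keep, , drop = FALSE]
  repeat {
    n <- nrow(vox)
    if (n < 3) break
    adj <- abs(vox[seq_len(n - 2), , drop = FALSE] -
                 vox[3:n, , drop = FALSE])
    drop_mid <- which(apply(adj <= 1, 1, all)) + 1L
    if (!length(drop_mid)) break
    # drop non-adjacent removals in one sweep to avoid over-pruning
    sel <- drop_mid[c(TRUE, diff(drop_mid) > 1)]
    vox <- vox[-sel, , drop = FALSE]
  }
  ok <- vox[, 1] >= 1 & vox[, 1] <= dims[1] &
    vox[, 2] >= 1 & vox[, 2] <= dims[2] &
    vox[, 3] >= 1 & vox[, 3] <= dims[3]
  unique(vox[ok, 1] + dims[1] * (vox[ok, 2] - 1) +
           dims[1] * dims[2] * (vox[ok, 3] - 1))
}

#' Generate a synthetic vessel tree and its ground truth
#'
#' Builds the branch list implied by the spec (mainstems with a gentle dip so
#' that Doppler projection is non-degenerate, diving vessels bifurcating at
#' depth), renders it as a binary tube volume, and derives exact truth:
#' the topology graph, per-branch tortuosity from analytic arc length,
#' per-layer vessel density (from rendered voxel counts), skeleton density
#' (from rasterized centerlines), and bifurcation counts (from construction).
#'
#' @param spec a [tree_spec()].
#' @return list with `volume` (logical 3D array) and `truth`
#'   (class `phantom_truth`): `graph` (a `skeleton_graph`), `per_branch`
#'   data.frame (branch_id, order, kind, tortuosity, velocity_mm_s,
#'   cos_theta, flow_sign), `per_layer` data.frame (layer, vessel_density,
#'   skeleton_density, bifurcation_count), `label_volume` (integer branch id
#'   per voxel), `voxel_size_um`.
#' @export
generate_vessel_tree <- function(spec) {
  stopifnot(inherits(spec, "tree_spec"))
  vox <- spec$voxel_size_um
  r_vox <- spec$radius_by_order / vox
  if (any(r_vox[seq_len(spec$branching_depth)] < 1))
    stop("unresolvable vessel: tube radius < 1 voxel at this voxel size",
         call. = FALSE)
  d <- spec$volume_shape
  set.seed(spec$rng_seed)

  nodes <- list()   # (z, y, x) voxel coords
  branches <- list()
  add_node <- function(p) { nodes[[length(nodes) + 1L]] <<- p; length(nodes) }
  add_branch <- function(na, nb, order, kind, flow_sign, amp) {
    p0 <- nodes[[na]]; p1 <- nodes[[nb]]
    u <- .perp_unit(p1 - p0, stats::runif(1, 0, 2 * pi))
    pts <- .branch_curve(p0, p1, amp, u)
    branches[[length(branches) + 1L]] <<- list(
      node_a = na, node_b = nb, order = order, kind = kind,
      flow_sign = flow_sign, pts = pts)
    invisible(NULL)
  }

  margin <- max(6, ceiling(max(r_vox)) + 2)
  y_pos <- seq(margin, d[2] - margin, length.out = spec$n_pial_vessels + 2)
  y_pos <- y_pos[-c(1, length(y_pos))]
  z_pial0 <- max(3, ceiling(r_vox[1]) + 1)
  z_div_um <- 240        # diving vessels bifurcate mid-L3
  z_term_um <- min(520, (d[1] - margin) * vox)
  amp <- spec$tortuosity_amplitude

  # Each tree owns a y corridor; children split in +/- x within it, so
  # subtrees can never collide and every constructed junction stays the
  # only junction in its neighbourhood.
  for (i in seq_len(spec$n_pial_vessels)) {
    kind <- if (i %% 2L == 1L) "artery" else "vein"
    fsign <- if (kind == "artery") 1 else -1
    y0 <- y_pos[i]
    a <- add_node(c(z_pial0, y0, margin))
    # gentle dip keeps cos(theta_z) away from zero for the mainstem
    dip <- 6
    if (spec$branching_depth >= 2L) {
      xj <- (margin + d[3] - margin) / 2
      j1 <- add_node(c(z_pial0 + dip / 2, y0, xj))
      b <- add_node(c(z_pial0 + dip, y0, d[3] - margin))
      add_branch(a, j1, 1L, kind, fsign, amp)
      add_branch(j1, b, 1L, kind, fsign, amp)
      pj <- nodes[[j1]]
      slant <- stats::runif(2, -3, 3)
      bif <- add_node(c(z_div_um / vox, pj[2] + slant[1], pj[3] + slant[2]))
      add_branch(j1, bif, 2L, kind, fsign, amp)
      if (spec$branching_depth >= 3L) {
        pb <- nodes[[bif]]
        for (s in c(-1, 1)) {
          dx <- s * stats::runif(1, 16, 22)
          dy <- stats::runif(1, -3, 3)
          term <- add_node(c(z_term_um / vox, pb[2] + dy, pb[3] + dx))
          add_branch(bif, term, 3L, kind, fsign, amp)
        }
      }
    } else {
      b <- add_node(c(z_pial0 + dip, y0, d[3] - margin))
      add_branch(a, b, 1L, kind, fsign, amp)
    }
  }

  # render tubes and the branch-label volume; the skeleton truth is the
  # centerline set of the rendered tube union, so where sibling tubes still
  # overlap just below a bifurcation their common segment is counted once
  volume <- array(FALSE, d)
  label <- array(0L, d)
  skel_idx <- integer(0)
  for (bi in seq_along(branches)) {
    br <- branches[[bi]]
    marked <- array(FALSE, d)
    marked <- .mark_tube(marked, d, br$pts, r_vox[br$order])
    volume <- volume | marked
    label[marked & label == 0L] <- bi   # parent keeps ownership at junctions
    cl <- .rasterize_centerline(br$pts, d)
    sib <- which(vapply(branches[seq_len(bi - 1L)], function(b2)
      b2$node_a == br$node_a && b2$order == br$order, logical(1)))
    if (length(sib)) {
      sib_pts <- do.call(rbind, lapply(branches[sib], `[[`, "pts"))
      cz <- ((cl - 1L) %% d[1]) + 1L
      cy <- ((cl - 1L) %/% d[1]) %% d[2] + 1L
      cx <- (cl - 1L) %/% (d[1] * d[2]) + 1L
      mind <- vapply(seq_along(cl), function(k)
        min((sib_pts[, 1] - cz[k])^2 + (sib_pts[, 2] - cy[k])^2 +
              (sib_pts[, 3] - cx[k])^2), numeric(1))
      cl <- cl[sqrt(mind) > 2 * r_vox[br$order]]
    }
    skel_idx <- union(skel_idx, cl)
  }

  # ground-truth graph
  node_mat <- do.call(rbind, nodes)
  deg <- integer(length(nodes))
  per_branch <- data.frame(
    branch_id = seq_along(branches),
    order = vapply(branches, `[[`, integer(1), "order"),
    kind = vapply(branches, `[[`, character(1), "kind"),
    node_a = vapply(branches, `[[`, integer(1), "node_a"),
    node_b = vapply(branches, `[[`, integer(1), "node_b"),
    stringsAsFactors = FALSE)
  for (bi in seq_along(branches)) {
    deg[branches[[bi]]$node_a] <- deg[branches[[bi]]$node_a] + 1L
    deg[branches[[bi]]$node_b] <- deg[branches[[bi]]$node_b] + 1L
  }
  path_len <- vapply(branches, function(b) .polyline_length(b$pts) * vox,
                     numeric(1))
  chord_len <- vapply(branches, function(b) {
    sqrt(sum((node_mat[b$node_b, ] - node_mat[b$node_a, ])^2)) * vox
  }, numeric(1))
  per_branch$tortuosity <- path_len / chord_len
  per_branch$velocity_mm_s <- spec$velocity_by_order[per_branch$order]
  # Doppler projection: signed cos(theta_z) from the chord, z pointing down
  cosz <- vapply(branches, function(b) {
    v <- node_mat[b$node_b, ] - node_mat[b$node_a, ]
    abs(v[1]) / sqrt(sum(v^2))
  }, numeric(1))
  per_branch$cos_theta <- cosz
  per_branch$flow_sign <- vapply(branches, `[[`, numeric(1), "flow_sign")

  nodes_df <- data.frame(
    node_id = seq_along(nodes),
    z_um = node_mat[, 1] * vox, y_um = node_mat[, 2] * vox,
    x_um = node_mat[, 3] * vox,
    degree = deg,
    kind = ifelse(deg == 1L, "endpoint",
                  ifelse(deg >= 3L, "bifurcation", "through")),
    stringsAsFactors = FALSE)
  edges_df <- data.frame(
    edge_id = per_branch$branch_id, node_a = per_branch$node_a,
    node_b = per_branch$node_b, path_length_um = path_len,
    chord_length_um = chord_len,
    n_voxels = vapply(branches, function(b) nrow(b$pts), numeric(1)),
    stringsAsFactors = FALSE)
  edges_df$path <- lapply(branches, `[[`, "pts")
  graph <- structure(list(nodes = nodes_df, edges = edges_df,
                          voxel_size_um = vox), class = "skeleton_graph")

  # per-layer truth (100-um strata, half-open [k, k+1) * 100 um)
  layers <- layer_spec()
  lay_vox <- layers$layer_thickness_um / vox
  zs <- (seq_len(d[1]) - 1)                    # surface at z = 0
  layer_of_z <- pmin(floor(zs / lay_vox), layers$n_layers - 1) + 1L
  in_range <- zs < layers$n_layers * lay_vox
  layer_voxels <- (d[2] * d[3]) * lay_vox
  vd <- sd_ <- bc <- numeric(layers$n_layers)
  skel_z <- ((skel_idx - 1) %% d[1])           # 0-based z of centerline voxels
  for (k in seq_len(layers$n_layers)) {
    zsel <- which(layer_of_z == k & in_range)
    vd[k] <- sum(volume[zsel, , ]) / layer_voxels
    sd_[k] <- sum(skel_z >= (k - 1) * lay_vox & skel_z < k * lay_vox) /
      layer_voxels
    zb <- node_mat[deg >= 3L, 1] - 1
    bc[k] <- sum(zb >= (k - 1) * lay_vox & zb < k * lay_vox)
  }
  per_layer <- data.frame(layer = seq_len(layers$n_layers),
                          vessel_density = vd, skeleton_density = sd_,
                          bifurcation_count = as.integer(bc))

  truth <- structure(list(graph = graph, per_branch = per_branch,
                          per_layer = per_layer, label_volume = label,
                          voxel_size_um = vox, volume_shape = d),
                     class = "phantom_truth")
  list(volume = volume, truth = truth)
}

#' Ground-truth velocity and Doppler-angle volumes of a phantom
#'
#' Maps the branch-label volume of a [generate_vessel_tree()] truth to a
#' signed axial velocity field (mm/s; positive = descending flow, the
#' arterial convention) and to the per-branch `cos(theta_z)` projection.
#'
#' @param truth a `phantom_truth`.
#' @return 3D numeric array.
#' @export
truth_velocity_volume <- function(truth) {
  stopifnot(inherits(truth, "phantom_truth"))
  v <- c(0, truth$per_branch$velocity_mm_s * truth$per_branch$flow_sign)
  array(v[truth$label_volume + 1L], dim(truth$label_volume))
}

#' @rdname truth_velocity_volume
#' @export
truth_cos_theta_volume <- function(truth) {
  stopifnot(inherits(truth, "phantom_truth"))
  ct <- c(1, truth$per_branch$cos_theta)
  array(ct[truth$label_volume + 1L], dim(truth$label_volume))
}

#' Render a Doppler phase volume from phantom ground truth
#'
#' Forward model of the velocimetry equation: for vessel voxels the
#' inter-A-scan phase shift is
#' `dphi = 4 * pi * n * T * v * cos(theta_z) / lambda0`, plus i.i.d.
#' Gaussian phase noise; background voxels carry pure noise.
#'
#' @param truth a `phantom_truth` from [generate_vessel_tree()].
#' @param params a [doppler_params()].
#' @param phase_noise_sd phase noise standard deviation, radians.
#' @param rng_seed seed for the noise draw.
#' @return 3D phase array, radians, in (-pi, pi].
#' @export
render_phase_volume <- function(truth, params = doppler_params(),
                                phase_noise_sd = 0, rng_seed = 1L) {
  stopifnot(inherits(truth, "phantom_truth"), inherits(params, "doppler_params"))
  v <- truth_velocity_volume(truth)
  ct <- truth_cos_theta_volume(truth)
  lambda0_mm <- params$lambda0_um * 1e-3
  phase <- 4 * pi * params$n_refractive * params$T_s * v * ct / lambda0_mm
  if (max(abs(phase)) >= pi)
    stop("phase wrap: velocities induce |dphi| >= pi; reduce velocity or T",
         call. = FALSE)
  if (phase_noise_sd > 0) {
    set.seed(rng_seed)
    phase <- phase + array(rnorm(length(phase), 0, phase_noise_sd), dim(phase))
  }
  phase
}

#' Simulate a laser-speckle frame stack tracking a prescribed flow response
#'
#' The generator model ties local speckle contrast to flow as
#' `K = 1 / sqrt(1 + c * flow)`: each pixel intensity is drawn from a
#' Gamma(M, M) distribution with `M = 1 + c * flow(t)`, the classic model of
#' M incoherently averaged speckle patterns (unit mean, contrast 1/sqrt(M)).
#' The prescribed curve is a baseline-relative perfusion change (Delta-CBF %),
#' which the generator inverts through the contrast model so that the
#' downstream perfusion index `1/K^2` reproduces it. This is a documented
#' statistical stand-in, not a coherent-optics simulation.
#'
#' @param flow_profile data.frame with `t_min` (minutes, stimulus onset at 0)
#'   and `dcbf_pct` (ideal baseline-relative response, %).
#' @param frame_shape (ny, nx) frame size in pixels.
#' @param fps frames per second (default 1).
#' @param baseline_flow baseline flow in arbitrary units.
#' @param c_flow contrast-model constant `c` (a.u.^-1).
#' @param seed integer seed; fixed seed gives reproducible frames.
#' @return object of class `lsci_stack`: `frames` (t, y, x array), `fps`,
#'   `exposure_ms`, `t_min` (frame times), and `truth` (the target response
#'   interpolated to frame times).
#' @export
simulate_lsci_stack <- function(flow_profile, frame_shape = c(64L, 64L),
                                fps = 1, baseline_flow = 100, c_flow = 0.05,
                                seed = 1L) {
  if (fps <= 0) stop("fps must be positive", call. = FALSE)
  stopifnot(is.data.frame(flow_profile),
            all(c("t_min", "dcbf_pct") %in% names(flow_profile)))
  t_frame <- seq(min(flow_profile$t_min), max(flow_profile$t_min),
                 by = 1 / (fps * 60))
  dcbf <- stats::approx(flow_profile$t_min, flow_profile$dcbf_pct,
                        xout = t_frame)$y
  p0 <- 1 + c_flow * baseline_flow
  m <- p0 * (1 + dcbf / 100)          # perfusion index target, = 1 + c*flow
  flow <- (m - 1) / c_flow
  if (any(flow <= 0))
    stop("flow profile must stay strictly positive", call. = FALSE)
  set.seed(seed)
  npx <- prod(frame_shape)
  frames <- array(0, c(length(t_frame), frame_shape))
  for (i in seq_along(t_frame))
    frames[i, , ] <- rgamma(npx, shape = m[i], rate = m[i])
  structure(list(frames = frames, fps = fps, exposure_ms = 10,
                 t_min = t_frame,
                 truth = data.frame(t_min = t_frame, dcbf_pct = dcbf,
                                    flow = flow)),
            class = "lsci_stack")
}

#' Specification of a two-group synthetic feature panel
#'
#' @param n_per_group animals per group (>= 2).
#' @param n_parameters number of parameters (default 36, the size of the
#'   vein/artery/microvasculature panel).
#' @param effect_size Cohen's d per parameter (recycled).
#' @param noise_sd per-parameter standard deviation (recycled).
#' @param rng_seed integer seed.
#' @return object of class `group_effect_spec`.
#' @export
group_effect_spec <- function(n_per_group = 6L, n_parameters = 36L,
                              effect_size = 0, noise_sd = 1, rng_seed = 1L) {
  if (n_per_group < 2L) stop("need at least 2 animals per group", call. = FALSE)
  if (any(!is.finite(effect_size))) stop("effect sizes must be finite", call. = FALSE)
  structure(list(n_per_group = as.integer(n_per_group),
                 n_parameters = as.integer(n_parameters),
                 effect_size = rep_len(effect_size, n_parameters),
                 noise_sd = rep_len(noise_sd, n_parameters),
                 rng_seed = as.integer(rng_seed)),
            class = "group_effect_spec")
}

#' Simulate an animal-by-parameter feature table
#'
#' Two groups labelled "E3" and "E4"; parameter k is Gaussian with a
#' group-mean offset of `effect_size[k] * noise_sd[k]` (Cohen's d).
#'
#' @param spec a [group_effect_spec()].
#' @return data.frame `animal_id, group, p01..pNN`.
#' @export
simulate_feature_table <- function(spec) {
  stopifnot(inherits(spec, "group_effect_spec"))
  set.seed(spec$rng_seed)
  n <- spec$n_per_group
  group <- factor(rep(c("E3", "E4"), each = n))
  out <- data.frame(animal_id = sprintf("a%02d", seq_len(2 * n)),
                    group = group)
  for (k in seq_len(spec$n_parameters)) {
    mu <- ifelse(group == "E4", spec$effect_size[k] * spec$noise_sd[k], 0)
    out[[sprintf("p%02d", k)]] <- rnorm(2 * n, mu, spec$noise_sd[k])
  }
  out
}
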