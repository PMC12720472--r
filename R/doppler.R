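# Doppler velocimetry: phase-shift volumes to quantitative axial velocity,
# per-vessel CBFv and diameter summaries, vein/artery typing and branch order.

#' Doppler velocimetry constants
#'
#' Constants of the phase-subtraction velocity equation
#' `v = lambda0 * dphi / (4 * pi * n * T * cos(theta_z))`.
#'
#' @param lambda0_um central wavelength, micrometers (default 1.31).
#' @param n_refractive tissue refractive index (default 1.38).
#' @param T_s inter-A-scan interval, seconds (default 1/6000, i.e. ~0.167 ms
#'   at a 6k A-lines/s line rate).
#' @param theta_z_deg default Doppler angle (degrees between flow and the
#'   incident beam); may be overridden per call.
#' @return object of class `doppler_params`.
#' @export
doppler_params <- function(lambda0_um = 1.31, n_refractive = 1.38,
                           T_s = 1 / 6000, theta_z_deg = 0) {
  stopifnot(lambda0_um > 0, n_refractive > 0, T_s > 0)
  if (any(abs(cos(theta_z_deg * pi / 180)) < 1e-12))
    stop("degenerate Doppler angle: cos(theta_z) = 0", call. = FALSE)
  structure(list(lambda0_um = lambda0_um, n_refractive = n_refractive,
                 T_s = T_s, theta_z_deg = theta_z_deg),
            class = "doppler_params")
}

#' Convert a Doppler phase volume to axial velocity
#'
#' Applies `v = lambda0 * dphi / (4 * pi * n * T * cos(theta_z))`
#' elementwise. The result is signed: the sign encodes axial flow direction
#' (positive = descending into the cortex with the phantom convention),
#' which downstream typing uses to separate arteries from veins.
#'
#' @param phase_volume 3D array of phase shifts, radians, in (-pi, pi].
#' @param params a [doppler_params()].
#' @param cos_theta optional override of `cos(theta_z)`: scalar or array the
#'   shape of `phase_volume` (e.g. from [truth_cos_theta_volume()]); defaults
#'   to `cos(params$theta_z_deg)`.
#' @param voxel_size_um voxel size carried into the result.
#' @param surface_aligned whether the volume is already surface-aligned.
#' @return object of class `flow_volume`: `data` (velocity, mm/s),
#'   `voxel_size_um`, `surface_aligned`.
#' @export
phase_to_velocity <- function(phase_volume, params = doppler_params(),
                              cos_theta = NULL, voxel_size_um = 4,
                              surface_aligned = FALSE) {
  .check_volume(phase_volume, "phase_volume")
  if (any(phase_volume > pi | phase_volume <= -pi))
    stop("wrapped phase: values outside (-pi, pi]; unwrap before conversion",
         call. = FALSE)
  if (is.null(cos_theta)) cos_theta <- cos(params$theta_z_deg * pi / 180)
  if (any(abs(cos_theta) < 1e-12))
    stop("degenerate Doppler angle: cos(theta_z) = 0", call. = FALSE)
  lambda0_mm <- params$lambda0_um * 1e-3
  v <- lambda0_mm * phase_volume /
    (4 * pi * params$n_refractive * params$T_s * cos_theta)
  structure(list(data = v, voxel_size_um = voxel_size_um,
                 surface_aligned = surface_aligned),
            class = "flow_volume")
}

.roi_slice <- function(vol, roi) {
  d <- dim(vol)
  if (roi$z0 < 1 || roi$y0 < 1 || roi$x0 < 1 ||
      roi$z1 > d[1] || roi$y1 > d[2] || roi$x1 > d[3] ||
      roi$z0 > roi$z1 || roi$y0 > roi$y1 || roi$x0 > roi$x1)
    stop("ROI outside volume or empty", call. = FALSE)
  vol[roi$z0:roi$z1, roi$y0:roi$y1, roi$x0:roi$x1]
}

#' Summarize per-vessel blood-flow velocity over ROIs
#'
#' Mean CBFv of a vessel from 3 to 10 ROI boxes placed along it: the mean
#' over ROIs of the mean absolute velocity within each ROI.
#'
#' @param flow a `flow_volume`.
#' @param rois data.frame of ROI boxes (`z0,y0,x0,z1,y1,x1`, 1-based
#'   inclusive), e.g. from [read_rois()].
#' @param vessel_id identifier carried into the record.
#' @return one-row data.frame: `vessel_id, cbfv_mm_s, roi_count`.
#' @export
summarize_cbfv <- function(flow, rois, vessel_id = NA) {
  stopifnot(inherits(flow, "flow_volume"))
  n <- nrow(rois)
  if (is.null(n) || n < 3 || n > 10)
    stop("protocol violation: 3 to 10 ROIs are required per vessel",
         call. = FALSE)
  roi_means <- vapply(seq_len(n), function(i) {
    vals <- .roi_slice(flow$data, rois[i, ])
    if (length(vals) == 0) stop("empty ROI", call. = FALSE)
    mean(abs(vals))
  }, numeric(1))
  data.frame(vessel_id = vessel_id, cbfv_mm_s = mean(roi_means),
             roi_count = n)
}

#' Measure vessel diameter from transects
#'
#' Each transect is a line segment crossing the vessel once; the diameter is
#' the mean in-vessel run length along the transects times the voxel size.
#' Transects running obliquely to the vessel cross-section inflate the run
#' length (a `1/sin` factor); runs longer than 1.5 times the shortest
#' transect run are flagged.
#'
#' @param binary_volume logical 3D array (vessel mask).
#' @param transects list of 2x3 matrices (endpoints in voxel coordinates,
#'   rows = start/end, columns = z,y,x).
#' @param voxel_size_um voxel size, micrometers.
#' @return list: `diameter_um`, `per_transect_um`, `oblique_flag`.
#' @export
measure_diameter <- function(binary_volume, transects, voxel_size_um = 4) {
  .check_volume(binary_volume, "binary_volume")
  runs <- vapply(transects, function(seg) {
    p0 <- seg[1, ]; p1 <- seg[2, ]
    len <- sqrt(sum((p1 - p0)^2))
    n <- max(2L, ceiling(len * 4))
    t <- seq(0, 1, length.out = n)
    pts <- round(outer(t, p1 - p0) + rep(p0, each = n))
    d <- dim(binary_volume)
    ok <- pts[, 1] >= 1 & pts[, 1] <= d[1] & pts[, 2] >= 1 &
      pts[, 2] <= d[2] & pts[, 3] >= 1 & pts[, 3] <= d[3]
    inside <- logical(n)
    inside[ok] <- binary_volume[cbind(pts[ok, 1], pts[ok, 2], pts[ok, 3])]
    if (!any(inside)) stop("transect entirely in background", call. = FALSE)
    # longest single run (the transect crosses the vessel once); the span of
    # k inside samples is (k - 1) sampling steps
    r <- rle(inside)
    (max(r$lengths[r$values]) - 1L) / (n - 1) * len
  }, numeric(1))
  per <- runs * voxel_size_um
  list(diameter_um = mean(per), per_transect_um = per,
       oblique_flag = per > 1.5 * min(per))
}

#' Classify a vessel as vein or artery and assign branch order
#'
#' Type from the Doppler flow direction: arteries descend (positive mean
#' signed axial flow with the package convention), veins ascend. Order from
#' graph topology: 1 for pial mainstem edges (both endpoints within
#' `pial_depth_um` of the surface), plus one per bifurcation away from the
#' mainstem, capped at 3; veins are capped at order 2 (with a warning), as
#' higher-order venous branches are not analyzed.
#'
#' @param flow a `flow_volume` (signed velocities).
#' @param graph a `skeleton_graph`.
#' @param vessel_id edge id in `graph$edges`.
#' @param pial_depth_um depth below which nodes count as pial (default 50).
#' @param noise_floor_mm_s minimum |mean signed flow| to call a direction.
#' @return list: `kind` ("artery"/"vein"), `order` (1-3).
#' @export
classify_vessel <- function(flow, graph, vessel_id, pial_depth_um = 50,
                            noise_floor_mm_s = 0.01) {
  stopifnot(inherits(flow, "flow_volume"), inherits(graph, "skeleton_graph"))
  e <- graph$edges
  row <- match(vessel_id, e$edge_id)
  if (is.na(row)) stop("unknown vessel_id", call. = FALSE)
  pts <- round(e$path[[row]])
  d <- dim(flow$data)
  ok <- pts[, 1] >= 1 & pts[, 1] <= d[1] & pts[, 2] >= 1 &
    pts[, 2] <= d[2] & pts[, 3] >= 1 & pts[, 3] <= d[3]
  v <- flow$data[cbind(pts[ok, 1], pts[ok, 2], pts[ok, 3])]
  mv <- mean(v)
  if (abs(mv) < noise_floor_mm_s)
    stop("indeterminate direction: |mean signed flow| below noise floor",
         call. = FALSE)
  kind <- if (mv > 0) "artery" else "vein"

  ord <- .edge_orders(graph, pial_depth_um)[row]
  cap <- if (kind == "vein") 2L else 3L
  if (ord > cap) {
    if (kind == "vein")
      warning("vein at graph order ", ord, " reported as order 2 (cap)",
              call. = FALSE)
    ord <- cap
  }
  list(kind = kind, order = as.integer(ord))
}

# Edge order by hops from the pial mainstem: mainstem edges (both nodes
# shallower than pial_depth_um) are order 1; each bifurcation crossed adds 1.
.edge_orders <- function(graph, pial_depth_um = 50) {
  n <- graph$nodes
  e <- graph$edges
  shallow <- n$z_um <= pial_depth_um
  is_main <- shallow[match(e$node_a, n$node_id)] &
    shallow[match(e$node_b, n$node_id)]
  ord <- ifelse(is_main, 1L, NA_integer_)
  if (all(is.na(ord))) ord[] <- 1L     # no pial mainstem: treat roots as order 1
  # breadth-first over edges through shared nodes
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(e))) {
      if (!is.na(ord[i])) next
      nb <- which((e$node_a %in% c(e$node_a[i], e$node_b[i]) |
                     e$node_b %in% c(e$node_a[i], e$node_b[i])) & !is.na(ord))
      if (length(nb)) {
        ord[i] <- min(ord[nb]) + 1L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  ord[is.na(ord)] <- 1L
  pmin(ord, 3L)
}
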