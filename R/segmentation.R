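# Volume preparation for morphometry: cortical-surface plane alignment,
# multiscale Hessian (Frangi) vessel segmentation, binary morphology denoise.

#' Segmentation configuration
#'
#' @param frangi_scales_um Gaussian scales of the vesselness filter,
#'   micrometers (ascending; should bracket the vessel radii of interest —
#'   the defaults span capillaries to arterioles, ~4-30 um radius).
#' @param vesselness_threshold binarization threshold as a fraction of the
#'   global vesselness maximum, in (0, 1).
#' @param morph_radius_voxels structuring-element radius of the closing.
#' @param min_component_voxels connected components smaller than this are
#'   removed as speckle.
#' @param alpha,beta Frangi plate/blob sensitivity constants.
#' @return object of class `segmentation_config`.
#' @export
segmentation_config <- function(frangi_scales_um = c(4, 8, 16),
                                vesselness_threshold = 0.12,
                                morph_radius_voxels = 1,
                                min_component_voxels = 27,
                                alpha = 0.5, beta = 0.5) {
  stopifnot(all(frangi_scales_um > 0), !is.unsorted(frangi_scales_um),
            vesselness_threshold > 0, vesselness_threshold < 1)
  structure(list(frangi_scales_um = frangi_scales_um,
                 vesselness_threshold = vesselness_threshold,
                 morph_radius_voxels = morph_radius_voxels,
                 min_component_voxels = min_component_voxels,
                 alpha = alpha, beta = beta),
            class = "segmentation_config")
}

# Shear-resample a volume along z by a per-column depth map (in um):
# column (y, x) is shifted so that depth zmap(y, x) maps to z = 0. Linear
# interpolation; binary volumes should be re-binarized by the caller.
.shear_volume <- function(vol, zmap_um, voxel_size_um) {
  d <- dim(vol)
  out <- array(0, d)
  z_old <- seq_len(d[1])
  shift_vox <- zmap_um / voxel_size_um
  for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    s <- shift_vox[y, x]
    src <- z_old + s                       # sample original at z + shift
    lo <- floor(src)
    w <- src - lo
    v_lo <- ifelse(lo >= 1 & lo <= d[1], vol[pmin(pmax(lo, 1), d[1]), y, x], 0)
    hi <- lo + 1
    v_hi <- ifelse(hi >= 1 & hi <= d[1], vol[pmin(pmax(hi, 1), d[1]), y, x], 0)
    v_lo[lo < 1 | lo > d[1]] <- 0
    v_hi[hi < 1 | hi > d[1]] <- 0
    out[, y, x] <- (1 - w) * v_lo + w * v_hi
  }
  out
}

#' Apply a known tilt to a volume (phantom helper)
#'
#' Shears each (y, x) column down by `a * x + b * y` micrometers, emulating a
#' tilted cranial-window surface. [align_surface_plane()] inverts this.
#'
#' @param vol 3D array.
#' @param slope_x,slope_y tilt slopes, um of depth per um of x/y.
#' @param voxel_size_um voxel size.
#' @return sheared volume (same dimension).
#' @export
tilt_volume <- function(vol, slope_x = 0, slope_y = 0, voxel_size_um = 4) {
  .check_volume(vol)
  d <- dim(vol)
  xs <- (seq_len(d[3]) - 1) * voxel_size_um
  ys <- (seq_len(d[2]) - 1) * voxel_size_um
  zmap <- -outer(ys * slope_y, xs * slope_x, "+")
  .shear_volume(vol * 1.0, zmap, voxel_size_um)
}

#' Align the cortical surface to a horizontal plane
#'
#' Detects the surface as the first suprathreshold voxel down each (y, x)
#' column (threshold by Otsu's method), fits a least-squares plane
#' `z = a*x + b*y + c` to the detected depths, and shear-resamples the
#' volume (linear interpolation) so that the fitted surface maps to z = 0.
#' This makes equal-depth layer division well defined.
#'
#' @param vol 3D intensity array (z, y, x).
#' @param voxel_size_um voxel size, micrometers.
#' @param max_missing_frac error if more than this fraction of columns has
#'   no detectable surface (default 0.2).
#' @param min_run consecutive suprathreshold voxels required below the
#'   first crossing for it to count as tissue (default 5); isolated bright
#'   noise voxels do not qualify as a surface.
#' @return object of class `alignment_result`: `tilt_plane` (a, b, c in um),
#'   `resampled_volume`, `residual_rms_um`, `surface_aligned = TRUE`.
#' @export
align_surface_plane <- function(vol, voxel_size_um = 4, max_missing_frac = 0.2,
                                min_run = 5L) {
  .check_volume(vol)
  d <- dim(vol)
  thr <- .otsu(vol)
  first_hit <- apply(vol >= thr, c(2, 3), function(col) {
    r <- rle(col)
    ends <- cumsum(r$lengths)
    i <- which(r$values & r$lengths >= min_run)
    if (length(i)) ends[i[1]] - r$lengths[i[1]] + 1L else NA_integer_
  })
  miss <- mean(is.na(first_hit))
  if (miss > max_missing_frac)
    stop("surface detection failed: ", round(100 * miss),
         "% of columns have no detectable surface", call. = FALSE)
  ys <- rep((seq_len(d[2]) - 1) * voxel_size_um, times = d[3])
  xs <- rep((seq_len(d[3]) - 1) * voxel_size_um, each = d[2])
  zs <- (as.vector(first_hit) - 1) * voxel_size_um
  fit <- lm(zs ~ xs + ys)
  cf <- coef(fit)                      # c, a, b
  plane <- c(a = unname(cf["xs"]), b = unname(cf["ys"]),
             c = unname(cf["(Intercept)"]))
  zmap <- outer((seq_len(d[2]) - 1) * voxel_size_um * plane["b"],
                (seq_len(d[3]) - 1) * voxel_size_um * plane["a"], "+") +
    plane["c"]
  res <- .shear_volume(vol * 1.0, zmap, voxel_size_um)
  structure(list(tilt_plane = plane, resampled_volume = res,
                 residual_rms_um = sqrt(mean(stats::residuals(fit)^2,
                                             na.rm = TRUE)),
                 voxel_size_um = voxel_size_um, surface_aligned = TRUE),
            class = "alignment_result")
}

#' Multiscale Frangi vesselness segmentation (3D)
#'
#' For each scale sigma the volume is Gaussian-smoothed, the
#' scale-normalized Hessian is formed by central differences, and its
#' eigenvalues (|l1| <= |l2| <= |l3|) feed the tubular vesselness
#' `(1 - exp(-Ra^2/2a^2)) * exp(-Rb^2/2b^2) * (1 - exp(-S^2/2c^2))`
#' for bright structures (l2, l3 < 0), with Ra = |l2|/|l3|,
#' Rb = |l1|/sqrt(|l2 l3|), S the Frobenius norm, and c half the maximum S
#' over all scales (one global constant, so weak blurred-tail responses at
#' mismatched scales are not rescaled up). The response is maximized over
#' scales and binarized at `vesselness_threshold` times the global maximum.
#'
#' @param vol 3D intensity array.
#' @param cfg a [segmentation_config()].
#' @param voxel_size_um voxel size, micrometers.
#' @return logical 3D array (vessel mask).
#' @export
frangi_segment <- function(vol, cfg = segmentation_config(), voxel_size_um = 4) {
  .check_volume(vol)
  if (max(vol) == min(vol))
    stop("constant volume: vesselness undefined", call. = FALSE)
  d <- dim(vol)
  per_scale <- vector("list", length(cfg$frangi_scales_um))
  for (si in seq_along(cfg$frangi_scales_um)) {
    scale_um <- cfg$frangi_scales_um[si]
    sigma <- scale_um / voxel_size_um
    s <- gauss_smooth(vol, sigma)
    d1z <- (.shift3c(s, -1, 0, 0) - .shift3c(s, 1, 0, 0)) / 2
    d1y <- (.shift3c(s, 0, -1, 0) - .shift3c(s, 0, 1, 0)) / 2
    d1x <- (.shift3c(s, 0, 0, -1) - .shift3c(s, 0, 0, 1)) / 2
    hzz <- .shift3c(s, -1, 0, 0) - 2 * s + .shift3c(s, 1, 0, 0)
    hyy <- .shift3c(s, 0, -1, 0) - 2 * s + .shift3c(s, 0, 1, 0)
    hxx <- .shift3c(s, 0, 0, -1) - 2 * s + .shift3c(s, 0, 0, 1)
    hzy <- (.shift3c(d1z, 0, -1, 0) - .shift3c(d1z, 0, 1, 0)) / 2
    hzx <- (.shift3c(d1z, 0, 0, -1) - .shift3c(d1z, 0, 0, 1)) / 2
    hyx <- (.shift3c(d1y, 0, 0, -1) - .shift3c(d1y, 0, 0, 1)) / 2
    nrm <- sigma^2                      # gamma = 2 scale normalization
    ev <- sym3_eigenvalues_cpp(as.numeric(hzz) * nrm, as.numeric(hyy) * nrm,
                               as.numeric(hxx) * nrm, as.numeric(hzy) * nrm,
                               as.numeric(hzx) * nrm, as.numeric(hyx) * nrm)
    l1 <- ev[, 1]; l2 <- ev[, 2]; l3 <- ev[, 3]
    S2 <- l1^2 + l2^2 + l3^2
    ra2 <- (l2 / l3)^2
    rb2 <- l1^2 / pmax(abs(l2 * l3), .Machine$double.eps)
    v <- (1 - exp(-ra2 / (2 * cfg$alpha^2))) * exp(-rb2 / (2 * cfg$beta^2))
    v[l2 > 0 | l3 > 0] <- 0
    v[!is.finite(v)] <- 0
    per_scale[[si]] <- list(v = v, S2 = S2)
  }
  cc2 <- max(vapply(per_scale, function(p) max(p$S2), numeric(1))) / 4
  best <- array(0, d)
  for (p in per_scale)
    best <- pmax(best, array(p$v * (1 - exp(-p$S2 / (2 * cc2))), d))
  best >= cfg$vesselness_threshold * max(best)
}

#' Morphological denoising of a binary vessel mask
#'
#' Closing (dilation then erosion) with a spherical structuring element,
#' followed by removal of 26-connected components smaller than
#' `min_component_voxels`.
#'
#' @param binary logical 3D array.
#' @param cfg a [segmentation_config()].
#' @return logical 3D array.
#' @export
morph_denoise <- function(binary, cfg = segmentation_config()) {
  .check_volume(binary, "binary")
  if (!is.logical(binary)) binary <- binary > 0
  out <- .erode3(.dilate3(binary, cfg$morph_radius_voxels),
                 cfg$morph_radius_voxels)
  lab <- .label3(out)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= cfg$min_component_voxels)
  out & array(lab %in% keep, dim(out))
}
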