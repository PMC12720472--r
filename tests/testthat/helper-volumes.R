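# Shared fixture builders: small digital tubes rendered in code.

# Mark every voxel within radius r of the polyline sampled in `pts`
# (n x 3 matrix of z, y, x voxel coordinates).
stamp_tube <- function(vol, pts, r) {
  d <- dim(vol)
  for (i in seq_len(nrow(pts))) {
    p <- pts[i, ]
    zr <- max(1, floor(p[1] - r)):min(d[1], ceiling(p[1] + r))
    yr <- max(1, floor(p[2] - r)):min(d[2], ceiling(p[2] + r))
    xr <- max(1, floor(p[3] - r)):min(d[3], ceiling(p[3] + r))
    for (z in zr) for (y in yr) for (x in xr)
      if ((z - p[1])^2 + (y - p[2])^2 + (x - p[3])^2 <= r^2)
        vol[z, y, x] <- TRUE
  }
  vol
}

# Straight vertical tube spanning z = z0..z1 at the lateral centre.
straight_tube <- function(d, r, z0 = 5, z1 = d[1] - 4) {
  vol <- array(FALSE, d)
  cy <- (d[2] + 1L) %/% 2L
  cx <- (d[3] + 1L) %/% 2L
  stamp_tube(vol, cbind(seq(z0, z1, by = 0.5), cy, cx), r)
}

# Five ROI boxes tiling a square frame, corners plus centre.
frame_rois <- function(ny, nx) {
  m <- floor(min(ny, nx) * 0.42)
  data.frame(y0 = c(4, 4, ny - m, ny - m, floor(ny / 3)),
             x0 = c(4, nx - m, 4, nx - m, floor(nx / 3)),
             y1 = c(4 + m, 4 + m, ny - 4, ny - 4, floor(ny / 3) + m),
             x1 = c(4 + m, nx - 4, 4 + m, nx - 4, floor(nx / 3) + m))
}
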