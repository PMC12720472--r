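# Shared array helpers for (z, y, x) volumes.

.check_volume <- function(vol, name = "volume") {
  if (!is.array(vol) || length(dim(vol)) != 3L)
    stop(name, " must be a 3D array with dim (z, y, x)", call. = FALSE)
  invisible(vol)
}

.as_int_volume <- function(vol) {
  v <- vol
  storage.mode(v) <- "integer"
  v
}

# Index a 3D array along one axis.
.index_axis <- function(a, axis, idx) {
  switch(axis,
         a[idx, , , drop = FALSE],
         a[, idx, , drop = FALSE],
         a[, , idx, drop = FALSE])
}

# Separable 1D convolution along `axis` with replicate (edge-clamp) padding.
.conv_axis <- function(a, k, axis) {
  n <- dim(a)[axis]
  half <- (length(k) - 1L) %/% 2L
  out <- array(0, dim(a))
  for (j in seq_along(k)) {
    idx <- pmin(pmax(seq_len(n) + (j - 1L - half), 1L), n)
    out <- out + k[j] * .index_axis(a, axis, idx)
  }
  out
}

.gauss_kernel <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

#' Gaussian smoothing of a 3D volume
#'
#' Separable Gaussian filtering with edge-replicate padding, used by the
#' vesselness filter and available for pre-smoothing noisy stacks.
#'
#' @param vol numeric 3D array (z, y, x).
#' @param sigma_vox standard deviation in voxels (scalar, isotropic).
#' @return smoothed array of the same dimension.
#' @export
gauss_smooth <- function(vol, sigma_vox) {
  .check_volume(vol)
  if (sigma_vox <= 0) return(vol)
  k <- .gauss_kernel(sigma_vox)
  for (axis in 1:3) vol <- .conv_axis(vol, k, axis)
  vol
}

# Shift a 3D array by (dz, dy, dx), filling exposed cells with `fill`.
.shift3 <- function(a, dz, dy, dx, fill = 0) {
  d <- dim(a)
  out <- array(fill, d)
  src <- tgt <- vector("list", 3)
  off <- c(dz, dy, dx)
  for (i in 1:3) {
    n <- d[i]
    if (off[i] >= 0) {
      tgt[[i]] <- seq_len(n - off[i]) + off[i]
      src[[i]] <- seq_len(n - off[i])
    } else {
      tgt[[i]] <- seq_len(n + off[i])
      src[[i]] <- seq_len(n + off[i]) - off[i]
    }
    if (abs(off[i]) >= n) return(out)
  }
  out[tgt[[1]], tgt[[2]], tgt[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# Shift with edge-replicate padding (for derivative stencils: avoids the
# artificial steps a zero fill would create at the volume faces).
.shift3c <- function(a, dz, dy, dx) {
  d <- dim(a)
  idx <- function(n, off) pmin(pmax(seq_len(n) - off, 1L), n)
  a[idx(d[1], dz), idx(d[2], dy), idx(d[3], dx), drop = FALSE]
}

.ball_offsets <- function(radius) {
  r <- as.integer(radius)
  g <- expand.grid(dz = -r:r, dy = -r:r, dx = -r:r)
  g[g$dz^2 + g$dy^2 + g$dx^2 <= radius^2, , drop = FALSE]
}

.dilate3 <- function(binary, radius) {
  offs <- .ball_offsets(radius)
  out <- array(FALSE, dim(binary))
  for (i in seq_len(nrow(offs)))
    out <- out | .shift3(binary, offs$dz[i], offs$dy[i], offs$dx[i], fill = FALSE)
  out
}

.erode3 <- function(binary, radius) !.dilate3(!binary, radius)

# Otsu threshold on 256 bins (between-class variance maximisation).
.otsu <- function(x) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(255L, as.integer((x - rng[1]) / diff(rng) * 256)) + 1L, 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(256L))
  mu_t <- mu[256L]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- 0
  k <- which.max(sb)
  rng[1] + (k - 0.5) / 256 * diff(rng)
}

# Connected-component labelling (default 26-connectivity).
.label3 <- function(binary, connectivity = 26L) {
  lab <- label_components_cpp(.as_int_volume(binary), dim(binary),
                              as.integer(connectivity))
  array(lab, dim(binary))
}
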