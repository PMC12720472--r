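# Laser speckle contrast imaging: spatial-contrast perfusion maps,
# baseline-relative Delta-CBF traces, and cerebrovascular-reactivity metrics.

# 2D moving-window box sums with reflected padding, applied per frame.
.box_stats <- function(frame, window) {
  half <- window %/% 2
  d <- dim(frame)
  refl <- function(n) {
    i <- seq_len(n + 2 * half) - half
    i[i < 1] <- 2 - i[i < 1]
    i[i > n] <- 2 * n - i[i > n]
    i
  }
  pad <- frame[refl(d[1]), refl(d[2])]
  n1 <- d[1] + 2 * half; n2 <- d[2] + 2 * half
  cs <- rbind(0, apply(pad, 2, cumsum))
  rs <- cs[(1 + window):(n1 + 1), , drop = FALSE] -
    cs[1:(n1 + 1 - window), , drop = FALSE]
  cs2 <- cbind(0, t(apply(rs, 1, cumsum)))
  cs2[, (1 + window):(n2 + 1), drop = FALSE] -
    cs2[, 1:(n2 + 1 - window), drop = FALSE]
}

#' Spatial speckle contrast and perfusion maps
#'
#' Per frame, the local speckle contrast `K = sd / mean` over a
#' `window x window` neighbourhood (default 5x5, with reflected edge
#' padding), converted to a relative perfusion index `1/K^2`. Windows with
#' zero local mean or zero contrast (saturated/static regions) are masked
#' as NA rather than propagated.
#'
#' @param stack an `lsci_stack` (from [simulate_lsci_stack()] or built from
#'   a TIFF frame stack) or a (t, y, x) array.
#' @param window spatial binning width in pixels (default 5).
#' @return list: `perfusion` (t, y, x array, 1/K^2), `contrast` (K),
#'   `t_min` frame times (if available).
#' @export
spatial_contrast <- function(stack, window = 5L) {
  frames <- if (inherits(stack, "lsci_stack")) stack$frames else stack
  .check_volume(frames, "frames")
  d <- dim(frames)
  if (d[2] < window || d[3] < window)
    stop("frame dimensions smaller than the contrast window", call. = FALSE)
  npx <- window^2
  K <- P <- array(NA_real_, d)
  for (i in seq_len(d[1])) {
    f <- frames[i, , ]
    s1 <- .box_stats(f, window)
    s2 <- .box_stats(f^2, window)
    mu <- s1 / npx
    v <- pmax(s2 / npx - mu^2, 0) * npx / (npx - 1)
    k <- sqrt(v) / mu
    k[mu <= 0] <- NA
    p <- 1 / k^2
    p[!is.finite(p)] <- NA               # K = 0: saturated, masked
    K[i, , ] <- k
    P[i, , ] <- p
  }
  list(perfusion = P, contrast = K,
       t_min = if (inherits(stack, "lsci_stack")) stack$t_min else NULL)
}

#' Baseline-relative Delta-CBF trace from a perfusion stack
#'
#' For each frame, `dCBF% = 100 * (P(t) - P_base) / P_base` where `P(t)` is
#' the mean perfusion in an ROI and `P_base` its mean over the pre-stimulus
#' baseline window; traces are averaged across ROIs.
#'
#' @param perfusion (t, y, x) perfusion array (from [spatial_contrast()]).
#' @param t_min frame times in minutes, stimulus onset at 0.
#' @param rois data.frame of 2D ROI boxes `y0,x0,y1,x1` (1-based inclusive);
#'   customarily 5 ROIs per subject within the microvasculature.
#' @param baseline_window_min (start, end) of the pre-stimulus baseline,
#'   minutes (default c(-5, 0)).
#' @return object of class `cvr_trace`: data.frame `t_min, dcbf_pct` plus
#'   attributes `baseline_window_min`, `n_rois`.
#' @export
delta_cbf_trace <- function(perfusion, t_min, rois,
                            baseline_window_min = c(-5, 0)) {
  .check_volume(perfusion, "perfusion")
  if (is.null(nrow(rois)) || nrow(rois) < 1)
    stop("at least one ROI is required", call. = FALSE)
  if (baseline_window_min[2] > 0)
    stop("baseline window must be wholly pre-onset", call. = FALSE)
  # half-open window: the onset frame belongs to the response, not baseline
  base_sel <- t_min >= baseline_window_min[1] & t_min < baseline_window_min[2]
  if (sum(base_sel) < 3)
    stop("baseline window must contain at least 3 frames", call. = FALSE)
  d <- dim(perfusion)
  traces <- vapply(seq_len(nrow(rois)), function(i) {
    r <- rois[i, ]
    if (r$y0 < 1 || r$x0 < 1 || r$y1 > d[2] || r$x1 > d[3])
      stop("ROI outside frame", call. = FALSE)
    # harmonic ROI pooling: 1 / mean(K^2), which inverts the ROI-pooled
    # squared contrast once instead of per pixel and so avoids the convexity
    # bias of averaging noisy per-pixel 1/K^2 values
    p <- 1 / apply(1 / perfusion[, r$y0:r$y1, r$x0:r$x1, drop = FALSE],
                   1, mean, na.rm = TRUE)
    pb <- mean(p[base_sel])
    100 * (p - pb) / pb
  }, numeric(d[1]))
  out <- data.frame(t_min = t_min, dcbf_pct = rowMeans(traces))
  structure(out, class = c("cvr_trace", "data.frame"),
            baseline_window_min = baseline_window_min, n_rois = nrow(rois))
}

#' Cerebrovascular reactivity metrics
#'
#' Quantifies a Delta-CBF response with three metrics: the peak response
#' `dCBF_p` (extremum of the smoothed post-onset trace; maximum for
#' dilation, minimum for constriction), the time to plateau `t_P` (first
#' time the smoothed trace reaches 95% of |dCBF_p| and stays there for at
#' least 2 consecutive minutes), and the integrated reactivity `IR`
#' (trapezoidal integral of the raw trace from onset to the end of the
#' recording, % x min, signed).
#'
#' @param trace a `cvr_trace` (or data.frame with `t_min`, `dcbf_pct`).
#' @param direction `"dilation"` or `"constriction"`.
#' @param smooth_min moving-average width for metric extraction, minutes
#'   (default 1).
#' @param plateau_frac plateau band as a fraction of the plateau level
#'   (default 0.95).
#' @param plateau_dwell_min minimum dwell inside the band, minutes (default 2).
#' @param plateau_tail_min trailing window whose median of the smoothed
#'   trace estimates the plateau level the band refers to (default 3;
#'   a robust reference, insensitive to the noise maximum).
#' @return object of class `cvr_metrics`: list with `t_p_min`, `dcbf_p_pct`,
#'   `ir_au`, and `t_p_flag` (TRUE when the trace never settles in the band
#'   and t_P falls back to the time of the extremum).
#' @export
cvr_metrics <- function(trace, direction = c("dilation", "constriction"),
                        smooth_min = 1, plateau_frac = 0.95,
                        plateau_dwell_min = 2, plateau_tail_min = 3) {
  direction <- match.arg(direction)
  t <- trace$t_min
  y <- trace$dcbf_pct
  post <- t >= 0
  if (!any(post)) stop("no post-onset samples", call. = FALSE)
  dt <- median(diff(t))
  h <- max(0L, round(smooth_min / dt / 2))
  n <- length(y)
  cs <- c(0, cumsum(y))
  lo <- pmax(1L, seq_len(n) - h)
  hi <- pmin(n, seq_len(n) + h)
  ys <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)   # centred MA, shrinking at edges
  sgn <- if (direction == "dilation") 1 else -1
  gp <- sgn * ys[post]; tp <- t[post]
  peak <- max(gp)
  ir <- sum(diff(tp) * (head(y[post], -1) + y[post][-1]) / 2)
  if (abs(peak) < .Machine$double.eps^0.5) {
    return(structure(list(t_p_min = NA_real_, dcbf_p_pct = 0, ir_au = ir,
                          t_p_flag = TRUE), class = "cvr_metrics"))
  }
  m <- length(gp)
  tail_n <- min(m, max(1L, round(plateau_tail_min / dt)))
  level <- median(gp[(m - tail_n + 1L):m])
  dwell <- max(1L, round(plateau_dwell_min / dt))
  t_p <- NA_real_
  flag <- FALSE
  if (level > 0) {
    band_lv <- plateau_frac * level
    # rolling forward mean over the dwell window (shrinking near the end)
    cg <- c(0, cumsum(gp))
    hi2 <- pmin(m, seq_len(m) + dwell - 1L)
    fmean <- (cg[hi2 + 1L] - cg[seq_len(m)]) / (hi2 - seq_len(m) + 1L)
    cand <- which(gp >= band_lv & fmean >= band_lv)
    if (length(cand)) t_p <- tp[cand[1]]
  }
  if (is.na(t_p)) {
    t_p <- tp[which.max(gp)]
    flag <- TRUE
  }
  structure(list(t_p_min = t_p, dcbf_p_pct = sgn * peak, ir_au = ir,
                 t_p_flag = flag), class = "cvr_metrics")
}

#' @export
print.cvr_metrics <- function(x, ...) {
  cat(sprintf("CVR metrics: t_P = %.2f min%s, dCBF_p = %.2f%%, IR = %.1f %%*min\n",
              x$t_p_min, if (x$t_p_flag) " (flagged)" else "",
              x$dcbf_p_pct, x$ir_au))
  invisible(x)
}

#' Stimulus-correlation pixel mask
#'
#' Per pixel, the Pearson correlation between its perfusion time course and
#' a boxcar stimulus regressor (0 during the pre-window, 1 during the
#' post-window); pixels with `|r| >= threshold` enter the mask. Pixels with
#' zero temporal variance are excluded.
#'
#' @param perfusion (t, y, x) perfusion array.
#' @param t_min frame times, minutes.
#' @param pre_window,post_window (start, end) minutes of the two periods;
#'   each must cover at least 3 frames.
#' @param threshold correlation magnitude cut-off (default 0.5).
#' @return logical (y, x) matrix.
#' @export
correlation_mask <- function(perfusion, t_min, pre_window, post_window,
                             threshold = 0.5) {
  .check_volume(perfusion, "perfusion")
  pre <- t_min >= pre_window[1] & t_min <= pre_window[2]
  post <- t_min >= post_window[1] & t_min <= post_window[2]
  if (sum(pre) < 3 || sum(post) < 3)
    stop("each window must contain at least 3 frames", call. = FALSE)
  sel <- pre | post
  reg <- as.numeric(post[sel])
  d <- dim(perfusion)
  ts <- matrix(perfusion[sel, , ], nrow = sum(sel))
  mu <- colMeans(ts)
  cts <- sweep(ts, 2, mu)
  sy <- sqrt(colSums(cts^2))
  creg <- reg - mean(reg)
  r <- colSums(cts * creg) / (sy * sqrt(sum(creg^2)))
  r[sy == 0 | !is.finite(r)] <- 0
  matrix(abs(r) >= threshold, d[2], d[3])
}
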