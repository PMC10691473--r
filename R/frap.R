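#' FRAP intensity series
#'
#' Container for the per-frame raw intensities of one cell around a bleach
#' event: the targeted chromocenter, the whole nucleus (used for
#' acquisition-photobleaching correction) and a dark background region. The
#' bleach occurs between frames `n_pre - 1` and `n_pre` (0-based: between
#' the last pre-bleach and the first post-bleach sample).
#'
#' @param times Time of each frame in seconds from the first frame.
#' @param chromo_raw,nucleus_raw,background_raw Raw intensity series.
#' @param n_pre Number of pre-bleach frames (>= 1).
#' @param cell_id Cell label.
#' @return An object of class `frap_series`. `initial_chromo_intensity`
#'   (the absolute pre-bleach chromocenter mean, an expression proxy) is
#'   computed on construction.
#' @export
frap_series <- function(times, chromo_raw, nucleus_raw, background_raw,
                        n_pre = 5, cell_id = "cell") {
  n <- length(times)
  if (length(chromo_raw) != n || length(nucleus_raw) != n ||
      length(background_raw) != n)
    stop("all series must have the same length")
  if (n_pre < 1 || n_pre >= n)
    stop("n_pre must be >= 1 and smaller than the series length")
  structure(list(times = as.numeric(times), chromo_raw = as.numeric(chromo_raw),
                 nucleus_raw = as.numeric(nucleus_raw),
                 background_raw = as.numeric(background_raw),
                 n_pre = as.integer(n_pre), cell_id = cell_id,
                 initial_chromo_intensity = mean(chromo_raw[seq_len(n_pre)])),
            class = "frap_series")
}

#' Extract FRAP series from a volumetric movie
#'
#' Measures per-frame intensities from a `y x x x z x t` stack: the
#' chromocenter and nucleus series are the mean over their masks of the
#' Z-summed image; the background series is the mean of the background
#' region. Masks are drawn on the maximum projection over Z and T, so a
#' chromocenter mask is the union of the focus' track (toy-movie mode; real
#' manual ROI drawing is out of scope).
#'
#' @param stack 4D array (`y, x, z, t`) or 3D array (`y, x, t`) for
#'   single-plane data.
#' @param chromo_mask,nucleus_mask,background_mask Logical matrices of the
#'   stack's XY shape.
#' @param times Frame times in seconds; defaults to
#'   `(0:(n_t-1)) * frame_interval`.
#' @param frame_interval Used when `times` is missing.
#' @param n_pre Number of pre-bleach frames.
#' @param cell_id Cell label.
#' @return A [frap_series()] object.
#' @export
project_and_measure <- function(stack, chromo_mask, nucleus_mask,
                                background_mask, times = NULL,
                                frame_interval = 6.15, n_pre = 5,
                                cell_id = "cell") {
  d <- dim(stack)
  if (length(d) == 3L) {
    stack <- array(stack, dim = c(d[1], d[2], 1L, d[3]))
    d <- dim(stack)
  }
  if (length(d) != 4L) stop("stack must be a (y, x, z, t) or (y, x, t) array")
  for (m in list(chromo_mask, nucleus_mask, background_mask)) {
    if (!is.logical(m) || !identical(dim(m), d[1:2]))
      stop("masks must be logical matrices matching the stack's XY shape")
    if (!any(m)) stop("empty mask")
  }
  n_t <- d[4]
  meas <- function(mask) vapply(seq_len(n_t), function(t_i) {
    z_sum <- apply(stack[, , , t_i, drop = FALSE], c(1, 2), sum)
    mean(z_sum[mask])
  }, numeric(1))
  if (is.null(times)) times <- (seq_len(n_t) - 1) * frame_interval
  frap_series(times = times, chromo_raw = meas(chromo_mask),
              nucleus_raw = meas(nucleus_mask),
              background_raw = meas(background_mask),
              n_pre = n_pre, cell_id = cell_id)
}

#' Background-subtract, normalize and photobleach-correct a FRAP series
#'
#' Applies the standard double-normalization: background is subtracted from
#' both the chromocenter and nucleus series, each is normalized to its own
#' pre-bleach mean, and the normalized chromocenter series is divided frame
#' by frame by the normalized nucleus series, cancelling any multiplicative
#' acquisition-photobleaching decay shared by the two. The corrected curve
#' has pre-bleach mean 1 by construction.
#'
#' Cells whose background-subtracted nuclear signal is not strictly positive
#' at every frame are flagged excluded (`ok = FALSE`), mirroring the
#' exclusion of cells with excessive movement from real analyses.
#'
#' @param series A [frap_series()] object.
#' @return A list of class `frap_corrected`: `times`, `curve`, `n_pre`,
#'   `cell_id`, `initial_chromo_intensity`, `ok`.
#' @export
correct_series <- function(series) {
  stopifnot(inherits(series, "frap_series"))
  pre <- seq_len(series$n_pre)
  chromo <- series$chromo_raw - series$background_raw
  nucleus <- series$nucleus_raw - series$background_raw
  ok <- all(nucleus > 0) && mean(chromo[pre]) > 0
  curve <- if (ok) {
    (chromo / mean(chromo[pre])) / (nucleus / mean(nucleus[pre]))
  } else rep(NA_real_, length(chromo))
  structure(list(times = series$times, curve = curve, n_pre = series$n_pre,
                 cell_id = series$cell_id,
                 initial_chromo_intensity = series$initial_chromo_intensity,
                 ok = ok),
            class = "frap_corrected")
}

#' Average corrected FRAP curves and summarize recovery
#'
#' Averages per-cell corrected curves on their common time base and reads
#' the recovery summary off the mean curve: `i_min` is the mean-curve value
#' at the first post-bleach frame (bleach depth), `i_max` the maximum of the
#' 3-frame moving average of the post-bleach mean curve (maximal recovery),
#' and `t_half` the time, from the first post-bleach frame, at which the
#' mean curve first crosses the half-recovery level
#' `i_min + (i_max - i_min) / 2`, located by linear interpolation between
#' frames. Excluded cells (see [correct_series()]) never contribute.
#'
#' @param curves A list of `frap_corrected` objects (or `frap_series`
#'   objects, corrected on the fly) on a common time base.
#' @param smooth_k Moving-average width (frames) used for `i_max`.
#' @return An object of class `frap_fit`: `times`, `mean`, `sd`, `n_cells`,
#'   `n_excluded`, `n_pre`, and `summary` (`i_min`, `i_max`, `t_half`).
#' @export
average_and_summarize <- function(curves, smooth_k = 3) {
  if (inherits(curves, "frap_corrected") || inherits(curves, "frap_series"))
    curves <- list(curves)
  curves <- lapply(curves, function(x)
    if (inherits(x, "frap_series")) correct_series(x) else x)
  stopifnot(all(vapply(curves, inherits, TRUE, "frap_corrected")))
  ok <- vapply(curves, `[[`, TRUE, "ok")
  n_excluded <- sum(!ok)
  curves <- curves[ok]
  if (!length(curves)) stop("no usable curve after exclusions")
  times <- curves[[1]]$times
  n_pre <- curves[[1]]$n_pre
  for (cv in curves)
    if (!isTRUE(all.equal(cv$times, times)) || cv$n_pre != n_pre)
      stop("curves must share a common time base and n_pre")
  mat <- do.call(rbind, lapply(curves, `[[`, "curve"))
  mcurve <- colMeans(mat)
  scurve <- if (nrow(mat) > 1) apply(mat, 2, stats::sd) else rep(0, ncol(mat))
  if (n_pre >= length(mcurve)) stop("no post-bleach frames")
  post_idx <- (n_pre + 1L):length(mcurve)
  t_post <- times[post_idx] - times[post_idx[1L]]
  post <- mcurve[post_idx]
  i_min <- post[1L]
  sm <- stats::filter(post, rep(1 / smooth_k, smooth_k), sides = 2)
  sm[is.na(sm)] <- post[is.na(sm)]
  i_max <- max(as.numeric(sm))
  half <- i_min + (i_max - i_min) / 2
  t_half <- .first_crossing(t_post, post, half)
  structure(list(times = times, mean = mcurve, sd = scurve,
                 n_cells = length(curves), n_excluded = n_excluded,
                 n_pre = n_pre,
                 summary = c(i_min = i_min, i_max = i_max, t_half = t_half)),
            class = "frap_fit")
}

# first time y crosses level (from below), linear interpolation; 0 if already
# at/above the level at t[1]
.first_crossing <- function(t, y, level) {
  if (y[1L] >= level) return(0)
  above <- which(y >= level)
  if (!length(above)) return(NA_real_)
  i <- above[1L]
  t[i - 1L] + (level - y[i - 1L]) / (y[i] - y[i - 1L]) * (t[i] - t[i - 1L])
}

#' @export
print.frap_fit <- function(x, ...) {
  s <- x$summary
  cat(sprintf("FRAP recovery (%d cells, %d excluded)\n", x$n_cells, x$n_excluded))
  cat(sprintf("  I_min  %.3f\n  I_max  %.3f\n  t_1/2  %.1f s\n",
              s["i_min"], s["i_max"], s["t_half"]))
  invisible(x)
}

#' @export
plot.frap_fit <- function(x, ...) {
  graphics::plot(x$times, x$mean, type = "l", xlab = "time (s)",
                 ylab = "corrected intensity", ylim = range(0, 1.1, x$mean), ...)
  graphics::arrows(x$times, x$mean - x$sd, x$times, x$mean + x$sd,
                   length = 0.02, angle = 90, code = 3, col = "grey60")
  graphics::abline(v = x$times[x$n_pre + 1L], lty = 3)
  invisible(x)
}

#' Compare recovery between two groups of cells
#'
#' Reduces each cell's corrected curve to a scalar and compares the two
#' groups with a Mann-Whitney (Wilcoxon rank-sum) test. The default scalar
#' is the mean corrected intensity over the first `window_s` seconds after
#' the bleach (early recovery); per-cell `t_half` or `i_min` (first
#' post-bleach value) can be selected instead. The exact p-value is used for
#' group sizes up to 20 without ties; the normal approximation with tie
#' correction otherwise.
#'
#' @param group_a,group_b Lists of `frap_corrected` (or `frap_series`)
#'   objects.
#' @param alternative Alternative hypothesis for `group_a` relative to
#'   `group_b` ("less", "greater", "two.sided").
#' @param scalar Per-cell summary to compare.
#' @param window_s Early-recovery window in seconds (for
#'   `scalar = "early_mean"`).
#' @return A list: `statistic` (Mann-Whitney U for group_a), `p_value`,
#'   `scalars_a`, `scalars_b`, `alternative`, `scalar`.
#' @export
compare_recovery <- function(group_a, group_b,
                             alternative = c("less", "greater", "two.sided"),
                             scalar = c("early_mean", "t_half", "i_min"),
                             window_s = 60) {
  alternative <- match.arg(alternative)
  scalar <- match.arg(scalar)
  val <- function(group) vapply(group, function(x) {
    if (inherits(x, "frap_series")) x <- correct_series(x)
    if (!x$ok) return(NA_real_)
    post <- (x$n_pre + 1L):length(x$curve)
    t_post <- x$times[post] - x$times[post[1L]]
    switch(scalar,
      early_mean = mean(x$curve[post][t_post <= window_s]),
      i_min = x$curve[post][1L],
      t_half = {
        fit <- average_and_summarize(list(x))
        unname(fit$summary["t_half"])
      })
  }, numeric(1))
  a <- val(group_a); b <- val(group_b)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 3 || length(b) < 3) stop("each group needs >= 3 usable cells")
  exact <- length(a) <= 20 && length(b) <= 20 && !any(duplicated(c(a, b)))
  wt <- stats::wilcox.test(a, b, alternative = alternative, exact = exact,
                           correct = !exact)
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       scalars_a = a, scalars_b = b, alternative = alternative,
       scalar = scalar)
}
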