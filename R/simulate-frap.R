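#' Simulate FRAP intensity series
#'
#' Generates per-cell chromocenter / whole-nucleus / background intensity
#' series around a bleach event. The ground-truth chromocenter signal is 1
#' for the `n_pre` pre-bleach frames and
#' `I(t) = plateau - (plateau - depth) * exp(-t / tau)` afterwards, with
#' `t = 0` at the first post-bleach frame. The whole-nucleus signal decays as
#' `exp(-acq_bleach_rate * t_total)` from the first frame (acquisition
#' photobleaching), and the observed chromocenter raw intensity is
#' `I(t) * nucleus_decay * scale + background` with multiplicative Gaussian
#' noise of coefficient of variation `noise_cv`. Per-cell absolute scales are
#' log-normal, providing an expression proxy (`initial_chromo_intensity`)
#' for high/low-expression stratification.
#'
#' @param kin A [frap_kinetics()] object.
#' @param n_cells Number of cells to simulate.
#' @param seed Integer seed.
#' @param n_pre Number of pre-bleach frames.
#' @param n_frames Total frames per series.
#' @param frame_interval Sampling interval, seconds.
#' @param scale_mean Median absolute chromocenter intensity (counts).
#' @param scale_cv Log-scale spread of the per-cell intensity scale.
#' @return A list of class `frap_sim`: `series` (list of `frap_series`
#'   objects) and `truth` (per-cell data frame with the generating
#'   parameters).
#' @export
simulate_frap <- function(kin, n_cells, seed, n_pre = 5, n_frames = 100,
                          frame_interval = 6.15, scale_mean = 1000,
                          scale_cv = 0.3) {
  stopifnot(inherits(kin, "frap_kinetics"))
  if (n_pre < 1) stop("n_pre must be >= 1")
  if (n_frames <= n_pre) stop("n_frames must exceed n_pre")
  if (missing(seed)) stop("seed is required")
  with_seed(seed, {
    t_total <- (seq_len(n_frames) - 1) * frame_interval
    t_post <- pmax(0, t_total - n_pre * frame_interval)
    i_gt <- ifelse(seq_len(n_frames) <= n_pre, 1,
                   kin$plateau - (kin$plateau - kin$depth) * exp(-t_post / kin$tau))
    decay <- exp(-kin$acq_bleach_rate * t_total)
    series <- vector("list", n_cells)
    scales <- scale_mean * exp(stats::rnorm(n_cells, sd = scale_cv))
    for (i in seq_len(n_cells)) {
      mnoise <- function(n) 1 + stats::rnorm(n, sd = kin$noise_cv)
      chromo <- i_gt * decay * scales[i] * mnoise(n_frames) + kin$background_level
      nucleus <- 0.6 * scales[i] * decay * mnoise(n_frames) + kin$background_level
      background <- kin$background_level * mnoise(n_frames)
      series[[i]] <- frap_series(
        times = t_total, chromo_raw = chromo, nucleus_raw = nucleus,
        background_raw = background, n_pre = n_pre,
        cell_id = sprintf("cell_%03d", i))
    }
    truth <- data.frame(cell_id = sprintf("cell_%03d", seq_len(n_cells)),
                        plateau = kin$plateau, depth = kin$depth,
                        tau = kin$tau, t_half = kin$tau * log(2),
                        scale = scales, stringsAsFactors = FALSE)
    structure(list(series = series, truth = truth, kinetics = kin,
                   frame_interval = frame_interval, seed = seed),
              class = "frap_sim")
  })
}

#' Render a toy FRAP movie
#'
#' Builds a small volumetric time series (`y x x x z x t`) whose chromocenter
#' disk, nuclear region and dark corner reproduce a simulated
#' [frap_series()], so that [project_and_measure()] can be exercised without
#' real microscopy data. The chromocenter disk drifts slowly to emulate
#' chromocenter movement; masks should be drawn on the union of its track.
#'
#' @param series A `frap_series` object (e.g. from [simulate_frap()]).
#' @param side Image side in pixels.
#' @param n_z Number of Z planes.
#' @param radius Chromocenter disk radius in pixels.
#' @param drift Per-frame drift of the disk center, pixels.
#' @param seed Seed for the Poisson pixel noise (`NULL` for noiseless).
#' @return A list: `stack` (4D array), `chromo_mask`, `nucleus_mask`,
#'   `background_mask` (logical matrices).
#' @export
render_frap_movie <- function(series, side = 48, n_z = 5, radius = 5,
                              drift = 0.08, seed = NULL) {
  stopifnot(inherits(series, "frap_series"))
  n_t <- length(series$times)
  xg <- matrix(rep(seq_len(side), each = side), side)
  yg <- matrix(rep(seq_len(side), times = side), side)
  c0 <- side / 2
  nuc_r <- side / 2 - 2
  nucleus_mask <- (xg - c0)^2 + (yg - c0)^2 <= nuc_r^2
  chromo_mask <- matrix(FALSE, side, side)
  stack <- array(0, dim = c(side, side, n_z, n_t))
  bg_per_z <- series$background_raw / n_z
  for (t_i in seq_len(n_t)) {
    cx <- c0 + drift * (t_i - 1)
    cy <- c0 - drift * (t_i - 1)
    disk <- (xg - cx)^2 + (yg - cy)^2 <= radius^2
    chromo_mask <- chromo_mask | disk
    # chromocenter pixels carry the chromocenter signal; the rest of the
    # nucleus carries the nuclear signal; outside is background only
    frame <- matrix(bg_per_z[t_i], side, side)
    frame[nucleus_mask] <- (series$nucleus_raw[t_i] - series$background_raw[t_i]) / n_z +
      bg_per_z[t_i]
    frame[disk] <- (series$chromo_raw[t_i] - series$background_raw[t_i]) / n_z +
      bg_per_z[t_i]
    for (z_i in seq_len(n_z)) stack[, , z_i, t_i] <- frame
  }
  if (!is.null(seed))
    stack <- with_seed(seed, array(stats::rpois(length(stack), stack), dim = dim(stack)))
  background_mask <- matrix(FALSE, side, side)
  background_mask[1:4, 1:4] <- TRUE
  list(stack = stack, chromo_mask = chromo_mask, nucleus_mask = nucleus_mask,
       background_mask = background_mask)
}
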