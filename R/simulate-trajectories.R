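#' Simulate two-state single-molecule trajectories
#'
#' Generates photoactivated-molecule trajectories for `n_cells` cells under a
#' bound/free mixture. Each molecule draws its state from
#' `Bernoulli(f_bound)`, performs 2D lateral Brownian motion with per-axis
#' step variance `2 * D * dt`, and carries an independent axial coordinate
#' with the same coefficient. A trajectory ends when the molecule's axial
#' position leaves the detection slab `+/- focal_depth / 2` (defocalization)
#' or when it photobleaches (geometric lifetime, mean `mean_lifetime`
#' frames). Observed positions add i.i.d. Gaussian localization error
#' `loc_error` per axis. Molecules observed for fewer than 2 frames are
#' dropped from the trajectory table but kept in the ground truth, so that
#' the truth-label bound fraction is exactly the simulated `f_bound` and so
#' that detection counts can include singletons.
#'
#' Activation times are spread uniformly over a movie long enough to keep the
#' mean density near `target_density` localizations per frame, emulating
#' photoactivation tuned to about one localization per frame.
#'
#' @param params A [two_state_params()] object.
#' @param cfg An [imaging_config()] object.
#' @param n_cells,traj_per_cell Number of cells and photoactivated molecules
#'   per cell.
#' @param seed Integer seed; identical seeds give identical output.
#' @param mean_lifetime Mean photobleaching lifetime in frames.
#' @param target_density Target mean localizations per frame per movie.
#' @param margin Spawn margin from the ROI edge, um.
#' @return A list of class `smt_sim` with elements `trajectories` (data frame
#'   with columns `trajectory`, `frame`, `x_um`, `y_um`, `intensity`,
#'   `cell_id`), `truth` (one row per simulated molecule: `cell_id`,
#'   `trajectory`, `state`, `d_true`, `n_locs`, `observed`), `params`, `cfg`.
#' @export
simulate_trajectories <- function(params, cfg, n_cells, traj_per_cell, seed,
                                  mean_lifetime = 8, target_density = 1,
                                  margin = 2) {
  stopifnot(inherits(params, "two_state_params"), inherits(cfg, "imaging_config"))
  if (n_cells < 1 || traj_per_cell < 1)
    stop("n_cells and traj_per_cell must be >= 1")
  if (missing(seed)) stop("seed is required")
  with_seed(seed, {
    dt <- cfg$frame_interval
    half_z <- cfg$focal_depth / 2
    roi_um <- cfg$roi_pixels * cfg$pixel_size
    if (2 * margin >= roi_um) stop("margin too large for the ROI")
    n_frames_movie <- max(10L, ceiling(traj_per_cell * mean_lifetime /
                                         target_density))
    traj_rows <- vector("list", n_cells)
    truth_rows <- vector("list", n_cells)
    traj_counter <- 0L
    for (c_i in seq_len(n_cells)) {
      cell <- sprintf("cell_%03d", c_i)
      bound <- stats::runif(traj_per_cell) < params$f_bound
      res_t <- vector("list", traj_per_cell)
      d_true <- ifelse(bound, params$d_bound, params$d_free)
      n_locs <- integer(traj_per_cell)
      for (m in seq_len(traj_per_cell)) {
        lifetime <- 1L + stats::rgeom(1L, prob = 1 / mean_lifetime)
        if (params$switching && lifetime > 1L) {
          st <- integer(lifetime)
          st[1L] <- if (bound[m]) 1L else 0L
          flip <- stats::runif(lifetime - 1L) < params$switch_rate
          for (j in 2L:lifetime) st[j] <- if (flip[j - 1L]) 1L - st[j - 1L] else st[j - 1L]
          d_step <- ifelse(st[-lifetime] == 1L, params$d_bound, params$d_free)
        } else {
          d_step <- rep(d_true[m], max(0L, lifetime - 1L))
        }
        sd_step <- sqrt(2 * d_step * dt)
        # axial survival inside the detection slab
        z <- stats::runif(1L, -half_z, half_z)
        n_obs <- 1L
        if (lifetime > 1L) {
          z_path <- z + cumsum(stats::rnorm(lifetime - 1L, sd = sd_step))
          exit <- which(abs(z_path) > half_z)
          n_obs <- if (length(exit)) exit[1L] else lifetime
        }
        n_locs[m] <- n_obs
        if (n_obs < 2L) next
        x0 <- stats::runif(1L, margin, roi_um - margin)
        y0 <- stats::runif(1L, margin, roi_um - margin)
        sd_obs <- sd_step[seq_len(n_obs - 1L)]
        x <- x0 + c(0, cumsum(stats::rnorm(n_obs - 1L, sd = sd_obs)))
        y <- y0 + c(0, cumsum(stats::rnorm(n_obs - 1L, sd = sd_obs)))
        x_obs <- x + stats::rnorm(n_obs, sd = cfg$loc_error)
        y_obs <- y + stats::rnorm(n_obs, sd = cfg$loc_error)
        start <- sample.int(max(1L, n_frames_movie - n_obs + 1L), 1L) - 1L
        res_t[[m]] <- data.frame(
          trajectory = traj_counter + m,
          frame = start + seq_len(n_obs) - 1L,
          x_um = x_obs, y_um = y_obs,
          intensity = stats::rpois(n_obs, 300),
          cell_id = cell, stringsAsFactors = FALSE)
      }
      truth_rows[[c_i]] <- data.frame(
        cell_id = cell, trajectory = traj_counter + seq_len(traj_per_cell),
        state = ifelse(bound, "bound", "free"), d_true = d_true,
        n_locs = n_locs, observed = n_locs >= 2L, stringsAsFactors = FALSE)
      traj_rows[[c_i]] <- do.call(rbind, res_t[!vapply(res_t, is.null, TRUE)])
      traj_counter <- traj_counter + traj_per_cell
    }
    trajectories <- do.call(rbind, traj_rows[!vapply(traj_rows, is.null, TRUE)])
    if (is.null(trajectories))
      trajectories <- data.frame(trajectory = integer(), frame = integer(),
                                 x_um = numeric(), y_um = numeric(),
                                 intensity = numeric(), cell_id = character())
    rownames(trajectories) <- NULL
    structure(list(trajectories = trajectories,
                   truth = do.call(rbind, truth_rows),
                   params = params, cfg = cfg, seed = seed),
              class = "smt_sim")
  })
}

#' @export
print.smt_sim <- function(x, ...) {
  cat(sprintf("Simulated SMT dataset: %d cells, %d molecules (%d observed trajectories)\n",
              length(unique(x$truth$cell_id)), nrow(x$truth),
              length(unique(x$trajectories$trajectory))))
  cat(sprintf("  f_bound %.2f, d_bound %.3g, d_free %.3g um^2/s\n",
              x$params$f_bound, x$params$d_bound, x$params$d_free))
  invisible(x)
}

# Pixel-integrated Gaussian PSF weights over integer pixels lo..hi for a spot
# at continuous position pos (pixel units, pixel i spans [i, i+1)).
.integrated_gauss <- function(lo, hi, pos, sigma) {
  edges <- lo:(hi + 1L)
  diff(stats::pnorm(edges, mean = pos, sd = sigma))
}

#' Render a movie from trajectories
#'
#' Renders each localization as a pixel-integrated 2D Gaussian with total
#' expected photons `photons_per_spot` on a uniform Poisson background,
#' producing an unsigned 16-bit movie stack. Image axes follow the matrix
#' convention: `movie[row, col, frame]` with row = y pixel index + 1 and
#' col = x pixel index + 1; a position `x_um` maps to pixel unit
#' `x_um / pixel_size` where pixel `i` spans `[i, i + 1)`.
#'
#' @param trajectories Data frame with `frame`, `x_um`, `y_um` (one cell).
#' @param cfg An [imaging_config()] object.
#' @param photons_per_spot Expected photons per rendered molecule.
#' @param bg_photons Expected background photons per pixel.
#' @param seed Seed for the Poisson noise (required when `noise = TRUE`).
#' @param n_frames Number of frames; defaults to `max(frame) + 1`.
#' @param noise Apply Poisson noise. When `FALSE` the noiseless expected
#'   image (double) is returned, which is useful for photon-count checks.
#' @return A 3D array `roi_pixels x roi_pixels x n_frames`.
#' @export
render_movie <- function(trajectories, cfg, photons_per_spot = 300,
                         bg_photons = 20, seed = NULL, n_frames = NULL,
                         noise = TRUE) {
  stopifnot(inherits(cfg, "imaging_config"))
  np <- cfg$roi_pixels
  roi_um <- np * cfg$pixel_size
  n <- nrow(trajectories)
  if (n > 0) {
    if (any(trajectories$x_um < 0 | trajectories$x_um >= roi_um |
            trajectories$y_um < 0 | trajectories$y_um >= roi_um))
      stop("trajectory coordinates outside the ROI")
  }
  if (is.null(n_frames))
    n_frames <- if (n > 0) max(trajectories$frame) + 1L else 1L
  movie <- array(as.numeric(bg_photons), dim = c(np, np, n_frames))
  if (n > 0) {
    xs <- trajectories$x_um / cfg$pixel_size
    ys <- trajectories$y_um / cfg$pixel_size
    fr <- trajectories$frame
    reach <- ceiling(5 * cfg$psf_sigma)
    for (i in seq_len(n)) {
      if (fr[i] >= n_frames) next
      cx <- floor(xs[i]); cy <- floor(ys[i])
      x_lo <- max(0L, cx - reach); x_hi <- min(np - 1L, cx + reach)
      y_lo <- max(0L, cy - reach); y_hi <- min(np - 1L, cy + reach)
      wx <- .integrated_gauss(x_lo, x_hi, xs[i], cfg$psf_sigma)
      wy <- .integrated_gauss(y_lo, y_hi, ys[i], cfg$psf_sigma)
      patch <- photons_per_spot * outer(wy, wx)
      movie[(y_lo:y_hi) + 1L, (x_lo:x_hi) + 1L, fr[i] + 1L] <-
        movie[(y_lo:y_hi) + 1L, (x_lo:x_hi) + 1L, fr[i] + 1L] + patch
    }
  }
  if (noise) {
    if (is.null(seed)) stop("seed is required when noise = TRUE")
    movie <- with_seed(seed, {
      noisy <- stats::rpois(length(movie), movie)
      array(pmin(noisy, 65535L), dim = dim(movie))
    })
    storage.mode(movie) <- "integer"
  }
  movie
}
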