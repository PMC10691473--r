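#' Diffusion-coefficient grid
#'
#' Log-spaced grid of candidate diffusion coefficients for the state-array
#' inference. The default 100-point grid spans 0.01-100 um^2/s — from the
#' chromatin-bound regime (< 0.1 um^2/s) to free-HaloTag mobility
#' (> 10 um^2/s) — and is constructed so that no grid point falls exactly on
#' the 0.1 um^2/s bound threshold.
#'
#' @param n Number of grid points.
#' @param d_min,d_max Grid range, um^2/s.
#' @param loc_error One-axis localization error sigma, um (shared with the
#'   simulator's [imaging_config()]).
#' @return An object of class `diffusion_grid` with elements `d` and
#'   `loc_error`.
#' @export
diffusion_grid <- function(n = 100, d_min = 1e-2, d_max = 1e2,
                           loc_error = 0.035) {
  if (n < 2 || d_min <= 0 || d_max <= d_min) stop("invalid grid range")
  d <- 10^seq(log10(d_min), log10(d_max), length.out = n)
  if (any(abs(d - 0.1) < 1e-12))
    stop("grid must not contain the 0.1 um^2/s bound threshold exactly")
  structure(list(d = d, loc_error = loc_error), class = "diffusion_grid")
}

.chromdyn_cache <- new.env(parent = emptyenv())

#' Expected observed jumps before defocalization
#'
#' Monte-Carlo estimate of the mean number of jumps a Brownian molecule with
#' coefficient `D` is observed to make before its axial position first
#' leaves the detection slab `+/- dz / 2`, starting uniformly inside the
#' slab, capped at `max_jumps`. Observed trajectories over-represent slow
#' molecules both in number and in length; dividing state occupations by
#' this weight converts jump-level evidence back to molecule-level
#' occupations.
#'
#' With `bleach_survival < 1`, jump `j` is additionally weighted by the
#' probability `bleach_survival^j` that the fluorophore has not yet
#' photobleached (geometric lifetime), so the weight becomes the expected
#' number of jumps actually observed per activated molecule under both
#' defocalization and photobleaching; survivors at the cap receive the
#' closed-form geometric tail. A fixed internal seed makes the estimate
#' deterministic; results are cached per parameter set.
#'
#' @param D Diffusion coefficient(s), um^2/s (vectorized).
#' @param dt Frame interval, s.
#' @param dz Focal depth, um.
#' @param max_jumps Cap on the jump count.
#' @param n_mc Monte-Carlo sample size.
#' @param bleach_survival Per-frame fluorophore survival probability in
#'   (0, 1]; 1 disables the photobleaching weighting.
#' @return Numeric vector of expected jump counts, same length as `D`.
#' @export
defocalization_weight <- function(D, dt, dz, max_jumps = 7, n_mc = 1e5,
                                  bleach_survival = 1) {
  if (dz <= 0) stop("dz must be > 0")
  if (bleach_survival <= 0 || bleach_survival > 1)
    stop("bleach_survival must be in (0, 1]")
  key <- paste(format(c(D, dt, dz, max_jumps, n_mc, bleach_survival),
                      digits = 15), collapse = "|")
  if (!is.null(.chromdyn_cache[[key]])) return(.chromdyn_cache[[key]])
  s <- bleach_survival
  tail_w <- if (s < 1) s^(max_jumps + 1) / (1 - s) else 0
  full_w <- if (s < 1) s * (1 - s^max_jumps) / (1 - s) + tail_w
            else as.numeric(max_jumps)
  out <- with_seed(770011L, {
    vapply(D, function(d_i) {
      if (d_i == 0) return(full_w)
      z <- stats::runif(n_mc, -dz / 2, dz / 2)
      alive <- rep(TRUE, n_mc)
      jumps <- 0
      sd_step <- sqrt(2 * d_i * dt)
      for (j in seq_len(max_jumps)) {
        idx <- which(alive)
        if (!length(idx)) break
        z[idx] <- z[idx] + stats::rnorm(length(idx), sd = sd_step)
        alive[idx] <- abs(z[idx]) <= dz / 2
        jumps <- jumps + s^j * sum(alive[idx])
      }
      (jumps + tail_w * sum(alive)) / n_mc
    }, numeric(1))
  })
  .chromdyn_cache[[key]] <- out
  out
}

#' State-array inference of the diffusion-coefficient spectrum
#'
#' Fits, per cell, the posterior occupation of a fixed grid of diffusion
#' coefficients from single-molecule trajectories, under the regular
#' Brownian motion with localization error (RBME) likelihood, and derives
#' the chromatin-bound fraction (occupation below 0.1 um^2/s).
#'
#' The estimator is an expectation-maximization-style fixed point on the
#' mixture occupations. Writing `w_t` for the jump count of trajectory `t`
#' and `defoc(D_k)` for the expected observed jumps per activated molecule
#' in state `k` ([defocalization_weight()]), the E-step assigns
#' responsibilities `r[t, k] ∝ pi[k] * defoc(D_k) * exp(loglik(traj_t |
#' D_k))` — the prior for an *observed* trajectory is the jump-level
#' occupation, since slow molecules are over-represented among observed
#' trajectories and jumps — and the M-step converts the collected jump-level
#' evidence back to molecule counts:
#' `pi[k] ∝ sum_t w_t * r[t, k] / defoc(D_k)`. Iteration starts from the
#' uniform occupation and stops when the largest occupation change falls below
#' `tol` or after `max_iter` sweeps. Trajectories longer than `split_cap`
#' jumps are split; if the dataset exceeds `max_total_jumps` jumps,
#' trajectories are uniformly subsampled with a fixed seed.
#'
#' The defocalization weight folds in geometric photobleaching with mean
#' lifetime `mean_lifetime` frames (matching the simulator's default), so
#' that it equals the expected number of observed jumps per activated
#' molecule in each state; this is what makes the occupations molecule-level
#' fractions rather than jump-level ones.
#'
#' The aggregate spectrum is the jump-count-weighted mean of the per-cell
#' occupations.
#'
#' @param trajectories Data frame with columns `trajectory`, `frame`,
#'   `x_um`, `y_um` and optionally `cell_id` (one cell assumed if absent).
#' @param grid A [diffusion_grid()].
#' @param cfg An [imaging_config()]; supplies the frame interval. The
#'   localization error is taken from `grid$loc_error`.
#' @param max_iter,tol Fixed-point iteration controls.
#' @param split_cap Maximum jumps per trajectory before splitting.
#' @param max_total_jumps Cap on total jumps (uniform subsampling beyond).
#' @param mean_lifetime Mean photobleaching lifetime in frames assumed for
#'   the defocalization weight.
#' @param defoc_max_jumps Cap passed to [defocalization_weight()].
#' @param correct_defocalization Apply the defocalization weights; `FALSE`
#'   yields the uncorrected (jump-level) occupations, mainly for assessing
#'   the correction itself.
#' @return An object of class `state_array`; see [bound_fraction()],
#'   `coef()`, `summary()`, `plot()`.
#' @export
state_array <- function(trajectories, grid = diffusion_grid(),
                        cfg = imaging_config(), max_iter = 1000, tol = 1e-6,
                        split_cap = 100L, max_total_jumps = 1e6,
                        mean_lifetime = 8, defoc_max_jumps = 30,
                        correct_defocalization = TRUE) {
  stopifnot(inherits(grid, "diffusion_grid"), inherits(cfg, "imaging_config"))
  if (is.null(trajectories$cell_id)) trajectories$cell_id <- "cell_001"
  K <- length(grid$d)
  defoc <- if (correct_defocalization)
    defocalization_weight(grid$d, cfg$frame_interval,
                          cfg$focal_depth, max_jumps = defoc_max_jumps,
                          bleach_survival = 1 - 1 / mean_lifetime)
  else rep(1, K)
  cells <- unique(trajectories$cell_id)
  occ <- matrix(NA_real_, length(cells), K,
                dimnames = list(cells, signif(grid$d, 4)))
  n_traj <- integer(length(cells)); n_jumps <- integer(length(cells))
  n_detections <- as.integer(table(factor(trajectories$cell_id,
                                          levels = cells)))
  iters <- integer(length(cells)); converged <- logical(length(cells))
  skipped <- character()
  for (ci in seq_along(cells)) {
    tr <- trajectories[trajectories$cell_id == cells[ci], , drop = FALSE]
    chunks <- .jump_chunks(tr, cap = split_cap)
    if (is.null(chunks)) {
      warning("cell '", cells[ci], "' has no trajectory with >= 1 jump; skipped")
      skipped <- c(skipped, cells[ci])
      next
    }
    if (sum(chunks$n_jumps) > max_total_jumps) {
      keep <- with_seed(424242L, {
        ord <- sample.int(length(chunks$n_jumps))
        ord[cumsum(chunks$n_jumps[ord]) <= max_total_jumps]
      })
      sel <- chunks$chunk_id %in% keep
      remap <- match(chunks$chunk_id[sel], keep)
      chunks <- list(dx = chunks$dx[sel], dy = chunks$dy[sel],
                     chunk_id = remap,
                     n_jumps = chunks$n_jumps[keep],
                     traj_of_chunk = chunks$traj_of_chunk[keep])
    }
    L <- .rbme_loglik_grid(chunks, grid$d, grid$loc_error, cfg$frame_interval)
    A <- exp(L - apply(L, 1, max))
    w <- chunks$n_jumps
    p <- rep(1 / K, K)
    it <- 0L; conv <- FALSE
    while (it < max_iter) {
      it <- it + 1L
      Wm <- A * rep(p * defoc, each = nrow(A))
      R <- Wm / rowSums(Wm)
      num <- colSums(R * w) / defoc
      p_new <- num / sum(num)
      if (max(abs(p_new - p)) < tol) { p <- p_new; conv <- TRUE; break }
      p <- p_new
    }
    occ[ci, ] <- p
    n_traj[ci] <- length(unique(chunks$traj_of_chunk))
    n_jumps[ci] <- sum(chunks$n_jumps)
    iters[ci] <- it; converged[ci] <- conv || max_iter == 0
  }
  used <- !is.na(occ[, 1L])
  if (!any(used)) stop("no cell with usable trajectories")
  aggregate <- colSums(occ[used, , drop = FALSE] * n_jumps[used]) /
    sum(n_jumps[used])
  structure(list(grid = grid, cfg = cfg, cell_ids = cells,
                 occupations = occ, n_traj = n_traj, n_jumps = n_jumps,
                 n_detections = n_detections,
                 iterations = iters, converged = converged,
                 skipped_cells = skipped, aggregate = aggregate,
                 defoc_weights = defoc),
            class = "state_array")
}

#' Chromatin-bound fraction of a diffusion spectrum
#'
#' Sum of the occupations at grid points with diffusion coefficient strictly
#' below `threshold` (default 0.1 um^2/s).
#'
#' @param x A `state_array` fit, or a normalized occupation vector.
#' @param threshold Bound threshold, um^2/s.
#' @param per_cell Return per-cell values instead of the aggregate (for
#'   `state_array` input).
#' @param d Grid coefficients (required when `x` is a bare vector).
#' @return Bound fraction in [0, 1] (vector if `per_cell`).
#' @export
bound_fraction <- function(x, threshold = 0.1, per_cell = FALSE, d = NULL) {
  if (inherits(x, "state_array")) {
    d <- x$grid$d
    occ <- if (per_cell) x$occupations else matrix(x$aggregate, 1)
  } else {
    if (is.null(d)) stop("grid coefficients 'd' required for a bare vector")
    occ <- matrix(x, 1)
  }
  sums <- rowSums(occ)
  bad <- !is.na(sums) & abs(sums - 1) > 1e-6
  if (any(bad)) stop("occupations are not normalized")
  res <- rowSums(occ[, d < threshold, drop = FALSE])
  if (per_cell) res else unname(res[1L])
}

#' @export
print.state_array <- function(x, ...) {
  used <- !is.na(x$occupations[, 1L])
  cat(sprintf("State-array diffusion spectrum: %d cells (%d skipped), %d grid points\n",
              sum(used), length(x$skipped_cells), length(x$grid$d)))
  cat(sprintf("  total trajectories %d, total jumps %d\n",
              sum(x$n_traj), sum(x$n_jumps)))
  cat(sprintf("  aggregate bound fraction (D < 0.1 um^2/s): %.3f\n",
              bound_fraction(x)))
  invisible(x)
}

#' @export
summary.state_array <- function(object, threshold = 0.1, ...) {
  used <- !is.na(object$occupations[, 1L])
  bf <- rep(NA_real_, length(object$cell_ids))
  bf[used] <- bound_fraction(object, threshold = threshold,
                             per_cell = TRUE)[used]
  data.frame(cell_id = object$cell_ids, n_trajectories = object$n_traj,
             n_jumps = object$n_jumps,
             n_detections = object$n_detections, bound_fraction = bf,
             converged = object$converged, row.names = NULL)
}

#' @export
coef.state_array <- function(object, ...) object$aggregate

#' @export
plot.state_array <- function(x, ...) {
  graphics::plot(x$grid$d, x$aggregate, type = "l", log = "x",
                 xlab = expression(D ~ (mu * m^2 / s)),
                 ylab = "mean posterior occupation", ...)
  graphics::abline(v = 0.1, lty = 3)
  invisible(x)
}
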