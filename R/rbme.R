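#' Log-likelihood of a trajectory under Brownian motion with localization
#' error
#'
#' Under regular Brownian motion with diffusion coefficient `D` observed at
#' interval `dt` with i.i.d. Gaussian localization error `sigma` per axis,
#' the vector of consecutive jumps along one axis is zero-mean multivariate
#' normal with tridiagonal covariance: `2 * D * dt + 2 * sigma^2` on the
#' diagonal and `-sigma^2` on the first off-diagonals (consecutive jumps
#' share one noisy endpoint). This function returns the sum of the two axis
#' log-densities, evaluated in O(n) per trajectory via the closed-form
#' eigendecomposition of the tridiagonal Toeplitz matrix (eigenvalues
#' `2*D*dt + 2*sigma^2*(1 - cos(k*pi/(n+1)))`, discrete sine transform
#' eigenvectors).
#'
#' @param trajectory Data frame with `x_um`, `y_um` ordered by frame, or a
#'   numeric matrix of positions with two columns (um).
#' @param D Diffusion coefficient, um^2/s (>= 0).
#' @param sigma One-axis localization error, um (>= 0).
#' @param dt Frame interval, s.
#' @return Log-likelihood (scalar).
#' @export
rbme_loglik <- function(trajectory, D, sigma, dt) {
  if (D < 0 || sigma < 0) stop("D and sigma must be >= 0")
  pos <- if (is.data.frame(trajectory))
    cbind(trajectory$x_um, trajectory$y_um) else as.matrix(trajectory)
  if (nrow(pos) < 2L) stop("trajectory needs at least 1 jump")
  jx <- diff(pos[, 1L]); jy <- diff(pos[, 2L])
  n <- length(jx)
  lam <- .rbme_eigvals(n, D, sigma, dt)
  if (any(lam <= 0)) return(-Inf)
  V <- .dst_basis(n)
  ux <- as.vector(crossprod(V, jx)); uy <- as.vector(crossprod(V, jy))
  -(n * log(2 * pi) + sum(log(lam))) - 0.5 * sum((ux^2 + uy^2) / lam)
}

.rbme_eigvals <- function(n, D, sigma, dt) {
  k <- seq_len(n)
  2 * D * dt + 2 * sigma^2 * (1 - cos(k * pi / (n + 1)))
}

.dst_basis <- function(n) {
  k <- seq_len(n)
  sqrt(2 / (n + 1)) * sin(outer(k, k) * pi / (n + 1))
}

# Split each trajectory into chunks of at most `cap` jumps and return the
# per-chunk jump vectors grouped by chunk length, plus bookkeeping.
.jump_chunks <- function(trajectories, cap = 100L) {
  tr <- trajectories[order(trajectories$trajectory, trajectories$frame), ]
  same <- c(FALSE, diff(tr$trajectory) == 0 & diff(tr$frame) == 1)
  dx <- c(NA, diff(tr$x_um))[same]
  dy <- c(NA, diff(tr$y_um))[same]
  traj_of_jump <- tr$trajectory[same]
  if (!length(dx)) return(NULL)
  # chunk index within each trajectory
  jump_rank <- sequence(rle(traj_of_jump)$lengths)
  chunk_key <- paste(traj_of_jump, (jump_rank - 1L) %/% cap)
  chunk_id <- match(chunk_key, unique(chunk_key))
  n_jumps <- tabulate(chunk_id)
  list(dx = dx, dy = dy, chunk_id = chunk_id, n_jumps = n_jumps,
       traj_of_chunk = traj_of_jump[!duplicated(chunk_id)])
}

# Log-likelihood matrix (chunks x grid points), computed per length group
# through the sine-transform representation; O(total_jumps) per grid point.
.rbme_loglik_grid <- function(chunks, grid_d, sigma, dt) {
  K <- length(grid_d)
  T_n <- length(chunks$n_jumps)
  L <- matrix(0, T_n, K)
  ord <- order(chunks$chunk_id)
  dx <- chunks$dx[ord]; dy <- chunks$dy[ord]
  offs <- c(0L, cumsum(chunks$n_jumps))
  for (n in sort(unique(chunks$n_jumps))) {
    rows <- which(chunks$n_jumps == n)
    X <- matrix(0, length(rows), n); Y <- matrix(0, length(rows), n)
    for (i in seq_along(rows)) {
      idx <- (offs[rows[i]] + 1L):offs[rows[i] + 1L]
      X[i, ] <- dx[idx]; Y[i, ] <- dy[idx]
    }
    V <- .dst_basis(n)
    U2 <- (X %*% V)^2 + (Y %*% V)^2
    for (k in seq_len(K)) {
      lam <- .rbme_eigvals(n, grid_d[k], sigma, dt)
      L[rows, k] <- -(n * log(2 * pi) + sum(log(lam))) -
        0.5 * drop(U2 %*% (1 / lam))
    }
  }
  L
}

#' Model-free per-trajectory diffusion estimate
#'
#' The method-of-moments estimator
#' `D_hat = max(0, mean(r^2) / (4 * dt) - sigma^2 / dt)`, where `r` are the
#' 2D jumps of one trajectory. Its histogram across trajectories is a
#' model-free sanity check of the spectrum's modes.
#'
#' @param trajectories Data frame with `trajectory`, `frame`, `x_um`,
#'   `y_um`.
#' @param cfg An [imaging_config()] object.
#' @return Data frame: `trajectory`, `n_jumps`, `d_hat`.
#' @export
per_trajectory_mle <- function(trajectories, cfg = imaging_config()) {
  tr <- trajectories[order(trajectories$trajectory, trajectories$frame), ]
  same <- c(FALSE, diff(tr$trajectory) == 0 & diff(tr$frame) == 1)
  r2 <- (c(NA, diff(tr$x_um))^2 + c(NA, diff(tr$y_um))^2)[same]
  id <- tr$trajectory[same]
  if (!length(r2)) return(data.frame(trajectory = integer(),
                                     n_jumps = integer(), d_hat = numeric()))
  msd <- tapply(r2, id, mean)
  n_jumps <- tapply(r2, id, length)
  data.frame(trajectory = as.integer(names(msd)),
             n_jumps = as.integer(n_jumps),
             d_hat = pmax(0, as.numeric(msd) / (4 * cfg$frame_interval) -
                             cfg$loc_error^2 / cfg$frame_interval),
             row.names = NULL)
}
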