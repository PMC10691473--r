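# Shared fixtures, lazily built and cached for the whole test run.
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

# Simulation + full inference for one study preset (20 cells x 250
# molecules, the study-scale condition).
preset_fit <- function(name, seed = 101) {
  fixture(paste0("fit_", name, "_", seed), function() {
    p <- preset(name)
    sim <- simulate_trajectories(p$two_state, imaging_config(),
                                 n_cells = 20, traj_per_cell = 250,
                                 seed = seed)
    list(preset = p, sim = sim, fit = state_array(sim$trajectories))
  })
}

# Simulate a cohort of cells with cell-to-cell variation in the number of
# photoactivated molecules (expression proxy), optionally with a planted
# dependence of f_bound on expression.
simulate_cohort <- function(n_cells, seed, traj_range = c(60, 240),
                            f_bound_fn = function(expr) 0.5,
                            d_free = 3.0, cfg = imaging_config()) {
  cells <- vector("list", n_cells)
  truths <- vector("list", n_cells)
  n_traj <- with_seed_helper(seed, round(runif(n_cells, traj_range[1],
                                               traj_range[2])))
  for (i in seq_len(n_cells)) {
    expr <- (n_traj[i] - traj_range[1]) / diff(traj_range)
    params <- two_state_params(f_bound = f_bound_fn(expr), d_free = d_free)
    sim <- simulate_trajectories(params, cfg, n_cells = 1,
                                 traj_per_cell = n_traj[i],
                                 seed = seed + i)
    sim$trajectories$cell_id <- sprintf("cell_%03d", i)
    sim$truth$cell_id <- sprintf("cell_%03d", i)
    cells[[i]] <- sim$trajectories
    truths[[i]] <- sim$truth
  }
  list(trajectories = do.call(rbind, cells), truth = do.call(rbind, truths))
}

with_seed_helper <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}

# Dense multivariate-normal RBME log-likelihood: explicit tridiagonal
# covariance, determinant() and solve(). Independent of the sine-transform
# path used by the package.
dense_rbme_loglik <- function(pos, D, sigma, dt) {
  jx <- diff(pos[, 1]); jy <- diff(pos[, 2])
  n <- length(jx)
  C <- matrix(0, n, n)
  diag(C) <- 2 * D * dt + 2 * sigma^2
  if (n > 1) for (i in seq_len(n - 1)) C[i, i + 1] <- C[i + 1, i] <- -sigma^2
  Ci <- solve(C)
  ld <- as.numeric(determinant(C, logarithm = TRUE)$modulus)
  ll_axis <- function(x) -0.5 * (n * log(2 * pi) + ld + drop(t(x) %*% Ci %*% x))
  ll_axis(jx) + ll_axis(jy)
}

# Exhaustive minimum-distance matching oracle for tiny frame pairs:
# enumerate every injective partial assignment, maximize matched count,
# then minimize total distance.
brute_force_matching <- function(dmat, radius) {
  nr <- nrow(dmat); nc <- ncol(dmat)
  best <- NULL; best_count <- -1; best_dist <- Inf
  explore <- function(r, cur, used, count, dist) {
    if (r > nr) {
      if (count > best_count || (count == best_count && dist < best_dist)) {
        best <<- cur; best_count <<- count; best_dist <<- dist
      }
      return(invisible())
    }
    for (cc in seq_len(nc)) {
      if (used[cc] || dmat[r, cc] > radius) next
      used[cc] <- TRUE; cur[r] <- cc
      explore(r + 1, cur, used, count + 1, dist + dmat[r, cc])
      used[cc] <- FALSE; cur[r] <- NA
    }
    explore(r + 1, cur, used, count, dist)
  }
  explore(1, rep(NA_integer_, nr), rep(FALSE, nc), 0, 0)
  best
}

# Exact Mann-Whitney one-sided p by enumeration of all group labelings.
enumerate_mw_p <- function(a, b, alternative = "less") {
  pooled <- c(a, b)
  m <- length(a)
  combos <- utils::combn(length(pooled), m)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  u_all <- apply(combos, 2, function(idx)
    sum(rank(pooled)[idx]) - m * (m + 1) / 2)
  switch(alternative,
         less = mean(u_all <= u_obs),
         greater = mean(u_all >= u_obs))
}
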