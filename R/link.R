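#' Trajectory linking settings
#'
#' @param search_radius Maximum jump between consecutive frames, um.
#' @param max_blinks Allowed missed frames; fixed at 0 (no gap closing).
#' @return An object of class `link_settings`.
#' @export
link_settings <- function(search_radius = 1.0, max_blinks = 0) {
  if (search_radius <= 0) stop("search_radius must be > 0")
  if (max_blinks != 0) stop("gap closing is not supported (max_blinks = 0)")
  structure(list(search_radius = search_radius, max_blinks = 0L),
            class = "link_settings")
}

# Optimal bipartite matching between active trajectory heads and new
# localizations: maximum cardinality first, then minimum total distance,
# then lowest row/column indices. Exact enumeration per connected component;
# components bigger than `cap` rows fall back to greedy nearest-pair.
.match_frame <- function(dmat, radius, cap = 9L) {
  nr <- nrow(dmat); nc <- ncol(dmat)
  assign_out <- rep(NA_integer_, nr)
  if (nr == 0L || nc == 0L) return(assign_out)
  feas <- dmat <= radius
  if (!any(feas)) return(assign_out)
  # connected components of the bipartite feasibility graph
  comp_row <- rep(0L, nr); comp_col <- rep(0L, nc); n_comp <- 0L
  for (r in seq_len(nr)) {
    if (comp_row[r] != 0L || !any(feas[r, ])) next
    n_comp <- n_comp + 1L
    stack_r <- r
    while (length(stack_r)) {
      cur <- stack_r[1L]; stack_r <- stack_r[-1L]
      if (comp_row[cur] != 0L) next
      comp_row[cur] <- n_comp
      for (cc in which(feas[cur, ])) {
        if (comp_col[cc] == 0L) {
          comp_col[cc] <- n_comp
          more <- which(feas[, cc] & comp_row == 0L)
          stack_r <- c(stack_r, more)
        }
      }
    }
  }
  for (k in seq_len(n_comp)) {
    rows <- which(comp_row == k)
    cols <- which(comp_col == k)
    if (length(rows) == 1L && length(cols) == 1L) {
      assign_out[rows] <- cols
      next
    }
    if (length(rows) > cap) {
      # greedy fallback (never reached at single-molecule densities)
      sub <- dmat[rows, cols, drop = FALSE]
      sub[!feas[rows, cols, drop = FALSE]] <- Inf
      while (any(is.finite(sub))) {
        ij <- which(sub == min(sub), arr.ind = TRUE)[1L, ]
        assign_out[rows[ij[1L]]] <- cols[ij[2L]]
        sub[ij[1L], ] <- Inf; sub[, ij[2L]] <- Inf
      }
      next
    }
    best <- .enumerate_matching(dmat[rows, cols, drop = FALSE],
                                feas[rows, cols, drop = FALSE])
    assign_out[rows] <- ifelse(is.na(best), NA_integer_, cols[best])
  }
  assign_out
}

# exhaustive search for the max-cardinality, min-total-distance assignment
.enumerate_matching <- function(dmat, feas) {
  nr <- nrow(dmat); nc <- ncol(dmat)
  best_assign <- rep(NA_integer_, nr)
  best_count <- -1L; best_dist <- Inf
  cur <- rep(NA_integer_, nr)
  used <- rep(FALSE, nc)
  recurse <- function(r, count, dist) {
    if (r > nr) {
      if (count > best_count ||
          (count == best_count && dist < best_dist - 1e-12)) {
        best_assign <<- cur; best_count <<- count; best_dist <<- dist
      }
      return(invisible())
    }
    # try columns in increasing index order so the first optimum found is
    # the lexicographically smallest assignment
    for (cc in seq_len(nc)) {
      if (used[cc] || !feas[r, cc]) next
      used[cc] <<- TRUE; cur[r] <<- cc
      recurse(r + 1L, count + 1L, dist + dmat[r, cc])
      used[cc] <<- FALSE; cur[r] <<- NA_integer_
    }
    recurse(r + 1L, count, dist)
  }
  recurse(1L, 0L, 0)
  best_assign
}

#' Link localizations into trajectories
#'
#' Connects localizations in consecutive frames by euclidean distance:
#' between each frame pair, candidate links within `search_radius` are
#' resolved by minimum-total-distance bipartite matching (maximum number of
#' links first; ties broken by lowest localization index). Unmatched
#' localizations start new trajectories and unmatched trajectories
#' terminate — there is no gap closing, so trajectories live on strictly
#' consecutive frames. Every input localization belongs to exactly one
#' trajectory; singletons are retained (they count toward per-cell detection
#' totals but carry no jumps).
#'
#' @param localizations Data frame with `frame` (integer), `x_um`, `y_um`.
#' @param settings A [link_settings()] object.
#' @return The input data frame with a `trajectory` column, ordered by
#'   trajectory then frame.
#' @export
link <- function(localizations, settings = link_settings()) {
  if (!nrow(localizations)) {
    localizations$trajectory <- integer()
    return(localizations)
  }
  locs <- localizations[order(localizations$frame), , drop = FALSE]
  locs$trajectory <- NA_integer_
  frames <- sort(unique(locs$frame))
  idx_f <- split(seq_len(nrow(locs)), factor(locs$frame, levels = frames))
  next_id <- 1L
  first <- idx_f[[1L]]
  locs$trajectory[first] <- seq_along(first)
  next_id <- length(first) + 1L
  active <- first   # row indices of current trajectory heads
  for (fi in seq_along(frames)[-1L]) {
    rows_new <- idx_f[[fi]]
    if (frames[fi] != frames[fi - 1L] + 1L) active <- integer()
    if (length(active) && length(rows_new)) {
      dmat <- sqrt(outer(locs$x_um[active], locs$x_um[rows_new], "-")^2 +
                   outer(locs$y_um[active], locs$y_um[rows_new], "-")^2)
      assign_to <- .match_frame(dmat, settings$search_radius)
    } else assign_to <- rep(NA_integer_, length(active))
    matched_new <- rep(FALSE, length(rows_new))
    for (a in seq_along(active)) {
      if (!is.na(assign_to[a])) {
        j <- rows_new[assign_to[a]]
        locs$trajectory[j] <- locs$trajectory[active[a]]
        matched_new[assign_to[a]] <- TRUE
      }
    }
    starts <- rows_new[!matched_new]
    if (length(starts)) {
      locs$trajectory[starts] <- next_id + seq_along(starts) - 1L
      next_id <- next_id + length(starts)
    }
    active <- rows_new
  }
  locs[order(locs$trajectory, locs$frame), , drop = FALSE]
}

#' Jump lengths and their distribution
#'
#' Extracts all euclidean displacements between consecutive frames of each
#' trajectory, with an empirical histogram/CDF and, optionally, the
#' closed-form mixture CDF
#' `P(r <= R) = sum_i f_i * (1 - exp(-R^2 / (4 * D_i * dt + 4 * sigma^2)))`
#' for model overlay.
#'
#' @param trajectories Data frame with `trajectory`, `frame`, `x_um`,
#'   `y_um`.
#' @param cfg An [imaging_config()] object (supplies `dt` and `sigma` for
#'   the model CDF).
#' @param binwidth Histogram bin width, um.
#' @param range Histogram range, um.
#' @param model Optional list with vectors `f` (fractions summing to 1) and
#'   `d` (diffusion coefficients) defining the overlay mixture.
#' @return A list of class `jump_lengths`: `jumps` (um), `breaks`,
#'   `density`, `ecdf`, and `model_cdf` (function of R, or `NULL`).
#' @export
jump_lengths <- function(trajectories, cfg = imaging_config(),
                         binwidth = 0.02, range = c(0, 1), model = NULL) {
  tr <- trajectories[order(trajectories$trajectory, trajectories$frame), ]
  same <- diff(tr$trajectory) == 0
  consecutive <- diff(tr$frame) == 1
  use <- same & consecutive
  jumps <- sqrt(diff(tr$x_um)[use]^2 + diff(tr$y_um)[use]^2)
  if (!length(jumps)) stop("no trajectory with >= 2 localizations")
  breaks <- seq(range[1], range[2], by = binwidth)
  h <- graphics::hist(pmin(jumps, range[2]), breaks = breaks, plot = FALSE)
  model_cdf <- NULL
  if (!is.null(model)) {
    if (abs(sum(model$f) - 1) > 1e-6) stop("model fractions must sum to 1")
    dt <- cfg$frame_interval; s2 <- cfg$loc_error^2
    f <- model$f; d <- model$d
    model_cdf <- function(R)
      vapply(R, function(r)
        sum(f * (1 - exp(-r^2 / (4 * d * dt + 4 * s2)))), numeric(1))
  }
  structure(list(jumps = jumps, breaks = breaks, density = h$density,
                 ecdf = stats::ecdf(jumps), model_cdf = model_cdf),
            class = "jump_lengths")
}
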