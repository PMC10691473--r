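#' Detection and localization settings
#'
#' `detection_settings()` parameterizes the generalized log-likelihood-ratio
#' (LLR) spot detector; `localization_settings()` the damped least-squares
#' integrated-Gaussian subpixel fit. Defaults are the tracking settings used
#' throughout: LLR kernel sigma 1.3 px in a 15 px window at threshold 18,
#' and a 9 px fit window with fixed PSF sigma 1.0 px, ridge 0.001, at most
#' 10 iterations with damping 0.3.
#'
#' @param kernel_sigma Gaussian kernel sigma of the LLR test, pixels.
#' @param window Odd LLR window side, pixels (>= 3).
#' @param threshold LLR statistic threshold (> 0).
#' @return An object of class `detection_settings`.
#' @export
detection_settings <- function(kernel_sigma = 1.3, window = 15,
                               threshold = 18.0) {
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) stop("window must be odd and >= 3")
  if (threshold <= 0) stop("threshold must be > 0")
  if (kernel_sigma <= 0) stop("kernel_sigma must be > 0")
  structure(list(kernel_sigma = kernel_sigma, window = window,
                 threshold = threshold), class = "detection_settings")
}

#' @rdname detection_settings
#' @param fit_window Odd fit window side, pixels.
#' @param psf_sigma Fixed PSF sigma of the fitted model, pixels.
#' @param ridge Ridge regularizer added to the normal equations.
#' @param max_iter Maximum Gauss-Newton iterations.
#' @param damp Step damping factor in (0, 1].
#' @export
localization_settings <- function(fit_window = 9, psf_sigma = 1.0,
                                  ridge = 0.001, max_iter = 10, damp = 0.3) {
  fit_window <- as.integer(fit_window)
  if (fit_window < 3L || fit_window %% 2L == 0L)
    stop("fit_window must be odd and >= 3")
  if (damp <= 0 || damp > 1) stop("damp must be in (0, 1]")
  structure(list(fit_window = fit_window, psf_sigma = psf_sigma,
                 ridge = ridge, max_iter = as.integer(max_iter), damp = damp),
            class = "localization_settings")
}

# 2D "same" convolution via FFT; kernels used here are symmetric, so this
# equals cross-correlation.
.conv2same <- function(img, kern) {
  H <- nrow(img); W <- ncol(img)
  h <- nrow(kern); w <- ncol(kern)
  P1 <- H + h - 1L; P2 <- W + w - 1L
  A <- matrix(0, P1, P2); A[1:H, 1:W] <- img
  B <- matrix(0, P1, P2); B[1:h, 1:w] <- kern
  C <- Re(stats::fft(stats::fft(A) * stats::fft(B), inverse = TRUE)) / (P1 * P2)
  r0 <- (h - 1L) / 2L; c0 <- (w - 1L) / 2L
  C[(r0 + 1L):(r0 + H), (c0 + 1L):(c0 + W)]
}

.gauss_kernel <- function(w, sigma) {
  c0 <- (w + 1) / 2
  g1 <- stats::dnorm(seq_len(w), mean = c0, sd = sigma)
  k <- outer(g1, g1)
  k / sum(k)
}

#' Detect spots by a generalized log-likelihood-ratio test
#'
#' For every pixel, compares the fit of a Gaussian kernel (sigma
#' `kernel_sigma`) plus flat background against flat background alone within
#' the surrounding `window x window` region, under i.i.d. Gaussian noise of
#' unknown variance. The statistic is `-(n/2) * log(1 - rho^2)` where `rho`
#' is the correlation of the window with the mean-centered kernel and
#' `n = window^2`; pixels exceeding `threshold` survive, and non-maximum
#' suppression within the kernel radius keeps one candidate per spot.
#' Pixels too close to the edge for a full window are never candidates.
#'
#' @param frame_image Numeric matrix (one movie frame).
#' @param settings A [detection_settings()] object.
#' @return Data frame of candidates: `y_px`, `x_px` (0-based integer pixel
#'   indices) and `llr` (the statistic).
#' @export
detect_llr <- function(frame_image, settings = detection_settings()) {
  frame_image <- matrix(as.numeric(frame_image), nrow(frame_image))
  w <- settings$window
  H <- nrow(frame_image); W <- ncol(frame_image)
  if (H < w || W < w) stop("image smaller than the detection window")
  n <- w * w
  g <- .gauss_kernel(w, settings$kernel_sigma)
  gc <- g - mean(g)
  sg2 <- sum(gc^2)
  box <- matrix(1, w, w)
  s1 <- .conv2same(frame_image, box)
  s2 <- .conv2same(frame_image^2, box)
  G <- .conv2same(frame_image, gc)
  rss0 <- pmax(s2 - s1^2 / n, 0)
  ratio <- ifelse(rss0 > 1e-12, G^2 / (sg2 * rss0), 0)
  ratio <- pmin(ratio, 1 - 1e-12)
  llr <- -(n / 2) * log1p(-ratio)
  hw <- (w - 1L) / 2L
  valid <- matrix(FALSE, H, W)
  valid[(hw + 1L):(H - hw), (hw + 1L):(W - hw)] <- TRUE
  llr[!valid] <- 0
  # non-maximum suppression within the kernel radius
  r <- max(1L, ceiling(2 * settings$kernel_sigma))
  dil <- llr
  for (dy in -r:r) for (dx in -r:r) {
    if (dy == 0L && dx == 0L) next
    sh <- matrix(-Inf, H, W)
    ys <- max(1L, 1L - dy):min(H, H - dy)
    xs <- max(1L, 1L - dx):min(W, W - dx)
    sh[ys, xs] <- llr[ys + dy, xs + dx]
    dil <- pmax(dil, sh)
  }
  keep <- which(llr > settings$threshold & llr >= dil, arr.ind = TRUE)
  data.frame(y_px = keep[, 1L] - 1L, x_px = keep[, 2L] - 1L,
             llr = llr[keep])
}

#' Subpixel localization by integrated-Gaussian least squares
#'
#' Refines candidate pixels to subpixel positions by iterative damped
#' Gauss-Newton least squares of a pixel-integrated 2D Gaussian of fixed
#' sigma `psf_sigma` plus flat background, within a `fit_window` square. A
#' ridge term stabilizes the normal equations; iteration stops after
#' `max_iter` steps or when the position update falls below 1e-4 px.
#' Candidates without a full fit-window margin, or whose normal equations
#' are singular, are dropped. Positions use the pixel-edge convention
#' (pixel `i` spans `[i, i + 1)`) and are converted to um with
#' `cfg$pixel_size`.
#'
#' @param frame_image Numeric matrix.
#' @param candidates Data frame with `y_px`, `x_px` (0-based), e.g. from
#'   [detect_llr()].
#' @param settings A [localization_settings()] object.
#' @param cfg An [imaging_config()] object.
#' @return Data frame: `x_um`, `y_um`, `x_px`, `y_px` (continuous),
#'   `amplitude` (photons), `background` (photons/pixel).
#' @export
localize_gaussian <- function(frame_image, candidates,
                              settings = localization_settings(),
                              cfg = imaging_config()) {
  frame_image <- matrix(as.numeric(frame_image), nrow(frame_image))
  fw <- settings$fit_window
  h <- (fw - 1L) / 2L
  H <- nrow(frame_image); W <- ncol(frame_image)
  s <- settings$psf_sigma
  out <- vector("list", nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    cy <- candidates$y_px[i]; cx <- candidates$x_px[i]
    if (cy < h || cx < h || cy > H - 1L - h || cx > W - 1L - h) next
    rows <- (cy - h):(cy + h)   # 0-based pixel indices
    cols <- (cx - h):(cx + h)
    y_data <- as.vector(frame_image[rows + 1L, cols + 1L])
    b <- min(y_data)
    A <- max(sum(y_data) - b * fw^2, 1e-3)
    px <- cx + 0.5; py <- cy + 0.5
    fit_ok <- TRUE
    for (it in seq_len(settings$max_iter)) {
      ex <- stats::pnorm(cols + 1, px, s) - stats::pnorm(cols, px, s)
      ey <- stats::pnorm(rows + 1, py, s) - stats::pnorm(rows, py, s)
      dex <- stats::dnorm(cols, px, s) - stats::dnorm(cols + 1, px, s)
      dey <- stats::dnorm(rows, py, s) - stats::dnorm(rows + 1, py, s)
      shape <- outer(ey, ex)
      model <- A * shape + b
      r <- y_data - as.vector(model)
      J <- cbind(as.vector(A * outer(ey, dex)),
                 as.vector(A * outer(dey, ex)),
                 as.vector(shape), 1)
      JtJ <- crossprod(J) + settings$ridge * diag(4)
      step <- tryCatch(solve(JtJ, crossprod(J, r)),
                       error = function(e) NULL)
      if (is.null(step)) { fit_ok <- FALSE; break }
      step <- settings$damp * step
      px <- px + step[1L]; py <- py + step[2L]
      A <- A + step[3L]; b <- b + step[4L]
      if (max(abs(step[1:2])) < 1e-4) break
    }
    if (!fit_ok || !is.finite(px) || !is.finite(py)) next
    if (px < 0 || py < 0 || px >= W || py >= H) next
    out[[i]] <- data.frame(x_um = px * cfg$pixel_size,
                           y_um = py * cfg$pixel_size,
                           x_px = px, y_px = py,
                           amplitude = A, background = b)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out))
    return(data.frame(x_um = numeric(), y_um = numeric(), x_px = numeric(),
                      y_px = numeric(), amplitude = numeric(),
                      background = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Detect and localize spots in a whole movie
#'
#' Runs [detect_llr()] and [localize_gaussian()] frame by frame and returns
#' a localization table. An optional nuclear mask discards localizations
#' whose pixel lies outside the nucleus.
#'
#' @param movie 3D array (`y, x, frame`), e.g. from [render_movie()] or
#'   [read_movie()].
#' @param dsettings,lsettings Detection and localization settings.
#' @param cfg An [imaging_config()] object.
#' @param mask Optional logical matrix of the movie's XY shape.
#' @return Data frame: `frame` (0-based), `x_um`, `y_um`, `amplitude`,
#'   `background`.
#' @export
detect_movie <- function(movie, dsettings = detection_settings(),
                         lsettings = localization_settings(),
                         cfg = imaging_config(), mask = NULL) {
  n_frames <- dim(movie)[3]
  res <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    img <- movie[, , f]
    cand <- detect_llr(img, dsettings)
    if (!nrow(cand)) next
    loc <- localize_gaussian(img, cand, lsettings, cfg)
    if (!nrow(loc)) next
    loc$frame <- f - 1L
    res[[f]] <- loc
  }
  res <- res[!vapply(res, is.null, TRUE)]
  if (!length(res))
    return(data.frame(frame = integer(), x_um = numeric(), y_um = numeric(),
                      amplitude = numeric(), background = numeric()))
  locs <- do.call(rbind, res)
  rownames(locs) <- NULL
  if (!is.null(mask)) {
    ij <- cbind(floor(locs$y_um / cfg$pixel_size) + 1L,
                floor(locs$x_um / cfg$pixel_size) + 1L)
    locs <- locs[mask[ij], , drop = FALSE]
  }
  locs[, c("frame", "x_um", "y_um", "amplitude", "background")]
}

#' Nuclear mask from bright-channel frames
#'
#' Builds a binary nuclear mask from bright-channel frames (e.g. the first
#' and last frames of a movie acquired with nuclear staining): maximum
#' projection, Otsu threshold, hole filling.
#'
#' @param frames 3D array (`y, x, frame`) or a matrix.
#' @return Logical matrix.
#' @export
nuclear_mask <- function(frames) {
  proj <- if (length(dim(frames)) == 3L) apply(frames, c(1, 2), max) else frames
  rng <- range(proj)
  if (diff(rng) == 0) return(matrix(TRUE, nrow(proj), ncol(proj)))
  norm <- (proj - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  bin <- EBImage::fillHull(EBImage::Image(norm > thr))
  matrix(as.logical(EBImage::imageData(bin)), nrow(proj))
}

#' Mean-detections-per-frame quality filter
#'
#' Movies with a mean of more than three detections per frame are excluded
#' (strict inequality: a mean of exactly 3.0 passes).
#'
#' @param per_frame_counts Integer vector of detections per frame.
#' @return `TRUE` (pass) or `FALSE` (fail), with the mean attached as
#'   attribute `mean_detections`.
#' @export
qc_mean_detections <- function(per_frame_counts) {
  if (!length(per_frame_counts)) stop("empty count series")
  m <- mean(per_frame_counts)
  structure(m <= 3.0, mean_detections = m)
}
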