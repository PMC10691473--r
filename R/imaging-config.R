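#' Imaging configuration
#'
#' Acquisition parameters shared by the trajectory simulator, the movie
#' renderer and the diffusion-spectrum inference. Defaults match stroboscopic
#' HILO fast-SMT acquisition: 7 ms exposure plus ~447 us camera dead time
#' treated as a single fixed sampling interval, a 16 um x 16 um ROI at
#' 0.16 um/pixel, and a 0.7 um detection slab.
#'
#' @param pixel_size Pixel size in um/pixel.
#' @param frame_interval Sampling interval in seconds (exposure + dead time).
#' @param focal_depth Axial detection depth in um; molecules are observed
#'   while their axial position lies within +/- `focal_depth / 2`.
#' @param loc_error One-axis localization error sigma in um, added i.i.d. to
#'   every observed coordinate. The same constant is used by the RBME
#'   likelihood.
#' @param roi_pixels Side of the square ROI in pixels.
#' @param psf_sigma Standard deviation of the rendered Gaussian PSF, pixels.
#' @return An object of class `imaging_config`.
#' @export
imaging_config <- function(pixel_size = 0.16, frame_interval = 0.00748,
                           focal_depth = 0.7, loc_error = 0.035,
                           roi_pixels = 100L, psf_sigma = 1.0) {
  cfg <- list(pixel_size = pixel_size, frame_interval = frame_interval,
              focal_depth = focal_depth, loc_error = loc_error,
              roi_pixels = as.integer(roi_pixels), psf_sigma = psf_sigma)
  for (nm in names(cfg)) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("imaging_config: '", nm, "' must be a single positive number")
  }
  structure(cfg, class = "imaging_config")
}

#' @export
print.imaging_config <- function(x, ...) {
  cat("Imaging configuration\n")
  cat(sprintf("  pixel size     %.3f um/px   ROI %d x %d px\n",
              x$pixel_size, x$roi_pixels, x$roi_pixels))
  cat(sprintf("  frame interval %.5f s\n", x$frame_interval))
  cat(sprintf("  focal depth    %.2f um      loc. error %.3f um\n",
              x$focal_depth, x$loc_error))
  cat(sprintf("  PSF sigma      %.2f px\n", x$psf_sigma))
  invisible(x)
}

#' Two-state mobility parameters
#'
#' Parameters of the bound/free mixture used by the trajectory simulator:
#' each molecule is chromatin-bound with probability `f_bound` and diffuses
#' with coefficient `d_bound`, otherwise it is free with coefficient
#' `d_free`. By default a molecule keeps one state for its whole trajectory,
#' matching the one-coefficient-per-trajectory assumption of the grid
#' inference; `switching` enables within-trajectory state changes for
#' robustness experiments.
#'
#' @param f_bound Fraction of molecules in the bound state, in [0, 1].
#' @param d_free Free-state diffusion coefficient, um^2/s.
#' @param d_bound Bound-state diffusion coefficient, um^2/s; must be below
#'   `d_free` and is expected to lie below the 0.1 um^2/s bound threshold.
#' @param switching Allow state changes within a trajectory.
#' @param switch_rate Per-frame probability of switching state when
#'   `switching` is `TRUE`.
#' @return An object of class `two_state_params`.
#' @export
two_state_params <- function(f_bound, d_free, d_bound = 0.02,
                             switching = FALSE, switch_rate = 0.05) {
  if (!is.numeric(f_bound) || f_bound < 0 || f_bound > 1)
    stop("f_bound must lie in [0, 1]")
  if (d_bound < 0 || d_free <= 0) stop("diffusion coefficients must be >= 0")
  if (d_bound >= d_free) stop("d_bound must be smaller than d_free")
  structure(list(f_bound = f_bound, d_bound = d_bound, d_free = d_free,
                 switching = isTRUE(switching), switch_rate = switch_rate),
            class = "two_state_params")
}

#' FRAP recovery kinetics
#'
#' Ground-truth parameters of a simulated fluorescence-recovery series. The
#' post-bleach chromocenter signal follows
#' `I(t) = plateau - (plateau - depth) * exp(-t / tau)` with `t = 0` at the
#' first post-bleach frame, so the half-recovery time is `tau * log(2)`.
#' Whole-nucleus signal decays exponentially with `acq_bleach_rate` to
#' emulate acquisition photobleaching.
#'
#' @param plateau Maximal recovery (normalized), the ground-truth I_max.
#' @param depth Bleach depth (normalized), the ground-truth I_min.
#' @param tau Exponential exchange time constant, seconds.
#' @param acq_bleach_rate Per-second decay rate of the whole-nucleus signal.
#'   Default corresponds to a 20% loss over 10 minutes.
#' @param noise_cv Coefficient of variation of multiplicative measurement
#'   noise on the intensity series.
#' @param background_level Additive background intensity (camera counts).
#' @return An object of class `frap_kinetics`.
#' @export
frap_kinetics <- function(plateau, depth, tau,
                          acq_bleach_rate = -log(0.8) / 600,
                          noise_cv = 0.02, background_level = 100) {
  if (depth < 0 || depth >= plateau || plateau > 1)
    stop("frap_kinetics requires 0 <= depth < plateau <= 1")
  if (tau <= 0) stop("tau must be positive")
  if (acq_bleach_rate < 0 || noise_cv < 0 || background_level < 0)
    stop("acq_bleach_rate, noise_cv and background_level must be >= 0")
  structure(list(plateau = plateau, depth = depth, tau = tau,
                 acq_bleach_rate = acq_bleach_rate, noise_cv = noise_cv,
                 background_level = background_level),
            class = "frap_kinetics")
}

#' Study-condition presets
#'
#' Simulation presets for the four imaged constructs: wild-type MeCP2-Halo
#' ("WT"), the G118E MBD mutant ("G118E"), the stably bound histone control
#' ("H2B") and the freely diffusing HaloTag-NLS control ("NLS"). Bound
#' fractions are the values reported for each construct (64%, 39%, 79%,
#' 11%); free-state coefficients reflect the reported mobility regimes
#' (G118E free population ~2-3 um^2/s, NLS > 10 um^2/s). FRAP kinetics are
#' provided for the two MeCP2 genotypes (recovery 92% with t1/2 = 26 s for
#' WT; 97% with t1/2 = 13 s for G118E).
#'
#' @param name One of "WT", "G118E", "H2B", "NLS".
#' @return A list with elements `name`, `two_state` and (for "WT" and
#'   "G118E") `frap`.
#' @export
preset <- function(name = c("WT", "G118E", "H2B", "NLS")) {
  name <- match.arg(name)
  two_state <- switch(name,
    WT    = two_state_params(f_bound = 0.64, d_free = 3.0),
    G118E = two_state_params(f_bound = 0.39, d_free = 2.5),
    H2B   = two_state_params(f_bound = 0.79, d_free = 2.0),
    NLS   = two_state_params(f_bound = 0.11, d_free = 12.0))
  frap <- switch(name,
    WT    = frap_kinetics(plateau = 0.92, depth = 0.45, tau = 26 / log(2)),
    G118E = frap_kinetics(plateau = 0.97, depth = 0.55, tau = 13 / log(2)),
    NULL)
  list(name = name, two_state = two_state, frap = frap)
}

# Run code with a private, seeded RNG stream, restoring the caller's state.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
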