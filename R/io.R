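#' Read and write trajectory tables
#'
#' Trajectory CSVs carry one row per localization with columns `trajectory`,
#' `frame`, `x_um`, `y_um`, `intensity`, `cell_id`; localization CSVs are
#' identical minus `trajectory`.
#'
#' @param trajectories Data frame to write.
#' @param path File path.
#' @return `read_trajectories()` returns the data frame;
#'   `write_trajectories()` returns `path` invisibly.
#' @export
write_trajectories <- function(trajectories, path) {
  utils::write.csv(trajectories, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read and write 16-bit multi-page TIFF movies
#'
#' Movies are stored one file per cell as unsigned 16-bit multi-page TIFF;
#' in memory they are 3D arrays (`y, x, frame`) of photon counts.
#'
#' @param movie 3D array of nonnegative integers < 2^16.
#' @param path File path.
#' @export
write_movie <- function(movie, path) {
  pages <- lapply(seq_len(dim(movie)[3]),
                  function(f) movie[, , f] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' @rdname write_movie
#' @export
read_movie <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  arr <- array(0L, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (f in seq_along(pages))
    arr[, , f] <- as.integer(round(pages[[f]] * 65535))
  arr
}

#' Read a simulation/analysis configuration
#'
#' YAML (or JSON) configuration for the simulator and pipeline. A `seed`
#' entry is mandatory. Recognized blocks: `imaging` (arguments of
#' [imaging_config()]), `two_state` (arguments of [two_state_params()]),
#' `frap` (arguments of [frap_kinetics()]), plus free-form entries.
#'
#' @param path Path to a .yaml/.yml/.json file.
#' @return A list with `seed`, and `imaging` / `two_state` / `frap`
#'   instantiated when present.
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(cfg$seed)) stop("config must set a seed")
  cfg$seed <- as.integer(cfg$seed)
  if (!is.null(cfg$imaging)) cfg$imaging <- do.call(imaging_config, cfg$imaging)
  if (!is.null(cfg$two_state)) cfg$two_state <- do.call(two_state_params, cfg$two_state)
  if (!is.null(cfg$frap)) cfg$frap <- do.call(frap_kinetics, cfg$frap)
  cfg
}

#' Write ground truth as a JSON sidecar
#'
#' @param truth Ground-truth data frame or list.
#' @param path Output path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
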