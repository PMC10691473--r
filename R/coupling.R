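#' Per-cell record of expression proxy and bound fraction
#'
#' Assembles the per-cell table coupling the detection count (every
#' localization in a cell's movie, singletons included — a proxy for protein
#' level, since the number of photoactivated molecules is proportional to
#' the total number present) with the inferred bound fraction.
#'
#' @param fit A `state_array` fit.
#' @param detections Named vector or data frame (`cell_id`, `n_detections`)
#'   of per-cell localization counts.
#' @param condition Condition/genotype label (recycled).
#' @param animal_id Optional per-cell animal labels (named like
#'   `detections`).
#' @return Data frame of class `cell_records`: `cell_id`, `n_detections`,
#'   `bound_fraction`, `condition`, `animal_id`.
#' @export
cell_records <- function(fit, detections, condition = "cond",
                         animal_id = NULL) {
  s <- summary(fit)
  if (is.data.frame(detections))
    detections <- stats::setNames(detections$n_detections, detections$cell_id)
  nd <- unname(detections[s$cell_id])
  if (any(is.na(nd))) stop("missing detection counts for some cells")
  if (!is.null(animal_id)) animal_id <- unname(animal_id[s$cell_id])
  out <- data.frame(cell_id = s$cell_id, n_detections = nd,
                    bound_fraction = s$bound_fraction,
                    condition = condition,
                    animal_id = if (is.null(animal_id)) NA_character_ else animal_id,
                    stringsAsFactors = FALSE)
  class(out) <- c("cell_records", "data.frame")
  out
}

#' Pearson correlation
#'
#' Product-moment correlation between two equal-length samples, as used to
#' relate per-cell detection counts (protein-level proxy) to per-cell bound
#' fractions.
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return Correlation coefficient in [-1, 1].
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance")
  stats::cor(x, y, method = "pearson")
}

#' Random-pairing null for a correlation
#'
#' Empirical null distribution of the Pearson correlation obtained by
#' randomly re-pairing `y` against `x` (`n_shuffles` seeded permutations of
#' `y`, sampled uniformly with replacement across replicates). Returns the
#' null correlations, their mean, and the two-sided empirical p-value of the
#' observed correlation (with the add-one correction
#' `(1 + #{|null| >= |obs|}) / (n_shuffles + 1)`).
#'
#' @param x,y As in [pearson()].
#' @param n_shuffles Number of permutations (>= 100).
#' @param seed Integer seed.
#' @return A list: `observed`, `null` (vector), `null_mean`, `p_value`.
#' @export
random_pairing_null <- function(x, y, n_shuffles = 1e4, seed) {
  if (n_shuffles < 100) stop("n_shuffles must be >= 100")
  if (missing(seed)) stop("seed is required")
  obs <- pearson(x, y)
  nulls <- with_seed(seed, {
    vapply(seq_len(n_shuffles),
           function(i) stats::cor(x, sample(y)), numeric(1))
  })
  list(observed = obs, null = nulls, null_mean = mean(nulls),
       p_value = (1 + sum(abs(nulls) >= abs(obs))) / (n_shuffles + 1))
}

#' Stratify FRAP cells by expression level
#'
#' Ranks FRAP cells by their absolute pre-bleach chromocenter intensity
#' (`initial_chromo_intensity`, the expression proxy) and contrasts the
#' top-`k` ("high") against the bottom-`k` ("low") expressing cells,
#' returning each group's mean corrected curve and recovery summary. Ties
#' are broken by cell order.
#'
#' @param series_list List of `frap_series` objects (>= `2 * k` cells).
#' @param k Group size.
#' @return A list: `high`, `low` (each a [average_and_summarize()]
#'   `frap_fit`), `high_cells`, `low_cells` (cell ids).
#' @export
stratify_expression <- function(series_list, k = 10) {
  n <- length(series_list)
  if (n < 2 * k) stop("need at least 2 * k cells")
  intensity <- vapply(series_list, `[[`, numeric(1), "initial_chromo_intensity")
  ord <- order(intensity, seq_len(n))   # ties broken by cell order
  low_idx <- ord[seq_len(k)]
  high_idx <- ord[(n - k + 1L):n]
  ids <- vapply(series_list, `[[`, character(1), "cell_id")
  list(high = average_and_summarize(series_list[high_idx]),
       low = average_and_summarize(series_list[low_idx]),
       high_cells = ids[high_idx], low_cells = ids[low_idx])
}

#' Per-animal bound-fraction summary and group comparison
#'
#' Averages per-cell bound fractions within each animal and compares the two
#' conditions with a Mann-Whitney test on the per-cell values (default
#' alternative "greater": the first condition is expected to bind more, as
#' for wild type versus mutant).
#'
#' @param records A [cell_records()] data frame with `animal_id` set.
#' @param conditions Length-2 character vector: the two condition labels to
#'   compare, in order (first vs second).
#' @param alternative Alternative hypothesis for the first condition.
#' @return A list: `per_animal` (data frame `condition`, `animal_id`,
#'   `n_cells`, `mean_bound_fraction`), `statistic`, `p_value`.
#' @export
per_animal_summary <- function(records, conditions = NULL,
                               alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  if (is.null(conditions)) conditions <- unique(records$condition)
  agg <- stats::aggregate(bound_fraction ~ condition + animal_id,
                          data = records, FUN = mean)
  cnt <- stats::aggregate(bound_fraction ~ condition + animal_id,
                          data = records, FUN = length)
  per_animal <- data.frame(condition = agg$condition,
                           animal_id = agg$animal_id, n_cells = cnt$bound_fraction,
                           mean_bound_fraction = agg$bound_fraction,
                           stringsAsFactors = FALSE)
  statistic <- p_value <- NA_real_
  if (length(conditions) == 2) {
    a <- records$bound_fraction[records$condition == conditions[1]]
    b <- records$bound_fraction[records$condition == conditions[2]]
    if (!length(a) || !length(b)) stop("empty condition group")
    wt <- stats::wilcox.test(a, b, alternative = alternative,
                             exact = length(a) <= 20 && length(b) <= 20 &&
                               !any(duplicated(c(a, b))))
    statistic <- unname(wt$statistic); p_value <- wt$p.value
  }
  list(per_animal = per_animal, statistic = statistic, p_value = p_value,
       alternative = alternative)
}
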