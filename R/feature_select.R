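#' Feature-selection configuration
#'
#' Parameters of the amplitude-distribution analysis that decides, per
#' processing window, whether RS amplitude or amplitude-times-samples is the
#' feature handed to the clustering stage.
#'
#' @param n_bins number of equal histogram intervals over `[0, MA]`.
#' @param smooth_width width (bins) of the centred moving-average smoother;
#'   the window shrinks at the histogram edges.
#' @param dmax_frac fraction of MA separating the two post-minimum modes
#'   that distinguishes the large-separation case (amplitude feature) from
#'   the small-separation case (product feature).
#' @param prominence_floor post-minimum maxima with smoothed height below
#'   this fraction of total mass are ignored as noise wiggles.
#' @return An object of class `feature_config`.
#' @export
feature_config <- function(n_bins = 50, smooth_width = 5,
                           dmax_frac = 0.35, prominence_floor = 0.005) {
  n_bins <- as.integer(n_bins)
  smooth_width <- as.integer(smooth_width)
  if (n_bins < 2L) stopf("'n_bins' must be >= 2")
  if (smooth_width < 1L) stopf("'smooth_width' must be >= 1")
  if (dmax_frac <= 0 || dmax_frac >= 1) stopf("'dmax_frac' must be in (0,1)")
  if (prominence_floor < 0) stopf("'prominence_floor' must be >= 0")
  structure(list(n_bins = n_bins, smooth_width = smooth_width,
                 dmax_frac = dmax_frac, prominence_floor = prominence_floor),
            class = "feature_config")
}

# Centred moving average with shrinking window at the edges.
smooth_ma <- function(x, width) {
  h <- width %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    mean(x[lo:hi])
  }, numeric(1))
}

#' Smoothed normalised amplitude distribution of a window's max-min points
#'
#' The range `[0, MA]` (MA = maximum amplitude in the window) is split into
#' `n_bins` equal intervals (top edge inclusive); counts are normalised by
#' the total number of points and smoothed with a centred moving average.
#' Local extrema of the smoothed series are located (strict-neighbour rule,
#' plateau-at-first-bin, one-sided comparison at the boundary bins); the
#' first local minimum separates the near-zero noise mode from the beat
#' modes, and `dmax_max` is the amplitude-axis distance between the bin
#' centres of the two tallest local maxima beyond that minimum.
#'
#' @param points a `maxmin_points` data.frame with at least 2 rows.
#' @param config a [feature_config].
#' @return An object of class `distribution_summary`: `MA`, `bin_edges`
#'   (length `n_bins + 1`), `bin_centers`, `raw_counts`, `normalized`,
#'   `smoothed`, `maxima_bins`, `minima_bins`, `first_min_bin`,
#'   `post_min_maxima` (bins, prominence-filtered, tallest first),
#'   `dmax_max` (`NA` unless at least two post-minimum maxima exist).
#' @export
amplitude_distribution <- function(points, config = feature_config()) {
  if (nrow(points) < 2L) stopf("window too sparse (< 2 max-min points)")
  amps <- points$amplitude
  MA <- max(amps)
  nb <- config$n_bins
  binw <- MA / nb
  # right-closed bins; amplitude > 0 always, MA lands in the last bin
  bins <- pmin(pmax(ceiling(amps / binw), 1L), nb)
  raw <- tabulate(bins, nbins = nb)
  normalized <- raw / length(amps)
  smoothed <- smooth_ma(normalized, config$smooth_width)
  ex <- local_extrema(smoothed, boundary = TRUE)
  first_min <- if (length(ex$min_idx)) min(ex$min_idx) else NA_integer_
  post <- integer(0)
  if (!is.na(first_min)) {
    post <- ex$max_idx[ex$max_idx > first_min]
    post <- post[smoothed[post] >= config$prominence_floor]
    post <- post[order(smoothed[post], decreasing = TRUE)]
  }
  centers <- (seq_len(nb) - 0.5) * binw
  dmax <- if (length(post) >= 2L)
    abs(centers[post[1L]] - centers[post[2L]]) else NA_real_
  structure(list(MA = MA, bin_edges = seq(0, MA, length.out = nb + 1L),
                 bin_centers = centers, raw_counts = raw,
                 normalized = normalized, smoothed = smoothed,
                 maxima_bins = ex$max_idx, minima_bins = ex$min_idx,
                 first_min_bin = first_min, post_min_maxima = post,
                 dmax_max = dmax, n_points = length(amps),
                 config = config),
            class = "distribution_summary")
}

#' Select the clustering feature for a window
#'
#' Decision table on the number of prominent local maxima beyond the first
#' local minimum of the smoothed amplitude distribution:
#' * exactly two, separated by at least `dmax_frac * MA` — the fetal and
#'   maternal amplitude modes are distinct, so RS **amplitude** is the
#'   feature (`case1`);
#' * exactly two, separated by less — amplitudes overlap, so
#'   **amplitude x samples** is the feature (`case2`);
#' * exactly one — fetal and maternal amplitudes merge into one mode, again
#'   **amplitude x samples** (`case3`);
#' * none, or more than two — **amplitude**, as the conservative fallback.
#'
#' A tie at exactly `dmax_frac * MA` counts as the separated case.
#'
#' @param points a `maxmin_points` data.frame (>= 2 rows).
#' @param config a [feature_config].
#' @return An object of class `feature_choice`: `case_id` (`"case1"`,
#'   `"case2"`, `"case3"`, `"fallback"`), `scenario`, `feature_name`
#'   (`"amplitude"` or `"product"`), `feature_values` (aligned with
#'   `points` rows) and `summary` (the [amplitude_distribution()] result).
#' @export
select_feature <- function(points, config = feature_config()) {
  summary <- amplitude_distribution(points, config)
  npost <- length(summary$post_min_maxima)
  if (npost == 2L) {
    case_id <- if (summary$dmax_max >= config$dmax_frac * summary$MA)
      "case1" else "case2"
  } else if (npost == 1L) {
    case_id <- "case3"
  } else {
    case_id <- "fallback"
  }
  feature_name <- if (case_id %in% c("case2", "case3")) "product" else
    "amplitude"
  scenario <- if (feature_name == "product") "scenario2" else "scenario1"
  structure(list(case_id = case_id, scenario = scenario,
                 feature_name = feature_name,
                 feature_values = points[[feature_name]],
                 summary = summary),
            class = "feature_choice")
}

#' @export
print.feature_choice <- function(x, ...) {
  cat(sprintf("<feature_choice> %s (%s): feature '%s' over %d points\n",
              x$case_id, x$scenario, x$feature_name,
              length(x$feature_values)))
  invisible(x)
}
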