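#' Locate max-min points (RS-peak candidates)
#'
#' Scans the signal for every local maximum followed immediately (in the
#' sequence of local extrema) by a local minimum — the discrete signature of
#' an RS deflection.  For each pair two features are computed: the amplitude
#' distance `max_val - min_val` and the sample span `min_idx - max_idx`,
#' plus their product.  No amplitude or time gating is applied here: noise
#' events are emitted too and left for the clustering stage to separate.
#'
#' Plateaus (runs of equal samples bounded by strictly smaller/larger
#' neighbours) count as a single extremum located at the run's first sample.
#' A local maximum whose next extremum is not a minimum is discarded.
#'
#' @param record an [ecg_record] (typically denoised).
#' @return A data.frame of class `maxmin_points`, ordered by `max_idx`, with
#'   columns `max_idx`, `min_idx` (0-based samples), `max_val`, `min_val`,
#'   `amplitude` (> 0), `n_samples` (>= 1) and `product`
#'   (`amplitude * n_samples`).  May have zero rows.
#' @export
#' @examples
#' r <- ecg_record(c(0, 1, 0, -1, 0), fs = 10)
#' find_maxmin_points(r)
find_maxmin_points <- function(record) {
  stopifnot(inherits(record, "ecg_record"))
  x <- record$samples
  empty <- data.frame(max_idx = integer(0), min_idx = integer(0),
                      max_val = numeric(0), min_val = numeric(0),
                      amplitude = numeric(0), n_samples = integer(0),
                      product = numeric(0))
  if (record$n < 3L) return(structure(empty, class = c("maxmin_points",
                                                       "data.frame")))
  ex <- local_extrema(x, boundary = FALSE)
  if (length(ex$max_idx) == 0L || length(ex$min_idx) == 0L)
    return(structure(empty, class = c("maxmin_points", "data.frame")))
  # merge extrema in index order; keep max immediately followed by min
  all_idx <- c(ex$max_idx, ex$min_idx)
  typ <- c(rep(1L, length(ex$max_idx)), rep(-1L, length(ex$min_idx)))
  o <- order(all_idx)
  all_idx <- all_idx[o]; typ <- typ[o]
  k <- length(all_idx)
  sel <- which(typ[-k] == 1L & typ[-1L] == -1L)
  if (length(sel) == 0L)
    return(structure(empty, class = c("maxmin_points", "data.frame")))
  mx <- all_idx[sel]; mn <- all_idx[sel + 1L]
  df <- data.frame(max_idx = mx - 1L, min_idx = mn - 1L,
                   max_val = x[mx], min_val = x[mn],
                   amplitude = x[mx] - x[mn],
                   n_samples = mn - mx,
                   product = (x[mx] - x[mn]) * (mn - mx))
  structure(df, class = c("maxmin_points", "data.frame"))
}
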