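#' Full-pipeline configuration
#'
#' Bundles the per-stage configurations and the windowing policy.  The
#' record is denoised once as a whole (avoiding window-edge wavelet
#' artifacts); feature extraction, feature selection, clustering and
#' refinement then run per window of `window_samples` samples, and the
#' RR-based FP/FN correction runs once on the concatenated beat train.
#'
#' @param window_samples processing window length in samples (default
#'   50,000; classification quality is insensitive over roughly
#'   10,000-60,000).
#' @param min_final_window a trailing partial window at least this long is
#'   processed on its own; a shorter one is merged into the previous window.
#' @param denoise a [denoise_config].
#' @param feature a [feature_config].
#' @param cluster a [cluster_config]; its seed is re-derived per window from
#'   `seed` so the whole run is reproducible.
#' @param refine a [refine_config].
#' @param correction a [correction_config].
#' @param eval_tol_ms matching tolerance (ms) used for seam-duplicate
#'   merging and downstream evaluation.
#' @param denoise_per_window denoise each window separately instead of the
#'   whole record.
#' @param seed integer master seed for all stochastic stages.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(window_samples = 50000, min_final_window = 10000,
                            denoise = denoise_config(),
                            feature = feature_config(),
                            cluster = cluster_config(),
                            refine = refine_config(),
                            correction = correction_config(),
                            eval_tol_ms = 50, denoise_per_window = FALSE,
                            seed = 1L) {
  if (window_samples < 1000) stopf("'window_samples' must be >= 1000")
  structure(list(window_samples = as.integer(window_samples),
                 min_final_window = as.integer(min_final_window),
                 denoise = denoise, feature = feature, cluster = cluster,
                 refine = refine, correction = correction,
                 eval_tol_ms = eval_tol_ms,
                 denoise_per_window = isTRUE(denoise_per_window),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# Window start/end (0-based, end exclusive) under the final-partial rule.
window_bounds <- function(n, window_samples, min_final) {
  starts <- seq.int(0L, n - 1L, by = window_samples)
  ends <- pmin(starts + window_samples, n)
  if (length(starts) > 1L && (ends[length(ends)] - starts[length(starts)]) <
        min_final) {
    ends[length(ends) - 1L] <- n
    starts <- starts[-length(starts)]
    ends <- ends[-length(ends)]
  }
  data.frame(start = starts, end = ends)
}

#' Run the full fetal QRS extraction pipeline
#'
#' Denoise, locate max-min points, then per window: select the
#' classification feature from the amplitude distribution, cluster into
#' maternal/fetal/noise with ++-seeded k-medoids, assign roles by cluster
#' median, and refine the fetal cluster with distribution-derived limits.
#' Detections from adjacent windows closer than the matching tolerance are
#' merged (larger amplitude wins) and the RR-based FP/FN correction is
#' applied once to the global fetal train.
#'
#' Windows whose max-min points cannot support a 3-cluster split (too few
#' points or fewer than 3 distinct feature values) contribute no detections
#' and are flagged in the diagnostics.
#'
#' @param record an [ecg_record] (raw; denoising is part of the pipeline).
#' @param config a [pipeline_config].
#' @return An object of class `fhr_pipeline_result`: `fetal` and `maternal`
#'   [annotation_set]s, `diagnostics` (per-window data.frame), `audit` (the
#'   FP/FN correction trail) and `denoised` (the denoised record).
#' @export
#' @examples
#' \donttest{
#' synth <- generate_aecg(scenario_preset("scenario1", duration_s = 60))
#' res <- run_pipeline(synth$record,
#'                     pipeline_config(window_samples = 20000, seed = 1))
#' run_evaluation(res$fetal, synth$fetal_truth, fs = synth$record$fs)
#' }
run_pipeline <- function(record, config = pipeline_config()) {
  stopifnot(inherits(record, "ecg_record"),
            inherits(config, "pipeline_config"))
  if (record$n < 1000L) stopf("record shorter than 1,000 samples")
  den <- if (config$denoise_per_window) record else
    denoise(record, config$denoise)
  bounds <- window_bounds(record$n, config$window_samples,
                          config$min_final_window)
  all_points <- if (config$denoise_per_window) NULL else
    find_maxmin_points(den)
  fetal_rows <- list()
  maternal_idx <- integer(0)
  diag_rows <- list()
  for (w in seq_len(nrow(bounds))) {
    s <- bounds$start[w]; e <- bounds$end[w]
    if (config$denoise_per_window) {
      seg <- ecg_record(record$samples[(s + 1L):e], fs = record$fs,
                        record_id = record$record_id, channel = record$channel)
      pts <- find_maxmin_points(denoise(seg, config$denoise))
      pts$max_idx <- pts$max_idx + s
      pts$min_idx <- pts$min_idx + s
    } else {
      pts <- all_points[all_points$max_idx >= s & all_points$max_idx < e, ,
                        drop = FALSE]
    }
    base_diag <- data.frame(window = w, start = s, end = e,
                            n_points = nrow(pts))
    if (nrow(pts) < 10L) {
      diag_rows[[w]] <- cbind(base_diag, case_id = "skipped",
                              feature = NA, n_fetal_raw = 0L,
                              n_fetal_refined = 0L)
      next
    }
    choice <- select_feature(pts, config$feature)
    if (length(unique(choice$feature_values)) < 3L) {
      diag_rows[[w]] <- cbind(base_diag, case_id = "skipped",
                              feature = choice$feature_name,
                              n_fetal_raw = 0L, n_fetal_refined = 0L)
      next
    }
    ccfg <- config$cluster
    ccfg$seed <- config$seed + w          # reproducible per-window stream
    km <- assign_roles(kmedoids_pp(choice$feature_values, ccfg))
    fet <- refine_fetal_cluster(pts, km, choice$summary, config$refine,
                                fs = record$fs)
    if (nrow(fet))
      fetal_rows[[length(fetal_rows) + 1L]] <- cbind(fet, window = w)
    maternal_idx <- c(maternal_idx,
                      pts$max_idx[km$roles[km$labels] == "maternal"])
    diag_rows[[w]] <- cbind(base_diag, case_id = choice$case_id,
                            feature = choice$feature_name,
                            n_fetal_raw = sum(km$roles[km$labels] == "fetal"),
                            n_fetal_refined = nrow(fet))
  }
  fet_all <- if (length(fetal_rows)) do.call(rbind, fetal_rows) else
    data.frame(max_idx = integer(0), amplitude = numeric(0),
               window = integer(0))
  fet_all <- fet_all[order(fet_all$max_idx), , drop = FALSE]

  ## merge seam duplicates: detections from different windows within the
  ## matching tolerance collapse to the larger-amplitude one
  tol <- config$eval_tol_ms * record$fs / 1000
  if (nrow(fet_all) >= 2L) {
    keep <- rep(TRUE, nrow(fet_all))
    for (i in 2:nrow(fet_all)) {
      prev <- max(which(keep[1:(i - 1L)]))
      if (fet_all$window[i] != fet_all$window[prev] &&
          fet_all$max_idx[i] - fet_all$max_idx[prev] <= tol) {
        if (fet_all$amplitude[i] >= fet_all$amplitude[prev])
          keep[prev] <- FALSE else keep[i] <- FALSE
      }
    }
    fet_all <- fet_all[keep, , drop = FALSE]
  }

  corrected <- correct_fp_fn(fet_all$max_idx, den, config$correction,
                             points = if (config$denoise_per_window) NULL
                                      else all_points)
  diagnostics <- do.call(rbind, diag_rows)
  structure(
    list(fetal = annotation_set(as.integer(corrected),
                                record_id = record$record_id,
                                kind = "fetal_detected"),
         maternal = annotation_set(unique(maternal_idx),
                                   record_id = record$record_id,
                                   kind = "maternal_detected"),
         diagnostics = diagnostics,
         audit = attr(corrected, "audit"),
         denoised = den,
         config = config),
    class = "fhr_pipeline_result")
}

#' @export
print.fhr_pipeline_result <- function(x, ...) {
  cat(sprintf(
    "<fhr_pipeline_result> %d fetal, %d maternal detections over %d windows\n",
    length(x$fetal$indices), length(x$maternal$indices),
    nrow(x$diagnostics)))
  invisible(x)
}

#' Evaluate detections against reference annotations
#'
#' Convenience composition of [match_detections()] and [compute_metrics()].
#'
#' @param detected,reference [annotation_set]s (or index vectors).
#' @param fs sampling rate in Hz.
#' @param tol_ms matching tolerance, ms.
#' @return An [compute_metrics()] `eval_report`.
#' @export
run_evaluation <- function(detected, reference, fs, tol_ms = 50) {
  m <- match_detections(detected, reference, fs, tol_ms)
  rid <- if (inherits(detected, "annotation_set")) detected$record_id else ""
  compute_metrics(m$TD, m$FN, m$FP, record_id = rid, tol_ms = tol_ms)
}
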