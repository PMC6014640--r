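#' Fetal-cluster refinement configuration
#'
#' Limits on amplitude and RS time span applied to the points classified as
#' fetal.  By default the amplitude bounds are derived from the window's
#' smoothed amplitude distribution: the lower bound is the bin-centre
#' amplitude of the first local minimum (the noise/fetal boundary) and,
#' when the distribution shows two well-separated post-minimum modes
#' (identifiably fetal and maternal), the upper bound is the midpoint
#' between those mode centres; otherwise the upper bound is MA.
#'
#' @param rs_width_max_ms maximal admissible fetal RS span, ms.
#' @param amp_low,amp_high absolute amplitude bounds overriding the
#'   distribution-derived ones (`NULL` = derive from the distribution).
#' @param dmax_frac mode-separation fraction used to decide whether fetal
#'   and maternal amplitude modes are identifiable (matches
#'   [feature_config()]'s `dmax_frac`).
#' @param maternal_refractory_ms half-width of an exclusion window around
#'   maternal R-peaks for duplicate suppression; 0 (default) disables it.
#' @return An object of class `refine_config`.
#' @export
refine_config <- function(rs_width_max_ms = 60, amp_low = NULL,
                          amp_high = NULL, dmax_frac = 0.35,
                          maternal_refractory_ms = 0) {
  if (rs_width_max_ms < 0 || maternal_refractory_ms < 0)
    stopf("time limits must be >= 0 ms")
  structure(list(rs_width_max_ms = rs_width_max_ms, amp_low = amp_low,
                 amp_high = amp_high, dmax_frac = dmax_frac,
                 maternal_refractory_ms = maternal_refractory_ms),
            class = "refine_config")
}

#' Refine the fetal cluster with amplitude and time limits
#'
#' Keeps the fetal-role points whose amplitude lies inside
#' `[A_low, A_high]` and whose RS span does not exceed
#' `rs_width_max_ms`; see [refine_config()] for how the bounds are derived
#' from the window's amplitude distribution.
#'
#' @param points the window's `maxmin_points` data.frame.
#' @param result a role-assigned [kmedoids_pp()] result for those points.
#' @param summary the window's [amplitude_distribution()] summary.
#' @param config a [refine_config].
#' @param fs sampling rate in Hz (to convert the ms limit to samples).
#' @return The surviving fetal candidate rows of `points`, ordered by
#'   `max_idx` (possibly zero rows).
#' @export
refine_fetal_cluster <- function(points, result, summary,
                                 config = refine_config(), fs) {
  stopifnot(inherits(result, "kmedoids_result"))
  if (all(is.na(result$roles))) stopf("roles not assigned; run assign_roles()")
  fet <- points[result$roles[result$labels] == "fetal", , drop = FALSE]
  if (nrow(fet) == 0L) return(fet)
  a_low <- config$amp_low
  if (is.null(a_low)) {
    a_low <- if (!is.na(summary$first_min_bin))
      summary$bin_centers[summary$first_min_bin] else 0
  }
  a_high <- config$amp_high
  if (is.null(a_high)) {
    a_high <- summary$MA
    post <- summary$post_min_maxima
    if (length(post) == 2L && !is.na(summary$dmax_max) &&
        summary$dmax_max >= config$dmax_frac * summary$MA) {
      a_high <- mean(summary$bin_centers[post[1:2]])
    }
  }
  max_span <- config$rs_width_max_ms * fs / 1000
  keep <- fet$amplitude >= a_low & fet$amplitude <= a_high &
    fet$n_samples <= max_span
  fet <- fet[keep, , drop = FALSE]
  if (config$maternal_refractory_ms > 0) {
    mat_idx <- points$max_idx[result$roles[result$labels] == "maternal"]
    if (length(mat_idx) && nrow(fet)) {
      half <- config$maternal_refractory_ms * fs / 1000
      near <- vapply(fet$max_idx,
                     function(i) any(abs(mat_idx - i) <= half), logical(1))
      fet <- fet[!near, , drop = FALSE]
    }
  }
  fet[order(fet$max_idx), , drop = FALSE]
}

#' RR-correction configuration
#'
#' Plausibility gates for the final false-positive / false-negative
#' correction pass, expressed as multiples of the running-median RR
#' interval and as an absolute physiological fetal-heart-rate band.
#'
#' @param fhr_min_bpm,fhr_max_bpm physiological FHR band, beats/min.
#' @param short_rr_frac RR intervals below this multiple of the running
#'   median flag a false positive.
#' @param long_rr_frac RR intervals above this multiple flag a gap with
#'   missed beats.
#' @param median_window_beats beats in the centred running-median window
#'   (shrunk at the train's ends).
#' @param search_margin_ms half-width, ms, of the search window around an
#'   expected beat position when recovering a missed beat.
#' @return An object of class `correction_config`.
#' @export
correction_config <- function(fhr_min_bpm = 100, fhr_max_bpm = 220,
                              short_rr_frac = 0.5, long_rr_frac = 1.5,
                              median_window_beats = 9,
                              search_margin_ms = 30) {
  if (fhr_min_bpm >= fhr_max_bpm) stopf("fhr_min_bpm must be < fhr_max_bpm")
  if (!(short_rr_frac > 0 && short_rr_frac < 1 && long_rr_frac > 1))
    stopf("require 0 < short_rr_frac < 1 < long_rr_frac")
  structure(list(fhr_min_bpm = fhr_min_bpm, fhr_max_bpm = fhr_max_bpm,
                 short_rr_frac = short_rr_frac, long_rr_frac = long_rr_frac,
                 median_window_beats = as.integer(median_window_beats),
                 search_margin_ms = search_margin_ms),
            class = "correction_config")
}

# Centred running median with a window shrinking at the ends.
running_median <- function(x, width) {
  h <- width %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i)
    stats::median(x[max(1L, i - h):min(n, i + h)]), numeric(1))
}

#' Correct false positives and false negatives from RR plausibility
#'
#' Two forward passes over the candidate fetal R-peak train.  FP pass: when
#' an RR interval is shorter than `short_rr_frac` times the local running
#' median RR, or implies a rate above `fhr_max_bpm`, the member of the pair
#' with the smaller RS amplitude is dropped.  FN pass: when an RR interval
#' exceeds `long_rr_frac` times the local median, or implies a rate below
#' `fhr_min_bpm`, the gap is scanned at each expected beat position (evenly
#' spaced) within `search_margin_ms` for the largest-amplitude unused
#' max-min point, which is inserted if found; unresolved gaps are logged in
#' the audit trail.
#'
#' @param candidates strictly increasing 0-based R-peak sample indices
#'   (numeric vector or [annotation_set]).
#' @param record the denoised [ecg_record] the candidates refer to; used to
#'   (re)compute max-min points when `points` is not supplied.
#' @param config a [correction_config].
#' @param points optionally, the precomputed `maxmin_points` of `record`.
#' @return Corrected integer index vector (strictly increasing) with
#'   attribute `audit`: a data.frame of removals/insertions/unresolved gaps.
#' @export
correct_fp_fn <- function(candidates, record, config = correction_config(),
                          points = NULL) {
  if (inherits(candidates, "annotation_set")) candidates <- candidates$indices
  cand <- as.integer(candidates)
  if (is.unsorted(cand, strictly = TRUE)) stopf("candidates must be strictly increasing")
  audit <- data.frame(action = character(0), index = integer(0),
                      reason = character(0))
  if (length(cand) < 2L) {
    attr(cand, "audit") <- audit
    return(cand)
  }
  fs <- record$fs
  if (is.null(points)) points <- find_maxmin_points(record)
  amp_of <- function(idx) {
    m <- match(idx, points$max_idx)
    a <- points$amplitude[m]
    a[is.na(a)] <- 0        # indices not backed by a max-min point
    a
  }
  rr_max <- 60 / config$fhr_min_bpm * fs   # longest plausible RR, samples
  rr_min <- 60 / config$fhr_max_bpm * fs   # shortest plausible RR, samples

  ## FP pass -----------------------------------------------------------
  rr0 <- diff(cand)
  med0 <- running_median(rr0, config$median_window_beats)
  kept <- cand[1L]
  pos <- 1L                                # index into the original RR series
  for (i in 2:length(cand)) {
    rr <- cand[i] - kept[length(kept)]
    med <- med0[min(pos, length(med0))]
    if (rr < config$short_rr_frac * med || rr < rr_min) {
      prev <- kept[length(kept)]
      if (amp_of(cand[i]) < amp_of(prev)) {
        audit <- rbind(audit, data.frame(action = "remove", index = cand[i],
                                         reason = "short RR"))
      } else {
        audit <- rbind(audit, data.frame(action = "remove", index = prev,
                                         reason = "short RR"))
        kept[length(kept)] <- cand[i]
      }
    } else {
      kept <- c(kept, cand[i])
    }
    pos <- i - 1L
  }

  ## FN pass -----------------------------------------------------------
  if (length(kept) >= 2L) {
    rr1 <- diff(kept)
    med1 <- running_median(rr1, config$median_window_beats)
    margin <- config$search_margin_ms * fs / 1000
    used <- kept
    out <- kept[1L]
    for (i in seq_along(rr1)) {
      gap <- rr1[i]
      if (gap > config$long_rr_frac * med1[i] || gap > rr_max) {
        n_missing <- max(1L, round(gap / med1[i]) - 1L)
        for (j in seq_len(n_missing)) {
          expected <- kept[i] + j * gap / (n_missing + 1L)
          in_win <- which(points$max_idx >= expected - margin &
                            points$max_idx <= expected + margin &
                            !(points$max_idx %in% used))
          if (length(in_win)) {
            pick <- in_win[which.max(points$amplitude[in_win])]
            ins <- points$max_idx[pick]
            used <- c(used, ins)
            out <- c(out, ins)
            audit <- rbind(audit, data.frame(action = "insert", index = ins,
                                             reason = "long RR gap"))
          } else {
            audit <- rbind(audit,
                           data.frame(action = "gap_unresolved",
                                      index = as.integer(round(expected)),
                                      reason = "no max-min point in window"))
          }
        }
      }
      out <- c(out, kept[i + 1L])
    }
    kept <- sort(unique(out))
  }
  res <- as.integer(kept)
  attr(res, "audit") <- audit
  res
}
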