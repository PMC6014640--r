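#' Match detections to reference beats within a time tolerance
#'
#' One-to-one greedy matching: reference beats are visited in order and
#' each is paired with the nearest unused detection within `tol_ms`.
#' Matched references are true detections (TD), unmatched references are
#' false negatives (FN), and leftover detections are false positives (FP).
#'
#' @param detected,reference [annotation_set]s (or 0-based index vectors)
#'   on the same record.
#' @param fs sampling rate in Hz.
#' @param tol_ms matching tolerance, ms (default 50: candidates differing
#'   by more than 50 ms from the reference are counted as FPs).
#' @return List with `TD`, `FN`, `FP` and `pairing`, a data.frame of
#'   matched (reference, detection) index pairs and their error in ms.
#' @export
match_detections <- function(detected, reference, fs, tol_ms = 50) {
  assert_scalar_num(fs, "fs", positive = TRUE)
  if (inherits(detected, "annotation_set")) detected <- detected$indices
  if (inherits(reference, "annotation_set")) reference <- reference$indices
  detected <- sort(as.numeric(detected))
  reference <- sort(as.numeric(reference))
  tol <- tol_ms * fs / 1000
  used <- logical(length(detected))
  ref_m <- integer(0); det_m <- integer(0)
  for (r in seq_along(reference)) {
    if (!length(detected)) break
    dist <- abs(detected - reference[r])
    dist[used] <- Inf
    j <- which.min(dist)
    if (length(j) && dist[j] <= tol) {
      used[j] <- TRUE
      ref_m <- c(ref_m, r); det_m <- c(det_m, j)
    }
  }
  TD <- length(ref_m)
  pairing <- data.frame(reference = reference[ref_m],
                        detected = detected[det_m],
                        error_ms = (detected[det_m] - reference[ref_m]) /
                          fs * 1000)
  list(TD = TD, FN = length(reference) - TD, FP = length(detected) - TD,
       pairing = pairing)
}

#' Detection performance metrics
#'
#' Sensitivity, positive predictive value, accuracy and F1 measure as
#' percentages:
#' `Se = 100 TD/(TD+FN)`, `PPV = 100 TD/(TD+FP)`,
#' `Acc = 100 TD/(TD+FN+FP)`, `F1 = 100 * 2 TD/(2 TD+FN+FP)`
#' (equivalently `2*PPV*Se/(PPV+Se)`).  Degenerate denominators (no
#' detections at all) yield 0 with a warning.
#'
#' @param TD,FN,FP true-detection, false-negative, false-positive counts.
#' @param record_id optional record label carried into the report.
#' @param tol_ms matching tolerance recorded in the report.
#' @return An object of class `eval_report` with raw (unrounded) metric
#'   fields `Se`, `PPV`, `Acc`, `F1`, the counts, and `total_fqrs = TD+FN`.
#'   The print method displays 2-decimal (half-up) values.
#' @export
#' @examples
#' compute_metrics(TD = 637, FN = 6, FP = 2)
compute_metrics <- function(TD, FN, FP, record_id = "", tol_ms = 50) {
  if (any(c(TD, FN, FP) < 0)) stopf("counts must be >= 0")
  if (TD + FN == 0) stopf("no reference beats (TD + FN == 0)")
  Se <- 100 * TD / (TD + FN)
  PPV <- if (TD + FP > 0) 100 * TD / (TD + FP) else {
    warnf("no detections: PPV undefined, reported as 0")
    0
  }
  Acc <- 100 * TD / (TD + FN + FP)
  F1 <- 100 * 2 * TD / (2 * TD + FN + FP)
  structure(list(record_id = record_id, total_fqrs = TD + FN,
                 TD = TD, FN = FN, FP = FP,
                 Se = Se, PPV = PPV, Acc = Acc, F1 = F1, tol_ms = tol_ms),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report>%s %d reference beats (tol %g ms)\n",
              if (nzchar(x$record_id)) paste0(" '", x$record_id, "':") else "",
              x$total_fqrs, x$tol_ms))
  cat(sprintf("  TD=%d FN=%d FP=%d\n", x$TD, x$FN, x$FP))
  cat(sprintf("  Se=%.2f%% PPV=%.2f%% Acc=%.2f%% F1=%.2f%%\n",
              round_half_up(x$Se), round_half_up(x$PPV),
              round_half_up(x$Acc), round_half_up(x$F1)))
  invisible(x)
}

#' Fetal heart rate series from detected beats
#'
#' Successive RR intervals and the instantaneous rate `60 / RR`, aligned to
#' the later beat of each pair.  No smoothing is applied.
#'
#' @param detected an [annotation_set] (or 0-based index vector) with at
#'   least 2 beats.
#' @param fs sampling rate in Hz.
#' @return An object of class `fhr_series`: `beat_times_s`, `rr_s`, `bpm`.
#' @export
#' @examples
#' fhr_series(annotation_set(seq(0, 4000, by = 400)), fs = 1000)$bpm
fhr_series <- function(detected, fs) {
  assert_scalar_num(fs, "fs", positive = TRUE)
  if (inherits(detected, "annotation_set")) detected <- detected$indices
  if (length(detected) < 2L) stopf("need >= 2 beats for an FHR series")
  t <- sort(as.numeric(detected)) / fs
  rr <- diff(t)
  structure(list(beat_times_s = t, rr_s = rr, bpm = 60 / rr),
            class = "fhr_series")
}

#' @export
print.fhr_series <- function(x, ...) {
  cat(sprintf("<fhr_series> %d beats over %.1f s, mean rate %.1f bpm\n",
              length(x$beat_times_s),
              diff(range(x$beat_times_s)), mean(x$bpm)))
  invisible(x)
}
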