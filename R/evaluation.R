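#' Rasterize segments to a per-sample logical mask
#'
#' Sample `i` (1-based) covers the half-open interval `[(i-1)/fs, i/fs)`; a
#' sample is marked when its interval lies inside a segment `[start_s, end_s)`.
#'
#' @param segments Tibble/data frame with `start_s`, `end_s` (disjoint, sorted).
#' @param rec_duration_s Recording duration in seconds.
#' @param fs Sampling rate in Hz.
#' @return Logical vector of length `round(rec_duration_s * fs)`.
#' @export
segments_to_mask <- function(segments, rec_duration_s, fs) {
  n <- round(rec_duration_s * fs)
  mask <- logical(n)
  if (NROW(segments) == 0) return(mask)
  check_segments(segments, rec_duration_s)
  for (i in seq_len(nrow(segments))) {
    s0 <- round(segments$start_s[i] * fs)
    s1 <- round(segments$end_s[i] * fs)
    if (s1 > s0) mask[(s0 + 1):min(s1, n)] <- TRUE
  }
  mask
}

check_segments <- function(segments, rec_duration_s = Inf, arg = "segments") {
  st <- segments$start_s; en <- segments$end_s
  if (any(en <= st)) {
    rps_error(sprintf("`%s` contains empty or inverted intervals", arg),
              "rps_usage_error")
  }
  if (any(st < 0) || any(en > rec_duration_s + 1e-9)) {
    rps_error(sprintf("`%s` exceeds the recording bounds", arg),
              "rps_usage_error")
  }
  if (is.unsorted(st) || any(st[-1] < en[-length(en)] - 1e-9)) {
    rps_error(sprintf("`%s` must be sorted and non-overlapping", arg),
              "rps_usage_error")
  }
  invisible(segments)
}

#' Convert a per-sample mask back to segments
#'
#' @param mask Logical vector.
#' @param fs Sampling rate in Hz.
#' @param source Value for the `source` column.
#' @return Tibble with `start_s`, `end_s`, `source`.
#' @export
mask_to_segments <- function(mask, fs, source = "expert") {
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- which(r$values)
  tibble::tibble(start_s = (starts[on] - 1) / fs, end_s = ends[on] / fs,
                 source = rep(source, length(on)))
}

#' Sample-wise confusion counts with fuzzy artifact borders
#'
#' Both labelings are rasterized to per-sample masks.  Agreeing samples are TP
#' (both marked) or TN (both clean).  Disagreeing runs adjacent to an expert
#' artifact border are "residual segments": under the `"literal"` rule a
#' residual is forgiven (detected-only counted TP, expert-only counted TN)
#' when it lasts at least `min_fraction` of the adjacent expert artifact's
#' duration and no more than `max_lenient_s`; otherwise it counts FP / FN.
#' Disagreeing runs not touching any expert border are plain FP / FN.  A
#' residual touching two artifacts uses the longer artifact for the fraction
#' test.
#'
#' @param detected,expert Segment tables (`start_s`, `end_s`), each internally
#'   disjoint and sorted.
#' @param rec_duration_s Recording duration in seconds.
#' @param fs Sampling rate in Hz.
#' @param min_fraction Minimum residual duration as a fraction of the adjacent
#'   artifact (default 0.10).
#' @param max_lenient_s Leniency cap in seconds (default 1.5).
#' @param rule `"literal"` applies both conditions; `"cap"` forgives any
#'   residual up to `max_lenient_s` (drops the fraction floor, so very small
#'   overshoots are not penalized); `"strict"` disables leniency entirely.
#' @return An object of class `confusion_counts`: list with `tp`, `fp`, `tn`,
#'   `fn` sample counts.
#' @export
fuzzy_confusion <- function(detected, expert, rec_duration_s, fs,
                            min_fraction = 0.10, max_lenient_s = 1.5,
                            rule = c("literal", "cap", "strict")) {
  rule <- match.arg(rule)
  det <- segments_to_mask(detected, rec_duration_s, fs)
  exp <- segments_to_mask(expert, rec_duration_s, fs)
  n <- length(det)
  tp <- sum(det & exp)
  tn <- sum(!det & !exp)
  fp <- 0L; fn <- 0L

  if (rule == "strict") {
    fp <- sum(det & !exp)
    fn <- sum(!det & exp)
    return(new_confusion(tp, fp, tn, fn))
  }

  # expert artifact index per sample (0 = clean), for adjacency lookups
  exp_segs <- if (NROW(expert)) expert else NULL
  exp_id <- integer(n)
  exp_dur <- numeric(0)
  if (!is.null(exp_segs)) {
    for (i in seq_len(nrow(exp_segs))) {
      s0 <- round(exp_segs$start_s[i] * fs); s1 <- round(exp_segs$end_s[i] * fs)
      if (s1 > s0) exp_id[(s0 + 1):min(s1, n)] <- i
    }
    exp_dur <- exp_segs$end_s - exp_segs$start_s
  }

  code <- det * 2L + exp  # 0 TN, 1 expert-only, 2 detected-only, 3 TP
  r <- rle(code)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (q in seq_along(r$values)) {
    v <- r$values[q]
    if (v != 1L && v != 2L) next
    a <- starts[q]; b <- ends[q]
    len <- b - a + 1L
    dur <- len / fs
    if (v == 2L) {
      # detected-only: adjacent if it abuts an expert artifact
      ids <- c(if (a > 1) exp_id[a - 1] else 0L,
               if (b < n) exp_id[b + 1] else 0L)
    } else {
      # expert-only: inside artifact exp_id[a]; adjacent if it touches the
      # artifact's own border
      id <- exp_id[a]
      touches <- (a == 1 || exp_id[a - 1] != id) ||
                 (b == n || exp_id[b + 1] != id)
      ids <- if (touches) id else 0L
    }
    ids <- unique(ids[ids > 0L])
    lenient <- FALSE
    if (length(ids)) {
      art_dur <- max(exp_dur[ids])
      lenient <- switch(rule,
        literal = dur >= min_fraction * art_dur && dur <= max_lenient_s,
        cap     = dur <= max_lenient_s)
    }
    if (v == 2L) {
      if (lenient) tp <- tp + len else fp <- fp + len
    } else {
      if (lenient) tn <- tn + len else fn <- fn + len
    }
  }
  new_confusion(tp, fp, tn, fn)
}

new_confusion <- function(tp, fp, tn, fn) {
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 tn = as.integer(tn), fn = as.integer(fn)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP %d  FP %d  TN %d  FN %d\n",
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Agreement metrics from confusion counts
#'
#' Cohen's kappa \eqn{K = (P_o - P_r)/(1 - P_r)} with the observed agreement
#' \eqn{P_o = (TP+TN)/N} and the chance agreement computed from the two
#' raters' marginals, plus sensitivity \eqn{Se = TP/(TP+FN)} and false
#' discovery rate \eqn{FDR = FP/(TP+FP)}.  `Se` is `NA` when `TP+FN = 0`
#' and `FDR` is `NA` when `TP+FP = 0`.
#'
#' @param counts A `confusion_counts` object (or list with tp/fp/tn/fn).
#' @return One-row tibble: `kappa`, `agreement`, `sensitivity`, `fdr`,
#'   `artifact_rate_detected`, `tp`, `fp`, `tn`, `fn`.
#' @export
kappa_from_counts <- function(counts) {
  tp <- as.numeric(counts$tp); fp <- as.numeric(counts$fp)
  tn <- as.numeric(counts$tn); fn <- as.numeric(counts$fn)
  total <- tp + fp + tn + fn
  if (is.null(total) || total <= 0) {
    rps_error("confusion counts sum to zero", "rps_usage_error")
  }
  po <- (tp + tn) / total
  pr <- ((tp + fn) * (tp + fp) + (tn + fp) * (tn + fn)) / total^2
  kappa <- if (abs(1 - pr) < 1e-15) NA_real_ else (po - pr) / (1 - pr)
  se <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  fdr <- if (tp + fp > 0) fp / (tp + fp) else NA_real_
  tibble::tibble(kappa = kappa, agreement = po, sensitivity = se, fdr = fdr,
                 artifact_rate_detected = (tp + fp) / total,
                 tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Evaluate detected segments against expert annotations
#'
#' Convenience composition of [fuzzy_confusion()] and [kappa_from_counts()].
#'
#' @inheritParams fuzzy_confusion
#' @return One-row tibble of agreement metrics.
#' @export
evaluate_detection <- function(detected, expert, rec_duration_s, fs,
                               min_fraction = 0.10, max_lenient_s = 1.5,
                               rule = c("literal", "cap", "strict")) {
  counts <- fuzzy_confusion(detected, expert, rec_duration_s, fs,
                            min_fraction, max_lenient_s, match.arg(rule))
  kappa_from_counts(counts)
}
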