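#' Behavioral and fMRI-based arousal indices
#'
#' The behavioral arousal index summarizes a pupil trace per fMRI frame
#' (median within the TR bin, divided by the per-scan maximum). The fMRI
#' arousal index projects an arousal spatial template (per-region correlation
#' of BOLD with the HRF-convolved behavioral index) onto successive frames.
#'
#' @name arousal
NULL

#' Behavioral arousal index from a pupil trace
#'
#' Each frame's value is the median of the valid (non-missing) pupil samples
#' within its TR bin, then the whole series is divided by the per-scan
#' maximum so that 1 corresponds to the eye fully open. Fast blinks (shorter
#' than half the bin) do not move the median. Frames whose bin has no valid
#' sample are linearly interpolated and flagged.
#'
#' @param pupil_trace numeric vector, `NA` for missing samples.
#' @param fps pupil sampling rate (Hz).
#' @param tr frame interval (s); `fps * tr` samples per frame.
#' @return list of class `arousal_trace`: `index` (per frame, in \[0, 1\]),
#'   `kind = "behavioral"`, `eye_open_ratio` (fraction of frames with at
#'   least half their samples valid), `interpolated` (logical flags).
#' @export
behavioral_index <- function(pupil_trace, fps = 6, tr = 2) {
  spf <- fps * tr
  if (spf < 1 || abs(spf - round(spf)) > 1e-9) {
    stop("fps * tr must be a positive integer")
  }
  spf <- as.integer(round(spf))
  n_frames <- length(pupil_trace) %/% spf
  bins <- matrix(pupil_trace[seq_len(n_frames * spf)], nrow = spf)
  med <- apply(bins, 2, function(x) median(x, na.rm = TRUE))
  valid <- colSums(!is.na(bins))
  interpolated <- valid == 0
  if (any(interpolated)) {
    ok <- which(!interpolated)
    med[interpolated] <- approx(ok, med[ok], xout = which(interpolated),
                                rule = 2)$y
  }
  idx <- med / max(med)
  structure(list(index = idx, kind = "behavioral",
                 eye_open_ratio = mean(valid >= spf / 2),
                 interpolated = interpolated),
            class = "arousal_trace")
}

# Canonical double-gamma HRF sampled at TR: response peak 6 s, undershoot
# peak 16 s, undershoot ratio 1/6, 32 s support.
canonical_hrf <- function(tr, duration = 32) {
  t <- seq(0, duration, by = tr)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / sum(h)
}

#' Convolve a frame-sampled trace with the canonical HRF
#'
#' Causal convolution with the canonical double-gamma hemodynamic response
#' function sampled at TR; the output is truncated to the input length.
#'
#' @param trace numeric vector sampled at TR.
#' @param tr frame interval in seconds.
#' @return convolved vector, same length as `trace`.
#' @export
hrf_convolve <- function(trace, tr = 2) {
  if (any(!is.finite(trace))) stop("trace must be finite")
  h <- canonical_hrf(tr)
  out <- stats::convolve(trace, rev(h), type = "open")
  out[seq_along(trace)]
}

#' Arousal spatial template from paired scans and behavioral indices
#'
#' Per region, the Pearson correlation between the BOLD signal and the
#' HRF-convolved behavioral arousal index, computed per scan and aggregated
#' across scans by Fisher-z averaging (back-transformed).
#'
#' @param scans list of T x N time-series matrices.
#' @param behavioral_traces list of `arousal_trace` objects (or numeric
#'   per-frame indices), paired with `scans`.
#' @param tr frame interval in seconds.
#' @return numeric vector of length N (per-region template values).
#' @export
arousal_template <- function(scans, behavioral_traces, tr = 2) {
  if (length(scans) == 0 || length(scans) != length(behavioral_traces)) {
    stop("scans and behavioral_traces must be paired, non-empty lists")
  }
  zs <- lapply(seq_along(scans), function(i) {
    x <- behavioral_traces[[i]]
    idx <- if (inherits(x, "arousal_trace")) x$index else x
    reg <- hrf_convolve(idx, tr)
    r <- as.numeric(cor(unclass(scans[[i]]), reg))
    atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))
  })
  template <- tanh(Reduce(`+`, zs) / length(zs))
  names(template) <- colnames(scans[[1]])
  template
}

#' fMRI-based arousal index by template projection
#'
#' Per frame, the Pearson correlation across regions between the frame's
#' BOLD vector and the arousal spatial template. Constant frames get index 0
#' and are flagged.
#'
#' @param ts T x N time-series matrix.
#' @param template per-region template (length N).
#' @return `arousal_trace` with `kind = "fmri_template"`, index in
#'   \[-1, 1\], and `flagged` marking degenerate frames.
#' @export
fmri_arousal_index <- function(ts, template) {
  ts <- unclass(ts)
  if (ncol(ts) != length(template)) stop("template length must equal N")
  sds <- apply(ts, 1, sd)
  flagged <- sds == 0
  idx <- numeric(nrow(ts))
  if (any(!flagged)) {
    idx[!flagged] <- as.numeric(cor(t(ts[!flagged, , drop = FALSE]), template))
  }
  structure(list(index = idx, kind = "fmri_template",
                 eye_open_ratio = NA_real_, flagged = flagged),
            class = "arousal_trace")
}

#' Assign frames to equal-sized arousal bins
#'
#' Frames are ranked by the arousal index (ties broken by frame order) and
#' split into `n_bins` contiguous rank groups of exactly equal size; the
#' remainder frames are dropped from the extremes (floor(r/2) lowest-ranked,
#' the rest highest-ranked). Bin 1 is lowest arousal.
#'
#' @param trace `arousal_trace` or numeric per-frame index.
#' @param n_bins number of bins.
#' @return integer vector of bin labels per frame (`NA` for dropped frames).
#' @export
bin_by_arousal <- function(trace, n_bins = 10) {
  idx <- if (inherits(trace, "arousal_trace")) trace$index else trace
  n <- length(idx)
  if (n < n_bins) stop("need at least n_bins frames")
  per_bin <- n %/% n_bins
  r <- n - per_bin * n_bins
  ord <- order(idx)                     # stable: ties by frame order
  drop_lo <- r %/% 2
  drop_hi <- r - drop_lo
  kept <- ord[seq.int(drop_lo + 1L, n - drop_hi)]
  assignment <- rep(NA_integer_, n)
  assignment[kept] <- rep(seq_len(n_bins), each = per_bin)
  assignment
}
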