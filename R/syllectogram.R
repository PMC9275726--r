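# Syllectogram analysis: stopped-flow light-transmission traces -> windowed
# aggregation indices (AI_T) and the hematocrit-corrected index (HAI).

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

# centered moving average with partial windows at the edges (no NA padding,
# so the trace start cannot leak raw noise into the smoothed minimum search)
moving_mean <- function(x, w) {
  w <- max(1L, as.integer(w))
  if (w <= 1L) return(x)
  n <- length(x)
  half <- w %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Construct a syllectogram trace
#'
#' A syllectogram is the transmitted-light intensity recorded after abrupt
#' cessation of blood flow; its rise tracks rouleaux formation and
#' three-dimensional aggregation. Traces carry one or two detector channels
#' sampled on a common time grid (nominally 12-bit ADC counts at 10-ms
#' intervals for up to 2 minutes).
#'
#' @param data Data frame with column `t_s` (seconds, strictly ascending) and
#'   one or two intensity channels named `ch1` (and `ch2`).
#' @param sample_id Sample identifier.
#' @return A `syl_trace` tibble (columns `t_s` and the channels) with the
#'   sample id and sampling interval stored as attributes.
#' @export
syl_trace <- function(data, sample_id = "trace") {
  stopifnot(is.data.frame(data))
  if (!"t_s" %in% names(data)) abort("trace needs a 't_s' column")
  chans <- intersect(c("ch1", "ch2"), names(data))
  if (!length(chans)) abort("trace needs at least one channel column ('ch1')")
  d <- as_tibble(data)[, c("t_s", chans)]
  if (nrow(d) == 0L) abort("empty trace")
  if (is.unsorted(d$t_s, strictly = TRUE)) abort("trace times must be strictly ascending")
  for (ch in chans) {
    x <- d[[ch]]
    if (any(!is.finite(x)) || any(x < 0))
      abort(paste0("channel ", ch, ": intensities must be finite and non-negative"))
  }
  class(d) <- c("syl_trace", class(d))
  attr(d, "sample_id") <- sample_id
  attr(d, "dt") <- if (nrow(d) > 1L) median(diff(d$t_s)) else NA_real_
  d
}

trace_channels <- function(trace) intersect(c("ch1", "ch2"), names(trace))

#' Detect the syllectogram start (I_MIN) per channel
#'
#' The starting time `t = 0` of the syllectogram is the intensity minimum
#' reached just after flow cessation. The minimum is located on a smoothed
#' copy of each channel (centered moving average over `smooth_s` seconds)
#' within the first `search_window_s` seconds; among near-minimal samples
#' (within twice the smoothed-series noise floor, estimated from the median
#' absolute first difference) the earliest is taken, so flat-bottomed noisy
#' traces are not biased towards a late start. Ties break to the earliest
#' index. `I_MIN` itself is estimated as the mean raw intensity over the
#' trailing `smooth_s` seconds up to the start index, which reduces to the
#' exact sample value on noise-free traces starting at their minimum.
#'
#' @param trace A [syl_trace()].
#' @param search_window_s Search window from the start of the record, seconds.
#' @param smooth_s Smoothing window, seconds.
#' @return The trace with attributes `t0_index` and `i_min` (named per
#'   channel) set; retrieve them with [start_indices()].
#' @export
detect_start <- function(trace, search_window_s = 2, smooth_s = 0.2) {
  stopifnot(inherits(trace, "syl_trace"))
  if (nrow(trace) == 0L) abort("empty trace")
  dur <- trace$t_s[nrow(trace)] - trace$t_s[1]
  if (search_window_s <= 0 || search_window_s > dur + 1e-09)
    abort("search window outside trace")
  dt <- attr(trace, "dt")
  w <- max(1L, round(smooth_s / dt))
  chans <- trace_channels(trace)
  t0 <- i_min <- setNames(numeric(length(chans)), chans)
  for (ch in chans) {
    x <- trace[[ch]]
    if (length(unique(x)) == 1L)
      warn(paste0("channel ", ch, ": constant (degenerate) trace; start set to first sample"))
    xs <- moving_mean(x, w)
    idx <- which(trace$t_s - trace$t_s[1] <= search_window_s + 1e-09)
    noise <- if (length(x) > 2L) mad(diff(x)) / sqrt(2) else 0
    delta <- 2 * noise / sqrt(w)
    mn <- min(xs[idx])
    i0 <- idx[which(xs[idx] <= mn + delta)[1]]
    # a raw sample far below the smoothed floor marks a sharp minimum that
    # the smoother would smear; trust it directly (earliest tie wins)
    j <- idx[which.min(x[idx])]
    if (x[j] < mn - 4 * noise) {
      t0[ch] <- j
      i_min[ch] <- x[j]
    } else {
      t0[ch] <- i0
      i_min[ch] <- mean(x[max(1L, i0 - w + 1L):i0])
    }
  }
  attr(trace, "t0_index") <- as.integer(t0)
  names(attr(trace, "t0_index")) <- chans
  attr(trace, "i_min") <- i_min
  attr(trace, "smooth_s") <- smooth_s
  trace
}

#' @rdname detect_start
#' @export
start_indices <- function(trace) attr(trace, "t0_index")

#' Windowed aggregation index of a syllectogram
#'
#' The aggregation index over a `window_s`-second measurement is the area
#' ratio `A / (A + B)` where `A` is the area enclosed between the syllectogram
#' and `I_MIN` and `B` the area between the syllectogram and `I_MAX`, so that
#' `A + B = (I_MAX - I_MIN) T` exactly. Integration is trapezoidal on the
#' recorded grid with no resampling. `I_MAX` is the mean intensity over the
#' final `imax_window_s` seconds of the window (a noise-robust window-end
#' value), so the index is computable from a `T`-second record alone; set
#' `imax_rule = "trace_end"` to reference the end of the full record instead.
#'
#' @param trace A [syl_trace()]; the start is detected with [detect_start()]
#'   defaults unless already present.
#' @param window_s Measurement window, seconds (conventionally 5, 10, 30, 60
#'   or 120).
#' @param imax_window_s Averaging window for the `I_MAX` estimate, seconds.
#' @param imax_rule `"window_end"` (default) or `"trace_end"`.
#' @return Named numeric vector of AI values in (0, 1), one per channel.
#' @examples
#' tr <- syl_trace(data.frame(t_s = seq(0, 5, 0.01),
#'                            ch1 = seq(0, 5, 0.01) * 100))
#' compute_ai(tr, window_s = 5) # linear ramp: AI = 0.5
#' @export
compute_ai <- function(trace, window_s = 5, imax_window_s = 0.1,
                       imax_rule = c("window_end", "trace_end")) {
  stopifnot(inherits(trace, "syl_trace"))
  imax_rule <- match.arg(imax_rule)
  if (window_s <= 0) abort("window must be positive")
  if (is.null(attr(trace, "t0_index"))) trace <- detect_start(trace)
  t0 <- attr(trace, "t0_index")
  imins <- attr(trace, "i_min")
  chans <- trace_channels(trace)
  out <- setNames(numeric(length(chans)), chans)
  for (ch in chans) {
    i0 <- t0[[ch]]
    tt <- trace$t_s - trace$t_s[i0]
    if (window_s > tt[length(tt)] + 1e-09)
      abort(paste0("window (", window_s, " s) exceeds trace beyond detected start"))
    sel <- which(tt >= 0 & tt <= window_s + 1e-09)
    tw <- tt[sel]
    iw <- trace[[ch]][sel]
    i_min <- imins[[ch]]
    i_max <- if (imax_rule == "window_end") {
      mean(iw[tw >= tw[length(tw)] - imax_window_s - 1e-09])
    } else {
      full <- trace[[ch]][tt >= 0]
      tfull <- tt[tt >= 0]
      mean(full[tfull >= tfull[length(tfull)] - imax_window_s - 1e-09])
    }
    if (i_max <= i_min) abort("degenerate syllectogram: no dynamic range (I_MAX <= I_MIN)")
    a <- trapz(tw, iw - i_min)
    out[ch] <- a / ((i_max - i_min) * (tw[length(tw)] - tw[1]))
  }
  out
}

#' Average the two detector channels with a quality-control flag
#'
#' The instrument records the syllectogram on two photodetectors ~9 mm apart;
#' averaging them reduces noise, and a large disagreement indicates an
#' artefact (typically an air bubble in one photometric path).
#'
#' @param ai_ch1,ai_ch2 AI values in `[0, 1]`.
#' @param tol Disagreement threshold setting the QC flag.
#' @return One-row tibble with columns `ai` (the mean) and `qc_flag`.
#' @export
average_detectors <- function(ai_ch1, ai_ch2, tol = 0.10) {
  for (v in c(ai_ch1, ai_ch2))
    if (!is.finite(v) || v < 0 || v > 1) abort("AI values must lie in [0, 1]")
  tibble(ai = (ai_ch1 + ai_ch2) / 2, qc_flag = abs(ai_ch1 - ai_ch2) > tol)
}

#' Aggregation indices over the standard measurement windows
#'
#' Computes the AI for each requested window, averaging detector channels
#' when two are present and flagging detector disagreement. Windows that do
#' not fit in the recorded trace are dropped with a warning.
#'
#' @inheritParams compute_ai
#' @param windows Window lengths in seconds.
#' @param tol Detector-disagreement threshold (see [average_detectors()]).
#' @return Tibble with columns `sample_id`, `window_s`, `ai`, `qc_flag`.
#' @export
aggregation_indices <- function(trace, windows = c(5, 10, 30, 60, 120),
                                tol = 0.10, ...) {
  stopifnot(inherits(trace, "syl_trace"))
  if (is.null(attr(trace, "t0_index"))) trace <- detect_start(trace)
  t0 <- max(attr(trace, "t0_index"))
  avail <- trace$t_s[nrow(trace)] - trace$t_s[t0]
  ok <- windows <= avail + 1e-09
  if (any(!ok))
    warn(paste0("windows dropped (exceed trace): ",
                paste(windows[!ok], collapse = ", "), " s"))
  purrr::map_dfr(windows[ok], function(w) {
    ai <- compute_ai(trace, window_s = w, ...)
    if (length(ai) == 2L) {
      res <- average_detectors(ai[["ch1"]], ai[["ch2"]], tol = tol)
    } else {
      res <- tibble(ai = unname(ai[1]), qc_flag = FALSE)
    }
    mutate(res, sample_id = attr(trace, "sample_id") %||% "trace",
           window_s = w, .before = 1)
  })
}

#' Hematocrit-corrected aggregation index (HAI)
#'
#' The AI rises nearly linearly with hematocrit at fixed plasma composition,
#' which confounds aggregability comparisons across samples. The corrected
#' index references every AI to hematocrit 0.40:
#' `HAI = AI - k (Ht - 0.40)`, with `k` the mean AI-vs-Ht slope across
#' fibrinogen levels (default 0.284). The result is not clamped to `[0, 1]`;
#' downstream consumers apply their own floors.
#'
#' @param ai Aggregation index in `[0, 1]` (vectorised).
#' @param ht Hematocrit fraction in (0, 1) (vectorised).
#' @param k Correction factor, AI units per Ht fraction.
#' @return Numeric HAI values.
#' @examples
#' compute_hai(0.60, ht = 0.25) # 0.6426
#' @export
compute_hai <- function(ai, ht, k = 0.284) {
  if (any(!is.finite(ai)) || any(ai < 0) || any(ai > 1))
    abort("AI must lie in [0, 1]")
  if (any(!is.finite(ht)) || any(ht <= 0) || any(ht >= 1))
    abort("hematocrit must lie in (0, 1)")
  ai - k * (ht - 0.40)
}

#' @export
print.syl_trace <- function(x, ...) {
  cat(sprintf("Syllectogram trace '%s': %d samples, %d channel(s), dt = %g s\n",
              attr(x, "sample_id") %||% "?", nrow(x),
              length(trace_channels(x)), attr(x, "dt")))
  NextMethod()
}
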