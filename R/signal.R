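#' Per-ROI fluorescence trace container
#'
#' A `trace_set` holds one fluorescence (or dF/F) time series per ROI as the
#' rows of a matrix, together with the sampling rate and ROI identities.
#'
#' @param values numeric matrix, one row per ROI, one column per frame.
#' @param fps sampling rate in frames per second.
#' @param roi_ids ROI identifiers (defaults to row index).
#' @param kind `"raw"` fluorescence or `"dff"`.
#' @return A list of class `trace_set`.
#' @export
trace_set <- function(values, fps, roi_ids = NULL, kind = c("raw", "dff")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (!is.numeric(values)) abort("trace values must be numeric")
  check_finite(values, "trace values")
  if (fps <= 0) abort("fps must be > 0")
  if (is.null(roi_ids)) roi_ids <- seq_len(nrow(values))
  if (length(roi_ids) != nrow(values))
    abort("roi_ids length must match the number of trace rows")
  structure(list(values = values, fps = fps, roi_ids = roi_ids, kind = kind),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("<trace_set: %d ROIs x %d frames @ %g fps, kind = %s>\n",
              nrow(x$values), ncol(x$values), x$fps, x$kind))
  invisible(x)
}

#' Extract raw per-ROI traces from an image stack
#'
#' The ROI mask (label image) is placed over every frame; each ROI's value
#' at frame t is the mean intensity over its mask pixels.
#'
#' @param stack numeric/integer array `c(H, W, n_frames)`.
#' @param rois a `roi_set` from [make_masks()], or a list containing a
#'   `labels` matrix.
#' @param fps sampling rate; defaults to the stack's `fps` attribute.
#' @return A [trace_set()] of kind `"raw"` (empty for an empty ROI set).
#' @export
extract_traces <- function(stack, rois, fps = attr(stack, "fps")) {
  labels <- if (!is.null(rois$labels)) rois$labels else rois
  if (is.null(fps)) abort("fps not given and stack carries no fps attribute")
  d <- dim(stack)
  if (any(dim(labels) != d[1:2]))
    abort("label image shape does not match stack frames")
  ids <- sort(unique(labels[labels > 0]))
  nf <- d[3]
  flat <- matrix(as.numeric(stack), d[1] * d[2], nf)
  values <- matrix(0, length(ids), nf)
  for (k in seq_along(ids)) {
    idx <- which(labels == ids[k])
    values[k, ] <- colMeans(flat[idx, , drop = FALSE])
  }
  trace_set(values, fps = fps, roi_ids = ids, kind = "raw")
}

# Centered sliding quantile with windows truncated at the trace ends.
sliding_quantile <- function(x, width, prob) {
  width <- min(width, length(x))
  zoo::rollapply(zoo::zoo(x), width = width,
                 FUN = function(v) unname(quantile(v, probs = prob,
                                                   names = FALSE)),
                 partial = TRUE, align = "center")
}

#' Compute dF/F with a sliding-percentile baseline
#'
#' The baseline `F0(t)` is the `percentile`-th percentile of the raw signal
#' in a centered window of `window` seconds (truncated at the trace ends);
#' `dff(t) = (F(t) - F0(t)) / F0(t)`.
#'
#' @param traces a raw [trace_set()].
#' @param percentile baseline percentile (default 20).
#' @param window baseline window length in seconds (default 10).
#' @return A [trace_set()] of kind `"dff"`.
#' @export
compute_dff <- function(traces, percentile = 20, window = 10) {
  if (!inherits(traces, "trace_set")) abort("traces must be a trace_set")
  w <- round(window * traces$fps)
  if (w < 2) abort("window * fps must cover at least 2 frames")
  vals <- traces$values
  out <- matrix(0, nrow(vals), ncol(vals))
  for (i in seq_len(nrow(vals))) {
    f0 <- as.numeric(sliding_quantile(vals[i, ], w, percentile / 100))
    if (any(f0 <= 0))
      abort("baseline F0 <= 0 for ROI ", traces$roi_ids[i],
            "; add a positive offset to the raw fluorescence first")
    out[i, ] <- (vals[i, ] - f0) / f0
  }
  trace_set(out, fps = traces$fps, roi_ids = traces$roi_ids, kind = "dff")
}

#' Build a library of unit-peak calcium waveform templates
#'
#' Templates are difference-of-exponential transients over a grid of rise
#' and decay time constants, each rescaled to peak at 1 and sampled over
#' `length_s` seconds. The library is what the template-matching event
#' detector slides along each trace.
#'
#' @param fps sampling rate in frames per second.
#' @param rise_taus,decay_taus grids of time constants in seconds; pairs
#'   with `rise >= decay` are dropped.
#' @param length_s template length in seconds (default 5).
#' @return A matrix, one template per row, of class `template_library`.
#' @export
template_library <- function(fps, rise_taus = c(0.1, 0.2, 0.4),
                             decay_taus = c(0.75, 1.5, 3.0), length_s = 5) {
  grid <- expand.grid(rise = rise_taus, decay = decay_taus)
  grid <- grid[grid$rise < grid$decay, , drop = FALSE]
  if (nrow(grid) == 0) abort("no valid rise < decay pairs in the grids")
  nfr <- round(length_s * fps)
  tpl <- t(apply(grid, 1, function(g) {
    k <- transient_kernel(g[["rise"]], g[["decay"]], fps,
                          support_s = length_s)
    k <- k[seq_len(min(length(k), nfr))]
    c(k, rep(0, nfr - length(k))) / max(k)
  }))
  rownames(tpl) <- sprintf("rise%g_decay%g", grid$rise, grid$decay)
  class(tpl) <- c("template_library", class(tpl))
  tpl
}

#' Read a template library from CSV (one template per row)
#' @param path CSV file of numeric rows; each row is rescaled to unit peak.
#' @param fps unused, kept for symmetry with [template_library()].
#' @export
read_template_csv <- function(path, fps = NULL) {
  m <- as.matrix(read.csv(path, header = FALSE))
  m <- m / apply(m, 1, max)
  class(m) <- c("template_library", class(m))
  m
}

# Sliding Pearson correlation of every length-L window of x against
# template segment y, via running sums; returns one value per window start.
# Zero-variance windows get similarity 0.
sliding_correlation <- function(x, y) {
  L <- length(y)
  T_ <- length(x)
  if (L > T_) abort("template longer than trace")
  cs <- cumsum(c(0, x)); cs2 <- cumsum(c(0, x^2))
  n_off <- T_ - L + 1
  sx <- cs[(L + 1):(T_ + 1)] - cs[1:n_off]          # window sums
  sx2 <- cs2[(L + 1):(T_ + 1)] - cs2[1:n_off]
  # cross terms via one-sided convolution filter
  conv <- stats::filter(x, rev(y), method = "convolution", sides = 1)
  sxy <- as.numeric(conv[L:T_])
  my <- mean(y)
  den_y <- sqrt(sum((y - my)^2))
  varx <- sx2 - sx^2 / L
  varx[varx < 0] <- 0
  num <- sxy - sx * my
  den <- sqrt(varx) * den_y
  r <- ifelse(den > 0, num / den, 0)
  pmin(pmax(r, -1), 1)
}

# running max of x over length-L windows (one per window start)
sliding_max <- function(x, L) {
  zoo::rollapply(zoo::zoo(x), width = L, FUN = max, align = "left")
}

#' Detect calcium events by template matching
#'
#' Slides a matching window along each dF/F trace; at each offset the
#' similarity is the maximum Pearson correlation between the window and the
#' leading `match_window` seconds of each library template (the rise and
#' early decay, where a transient's shape is discriminative; the slow tail
#' of an earlier event would otherwise dominate the window). An offset is a
#' candidate when similarity >= `similarity` and the window's peak dF/F
#' rises at least `min_amplitude` above the value at the window start (a
#' decaying tail never qualifies: its peak is the window start itself).
#' Events are the strict local maxima of the similarity profile among
#' candidates; overlapping detections closer than `min_separation` seconds
#' collapse to the offset of maximal similarity. Zero-variance windows have
#' similarity 0 by definition.
#'
#' @param dff a dF/F [trace_set()].
#' @param templates a [template_library()] (built at `dff$fps` by default).
#' @param similarity Pearson similarity threshold (default 0.7).
#' @param min_amplitude minimum event amplitude in dF/F, measured from the
#'   window-start value to the window peak (default 0.01).
#' @param match_window seconds of each template used for matching (default
#'   1.5; must cover the template peaks).
#' @param min_separation minimum time between detected events in seconds
#'   (default 0.25); the weaker of two closer detections is discarded.
#' @return An `event_raster`: a list with `events` (data.frame `roi`,
#'   `onset_frame` 1-based, `onset_s`, `amplitude`, `similarity`), `fps`,
#'   `duration` (s) and `n_roi`.
#' @export
detect_events <- function(dff, templates = NULL, similarity = 0.7,
                          min_amplitude = 0.01, match_window = 1.5,
                          min_separation = 0.25) {
  if (!inherits(dff, "trace_set")) abort("dff must be a trace_set")
  if (is.null(templates)) templates <- template_library(dff$fps)
  L <- min(ncol(templates), max(2L, round(match_window * dff$fps)))
  T_ <- ncol(dff$values)
  if (L > T_) abort("matching window exceeds trace length")
  seg <- templates[, seq_len(L), drop = FALSE]
  ms <- max(1L, round(min_separation * dff$fps))
  all_events <- vector("list", nrow(dff$values))
  for (i in seq_len(nrow(dff$values))) {
    x <- dff$values[i, ]
    n_off <- T_ - L + 1
    best <- rep(-1, n_off)
    for (k in seq_len(nrow(seg)))
      best <- pmax(best, sliding_correlation(x, seg[k, ]))
    peaks <- as.numeric(sliding_max(x, L))
    amp <- peaks - x[seq_len(n_off)]
    cand <- best >= similarity & amp >= min_amplitude
    # strict local maxima of the similarity profile among candidates
    is_max <- cand & best > c(-Inf, best[-n_off]) &
      best >= c(best[-1], -Inf)
    idx <- which(is_max)
    if (length(idx) == 0) next
    ord <- idx[order(-best[idx])]
    kept <- integer(0)
    for (o in ord)
      if (length(kept) == 0 || min(abs(kept - o)) > ms) kept <- c(kept, o)
    kept <- sort(kept)
    all_events[[i]] <- data.frame(
      roi = dff$roi_ids[i], onset_frame = kept,
      onset_s = (kept - 1) / dff$fps,
      amplitude = amp[kept], similarity = best[kept])
  }
  events <- do.call(rbind, all_events)
  if (is.null(events))
    events <- data.frame(roi = integer(0), onset_frame = integer(0),
                         onset_s = numeric(0), amplitude = numeric(0),
                         similarity = numeric(0))
  rownames(events) <- NULL
  structure(list(events = events, fps = dff$fps, duration = T_ / dff$fps,
                 n_roi = nrow(dff$values)),
            class = "event_raster")
}

#' @export
print.event_raster <- function(x, ...) {
  cat(sprintf("<event_raster: %d events over %d ROIs, %.1f s>\n",
              nrow(x$events), x$n_roi, x$duration))
  invisible(x)
}

#' Whole-tissue activity trace and event rate
#'
#' The whole-tissue trace is the mean dF/F across ROIs at each frame
#' (`method = "sum"` reproduces the summed trace for plotting, at the cost
#' of an N-dependent amplitude scale). Whole-tissue events are detected by
#' running [detect_events()] on that single trace; the firing rate is the
#' event count divided by the recording length in minutes.
#'
#' @param dff a dF/F [trace_set()] with at least one ROI.
#' @param method `"mean"` (default, N-invariant) or `"sum"`.
#' @return [whole_tissue_trace()]: a one-row [trace_set()].
#' @export
whole_tissue_trace <- function(dff, method = c("mean", "sum")) {
  method <- match.arg(method)
  if (!inherits(dff, "trace_set")) abort("dff must be a trace_set")
  if (nrow(dff$values) < 1) abort("need at least one ROI")
  v <- if (method == "mean") colMeans(dff$values) else colSums(dff$values)
  trace_set(matrix(v, nrow = 1), fps = dff$fps, roi_ids = "whole_tissue",
            kind = dff$kind)
}

#' @rdname whole_tissue_trace
#' @inheritParams detect_events
#' @export
detect_whole_tissue_events <- function(dff, templates = NULL,
                                       similarity = 0.7,
                                       min_amplitude = 0.01,
                                       method = c("mean", "sum")) {
  wt <- whole_tissue_trace(dff, method = match.arg(method))
  detect_events(wt, templates = templates, similarity = similarity,
                min_amplitude = min_amplitude)
}

#' @rdname whole_tissue_trace
#' @param events an `event_raster` or an event count.
#' @param duration recording length in seconds (taken from the raster when
#'   one is given).
#' @return [firing_rate()]: events per minute.
#' @export
firing_rate <- function(events, duration = NULL) {
  if (inherits(events, "event_raster")) {
    if (is.null(duration)) duration <- events$duration
    n <- nrow(events$events)
  } else n <- as.numeric(events)
  if (is.null(duration) || duration <= 0) abort("duration (s) must be > 0")
  n / (duration / 60)
}

#' Write / read trace CSV (rows = frames, columns = ROI ids, first column
#' time in seconds)
#' @param traces a [trace_set()].
#' @param path CSV file path.
#' @export
write_traces_csv <- function(traces, path) {
  df <- data.frame(time_s = (seq_len(ncol(traces$values)) - 1) / traces$fps,
                   t(traces$values))
  names(df) <- c("time_s", paste0("roi_", traces$roi_ids))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces_csv
#' @param kind trace kind of the file being read.
#' @export
read_traces_csv <- function(path, kind = c("raw", "dff")) {
  df <- read.csv(path, check.names = FALSE)
  tt <- df[[1]]
  fps <- 1 / stats::median(diff(tt))
  ids <- sub("^roi_", "", names(df)[-1])
  trace_set(t(as.matrix(df[, -1, drop = FALSE])), fps = fps, roi_ids = ids,
            kind = match.arg(kind))
}

#' Write detected events to CSV
#' @param raster an `event_raster`.
#' @param path CSV file path.
#' @export
write_events_csv <- function(raster, path) {
  write.csv(raster$events, path, row.names = FALSE)
  invisible(path)
}
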