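#' Maximum projection of an image stack across time
#'
#' @param stack numeric/integer array `c(H, W, n_frames)` with at least one
#'   frame.
#' @return An `H x W` matrix, pixelwise maximum over frames.
#' @export
max_projection <- function(stack) {
  d <- dim(stack)
  if (is.null(d) || length(d) != 3 || d[3] < 1)
    abort("stack must be an H x W x n_frames array with >= 1 frame")
  flat <- matrix(as.numeric(stack), d[1] * d[2], d[3])
  proj <- flat[, 1]
  for (t in seq_len(d[3])[-1]) proj <- pmax(proj, flat[, t])
  matrix(proj, d[1], d[2])
}

#' Parameters for cell-body (seed) detection
#'
#' Defaults follow the smoothing / adaptive-threshold / LoG-pyramid settings
#' used for GCaMP-labelled somata in microtissue recordings: a smoothing
#' sigma matched to cell-body size (2.5 px), a 5-px local-mean neighborhood,
#' a threshold fraction of 0.013 (midpoint of the curated 0.008-0.018
#' range), LoG scales 1-5 px and a blob response threshold of 0.01.
#'
#' @param smooth_sigma Gaussian smoothing sigma in pixels.
#' @param block_size odd side of the square local-mean neighborhood.
#' @param threshold_fraction fraction above the local mean a pixel must
#'   reach to count as foreground.
#' @param log_min_sigma,log_max_sigma LoG scale range in pixels.
#' @param log_n_sigma number of scales in the pyramid.
#' @param log_threshold minimum (scale-normalized) LoG response of a blob.
#' @param threshold_mode `"multiplicative"`: foreground when
#'   `pixel > local_mean * (1 + threshold_fraction)`; `"additive"`:
#'   `pixel > local_mean + threshold_fraction`.
#' @param scale_normalized multiply each LoG response by sigma^2 so blob
#'   strength is comparable across scales.
#' @param exclude_border peaks within this many pixels of the image border
#'   are discarded (boundary padding makes filter responses there
#'   unreliable).
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(smooth_sigma = 2.5, block_size = 5,
                             threshold_fraction = 0.013,
                             log_min_sigma = 1, log_max_sigma = 5,
                             log_n_sigma = 10, log_threshold = 0.01,
                             threshold_mode = c("multiplicative", "additive"),
                             scale_normalized = TRUE, exclude_border = 2) {
  p <- list(smooth_sigma = smooth_sigma, block_size = as.integer(block_size),
            threshold_fraction = threshold_fraction,
            log_min_sigma = log_min_sigma, log_max_sigma = log_max_sigma,
            log_n_sigma = as.integer(log_n_sigma),
            log_threshold = log_threshold,
            threshold_mode = match.arg(threshold_mode),
            scale_normalized = isTRUE(scale_normalized),
            exclude_border = as.integer(exclude_border))
  if (p$block_size < 3 || p$block_size %% 2 == 0)
    abort("block_size must be odd and >= 3")
  if (p$log_min_sigma >= p$log_max_sigma)
    abort("log_min_sigma must be < log_max_sigma")
  if (p$threshold_fraction < 0) abort("threshold_fraction must be >= 0")
  if (p$smooth_sigma < 0) abort("smooth_sigma must be >= 0")
  class(p) <- "detection_params"
  p
}

# local mean over a block_size square, edges padded by replication
local_mean <- function(img, block_size) {
  k <- matrix(1 / block_size^2, block_size, block_size)
  as.matrix(EBImage::filter2(img, k, boundary = "replicate"))
}

# zero-sum LoG kernel at scale sigma (positive response at bright blobs
# after negation)
log_kernel <- function(sigma) {
  r <- max(2L, as.integer(ceiling(3 * sigma)))
  g <- expand.grid(x = -r:r, y = -r:r)
  r2 <- g$x^2 + g$y^2
  k <- (r2 - 2 * sigma^2) / sigma^4 * exp(-r2 / (2 * sigma^2))
  k <- k - mean(k)
  matrix(k, 2 * r + 1, 2 * r + 1)
}

#' Detect cell-body seeds on a maximum projection
#'
#' Pipeline: Gaussian smoothing, adaptive thresholding against the local
#' mean, Euclidean distance transform of the foreground, a multi-scale
#' Laplacian-of-Gaussian pyramid on the distance map, local-maxima blob
#' detection above `log_threshold`, and non-maxima suppression (the weaker
#' of two detections closer than `sqrt(2)` times the smaller detection's
#' scale is discarded). Coordinates are 0-based with x = column, y = row.
#'
#' @param projection a numeric matrix (e.g. from [max_projection()]).
#' @param params a [detection_params()].
#' @return A data.frame with columns `x`, `y` (integer, 0-based), `scale`
#'   (the LoG sigma) and `response`; zero rows when nothing is above
#'   threshold.
#' @export
detect_seeds <- function(projection, params = detection_params()) {
  check_finite(projection, "projection")
  smoothed <- if (params$smooth_sigma > 0)
    as.matrix(EBImage::gblur(projection, sigma = params$smooth_sigma))
  else projection
  lm_ <- local_mean(smoothed, params$block_size)
  binary <- if (params$threshold_mode == "multiplicative")
    smoothed > lm_ * (1 + params$threshold_fraction)
  else smoothed > lm_ + params$threshold_fraction
  if (!any(binary))
    return(data.frame(x = integer(0), y = integer(0), scale = numeric(0),
                      response = numeric(0)))
  dmap <- as.matrix(EBImage::distmap(EBImage::Image(binary * 1)))
  sigmas <- seq(params$log_min_sigma, params$log_max_sigma,
                length.out = params$log_n_sigma)
  h <- nrow(dmap); w <- ncol(dmap)
  resp <- array(0, dim = c(h, w, length(sigmas)))
  for (s in seq_along(sigmas)) {
    r <- -as.matrix(EBImage::filter2(dmap, log_kernel(sigmas[s]),
                                     boundary = "replicate"))
    if (params$scale_normalized) r <- r * sigmas[s]^2
    resp[, , s] <- r
  }
  peaks <- find_peaks_3d(resp, params$log_threshold, params$exclude_border)
  if (nrow(peaks) == 0)
    return(data.frame(x = integer(0), y = integer(0), scale = numeric(0),
                      response = numeric(0)))
  det <- data.frame(x = peaks$col - 1L, y = peaks$row - 1L,
                    scale = sigmas[peaks$slice], response = peaks$value)
  nms_seeds(det)
}

# local maxima of a 3-D response array (26-neighborhood) above a threshold,
# excluding a border margin where the boundary padding biases the response
find_peaks_3d <- function(resp, threshold, exclude_border = 0L) {
  d <- dim(resp)
  is_peak <- resp > threshold
  if (exclude_border > 0) {
    b <- exclude_border
    is_peak[c(seq_len(min(b, d[1])), d[1] - seq_len(min(b, d[1])) + 1), , ] <- FALSE
    is_peak[, c(seq_len(min(b, d[2])), d[2] - seq_len(min(b, d[2])) + 1), ] <- FALSE
  }
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    shifted <- array(-Inf, dim = d)
    xs <- max(1, 1 + dx):min(d[1], d[1] + dx)
    ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
    zs <- max(1, 1 + dz):min(d[3], d[3] + dz)
    shifted[xs, ys, zs] <- resp[xs - dx, ys - dy, zs - dz]
    is_peak <- is_peak & (resp >= shifted)
  }
  idx <- which(is_peak, arr.ind = TRUE)
  data.frame(row = idx[, 1], col = idx[, 2], slice = idx[, 3],
             value = resp[idx])
}

# greedy non-maxima suppression by descending response
nms_seeds <- function(det) {
  det <- det[order(-det$response), , drop = FALSE]
  keep <- logical(nrow(det))
  for (i in seq_len(nrow(det))) {
    kept <- which(keep)
    if (length(kept) > 0) {
      dd <- sqrt((det$x[kept] - det$x[i])^2 + (det$y[kept] - det$y[i])^2)
      lim <- sqrt(2) * pmin(det$scale[kept], det$scale[i])
      if (any(dd < lim)) next
    }
    keep[i] <- TRUE
  }
  out <- det[keep, , drop = FALSE]
  out <- out[order(out$y, out$x), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Curate detected seeds with a boundary mask and explicit removals
#'
#' Replaces the interactive curation step with two rules: seeds falling
#' outside a tissue boundary mask are removed, and explicitly listed seed
#' indices are removed. Input order is preserved.
#'
#' @param seeds data.frame with 0-based `x`, `y` columns.
#' @param boundary `NULL` (keep all) or a logical/0-1 matrix the size of the
#'   image; seeds on `FALSE`/0 pixels are dropped.
#' @param removals integer indices (1-based, into `seeds`) to drop.
#' @return The filtered seeds data.frame.
#' @export
curate_seeds <- function(seeds, boundary = NULL, removals = integer(0)) {
  n <- nrow(seeds)
  if (length(removals) > 0 &&
      (any(removals < 1) || any(removals > n) ||
       any(removals != round(removals))))
    abort("removal indices must be integers in [1, ", n, "]")
  keep <- rep(TRUE, n)
  keep[removals] <- FALSE
  if (!is.null(boundary)) {
    inside <- boundary[cbind(seeds$y + 1L, seeds$x + 1L)] > 0
    keep <- keep & inside
  }
  out <- seeds[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build circular ROI masks around seed positions
#'
#' Each ROI is the set of integer pixels within `radius` of its seed,
#' clipped at the image border; pixels claimed by several ROIs go to the
#' nearest seed (ties to the lower seed id). The result carries a label
#' image mapping each pixel to its ROI id (0 = background).
#'
#' @param seeds data.frame with 0-based `x`, `y` columns.
#' @param radius mask radius in pixels (>= 1; 3 is the conventional value
#'   for somata at 10x).
#' @param image_shape `c(H, W)`.
#' @return A list of class `roi_set`: `seeds`, `radius`, `image_shape`,
#'   `labels` (integer `H x W` matrix).
#' @export
make_masks <- function(seeds, radius = 3, image_shape) {
  if (radius < 1) abort("radius must be >= 1")
  h <- image_shape[1]; w <- image_shape[2]
  if (nrow(seeds) > 0 &&
      (any(seeds$x < 0 | seeds$x > w - 1 | seeds$y < 0 | seeds$y > h - 1)))
    abort("seeds outside image bounds")
  if (anyDuplicated(seeds[, c("x", "y")])) abort("duplicate seeds")
  labels <- matrix(0L, h, w)
  best_d2 <- matrix(Inf, h, w)
  r <- ceiling(radius)
  offs <- expand.grid(dx = -r:r, dy = -r:r)
  offs <- offs[offs$dx^2 + offs$dy^2 <= radius^2, , drop = FALSE]
  for (i in seq_len(nrow(seeds))) {
    px <- seeds$x[i] + offs$dx
    py <- seeds$y[i] + offs$dy
    ok <- px >= 0 & px <= w - 1 & py >= 0 & py <= h - 1
    px <- px[ok]; py <- py[ok]
    d2 <- (px - seeds$x[i])^2 + (py - seeds$y[i])^2
    idx <- cbind(py + 1L, px + 1L)
    closer <- d2 < best_d2[idx]
    if (any(closer)) {
      labels[idx[closer, , drop = FALSE]] <- i
      best_d2[idx[closer, , drop = FALSE]] <- d2[closer]
    }
  }
  structure(list(seeds = seeds, radius = radius,
                 image_shape = as.integer(image_shape), labels = labels),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set: %d ROIs, radius %g px, image %d x %d>\n",
              nrow(x$seeds), x$radius, x$image_shape[1], x$image_shape[2]))
  invisible(x)
}

#' Write / read seed positions as CSV (id, x, y, scale; 0-based pixels)
#' @param seeds data.frame with `x`, `y` and optionally `scale`.
#' @param path CSV file path.
#' @export
write_seeds_csv <- function(seeds, path) {
  df <- data.frame(id = seq_len(nrow(seeds)), x = seeds$x, y = seeds$y,
                   scale = if ("scale" %in% names(seeds)) seeds$scale else NA)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_seeds_csv
#' @export
read_seeds_csv <- function(path) {
  df <- read.csv(path)
  df[, intersect(c("x", "y", "scale"), names(df)), drop = FALSE]
}
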