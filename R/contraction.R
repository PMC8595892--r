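#' Detect agarose peg positions in a phase image
#'
#' The image is binarized (Otsu threshold by default, flipped when
#' `polarity = "dark"`), edges are traced with a Canny-style detector
#' (Gaussian smoothing, Sobel gradients, magnitude threshold), edge rings
#' are hole-filled and labelled, and components whose equivalent diameter
#' `2 sqrt(area / pi)` lies within `tol` of `expected_diameter` are kept as
#' pegs.
#'
#' @param image numeric matrix (grayscale phase image).
#' @param expected_diameter expected peg diameter in pixels.
#' @param polarity are pegs `"bright"` (default) or `"dark"` relative to
#'   the background?
#' @param tol relative tolerance on the equivalent diameter (default 0.25).
#' @param smooth_sigma Gaussian sigma for the edge detector.
#' @return A list of class `peg_layout`: `centroids` (matrix of 0-based
#'   x/y), `diameter` (mean measured equivalent diameter), `n_pegs`.
#'   Errors when fewer than 3 pegs are found, naming the count.
#' @export
detect_pegs <- function(image, expected_diameter, polarity = c("bright",
                                                               "dark"),
                        tol = 0.25, smooth_sigma = 1) {
  polarity <- match.arg(polarity)
  if (expected_diameter <= 0) abort("expected_diameter must be > 0")
  img <- image / max(image, 1e-12)
  if (polarity == "dark") img <- 1 - img
  thr <- EBImage::otsu(EBImage::Image(img))
  binary <- img > thr
  edges <- canny_edges(binary * 1, smooth_sigma = smooth_sigma)
  filled <- as.matrix(EBImage::fillHull(EBImage::Image(edges * 1))) > 0
  lab <- EBImage::bwlabel(EBImage::Image(filled * 1))
  labm <- as.matrix(lab)
  n_comp <- max(labm)
  cents <- NULL; diams <- numeric(0)
  for (k in seq_len(n_comp)) {
    idx <- which(labm == k, arr.ind = TRUE)
    d_eq <- 2 * sqrt(nrow(idx) / pi)
    if (abs(d_eq - expected_diameter) > tol * expected_diameter) next
    cents <- rbind(cents, c(x = mean(idx[, 2]) - 1, y = mean(idx[, 1]) - 1))
    diams <- c(diams, d_eq)
  }
  n_found <- if (is.null(cents)) 0L else nrow(cents)
  if (n_found < 3)
    abort("found ", n_found, " peg(s); need at least 3 to define the ",
          "center region")
  structure(list(centroids = cents, diameter = mean(diams),
                 n_pegs = n_found),
            class = "peg_layout")
}

# Sobel-gradient edge map of a binary/grayscale image (single-threshold
# Canny variant; no hysteresis or thinning, which the downstream hole-fill
# does not need)
canny_edges <- function(img, smooth_sigma = 1, threshold = NULL) {
  sm <- if (smooth_sigma > 0)
    as.matrix(EBImage::gblur(img, sigma = smooth_sigma)) else img
  sx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  gx <- as.matrix(EBImage::filter2(sm, sx, boundary = "replicate"))
  gy <- as.matrix(EBImage::filter2(sm, t(sx), boundary = "replicate"))
  mag <- sqrt(gx^2 + gy^2)
  if (is.null(threshold)) threshold <- 0.5 * max(mag)
  mag >= threshold
}

#' Microtissue contraction as percent tissue-positive pixels
#'
#' The center region of interest is the circle centered at the mean of the
#' peg centroids with radius equal to the distance from that mean to the
#' nearest peg centroid minus half the peg diameter (the circle inscribed
#' inside the peg ring). Contraction is reported as
#' `100 * white pixels in ROI / ROI pixels` on a binarized tissue image
#' (tissue white, background black).
#'
#' @param binary_tissue logical or 0/1 matrix, tissue-positive pixels TRUE.
#' @param pegs a `peg_layout` from [detect_pegs()] (or a list with
#'   `centroids` and `diameter`).
#' @return A list: `percent_white`, `roi_center` (x, y), `roi_radius`,
#'   `roi_pixels`.
#' @export
contraction_fraction <- function(binary_tissue, pegs) {
  cents <- pegs$centroids
  if (is.null(cents) || nrow(cents) < 3) abort("need at least 3 pegs")
  ctr <- colMeans(cents)
  d_to_pegs <- sqrt((cents[, "x"] - ctr["x"])^2 +
                    (cents[, "y"] - ctr["y"])^2)
  radius <- min(d_to_pegs) - pegs$diameter / 2
  if (radius <= 0) abort("degenerate center ROI (radius <= 0)")
  h <- nrow(binary_tissue); w <- ncol(binary_tissue)
  cols0 <- rep(0:(w - 1), each = h)
  rows0 <- rep(0:(h - 1), times = w)
  inside <- (cols0 - ctr["x"])^2 + (rows0 - ctr["y"])^2 <= radius^2
  n_roi <- sum(inside)
  if (n_roi == 0) abort("center ROI covers no pixels")
  white <- sum(binary_tissue[inside] > 0)
  list(percent_white = 100 * white / n_roi,
       roi_center = unname(ctr), roi_radius = unname(radius),
       roi_pixels = n_roi)
}
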