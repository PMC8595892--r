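#' Configuration for the synthetic microcircuit activity generator
#'
#' Builds a validated configuration for [generate_activity()] and
#' [render_stack()]. The generator emulates the statistical structure of
#' spontaneous calcium activity in a self-assembled neural microtissue:
#' cells are partitioned into latent modules; each module fires coordinated
#' calcium events, the whole tissue fires synchronous bursts, and each cell
#' additionally fires independent noise events. Every event contributes a
#' difference-of-exponentials fluorescence transient with GCaMP6s-like
#' kinetics (fast rise, slow decay).
#'
#' @param n_cells number of cells in the field of view.
#' @param n_modules number of latent modules the cells are partitioned into.
#' @param duration recording length in seconds.
#' @param fps sampling rate in frames per second.
#' @param p_intra probability that a cell fires at one of its own module's
#'   events.
#' @param p_inter probability that a cell fires at another module's event.
#'   Must satisfy `0 <= p_inter <= p_intra <= 1`.
#' @param module_event_rate module event rate, events per minute per module.
#' @param global_burst_rate tissue-wide synchronous burst rate, bursts per
#'   minute. All cells fire at a burst.
#' @param noise_event_rate independent noise-event rate, events per minute
#'   per cell.
#' @param rise_tau,decay_tau transient rise and decay time constants in
#'   seconds; `rise_tau < decay_tau`.
#' @param amplitude_mean mean event amplitude in dF/F units.
#' @param amplitude_cv coefficient of variation of event amplitudes
#'   (log-normal draws).
#' @param noise_sd standard deviation of additive Gaussian sensor noise, in
#'   dF/F units.
#' @param seed integer RNG seed; identical seed and config give bit-identical
#'   output.
#' @param field_size image size `c(height, width)` in pixels, used by
#'   [render_stack()] and for cell positions.
#' @param cell_radius cell-body scale in pixels (Gaussian blob sigma and
#'   minimum-spacing unit).
#' @param baseline_f baseline fluorescence of the rendered image, arbitrary
#'   intensity units.
#' @param render_gain intensity units added per unit dF/F when rendering.
#' @param clumped if `TRUE`, cell positions are drawn without the
#'   minimum-spacing constraint (for ROI merge/splitting experiments).
#'
#' @return A list of class `synth_config`.
#' @export
#' @examples
#' cfg <- synth_config(n_cells = 12, n_modules = 3, duration = 60, seed = 7)
#' sim <- generate_activity(cfg)
#' table(sim$truth$module_labels)
synth_config <- function(n_cells = 60, n_modules = 3, duration = 240,
                         fps = 15, p_intra = 0.9, p_inter = 0.05,
                         module_event_rate = 3, global_burst_rate = 1,
                         noise_event_rate = 0.5, rise_tau = 0.2,
                         decay_tau = 1.5, amplitude_mean = 0.5,
                         amplitude_cv = 0.3, noise_sd = 0.02, seed = 1,
                         field_size = c(128L, 128L), cell_radius = 4,
                         baseline_f = 100, render_gain = 100,
                         clumped = FALSE) {
  cfg <- list(n_cells = as.integer(n_cells), n_modules = as.integer(n_modules),
              duration = duration, fps = fps, p_intra = p_intra,
              p_inter = p_inter, module_event_rate = module_event_rate,
              global_burst_rate = global_burst_rate,
              noise_event_rate = noise_event_rate, rise_tau = rise_tau,
              decay_tau = decay_tau, amplitude_mean = amplitude_mean,
              amplitude_cv = amplitude_cv, noise_sd = noise_sd,
              seed = as.integer(seed), field_size = as.integer(field_size),
              cell_radius = cell_radius, baseline_f = baseline_f,
              render_gain = render_gain, clumped = isTRUE(clumped))
  num <- cfg[!(names(cfg) %in% "clumped")]
  check_finite(unlist(num), "synth_config values")
  if (cfg$n_cells < 1) abort("n_cells must be >= 1")
  if (cfg$n_modules < 1 || cfg$n_modules > cfg$n_cells)
    abort("n_modules must be in [1, n_cells]")
  if (cfg$duration <= 0) abort("duration must be > 0")
  if (cfg$fps <= 0) abort("fps must be > 0")
  if (cfg$p_inter < 0 || cfg$p_intra > 1 || cfg$p_inter > cfg$p_intra)
    abort("need 0 <= p_inter <= p_intra <= 1")
  rates <- c(cfg$module_event_rate, cfg$global_burst_rate,
             cfg$noise_event_rate)
  if (any(rates < 0)) abort("event rates must be >= 0")
  if (cfg$rise_tau <= 0 || cfg$rise_tau >= cfg$decay_tau)
    abort("need 0 < rise_tau < decay_tau")
  if (cfg$amplitude_mean < 0 || cfg$amplitude_cv < 0 || cfg$noise_sd < 0)
    abort("amplitude_mean, amplitude_cv and noise_sd must be >= 0")
  if (length(cfg$field_size) != 2 || any(cfg$field_size < 1))
    abort("field_size must be two positive integers (H, W)")
  if (cfg$cell_radius <= 0) abort("cell_radius must be > 0")
  class(cfg) <- "synth_config"
  cfg
}

# Unit-peak difference-of-exponentials transient sampled on a frame grid.
# Rescaled so max equals 1; amplitudes then read directly in dF/F units.
transient_kernel <- function(rise_tau, decay_tau, fps,
                             support_s = 8 * decay_tau) {
  t <- seq(0, support_s, by = 1 / fps)
  k <- exp(-t / decay_tau) - exp(-t / rise_tau)
  t_peak <- rise_tau * decay_tau / (decay_tau - rise_tau) *
    log(decay_tau / rise_tau)
  peak <- exp(-t_peak / decay_tau) - exp(-t_peak / rise_tau)
  k / peak
}

poisson_times <- function(rate_per_min, duration) {
  n <- rpois(1, rate_per_min * duration / 60)
  sort(runif(n, 0, duration))
}

draw_amplitudes <- function(n, mean, cv) {
  if (n == 0) return(numeric(0))
  if (mean == 0) return(numeric(n))
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# Rejection-sample cell centroids, uniform over the field with a minimum
# center-to-center spacing of 2*cell_radius (disabled when clumped).
draw_positions <- function(n, field_size, cell_radius, clumped,
                           max_tries = 20000L) {
  h <- field_size[1]; w <- field_size[2]
  margin <- cell_radius
  if (2 * margin >= min(h, w)) abort("field_size too small for cell_radius")
  xs <- numeric(0); ys <- numeric(0)
  tries <- 0L
  while (length(xs) < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      abort("could not place ", n, " cells with the spacing constraint; ",
            "enlarge field_size or set clumped = TRUE")
    x <- runif(1, margin, w - 1 - margin)
    y <- runif(1, margin, h - 1 - margin)
    if (!clumped && length(xs) > 0 &&
        min((xs - x)^2 + (ys - y)^2) < (2 * cell_radius)^2) next
    xs <- c(xs, x); ys <- c(ys, y)
  }
  cbind(x = xs, y = ys)
}

#' Generate synthetic microcircuit calcium activity with known ground truth
#'
#' Draws module, burst, and noise event times as Poisson processes, assigns
#' events to cells by the intra-/inter-module participation probabilities,
#' and convolves the per-cell event trains with a unit-peak
#' difference-of-exponentials transient. Module events and global bursts
#' carry a single amplitude shared by every participating cell, so cells
#' firing at the same population event produce identical transient shapes;
#' noise events draw one amplitude per cell. Returned traces are on the dF/F
#' scale (baseline 0) with additive Gaussian noise of sd `noise_sd`.
#'
#' @param config a [synth_config()].
#' @return A list with elements:
#'   \describe{
#'     \item{truth}{ground truth: `module_labels` (integer per cell),
#'       `event_times` (list of per-cell event onset times, s),
#'       `burst_times` (tissue-wide burst times, s),
#'       `module_event_times` (list per module), and `positions`
#'       (per-cell x/y pixel centroids, 0-based).}
#'     \item{traces}{a [trace_set()] of kind `"dff"`, one row per cell.}
#'   }
#' @export
generate_activity <- function(config) {
  if (!inherits(config, "synth_config")) config <- do.call(synth_config, config)
  set.seed(config$seed)
  n <- config$n_cells
  nf <- round(config$duration * config$fps)
  labels <- sort(rep_len(seq_len(config$n_modules), n))

  positions <- draw_positions(n, config$field_size, config$cell_radius,
                              config$clumped)

  module_times <- lapply(seq_len(config$n_modules), function(m)
    poisson_times(config$module_event_rate, config$duration))
  burst_times <- poisson_times(config$global_burst_rate, config$duration)

  # per-cell event lists: (time, amplitude)
  ev_t <- vector("list", n)
  ev_a <- vector("list", n)
  for (m in seq_len(config$n_modules)) {
    tm <- module_times[[m]]
    amps <- draw_amplitudes(length(tm), config$amplitude_mean,
                            config$amplitude_cv)
    for (k in seq_along(tm)) {
      p <- ifelse(labels == m, config$p_intra, config$p_inter)
      fire <- runif(n) < p
      for (i in which(fire)) {
        ev_t[[i]] <- c(ev_t[[i]], tm[k])
        ev_a[[i]] <- c(ev_a[[i]], amps[k])
      }
    }
  }
  burst_amps <- draw_amplitudes(length(burst_times), config$amplitude_mean,
                                config$amplitude_cv)
  for (k in seq_along(burst_times)) {
    for (i in seq_len(n)) {
      ev_t[[i]] <- c(ev_t[[i]], burst_times[k])
      ev_a[[i]] <- c(ev_a[[i]], burst_amps[k])
    }
  }
  for (i in seq_len(n)) {
    tn <- poisson_times(config$noise_event_rate, config$duration)
    ev_t[[i]] <- c(ev_t[[i]], tn)
    ev_a[[i]] <- c(ev_a[[i]], draw_amplitudes(length(tn),
                                              config$amplitude_mean,
                                              config$amplitude_cv))
  }

  kern <- transient_kernel(config$rise_tau, config$decay_tau, config$fps)
  lk <- length(kern)
  values <- matrix(0, nrow = n, ncol = nf)
  for (i in seq_len(n)) {
    o <- order(ev_t[[i]])
    ev_t[[i]] <- ev_t[[i]][o]
    ev_a[[i]] <- ev_a[[i]][o]
    tr <- numeric(nf)
    for (k in seq_along(ev_t[[i]])) {
      f0 <- floor(ev_t[[i]][k] * config$fps) + 1  # first frame at/after onset
      if (f0 > nf) next
      idx <- f0:min(nf, f0 + lk - 1)
      tr[idx] <- tr[idx] + ev_a[[i]][k] * kern[seq_along(idx)]
    }
    values[i, ] <- tr
  }
  if (config$noise_sd > 0)
    values <- values + matrix(rnorm(n * nf, sd = config$noise_sd), n, nf)

  truth <- list(module_labels = labels, event_times = ev_t,
                event_amplitudes = ev_a, burst_times = burst_times,
                module_event_times = module_times, positions = positions)
  class(truth) <- "ground_truth"
  traces <- trace_set(values, fps = config$fps,
                      roi_ids = seq_len(n), kind = "dff")
  list(truth = truth, traces = traces)
}

#' Render synthetic activity as a 16-bit time-lapse image stack
#'
#' Each frame is `baseline_f + render_gain * sum_i trace_i(t) * blob_i`,
#' where `blob_i` is a unit-peak isotropic 2-D Gaussian centered at cell
#' i's position with sigma `cell_radius / 2` (a Gaussian of sigma r/2 has
#' full width at half maximum close to a disk of radius r, so `cell_radius`
#' reads as the apparent cell-body radius), quantized to 16-bit integers.
#' Deterministic given its inputs. Overlapping or identical cell positions
#' are allowed; their blobs superpose additively.
#'
#' @param truth,traces output of [generate_activity()].
#' @param config the [synth_config()] used to generate them.
#' @return Integer array `c(H, W, n_frames)` with attributes `fps` and
#'   `bit_depth = 16`.
#' @export
render_stack <- function(truth, traces, config) {
  h <- config$field_size[1]; w <- config$field_size[2]
  values <- traces$values
  n <- nrow(values); nf <- ncol(values)
  if (n > 0 && nrow(truth$positions) != n)
    abort("positions and traces disagree on cell count")
  if (n > 0) {
    inside <- truth$positions[, "x"] >= 0 & truth$positions[, "x"] <= w - 1 &
      truth$positions[, "y"] >= 0 & truth$positions[, "y"] <= h - 1
    if (!all(inside)) abort("cell positions outside field_size")
  }
  # pixel-by-cell blob gain matrix (unit peak per blob)
  cols0 <- rep(0:(w - 1), each = h)
  rows0 <- rep(0:(h - 1), times = w)
  B <- matrix(0, nrow = h * w, ncol = max(n, 1))
  for (i in seq_len(n)) {
    dx <- cols0 - truth$positions[i, "x"]
    dy <- rows0 - truth$positions[i, "y"]
    B[, i] <- exp(-(dx^2 + dy^2) / (2 * (config$cell_radius / 2)^2))
  }
  flat <- if (n > 0) B %*% values * config$render_gain + config$baseline_f
          else matrix(config$baseline_f, h * w, nf)
  flat <- pmin(pmax(round(flat), 0), 65535)
  stack <- array(as.integer(flat), dim = c(h, w, nf))
  attr(stack, "fps") <- traces$fps
  attr(stack, "bit_depth") <- 16L
  stack
}

#' Write / read a multi-page 16-bit grayscale TIFF stack
#'
#' Intensities are stored as 16-bit samples; values are integer counts in
#' `[0, 65535]`.
#'
#' @param stack integer array `c(H, W, n_frames)`.
#' @param path output file.
#' @export
write_stack_tiff <- function(stack, path) {
  frames <- lapply(seq_len(dim(stack)[3]),
                   function(t) stack[, , t] / 65535)
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @param fps sampling rate to attach to the stack read back.
#' @export
read_stack_tiff <- function(path, fps = NULL) {
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  h <- nrow(frames[[1]]); w <- ncol(frames[[1]])
  stack <- array(0L, dim = c(h, w, length(frames)))
  for (t in seq_along(frames))
    stack[, , t] <- as.integer(round(frames[[t]] * 65535))
  if (!is.null(fps)) attr(stack, "fps") <- fps
  attr(stack, "bit_depth") <- 16L
  stack
}

#' Write synthetic ground truth to plain-text files
#'
#' Labels and positions go to a JSON file, event times to a long-format CSV
#' (`cell`, `onset_s`, `amplitude`), burst times to a CSV.
#'
#' @param truth a `ground_truth` from [generate_activity()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_ground_truth <- function(truth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pj <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(
    list(module_labels = truth$module_labels,
         positions = as.data.frame(truth$positions),
         coordinate_convention = "0-based, x = column, y = row"),
    pj, digits = NA)
  ev <- do.call(rbind, lapply(seq_along(truth$event_times), function(i) {
    if (length(truth$event_times[[i]]) == 0) return(NULL)
    data.frame(cell = i, onset_s = truth$event_times[[i]],
               amplitude = truth$event_amplitudes[[i]])
  }))
  if (is.null(ev)) ev <- data.frame(cell = integer(0), onset_s = numeric(0),
                                    amplitude = numeric(0))
  pe <- file.path(dir, "event_times.csv")
  write.csv(ev, pe, row.names = FALSE)
  pb <- file.path(dir, "burst_times.csv")
  write.csv(data.frame(burst_s = truth$burst_times), pb, row.names = FALSE)
  invisible(c(pj, pe, pb))
}
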