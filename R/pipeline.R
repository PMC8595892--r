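#' Run the full analysis chain on one recording
#'
#' Orchestrates ROI detection, trace extraction, dF/F, event detection,
#' whole-tissue firing rate, and the functional-connectivity graph metrics
#' on one time-lapse stack, with optional curation and output writing. The
#' run is deterministic: every stage is a pure function of the stack and
#' the configuration.
#'
#' @param stack an `H x W x n_frames` array, or a path to a multi-page
#'   TIFF.
#' @param fps sampling rate in frames/s (default: the stack's attribute,
#'   else 15).
#' @param detection a [detection_params()].
#' @param roi_radius circular ROI mask radius in pixels (default 3).
#' @param boundary,removals passed to [curate_seeds()].
#' @param similarity,min_amplitude passed to [detect_events()].
#' @param baseline_percentile,baseline_window passed to [compute_dff()].
#' @param connectome_threshold passed to [connectome_edges()].
#' @param max_modules passed to [detect_modules()].
#' @param group optional group label recorded in the metrics (condition,
#'   week, ...).
#' @param out_dir if given, CSV/JSON artifacts are written there.
#' @return A list of class `recording_result`: `metrics` (named list of
#'   scalars), `seeds`, `rois`, `dff`, `events`, `cm`, `partition`,
#'   `edges`, and `provenance`.
#' @export
run_recording <- function(stack, fps = NULL,
                          detection = detection_params(),
                          roi_radius = 3, boundary = NULL,
                          removals = integer(0),
                          similarity = 0.7, min_amplitude = 0.01,
                          baseline_percentile = 20, baseline_window = 10,
                          connectome_threshold = 0.5, max_modules = 10,
                          group = NA_character_, out_dir = NULL) {
  if (is.character(stack)) {
    if (!file.exists(stack)) abort("stack file not found: ", stack)
    stack <- read_stack_tiff(stack, fps = fps)
  }
  if (is.null(fps)) fps <- attr(stack, "fps")
  if (is.null(fps)) fps <- 15
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      abort("stage '", name, "' failed: ", conditionMessage(e)))
  }
  proj <- run_stage("max_projection", max_projection(stack))
  seeds <- run_stage("detect_seeds", detect_seeds(proj, detection))
  seeds <- run_stage("curate_seeds",
                     curate_seeds(seeds, boundary = boundary,
                                  removals = removals))
  if (nrow(seeds) < 2) abort("stage 'detect_seeds' failed: fewer than 2 ",
                             "ROIs detected")
  rois <- run_stage("make_masks",
                    make_masks(seeds, radius = roi_radius,
                               image_shape = dim(stack)[1:2]))
  raw <- run_stage("extract_traces", extract_traces(stack, rois, fps = fps))
  dff <- run_stage("compute_dff",
                   compute_dff(raw, percentile = baseline_percentile,
                               window = baseline_window))
  events <- run_stage("detect_events",
                      detect_events(dff, similarity = similarity,
                                    min_amplitude = min_amplitude))
  wt_events <- run_stage("whole_tissue",
                         detect_whole_tissue_events(
                           dff, similarity = similarity,
                           min_amplitude = min_amplitude))
  cm <- run_stage("correlation_matrix",
                  correlation_matrix(dff, positions = seeds[, c("x", "y")]))
  gm <- run_stage("graph_metrics", graph_metrics(cm))
  part <- run_stage("detect_modules",
                    detect_modules(cm, max_modules = max_modules))
  edges <- run_stage("connectome_edges",
                     connectome_edges(cm, threshold = connectome_threshold))
  metrics <- list(
    group = group,
    n_rois = nrow(seeds),
    avg_correlation = gm$avg_correlation,
    avg_clustering = gm$avg_clustering,
    avg_path_length = gm$avg_path_length,
    firing_rate_per_min = firing_rate(wt_events),
    modularity_q = part$modularity_q,
    n_modules = part$n_modules,
    mean_intra_corr = if (length(part$intra_corrs)) mean(part$intra_corrs)
                      else NA_real_,
    mean_inter_corr = if (length(part$inter_corrs)) mean(part$inter_corrs)
                      else NA_real_)
  provenance <- list(package = "microfc",
                     version = as.character(utils::packageVersion("microfc")),
                     fps = fps, roi_radius = roi_radius,
                     similarity = similarity, min_amplitude = min_amplitude,
                     baseline_percentile = baseline_percentile,
                     baseline_window = baseline_window,
                     detection = unclass(detection))
  res <- structure(list(metrics = metrics, seeds = seeds, rois = rois,
                        dff = dff, events = events, wt_events = wt_events,
                        cm = cm, partition = part, edges = edges,
                        provenance = provenance),
                   class = "recording_result")
  if (!is.null(out_dir)) write_recording(res, out_dir)
  res
}

#' @export
print.recording_result <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(paste0("<recording_result: %d ROIs | corr %.3f | clust %.3f",
                     " | L %.2f | Q %.3f | %d modules | %.2f ev/min>\n"),
              m$n_rois, m$avg_correlation, m$avg_clustering,
              m$avg_path_length, m$modularity_q, m$n_modules,
              m$firing_rate_per_min))
  invisible(x)
}

#' Write the artifacts of a recording run to a directory
#' @param res a `recording_result`.
#' @param dir output directory.
#' @export
write_recording <- function(res, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_seeds_csv(res$seeds, file.path(dir, "seeds.csv"))
  write_traces_csv(res$dff, file.path(dir, "dff.csv"))
  write_events_csv(res$events, file.path(dir, "events.csv"))
  write_events_csv(res$wt_events, file.path(dir, "whole_tissue_events.csv"))
  write_correlation_csv(res$cm, file.path(dir, "correlation_matrix.csv"))
  write.csv(res$edges, file.path(dir, "connectome_edges.csv"),
            row.names = FALSE)
  write.csv(data.frame(roi = res$cm$roi_ids, module = res$partition$labels),
            file.path(dir, "partition.csv"), row.names = FALSE)
  jsonlite::write_json(c(res$metrics, list(provenance = res$provenance)),
                       file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Collect per-recording metrics into a group table
#'
#' @param results list of `recording_result` objects.
#' @return data.frame, one row per recording, columns = group label plus
#'   the scalar metrics.
#' @export
group_table <- function(results) {
  do.call(rbind, lapply(results, function(r)
    as.data.frame(r$metrics[c("group", "n_rois", "avg_correlation",
                              "avg_clustering", "avg_path_length",
                              "firing_rate_per_min", "modularity_q",
                              "n_modules")])))
}

#' Compare a metric between groups
#'
#' Two groups: unpaired two-tailed t-test (Student by default; set
#' `welch = TRUE` for unequal variances, `paired = TRUE` for matched
#' before/after comparisons). Three or more groups: one-way ANOVA followed
#' by Tukey HSD. Routine significance reporting at alpha 0.05.
#'
#' @param table a data.frame with a `group` column (see [group_table()]).
#' @param metric name of the metric column to compare.
#' @param welch,paired t-test variants (two-group designs only).
#' @param alpha significance level (reporting only).
#' @return A list: `design` (`"two-group"` or `"multi-group"`), `statistic`,
#'   `p_value`, `significant`, plus `tukey` (data.frame) for multi-group
#'   designs.
#' @export
compare_groups <- function(table, metric, welch = FALSE, paired = FALSE,
                           alpha = 0.05) {
  if (!metric %in% names(table)) abort("no column '", metric, "' in table")
  g <- factor(table$group)
  y <- table[[metric]]
  sizes <- table(g)
  if (length(sizes) < 2) abort("need at least 2 groups")
  if (any(sizes < 2)) abort("each group needs at least 2 observations")
  if (length(sizes) == 2) {
    lv <- levels(g)
    tt <- t.test(y[g == lv[1]], y[g == lv[2]], var.equal = !welch,
                 paired = paired)
    list(design = "two-group", test = tt$method,
         statistic = unname(tt$statistic), p_value = tt$p.value,
         significant = tt$p.value < alpha)
  } else {
    fit <- aov(y ~ g)
    an <- summary(fit)[[1]]
    tk <- TukeyHSD(fit)$g
    list(design = "multi-group", test = "one-way ANOVA + Tukey HSD",
         statistic = an[["F value"]][1], p_value = an[["Pr(>F)"]][1],
         significant = an[["Pr(>F)"]][1] < alpha,
         tukey = data.frame(comparison = rownames(tk),
                            diff = tk[, "diff"], p_adj = tk[, "p adj"],
                            row.names = NULL))
  }
}
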