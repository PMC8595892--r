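test_that("config validation rejects inconsistent parameters", {
  expect_error(synth_config(p_intra = 0.2, p_inter = 0.5), "p_inter")
  expect_error(synth_config(rise_tau = 2, decay_tau = 1), "rise_tau")
  expect_error(synth_config(duration = 0), "duration")
  expect_error(synth_config(module_event_rate = -1), "rates")
  expect_error(synth_config(noise_sd = NaN), "finite")
})

test_that("no events and no noise give identically zero traces", {
  cfg <- synth_config(n_cells = 10, duration = 20, module_event_rate = 0,
                      global_burst_rate = 0, noise_event_rate = 0,
                      noise_sd = 0, seed = 1)
  sim <- generate_activity(cfg)
  expect_true(all(sim$traces$values == 0))
  expect_equal(sum(lengths(sim$truth$event_times)), 0)
})

test_that("full intra-module coupling yields identical same-module traces", {
  cfg <- synth_config(n_cells = 6, n_modules = 2, p_intra = 1, p_inter = 0,
                      duration = 60, global_burst_rate = 0,
                      noise_event_rate = 0, noise_sd = 0, seed = 3)
  sim <- generate_activity(cfg)
  lab <- sim$truth$module_labels
  same <- which(lab == lab[1])
  expect_gt(sd(sim$traces$values[same[1], ]), 0)
  expect_equal(cor(sim$traces$values[same[1], ], sim$traces$values[same[2], ]),
               1.0)
})

test_that("identical seed and config reproduce activity and stack exactly", {
  cfg <- render_test_config(seed = 9)
  a <- generate_activity(cfg)
  b <- generate_activity(cfg)
  expect_identical(a$truth, b$truth)
  expect_identical(a$traces$values, b$traces$values)
  expect_identical(render_stack(a$truth, a$traces, cfg),
                   render_stack(b$truth, b$traces, cfg))
})

test_that("within-module correlation exceeds between-module correlation", {
  cfg <- synth_config(n_cells = 60, n_modules = 3, p_intra = 0.9,
                      p_inter = 0.05, duration = 240, fps = 15, seed = 21)
  sim <- generate_activity(cfg)
  w <- cor(t(sim$traces$values))
  lab <- sim$truth$module_labels
  same <- outer(lab, lab, "==") & upper.tri(w)
  diff <- !outer(lab, lab, "==") & upper.tri(w)
  expect_gt(mean(w[same]), mean(w[diff]))
})

test_that("mean within-module correlation is monotone in p_intra", {
  for (s in 1:5) {
    within_corr <- sapply(c(0.4, 0.9), function(p) {
      cfg <- synth_config(n_cells = 30, n_modules = 3, p_intra = p,
                          p_inter = 0.05, duration = 120, seed = s)
      sim <- generate_activity(cfg)
      w <- cor(t(sim$traces$values))
      lab <- sim$truth$module_labels
      mean(w[outer(lab, lab, "==") & upper.tri(w)])
    })
    expect_gt(within_corr[2], within_corr[1])
  }
})

test_that("realized global burst count is Poisson-consistent with the rate", {
  cfg <- synth_config(duration = 240, global_burst_rate = 3, seed = 5)
  sim <- generate_activity(cfg)
  expected <- cfg$global_burst_rate * cfg$duration / 60
  observed <- length(sim$truth$burst_times)
  expect_lt(abs(observed - expected), 3 * sqrt(expected))
})

test_that("positions respect the field and the minimum spacing", {
  cfg <- synth_config(n_cells = 40, seed = 2)
  sim <- generate_activity(cfg)
  pos <- sim$truth$positions
  expect_true(all(pos[, "x"] >= 0 & pos[, "x"] <= cfg$field_size[2] - 1))
  expect_true(all(pos[, "y"] >= 0 & pos[, "y"] <= cfg$field_size[1] - 1))
  expect_gte(min(dist(pos)), 2 * cfg$cell_radius)
  expect_length(sim$truth$module_labels, cfg$n_cells)
})

test_that("rendering zero traces gives uniform baseline frames", {
  cfg <- synth_config(n_cells = 3, duration = 1, fps = 5,
                      module_event_rate = 0, global_burst_rate = 0,
                      noise_event_rate = 0, noise_sd = 0, seed = 1)
  sim <- generate_activity(cfg)
  stack <- render_stack(sim$truth, sim$traces, cfg)
  expect_true(all(stack == round(cfg$baseline_f)))
})

test_that("a single cell's pixel trace peaks at the trace's peak frame", {
  cfg <- synth_config(n_cells = 1, n_modules = 1, duration = 30,
                      module_event_rate = 6, global_burst_rate = 0,
                      noise_event_rate = 0, noise_sd = 0, seed = 7)
  sim <- generate_activity(cfg)
  expect_gt(max(sim$traces$values), 0)
  stack <- render_stack(sim$truth, sim$traces, cfg)
  px <- round(sim$truth$positions[1, "x"]) + 1
  py <- round(sim$truth$positions[1, "y"]) + 1
  pixel_trace <- stack[py, px, ]
  # 16-bit quantization can tie neighboring frames; the trace's peak frame
  # must attain the pixel maximum
  expect_equal(pixel_trace[which.max(sim$traces$values[1, ])],
               max(pixel_trace))
})

test_that("max projection of 20 well-separated cells has 20 local maxima", {
  cfg <- render_test_config(seed = 11)
  sim <- generate_activity(cfg)
  stack <- render_stack(sim$truth, sim$traces, cfg)
  proj <- max_projection(stack)
  # brute-force 8-neighborhood scan; plateaus merged as one maximum
  h <- nrow(proj); w <- ncol(proj)
  is_max <- matrix(FALSE, h, w)
  for (r in 2:(h - 1)) for (c in 2:(w - 1)) {
    nb <- proj[(r - 1):(r + 1), (c - 1):(c + 1)]
    if (proj[r, c] >= max(nb) && proj[r, c] > cfg$baseline_f + 2)
      is_max[r, c] <- TRUE
  }
  n_peaks <- max(EBImage::bwlabel(EBImage::Image(is_max * 1)))
  expect_equal(n_peaks, cfg$n_cells)
})

test_that("ground truth and traces round-trip through text files", {
  cfg <- synth_config(n_cells = 4, duration = 10, seed = 13)
  sim <- generate_activity(cfg)
  dir <- withr::local_tempdir()
  write_ground_truth(sim$truth, dir)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_equal(gt$module_labels, sim$truth$module_labels)
  p <- file.path(dir, "traces.csv")
  write_traces_csv(sim$traces, p)
  back <- read_traces_csv(p, kind = "dff")
  expect_equal(back$values, sim$traces$values, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(back$fps, sim$traces$fps, tolerance = 1e-6)
})
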