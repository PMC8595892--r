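test_that("correlation matrix reproduces hand-computed Pearson values", {
  v <- rbind(c(1, 2, 3, 4), c(1, 2, 2, 4))
  d <- trace_set(v, fps = 1, kind = "dff")
  cm <- correlation_matrix(d)
  # textbook sum formula
  x <- v[1, ]; y <- v[2, ]
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(cm$w[1, 2], r)
  expect_equal(cm$w[2, 1], r)
  expect_equal(diag(cm$w), c(1, 1))

  same <- trace_set(rbind(x, x), fps = 1, kind = "dff")
  expect_equal(correlation_matrix(same)$w[1, 2], 1.0)
  anti <- trace_set(rbind(x - mean(x), -(x - mean(x))), fps = 1,
                    kind = "dff")
  expect_equal(correlation_matrix(anti)$w[1, 2], -1.0)
})

test_that("zero-variance traces get zero correlations with a warning", {
  v <- rbind(sin(1:50), rep(1, 50), cos(1:50))
  expect_warning(cm <- correlation_matrix(trace_set(v, fps = 1,
                                                    kind = "dff")),
                 "zero-variance")
  expect_equal(cm$w[2, c(1, 3)], c(0, 0))
  expect_equal(cm$w[2, 2], 1)
})

test_that("average correlation is the off-diagonal mean and permutation-invariant", {
  w <- diag(3)
  w[1, 2] <- w[2, 1] <- 0.2
  w[1, 3] <- w[3, 1] <- 0.4
  w[2, 3] <- w[3, 2] <- 0.6
  cm <- corr_matrix(w)
  expect_equal(average_correlation(cm), 0.4)
  p <- c(3, 1, 2)
  expect_equal(average_correlation(corr_matrix(w[p, p])), 0.4)
  expect_equal(average_correlation(corr_matrix(matrix(1, 4, 4))), 1)
})

test_that("clustering closed forms: complete graph and open path", {
  w <- matrix(0.7, 5, 5); diag(w) <- 1
  cc <- clustering_coefficients(corr_matrix(w))
  expect_equal(cc$per_node, rep(1, 5))
  expect_equal(cc$mean, 1)
  path <- diag(3)
  path[1, 2] <- path[2, 1] <- 0.8
  path[2, 3] <- path[3, 2] <- 0.6
  cc2 <- clustering_coefficients(corr_matrix(path))
  expect_equal(cc2$per_node[2], 0)
})

test_that("path length closed forms and homogeneity", {
  w <- matrix(1, 4, 4)
  expect_equal(path_length(corr_matrix(w)), 1.0)
  w3 <- diag(3)
  w3[1, 2] <- w3[2, 1] <- 0.5
  w3[2, 3] <- w3[3, 2] <- 0.5
  w3[1, 3] <- w3[3, 1] <- 0.1
  expect_equal(path_length(corr_matrix(w3)), 8 / 3)  # D_ac = min(10, 4)
  half <- w3 * 0.5; diag(half) <- 1
  expect_equal(path_length(corr_matrix(half)), 2 * path_length(corr_matrix(w3)))
})

test_that("disconnected pairs use the surrogate distance or Inf", {
  w <- diag(4)
  w[1, 2] <- w[2, 1] <- 0.5
  w[3, 4] <- w[4, 3] <- 0.5
  cm <- corr_matrix(w)
  # max finite distance 2, so unreachable pairs contribute 4 * 2 = 8
  expect_equal(path_length(cm), (2 + 2 + 4 * 8) / 6)
  expect_equal(path_length(cm, unreachable = "strict"), Inf)
})

test_that("modularity closed forms: one module, two cliques", {
  w <- matrix(0.8, 6, 6); diag(w) <- 1
  cm <- corr_matrix(w)
  expect_equal(modularity_q(cm, rep(1, 6)), 0)
  w2 <- matrix(0, 8, 8)
  w2[1:4, 1:4] <- 1
  w2[5:8, 5:8] <- 1
  diag(w2) <- 1
  expect_equal(modularity_q(corr_matrix(w2), rep(1:2, each = 4)), 0.5)
  expect_error(modularity_q(cm, rep(1, 3)), "labels")
})

test_that("graph metrics agree with brute-force oracles on random graphs", {
  for (i in 1:25) {
    n <- 5 + (i %% 4)
    w <- random_corr(n, seed = 1000 + i)
    cm <- corr_matrix(w)
    expect_equal(clustering_coefficients(cm)$per_node, onnela_brute(w),
                 tolerance = 1e-10)
    expect_equal(path_length(cm), path_length_brute(w), tolerance = 1e-10)
    set.seed(2000 + i)
    labels <- sample(1:3, n, replace = TRUE)
    expect_equal(modularity_q(cm, labels), modularity_brute(w, labels),
                 tolerance = 1e-10)
  }
})

test_that("modularity agrees with igraph on weighted graphs", {
  for (i in 1:5) {
    w <- random_corr(8, seed = 300 + i)
    wc <- w; diag(wc) <- 0
    g <- igraph::graph_from_adjacency_matrix(wc, mode = "undirected",
                                             weighted = TRUE)
    set.seed(400 + i)
    labels <- sample(1:3, 8, replace = TRUE)
    expect_equal(modularity_q(corr_matrix(w), labels),
                 igraph::modularity(g, labels,
                                    weights = igraph::E(g)$weight),
                 tolerance = 1e-10)
  }
})

test_that("planted two-block structure is recovered exactly", {
  w <- matrix(0.1, 12, 12)
  w[1:6, 1:6] <- 0.9
  w[7:12, 7:12] <- 0.9
  diag(w) <- 1
  part <- detect_modules(corr_matrix(w))
  expect_equal(part$n_modules, 2)
  expect_equal(length(unique(part$labels[1:6])), 1)
  expect_equal(length(unique(part$labels[7:12])), 1)
  expect_true(part$labels[1] != part$labels[7])
})

test_that("a structureless matrix yields a single module with Q = 0", {
  w <- matrix(0.5, 9, 9); diag(w) <- 1
  part <- detect_modules(corr_matrix(w))
  expect_equal(part$n_modules, 1)
  expect_equal(part$modularity_q, 0)
})

test_that("modularity of planted blocks grows with the weight gap", {
  qs <- sapply(seq(0.1, 0.5, by = 0.1), function(gap) {
    w <- matrix(0.5 - gap, 10, 10)
    w[1:5, 1:5] <- 0.5 + gap
    w[6:10, 6:10] <- 0.5 + gap
    diag(w) <- 1
    detect_modules(corr_matrix(w))$modularity_q
  })
  expect_true(all(diff(qs) >= 0))
})

test_that("generator module labels are recovered by hierarchical clustering", {
  cfg <- synth_config(seed = 51)
  sim <- generate_activity(cfg)
  part <- detect_modules(correlation_matrix(sim$traces))
  skip_if_not_installed("mclust")
  ari <- mclust::adjustedRandIndex(part$labels, sim$truth$module_labels)
  expect_gte(ari, 0.9)
})

test_that("intra/inter summaries on planted blocks and single modules", {
  w <- matrix(0.1, 10, 10)
  w[1:5, 1:5] <- 0.9
  w[6:10, 6:10] <- 0.9
  diag(w) <- 1
  cm <- corr_matrix(w)
  ii <- intra_inter_correlations(cm, rep(1:2, each = 5))
  expect_equal(unname(ii$intra), c(0.9, 0.9))
  expect_equal(unname(ii$inter), 0.1)
  single <- intra_inter_correlations(cm, rep(1, 10))
  expect_equal(unname(single$intra), average_correlation(cm))
  expect_length(single$inter, 0)
  # singleton modules are excluded from intra
  ii3 <- intra_inter_correlations(cm, c(rep(1, 9), 2))
  expect_length(ii3$intra, 1)
})

test_that("connectome edge lists filter and sort by weight", {
  w <- diag(3)
  w[1, 2] <- w[2, 1] <- 0.6
  w[1, 3] <- w[3, 1] <- 0.9
  w[2, 3] <- w[3, 2] <- 0.2
  cm <- corr_matrix(w)
  e <- connectome_edges(cm)
  expect_equal(e$weight, c(0.9, 0.6))
  expect_equal(e$i, c(1, 1))
  expect_equal(e$j, c(3, 2))
  all04 <- matrix(0.4, 5, 5); diag(all04) <- 1
  expect_equal(nrow(connectome_edges(corr_matrix(all04))), 0)
  expect_equal(nrow(connectome_edges(cm, threshold = -1)), 3)
})

test_that("regression results match closed-form least squares", {
  # exact linear relation between distance and correlation
  pos <- cbind(x = c(0, 10, 20, 35, 50), y = 0)
  n <- 5
  d <- as.matrix(dist(pos))
  w <- 1 - d / 100
  diag(w) <- 1
  cm <- corr_matrix(w, positions = pos)
  fit <- suppressWarnings(distance_correlation_regression(cm))
  expect_equal(fit$slope, -0.01, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1.0, tolerance = 1e-12)
  # constant correlations: flat fit
  wc <- matrix(0.3, 5, 5); diag(wc) <- 1
  flat <- distance_correlation_regression(corr_matrix(wc, positions = pos))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)
})

test_that("hand-made points match the normal equations", {
  x <- c(1, 2, 4, 6, 9)
  y <- c(0.9, 0.8, 0.75, 0.5, 0.3)
  slope <- (sum(x * y) - length(x) * mean(x) * mean(y)) /
    (sum(x^2) - length(x) * mean(x)^2)
  intercept <- mean(y) - slope * mean(x)
  fit <- microfc:::ols_summary(x, y)
  expect_equal(fit$slope, slope, tolerance = 1e-12)
  expect_equal(fit$intercept, intercept, tolerance = 1e-12)
  pred <- intercept + slope * x
  r2 <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  expect_equal(fit$r_squared, r2, tolerance = 1e-12)
})

test_that("module size regression needs three modules and runs OLS", {
  w <- matrix(0.05, 12, 12)
  w[1:3, 1:3] <- 0.9
  w[4:7, 4:7] <- 0.8
  w[8:12, 8:12] <- 0.7
  diag(w) <- 1
  cm <- corr_matrix(w)
  labels <- rep(1:3, c(3, 4, 5))
  part <- structure(list(labels = labels), class = "module_partition")
  fit <- suppressWarnings(module_size_regression(part, cm))
  expect_equal(fit$slope, -0.1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("all metrics are invariant under node permutation", {
  w <- random_corr(7, seed = 77)
  pos <- cbind(x = runif(7, 0, 50), y = runif(7, 0, 50))
  cm <- corr_matrix(w, positions = pos)
  set.seed(7)
  p <- sample(7)
  cmp <- corr_matrix(w[p, p], positions = pos[p, ])
  expect_equal(average_correlation(cmp), average_correlation(cm))
  expect_equal(clustering_coefficients(cmp)$mean,
               clustering_coefficients(cm)$mean)
  expect_equal(path_length(cmp), path_length(cm))
  labels <- c(1, 1, 2, 2, 2, 3, 3)
  expect_equal(modularity_q(cmp, labels[p]), modularity_q(cm, labels))
  expect_equal(distance_correlation_regression(cmp)$slope,
               distance_correlation_regression(cm)$slope)
})
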