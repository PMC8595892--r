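# Independent brute-force oracles for the graph metrics, plus small
# fixture builders shared across test files.

# Onnela clustering by explicit triple enumeration
onnela_brute <- function(w) {
  w[w < 0] <- 0
  diag(w) <- 0
  n <- nrow(w)
  mx <- max(w)
  if (mx == 0) return(rep(0, n))
  wh <- w / mx
  ci <- numeric(n)
  for (i in 1:n) {
    k <- sum(w[i, ] > 0)
    if (k < 2) next
    acc <- 0
    for (j in 1:n) for (l in 1:n) {
      if (j == i || l == i || j == l) next
      acc <- acc + (wh[i, j] * wh[i, l] * wh[j, l])^(1 / 3)
    }
    ci[i] <- acc / (k * (k - 1))
  }
  ci
}

# weighted path length by Floyd-Warshall on 1/w lengths
path_length_brute <- function(w, unreachable = "surrogate") {
  w[w < 0] <- 0
  diag(w) <- 0
  n <- nrow(w)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[w > 0] <- 1 / w[w > 0]
  for (k in 1:n) for (i in 1:n) for (j in 1:n)
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  off <- D[upper.tri(D)]
  if (any(is.infinite(off))) {
    if (unreachable == "strict") return(Inf)
    finite <- off[is.finite(off)]
    off[is.infinite(off)] <- if (length(finite)) n * max(finite) else n
  }
  mean(off)
}

# Newman Q by explicit double loop (null model keeps the i = j term)
modularity_brute <- function(w, labels) {
  w[w < 0] <- 0
  diag(w) <- 0
  n <- nrow(w)
  s <- rowSums(w)
  m2 <- sum(s)
  q <- 0
  for (i in 1:n) for (j in 1:n)
    if (labels[i] == labels[j]) q <- q + w[i, j] - s[i] * s[j] / m2
  q / m2
}

# random symmetric correlation-like matrix with unit diagonal
random_corr <- function(n, seed, lo = 0, hi = 1) {
  set.seed(seed)
  w <- matrix(runif(n * n, lo, hi), n, n)
  w <- (w + t(w)) / 2
  diag(w) <- 1
  w
}

# event recall/precision against ground-truth onset times
event_match_stats <- function(raster, truth, tol = 0.5) {
  rec <- c(); prec <- c()
  for (i in seq_along(truth$event_times)) {
    gt <- truth$event_times[[i]]
    dt <- raster$events$onset_s[raster$events$roi == i]
    if (length(gt))
      rec <- c(rec, vapply(gt, function(t) any(abs(dt - t) <= tol),
                           logical(1)))
    if (length(dt))
      prec <- c(prec, vapply(dt, function(t) any(abs(gt - t) <= tol),
                             logical(1)))
  }
  c(recall = mean(rec), precision = mean(prec))
}

# greedy bipartite nearest-neighbor matching of seeds to planted positions
seed_match_stats <- function(seeds, positions, tol = 3) {
  matched <- rep(FALSE, nrow(positions))
  used <- rep(FALSE, nrow(seeds))
  for (i in seq_len(nrow(positions))) {
    if (nrow(seeds) == 0) break
    d <- sqrt((seeds$x - positions[i, "x"])^2 +
              (seeds$y - positions[i, "y"])^2)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && d[j] <= tol) {
      matched[i] <- TRUE
      used[j] <- TRUE
    }
  }
  list(recall = mean(matched), spurious = sum(!used))
}

# fast config for rendered-stack tests: 20 resolvable cells, 30 s
render_test_config <- function(seed, ...) {
  synth_config(n_cells = 20, n_modules = 2, duration = 30, seed = seed,
               noise_sd = 0, global_burst_rate = 4, noise_event_rate = 2,
               ...)
}
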