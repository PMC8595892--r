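#' Pearson functional-connectivity matrix from dF/F traces
#'
#' Edge weight `w_ij` is the Pearson correlation between the full-length
#' dF/F traces of ROIs i and j. The matrix is symmetric with unit diagonal.
#' A zero-variance trace gets correlation 0 to every other node (with a
#' warning); the node is kept.
#'
#' @param dff a dF/F [trace_set()] with at least 2 ROIs.
#' @param positions optional per-ROI `(x, y)` pixel centroids (matrix or
#'   data.frame), used by connectome plots and distance regressions.
#' @return A list of class `corr_matrix`: `w` (N x N), `roi_ids`,
#'   `positions`.
#' @export
correlation_matrix <- function(dff, positions = NULL) {
  if (!inherits(dff, "trace_set")) abort("dff must be a trace_set")
  n <- nrow(dff$values)
  if (n < 2) abort("need at least 2 ROIs")
  sds <- apply(dff$values, 1, sd)
  w <- suppressWarnings(cor(t(dff$values)))
  if (any(sds == 0)) {
    warning("zero-variance trace(s): ",
            paste(dff$roi_ids[sds == 0], collapse = ", "),
            "; their correlations set to 0", call. = FALSE)
    w[sds == 0, ] <- 0
    w[, sds == 0] <- 0
  }
  diag(w) <- 1
  if (!is.null(positions)) {
    positions <- as.matrix(positions)[, 1:2, drop = FALSE]
    colnames(positions) <- c("x", "y")
    if (nrow(positions) != n) abort("positions must have one row per ROI")
  }
  corr_matrix(w, roi_ids = dff$roi_ids, positions = positions)
}

#' @rdname correlation_matrix
#' @param w symmetric numeric matrix of Pearson coefficients with unit
#'   diagonal.
#' @param roi_ids node identifiers.
#' @export
corr_matrix <- function(w, roi_ids = NULL, positions = NULL) {
  w <- as.matrix(w)
  if (nrow(w) != ncol(w)) abort("w must be square")
  if (max(abs(w - t(w))) > 1e-8) abort("w must be symmetric")
  w <- (w + t(w)) / 2
  if (any(abs(w) > 1 + 1e-8)) abort("|w_ij| must be <= 1")
  diag(w) <- 1
  if (is.null(roi_ids)) roi_ids <- seq_len(nrow(w))
  structure(list(w = w, roi_ids = roi_ids, positions = positions),
            class = "corr_matrix")
}

#' @export
print.corr_matrix <- function(x, ...) {
  cat(sprintf("<corr_matrix: %d nodes, mean off-diagonal %.3f>\n",
              nrow(x$w), average_correlation(x)))
  invisible(x)
}

# non-negative weight matrix for the graph-theoretic formulas: negatives
# clipped to 0, diagonal zeroed. Raw signed values stay in cm$w.
clipped_weights <- function(cm) {
  w <- cm$w
  w[w < 0] <- 0
  diag(w) <- 0
  w
}

#' Average correlation of a functional-connectivity matrix
#'
#' Mean of the N(N-1)/2 off-diagonal upper-triangle Pearson coefficients
#' (signed; no clipping).
#'
#' @param cm a [corr_matrix()].
#' @return A scalar.
#' @export
average_correlation <- function(cm) {
  n <- nrow(cm$w)
  if (n < 2) abort("need at least 2 nodes")
  mean(cm$w[upper.tri(cm$w)])
}

#' Onnela weighted clustering coefficients
#'
#' Threshold-free weighted clustering: with weights max-normalized as
#' `what_ij = w_ij / max(w)`, node i's coefficient is the sum of geometric-
#' mean triangle intensities `(what_ij what_ik what_jk)^(1/3)` over ordered
#' neighbor pairs, divided by `k_i (k_i - 1)`. Negative correlations are
#' clipped to 0 first. By default `k_i` counts strictly positive weights
#' (`degree = "positive"`); `degree = "all"` uses N-1 for every node.
#' Nodes with `k_i < 2` get coefficient 0.
#'
#' @param cm a [corr_matrix()].
#' @param degree how to count the degree `k_i` in the normalization.
#' @return A list: `per_node` (C_i vector) and `mean`.
#' @export
clustering_coefficients <- function(cm, degree = c("positive", "all")) {
  degree <- match.arg(degree)
  w <- clipped_weights(cm)
  n <- nrow(w)
  mx <- max(w)
  if (mx == 0)
    return(list(per_node = rep(0, n), mean = 0))
  what <- (w / mx)^(1 / 3)
  tri <- diag(what %*% what %*% what)  # 2 * sum over unordered triangles
  k <- if (degree == "positive") rowSums(w > 0) else rep(n - 1, n)
  ci <- ifelse(k >= 2, tri / (k * (k - 1)), 0)
  list(per_node = as.numeric(ci), mean = mean(ci))
}

#' Weighted characteristic path length
#'
#' Each positive-weight pair carries an edge of length `1 / w_ij`
#' (negatives clipped to 0 first; zero weight means no direct edge). All
#' pairwise shortest-path distances D_ij are computed exactly and averaged
#' over ordered pairs, `L = sum_{i != j} D_ij / (N (N - 1))`. Pairs with no
#' connecting path contribute `N * max(finite D)` by default so L stays
#' finite on fragmented graphs; `unreachable = "strict"` returns `Inf`
#' instead.
#'
#' @param cm a [corr_matrix()].
#' @param unreachable `"surrogate"` (default) or `"strict"`.
#' @return The scalar L.
#' @export
path_length <- function(cm, unreachable = c("surrogate", "strict")) {
  unreachable <- match.arg(unreachable)
  w <- clipped_weights(cm)
  n <- nrow(w)
  if (n < 2) abort("need at least 2 nodes")
  len <- ifelse(w > 0, 1 / w, 0)
  g <- igraph::graph_from_adjacency_matrix(len, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  D <- igraph::distances(g, algorithm = "dijkstra")
  off <- D[upper.tri(D)]
  if (any(is.infinite(off))) {
    if (unreachable == "strict") return(Inf)
    finite <- off[is.finite(off)]
    sub <- if (length(finite) > 0) n * max(finite) else n
    off[is.infinite(off)] <- sub
  }
  mean(off)  # = sum over ordered pairs / (N (N - 1))
}

#' Weighted Newman modularity of a partition
#'
#' `Q = (1 / 2m) * sum_ij [w_ij - s_i s_j / 2m] delta(c_i, c_j)` with node
#' strengths `s_i = sum_{j != i} w_ij`, total weight `2m = sum_ij w_ij`
#' (both orders) and no self-edges (`w_ii = 0`; the null-model term
#' `s_i^2 / 2m` is kept for i = j, as in the standard weighted form). With
#' this convention a single-module partition has Q = 0 exactly. Negative
#' correlations are clipped to 0 first.
#'
#' @param cm a [corr_matrix()].
#' @param labels integer module label per node.
#' @return The scalar Q in `[-1, 1]`.
#' @export
modularity_q <- function(cm, labels) {
  w <- clipped_weights(cm)
  n <- nrow(w)
  if (length(labels) != n) abort("labels length must equal node count")
  s <- rowSums(w)
  m2 <- sum(s)
  if (m2 <= 0) abort("total positive weight is 0; Q undefined")
  same <- outer(labels, labels, "==")
  sum((w - outer(s, s) / m2)[same]) / m2
}

#' Detect modules by hierarchical clustering of the correlation structure
#'
#' Agglomerative clustering (average linkage by default) on the distance
#' `1 - w_ij`; the dendrogram is cut into k = 1..`max_modules` clusters and
#' the cut maximizing Newman Q is returned (ties go to fewer modules).
#'
#' @param cm a [corr_matrix()].
#' @param max_modules largest cut examined (default 10).
#' @param linkage `stats::hclust` method (default `"average"`).
#' @return A list of class `module_partition`: `labels`, `n_modules`,
#'   `modularity_q`, `intra_corrs`, `inter_corrs` (see
#'   [intra_inter_correlations()]).
#' @export
detect_modules <- function(cm, max_modules = 10, linkage = "average") {
  n <- nrow(cm$w)
  if (n < 2) abort("need at least 2 nodes")
  d <- 1 - cm$w
  diag(d) <- 0
  hc <- hclust(as.dist(d), method = linkage)
  kmax <- min(max_modules, n)
  qs <- numeric(kmax)
  cuts <- matrix(0L, n, kmax)
  for (k in seq_len(kmax)) {
    cuts[, k] <- cutree(hc, k = k)
    qs[k] <- modularity_q(cm, cuts[, k])
  }
  best <- which.max(qs)  # first max -> smaller k on ties
  labels <- cuts[, best]
  ii <- intra_inter_correlations(cm, labels)
  structure(list(labels = labels, n_modules = best,
                 modularity_q = qs[best], q_by_k = qs,
                 intra_corrs = ii$intra, inter_corrs = ii$inter),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("<module_partition: %d modules, Q = %.3f, sizes: %s>\n",
              x$n_modules, x$modularity_q,
              paste(table(x$labels), collapse = ", ")))
  invisible(x)
}

#' Intra- and inter-modular correlations
#'
#' One intra entry per module: the mean off-diagonal (signed) correlation
#' over node pairs within it, with singleton modules excluded. One inter
#' entry per unordered module pair: the mean correlation over cross pairs.
#'
#' @param cm a [corr_matrix()].
#' @param labels integer module label per node.
#' @return A list with `intra` (named by module) and `inter` (named by
#'   module pair) numeric vectors.
#' @export
intra_inter_correlations <- function(cm, labels) {
  w <- cm$w
  mods <- sort(unique(labels))
  intra <- numeric(0)
  for (m in mods) {
    idx <- which(labels == m)
    if (length(idx) < 2) next
    sub <- w[idx, idx]
    intra <- c(intra, stats::setNames(mean(sub[upper.tri(sub)]),
                                      as.character(m)))
  }
  inter <- numeric(0)
  if (length(mods) > 1) {
    for (a in seq_along(mods)[-length(mods)]) for (b in (a + 1):length(mods)) {
      ia <- which(labels == mods[a]); ib <- which(labels == mods[b])
      inter <- c(inter, stats::setNames(mean(w[ia, ib, drop = FALSE]),
                                        paste0(mods[a], "-", mods[b])))
    }
  }
  list(intra = intra, inter = inter)
}

#' Connectome edge list above a correlation threshold
#'
#' All unordered node pairs with `w_ij > threshold`, sorted by descending
#' weight. 0.5 is the conventional display threshold for correlational
#' connectomes.
#'
#' @param cm a [corr_matrix()].
#' @param threshold correlation cutoff (default 0.5).
#' @return data.frame `i`, `j` (node indices, i < j), `weight`.
#' @export
connectome_edges <- function(cm, threshold = 0.5) {
  w <- cm$w
  n <- nrow(w)
  ut <- which(upper.tri(w) & w > threshold, arr.ind = TRUE)
  out <- data.frame(i = ut[, 1], j = ut[, 2], weight = w[ut])
  out <- out[order(-out$weight), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Graph-level summary metrics
#'
#' @param cm a [corr_matrix()].
#' @return A list of class `graph_metrics`: `avg_correlation`,
#'   `avg_clustering`, `avg_path_length`, `n_nodes`.
#' @export
graph_metrics <- function(cm) {
  structure(list(avg_correlation = average_correlation(cm),
                 avg_clustering = clustering_coefficients(cm)$mean,
                 avg_path_length = path_length(cm),
                 n_nodes = nrow(cm$w)),
            class = "graph_metrics")
}

ols_summary <- function(x, y) {
  if (sd(y) == 0)  # flat response: no fit to speak of
    return(list(slope = 0, intercept = y[1], r_squared = 0, p_slope = 1))
  fit <- lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = sm$r.squared,
       p_slope = unname(sm$coefficients[2, 4]))
}

#' Correlation-versus-distance and module-size regressions
#'
#' `distance_correlation_regression()` regresses the pairwise correlation
#' `w_ij` on the Euclidean distance between ROI centroids (all unordered
#' pairs). `module_size_regression()` regresses each module's intra-modular
#' mean correlation on its node count. Both return ordinary least-squares
#' slope, intercept, R-squared, and the slope p-value.
#'
#' @param cm a [corr_matrix()] with `positions` (first form).
#' @return A list: `slope`, `intercept`, `r_squared`, `p_slope`.
#' @export
distance_correlation_regression <- function(cm) {
  if (is.null(cm$positions)) abort("cm has no node positions")
  n <- nrow(cm$w)
  ut <- which(upper.tri(cm$w), arr.ind = TRUE)
  if (nrow(ut) < 3) abort("need at least 3 node pairs")
  dd <- sqrt((cm$positions[ut[, 1], "x"] - cm$positions[ut[, 2], "x"])^2 +
             (cm$positions[ut[, 1], "y"] - cm$positions[ut[, 2], "y"])^2)
  ols_summary(dd, cm$w[ut])
}

#' @rdname distance_correlation_regression
#' @param partition a `module_partition` from [detect_modules()].
#' @export
module_size_regression <- function(partition, cm) {
  labels <- partition$labels
  intra <- intra_inter_correlations(cm, labels)$intra
  sizes <- as.numeric(table(labels)[names(intra)])
  if (length(intra) < 3)
    abort("need at least 3 modules of size >= 2 for the regression")
  ols_summary(sizes, as.numeric(intra))
}

#' Write a correlation matrix / edge list / partition to CSV
#' @param cm a [corr_matrix()].
#' @param path CSV file path.
#' @export
write_correlation_csv <- function(cm, path) {
  df <- as.data.frame(cm$w)
  names(df) <- cm$roi_ids
  write.csv(cbind(roi = cm$roi_ids, df), path, row.names = FALSE)
  invisible(path)
}
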