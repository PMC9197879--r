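#' k-nearest-neighbour affinity graph
#'
#' Builds the symmetric affinity graph underlying the diffusion-map
#' pseudotime: Euclidean k-nearest neighbours with an adaptive Gaussian
#' kernel whose per-cell bandwidth is the distance to the k-th neighbour,
#' symmetrized by taking the maximum of the two directed affinities (union
#' of neighbourhoods). Self-loops are excluded; exact duplicate rows get
#' capped affinity 1 on their zero-distance edge.
#'
#' @param table a standardized [feature_table()], or a numeric matrix of
#'   per-cell coordinates.
#' @param k number of neighbours, `1 <= k < n`.
#' @return An object of class `knn_graph`: list with `affinity` (dense
#'   symmetric matrix, zero diagonal), `neighbors` (n x k index matrix),
#'   `bandwidth`, `k` and `cells`.
#' @export
knn_graph <- function(table, k) {
  m <- if (inherits(table, "feature_table")) table$features else as.matrix(table)
  n <- nrow(m)
  if (k < 1L || k >= n) stop("k must satisfy 1 <= k < n")
  d <- as.matrix(stats::dist(m))
  diag(d) <- Inf
  nb <- matrix(apply(d, 1L, function(row) order(row)[seq_len(k)]),
               nrow = n, ncol = k, byrow = TRUE)
  bw <- d[cbind(seq_len(n), nb[, k])]
  bw[bw <= 0] <- min(d[d > 0 & is.finite(d)], na.rm = TRUE) * 1e-3
  aff <- matrix(0, n, n)
  for (i in seq_len(n)) {
    js <- nb[i, ]
    aff[i, js] <- exp(-d[i, js]^2 / (bw[i] * bw[js]))
  }
  aff[!is.finite(aff)] <- 1
  aff <- pmax(aff, t(aff))
  aff <- pmin(aff, 1)
  diag(aff) <- 0
  cells <- rownames(m)
  if (is.null(cells)) cells <- as.character(seq_len(n))
  dimnames(aff) <- list(cells, cells)
  structure(list(affinity = aff, neighbors = nb, bandwidth = bw, k = k,
                 cells = cells),
            class = "knn_graph")
}

#' Diffusion-map components
#'
#' Spectral coordinates of the row-normalized transition operator of an
#' affinity graph: the top non-trivial right eigenvectors, scaled by their
#' eigenvalues. Computed through the symmetric conjugate
#' D^-1/2 W D^-1/2 so the eigenproblem is symmetric and stable. If the
#' graph is disconnected, the decomposition is restricted to the largest
#' connected component with a warning.
#'
#' @param graph a [knn_graph()].
#' @param n_components number of non-trivial components to keep (default 5).
#' @return List with `components` (cells x n_components matrix),
#'   `eigenvalues` (descending, all at most 1), and `cells` (ids retained).
#' @export
diffusion_components <- function(graph, n_components = 5L) {
  stopifnot(inherits(graph, "knn_graph"))
  W <- graph$affinity
  g <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected")
  comp <- igraph::components(g)
  keep <- seq_len(nrow(W))
  if (comp$no > 1L) {
    warning("affinity graph has ", comp$no,
            " components; using the largest (",
            max(comp$csize), " of ", nrow(W), " cells)")
    keep <- which(comp$membership == which.max(comp$csize))
    W <- W[keep, keep, drop = FALSE]
  }
  n <- nrow(W)
  if (n_components >= n)
    stop("n_components must be smaller than the component size")
  deg <- rowSums(W)
  if (any(deg <= 0)) stop("graph has an isolated vertex after restriction")
  inv_sqrt <- 1 / sqrt(deg)
  S <- W * tcrossprod(inv_sqrt)
  es <- eigen(S, symmetric = TRUE)
  if (any(!is.finite(es$values)))
    stop("eigendecomposition failed: non-finite eigenvalues")
  # right eigenvectors of D^-1 W: psi = D^-1/2 u; first (lambda ~ 1) is
  # constant and dropped
  sel <- seq(2L, n_components + 1L)
  lambda <- es$values[sel]
  psi <- es$vectors[, sel, drop = FALSE] * inv_sqrt
  comps <- sweep(psi, 2L, lambda, "*")
  rownames(comps) <- graph$cells[keep]
  colnames(comps) <- paste0("DC", seq_len(n_components))
  attr(comps, "eigenvalues") <- lambda
  list(components = comps, eigenvalues = lambda, cells = graph$cells[keep])
}

#' Diffusion pseudotime from a start cell
#'
#' Per-cell diffusion distance from the designated start cell in component
#' space, min-max normalized to [0, 1]: the start cell is 0 and the
#' diffusion-farthest cell is 1. When the component matrix carries its
#' eigenvalues (as produced by [diffusion_components()]), the distance uses
#' the accumulated multi-scale weighting lambda/(1 - lambda) per component
#' - the standard diffusion-pseudotime metric, which sums the diffusion
#' distances over all diffusion times and so emphasizes the slow, global
#' trajectory axes over fast noise modes. Without eigenvalues the plain
#' Euclidean distance in the supplied space is used.
#'
#' @param components cells x components matrix from
#'   [diffusion_components()] (or any per-cell coordinate matrix).
#' @param start_cell cell id (row name) of the root of the trajectory.
#' @return Named numeric vector of pseudotime values in [0, 1].
#' @export
diffusion_pseudotime <- function(components, start_cell) {
  lambda <- attr(components, "eigenvalues")
  components <- as.matrix(components)
  if (!start_cell %in% rownames(components))
    stop("start cell '", start_cell, "' not found")
  if (!is.null(lambda)) {
    # components come eigenvalue-scaled (lambda * psi); reweight to the
    # accumulated-diffusion scale (lambda / (1 - lambda)) * psi
    w <- 1 / pmax(1 - lambda, 1e-12)
    components <- sweep(components, 2L, w, "*")
  }
  delta <- sweep(components, 2L, components[start_cell, ])
  d <- sqrt(rowSums(delta^2))
  rng <- range(d)
  if (rng[2] <= rng[1]) stop("degenerate component space: all cells coincide")
  stats::setNames((d - rng[1]) / (rng[2] - rng[1]), rownames(components))
}

#' Community states on a neighbourhood graph
#'
#' Louvain modularity communities on the kNN affinity graph, the
#' morphological analogue of Phenograph clustering of a developmental
#' trajectory (neighbourhood parameter k = 20 by convention).
#'
#' @param graph a [knn_graph()] (build it with `k = 20` for the standard
#'   configuration).
#' @param seed integer seed (Louvain is seed-deterministic).
#' @return Named integer vector of community labels (1-based).
#' @export
community_states <- function(graph, seed = 1L) {
  stopifnot(inherits(graph, "knn_graph"))
  g <- igraph::graph_from_adjacency_matrix(graph$affinity, mode = "undirected",
                                           weighted = TRUE)
  if (igraph::vcount(g) == 1L)
    return(stats::setNames(1L, graph$cells))
  set.seed(seed)
  cl <- igraph::cluster_louvain(g)
  stats::setNames(as.integer(igraph::membership(cl)), graph$cells)
}

#' Morphological pseudotime of developmental snapshots
#'
#' The pipeline entry point for ordering developmental morphometric
#' snapshots along a maturation trajectory: standardize, build the adaptive
#' kNN affinity graph, extract diffusion components, anchor the trajectory
#' at a start cell, normalize the accumulated diffusion distances to a
#' [0,1] pseudo-timeline, and partition the cells into morphological
#' communities on a k = 20 neighbourhood graph.
#'
#' The default start cell is chosen robustly among the expert-stage-1 cells
#' (all cells when no staging is available): the candidates with the
#' smallest composite axonal-size score (mean standardized value over the
#' `start_features` present in the table) are collected, and the start is
#' the candidate closest to the others in diffusion-component space (their
#' medoid). Anchoring at a medoid of several highly immature cells avoids
#' handing the trajectory root to a single noisy measurement. Pass
#' `start_cell` to override.
#'
#' @param table a [feature_table()] of developmental features; standardized
#'   internally unless `already_standardized = TRUE`.
#' @param k neighbour count for the trajectory graph (default 10, the
#'   conventional neighbourhood scale for diffusion-map pseudotime at a few
#'   hundred cells; smaller values such as 3 reproduce sparser-kernel
#'   configurations but fragment more easily).
#' @param n_components number of diffusion components (default 5).
#' @param community_k neighbour count for the community graph (default 20).
#' @param start_cell optional cell id anchoring pseudotime 0.
#' @param start_features features averaged into the immaturity score used
#'   for default start-cell selection (missing ones are ignored).
#' @param n_start_candidates size of the candidate root set (default 8).
#' @param seed integer seed (community detection).
#' @param already_standardized skip internal standardization.
#' @return An object of class `morpho_pseudotime`: list with `pseudotime`
#'   (named, in [0,1]), `components`, `eigenvalues`, `embedding` (first two
#'   components), `start_cell`, `communities`, `cells` and `params`. Cells
#'   outside the largest graph component (if any) are dropped with a
#'   warning.
#' @examples
#' sim <- simulate_development(n_bc = 60, n_sc = 40, seed = 1)
#' pt <- morpho_pseudotime(sim$table, seed = 1)
#' pt
#' cor(pt$pseudotime, sim$truth$s[names(pt$pseudotime)], method = "spearman")
#' @export
morpho_pseudotime <- function(table, k = 10L, n_components = 5L,
                              community_k = 20L, start_cell = NULL,
                              start_features = c("axon_length",
                                                 "axon_tangential_span",
                                                 "axon_ml_height",
                                                 "soma_volume_ellipsoid"),
                              n_start_candidates = 8L,
                              seed = 1L, already_standardized = FALSE) {
  stopifnot(inherits(table, "feature_table"))
  std <- if (already_standardized) table else standardize(table)
  g <- knn_graph(std, k = k)
  dc <- diffusion_components(g, n_components = n_components)
  cells <- dc$cells
  if (is.null(start_cell))
    start_cell <- default_start_cell(table, std, dc, start_features,
                                     n_start_candidates)
  if (!start_cell %in% cells)
    stop("start cell '", start_cell, "' is not in the trajectory component")
  pt <- diffusion_pseudotime(dc$components, start_cell)
  ck <- min(community_k, length(cells) - 1L)
  cg <- knn_graph(ft_subset(std, cells = cells), k = ck)
  communities <- community_states(cg, seed = seed)
  structure(
    list(pseudotime = pt, components = dc$components,
         eigenvalues = dc$eigenvalues,
         embedding = dc$components[, 1:2, drop = FALSE],
         start_cell = start_cell, communities = communities, cells = cells,
         params = list(k = k, n_components = n_components,
                       community_k = ck, seed = seed)),
    class = "morpho_pseudotime")
}

default_start_cell <- function(table, std, dc, start_features,
                               n_start_candidates) {
  md <- table$metadata
  cells <- dc$cells
  pool <- cells
  if (!is.null(md$expert_stage) && any(!is.na(md$expert_stage))) {
    stage1 <- md$cell_id[!is.na(md$expert_stage) & md$expert_stage == 1L]
    if (length(intersect(stage1, cells))) pool <- intersect(stage1, cells)
  }
  sf <- intersect(start_features, colnames(std$features))
  if (!length(sf)) return(pool[1L])
  score <- rowMeans(std$features[pool, sf, drop = FALSE])
  cand <- pool[order(score)][seq_len(min(n_start_candidates, length(pool)))]
  if (length(cand) == 1L) return(cand)
  D <- as.matrix(stats::dist(dc$components[cand, , drop = FALSE]))
  cand[which.min(rowSums(D))]
}

#' @export
print.morpho_pseudotime <- function(x, ...) {
  cat("Morphological pseudotime: ", length(x$pseudotime), " cells, ",
      length(unique(x$communities)), " communities\n", sep = "")
  cat("  start cell: ", x$start_cell, " (k = ", x$params$k,
      ", components = ", x$params$n_components, ")\n", sep = "")
  invisible(x)
}

#' @export
summary.morpho_pseudotime <- function(object, ...) {
  cat("Morphological pseudotime over", length(object$pseudotime), "cells\n")
  print(summary(object$pseudotime))
  cat("Eigenvalues:", paste(round(object$eigenvalues, 4), collapse = ", "),
      "\n")
  cat("Community sizes:\n")
  print(table(object$communities))
  invisible(object)
}

#' @export
plot.morpho_pseudotime <- function(x, color = c("pseudotime", "community"),
                                   ...) {
  color <- match.arg(color)
  val <- if (color == "pseudotime") {
    grDevices::hcl.colors(100, "viridis")[
      pmax(1L, ceiling(x$pseudotime * 100))]
  } else {
    grDevices::hcl.colors(max(x$communities), "Dark 3")[x$communities]
  }
  graphics::plot(x$embedding, col = val, pch = 16,
                 xlab = "DC1", ylab = "DC2",
                 main = paste("Trajectory colored by", color), ...)
  invisible(x)
}

#' Principal-component scores of a feature table
#'
#' Top principal-component coordinates of a standardized feature table, the
#' denoising step the reference single-cell protocols run before manifold
#' learning and the recommended coordinate space for nearest-neighbour
#' statistics: with tens of partially redundant morphometric features, the
#' leading components retain the maturation and fate-divergence axes while
#' shedding per-feature measurement noise.
#'
#' @param table a standardized [feature_table()] (or numeric matrix).
#' @param n_pcs number of components to keep (default 5).
#' @return Numeric matrix (cells x `n_pcs`) with cell-id row names.
#' @seealso [cosort()], [knn_same_fate_fraction()]
#' @export
pc_embedding <- function(table, n_pcs = 5L) {
  m <- if (inherits(table, "feature_table")) table$features else as.matrix(table)
  if (n_pcs > min(dim(m)))
    stop("n_pcs exceeds the feature-table rank")
  # columns are already centred/scaled by standardize(); no re-centering so
  # the scores are an orthogonal rotation of the standardized data
  pr <- stats::prcomp(m, center = FALSE, scale. = FALSE)
  scores <- pr$x[, seq_len(n_pcs), drop = FALSE]
  rownames(scores) <- rownames(m)
  scores
}

#' Concordance of pseudotime with expert maturation staging
#'
#' Spearman rank correlation between pseudotime and the 4-level expert
#' maturation stage, plus per-stage pseudotime summaries; the standard
#' validation that the inferred ordering reproduces expert-directed
#' maturity.
#'
#' @param pseudotime named per-cell pseudotime values.
#' @param expert_stage named (or parallel) integer stages 1..4; `NA`s are
#'   dropped.
#' @return List with `spearman_rho` and `per_stage` (data frame of n,
#'   median, IQR per stage).
#' @export
stage_concordance <- function(pseudotime, expert_stage) {
  if (!is.null(names(expert_stage)) && !is.null(names(pseudotime)))
    expert_stage <- expert_stage[names(pseudotime)]
  keep <- !is.na(expert_stage) & !is.na(pseudotime)
  pt <- pseudotime[keep]
  st <- as.integer(expert_stage[keep])
  if (length(unique(st)) < 2L)
    stop("stage concordance needs at least 2 distinct stages")
  rho <- stats::cor(pt, st, method = "spearman")
  per_stage <- do.call(rbind, lapply(sort(unique(st)), function(s) {
    v <- pt[st == s]
    data.frame(stage = s, n = length(v), median = stats::median(v),
               q25 = stats::quantile(v, 0.25)[[1L]],
               q75 = stats::quantile(v, 0.75)[[1L]])
  }))
  list(spearman_rho = rho, per_stage = per_stage)
}

#' Feature trends along pseudotime
#'
#' Binned mean trends of selected features along the pseudo-timeline, per
#' fate group when fate labels are given, with percentile bootstrap
#' confidence intervals. Non-monotone trends (such as the
#' expansion-then-retraction of stellate axonal span) appear as interior
#' maxima of the binned means.
#'
#' @param table a [feature_table()] (raw feature units are reported).
#' @param pseudotime named per-cell values in [0, 1].
#' @param features feature names to summarize.
#' @param n_bins number of equal-width pseudotime bins (default 5).
#' @param ci confidence level (default 0.95).
#' @param fate optional named per-cell group labels.
#' @param reps bootstrap replicates (default 500; 0 suppresses CIs).
#' @param seed integer seed for the bootstrap.
#' @return Data frame of class `feature_trends` with columns `feature`,
#'   `group`, `bin`, `bin_mid`, `n`, `mean`, `ci_lo`, `ci_hi`. Empty bins
#'   are omitted (gaps in the curve).
#' @export
feature_trends <- function(table, pseudotime, features, n_bins = 5L,
                           ci = 0.95, fate = NULL, reps = 500L, seed = 1L) {
  stopifnot(inherits(table, "feature_table"))
  cells <- intersect(names(pseudotime), rownames(table$features))
  pt <- pseudotime[cells]
  if (any(pt < 0 | pt > 1)) stop("pseudotime must lie in [0, 1]")
  if (!all(features %in% colnames(table$features)))
    stop("unknown feature(s): ",
         paste(setdiff(features, colnames(table$features)), collapse = ", "))
  groups <- if (is.null(fate)) rep("all", length(cells)) else
    as.character(fate[cells])
  bins <- bin_pseudotime(pt, width = 1 / n_bins)
  mids <- (seq_len(n_bins) - 0.5) / n_bins
  set.seed(seed)
  alpha <- (1 - ci) / 2
  rows <- list()
  for (f in features) {
    vals <- table$features[cells, f]
    for (g in unique(groups)) {
      for (b in 0:(n_bins - 1L)) {
        sel <- which(groups == g & bins == b)
        if (!length(sel)) next
        v <- vals[sel]
        if (reps > 0L && length(v) >= 2L) {
          boots <- replicate(reps, mean(sample(v, replace = TRUE)))
          qs <- stats::quantile(boots, c(alpha, 1 - alpha), names = FALSE)
        } else qs <- c(NA_real_, NA_real_)
        rows[[length(rows) + 1L]] <- data.frame(
          feature = f, group = g, bin = b, bin_mid = mids[b + 1L],
          n = length(v), mean = mean(v), ci_lo = qs[1L], ci_hi = qs[2L],
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("feature_trends", "data.frame")
  out
}

#' @export
plot.feature_trends <- function(x, feature = NULL, ...) {
  if (is.null(feature)) feature <- x$feature[1L]
  d <- x[x$feature == feature, ]
  graphics::plot(NULL, xlim = c(0, 1), ylim = range(c(d$ci_lo, d$ci_hi, d$mean),
                                                    na.rm = TRUE),
                 xlab = "pseudotime", ylab = feature, main = feature, ...)
  for (gi in seq_along(unique(d$group))) {
    g <- unique(d$group)[gi]
    dg <- d[d$group == g, ]
    graphics::lines(dg$bin_mid, dg$mean, col = gi, type = "b", pch = 16)
    if (!all(is.na(dg$ci_lo)))
      graphics::arrows(dg$bin_mid, dg$ci_lo, dg$bin_mid, dg$ci_hi,
                       angle = 90, code = 3, length = 0.03, col = gi)
  }
  graphics::legend("topleft", legend = unique(d$group),
                   col = seq_along(unique(d$group)), lty = 1, bty = "n")
  invisible(x)
}
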