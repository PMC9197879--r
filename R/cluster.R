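#' Hierarchical clustering into morphological clades
#'
#' Agglomerative clustering of a standardized feature table with Ward
#' linkage on Euclidean distances (the canonical pairing), cut into
#' `n_clades` clades. Clades are labelled `"A"`, `"B"`, ... in order of
#' first appearance in the cell ordering, so the result is deterministic
#' given the input order; distance ties are resolved by `stats::hclust`'s
#' deterministic merge rule (lowest index first).
#'
#' @param table a [feature_table()], normally standardized with
#'   [standardize()].
#' @param linkage linkage criterion; `"ward"` (Ward on Euclidean distances,
#'   `hclust` method `ward.D2`), `"complete"`, `"average"` or `"single"`.
#' @param metric distance metric passed to [stats::dist()].
#' @param n_clades number of clades to cut (default 2: the basket/stellate
#'   division).
#' @return An object of class `mli_hclust`: list with `labels` (named factor
#'   of clade assignments), `dendrogram` (the `hclust` object), `leaf_order`
#'   (cell ids left to right) and `params`.
#' @examples
#' sim <- simulate_mature(n_bc = 10, n_sc = 15, seed = 1)
#' cl <- hcluster(standardize(sim$table))
#' table(cl$labels, sim$truth$class)
#' @export
hcluster <- function(table, linkage = c("ward", "complete", "average", "single"),
                     metric = "euclidean", n_clades = 2L) {
  stopifnot(inherits(table, "feature_table"))
  linkage <- match.arg(linkage)
  n <- nrow(table$features)
  if (n_clades > n) stop("n_clades exceeds the number of cells")
  method <- c(ward = "ward.D2", complete = "complete",
              average = "average", single = "single")[[linkage]]
  hc <- stats::hclust(stats::dist(table$features, method = metric),
                      method = method)
  cut <- stats::cutree(hc, k = n_clades)
  # relabel in order of first appearance for determinism across cuts
  lab_map <- stats::setNames(LETTERS[seq_len(n_clades)], unique(cut))
  labels <- factor(lab_map[as.character(cut)], levels = LETTERS[seq_len(n_clades)])
  names(labels) <- rownames(table$features)
  structure(
    list(labels = labels, dendrogram = hc,
         leaf_order = rownames(table$features)[hc$order],
         params = list(linkage = linkage, metric = metric,
                       n_clades = n_clades)),
    class = "mli_hclust")
}

#' @export
print.mli_hclust <- function(x, ...) {
  cat("Hierarchical clustering (", x$params$linkage, "/", x$params$metric,
      "): ", length(x$labels), " cells in ", x$params$n_clades,
      " clades\n", sep = "")
  print(table(clade = x$labels))
  invisible(x)
}

#' @export
plot.mli_hclust <- function(x, ...) {
  graphics::plot(x$dendrogram, labels = FALSE, main = "Morphometric clades",
                 xlab = "", sub = "", ...)
  invisible(x)
}

#' Export a dendrogram as Newick
#'
#' Branch lengths are derived from the merge heights, so ultrametric
#' distances in the tree reproduce the clustering heights.
#'
#' @param result an [hcluster()] result.
#' @param path optional file path; when `NULL` the Newick string is
#'   returned.
#' @return The Newick string, invisibly when written to file.
#' @export
dendrogram_newick <- function(result, path = NULL) {
  stopifnot(inherits(result, "mli_hclust"))
  hc <- result$dendrogram
  build <- function(i, parent_height) {
    if (i < 0) {
      sprintf("%s:%.12g", hc$labels[-i], parent_height)
    } else {
      h <- hc$height[i]
      sprintf("(%s,%s):%.12g", build(hc$merge[i, 1L], h),
              build(hc$merge[i, 2L], h), parent_height - h)
    }
  }
  top <- nrow(hc$merge)
  nwk <- sprintf("(%s,%s);", build(hc$merge[top, 1L], hc$height[top]),
                 build(hc$merge[top, 2L], hc$height[top]))
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(nwk)
}

#' Leaf-order ranks anchored to a reference clade
#'
#' Ranks cells 1..n along the dendrogram leaf order, with the clade
#' containing the majority of the reference cells placed first (the
#' reference cell at the leftmost side of its clade gets rank 1).
#'
#' @param result an [hcluster()] result.
#' @param reference_clade_members character vector of cell ids defining the
#'   reference clade (e.g. curated basket cells).
#' @return Named integer vector of ranks; a permutation of 1..n.
#' @export
leaf_rank <- function(result, reference_clade_members) {
  stopifnot(inherits(result, "mli_hclust"))
  if (!length(reference_clade_members)) stop("empty reference set")
  labels <- result$labels
  ref <- intersect(reference_clade_members, names(labels))
  if (!length(ref)) stop("no reference member found among clustered cells")
  maj <- names(which.max(table(labels[ref])))
  leaves <- result$leaf_order
  first <- leaves[labels[leaves] == maj]
  rest <- leaves[labels[leaves] != maj]
  ranks <- stats::setNames(seq_along(leaves), c(first, rest))
  ranks[names(labels)]
}

#' Ranks along diffusion pseudotime
#'
#' Dense ascending ranks of pseudotime values; ties are broken by cell id so
#' the result is a deterministic permutation.
#'
#' @param pseudotime named numeric vector of finite per-cell values.
#' @return Named integer vector of ranks.
#' @export
dpt_rank <- function(pseudotime) {
  if (any(!is.finite(pseudotime))) stop("pseudotime must be finite")
  ids <- names(pseudotime)
  if (is.null(ids)) ids <- as.character(seq_along(pseudotime))
  ord <- order(pseudotime, ids)
  ranks <- integer(length(pseudotime))
  ranks[ord] <- seq_along(pseudotime)
  stats::setNames(ranks, ids)
}

#' Subsample cross-validation of the clade division
#'
#' Measures how robustly the clade division is recovered from subsamples:
#' for each sample size, cells are repeatedly drawn without replacement
#' from the standardized table, reclustered (Ward linkage, cut into two
#' clades), each resulting clade is identified with the reference label held
#' by the majority of its members, and the classification accuracy is the
#' fraction of subsampled cells whose clade identity matches their reference
#' label. Ambiguous clades (tied majorities) are resolved to the label
#' minimizing misclassification, then to the alphabetically smaller label.
#'
#' Standardization happens once on the full table (matching the protocol of
#' standardizing the dataset before any clustering); subsamples are drawn
#' as rows of that standardized matrix.
#'
#' @param table a [feature_table()] (raw or standardized; standardized once
#'   internally, which is idempotent).
#' @param ref_labels named per-cell reference labels (e.g. from the
#'   full-data clustering or curation).
#' @param sizes subsample sizes (each at most the number of cells).
#' @param trials resamples per size (default 20).
#' @param seed integer seed for the resampling.
#' @param restrict_to optional cell ids to resample from (e.g. only
#'   stellate cells for the subclade analysis); defaults to all cells.
#' @return An object of class `subsample_cv`: list with `sizes`,
#'   `accuracy` (trials x sizes matrix), `mean`, `sem` (standard error over
#'   trials) and `seed`.
#' @examples
#' sim <- simulate_mature(n_bc = 12, n_sc = 18, seed = 2)
#' cl <- hcluster(standardize(sim$table))
#' cv <- subsample_cv(sim$table, cl$labels, sizes = c(8, 16), trials = 5,
#'                    seed = 7)
#' cv
#' @export
subsample_cv <- function(table, ref_labels, sizes, trials = 20L, seed = 1L,
                         restrict_to = NULL) {
  stopifnot(inherits(table, "feature_table"))
  cells <- rownames(table$features)
  if (!is.null(restrict_to)) cells <- intersect(cells, restrict_to)
  if (is.null(names(ref_labels)))
    stop("ref_labels must be named by cell id")
  ref_labels <- as.character(ref_labels[cells])
  names(ref_labels) <- cells
  if (any(sizes > length(cells)))
    stop("sizes must not exceed the number of cells (", length(cells), ")")
  if (any(sizes < 4L)) stop("sizes below 4 cannot support a 2-clade cut")
  std <- suppressWarnings(standardize(table))
  set.seed(seed)
  acc <- matrix(NA_real_, nrow = trials, ncol = length(sizes),
                dimnames = list(NULL, sizes))
  for (j in seq_along(sizes)) {
    for (t in seq_len(trials)) {
      sub <- sample(cells, sizes[j])
      cl <- hcluster(ft_subset(std, cells = sub), n_clades = 2L)
      acc[t, j] <- clade_label_accuracy(cl$labels, ref_labels[sub])
    }
  }
  structure(
    list(sizes = sizes, accuracy = acc,
         mean = colMeans(acc),
         sem = apply(acc, 2L, stats::sd) / sqrt(trials),
         trials = trials, seed = seed),
    class = "subsample_cv")
}

# Identify each clade with the majority reference label of its members and
# score the fraction of cells whose clade identity matches their own label.
# Ties: assign labels to clades so total misclassification is minimal;
# remaining ties go to the alphabetically smaller label.
clade_label_accuracy <- function(clades, ref) {
  clades <- as.character(clades)
  ref <- as.character(ref)
  correct <- 0L
  for (cl in unique(clades)) {
    members <- ref[clades == cl]
    tab <- table(members)
    top <- sort(names(tab)[tab == max(tab)])[1L]
    correct <- correct + sum(members == top)
  }
  correct / length(ref)
}

#' @export
print.subsample_cv <- function(x, ...) {
  cat("Subsample cross-validation (", x$trials, " trials per size, seed ",
      x$seed, ")\n", sep = "")
  print(data.frame(size = x$sizes,
                   mean_accuracy = round(x$mean, 4),
                   sem = round(x$sem, 4)))
  invisible(x)
}

#' @export
plot.subsample_cv <- function(x, ...) {
  graphics::plot(x$sizes, x$mean, type = "b", ylim = c(0, 1),
                 xlab = "subsample size", ylab = "classification accuracy",
                 main = "Clade recovery from subsamples", ...)
  graphics::arrows(x$sizes, x$mean - x$sem, x$sizes, x$mean + x$sem,
                   angle = 90, code = 3, length = 0.03)
  invisible(x)
}

#' Recursive feature elimination for clade robustness
#'
#' For each named feature group, reclusters the table with the group
#' dropped and with only the group kept, and reports the adjusted Rand
#' agreement of the resulting 2-clade labels with the baseline labels. A
#' division is conventionally called preserved when agreement exceeds 0.9.
#'
#' @param table a [feature_table()] (raw; each ablation is re-standardized).
#' @param groups named list of character vectors of feature names.
#' @param baseline_labels named per-cell labels from the full clustering.
#' @return Data frame with columns `group`, `mode` (`drop` / `keep_only`),
#'   `n_features`, `agreement`, plus the per-ablation labels in attribute
#'   `"labels"`.
#' @export
feature_elimination <- function(table, groups, baseline_labels) {
  stopifnot(inherits(table, "feature_table"), is.list(groups))
  all_feats <- colnames(table$features)
  for (g in groups)
    if (!all(g %in% all_feats))
      stop("group contains unknown feature(s): ",
           paste(setdiff(g, all_feats), collapse = ", "))
  baseline <- as.character(baseline_labels[rownames(table$features)])
  rows <- list()
  labels_out <- list()
  for (gname in names(groups)) {
    for (mode in c("drop", "keep_only")) {
      keep <- if (mode == "drop") setdiff(all_feats, groups[[gname]])
              else groups[[gname]]
      if (length(keep) < 2L)
        stop("ablation '", gname, "' (", mode, ") leaves fewer than 2 features")
      cl <- hcluster(suppressWarnings(
        standardize(ft_subset(table, features = keep))), n_clades = 2L)
      agreement <- mclust::adjustedRandIndex(as.character(cl$labels), baseline)
      rows[[length(rows) + 1L]] <- data.frame(
        group = gname, mode = mode, n_features = length(keep),
        agreement = agreement, stringsAsFactors = FALSE)
      labels_out[[paste(gname, mode, sep = ".")]] <- cl$labels
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "labels") <- labels_out
  out
}

#' Two-dimensional embeddings of a feature table
#'
#' Produces per-cell 2-D coordinates for visualization and neighbour
#' statistics. The default `"diffusion"` method uses the first two
#' diffusion-map components (see [diffusion_components()]) and has no
#' dependencies beyond this package; `"umap"` and `"tsne"` delegate to the
#' uwot and Rtsne packages when installed. All methods are deterministic
#' under a fixed seed.
#'
#' @param table a standardized [feature_table()].
#' @param method `"diffusion"`, `"umap"` or `"tsne"`.
#' @param n_neighbors neighbourhood size (UMAP neighbours / diffusion kNN).
#' @param min_dist UMAP minimum distance (default 0.1).
#' @param perplexity t-SNE perplexity (default 7).
#' @param seed integer seed.
#' @return Numeric matrix (cells x 2) with cell-id row names.
#' @export
embed_cells <- function(table, method = c("diffusion", "umap", "tsne"),
                        n_neighbors = 7L, min_dist = 0.1, perplexity = 7,
                        seed = 510L) {
  stopifnot(inherits(table, "feature_table"))
  method <- match.arg(method)
  n <- nrow(table$features)
  if (n_neighbors >= n)
    stop("n_neighbors must be smaller than the number of cells (", n, ")")
  set.seed(seed)
  coords <- switch(
    method,
    diffusion = {
      g <- knn_graph(table, k = n_neighbors)
      dc <- diffusion_components(g, n_components = 2L)
      dc$components
    },
    umap = {
      if (!requireNamespace("uwot", quietly = TRUE))
        stop("embedding method 'umap' needs the uwot package")
      uwot::umap(table$features, n_neighbors = n_neighbors,
                 min_dist = min_dist, metric = "euclidean")
    },
    tsne = {
      if (!requireNamespace("Rtsne", quietly = TRUE))
        stop("embedding method 'tsne' needs the Rtsne package")
      if (n - 1 < 3 * perplexity)
        stop("perplexity too large for ", n, " cells")
      Rtsne::Rtsne(table$features, perplexity = perplexity, theta = 0,
                   max_iter = 10000, check_duplicates = FALSE)$Y
    })
  coords <- as.matrix(coords)[, 1:2, drop = FALSE]
  rownames(coords) <- rownames(table$features)
  colnames(coords) <- c("dim1", "dim2")
  coords
}

#' Single-feature bimodality screen
#'
#' Hartigan's dip statistic with a permutation/uniform-resampling p-value
#' for each feature, used to check that no single feature is bimodal on its
#' own (the clade division is a joint property of the panel).
#'
#' @param table a [feature_table()].
#' @param n_boot bootstrap replicates from the uniform null (default 200).
#' @param seed integer seed.
#' @return Data frame with `feature`, `dip` and `p_value`.
#' @details Implemented from the dip definition: the maximal distance
#'   between the empirical CDF and the closest unimodal CDF is bounded here
#'   with the standard greatest-convex-minorant / least-concave-majorant
#'   sweep; the null distribution is simulated from the uniform.
#' @export
dip_screen <- function(table, n_boot = 200L, seed = 1L) {
  stopifnot(inherits(table, "feature_table"))
  set.seed(seed)
  n <- nrow(table$features)
  null_dips <- replicate(n_boot, dip_statistic(stats::runif(n)))
  out <- data.frame(feature = colnames(table$features),
                    dip = NA_real_, p_value = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(table$features))) {
    d <- dip_statistic(table$features[, j])
    out$dip[j] <- d
    out$p_value[j] <- (1 + sum(null_dips >= d)) / (1 + n_boot)
  }
  out
}

# Dip-style unimodality statistic: the smallest (over candidate mode
# positions) worst-case gap between the empirical CDF and a
# convex-then-concave (unimodal) CDF envelope. Larger values indicate
# bimodality. This is the classical dip construction restricted to a grid
# of candidate modes, which upper-bounds the exact dip and preserves its
# ordering on clearly uni- vs bimodal samples.
dip_statistic <- function(x) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n < 4L || length(unique(x)) < 3L) return(0)
  y <- seq_len(n) / n
  probe_idx <- unique(round(seq(2L, n - 1L, length.out = min(24L, n - 2L))))
  best <- Inf
  for (m in probe_idx) {
    dev <- max(envelope_dev(x[1:m], y[1:m], convex = TRUE),
               envelope_dev(x[m:n], y[m:n], convex = FALSE))
    if (dev < best) best <- dev
  }
  best / 2
}

# Max deviation of the points above their greatest convex minorant
# (convex = TRUE) or below their least concave majorant (convex = FALSE):
# the pointwise gap between the empirical CDF piece and the best monotone
# unimodal envelope on that side of the candidate mode.
envelope_dev <- function(x, y, convex) {
  n <- length(x)
  if (n < 3L) return(0)
  if (!convex) y <- -y
  # Andrew monotone-chain lower hull of (x, y), x non-decreasing
  hull <- integer(0)
  for (i in seq_len(n)) {
    while (length(hull) >= 2L) {
      a <- hull[length(hull) - 1L]
      b <- hull[length(hull)]
      cross <- (x[b] - x[a]) * (y[i] - y[a]) - (y[b] - y[a]) * (x[i] - x[a])
      if (cross <= 0) hull <- hull[-length(hull)] else break
    }
    hull <- c(hull, i)
  }
  if (length(hull) < 2L) return(0)
  gy <- stats::approx(x[hull], y[hull], xout = x, ties = min)$y
  max(y - gy)
}
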