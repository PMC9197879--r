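test_that("standardize centres and scales with the population convention", {
  ft <- toy_table(matrix(c(1, 2, 3), 3, 1, dimnames = list(NULL, "f")))
  z <- standardize(ft)$features[, "f"]
  expect_equal(unname(z), c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-6)
  # sample-sd convention on request
  z2 <- standardize(ft, sd = "sample")$features[, "f"]
  expect_equal(unname(z2), c(-1, 0, 1))
  # idempotence to 1e-10
  big <- toy_table(matrix(rnorm(200), 40, 5))
  s1 <- standardize(big)
  s2 <- standardize(s1)
  expect_equal(s2$features, s1$features, tolerance = 1e-10)
  # constant columns dropped with a warning
  cc <- toy_table(cbind(f1 = rnorm(10), f2 = rep(3, 10)))
  expect_warning(out <- standardize(cc), "constant feature")
  expect_equal(colnames(out$features), "f1")
  expect_error(standardize(toy_table(matrix(1, 1, 2))), "at least 2")
})

test_that("hcluster recovers well-separated synthetic classes exactly", {
  sim <- simulate_mature(n_bc = 15, n_sc = 30, separation = 4,
                         gradient_amplitude = 0, seed = 8)
  cl <- hcluster(standardize(sim$table))
  expect_equal(mclust::adjustedRandIndex(as.character(cl$labels),
                                         sim$truth$class), 1)
  expect_setequal(levels(cl$labels), c("A", "B"))
  expect_setequal(cl$leaf_order, rownames(sim$table$features))
  # deterministic given the input
  cl2 <- hcluster(standardize(sim$table))
  expect_identical(cl$labels, cl2$labels)
  expect_error(hcluster(standardize(sim$table), n_clades = 100), "exceeds")
})

test_that("duplicate rows merge first at height zero", {
  m <- matrix(rnorm(12), 6, 2)
  m[2, ] <- m[1, ]
  cl <- hcluster(toy_table(m))
  expect_equal(min(cl$dendrogram$height), 0)
  expect_equal(cl$dendrogram$merge[1, ], c(-1L, -2L))
})

test_that("hcluster agrees with generator labels above 4 pooled SDs", {
  # per-feature shift 4 over 6 informative features: between-centroid
  # distance ~9.8 pooled SDs, comfortably inside the >= 4 SD regime where
  # the two-clade cut must reproduce the generator labels
  for (seed in 1:5) {
    sim <- simulate_mature(n_bc = 15, n_sc = 40, separation = 4,
                           gradient_amplitude = 0, seed = seed)
    cl <- hcluster(standardize(sim$table))
    ari <- mclust::adjustedRandIndex(as.character(cl$labels), sim$truth$class)
    expect_gte(ari, 0.95)
  }
})

test_that("dendrogram exports to Newick with merge-height branch lengths", {
  sim <- simulate_mature(n_bc = 5, n_sc = 7, seed = 2)
  cl <- hcluster(standardize(sim$table))
  nwk <- dendrogram_newick(cl)
  tr <- ape::read.tree(text = nwk)
  expect_equal(sort(tr$tip.label), sort(rownames(sim$table$features)))
  # ultrametric: root-to-tip distances all equal the top merge height
  depths <- ape::node.depth.edgelength(tr)[seq_along(tr$tip.label)]
  expect_equal(max(abs(depths - max(cl$dendrogram$height))), 0,
               tolerance = 1e-8)
})

test_that("leaf_rank anchors the reference clade at rank 1", {
  m <- rbind(a = c(0, 0), b = c(0.5, 0), c = c(10, 10), d = c(10.5, 10))
  colnames(m) <- c("f1", "f2")
  cl <- hcluster(feature_table(m))
  r1 <- leaf_rank(cl, c("a", "b"))
  expect_setequal(sort(unname(r1)), 1:4)
  expect_true(all(r1[c("a", "b")] %in% 1:2))
  r2 <- leaf_rank(cl, c("c", "d"))
  expect_true(all(r2[c("c", "d")] %in% 1:2))
  expect_error(leaf_rank(cl, character(0)), "empty reference")
  # permutation property on random fixtures
  for (seed in 1:3) {
    sim <- simulate_mature(n_bc = 8, n_sc = 12, seed = seed)
    cl <- hcluster(standardize(sim$table))
    ref <- names(sim$truth$class)[sim$truth$class == "BC"]
    rk <- leaf_rank(cl, ref)
    expect_setequal(sort(unname(rk)), seq_along(rk))
    clade <- names(which.max(table(cl$labels[ref])))
    expect_setequal(unname(rk[names(cl$labels)[cl$labels == clade]]),
                    seq_len(sum(cl$labels == clade)))
  }
})

test_that("dpt_rank produces deterministic dense ranks", {
  expect_equal(unname(dpt_rank(c(a = 0.1, b = 0.5, c = 0.3))), c(1L, 3L, 2L))
  expect_equal(unname(dpt_rank(c(b = 1, a = 1, c = 1))), c(2L, 1L, 3L))
  expect_error(dpt_rank(c(a = 1, b = NA)), "finite")
  set.seed(9)
  for (i in 1:3) {
    v <- stats::setNames(rnorm(30), sprintf("c%02d", 1:30))
    rk <- dpt_rank(v)
    expect_equal(names(sort(v)), names(sort(rk)))
    expect_setequal(unname(rk), 1:30)
  }
})

test_that("subsample_cv is perfect on separable clusters and self-consistent", {
  all_feats <- colnames(simulate_mature(seed = 1)$table$features)
  sim <- simulate_mature(n_bc = 12, n_sc = 24, separation = 5,
                         gradient_amplitude = 0, informative = all_feats,
                         seed = 3)
  cl <- hcluster(standardize(sim$table))
  cv <- subsample_cv(sim$table, cl$labels, sizes = c(8, 16, 24), trials = 10,
                     seed = 5)
  expect_equal(unname(cv$mean), rep(1, 3))
  # size = n reproduces the full-data clustering, accuracy 1
  cv_full <- subsample_cv(sim$table, cl$labels, sizes = 36, trials = 3, seed = 1)
  expect_equal(unname(cv_full$mean), 1)
  expect_error(subsample_cv(sim$table, cl$labels, sizes = 50, trials = 2,
                            seed = 1), "exceed")
})

test_that("subsample_cv matches an exhaustive per-trial enumeration oracle", {
  # 6 cells, one of them (f) overlapping the other class
  m <- rbind(a = c(0, 0), b = c(0.4, 0.1), c = c(0.2, 0.4),
             d = c(8, 8), e = c(8.3, 8.2), f = c(4.2, 4.4))
  colnames(m) <- c("f1", "f2")
  tab <- feature_table(m)
  ref <- c(a = "A", b = "A", c = "A", d = "B", e = "B", f = "B")
  trials <- 25L
  cv <- subsample_cv(tab, ref, sizes = 4L, trials = trials, seed = 42)
  # oracle: replay the seeded subsets, recluster each with base tools on
  # the once-standardized matrix
  mz <- sweep(m, 2L, colMeans(m))
  mz <- sweep(mz, 2L, sqrt(colSums(mz^2) / nrow(mz)), "/")
  oracle_one <- function(sub) {
    cut <- stats::cutree(stats::hclust(stats::dist(mz[sub, , drop = FALSE]),
                                       "ward.D2"), k = 2)
    correct <- 0L
    for (cl_id in unique(cut)) {
      members <- ref[sub][cut == cl_id]
      top <- sort(names(which(table(members) == max(table(members)))))[1L]
      correct <- correct + sum(members == top)
    }
    correct / length(sub)
  }
  set.seed(42)
  for (t in seq_len(trials)) {
    sub <- sample(rownames(m), 4L)
    expect_equal(unname(cv$accuracy[t, 1L]), oracle_one(sub))
  }
})

test_that("feature elimination reports adjusted agreement per ablation", {
  sim <- simulate_mature(n_bc = 15, n_sc = 30, separation = 4,
                         gradient_amplitude = 0, seed = 6)
  informative <- c("axon_length", "axon_tangential_span", "axon_ml_height",
                   "axon_sholl_100", "collateral_down_length",
                   "weighted_basket_score")
  noise <- c("dendrite_length", "filopodia_count")
  cl <- hcluster(standardize(sim$table))
  rep <- feature_elimination(sim$table,
                             groups = list(axonal = informative, noise = noise),
                             baseline_labels = cl$labels)
  get <- function(g, m) rep$agreement[rep$group == g & rep$mode == m]
  # the split lives in the axonal group: keeping only it preserves the
  # division, dropping it destroys the division
  expect_gte(get("axonal", "keep_only"), 0.95)
  expect_lt(get("axonal", "drop"), 0.5)
  # dropping pure-noise features leaves the division intact
  expect_gte(get("noise", "drop"), 0.95)
  expect_error(feature_elimination(sim$table, list(bad = c("nope")), cl$labels),
               "unknown feature")
  all_but_one <- colnames(sim$table$features)[-1]
  expect_error(
    feature_elimination(sim$table, list(g = all_but_one), cl$labels),
    "fewer than 2")
})

test_that("embeddings separate synthetic classes and are seed-deterministic", {
  sim <- simulate_mature(n_bc = 15, n_sc = 30, separation = 4, seed = 10)
  std <- standardize(sim$table)
  em <- embed_cells(std, "diffusion", n_neighbors = 7, seed = 3)
  expect_equal(dim(em), c(45L, 2L))
  sil <- cluster::silhouette(as.integer(factor(sim$truth$class)),
                             stats::dist(em))
  expect_gt(mean(sil[, 3]), 0.5)
  em2 <- embed_cells(std, "diffusion", n_neighbors = 7, seed = 3)
  expect_identical(em, em2)
  expect_error(embed_cells(std, "diffusion", n_neighbors = 100), "smaller")
  expect_error(embed_cells(std, "sammon"), "arg")
})

test_that("dip screen flags bimodal features only", {
  set.seed(2)
  ft <- toy_table(cbind(unimodal = rnorm(200),
                        bimodal = c(rnorm(100, -3), rnorm(100, 3))))
  out <- dip_screen(ft, n_boot = 200, seed = 1)
  expect_lt(out$p_value[out$feature == "bimodal"], 0.05)
  expect_gt(out$p_value[out$feature == "unimodal"], 0.2)
  expect_gt(out$dip[out$feature == "bimodal"],
            out$dip[out$feature == "unimodal"])
})
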