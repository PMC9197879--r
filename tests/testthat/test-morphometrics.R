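geom <- default_geom()

test_that("total_length sums edges of the requested compartment", {
  rec <- recon_from(straight_process(25, n_nodes = 5L, structure = "axon"))
  expect_equal(total_length(rec, "axon"), 25)
  expect_equal(total_length(rec, "dendrite"), 0)
  expect_error(total_length(rec, "axoplasm"), "unknown compartment")

  expect_equal(total_length(y_tree(stem = 3, arm1 = 10, arm2 = 7), "axon"), 20)

  # independent edge-sum oracle on a 200-node random tree
  rec2 <- random_tree(200, seed = 11)
  nd <- rec2$nodes
  oracle <- 0
  for (i in seq_len(nrow(nd))) {
    if (nd$parent[i] == -1L) next
    p <- which(nd$id == nd$parent[i])
    oracle <- oracle + euclid(unlist(nd[i, c("x", "y", "z")]),
                              unlist(nd[p, c("x", "y", "z")]))
  }
  expect_equal(total_length(rec2, "axon"), oracle, tolerance = 1e-12)
})

test_that("axon plus dendrite length equals total non-soma cable", {
  for (seed in 1:4) {
    rec <- random_tree(120, seed = seed)
    nd <- rec$nodes
    nd$structure[seq(2, 120, by = 2)] <- "dendrite"
    rec <- recon_from(nd)
    total <- sum(vapply(swc_structures(), function(cmp)
      total_length(rec, cmp), numeric(1L)))
    expect_equal(total_length(rec, "axon") + total_length(rec, "dendrite") +
                   total_length(rec, "soma"), total)
  }
})

test_that("sholl_counts matches the crossing contract", {
  rec <- recon_from(straight_process(60, n_nodes = 12L, structure = "dendrite"))
  expect_equal(unname(sholl_counts(rec, "dendrite", c(10, 50, 100))),
               c(1L, 1L, 0L))
  # a process that exits and re-enters the 50 um sphere crosses it twice
  # (out to 60, back to 40, out again)
  pts_r <- c(seq(5, 60, by = 5), seq(55, 40, by = -5), seq(45, 60, by = 5))
  n <- length(pts_r)
  nd <- nodes_df(id = c(1L, 1L + seq_len(n)),
                 parent = c(-1L, 1L, 1L + seq_len(n - 1L)),
                 structure = c("soma", rep("dendrite", n)),
                 x = c(0, pts_r), y = 0)
  rec2 <- recon_from(nd)
  expect_equal(unname(sholl_counts(rec2, "dendrite", c(50))), 3L)
  expect_equal(unname(sholl_counts(rec2, "dendrite", c(42.5))), 3L)
  # zero beyond the maximal extent, zeros for an absent compartment
  expect_equal(unname(sholl_counts(rec2, "dendrite", c(100, 200))), c(0L, 0L))
  expect_equal(unname(sholl_counts(rec2, "axon", c(10))), 0L)
  expect_error(sholl_counts(rec2, "dendrite", c(50, 10)), "increasing")
})

test_that("sholl_counts agrees with a dense arc-length sampling oracle", {
  # oracle: walk every root-to-tip path at fine arc resolution and count
  # sign changes of (distance - r); each edge contributes the crossings
  # between its endpoint distances (the distance along a straight edge is
  # monotone between endpoints whenever the radius separates them)
  rec <- random_tree(150, seed = 21)
  center <- colMeans(rec$nodes[rec$nodes$structure == "soma",
                               c("x", "y", "z"), drop = FALSE])
  radii <- c(5, 10, 20, 40)
  nd <- rec$nodes
  counts <- integer(length(radii))
  for (i in seq_len(nrow(nd))) {
    if (nd$parent[i] == -1L) next
    p <- which(nd$id == nd$parent[i])
    a <- unlist(nd[p, c("x", "y", "z")])
    b <- unlist(nd[i, c("x", "y", "z")])
    ts <- seq(0, 1, length.out = 200L)
    d <- vapply(ts, function(t) euclid(a + t * (b - a), center), numeric(1L))
    for (j in seq_along(radii)) {
      sgn <- d >= radii[j]
      # crossings where the endpoints disagree (spec's per-edge contract)
      counts[j] <- counts[j] + (sgn[1L] != sgn[length(sgn)])
    }
  }
  expect_equal(unname(sholl_counts(rec, "axon", radii)), counts)
})

test_that("branch levels follow the path branch-point count", {
  rec <- recon_from(straight_process(30, structure = "axon"))
  expect_equal(branch_levels(rec, "axon"), list(mean = 0, max = 0L))
  bl <- branch_levels(y_tree(), "axon")
  expect_equal(bl$max, 1L)
  expect_equal(bl$mean, 2 / 3)
  expect_equal(branch_levels(rec, "dendrite"),
               list(mean = NA_real_, max = NA_integer_))

  # full binary tree of depth 4: oracle by explicit path enumeration
  id <- 1L; nodes <- nodes_df(1L, -1L, "soma", 0, 0)
  grow <- function(parent, depth, px, py) {
    if (depth == 0) return(invisible())
    for (dx in c(-1, 1) * 2^depth) {
      id <<- id + 1L
      this_id <- id
      nodes <<- rbind(nodes, nodes_df(this_id, parent, "axon",
                                      px + dx, py + 10))
      grow(this_id, depth - 1L, px + dx, py + 10)
    }
  }
  grow(1L, 4L, 0, 0)
  rec4 <- recon_from(nodes)
  # levels: segments at depth d below the first bifurcation have level d;
  # the two stems from the root anchor are level 1 (the soma anchor itself
  # carries two axon children, hence is a branch point)
  oracle_levels <- rep(1:4, times = 2^(1:4))
  bl4 <- branch_levels(rec4, "axon")
  expect_equal(bl4$max, max(oracle_levels))
  expect_equal(bl4$mean, mean(oracle_levels))
})

test_that("straightness is chord over arc, aggregated length-weighted", {
  rec <- recon_from(straight_process(40, structure = "axon"))
  expect_equal(straightness(rec, "axon"), 1)
  expect_equal(straightness(semicircle_recon(10), "axon"), 2 / pi,
               tolerance = 1e-4)
  # length-weighted aggregation oracle on a two-segment tree:
  # straight arm (ratio 1) + semicircular arm
  semi <- semicircle_recon(5, n = 200L)
  nd <- semi$nodes
  extra_id <- max(nd$id) + 1L
  nd <- rbind(nd, nodes_df(extra_id, 1L, "axon", x = 0, y = -20))
  rec2 <- recon_from(nd)
  w <- c(5 * pi, 20)
  r <- c(2 / pi, 1)
  expect_equal(straightness(rec2, "axon"), sum(w * r) / sum(w),
               tolerance = 1e-3)
  expect_equal(straightness(rec2, "axon", weighted = FALSE), mean(r),
               tolerance = 1e-3)
  # zero-length segment excluded with a warning
  nd3 <- rbind(nd, nodes_df(extra_id + 1L, 1L, "axon", x = 0, y = 0))
  expect_warning(straightness(recon_from(nd3), "axon"), "zero-length")
})

test_that("filopodia counts terminal dendritic branches under the threshold", {
  # dendrite shaft with three terminal side branches of 1.0, 1.4 and 2.0 um
  nd <- straight_process(30, n_nodes = 6L, structure = "dendrite")
  tips <- rbind(
    nodes_df(8L, 3L, "dendrite", x = 1.0, y = 10),
    nodes_df(9L, 4L, "dendrite", x = 1.4, y = 15),
    nodes_df(10L, 5L, "dendrite", x = 2.0, y = 20))
  rec <- recon_from(rbind(nd, tips))
  fl <- filopodia(rec)
  expect_equal(fl$count, 2L)
  expect_equal(fl$density, 2 / total_length(rec, "dendrite"))
  # none below threshold
  rec2 <- recon_from(straight_process(30, structure = "dendrite"))
  expect_equal(filopodia(rec2), list(count = 0L, density = 0))
  # terminal-enumeration oracle on a synthetic fixture
  fx <- simulate_swc(n_filopodia = 3L, seed = 77)
  expect_equal(filopodia(fx$recon)$count, 3L)
})

test_that("spans are coordinate extents along the layer axes", {
  # axon nodes covering [0, 80] along the PCL in a single sagittal line
  xs <- seq(0, 80, by = 10)
  nd <- nodes_df(id = c(1L, 1L + seq_along(xs)),
                 parent = c(-1L, 1L, 1L + seq_len(length(xs) - 1L)),
                 structure = c("soma", rep("axon", length(xs))),
                 x = c(0, xs), y = 0)
  rec <- recon_from(nd)
  sp <- spans(rec, geom, "axon")
  expect_equal(sp$tangential_span, 80)
  expect_equal(sp$z_depth, 0)
  expect_equal(sp$ml_height_covered, 0)
  # single compartment node -> all-zero extents
  rec1 <- recon_from(nodes_df(1:2, c(-1L, 1L), c("soma", "axon"),
                              x = c(0, 5), y = c(0, 5)))
  expect_equal(unlist(spans(rec1, geom, "axon")),
               c(ml_height_covered = 0, tangential_span = 0, z_depth = 0))
  # empty compartment flagged
  spd <- spans(rec, geom, "dendrite")
  expect_true(isTRUE(attr(spd, "empty")))
  expect_equal(spd$tangential_span, 0)
  # rotating the frame about z transforms spans per projection arithmetic
  th <- 0.3
  geom_rot <- layer_geometry(0, 120,
                             normal = c(-sin(th), cos(th), 0),
                             tangential = c(cos(th), sin(th), 0),
                             z = c(0, 0, 1))
  sp_rot <- spans(rec, geom_rot, "axon")
  expect_equal(sp_rot$tangential_span, 80 * cos(th), tolerance = 1e-10)
  expect_equal(sp_rot$ml_height_covered, 80 * sin(th), tolerance = 1e-10)
})

test_that("collateral classification applies the angle threshold", {
  # main shaft along +x with one 90-degree branch toward the ML top and one
  # 20-degree branch (excluded)
  shaft <- straight_process(100, n_nodes = 10L, dir = c(1, 0, 0),
                            structure = "axon")
  up_id <- 12L; ex_id <- 13L
  branches <- rbind(
    nodes_df(up_id, 4L, "axon", x = 30, y = 15),               # 90 deg up
    nodes_df(ex_id, 6L, "axon",                                 # 20 deg off
             x = 50 + 12 * cos(20 * pi / 180),
             y = 12 * sin(20 * pi / 180)))
  rec <- recon_from(rbind(shaft, branches))
  cc <- classify_collaterals(rec, geom)
  expect_equal(cc$up$count, 1L)
  expect_equal(cc$down$count, 0L)
  expect_equal(cc$up$total_length, 15)
  expect_equal(cc$up$percent, 100)
  # with the threshold lowered below 20 degrees the second branch counts
  cc2 <- classify_collaterals(rec, geom, angle_threshold = 15)
  expect_equal(cc2$up$count + cc2$down$count, 2L)
  expect_error(classify_collaterals(
    recon_from(straight_process(10, structure = "dendrite")), geom),
    "axonless")
})

test_that("collateral classes match the generator's per-branch angle oracle", {
  for (seed in c(3, 9, 15)) {
    fx <- simulate_swc(n_coll_up = 2L, n_coll_down = 1L, n_coll_excluded = 2L,
                       seed = seed)
    cc <- classify_collaterals(fx$recon, fx$geom)
    expect_equal(cc$up$count, 2L)
    expect_equal(cc$down$count, 1L)
    expect_equal(cc$up$total_length, unname(fx$truth["collateral_up_length"]),
                 tolerance = 1e-9)
  }
})

test_that("weighted_basket_score applies the 1 / 0.75 / 0.5 scale", {
  expect_equal(weighted_basket_score(c(full = 2, basket_like = 0, partial = 1)), 2.5)
  expect_equal(weighted_basket_score(c(full = 0, basket_like = 0, partial = 0)), 0)
  expect_equal(weighted_basket_score(c(full = 1, basket_like = 1, partial = 1)), 2.25)
  # additive over disjoint terminal sets
  a <- c(full = 2, basket_like = 1, partial = 0)
  b <- c(full = 0, basket_like = 2, partial = 3)
  expect_equal(weighted_basket_score(a + b),
               weighted_basket_score(a) + weighted_basket_score(b))
  expect_error(weighted_basket_score(c(full = -1, basket_like = 0, partial = 0)),
               ">= 0")
})

test_that("ellipsoid soma volume supports both formula conventions", {
  expect_equal(soma_volume_ellipsoid(1, 1, 1), 4 * pi / 3)
  expect_equal(soma_volume_ellipsoid(1, 1, 1, formula = "geometric"), pi / 6)
  expect_equal(soma_volume_ellipsoid(2, 1, 1), 2 * soma_volume_ellipsoid(1, 1, 1))
  expect_error(soma_volume_ellipsoid(0, 1, 1), "> 0")
})

test_that("structural counts identify primaries, PCL tips and axon origin", {
  # soma with three dendritic children, axon rooted on a dendrite, one axon
  # tip below the PCL top
  nd <- rbind(
    nodes_df(1L, -1L, "soma", 0, 50),
    nodes_df(2L, 1L, "dendrite", 5, 60),
    nodes_df(3L, 1L, "dendrite", -5, 60),
    nodes_df(4L, 1L, "dendrite", 0, 65),
    nodes_df(5L, 2L, "axon", 20, 50),
    nodes_df(6L, 5L, "axon", 40, -4),
    nodes_df(7L, 5L, "axon", 40, 80))
  sc <- structural_counts(recon_from(nd), geom)
  expect_equal(sc$primary_dendrites, 3L)
  expect_equal(sc$pcl_reaching_branches, 1L)
  expect_true(sc$axon_carrying_dendrite)
  # all tips above the PCL and axon from soma
  rec2 <- y_tree()
  nd2 <- rec2$nodes
  nd2$y <- nd2$y + 50
  sc2 <- structural_counts(recon_from(nd2), geom)
  expect_equal(sc2$pcl_reaching_branches, 0L)
  expect_false(sc2$axon_carrying_dendrite)
})

test_that("extract_features matches construction ground truth and flags", {
  for (seed in c(2, 13, 28)) {
    fx <- simulate_swc(seed = seed, axon_from_dendrite = seed %% 2 == 0)
    for (preset in c("mature_27", "developmental_28")) {
      fv <- extract_features(fx$recon, fx$geom, feature_schema(preset))
      truth <- fx$truth[names(fv)]
      rel <- abs(as.numeric(fv) - truth) / pmax(1e-9, abs(truth))
      expect_lt(max(rel), 1e-6)
      expect_true(all(attr(fv, "provenance") %in%
                        c("computed", "annotated")))
    }
  }
  # dendrite-less fixture: dendritic features flagged missing
  rec <- y_tree()
  rec$annotations <- annotation_record()
  rec$annotations$soma_volume <- 100
  fv <- extract_features(rec, geom, feature_schema("mature_27"))
  prov <- attr(fv, "provenance")
  expect_true(all(prov[c("dendrite_length", "filopodia_count",
                         "dendrite_ml_height")] == "missing"))
  expect_true(all(is.na(fv[c("dendrite_length", "filopodia_count")])))
  expect_equal(prov[["soma_volume"]], "annotated")
  # missing required annotation errors with the feature name
  rec2 <- y_tree()
  expect_error(extract_features(rec2, geom, feature_schema("mature_27")),
               "weighted_basket_score|soma_volume")
})

test_that("features are invariant under rigid translation except location", {
  fx <- simulate_swc(seed = 5)
  shifted <- fx$recon
  shifted$nodes$x <- shifted$nodes$x + 40
  shifted$nodes$z <- shifted$nodes$z - 17
  sch <- feature_schema("developmental_28")
  fv1 <- extract_features(fx$recon, fx$geom, sch)
  fv2 <- extract_features(shifted, fx$geom, sch)
  loc <- c("soma_height", "relative_ml_position")
  expect_equal(as.numeric(fv2[setdiff(names(fv2), loc)]),
               as.numeric(fv1[setdiff(names(fv1), loc)]), tolerance = 1e-9)
  # a normal-axis translation shifts soma height by exactly that amount
  shifted$nodes$y <- shifted$nodes$y + 10
  fv3 <- extract_features(shifted, fx$geom, sch)
  expect_equal(unname(fv3["soma_height"] - fv1["soma_height"]), 10)
})

test_that("feature schemas have the declared sizes and subset structure", {
  m27 <- feature_schema("mature_27")
  d28 <- feature_schema("developmental_28")
  c19 <- feature_schema("clustering_19")
  expect_equal(nrow(m27$features), 27L)
  expect_equal(nrow(d28$features), 28L)
  expect_equal(length(c19$clustering_subset), 19L)
  expect_true(all(c19$clustering_subset %in% c19$features$name))
  f <- withr::local_tempfile(fileext = ".yaml")
  write_feature_schema(c19, f)
  back <- read_feature_schema(f)
  expect_equal(back$features$name, c19$features$name)
  expect_equal(back$clustering_subset, c19$clustering_subset)
})
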