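#' Simulate a mature two-type morphometric population
#'
#' Generates a feature table emulating a mature interneuron population with
#' two discrete morphological classes (basket-like `BC`, stellate-like
#' `SC`) plus a continuous within-SC gradient. Features are class-
#' conditional Gaussians with diagonal covariance; the class mean
#' difference is confined to the informative (axonal) feature group, and SC
#' cells carry an additional continuous gradient component on the axon-span
#' features, mirroring the short-to-long-axon stellate continuum.
#'
#' Defaults reproduce the structure of the mature study population: 19
#' basket and 60 stellate cells, a clear axonal class separation, and a
#' unit-scale stellate gradient.
#'
#' @param n_bc,n_sc class sizes (each at least 2).
#' @param separation per-feature class mean difference, in noise SD units,
#'   applied to every informative feature (default 2; with the default six
#'   informative features the total class separation is about 4.9 pooled
#'   SDs).
#' @param gradient_amplitude amplitude of the SC gradient (default 2).
#' @param noise_sd within-class SD (must be positive).
#' @param informative character vector of informative feature names.
#' @param gradient_features features carrying the SC gradient.
#' @param seed integer seed; the generator is a pure function of it.
#' @return List with `table` (a [feature_table()] whose metadata carries
#'   `true_class`) and `truth` (list with `class` and `gradient`, named by
#'   cell).
#' @export
simulate_mature <- function(n_bc = 19L, n_sc = 60L, separation = 2,
                            gradient_amplitude = 2, noise_sd = 1,
                            informative = c("axon_length",
                                            "axon_tangential_span",
                                            "axon_ml_height",
                                            "axon_sholl_100",
                                            "collateral_down_length",
                                            "weighted_basket_score"),
                            gradient_features = c("axon_length",
                                                  "axon_tangential_span"),
                            seed = 1L) {
  if (n_bc < 2L || n_sc < 2L) stop("class sizes must be at least 2")
  if (noise_sd <= 0) stop("degenerate covariance: noise_sd must be > 0")
  if (separation < 0 || gradient_amplitude < 0)
    stop("separation and gradient amplitude must be >= 0")
  feats <- unique(c(informative,
                    "dendrite_length", "filopodia_count", "filopodia_density",
                    "dendrite_ml_height", "soma_volume",
                    "relative_ml_position", gradient_features))
  set.seed(seed)
  n <- n_bc + n_sc
  cls <- c(rep("BC", n_bc), rep("SC", n_sc))
  ids <- sprintf("cell%03d", seq_len(n))
  m <- matrix(stats::rnorm(n * length(feats), sd = noise_sd), n, length(feats),
              dimnames = list(ids, feats))
  m[cls == "BC", informative] <- m[cls == "BC", informative] +
    separation * noise_sd
  grad <- stats::setNames(rep(NA_real_, n), ids)
  grad[cls == "SC"] <- stats::runif(n_sc)
  for (f in gradient_features)
    m[cls == "SC", f] <- m[cls == "SC", f] +
      gradient_amplitude * grad[cls == "SC"]
  md <- data.frame(cell_id = ids, true_class = cls, stringsAsFactors = FALSE)
  list(table = feature_table(m, md),
       truth = list(class = stats::setNames(cls, ids), gradient = grad))
}

#' Simulate a developmental two-fate trajectory
#'
#' Generates developmental morphometric snapshots of two birthdate cohorts
#' maturing along a latent variable `s` in [0, 1]. Cells are drawn from
#' `n_states` snapshot windows (truncated-Gaussian jitter around evenly
#' spaced centres, emulating the developmental variability present in
#' tissue at any collection time point). Most features grow monotonically
#' with `s`; the two fates share identical mean trajectories up to the
#' divergence point `s_div` and deviate afterwards. The stellate fate's
#' axonal span follows a hump (expansion then retraction), the basket fate
#' gains descending collaterals and PCL-reaching branches, and a small
#' fraction of the early-born cohort follows a rare short-range stellate
#' trajectory.
#'
#' With `s_div = 1` the fates never diverge (the positional-cue null
#' scenario); with small `s_div` they diverge early (the early-commitment
#' scenario). Feature names follow the developmental 28-feature schema so
#' simulated tables are drop-in inputs for [morpho_pseudotime()].
#'
#' @param n_bc,n_sc cohort sizes (defaults 423 early-born and 309
#'   late-born, the study condition).
#' @param s_div divergence point in (0, 1]; default 0.1 (early divergence).
#' @param sigma Gaussian feature noise SD (default 0.2; trajectory
#'   amplitudes are order 1).
#' @param rare_sc_fraction fraction of the early-born cohort following the
#'   rare short-range stellate trajectory (default 0.05; must be < 0.5).
#' @param n_states number of snapshot windows (default 8).
#' @param state_jitter SD of the within-window jitter of `s` (default
#'   0.06).
#' @param seed integer seed.
#' @return List with `table` (a [feature_table()], metadata `fate_label`,
#'   `expert_stage`, `dpi`) and `truth` (named vectors `s`, `state`,
#'   `lineage`, `fate`).
#' @export
simulate_development <- function(n_bc = 423L, n_sc = 309L, s_div = 0.1,
                                 sigma = 0.2, rare_sc_fraction = 0.05,
                                 n_states = 8L, state_jitter = 0.06,
                                 seed = 1L) {
  if (!(s_div > 0 && s_div <= 1)) stop("s_div must lie in (0, 1]")
  if (sigma <= 0) stop("sigma must be > 0")
  if (rare_sc_fraction < 0 || rare_sc_fraction >= 0.5)
    stop("rare_sc_fraction must lie in [0, 0.5)")
  set.seed(seed)
  n <- n_bc + n_sc
  fate <- c(rep("BC_fated", n_bc), rep("SC_fated", n_sc))
  ids <- sprintf("dev%04d", seq_len(n))
  lineage <- ifelse(fate == "BC_fated", "BC", "SC")
  if (n_bc > 0L && rare_sc_fraction > 0) {
    n_rare <- round(rare_sc_fraction * n_bc)
    if (n_rare > 0L)
      lineage[sample(which(fate == "BC_fated"), n_rare)] <- "SC_short"
  }
  state <- sample.int(n_states, n, replace = TRUE)
  centers <- (state - 0.5) / n_states
  s <- stats::rnorm(n, centers, state_jitter)
  while (any(bad <- s < 0 | s > 1))
    s[bad] <- stats::rnorm(sum(bad), centers[bad], state_jitter)

  mu <- dev_mean_trajectories(s, lineage, s_div)
  m <- mu + matrix(stats::rnorm(n * ncol(mu), sd = sigma), n, ncol(mu))
  dimnames(m) <- dimnames(mu)
  rownames(m) <- ids

  md <- data.frame(
    cell_id = ids, fate_label = fate,
    expert_stage = pmin(4L, 1L + as.integer(floor(s * 4))),
    dpi = round(5 + 20 * centers),
    stringsAsFactors = FALSE)
  list(table = feature_table(m, md),
       truth = list(s = stats::setNames(s, ids),
                    state = stats::setNames(state, ids),
                    lineage = stats::setNames(lineage, ids),
                    fate = stats::setNames(fate, ids)))
}

# Mean feature trajectories for the developmental generator. Shared growth
# up to s_div; lineage-specific deviations afterwards, scaled by
# u = (s - s_div) / (1 - s_div) so mu_BC(s) == mu_SC(s) exactly for
# s <= s_div.
dev_mean_trajectories <- function(s, lineage, s_div) {
  feats <- feature_schema("developmental_28")$features$name
  # common growth slopes (order-1 amplitudes; standardization absorbs scale)
  slope <- stats::setNames(rep(1, length(feats)), feats)
  slope[c("axon_length", "axon_tangential_span")] <- 1.5
  slope[c("axon_sholl_10", "axon_sholl_50")] <- 1.2
  slope[c("axon_sholl_100", "axon_sholl_150", "axon_sholl_200")] <- 0.8
  slope["axon_straightness"] <- -0.4
  slope["relative_ml_position"] <- -1       # inside-out settling: cells descend
  slope[c("soma_x_diameter", "soma_y_diameter", "soma_z_diameter")] <- 0.6
  slope["soma_volume_ellipsoid"] <- 1.8
  slope[c("collateral_up_count", "collateral_up_length",
          "collateral_up_percent")] <- 0.5
  slope[c("collateral_down_count", "collateral_down_length",
          "collateral_down_percent")] <- 0.5
  slope["pcl_reaching_branches"] <- 0.3
  slope["primary_dendrites"] <- 0.4

  mu <- outer(s, slope)
  colnames(mu) <- feats
  if (s_div >= 1) return(mu)
  # Fate divergence is transversal to the maturation axis: after s_div the
  # two fates deviate in mirrored directions on a set of weakly growing
  # features, so the shared growth axis (and hence pseudotime) is
  # preserved while the cohorts become separable. The onset saturates on a
  # commitment timescale of 0.12 (about one snapshot window), so an early
  # divergence produces cohorts that are already distinguishable at the
  # earliest post-divergence snapshots.
  u <- 1 - exp(-pmax(0, s - s_div) / 0.12)
  uu <- pmax(0, (s - s_div) / (1 - s_div))  # linear remaining-range ramp

  # mirrored fate axis: +1 for basket-fated, -1 for stellate-fated cells
  fate_axis <- stats::setNames(rep(0, length(feats)), feats)
  fate_axis[c("collateral_down_count", "collateral_down_length",
              "collateral_down_percent", "pcl_reaching_branches")] <- 0.5
  fate_axis[c("collateral_up_count", "collateral_up_length",
              "collateral_up_percent")] <- -0.5
  fate_axis["relative_ml_position"] <- -0.5   # SCs settle higher in the ML
  fate_axis["axon_sholl_100"] <- 0.4          # BCs reach farther while migrating

  sign_of <- c(BC = 1, SC = -1, SC_short = -1)
  mu <- mu + outer(u * sign_of[lineage], fate_axis)
  # stellate axonal span: expansion then retraction (interior peak, net
  # decline by the end of the trajectory); basket span keeps growing
  sc <- lineage != "BC"
  mu[sc, "axon_tangential_span"] <- mu[sc, "axon_tangential_span"] +
    1.0 * sin(pi * uu[sc]) - 1.2 * uu[sc]
  # rare short-range early-born stellate lineage: stunted axonal growth
  rare <- lineage == "SC_short"
  if (any(rare)) {
    for (f in c("axon_length", "axon_tangential_span",
                "axon_mean_branch_level", "axon_max_branch_level",
                "axon_sholl_150", "axon_sholl_200"))
      mu[rare, f] <- mu[rare, f] - 0.8 * u[rare]
  }
  mu
}

#' Simulate an SWC reconstruction with analytic ground truth
#'
#' Builds a synthetic interneuron reconstruction whose morphometric
#' features are known exactly at construction time: a point soma placed in
#' the molecular layer, straight radial dendrites carrying short terminal
#' filopodia and longer terminal side branches, and a straight tangential
#' axon shaft with collaterals at configured angles (some steeper than the
#' inclusion threshold, some shallower). All segments are straight
#' polylines, so lengths, spans, Sholl crossings, branch levels,
#' straightness, filopodia, collateral classes and structural counts are
#' computed analytically during construction and returned as ground truth.
#'
#' @param n_dendrites number of primary dendrites (default 3).
#' @param n_filopodia short (< 1.5 um) terminal dendritic side branches
#'   (default 2).
#' @param n_long_side longer terminal dendritic side branches (default 1).
#' @param n_coll_up,n_coll_down collaterals steeper than the threshold,
#'   directed towards the ML top / the PCL (defaults 2 and 2).
#' @param n_coll_excluded collaterals shallower than the threshold
#'   (default 1).
#' @param angle_threshold collateral inclusion threshold in degrees.
#' @param axon_from_dendrite attach the axon to a dendrite instead of the
#'   soma (axon-carrying dendrite)?
#' @param ml_thickness molecular-layer thickness in micrometres.
#' @param seed integer seed.
#' @return List with `recon` (a [neuron_reconstruction()] carrying soma
#'   diameter and basket-terminal annotations), `geom` (the
#'   [layer_geometry()]), and `truth` (named numeric vector of ground-truth
#'   feature values covering the mature and developmental panels).
#' @examples
#' fx <- simulate_swc(seed = 42)
#' fv <- extract_features(fx$recon, fx$geom, feature_schema("developmental_28"))
#' all.equal(as.numeric(fv), unname(fx$truth[names(fv)]), tolerance = 1e-8)
#' @export
simulate_swc <- function(n_dendrites = 3L, n_filopodia = 2L, n_long_side = 1L,
                         n_coll_up = 2L, n_coll_down = 2L,
                         n_coll_excluded = 1L, angle_threshold = 30,
                         axon_from_dendrite = FALSE, ml_thickness = 120,
                         seed = 1L) {
  if (n_dendrites < 1L) stop("need at least one primary dendrite")
  set.seed(seed)
  geom <- layer_geometry(pcl_top = 0, ml_top = ml_thickness)
  soma_h <- stats::runif(1, 0.25, 0.8) * ml_thickness
  soma <- c(0, soma_h, 0)

  b <- swc_builder(soma)

  # --- dendrites: straight radial shafts with terminal side branches ------
  dend_total <- 0
  dend_seg_levels <- integer(0)
  filo_placed <- 0L
  base_level <- if (n_dendrites >= 2L) 1L else 0L
  side_specs <- c(rep("filo", n_filopodia), rep("long", n_long_side))
  # spread side branches across dendrites
  side_assign <- if (length(side_specs))
    sort(rep_len(seq_len(n_dendrites), length(side_specs))) else integer(0)
  axon_anchor <- NULL
  dend_first_nodes <- integer(0)
  for (di in seq_len(n_dendrites)) {
    dir <- unit_vec(c(stats::runif(1, -0.6, 0.6), stats::runif(1, 0.6, 1),
                      stats::runif(1, -0.4, 0.4)))
    len <- stats::runif(1, 20, 40)
    n_nodes <- sample(4:6, 1L)
    shaft <- b$polyline(b$soma_idx, dir, len, n_nodes, "dendrite")
    dend_first_nodes <- c(dend_first_nodes, shaft$node_idx[1L])
    dend_total <- dend_total + len
    my_sides <- side_specs[side_assign == di]
    if (length(my_sides)) {
      # attachment nodes: interior, within the first 70% of the shaft
      interior <- shaft$node_idx[-c(1L, length(shaft$node_idx))]
      interior <- interior[shaft$arc[-c(1L, length(shaft$arc))] <= 0.7 * len]
      if (length(interior) < length(my_sides))
        stop("infeasible geometry: too many dendritic side branches")
      att <- sample(interior, length(my_sides))
      m_d <- length(my_sides)
      for (si in seq_along(my_sides)) {
        sdir <- unit_vec(dir + c(0.9, -0.2, 0.3) * (if (si %% 2) 1 else -1))
        slen <- if (my_sides[si] == "filo") stats::runif(1, 0.5, 1.4)
                else stats::runif(1, 4, 12)
        b$polyline(att[si], sdir, slen, 2L, "dendrite")
        dend_total <- dend_total + slen
        if (my_sides[si] == "filo") filo_placed <- filo_placed + 1L
      }
      # order attachments along the shaft for level bookkeeping
      dend_seg_levels <- c(dend_seg_levels,
                           base_level,                       # piece before 1st
                           rep(base_level + seq_len(m_d), each = 2L))
    } else {
      dend_seg_levels <- c(dend_seg_levels, base_level)
    }
    if (axon_from_dendrite && is.null(axon_anchor)) {
      # a node of the first dendrite shaft carries the axon
      axon_anchor <- shaft$node_idx[2L]
    }
  }
  if (is.null(axon_anchor)) axon_anchor <- b$soma_idx

  # --- axon: straight tangential shaft with angled collaterals ------------
  main_len <- stats::runif(1, 150, 250)
  n_shaft_nodes <- sample(14:20, 1L)
  shaft <- b$polyline(axon_anchor, c(1, 0, 0), main_len, n_shaft_nodes, "axon")
  n_coll <- n_coll_up + n_coll_down + n_coll_excluded
  # attachment nodes: interior, within the first 60% of the shaft, distinct
  interior_mask <- seq_along(shaft$node_idx) > 1L &
    seq_along(shaft$node_idx) < length(shaft$node_idx) &
    shaft$arc <= 0.6 * main_len
  cand <- which(interior_mask)
  if (length(cand) < n_coll) stop("infeasible geometry: too many collaterals")
  att_pos <- sort(sample(cand, n_coll))
  coll_class <- sample(c(rep("up", n_coll_up), rep("down", n_coll_down),
                         rep("excluded", n_coll_excluded)))
  axon_total <- main_len
  up_len <- 0; down_len <- 0
  axon_tips <- list(b$coords(shaft$node_idx[length(shaft$node_idx)]))
  for (ci in seq_len(n_coll)) {
    node <- shaft$node_idx[att_pos[ci]]
    theta <- switch(coll_class[ci],
                    up = stats::runif(1, angle_threshold + 10, 90),
                    down = stats::runif(1, angle_threshold + 10, 90),
                    excluded = stats::runif(1, 5, angle_threshold - 10))
    sgn <- switch(coll_class[ci], up = 1, down = -1,
                  excluded = sample(c(-1, 1), 1L))
    dir <- c(cos(theta * pi / 180), sgn * sin(theta * pi / 180), 0)
    clen <- stats::runif(1, 10, min(40, 0.3 * main_len))
    pl <- b$polyline(node, dir, clen, sample(3:5, 1L), "axon")
    axon_total <- axon_total + clen
    if (coll_class[ci] == "up") up_len <- up_len + clen
    if (coll_class[ci] == "down") down_len <- down_len + clen
    axon_tips[[length(axon_tips) + 1L]] <- b$coords(pl$node_idx[length(pl$node_idx)])
  }
  axon_seg_levels <- c(0L, rep(seq_len(n_coll), each = 2L))

  nodes <- b$nodes()
  # --- analytic ground truth ----------------------------------------------
  axon_nodes <- nodes[nodes$structure == "axon", c("x", "y", "z")]
  dend_nodes <- nodes[nodes$structure == "dendrite", c("x", "y", "z")]
  # Sholl: per-edge straddle counts from the generator's own node table
  sholl_truth <- generator_sholl(nodes, soma, c(10, 50, 100, 150, 200))
  incl_total <- up_len + down_len
  tip_y <- vapply(axon_tips, `[[`, numeric(1L), 2L)

  soma_diam <- stats::runif(3, 6, 12)
  baskets <- c(full = sample(0:4, 1L), basket_like = sample(0:3, 1L),
               partial = sample(0:3, 1L))
  soma_render_volume <- stats::runif(1, 300, 900)

  truth <- c(
    axon_length = axon_total,
    dendrite_length = dend_total,
    axon_straightness = 1,
    axon_mean_branch_level = mean(axon_seg_levels),
    axon_max_branch_level = max(axon_seg_levels),
    dendrite_mean_branch_level = mean(dend_seg_levels),
    axon_sholl_10 = sholl_truth[["10"]],
    axon_sholl_50 = sholl_truth[["50"]],
    axon_sholl_100 = sholl_truth[["100"]],
    axon_sholl_150 = sholl_truth[["150"]],
    axon_sholl_200 = sholl_truth[["200"]],
    axon_ml_height = max(axon_nodes$y) - min(axon_nodes$y),
    axon_tangential_span = max(axon_nodes$x) - min(axon_nodes$x),
    axon_z_depth = max(axon_nodes$z) - min(axon_nodes$z),
    dendrite_ml_height = max(dend_nodes$y) - min(dend_nodes$y),
    collateral_up_count = n_coll_up,
    collateral_up_length = up_len,
    collateral_up_percent = if (incl_total > 0) 100 * up_len / incl_total else 0,
    collateral_down_count = n_coll_down,
    collateral_down_length = down_len,
    collateral_down_percent = if (incl_total > 0) 100 * down_len / incl_total else 0,
    filopodia_count = filo_placed,
    filopodia_density = filo_placed / dend_total,
    primary_dendrites = n_dendrites,
    pcl_reaching_branches = sum(tip_y < 0),
    axon_carrying_dendrite = as.numeric(axon_from_dendrite),
    axon_segment_count = 2L * n_coll + 1L,
    axon_terminal_count = n_coll + 1L,
    soma_height = soma_h,
    relative_ml_position = soma_h / ml_thickness,
    soma_x_diameter = soma_diam[1L],
    soma_y_diameter = soma_diam[2L],
    soma_z_diameter = soma_diam[3L],
    soma_volume_ellipsoid = 4 / 3 * pi * prod(soma_diam),
    soma_volume = soma_render_volume,
    weighted_basket_score = baskets[["full"]] + 0.75 * baskets[["basket_like"]] +
      0.5 * baskets[["partial"]]
  )

  ann <- annotation_record(basket_terminal_counts = baskets)
  ann$soma_diameters <- c(x = soma_diam[1L], y = soma_diam[2L],
                          z = soma_diam[3L])
  ann$soma_volume <- soma_render_volume
  recon <- neuron_reconstruction(sprintf("synth%05d", seed), nodes, ann)
  list(recon = recon, geom = geom, truth = truth)
}

# incremental SWC node builder: point soma root plus straight polylines
swc_builder <- function(soma) {
  env <- new.env(parent = emptyenv())
  env$df <- data.frame(id = 1L, parent = -1L, structure = "soma",
                       x = soma[1L], y = soma[2L], z = soma[3L],
                       radius = 4, stringsAsFactors = FALSE)
  b <- list()
  b$soma_idx <- 1L
  # straight polyline of total `len` from node `from` along unit `dir`,
  # with n_nodes new nodes at equal arc spacing; returns node ids and arcs
  b$polyline <- function(from, dir, len, n_nodes, structure) {
    dir <- unit_vec(dir)
    p0 <- as.numeric(env$df[env$df$id == from, c("x", "y", "z")])
    arcs <- seq_len(n_nodes) / n_nodes * len
    ids <- max(env$df$id) + seq_len(n_nodes)
    parents <- c(from, ids[-n_nodes])
    pts <- t(vapply(arcs, function(a) p0 + a * dir, numeric(3L)))
    env$df <- rbind(env$df, data.frame(
      id = ids, parent = parents, structure = structure,
      x = pts[, 1L], y = pts[, 2L], z = pts[, 3L], radius = 0.5,
      stringsAsFactors = FALSE))
    list(node_idx = c(from, ids), arc = c(0, arcs))
  }
  b$coords <- function(id)
    as.numeric(env$df[env$df$id == id, c("x", "y", "z")])
  b$nodes <- function() env$df
  b
}

# ground-truth Sholl crossings per compartment edge, computed directly from
# the generator's node table (independent of the package's tree machinery)
generator_sholl <- function(nodes, center, radii) {
  ax <- nodes[nodes$structure == "axon", ]
  pos <- rbind(nodes[, c("x", "y", "z")])
  rownames(pos) <- nodes$id
  out <- stats::setNames(numeric(length(radii)), radii)
  for (i in seq_len(nrow(ax))) {
    p_child <- as.numeric(ax[i, c("x", "y", "z")])
    p_parent <- as.numeric(pos[as.character(ax$parent[i]), ])
    d1 <- sqrt(sum((p_child - center)^2))
    d2 <- sqrt(sum((p_parent - center)^2))
    lo <- min(d1, d2); hi <- max(d1, d2)
    for (j in seq_along(radii))
      if (lo < radii[j] && hi >= radii[j]) out[j] <- out[j] + 1
  }
  out
}
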