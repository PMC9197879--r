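# Small programmatic fixtures shared across the suite.

# data frame of SWC-style nodes from parallel vectors
nodes_df <- function(id, parent, structure, x, y, z = 0, radius = 0.5) {
  data.frame(id = id, parent = parent, structure = structure,
             x = x, y = y, z = z, radius = radius,
             stringsAsFactors = FALSE)
}

# soma at origin plus one straight process of `len` subdivided into
# `n_nodes` nodes along unit vector `dir`
straight_process <- function(len, n_nodes = 6L, dir = c(0, 1, 0),
                             structure = "dendrite") {
  arcs <- seq_len(n_nodes) / n_nodes * len
  nodes_df(
    id = c(1L, 1L + seq_len(n_nodes)),
    parent = c(-1L, 1L, 1L + seq_len(n_nodes - 1L)),
    structure = c("soma", rep(structure, n_nodes)),
    x = c(0, arcs * dir[1]), y = c(0, arcs * dir[2]), z = c(0, arcs * dir[3]),
    radius = c(4, rep(0.5, n_nodes)))
}

recon_from <- function(nodes, cell_id = "fix") {
  neuron_reconstruction(cell_id, nodes)
}

# Y-shaped tree: stem of `stem` then two arms, all along distinct
# directions, with `structure` processes
y_tree <- function(stem = 3, arm1 = 10, arm2 = 7, structure = "axon") {
  nodes <- nodes_df(
    id = 1:4, parent = c(-1L, 1L, 2L, 2L),
    structure = c("soma", rep(structure, 3)),
    x = c(0, stem, stem + arm1, stem),
    y = c(0, 0, 0, arm2))
  recon_from(nodes)
}

# semicircular arc of radius r (arc length pi * r) discretized finely,
# attached to a soma at the arc start
semicircle_recon <- function(r = 10, n = 400L, structure = "axon") {
  th <- seq(0, pi, length.out = n + 1L)[-1L]
  nodes <- nodes_df(
    id = c(1L, 1L + seq_len(n)),
    parent = c(-1L, 1L, 1L + seq_len(n - 1L)),
    structure = c("soma", rep(structure, n)),
    x = c(0, r - r * cos(th)), y = c(0, r * sin(th)))
  recon_from(nodes)
}

# seeded random tree: each non-root node attaches to a uniformly chosen
# earlier node at a random offset
random_tree <- function(n = 200L, structure = "axon", seed = 1L) {
  set.seed(seed)
  x <- y <- z <- numeric(n)
  parent <- c(-1L, integer(n - 1L))
  for (i in 2:n) {
    p <- sample.int(i - 1L, 1L)
    parent[i] <- p
    step <- stats::rnorm(3, sd = 4)
    x[i] <- x[p] + step[1]; y[i] <- y[p] + step[2]; z[i] <- z[p] + step[3]
  }
  recon_from(nodes_df(id = seq_len(n), parent = parent,
                      structure = c("soma", rep(structure, n - 1L)),
                      x = x, y = y, z = z))
}

default_geom <- function() layer_geometry(pcl_top = 0, ml_top = 120)

# tiny feature table with named rows/columns
toy_table <- function(m, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("c%02d", seq_len(nrow(m)))
  rownames(m) <- ids
  if (is.null(colnames(m))) colnames(m) <- sprintf("f%d", seq_len(ncol(m)))
  feature_table(m)
}

euclid <- function(a, b) sqrt(sum((a - b)^2))
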