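#' Total cable length of a compartment
#'
#' Sum of Euclidean parent-child distances over all edges whose child node
#' carries the given structure label.
#'
#' @param recon a [neuron_reconstruction()].
#' @param compartment `"axon"`, `"dendrite"`, `"soma"` or `"unspecified"`.
#' @return Length in micrometres (0 for an empty compartment).
#' @export
total_length <- function(recon, compartment) {
  check_compartment(compartment)
  ix <- recon_index(recon)
  sel <- ix$structure == compartment & !is.na(ix$parent)
  sum(ix$edge_len[sel])
}

#' Sholl intersection counts
#'
#' Counts arbor crossings of concentric spheres centred on the soma
#' centroid. An edge crosses radius `r` when its two endpoint distances from
#' the centre straddle `r`; a process that exits and re-enters a sphere is
#' counted at each crossing.
#'
#' @param recon a [neuron_reconstruction()].
#' @param compartment compartment whose edges are counted.
#' @param radii strictly increasing positive radii (micrometres); defaults to
#'   the standard panel 10, 50, 100, 150, 200.
#' @return Integer vector of counts, named by radius.
#' @export
sholl_counts <- function(recon, compartment, radii = c(10, 50, 100, 150, 200)) {
  check_compartment(compartment)
  if (any(radii <= 0) || any(diff(radii) <= 0))
    stop("radii must be strictly increasing and > 0")
  ix <- recon_index(recon)
  center <- soma_centroid(recon)
  sel <- which(ix$structure == compartment & !is.na(ix$parent))
  out <- stats::setNames(integer(length(radii)), radii)
  if (!length(sel)) return(out)
  d_child <- sqrt(rowSums(sweep(ix$coords[sel, , drop = FALSE], 2L, center)^2))
  d_parent <- sqrt(rowSums(
    sweep(ix$coords[ix$parent[sel], , drop = FALSE], 2L, center)^2))
  lo <- pmin(d_child, d_parent)
  hi <- pmax(d_child, d_parent)
  for (j in seq_along(radii))
    out[j] <- sum(lo < radii[j] & hi >= radii[j])
  out
}

#' Branch level statistics
#'
#' The branch level of a branch segment is the number of branch points on
#' the path from the compartment attachment to that segment: the stem is
#' level 0, daughters of the first bifurcation are level 1, and so on.
#'
#' @inheritParams total_length
#' @return List with `mean` (over segments) and `max`; `(0, 0)` for an
#'   unbranched process, `(NA, NA)` for an empty compartment.
#' @export
branch_levels <- function(recon, compartment) {
  check_compartment(compartment)
  segs <- compartment_segments(recon_index(recon), compartment)
  if (!length(segs)) return(list(mean = NA_real_, max = NA_integer_))
  levels <- vapply(segs, `[[`, integer(1L), "level")
  list(mean = mean(levels), max = max(levels))
}

#' Arbor straightness
#'
#' Per branch segment, the ratio of Euclidean endpoint distance to geodesic
#' (path) length; 1 for a straight segment, 2/pi for a semicircular arc.
#' Segments are aggregated as a length-weighted mean by default (so the
#' aggregate equals total chord length over total path length);
#' `weighted = FALSE` switches to the unweighted mean over segments.
#'
#' @inheritParams total_length
#' @param weighted length-weight the per-segment ratios?
#' @return Ratio in (0, 1].
#' @export
straightness <- function(recon, compartment, weighted = TRUE) {
  check_compartment(compartment)
  segs <- compartment_segments(recon_index(recon), compartment)
  if (!length(segs)) stop("empty compartment: no segments to measure")
  lens <- vapply(segs, `[[`, numeric(1L), "length")
  chords <- vapply(segs, `[[`, numeric(1L), "chord")
  zero <- lens <= 0
  if (any(zero)) {
    warning("excluding ", sum(zero), " zero-length segment(s)")
    lens <- lens[!zero]
    chords <- chords[!zero]
  }
  if (!length(lens)) stop("no segments with positive length")
  if (weighted) sum(chords) / sum(lens) else mean(chords / lens)
}

#' Dendritic filopodia count and density
#'
#' Filopodia are terminal dendritic branch segments shorter than the
#' threshold (default 1.5 micrometres). Density normalizes the count to the
#' total dendritic cable length.
#'
#' @param recon a [neuron_reconstruction()].
#' @param threshold length threshold in micrometres; terminals strictly
#'   shorter qualify.
#' @return List with `count` and `density` (per micrometre).
#' @export
filopodia <- function(recon, threshold = 1.5) {
  segs <- compartment_segments(recon_index(recon), "dendrite")
  lens <- vapply(segs, `[[`, numeric(1L), "length")
  term <- vapply(segs, `[[`, logical(1L), "terminal")
  count <- sum(term & lens < threshold)
  dend_len <- sum(lens)
  if (dend_len <= 0) {
    if (count > 0) stop("undefined filopodia density: zero dendrite length")
    return(list(count = 0L, density = 0))
  }
  list(count = as.integer(count), density = count / dend_len)
}

#' Laminar spans of a compartment
#'
#' Coordinate extents (max minus min of node projections) of a compartment
#' along the molecular-layer normal axis (height of ML covered), the
#' tangential axis (span along the PCL) and the parallel-fibre axis
#' (z-depth).
#'
#' @inheritParams total_length
#' @param geom a [layer_geometry()].
#' @return Named list `ml_height_covered`, `tangential_span`, `z_depth`
#'   (micrometres). For an empty compartment all three are 0 and the result
#'   carries attribute `empty = TRUE`.
#' @export
spans <- function(recon, geom, compartment) {
  check_compartment(compartment)
  stopifnot(inherits(geom, "layer_geometry"))
  ix <- recon_index(recon)
  pts <- ix$coords[ix$structure == compartment, , drop = FALSE]
  if (nrow(pts) == 0L) {
    out <- list(ml_height_covered = 0, tangential_span = 0, z_depth = 0)
    attr(out, "empty") <- TRUE
    return(out)
  }
  ext <- function(axis) {
    p <- pts %*% axis
    max(p) - min(p)
  }
  list(ml_height_covered = ext(geom$normal),
       tangential_span = ext(geom$tangential),
       z_depth = ext(geom$z))
}

#' Classify oriented axon collaterals
#'
#' Identifies the main axon as the geodesically longest root-to-tip axonal
#' path, then classifies each side branch by the angle between its initial
#' direction and the local main-axon direction. Branches deviating by more
#' than `angle_threshold` degrees are classed as upward or downward by the
#' molecular-layer-normal component of their initial direction; shallower
#' branches are excluded, following the convention that only collaterals
#' clearly leaving the main shaft are counted. Directions are secants over
#' the first `probe` micrometres of arc (or the whole branch if shorter),
#' which makes the classification robust to node jitter.
#'
#' @param recon a [neuron_reconstruction()].
#' @param geom a [layer_geometry()].
#' @param angle_threshold inclusion threshold in degrees (default 30).
#' @param probe secant arc length in micrometres (default 5).
#' @return List with components `up` and `down`, each a list
#'   `count`, `total_length` (of the full collateral subtrees, micrometres)
#'   and `percent` (of total included collateral length).
#' @export
classify_collaterals <- function(recon, geom, angle_threshold = 30, probe = 5) {
  stopifnot(inherits(geom, "layer_geometry"))
  ix <- recon_index(recon)
  is_axon <- ix$structure == "axon"
  if (!any(is_axon)) stop("axonless cell: no axon nodes")
  main <- main_axon_path(ix)
  on_main <- logical(nrow(ix$nodes))
  on_main[main] <- TRUE
  main_pos <- stats::setNames(seq_along(main), main)

  res <- list(up = list(count = 0L, total_length = 0),
              down = list(count = 0L, total_length = 0))
  for (k in seq_along(main)) {
    m <- main[k]
    kids <- ix$children[[m]]
    side <- kids[is_axon[kids] & !on_main[kids]]
    for (c0 in side) {
      bdir <- branch_initial_direction(ix, m, c0, probe)
      # local shaft direction: forward along the main path from m
      fwd_chain <- main[k:length(main)]
      if (length(fwd_chain) < 2L) next  # attachment at path end; no local direction
      mdir <- point_along_chain(ix, fwd_chain, probe) - ix$coords[m, ]
      if (sqrt(sum(mdir^2)) == 0) next
      if (angle_deg(bdir, mdir) <= angle_threshold) next
      cls <- if (sum(bdir * geom$normal) >= 0) "up" else "down"
      sub <- compartment_subtree(ix, c0, "axon")
      sub_len <- sum(ix$edge_len[sub], na.rm = TRUE)  # includes edge m -> c0
      res[[cls]]$count <- res[[cls]]$count + 1L
      res[[cls]]$total_length <- res[[cls]]$total_length + sub_len
    }
  }
  tot <- res$up$total_length + res$down$total_length
  res$up$percent <- if (tot > 0) 100 * res$up$total_length / tot else 0
  res$down$percent <- if (tot > 0) 100 * res$down$total_length / tot else 0
  res
}

# Longest geodesic root-to-tip axonal path; returns node indices in order.
main_axon_path <- function(ix) {
  is_axon <- ix$structure == "axon"
  roots <- which(is_axon &
                   (is.na(ix$parent) | !is_axon[ix$parent]))
  if (!length(roots)) stop("axonless cell: no axon subtree root")
  best <- NULL
  best_dist <- -Inf
  for (r in roots) {
    dist <- stats::setNames(0, r)
    stack <- r
    dists <- numeric(nrow(ix$nodes))
    dists[r] <- 0
    visited <- r
    while (length(stack)) {
      cur <- stack[[1L]]; stack <- stack[-1L]
      kids <- ix$children[[cur]]
      kids <- kids[is_axon[kids]]
      for (kk in kids) {
        dists[kk] <- dists[cur] + ix$edge_len[kk]
        visited <- c(visited, kk)
        stack <- c(stack, kk)
      }
    }
    tips <- visited[vapply(visited, function(v) {
      kids <- ix$children[[v]]
      !any(is_axon[kids])
    }, logical(1L))]
    if (!length(tips)) tips <- r
    tip <- tips[which.max(dists[tips])]
    if (dists[tip] > best_dist) {
      best_dist <- dists[tip]
      # reconstruct path tip -> r via tree parents
      path <- tip
      while (path[1L] != r) path <- c(ix$parent[path[1L]], path)
      best <- path
    }
  }
  best
}

# Unit secant over the first min(probe, branch length) of arc from the
# attachment node m into the branch starting at child c0, following the
# chain until the first axonal branch point.
branch_initial_direction <- function(ix, m, c0, probe) {
  is_axon <- ix$structure == "axon"
  chain <- c(m, c0)
  cur <- c0
  arc <- ix$edge_len[c0]
  while (arc < probe) {
    kids <- ix$children[[cur]]
    kids <- kids[is_axon[kids]]
    if (length(kids) != 1L) break
    cur <- kids
    chain <- c(chain, cur)
    arc <- arc + ix$edge_len[cur]
  }
  unit_vec(point_along_chain(ix, chain, probe) - ix$coords[m, ])
}

#' Weighted basket score
#'
#' Purkinje-soma-targeting axon terminals are scored on a weighted scale:
#' full baskets that enwrap the soma and form pinceau structures weigh 1,
#' basket-like terminals that reach the soma base or axon initial segment
#' without pinceaux weigh 0.75, and terminals that only partially envelop
#' the soma weigh 0.5.
#'
#' @param counts named numeric vector (or list) with non-negative entries
#'   `full`, `basket_like`, `partial`.
#' @return The weighted sum.
#' @examples
#' weighted_basket_score(c(full = 2, basket_like = 0, partial = 1))  # 2.5
#' @export
weighted_basket_score <- function(counts) {
  counts <- unlist(counts)
  need <- c("full", "basket_like", "partial")
  if (!all(need %in% names(counts)))
    stop("counts needs entries full, basket_like, partial")
  counts <- counts[need]
  if (any(counts < 0)) stop("basket terminal counts must be >= 0")
  sum(counts * c(1, 0.75, 0.5))
}

#' Ellipsoid soma volume
#'
#' Approximates soma volume from three orthogonal diameters. The
#' `"as_printed"` mode uses V = 4/3 pi * dx * dy * dz, the formula employed
#' for the developmental dataset this package targets; the `"geometric"`
#' mode uses the mathematically standard ellipsoid volume
#' V = pi/6 * dx * dy * dz (semi-axes = diameters / 2). The two differ by a
#' constant factor of 8 and are interchangeable for any analysis that
#' standardizes features.
#'
#' @param dx,dy,dz positive diameters in micrometres.
#' @param formula `"as_printed"` (default) or `"geometric"`.
#' @return Volume in cubic micrometres.
#' @examples
#' soma_volume_ellipsoid(1, 1, 1)                        # 4*pi/3
#' soma_volume_ellipsoid(1, 1, 1, formula = "geometric") # pi/6
#' @export
soma_volume_ellipsoid <- function(dx, dy, dz,
                                  formula = c("as_printed", "geometric")) {
  formula <- match.arg(formula)
  if (any(c(dx, dy, dz) <= 0)) stop("diameters must be > 0")
  k <- if (formula == "as_printed") 4 / 3 * pi else pi / 6
  k * dx * dy * dz
}

#' Structural counts
#'
#' Counts of discrete structural attributes: the number of primary dendrites
#' (dendritic branches arising directly from the soma), the number of axon
#' tips reaching below the top of the Purkinje cell layer, and whether the
#' axon initial segment originates from a basal dendrite rather than the
#' soma (axon-carrying dendrite).
#'
#' @param recon a [neuron_reconstruction()].
#' @param geom a [layer_geometry()].
#' @return List `primary_dendrites`, `pcl_reaching_branches`,
#'   `axon_carrying_dendrite`.
#' @export
structural_counts <- function(recon, geom) {
  stopifnot(inherits(geom, "layer_geometry"))
  ix <- recon_index(recon)
  is_axon <- ix$structure == "axon"
  soma_nodes <- which(ix$structure == "soma")
  primary <- sum(vapply(soma_nodes, function(s)
    sum(ix$structure[ix$children[[s]]] == "dendrite"), integer(1L)))
  axon_tips <- which(is_axon & vapply(seq_along(ix$children), function(i)
    !any(is_axon[ix$children[[i]]]), logical(1L)))
  proj <- if (length(axon_tips))
    ix$coords[axon_tips, , drop = FALSE] %*% geom$normal else numeric(0)
  pcl_reaching <- sum(proj < geom$pcl_top)
  axon_roots <- which(is_axon & (is.na(ix$parent) | !is_axon[ix$parent]))
  acd <- any(!is.na(ix$parent[axon_roots]) &
               ix$structure[ix$parent[axon_roots]] == "dendrite")
  list(primary_dendrites = as.integer(primary),
       pcl_reaching_branches = as.integer(pcl_reaching),
       axon_carrying_dendrite = acd)
}
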