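# Internal tree machinery shared by the morphometric operations.
#
# Conventions: an edge belongs to the compartment of its CHILD node; the
# "compartment subgraph" of e.g. the axon is the set of axon-child edges.
# A branch segment is a maximal unbranched chain of compartment edges;
# segments start at compartment attachment points (nodes whose own incoming
# edge is outside the compartment) or at branch points (nodes with >= 2
# children inside the compartment).

recon_index <- function(recon) {
  nd <- recon$nodes
  n <- nrow(nd)
  idx_of <- stats::setNames(seq_len(n), nd$id)
  parent_idx <- ifelse(nd$parent == -1L, NA_integer_,
                       idx_of[as.character(nd$parent)])
  coords <- as.matrix(nd[, c("x", "y", "z")])
  elen <- rep(NA_real_, n)
  has_parent <- !is.na(parent_idx)
  elen[has_parent] <- sqrt(rowSums(
    (coords[has_parent, , drop = FALSE] -
       coords[parent_idx[has_parent], , drop = FALSE])^2))
  children <- vector("list", n)
  for (i in which(has_parent))
    children[[parent_idx[i]]] <- c(children[[parent_idx[i]]], i)
  list(nodes = nd, coords = coords, parent = parent_idx, edge_len = elen,
       children = children, structure = nd$structure)
}

check_compartment <- function(compartment) {
  if (!is.character(compartment) || length(compartment) != 1L ||
      !compartment %in% swc_structures())
    stop("unknown compartment: must be one of ",
         paste(swc_structures(), collapse = ", "))
  compartment
}

# Maximal unbranched chains of compartment edges. Returns a list of segments,
# each a list(nodes = node indices from start anchor to end, length, chord,
# terminal, level). Level = number of branch points on the path from the
# compartment attachment to the segment (counting the segment's own start
# anchor when it is a branch point).
compartment_segments <- function(ix, compartment) {
  in_comp <- ix$structure == compartment
  # out-degree within the compartment
  outdeg <- vapply(seq_along(ix$children), function(i)
    sum(in_comp[ix$children[[i]]]), integer(1L))
  # attachment anchors: parents of compartment edges whose own incoming edge
  # is not a compartment edge
  is_anchor_root <- outdeg > 0L &
    (!in_comp | is.na(ix$parent))
  segments <- list()
  walk <- function(anchor, level) {
    comp_children <- ix$children[[anchor]][in_comp[ix$children[[anchor]]]]
    child_level <- level + if (length(comp_children) >= 2L) 1L else 0L
    for (c0 in comp_children) {
      chain <- c(anchor, c0)
      cur <- c0
      while (outdeg[cur] == 1L) {
        nxt <- ix$children[[cur]][in_comp[ix$children[[cur]]]]
        chain <- c(chain, nxt)
        cur <- nxt
      }
      seg_len <- sum(ix$edge_len[chain[-1L]])
      chord <- sqrt(sum((ix$coords[cur, ] - ix$coords[anchor, ])^2))
      segments[[length(segments) + 1L]] <<- list(
        nodes = chain, length = seg_len, chord = chord,
        terminal = outdeg[cur] == 0L, level = child_level)
      if (outdeg[cur] >= 2L) walk(cur, child_level)
    }
  }
  for (a in which(is_anchor_root)) walk(a, 0L)
  segments
}

# All node indices reachable from `start` through compartment edges
# (including start).
compartment_subtree <- function(ix, start, compartment) {
  in_comp <- ix$structure == compartment
  acc <- integer(0)
  stack <- start
  while (length(stack)) {
    cur <- stack[[1L]]
    stack <- stack[-1L]
    acc <- c(acc, cur)
    kids <- ix$children[[cur]]
    stack <- c(stack, kids[in_comp[kids]])
  }
  acc
}

# Point `arc` micrometres along the polyline through node indices `chain`,
# clamped to the chain end.
point_along_chain <- function(ix, chain, arc) {
  if (length(chain) == 1L) return(ix$coords[chain, ])
  seg_lens <- ix$edge_len[chain[-1L]]
  cum <- cumsum(seg_lens)
  if (arc >= cum[length(cum)]) return(ix$coords[chain[length(chain)], ])
  j <- which(cum >= arc)[1L]
  lo <- if (j == 1L) 0 else cum[j - 1L]
  frac <- if (seg_lens[j] > 0) (arc - lo) / seg_lens[j] else 0
  p0 <- ix$coords[chain[j], ]
  p1 <- ix$coords[chain[j + 1L], ]
  p0 + frac * (p1 - p0)
}

unit_vec <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("zero-length direction vector")
  v / nv
}

angle_deg <- function(u, v) {
  d <- sum(unit_vec(u) * unit_vec(v))
  acos(max(-1, min(1, d))) * 180 / pi
}
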