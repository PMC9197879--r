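#' Single-neuron reconstruction
#'
#' A `neuron_reconstruction` is a validated rooted tree of 3-D sample points
#' (soma, dendrite, axon) in micrometres, the unit on which every morphometric
#' feature is computed. Nodes follow the SWC convention: each node has an
#' integer id, a parent id (`-1` for the root), a structure label, Cartesian
#' coordinates and a radius.
#'
#' @param cell_id character scalar identifying the cell.
#' @param nodes data frame with columns `id`, `parent`, `structure`
#'   (one of `"soma"`, `"axon"`, `"dendrite"`, `"unspecified"`), `x`, `y`,
#'   `z` (micrometres) and `radius` (micrometres, non-negative).
#' @param annotations optional named list of per-cell annotations (see
#'   [annotation_record()]).
#'
#' @return An object of class `neuron_reconstruction`: a list with elements
#'   `cell_id`, `nodes` and `annotations`.
#'
#' @details Validation enforces the tree invariants: exactly one root, every
#'   parent id declared (in any position, forward references included), no
#'   cycles, at least one soma node, finite coordinates and non-negative
#'   radii. Node order is preserved as given.
#'
#' @examples
#' nodes <- data.frame(
#'   id = 1:3, parent = c(-1L, 1L, 1L),
#'   structure = c("soma", "dendrite", "axon"),
#'   x = c(0, 0, 10), y = c(0, 10, 0), z = 0, radius = c(4, 0.5, 0.4)
#' )
#' rec <- neuron_reconstruction("cell01", nodes)
#' rec
#' @seealso [read_swc()], [write_swc()], [extract_features()]
#' @export
neuron_reconstruction <- function(cell_id, nodes, annotations = list()) {
  stopifnot(is.character(cell_id), length(cell_id) == 1L)
  required <- c("id", "parent", "structure", "x", "y", "z", "radius")
  missing_cols <- setdiff(required, names(nodes))
  if (length(missing_cols))
    stop("nodes is missing column(s): ", paste(missing_cols, collapse = ", "))
  nodes <- as.data.frame(nodes)[required]
  nodes$id <- as.integer(nodes$id)
  nodes$parent <- as.integer(nodes$parent)
  nodes$structure <- as.character(nodes$structure)

  bad <- setdiff(unique(nodes$structure), swc_structures())
  if (length(bad))
    stop("unknown structure label(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(nodes$id))
    stop("duplicate node id(s): ",
         paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
  coords <- as.matrix(nodes[, c("x", "y", "z")])
  if (!all(is.finite(coords)))
    stop("non-finite coordinates in node(s): ",
         paste(nodes$id[!apply(is.finite(coords), 1L, all)], collapse = ", "))
  if (any(!is.finite(nodes$radius) | nodes$radius < 0))
    stop("radius must be finite and >= 0")

  roots <- nodes$id[nodes$parent == -1L]
  if (length(roots) == 0L)
    stop("no root node (parent -1) found")
  if (length(roots) > 1L)
    stop("multiple roots found (ids ", paste(roots, collapse = ", "),
         "): reconstruction must be a single tree")
  nonroot <- nodes[nodes$parent != -1L, ]
  undeclared <- setdiff(nonroot$parent, nodes$id)
  if (length(undeclared)) {
    offender <- nonroot$id[match(undeclared[1L], nonroot$parent)]
    stop("malformed reconstruction: node ", offender,
         " references undeclared parent ", undeclared[1L])
  }
  # acyclicity: walk each node to the root, bounded by n steps
  parent_of <- stats::setNames(nodes$parent, nodes$id)
  n <- nrow(nodes)
  for (id in nodes$id) {
    cur <- id
    steps <- 0L
    while (parent_of[[as.character(cur)]] != -1L) {
      cur <- parent_of[[as.character(cur)]]
      steps <- steps + 1L
      if (steps > n)
        stop("cycle detected involving node ", id)
    }
  }
  if (!any(nodes$structure == "soma"))
    stop("missing soma: reconstruction has no soma node")

  structure(
    list(cell_id = cell_id, nodes = nodes, annotations = annotations),
    class = "neuron_reconstruction"
  )
}

swc_structures <- function() c("soma", "axon", "dendrite", "unspecified")

# SWC integer type codes (NeuroMorpho convention); everything else is
# "unspecified" on read and written back as 0.
swc_code_to_structure <- function(code) {
  out <- rep("unspecified", length(code))
  out[code == 1] <- "soma"
  out[code == 2] <- "axon"
  out[code == 3] <- "dendrite"
  out
}

swc_structure_to_code <- function(structure) {
  unname(c(soma = 1L, axon = 2L, dendrite = 3L, unspecified = 0L)[structure])
}

#' @export
print.neuron_reconstruction <- function(x, ...) {
  tab <- table(factor(x$nodes$structure, levels = swc_structures()))
  cat("Neuron reconstruction '", x$cell_id, "': ", nrow(x$nodes),
      " nodes (", paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Per-cell annotation record
#'
#' Annotations carry per-cell information that is measured outside the
#' reconstruction itself: the birthdate-inferred fate cohort (tamoxifen at P0
#' marks early-born, basket-fated cells; P4-P7 marks late-born,
#' stellate-fated cells), the expert maturation stage (1-4), days post
#' injection, folium of origin, the curated morphological class, and counts
#' of Purkinje-soma-targeting axon terminals by category (used by
#' [weighted_basket_score()]).
#'
#' @param fate_label one of `"BC_fated"`, `"SC_fated"`, `"unknown"`.
#' @param expert_stage integer maturation stage in 1..4, or `NA`.
#' @param dpi days post tamoxifen injection, or `NA`.
#' @param folium folium label, or `NA`.
#' @param curated_class one of `"canonical_BC"`, `"canonical_SC"`,
#'   `"non_canonical"`, `"unassigned"`.
#' @param basket_terminal_counts named numeric vector with non-negative
#'   entries `full`, `basket_like`, `partial`.
#' @return A named list of class `annotation_record`.
#' @examples
#' annotation_record(fate_label = "BC_fated", expert_stage = 2, dpi = 10)
#' @export
annotation_record <- function(fate_label = "unknown",
                              expert_stage = NA_integer_,
                              dpi = NA_real_,
                              folium = NA_character_,
                              curated_class = "unassigned",
                              basket_terminal_counts = c(full = 0, basket_like = 0, partial = 0)) {
  fate_label <- match.arg(fate_label, c("BC_fated", "SC_fated", "unknown"))
  curated_class <- match.arg(
    curated_class, c("canonical_BC", "canonical_SC", "non_canonical", "unassigned"))
  if (!is.na(expert_stage)) {
    expert_stage <- as.integer(expert_stage)
    if (!expert_stage %in% 1:4) stop("expert_stage must be in 1..4")
  }
  btc <- basket_terminal_counts
  if (!all(c("full", "basket_like", "partial") %in% names(btc)))
    stop("basket_terminal_counts needs entries full, basket_like, partial")
  if (any(btc < 0)) stop("basket terminal counts must be >= 0")
  structure(
    list(fate_label = fate_label, expert_stage = expert_stage, dpi = dpi,
         folium = folium, curated_class = curated_class,
         basket_terminal_counts = btc[c("full", "basket_like", "partial")]),
    class = "annotation_record"
  )
}

#' Read a neuron reconstruction from an SWC file
#'
#' Parses the SWC interchange dialect used by NeuroMorpho.Org: whitespace
#' separated columns `id type x y z radius parent`, `#` comment lines,
#' 1-based node ids and parent `-1` for the root. Structure type codes map
#' 1 to soma, 2 to axon, 3 to dendrite; any other code becomes
#' `"unspecified"`.
#'
#' @param path path to an SWC file.
#' @param cell_id cell identifier; defaults to the file name without
#'   extension.
#' @return A [neuron_reconstruction()].
#' @examples
#' f <- tempfile(fileext = ".swc")
#' writeLines(c("# toy", "1 1 0 0 0 4 -1", "2 3 0 10 0 0.5 1",
#'              "3 2 10 0 0 0.4 1"), f)
#' read_swc(f)
#' @export
read_swc <- function(path, cell_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(cell_id))
    cell_id <- sub("\\.[sS][wW][cC]$", "", basename(path))
  raw <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", raw))
  if (!length(keep)) stop("no data lines in SWC file: ", path)
  fields <- strsplit(trimws(raw[keep]), "\\s+")
  n_fields <- lengths(fields)
  if (any(n_fields != 7L))
    stop("parse error in ", path, " at line ", keep[which(n_fields != 7L)[1L]],
         ": expected 7 whitespace-separated fields")
  m <- suppressWarnings(matrix(as.numeric(unlist(fields)), ncol = 7L, byrow = TRUE))
  if (anyNA(m)) {
    bad_row <- which(apply(is.na(m), 1L, any))[1L]
    stop("parse error in ", path, " at line ", keep[bad_row],
         ": non-numeric field")
  }
  nodes <- data.frame(
    id = as.integer(m[, 1L]),
    parent = as.integer(m[, 7L]),
    structure = swc_code_to_structure(m[, 2L]),
    x = m[, 3L], y = m[, 4L], z = m[, 5L],
    radius = m[, 6L]
  )
  neuron_reconstruction(cell_id, nodes)
}

#' Write a neuron reconstruction to an SWC file
#'
#' Emits the canonical column order `id type x y z radius parent`, one node
#' per line in stored node order, with a single header comment. Output is
#' deterministic for a given reconstruction; coordinates and radii are
#' printed with enough digits to round-trip through [read_swc()] losslessly.
#'
#' @param recon a [neuron_reconstruction()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(recon, path) {
  stopifnot(inherits(recon, "neuron_reconstruction"))
  nd <- recon$nodes
  lines <- c(
    paste0("# SWC export of cell ", recon$cell_id),
    sprintf("%d %d %s %s %s %s %d",
            nd$id, swc_structure_to_code(nd$structure),
            format(nd$x, digits = 15, trim = TRUE, scientific = FALSE),
            format(nd$y, digits = 15, trim = TRUE, scientific = FALSE),
            format(nd$z, digits = 15, trim = TRUE, scientific = FALSE),
            format(nd$radius, digits = 15, trim = TRUE, scientific = FALSE),
            nd$parent)
  )
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write SWC file: ", path)
  invisible(path)
}
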