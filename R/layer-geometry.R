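#' Molecular-layer coordinate frame
#'
#' Laminar features (soma height, relative molecular-layer position, spans,
#' collateral orientation) are measured in a per-section coordinate frame:
#' `normal` points from the Purkinje cell layer (PCL) towards the pial
#' surface, `tangential` runs along the PCL in the sagittal plane, and `z`
#' follows the parallel fibres. `pcl_top` and `ml_top` are the positions of
#' the top of the PCL and the top of the molecular layer (ML) along the
#' normal axis, so the ML thickness is `ml_top - pcl_top`.
#'
#' The default frame is the image frame of a sagittal section: normal `+y`,
#' tangential `+x`, parallel fibres `+z`.
#'
#' @param pcl_top,ml_top positions (micrometres) of the PCL top and ML top on
#'   the normal axis; `ml_top` must exceed `pcl_top`.
#' @param normal,tangential,z the three axes; they must be mutually
#'   orthogonal unit vectors (checked to 1e-8).
#' @return An object of class `layer_geometry`.
#' @examples
#' geom <- layer_geometry(pcl_top = 0, ml_top = 120)
#' geom
#' @export
layer_geometry <- function(pcl_top, ml_top,
                           normal = c(0, 1, 0),
                           tangential = c(1, 0, 0),
                           z = c(0, 0, 1)) {
  stopifnot(is.numeric(pcl_top), is.numeric(ml_top))
  if (!(ml_top > pcl_top)) stop("ml_top must be greater than pcl_top")
  axes <- rbind(normal, tangential, z)
  if (ncol(axes) != 3L) stop("axes must be length-3 vectors")
  gram <- axes %*% t(axes)
  if (max(abs(gram - diag(3))) > 1e-8)
    stop("normal, tangential and z must be mutually orthogonal unit vectors")
  structure(
    list(pcl_top = as.numeric(pcl_top), ml_top = as.numeric(ml_top),
         normal = as.numeric(normal), tangential = as.numeric(tangential),
         z = as.numeric(z)),
    class = "layer_geometry"
  )
}

#' @export
print.layer_geometry <- function(x, ...) {
  cat("Molecular-layer geometry: PCL top ", x$pcl_top, ", ML top ", x$ml_top,
      " (thickness ", x$ml_top - x$pcl_top, " um)\n", sep = "")
  invisible(x)
}

#' Read per-section layer geometry from a YAML file
#'
#' The file holds scalar fields `pcl_top` and `ml_top` and optional 3-vector
#' fields `normal`, `tangential`, `z` (defaulting to the sagittal image
#' frame).
#'
#' @param path path to a YAML file.
#' @return A [layer_geometry()].
#' @export
read_layer_geometry <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y$pcl_top) || is.null(y$ml_top))
    stop("layer geometry YAML needs pcl_top and ml_top")
  args <- list(pcl_top = y$pcl_top, ml_top = y$ml_top)
  for (ax in c("normal", "tangential", "z"))
    if (!is.null(y[[ax]])) args[[ax]] <- as.numeric(y[[ax]])
  do.call(layer_geometry, args)
}

#' Write layer geometry to YAML
#'
#' @param geom a [layer_geometry()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_layer_geometry <- function(geom, path) {
  stopifnot(inherits(geom, "layer_geometry"))
  yaml::write_yaml(unclass(geom), path)
  invisible(path)
}

# Soma centroid: unweighted mean of soma node coordinates. Accepts both
# single-point and contour-style soma representations.
soma_centroid <- function(recon) {
  nd <- recon$nodes
  soma <- nd[nd$structure == "soma", c("x", "y", "z"), drop = FALSE]
  if (nrow(soma) == 0L) stop("missing soma: reconstruction has no soma node")
  colMeans(as.matrix(soma))
}

#' Soma height above the Purkinje cell layer
#'
#' The distance from the top of the PCL to the centre of the soma, measured
#' along the molecular-layer normal axis. Multi-point somas are reduced to
#' their unweighted centroid.
#'
#' @param recon a [neuron_reconstruction()].
#' @param geom a [layer_geometry()].
#' @return Soma height in micrometres (negative if the soma centroid lies
#'   below the PCL top).
#' @examples
#' nodes <- data.frame(id = 1:2, parent = c(-1L, 1L),
#'                     structure = c("soma", "dendrite"),
#'                     x = 0, y = c(30, 60), z = 0, radius = c(4, .5))
#' rec <- neuron_reconstruction("c1", nodes)
#' soma_height(rec, layer_geometry(0, 120))  # 30
#' @export
soma_height <- function(recon, geom) {
  stopifnot(inherits(geom, "layer_geometry"))
  sum(soma_centroid(recon) * geom$normal) - geom$pcl_top
}

#' Relative laminar position within the molecular layer
#'
#' Soma height divided by molecular-layer thickness: 0 at the PCL top, 1 at
#' the ML top.
#'
#' @param soma_h soma height in micrometres (see [soma_height()]).
#' @param geom a [layer_geometry()].
#' @return Dimensionless ratio.
#' @export
relative_ml_position <- function(soma_h, geom) {
  stopifnot(inherits(geom, "layer_geometry"))
  thickness <- geom$ml_top - geom$pcl_top
  if (!(thickness > 0)) stop("ML thickness must be positive")
  soma_h / thickness
}
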