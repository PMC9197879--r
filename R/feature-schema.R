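#' Morphometric feature schemas
#'
#' A feature schema declares an ordered panel of named features, the
#' compartment each describes, whether it is computed from the
#' reconstruction or passed through from annotations, and which subset is
#' used for clustering. Three presets are provided:
#'
#' * `"mature_27"` - the 27-feature panel describing dendrites, axon, soma
#'   and location of mature cells;
#' * `"developmental_28"` - the 28-feature axon/soma/location panel for
#'   developmental snapshots;
#' * `"clustering_19"` - the 19-feature clustering subset of the mature
#'   panel, which compiles the soma-targeting terminal information into the
#'   single weighted basket score to avoid over-weighting basket features.
#'
#' The preset memberships are a documented, editable default (the
#' field-standard panels vary between studies); build a custom schema by
#' passing your own `features` data frame.
#'
#' @param preset one of `"mature_27"`, `"developmental_28"`,
#'   `"clustering_19"`, or `"custom"`.
#' @param features for `preset = "custom"`, a data frame with columns
#'   `name`, `compartment` (`"axon"`, `"dendrite"`, `"soma"`, `"location"`),
#'   `units`, `source` (`"computed"` or `"annotated"`).
#' @param clustering_subset character vector of feature names used for
#'   clustering; defaults to all features.
#' @param name schema name (defaults to the preset).
#' @return An object of class `feature_schema`.
#' @examples
#' feature_schema("developmental_28")
#' @export
feature_schema <- function(preset = c("mature_27", "developmental_28",
                                      "clustering_19", "custom"),
                           features = NULL, clustering_subset = NULL,
                           name = NULL) {
  preset <- match.arg(preset)
  if (preset != "custom") {
    features <- schema_preset_features(preset)
    if (is.null(clustering_subset))
      clustering_subset <- schema_preset_subset(preset, features$name)
  }
  if (is.null(features)) stop("custom schema needs a features data frame")
  features <- as.data.frame(features)
  stopifnot(all(c("name", "compartment", "units", "source") %in% names(features)))
  if (anyDuplicated(features$name))
    stop("duplicate feature names in schema")
  if (!all(features$compartment %in% c("axon", "dendrite", "soma", "location")))
    stop("compartment must be axon, dendrite, soma or location")
  if (!all(features$source %in% c("computed", "annotated")))
    stop("source must be computed or annotated")
  if (is.null(clustering_subset)) clustering_subset <- features$name
  if (!all(clustering_subset %in% features$name))
    stop("clustering_subset must be a subset of schema features")
  structure(list(name = if (is.null(name)) preset else name,
                 features = features,
                 clustering_subset = clustering_subset),
            class = "feature_schema")
}

schema_row <- function(name, compartment, units, source = "computed") {
  data.frame(name = name, compartment = compartment, units = units,
             source = source, stringsAsFactors = FALSE)
}

schema_preset_features <- function(preset) {
  axon_core <- rbind(
    schema_row("axon_length", "axon", "um"),
    schema_row("axon_straightness", "axon", "ratio"),
    schema_row("axon_mean_branch_level", "axon", "count"),
    schema_row("axon_sholl_10", "axon", "count"),
    schema_row("axon_sholl_50", "axon", "count"),
    schema_row("axon_sholl_100", "axon", "count"),
    schema_row("axon_sholl_150", "axon", "count"),
    schema_row("axon_sholl_200", "axon", "count"),
    schema_row("axon_ml_height", "axon", "um"),
    schema_row("axon_tangential_span", "axon", "um"),
    schema_row("axon_z_depth", "axon", "um"),
    schema_row("collateral_up_count", "axon", "count"),
    schema_row("collateral_up_length", "axon", "um"),
    schema_row("collateral_up_percent", "axon", "percent"),
    schema_row("collateral_down_count", "axon", "count"),
    schema_row("collateral_down_length", "axon", "um"),
    schema_row("collateral_down_percent", "axon", "percent")
  )
  if (preset %in% c("mature_27", "clustering_19")) {
    rbind(
      schema_row("dendrite_length", "dendrite", "um"),
      schema_row("dendrite_mean_branch_level", "dendrite", "count"),
      schema_row("filopodia_count", "dendrite", "count"),
      schema_row("filopodia_density", "dendrite", "per_um"),
      schema_row("primary_dendrites", "dendrite", "count"),
      schema_row("dendrite_ml_height", "dendrite", "um"),
      schema_row("axon_carrying_dendrite", "dendrite", "boolean"),
      axon_core,
      schema_row("weighted_basket_score", "axon", "score", "annotated"),
      schema_row("soma_volume", "soma", "um3", "annotated"),
      schema_row("relative_ml_position", "location", "ratio")
    )
  } else {
    rbind(
      axon_core,
      schema_row("axon_max_branch_level", "axon", "count"),
      schema_row("axon_segment_count", "axon", "count"),
      schema_row("axon_terminal_count", "axon", "count"),
      schema_row("pcl_reaching_branches", "axon", "count"),
      schema_row("primary_dendrites", "dendrite", "count"),
      schema_row("soma_x_diameter", "soma", "um", "annotated"),
      schema_row("soma_y_diameter", "soma", "um", "annotated"),
      schema_row("soma_z_diameter", "soma", "um", "annotated"),
      schema_row("soma_volume_ellipsoid", "soma", "um3", "annotated"),
      schema_row("soma_height", "location", "um"),
      schema_row("relative_ml_position", "location", "ratio")
    )
  }
}

schema_preset_subset <- function(preset, all_names) {
  if (preset == "clustering_19") {
    c("dendrite_length", "dendrite_mean_branch_level", "filopodia_count",
      "filopodia_density", "primary_dendrites", "dendrite_ml_height",
      "axon_length", "axon_straightness", "axon_mean_branch_level",
      "axon_sholl_50", "axon_sholl_100", "axon_sholl_150",
      "axon_ml_height", "axon_tangential_span", "axon_z_depth",
      "collateral_up_percent", "collateral_down_percent",
      "weighted_basket_score", "relative_ml_position")
  } else {
    all_names
  }
}

#' @export
print.feature_schema <- function(x, ...) {
  cat("Feature schema '", x$name, "': ", nrow(x$features), " features (",
      length(x$clustering_subset), " in clustering subset)\n", sep = "")
  tab <- table(x$features$compartment)
  cat("  ", paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Read or write a feature schema as YAML
#'
#' @param path YAML file path.
#' @return For `read_feature_schema`, a [feature_schema()]; for
#'   `write_feature_schema`, `path` invisibly.
#' @export
read_feature_schema <- function(path) {
  y <- yaml::read_yaml(path)
  feats <- do.call(rbind, lapply(y$features, function(f)
    schema_row(f$name, f$compartment, f$units,
               if (is.null(f$source)) "computed" else f$source)))
  feature_schema("custom", features = feats,
                 clustering_subset = unlist(y$clustering_subset),
                 name = y$name)
}

#' @rdname read_feature_schema
#' @param schema a [feature_schema()].
#' @export
write_feature_schema <- function(schema, path) {
  stopifnot(inherits(schema, "feature_schema"))
  y <- list(
    name = schema$name,
    features = lapply(seq_len(nrow(schema$features)), function(i)
      as.list(schema$features[i, ])),
    clustering_subset = as.list(schema$clustering_subset)
  )
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Extract a morphometric feature vector
#'
#' Computes every feature declared by the schema from a reconstruction and
#' its layer geometry. Annotated features (soma diameters, rendered soma
#' volume, the weighted basket score) are passed through from the cell's
#' annotations with provenance `"annotated"`; computed features on an empty
#' compartment come back `NA` with provenance `"missing"`.
#'
#' @param recon a [neuron_reconstruction()].
#' @param geom a [layer_geometry()].
#' @param schema a [feature_schema()].
#' @param sholl_radii,filopodia_threshold,collateral_angle configuration of
#'   the underlying operations (defaults: 10/50/100/150/200 um, 1.5 um,
#'   30 degrees).
#' @return Named numeric vector of class `feature_vector` with attributes
#'   `cell_id` and `provenance` (`"computed"`, `"annotated"` or
#'   `"missing"` per feature). Boolean features are encoded 0/1.
#' @seealso [simulate_swc()] for fixtures with analytically known values.
#' @export
extract_features <- function(recon, geom, schema = feature_schema("mature_27"),
                             sholl_radii = c(10, 50, 100, 150, 200),
                             filopodia_threshold = 1.5,
                             collateral_angle = 30) {
  stopifnot(inherits(recon, "neuron_reconstruction"),
            inherits(geom, "layer_geometry"),
            inherits(schema, "feature_schema"))
  ix <- recon_index(recon)
  has <- function(comp) any(ix$structure == comp)
  ann <- recon$annotations

  # shared intermediate results, computed once
  cache <- new.env(parent = emptyenv())
  get_cached <- function(key, fn) {
    if (!exists(key, envir = cache)) assign(key, fn(), envir = cache)
    get(key, envir = cache)
  }
  axon_sholl <- function() sholl_counts(recon, "axon", sholl_radii)
  coll <- function() classify_collaterals(recon, geom,
                                          angle_threshold = collateral_angle)
  axon_bl <- function() branch_levels(recon, "axon")
  dend_bl <- function() branch_levels(recon, "dendrite")
  filo <- function() filopodia(recon, filopodia_threshold)
  struct <- function() structural_counts(recon, geom)
  axon_segs <- function() compartment_segments(ix, "axon")

  compute_one <- function(name) {
    switch(
      name,
      axon_length = total_length(recon, "axon"),
      dendrite_length = total_length(recon, "dendrite"),
      axon_straightness = straightness(recon, "axon"),
      axon_mean_branch_level = get_cached("abl", axon_bl)$mean,
      axon_max_branch_level = get_cached("abl", axon_bl)$max,
      dendrite_mean_branch_level = get_cached("dbl", dend_bl)$mean,
      axon_sholl_10 = get_cached("sholl", axon_sholl)[["10"]],
      axon_sholl_50 = get_cached("sholl", axon_sholl)[["50"]],
      axon_sholl_100 = get_cached("sholl", axon_sholl)[["100"]],
      axon_sholl_150 = get_cached("sholl", axon_sholl)[["150"]],
      axon_sholl_200 = get_cached("sholl", axon_sholl)[["200"]],
      axon_ml_height = spans(recon, geom, "axon")$ml_height_covered,
      axon_tangential_span = spans(recon, geom, "axon")$tangential_span,
      axon_z_depth = spans(recon, geom, "axon")$z_depth,
      dendrite_ml_height = spans(recon, geom, "dendrite")$ml_height_covered,
      collateral_up_count = get_cached("coll", coll)$up$count,
      collateral_up_length = get_cached("coll", coll)$up$total_length,
      collateral_up_percent = get_cached("coll", coll)$up$percent,
      collateral_down_count = get_cached("coll", coll)$down$count,
      collateral_down_length = get_cached("coll", coll)$down$total_length,
      collateral_down_percent = get_cached("coll", coll)$down$percent,
      filopodia_count = get_cached("filo", filo)$count,
      filopodia_density = get_cached("filo", filo)$density,
      primary_dendrites = get_cached("struct", struct)$primary_dendrites,
      pcl_reaching_branches = get_cached("struct", struct)$pcl_reaching_branches,
      axon_carrying_dendrite =
        as.numeric(get_cached("struct", struct)$axon_carrying_dendrite),
      axon_segment_count = length(get_cached("asegs", axon_segs)),
      axon_terminal_count = sum(vapply(get_cached("asegs", axon_segs),
                                       `[[`, logical(1L), "terminal")),
      soma_height = soma_height(recon, geom),
      relative_ml_position = relative_ml_position(soma_height(recon, geom), geom),
      stop("no rule to compute feature '", name, "'")
    )
  }

  feature_compartment_present <- function(comp) {
    switch(comp,
           axon = has("axon"), dendrite = has("dendrite"),
           soma = has("soma"), location = has("soma"))
  }

  annotated_value <- function(name) {
    val <- switch(
      name,
      weighted_basket_score =
        if (!is.null(ann$basket_terminal_counts))
          weighted_basket_score(ann$basket_terminal_counts) else NULL,
      soma_volume = ann$soma_volume,
      soma_x_diameter = ann$soma_diameters[["x"]],
      soma_y_diameter = ann$soma_diameters[["y"]],
      soma_z_diameter = ann$soma_diameters[["z"]],
      soma_volume_ellipsoid =
        if (!is.null(ann$soma_diameters))
          soma_volume_ellipsoid(ann$soma_diameters[["x"]],
                                ann$soma_diameters[["y"]],
                                ann$soma_diameters[["z"]]) else NULL,
      ann[[name]]
    )
    if (is.null(val))
      stop("missing required annotation for feature '", name, "'")
    as.numeric(val)
  }

  nms <- schema$features$name
  values <- numeric(length(nms))
  provenance <- character(length(nms))
  for (i in seq_along(nms)) {
    row <- schema$features[i, ]
    if (row$source == "annotated") {
      values[i] <- annotated_value(row$name)
      provenance[i] <- "annotated"
    } else if (!feature_compartment_present(row$compartment)) {
      values[i] <- NA_real_
      provenance[i] <- "missing"
    } else {
      values[i] <- as.numeric(compute_one(row$name))
      provenance[i] <- "computed"
    }
  }
  structure(stats::setNames(values, nms), cell_id = recon$cell_id,
            provenance = stats::setNames(provenance, nms),
            class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat("Feature vector for cell '", attr(x, "cell_id"), "' (",
      length(x), " features)\n", sep = "")
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Compile feature vectors into a feature table
#'
#' @param recons list of [neuron_reconstruction()]s.
#' @param geom a single [layer_geometry()] shared by all cells, or a list of
#'   geometries parallel to `recons`.
#' @param schema a [feature_schema()].
#' @param ... passed to [extract_features()].
#' @return A [feature_table()] with one row per reconstruction; fate labels
#'   and stages present in the annotations are carried into metadata.
#' @export
compile_feature_table <- function(recons, geom,
                                  schema = feature_schema("mature_27"), ...) {
  geoms <- if (inherits(geom, "layer_geometry"))
    rep(list(geom), length(recons)) else geom
  stopifnot(length(geoms) == length(recons))
  vecs <- mapply(function(r, g) extract_features(r, g, schema, ...),
                 recons, geoms, SIMPLIFY = FALSE)
  m <- do.call(rbind, lapply(vecs, as.numeric))
  colnames(m) <- schema$features$name
  rownames(m) <- vapply(recons, `[[`, character(1L), "cell_id")
  md <- data.frame(cell_id = rownames(m), stringsAsFactors = FALSE)
  for (field in c("fate_label", "expert_stage", "dpi", "folium", "curated_class")) {
    vals <- lapply(recons, function(r) {
      v <- r$annotations[[field]]
      if (is.null(v)) NA else v
    })
    if (!all(is.na(unlist(vals)))) md[[field]] <- unlist(vals)
  }
  feature_table(m, md)
}
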