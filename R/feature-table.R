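#' Cells-by-features morphometric table
#'
#' The substrate for clustering and pseudotime: a numeric matrix of named
#' morphometric features (rows = cells) together with per-cell metadata.
#' Metadata columns use the reserved names `cell_id`, `fate_label`,
#' `expert_stage`, `dpi`, `folium`, `curated_class`; any further metadata
#' columns can be declared via `extra_metadata`.
#'
#' @param features numeric matrix (or data frame) of feature values, one row
#'   per cell; row names (or a metadata `cell_id`) identify cells.
#' @param metadata data frame of per-cell metadata with a `cell_id` column;
#'   defaults to just the cell ids.
#' @return An object of class `feature_table` with elements `features`
#'   (numeric matrix with cell-id row names) and `metadata` (data frame).
#' @examples
#' m <- matrix(rnorm(6), 2, 3,
#'             dimnames = list(c("a", "b"), c("f1", "f2", "f3")))
#' ft <- feature_table(m)
#' ft
#' @export
feature_table <- function(features, metadata = NULL) {
  features <- as.matrix(features)
  if (!is.numeric(features)) stop("features must be numeric")
  if (is.null(rownames(features))) {
    if (!is.null(metadata) && !is.null(metadata$cell_id))
      rownames(features) <- as.character(metadata$cell_id)
    else
      rownames(features) <- sprintf("cell%03d", seq_len(nrow(features)))
  }
  if (is.null(colnames(features)))
    stop("features must have column (feature) names")
  if (anyDuplicated(rownames(features)))
    stop("duplicate cell_id: ",
         paste(unique(rownames(features)[duplicated(rownames(features))]),
               collapse = ", "))
  if (is.null(metadata))
    metadata <- data.frame(cell_id = rownames(features),
                           stringsAsFactors = FALSE)
  metadata <- as.data.frame(metadata)
  if (is.null(metadata$cell_id)) metadata$cell_id <- rownames(features)
  metadata$cell_id <- as.character(metadata$cell_id)
  if (nrow(metadata) != nrow(features) ||
      !identical(metadata$cell_id, rownames(features)))
    stop("metadata rows must match feature rows (by cell_id, same order)")
  structure(list(features = features, metadata = metadata),
            class = "feature_table")
}

reserved_metadata_cols <- function() {
  c("cell_id", "fate_label", "expert_stage", "dpi", "folium", "curated_class")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("Feature table: ", nrow(x$features), " cells x ", ncol(x$features),
      " features\n", sep = "")
  cat("  features: ",
      paste(utils::head(colnames(x$features), 6L), collapse = ", "),
      if (ncol(x$features) > 6L) ", ..." else "", "\n", sep = "")
  meta <- setdiff(names(x$metadata), "cell_id")
  if (length(meta))
    cat("  metadata: ", paste(meta, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$features)

#' @export
as.data.frame.feature_table <- function(x, ...) {
  cbind(x$metadata, as.data.frame(x$features))
}

#' Subset a feature table
#'
#' @param x a [feature_table()].
#' @param cells cell selector (indices, ids or logical).
#' @param features feature selector (indices, names or logical).
#' @return A [feature_table()] restricted to the selection.
#' @export
ft_subset <- function(x, cells = NULL, features = NULL) {
  stopifnot(inherits(x, "feature_table"))
  f <- x$features
  md <- x$metadata
  if (!is.null(cells)) {
    if (is.character(cells)) cells <- match(cells, rownames(f))
    f <- f[cells, , drop = FALSE]
    md <- md[cells, , drop = FALSE]
  }
  if (!is.null(features)) f <- f[, features, drop = FALSE]
  feature_table(f, md)
}

#' Read a feature table from delimited text
#'
#' One row per cell; reserved column names (`cell_id`, `fate_label`,
#' `expert_stage`, `dpi`, `folium`, `curated_class`, plus any in
#' `extra_metadata`) are split into metadata, all remaining columns are
#' parsed as numeric features.
#'
#' @param path path to a CSV (default) or TSV file with a header row.
#' @param sep field separator; `","` or `"\t"`.
#' @param extra_metadata further column names to treat as metadata.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, sep = ",", extra_metadata = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (is.null(df$cell_id))
    stop("schema error: feature table has no cell_id column")
  if (anyDuplicated(df$cell_id))
    stop("duplicate cell_id: ",
         paste(unique(df$cell_id[duplicated(df$cell_id)]), collapse = ", "))
  meta_cols <- intersect(names(df), c(reserved_metadata_cols(), extra_metadata))
  feat_cols <- setdiff(names(df), meta_cols)
  if (!length(feat_cols)) stop("no feature columns found")
  feats <- df[feat_cols]
  for (cn in feat_cols) {
    v <- feats[[cn]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v) & v != "NA")
      if (length(bad))
        stop("non-numeric feature value at row ", bad[1L],
             " (cell ", df$cell_id[bad[1L]], "), column '", cn, "'")
      feats[[cn]] <- vn
    }
  }
  m <- as.matrix(feats)
  rownames(m) <- as.character(df$cell_id)
  feature_table(m, df[meta_cols])
}

#' Write a feature table to delimited text
#'
#' Metadata columns come first (starting with `cell_id`), then features;
#' round-trips through [read_feature_table()].
#'
#' @param table a [feature_table()].
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, sep = ",") {
  stopifnot(inherits(table, "feature_table"))
  df <- as.data.frame(table)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Zero-mean standardize a feature table
#'
#' Centers every feature column to mean zero and scales it to unit standard
#' deviation. The default uses the population (1/n) standard deviation so
#' that standardization is exactly idempotent; `sd = "sample"` switches to
#' the 1/(n-1) convention. Constant columns carry no information for
#' clustering and are dropped with a warning.
#'
#' @param table a [feature_table()].
#' @param sd `"population"` (default) or `"sample"`.
#' @return A standardized [feature_table()].
#' @examples
#' ft <- feature_table(matrix(c(1, 2, 3), 3, 1, dimnames = list(NULL, "f")))
#' standardize(ft)$features  # -1.2247, 0, 1.2247
#' @export
standardize <- function(table, sd = c("population", "sample")) {
  stopifnot(inherits(table, "feature_table"))
  sd <- match.arg(sd)
  m <- table$features
  if (nrow(m) < 2L) stop("standardization needs at least 2 cells")
  centered <- sweep(m, 2L, colMeans(m))
  denom <- if (sd == "population") nrow(m) else nrow(m) - 1L
  sds <- sqrt(colSums(centered^2) / denom)
  const <- sds < .Machine$double.eps^0.5 * (1 + max(abs(m)))
  if (any(const)) {
    warning("dropping constant feature column(s): ",
            paste(colnames(m)[const], collapse = ", "))
    centered <- centered[, !const, drop = FALSE]
    sds <- sds[!const]
  }
  if (!ncol(centered)) stop("no non-constant features left")
  feature_table(sweep(centered, 2L, sds, "/"), table$metadata)
}
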