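# Volume, ROI and table I/O.
#
# Volumes travel as multi-page TIFF (one page per z-slice, axes "zyx") with a
# JSON sidecar <file>.json. TIFF samples are stored affinely rescaled to
# [0, 1]; the sidecar records the offset/scale to undo the transform along
# with voxel size, so signed quantities (phase in radians, velocity in mm/s)
# round-trip exactly to 32-bit precision.

#' Write a 3D volume as a multi-page TIFF with JSON sidecar
#'
#' @param vol numeric or logical 3D array (z, y, x).
#' @param path output TIFF path; the sidecar is written to `paste0(path, ".json")`.
#' @param voxel_size_um voxel edge length in micrometers (isotropic).
#' @return `path`, invisibly.
#' @export
write_volume_tiff <- function(vol, path, voxel_size_um) {
  .check_volume(vol)
  v <- vol * 1.0
  offset <- min(v)
  scale <- max(v) - offset
  if (scale == 0) scale <- 1
  v <- (v - offset) / scale
  pages <- lapply(seq_len(dim(v)[1]), function(z) v[z, , ])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  meta <- list(voxel_size_um = voxel_size_um, axes = "zyx",
               dims = dim(vol), offset = offset, scale = scale)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a volume written by [write_volume_tiff()]
#'
#' @param path TIFF path with sidecar `paste0(path, ".json")` alongside.
#' @return list with `data` (3D array, z-y-x) and `voxel_size_um`.
#' @export
read_volume_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- as.integer(meta$dims)
  vol <- array(0, d)
  for (z in seq_len(d[1])) vol[z, , ] <- pages[[z]]
  vol <- vol * meta$scale + meta$offset
  list(data = vol, voxel_size_um = meta$voxel_size_um)
}

#' Read ROI boxes from JSON
#'
#' ROIs are axis-aligned boxes `{vessel_id, z0, y0, x0, z1, y1, x1}` with
#' 1-based inclusive voxel bounds.
#'
#' @param path JSON file containing an array of ROI objects.
#' @return data.frame with one row per ROI.
#' @export
read_rois <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("vessel_id", "z0", "y0", "x0", "z1", "y1", "x1")
  if (!all(need %in% names(df)))
    stop("ROI JSON must contain fields: ", paste(need, collapse = ", "),
         call. = FALSE)
  as.data.frame(df)
}

#' Read/write animal-by-parameter feature tables
#'
#' CSV layout: `animal_id,group,<param1>,<param2>,...` with one row per
#' animal and a two-level group factor.
#'
#' @param path CSV file path.
#' @return data.frame with `animal_id`, `group` and numeric parameter columns.
#' @export
read_feature_table <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  if (!all(c("animal_id", "group") %in% names(df)[1:2]))
    stop("feature CSV must start with columns animal_id,group", call. = FALSE)
  df$group <- factor(df$group)
  df
}

#' @param table feature table as returned by [simulate_feature_table()].
#' @rdname read_feature_table
#' @export
write_feature_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Export a skeleton graph to node/edge CSV tables or GraphML
#'
#' @param graph a `skeleton_graph` from [build_graph()].
#' @param nodes_path,edges_path output CSVs for the node and edge tables.
#' @return invisibly, the list of written paths.
#' @export
write_graph_tables <- function(graph, nodes_path, edges_path) {
  nodes <- graph$nodes
  edges <- graph$edges[, c("edge_id", "node_a", "node_b",
                           "path_length_um", "chord_length_um", "n_voxels")]
  write.csv(nodes, nodes_path, row.names = FALSE)
  write.csv(edges, edges_path, row.names = FALSE)
  invisible(list(nodes = nodes_path, edges = edges_path))
}

#' @param path output GraphML path.
#' @rdname write_graph_tables
#' @export
write_graphml <- function(graph, path) {
  g <- igraph::graph_from_data_frame(
    graph$edges[, c("node_a", "node_b", "edge_id", "path_length_um",
                    "chord_length_um")],
    directed = FALSE,
    vertices = graph$nodes[, c("node_id", "z_um", "y_um", "x_um",
                               "degree", "kind")])
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
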