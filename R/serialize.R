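# Plain-text serialization: cameras and RBM models as JSON, marker
# observations / similar-frame pairs / embeddings as CSV, motion graphs
# as JSON. (No HDF5 dependency is available in the target environment;
# the formats below are equivalent, self-describing containers.)

#' Write / read a camera rig as JSON
#'
#' Each camera is stored as L[11], k1, k2, p1, p2, principal point and
#' image size.
#'
#' @param rig list of `camera_model` objects.
#' @param path JSON file path.
#' @return `path` / list of `camera_model`.
#' @export
write_cameras <- function(rig, path) {
  jsonlite::write_json(lapply(rig, unclass), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_cameras
#' @export
read_cameras <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(if (is.data.frame(raw)) nrow(raw) else length(raw)), function(i) {
    cm <- if (is.data.frame(raw)) lapply(raw, function(col) col[[i]]) else raw[[i]]
    camera_model(unlist(cm$L), k1 = cm$k1, k2 = cm$k2, p1 = cm$p1, p2 = cm$p2,
                 principal_point = unlist(cm$principal_point),
                 image_size = unlist(cm$image_size))
  })
}

#' Write / read marker observations as CSV (camera, frame, marker, u, v)
#' @param obs observation data.frame.
#' @param path CSV path.
#' @export
write_observations <- function(obs, path) {
  utils::write.csv(obs, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) utils::read.csv(path)

#' Write / read a ConvRBM model as JSON
#' @param model a `conv_rbm`.
#' @param path JSON path.
#' @export
write_rbm <- function(model, path) {
  obj <- unclass(model)
  obj$W <- list(dim = dim(model$W), data = as.numeric(model$W))
  obj$visible_bias <- list(dim = dim(model$visible_bias),
                           data = as.numeric(model$visible_bias))
  if (!is.null(obj$A)) obj$A <- list(dim = dim(model$A), data = as.numeric(model$A))
  if (!is.null(obj$B)) obj$B <- list(dim = dim(model$B), data = as.numeric(model$B))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_rbm
#' @export
read_rbm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- conv_rbm(n_positions = obj$n_positions, n_channels = obj$n_channels,
                    n_filters = obj$n_filters, kernel_width = obj$kernel_width,
                    temporal_window = obj$temporal_window,
                    history_order = obj$history_order,
                    visible_type = obj$visible_type,
                    input_mode = obj$input_mode %||% "positions")
  model$W <- array(obj$W$data, dim = obj$W$dim)
  model$hidden_bias <- as.numeric(obj$hidden_bias)
  model$visible_bias <- matrix(obj$visible_bias$data, obj$visible_bias$dim[1],
                               obj$visible_bias$dim[2])
  if (!is.null(obj$A) && length(obj$A)) model$A <- array(obj$A$data, dim = obj$A$dim)
  if (!is.null(obj$B) && length(obj$B)) model$B <- array(obj$B$data, dim = obj$B$dim)
  model
}

#' Write / read a motion graph as JSON (nodes, edges, similarities)
#' @param mg a `motion_graph`.
#' @param path JSON path.
#' @export
write_graph <- function(mg, path) {
  g <- mg$graph
  edges <- if (igraph::ecount(g)) {
    data.frame(from = as.integer(igraph::ends(g, igraph::E(g))[, 1]),
               to = as.integer(igraph::ends(g, igraph::E(g))[, 2]),
               similarity = igraph::E(g)$similarity,
               type = igraph::E(g)$type,
               seq_a = igraph::E(g)$seq_a, frame_a = igraph::E(g)$frame_a,
               seq_b = igraph::E(g)$seq_b, frame_b = igraph::E(g)$frame_b)
  } else data.frame()
  jsonlite::write_json(list(n_nodes = igraph::vcount(g),
                            membership = mg$membership, edges = edges,
                            sequences = mg$sequences,
                            n_frames = as.list(mg$n_frames)),
                       path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}
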