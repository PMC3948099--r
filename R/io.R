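.STATE_FORMAT <- "idionet-state"
.STATE_VERSION <- 1L

#' Write a network state to a JSON file
#'
#' Stores the occupied node indices, the self set, and the bitstring length
#' in a small versioned JSON document; [readState()] restores it exactly.
#'
#' @param state a [NetworkState-class].
#' @param path file path.
#' @param meta optional named list of extra metadata (parameters, time,
#'   seed) stored verbatim.
#' @return \code{path}, invisibly.
#' @export
writeState <- function(state, path, meta = list()) {
  doc <- c(list(format = .STATE_FORMAT, version = .STATE_VERSION,
                d = state@d,
                occupied = which(state@occupation == 1L) - 1L,
                selfNodes = state@selfNodes),
           meta)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a network state written by [writeState()]
#'
#' @param path file path.
#' @return a [NetworkState-class]; extra metadata is attached as attribute
#'   \code{"meta"}.
#' @export
readState <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$format) || doc$format != .STATE_FORMAT)
    stop("not an idionet state file: ", path)
  if (is.null(doc$version) || doc$version != .STATE_VERSION)
    stop("unsupported state file version: ", doc$version)
  d <- as.integer(doc$d)
  occ <- integer(2L^d)
  occ[as.integer(doc$occupied) + 1L] <- 1L
  state <- new("NetworkState", d = d, occupation = occ,
               selfNodes = sort(as.integer(doc$selfNodes)))
  attr(state, "meta") <- doc[setdiff(names(doc),
    c("format", "version", "d", "occupied", "selfNodes"))]
  state
}

#' Write a trajectory as TSV
#'
#' Columns: \code{time}, total occupation \code{nG}, and the d
#' center-of-mass components \code{R_1 .. R_d}.
#'
#' @param traj a [Trajectory-class].
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
writeTrajectoryTSV <- function(traj, path) {
  df <- data.frame(time = seq_along(traj@total), nG = traj@total,
                   traj@com)
  names(df)[-(1:2)] <- paste0("R_", seq_len(traj@d))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export the expressed network as GraphML
#'
#' The subgraph induced by the occupied nodes, with node attributes
#' \code{idiotype} (bitstring) and \code{self}, written via igraph for
#' interchange with standard graph tooling.
#'
#' @param state a [NetworkState-class].
#' @param graph the matching [BaseGraph-class].
#' @param path file path.
#' @return the igraph object, invisibly.
#' @export
exportGraphML <- function(state, graph, path) {
  occNodes <- which(state@occupation == 1L)      # 1-based
  sub <- graph@adjacency[occNodes, occNodes, drop = FALSE]
  g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected")
  igraph::V(g)$idiotype <- idiotypeString(occNodes - 1L, graph@d)
  igraph::V(g)$self <- (occNodes - 1L) %in% state@selfNodes
  igraph::write_graph(g, path, format = "graphml")
  invisible(g)
}
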