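#' Write an image stack to multi-page TIFF with a JSON sidecar
#'
#' Pages are written channel-major (all z slices of the first channel, then
#' the next channel) as 32-bit float TIFF. Channel names, voxel spacing,
#' dimensions and the provenance log go to `<path>.json`, since baseline
#' TIFF carries no standard microscopy metadata. Intensities are written
#' as-is and are expected in `[0, 1]`.
#'
#' @param stack an [image_stack].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  pages <- list()
  for (ch in names(stack$channels)) {
    a <- stack$channels[[ch]]
    a <- pmin(pmax(a, 0), 1)
    for (k in seq_len(dim(a)[3])) {
      # TIFF pages are row-major images: rows = y, cols = x
      pages[[length(pages) + 1L]] <- t(a[, , k])
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(channels = names(stack$channels),
               dim = dim(stack$channels[[1]]),
               spacing_um = stack$spacing_um,
               log = stack$log)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an image stack written by [write_stack()]
#'
#' @param path TIFF path (the `<path>.json` sidecar must exist).
#' @return An [image_stack].
#' @export
read_stack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- as.integer(meta$dim)
  chans <- list()
  i <- 0L
  for (ch in meta$channels) {
    a <- array(0, d)
    for (k in seq_len(d[3])) {
      i <- i + 1L
      a[, , k] <- t(pages[[i]])
    }
    chans[[ch]] <- a
  }
  image_stack(chans, as.numeric(meta$spacing_um))
}

#' Write a spatial graph to SWC
#'
#' One SWC file per connected component (`<prefix>_c<k>.swc`), soma nodes
#' as type 1 and neurite centreline points as type 3, with a JSON sidecar
#' (`<prefix>.json`) carrying the component partition and per-component
#' file names. SWC is a tree format: within each component a spanning tree
#' rooted at a soma (or the first node) defines parent links, and any extra
#' edges closing cycles are emitted as additional parentless chains.
#'
#' @param g a [spatial_graph].
#' @param prefix output path prefix.
#' @param neurite_radius_um radius written for neurite points.
#' @return Character vector of files written, invisibly.
#' @export
write_swc <- function(g, prefix, neurite_radius_um = 0.5) {
  stopifnot(inherits(g, "spatial_graph"))
  files <- character(0)
  ncomp <- if (length(g$node_components)) max(g$node_components) else 0
  for (comp in seq_len(ncomp)) {
    nodes_c <- which(g$node_components == comp)
    edges_c <- which(g$components == comp)
    if (length(nodes_c) == 0) next
    soma_c <- nodes_c[g$nodes$kind[nodes_c] == "soma"]
    root <- if (length(soma_c)) soma_c[1] else nodes_c[1]
    rows <- list()
    nid <- 0L
    swc_id_of_node <- integer(nrow(g$nodes))
    emit <- function(pos, type, radius, parent) {
      nid <<- nid + 1L
      rows[[nid]] <<- c(nid, type, pos[1], pos[2], pos[3], radius, parent)
      nid
    }
    node_type <- function(v) if (g$nodes$kind[v] == "soma") 1L else 3L
    node_radius <- function(v)
      if (g$nodes$kind[v] == "soma") 6 else neurite_radius_um
    swc_id_of_node[root] <- emit(as.numeric(g$nodes[root, c("x", "y", "z")]),
                                 node_type(root), node_radius(root), -1L)
    visited_e <- logical(nrow(g$edges))
    queue <- root
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      inc <- edges_c[!visited_e[edges_c] &
                     (g$edges$from[edges_c] == v | g$edges$to[edges_c] == v)]
      for (e in inc) {
        if (visited_e[e]) next
        visited_e[e] <- TRUE
        w <- if (g$edges$from[e] == v) g$edges$to[e] else g$edges$from[e]
        p <- g$polylines[[e]]
        if (g$edges$from[e] != v) p <- p[nrow(p):1, , drop = FALSE]
        parent <- swc_id_of_node[v]
        if (nrow(p) > 2) for (k in 2:(nrow(p) - 1)) {
          parent <- emit(p[k, ], 3L, neurite_radius_um, parent)
        }
        if (swc_id_of_node[w] == 0L) {
          swc_id_of_node[w] <- emit(as.numeric(g$nodes[w, c("x", "y", "z")]),
                                    node_type(w), node_radius(w), parent)
          queue <- c(queue, w)
        } else {
          # cycle-closing edge: terminal point repeated as a leaf
          emit(as.numeric(g$nodes[w, c("x", "y", "z")]), node_type(w),
               node_radius(w), parent)
        }
      }
    }
    f <- sprintf("%s_c%d.swc", prefix, comp)
    m <- do.call(rbind, rows)
    lines <- c("# SWC export: id type x y z radius parent",
               apply(m, 1, function(r)
                 sprintf("%d %d %.4f %.4f %.4f %.4f %d",
                         as.integer(r[1]), as.integer(r[2]), r[3], r[4], r[5],
                         r[6], as.integer(r[7]))))
    writeLines(lines, f)
    files <- c(files, f)
  }
  jsonlite::write_json(
    list(files = files,
         component_of_edge = g$components,
         mode = g$mode,
         total_length_um = total_length(g)),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(files)
}

#' Read an SWC file into a spatial graph
#'
#' Inverse of [write_swc()] for tree-shaped files: SWC points become
#' polyline vertices, with nodes at somas (type 1), branch points and
#' leaves.
#'
#' @param path SWC file path.
#' @return A [spatial_graph].
#' @export
read_swc <- function(path) {
  raw <- read.table(path, comment.char = "#",
                    col.names = c("id", "type", "x", "y", "z", "radius",
                                  "parent"))
  if (nrow(raw) == 0) return(spatial_graph())
  raw <- raw[order(raw$id), ]
  nchild <- tabulate(raw$parent[raw$parent > 0], nbins = max(raw$id))
  is_node <- raw$parent == -1 | nchild[raw$id] >= 2 | nchild[raw$id] == 0 |
    raw$type == 1
  node_rows <- which(is_node)
  node_of_id <- integer(max(raw$id))
  nodes <- data.frame(x = raw$x[node_rows], y = raw$y[node_rows],
                      z = raw$z[node_rows],
                      kind = ifelse(raw$type[node_rows] == 1, "soma", "end"),
                      stringsAsFactors = FALSE)
  node_of_id[raw$id[node_rows]] <- seq_along(node_rows)
  edges <- data.frame(from = integer(0), to = integer(0))
  polylines <- list()
  # walk from every non-root node point back to the previous node point
  for (r in node_rows) {
    id <- raw$id[r]
    if (raw$parent[r] == -1) next
    pts <- raw[r, c("x", "y", "z")]
    pid <- raw$parent[r]
    while (pid > 0 && node_of_id[pid] == 0) {
      pr <- which(raw$id == pid)
      pts <- rbind(raw[pr, c("x", "y", "z")], pts)
      pid <- raw$parent[pr]
    }
    if (pid <= 0) next
    pr <- which(raw$id == pid)
    pts <- rbind(raw[pr, c("x", "y", "z")], pts)
    edges <- rbind(edges, data.frame(from = node_of_id[pid],
                                     to = node_of_id[id]))
    polylines[[length(polylines) + 1L]] <- as.matrix(pts)
  }
  spatial_graph(nodes, edges, polylines, mode = "skeleton")
}

#' Write somas to CSV
#'
#' Columns `x`, `y`, `z`, `radius`, `merged` (micrometres).
#'
#' @param somas soma data frame from [detect_somas()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_somas_csv <- function(somas, path) {
  cols <- intersect(c("x", "y", "z", "radius", "merged"), names(somas))
  write.csv(somas[, cols, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' Write per-sample metrics and a JSON detail record
#'
#' @param metrics a data frame of [network_metrics()] rows (possibly with a
#'   `condition` column).
#' @param path_csv CSV output path.
#' @param path_json optional JSON output path.
#' @return `path_csv`, invisibly.
#' @export
write_metrics <- function(metrics, path_csv, path_json = NULL) {
  write.csv(as.data.frame(metrics), path_csv, row.names = FALSE)
  if (!is.null(path_json))
    jsonlite::write_json(as.data.frame(metrics), path_json, auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
  invisible(path_csv)
}
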