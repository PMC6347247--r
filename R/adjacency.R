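#' Area contiguity graph
#'
#' Symmetric, undirected adjacency between areas — the neighbourhood
#' structure of the spatial (CAR) random effect. Nodes are area ids;
#' isolated nodes are retained (their spatial effect is pinned at zero by
#' the per-component sum-to-zero constraint). Self-loops are forbidden.
#'
#' @param area_ids Character vector of unique node ids.
#' @param edges Two-column matrix or data.frame of area ids, one row per
#'   undirected edge; duplicates and reversed duplicates are collapsed.
#' @return An object of class `adjacency_graph` with fields `area_ids`,
#'   `edges` (integer node-index matrix, `from < to`), `components`
#'   (integer membership vector) and `n_components`.
#' @examples
#' g <- adjacency_graph(c("A", "B", "C"), cbind("A", "B"))
#' g$n_components  # 2: {A,B} and isolated C
#' @export
adjacency_graph <- function(area_ids, edges = NULL) {
  area_ids <- as.character(area_ids)
  if (anyDuplicated(area_ids)) {
    stop("duplicate area ids in graph", call. = FALSE)
  }
  n <- length(area_ids)
  if (is.null(edges) || NROW(edges) == 0L) {
    eidx <- matrix(integer(0), ncol = 2L)
  } else {
    edges <- as.matrix(edges)
    if (ncol(edges) != 2L) stop("`edges` must have two columns", call. = FALSE)
    from <- match(as.character(edges[, 1L]), area_ids)
    to <- match(as.character(edges[, 2L]), area_ids)
    if (anyNA(from) || anyNA(to)) {
      bad <- unique(c(edges[, 1L][is.na(from)], edges[, 2L][is.na(to)]))
      stop("edge endpoint(s) absent from node set: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (any(from == to)) {
      stop("self-loops are not allowed (node ",
           area_ids[from[which(from == to)[1L]]], ")", call. = FALSE)
    }
    eidx <- unique(cbind(pmin(from, to), pmax(from, to)))
    eidx <- eidx[order(eidx[, 1L], eidx[, 2L]), , drop = FALSE]
  }
  ig <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(eidx)) ig <- igraph::add_edges(ig, t(eidx))
  comp <- igraph::components(ig)
  structure(list(area_ids = area_ids, edges = eidx,
                 components = as.integer(comp$membership),
                 n_components = comp$no),
            class = "adjacency_graph")
}

#' @export
print.adjacency_graph <- function(x, ...) {
  cat("<adjacency_graph> ", length(x$area_ids), " nodes, ",
      nrow(x$edges), " edges, ", x$n_components, " component(s)\n", sep = "")
  invisible(x)
}

#' @rdname adjacency_graph
#' @param graph An `adjacency_graph`.
#' @return `neighbor_lists()`: list of integer neighbour-index vectors,
#'   one per node.
#' @export
neighbor_lists <- function(graph) {
  stopifnot(inherits(graph, "adjacency_graph"))
  n <- length(graph$area_ids)
  nbs <- vector("list", n)
  for (i in seq_len(n)) nbs[[i]] <- integer(0)
  e <- graph$edges
  for (k in seq_len(nrow(e))) {
    nbs[[e[k, 1L]]] <- c(nbs[[e[k, 1L]]], e[k, 2L])
    nbs[[e[k, 2L]]] <- c(nbs[[e[k, 2L]]], e[k, 1L])
  }
  nbs
}

#' Read an adjacency graph from a GAL neighbour file or edge-list CSV
#'
#' GAL dialect: a header line whose last numeric token is the node count,
#' then per node an "id degree" line followed by a line of neighbour ids
#' (the neighbour line is absent or empty for degree-0 nodes). An edge
#' listed in only one direction is symmetrized with a warning. Files ending
#' in `.csv` are read as a two-column `from,to` edge list over the union of
#' ids seen (plus `area_ids` if supplied).
#'
#' @param path Path to a `.gal` or `.csv` file.
#' @param area_ids Optional full node set; ids present here but absent from
#'   the file are kept as isolated nodes.
#' @return An `adjacency_graph`.
#' @export
read_adjacency <- function(path, area_ids = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
    nodes <- unique(c(area_ids, df[[1L]], df[[2L]]))
    g <- adjacency_graph(nodes, as.matrix(df[, 1:2]))
  } else {
    g <- read_gal(path, area_ids)
  }
  message(sprintf("read_adjacency: %d nodes, %d edges, %d component(s) from %s",
                  length(g$area_ids), nrow(g$edges), g$n_components, path))
  g
}

read_gal <- function(path, area_ids = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^\\s*$", lines)]
  if (!length(lines)) stop("empty GAL file: ", path, call. = FALSE)
  header <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  n <- suppressWarnings(as.integer(header[min(2L, length(header))]))
  if (is.na(n)) n <- suppressWarnings(as.integer(header[1L]))
  if (is.na(n) || n < 0L) {
    stop("malformed GAL header in ", path, call. = FALSE)
  }
  ids <- character(n)
  nb_ids <- vector("list", n)
  pos <- 2L
  for (k in seq_len(n)) {
    if (pos > length(lines)) {
      stop("GAL file truncated: expected ", n, " node records in ", path,
           call. = FALSE)
    }
    rec <- strsplit(trimws(lines[pos]), "\\s+")[[1L]]
    if (length(rec) != 2L) {
      stop("malformed GAL node line ", pos, " in ", path, call. = FALSE)
    }
    ids[k] <- rec[1L]
    deg <- suppressWarnings(as.integer(rec[2L]))
    if (is.na(deg) || deg < 0L) {
      stop("malformed degree on GAL line ", pos, " in ", path, call. = FALSE)
    }
    pos <- pos + 1L
    if (deg > 0L) {
      nbrs <- strsplit(trimws(lines[pos]), "\\s+")[[1L]]
      if (length(nbrs) != deg) {
        stop(sprintf("GAL node '%s' declares degree %d but lists %d neighbours",
                     ids[k], deg, length(nbrs)), call. = FALSE)
      }
      nb_ids[[k]] <- nbrs
      pos <- pos + 1L
    } else {
      nb_ids[[k]] <- character(0)
    }
  }
  all_ids <- unique(c(ids, area_ids))
  unknown <- setdiff(unlist(nb_ids), all_ids)
  if (length(unknown)) {
    stop("GAL neighbour id(s) absent from node set: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(vapply(seq_len(n), function(k) ids[k] %in% nb_ids[[k]], logical(1)))) {
    stop("self-loops are not allowed in GAL file ", path, call. = FALSE)
  }
  edges <- do.call(rbind, lapply(seq_len(n), function(k) {
    if (length(nb_ids[[k]])) cbind(ids[k], nb_ids[[k]]) else NULL
  }))
  # detect one-sided listings before symmetrization collapses them
  if (!is.null(edges)) {
    key <- paste(edges[, 1L], edges[, 2L])
    rev_key <- paste(edges[, 2L], edges[, 1L])
    if (!all(key %in% rev_key)) {
      warning("asymmetric GAL neighbour lists in ", path,
              "; symmetrizing", call. = FALSE)
    }
  }
  adjacency_graph(all_ids, edges)
}

#' Write an adjacency graph as a GAL neighbour file
#'
#' @param graph An `adjacency_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gal <- function(graph, path) {
  stopifnot(inherits(graph, "adjacency_graph"))
  nbs <- neighbor_lists(graph)
  ids <- graph$area_ids
  out <- character(0)
  for (k in seq_along(ids)) {
    deg <- length(nbs[[k]])
    out <- c(out, paste(ids[k], deg))
    if (deg > 0L) out <- c(out, paste(ids[nbs[[k]]], collapse = " "))
  }
  writeLines(c(as.character(length(ids)), out), path)
  invisible(path)
}
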