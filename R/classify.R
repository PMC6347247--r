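#' Bin smoothed risks and exceedance probabilities for mapping
#'
#' Assigns each area to one relative-risk bin and one exceedance-
#' probability bin using half-open intervals `[edge_k, edge_{k+1})`;
#' values below the first or at/above the last edge fall into the outer
#' bins. Default RR edges are data-driven septiles; default PP edges are
#' 0.1, 0.2, ..., 0.9 — map-legend conventions, overridable.
#'
#' @param summary A `bym_fit`, or a data.frame with columns `area_id`,
#'   `rr_mean`, `pp`.
#' @param rr_edges,pp_edges Strictly increasing numeric bin edges.
#' @return A data.frame `area_id`, `rr_bin`, `pp_bin` (factors) with the
#'   edges attached as attributes `rr_edges`, `pp_edges`. Areas with
#'   missing risk get `NA` bins.
#' @export
classify_risk <- function(summary, rr_edges = NULL,
                          pp_edges = seq(0.1, 0.9, by = 0.1)) {
  if (inherits(summary, "bym_fit")) summary <- summary$summary
  stopifnot(all(c("area_id", "rr_mean", "pp") %in% names(summary)))
  if (is.null(rr_edges)) {
    rr_edges <- unique(stats::quantile(summary$rr_mean,
                                       probs = seq_len(6) / 7,
                                       na.rm = TRUE, names = FALSE))
  }
  check_edges <- function(e, what) {
    if (length(e) < 1L || anyNA(e) || is.unsorted(e, strictly = TRUE)) {
      stop("`", what, "` must be strictly increasing", call. = FALSE)
    }
  }
  check_edges(rr_edges, "rr_edges")
  check_edges(pp_edges, "pp_edges")
  data.frame(area_id = summary$area_id,
             rr_bin = bin_halfopen(summary$rr_mean, rr_edges),
             pp_bin = bin_halfopen(summary$pp, pp_edges),
             stringsAsFactors = FALSE) |>
    structure(rr_edges = rr_edges, pp_edges = pp_edges)
}

bin_halfopen <- function(x, edges) {
  labels <- c(paste0("<", edges[1L]),
              if (length(edges) > 1L)
                paste0("[", edges[-length(edges)], ",", edges[-1L], ")"),
              paste0(">=", edges[length(edges)]))
  idx <- findInterval(x, edges) + 1L
  factor(labels[idx], levels = labels)
}

#' Write a posterior summary as GeoJSON
#'
#' Emits an RFC 7946 FeatureCollection with one feature per area carrying
#' `area_id`, `observed`, `expected`, `smr`, `rr_mean`, `rr_q025`,
#' `rr_q975`, `pp` (and bins when a classification is supplied) as
#' properties. Geometries come from an optional GeoJSON file whose
#' features have an `area_id` property; without one, point features are
#' placed on the graph's lattice coordinates — adequate for synthetic
#' data, not cartography.
#'
#' @param summary A `bym_fit` or its `summary` data.frame.
#' @param path Output `.geojson` path.
#' @param graph Optional `adjacency_graph` supplying point coordinates.
#' @param geometry_path Optional GeoJSON file with per-area geometries.
#' @param classification Optional output of [classify_risk()].
#' @return `path`, invisibly.
#' @export
write_geojson <- function(summary, path, graph = NULL, geometry_path = NULL,
                          classification = NULL) {
  if (inherits(summary, "bym_fit")) summary <- summary$summary
  props <- summary
  if (!is.null(classification)) {
    m <- match(props$area_id, classification$area_id)
    props$rr_bin <- as.character(classification$rr_bin[m])
    props$pp_bin <- as.character(classification$pp_bin[m])
  }
  geoms <- NULL
  if (!is.null(geometry_path)) {
    gj <- jsonlite::read_json(geometry_path)
    feats <- gj$features
    gids <- vapply(feats, function(f) as.character(f$properties$area_id), "")
    missing_ids <- setdiff(props$area_id, gids)
    if (length(missing_ids)) {
      stop("area(s) absent from geometry file: ",
           paste(missing_ids, collapse = ", "), call. = FALSE)
    }
    geoms <- lapply(feats, `[[`, "geometry")[match(props$area_id, gids)]
  } else if (!is.null(graph)) {
    xy <- lattice_coords(graph)
    xy <- xy[match(props$area_id, rownames(xy)), , drop = FALSE]
    geoms <- lapply(seq_len(nrow(xy)), function(i) {
      list(type = "Point",
           coordinates = c(unname(xy[i, 2L]), unname(xy[i, 1L])))
    })
  } else {
    stop("either `graph` or `geometry_path` must be supplied", call. = FALSE)
  }
  features <- lapply(seq_len(nrow(props)), function(i) {
    p <- as.list(props[i, , drop = FALSE])
    p <- lapply(p, function(v) if (is.factor(v)) as.character(v) else v)
    list(type = "Feature", geometry = geoms[[i]], properties = p)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = FALSE)
  invisible(path)
}
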