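# VesselNetwork: a spatial graph of nodes and radius-bearing segments.
# Coordinates are physical micrometres (x right, y down); radii in um.

#' Construct a vessel network
#'
#' A `vessel_network` is the central container of the package: a planar spatial
#' graph whose nodes are branch points, vessel tips, or flow boundaries, and
#' whose segments carry centerline geometry (a polyline), a per-vertex radius
#' profile, a vascular region label, and marker-derived attributes
#' (`lumen_fraction`, `has_matrix`).
#'
#' @param nodes data.frame with columns `id` (integer), `x`, `y` (um).
#' @param segments data.frame with columns `id`, `a`, `b` (node ids), `region`
#'   (one of `"artery"`, `"vein"`, `"capillary"`, `"sprouting_front"`, or
#'   `"unknown"`), `lumen_fraction` in `[0, 1]`, `has_matrix` (logical),
#'   `stage` (character or `NA`), `cell_count` (numeric or `NA`).
#' @param geometry list (parallel to `segments`) of n x 2 polyline matrices.
#' @param radius_profiles list of per-vertex radius vectors (um), parallel to
#'   `geometry`.
#' @param meta optional list of generator metadata (e.g. `inlets`, `outlets`,
#'   `optic_center`, `retina_radius`).
#' @param validate check invariants (polyline endpoints on node coordinates,
#'   positive lengths and radii, lumen fractions in range).
#'
#' @return An object of class `vessel_network` with elements `nodes`,
#'   `segments` (with derived `length` and `mean_radius` columns), `geometry`,
#'   `radius_profiles`, and `meta`.
#' @export
vessel_network <- function(nodes, segments, geometry, radius_profiles,
                           meta = list(), validate = TRUE) {
  nodes <- as.data.frame(nodes)
  segments <- as.data.frame(segments)
  n_seg <- nrow(segments)
  if (length(geometry) != n_seg || length(radius_profiles) != n_seg) {
    stop_input("geometry/radius_profiles must have one entry per segment")
  }
  for (col in c("lumen_fraction", "has_matrix", "stage", "cell_count")) {
    if (is.null(segments[[col]])) {
      segments[[col]] <- switch(col,
        lumen_fraction = 1, has_matrix = TRUE,
        stage = NA_character_, cell_count = NA_real_)
    }
  }
  segments$length <- vapply(geometry, polyline_length, numeric(1))
  segments$mean_radius <- vapply(radius_profiles, function(r) mean(r), numeric(1))
  net <- structure(list(nodes = nodes, segments = segments,
                        geometry = geometry, radius_profiles = radius_profiles,
                        meta = meta),
                   class = "vessel_network")
  if (validate) validate_network(net)
  net
}

validate_network <- function(net, tol = 1e-6) {
  s <- net$segments
  if (any(s$length <= 0)) stop_input("segment with non-positive length")
  if (any(s$lumen_fraction < 0 | s$lumen_fraction > 1)) {
    stop_input("lumen_fraction outside [0, 1]")
  }
  lum <- s$lumen_fraction > 0
  if (any(s$mean_radius[lum] <= 0)) stop_input("lumenized segment with non-positive radius")
  node_xy <- as.matrix(net$nodes[, c("x", "y")])
  rownames(node_xy) <- NULL
  ia <- match(s$a, net$nodes$id)
  ib <- match(s$b, net$nodes$id)
  if (anyNA(ia) || anyNA(ib)) stop_input("segment endpoint references missing node id")
  for (i in seq_len(nrow(s))) {
    g <- net$geometry[[i]]
    if (length(net$radius_profiles[[i]]) != nrow(g)) {
      stop_input("radius profile length mismatch on segment ", s$id[i])
    }
    da <- sqrt(sum((g[1, ] - node_xy[ia[i], ])^2))
    db <- sqrt(sum((g[nrow(g), ] - node_xy[ib[i], ])^2))
    if (da > tol || db > tol) {
      stop_input("polyline endpoints do not coincide with node coordinates on segment ",
                 s$id[i])
    }
  }
  invisible(net)
}

#' @export
print.vessel_network <- function(x, ...) {
  cat(sprintf("<vessel_network> %d nodes, %d segments (%s)\n",
              nrow(x$nodes), nrow(x$segments),
              paste(sprintf("%s: %d", names(table(x$segments$region)),
                            as.integer(table(x$segments$region))),
                    collapse = ", ")))
  cat(sprintf("  total centerline length %.0f um, vascularized area %.0f um^2\n",
              sum(x$segments$length), vascularized_area(x)))
  invisible(x)
}

#' Node degrees of a vessel network
#'
#' @param net a [vessel_network()].
#' @return Named integer vector, one entry per node id.
#' @export
node_degrees <- function(net) {
  ids <- net$nodes$id
  tab <- table(factor(c(net$segments$a, net$segments$b), levels = ids))
  setNames(as.integer(tab), ids)
}

#' Vascularized area of a network
#'
#' Graph-based convention: the sum over segments of `length * 2 * mean_radius`
#' (each vessel contributes its projected footprint). A raster-mask
#' alternative is available via [stack_vascularized_area()].
#'
#' @param net a [vessel_network()].
#' @return Area in um^2.
#' @export
vascularized_area <- function(net) {
  sum(net$segments$length * 2 * net$segments$mean_radius)
}

#' Convert a vessel network to an igraph graph
#'
#' @param net a [vessel_network()].
#' @return An undirected `igraph` graph; vertex name = node id, edge attribute
#'   `segment_id`.
#' @export
as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(net$segments$a),
               to = as.character(net$segments$b),
               segment_id = net$segments$id),
    directed = FALSE,
    vertices = data.frame(name = as.character(net$nodes$id)))
  g
}

# Flat table of all polyline vertices: segment id, vertex index, x, y, radius.
vertex_table <- function(net) {
  n <- vapply(net$geometry, nrow, integer(1))
  xy <- do.call(rbind, net$geometry)
  data.frame(segment_id = rep(net$segments$id, n),
             vertex = unlist(lapply(n, seq_len), use.names = FALSE),
             x = xy[, 1], y = xy[, 2],
             r = unlist(net$radius_profiles, use.names = FALSE))
}

NETWORK_SCHEMA_VERSION <- 1L

#' Write a vessel network to JSON
#'
#' The schema is versioned and round-trips all fields exactly (coordinates are
#' serialised at full double precision), so `read_network(write_network(net))`
#' is the identity.
#'
#' @param net a [vessel_network()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  segs <- lapply(seq_len(nrow(net$segments)), function(i) {
    s <- net$segments[i, ]
    out <- list(id = s$id, a = s$a, b = s$b,
                polyline = unname(net$geometry[[i]]),
                radius_profile = net$radius_profiles[[i]],
                region = s$region,
                lumen_fraction = s$lumen_fraction,
                has_matrix = s$has_matrix)
    if (!is.na(s$stage)) out$stage <- s$stage
    if (!is.na(s$cell_count)) out$cell_count <- s$cell_count
    out
  })
  obj <- list(schema_version = NETWORK_SCHEMA_VERSION,
              nodes = lapply(seq_len(nrow(net$nodes)), function(i) {
                list(id = net$nodes$id[i], x = net$nodes$x[i], y = net$nodes$y[i])
              }),
              segments = segs,
              meta = net$meta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}

#' Read a vessel network from JSON
#'
#' @param path file written by [write_network()].
#' @return A [vessel_network()].
#' @export
read_network <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$schema_version)) stop_parse("missing schema_version")
  for (fld in c("nodes", "segments")) {
    if (is.null(obj[[fld]])) stop_parse("missing field '", fld, "'")
  }
  nodes <- do.call(rbind, lapply(obj$nodes, function(n) {
    for (fld in c("id", "x", "y")) {
      if (is.null(n[[fld]])) stop_parse("node missing field '", fld, "'")
    }
    data.frame(id = as.integer(n$id), x = as.numeric(n$x), y = as.numeric(n$y))
  }))
  if (is.null(nodes)) nodes <- data.frame(id = integer(0), x = numeric(0), y = numeric(0))
  geometry <- list(); radius_profiles <- list()
  seg_rows <- lapply(seq_along(obj$segments), function(i) {
    s <- obj$segments[[i]]
    sid <- s$id %||% sprintf("<#%d>", i)
    for (fld in c("id", "a", "b", "polyline", "radius_profile", "region",
                  "lumen_fraction", "has_matrix")) {
      if (is.null(s[[fld]])) {
        stop_parse("segment ", sid, " missing field '", fld, "'")
      }
    }
    data.frame(id = as.integer(s$id), a = as.integer(s$a), b = as.integer(s$b),
               region = as.character(s$region),
               lumen_fraction = as.numeric(s$lumen_fraction),
               has_matrix = as.logical(s$has_matrix),
               stage = if (is.null(s$stage)) NA_character_ else as.character(s$stage),
               cell_count = if (is.null(s$cell_count)) NA_real_ else as.numeric(s$cell_count))
  })
  segments <- if (length(seg_rows)) do.call(rbind, seg_rows) else
    data.frame(id = integer(0), a = integer(0), b = integer(0),
               region = character(0), lumen_fraction = numeric(0),
               has_matrix = logical(0), stage = character(0), cell_count = numeric(0))
  geometry <- lapply(obj$segments, function(s) {
    m <- do.call(rbind, lapply(s$polyline, function(p) as.numeric(unlist(p))))
    if (is.null(m) || ncol(m) != 2) stop_parse("segment ", s$id, " has malformed polyline")
    m
  })
  radius_profiles <- lapply(obj$segments, function(s) as.numeric(unlist(s$radius_profile)))
  meta <- obj$meta %||% list()
  for (k in c("inlets", "outlets")) if (!is.null(meta[[k]])) meta[[k]] <- as.integer(unlist(meta[[k]]))
  for (k in c("optic_center")) if (!is.null(meta[[k]])) meta[[k]] <- as.numeric(unlist(meta[[k]]))
  for (k in c("retina_radius", "pixel_size", "seed")) {
    if (!is.null(meta[[k]])) meta[[k]] <- as.numeric(unlist(meta[[k]]))
  }
  vessel_network(nodes, segments, geometry, radius_profiles, meta = meta,
                 validate = nrow(segments) > 0)
}
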