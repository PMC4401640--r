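# Rasterize a network + cells + events into binary channel masks, emulating
# segmented multichannel microscopy (lumen / basement membrane / nuclei /
# Golgi / apoptosis channels).

#' Construct an image stack
#'
#' @param channels named list of equally sized numeric matrices (row = y,
#'   col = x; 0/1 masks).
#' @param pixel_size um per pixel (> 0).
#' @param origin 2-vector: physical position (um) of the outer corner of
#'   pixel (1,1); pixel centres are `origin + (index - 0.5) * pixel_size`.
#' @return list of class `image_stack`.
#' @export
image_stack <- function(channels, pixel_size, origin = c(0, 0)) {
  if (pixel_size <= 0) stop_input("pixel_size must be > 0")
  dims <- vapply(channels, dim, integer(2))
  if (ncol(dims) && any(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])) {
    stop_input("all channels must share the same shape")
  }
  structure(list(channels = channels, pixel_size = pixel_size, origin = origin),
            class = "image_stack")
}

#' Vascularized area of an image stack
#'
#' Positive pixels of the lumen channel (falling back to the matrix channel)
#' times the pixel area — the raster-mask alternative to the graph
#' convention of [vascularized_area()].
#'
#' @param stack an [image_stack()].
#' @return Area in um^2.
#' @export
stack_vascularized_area <- function(stack) {
  ch <- stack$channels$lumen %||% stack$channels$matrix
  if (is.null(ch)) stop_input("stack has neither lumen nor matrix channel")
  sum(ch > 0) * stack$pixel_size^2
}

# stamp disks of physical radius r (um) at points (x, y) into matrix `img`
stamp_disks <- function(img, x, y, r, origin, px) {
  if (!length(x)) return(img)
  nr <- nrow(img); nc <- ncol(img)
  rb <- round(pmax(r, px / 2) / px * 2) / 2    # radius in px, 0.5 px buckets
  for (rv in unique(rb)) {
    sel <- which(rb == rv)
    w <- floor(rv)
    off <- expand.grid(dr = -w:w, dc = -w:w)
    off <- off[off$dr^2 + off$dc^2 <= rv^2 + 1e-9, ]
    ci <- floor((x[sel] - origin[1]) / px) + 1L
    ri <- floor((y[sel] - origin[2]) / px) + 1L
    rr <- outer(off$dr, ri, "+"); cc <- outer(off$dc, ci, "+")
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    img[cbind(rr[ok], cc[ok])] <- 1
  }
  img
}

#' Render a network (plus cells and events) to channel masks
#'
#' Channels: `lumen` (per-segment disks of the local radius along the
#' centerline, drawn over the lumenized fraction of each segment's arc),
#' `matrix` (basement membrane: full footprint of every `has_matrix`
#' segment, including regressed ones), `nuclei`, `golgi`, `caspase` (small
#' disks at point coordinates). The channel order manifest is embedded in
#' the stack and in the sidecar file written by [write_image_stack()].
#'
#' @param net a [vessel_network()].
#' @param cells optional cell table (nucleus/Golgi positions).
#' @param cfg a [gen_config()] (supplies `pixel_size`).
#' @param events optional apoptosis event table (`x`, `y`).
#' @param fov optional field of view `c(xmin, xmax, ymin, ymax)` (um); must
#'   contain the network bounding box. Default: bounding box plus a margin.
#' @param point_radius radius of nucleus/Golgi/caspase disks (um).
#' @return An [image_stack()] with a `channel_order` attribute in
#'   `$manifest`.
#' @export
render_masks <- function(net, cells = NULL, cfg = NULL, events = NULL,
                         fov = NULL, point_radius = 2) {
  px <- if (!is.null(cfg)) cfg$pixel_size else net$meta$pixel_size %||% 1
  if (px <= 0) stop_input("pixel_size must be > 0")
  xy <- do.call(rbind, net$geometry)
  rmax <- max(unlist(net$radius_profiles))
  pad <- rmax + 4 * px
  bb <- c(min(xy[, 1]) - pad, max(xy[, 1]) + pad,
          min(xy[, 2]) - pad, max(xy[, 2]) + pad)
  if (!is.null(fov)) {
    if (fov[1] > bb[1] || fov[2] < bb[2] || fov[3] > bb[3] || fov[4] < bb[4]) {
      stop_config("field of view smaller than the network bounding box")
    }
    bb <- fov
  }
  origin <- c(bb[1], bb[3])
  nc <- ceiling((bb[2] - bb[1]) / px)
  nr <- ceiling((bb[4] - bb[3]) / px)
  zero <- matrix(0, nr, nc)
  lumen <- zero; matrixch <- zero
  step <- px / 2
  for (i in seq_len(nrow(net$segments))) {
    g <- net$geometry[[i]]
    L <- net$segments$length[i]
    npt <- max(2L, ceiling(L / step) + 1L)
    tt <- seq(0, 1, length.out = npt)
    at <- polyline_at(g, tt)
    prof <- net$radius_profiles[[i]]
    cl <- polyline_cumlen(g)
    rr <- approx(cl / max(cl), prof, xout = tt, rule = 2)$y
    if (net$segments$has_matrix[i]) {
      matrixch <- stamp_disks(matrixch, at$xy[, 1], at$xy[, 2], rr, origin, px)
    }
    lf <- net$segments$lumen_fraction[i]
    if (lf > 0) {
      keep <- tt <= lf  # contiguous lumen from the a-end
      lumen <- stamp_disks(lumen, at$xy[keep, 1], at$xy[keep, 2], rr[keep],
                           origin, px)
    }
  }
  nuclei <- zero; golgi <- zero; caspase <- zero
  if (!is.null(cells) && nrow(cells)) {
    nuclei <- stamp_disks(nuclei, cells$nucleus_x, cells$nucleus_y,
                          rep(point_radius, nrow(cells)), origin, px)
    gok <- !is.na(cells$golgi_x)
    golgi <- stamp_disks(golgi, cells$golgi_x[gok], cells$golgi_y[gok],
                         rep(point_radius, sum(gok)), origin, px)
  }
  if (!is.null(events) && nrow(events)) {
    caspase <- stamp_disks(caspase, events$x, events$y,
                           rep(point_radius, nrow(events)), origin, px)
  }
  st <- image_stack(list(lumen = lumen, matrix = matrixch, nuclei = nuclei,
                         golgi = golgi, caspase = caspase), px, origin)
  st$manifest <- list(channel_order = names(st$channels), pixel_size = px,
                      origin = origin)
  st
}

#' Write / read an image stack as multi-page TIFF plus sidecar manifest
#'
#' The TIFF holds one page per channel; the YAML sidecar (`<path>.yaml`)
#' records channel order, pixel size, and origin.
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  tiff::writeTIFF(lapply(stack$channels, function(m) {
    storage.mode(m) <- "double"
    m
  }), path, bits.per.sample = 8)
  yaml::write_yaml(list(channel_order = names(stack$channels),
                        pixel_size = stack$pixel_size,
                        origin = as.numeric(stack$origin)),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(path) {
  manifest_path <- paste0(path, ".yaml")
  if (!file.exists(manifest_path)) stop_input("missing sidecar manifest ", manifest_path)
  man <- yaml::read_yaml(manifest_path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != length(man$channel_order)) {
    stop_parse("channel manifest does not match TIFF page count")
  }
  channels <- setNames(lapply(pages, function(p) (p > 0) * 1), man$channel_order)
  image_stack(channels, man$pixel_size, as.numeric(man$origin))
}
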