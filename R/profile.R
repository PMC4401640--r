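# Radial profiling of cell density, branchpoint density, wall shear stress
# and marker densities as a function of distance from the optic nerve.

#' Radial profile of a vascular plexus
#'
#' Bins every quantity by distance from `optic_center`: nuclei by nucleus
#' position, branchpoints (nodes of degree >= 3) by node position, regression
#' profiles by segment midpoint, and vascularized area / wall shear stress by
#' apportioning each polyline's arc length over the bins it crosses (segments
#' straddling a bin edge contribute to each bin in proportion to the arc
#' length inside it, so merging adjacent bins is exactly additive). Mean wall
#' shear stress is arc-length weighted. Densities in empty bins (zero
#' vascularized area) are `NA`, never divide-by-zero.
#'
#' @param net a [vessel_network()].
#' @param cells optional cell table with `nucleus_x/y`.
#' @param flow optional [wall_shear()] solution (for the shear column).
#' @param profiles optional [detect_profiles()] output.
#' @param optic_center 2-vector (um); defaults to `net$meta$optic_center`.
#' @param bin_width radial bin width (um, default 100).
#' @param step arc-discretisation step for area apportioning (um).
#' @return data.frame of class `radial_profile`, one row per bin: `r_lo`,
#'   `r_hi`, `vascularized_area`, `n_nuclei`, `cell_density`,
#'   `n_branchpoints`, `branchpoint_density`, `mean_tau`, `n_profiles`,
#'   `profile_density`.
#' @export
radial_profile <- function(net, cells = NULL, flow = NULL, profiles = NULL,
                           optic_center = net$meta$optic_center,
                           bin_width = 100, step = 2) {
  if (is.null(optic_center)) stop_input("optic_center required")
  xy_all <- do.call(rbind, net$geometry)
  bb <- apply(xy_all, 2, range)
  if (optic_center[1] < bb[1, 1] || optic_center[1] > bb[2, 1] ||
      optic_center[2] < bb[1, 2] || optic_center[2] > bb[2, 2]) {
    warning("optic_center lies outside the network bounding box")
  }
  rad <- function(x, y) sqrt((x - optic_center[1])^2 + (y - optic_center[2])^2)
  r_max <- max(rad(xy_all[, 1], xy_all[, 2]))
  if (!is.null(cells) && nrow(cells)) {
    r_max <- max(r_max, rad(cells$nucleus_x, cells$nucleus_y))
  }
  edges <- seq(0, ceiling(r_max / bin_width) * bin_width, by = bin_width)
  nb <- length(edges) - 1L
  binof <- function(r) pmin(pmax(findInterval(r, edges, rightmost.closed = TRUE), 1L), nb)

  # vascularized area and length-weighted tau per bin
  area <- numeric(nb); len <- numeric(nb); tau_wsum <- numeric(nb)
  tau_len <- numeric(nb)
  taus <- if (!is.null(flow)) {
    flow$segments$tau[match(net$segments$id, flow$segments$segment_id)]
  } else rep(NA_real_, nrow(net$segments))
  for (i in seq_len(nrow(net$segments))) {
    g <- net$geometry[[i]]
    L <- net$segments$length[i]
    npt <- max(2L, ceiling(L / step) + 1L)
    at <- polyline_at(g, seq(0, 1, length.out = npt))
    mids <- (at$xy[-1, , drop = FALSE] + at$xy[-npt, , drop = FALSE]) / 2
    dl <- rep(L / (npt - 1), npt - 1)  # exact arc-length apportioning
    b <- binof(rad(mids[, 1], mids[, 2]))
    add <- tapply(dl, b, sum)
    idx <- as.integer(names(add))
    len[idx] <- len[idx] + add
    area[idx] <- area[idx] + add * 2 * net$segments$mean_radius[i]
    if (!is.na(taus[i])) {
      tau_wsum[idx] <- tau_wsum[idx] + add * taus[i]
      tau_len[idx] <- tau_len[idx] + add
    }
  }
  n_nuc <- integer(nb)
  if (!is.null(cells) && nrow(cells)) {
    t <- table(binof(rad(cells$nucleus_x, cells$nucleus_y)))
    n_nuc[as.integer(names(t))] <- as.integer(t)
  }
  deg <- node_degrees(net)
  bp <- net$nodes[deg[as.character(net$nodes$id)] >= 3, ]
  n_bp <- integer(nb)
  if (nrow(bp)) {
    t <- table(binof(rad(bp$x, bp$y)))
    n_bp[as.integer(names(t))] <- as.integer(t)
  }
  n_prof <- integer(nb)
  if (!is.null(profiles) && nrow(profiles)) {
    kk <- match(profiles$segment_id, net$segments$id)
    mids <- t(vapply(net$geometry[kk], function(g) polyline_at(g, 0.5)$xy[1, ],
                     numeric(2)))
    t <- table(binof(rad(mids[, 1], mids[, 2])))
    n_prof[as.integer(names(t))] <- as.integer(t)
  }
  out <- data.frame(r_lo = edges[-length(edges)], r_hi = edges[-1],
                    vascularized_area = area,
                    n_nuclei = n_nuc,
                    cell_density = ifelse(area > 0, n_nuc / area, NA_real_),
                    n_branchpoints = n_bp,
                    branchpoint_density = ifelse(area > 0, n_bp / area, NA_real_),
                    mean_tau = ifelse(tau_len > 0, tau_wsum / tau_len, NA_real_),
                    n_profiles = n_prof,
                    profile_density = ifelse(area > 0, n_prof / area, NA_real_))
  class(out) <- c("radial_profile", "data.frame")
  out
}

#' Marker event densities over vascularized tissue
#'
#' Counts events per marker and normalises per 100 um^2 of vascularized area.
#' For nuclear markers (EdU-like), also reports the fraction of endothelial
#' (Erg-positive) nuclei that are marker-positive, matching each event to its
#' nearest nucleus within `match_dist`.
#'
#' @param events data.frame with `x`, `y` and optionally `marker` columns.
#' @param area_source vascularized area: a number (um^2), a
#'   [vessel_network()] (graph convention, sum of `2 r L`), or an
#'   `image_stack` (positive lumen-mask pixels times pixel area).
#' @param cells optional cell table with nucleus positions (for nuclear
#'   fractions).
#' @param match_dist nearest-nucleus matching distance (um, default 5).
#' @return data.frame, one row per marker: `marker`, `n_events`,
#'   `per_100um2`, `frac_nuclei_positive`.
#' @export
marker_density <- function(events, area_source, cells = NULL, match_dist = 5) {
  area <- if (is.numeric(area_source)) {
    area_source
  } else if (inherits(area_source, "vessel_network")) {
    vascularized_area(area_source)
  } else if (inherits(area_source, "image_stack")) {
    stack_vascularized_area(area_source)
  } else {
    stop_input("area_source must be a number, vessel_network, or image_stack")
  }
  if (!is.numeric(area) || area <= 0) stop_input("vascularized area must be > 0")
  if (is.null(events$marker)) events$marker <- "event"
  markers <- sort(unique(events$marker))
  if (!length(markers)) {
    return(data.frame(marker = character(0), n_events = integer(0),
                      per_100um2 = numeric(0), frac_nuclei_positive = numeric(0)))
  }
  rows <- lapply(markers, function(mk) {
    ev <- events[events$marker == mk, , drop = FALSE]
    frac <- NA_real_
    if (!is.null(cells) && nrow(cells) > 0) {
      if (nrow(ev) > 0) {
        nn <- nn_lookup(cbind(cells$nucleus_x, cells$nucleus_y),
                        cbind(ev$x, ev$y))
        hit <- unique(nn$index[nn$dist <= match_dist])
        frac <- length(hit) / nrow(cells)
      } else frac <- 0
    }
    data.frame(marker = mk, n_events = nrow(ev),
               per_100um2 = nrow(ev) / area * 100,
               frac_nuclei_positive = frac)
  })
  do.call(rbind, rows)
}
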