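# Synthetic retinal plexus generator.
#
# The plexus is a radial spoke-and-mesh construction: arterial and venous
# spokes alternate around the optic nerve head, concentric capillary rings are
# connected by staggered radial capillaries (a polar "brick wall", giving the
# degree-3 branch points typical of a capillary mesh), and blind-ended sprout
# stubs decorate the outer rim. This is a geometric stand-in, not a growth
# model: it carries the statistical structure the downstream analyses need
# (radii, regions, flow topology, radial gradients) with known ground truth.

#' Generate a synthetic retinal vessel network
#'
#' Builds a planar plexus with radial arteries and veins emanating from the
#' optic centre, a honeycomb-like capillary mesh between them, and blind-ended
#' sprout segments at the outer rim. Every segment carries a polyline, a
#' radius profile, and a region label (`artery`, `vein`, `capillary`,
#' `sprouting_front`). Each artery has exactly one inlet node and each vein
#' one outlet node at the optic nerve head; these are recorded in
#' `net$meta$inlets` / `net$meta$outlets`.
#'
#' @param cfg a [gen_config()].
#' @return A [vessel_network()] connected from every inlet to every outlet.
#' @export
generate_network <- function(cfg) {
  validate_gen_config(cfg)
  if (cfg$n_arteries < 1L || cfg$n_veins < 1L) {
    stop_config("need at least one artery and one vein (no inlet/outlet otherwise)")
  }
  spacing <- cfg$capillary_spacing
  r_inner <- 1.5 * spacing
  sprout_len <- 0.7 * spacing
  r_front <- cfg$retina_radius - sprout_len
  K <- floor((r_front - r_inner) / spacing)
  if (K < 2) {
    stop_config("infeasible geometry: retina_radius too small for capillary_spacing")
  }
  n_sp <- cfg$n_arteries + cfg$n_veins
  spoke_theta <- 2 * pi * (seq_len(n_sp) - 1) / n_sp + pi / n_sp
  # alternate artery/vein while both remain, then append the surplus kind
  kinds <- character(n_sp)
  na <- cfg$n_arteries; nv <- cfg$n_veins
  want <- "artery"
  for (j in seq_len(n_sp)) {
    if (want == "artery" && na > 0) { kinds[j] <- "artery"; na <- na - 1 }
    else if (nv > 0) { kinds[j] <- "vein"; nv <- nv - 1 }
    else { kinds[j] <- "artery"; na <- na - 1 }
    want <- if (kinds[j] == "artery") "vein" else "artery"
  }

  with_substream(cfg$seed, 101L, {
    nodes_x <- numeric(0); nodes_y <- numeric(0)
    add_node <- function(x, y) {
      nodes_x[length(nodes_x) + 1L] <<- x
      nodes_y[length(nodes_y) + 1L] <<- y
      length(nodes_x)
    }
    seg_list <- list()
    add_seg <- function(a, b, xy, rad, region) {
      seg_list[[length(seg_list) + 1L]] <<- list(a = a, b = b, xy = xy,
                                                 rad = rad, region = region)
    }
    # spoke radius taper (um) as a function of radial position
    spoke_radius <- function(kind, r) {
      r0 <- if (kind == "artery") cfg$radius_artery else cfg$radius_vein
      pmax(1.3 * cfg$radius_capillary, r0 * (1 - 0.75 * r / cfg$retina_radius))
    }
    cap_rad_profile <- function(n) {
      cfg$radius_capillary * pmin(pmax(1 + rnorm(n, 0, 0.03), 0.9), 1.1)
    }
    sample_arc <- function(r0, th0, r1, th1, step = 6) {
      dth <- th1 - th0
      arc <- abs(dth) * (r0 + r1) / 2
      npt <- max(2L, ceiling(arc / step) + 1L)
      th <- seq(th0, th1, length.out = npt)
      rr <- seq(r0, r1, length.out = npt)
      cbind(rr * cos(th), rr * sin(th))
    }
    sample_line <- function(p0, p1, step = 6) {
      L <- sqrt(sum((p1 - p0)^2))
      npt <- max(2L, ceiling(L / step) + 1L)
      t <- seq(0, 1, length.out = npt)
      cbind(p0[1] + t * (p1[1] - p0[1]), p0[2] + t * (p1[2] - p0[2]))
    }

    # --- ring nodes -------------------------------------------------------
    ring_node_id <- vector("list", K + 1L)  # node ids, sorted by angle
    ring_theta <- vector("list", K + 1L)
    ring_rad <- vector("list", K + 1L)
    ring_spoke <- vector("list", K + 1L)    # 0 = filler, j = spoke index
    for (k in 0:K) {
      r_k <- r_inner + k * spacing
      m <- max(2L * n_sp, round(2 * pi * r_k / spacing))
      slot <- 2 * pi / m
      th <- (seq_len(m) - 0.5) * slot
      # circular distance to nearest spoke angle
      dmin <- vapply(th, function(a) {
        d <- abs(((a - spoke_theta + pi) %% (2 * pi)) - pi)
        min(d)
      }, numeric(1))
      th <- th[dmin > 0.35 * slot]
      th <- th + runif(length(th), -0.12, 0.12) * slot
      jr_hi <- if (k == K) 0 else 0.08
      rr <- r_k + runif(length(th), -0.08, jr_hi) * spacing
      ang <- c(th, spoke_theta)
      rad <- c(rr, rep(r_k, n_sp))
      spk <- c(rep(0L, length(th)), seq_len(n_sp))
      ord <- order(ang)
      ang <- ang[ord]; rad <- rad[ord]; spk <- spk[ord]
      ids <- vapply(seq_along(ang), function(i) {
        add_node(rad[i] * cos(ang[i]), rad[i] * sin(ang[i]))
      }, integer(1))
      ring_node_id[[k + 1L]] <- ids
      ring_theta[[k + 1L]] <- ang
      ring_rad[[k + 1L]] <- rad
      ring_spoke[[k + 1L]] <- spk
    }

    # --- ring arcs (capillaries) -----------------------------------------
    for (k in 0:K) {
      ids <- ring_node_id[[k + 1L]]; ang <- ring_theta[[k + 1L]]
      rad <- ring_rad[[k + 1L]]
      m <- length(ids)
      for (i in seq_len(m)) {
        j <- if (i == m) 1L else i + 1L
        th1 <- if (i == m) ang[j] + 2 * pi else ang[j]
        xy <- sample_arc(rad[i], ang[i], rad[j], th1)
        add_seg(ids[i], ids[j], xy, cap_rad_profile(nrow(xy)), "capillary")
      }
    }

    # --- staggered radial connectors (capillaries) -----------------------
    for (k in 0:(K - 1L)) {
      ids0 <- ring_node_id[[k + 1L]]; ang0 <- ring_theta[[k + 1L]]
      spk0 <- ring_spoke[[k + 1L]]
      ids1 <- ring_node_id[[k + 2L]]; ang1 <- ring_theta[[k + 2L]]
      spk1 <- ring_spoke[[k + 2L]]
      fill0 <- which(spk0 == 0L)
      cand <- fill0[seq_along(fill0) %% 2L == k %% 2L]
      free1 <- which(spk1 == 0L)
      used1 <- logical(length(ids1))
      slot1 <- 2 * pi / length(ids1)
      for (i in cand) {
        d <- abs(((ang1[free1] - ang0[i] + pi) %% (2 * pi)) - pi)
        j <- free1[which.min(d)]
        if (length(j) == 0 || used1[j] || min(d) > 2.2 * slot1) next
        used1[j] <- TRUE
        p0 <- c(nodes_x[ids0[i]], nodes_y[ids0[i]])
        p1 <- c(nodes_x[ids1[j]], nodes_y[ids1[j]])
        xy <- sample_line(p0, p1)
        add_seg(ids0[i], ids1[j], xy, cap_rad_profile(nrow(xy)), "capillary")
      }
    }

    # --- spokes (arteries and veins) -------------------------------------
    inlets <- integer(0); outlets <- integer(0)
    # boundary stubs start at the nerve head, spaced so that adjacent trunk
    # vessels do not touch (chord between roots > vessel diameters + margin)
    rmax_bnd <- max(cfg$radius_artery, cfg$radius_vein)
    r_root <- min(r_inner / 2,
                  max(5, (2 * rmax_bnd + 6) / (2 * sin(pi / n_sp))))
    for (j in seq_len(n_sp)) {
      kind <- kinds[j]
      th <- spoke_theta[j]
      root <- add_node(r_root * cos(th), r_root * sin(th))
      if (kind == "artery") inlets <- c(inlets, root) else outlets <- c(outlets, root)
      chain <- c(root, vapply(0:K, function(k) {
        ids <- ring_node_id[[k + 1L]]
        ids[which(ring_spoke[[k + 1L]] == j)]
      }, integer(1)))
      for (k in seq_len(length(chain) - 1L)) {
        p0 <- c(nodes_x[chain[k]], nodes_y[chain[k]])
        p1 <- c(nodes_x[chain[k + 1L]], nodes_y[chain[k + 1L]])
        xy <- sample_line(p0, p1)
        rr <- sqrt(rowSums(xy^2))
        add_seg(chain[k], chain[k + 1L], xy, spoke_radius(kind, rr), kind)
      }
    }

    # --- sprout stubs at the outer rim -----------------------------------
    idsK <- ring_node_id[[K + 1L]]; angK <- ring_theta[[K + 1L]]
    radK <- ring_rad[[K + 1L]]; spkK <- ring_spoke[[K + 1L]]
    fillK <- which(spkK == 0L)
    sprout_at <- fillK[seq_along(fillK) %% 2L == 0L]
    for (i in sprout_at) {
      th <- angK[i] + runif(1, -0.08, 0.08)
      tip_r <- min(radK[i] + sprout_len, cfg$retina_radius - 1)
      tip <- add_node(tip_r * cos(th), tip_r * sin(th))
      p0 <- c(nodes_x[idsK[i]], nodes_y[idsK[i]])
      p1 <- c(nodes_x[tip], nodes_y[tip])
      xy <- sample_line(p0, p1, step = 5)
      add_seg(idsK[i], tip, xy, rep(0.9 * cfg$radius_capillary, nrow(xy)),
              "sprouting_front")
    }

    # --- merge degree-2 chains so every emitted node is a tip or a branch
    # point (matching what centerline extraction recovers) -----------------
    seg_list <- merge_deg2_chains(seg_list)

    # --- assemble ---------------------------------------------------------
    cx <- cfg$optic_center[1]; cy <- cfg$optic_center[2]
    a_ids <- vapply(seg_list, `[[`, integer(1), "a")
    b_ids <- vapply(seg_list, `[[`, integer(1), "b")
    used <- sort(unique(c(a_ids, b_ids)))
    remap <- integer(length(nodes_x)); remap[used] <- seq_along(used)
    nodes <- data.frame(id = seq_along(used),
                        x = nodes_x[used] + cx, y = nodes_y[used] + cy)
    segments <- data.frame(
      id = seq_along(seg_list),
      a = remap[a_ids], b = remap[b_ids],
      region = vapply(seg_list, `[[`, character(1), "region"),
      lumen_fraction = 1, has_matrix = TRUE,
      stage = NA_character_, cell_count = NA_real_)
    geometry <- lapply(seg_list, function(s) {
      s$xy + matrix(c(cx, cy), nrow(s$xy), 2, byrow = TRUE)
    })
    radius_profiles <- lapply(seg_list, `[[`, "rad")
    vessel_network(nodes, segments, geometry, radius_profiles,
                   meta = list(inlets = remap[inlets], outlets = remap[outlets],
                               optic_center = cfg$optic_center,
                               retina_radius = cfg$retina_radius,
                               pixel_size = cfg$pixel_size, seed = cfg$seed))
  })
}

# Merge chains of degree-2 nodes in a raw segment list (elements: a, b, xy,
# rad, region). Pure all-degree-2 cycles are left untouched.
merge_deg2_chains <- function(segs) {
  if (length(segs) < 2) return(segs)
  ends_a <- vapply(segs, `[[`, integer(1), "a")
  ends_b <- vapply(segs, `[[`, integer(1), "b")
  deg <- table(c(ends_a, ends_b))
  incid <- split(rep(seq_along(segs), 2), c(ends_a, ends_b))
  visited <- logical(length(segs))
  orient_from <- function(s, nd) {
    if (s$a == nd) return(s)
    s2 <- s
    s2$a <- s$b; s2$b <- s$a
    s2$xy <- s$xy[nrow(s$xy):1, , drop = FALSE]
    s2$rad <- rev(s$rad)
    s2
  }
  out <- list()
  for (k in seq_along(segs)) {
    if (visited[k]) next
    s <- segs[[k]]
    da <- deg[as.character(s$a)]; db <- deg[as.character(s$b)]
    if (da == 2 && db == 2) next  # chain interior; reached from an end
    cur <- if (da != 2) s else orient_from(s, s$b)
    visited[k] <- TRUE
    repeat {
      nd <- cur$b
      if (deg[as.character(nd)] != 2) break
      nxt <- incid[[as.character(nd)]]
      nxt <- nxt[!visited[nxt]]
      if (!length(nxt)) break
      nseg <- orient_from(segs[[nxt[1]]], nd)
      visited[nxt[1]] <- TRUE
      cur$b <- nseg$b
      cur$xy <- rbind(cur$xy, nseg$xy[-1, , drop = FALSE])
      cur$rad <- c(cur$rad, nseg$rad[-1])
    }
    out[[length(out) + 1L]] <- cur
  }
  c(out, segs[!visited])
}
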