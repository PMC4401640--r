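# Centerline extraction: binary lumen mask -> 1-px skeleton + distance map
# -> vessel graph with per-segment radius profiles.

# shift a logical/numeric matrix by (dr, dc), zero-filled
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# Zhang-Suen morphological thinning to a 1-px, 8-connected medial skeleton.
# `anchor` marks pixels that may never be deleted (distance-transform ridge
# points), which keeps the medial axis of blind-ended branches from being
# eroded away.
zhang_suen <- function(img, anchor = NULL) {
  img <- (img != 0) * 1
  if (is.null(anchor)) anchor <- matrix(FALSE, nrow(img), ncol(img))
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      # neighbours in Zhang-Suen order P2..P9 (N, NE, E, SE, S, SW, W, NW);
      # rows increase downwards, so "N" is row - 1
      P2 <- shift_mat(img, 1, 0)   # value of the pixel's north neighbour
      P3 <- shift_mat(img, 1, -1)
      P4 <- shift_mat(img, 0, -1)
      P5 <- shift_mat(img, -1, -1)
      P6 <- shift_mat(img, -1, 0)
      P7 <- shift_mat(img, -1, 1)
      P8 <- shift_mat(img, 0, 1)
      P9 <- shift_mat(img, 1, 1)
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- (P2 == 0 & P3 == 1) + (P3 == 0 & P4 == 1) + (P4 == 0 & P5 == 1) +
           (P5 == 0 & P6 == 1) + (P6 == 0 & P7 == 1) + (P7 == 0 & P8 == 1) +
           (P8 == 0 & P9 == 1) + (P9 == 0 & P2 == 1)
      if (sub == 1) {
        cond <- img == 1 & !anchor & B >= 2 & B <= 6 & A == 1 &
          (P2 * P4 * P6 == 0) & (P4 * P6 * P8 == 0)
      } else {
        cond <- img == 1 & !anchor & B >= 2 & B <= 6 & A == 1 &
          (P2 * P4 * P8 == 0) & (P2 * P6 * P8 == 0)
      }
      if (any(cond)) {
        img[cond] <- 0
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  img == 1
}

# Sequential removal of 8-simple pixels to enforce a unit-width skeleton.
# Zhang-Suen (a parallel scheme) leaves 2-px staircases on diagonal runs;
# deleting simple points (foreground neighbours form a single 8-connected
# set, at least one 4-neighbour is background, pixel is not an endpoint)
# thins them to single-pixel paths without changing topology.
unit_width <- function(skel) {
  # ring coordinates N, NE, E, SE, S, SW, W, NW and their mutual adjacencies
  ring <- matrix(c(-1, 0, -1, 1, 0, 1, 1, 1, 1, 0, 1, -1, 0, -1, -1, -1),
                 ncol = 2, byrow = TRUE)
  adj <- list(c(2, 8, 3, 7), c(1, 3), c(2, 4, 1, 5), c(3, 5), c(4, 6, 3, 7),
              c(5, 7), c(6, 8, 5, 1), c(7, 1))
  nr <- nrow(skel); nc <- ncol(skel)
  repeat {
    pix <- which(skel, arr.ind = TRUE)
    pix <- pix[order(pix[, 1], pix[, 2]), , drop = FALSE]
    removed <- FALSE
    for (k in seq_len(nrow(pix))) {
      r <- pix[k, 1]; c <- pix[k, 2]
      if (!skel[r, c]) next
      rr <- r + ring[, 1]; cc <- c + ring[, 2]
      ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
      fg <- logical(8)
      fg[ok] <- skel[cbind(rr[ok], cc[ok])]
      B <- sum(fg)
      if (B < 2 || B > 6) next
      if (fg[1] && fg[3] && fg[5] && fg[7]) next  # no background 4-neighbour
      # connected components of fg neighbours (union-find over ring adjacency)
      parent <- seq_len(8)
      find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
      for (i in which(fg)) for (j in adj[[i]]) {
        if (j > i && fg[j]) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[rj] <- ri
        }
      }
      comps <- length(unique(vapply(which(fg), find, integer(1))))
      if (comps == 1) {
        skel[r, c] <- FALSE
        removed <- TRUE
      }
    }
    if (!removed) break
  }
  skel
}

#' Skeletonize a binary vessel mask
#'
#' Reduces the largest connected component of a binary mask to a 1-px-wide
#' medial-axis skeleton (Zhang–Suen thinning) and returns the Euclidean
#' distance transform of that component alongside, from which vessel radii
#' are read. Smaller disconnected blobs are dropped (documented behaviour).
#'
#' @param mask binary matrix (anything non-zero is foreground).
#' @param min_hole_area background holes smaller than this (px^2) are filled
#'   before thinning; sub-resolution holes left by disk rasterization at
#'   junctions would otherwise create spurious skeleton loops. Genuine mesh
#'   openings are orders of magnitude larger.
#' @return list: `skeleton` (logical matrix), `distance` (numeric matrix,
#'   px units), `n_components_dropped`.
#' @export
skeletonize <- function(mask, min_hole_area = 25) {
  m <- (as.matrix(mask) != 0)
  if (!any(m)) stop_input("empty mask")
  lab <- EBImage::bwlabel(m * 1)
  tab <- tabulate(lab[lab > 0])
  keep <- which.max(tab)
  m <- lab == keep
  if (min_hole_area > 0) {
    bg <- EBImage::bwlabel((!m) * 1)
    sz <- tabulate(bg[bg > 0])
    border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
    small <- which(sz < min_hole_area)
    small <- setdiff(small, border)
    if (length(small)) m[bg %in% small] <- TRUE
  }
  dist <- as.matrix(EBImage::distmap(m * 1))
  # anchor the distance-transform ridge (3x3 local maxima away from the
  # boundary): thinning may not delete medial-axis points, so the spine of
  # blind-ended branches survives
  nb_max <- matrix(0, nrow(m), ncol(m))
  for (k in seq_len(nrow(NB_OFFSETS))) {
    nb_max <- pmax(nb_max, shift_mat(dist, NB_OFFSETS[k, 1], NB_OFFSETS[k, 2]))
  }
  anchor <- m & (dist + 1e-9 >= nb_max) & dist >= 1.5
  list(skeleton = unit_width(zhang_suen(m, anchor)), distance = dist,
       n_components_dropped = length(tab) - 1L)
}

NB_OFFSETS <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                    dc = c(-1, 0, 1, -1, 1, -1, 0, 1))

# indices of 8-neighbour skeleton pixels of linear index i in matrix M
# (M holds 0 for background, pixel rank otherwise)
skel_neighbors <- function(r, c, M) {
  rr <- r + NB_OFFSETS[, 1]; cc <- c + NB_OFFSETS[, 2]
  ok <- rr >= 1 & rr <= nrow(M) & cc >= 1 & cc <= ncol(M)
  idx <- M[cbind(rr[ok], cc[ok])]
  sort(idx[idx > 0])
}

#' Build a vessel graph from a skeleton and distance map
#'
#' Skeleton pixels with other than 2 neighbours become nodes (degree-1 tips
#' and degree >= 3 branch points; adjacent node pixels are clustered into a
#' single node at their centroid), maximal paths between nodes become
#' segments. The radius profile is the distance-map value along the path
#' times `pixel_size`; the per-segment `mean_radius` excludes the 3 px
#' nearest each node, where distance-transform radii inflate at junctions.
#' Spur segments shorter than `prune_length` are removed, short internal
#' segments (thinning artefacts at wide junctions) shorter than
#' `fuse_length` are contracted, and degree-2 node chains merged. Path
#' tracing visits pixels in lexicographic order, so extraction is
#' deterministic.
#'
#' @param skeleton,distance output of [skeletonize()].
#' @param pixel_size um per pixel.
#' @param origin physical position (um) of the outer corner of pixel (1,1).
#' @param prune_length spur-pruning threshold (um; default 4 pixels).
#' @param fuse_length junction-fusion threshold (um; default 3 pixels).
#' @return A [vessel_network()] with `region = "unknown"` everywhere.
#' @export
build_graph <- function(skeleton, distance, pixel_size = 1, origin = c(0, 0),
                        prune_length = 4 * pixel_size,
                        fuse_length = 3 * pixel_size) {
  if (!any(skeleton)) stop_input("empty skeleton")
  nr <- nrow(skeleton)
  pix <- which(skeleton, arr.ind = TRUE)
  pix <- pix[order(pix[, 1], pix[, 2]), , drop = FALSE]
  np <- nrow(pix)
  M <- matrix(0L, nr, ncol(skeleton))
  M[pix] <- seq_len(np)
  nb_count <- integer(np)
  nb_list <- vector("list", np)
  for (i in seq_len(np)) {
    nb <- skel_neighbors(pix[i, 1], pix[i, 2], M)
    nb_list[[i]] <- nb
    nb_count[i] <- length(nb)
  }
  is_node <- nb_count != 2L
  # cluster adjacent node pixels (8-connectivity BFS)
  cluster <- integer(np)
  ncl <- 0L
  for (i in which(is_node)) {
    if (cluster[i] > 0L) next
    ncl <- ncl + 1L
    queue <- i
    cluster[i] <- ncl
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      for (q in nb_list[[cur]]) {
        if (is_node[q] && cluster[q] == 0L) {
          cluster[q] <- ncl
          queue <- c(queue, q)
        }
      }
    }
  }
  visited <- logical(np)
  raw <- list()
  add_raw <- function(c1, c2, path_idx) {
    raw[[length(raw) + 1L]] <<- list(a = c1, b = c2, path = path_idx)
  }
  # walks from node clusters through regular pixels
  for (i in which(is_node)) {
    for (q in nb_list[[i]]) {
      if (is_node[q] || visited[q]) next
      path <- c(i, q)
      visited[q] <- TRUE
      prev <- i; cur <- q
      end_cluster <- NA_integer_
      repeat {
        nbs <- setdiff(nb_list[[cur]], prev)
        node_nbs <- nbs[is_node[nbs]]
        # don't jump back into the start cluster through a junction-blob
        # diagonal on the very first step
        if (length(path) == 2L) {
          node_nbs <- node_nbs[!(cluster[node_nbs] == cluster[i] &
                                   node_nbs %in% nb_list[[i]])]
        }
        if (length(node_nbs)) {
          path <- c(path, node_nbs[1])
          end_cluster <- cluster[node_nbs[1]]
          break
        }
        reg <- nbs[!is_node[nbs] & !visited[nbs]]
        if (!length(reg)) break  # dead end (shouldn't occur) or closed walk
        nxt <- reg[1]
        path <- c(path, nxt)
        visited[nxt] <- TRUE
        prev <- cur; cur <- nxt
      }
      if (!is.na(end_cluster)) add_raw(cluster[i], end_cluster, path)
    }
  }
  # direct node-node adjacencies between different clusters (no regular
  # pixel in between), deduped per cluster pair
  seen_pair <- character(0)
  for (i in which(is_node)) {
    for (q in nb_list[[i]]) {
      if (!is_node[q] || cluster[q] == cluster[i]) next
      key <- paste(min(cluster[i], cluster[q]), max(cluster[i], cluster[q]))
      if (key %in% seen_pair) next
      seen_pair <- c(seen_pair, key)
      add_raw(cluster[i], cluster[q], c(i, q))
    }
  }
  # isolated cycles: unvisited regular pixels form pure loops
  for (i in seq_len(np)) {
    if (is_node[i] || visited[i]) next
    ncl <- ncl + 1L
    cluster[i] <- ncl
    is_node[i] <- TRUE
    for (q in nb_list[[i]]) {
      if (!is_node[q] && !visited[q]) {
        path <- c(i, q)
        visited[q] <- TRUE
        prev <- i; cur <- q
        repeat {
          nbs <- setdiff(nb_list[[cur]], prev)
          if (any(nbs == i)) { path <- c(path, i); break }
          reg <- nbs[!is_node[nbs] & !visited[nbs]]
          if (!length(reg)) break
          nxt <- reg[1]
          path <- c(path, nxt); visited[nxt] <- TRUE
          prev <- cur; cur <- nxt
        }
        if (path[length(path)] == i) add_raw(ncl, ncl, path)
        break
      }
    }
  }
  if (!length(raw)) stop_input("skeleton yields no segments")

  # cluster centroids (pixel coords)
  cent_r <- tapply(pix[, 1][cluster > 0], cluster[cluster > 0], mean)
  cent_c <- tapply(pix[, 2][cluster > 0], cluster[cluster > 0], mean)
  to_um <- function(r, c) cbind(origin[1] + (c - 0.5) * pixel_size,
                                origin[2] + (r - 0.5) * pixel_size)
  segs <- lapply(raw, function(s) {
    p <- s$path
    xy <- to_um(pix[p, 1], pix[p, 2])
    # the distance transform reaches to the nearest *background pixel
    # centre*, half a pixel beyond the vessel boundary; calibrate it out
    rad <- pmax(distance[pix[p, , drop = FALSE]] - 0.5, 0.5) * pixel_size
    # endpoints at cluster centroids
    xy[1, ] <- to_um(cent_r[as.character(s$a)], cent_c[as.character(s$a)])
    xy[nrow(xy), ] <- to_um(cent_r[as.character(s$b)], cent_c[as.character(s$b)])
    list(a = s$a, b = s$b, xy = xy, rad = rad)
  })

  seg_len <- function(s) polyline_length(s$xy)
  # --- spur pruning (iterative) ---
  repeat {
    if (!length(segs)) break
    ends <- c(vapply(segs, `[[`, numeric(1), "a"), vapply(segs, `[[`, numeric(1), "b"))
    deg <- table(ends)
    lens <- vapply(segs, seg_len, numeric(1))
    spur <- vapply(seq_along(segs), function(k) {
      s <- segs[[k]]
      (deg[as.character(s$a)] == 1 || deg[as.character(s$b)] == 1) &&
        lens[k] < prune_length && length(segs) > 1
    }, logical(1))
    if (!any(spur)) break
    segs <- segs[!spur]
  }
  # --- fuse short internal segments (contract node pairs) ---
  repeat {
    if (!length(segs)) break
    ends <- c(vapply(segs, `[[`, numeric(1), "a"), vapply(segs, `[[`, numeric(1), "b"))
    deg <- table(ends)
    lens <- vapply(segs, seg_len, numeric(1))
    k <- which(vapply(seq_along(segs), function(k) {
      s <- segs[[k]]
      # thinning splits an X crossing into two T's separated by roughly the
      # vessel width; the distance map along that short connector carries the
      # local radius, so the fusion threshold adapts to it
      thr <- max(fuse_length, 1.2 * (max(s$rad) + 0.5 * pixel_size))
      s$a != s$b && lens[k] < thr &&
        deg[as.character(s$a)] >= 3 && deg[as.character(s$b)] >= 3
    }, logical(1)))[1]
    if (is.na(k)) break
    s <- segs[[k]]
    keep_id <- min(s$a, s$b); drop_id <- max(s$a, s$b)
    new_xy <- (s$xy[1, ] + s$xy[nrow(s$xy), ]) / 2
    segs <- segs[-k]
    segs <- lapply(segs, function(t) {
      if (t$a %in% c(keep_id, drop_id)) { t$a <- keep_id; t$xy[1, ] <- new_xy }
      if (t$b %in% c(keep_id, drop_id)) { t$b <- keep_id; t$xy[nrow(t$xy), ] <- new_xy }
      t
    })
  }
  # fusing two junction clusters that were also connected by a second short
  # path leaves a tiny self-loop; drop those artefacts
  if (length(segs)) {
    lens <- vapply(segs, seg_len, numeric(1))
    arte <- vapply(seq_along(segs), function(k) {
      s <- segs[[k]]
      s$a == s$b &&
        lens[k] < 2 * max(fuse_length, 1.2 * (max(s$rad) + 0.5 * pixel_size))
    }, logical(1))
    segs <- segs[!arte]
  }
  # --- merge degree-2 node chains ---
  repeat {
    if (length(segs) < 2) break
    ends <- c(vapply(segs, `[[`, numeric(1), "a"), vapply(segs, `[[`, numeric(1), "b"))
    deg <- table(ends)
    two <- as.numeric(names(deg)[deg == 2])
    merged <- FALSE
    for (nd in two) {
      inc <- which(vapply(segs, function(s) s$a == nd || s$b == nd, logical(1)))
      if (length(inc) != 2) next  # self-loop through nd
      s1 <- segs[[inc[1]]]; s2 <- segs[[inc[2]]]
      # orient s1 to end at nd, s2 to start at nd
      if (s1$a == nd) { s1$xy <- s1$xy[nrow(s1$xy):1, , drop = FALSE]
                        s1$rad <- rev(s1$rad); tmp <- s1$a; s1$a <- s1$b; s1$b <- tmp }
      if (s2$b == nd) { s2$xy <- s2$xy[nrow(s2$xy):1, , drop = FALSE]
                        s2$rad <- rev(s2$rad); tmp <- s2$a; s2$a <- s2$b; s2$b <- tmp }
      new <- list(a = s1$a, b = s2$b,
                  xy = rbind(s1$xy, s2$xy[-1, , drop = FALSE]),
                  rad = c(s1$rad, s2$rad[-1]))
      segs <- c(segs[-inc], list(new))
      merged <- TRUE
      break
    }
    if (!merged) break
  }

  # smooth the pixel-staircase centerlines (moving average over 5 vertices,
  # endpoints pinned) so tangents, lengths, and local flow directions are not
  # quantized to pixel steps
  segs <- lapply(segs, function(s) {
    n <- nrow(s$xy)
    if (n >= 5) {
      sm <- s$xy
      for (d in c(-2, -1, 1, 2)) {
        idx <- pmin(pmax(seq_len(n) + d, 1), n)
        sm <- sm + s$xy[idx, , drop = FALSE]
      }
      sm <- sm / 5
      sm[1, ] <- s$xy[1, ]; sm[n, ] <- s$xy[n, ]
      s$xy <- sm
    }
    s
  })

  # --- assemble vessel_network ---
  used <- sort(unique(c(vapply(segs, `[[`, numeric(1), "a"),
                        vapply(segs, `[[`, numeric(1), "b"))))
  node_xy <- t(vapply(used, function(u) {
    # node coordinate: endpoint of some incident segment
    for (s in segs) {
      if (s$a == u) return(s$xy[1, ])
      if (s$b == u) return(s$xy[nrow(s$xy), ])
    }
  }, numeric(2)))
  remap <- setNames(seq_along(used), used)
  nodes <- data.frame(id = seq_along(used), x = node_xy[, 1], y = node_xy[, 2])
  segments <- data.frame(
    id = seq_along(segs),
    a = as.integer(remap[as.character(vapply(segs, `[[`, numeric(1), "a"))]),
    b = as.integer(remap[as.character(vapply(segs, `[[`, numeric(1), "b"))]),
    region = "unknown", lumen_fraction = 1, has_matrix = TRUE,
    stage = NA_character_, cell_count = NA_real_)
  geometry <- lapply(segs, `[[`, "xy")
  radius_profiles <- lapply(segs, `[[`, "rad")
  net <- vessel_network(nodes, segments, geometry, radius_profiles,
                        meta = list(pixel_size = pixel_size, origin = origin))
  # junction-guarded mean radius (exclude 3 px nearest each node)
  net$segments$mean_radius <- vapply(radius_profiles, function(p) {
    n <- length(p)
    if (n > 7) mean(p[4:(n - 3)]) else mean(p[max(1, ceiling(n / 2))])
  }, numeric(1))
  net
}

#' Annotate extracted segments with marker-channel coverage
#'
#' Sets per-segment `lumen_fraction` (fraction of polyline vertices whose
#' lumen channel is positive within the local radius) and `has_matrix`
#' (matrix channel positive over at least `matrix_frac` of vertices).
#'
#' @param net a [vessel_network()] in the stack's coordinate frame.
#' @param stack an [image_stack()] with `lumen` and `matrix` channels.
#' @param matrix_frac coverage threshold for `has_matrix` (default 0.9).
#' @return The annotated network.
#' @export
annotate_segments <- function(net, stack, matrix_frac = 0.9) {
  for (ch in c("lumen", "matrix")) {
    if (is.null(stack$channels[[ch]])) stop_input("missing required channel '", ch, "'")
  }
  px <- stack$pixel_size
  lum <- stack$channels$lumen
  mat <- stack$channels$matrix
  nr <- nrow(lum); nc <- ncol(lum)
  sample_positive <- function(chan, x, y, r) {
    ci <- floor((x - stack$origin[1]) / px) + 1L
    ri <- floor((y - stack$origin[2]) / px) + 1L
    w <- max(0L, min(3L, floor(r / px)))
    hit <- logical(length(x))
    for (dr in -w:w) for (dc in -w:w) {
      if (dr^2 + dc^2 > (w + 0.5)^2) next
      rr <- ri + dr; cc <- ci + dc
      ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
      hit[ok] <- hit[ok] | chan[cbind(rr[ok], cc[ok])] > 0
    }
    hit
  }
  # widest vessel incident to each node, for the junction guard below
  segs <- net$segments
  node_rmax <- tapply(rep(segs$mean_radius, 2), c(segs$a, segs$b), max)
  for (i in seq_len(nrow(net$segments))) {
    g <- net$geometry[[i]]
    r <- net$segments$mean_radius[i]
    # junction guard: vertices inside a neighbour's footprint at either node
    # would read the neighbour's lumen, so restrict to interior vertices
    cl <- polyline_cumlen(g)
    L <- cl[length(cl)]
    rj <- max(node_rmax[as.character(segs$a[i])],
              node_rmax[as.character(segs$b[i])], r, na.rm = TRUE)
    guard <- min(0.4 * L, 1.2 * rj + 3 * px)
    interior <- cl >= guard & cl <= L - guard
    if (!any(interior)) interior[which.min(abs(cl - L / 2))] <- TRUE
    lum_hit <- sample_positive(lum, g[interior, 1], g[interior, 2], r)
    mat_hit <- sample_positive(mat, g[interior, 1], g[interior, 2], r)
    net$segments$lumen_fraction[i] <- mean(lum_hit)
    net$segments$has_matrix[i] <- mean(mat_hit) >= matrix_frac
  }
  net
}
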