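# Nucleus-to-Golgi axial polarity and its relation to local flow.

#' Pair nucleus and Golgi point sets into cells
#'
#' Greedy globally-nearest one-to-one matching: the closest available
#' nucleus-Golgi pair is accepted repeatedly until no candidate pair within
#' `max_pair_dist` remains. Unpaired nuclei are retained with an undefined
#' polarity vector and `paired = FALSE`.
#'
#' @param nuclei,golgis n x 2 matrices or data.frames of 2D points (um), in
#'   the same coordinate frame.
#' @param max_pair_dist maximum nucleus-Golgi separation (um, default 10).
#' @return A `cell_table` data.frame: `cell_id`, `nucleus_x/y`, `golgi_x/y`,
#'   `px`, `py` (polarity vector Golgi - nucleus), `pmag`, `paired`.
#' @export
pair_points <- function(nuclei, golgis, max_pair_dist = 10) {
  nuc <- as.matrix(nuclei); gol <- as.matrix(golgis)
  nn <- nrow(nuc); ng <- nrow(gol)
  if (nn == 0) {
    return(empty_cell_table())
  }
  pair <- rep(NA_integer_, nn)
  if (ng > 0) {
    # candidate pairs within range, greedily accepted in distance order
    cand_i <- integer(0); cand_j <- integer(0); cand_d <- numeric(0)
    for (i in seq_len(nn)) {
      d <- sqrt((gol[, 1] - nuc[i, 1])^2 + (gol[, 2] - nuc[i, 2])^2)
      j <- which(d <= max_pair_dist)
      cand_i <- c(cand_i, rep(i, length(j)))
      cand_j <- c(cand_j, j)
      cand_d <- c(cand_d, d[j])
    }
    ord <- order(cand_d, cand_i, cand_j)
    used_g <- logical(ng)
    for (k in ord) {
      i <- cand_i[k]; j <- cand_j[k]
      if (is.na(pair[i]) && !used_g[j]) {
        pair[i] <- j; used_g[j] <- TRUE
      }
    }
  }
  gx <- ifelse(is.na(pair), NA_real_, gol[pair, 1])
  gy <- ifelse(is.na(pair), NA_real_, gol[pair, 2])
  out <- data.frame(cell_id = seq_len(nn),
                    nucleus_x = nuc[, 1], nucleus_y = nuc[, 2],
                    golgi_x = gx, golgi_y = gy,
                    px = gx - nuc[, 1], py = gy - nuc[, 2],
                    paired = !is.na(pair))
  out$pmag <- sqrt(out$px^2 + out$py^2)
  class(out) <- c("cell_table", "data.frame")
  out
}

empty_cell_table <- function() {
  out <- data.frame(cell_id = integer(0), nucleus_x = numeric(0),
                    nucleus_y = numeric(0), golgi_x = numeric(0),
                    golgi_y = numeric(0), px = numeric(0), py = numeric(0),
                    paired = logical(0), pmag = numeric(0))
  class(out) <- c("cell_table", "data.frame")
  out
}

# ensure a cell table has the derived polarity columns
ensure_polarity_columns <- function(cells) {
  if (is.null(cells$px)) {
    cells$px <- cells$golgi_x - cells$nucleus_x
    cells$py <- cells$golgi_y - cells$nucleus_y
  }
  if (is.null(cells$pmag)) cells$pmag <- sqrt(cells$px^2 + cells$py^2)
  cells
}

#' Assign cells to their nearest vessel segment
#'
#' Each cell is assigned to the segment whose centerline polyline is nearest
#' to its nucleus; ties break to the lower segment id. Cells farther than
#' `max_assign_dist` are left unassigned (`segment_id = NA`) and excluded
#' from flow statistics downstream.
#'
#' @param cells a `cell_table` (see [pair_points()] or [generate_cells()]).
#' @param net a [vessel_network()].
#' @param max_assign_dist maximum nucleus-to-centerline distance (um).
#' @return The cell table with `segment_id`, `vertex` (nearest polyline
#'   vertex), `distance_to_segment` (um), and `region` columns.
#' @export
assign_to_segments <- function(cells, net, max_assign_dist = 15) {
  cells <- ensure_polarity_columns(cells)
  if (nrow(cells) == 0) {
    cells$segment_id <- integer(0); cells$vertex <- integer(0)
    cells$distance_to_segment <- numeric(0); cells$region <- character(0)
    return(cells)
  }
  vt <- vertex_table(net)
  nn <- nn_lookup(as.matrix(vt[, c("x", "y")]),
                  cbind(cells$nucleus_x, cells$nucleus_y))
  seg0 <- vt$segment_id[nn$index]
  # the nearest vertex may belong to a neighbouring segment near a junction;
  # refine by exact point-to-polyline distance over the nearest segment and
  # every segment sharing a node with it (ties break to the lower id)
  segs <- net$segments
  incid <- split(rep(segs$id, 2), c(segs$a, segs$b))
  seg <- integer(nrow(cells)); vert <- integer(nrow(cells))
  dist <- numeric(nrow(cells))
  poly_dist <- function(px, py, g) {
    if (nrow(g) < 2) return(sqrt((g[1, 1] - px)^2 + (g[1, 2] - py)^2))
    min(point_seg_dist(px, py, g[-nrow(g), 1], g[-nrow(g), 2],
                       g[-1, 1], g[-1, 2]))
  }
  for (i in seq_len(nrow(cells))) {
    k0 <- match(seg0[i], segs$id)
    cand <- sort(unique(c(seg0[i],
                          incid[[as.character(segs$a[k0])]],
                          incid[[as.character(segs$b[k0])]])))
    best <- NA_integer_; bd <- Inf
    for (sid in cand) {
      d <- poly_dist(cells$nucleus_x[i], cells$nucleus_y[i],
                     net$geometry[[match(sid, segs$id)]])
      if (d < bd - 1e-12) { bd <- d; best <- sid }
    }
    seg[i] <- best; dist[i] <- bd
    g <- net$geometry[[match(best, segs$id)]]
    vert[i] <- which.min((g[, 1] - cells$nucleus_x[i])^2 +
                           (g[, 2] - cells$nucleus_y[i])^2)
  }
  too_far <- dist > max_assign_dist
  seg[too_far] <- NA_integer_; vert[too_far] <- NA_integer_
  cells$segment_id <- seg
  cells$vertex <- vert
  cells$distance_to_segment <- dist
  cells$region <- net$segments$region[match(seg, net$segments$id)]
  cells
}

#' Angle to flow and scalar product per cell
#'
#' For each assigned cell on a perfused segment, computes the angle `theta`
#' (degrees, in `[0, 180]`) between the polarity vector and the oriented flow
#' direction at the cell's nearest polyline vertex, and the scalar product
#' `s = |p| cos(theta)` (um; positive = polarized with flow, negative =
#' against). Cells on non-perfused segments, unassigned cells, and cells with
#' `|p| = 0` get `NA`.
#'
#' @param cells output of [assign_to_segments()].
#' @param net the [vessel_network()].
#' @param flow a [wall_shear()] solution (flow directions required).
#' @return The cell table with `theta_deg`, `scalar_product`, `against_flow`
#'   (`theta in [135, 180]`, closed interval) columns.
#' @export
angle_and_scalar <- function(cells, net, flow) {
  if (is.null(flow$flow_dir)) stop_precondition("flow directions missing; run wall_shear()")
  cells <- ensure_polarity_columns(cells)
  n <- nrow(cells)
  theta <- rep(NA_real_, n); s <- rep(NA_real_, n)
  if (n > 0 && !is.null(cells$segment_id)) {
    seg_idx <- match(cells$segment_id, net$segments$id)
    for (i in seq_len(n)) {
      k <- seg_idx[i]
      if (is.na(k) || is.na(cells$vertex[i])) next
      fd <- flow$flow_dir[[k]]
      v <- min(cells$vertex[i], nrow(fd))
      f <- fd[v, ]
      if (anyNA(f)) next
      p <- c(cells$px[i], cells$py[i])
      pm <- cells$pmag[i]
      if (is.na(pm) || pm == 0) next
      sp <- sum(p * f)                  # |f| = 1, so this is |p| cos(theta)
      cth <- min(max(sp / pm, -1), 1)
      theta[i] <- rad2deg(acos(cth))
      s[i] <- sp
    }
  }
  cells$theta_deg <- theta
  cells$scalar_product <- s
  cells$against_flow <- !is.na(theta) & theta >= 135
  cells$against_flow[is.na(theta)] <- NA
  cells
}

circular_summary <- function(theta_deg) {
  t <- deg2rad(theta_deg[!is.na(theta_deg)])
  if (!length(t)) return(list(mean_deg = NA_real_, resultant = NA_real_))
  C <- mean(cos(t)); S <- mean(sin(t))
  list(mean_deg = rad2deg(atan2(S, C)) %% 360, resultant = sqrt(C^2 + S^2))
}

#' Per-region polarity statistics
#'
#' For each region (and pooled over all cells): number of angle-defined
#' cells, fraction polarized against flow (`theta` in the closed window
#' `[135, 180]`, i.e. 180 degrees +/- 45), circular mean and resultant length
#' of `theta`, mean polarity magnitude, and a 12-bin (15-degree) histogram of
#' `theta`. If a `replicate` column is present, the mean of per-replicate
#' against-flow fractions is also reported (`frac_against_replicate_mean`),
#' alongside the pooled per-cell fraction.
#'
#' @param cells output of [angle_and_scalar()].
#' @param window against-flow window in degrees (closed; default `c(135, 180)`).
#' @return A list of class `polarity_stats`: `by_region` data.frame and
#'   `histograms` (named list of 12-bin counts).
#' @export
region_stats <- function(cells, window = c(135, 180)) {
  regions <- c(sort(unique(cells$region[!is.na(cells$region)])), "all")
  rows <- list(); hists <- list()
  breaks <- seq(0, 180, by = 15)
  for (rg in regions) {
    sub <- if (rg == "all") cells else cells[!is.na(cells$region) & cells$region == rg, ]
    th <- sub$theta_deg
    ok <- !is.na(th)
    n <- sum(ok)
    frac <- if (n > 0) mean(th[ok] >= window[1] & th[ok] <= window[2]) else NA_real_
    circ <- circular_summary(th)
    frep <- NA_real_
    if (!is.null(sub$replicate) && n > 0) {
      per <- tapply(th[ok] >= window[1] & th[ok] <= window[2], sub$replicate[ok], mean)
      frep <- mean(per)
    }
    rows[[rg]] <- data.frame(region = rg, n = n,
                             frac_against = frac,
                             frac_against_replicate_mean = frep,
                             circ_mean_deg = circ$mean_deg,
                             resultant = circ$resultant,
                             mean_pmag = if (nrow(sub)) mean(sub$pmag, na.rm = TRUE) else NA_real_)
    h <- if (n > 0) {
      tabulate(findInterval(pmin(th[ok], 180 - 1e-9), breaks), nbins = 12)
    } else rep(0L, 12)
    hists[[rg]] <- h
  }
  structure(list(by_region = do.call(rbind, rows), histograms = hists,
                 window = window),
            class = "polarity_stats")
}

#' Sign-stratified regression of scalar product on wall shear stress
#'
#' Ordinary least squares of the scalar product `s` (um) on the wall shear
#' stress `tau` (Pa) of the cell's segment, fitted separately on the `s > 0`
#' (with-flow) and `s < 0` (against-flow) strata and pooled, per region and
#' overall. Gradients carry units um/Pa. Strata with fewer than 3 cells or
#' with zero shear variance are skipped with a warning.
#'
#' @param cells output of [angle_and_scalar()].
#' @param flow a [wall_shear()] solution.
#' @return data.frame `region`, `stratum`, `gradient`, `intercept`, `R`, `n`.
#' @export
shear_regressions <- function(cells, flow) {
  tau <- flow$segments$tau[match(cells$segment_id, flow$segments$segment_id)]
  ok <- !is.na(cells$scalar_product) & !is.na(tau)
  d <- data.frame(s = cells$scalar_product[ok], tau = tau[ok],
                  region = cells$region[ok])
  regions <- c(sort(unique(d$region)), "all")
  out <- list()
  for (rg in regions) {
    sub <- if (rg == "all") d else d[d$region == rg, ]
    for (str in c("pooled", "positive", "negative")) {
      ss <- switch(str, pooled = sub, positive = sub[sub$s > 0, ],
                   negative = sub[sub$s < 0, ])
      if (nrow(ss) < 3) {
        warning(sprintf("stratum '%s' in region '%s' skipped: fewer than 3 cells",
                        str, rg))
        next
      }
      if (sd(ss$tau) == 0) {
        warning(sprintf("stratum '%s' in region '%s' skipped: zero shear variance",
                        str, rg))
        next
      }
      fit <- lm(s ~ tau, data = ss)
      out[[length(out) + 1L]] <- data.frame(
        region = rg, stratum = str,
        gradient = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
        R = cor(ss$s, ss$tau), n = nrow(ss))
    }
  }
  if (!length(out)) return(data.frame(region = character(0), stratum = character(0),
                                      gradient = numeric(0), intercept = numeric(0),
                                      R = numeric(0), n = integer(0)))
  do.call(rbind, out)
}

#' Project polarity vectors on a body axis
#'
#' Signed projection `p . axis` per cell, with the fractions projecting
#' positively ("dorsal"), negatively ("ventral"), and exactly zero. A
#' non-unit axis is normalized with a warning.
#'
#' @param cells a `cell_table` with polarity vectors.
#' @param axis unit 2-vector defining the dorsal direction.
#' @return list: `projection` (per-cell), `frac_dorsal`, `frac_ventral`,
#'   `frac_zero`, `n`.
#' @export
axis_projection <- function(cells, axis) {
  nrm <- sqrt(sum(axis^2))
  if (nrm == 0) stop_input("axis must be non-zero")
  if (abs(nrm - 1) > 1e-9) {
    warning("axis is not unit length; normalizing")
    axis <- axis / nrm
  }
  cells <- ensure_polarity_columns(cells)
  proj <- cells$px * axis[1] + cells$py * axis[2]
  ok <- !is.na(proj)
  list(projection = proj,
       frac_dorsal = if (any(ok)) mean(proj[ok] > 0) else NA_real_,
       frac_ventral = if (any(ok)) mean(proj[ok] < 0) else NA_real_,
       frac_zero = if (any(ok)) mean(proj[ok] == 0) else NA_real_,
       n = sum(ok))
}

# Seeded two-sided permutation test on a group difference in means.
# Returns the observed difference (g1 - g0) and p-value with B label perms.
permutation_group_test <- function(y, g, n_perm = 10000, seed = 1) {
  ok <- !is.na(y) & !is.na(g)
  y <- y[ok]; g <- as.logical(g[ok])
  n1 <- sum(g); n0 <- sum(!g); n <- length(y)
  if (n1 == 0 || n0 == 0) return(list(obs = NA_real_, p = NA_real_, n1 = n1, n0 = n0))
  obs <- mean(y[g]) - mean(y[!g])
  tot <- sum(y)
  with_substream(seed, 7L, {
    s1 <- vapply(seq_len(n_perm), function(b) sum(y[sample.int(n, n1)]), numeric(1))
    stat <- s1 / n1 - (tot - s1) / n0
    p <- (1 + sum(abs(stat) >= abs(obs) - 1e-12)) / (n_perm + 1)
    list(obs = obs, p = p, n1 = n1, n0 = n0)
  })
}

#' Polarity misalignment near regression sites and in low-shear segments
#'
#' Compares polarity magnitude `|p|` and the against-flow fraction between
#' (a) cells on low- versus high-shear segments ([classify_flow()] labels)
#' and (b) cells adjacent (nucleus within `adjacency_dist` of a detected
#' regression-profile centerline) versus non-adjacent. Reports group medians
#' (or proportions), a rank-based effect direction, and a seeded permutation
#' p-value (difference-in-means statistic, `n_perm` label permutations).
#' Comparisons with an empty group are skipped with a warning.
#'
#' @param cells output of [angle_and_scalar()].
#' @param net the [vessel_network()].
#' @param flow a [wall_shear()] solution.
#' @param profiles detected regression profiles ([detect_profiles()]).
#' @param adjacency_dist um (default 20).
#' @param low_q low-shear quantile for [classify_flow()].
#' @param n_perm number of permutations (default 10000).
#' @param seed permutation seed.
#' @return Nested list of comparisons: `shear` and `regression_adjacency`,
#'   each with `magnitude` and `against_flow` entries.
#' @export
misalignment_near_regression <- function(cells, net, flow, profiles,
                                         adjacency_dist = 20, low_q = 0.25,
                                         n_perm = 10000, seed = 1) {
  cls <- classify_flow(net, flow, low_q)
  lab <- cls$label[match(cells$segment_id, cls$segment_id)]
  adj <- rep(FALSE, nrow(cells))
  if (nrow(profiles) > 0) {
    kk <- match(profiles$segment_id, net$segments$id)
    vt <- do.call(rbind, net$geometry[kk])
    nn <- nn_lookup(vt, cbind(cells$nucleus_x, cells$nucleus_y))
    adj <- nn$dist <= adjacency_dist
  }
  run_pair <- function(y, g, tag) {
    ok <- !is.na(y) & !is.na(g)
    if (!any(g[ok] %in% TRUE) || !any(g[ok] %in% FALSE)) {
      warning("comparison '", tag, "' skipped: a group is empty")
      return(NULL)
    }
    pt <- permutation_group_test(y[ok], g[ok], n_perm, seed)
    m1 <- median(y[ok][g[ok]]); m0 <- median(y[ok][!g[ok]])
    list(median_group1 = m1, median_group0 = m0,
         direction = if (m1 < m0) "group1 < group0"
                     else if (m1 > m0) "group1 > group0" else "tied",
         mean_diff = pt$obs, p_value = pt$p, n1 = pt$n1, n0 = pt$n0)
  }
  g_low <- ifelse(is.na(lab), NA, lab == "low")
  list(
    shear = list(
      magnitude = run_pair(cells$pmag, g_low, "shear/magnitude"),
      against_flow = run_pair(as.numeric(cells$against_flow), g_low,
                              "shear/against_flow")),
    regression_adjacency = list(
      magnitude = run_pair(cells$pmag, adj, "adjacency/magnitude"),
      against_flow = run_pair(as.numeric(cells$against_flow), adj,
                              "adjacency/against_flow")),
    adjacency_dist = adjacency_dist, n_perm = n_perm)
}
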