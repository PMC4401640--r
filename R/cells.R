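# Synthetic endothelial cells: nucleus + Golgi point pairs with polarity
# sampled relative to local flow direction.

#' Sample from a von Mises distribution
#'
#' Best–Fisher rejection sampler for the von Mises distribution on
#' `(-pi, pi]`, the standard unimodal circular family. `kappa = 0` reduces to
#' the uniform distribution on the circle.
#'
#' @param n number of draws.
#' @param mu mean direction (radians).
#' @param kappa concentration (>= 0).
#' @return Numeric vector of angles in `(-pi, pi]`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 0) {
  if (kappa < 0) stop_input("kappa must be >= 0")
  if (n == 0) return(numeric(0))
  if (kappa == 0) return(runif(n, -pi, pi) + (mu %% (2 * pi)) * 0)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- runif(1); u2 <- runif(1); u3 <- runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u2 > 0 || log(c_ / u2) + 1 - c_ >= 0) {
      theta <- sign(u3 - 0.5) * acos(f)
      out[i] <- theta + mu
      i <- i + 1L
    }
  }
  ((out + pi) %% (2 * pi)) - pi
}

# Closed-form von Mises probability mass of {|theta| <= half_width} (radians),
# used as an independent oracle for the against-flow window fraction.
vonmises_window_mass <- function(kappa, half_width = pi / 4) {
  if (kappa == 0) return(half_width / pi)
  dens <- function(t) exp(kappa * (cos(t) - 1))
  integrate(dens, -half_width, half_width, rel.tol = 1e-10)$value /
    integrate(dens, -pi, pi, rel.tol = 1e-10)$value
}

#' Generate synthetic endothelial cells with polarity vectors
#'
#' Places nuclei on segment centerlines with a planted radial density gradient
#' (cell density per vascularized area decreasing linearly from the optic
#' centre to the rim; centre:edge ratio 2:1), then positions each Golgi at
#' `nucleus + magnitude * u(angle)`. Under `mode = "vonmises_against_flow"`
#' the polarity direction is sampled von Mises-centred at 180 degrees to the
#' local flow direction with concentration `kappa`; cells on unperfused
#' segments (sprouts, retracting segments) receive a uniformly random
#' direction. Exactly `n_cells_target` cells are emitted; segments with
#' `cell_count == 0` (resolved regression) host none, and segments with
#' `lumen_fraction` below 0.5 host cells at half weight.
#'
#' @param net a [vessel_network()].
#' @param cfg the [gen_config()].
#' @param flow a flow solution from [wall_shear()]; required when
#'   `cfg$polarity_model$mode == "vonmises_against_flow"`.
#' @return A list with `cells` (class `cell_table`: `cell_id`, `nucleus_x`,
#'   `nucleus_y`, `golgi_x`, `golgi_y`, `region`) and `truth` (data.frame
#'   with the true segment and true polarity angle relative to flow, degrees).
#' @export
generate_cells <- function(net, cfg, flow = NULL) {
  pm <- cfg$polarity_model
  if (pm$mode == "vonmises_against_flow" && is.null(flow)) {
    stop_precondition("polarity mode 'vonmises_against_flow' requires a flow solution")
  }
  segs <- net$segments
  mid <- t(vapply(net$geometry, function(g) polyline_at(g, 0.5)$xy[1, ], numeric(2)))
  r_mid <- sqrt((mid[, 1] - cfg$optic_center[1])^2 + (mid[, 2] - cfg$optic_center[2])^2)
  grad <- 0.5  # planted central:peripheral density ratio 2:1
  w <- segs$length * 2 * segs$mean_radius * (1 - grad * pmin(r_mid / cfg$retina_radius, 1))
  w[segs$mean_radius <= 0] <- segs$length[segs$mean_radius <= 0] * 0
  w[!is.na(segs$cell_count) & segs$cell_count == 0] <- 0
  w[segs$lumen_fraction < 0.5 & w > 0] <- w[segs$lumen_fraction < 0.5 & w > 0] * 0.5
  if (all(w <= 0) && cfg$n_cells_target > 0) stop_config("no segment can host cells")

  with_substream(cfg$seed, 303L, {
    counts <- as.vector(rmultinom(1, cfg$n_cells_target, w))
    total <- sum(counts)
    nx <- numeric(total); ny <- numeric(total)
    tx <- numeric(total); ty <- numeric(total)
    seg_of <- integer(total); q_of <- numeric(total)
    pos <- 1L
    for (k in which(counts > 0)) {
      m <- counts[k]
      at <- polyline_at(net$geometry[[k]], runif(m))
      idx <- pos:(pos + m - 1L)
      nx[idx] <- at$xy[, 1]; ny[idx] <- at$xy[, 2]
      tx[idx] <- at$tangent[, 1]; ty[idx] <- at$tangent[, 2]
      seg_of[idx] <- segs$id[k]
      pos <- pos + m
    }
    if (!is.null(flow)) {
      fs <- flow$segments
      qmap <- setNames(fs$Q, fs$segment_id)
      pmap <- setNames(fs$perfused, fs$segment_id)
      q_of <- qmap[as.character(seg_of)]
      q_of[is.na(q_of)] <- 0
      q_of[!pmap[as.character(seg_of)] %in% TRUE] <- 0
    } else {
      q_of <- rep(0, total)
    }
    has_flow <- q_of != 0
    # oriented flow direction = tangent * sign(Q)
    fx <- tx * sign(q_of); fy <- ty * sign(q_of)
    delta <- rep(NA_real_, total)
    phi <- numeric(total)
    nf <- sum(has_flow)
    if (pm$mode == "vonmises_against_flow") {
      delta[has_flow] <- rvonmises(nf, 0, pm$kappa)
    } else {
      delta[has_flow] <- runif(nf, -pi, pi)
    }
    phi[has_flow] <- atan2(fy[has_flow], fx[has_flow]) + pi + delta[has_flow]
    phi[!has_flow] <- runif(total - nf, 0, 2 * pi)
    mag <- if (pm$magnitude_sd == 0) {
      rep(pm$magnitude_mean, total)
    } else {
      pmax(rnorm(total, pm$magnitude_mean, pm$magnitude_sd), 0.1)
    }
    gx <- nx + mag * cos(phi); gy <- ny + mag * sin(phi)
    region <- segs$region[match(seg_of, segs$id)]
    cells <- data.frame(cell_id = seq_len(total),
                        nucleus_x = nx, nucleus_y = ny,
                        golgi_x = gx, golgi_y = gy,
                        region = region)
    class(cells) <- c("cell_table", "data.frame")
    truth <- data.frame(cell_id = seq_len(total), segment_id = seg_of,
                        true_angle_deg = 180 - abs(rad2deg(delta)),
                        magnitude = mag)
    list(cells = cells, truth = truth)
  })
}
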