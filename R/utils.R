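# Internal helpers: classed conditions, seed substreams, geometry, nearest
# neighbours. Nothing here is exported.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("polarflow_config_error", "error")))
}
stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("polarflow_input_error", "error")))
}
stop_parse <- function(...) {
  stop(errorCondition(paste0(...), class = c("polarflow_parse_error", "error")))
}
stop_precondition <- function(...) {
  stop(errorCondition(paste0(...), class = c("polarflow_precondition_error", "error")))
}
stop_unsolvable <- function(...) {
  stop(errorCondition(paste0(...), class = c("polarflow_unsolvable_error", "error")))
}

# Derive a reproducible substream from a master seed and a fixed stage offset,
# run `code` under it, and restore the caller's RNG state afterwards.
# Derived seeds stay below 2^31 - 1.
with_substream <- function(seed, offset, code) {
  s <- (abs(as.integer(seed)) %% 1000003L) * 2048L + as.integer(offset)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(s)
  force(code)
}

# sample() that never falls into the sample.int trap for length-1 x
safe_sample <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# Arc length of a polyline (n x 2 matrix)
polyline_length <- function(xy) {
  if (nrow(xy) < 2) return(0)
  sum(sqrt(rowSums((xy[-1, , drop = FALSE] - xy[-nrow(xy), , drop = FALSE])^2)))
}

# Cumulative arc length at each vertex
polyline_cumlen <- function(xy) {
  if (nrow(xy) < 2) return(0)
  c(0, cumsum(sqrt(rowSums((xy[-1, , drop = FALSE] - xy[-nrow(xy), , drop = FALSE])^2))))
}

# Point and unit tangent at arc-length fractions t (vector in [0,1]) along a
# polyline. Returns list(xy = n x 2, tangent = n x 2, vertex = nearest vertex).
polyline_at <- function(xy, t) {
  cl <- polyline_cumlen(xy)
  L <- cl[length(cl)]
  s <- pmin(pmax(t, 0), 1) * L
  i <- findInterval(s, cl, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), nrow(xy) - 1L)
  seg_len <- cl[i + 1L] - cl[i]
  f <- ifelse(seg_len > 0, (s - cl[i]) / seg_len, 0)
  p0 <- xy[i, , drop = FALSE]
  p1 <- xy[i + 1L, , drop = FALSE]
  pos <- p0 + f * (p1 - p0)
  tng <- p1 - p0
  nrm <- sqrt(rowSums(tng^2))
  nrm[nrm == 0] <- 1
  tng <- tng / nrm
  vertex <- ifelse(f < 0.5, i, i + 1L)
  list(xy = pos, tangent = tng, vertex = as.integer(vertex))
}

# Unit tangents at every vertex of a polyline (central differences).
polyline_tangents <- function(xy) {
  n <- nrow(xy)
  if (n == 1) return(matrix(c(1, 0), 1, 2))
  d <- rbind(xy[2, ] - xy[1, ],
             if (n > 2) xy[3:n, , drop = FALSE] - xy[1:(n - 2), , drop = FALSE],
             xy[n, ] - xy[n - 1, ])
  nrm <- sqrt(rowSums(d^2))
  nrm[nrm == 0] <- 1
  d / nrm
}

# Nearest-neighbour lookup: for each row of `query`, the index of the nearest
# row of `ref` and the distance. Grid-hashed so large tables stay cheap.
nn_lookup <- function(ref, query) {
  nr <- nrow(ref)
  nq <- nrow(query)
  if (nr == 0L || nq == 0L) {
    return(list(index = rep(NA_integer_, nq), dist = rep(NA_real_, nq)))
  }
  if (as.double(nr) * nq <= 4e6) {
    d2 <- outer(query[, 1], ref[, 1], "-")^2 + outer(query[, 2], ref[, 2], "-")^2
    idx <- max.col(-d2, ties.method = "first")
    return(list(index = idx, dist = sqrt(d2[cbind(seq_len(nq), idx)])))
  }
  # grid hash on ref
  rng <- apply(rbind(ref, query), 2, range)
  h <- max((rng[2, 1] - rng[1, 1]), (rng[2, 2] - rng[1, 2])) / max(1, sqrt(nr))
  h <- max(h, 1e-9)
  cx <- function(p) floor((p[, 1] - rng[1, 1]) / h)
  cy <- function(p) floor((p[, 2] - rng[1, 2]) / h)
  key <- function(ix, iy) paste(ix, iy, sep = ",")
  buckets <- split(seq_len(nr), key(cx(ref), cy(ref)))
  qx <- cx(query); qy <- cy(query)
  idx <- integer(nq); dst <- numeric(nq)
  for (q in seq_len(nq)) {
    ring <- 1L
    best_i <- NA_integer_; best_d <- Inf
    repeat {
      cand <- integer(0)
      for (ix in (qx[q] - ring):(qx[q] + ring)) {
        for (iy in (qy[q] - ring):(qy[q] + ring)) {
          b <- buckets[[key(ix, iy)]]
          if (!is.null(b)) cand <- c(cand, b)
        }
      }
      if (length(cand)) {
        d2 <- (ref[cand, 1] - query[q, 1])^2 + (ref[cand, 2] - query[q, 2])^2
        j <- which.min(d2)
        if (d2[j] < best_d^2) { best_d <- sqrt(d2[j]); best_i <- cand[j] }
        # found a point and the ring already covers best_d -> done
        if (best_d <= ring * h) break
      }
      ring <- ring * 2L
      if (ring > 2 * (max(abs(range(qx)), abs(range(qy))) + 2)) break
    }
    idx[q] <- best_i; dst[q] <- best_d
  }
  list(index = idx, dist = dst)
}

# Distance from point p to segment a-b
point_seg_dist <- function(px, py, ax, ay, bx, by) {
  vx <- bx - ax; vy <- by - ay
  L2 <- vx^2 + vy^2
  t <- ifelse(L2 > 0, ((px - ax) * vx + (py - ay) * vy) / L2, 0)
  t <- pmin(pmax(t, 0), 1)
  sqrt((ax + t * vx - px)^2 + (ay + t * vy - py)^2)
}
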