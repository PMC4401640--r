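# Detection, staging and quantification of vessel regression profiles:
# basement-membrane-positive, lumen-deficient segments, staged after the
# four-step regression sequence (selection, stenosis, retraction, resolution).

#' Detect regression profiles
#'
#' A segment is a regression profile iff it retains basement membrane
#' (`has_matrix`) and is lumen-deficient: `lumen_fraction` below the
#' continuity threshold, or a focal stenosis dip (minimum radius below
#' `stenosis_ratio` times the segment's median radius). Stages:
#' * `4_resolution`: `lumen_fraction == 0` and no resident cells;
#' * `3_retraction`: `lumen_fraction` below the continuity threshold
#'   (lumen disrupted) but not fully resolved;
#' * `2_stenosis`: lumen continuous with a focal radius dip.
#'
#' Stage 1 (selection) precedes any visible morphology and is not detectable
#' in a static frame. The rules are ordered, so every profile receives
#' exactly one stage.
#'
#' @param net an annotated [vessel_network()] (`lumen_fraction`, `has_matrix`
#'   set; `cell_count` where known — `NA` cell counts are treated as
#'   unmeasured and do not block stage 4).
#' @param cell_counts optional named vector of resident cell counts by
#'   segment id (e.g. from table of [assign_to_segments()] output),
#'   overriding the network's `cell_count` attribute.
#' @param continuity_threshold lumen_fraction at/above which the lumen counts
#'   as continuous (default 0.95).
#' @param disconnect_threshold lumen_fraction below which the lumen counts as
#'   disconnected (default 0.5); retained for reporting.
#' @param stenosis_ratio focal dip detection ratio (default 0.5).
#' @return data.frame of class `regression_profiles`: `segment_id`, `stage`,
#'   `lumen_fraction`, `radius_dip_ratio`, `cell_count`.
#' @export
detect_profiles <- function(net, cell_counts = NULL,
                            continuity_threshold = 0.95,
                            disconnect_threshold = 0.5,
                            stenosis_ratio = 0.5) {
  segs <- net$segments
  if (is.null(segs$lumen_fraction) || is.null(segs$has_matrix)) {
    stop_precondition("network not annotated: lumen_fraction / has_matrix required")
  }
  cc <- segs$cell_count
  if (!is.null(cell_counts)) {
    ov <- cell_counts[as.character(segs$id)]
    cc <- ifelse(is.na(ov), 0, as.numeric(ov))
  }
  dip <- vapply(net$radius_profiles, function(p) {
    md <- median(p)
    if (md <= 0) return(Inf)
    min(p) / md
  }, numeric(1))
  lf <- segs$lumen_fraction
  is_prof <- segs$has_matrix & (lf < continuity_threshold | dip < stenosis_ratio)
  idx <- which(is_prof)
  stage <- character(length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]
    resident <- cc[i]
    no_cells <- is.na(resident) || resident == 0
    stage[j] <- if (lf[i] == 0 && no_cells) "4_resolution"
      else if (lf[i] < continuity_threshold) "3_retraction"
      else "2_stenosis"
  }
  out <- data.frame(segment_id = segs$id[idx], stage = stage,
                    lumen_fraction = lf[idx],
                    radius_dip_ratio = dip[idx],
                    cell_count = cc[idx])
  class(out) <- c("regression_profiles", "data.frame")
  out
}

#' Apoptosis colocalization with regression profiles
#'
#' A profile is apoptosis-positive iff any apoptotic event lies within
#' `coloc_dist` of its centerline. Returns the percentage of positive
#' profiles, the complementary percentage, and per-profile flags with the
#' distance to the nearest event. With zero profiles the percentages are
#' `NA` (undefined), not 0.
#'
#' @param profiles output of [detect_profiles()].
#' @param net the [vessel_network()].
#' @param events data.frame of apoptotic points (`x`, `y`).
#' @param coloc_dist distance rule (um, default 10).
#' @return list: `percentage`, `complement_percentage`, `n_profiles`,
#'   `n_positive`, `profiles` (with `coloc_apoptosis`,
#'   `dist_nearest_apoptosis` columns).
#' @export
colocalize_apoptosis <- function(profiles, net, events, coloc_dist = 10) {
  n <- nrow(profiles)
  if (n == 0) {
    return(list(percentage = NA_real_, complement_percentage = NA_real_,
                n_profiles = 0L, n_positive = 0L, profiles = profiles))
  }
  dmin <- rep(Inf, n)
  if (!is.null(events) && nrow(events) > 0) {
    ev <- cbind(events$x, events$y)
    for (j in seq_len(n)) {
      k <- match(profiles$segment_id[j], net$segments$id)
      g <- net$geometry[[k]]
      # point-to-edge distance: vertex spacing may exceed the rule
      dmin[j] <- min(vapply(seq_len(nrow(ev)), function(e) {
        if (nrow(g) < 2) return(sqrt(sum((g[1, ] - ev[e, ])^2)))
        min(point_seg_dist(ev[e, 1], ev[e, 2],
                           g[-nrow(g), 1], g[-nrow(g), 2],
                           g[-1, 1], g[-1, 2]))
      }, numeric(1)))
    }
  }
  pos <- dmin <= coloc_dist
  profiles$coloc_apoptosis <- pos
  profiles$dist_nearest_apoptosis <- dmin
  list(percentage = 100 * mean(pos),
       complement_percentage = 100 * (1 - mean(pos)),
       n_profiles = n, n_positive = sum(pos),
       profiles = profiles)
}

#' Regression profile counts per vascularized area
#'
#' @param profiles output of [detect_profiles()].
#' @param net the [vessel_network()] (area via the graph convention).
#' @return list: `count`, `per_100um2`, `vascularized_area`.
#' @export
regression_counts <- function(profiles, net) {
  area <- vascularized_area(net)
  if (area <= 0) stop_input("vascularized area must be > 0")
  list(count = nrow(profiles),
       per_100um2 = nrow(profiles) / area * 100,
       vascularized_area = area)
}

#' Association of regression profiles with low-shear segments
#'
#' Cross-tabulates perfused segments of the *pre-regression* flow solution by
#' {profile, non-profile} x {low-shear, high-shear}, reports the odds ratio
#' (Haldane–Anscombe 0.5 correction when any cell is empty), and a seeded
#' permutation p-value. The permutation statistic is the mean rank of the
#' profile segments' wall shear stress (a continuous statistic, avoiding the
#' granularity of the dichotomized table); profile labels are permuted across
#' perfused segments.
#'
#' @param net the [vessel_network()].
#' @param flow a [wall_shear()] solution on the pre-regression network.
#' @param profiles output of [detect_profiles()] (or any data.frame with a
#'   `segment_id` column).
#' @param low_q low-shear quantile (default 0.25).
#' @param n_perm permutations (default 10000).
#' @param seed permutation seed.
#' @return list: `table` (2x2), `odds_ratio`, `corrected` (logical),
#'   `direction`, `p_value`, `n_perm`.
#' @export
low_flow_association <- function(net, flow, profiles, low_q = 0.25,
                                 n_perm = 10000, seed = 1) {
  cls <- classify_flow(net, flow, low_q)
  is_prof <- cls$segment_id %in% profiles$segment_id
  is_low <- cls$label == "low"
  tab <- matrix(c(sum(is_prof & is_low), sum(is_prof & !is_low),
                  sum(!is_prof & is_low), sum(!is_prof & !is_low)),
                2, 2, byrow = TRUE,
                dimnames = list(c("profile", "non_profile"), c("low", "high")))
  degenerate <- sum(is_prof) == 0 || all(is_prof) || sum(is_low) == 0 || all(is_low)
  corrected <- any(tab == 0)
  or <- if (degenerate) NA_real_ else {
    t2 <- tab + if (corrected) 0.5 else 0
    (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  }
  p <- NA_real_; direction <- NA_character_
  if (!degenerate) {
    rk <- rank(cls$tau)
    obs <- mean(rk[is_prof])
    m <- sum(is_prof); n <- length(rk)
    p <- with_substream(seed, 11L, {
      stat <- vapply(seq_len(n_perm), function(b) mean(rk[sample.int(n, m)]),
                     numeric(1))
      e <- (n + 1) / 2
      (1 + sum(abs(stat - e) >= abs(obs - e) - 1e-12)) / (n_perm + 1)
    })
    direction <- if (obs < (n + 1) / 2) "low-flow enriched" else "high-flow enriched"
  }
  list(table = tab, odds_ratio = or, corrected = corrected,
       direction = direction, p_value = p, n_perm = n_perm)
}
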