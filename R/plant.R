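# Plant regression profiles and apoptotic events with known ground truth.

#' Plant regression profiles and apoptotic events
#'
#' Selects a `regression_rate` fraction of capillary segments (without
#' replacement), assigns each a stage from `stage_mix`, and alters the
#' observable segment attributes accordingly:
#' * stage 1 (selection): no morphological change (recorded in the ground
#'   truth only; the selection step precedes visible morphology);
#' * stage 2 (stenosis): a focal radius dip to 30% of the local radius over
#'   the middle third of the segment, lumen continuous;
#' * stage 3 (retraction): `lumen_fraction` drawn in (0.05, 0.45), below the
#'   perfusion/disconnection threshold;
#' * stage 4 (resolution): `lumen_fraction = 0`, resident `cell_count = 0`,
#'   basement membrane retained (`has_matrix` stays `TRUE`).
#'
#' Apoptotic events are drawn `Poisson(apoptosis_total_mean)`. A
#' `coloc_rate` fraction of the *detectable* (stage >= 2) planted segments
#' receive one event on their centerline midpoint (randomized rounding of the
#' quota keeps the planted rate unbiased across replicates); the remaining
#' events are placed uniformly along the non-regressing vasculature, excluding
#' the `coloc_dist` corridor around detectable regression centerlines so the
#' planted colocalization rate is identifiable.
#'
#' @param net a [vessel_network()] from [generate_network()].
#' @param cfg the [gen_config()] used to generate it.
#' @return A list with elements `network` (modified copy), `truth` (class
#'   `ground_truth`: `regression` data.frame of `segment_id`, `stage`;
#'   `apoptosis` data.frame of `x`, `y`, `coloc`, `segment_id`), and
#'   `events` (the apoptosis points as a marker event table).
#' @export
plant_regression_and_apoptosis <- function(net, cfg) {
  cap_ids <- net$segments$id[net$segments$region == "capillary"]
  n_reg <- round(cfg$regression_rate * length(cap_ids))
  if (n_reg > length(cap_ids)) {
    stop_config("regression_rate demands more segments than capillaries available")
  }
  with_substream(cfg$seed, 202L, {
    sel <- if (n_reg > 0) safe_sample(cap_ids, n_reg) else integer(0)
    stages <- if (n_reg > 0) {
      safe_sample(STAGE_LEVELS, n_reg, replace = TRUE, prob = cfg$stage_mix)
    } else character(0)
    seg_idx <- match(sel, net$segments$id)
    for (i in seq_along(sel)) {
      k <- seg_idx[i]
      if (stages[i] == "2_stenosis") {
        prof <- net$radius_profiles[[k]]
        n <- length(prof)
        t <- if (n > 1) (seq_len(n) - 1) / (n - 1) else 0.5
        dip <- abs(t - 0.5) < 1 / 6
        if (!any(dip)) dip[ceiling(n / 2)] <- TRUE
        prof[dip] <- prof[dip] * 0.30
        net$radius_profiles[[k]] <- prof
        net$segments$mean_radius[k] <- mean(prof)
      } else if (stages[i] == "3_retraction") {
        net$segments$lumen_fraction[k] <- runif(1, 0.05, 0.45)
      } else if (stages[i] == "4_resolution") {
        net$segments$lumen_fraction[k] <- 0
        net$segments$cell_count[k] <- 0
      }
    }
    detectable <- sel[stages != "1_selection"]

    n_events <- rpois(1, cfg$apoptosis_total_mean)
    q <- cfg$coloc_rate * length(detectable)
    n_coloc <- floor(q) + rbinom(1, 1, q - floor(q))
    n_coloc <- min(n_coloc, length(detectable), n_events)
    coloc_segs <- if (n_coloc > 0) safe_sample(detectable, n_coloc) else integer(0)

    ev <- data.frame(x = numeric(0), y = numeric(0), coloc = logical(0),
                     segment_id = integer(0))
    for (s in coloc_segs) {
      k <- match(s, net$segments$id)
      p <- polyline_at(net$geometry[[k]], 0.5)$xy
      ev <- rbind(ev, data.frame(x = p[1] + rnorm(1, 0, 1),
                                 y = p[2] + rnorm(1, 0, 1),
                                 coloc = TRUE, segment_id = s))
    }

    n_rest <- n_events - n_coloc
    if (n_rest > 0) {
      host <- net$segments$id[!(net$segments$id %in% detectable)]
      hidx <- match(host, net$segments$id)
      w <- net$segments$length[hidx]
      reg_vt <- NULL
      if (length(detectable)) {
        kk <- match(detectable, net$segments$id)
        reg_vt <- do.call(rbind, net$geometry[kk])
      }
      placed <- 0L; tries <- 0L
      while (placed < n_rest && tries < 60L) {
        m <- n_rest - placed
        segs <- safe_sample(host, m, replace = TRUE, prob = w)
        tt <- runif(m)
        pts <- t(vapply(seq_len(m), function(i) {
          k <- match(segs[i], net$segments$id)
          polyline_at(net$geometry[[k]], tt[i])$xy[1, ]
        }, numeric(2)))
        pts <- pts + matrix(rnorm(2 * m, 0, 1), m, 2)
        ok <- rep(TRUE, m)
        if (!is.null(reg_vt)) {
          nn <- nn_lookup(reg_vt, pts)
          ok <- nn$dist > cfg$coloc_dist + 2
        }
        if (any(ok)) {
          ev <- rbind(ev, data.frame(x = pts[ok, 1], y = pts[ok, 2],
                                     coloc = FALSE, segment_id = segs[ok]))
          placed <- placed + sum(ok)
        }
        tries <- tries + 1L
      }
    }
    truth <- structure(
      list(regression = data.frame(segment_id = sel, stage = stages),
           apoptosis = ev,
           coloc_rate_planted = if (length(detectable)) {
             n_coloc / length(detectable)
           } else NA_real_,
           n_detectable = length(detectable)),
      class = "ground_truth")
    list(network = net, truth = truth, events = ev)
  })
}
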