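# Regression-profile detection, staging, colocalization, flow association.

test_that("planted stages are recovered with a diagonal confusion matrix", {
  agree <- c(); total <- c()
  for (s in 1:10) {
    cfg <- small_cfg(seed = s, regression_rate = 0.12)
    net <- generate_network(cfg)
    pl <- plant_regression_and_apoptosis(net, cfg)
    prof <- detect_profiles(pl$network)
    truth <- pl$truth$regression[pl$truth$regression$stage != "1_selection", ]
    expect_setequal(prof$segment_id, truth$segment_id)
    m <- merge(prof, truth, by = "segment_id")
    agree <- c(agree, sum(m$stage.x == m$stage.y))
    total <- c(total, nrow(m))
  }
  expect_gte(sum(agree) / sum(total), 0.95)
})

test_that("profile definition boundaries hold", {
  w <- small_world()
  # a fully lumenized uniform segment is not a profile
  normal <- setdiff(w$net$segments$id, w$truth$regression$segment_id)
  prof <- detect_profiles(w$net)
  expect_false(any(prof$segment_id %in% normal))
  # lumen-negative but matrix-negative segment is not a profile
  net2 <- w$net
  k <- match(normal[1], net2$segments$id)
  net2$segments$lumen_fraction[k] <- 0
  net2$segments$has_matrix[k] <- FALSE
  prof2 <- detect_profiles(net2)
  expect_false(normal[1] %in% prof2$segment_id)
  # unannotated input is a precondition error
  net3 <- w$net
  net3$segments$lumen_fraction <- NULL
  expect_error(detect_profiles(net3), class = "polarflow_precondition_error")
})

test_that("the detector is monotone in lumen loss", {
  w <- small_world()
  prof1 <- detect_profiles(w$net)
  net2 <- w$net
  set.seed(21)
  drop <- sample(nrow(net2$segments), 30)
  net2$segments$lumen_fraction[drop] <-
    net2$segments$lumen_fraction[drop] * runif(30, 0, 0.9)
  prof2 <- detect_profiles(net2)
  expect_true(all(prof1$segment_id %in% prof2$segment_id))
  # every profile has exactly one stage
  expect_true(all(prof2$stage %in% c("2_stenosis", "3_retraction", "4_resolution")))
  expect_identical(anyDuplicated(prof2$segment_id), 0L)
})

test_that("colocalization follows the distance rule and handles empties", {
  net <- tube_network(r = 4, L = 100)
  net$segments$lumen_fraction <- 0
  net$segments$cell_count <- 0
  prof <- detect_profiles(net)
  expect_identical(nrow(prof), 1L)
  # event on the centerline: 100%
  res <- colocalize_apoptosis(prof, net, data.frame(x = 50, y = 0))
  expect_equal(res$percentage, 100)
  expect_equal(res$complement_percentage, 0)
  # event beyond coloc_dist: 0%
  res2 <- colocalize_apoptosis(prof, net, data.frame(x = 50, y = 30))
  expect_equal(res2$percentage, 0)
  # no events at all: 0%
  res3 <- colocalize_apoptosis(prof, net, data.frame(x = numeric(0), y = numeric(0)))
  expect_equal(res3$percentage, 0)
  # zero profiles: undefined (NA), not zero
  res4 <- colocalize_apoptosis(prof[0, ], net, data.frame(x = 50, y = 0))
  expect_true(is.na(res4$percentage))
})

test_that("planted colocalization rate is recovered across replicates", {
  pcts <- c(); planted <- c()
  for (s in 1:6) {
    cfg <- small_cfg(seed = s + 100, regression_rate = 0.12,
                     apoptosis_total_mean = 30, coloc_rate = 0.2)
    net <- generate_network(cfg)
    pl <- plant_regression_and_apoptosis(net, cfg)
    res <- colocalize_apoptosis(detect_profiles(pl$network), pl$network,
                                pl$events, coloc_dist = cfg$coloc_dist)
    pcts <- c(pcts, res$percentage)
    planted <- c(planted, 100 * pl$truth$coloc_rate_planted)
  }
  # the pipeline recovers exactly what was planted, replicate by replicate
  expect_equal(pcts, planted, tolerance = 1e-9)
  se <- sd(pcts) / sqrt(length(pcts))
  expect_lt(abs(mean(pcts) - 20), 2 * se + 2)
})

test_that("regression counts scale with vascularized area", {
  w <- small_world()
  prof <- detect_profiles(w$net)
  rc <- regression_counts(prof, w$net)
  expect_identical(rc$count, nrow(prof))
  expect_equal(rc$per_100um2, nrow(prof) / vascularized_area(w$net) * 100)
  # doubling the network by disjoint union leaves the density unchanged
  net2 <- w$net
  n_node <- max(net2$nodes$id)
  nodes2 <- net2$nodes
  nodes2$id <- nodes2$id + n_node
  nodes2$x <- nodes2$x + 3000
  segs2 <- net2$segments
  segs2$id <- segs2$id + max(segs2$id)
  segs2$a <- segs2$a + n_node
  segs2$b <- segs2$b + n_node
  geom2 <- lapply(net2$geometry, function(g) {
    g + matrix(c(3000, 0), nrow(g), 2, byrow = TRUE)
  })
  dbl <- vessel_network(rbind(net2$nodes, nodes2), rbind(net2$segments, segs2),
                        c(net2$geometry, geom2),
                        c(net2$radius_profiles, net2$radius_profiles))
  prof_dbl <- detect_profiles(dbl)
  rc_dbl <- regression_counts(prof_dbl, dbl)
  expect_identical(rc_dbl$count, 2L * rc$count)
  expect_equal(rc_dbl$per_100um2, rc$per_100um2, tolerance = 1e-9)
})

test_that("profiles planted on low-shear segments are flagged as enriched", {
  w <- small_world()
  cls <- classify_flow(w$net0, w$pre_flow)
  low_caps <- cls$segment_id[cls$label == "low"]
  profiles <- data.frame(segment_id = low_caps[1:20])
  res <- low_flow_association(w$net0, w$pre_flow, profiles, n_perm = 999, seed = 5)
  expect_identical(res$direction, "low-flow enriched")
  expect_gt(res$odds_ratio, 1)
  expect_lt(res$p_value, 0.01)
  # degenerate margins: odds ratio flagged NA
  res0 <- low_flow_association(w$net0, w$pre_flow,
                               data.frame(segment_id = integer(0)),
                               n_perm = 99, seed = 1)
  expect_true(is.na(res0$odds_ratio))
  # empty-cell table still yields a finite corrected odds ratio
  one <- data.frame(segment_id = low_caps[1])
  res1 <- low_flow_association(w$net0, w$pre_flow, one, n_perm = 99, seed = 1)
  expect_true(res1$corrected)
  expect_true(is.finite(res1$odds_ratio))
})
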