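# Synthetic plexus generator: topology, determinism, planted ground truth.

test_that("degenerate configurations are refused", {
  expect_error(gen_config(capillary_spacing = 3000), class = "polarflow_config_error")
  expect_error(gen_config(stage_mix = c(0.5, 0.5, 0.2, 0)),
               class = "polarflow_config_error")
  expect_error(gen_config(polarity_model = list(kappa = -1)),
               class = "polarflow_config_error")
  expect_error(generate_network(gen_config(n_arteries = 0)),
               class = "polarflow_config_error")
})

test_that("every non-sprout segment lies on an inlet-to-outlet path", {
  # oracle: with a virtual source-sink edge added, an edge lies on a simple
  # inlet->outlet path iff it shares a biconnected component with that edge
  net <- generate_network(small_cfg(seed = 1))
  g <- as_igraph(net)
  g <- igraph::add_vertices(g, 2, name = c("SRC", "SNK"))
  for (i in net$meta$inlets) g <- igraph::add_edges(g, c("SRC", as.character(i)))
  for (o in net$meta$outlets) g <- igraph::add_edges(g, c(as.character(o), "SNK"))
  g <- igraph::add_edges(g, c("SRC", "SNK"))
  virt <- igraph::ecount(g)
  bc <- igraph::biconnected_components(g)
  on_path <- rep(FALSE, igraph::ecount(g))
  for (comp in bc$component_edges) {
    if (virt %in% comp) on_path[comp] <- TRUE
  }
  eseg <- igraph::edge_attr(g, "segment_id")
  sprout <- net$segments$region[match(eseg, net$segments$id)] == "sprouting_front"
  real <- !is.na(eseg) & !sprout
  expect_true(all(on_path[real]))
  # sprouts are blind-ended: never on such a path
  expect_false(any(on_path[which(!is.na(eseg) & sprout)]))
})

test_that("identical config and seed give byte-identical network JSON", {
  cfg <- small_cfg(seed = 11)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_network(generate_network(cfg), p1)
  write_network(generate_network(cfg), p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("geometry stays inside the retina and regions are labelled", {
  net <- generate_network(small_cfg(seed = 4))
  xy <- do.call(rbind, net$geometry)
  expect_lte(max(sqrt(xy[, 1]^2 + xy[, 2]^2)), 220)
  expect_setequal(unique(net$segments$region),
                  c("artery", "vein", "capillary", "sprouting_front"))
  expect_length(net$meta$inlets, 2)
  expect_length(net$meta$outlets, 2)
  deg <- node_degrees(net)
  expect_true(all(deg[as.character(c(net$meta$inlets, net$meta$outlets))] == 1))
  # no degree-2 nodes survive generation
  expect_false(any(deg == 2))
})

test_that("emitted cell count is calibrated to the target", {
  # exact by construction for any seed; check a handful
  for (s in 1:3) {
    w <- small_world(seed = s, n_cells = 400)
    expect_identical(nrow(w$cells), 400L)
  }
})

test_that("apoptosis event count is Poisson-calibrated", {
  ns <- vapply(1:20, function(s) {
    cfg <- small_cfg(seed = s, apoptosis_total_mean = 40)
    net <- generate_network(cfg)
    nrow(plant_regression_and_apoptosis(net, cfg)$events)
  }, numeric(1))
  se <- sqrt(40 / 20)
  expect_lt(abs(mean(ns) - 40), 2 * se)
})

test_that("planting honours rates, stages, and the coloc distance rule", {
  cfg <- small_cfg(seed = 5, regression_rate = 0)
  net <- generate_network(cfg)
  pl <- plant_regression_and_apoptosis(net, cfg)
  expect_identical(nrow(pl$truth$regression), 0L)
  expect_identical(nrow(detect_profiles(pl$network)), 0L)

  # saturation: coloc_rate = 1 flags every detectable profile
  cfg2 <- small_cfg(seed = 6, regression_rate = 0.15, coloc_rate = 1,
                    apoptosis_total_mean = 200)
  net2 <- generate_network(cfg2)
  pl2 <- plant_regression_and_apoptosis(net2, cfg2)
  det <- pl2$truth$regression$segment_id[pl2$truth$regression$stage != "1_selection"]
  expect_gt(length(det), 0)
  res <- colocalize_apoptosis(detect_profiles(pl2$network), pl2$network,
                              pl2$events, coloc_dist = cfg2$coloc_dist)
  expect_equal(res$percentage, 100)
  # coloc-flagged events lie within coloc_dist of a planted segment centerline
  ev <- pl2$events[pl2$events$coloc, ]
  for (i in seq_len(nrow(ev))) {
    k <- match(ev$segment_id[i], net2$segments$id)
    g <- pl2$network$geometry[[k]]
    d <- min(sqrt((g[, 1] - ev$x[i])^2 + (g[, 2] - ev$y[i])^2))
    expect_lt(d, cfg2$coloc_dist)
  }

  # pure-resolution mix: every planted segment empty of lumen and cells
  cfg3 <- small_cfg(seed = 7, stage_mix = c(0, 0, 0, 1), regression_rate = 0.1)
  net3 <- generate_network(cfg3)
  pl3 <- plant_regression_and_apoptosis(net3, cfg3)
  idx <- match(pl3$truth$regression$segment_id, pl3$network$segments$id)
  expect_true(all(pl3$network$segments$lumen_fraction[idx] == 0))
  expect_true(all(pl3$network$segments$cell_count[idx] == 0))
})

test_that("polarity sampling matches its target distribution", {
  # kappa = 0: angle to flow uniform on [0, 180]
  w0 <- small_world(seed = 2, n_cells = 5000, kappa = 0)
  th <- w0$cell_truth$true_angle_deg
  th <- th[!is.na(th)]
  expect_gt(length(th), 4000)
  ks <- suppressWarnings(stats::ks.test(th, "punif", 0, 180))
  expect_gt(ks$p.value, 0.01)
  # kappa = 50: essentially all mass in the against-flow window
  w50 <- small_world(seed = 2, n_cells = 2000, kappa = 50)
  th50 <- w50$cell_truth$true_angle_deg
  th50 <- th50[!is.na(th50)]
  expect_gt(mean(th50 >= 135 & th50 <= 180), 0.99)
  # degenerate magnitude: |p| exactly the mean
  cfg <- small_cfg(seed = 3, n_cells_target = 200,
                   polarity_model = list(mode = "uniform", magnitude_mean = 5,
                                         magnitude_sd = 0))
  net <- generate_network(cfg)
  gen <- generate_cells(net, cfg, flow = NULL)
  pm <- sqrt((gen$cells$golgi_x - gen$cells$nucleus_x)^2 +
             (gen$cells$golgi_y - gen$cells$nucleus_y)^2)
  expect_equal(pm, rep(5, 200), tolerance = 1e-12)
  # vonmises mode without a flow solution is a precondition error
  expect_error(generate_cells(net, small_cfg(seed = 3), flow = NULL),
               class = "polarflow_precondition_error")
})
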