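# Hand-built networks with known closed-form behaviour, plus a small
# generated "world" shared across test files.

# single straight tube along x: nodes at (0,0) and (L,0)
tube_network <- function(r = 4, L = 100, npt = 11) {
  xy <- cbind(seq(0, L, length.out = npt), 0)
  vessel_network(
    nodes = data.frame(id = 1:2, x = c(0, L), y = c(0, 0)),
    segments = data.frame(id = 1L, a = 1L, b = 2L, region = "capillary",
                          lumen_fraction = 1, has_matrix = TRUE,
                          stage = NA_character_, cell_count = NA_real_),
    geometry = list(xy),
    radius_profiles = list(rep(r, npt)),
    meta = list(inlets = 1L, outlets = 2L))
}

# two identical tubes in parallel between the same two nodes
parallel_network <- function(r = 4, L = 100) {
  xy <- cbind(seq(0, L, length.out = 11), 0)
  vessel_network(
    nodes = data.frame(id = 1:2, x = c(0, L), y = c(0, 0)),
    segments = data.frame(id = 1:2, a = 1L, b = 2L, region = "capillary",
                          lumen_fraction = 1, has_matrix = TRUE,
                          stage = NA_character_, cell_count = NA_real_),
    geometry = list(xy, xy),
    radius_profiles = list(rep(r, 11), rep(r, 11)),
    meta = list(inlets = 1L, outlets = 2L))
}

# T-junction: inlet 1 -- 2 -- outlet 3, plus blind branch 2 -- 4
t_junction_network <- function(r = 4, L = 100) {
  seg <- function(p0, p1) cbind(seq(p0[1], p1[1], length.out = 6),
                                seq(p0[2], p1[2], length.out = 6))
  vessel_network(
    nodes = data.frame(id = 1:4, x = c(0, L, 2 * L, L), y = c(0, 0, 0, L)),
    segments = data.frame(id = 1:3, a = c(1L, 2L, 2L), b = c(2L, 3L, 4L),
                          region = "capillary", lumen_fraction = 1,
                          has_matrix = TRUE, stage = NA_character_,
                          cell_count = NA_real_),
    geometry = list(seg(c(0, 0), c(L, 0)), seg(c(L, 0), c(2 * L, 0)),
                    seg(c(L, 0), c(L, L))),
    radius_profiles = rep(list(rep(r, 6)), 3),
    meta = list(inlets = 1L, outlets = 3L))
}

# "H" of 5 segments: 4 tips, 2 degree-3 nodes
h_network <- function(r = 4, L = 60) {
  seg <- function(p0, p1) cbind(seq(p0[1], p1[1], length.out = 7),
                                seq(p0[2], p1[2], length.out = 7))
  nodes <- data.frame(id = 1:6,
                      x = c(0, 0, 0, 2 * L, 2 * L, 2 * L),
                      y = c(0, L, 2 * L, 0, L, 2 * L))
  vessel_network(
    nodes = nodes,
    segments = data.frame(id = 1:5,
                          a = c(1L, 2L, 5L, 2L, 5L),
                          b = c(2L, 3L, 4L, 5L, 6L),
                          region = "capillary", lumen_fraction = 1,
                          has_matrix = TRUE, stage = NA_character_,
                          cell_count = NA_real_),
    geometry = list(seg(c(0, 0), c(0, L)), seg(c(0, L), c(0, 2 * L)),
                    seg(c(2 * L, L), c(2 * L, 0)),
                    seg(c(0, L), c(2 * L, L)),
                    seg(c(2 * L, L), c(2 * L, 2 * L))),
    radius_profiles = rep(list(rep(r, 7)), 5))
}

# compact generated retina used by many tests; ... overrides any field
small_cfg <- function(seed = 1, ...) {
  args <- list(retina_radius = 220, capillary_spacing = 40,
               n_arteries = 2, n_veins = 2,
               radius_artery = 6, radius_vein = 7, radius_capillary = 3.5,
               n_cells_target = 300, apoptosis_total_mean = 15,
               regression_rate = 0.05, pixel_size = 1, seed = seed)
  ov <- list(...)
  args[names(ov)] <- ov
  do.call(gen_config, args)
}

# medium world with flow and cells, memoised per session
.world_cache <- new.env(parent = emptyenv())
small_world <- function(seed = 1, n_cells = 600, kappa = 4) {
  key <- paste(seed, n_cells, kappa)
  if (!is.null(.world_cache[[key]])) return(.world_cache[[key]])
  cfg <- gen_config(retina_radius = 300, capillary_spacing = 35,
                    n_arteries = 3, n_veins = 3,
                    radius_artery = 6, radius_vein = 7, radius_capillary = 3.5,
                    n_cells_target = n_cells, apoptosis_total_mean = 20,
                    regression_rate = 0.04, pixel_size = 1, seed = seed,
                    polarity_model = list(mode = "vonmises_against_flow",
                                          kappa = kappa, magnitude_mean = 5,
                                          magnitude_sd = 1.5))
  net0 <- generate_network(cfg)
  pre_flow <- solve_haemodynamics(net0)
  pl <- plant_regression_and_apoptosis(net0, cfg)
  flow <- solve_haemodynamics(pl$network)
  gen <- generate_cells(pl$network, cfg, flow)
  w <- list(cfg = cfg, net0 = net0, pre_flow = pre_flow, net = pl$network,
            truth = pl$truth, events = pl$events, flow = flow,
            cells = gen$cells, cell_truth = gen$truth)
  .world_cache[[key]] <- w
  w
}

# rotate a network and cell table by `ang` radians about the origin
rotate_world <- function(net, cells, ang) {
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
  rot <- function(m) m %*% t(R)
  nodes <- net$nodes
  nm <- rot(cbind(nodes$x, nodes$y))
  nodes$x <- nm[, 1]; nodes$y <- nm[, 2]
  geometry <- lapply(net$geometry, rot)
  net2 <- vessel_network(nodes, net$segments[, c("id", "a", "b", "region",
                                                 "lumen_fraction", "has_matrix",
                                                 "stage", "cell_count")],
                         geometry, net$radius_profiles, meta = net$meta)
  cm <- rot(cbind(cells$nucleus_x, cells$nucleus_y))
  gm <- rot(cbind(cells$golgi_x, cells$golgi_y))
  cells2 <- cells
  cells2$nucleus_x <- cm[, 1]; cells2$nucleus_y <- cm[, 2]
  cells2$golgi_x <- gm[, 1]; cells2$golgi_y <- gm[, 2]
  cells2$px <- NULL; cells2$py <- NULL; cells2$pmag <- NULL
  list(net = net2, cells = cells2)
}
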