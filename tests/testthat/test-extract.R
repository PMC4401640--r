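# Skeletonization, graph building, and mask annotation.

test_that("a straight stripe skeletonizes to its midline", {
  mask <- matrix(0, 60, 220)
  mask[23:38, 11:210] <- 1  # 16 px wide, 200 px long
  sk <- skeletonize(mask)
  # distance map peaks at half the stripe width on the midline
  expect_lt(abs(max(sk$distance[sk$skeleton]) - 8), 1.01)
  # single path: exactly two endpoint pixels, no branch pixels
  net <- build_graph(sk$skeleton, sk$distance, pixel_size = 1)
  expect_identical(nrow(net$segments), 1L)
  deg <- node_degrees(net)
  expect_identical(sort(unname(deg)), c(1L, 1L))
  # midline: skeleton y-coordinates stay within 1 px of the stripe centre
  ys <- which(sk$skeleton, arr.ind = TRUE)[, 1]
  interior <- which(sk$skeleton, arr.ind = TRUE)[, 2] > 25 &
    which(sk$skeleton, arr.ind = TRUE)[, 2] < 195
  expect_true(all(abs(ys[interior] - 30.5) <= 1))
})

test_that("a filled disk collapses to a few central pixels", {
  mask <- matrix(0, 101, 101)
  xs <- row(mask) - 51; ys <- col(mask) - 51
  mask[xs^2 + ys^2 <= 40^2] <- 1
  sk <- skeletonize(mask)
  pix <- which(sk$skeleton, arr.ind = TRUE)
  expect_lt(nrow(pix), 30)
  d <- sqrt((pix[, 1] - 51)^2 + (pix[, 2] - 51)^2)
  expect_lt(max(d), 10)
})

test_that("only the largest connected component is kept", {
  mask <- matrix(0, 80, 80)
  mask[10:20, 10:60] <- 1   # large blob
  mask[60:64, 60:64] <- 1   # small blob
  sk <- skeletonize(mask)
  expect_identical(sk$n_components_dropped, 1L)
  pix <- which(sk$skeleton, arr.ind = TRUE)
  expect_true(all(pix[, 1] <= 25))
  expect_error(skeletonize(matrix(0, 5, 5)), class = "polarflow_input_error")
})

test_that("a rendered tube recovers its radius within half a micron", {
  net <- tube_network(r = 4, L = 120)
  cfg <- gen_config(pixel_size = 0.5, seed = 1)
  st <- render_masks(net, cfg = cfg)
  # rasterized stripe width: 16 px +- 1 at 0.5 um/px
  mid_col <- ncol(st$channels$lumen) %/% 2
  expect_lt(abs(sum(st$channels$lumen[, mid_col]) - 16), 1.5)
  sk <- skeletonize(st$channels$lumen)
  ex <- build_graph(sk$skeleton, sk$distance, st$pixel_size, st$origin)
  expect_identical(nrow(ex$segments), 1L)
  expect_lt(abs(ex$segments$mean_radius - 4), 0.5)
  expect_lt(abs(ex$segments$length - 120), 6)
})

test_that("an H-shaped network extracts with exact topology", {
  net <- h_network(r = 4, L = 60)
  cfg <- gen_config(pixel_size = 1, seed = 1)
  st <- render_masks(net, cfg = cfg)
  sk <- skeletonize(st$channels$lumen)
  ex <- build_graph(sk$skeleton, sk$distance, st$pixel_size, st$origin)
  expect_identical(nrow(ex$segments), 5L)
  deg <- table(node_degrees(ex))
  expect_identical(unname(deg[["1"]]), 4L)
  expect_identical(unname(deg[["3"]]), 2L)
})

test_that("pruning is a no-op on a clean mask", {
  net <- tube_network(r = 4, L = 120)
  st <- render_masks(net, cfg = gen_config(pixel_size = 1, seed = 1))
  sk <- skeletonize(st$channels$lumen)
  e0 <- build_graph(sk$skeleton, sk$distance, 1, st$origin, prune_length = 0)
  e2 <- build_graph(sk$skeleton, sk$distance, 1, st$origin, prune_length = 2)
  expect_identical(nrow(e0$segments), nrow(e2$segments))
  expect_identical(sort(node_degrees(e0)), sort(node_degrees(e2)))
})

test_that("dilating the mask increases every radius by the dilation width", {
  w <- small_world()
  st <- render_masks(w$net0, cfg = w$cfg)
  k <- 2
  dil <- EBImage::dilate(st$channels$lumen, EBImage::makeBrush(2 * k + 1, "disc"))
  sk1 <- skeletonize(st$channels$lumen)
  sk2 <- skeletonize(as.matrix(dil))
  e1 <- build_graph(sk1$skeleton, sk1$distance, 1, st$origin)
  e2 <- build_graph(sk2$skeleton, sk2$distance, 1, st$origin)
  m1 <- t(vapply(e1$geometry, function(g) colMeans(g), numeric(2)))
  m2 <- t(vapply(e2$geometry, function(g) colMeans(g), numeric(2)))
  nn <- vapply(seq_len(nrow(m2)), function(i) {
    which.min((m1[, 1] - m2[i, 1])^2 + (m1[, 2] - m2[i, 2])^2)
  }, integer(1))
  dr <- e2$segments$mean_radius - e1$segments$mean_radius[nn]
  expect_lt(abs(median(dr) - k), 1)
})

test_that("annotation recovers lumen coverage and matrix retention", {
  w <- small_world()
  cells <- w$cells
  st <- render_masks(w$net, cells, w$cfg, w$events)
  ann <- annotate_segments(w$net, st)
  truth <- w$truth$regression
  s4 <- truth$segment_id[truth$stage == "4_resolution"]
  s0 <- setdiff(ann$segments$id, truth$segment_id)
  idx4 <- match(s4, ann$segments$id)
  idx0 <- match(s0, ann$segments$id)
  # resolved segments: matrix retained, no lumen
  expect_true(all(ann$segments$lumen_fraction[idx4] == 0))
  expect_true(all(ann$segments$has_matrix[idx4]))
  # untouched segments fully lumenized
  expect_gt(mean(ann$segments$lumen_fraction[idx0] > 0.95), 0.95)
  # missing channel errors; all-zero lumen gives zero fractions
  st2 <- st; st2$channels$lumen <- NULL
  expect_error(annotate_segments(w$net, st2), class = "polarflow_input_error")
  st3 <- st; st3$channels$lumen[] <- 0
  ann3 <- annotate_segments(w$net, st3)
  expect_true(all(ann3$segments$lumen_fraction == 0))
})

test_that("mask-rendered plexuses round-trip topology and radii", {
  # full extraction fidelity check: topology-exact in >= 95% of seeds,
  # radii within one pixel for >= 95% of segments
  topo <- function(net) {
    c(as.integer(table(factor(node_degrees(net), levels = 1:8))),
      nseg = nrow(net$segments))
  }
  n_exact <- 0; errs <- c()
  for (s in 1:8) {
    cfg <- small_cfg(seed = s, n_cells_target = 50)
    net <- generate_network(cfg)
    st <- render_masks(net, cfg = cfg)
    sk <- skeletonize(st$channels$lumen)
    ex <- build_graph(sk$skeleton, sk$distance, st$pixel_size, st$origin)
    n_exact <- n_exact + identical(topo(net), topo(ex))
    gm <- t(vapply(net$geometry, function(g) polarflow:::polyline_at(g, 0.5)$xy[1, ],
                   numeric(2)))
    em <- t(vapply(ex$geometry, function(g) polarflow:::polyline_at(g, 0.5)$xy[1, ],
                   numeric(2)))
    nn <- vapply(seq_len(nrow(em)), function(i) {
      which.min((gm[, 1] - em[i, 1])^2 + (gm[, 2] - em[i, 2])^2)
    }, integer(1))
    errs <- c(errs, abs(ex$segments$mean_radius - net$segments$mean_radius[nn]))
  }
  expect_gte(n_exact / 8, 0.95)
  expect_gte(mean(errs <= 1 * 1), 0.95)  # 1 px = 1 um here
})
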